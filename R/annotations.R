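#' Read a pixel annotation table
#'
#' The annotation CSV carries the product of histology co-registration: one
#' row per pixel with header `sample_id,x,y,patient_id,tissue_label`. Labels
#' outside `NCE`, `stroma`, `cancer`, `matrix` are rejected at parse time to
#' catch typos early.
#'
#' @param path CSV path.
#' @return a tibble with the five annotation columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           x = readr::col_integer(),
                           y = readr::col_integer(),
                           patient_id = readr::col_character(),
                           tissue_label = readr::col_character()
                         ))
  validate_annotations(ann)
}

#' Write a pixel annotation table
#' @param annotations tibble with columns
#'   `sample_id,x,y,patient_id,tissue_label`.
#' @param path output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  readr::write_csv(annotations, path)
  invisible(path)
}

#' @noRd
validate_annotations <- function(ann) {
  req <- c("sample_id", "x", "y", "patient_id", "tissue_label")
  if (!all(req %in% names(ann))) {
    abort(paste0("Annotation table must have columns: ",
                 paste(req, collapse = ",")))
  }
  bad <- setdiff(unique(ann$tissue_label), ANNOT_LABELS)
  if (length(bad)) {
    abort(paste0("Unknown tissue labels in annotations: ",
                 paste(bad, collapse = ", ")))
  }
  key <- paste(ann$sample_id, ann$x, ann$y, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (sample_id, x, y) keys in annotation table.")
  }
  as_tibble(ann)[req]
}

#' Attach histology annotations to a dataset
#'
#' Matches annotation rows to dataset pixels on `(sample_id, x, y)`. Matched
#' pixels receive their tissue label and patient id; unmatched pixels remain
#' `"unannotated"`. Annotation keys that do not exist in the dataset are
#' skipped with a warning. Never alters m/z or intensity data.
#'
#' @param dataset an [msi_dataset].
#' @param annotations annotation tibble (see [read_annotations()]).
#' @return the annotated [msi_dataset]; per-label match counts are stored in
#'   `provenance$annotation_counts`.
#' @export
attach_annotations <- function(dataset, annotations) {
  stopifnot(inherits(dataset, "msi_dataset"))
  annotations <- validate_annotations(annotations)
  px <- dataset$pixels
  dkey <- paste(px$sample_id, px$x, px$y, sep = "\r")
  akey <- paste(annotations$sample_id, annotations$x, annotations$y,
                sep = "\r")
  pos <- match(akey, dkey)
  if (anyNA(pos)) {
    warn(sprintf("%d annotation rows matched no dataset pixel; skipped.",
                 sum(is.na(pos))))
  }
  keep <- !is.na(pos)
  px$tissue_label[pos[keep]] <- annotations$tissue_label[keep]
  px$patient_id[pos[keep]] <- annotations$patient_id[keep]
  dataset$pixels <- px
  counts <- table(factor(px$tissue_label, levels = TISSUE_LABELS))
  dataset$provenance$annotation_counts <- as.list(counts)
  dataset
}
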