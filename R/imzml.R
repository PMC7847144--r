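#' Write an MSI dataset as an imzML/ibd pair
#'
#' Continuous-mode imzML (one shared m/z axis) is written when the dataset
#' has a shared axis, which is always true for in-memory datasets; a
#' processed-mode writer (per-spectrum axes) is available for interoperability
#' testing. Alongside `<stem>.imzML` and `<stem>.ibd`, two plain-text sidecars
#' are written: `<stem>.annotations.csv` (header
#' `sample_id,x,y,patient_id,tissue_label`) and, when the dataset holds more
#' than one sample, `<stem>.layout.csv` mapping each sample to its x/y tile
#' offset in the single imzML pixel grid.
#'
#' Pixel coordinates are 0-based in memory and 1-based in the imzML file, per
#' the format's convention.
#'
#' @param dataset an [msi_dataset].
#' @param path output path ending in `.imzML`.
#' @param mode `"continuous"` (default) or `"processed"`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path, mode = c("continuous", "processed")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  mode <- match.arg(mode)
  if (n_spectra(dataset) == 0) abort("Cannot write an empty dataset.")

  px <- dataset$pixels
  samples <- unique(px$sample_id)
  # tile samples horizontally into one pixel grid
  widths <- vapply(samples, function(s) max(px$x[px$sample_id == s]) + 1L,
                   integer(1))
  offsets <- c(0L, cumsum(head(widths, -1)))
  names(offsets) <- samples
  gx <- px$x + offsets[px$sample_id]
  gy <- px$y

  spectra <- lapply(seq_len(n_spectra(dataset)), function(i) {
    list(mz = dataset$mz, intensity = dataset$intensity[i, ],
         x = gx[i], y = gy[i])
  })
  write_imzml_raw(spectra, path, mode = mode, polarity = dataset$polarity)

  stem <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  write_annotations(
    tibble(
      sample_id = px$sample_id, x = px$x, y = px$y,
      patient_id = px$patient_id, tissue_label = px$tissue_label
    ),
    paste0(stem, ".annotations.csv")
  )
  if (length(samples) > 1) {
    readr::write_csv(
      tibble(sample_id = samples, x_offset = unname(offsets), y_offset = 0L),
      paste0(stem, ".layout.csv")
    )
  }
  invisible(path)
}

# Low-level writer: spectra is a list of list(mz, intensity, x, y) with
# 0-based coordinates. No validation beyond length matching, so tests can
# construct deliberately malformed files.
#' @noRd
write_imzml_raw <- function(spectra, path, mode = "continuous",
                            polarity = "positive") {
  stem <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(stem, ".ibd")
  n <- length(spectra)

  uuid_raw <- as.raw(strtoi(
    substring(rlang::hash(list(n, spectra[[1]]$mz[1], mode)),
              seq(1, 31, 2), seq(2, 32, 2)), 16L
  ))
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_raw, con)
  pos <- 16

  offs <- vector("list", n)
  if (mode == "continuous") {
    mz <- spectra[[1]]$mz
    writeBin(as.numeric(mz), con, size = 8, endian = "little")
    mz_off <- pos
    mz_len <- length(mz)
    pos <- pos + 8 * mz_len
    for (i in seq_len(n)) {
      y <- as.numeric(spectra[[i]]$intensity)
      writeBin(y, con, size = 8, endian = "little")
      offs[[i]] <- list(mz_off = mz_off, mz_len = mz_len,
                        int_off = pos, int_len = length(y))
      pos <- pos + 8 * length(y)
    }
  } else {
    for (i in seq_len(n)) {
      m <- as.numeric(spectra[[i]]$mz)
      y <- as.numeric(spectra[[i]]$intensity)
      writeBin(m, con, size = 8, endian = "little")
      mz_off <- pos; pos <- pos + 8 * length(m)
      writeBin(y, con, size = 8, endian = "little")
      offs[[i]] <- list(mz_off = mz_off, mz_len = length(m),
                        int_off = pos, int_len = length(y))
      pos <- pos + 8 * length(y)
    }
  }

  uuid_str <- paste0(
    "{", paste(format(uuid_raw)[1:4], collapse = ""), "-",
    paste(format(uuid_raw)[5:6], collapse = ""), "-",
    paste(format(uuid_raw)[7:8], collapse = ""), "-",
    paste(format(uuid_raw)[9:10], collapse = ""), "-",
    paste(format(uuid_raw)[11:16], collapse = ""), "}"
  )
  mode_acc <- if (mode == "continuous") {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>'
  }
  pol_acc <- if (polarity == "positive") {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  }
  max_x <- max(vapply(spectra, function(s) s$x, numeric(1))) + 1
  max_y <- max(vapply(spectra, function(s) s$y, numeric(1))) + 1

  bda <- function(group, off, len) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="', group, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', len, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * len, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', off, '"/>',
      "<binary/></binaryDataArray>"
    )
  }
  spec_xml <- vapply(seq_len(n), function(i) {
    o <- offs[[i]]
    paste0(
      '<spectrum index="', i - 1L, '" id="spectrum=', i,
      '" defaultArrayLength="', o$int_len, '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      spectra[[i]]$x + 1L, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      spectra[[i]]$y + 1L, '"/>',
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      bda("mzArray", o$mz_off, o$mz_len),
      bda("intensityArray", o$int_off, o$int_len),
      "</binaryDataArrayList></spectrum>"
    )
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="', uuid_str, '"/>',
    mode_acc,
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', max_x, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', max_y, '"/>',
    "</scanSettings></scanSettingsList>",
    '<softwareList count="1"><software id="msidiff" version="0.1"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    "</instrumentConfigurationList>",
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="msidiff">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    "</processingMethod></dataProcessing></dataProcessingList>",
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">', pol_acc,
    '<spectrumList count="', n, '">',
    paste(spec_xml, collapse = ""),
    "</spectrumList></run></mzML>\n"
  )
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read an imzML/ibd pair into an MSI dataset
#'
#' Continuous-mode files map directly onto the shared-axis in-memory
#' representation. Processed-mode files are resampled onto a common axis by
#' linear interpolation with bin width equal to the median native spacing,
#' which is required before mean-spectrum computation. All spectra start out
#' `tissue_label = "unannotated"`; use [attach_annotations()] with an
#' annotation table to label them. A `<stem>.layout.csv` sidecar (written by
#' [write_imzml()] for multi-sample datasets) restores per-sample 0-based
#' coordinates; without it all pixels belong to a single sample `"s1"`.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @return an [msi_dataset] (unannotated).
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  stem <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(stem, ".ibd")
  if (!file.exists(ibd_path)) {
    abort(paste0("Missing binary companion: ", ibd_path))
  }

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  continuous <- length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='IMS:1000030']")) > 0
  polarity <- if (length(xml2::xml_find_all(
    doc, "//cvParam[@accession='MS:1000129']")) > 0) "negative" else "positive"

  specs <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  if (length(specs) == 0) abort("imzML file contains no spectra.")

  get_pos <- function(node, acc) {
    as.integer(xml2::xml_attr(xml2::xml_find_first(
      node, paste0(".//scan/cvParam[@accession='", acc, "']")), "value"))
  }
  get_arr <- function(node, group) {
    b <- xml2::xml_find_first(node, paste0(
      ".//binaryDataArray[referenceableParamGroupRef/@ref='", group, "']"))
    if (is.na(b)) abort("imzML spectrum lacks an expected binary data array.")
    val <- function(acc) as.numeric(xml2::xml_attr(xml2::xml_find_first(
      b, paste0(".//cvParam[@accession='", acc, "']")), "value"))
    list(offset = val("IMS:1000102"), length = val("IMS:1000103"))
  }

  ibd_size <- file.info(ibd_path)$size
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_at <- function(offset, n) {
    if (offset + 8 * n > ibd_size) {
      abort("Corrupt ibd: binary array extends past end of file.")
    }
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = n, size = 8, endian = "little")
  }

  n <- length(specs)
  xs <- ys <- integer(n)
  mz_list <- int_list <- vector("list", n)
  shared_mz <- NULL
  for (i in seq_len(n)) {
    node <- specs[[i]]
    xs[i] <- get_pos(node, "IMS:1000050") - 1L
    ys[i] <- get_pos(node, "IMS:1000051") - 1L
    ma <- get_arr(node, "mzArray")
    ia <- get_arr(node, "intensityArray")
    if (continuous && !is.null(shared_mz)) {
      mzv <- shared_mz
    } else {
      mzv <- read_at(ma$offset, ma$length)
      if (length(mzv) > 1 && any(diff(mzv) <= 0)) {
        abort("Validation error: m/z axis is not strictly increasing.")
      }
      if (continuous) shared_mz <- mzv
    }
    mz_list[[i]] <- mzv
    int_list[[i]] <- read_at(ia$offset, ia$length)
  }

  if (continuous) {
    mz <- shared_mz
    intensity <- do.call(rbind, int_list)
  } else {
    # resample processed-mode spectra onto a common axis
    step <- median(unlist(lapply(mz_list, function(m) median(diff(m)))))
    lo <- min(vapply(mz_list, min, numeric(1)))
    hi <- max(vapply(mz_list, max, numeric(1)))
    mz <- seq(lo, hi, by = step)
    intensity <- do.call(rbind, lapply(seq_len(n), function(i) {
      approx(mz_list[[i]], int_list[[i]], xout = mz, rule = 1)$y
    }))
    intensity[is.na(intensity)] <- 0
  }
  intensity[intensity < 0] <- 0

  sample_id <- rep("s1", n)
  lx <- xs
  ly <- ys
  layout_path <- paste0(stem, ".layout.csv")
  if (file.exists(layout_path)) {
    layout <- readr::read_csv(layout_path, show_col_types = FALSE)
    layout <- layout[order(layout$x_offset), ]
    idx <- findInterval(xs, layout$x_offset)
    sample_id <- layout$sample_id[idx]
    lx <- xs - layout$x_offset[idx]
    ly <- ys - layout$y_offset[idx]
  }

  msi_dataset(
    mz = mz, intensity = intensity,
    pixels = tibble(
      sample_id = sample_id, x = as.integer(lx), y = as.integer(ly),
      patient_id = sample_id, tissue_label = "unannotated"
    ),
    polarity = polarity,
    provenance = list(source = path, mode = if (continuous) "continuous" else "processed")
  )
}
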