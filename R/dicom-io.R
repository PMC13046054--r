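# Case discovery and classification. One case per subdirectory; each DICOM
# series inside a case becomes one ImageRecord (DM single image or DBT slice
# stack). Source files are never written to: annotations live in sidecars and
# a checksum manifest taken at scan time lets any later step prove it.

#' Construct an image record
#'
#' @param file_paths character vector of DICOM file paths, in slice order.
#' @param modality_kind `"DM"` or `"DBT"`.
#' @param laterality `"L"`, `"R"` or `"unknown"`.
#' @param view `"CC"`, `"MLO"` or `"unknown"`.
#' @param pixel_spacing_mm numeric length-2 (row, col) spacing in mm.
#' @param n_slices number of slices (1 for DM).
#' @param rows,cols image dimensions in pixels.
#' @param ordering_key which tag ordered the slices
#'   (`"slice_location"`, `"instance_number"`, `"file_name"` or `"none"`).
#' @param series_uid DICOM SeriesInstanceUID, if present.
#' @return an object of class `mt_image_record`.
#' @export
image_record <- function(file_paths, modality_kind, laterality, view,
                         pixel_spacing_mm, n_slices, rows, cols,
                         ordering_key = "none", series_uid = NA_character_) {
  stopifnot(modality_kind %in% c("DM", "DBT"),
            laterality %in% c("L", "R", "unknown"),
            view %in% c("CC", "MLO", "unknown"),
            length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0),
            n_slices >= 1L, rows >= 1L, cols >= 1L)
  if ((n_slices == 1L) != (modality_kind == "DM"))
    stop("n_slices must be 1 exactly for DM records")
  structure(list(file_paths = file_paths, modality_kind = modality_kind,
                 laterality = laterality, view = view,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 n_slices = as.integer(n_slices), rows = as.integer(rows),
                 cols = as.integer(cols), ordering_key = ordering_key,
                 series_uid = series_uid),
            class = "mt_image_record")
}

#' @export
print.mt_image_record <- function(x, ...) {
  cat(sprintf("<%s %s %s %dx%d x%d slices, spacing %.3gx%.3g mm>\n",
              x$modality_kind, x$laterality, x$view, x$rows, x$cols,
              x$n_slices, x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  invisible(x)
}

#' Classify modality kind, laterality and view from DICOM metadata
#'
#' Laterality is read from ImageLaterality (0020,0062), falling back to
#' Laterality (0020,0060); view from ViewPosition (0018,5101). The object is
#' DBT when it is multiframe or belongs to a series of more than one spatially
#' ordered frame, DM otherwise. Missing tags yield `"unknown"`; pixel data is
#' never consulted.
#'
#' @param meta named list of DICOM attributes (as from the codec reader).
#' @param n_in_series number of single-frame objects sharing this object's
#'   series (1 when the object stands alone).
#' @return list with elements `modality_kind`, `laterality`, `view`.
#' @export
classify_image <- function(meta, n_in_series = 1L) {
  lat <- meta$ImageLaterality %||% meta$Laterality %||% "unknown"
  if (!lat %in% c("L", "R")) lat <- "unknown"
  view <- meta$ViewPosition %||% "unknown"
  if (!view %in% c("CC", "MLO")) view <- "unknown"
  nf <- meta$NumberOfFrames %||% 1L
  kind <- if (nf > 1L || n_in_series > 1L) "DBT" else "DM"
  list(modality_kind = kind, laterality = lat, view = view)
}

# order a list of per-file meta by the fallback chain; returns list(order, key)
.slice_order <- function(metas, paths) {
  locs <- vapply(metas, function(m) (m$SliceLocation %||% NA_real_)[1], 0)
  inst <- vapply(metas, function(m) as.numeric(m$InstanceNumber %||% NA_integer_), 0)
  if (!anyNA(locs) && !anyDuplicated(locs)) {
    list(order = order(locs), key = "slice_location")
  } else if (!anyNA(inst) && !anyDuplicated(inst)) {
    list(order = order(inst), key = "instance_number")
  } else {
    list(order = order(basename(paths), method = "radix"), key = "file_name")
  }
}

#' Scan a directory tree of DICOM cases
#'
#' Each immediate subdirectory of `root_path` that contains at least one
#' parseable DICOM file becomes a case. Files sharing a SeriesInstanceUID are
#' grouped into one image record (a multi-file series, or a single multiframe
#' object, is a DBT stack). Non-DICOM files are kept in the case's
#' `unclassified` list. An MD5 manifest of every DICOM file is recorded so
#' that [verify_unmodified()] can later prove the sources untouched.
#'
#' @param root_path directory containing one subdirectory per case.
#' @return list of `mt_case_record`, ordered lexicographically by case id.
#'   Each record has `case_id`, `case_dir`, `images`, `unclassified`
#'   and `checksum_manifest`.
#' @export
scan_case_directory <- function(root_path) {
  if (!dir.exists(root_path)) stop("root path does not exist: ", root_path)
  subdirs <- list.dirs(root_path, recursive = FALSE, full.names = TRUE)
  subdirs <- subdirs[order(basename(subdirs), method = "radix")]
  cases <- list()
  for (d in subdirs) {
    files <- list.files(d, full.names = TRUE, recursive = FALSE)
    files <- files[!dir.exists(files)]
    files <- files[order(basename(files), method = "radix")]
    is_dcm <- vapply(files, dcm_is_dicom, TRUE)
    dcm_files <- files[is_dcm]
    if (length(dcm_files) == 0L) {
      warning("no DICOM files in ", d, "; case skipped", call. = FALSE)
      next
    }
    metas <- lapply(dcm_files, function(f) dcm_read(f, pixel = FALSE)$meta)
    series <- vapply(seq_along(dcm_files), function(i) {
      metas[[i]]$SeriesInstanceUID %||% paste0("file:", basename(dcm_files[i]))
    }, "")
    images <- list()
    for (uid in unique(series)) {
      idx <- which(series == uid)
      smetas <- metas[idx]; spaths <- dcm_files[idx]
      ord <- .slice_order(smetas, spaths)
      smetas <- smetas[ord$order]; spaths <- spaths[ord$order]
      frames <- vapply(smetas, function(m) as.integer(m$NumberOfFrames %||% 1L), 0L)
      n_slices <- sum(frames)
      cls <- classify_image(smetas[[1]], n_in_series = length(idx))
      if (n_slices > 1L) cls$modality_kind <- "DBT"
      spacing <- smetas[[1]]$PixelSpacing
      if (is.null(spacing) || length(spacing) != 2L || any(spacing <= 0)) {
        warning("missing/invalid PixelSpacing in ", spaths[1],
                "; assuming 1 mm", call. = FALSE)
        spacing <- c(1, 1)
      }
      images[[length(images) + 1L]] <- image_record(
        file_paths = spaths, modality_kind = cls$modality_kind,
        laterality = cls$laterality, view = cls$view,
        pixel_spacing_mm = spacing, n_slices = n_slices,
        rows = smetas[[1]]$Rows, cols = smetas[[1]]$Columns,
        ordering_key = if (length(idx) > 1L) ord$key else "none",
        series_uid = uid)
    }
    manifest <- tools::md5sum(dcm_files)
    cases[[length(cases) + 1L]] <- structure(
      list(case_id = basename(d), case_dir = d, images = images,
           unclassified = files[!is_dcm], checksum_manifest = manifest),
      class = "mt_case_record")
  }
  cases
}

#' @export
print.mt_case_record <- function(x, ...) {
  cat(sprintf("<case %s: %d image(s), %d unclassified file(s)>\n",
              x$case_id, length(x$images), length(x$unclassified)))
  for (im in x$images) print(im)
  invisible(x)
}

#' Load the pixel data of an image record as a slice stack
#'
#' @param record an `mt_image_record`.
#' @return numeric array of dimension `n_slices x rows x cols`, slices in
#'   record order; raw stored values, no windowing. DM images come back with
#'   a leading dimension of 1.
#' @export
load_stack <- function(record) {
  stopifnot(inherits(record, "mt_image_record"))
  missing <- record$file_paths[!file.exists(record$file_paths)]
  if (length(missing) > 0L)
    stop("missing image file(s): ", paste(missing, collapse = ", "))
  out <- array(0, dim = c(record$n_slices, record$rows, record$cols))
  s <- 1L
  for (f in record$file_paths) {
    dec <- tryCatch(dcm_read(f, pixel = TRUE),
                    error = function(e) stop("failed to decode ", f, ": ",
                                             conditionMessage(e), call. = FALSE))
    px <- dec$pixel
    if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
    for (k in seq_len(dim(px)[3])) {
      out[s, , ] <- px[, , k]
      s <- s + 1L
    }
  }
  out
}

#' Verify that a case's DICOM files are unmodified since scan time
#'
#' Recomputes the MD5 digest of every file in the case's checksum manifest.
#'
#' @param case an `mt_case_record` from [scan_case_directory()].
#' @return `TRUE` iff every manifest file exists and matches its digest;
#'   otherwise `FALSE`, with attributes `missing` and `changed` listing the
#'   offending paths.
#' @export
verify_unmodified <- function(case) {
  stopifnot(inherits(case, "mt_case_record"))
  paths <- names(case$checksum_manifest)
  missing <- paths[!file.exists(paths)]
  present <- setdiff(paths, missing)
  now <- tools::md5sum(present)
  changed <- present[now != case$checksum_manifest[present]]
  ok <- length(missing) == 0L && length(changed) == 0L
  if (!ok) {
    attr(ok, "missing") <- missing
    attr(ok, "changed") <- changed
  }
  ok
}
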