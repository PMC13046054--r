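# Exporters: binary PNG masks per annotation, a per-case CSV table, or a
# plain-text report. Deterministic given the annotation set; measurement
# columns are computed by the measurements module on the same contour.

.export_csv_columns <- c("annotation_id", "case_id", "laterality", "view",
                         "modality_kind", "slice_index", "lesion_type",
                         "mass_shape", "mass_margin", "mass_density",
                         "calc_morphology", "calc_distribution",
                         "feret_mm", "area_mm2", "vertex_count")

# resolve the image record an annotation refers to, if a case is supplied
.resolve_image <- function(case, a) {
  if (is.null(case)) return(NULL)
  for (im in case$images) {
    if (im$laterality == a$laterality && im$view == a$view &&
        im$modality_kind == a$modality_kind) return(im)
  }
  NULL
}

.ann_row <- function(a, spacing) {
  sr <- size_report(a$contour, spacing)
  data.frame(annotation_id = a$annotation_id, case_id = a$case_id,
             laterality = a$laterality, view = a$view,
             modality_kind = a$modality_kind, slice_index = a$slice_index,
             lesion_type = a$morphology$lesion_type,
             mass_shape = a$morphology$mass_shape,
             mass_margin = a$morphology$mass_margin,
             mass_density = a$morphology$mass_density,
             calc_morphology = a$morphology$calc_morphology,
             calc_distribution = a$morphology$calc_distribution,
             feret_mm = sr$feret_mm, area_mm2 = sr$area_mm2,
             vertex_count = sr$vertex_count,
             stringsAsFactors = FALSE)
}

#' Export an annotation set
#'
#' \describe{
#'   \item{mask}{one 8-bit 0/255 PNG mask per annotation (slice index in the
#'     file name for DBT); requires `case` to size the mask.}
#'   \item{csv}{one RFC-4180 table, one row per annotation, with the image
#'     reference, morphology descriptors, Feret diameter (mm), area (mm^2)
#'     and vertex count.}
#'   \item{text}{a human-readable per-case report.}
#' }
#' Slice indices are reported 1-based. All outputs are deterministic given
#' the set.
#'
#' @param set an `mt_annotation_set`.
#' @param format `"mask"`, `"csv"` or `"text"`.
#' @param out_dir output directory (created if absent).
#' @param case optional `mt_case_record` used to resolve per-image pixel
#'   spacing and mask dimensions; without it, measurements assume 1 mm
#'   isotropic pixels and mask export is unavailable.
#' @return character vector of written paths.
#' @export
export_annotations <- function(set, format = c("mask", "csv", "text"),
                               out_dir, case = NULL) {
  stopifnot(inherits(set, "mt_annotation_set"))
  format <- match.arg(format)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)

  spacing_of <- function(a) {
    im <- .resolve_image(case, a)
    if (is.null(im)) c(1, 1) else im$pixel_spacing_mm
  }

  if (format == "csv") {
    rows <- lapply(set$annotations, function(a) .ann_row(a, spacing_of(a)))
    df <- if (length(rows) == 0L) {
      empty <- as.data.frame(stats::setNames(
        replicate(length(.export_csv_columns), character(0), simplify = FALSE),
        .export_csv_columns))
      empty
    } else do.call(rbind, rows)
    path <- file.path(out_dir, paste0(set$case_id, "_annotations.csv"))
    utils::write.csv(df, path, row.names = FALSE)
    return(path)
  }

  if (format == "mask") {
    if (is.null(case))
      stop("mask export needs the case record to size the masks")
    paths <- character(0)
    for (a in set$annotations) {
      im <- .resolve_image(case, a)
      if (is.null(im))
        stop("annotation ", a$annotation_id,
             " references no image in the case (",
             a$laterality, "/", a$view, "/", a$modality_kind, ")")
      mask <- rasterize(a$contour, im$rows, im$cols)
      fname <- if (a$modality_kind == "DBT")
        sprintf("%s_slice%03d_mask.png", a$annotation_id, a$slice_index)
      else sprintf("%s_mask.png", a$annotation_id)
      path <- file.path(out_dir, fname)
      png::writePNG(mask * 1.0, path)  # 0/1 -> 0/255 8-bit gray
      paths <- c(paths, path)
    }
    return(paths)
  }

  # text report
  lines <- c(sprintf("Annotation report for case %s", set$case_id),
             sprintf("schema %s, %d annotation(s)", set$schema_version,
                     length(set$annotations)), "")
  for (a in set$annotations) {
    sr <- size_report(a$contour, spacing_of(a))
    col <- a$display_color
    lines <- c(lines,
      sprintf("%s  [%s %s %s, slice %d]", a$annotation_id, a$laterality,
              a$view, a$modality_kind, a$slice_index),
      sprintf("  lesion type: %s (outline RGB %d,%d,%d)",
              a$morphology$lesion_type, col[1], col[2], col[3]),
      if (a$morphology$lesion_type == "mass")
        sprintf("  shape %s, margin %s, density %s", a$morphology$mass_shape,
                a$morphology$mass_margin, a$morphology$mass_density),
      if (a$morphology$lesion_type == "microcalcification")
        sprintf("  morphology %s, distribution %s",
                a$morphology$calc_morphology, a$morphology$calc_distribution),
      sprintf("  Feret %.2f mm, area %.2f mm^2, %d vertices",
              sr$feret_mm, sr$area_mm2, sr$vertex_count),
      sprintf("  reader %s, created %s", a$reader_id, a$created_utc), "")
  }
  path <- file.path(out_dir, paste0(set$case_id, "_report.txt"))
  writeLines(lines, path)
  path
}
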