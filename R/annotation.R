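# Annotation data model: BI-RADS morphology descriptors, per-lesion display
# colors, the per-case annotation set, and non-destructive JSON sidecar
# persistence (one `<case_id>.annotations` file per case directory; DICOM
# sources are never touched).

ANNOTATION_SCHEMA_VERSION <- "1.0"

.birads_vocab <- list(
  lesion_type = c("mass", "microcalcification", "architectural_distortion",
                  "asymmetry"),
  mass_shape = c("oval", "round", "irregular", "none"),
  mass_margin = c("circumscribed", "obscured", "microlobulated", "indistinct",
                  "spiculated", "none"),
  mass_density = c("high", "equal", "low", "fat_containing", "none"),
  calc_morphology = c("typically_benign", "amorphous", "coarse_heterogeneous",
                      "fine_pleomorphic", "fine_linear_branching", "none"),
  calc_distribution = c("diffuse", "regional", "grouped", "linear",
                        "segmental", "none")
)

.lesion_colors <- list(
  mass = c(255L, 0L, 0L),
  microcalcification = c(0L, 160L, 255L),
  architectural_distortion = c(255L, 200L, 0L),
  asymmetry = c(0L, 200L, 0L)
)

#' Canonical display color for a lesion type
#'
#' Fixed injective mapping; masses are outlined in red.
#'
#' @param lesion_type one of `"mass"`, `"microcalcification"`,
#'   `"architectural_distortion"`, `"asymmetry"`.
#' @return integer RGB triple in 0..255.
#' @export
lesion_color <- function(lesion_type) {
  lesion_type <- match.arg(lesion_type, .birads_vocab$lesion_type)
  .lesion_colors[[lesion_type]]
}

#' Construct a BI-RADS morphology descriptor set
#'
#' Masses carry shape, margin and density; calcifications carry morphology
#' and distribution; architectural distortion and asymmetry carry no
#' sub-descriptors. Inapplicable fields stay `"none"`.
#'
#' @param lesion_type lesion type, see [lesion_color()].
#' @param mass_shape,mass_margin,mass_density mass descriptors.
#' @param calc_morphology,calc_distribution calcification descriptors.
#' @return an `mt_morphology` list.
#' @export
morphology <- function(lesion_type, mass_shape = "none", mass_margin = "none",
                       mass_density = "none", calc_morphology = "none",
                       calc_distribution = "none") {
  m <- list(lesion_type = lesion_type, mass_shape = mass_shape,
            mass_margin = mass_margin, mass_density = mass_density,
            calc_morphology = calc_morphology,
            calc_distribution = calc_distribution)
  for (f in names(m)) {
    if (!is.character(m[[f]]) || length(m[[f]]) != 1L ||
        !m[[f]] %in% .birads_vocab[[f]])
      stop("invalid value for ", f, ": ", m[[f]])
  }
  structure(m, class = "mt_morphology")
}

#' Validate BI-RADS descriptor consistency
#'
#' @param m an `mt_morphology` (or plain named list with the same fields).
#' @return character vector of violations, each naming the offending field;
#'   empty when the descriptor set is consistent.
#' @export
validate_morphology <- function(m) {
  v <- character(0)
  for (f in names(.birads_vocab)) {
    val <- m[[f]]
    if (is.null(val) || !val %in% .birads_vocab[[f]]) {
      v <- c(v, sprintf("%s: unknown value '%s'", f, val %||% "<missing>"))
    }
  }
  if (length(v) > 0L) return(v)
  mass_fields <- c("mass_shape", "mass_margin", "mass_density")
  calc_fields <- c("calc_morphology", "calc_distribution")
  need_none <- function(fields)
    vapply(fields, function(f) if (m[[f]] != "none")
      sprintf("%s: must be 'none' for lesion_type %s (got '%s')", f,
              m$lesion_type, m[[f]]) else NA_character_, "")
  need_set <- function(fields)
    vapply(fields, function(f) if (m[[f]] == "none")
      sprintf("%s: required for lesion_type %s", f, m$lesion_type)
      else NA_character_, "")
  v <- switch(m$lesion_type,
    mass = c(need_set(mass_fields), need_none(calc_fields)),
    microcalcification = c(need_set(calc_fields), need_none(mass_fields)),
    c(need_none(mass_fields), need_none(calc_fields)))
  unname(v[!is.na(v)])
}

#' Create an annotation
#'
#' One lesion finding: image reference, slice, morphology and contour. The
#' display color is fixed by the lesion type. The contour must simplify to a
#' simple polygon with at least 3 vertices.
#'
#' @param case_id case identifier.
#' @param laterality,view,modality_kind image reference.
#' @param slice_index 1-based slice (1 for DM).
#' @param morph an `mt_morphology` with no validation violations.
#' @param contour an `mt_contour`.
#' @param reader_id annotating reader identifier.
#' @param annotation_id optional explicit id (assigned by
#'   [add_annotation()] when `NA`).
#' @param created_utc timestamp string; defaults to the current UTC time.
#' @return an `mt_annotation`.
#' @export
annotation <- function(case_id, laterality, view, modality_kind, slice_index,
                       morph, contour, reader_id = "reader",
                       annotation_id = NA_character_,
                       created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  viol <- validate_morphology(morph)
  if (length(viol) > 0L)
    stop("invalid morphology: ", paste(viol, collapse = "; "))
  stopifnot(inherits(contour, "mt_contour"), slice_index >= 1L)
  simp <- simplify_collinear(contour$points)
  if (nrow(simp) < 3L) stop("contour has fewer than 3 distinct vertices")
  if (!is_simple_polygon(contour$points))
    stop("self-intersecting contour")
  structure(list(annotation_id = annotation_id, case_id = case_id,
                 laterality = laterality, view = view,
                 modality_kind = modality_kind,
                 slice_index = as.integer(slice_index), morphology = morph,
                 contour = contour, created_utc = created_utc,
                 reader_id = reader_id,
                 display_color = lesion_color(morph$lesion_type)),
            class = "mt_annotation")
}

#' Create an empty annotation set for a case
#'
#' @param case_id case identifier.
#' @return an `mt_annotation_set`.
#' @export
annotation_set <- function(case_id) {
  structure(list(case_id = case_id, annotations = list(),
                 schema_version = ANNOTATION_SCHEMA_VERSION),
            class = "mt_annotation_set")
}

#' Add an annotation to a set
#'
#' Assigns the next sequential annotation id (`ann-000001`, ...) when the
#' annotation has none.
#'
#' @param set an `mt_annotation_set`.
#' @param ann an `mt_annotation` for the same case.
#' @return the updated set.
#' @export
add_annotation <- function(set, ann) {
  stopifnot(inherits(set, "mt_annotation_set"), inherits(ann, "mt_annotation"))
  if (ann$case_id != set$case_id) stop("annotation belongs to another case")
  ids <- vapply(set$annotations, `[[`, "", "annotation_id")
  if (is.na(ann$annotation_id)) {
    nums <- suppressWarnings(as.integer(sub("^ann-", "", ids)))
    nxt <- if (length(nums) == 0L || all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
    ann$annotation_id <- sprintf("ann-%06d", nxt)
  } else if (ann$annotation_id %in% ids) {
    stop("duplicate annotation_id: ", ann$annotation_id)
  }
  set$annotations[[length(set$annotations) + 1L]] <- ann
  set
}

#' Delete an annotation from a set
#'
#' @param set an `mt_annotation_set`.
#' @param annotation_id id of the annotation to remove.
#' @return the set without that annotation; all others untouched.
#' @export
delete_annotation <- function(set, annotation_id) {
  stopifnot(inherits(set, "mt_annotation_set"))
  ids <- vapply(set$annotations, `[[`, "", "annotation_id")
  hit <- which(ids == annotation_id)
  if (length(hit) == 0L) stop("no annotation with id ", annotation_id)
  set$annotations <- set$annotations[-hit]
  set
}

#' @export
print.mt_annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set for case %s: %d annotation(s), schema %s>\n",
              x$case_id, length(x$annotations), x$schema_version))
  invisible(x)
}

.sidecar_path <- function(case_dir, case_id) {
  file.path(case_dir, paste0(case_id, ".annotations"))
}

.ann_to_list <- function(a) {
  list(annotation_id = a$annotation_id, case_id = a$case_id,
       laterality = a$laterality, view = a$view,
       modality_kind = a$modality_kind, slice_index = a$slice_index,
       morphology = unclass(a$morphology),
       contour = list(points = unname(a$contour$points),
                      waypoint_indices = a$contour$waypoint_indices,
                      mode = a$contour$mode,
                      weights = if (is.null(a$contour$weights)) NULL
                                else unname(a$contour$weights)),
       created_utc = a$created_utc, reader_id = a$reader_id,
       display_color = a$display_color)
}

.ann_from_list <- function(l) {
  pts <- matrix(as.integer(unlist(l$contour$points)), ncol = 2L, byrow = TRUE)
  w <- as.numeric(unlist(l$contour$weights))
  ctr <- .new_contour(pts, unlist(l$contour$waypoint_indices), l$contour$mode,
                      if (length(w) == 3L) stats::setNames(w, c("z", "g", "d")))
  m <- do.call(morphology, l$morphology)
  annotation(case_id = l$case_id, laterality = l$laterality, view = l$view,
             modality_kind = l$modality_kind, slice_index = l$slice_index,
             morph = m, contour = ctr, reader_id = l$reader_id,
             annotation_id = l$annotation_id, created_utc = l$created_utc)
}

#' Save an annotation set to its sidecar file
#'
#' Writes a single JSON sidecar `<case_id>.annotations` into the case
#' directory; the write is atomic (temp file + rename) and never touches the
#' DICOM sources. Sets containing morphology violations are refused.
#'
#' @param set an `mt_annotation_set`.
#' @param case_dir the case subdirectory.
#' @return the sidecar path, invisibly.
#' @export
save_annotations <- function(set, case_dir) {
  stopifnot(inherits(set, "mt_annotation_set"))
  if (!dir.exists(case_dir)) stop("case directory does not exist: ", case_dir)
  for (a in set$annotations) {
    viol <- validate_morphology(a$morphology)
    if (length(viol) > 0L)
      stop("annotation ", a$annotation_id, " has morphology violations: ",
           paste(viol, collapse = "; "))
    if (!is_simple_polygon(a$contour$points))
      stop("annotation ", a$annotation_id, " has a self-intersecting contour")
  }
  ids <- vapply(set$annotations, `[[`, "", "annotation_id")
  if (anyDuplicated(ids) > 0L) stop("duplicate annotation ids in set")
  payload <- list(schema_version = set$schema_version, case_id = set$case_id,
                  annotations = lapply(set$annotations, .ann_to_list))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path <- .sidecar_path(case_dir, set$case_id)
  tmp <- paste0(path, ".tmp")
  writeLines(js, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a case's annotation set from its sidecar file
#'
#' @param case_dir the case subdirectory.
#' @param case_id case identifier; defaults to the directory name.
#' @return the `mt_annotation_set`.
#' @export
load_annotations <- function(case_dir, case_id = basename(case_dir)) {
  path <- .sidecar_path(case_dir, case_id)
  if (!file.exists(path)) stop("no annotation sidecar at ", path)
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                      error = function(e)
                        stop("corrupt sidecar ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(payload$schema_version, ANNOTATION_SCHEMA_VERSION))
    stop("unsupported sidecar schema_version '", payload$schema_version,
         "' (supported: ", ANNOTATION_SCHEMA_VERSION, ")")
  set <- annotation_set(payload$case_id)
  for (l in payload$annotations) set <- add_annotation(set, .ann_from_list(l))
  set
}
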