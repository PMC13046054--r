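# Lesion size quantification. All measurements are 2-D within the annotated
# slice: vertices are scaled to millimetres by the (row, col) pixel spacing
# and treated as continuous geometry, so the Feret diameter is the true
# largest extent of the ROI polygon rather than a rasterization-dependent
# caliper.

.scaled_vertices <- function(contour, pixel_spacing_mm) {
  pts <- if (inherits(contour, "mt_contour")) contour$points else contour
  stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0))
  cbind(pts[, 1] * pixel_spacing_mm[1], pts[, 2] * pixel_spacing_mm[2])
}

# max pairwise squared distance, all pairs (exact reference)
.feret_allpairs_sq <- function(v) {
  d <- stats::dist(v)
  max(d)^2
}

# convex hull + rotating calipers; returns max squared vertex distance
.feret_calipers_sq <- function(v) {
  h <- grDevices::chull(v[, 2], v[, 1])   # counter-clockwise in (x=col, y=row)
  hv <- v[h, , drop = FALSE]
  m <- nrow(hv)
  if (m == 1L) return(0)
  if (m == 2L) return(sum((hv[1, ] - hv[2, ])^2))
  d2 <- function(i, j) sum((hv[i, ] - hv[j, ])^2)
  area2 <- function(i, j, k) abs((hv[j, 2] - hv[i, 2]) * (hv[k, 1] - hv[i, 1]) -
                                 (hv[j, 1] - hv[i, 1]) * (hv[k, 2] - hv[i, 2]))
  best <- 0
  k <- 2L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if (k == i || k == j) k <- (k %% m) + 1L
    # advance the antipodal point while the triangle area keeps growing
    repeat {
      kn <- (k %% m) + 1L
      if (kn != i && area2(i, j, kn) > area2(i, j, k)) k <- kn else break
    }
    best <- max(best, d2(i, k), d2(j, k))
  }
  best
}

#' Feret diameter of a contour
#'
#' The largest extent of the ROI: the maximum Euclidean distance between any
#' two contour vertices, after scaling rows and columns by the pixel spacing.
#' Polygons with more than 500 vertices use convex hull plus rotating
#' calipers; smaller ones use the all-pairs computation. Both give the exact
#' maximum (the farthest pair is always an antipodal hull pair).
#'
#' @param contour an `mt_contour` or n x 2 (row, col) vertex matrix, n >= 3.
#' @param pixel_spacing_mm (row, col) spacing in mm.
#' @return diameter in mm. Degenerate (collinear) input returns the segment
#'   length with a warning.
#' @export
feret_diameter <- function(contour, pixel_spacing_mm) {
  v <- .scaled_vertices(contour, pixel_spacing_mm)
  if (nrow(v) < 3L) stop("need at least 3 vertices")
  v <- unique(v)
  if (nrow(v) < 3L || shoelace_area(v) == 0)
    warning("degenerate (collinear) contour; Feret is the segment length")
  sq <- if (nrow(v) > 500L) .feret_calipers_sq(v) else .feret_allpairs_sq(v)
  sqrt(sq)
}

#' Cross-section area of a contour
#'
#' Shoelace area of the polygon in mm-scaled coordinates; independent of
#' vertex orientation.
#'
#' @inheritParams feret_diameter
#' @return area in mm^2.
#' @export
contour_area <- function(contour, pixel_spacing_mm) {
  pts <- if (inherits(contour, "mt_contour")) contour$points else contour
  if (!is_simple_polygon(pts)) stop("self-intersecting contour")
  v <- .scaled_vertices(pts, pixel_spacing_mm)
  shoelace_area(v)
}

#' Area of a circle given its diameter
#'
#' The circular approximation used to convert a single pathological size
#' measurement to an assumed cross-section area.
#'
#' @param d_mm diameter in mm, > 0.
#' @return area \eqn{\pi (d/2)^2} in mm^2.
#' @export
circular_area_from_diameter <- function(d_mm) {
  if (any(d_mm <= 0)) stop("diameter must be positive")
  pi * (d_mm / 2)^2
}

#' Full size report for one contour
#'
#' @inheritParams feret_diameter
#' @return an `mt_size_report`: `feret_mm`, `area_mm2`,
#'   `equivalent_circle_diameter_mm` (\eqn{2\sqrt{A/\pi}}), `vertex_count`.
#' @export
size_report <- function(contour, pixel_spacing_mm) {
  pts <- if (inherits(contour, "mt_contour")) contour$points else contour
  f <- feret_diameter(pts, pixel_spacing_mm)
  a <- contour_area(pts, pixel_spacing_mm)
  structure(list(feret_mm = f, area_mm2 = a,
                 equivalent_circle_diameter_mm = 2 * sqrt(a / pi),
                 vertex_count = nrow(simplify_collinear(pts))),
            class = "mt_size_report")
}

#' @export
print.mt_size_report <- function(x, ...) {
  cat(sprintf("Feret %.2f mm | area %.2f mm^2 | eq. circle diameter %.2f mm | %d vertices\n",
              x$feret_mm, x$area_mm2, x$equivalent_circle_diameter_mm,
              x$vertex_count))
  invisible(x)
}

#' Compare annotated sizes against reference (pathological) sizes
#'
#' Per-case signed differences annotated minus reference, with mean and
#' sample (n-1) standard deviation. Positive mean: annotations run larger
#' than the reference; the print method states the direction explicitly.
#'
#' @param annotated,reference numeric vectors of equal length, n >= 2; mm for
#'   diameters or mm^2 for areas.
#' @return an `mt_comparison_report`: `n`, `mean_diff`, `sd_diff`,
#'   `per_case_diffs`.
#' @export
size_comparison <- function(annotated, reference) {
  if (length(annotated) != length(reference))
    stop("annotated and reference must have equal length")
  if (length(annotated) < 2L) stop("need at least 2 cases")
  d <- annotated - reference
  structure(list(n = length(d), mean_diff = mean(d), sd_diff = stats::sd(d),
                 per_case_diffs = d),
            class = "mt_comparison_report")
}

#' @export
print.mt_comparison_report <- function(x, ...) {
  dir <- if (x$mean_diff >= 0) "annotations larger than reference"
         else "annotations smaller than reference"
  cat(sprintf("n = %d, difference (annotated - reference) = %.1f ± %.1f (%s)\n",
              x$n, x$mean_diff, x$sd_diff, dir))
  invisible(x)
}
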