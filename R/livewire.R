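# Intelligent-scissors (live-wire) contour tracing. A static cost map is
# built once per image from three local features -- gradient magnitude,
# Laplacian zero-crossings, gradient direction -- and user waypoints are
# connected by exact Dijkstra shortest paths on the 8-connected pixel graph.

#' Default intelligent-scissors feature weights
#'
#' Order: Laplacian zero-crossing, gradient magnitude, gradient direction.
#' @export
LIVEWIRE_WEIGHTS <- c(z = 0.43, g = 0.43, d = 0.14)

#' Build the local cost map for live-wire tracing
#'
#' Three per-pixel features drive the edge cost:
#' \itemize{
#'   \item gradient cost \eqn{f_G(q) = 1 - G(q)/\max G}, with \eqn{G} the
#'     Sobel gradient magnitude -- 0 on the strongest edge, 1 in flat areas;
#'   \item Laplacian zero-crossing cost \eqn{f_Z(q)}: 0 where the
#'     Laplacian-of-Gaussian changes sign within the 4-neighborhood (taking
#'     the pixel with the smaller magnitude), 1 elsewhere;
#'   \item the unit gradient direction field, used by the direction feature
#'     \eqn{f_D(p,q)} penalizing steps that cut across local edge direction.
#' }
#' The local edge cost during search is
#' \eqn{l(p,q) = [w_Z f_Z(q) + w_D f_D(p,q) + w_G f_G(q)] \cdot len(p,q)}
#' with \eqn{len} 1 for axial and \eqn{\sqrt 2} for diagonal steps.
#' A constant image yields the valid degenerate map \eqn{f_G \equiv 1},
#' \eqn{f_Z \equiv 1}.
#'
#' @param image 2-D numeric matrix, at least 16 x 16.
#' @param weights nonnegative weight triple `(z, g, d)`; normalized to sum 1.
#' @param log_sigma Gaussian scale (px) of the Laplacian-of-Gaussian.
#' @return an `mt_cost_map`: list with `gradient_cost`, `laplacian_cost`,
#'   `grad_row`, `grad_col` (unit gradient field), `weights`.
#' @export
compute_cost_map <- function(image, weights = LIVEWIRE_WEIGHTS, log_sigma = 1) {
  stopifnot(is.matrix(image), nrow(image) >= 16L, ncol(image) >= 16L)
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  image <- matrix(as.numeric(image), nrow(image), ncol(image))

  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)  # d/dcol
  gc_ <- .conv2_replicate(image, sob)
  gr_ <- .conv2_replicate(image, t(sob))
  gmag <- sqrt(gr_^2 + gc_^2)
  gmax <- max(gmag)
  if (gmax > 0) {
    f_g <- 1 - gmag / gmax
    nz <- gmag > 0
    ur <- matrix(0, nrow(image), ncol(image)); uc <- ur
    ur[nz] <- gr_[nz] / gmag[nz]
    uc[nz] <- gc_[nz] / gmag[nz]
  } else {
    f_g <- matrix(1, nrow(image), ncol(image))
    ur <- matrix(0, nrow(image), ncol(image)); uc <- ur
  }

  lap <- .conv2_replicate(.gauss_blur(image, log_sigma),
                          matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L))
  f_z <- matrix(1, nrow(image), ncol(image))
  # sign change towards any 4-neighbor, the crossing assigned to the smaller
  # |LoG|; an exact zero counts only when it separates a positive and a
  # negative neighbor (so a constant image keeps f_Z = 1 everywhere)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  nr <- nrow(image); nc <- ncol(image)
  nmin <- matrix(Inf, nr, nc); nmax <- matrix(-Inf, nr, nc)
  for (s in shifts) {
    rs <- pmin(pmax(seq_len(nr) + s[1], 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + s[2], 1L), nc)
    nbrv <- lap[rs, cs]
    f_z[lap * nbrv < 0 & abs(lap) <= abs(nbrv)] <- 0
    nmin <- pmin(nmin, nbrv); nmax <- pmax(nmax, nbrv)
  }
  f_z[lap == 0 & nmin < 0 & nmax > 0] <- 0

  structure(list(gradient_cost = f_g, laplacian_cost = f_z,
                 grad_row = ur, grad_col = uc,
                 weights = c(z = weights[1], g = weights[2], d = weights[3])),
            class = "mt_cost_map")
}

#' @export
print.mt_cost_map <- function(x, ...) {
  cat(sprintf("<live-wire cost map %dx%d, weights z=%.3g g=%.3g d=%.3g>\n",
              nrow(x$gradient_cost), ncol(x$gradient_cost),
              x$weights[1], x$weights[2], x$weights[3]))
  invisible(x)
}

.check_coord <- function(p, nr, nc, what = "coordinate") {
  if (length(p) != 2L || any(p < 1) || p[1] > nr || p[2] > nc)
    stop(what, " (", paste(p, collapse = ","), ") outside image bounds ",
         nr, "x", nc)
  as.integer(round(p))
}

#' Minimum-cost path between two pixels
#'
#' Exact Dijkstra search on the 8-connected pixel graph under the cost map.
#' Ties are broken by the fixed neighbor order N, NE, E, SE, S, SW, W, NW and
#' FIFO among equal keys, so results are reproducible across runs.
#'
#' @param cost_map an `mt_cost_map`.
#' @param start,end (row, col) coordinates, 1-based.
#' @return an `mt_polyline`: list with `points` (m x 2 integer matrix,
#'   consecutive points 8-neighbors) and `cost` (exact minimum path cost).
#' @export
shortest_path <- function(cost_map, start, end) {
  stopifnot(inherits(cost_map, "mt_cost_map"))
  nr <- nrow(cost_map$gradient_cost); nc <- ncol(cost_map$gradient_cost)
  start <- .check_coord(start, nr, nc, "start")
  end <- .check_coord(end, nr, nc, "end")
  if (all(start == end))
    return(structure(list(points = matrix(start, 1L, 2L), cost = 0),
                     class = "mt_polyline"))
  res <- .dijkstra_cpp(cost_map$laplacian_cost, cost_map$gradient_cost,
                       cost_map$grad_row, cost_map$grad_col,
                       unname(cost_map$weights), start, end)
  structure(list(points = res$path, cost = res$cost), class = "mt_polyline")
}

#' @export
print.mt_polyline <- function(x, ...) {
  cat(sprintf("<polyline of %d points, cost %.6g>\n", nrow(x$points), x$cost))
  invisible(x)
}

# crop a cost map to a window; returns list(map, r0, c0) with 1-based offsets
.crop_cost_map <- function(cost_map, rlim, clim) {
  sub <- function(m) m[rlim[1]:rlim[2], clim[1]:clim[2], drop = FALSE]
  m <- structure(list(gradient_cost = sub(cost_map$gradient_cost),
                      laplacian_cost = sub(cost_map$laplacian_cost),
                      grad_row = sub(cost_map$grad_row),
                      grad_col = sub(cost_map$grad_col),
                      weights = cost_map$weights),
                 class = "mt_cost_map")
  list(map = m, r0 = rlim[1] - 1L, c0 = clim[1] - 1L)
}

# shortest path between two waypoints, searched inside a padded bounding box
# (pad = 2 x Chebyshev distance, clipped to the image); full image if
# bounding_box = FALSE
.segment_path <- function(cost_map, a, b, bounding_box = TRUE) {
  nr <- nrow(cost_map$gradient_cost); nc <- ncol(cost_map$gradient_cost)
  if (!bounding_box)
    return(shortest_path(cost_map, a, b)$points)
  cheb <- max(abs(a - b))
  pad <- max(4L, 2L * cheb)
  rlim <- c(max(1L, min(a[1], b[1]) - pad), min(nr, max(a[1], b[1]) + pad))
  clim <- c(max(1L, min(a[2], b[2]) - pad), min(nc, max(a[2], b[2]) + pad))
  cr <- .crop_cost_map(cost_map, rlim, clim)
  p <- shortest_path(cr$map, a - c(cr$r0, cr$c0), b - c(cr$r0, cr$c0))
  cbind(p$points[, 1] + cr$r0, p$points[, 2] + cr$c0)
}

.new_contour <- function(points, waypoint_indices, mode, weights = NULL) {
  structure(list(points = points, waypoint_indices = as.integer(waypoint_indices),
                 mode = mode, weights = weights),
            class = "mt_contour")
}

#' @export
print.mt_contour <- function(x, ...) {
  cat(sprintf("<%s contour: %d points, %d waypoints>\n", x$mode,
              nrow(x$points), length(x$waypoint_indices)))
  invisible(x)
}

#' Trace a closed lesion contour through waypoints
#'
#' Connects consecutive waypoints (and the last back to the first) by
#' minimum-cost live-wire paths, each searched within a padded bounding box
#' around the waypoint pair (pad = twice their Chebyshev distance).
#'
#' @param image 2-D numeric matrix.
#' @param waypoints k x 2 matrix of (row, col) waypoints, k >= 3, in order
#'   around the lesion.
#' @param weights live-wire feature weights, see [compute_cost_map()].
#' @param cost_map optionally a precomputed `mt_cost_map` for `image`.
#' @param bounding_box search inside padded per-segment boxes (default) or
#'   the whole image.
#' @return an `mt_contour` with `mode = "assisted"`: `points` closed chain
#'   (last point 8-connects back to the first, which is waypoint 1),
#'   `waypoint_indices` positions of the waypoints within `points`.
#' @export
trace_contour <- function(image, waypoints, weights = LIVEWIRE_WEIGHTS,
                          cost_map = NULL, bounding_box = TRUE) {
  waypoints <- matrix(as.integer(round(waypoints)), ncol = 2L)
  if (nrow(waypoints) < 3L)
    stop("need at least 3 waypoints for a closed contour")
  if (is.null(cost_map)) cost_map <- compute_cost_map(image, weights)
  nr <- nrow(cost_map$gradient_cost); nc <- ncol(cost_map$gradient_cost)
  for (i in seq_len(nrow(waypoints)))
    .check_coord(waypoints[i, ], nr, nc, "waypoint")
  k <- nrow(waypoints)
  segs <- vector("list", k)
  for (i in seq_len(k)) {
    a <- waypoints[i, ]
    b <- waypoints[if (i == k) 1L else i + 1L, ]
    p <- .segment_path(cost_map, a, b, bounding_box)
    segs[[i]] <- p[-nrow(p), , drop = FALSE]  # drop junction (next seg starts there)
  }
  lens <- vapply(segs, nrow, 0L)
  pts <- do.call(rbind, segs)
  wp_idx <- cumsum(c(1L, lens[-k]))
  .new_contour(pts, wp_idx, "assisted", cost_map$weights)
}

# split contour points into per-segment lists (segment i runs from waypoint i
# up to, not including, waypoint i+1)
.contour_segments <- function(contour) {
  n <- nrow(contour$points)
  wp <- contour$waypoint_indices
  k <- length(wp)
  ends <- c(wp[-1] - 1L, n)
  lapply(seq_len(k), function(i)
    contour$points[wp[i]:ends[i], , drop = FALSE])
}

.rebuild_contour <- function(segs, mode, weights) {
  lens <- vapply(segs, nrow, 0L)
  .new_contour(do.call(rbind, segs), cumsum(c(1L, lens[-length(lens)])),
               mode, weights)
}

#' Move one waypoint of an assisted contour
#'
#' Recomputes only the two path segments incident to waypoint `k`; every
#' other segment is reused untouched.
#'
#' @param image the image the contour was traced on.
#' @param contour an assisted `mt_contour`.
#' @param k waypoint ordinal (1-based).
#' @param new_pos new (row, col) position.
#' @param cost_map optional precomputed cost map.
#' @return the updated `mt_contour`.
#' @export
adjust_waypoint <- function(image, contour, k, new_pos, cost_map = NULL) {
  stopifnot(inherits(contour, "mt_contour"))
  if (contour$mode != "assisted")
    stop("waypoint editing applies to assisted contours only")
  nwp <- length(contour$waypoint_indices)
  if (k < 1L || k > nwp) stop("waypoint ordinal out of range")
  if (is.null(cost_map)) cost_map <- compute_cost_map(image, contour$weights)
  nr <- nrow(cost_map$gradient_cost); nc <- ncol(cost_map$gradient_cost)
  new_pos <- .check_coord(new_pos, nr, nc, "new waypoint position")
  wp <- contour$points[contour$waypoint_indices, , drop = FALSE]
  wp[k, ] <- new_pos
  segs <- .contour_segments(contour)
  prev <- if (k == 1L) nwp else k - 1L
  nxt <- if (k == nwp) 1L else k + 1L
  pin <- .segment_path(cost_map, wp[prev, ], wp[k, ])
  pout <- .segment_path(cost_map, wp[k, ], wp[nxt, ])
  segs[[prev]] <- pin[-nrow(pin), , drop = FALSE]
  segs[[k]] <- pout[-nrow(pout), , drop = FALSE]
  .rebuild_contour(segs, "assisted", contour$weights)
}

#' Insert a waypoint into an assisted contour
#'
#' @inheritParams adjust_waypoint
#' @param after insert the new waypoint after this ordinal (0 to prepend).
#' @param pos (row, col) position of the new waypoint.
#' @return contour retraced through the edited waypoint list; identical to
#'   [trace_contour()] on that list.
#' @export
add_waypoint <- function(image, contour, after, pos, cost_map = NULL) {
  stopifnot(inherits(contour, "mt_contour"))
  if (contour$mode != "assisted")
    stop("waypoint editing applies to assisted contours only")
  nwp <- length(contour$waypoint_indices)
  if (after < 0L || after > nwp) stop("'after' out of range")
  wp <- contour$points[contour$waypoint_indices, , drop = FALSE]
  wp <- rbind(wp[seq_len(after), , drop = FALSE], matrix(pos, 1L),
              if (after < nwp) wp[(after + 1L):nwp, , drop = FALSE])
  trace_contour(image, wp, weights = contour$weights, cost_map = cost_map)
}

#' Remove a waypoint from an assisted contour
#'
#' @inheritParams adjust_waypoint
#' @return contour retraced through the remaining waypoints; at least 3 must
#'   remain.
#' @export
remove_waypoint <- function(image, contour, k, cost_map = NULL) {
  stopifnot(inherits(contour, "mt_contour"))
  if (contour$mode != "assisted")
    stop("waypoint editing applies to assisted contours only")
  nwp <- length(contour$waypoint_indices)
  if (k < 1L || k > nwp) stop("waypoint ordinal out of range")
  if (nwp <= 3L) stop("cannot remove: a closed contour needs at least 3 waypoints")
  wp <- contour$points[contour$waypoint_indices, , drop = FALSE]
  trace_contour(image, wp[-k, , drop = FALSE], weights = contour$weights,
                cost_map = cost_map)
}

#' Convert a freehand stroke to a closed 8-connected contour
#'
#' Consecutive duplicate points are dropped, the stroke is closed (the first
#' point is appended when the gap exceeds one 8-connected step), samples are
#' joined by Bresenham chains, and display waypoints are derived by uniform
#' arc-length subsampling (about every 24th chain point, at least 4).
#'
#' @param stroke n x 2 matrix of (row, col) samples, n >= 8.
#' @return an `mt_contour` with `mode = "freehand"`.
#' @export
freehand_to_contour <- function(stroke) {
  stroke <- matrix(as.integer(round(stroke)), ncol = 2L)
  if (nrow(stroke) < 8L)
    stop("need at least 8 stroke points")
  keep <- c(TRUE, rowSums(abs(diff(stroke))) > 0)
  stroke <- stroke[keep, , drop = FALSE]
  n <- nrow(stroke)
  if (n >= 2L && all(stroke[n, ] == stroke[1, ])) {
    stroke <- stroke[-n, , drop = FALSE]
    n <- n - 1L
  }
  closed <- rbind(stroke, stroke[1, ])
  chain <- matrix(0L, 0L, 2L)
  for (i in seq_len(nrow(closed) - 1L)) {
    seg <- bresenham(closed[i, ], closed[i + 1L, ])
    chain <- rbind(chain, seg[-nrow(seg), , drop = FALSE])
  }
  keep <- c(TRUE, rowSums(abs(diff(chain))) > 0)
  chain <- chain[keep, , drop = FALSE]
  m <- nrow(chain)
  if (m < 3L) stop("degenerate stroke: fewer than 3 distinct chain points")
  nwp <- max(4L, floor(m / 24))
  wp_idx <- 1L + floor((seq_len(nwp) - 1L) * m / nwp)
  .new_contour(chain, unique(wp_idx), "freehand")
}
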