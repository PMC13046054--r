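# Planar geometry on (row, col) coordinates: convolution helpers, Bresenham
# chains, shoelace area, polygon simplification and simplicity testing,
# even-odd rasterization and Moore boundary tracing. All pixel coordinates are
# 1-based pixel centers; polygons are n x 2 matrices (row, col), implicitly
# closed (last vertex connects to the first, never repeated).

# direct 2-D correlation with replicate padding; exact for small kernels
.conv2_replicate <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  rows <- c(rep(1L, pr), seq_len(nr), rep(nr, pr))
  cols <- c(rep(1L, pc), seq_len(nc), rep(nc, pc))
  p <- m[rows, cols, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    w <- k[i, j]
    if (w != 0) out <- out + w * p[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
  }
  out
}

# separable Gaussian blur, replicate boundary; radius = ceil(3*sigma)
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- as.integer(ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  m <- .conv2_replicate(m, matrix(g, ncol = 1L))
  .conv2_replicate(m, matrix(g, nrow = 1L))
}

#' 8-connected line rasterization (Bresenham)
#'
#' @param p,q integer (row, col) endpoints.
#' @return integer matrix of points from `p` to `q` inclusive, consecutive
#'   points 8-neighbors.
#' @keywords internal
bresenham <- function(p, q) {
  r0 <- as.integer(round(p[1])); c0 <- as.integer(round(p[2]))
  r1 <- as.integer(round(q[1])); c1 <- as.integer(round(q[2]))
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- as.integer(sign(r1 - r0)); sc <- as.integer(sign(c1 - c0))
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

#' Signed and absolute shoelace area of a polygon
#'
#' @param pts n x 2 matrix of (row, col) vertices, implicitly closed.
#' @param signed return the signed area (positive for counter-clockwise in
#'   (col, row) axes) instead of the absolute value.
#' @return area in squared coordinate units.
#' @export
shoelace_area <- function(pts, signed = FALSE) {
  r <- pts[, 1]; c <- pts[, 2]
  rn <- c(r[-1], r[1]); cn <- c(c[-1], c[1])
  a <- sum(c * rn - cn * r) / 2
  if (signed) a else abs(a)
}

# drop consecutive duplicate vertices (closed polygon)
.dedupe_closed <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n > 1L && all(pts[n, ] == pts[1, ])) pts <- pts[-n, , drop = FALSE]
  pts
}

#' Remove collinear runs from a closed polygon
#'
#' Drops every vertex lying exactly on the segment between its neighbors
#' (zero cross product), after removing consecutive duplicates.
#'
#' @param pts n x 2 vertex matrix, implicitly closed.
#' @return simplified vertex matrix.
#' @export
simplify_collinear <- function(pts) {
  # iterate to a fixpoint: removing a zero-area spike tip (prev == next)
  # leaves an adjacent duplicate that needs another pass
  repeat {
    pts <- .dedupe_closed(pts)
    n <- nrow(pts)
    if (n < 3L) return(pts)
    prv <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
    nxt <- pts[c(seq_len(n)[-1], 1L), , drop = FALSE]
    cross <- (pts[, 1] - prv[, 1]) * (nxt[, 2] - pts[, 2]) -
             (pts[, 2] - prv[, 2]) * (nxt[, 1] - pts[, 1])
    keep <- cross != 0
    if (!any(keep)) return(pts[1:2, , drop = FALSE])
    if (all(keep)) return(pts)
    pts <- pts[keep, , drop = FALSE]
  }
}

#' Test whether a closed polygon is simple
#'
#' A polygon is simple when no vertex repeats and no two non-adjacent edges
#' intersect. Collinear runs are simplified first.
#'
#' @param pts n x 2 vertex matrix, implicitly closed.
#' @return logical scalar.
#' @export
is_simple_polygon <- function(pts) {
  pts <- simplify_collinear(pts)
  n <- nrow(pts)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(pts) > 0L) return(FALSE)
  a <- pts
  b <- pts[c(seq_len(n)[-1], 1L), , drop = FALSE]
  orient <- function(pr, pc, qr, qc, rr, rc)
    sign((qc - pc) * (rr - pr) - (qr - pr) * (rc - pc))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n is adjacent to edge 1
    if (length(js) == 0L) next
    o1 <- orient(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    o2 <- orient(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    o3 <- orient(a[js, 1], a[js, 2], b[js, 1], b[js, 2], a[i, 1], a[i, 2])
    o4 <- orient(a[js, 1], a[js, 2], b[js, 1], b[js, 2], b[i, 1], b[i, 2])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0))
      return(FALSE)
  }
  TRUE
}

#' Rasterize a closed contour to a binary mask
#'
#' Pixel centers strictly inside the polygon (even-odd rule) are set, and the
#' 8-connected boundary chain is set, so the mask is boundary-inclusive.
#' Because the boundary ring is included whole, the pixel count exceeds the
#' shoelace area by about half the perimeter (Pick's theorem); the two agree
#' to a few percent only for regions upwards of ~100 px across.
#'
#' @param contour an `mt_contour`, or an n x 2 vertex matrix.
#' @param rows,cols mask dimensions.
#' @param strict reject self-intersecting polygons (default). With
#'   `strict = FALSE` the even-odd fill is applied as-is, which is
#'   well-defined (if ambiguous to interpret) for self-crossing outlines;
#'   used when scoring imperfect traced contours against ground truth.
#' @return integer matrix (`rows` x `cols`) of 0/1.
#' @export
rasterize <- function(contour, rows, cols, strict = TRUE) {
  pts <- if (inherits(contour, "mt_contour")) contour$points else contour
  if (strict && !is_simple_polygon(pts))
    stop("contour is self-intersecting; refusing to rasterize")
  if (any(pts[, 1] < 1 | pts[, 1] > rows | pts[, 2] < 1 | pts[, 2] > cols))
    stop("contour does not fit in a ", rows, "x", cols, " mask")
  mask <- matrix(0L, rows, cols)
  n <- nrow(pts)
  r1 <- pts[, 1]; c1 <- pts[, 2]
  r2 <- c(r1[-1], r1[1]); c2 <- c(c1[-1], c1[1])
  for (r in seq_len(rows)) {
    crosses <- (r1 > r) != (r2 > r)
    if (any(crosses)) {
      xc <- c1[crosses] + (r - r1[crosses]) / (r2[crosses] - r1[crosses]) *
        (c2[crosses] - c1[crosses])
      xc <- sort(xc)
      # pixel c is inside iff an odd number of crossings lie strictly right of c
      nright <- length(xc) - findInterval(seq_len(cols), xc)
      mask[r, nright %% 2L == 1L] <- 1L
    }
  }
  for (i in seq_len(n)) {
    seg <- bresenham(pts[i, ], pts[if (i == n) 1L else i + 1L, ])
    mask[cbind(seg[, 1], seg[, 2])] <- 1L
  }
  mask
}

#' Trace the outer boundary of a binary mask
#'
#' Moore-neighbor tracing with Jacob's stopping criterion, starting from the
#' first foreground pixel in row-major scan order. Useful for turning an
#' exported mask back into a polygon.
#'
#' @param mask 0/1 matrix with one 8-connected foreground component.
#' @return n x 2 matrix of boundary pixel (row, col) coordinates, implicitly
#'   closed, clockwise in (row, col) screen orientation.
#' @export
mask_to_contour <- function(mask) {
  idx <- which(t(mask) == 1L)  # row-major scan
  if (length(idx) == 0L) stop("empty mask")
  nc <- ncol(mask)
  first <- idx[1]
  sr <- (first - 1L) %/% nc + 1L
  sc <- (first - 1L) %% nc + 1L
  if (sum(mask) == 1L) return(matrix(c(sr, sc), 1L, 2L))
  # Moore neighborhood in clockwise order starting W
  nbr <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                ncol = 2L, byrow = TRUE)
  dir_index <- function(dr, dc) which(nbr[, 1] == dr & nbr[, 2] == dc)
  at <- function(r, c) r >= 1L && r <= nrow(mask) && c >= 1L && c <= ncol(mask) &&
    mask[r, c] == 1L
  maxit <- 4L * sum(mask) + 8L
  path <- matrix(0L, maxit, 2L)
  np <- 0L
  cur <- c(sr, sc)
  b <- 1L  # scan start: the W neighbor, background for the scan-order start pixel
  start_state <- NULL
  for (it in seq_len(maxit)) {
    np <- np + 1L
    path[np, ] <- cur
    nxt <- NULL
    for (k in 1:7) {
      j <- (b - 1L + k) %% 8L + 1L
      r2 <- cur[1] + nbr[j, 1]; c2 <- cur[2] + nbr[j, 2]
      if (at(r2, c2)) {
        jprev <- (j - 2L) %% 8L + 1L  # background neighbor examined just before
        bg <- cur + nbr[jprev, ]
        nxt <- c(r2, c2)
        b <- dir_index(bg[1] - r2, bg[2] - c2)
        break
      }
    }
    if (is.null(nxt)) break  # isolated pixel
    cur <- nxt
    state <- c(cur, b)
    if (is.null(start_state)) {
      start_state <- state
    } else if (all(state == start_state)) break
  }
  out <- path[seq_len(np), , drop = FALSE]
  .dedupe_closed(out)
}
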