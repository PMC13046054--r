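# Shared fixtures: cached phantom cases, Dice, waypoint generators, random
# simple polygons and random valid morphologies. Everything is generated in
# code under fixed seeds; nothing is stored on disk between runs.

.fixture_env <- new.env(parent = emptyenv())

# write (once per session) and scan the default disk phantom case
disk_phantom_fixture <- function(seed = 1, contrast = 0.25, blur = 2) {
  key <- sprintf("disk_%d_%g_%g", seed, contrast, blur)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  root <- file.path(tempdir(), paste0("phroot_", key))
  spec <- phantom_disk_spec(seed = seed, contrast = contrast,
                            edge_blur_sigma_px = blur)
  write_phantom_case(root, "case001", spec)
  case <- scan_case_directory(root)[[1]]
  img <- load_stack(case$images[[1]])[1, , ]
  fx <- list(root = root, spec = spec, case = case, img = img,
             truth_poly = mammotrace:::.lesion_truth_polygon(spec$lesions[[1]]))
  .fixture_env[[key]] <- fx
  fx
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# waypoints on a circle of given radius, optional radial jitter (px)
circle_waypoints <- function(center, radius, n = 12, jitter = 0) {
  theta <- (seq_len(n) - 1) * 2 * pi / n
  r <- radius + if (jitter > 0) stats::runif(n, -jitter, jitter) else 0
  cbind(round(center[1] + r * cos(theta)), round(center[2] + r * sin(theta)))
}

# random star-shaped (hence simple) polygon around a center
random_simple_polygon <- function(center = c(100, 100), rmin = 20, rmax = 40,
                                  n = 24) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

# integer-vertex variant that is guaranteed simple after rounding
random_integer_polygon <- function(center = c(100, 100), rmin = 20,
                                   rmax = 40, n = 24) {
  repeat {
    poly <- round(random_simple_polygon(center, rmin, rmax, n))
    storage.mode(poly) <- "integer"
    if (is_simple_polygon(poly)) return(poly)
  }
}

random_morphology <- function() {
  lt <- sample(c("mass", "microcalcification", "architectural_distortion",
                 "asymmetry"), 1)
  switch(lt,
    mass = morphology("mass",
      mass_shape = sample(c("oval", "round", "irregular"), 1),
      mass_margin = sample(c("circumscribed", "obscured", "microlobulated",
                             "indistinct", "spiculated"), 1),
      mass_density = sample(c("high", "equal", "low", "fat_containing"), 1)),
    microcalcification = morphology("microcalcification",
      calc_morphology = sample(c("typically_benign", "amorphous",
                                 "coarse_heterogeneous", "fine_pleomorphic",
                                 "fine_linear_branching"), 1),
      calc_distribution = sample(c("diffuse", "regional", "grouped", "linear",
                                   "segmental"), 1)),
    morphology(lt))
}

random_annotation_set <- function(case_id, modality = "DM") {
  set <- annotation_set(case_id)
  for (i in seq_len(sample(1:3, 1))) {
    poly <- random_integer_polygon()
    ctr <- mammotrace:::.new_contour(poly, c(1L, 8L, 16L), "assisted",
                                     stats::setNames(c(0.43, 0.43, 0.14),
                                                     c("z", "g", "d")))
    ann <- annotation(case_id, sample(c("L", "R"), 1),
                      sample(c("CC", "MLO"), 1), modality,
                      if (modality == "DM") 1L else sample(1:10, 1),
                      random_morphology(), ctr,
                      reader_id = sprintf("reader%d", sample(1:3, 1)),
                      created_utc = "2026-01-01T00:00:00Z")
    set <- add_annotation(set, ann)
  }
  set
}

# smooth wavy closed polygon used for rasterization-consistency checks;
# mean radius large enough that boundary-inclusive rasterization stays
# within 2% of the shoelace area
random_smooth_polygon <- function(center, rmean, n = 180) {
  k <- sample(2:6, 2)
  a <- stats::runif(2, 0, 0.04)
  phi <- stats::runif(2, 0, 2 * pi)
  theta <- (seq_len(n) - 1) * 2 * pi / n
  r <- rmean * (1 + a[1] * cos(k[1] * theta + phi[1]) +
                a[2] * cos(k[2] * theta + phi[2]))
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}
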