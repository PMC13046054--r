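# Synthetic DM/DBT phantom cases. Backgrounds are power-law (1/f^beta)
# textures -- the classical spectral model of mammographic structure noise --
# and lesions are analytic shapes (ellipses, star-convex spiculated masses,
# calcification clusters) blended in with known contrast and edge blur, so
# every downstream module can be tested against exact ground truth.

#' Phantom case specification
#'
#' The seed fully determines pixel content and metadata, so two generations
#' from the same spec are byte-identical.
#'
#' @param rows,cols image size in px.
#' @param n_slices 1 for DM, >1 for a DBT stack.
#' @param pixel_spacing_mm (row, col) spacing in mm.
#' @param noise_exponent spectral exponent beta of the 1/f^beta background.
#' @param mean_level background mean in stored pixel units.
#' @param amplitude background standard deviation in stored pixel units
#'   (0 gives a constant background).
#' @param dynamic_range reference intensity range; lesion contrast is a
#'   fraction of this.
#' @param lesions list of [lesion_spec()] entries.
#' @param laterality,view DICOM laterality ("L"/"R") and view ("CC"/"MLO").
#' @param seed integer seed.
#' @param multiframe write DBT as one multiframe file instead of a
#'   one-file-per-slice series.
#' @param study_date fixed DICOM study date (determinism).
#' @return an `mt_phantom_spec`.
#' @export
phantom_spec <- function(rows = 512L, cols = 512L, n_slices = 1L,
                         pixel_spacing_mm = c(0.1, 0.1), noise_exponent = 3,
                         mean_level = 600, amplitude = 80,
                         dynamic_range = 1000, lesions = list(),
                         laterality = "L", view = "CC", seed = 1L,
                         multiframe = FALSE, study_date = "20240101") {
  stopifnot(rows >= 32L, cols >= 32L, n_slices >= 1L,
            all(pixel_spacing_mm > 0), amplitude >= 0,
            laterality %in% c("L", "R"), view %in% c("CC", "MLO"))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_slices = as.integer(n_slices),
                 pixel_spacing_mm = pixel_spacing_mm,
                 noise_exponent = noise_exponent, mean_level = mean_level,
                 amplitude = amplitude, dynamic_range = dynamic_range,
                 lesions = lesions, laterality = laterality, view = view,
                 seed = as.integer(seed), multiframe = multiframe,
                 study_date = study_date),
            class = "mt_phantom_spec")
}

#' Lesion specification for a phantom
#'
#' Shapes: `"ellipse"` (semi-axes `radius_px`, circle when scalar),
#' `"star_convex"` -- a spiculated outline with radius
#' \eqn{r(\theta) = R (1 + A \cos(n\theta))} -- and `"calc_cluster"`,
#' bright discs scattered in a containing circle whose ground truth is that
#' circle (calcified areas are outlined roughly, not per calcification).
#'
#' @param shape lesion shape.
#' @param center (row, col) center in px.
#' @param radius_px radius, or (row, col) semi-axes for an ellipse.
#' @param contrast additive lesion contrast as a fraction of the phantom
#'   dynamic range.
#' @param edge_blur_sigma_px Gaussian blur of the lesion edge, px.
#' @param slice_index slice carrying the lesion (1-based; 1 for DM).
#' @param n_spicules,spicule_amplitude star-convex parameters.
#' @param n_calcs,calc_radius calcification cluster parameters.
#' @return an `mt_lesion_spec`.
#' @export
lesion_spec <- function(shape = c("ellipse", "star_convex", "calc_cluster"),
                        center, radius_px, contrast = 0.25,
                        edge_blur_sigma_px = 2, slice_index = 1L,
                        n_spicules = 8L, spicule_amplitude = 0.3,
                        n_calcs = 12L, calc_radius = 2) {
  shape <- match.arg(shape)
  if (length(radius_px) == 1L) radius_px <- c(radius_px, radius_px)
  stopifnot(all(radius_px > 0), contrast > 0, edge_blur_sigma_px >= 0)
  structure(list(shape = shape, center = center, radius_px = radius_px,
                 contrast = contrast, edge_blur_sigma_px = edge_blur_sigma_px,
                 slice_index = as.integer(slice_index),
                 n_spicules = as.integer(n_spicules),
                 spicule_amplitude = spicule_amplitude,
                 n_calcs = as.integer(n_calcs), calc_radius = calc_radius),
            class = "mt_lesion_spec")
}

#' The default disk phantom
#'
#' A DM phantom with a centered circular lesion of radius 60 px, the standard
#' substrate for live-wire recovery tests.
#'
#' @param seed integer seed.
#' @param contrast lesion contrast fraction.
#' @param edge_blur_sigma_px lesion edge blur in px.
#' @return an `mt_phantom_spec`.
#' @export
phantom_disk_spec <- function(seed = 1L, contrast = 0.25,
                              edge_blur_sigma_px = 2) {
  phantom_spec(seed = seed, lesions = list(
    lesion_spec("ellipse", center = c(256, 256), radius_px = 60,
                contrast = contrast, edge_blur_sigma_px = edge_blur_sigma_px)))
}

# one 1/f^beta field, unit variance, zero mean; consumes the current RNG
.background_field <- function(rows, cols, beta) {
  noise <- matrix(stats::rnorm(rows * cols), rows, cols)
  fr <- c(0:(rows %/% 2), -((rows - rows %/% 2 - 1):1)) / rows
  fc <- c(0:(cols %/% 2), -((cols - cols %/% 2 - 1):1)) / cols
  f <- sqrt(outer(fr^2, fc^2, `+`))
  h <- matrix(0, rows, cols)
  h[f > 0] <- f[f > 0]^(-beta / 2)
  field <- Re(stats::fft(stats::fft(noise) * h, inverse = TRUE)) / (rows * cols)
  field <- field - mean(field)
  s <- stats::sd(field)
  if (s > 0) field <- field / s
  field
}

#' Generate the textured background of a phantom
#'
#' Inverse-spectral synthesis: white Gaussian noise shaped to a power
#' spectrum proportional to \eqn{1/f^\beta}, standardized and scaled to the
#' spec's mean level and amplitude. Deterministic in the spec seed; equals
#' the first slice of the full phantom stack.
#'
#' @param spec an `mt_phantom_spec`.
#' @return rows x cols numeric matrix.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "mt_phantom_spec"))
  set.seed(spec$seed)
  spec$mean_level + spec$amplitude *
    .background_field(spec$rows, spec$cols, spec$noise_exponent)
}

# analytic boundary radius at angle theta (theta = atan2(dcol, drow))
.lesion_radius <- function(lesion, theta) {
  switch(lesion$shape,
    ellipse = {
      a <- lesion$radius_px[1]; b <- lesion$radius_px[2]
      if (a == b) rep(a, length(theta))
      else a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    star_convex = lesion$radius_px[1] *
      (1 + lesion$spicule_amplitude * cos(lesion$n_spicules * theta)),
    calc_cluster = rep(lesion$radius_px[1], length(theta)))
}

# ground-truth polygon sampled at 1 degree steps
.lesion_truth_polygon <- function(lesion) {
  theta <- (0:359) * pi / 180
  r <- .lesion_radius(lesion, theta)
  cbind(lesion$center[1] + r * cos(theta), lesion$center[2] + r * sin(theta))
}

#' Render one lesion into an image
#'
#' Adds `contrast * dynamic_range` inside the analytic lesion region,
#' Gaussian-blurred by the edge blur sigma, and returns the exact ground
#' truth: the boundary polygon sampled at 1 degree steps plus its true Feret
#' diameter and shoelace area in mm units. Calcification clusters scatter
#' `n_calcs` bright discs inside the containing circle (consuming the
#' current RNG stream); their ground truth is the containing circle.
#'
#' @param image rows x cols numeric matrix.
#' @param lesion an `mt_lesion_spec`; must fit with >= 8 px margin.
#' @param dynamic_range intensity range the contrast fraction refers to.
#' @param pixel_spacing_mm (row, col) spacing used for the mm ground truth.
#' @return list with `image` (lesion added) and `truth` (list: `polygon`,
#'   `true_feret_mm`, `true_area_mm2`, `slice_index`).
#' @export
render_lesion <- function(image, lesion, dynamic_range = 1000,
                          pixel_spacing_mm = c(0.1, 0.1)) {
  stopifnot(inherits(lesion, "mt_lesion_spec"))
  nr <- nrow(image); nc <- ncol(image)
  rmax <- max(.lesion_radius(lesion, (0:359) * pi / 180))
  if (lesion$center[1] - rmax < 8 || lesion$center[1] + rmax > nr - 8 ||
      lesion$center[2] - rmax < 8 || lesion$center[2] + rmax > nc - 8)
    stop("lesion does not fit inside the image with an 8 px margin")

  dr <- matrix(seq_len(nr) - lesion$center[1], nr, nc)
  dc <- matrix(seq_len(nc) - lesion$center[2], nr, nc, byrow = TRUE)
  dist <- sqrt(dr^2 + dc^2)
  amp <- lesion$contrast * dynamic_range

  if (lesion$shape == "calc_cluster") {
    bump <- matrix(0, nr, nc)
    rad <- lesion$radius_px[1]
    for (i in seq_len(lesion$n_calcs)) {
      # rejection-free uniform position in the containing circle
      rho <- rad * 0.8 * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      ctr <- lesion$center + rho * c(cos(ang), sin(ang))
      d2 <- (matrix(seq_len(nr), nr, nc) - ctr[1])^2 +
            (matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr[2])^2
      bump[d2 <= lesion$calc_radius^2] <- amp
    }
  } else {
    theta <- atan2(dc, dr)
    bump <- matrix(0, nr, nc)
    bump[dist <= .lesion_radius(lesion, theta)] <- amp
  }
  if (lesion$edge_blur_sigma_px > 0)
    bump <- .gauss_blur(bump, lesion$edge_blur_sigma_px)

  poly <- .lesion_truth_polygon(lesion)
  truth <- list(polygon = poly,
                true_feret_mm = feret_diameter(poly, pixel_spacing_mm),
                true_area_mm2 = contour_area(poly, pixel_spacing_mm),
                slice_index = lesion$slice_index)
  list(image = image + bump, truth = truth)
}

#' Render a full phantom stack with ground truth
#'
#' @param spec an `mt_phantom_spec`.
#' @return list with `stack` (n_slices x rows x cols integer array, values
#'   clipped to [0, 4095]) and `truth` (one entry per lesion, in spec order).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "mt_phantom_spec"))
  set.seed(spec$seed)
  stack <- array(0L, dim = c(spec$n_slices, spec$rows, spec$cols))
  truths <- vector("list", length(spec$lesions))
  for (s in seq_len(spec$n_slices)) {
    img <- spec$mean_level + spec$amplitude *
      .background_field(spec$rows, spec$cols, spec$noise_exponent)
    for (li in seq_along(spec$lesions)) {
      lesion <- spec$lesions[[li]]
      if (lesion$slice_index == s) {
        res <- render_lesion(img, lesion, spec$dynamic_range,
                             spec$pixel_spacing_mm)
        img <- res$image
        truths[[li]] <- res$truth
      }
    }
    stack[s, , ] <- pmin(pmax(round(img), 0), 4095)
  }
  list(stack = stack, truth = truths)
}

.phantom_uid <- function(spec, image_index, k) {
  paste0(.DCM_UID_ROOT, ".", spec$seed, ".", image_index, ".", k)
}

#' Write a phantom case directory
#'
#' Writes valid DICOM files (single-frame for DM; an ordered slice series or
#' one multiframe object for DBT) with laterality, view and pixel-spacing
#' tags set, plus a ground-truth CSV (`<case_id>_ground_truth.csv`) and one
#' vertex CSV per lesion. Scanning the directory round-trips all metadata.
#'
#' @param out_dir root directory; the case subdirectory is created inside.
#' @param case_id case (subdirectory) name.
#' @param specs one `mt_phantom_spec` or a list of them (one per image).
#' @return the case directory path, invisibly.
#' @export
write_phantom_case <- function(out_dir, case_id, specs) {
  if (inherits(specs, "mt_phantom_spec")) specs <- list(specs)
  case_dir <- file.path(out_dir, case_id)
  if (!dir.exists(case_dir) && !dir.create(case_dir, recursive = TRUE))
    stop("cannot create case directory ", case_dir)
  gt_rows <- list()
  for (ii in seq_along(specs)) {
    spec <- specs[[ii]]
    ph <- render_phantom(spec)
    base_tags <- list(
      Modality = "MG", ImageLaterality = spec$laterality,
      ViewPosition = spec$view,
      PixelSpacing = sprintf("%.6g", spec$pixel_spacing_mm),
      StudyDate = spec$study_date,
      StudyInstanceUID = paste0(.DCM_UID_ROOT, ".", spec$seed, ".0"),
      SeriesInstanceUID = .phantom_uid(spec, ii, 0L),
      SeriesNumber = ii,
      SeriesDescription = if (spec$n_slices > 1L) "DBT stack" else "DM projection")
    if (spec$n_slices == 1L || spec$multiframe) {
      px <- array(0L, dim = c(spec$rows, spec$cols, spec$n_slices))
      for (s in seq_len(spec$n_slices)) px[, , s] <- ph$stack[s, , ]
      tags <- c(base_tags, list(SOPInstanceUID = .phantom_uid(spec, ii, 1L),
                                InstanceNumber = 1L))
      fname <- sprintf("%s_img%02d_%s%s.dcm", case_id, ii, spec$laterality,
                       spec$view)
      dcm_write(file.path(case_dir, fname),
                if (spec$n_slices == 1L) px[, , 1L] else px, tags)
    } else {
      for (s in seq_len(spec$n_slices)) {
        tags <- c(base_tags, list(
          SOPInstanceUID = .phantom_uid(spec, ii, s),
          InstanceNumber = s,
          SliceLocation = sprintf("%.2f", s * 1.0)))
        fname <- sprintf("%s_img%02d_%s%s_s%03d.dcm", case_id, ii,
                         spec$laterality, spec$view, s)
        dcm_write(file.path(case_dir, fname), ph$stack[s, , ], tags)
      }
    }
    for (li in seq_along(ph$truth)) {
      tr <- ph$truth[[li]]
      if (is.null(tr)) next
      lesion_id <- sprintf("img%02d_lesion%02d", ii, li)
      vfile <- sprintf("%s_gt_%s.csv", case_id, lesion_id)
      utils::write.csv(data.frame(row = tr$polygon[, 1], col = tr$polygon[, 2]),
                       file.path(case_dir, vfile), row.names = FALSE)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        lesion_id = lesion_id, image_index = ii,
        slice_index = tr$slice_index, true_feret_mm = tr$true_feret_mm,
        true_area_mm2 = tr$true_area_mm2, contour_file = vfile,
        stringsAsFactors = FALSE)
    }
  }
  gt <- if (length(gt_rows) > 0L) do.call(rbind, gt_rows) else
    data.frame(lesion_id = character(0), image_index = integer(0),
               slice_index = integer(0), true_feret_mm = numeric(0),
               true_area_mm2 = numeric(0), contour_file = character(0))
  utils::write.csv(gt, file.path(case_dir, paste0(case_id, "_ground_truth.csv")),
                   row.names = FALSE)
  invisible(case_dir)
}
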