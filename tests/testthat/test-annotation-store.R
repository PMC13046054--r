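# BI-RADS morphology model, lesion colors, sidecar persistence, deletion
# and exports.

test_that("lesion colors are fixed, injective and deterministic", {
  expect_identical(lesion_color("mass"), c(255L, 0L, 0L))
  types <- c("mass", "microcalcification", "architectural_distortion",
             "asymmetry")
  cols <- lapply(types, lesion_color)
  expect_identical(length(unique(cols)), 4L)
  expect_identical(lesion_color("asymmetry"), lesion_color("asymmetry"))
})

test_that("morphology validation enforces the per-type descriptor rules", {
  ok <- morphology("mass", "irregular", "spiculated", "high")
  expect_identical(validate_morphology(ok), character(0))

  bad <- ok; bad$calc_distribution <- "grouped"
  v <- validate_morphology(bad)
  expect_length(v, 1L)
  expect_match(v, "calc_distribution")

  asym <- morphology("asymmetry"); asym$mass_shape <- "oval"
  expect_length(validate_morphology(asym), 1L)

  calc <- morphology("microcalcification", calc_morphology = "amorphous",
                     calc_distribution = "grouped")
  expect_identical(validate_morphology(calc), character(0))
  calc$calc_morphology <- "none"
  expect_match(validate_morphology(calc), "calc_morphology")

  # unknown vocabulary is rejected at construction
  expect_error(morphology("mass", "blobby", "spiculated", "high"),
               "invalid value")
})

test_that("sidecar save/load is an identity and saves are atomic", {
  dir <- withr::local_tempdir()
  set.seed(31)
  for (i in 1:10) {
    set <- random_annotation_set(sprintf("case%03d", i))
    cdir <- file.path(dir, set$case_id); dir.create(cdir)
    p1 <- save_annotations(set, cdir)
    loaded <- load_annotations(cdir)
    save_annotations(loaded, cdir)
    # save(load(save(S))) is byte-identical to save(S)
    bytes1 <- readLines(p1)
    expect_identical(bytes1, readLines(save_annotations(loaded, cdir)))
    expect_identical(length(loaded$annotations), length(set$annotations))
    for (k in seq_along(set$annotations)) {
      a <- set$annotations[[k]]; b <- loaded$annotations[[k]]
      expect_identical(a$morphology, b$morphology)
      expect_identical(unname(a$contour$points), unname(b$contour$points))
      expect_identical(a$slice_index, b$slice_index)
      expect_identical(a$display_color, b$display_color)
    }
    expect_length(list.files(cdir, pattern = "\\.tmp$"), 0L)
  }

  # empty set round-trips too
  cdir <- file.path(dir, "empty"); dir.create(cdir)
  save_annotations(annotation_set("empty"), cdir)
  expect_length(load_annotations(cdir)$annotations, 0L)
})

test_that("corrupt or mismatched sidecars fail loudly", {
  dir <- withr::local_tempdir()
  cdir <- file.path(dir, "caseZ"); dir.create(cdir)
  set <- annotation_set("caseZ")
  p <- save_annotations(set, cdir)
  writeLines(c("{ not json"), p)
  expect_error(load_annotations(cdir), "corrupt sidecar")

  js <- jsonlite::toJSON(list(schema_version = "9.9", case_id = "caseZ",
                              annotations = list()), auto_unbox = TRUE)
  writeLines(js, p)
  expect_error(load_annotations(cdir), "schema_version '9.9'")
})

test_that("saving refuses invalid morphology and self-intersection", {
  dir <- withr::local_tempdir()
  cdir <- file.path(dir, "caseV"); dir.create(cdir)
  set.seed(32)
  set <- random_annotation_set("caseV")
  set$annotations[[1]]$morphology$mass_shape <-
    if (set$annotations[[1]]$morphology$lesion_type == "mass") "none" else "oval"
  expect_error(save_annotations(set, cdir), "violations")

  bow <- mammotrace:::.new_contour(
    rbind(c(1L, 1L), c(10L, 10L), c(1L, 10L), c(10L, 1L)), 1L, "assisted")
  expect_error(annotation("caseV", "L", "CC", "DM", 1,
                          morphology("asymmetry"), bow),
               "self-intersecting")
})

test_that("delete_annotation removes exactly the named annotation", {
  set.seed(33)
  set <- random_annotation_set("caseD")
  ids <- vapply(set$annotations, `[[`, "", "annotation_id")
  rest <- delete_annotation(set, ids[1])
  expect_length(rest$annotations, length(ids) - 1L)
  if (length(ids) > 1L)
    expect_identical(rest$annotations, set$annotations[-1])
  expect_error(delete_annotation(set, "ann-999999"), "no annotation")

  one <- annotation_set("caseD")
  a1 <- set$annotations[[1]]; a1$annotation_id <- NA_character_
  one <- add_annotation(one, a1)
  expect_length(delete_annotation(one, "ann-000001")$annotations, 0L)
})

test_that("exports are deterministic and consistent with measurements", {
  root <- withr::local_tempdir()
  write_phantom_case(root, "c1", phantom_spec(
    rows = 128, cols = 128, seed = 6,
    lesions = list(lesion_spec("ellipse", c(64, 64), c(30, 20)))))
  cs <- scan_case_directory(root)[[1]]
  img <- load_stack(cs$images[[1]])[1, , ]
  theta <- (0:9) * 2 * pi / 10
  ell_wp <- cbind(round(64 + 30 * cos(theta)), round(64 + 20 * sin(theta)))
  ctr <- trace_contour(img, ell_wp)
  set <- add_annotation(annotation_set("c1"), annotation(
    "c1", "L", "CC", "DM", 1L, morphology("mass", "oval", "obscured", "low"),
    ctr, created_utc = "2026-01-01T00:00:00Z"))

  out1 <- file.path(root, "o1"); out2 <- file.path(root, "o2")
  csv1 <- export_annotations(set, "csv", out1, case = cs)
  csv2 <- export_annotations(set, "csv", out2, case = cs)
  expect_identical(readLines(csv1), readLines(csv2))

  df <- utils::read.csv(csv1)
  expect_identical(nrow(df), 1L)
  expect_identical(df$slice_index, 1L)
  sp <- cs$images[[1]]$pixel_spacing_mm
  expect_equal(df$feret_mm, feret_diameter(ctr, sp), tolerance = 1e-9)
  expect_equal(df$area_mm2, contour_area(ctr, sp), tolerance = 1e-9)

  masks <- export_annotations(set, "mask", out1, case = cs)
  expect_length(masks, 1L)
  expect_false(grepl("slice", basename(masks)))  # DM: no slice in the name
  png_mask <- png::readPNG(masks)
  expect_setequal(unique(as.vector(png_mask)), c(0, 1))
  expect_identical(sum(png_mask == 1),
                   sum(rasterize(ctr, 128, 128)))

  # empty set gives a header-only csv
  empty_csv <- export_annotations(annotation_set("c1"), "csv",
                                  file.path(root, "o3"))
  expect_identical(length(readLines(empty_csv)), 1L)
})
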