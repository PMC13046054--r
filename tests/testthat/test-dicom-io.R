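# Case discovery, metadata classification, stack loading and the
# non-mutation guarantee.

test_that("scanning handles empty roots and non-DICOM-only subdirectories", {
  root <- withr::local_tempdir()
  expect_identical(scan_case_directory(root), list())

  dir.create(file.path(root, "caseX"))
  writeLines("not dicom", file.path(root, "caseX", "note.txt"))
  expect_warning(cases <- scan_case_directory(root), "skipped")
  expect_length(cases, 0L)

  expect_error(scan_case_directory(file.path(root, "nope")), "does not exist")
})

test_that("phantom cases scan into correctly classified records", {
  root <- withr::local_tempdir()
  # two cases of 4 DM images each (both breasts, both views)
  combos <- expand.grid(lat = c("L", "R"), view = c("CC", "MLO"),
                        stringsAsFactors = FALSE)
  for (cid in c("case001", "case002")) {
    specs <- lapply(seq_len(nrow(combos)), function(i)
      phantom_spec(rows = 48, cols = 48, laterality = combos$lat[i],
                   view = combos$view[i], seed = 10 + i))
    write_phantom_case(root, cid, specs)
  }
  cases <- scan_case_directory(root)
  expect_length(cases, 2L)
  expect_identical(vapply(cases, `[[`, "", "case_id"), c("case001", "case002"))
  for (cs in cases) {
    expect_length(cs$images, 4L)
    got <- t(vapply(cs$images, function(im) c(im$laterality, im$view),
                    c("", "")))
    expect_setequal(paste(got[, 1], got[, 2]),
                    paste(combos$lat, combos$view))
    expect_true(all(vapply(cs$images, `[[`, "", "modality_kind") == "DM"))
  }
  # determinism: a second scan yields identical records
  expect_identical(cases, scan_case_directory(root))
})

test_that("classify_image follows the tag contract without guessing", {
  expect_identical(
    classify_image(list(ImageLaterality = "L", ViewPosition = "MLO")),
    list(modality_kind = "DM", laterality = "L", view = "MLO"))
  expect_identical(classify_image(list(ViewPosition = "CC"))$laterality,
                   "unknown")
  expect_identical(classify_image(list(Laterality = "R"))$laterality, "R")
  expect_identical(classify_image(list())$view, "unknown")
  expect_identical(
    classify_image(list(NumberOfFrames = 40L))$modality_kind, "DBT")
  expect_identical(classify_image(list(), n_in_series = 12L)$modality_kind,
                   "DBT")
})

test_that("DBT stacks round-trip metadata and load in slice order", {
  root <- withr::local_tempdir()
  spec <- phantom_spec(rows = 40, cols = 40, n_slices = 40, laterality = "R",
                       view = "MLO", seed = 5)
  write_phantom_case(root, "dbt1", spec)
  cs <- scan_case_directory(root)[[1]]
  im <- cs$images[[1]]
  expect_identical(im$modality_kind, "DBT")
  expect_identical(im$laterality, "R")
  expect_identical(im$view, "MLO")
  expect_identical(im$n_slices, 40L)
  expect_identical(im$ordering_key, "slice_location")
  stk <- load_stack(im)
  expect_identical(dim(stk), c(40L, 40L, 40L))
  # slices in the written order
  ph <- render_phantom(spec)
  expect_equal(stk, ph$stack * 1.0, ignore_attr = TRUE)

  # multiframe dialect normalizes to the same stack
  spec_mf <- phantom_spec(rows = 40, cols = 40, n_slices = 40,
                          laterality = "R", view = "MLO", seed = 5,
                          multiframe = TRUE)
  write_phantom_case(root, "dbt2", spec_mf)
  cs2 <- scan_case_directory(root)
  im2 <- cs2[[2]]$images[[1]]
  expect_identical(im2$modality_kind, "DBT")
  expect_identical(im2$n_slices, 40L)
  expect_equal(load_stack(im2), stk)
})

test_that("load_stack reports missing and undecodable files by name", {
  root <- withr::local_tempdir()
  write_phantom_case(root, "c1", phantom_spec(rows = 32, cols = 32, seed = 2))
  cs <- scan_case_directory(root)[[1]]
  im <- cs$images[[1]]
  stk <- load_stack(im)
  expect_identical(dim(stk)[1], 1L)
  im$file_paths <- file.path(root, "gone.dcm")
  expect_error(load_stack(im), "gone.dcm")
})

test_that("verify_unmodified detects byte-level tampering", {
  root <- withr::local_tempdir()
  write_phantom_case(root, "c1", phantom_spec(rows = 32, cols = 32, seed = 3))
  cs <- scan_case_directory(root)[[1]]
  expect_true(verify_unmodified(cs))
  f <- names(cs$checksum_manifest)[1]
  con <- file(f, "ab"); writeBin(as.raw(7L), con); close(con)
  ok <- verify_unmodified(cs)
  expect_false(ok)
  expect_identical(attr(ok, "changed"), f)
  # missing file reported too
  file.remove(f)
  ok2 <- verify_unmodified(cs)
  expect_false(ok2)
  expect_identical(attr(ok2, "missing"), f)
})

test_that("an annotate+export session leaves the DICOM sources untouched", {
  root <- withr::local_tempdir()
  write_phantom_case(root, "c1", phantom_spec(
    rows = 128, cols = 128, seed = 4,
    lesions = list(lesion_spec("ellipse", c(64, 64), 25))))
  cs <- scan_case_directory(root)[[1]]
  img <- load_stack(cs$images[[1]])[1, , ]
  ctr <- trace_contour(img, circle_waypoints(c(64, 64), 25, 8))
  set <- add_annotation(annotation_set("c1"), annotation(
    "c1", cs$images[[1]]$laterality, cs$images[[1]]$view, "DM", 1L,
    morphology("mass", "round", "circumscribed", "equal"), ctr,
    created_utc = "2026-01-01T00:00:00Z"))
  save_annotations(set, cs$case_dir)
  export_annotations(set, "csv", file.path(root, "out"), case = cs)
  export_annotations(set, "mask", file.path(root, "out"), case = cs)
  export_annotations(set, "text", file.path(root, "out"), case = cs)
  expect_true(verify_unmodified(cs))
})
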