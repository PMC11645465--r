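test_that("a written phantom round-trips through read_rtstruct", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(phantom_spec(), dir)
  expect_length(files$ct, 30L)
  loaded <- read_rtstruct(files$rtstruct, dir)
  expect_s3_class(loaded$document, "rtstruct_doc")
  expect_equal(loaded$grid$slice_count, 30L)
  expect_equal(loaded$grid$spacing, 2.5)
  expect_equal(contoured_slices(loaded$document$structures[[1]]), 10:20)
})

test_that("write-then-read reproduces contour data numerically", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(two_structure_spec(), dir)
  first <- read_rtstruct(files$rtstruct, dir)
  out <- file.path(dir, "rewritten.dcm")
  write_rtstruct(first$document, out, grid = first$grid)
  second <- read_rtstruct(out, dir)

  expect_equal(length(second$document$structures),
               length(first$document$structures))
  for (i in seq_along(first$document$structures)) {
    expect_equal(contour_points(second$document$structures[[i]]),
                 contour_points(first$document$structures[[i]]))
  }
  # fresh instance UID, same frame of reference
  expect_false(identical(second$document$sop_instance_uid,
                         first$document$sop_instance_uid))
  expect_identical(second$document$frame_of_reference_uid,
                   first$document$frame_of_reference_uid)
})

test_that("an explicit grid spec replaces the CT series", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(phantom_spec(), dir)
  via_ct <- read_rtstruct(files$rtstruct, dir)
  via_spec <- read_rtstruct(files$rtstruct, "30:0:2.5")
  expect_equal(contoured_slices(via_spec$document$structures[[1]]),
               contoured_slices(via_ct$document$structures[[1]]))
  via_obj <- read_rtstruct(files$rtstruct, grid_from_spec(30, 0, 2.5))
  expect_equal(contoured_slices(via_obj$document$structures[[1]]), 10:20)
})

test_that("non-RTSTRUCT input and bad paths are rejected with context", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(phantom_spec(), dir)
  expect_error(read_rtstruct(files$ct[1], dir), "not an RT Structure Set")
  txt <- file.path(dir, "notdicom.dcm")
  writeLines("hello", txt)
  expect_error(read_rtstruct(txt, dir), "not a DICOM")
  expect_error(read_rtstruct(file.path(dir, "absent.dcm"), dir),
               "no such file")
})

test_that("a contour z midway between slices is an ambiguity error", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(phantom_spec(), dir)
  # shift the grid by half a spacing: every contour z is now exactly midway
  expect_error(read_rtstruct(files$rtstruct, "30:1.25:2.5"),
               "ambiguous")
})

test_that("list_structures reports one ordered row per ROI", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(two_structure_spec(), dir)
  loaded <- read_rtstruct(files$rtstruct, dir)
  tab <- list_structures(loaded$document)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$name, c("PTV", "Heart"))
  expect_equal(tab$roi_number, c(1L, 2L))
  expect_equal(tab$n_slices, c(11L, 5L))

  empty <- loaded$document
  empty$structures <- list()
  expect_equal(nrow(list_structures(empty)), 0L)

  # a structure holding only a point contour lists zero contoured slices
  pt_doc <- loaded$document
  pt_doc$structures <- list(rt_structure(9L, "Marker", list(
    planar_contour(matrix(c(0, 0, 10), nrow = 1), geometric_type = "point")
  )))
  tab2 <- list_structures(pt_doc)
  expect_equal(tab2$n_contours, 1L)
  expect_equal(tab2$n_slices, 0L)
})

test_that("editing one structure conserves the other byte-for-byte", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(two_structure_spec(), dir)
  loaded <- read_rtstruct(files$rtstruct, dir)
  heart_strings_before <- vapply(
    loaded$document$structures[[2]]$contours,
    function(ct) ct$data_string, character(1))

  res <- deinterpolate_rtstruct(loaded$document, "PTV",
                                deinterp_params("keep", 3), loaded$grid)
  out <- file.path(dir, "edited.dcm")
  write_rtstruct(res$document, out, grid = loaded$grid)
  back <- read_rtstruct(out, dir)

  heart_after <- back$document$structures[[2]]
  expect_equal(heart_after$name, "Heart")
  heart_strings_after <- vapply(heart_after$contours,
                                function(ct) ct$data_string, character(1))
  expect_identical(heart_strings_after, heart_strings_before)
  expect_equal(contoured_slices(back$document$structures[[1]]),
               c(10L, 11L, 13L, 14L, 16L, 17L, 19L, 20L))
})

test_that("selection validation names the available structures", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(two_structure_spec(), dir)
  loaded <- read_rtstruct(files$rtstruct, dir)
  expect_error(
    deinterpolate_rtstruct(loaded$document, "Nonexistent",
                           deinterp_params("keep", 3)),
    "PTV, Heart")
  expect_error(
    deinterpolate_rtstruct(loaded$document, 99L,
                           deinterp_params("keep", 3)),
    "available: 1, 2")
})

test_that("writing to an unwritable path names the path", {
  ph <- generate_phantom(phantom_spec())
  bad <- file.path(tempdir(), "no_such_dir_xyz", "out.dcm")
  expect_error(write_rtstruct(ph$document, bad), "no_such_dir_xyz")
})

test_that("written files are readable by an independent DICOM implementation", {
  dir <- withr::local_tempdir()
  files <- write_phantom_series(two_structure_spec(), dir)
  script <- paste(
    "import pydicom, json, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "rois = {str(r.ReferencedROINumber): len(r.ContourSequence)",
    "        for r in ds.ROIContourSequence}",
    "names = [str(r.ROIName) for r in ds.StructureSetROISequence]",
    "c0 = ds.ROIContourSequence[0].ContourSequence[0]",
    "print(json.dumps({'modality': str(ds.Modality), 'names': names,",
    "  'rois': rois, 'z': float(c0.ContourData[2]),",
    "  'npts': int(c0.NumberOfContourPoints)}))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(files$rtstruct)),
                 stdout = TRUE, stderr = FALSE)
  info <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(info$modality, "RTSTRUCT")
  expect_setequal(info$names, c("PTV", "Heart"))
  expect_equal(info$rois[["1"]], 11L)   # PTV: slices 10..20
  expect_equal(info$rois[["2"]], 5L)    # Heart: slices 5..9
  expect_equal(info$z, 22.5)            # slice 10 at z = 9 * 2.5
  expect_equal(info$npts, 24L)
})
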