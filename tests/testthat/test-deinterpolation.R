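test_that("find_start_layer returns the lowest contoured slice", {
  expect_equal(find_start_layer(10:20), 10L)
  expect_equal(find_start_layer(integer()), NA_integer_)
  expect_equal(find_start_layer(c(7L, 3L, 12L)), 3L)
})

test_that("positional_offset is slice minus start plus one", {
  expect_equal(positional_offset(11, 10), 2L)
  expect_equal(positional_offset(10, 10), 1L)
  expect_equal(positional_offset(15, 10), 6L)
  expect_equal(positional_offset(10:20, 10), 1:11)
  expect_error(positional_offset(9, 10), "before the starting layer")
})

test_that("plan_clearing reproduces the canonical keep/erase patterns", {
  keep3 <- plan_clearing(10:20, deinterp_params("keep", 3))
  expect_equal(keep3$start_layer, 10L)
  expect_equal(keep3$to_clear, c(12L, 15L, 18L))
  expect_equal(keep3$kept, c(10L, 11L, 13L, 14L, 16L, 17L, 19L, 20L))

  erase3 <- plan_clearing(10:20, deinterp_params("erase", 3))
  expect_equal(erase3$to_clear, c(10L, 11L, 13L, 14L, 16L, 17L, 19L, 20L))
  expect_equal(erase3$kept, c(12L, 15L, 18L))

  # preserve_first shifts the erase pattern's phase to keep the start layer
  erase3p <- plan_clearing(10:20,
                           deinterp_params("erase", 3, preserve_first = TRUE))
  expect_equal(erase3p$kept, c(10L, 13L, 16L, 19L))
  expect_equal(erase3p$to_clear, c(11L, 12L, 14L, 15L, 17L, 18L, 20L))

  # empty structure: empty plan, not an error
  empty <- plan_clearing(integer(), deinterp_params("keep", 3))
  expect_equal(empty$to_clear, integer())
  expect_true(is.na(empty$start_layer))
})

test_that("offsets follow slice numbers, not ordinal position, across gaps", {
  gapped <- plan_clearing(c(10L, 12L, 14L), deinterp_params("keep", 3))
  expect_equal(gapped$to_clear, 12L)  # k(12)=3; k(14)=5 is not divisible
  expect_equal(gapped$kept, c(10L, 14L))
})

test_that("layer_range restricts clearing but not start-layer detection", {
  p <- deinterp_params("keep", 3, layer_range = c(13L, 20L))
  plan <- plan_clearing(10:20, p)
  expect_equal(plan$start_layer, 10L)      # detected on the full set
  expect_equal(plan$to_clear, c(15L, 18L)) # 12 lies outside the range
  expect_true(all(c(10:12) %in% plan$kept))
})

test_that("preserve_first changes nothing in keep mode", {
  a <- plan_clearing(10:20, deinterp_params("keep", 4))
  b <- plan_clearing(10:20, deinterp_params("keep", 4, preserve_first = TRUE))
  expect_equal(a$to_clear, b$to_clear)
  # and the start layer is never cleared in keep mode
  expect_false(10L %in% a$to_clear)
})

test_that("apply_plan removes exactly the planned contours", {
  s <- make_structure(10:20)
  plan <- plan_clearing(contoured_slices(s), deinterp_params("keep", 3),
                        roi_number = s$roi_number)
  res <- apply_plan(s, plan, deinterp_params("keep", 3))
  expect_equal(contoured_slices(res$structure),
               c(10L, 11L, 13L, 14L, 16L, 17L, 19L, 20L))
  expect_equal(res$entry$contours_removed, 3L)
  expect_equal(res$entry$start_layer, 10L)

  # survivors are unchanged point for point
  kept_orig <- Filter(function(ct) !(ct$slice_number %in% plan$to_clear),
                      s$contours)
  expect_equal(contour_points(res$structure),
               lapply(kept_orig, function(ct) ct$points))

  # an empty plan leaves the structure untouched
  empty <- plan_clearing(integer(), deinterp_params("keep", 3))
  res0 <- apply_plan(s, empty, deinterp_params("keep", 3))
  expect_equal(length(res0$structure$contours), length(s$contours))
  expect_equal(res0$entry$contours_removed, 0L)

  # every polygon on a cleared slice is removed
  multi <- make_structure(10:12, polys_per_slice = 2L)
  plan12 <- plan_clearing(contoured_slices(multi), deinterp_params("keep", 3))
  expect_equal(plan12$to_clear, 12L)
  resm <- apply_plan(multi, plan12, deinterp_params("keep", 3))
  expect_equal(resm$entry$contours_removed, 2L)
  expect_false(12L %in% contoured_slices(resm$structure))
})

test_that("deinterpolate processes structures independently", {
  s1 <- make_structure(10:20, roi = 1L, name = "PTV")
  s2 <- make_structure(5:9, roi = 2L, name = "Heart")
  res <- deinterpolate(list(s1, s2), deinterp_params("keep", 2))
  e <- res$report$entries
  expect_equal(e[[1]]$start_layer, 10L)
  expect_equal(e[[2]]$start_layer, 5L)
  expect_equal(e[[1]]$cleared, c(11L, 13L, 15L, 17L, 19L))
  expect_equal(e[[2]]$cleared, c(6L, 8L))
})

test_that("copy_before_edit leaves the original untouched and edits a copy", {
  s <- make_structure(10:20, roi = 3L, name = "Heart")
  res <- deinterpolate(list(s), deinterp_params("keep", 3,
                                                copy_before_edit = TRUE))
  expect_equal(length(res$structures), 2L)
  names_out <- vapply(res$structures, function(x) x$name, character(1))
  expect_setequal(names_out, c("Heart", "Heart_edit"))
  orig <- res$structures[[which(names_out == "Heart")]]
  copy <- res$structures[[which(names_out == "Heart_edit")]]
  expect_equal(contour_points(orig), contour_points(s))
  expect_equal(contoured_slices(copy),
               c(10L, 11L, 13L, 14L, 16L, 17L, 19L, 20L))
  expect_false(copy$roi_number == orig$roi_number)
})

test_that("every report entry satisfies the partition invariant", {
  set.seed(7)
  for (i in 1:25) {
    slices <- sort(sample(1:30, sample(1:15, 1)))
    s <- make_structure(slices)
    mode <- sample(c("keep", "erase"), 1)
    n <- sample(2:4, 1)
    pf <- sample(c(TRUE, FALSE), 1)
    res <- deinterpolate(list(s), deinterp_params(mode, n,
                                                  preserve_first = pf))
    e <- res$report$entries[[1]]
    expect_length(intersect(e$cleared, e$kept), 0)
    expect_equal(sort(union(e$cleared, e$kept)), slices)
  }
})

test_that("plans agree with the positional walking oracle on random sets", {
  set.seed(99)
  for (i in 1:60) {
    slices <- sort(sample(1:40, sample(1:20, 1)))
    n <- sample(2:4, 1)
    mode <- sample(c("keep", "erase"), 1)
    pf <- mode == "erase" && sample(c(TRUE, FALSE), 1)
    plan <- plan_clearing(slices, deinterp_params(mode, n,
                                                  preserve_first = pf))
    expect_equal(plan$to_clear, oracle_cleared(slices, mode, n, pf),
                 info = sprintf("mode=%s n=%d pf=%s slices=%s", mode, n, pf,
                                paste(slices, collapse = ",")))
  }
})

test_that("planning is deterministic", {
  p <- deinterp_params("erase", 4, preserve_first = TRUE)
  a <- plan_clearing(c(3:8, 15:22), p)
  b <- plan_clearing(c(3:8, 15:22), p)
  expect_identical(a, b)
})
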