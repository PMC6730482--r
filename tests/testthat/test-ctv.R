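# Small CTV fixture: line phantom WMPL plus box GTV and a generous brain.
ctv_fixture <- function(seed = 1) {
  ph <- line_phantom(seed = seed, jitter_sd = 0.3)
  a <- identity_affine_for(ph)
  w <- suppressMessages(path_length(densify(ph$streamlines, 0.5),
                                    ph$rois$GTV, a))
  brain_vals <- array(TRUE, ph$fa$dims)
  brain <- roi_mask(volume_grid(brain_vals, ph$fa$voxel_sizes), role = "brain")
  list(ph = ph, w = w, gtv = ph$rois$GTV, brain = brain)
}

test_that("EPL thresholding keeps visited voxels up to the threshold", {
  fx <- ctv_fixture()
  m <- threshold_wmpl(fx$w, 10)
  v <- fx$w$values
  expect_identical(m$values, array(v != -1 & v <= 10, dim = fx$w$dims))
  # all-fill map -> empty mask
  allfill <- fx$w
  allfill$values[] <- -1
  expect_identical(sum(threshold_wmpl(allfill, 10)$values), 0L)
  # monotone in epl
  m2 <- threshold_wmpl(fx$w, 14)
  expect_true(all(m2$values[m$values]))
})

test_that("metric dilation matches the brute-force distance definition", {
  # anisotropic voxels as in a typical DW-MRI acquisition
  dims <- c(12, 10, 8)
  vs <- c(1.09, 1.09, 2)
  set.seed(7)
  src <- array(FALSE, dims)
  src[sample(prod(dims), 6)] <- TRUE
  mask <- roi_mask(volume_grid(src, vs))
  r <- 3.2
  dil <- dilate_mask(mask, r)
  bf <- brute_force_min_dist(mask)
  expect_identical(dil$values, array(bf <= r + 1e-9, dim = dims))
  # squared EDT itself agrees
  d2 <- distance_transform_sq(mask)
  expect_equal(sqrt(d2), bf, tolerance = 1e-9)
})

test_that("anisotropic CTV = dilated union clipped to brain, GTV always inside", {
  fx <- ctv_fixture()
  ctv <- build_anisotropic_ctv(fx$w, fx$gtv, fx$brain, epl = 10, r = 5)
  inside_brain_gtv <- fx$gtv$values & fx$brain$values
  expect_true(all(ctv$values[inside_brain_gtv]))
  # empty WMPL reduces to a pure GTV dilation; count checked by brute force
  allfill <- fx$w
  allfill$values[] <- -1
  pure <- build_anisotropic_ctv(allfill, fx$gtv, fx$brain, epl = 10, r = 5)
  bf <- brute_force_min_dist(fx$gtv)
  expect_identical(sum(pure$values), sum(bf <= 5 + 1e-9))
  # brain mask equal to GTV clips the output to the GTV itself
  clipped <- build_anisotropic_ctv(fx$w, fx$gtv, fx$gtv, epl = 10, r = 5)
  expect_identical(clipped$values, fx$gtv$values)
  # empty GTV errors
  empty <- fx$gtv
  empty$values[] <- FALSE
  expect_error(build_anisotropic_ctv(fx$w, empty, fx$brain, 10), "empty")
})

test_that("the default configuration emits 3 anisotropic masks + 1 control, nested", {
  fx <- ctv_fixture()
  ctvs <- build_ctv_set(fx$w, fx$gtv, fx$brain)
  expect_length(ctvs$anisotropic, 3L)
  expect_named(ctvs$anisotropic, c("epl_10mm", "epl_20mm", "epl_30mm"))
  expect_s3_class(ctvs$isotropic, "volume_grid")
  n1 <- ctvs$anisotropic[[1]]$values
  n2 <- ctvs$anisotropic[[2]]$values
  n3 <- ctvs$anisotropic[[3]]$values
  expect_true(all(n2[n1]))
  expect_true(all(n3[n2]))
  gb <- fx$gtv$values & fx$brain$values
  for (m in c(ctvs$anisotropic, list(ctvs$isotropic)))
    expect_true(all(m$values[gb]))
})

test_that("isotropic control: margin 0 clips to brain; ball count is exact", {
  dims <- c(45, 45, 45)
  vs <- c(1, 1, 1)
  gtv_vals <- array(FALSE, dims)
  gtv_vals[23, 23, 23] <- TRUE
  gtv <- roi_mask(volume_grid(gtv_vals, vs), role = "GTV")
  brain <- roi_mask(volume_grid(array(TRUE, dims), vs), role = "brain")
  iso <- build_isotropic_ctv(gtv, brain, margin = 20)
  # discrete ball count from the brute-force distance transform
  bf <- brute_force_min_dist(gtv)
  expect_identical(sum(iso$values), sum(bf <= 20 + 1e-9))
  expect_identical(sum(build_isotropic_ctv(gtv, brain, margin = 0)$values), 1L)
  # invariance of a symmetric GTV under 90 degree grid rotations
  rot <- aperm(iso$values, c(2, 1, 3))
  expect_identical(rot, iso$values)
})

test_that("volume comparison arithmetic and coverage behave per contract", {
  dims <- c(10, 10, 10)
  vs <- c(1, 1, 2)
  a_vals <- array(FALSE, dims); a_vals[1:5, , ] <- TRUE
  b_vals <- array(FALSE, dims); b_vals[1:10, , ] <- TRUE
  a <- roi_mask(volume_grid(a_vals, vs))
  b <- roi_mask(volume_grid(b_vals, vs))
  cmp <- compare_ctvs(a, b)
  expect_equal(cmp$percent_difference, -50)
  expect_identical(compare_ctvs(a, a)$percent_difference, 0)
  expect_true(is.na(cmp$coverage_a))

  rec_vals <- array(FALSE, dims); rec_vals[4:7, 1:2, 1:2] <- TRUE
  rec <- roi_mask(volume_grid(rec_vals, vs), role = "recurrence")
  cmp2 <- compare_ctvs(a, b, rec)
  expect_equal(cmp2$coverage_a, 0.5)
  expect_equal(cmp2$coverage_b, 1)

  # antisymmetry only up to the differing denominator
  fwd <- compare_ctvs(a, b)$percent_difference
  bwd <- compare_ctvs(b, a)$percent_difference
  expect_equal(bwd, -fwd * mask_volume(b) / mask_volume(a))
})

test_that("recurrence along the bundle favors the anisotropic expansion", {
  # recurrence planted beyond the isotropic margin but within the bundle's
  # path length: the anisotropic CTV reaches it, the control cannot
  dims <- c(60, 21, 21)
  vs <- c(1, 1, 1)
  hdr <- streamline_header(dims, vs, "RAS")
  xs <- seq(2.5, 57.5, by = 0.5)
  s <- streamline_set(list(cbind(xs, 10.5, 10.5)), hdr)
  gtv_vals <- array(FALSE, dims); gtv_vals[3:8, 9:13, 9:13] <- TRUE
  gtv <- roi_mask(volume_grid(gtv_vals, vs), role = "GTV")
  brain <- roi_mask(volume_grid(array(TRUE, dims), vs), role = "brain")
  a <- reconcile_affine(hdr, gtv)
  w <- path_length(s, gtv, a)
  ctvs <- build_ctv_set(w, gtv, brain,
                        expansion_config(epl_list = c(10, 20, 30)))
  rec_vals <- array(FALSE, dims); rec_vals[34:38, 10:12, 10:12] <- TRUE
  rec <- roi_mask(volume_grid(rec_vals, vs), role = "recurrence")
  cmp <- compare_ctvs(ctvs$anisotropic$epl_30mm, ctvs$isotropic, rec)
  expect_gte(cmp$coverage_a, cmp$coverage_b)
  expect_equal(cmp$coverage_a, 1)
  expect_lt(cmp$coverage_b, 1)
})

test_that("expansion configuration is validated", {
  expect_error(expansion_config(epl_list = c(20, 10)), "increasing")
  expect_error(expansion_config(expansion_radius = 0), "expansion_radius")
  expect_error(expansion_config(isotropic_margin = -1), "isotropic_margin")
})
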