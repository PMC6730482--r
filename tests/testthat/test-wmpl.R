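# Hand-built straight-line case with arithmetic ground truth: vertices every
# 1 mm along +x on a 1 mm grid, first vertices inside a low-x box ROI.
straight_case <- function() {
  dims <- c(25, 7, 7)
  hdr <- streamline_header(dims, c(1, 1, 1), "RAS")
  xs <- seq(1.5, 21.5, by = 1)  # 21 vertices, voxels x = 1..21
  s <- streamline_set(list(cbind(xs, 3.5, 3.5)), hdr)
  roi_vals <- array(FALSE, dims)
  roi_vals[1:4, , ] <- TRUE     # voxels x = 0..3 -> vertices 1..3 interior
  roi <- roi_mask(volume_grid(roi_vals, c(1, 1, 1)), role = "GTV")
  a <- reconcile_affine(hdr, roi)
  list(s = s, roi = roi, a = a)
}

test_that("straight streamline distances count segments past the ROI", {
  cs <- straight_case()
  w <- path_length(cs$s, cs$roi, cs$a)
  # last interior vertex at x = 3.5 (voxel 3); vertex 10 segments later sits
  # at x = 13.5, voxel 13, and must read exactly 10 mm
  expect_identical(w$values[14, 4, 4], 10)
  # every ROI-interior vertex's voxel reads 0
  expect_identical(unname(w$values[cbind(2:4, 4, 4)]), rep(0, 3))
  # untouched voxel -> fill (-1 by default)
  expect_identical(w$values[1, 1, 1], -1)
  expect_identical(attr(w, "fill"), -1)
})

test_that("a streamline entering the ROI mid-course is symmetric", {
  dims <- c(31, 7, 7)
  hdr <- streamline_header(dims, c(1, 1, 1), "RAS")
  xs <- seq(5.5, 25.5, by = 1)  # 21 vertices; middle vertex at x = 15.5
  s <- streamline_set(list(cbind(xs, 3.5, 3.5)), hdr)
  roi_vals <- array(FALSE, dims)
  roi_vals[16, 4, 4] <- TRUE    # only the middle vertex's voxel
  roi <- roi_mask(volume_grid(roi_vals, c(1, 1, 1)), role = "GTV")
  a <- reconcile_affine(hdr, roi)
  w <- path_length(s, roi, a)
  for (d in 1:10) {
    expect_identical(w$values[16 + d, 4, 4], as.numeric(d))
    expect_identical(w$values[16 - d, 4, 4], as.numeric(d))
  }
  # oracle agrees on the 21-vertex fixture
  wo <- path_length_oracle(s, roi, a)
  expect_identical(w$values, wo$values)
})

test_that("empty inputs behave per contract", {
  cs <- straight_case()
  empty_roi <- cs$roi
  empty_roi$values[] <- FALSE
  expect_error(path_length(cs$s, empty_roi, cs$a), "empty")
  expect_error(path_length_oracle(cs$s, empty_roi, cs$a), "empty")

  empty_s <- streamline_set(list(), cs$s$header)
  expect_warning(w <- path_length(empty_s, cs$roi, cs$a), "empty streamline")
  expect_true(all(w$values == -1))
})

test_that("streamlines missing the ROI deposit nothing and are counted", {
  dims <- c(20, 9, 9)
  hdr <- streamline_header(dims, c(1, 1, 1), "RAS")
  s <- streamline_set(list(cbind(seq(1.5, 18.5, 1), 2.5, 2.5),
                           cbind(seq(1.5, 18.5, 1), 6.5, 6.5)), hdr)
  roi_vals <- array(FALSE, dims)
  roi_vals[1:3, 1:4, 1:4] <- TRUE  # touches only the first line
  roi <- roi_mask(volume_grid(roi_vals, c(1, 1, 1)), role = "GTV")
  a <- reconcile_affine(hdr, roi)
  expect_message(w <- path_length(s, roi, a), "never touched")
  expect_true(all(w$values[, 7, 7] == -1))
  expect_identical(attr(w, "n_skipped"), 1L)
})

test_that("path_length equals the brute-force oracle on random phantoms", {
  for (seed in 1:12) {
    ph <- random_phantom(seed)
    a <- identity_affine_for(ph)
    w <- suppressMessages(path_length(ph$streamlines, ph$rois$GTV, a))
    wo <- suppressMessages(path_length_oracle(ph$streamlines, ph$rois$GTV, a))
    expect_identical(w$values, wo$values)
  }
})

test_that("union of streamline sets gives the pointwise-min map", {
  ph <- line_phantom(seed = 9, n_streamlines = 4, jitter_sd = 0.6)
  a <- identity_affine_for(ph)
  s <- ph$streamlines
  s1 <- s; s1$polylines <- s$polylines[1:2]
  s2 <- s; s2$polylines <- s$polylines[3:4]
  w <- suppressMessages(path_length(s, ph$rois$GTV, a))
  w1 <- suppressMessages(path_length(s1, ph$rois$GTV, a))
  w2 <- suppressMessages(path_length(s2, ph$rois$GTV, a))
  lift <- function(v) ifelse(v == -1, Inf, v)
  merged <- pmin(lift(w1$values), lift(w2$values))
  merged[is.infinite(merged)] <- -1
  expect_identical(w$values, array(merged, dim = w$dims))
})

test_that("uniform scaling by 2 scales every non-fill value exactly", {
  ph <- line_phantom(seed = 13, jitter_sd = 0.4)
  a <- identity_affine_for(ph)
  w <- suppressMessages(path_length(ph$streamlines, ph$rois$GTV, a))

  s2 <- ph$streamlines
  s2$polylines <- lapply(s2$polylines, function(p) 2 * p)
  s2$header$voxel_sizes <- 2 * s2$header$voxel_sizes
  roi2 <- ph$rois$GTV
  roi2$voxel_sizes <- 2 * roi2$voxel_sizes
  roi2$affine[1:3, ] <- 2 * roi2$affine[1:3, ]
  a2 <- reconcile_affine(s2$header, roi2)
  w2 <- suppressMessages(path_length(s2, roi2, a2))
  expected <- w$values
  expected[expected != -1] <- 2 * expected[expected != -1]
  expect_identical(w2$values, expected)
})

test_that("reversing every polyline leaves the map unchanged", {
  ph <- line_phantom(seed = 17, jitter_sd = 0.5)
  a <- identity_affine_for(ph)
  w <- suppressMessages(path_length(ph$streamlines, ph$rois$GTV, a))
  sr <- ph$streamlines
  sr$polylines <- lapply(sr$polylines, function(p) p[nrow(p):1, , drop = FALSE])
  wr <- suppressMessages(path_length(sr, ph$rois$GTV, a))
  expect_equal(wr$values, w$values, tolerance = 1e-9)
})

test_that("no value exceeds the longest streamline and fill/zero invariants hold", {
  for (seed in c(2, 21)) {
    ph <- random_phantom(seed)
    a <- identity_affine_for(ph)
    w <- suppressMessages(path_length(ph$streamlines, ph$rois$GTV, a))
    v <- w$values
    expect_true(all(v == -1 | v >= 0))
    expect_lte(max(v), max(streamline_lengths(ph$streamlines)))
  }
})

test_that("densify preserves arc length and honors max_step", {
  ph <- line_phantom(seed = 23, jitter_sd = 0.3)
  s <- ph$streamlines
  before <- streamline_lengths(s)
  d <- densify(s, 0.3)
  after <- streamline_lengths(d)
  expect_equal(after, before, tolerance = 1e-9)
  max_seg <- max(vapply(d$polylines, function(p)
    max(sqrt(rowSums(diff(p)^2))), numeric(1)))
  expect_lte(max_seg, 0.3 + 1e-12)

  # max_step >= longest segment leaves the set unchanged
  expect_identical(densify(s, 10)$polylines, s$polylines)

  # a single 10 mm segment at 1 mm max_step -> 11 vertices, length kept
  hdr <- streamline_header(c(20, 5, 5), c(1, 1, 1), "RAS")
  one <- streamline_set(list(rbind(c(1, 2.5, 2.5), c(11, 2.5, 2.5))), hdr)
  d1 <- densify(one, 1)
  expect_identical(nrow(d1$polylines[[1]]), 11L)
  expect_equal(streamline_lengths(d1), 10, tolerance = 1e-12)
})

test_that("wmpl NIfTI export round-trips with its sidecar", {
  ph <- line_phantom(seed = 29, jitter_sd = 0)
  a <- identity_affine_for(ph)
  w <- suppressMessages(path_length(ph$streamlines, ph$rois$GTV, a))
  f <- tempfile(fileext = ".nii.gz")
  write_wmpl(w, f)
  got <- read_volume(f)
  expect_equal(got$values, w$values, tolerance = 1e-5)
  sidecar <- jsonlite::read_json(sub("\\.nii\\.gz$", ".json", f))
  expect_identical(sidecar$fill, -1L)
  expect_identical(sidecar$n_visited, sum(w$values != -1))
})
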