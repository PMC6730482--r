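# Shared fixture builders. Everything is generated in code at test time;
# ground truths come from closed forms or the brute-force oracle, never from
# the module under test.

# A small line-bundle phantom crossing a box GTV at the low-x end.
line_phantom <- function(seed = 1, n_streamlines = 3, jitter_sd = 0.3,
                         voxel_sizes = c(1, 1, 1)) {
  dims <- c(20, 12, 12)
  ext <- dims * voxel_sizes
  spec <- phantom_spec(
    dims = dims, voxel_sizes = voxel_sizes,
    bundles = list(list(kind = "line",
                        start = c(0.08 * ext[1], ext[2] / 2, ext[3] / 2),
                        end = c(0.92 * ext[1], ext[2] / 2, ext[3] / 2),
                        n_streamlines = n_streamlines,
                        spacing = min(voxel_sizes),
                        jitter_sd = jitter_sd)),
    rois = list(list(shape = "box", min = c(0, 0, 0),
                     max = c(0.2 * ext[1], ext[2], ext[3]), role = "GTV")),
    seed = seed)
  make_phantom(spec)
}

# Randomized mixed phantom for oracle-equivalence sweeps: line or arc
# bundles, jitter on or off, anisotropic voxels, sphere or box ROI.
random_phantom <- function(seed) {
  set.seed(seed)
  vs <- round(runif(3, 0.8, 2.2), 2)
  dims <- sample(10:14, 3, replace = TRUE)
  ext <- dims * vs
  margin <- 0.1 * ext
  kind <- sample(c("line", "arc"), 1)
  jitter <- sample(c(0, 0.25), 1)
  spacing <- round(min(vs) * runif(1, 0.5, 1), 2)
  if (kind == "line") {
    start <- margin + runif(3) * 0.2 * ext
    end <- ext - margin - runif(3) * 0.2 * ext
    bundle <- list(kind = "line", start = start, end = end,
                   n_streamlines = sample(2:4, 1), spacing = spacing,
                   jitter_sd = jitter)
    roi_center <- start
  } else {
    z <- runif(1, margin[3], ext[3] - margin[3])
    ctr <- c(ext[1] / 2, ext[2] / 2, z)
    radius <- 0.5 * min(ext[1], ext[2]) - max(margin[1:2]) - 3 * jitter
    radius <- max(radius, 2)
    th0 <- runif(1, 0, pi)
    bundle <- list(kind = "arc", center = ctr, radius = radius,
                   theta_start = th0, theta_end = th0 + runif(1, 1, 2.5),
                   n_streamlines = sample(2:4, 1), spacing = spacing,
                   jitter_sd = jitter)
    roi_center <- ctr + c(radius * cos(th0), radius * sin(th0), 0)
  }
  roi <- if (runif(1) < 0.5) {
    list(shape = "sphere", center = roi_center,
         radius = max(2.5, 2 * max(vs)), role = "GTV")
  } else {
    list(shape = "box", min = roi_center - 2.5 * vs,
         max = roi_center + 2.5 * vs, role = "GTV")
  }
  spec <- phantom_spec(dims = dims, voxel_sizes = vs, bundles = list(bundle),
                       rois = list(roi), seed = seed)
  make_phantom(spec)
}

# Quarter-circle bundle (radius r) with a single-voxel ROI at the arc start;
# the far-end WMPL is analytically r * pi / 2 up to the chord deficit.
quarter_circle_phantom <- function(r = 20, spacing = 1) {
  dims <- c(2 * r + 8, r + 8, 9)
  ctr <- c(r + 4, 4, 4.5)
  start <- ctr + c(r, 0, 0)
  spec <- phantom_spec(
    dims = dims, voxel_sizes = c(1, 1, 1),
    bundles = list(list(kind = "arc", center = ctr, radius = r,
                        theta_start = 0, theta_end = pi / 2,
                        n_streamlines = 1, spacing = spacing,
                        jitter_sd = 0)),
    rois = list(list(shape = "box",
                     min = floor(start) + c(0.2, 0.2, 0) + c(0, 0, 0.2),
                     max = floor(start) + c(0.8, 0.8, 0.8), role = "GTV")),
    seed = 1)
  make_phantom(spec)
}

identity_affine_for <- function(phantom, roi = phantom$rois$GTV) {
  reconcile_affine(phantom$streamlines$header, roi)
}

# Brute-force nearest-source-center distances (mm) for every voxel of a
# grid, against the centers of a source mask. Independent of the EDT code.
brute_force_min_dist <- function(mask) {
  dims <- mask$dims
  vs <- mask$voxel_sizes
  idx <- which(array(TRUE, dim = dims), arr.ind = TRUE)
  centers <- sweep(idx - 0.5, 2, vs, "*")
  src <- which(mask$values, arr.ind = TRUE)
  stopifnot(nrow(src) > 0)
  src_centers <- sweep(src - 0.5, 2, vs, "*")
  out <- array(Inf, dim = dims)
  for (r in seq_len(nrow(src_centers))) {
    d <- sqrt((centers[, 1] - src_centers[r, 1])^2 +
              (centers[, 2] - src_centers[r, 2])^2 +
              (centers[, 3] - src_centers[r, 3])^2)
    out[idx] <- pmin(out[idx], d)
  }
  out
}

# Deterministic parallel-line streamline set (no jitter), offsets in y.
parallel_lines_set <- function(offsets_y, dims = c(30, 30, 10),
                               voxel_sizes = c(1, 1, 1),
                               x0 = 2, x1 = 28, z = 5, spacing = 1) {
  polylines <- lapply(offsets_y, function(dy) {
    xs <- seq(x0, x1, by = spacing)
    cbind(xs, rep(dy, length(xs)), rep(z, length(xs)))
  })
  hdr <- streamline_header(dims, voxel_sizes, "RAS", length(polylines))
  streamline_set(polylines, hdr)
}
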