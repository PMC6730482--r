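#' @title Minimal deterministic fiber tracker
#' @description A deterministic streamline tracker over a supplied per-voxel
#'   principal-direction field: one seed at the center of every voxel whose
#'   fractional anisotropy (FA) exceeds the seeding threshold, bidirectional
#'   fixed-step propagation along the nearest-voxel direction (sign-aligned
#'   with the incoming heading), terminating when FA drops to or below the
#'   threshold, the turning angle exceeds the maximum, the position leaves
#'   the grid, or the length cap is reached. FA and directions are looked up
#'   nearest-voxel, which keeps phantom expectations exact.
#' @name deterministic-tracker
NULL

#' Tracker configuration
#'
#' @param fa_threshold FA seeding/stopping threshold in (0, 1); default 0.15.
#' @param max_angle Maximum turning angle per step, degrees in (0, 90];
#'   default 60.
#' @param step_size Step length in mm (> 0).
#' @param seeds_per_voxel Seeds per suprathreshold voxel; only the default 1
#'   (voxel-center seeding) is supported.
#' @param max_length Per-direction length cap in mm; default 250.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(fa_threshold = 0.15, max_angle = 60,
                           step_size = 0.5, seeds_per_voxel = 1L,
                           max_length = 250) {
  if (!(fa_threshold > 0 && fa_threshold < 1))
    stop("fa_threshold must lie in (0, 1)", call. = FALSE)
  if (!(max_angle > 0 && max_angle <= 90))
    stop("max_angle must lie in (0, 90] degrees", call. = FALSE)
  if (step_size <= 0) stop("step_size must be positive", call. = FALSE)
  if (seeds_per_voxel != 1L)
    stop("only seeds_per_voxel = 1 (voxel-center seeding) is supported",
         call. = FALSE)
  if (max_length <= 0) stop("max_length must be positive", call. = FALSE)
  structure(list(fa_threshold = fa_threshold, max_angle = max_angle,
                 step_size = step_size, seeds_per_voxel = 1L,
                 max_length = max_length),
            class = "tracker_config")
}

#' Deterministic fiber tracking on a direction field
#'
#' @param fa A [volume_grid()] of FA values in `[0, 1]`.
#' @param directions 4-D array `dims x 3` of unit vectors (streamline-frame
#'   mm directions), defined wherever FA exceeds the threshold.
#' @param cfg A [tracker_config()].
#' @return A [streamline_set()] in the FA grid's voxel-mm frame (identity
#'   voxel order relative to that grid).
#' @export
track_deterministic <- function(fa, directions, cfg = tracker_config()) {
  stopifnot(inherits(fa, "volume_grid"), inherits(cfg, "tracker_config"))
  dims <- fa$dims
  if (!all(dim(directions) == c(dims, 3L)))
    stop("directions must be a dims x 3 array matching the FA grid",
         call. = FALSE)
  vs <- fa$voxel_sizes
  fav <- fa$values
  thr <- cfg$fa_threshold
  cos_max <- cos(cfg$max_angle * pi / 180)

  dir_at <- function(v) directions[v[1], v[2], v[3], ]
  vox_of <- function(p) floor(p / vs) + 1  # 1-based array index
  in_grid <- function(v) all(v >= 1) && all(v <= dims)

  walk <- function(p0, h0) {
    pts <- list()
    p <- p0
    h <- h0
    len <- 0
    repeat {
      v <- vox_of(p)
      d <- dir_at(v)
      if (sum(d * h) < 0) d <- -d
      if (sum(d * h) < cos_max) break        # turn sharper than max_angle
      pn <- p + cfg$step_size * d
      vn <- vox_of(pn)
      if (!in_grid(vn)) break                # leaves the grid
      if (fav[vn[1], vn[2], vn[3]] <= thr) break
      len <- len + cfg$step_size
      if (len > cfg$max_length) break
      pts[[length(pts) + 1L]] <- pn
      p <- pn
      h <- d
    }
    pts
  }

  seeds <- which(fav > thr, arr.ind = TRUE)
  polylines <- list()
  for (r in seq_len(nrow(seeds))) {
    v <- seeds[r, ]
    p0 <- (v - 0.5) * vs                     # voxel center, corner-origin mm
    d0 <- dir_at(v)
    if (!all(is.finite(d0)) || sum(d0^2) == 0) next
    fwd <- walk(p0, d0)
    bwd <- walk(p0, -d0)
    n <- length(fwd) + length(bwd) + 1L
    if (n < 2L) next
    pl <- matrix(0, n, 3)
    i <- 1L
    for (q in rev(bwd)) { pl[i, ] <- q; i <- i + 1L }
    pl[i, ] <- p0; i <- i + 1L
    for (q in fwd) { pl[i, ] <- q; i <- i + 1L }
    polylines[[length(polylines) + 1L]] <- pl
  }
  if (length(polylines) == 0L)
    warning("no streamlines emitted (no suprathreshold seeds or all walks ",
            "terminated immediately)", call. = FALSE)
  hdr <- streamline_header(dims = dims, voxel_sizes = vs,
                           voxel_order = fa$axis_codes,
                           n_streamlines = length(polylines))
  streamline_set(polylines, hdr)
}

#' Read a per-voxel direction field from 4-D NIfTI
#'
#' @param path Path to a 4-D NIfTI whose last axis has extent 3.
#' @return List with `field` (4-D array) and `grid` (a [volume_grid()] of
#'   the vector norms, useful for alignment checks).
#' @export
read_direction_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 4L || d[4] != 3L)
    stop("direction field must be 4-D with last axis of extent 3",
         call. = FALSE)
  vs <- as.numeric(RNifti::pixdim(img))[1:3]
  affine <- RNifti::xform(img)
  attributes(affine) <- list(dim = dim(affine))
  norms <- sqrt(arr[, , , 1]^2 + arr[, , , 2]^2 + arr[, , , 3]^2)
  grid <- volume_grid(norms, voxel_sizes = vs, affine = affine,
                      axis_codes = RNifti::orientation(img))
  list(field = arr, grid = grid)
}
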