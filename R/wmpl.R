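#' @title White-matter path-length mapping
#' @description The WMPL map assigns each voxel the shortest distance,
#'   measured as arc length along any streamline, back to a target ROI such
#'   as the gross tumor volume. Voxels never visited by a streamline vertex
#'   hold a sentinel fill value (default -1). Distances are taken to the
#'   nearest ROI-interior vertex in either direction along a polyline, and
#'   voxel visitation is vertex-based: [densify()] controls the
#'   discretization.
#' @name wmpl-core
NULL

#' Construct a path-length map container
#'
#' @param grid A [volume_grid()] carrying the WMPL values.
#' @param fill The sentinel used for unvisited voxels.
#' @param n_skipped Number of streamlines that never touched the ROI.
#' @return A `path_length_map` (subclass of `volume_grid`).
#' @export
path_length_map <- function(grid, fill = -1, n_skipped = 0L) {
  stopifnot(inherits(grid, "volume_grid"))
  v <- grid$values
  bad <- v != fill & v < 0
  if (any(bad))
    stop("path-length values must be >= 0 or equal to the fill value",
         call. = FALSE)
  attr(grid, "fill") <- fill
  attr(grid, "n_skipped") <- as.integer(n_skipped)
  class(grid) <- unique(c("path_length_map", class(grid)))
  grid
}

#' @export
print.path_length_map <- function(x, ...) {
  fill <- attr(x, "fill")
  vis <- x$values != fill
  cat(sprintf(
    "<path_length_map> %d x %d x %d voxels, %d visited, fill = %g\n",
    x$dims[1], x$dims[2], x$dims[3], sum(vis), fill))
  if (any(vis))
    cat(sprintf("  WMPL range %.3f - %.3f mm\n",
                min(x$values[vis]), max(x$values[vis])))
  invisible(x)
}

# Cumulative arc length by sequential double-precision accumulation.
# (Base cumsum accumulates in long double; a plain sequential fold keeps the
# partial sums reproducible by any straightforward reimplementation.)
cumulative_length <- function(p) {
  seg <- sqrt(rowSums(diff(p)^2))
  c(0, Reduce(`+`, seg, accumulate = TRUE))
}

# Distance from each x to the nearest element of the sorted vector s.
nearest_distance <- function(x, s) {
  i <- findInterval(x, s)
  n <- length(s)
  lo <- ifelse(i >= 1L, s[pmax(i, 1L)], NA_real_)
  hi <- ifelse(i < n, s[pmin(i + 1L, n)], NA_real_)
  pmin(abs(x - lo), abs(x - hi), na.rm = TRUE)
}

#' Compute a white-matter path-length map
#'
#' For each streamline, vertices are classified ROI-interior or not by voxel
#' membership ([point_to_voxel()]); each vertex's path distance is the
#' minimum over ROI-interior vertices of the absolute difference in
#' cumulative arc length (so distance is measured along the polyline, in
#' either direction); each vertex deposits its distance into the voxel it
#' occupies and the map keeps the minimum deposit per voxel. Streamlines
#' with no ROI-interior vertex contribute nothing and are counted.
#'
#' @param s A [streamline_set()].
#' @param roi A nonempty [roi_mask()] on the output grid.
#' @param a The `tract_affine` reconciling `s` with `roi`'s grid
#'   (from [reconcile_affine()]).
#' @param fill Sentinel value for voxels no streamline vertex visits
#'   (default -1).
#' @return A [path_length_map()] on `roi`'s grid.
#' @seealso [path_length_oracle()] for the brute-force reference,
#'   [densify()] for controlling vertex-based voxel visitation.
#' @export
path_length <- function(s, roi, a, fill = -1) {
  stopifnot(inherits(s, "streamline_set"), inherits(roi, "roi_mask"),
            inherits(a, "tract_affine"))
  if (is_empty_mask(roi)) stop("target ROI is empty", call. = FALSE)
  dims <- roi$dims
  if (length(s$polylines) == 0L)
    warning("empty streamline set: returning an all-fill map", call. = FALSE)

  best <- array(Inf, dim = dims)
  roi_arr <- roi$values
  n_skipped <- 0L
  for (p in s$polylines) {
    v <- point_to_voxel(p, a)
    inb <- !is.na(v[, 1])
    interior <- rep(FALSE, nrow(p))
    if (any(inb))
      interior[inb] <- roi_arr[v[inb, , drop = FALSE] + 1L]
    if (!any(interior)) {
      n_skipped <- n_skipped + 1L
      next
    }
    cl <- cumulative_length(p)
    d <- nearest_distance(cl, cl[interior])
    lin <- 1L + v[inb, 1] + dims[1] * (v[inb, 2] + dims[2] * v[inb, 3])
    dmin <- tapply(d[inb], lin, min)
    idx <- as.integer(names(dmin))
    best[idx] <- pmin(best[idx], as.numeric(dmin))
  }
  if (n_skipped > 0L)
    message(n_skipped, " streamline(s) never touched the ROI")
  out <- array(fill, dim = dims)
  vis <- is.finite(best)
  out[vis] <- best[vis]
  grid <- roi
  grid$values <- out
  class(grid) <- "volume_grid"
  attr(grid, "role") <- NULL
  path_length_map(grid, fill = fill, n_skipped = n_skipped)
}

#' Brute-force path-length oracle
#'
#' Independent reference implementation of [path_length()] by exhaustive
#' per-vertex-pair enumeration with explicit loops and no shared code with
#' the production path. Intended for verification; quadratic in vertices per
#' streamline.
#'
#' @inheritParams path_length
#' @return A [path_length_map()].
#' @export
path_length_oracle <- function(s, roi, a, fill = -1) {
  stopifnot(inherits(s, "streamline_set"), inherits(roi, "roi_mask"),
            inherits(a, "tract_affine"))
  if (sum(roi$values) == 0) stop("target ROI is empty", call. = FALSE)
  dims <- roi$dims
  out <- array(fill, dim = dims)
  if (length(s$polylines) == 0L)
    warning("empty streamline set: returning an all-fill map", call. = FALSE)

  vox_of <- function(pt) {
    v <- integer(3)
    for (ax in 1:3) {
      u <- floor(pt[ax] / a$voxel_sizes[ax])
      g <- a$perm[ax]
      v[g] <- if (a$signs[ax] > 0) u else a$dims[g] - 1 - u
    }
    if (any(v < 0) || any(v >= dims)) NULL else as.integer(v)
  }

  for (p in s$polylines) {
    n <- nrow(p)
    cl <- numeric(n)
    for (i in seq_len(n - 1)) {
      dx <- p[i + 1, ] - p[i, ]
      cl[i + 1] <- cl[i] + sqrt(sum(dx^2))
    }
    vox <- vector("list", n)
    interior <- logical(n)
    for (k in seq_len(n)) {
      vox[[k]] <- vox_of(p[k, ])
      if (!is.null(vox[[k]]))
        interior[k] <- roi$values[vox[[k]][1] + 1, vox[[k]][2] + 1,
                                  vox[[k]][3] + 1]
    }
    if (!any(interior)) next
    for (k in seq_len(n)) {
      if (is.null(vox[[k]])) next
      d <- Inf
      for (m in seq_len(n)) {
        if (!interior[m]) next
        dm <- abs(cl[k] - cl[m])
        if (dm < d) d <- dm
      }
      vk <- vox[[k]] + 1L
      cur <- out[vk[1], vk[2], vk[3]]
      if (cur == fill || d < cur) out[vk[1], vk[2], vk[3]] <- d
    }
  }
  grid <- roi
  grid$values <- out
  class(grid) <- "volume_grid"
  attr(grid, "role") <- NULL
  path_length_map(grid, fill = fill)
}

#' Densify streamlines by linear interpolation
#'
#' Inserts vertices along any segment longer than `max_step` so that no
#' segment exceeds it; total arc length is unchanged (collinear insertion).
#' This is the documented mitigation for vertex-based voxel visitation: a
#' segment crossing a voxel with no vertex inside deposits nothing, so the
#' pipeline densifies to half the smallest voxel size by default.
#'
#' @param s A [streamline_set()].
#' @param max_step Maximum allowed segment length (mm, > 0).
#' @return A densified [streamline_set()].
#' @export
densify <- function(s, max_step) {
  stopifnot(inherits(s, "streamline_set"), max_step > 0)
  polylines <- lapply(s$polylines, function(p) {
    seg <- sqrt(rowSums(diff(p)^2))
    if (all(seg <= max_step)) return(p)
    pieces <- vector("list", length(seg))
    for (i in seq_along(seg)) {
      k <- ceiling(seg[i] / max_step)
      t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
      pieces[[i]] <- cbind(p[i, 1] + t * (p[i + 1, 1] - p[i, 1]),
                           p[i, 2] + t * (p[i + 1, 2] - p[i, 2]),
                           p[i, 3] + t * (p[i + 1, 3] - p[i, 3]))
    }
    rbind(do.call(rbind, pieces), p[nrow(p), , drop = FALSE])
  })
  out <- s
  out$polylines <- polylines
  out$header$n_streamlines <- length(polylines)
  out
}

#' Total arc length of each streamline
#'
#' @param s A [streamline_set()].
#' @return Numeric vector of lengths (mm).
#' @export
streamline_lengths <- function(s) {
  vapply(s$polylines, function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1))
}

#' Write a path-length map to NIfTI with a JSON sidecar
#'
#' The map is written as float32 in the ROI grid's frame; the fill value and
#' visitation counts go into `<path>.json` alongside.
#'
#' @param w A [path_length_map()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_wmpl <- function(w, path) {
  stopifnot(inherits(w, "path_length_map"))
  write_volume(w, path, datatype = "float")
  sidecar <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(
    list(fill = attr(w, "fill"),
         n_visited = sum(w$values != attr(w, "fill")),
         n_streamlines_skipped = attr(w, "n_skipped") %||% 0L),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
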