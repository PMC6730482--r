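#' @title Synthetic tractography phantoms
#' @description Generates streamline bundles with analytically known
#'   geometry (straight lines and circular arcs), together with an FA
#'   volume, a per-voxel principal-direction field and spherical or cuboid
#'   ROI masks, so every pipeline stage can be tested without patient data.
#'   Generation is a pure function of the spec (seed included); lateral
#'   jitter is Gaussian in the plane orthogonal to the curve tangent,
#'   truncated at 3 standard deviations so curves stay in-grid.
#' @name phantoms
NULL

#' Specify a phantom
#'
#' Bundle curves live in the grid's own TrackVis voxel-mm frame
#' (corner-origin; the grid spans `[0, dims * voxel_sizes]` mm per axis).
#'
#' @param dims Grid dimensions (3 positive integers).
#' @param voxel_sizes Voxel sizes in mm.
#' @param bundles List of bundle specs. A line bundle:
#'   `list(kind = "line", start =, end =, n_streamlines =, spacing =,
#'   jitter_sd = 0)`. An arc bundle (circular, in a plane of constant z):
#'   `list(kind = "arc", center =, radius =, theta_start =, theta_end =,
#'   n_streamlines =, spacing =, jitter_sd = 0)` with angles in radians and
#'   `spacing` measured along the arc.
#' @param rois List of ROI specs: `list(shape = "sphere", center =,
#'   radius =, role =)` or `list(shape = "box", min =, max =, role =)`
#'   (world-frame mm in the grid's voxel-mm space).
#' @param seed Integer random seed recorded in the phantom.
#' @param fa_inside FA value inside bundle corridors (default 0.8).
#' @param corridor_width Corridor half-width in voxels around each curve
#'   (default 2).
#' @param axis_codes Orientation label of the phantom grid (default "RAS").
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims, voxel_sizes, bundles, rois = list(),
                         seed = 1L, fa_inside = 0.8, corridor_width = 2,
                         axis_codes = "RAS") {
  dims <- as.integer(dims)
  voxel_sizes <- as.numeric(voxel_sizes)
  stopifnot(length(dims) == 3L, all(dims > 0L),
            length(voxel_sizes) == 3L, all(voxel_sizes > 0))
  for (b in bundles) {
    if (!b$kind %in% c("line", "arc"))
      stop("bundle kind must be 'line' or 'arc'", call. = FALSE)
    if ((b$spacing %||% 1) <= 0)
      stop("bundle vertex spacing must be > 0", call. = FALSE)
  }
  structure(list(dims = dims, voxel_sizes = voxel_sizes, bundles = bundles,
                 rois = rois, seed = as.integer(seed), fa_inside = fa_inside,
                 corridor_width = corridor_width,
                 axis_codes = validate_axis_codes(axis_codes)),
            class = "phantom_spec")
}

# Sample the base curve of a bundle at its vertex spacing; returns the
# vertex matrix plus unit tangents and exact arc-length parameters.
sample_base_curve <- function(b) {
  if (b$kind == "line") {
    start <- as.numeric(b$start)
    end <- as.numeric(b$end)
    L <- sqrt(sum((end - start)^2))
    nseg <- max(1L, round(L / b$spacing))
    t <- seq(0, 1, length.out = nseg + 1L)
    pts <- cbind(start[1] + t * (end[1] - start[1]),
                 start[2] + t * (end[2] - start[2]),
                 start[3] + t * (end[3] - start[3]))
    tangent <- matrix(rep((end - start) / L, each = nrow(pts)), ncol = 3)
    list(points = pts, tangents = tangent, arclen = t * L, total = L)
  } else {
    ctr <- as.numeric(b$center)
    r <- b$radius
    span <- b$theta_end - b$theta_start
    L <- abs(span) * r
    nseg <- max(1L, round(L / b$spacing))
    th <- seq(b$theta_start, b$theta_end, length.out = nseg + 1L)
    pts <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th),
                 rep(ctr[3], nseg + 1L))
    sgn <- sign(span)
    tangent <- cbind(-sgn * sin(th), sgn * cos(th), 0)
    list(points = pts, tangents = tangent,
         arclen = abs(th - b$theta_start) * r, total = L)
  }
}

# Orthonormal basis of the plane orthogonal to each vertex tangent; for
# lines a constant pair, for planar arcs the radial direction and z.
orthogonal_frame <- function(b, base) {
  if (b$kind == "line") {
    t1 <- base$tangents[1, ]
    ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * t1) * t1
    u <- u / sqrt(sum(u^2))
    w <- c(t1[2] * u[3] - t1[3] * u[2],
           t1[3] * u[1] - t1[1] * u[3],
           t1[1] * u[2] - t1[2] * u[1])
    n <- nrow(base$points)
    list(u = matrix(rep(u, each = n), ncol = 3),
         w = matrix(rep(w, each = n), ncol = 3))
  } else {
    ctr <- as.numeric(b$center)
    radial <- sweep(base$points, 2, ctr)
    radial[, 3] <- 0
    radial <- radial / sqrt(rowSums(radial^2))
    n <- nrow(base$points)
    list(u = radial, w = matrix(rep(c(0, 0, 1), each = n), ncol = 3))
  }
}

rnorm_trunc3 <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  x <- rnorm(n, 0, sd)
  pmin(pmax(x, -3 * sd), 3 * sd)
}

#' Generate a phantom
#'
#' Deterministic given the spec's seed: the same spec yields a bit-identical
#' phantom. Each streamline of a bundle is the base curve offset by a
#' constant random vector in the plane orthogonal to the local tangent
#' (truncated Gaussian, 3 sd), so jitter-free bundles keep their analytic
#' arc lengths exactly. FA is `fa_inside` within a corridor of
#' `corridor_width` voxels around the curves and 0 elsewhere; the direction
#' field holds the unit tangent of the nearest curve vertex.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `streamlines`
#'   ([streamline_set()]), `fa` ([volume_grid()]), `directions` (4-D array),
#'   `rois` (named list of [roi_mask()]s by role), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$dims
  vs <- spec$voxel_sizes
  extent <- dims * vs

  polylines <- list()
  all_vertices <- list()
  all_tangents <- list()
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    base <- sample_base_curve(b)
    if (any(base$points < 0) || any(sweep(base$points, 2, extent) >= 0))
      stop("bundle ", bi, " exits the grid (extent ",
           paste(signif(extent, 4), collapse = " x "), " mm)", call. = FALSE)
    frame <- orthogonal_frame(b, base)
    sd <- b$jitter_sd %||% 0
    for (s in seq_len(b$n_streamlines)) {
      off <- rnorm_trunc3(2L, sd)
      p <- base$points + off[1] * frame$u + off[2] * frame$w
      polylines[[length(polylines) + 1L]] <- p
    }
    all_vertices[[bi]] <- base$points
    all_tangents[[bi]] <- base$tangents
  }

  hdr <- streamline_header(dims = dims, voxel_sizes = vs,
                           voxel_order = spec$axis_codes,
                           n_streamlines = length(polylines))
  streamlines <- streamline_set(polylines, hdr)

  # FA corridor: voxels whose center lies within corridor_width voxels
  # (in mm: corridor_width * min voxel size) of a base-curve vertex.
  seed_mask <- array(FALSE, dim = dims)
  verts <- do.call(rbind, all_vertices)
  tans <- do.call(rbind, all_tangents)
  vidx <- floor(sweep(verts, 2, vs, "/"))
  keep <- vidx[, 1] >= 0 & vidx[, 1] < dims[1] &
          vidx[, 2] >= 0 & vidx[, 2] < dims[2] &
          vidx[, 3] >= 0 & vidx[, 3] < dims[3]
  seed_mask[vidx[keep, , drop = FALSE] + 1L] <- TRUE
  seed_grid <- roi_mask(volume_grid(seed_mask, vs,
                                    axis_codes = spec$axis_codes),
                        role = "generic")
  corridor_mm <- spec$corridor_width * min(vs)
  corridor <- dilate_mask(seed_grid, corridor_mm)

  fa_vals <- array(0, dim = dims)
  fa_vals[corridor$values] <- spec$fa_inside
  fa <- volume_grid(fa_vals, vs, axis_codes = spec$axis_codes)

  # direction field: unit tangent of the nearest base-curve vertex
  directions <- array(0, dim = c(dims, 3L))
  corr_idx <- which(corridor$values, arr.ind = TRUE)
  if (nrow(corr_idx) > 0) {
    centers <- sweep(corr_idx - 0.5, 2, vs, "*")
    nearest <- vapply(seq_len(nrow(centers)), function(r) {
      d2 <- (verts[, 1] - centers[r, 1])^2 + (verts[, 2] - centers[r, 2])^2 +
            (verts[, 3] - centers[r, 3])^2
      which.min(d2)
    }, integer(1))
    for (ax in 1:3)
      directions[cbind(corr_idx, ax)] <- tans[nearest, ax]
  }

  rois <- list()
  for (rs in spec$rois) {
    role <- rs$role %||% "generic"
    mask <- array(FALSE, dim = dims)
    ctr_idx <- which(array(TRUE, dim = dims), arr.ind = TRUE)
    centers <- sweep(ctr_idx - 0.5, 2, vs, "*")
    if (rs$shape == "sphere") {
      c0 <- as.numeric(rs$center)
      d2 <- (centers[, 1] - c0[1])^2 + (centers[, 2] - c0[2])^2 +
            (centers[, 3] - c0[3])^2
      mask[ctr_idx] <- d2 <= rs$radius^2
    } else if (rs$shape == "box") {
      lo <- as.numeric(rs$min)
      hi <- as.numeric(rs$max)
      mask[ctr_idx] <- centers[, 1] >= lo[1] & centers[, 1] <= hi[1] &
                       centers[, 2] >= lo[2] & centers[, 2] <= hi[2] &
                       centers[, 3] >= lo[3] & centers[, 3] <= hi[3]
    } else stop("unknown ROI shape: ", rs$shape, call. = FALSE)
    rois[[role]] <- roi_mask(volume_grid(mask, vs,
                                         axis_codes = spec$axis_codes),
                             role = if (role %in% c("GTV", "brain",
                                                    "recurrence")) role
                                    else "generic")
  }

  structure(list(streamlines = streamlines, fa = fa, directions = directions,
                 rois = rois, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d streamlines, %d x %d x %d grid, %d ROI(s), seed %d\n",
              length(x$streamlines$polylines), x$spec$dims[1], x$spec$dims[2],
              x$spec$dims[3], length(x$rois), x$spec$seed))
  invisible(x)
}

#' Analytic WMPL expectations for a jitter-free phantom
#'
#' For bundles with zero jitter the along-curve distance from any vertex
#' back to the ROI is known in closed form (line: distance along the line;
#' arc: radius times angular offset). Returns, per visited voxel of the
#' base curves, the analytic path length to the nearest ROI-interior
#' vertex together with a stated tolerance: the vertex-spacing
#' discretization bound plus (for arcs) the chord-vs-arc deficit.
#'
#' @param spec A [phantom_spec()] whose bundles all have `jitter_sd = 0`.
#' @param roi The target [roi_mask()] (on the phantom grid).
#' @return A data frame with 0-based voxel indices `i, j, k`, the analytic
#'   `wmpl_mm`, and `tol_mm`.
#' @export
expected_wmpl <- function(spec, roi) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(roi, "roi_mask"))
  for (b in spec$bundles)
    if ((b$jitter_sd %||% 0) != 0)
      stop("analytic expectations are only defined for jitter-free bundles",
           call. = FALSE)
  vs <- spec$voxel_sizes
  dims <- spec$dims
  rows <- list()
  for (b in spec$bundles) {
    base <- sample_base_curve(b)
    vidx <- floor(sweep(base$points, 2, vs, "/"))
    inb <- vidx[, 1] >= 0 & vidx[, 1] < dims[1] &
           vidx[, 2] >= 0 & vidx[, 2] < dims[2] &
           vidx[, 3] >= 0 & vidx[, 3] < dims[3]
    interior <- rep(FALSE, nrow(vidx))
    interior[inb] <- roi$values[vidx[inb, , drop = FALSE] + 1L]
    if (!any(interior)) next
    tin <- base$arclen[interior]
    # chord-vs-arc deficit bound over the whole curve (zero for lines)
    chord_bound <- if (b$kind == "arc")
      base$total * (b$spacing^2 / (24 * b$radius^2)) else 0
    for (k in which(inb)) {
      d <- min(abs(base$arclen[k] - tin))
      rows[[length(rows) + 1L]] <-
        data.frame(i = vidx[k, 1], j = vidx[k, 2], kk = vidx[k, 3],
                   wmpl_mm = d, tol_mm = b$spacing / 2 + chord_bound)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      wmpl_mm = numeric(), tol_mm = numeric()))
  df <- do.call(rbind, rows)
  names(df) <- c("i", "j", "k", "wmpl_mm", "tol_mm")
  # several vertices can share a voxel: keep the minimum, like the map does
  agg <- stats::aggregate(cbind(wmpl_mm, tol_mm) ~ i + j + k, data = df,
                          FUN = min)
  agg[order(agg$i, agg$j, agg$k), , drop = FALSE]
}
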