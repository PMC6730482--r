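#' @title Per-slice contour extraction
#' @description Vendor-neutral substitute for treatment-planning contour
#'   transfer: each axial slice of a binary mask is traced into closed
#'   polygons running along voxel boundaries, with the mask interior on the
#'   left of each directed edge. Holes emerge as separate loops and even-odd
#'   rasterization of the polygons at voxel centers recovers the mask
#'   exactly.
#' @name slice-contours
NULL

# Trace all closed boundary loops of one binary slice. Vertices live on the
# corner lattice: corner (ci, cj) (0-based) is the lower corner of voxel
# (ci, cj), so voxel (i, j) spans corners i..i+1 x j..j+1. At checkerboard
# corners (two incoming, two outgoing edges) the sharpest left turn is taken,
# which hugs the interior region and keeps diagonally touching regions as
# separate simple loops.
trace_slice_loops <- function(m) {
  nx <- nrow(m)
  ny <- ncol(m)
  inside <- function(i, j) i >= 1 && i <= nx && j >= 1 && j <= ny && m[i, j]

  # directed edges: from-corner, to-corner (corner key = ci + (nx+1)*cj)
  from <- integer(0); to <- integer(0)
  key <- function(ci, cj) ci + (nx + 1L) * cj + 1L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!m[i, j]) next
    ci <- i - 1L; cj <- j - 1L
    if (!inside(i, j - 1)) {  # bottom: +x
      from <- c(from, key(ci, cj));       to <- c(to, key(ci + 1L, cj))
    }
    if (!inside(i + 1, j)) {  # right: +y
      from <- c(from, key(ci + 1L, cj));  to <- c(to, key(ci + 1L, cj + 1L))
    }
    if (!inside(i, j + 1)) {  # top: -x
      from <- c(from, key(ci + 1L, cj + 1L)); to <- c(to, key(ci, cj + 1L))
    }
    if (!inside(i - 1, j)) {  # left: -y
      from <- c(from, key(ci, cj + 1L)); to <- c(to, key(ci, cj))
    }
  }
  if (length(from) == 0L) return(list())

  corner_xy <- function(k) {
    k0 <- k - 1L
    c(k0 %% (nx + 1L), k0 %/% (nx + 1L))
  }
  out_edges <- split(seq_along(from), from)
  used <- logical(length(from))
  loops <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    loop_keys <- from[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      nxt_vertex <- to[e]
      cand <- out_edges[[as.character(nxt_vertex)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break  # loop closed
      if (length(cand) > 1L) {
        # ambiguous corner: prefer the sharpest left turn w.r.t. the
        # incoming direction (cross product z-component largest)
        din <- corner_xy(to[e]) - corner_xy(from[e])
        turn <- vapply(cand, function(ec) {
          dout <- corner_xy(to[ec]) - corner_xy(from[ec])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        cand <- cand[which.max(turn)]
      }
      e <- cand[1]
      loop_keys <- c(loop_keys, from[e])
    }
    loops[[length(loops) + 1L]] <- loop_keys
  }
  lapply(loops, function(ks) t(vapply(ks, corner_xy, numeric(2))))
}

#' Extract per-slice closed contours from a binary mask
#'
#' @param mask A [roi_mask()].
#' @return A list of class `slice_contours`; each element is a list with
#'   `slice` (1-based index along the third grid axis), `corners` (`n x 2`
#'   matrix of 0-based corner-lattice coordinates in the slice plane) and
#'   `world` (`n x 3` matrix of world-mm vertices through the grid affine).
#'   Empty slices contribute no polygons.
#' @seealso [rasterize_contours()] for the exact inverse at voxel-center
#'   sampling.
#' @export
extract_slice_contours <- function(mask) {
  stopifnot(inherits(mask, "volume_grid"))
  v <- mask$values
  if (!is.logical(v)) v <- array(v != 0, dim = mask$dims)
  out <- list()
  for (k in seq_len(mask$dims[3])) {
    loops <- trace_slice_loops(v[, , k, drop = TRUE])
    for (lp in loops) {
      # corner (ci, cj) -> continuous 0-based voxel index (ci - 0.5, cj - 0.5)
      idx <- cbind(lp[, 1] - 0.5, lp[, 2] - 0.5, k - 1)
      world <- apply_affine(idx, mask$affine)
      out[[length(out) + 1L]] <- list(slice = k, corners = lp, world = world)
    }
  }
  structure(out, class = "slice_contours",
            dims = mask$dims, voxel_sizes = mask$voxel_sizes,
            affine = mask$affine, axis_codes = mask$axis_codes)
}

# Even-odd point-in-polygon for points strictly off the edges.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize slice contours back to a binary mask
#'
#' Even-odd rule at voxel centers, in the corner-lattice frame in which the
#' contours were traced; voxel centers sit half a voxel away from any
#' contour edge, so the test is numerically robust and the round trip with
#' [extract_slice_contours()] is exact.
#'
#' @param contours A `slice_contours` object.
#' @return A [roi_mask()] on the original grid.
#' @export
rasterize_contours <- function(contours) {
  stopifnot(inherits(contours, "slice_contours"))
  dims <- attr(contours, "dims")
  v <- array(FALSE, dim = dims)
  # voxel (i, j) (0-based) has its center at corner-lattice (i + 0.5, j + 0.5)
  centers <- expand.grid(i = seq_len(dims[1]) - 0.5, j = seq_len(dims[2]) - 0.5)
  for (ct in contours) {
    k <- ct$slice
    hit <- points_in_polygon(centers$i, centers$j, ct$corners)
    sl <- v[, , k]
    sl <- xor(sl, matrix(hit, dims[1], dims[2]))
    v[, , k] <- sl
  }
  g <- volume_grid(v, attr(contours, "voxel_sizes"),
                   attr(contours, "affine"), attr(contours, "axis_codes"))
  roi_mask(g, role = "generic")
}

#' Write slice contours as JSON
#'
#' @param contours A `slice_contours` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(contours, path) {
  stopifnot(inherits(contours, "slice_contours"))
  payload <- lapply(unclass(contours), function(ct)
    list(slice = ct$slice,
         vertices_mm = apply(ct$world, 1, function(r) r, simplify = FALSE)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
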