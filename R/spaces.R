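#' @title Reconciling voxel-grid and streamline coordinate frames
#' @description TrackVis streamline points live in a voxel-size-scaled,
#'   corner-origin space whose axes follow the header's `voxel_order`, while
#'   NIfTI grids index voxels along their own (possibly different) axis
#'   order. [reconcile_affine()] builds the 4x4 map from grid voxel indices
#'   to streamline point coordinates using the orientation labels alone —
#'   never dimension-matching heuristics, so cubic grids reconcile correctly.
#' @name tract-spaces
NULL

OPPOSITE_CODE <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

#' Map between grid voxel indices and streamline point space
#'
#' Returns the affine sending 0-based voxel index `(i, j, k)` of `grid` to
#' the TrackVis voxel-mm coordinate of that voxel's center in the streamline
#' frame described by `header`: along each streamline axis, voxel `i` spans
#' the half-open interval `[i * vs, (i + 1) * vs)` and its center maps to
#' `(i + 0.5) * vs`. Axis correspondence and flips are derived from the
#' orientation letters (`header$voxel_order` vs `grid$axis_codes`).
#'
#' @param header A [streamline_header()].
#' @param grid A [volume_grid()] describing the same physical volume.
#' @return An object of class `tract_affine`: list with the 4x4 `matrix`,
#'   the permutation `perm` (grid axis feeding each streamline axis), axis
#'   `signs`, streamline-order `voxel_sizes`, and grid `dims`.
#' @examples
#' g <- volume_grid(array(0, c(4, 5, 6)), c(1, 1, 2))
#' h <- streamline_header(c(4, 5, 6), c(1, 1, 2), "RAS")
#' reconcile_affine(h, g)$matrix
#' @export
reconcile_affine <- function(header, grid) {
  stopifnot(inherits(header, "streamline_header"),
            inherits(grid, "volume_grid"))
  sc <- strsplit(header$voxel_order, "")[[1]]
  gc <- strsplit(grid$axis_codes, "")[[1]]
  perm <- integer(3)
  signs <- numeric(3)
  for (s in 1:3) {
    same <- which(gc == sc[s])
    opp <- which(gc == OPPOSITE_CODE[[sc[s]]])
    if (length(same) == 1L) {
      perm[s] <- same; signs[s] <- 1
    } else if (length(opp) == 1L) {
      perm[s] <- opp; signs[s] <- -1
    } else {
      stop("cannot reconcile axis '", sc[s], "' of streamline order ",
           header$voxel_order, " with grid orientation ", grid$axis_codes,
           call. = FALSE)
    }
  }
  if (anyDuplicated(perm))
    stop("degenerate axis correspondence between ", header$voxel_order,
         " and ", grid$axis_codes, call. = FALSE)
  if (!all(header$dims == grid$dims[perm]))
    stop("grid dims (", paste(grid$dims, collapse = ", "),
         ") and streamline header dims (", paste(header$dims, collapse = ", "),
         ") do not agree under the orientation-derived permutation",
         call. = FALSE)
  if (any(abs(header$voxel_sizes - grid$voxel_sizes[perm]) > 1e-3))
    stop("voxel sizes disagree beyond 1e-3 mm: grid (",
         paste(grid$voxel_sizes, collapse = ", "), ") vs header (",
         paste(header$voxel_sizes, collapse = ", "), ")", call. = FALSE)

  vs <- header$voxel_sizes
  m <- matrix(0, 4, 4)
  m[4, 4] <- 1
  for (s in 1:3) {
    g <- perm[s]
    m[s, g] <- signs[s] * vs[s]
    offset <- if (signs[s] < 0) grid$dims[g] - 1 else 0
    m[s, 4] <- vs[s] * (offset + 0.5)
  }
  structure(
    list(matrix = m, perm = perm, signs = signs, voxel_sizes = vs,
         dims = grid$dims),
    class = "tract_affine"
  )
}

#' @export
print.tract_affine <- function(x, ...) {
  cat("<tract_affine> grid voxel index -> streamline point (mm)\n")
  print(x$matrix)
  invisible(x)
}

#' Apply a homogeneous affine to points
#'
#' @param points `n x 3` matrix (or length-3 vector) of coordinates.
#' @param a A `tract_affine` or plain 4x4 matrix.
#' @param inverse Apply the inverse map instead.
#' @return `n x 3` matrix of transformed coordinates.
#' @export
apply_affine <- function(points, a, inverse = FALSE) {
  m <- if (inherits(a, "tract_affine")) a$matrix else a
  if (inverse) m <- solve(m)
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  out <- cbind(p, 1) %*% t(m)
  out[, 1:3, drop = FALSE]
}

#' Assign streamline points to grid voxels
#'
#' Applies the floor convention on the half-open voxel boxes of the
#' streamline frame — a point exactly on a boundary belongs to the
#' higher-index voxel — then maps the streamline-frame voxel index to the
#' grid's axis order. Out-of-bounds points yield `NA` rows, never errors.
#'
#' @param points `n x 3` matrix (or length-3 vector) of coordinates in the
#'   streamline point space.
#' @param a A `tract_affine` from [reconcile_affine()].
#' @return `n x 3` integer matrix of 0-based grid voxel indices (`NA` rows
#'   for points outside the grid).
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
#' a <- reconcile_affine(streamline_header(c(4, 4, 4), c(1, 1, 1)), g)
#' point_to_voxel(c(0.5, 0.5, 0.5), a)  # voxel (0, 0, 0)
#' point_to_voxel(c(2.0, 0.5, 0.5), a)  # boundary -> voxel (2, 0, 0)
#' @export
point_to_voxel <- function(points, a) {
  stopifnot(inherits(a, "tract_affine"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  u <- floor(sweep(p, 2, a$voxel_sizes, "/"))
  v <- matrix(NA_integer_, nrow(u), 3)
  for (s in 1:3) {
    g <- a$perm[s]
    v[, g] <- as.integer(if (a$signs[s] > 0) u[, s]
                         else a$dims[g] - 1 - u[, s])
  }
  oob <- rep(FALSE, nrow(v))
  for (g in 1:3) oob <- oob | v[, g] < 0L | v[, g] >= a$dims[g]
  v[oob, ] <- NA_integer_
  v
}

#' Streamline-frame coordinates of grid voxel centers
#'
#' Inverse companion of [point_to_voxel()]: maps 0-based grid voxel indices
#' to the streamline-space coordinates of the voxel centers.
#'
#' @param voxels `n x 3` matrix (or length-3 vector) of 0-based indices.
#' @param a A `tract_affine`.
#' @return `n x 3` matrix of points.
#' @export
voxel_to_point <- function(voxels, a) {
  v <- if (is.matrix(voxels)) voxels else matrix(voxels, ncol = 3)
  apply_affine(v, a)
}
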