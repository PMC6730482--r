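#' Construct a volume grid
#'
#' A `volume_grid` is the package's container for a 3-D scalar or binary
#' lattice together with its geometry: voxel sizes in mm, a voxel-to-world
#' affine (0-based voxel indices, NIfTI convention) and a three-letter
#' anatomical orientation code giving the world direction each voxel axis
#' points toward (e.g. `"RAS"`, `"LPS"`).
#'
#' @param values 3-D numeric or logical array.
#' @param voxel_sizes Positive numeric vector of length 3 (mm).
#' @param affine 4x4 voxel-to-world matrix; its bottom row must be
#'   `(0, 0, 0, 1)` and the column norms of its upper-left 3x3 block must
#'   equal `voxel_sizes`. Defaults to a diagonal affine consistent with
#'   `axis_codes`, with the center of voxel `(0, 0, 0)` at the world origin.
#' @param axis_codes Three-letter orientation string; each letter is one of
#'   R/L, A/P, S/I and names the world direction of the corresponding voxel
#'   axis.
#' @return An object of class `volume_grid`: a list with elements `values`,
#'   `dims`, `voxel_sizes`, `affine`, `axis_codes`.
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 4)), voxel_sizes = c(1, 1, 2))
#' g$dims
#' @export
volume_grid <- function(values, voxel_sizes, affine = NULL,
                        axis_codes = "RAS") {
  values <- if (is.logical(values)) values else as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ", length(dim(values)),
         " dimensions", call. = FALSE)
  dims <- dim(values)
  if (any(dims < 1L)) stop("all grid dimensions must be positive", call. = FALSE)
  voxel_sizes <- as.numeric(voxel_sizes)
  if (length(voxel_sizes) != 3L || any(!is.finite(voxel_sizes)) ||
      any(voxel_sizes <= 0))
    stop("`voxel_sizes` must be 3 positive lengths in mm", call. = FALSE)
  axis_codes <- validate_axis_codes(axis_codes)
  if (is.null(affine)) affine <- default_affine(voxel_sizes, axis_codes)
  validate_affine(affine, voxel_sizes)
  structure(
    list(values = values, dims = as.integer(dims), voxel_sizes = voxel_sizes,
         affine = affine, axis_codes = axis_codes),
    class = "volume_grid"
  )
}

validate_axis_codes <- function(axis_codes) {
  axis_codes <- toupper(as.character(axis_codes)[1])
  letters3 <- strsplit(axis_codes, "")[[1]]
  axes <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  if (length(letters3) != 3L || !all(letters3 %in% names(axes)) ||
      anyDuplicated(axes[letters3]))
    stop("`axis_codes` must name three distinct anatomical axes, e.g. \"RAS\"",
         call. = FALSE)
  axis_codes
}

default_affine <- function(voxel_sizes, axis_codes) {
  letters3 <- strsplit(axis_codes, "")[[1]]
  world_axis <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)[letters3]
  world_sign <- c(R = 1, L = -1, A = 1, P = -1, S = 1, I = -1)[letters3]
  m <- diag(4)
  m[1:3, 1:3] <- 0
  for (ax in 1:3) m[world_axis[ax], ax] <- world_sign[ax] * voxel_sizes[ax]
  m
}

validate_affine <- function(affine, voxel_sizes = NULL, tol = 1e-6) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > tol)
    stop("affine bottom row must be (0, 0, 0, 1)", call. = FALSE)
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12)
    stop("affine is not invertible", call. = FALSE)
  if (!is.null(voxel_sizes)) {
    norms <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(abs(norms - voxel_sizes) > tol * pmax(1, voxel_sizes)))
      stop("affine column norms (", paste(signif(norms, 6), collapse = ", "),
           ") do not match voxel sizes (",
           paste(voxel_sizes, collapse = ", "), ")", call. = FALSE)
  }
  invisible(affine)
}

#' Tag a binary grid as a region-of-interest mask
#'
#' Wraps (or converts) a [volume_grid()] into a binary ROI mask with a role
#' label. Non-binary input values are rejected; use `read_volume(role=)` for
#' tolerant binarization of files.
#'
#' @param grid A `volume_grid` (numeric values restricted to 0/1, or logical).
#' @param role One of `"GTV"`, `"brain"`, `"recurrence"`, `"generic"`.
#' @return The grid with class `roi_mask` prepended, logical values, and a
#'   `role` attribute.
#' @export
roi_mask <- function(grid, role = c("generic", "GTV", "brain", "recurrence")) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "volume_grid"))
  v <- grid$values
  if (!is.logical(v)) {
    if (!all(v %in% c(0, 1)))
      stop("mask values must be binary (0/1); got other values", call. = FALSE)
    v <- array(v == 1, dim = grid$dims)
  }
  grid$values <- v
  attr(grid, "role") <- role
  class(grid) <- unique(c("roi_mask", class(grid)))
  grid
}

mask_count <- function(mask) sum(mask$values)

is_empty_mask <- function(mask) mask_count(mask) == 0L

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d x %d voxels, %s mm, %s\n",
              class(x)[1], x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$voxel_sizes, 4), collapse = " x "),
              x$axis_codes))
  if (inherits(x, "roi_mask"))
    cat(sprintf("  role: %s, %d voxels set\n",
                attr(x, "role") %||% "generic", sum(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

grids_aligned <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    max(abs(a$voxel_sizes - b$voxel_sizes)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b))
    stop(what, " are not aligned: ",
         paste(a$dims, collapse = "x"), " @ ",
         paste(signif(a$voxel_sizes, 4), collapse = "x"), " mm vs ",
         paste(b$dims, collapse = "x"), " @ ",
         paste(signif(b$voxel_sizes, 4), collapse = "x"), " mm",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a scalar volume or binary mask from a NIfTI-1 file (gzipped or not).
#' When `role` is given the volume is binarized at `> 0`; the number of input
#' voxels that were neither 0 nor 1 is reported with a warning so that
#' probabilistic maps are never silently misread as masks.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param role `NULL` for a scalar volume, or an ROI role (see [roi_mask()])
#'   to binarize.
#' @return A [volume_grid()] (with class `roi_mask` when `role` is given).
#' @export
read_volume <- function(path, role = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L) {
    if (d[4] != 1L)
      stop("4-D input with ", d[4], " volumes; expected a single 3-D volume",
           call. = FALSE)
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a 3-D volume, got ", length(d), " dimensions", call. = FALSE)
  }
  arr <- array(as.numeric(arr), dim = d)  # plain array, RNifti attrs dropped
  affine <- unclass(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(affine) <- list(dim = dim(affine))
  vs <- as.numeric(RNifti::pixdim(img))[1:3]
  codes <- RNifti::orientation(img)
  g <- volume_grid(arr, voxel_sizes = vs, affine = affine, axis_codes = codes)
  if (!is.null(role)) {
    nonbin <- sum(arr != 0 & arr != 1)
    if (nonbin > 0)
      warning(nonbin, " non-binary voxels binarized at > 0", call. = FALSE)
    g$values <- array(arr > 0, dim = g$dims)
    g <- roi_mask(g, role = role)
  }
  g
}

#' Write a volume grid to NIfTI-1
#'
#' @param grid A [volume_grid()] or mask.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype, e.g. `"float"` or `"uint8"` (masks default
#'   to `"uint8"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path,
                         datatype = if (is.logical(grid$values)) "uint8"
                                    else "float") {
  vals <- grid$values
  if (is.logical(vals)) vals <- array(as.integer(vals), dim = grid$dims)
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$voxel_sizes
  # qform<- renormalizes scaling through the quaternion; sform keeps the
  # matrix verbatim, so the full anisotropic affine survives a round trip.
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
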