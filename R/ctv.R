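#' @title Anisotropic clinical target volume construction
#' @description Turns a WMPL map into radiotherapy target masks: voxels whose
#'   path length does not exceed a chosen expansion path length (EPL) are
#'   unioned with the GTV, expanded by an exact metric (world-mm) dilation to
#'   suppress small contour islands, and clipped to the brain. An isotropic
#'   control expansion of the GTV is built the same way for comparison.
#' @name ctv-builder
NULL

#' Expansion configuration
#'
#' @param epl_list Strictly increasing EPL thresholds in mm
#'   (default `c(10, 20, 30)`, i.e. 1, 2 and 3 cm).
#' @param expansion_radius Radius in mm of the final metric dilation applied
#'   to the GTV/WMPL union (default 5).
#' @param isotropic_margin Margin in mm of the isotropic control expansion
#'   (default 20).
#' @param clip_isotropic Clip the isotropic control to the brain mask too
#'   (default `TRUE`).
#' @param expand_isotropic Apply the island-suppression dilation to the
#'   isotropic control as well (default `FALSE`; it belongs to the
#'   anisotropic construction).
#' @return An object of class `expansion_config`.
#' @export
expansion_config <- function(epl_list = c(10, 20, 30), expansion_radius = 5,
                             isotropic_margin = 20, clip_isotropic = TRUE,
                             expand_isotropic = FALSE) {
  epl_list <- as.numeric(epl_list)
  if (length(epl_list) < 1L || any(epl_list <= 0) ||
      is.unsorted(epl_list, strictly = TRUE))
    stop("epl_list must be strictly increasing positive lengths (mm)",
         call. = FALSE)
  if (expansion_radius <= 0) stop("expansion_radius must be > 0", call. = FALSE)
  if (isotropic_margin <= 0) stop("isotropic_margin must be > 0", call. = FALSE)
  structure(list(epl_list = epl_list, expansion_radius = expansion_radius,
                 isotropic_margin = isotropic_margin,
                 clip_isotropic = isTRUE(clip_isotropic),
                 expand_isotropic = isTRUE(expand_isotropic)),
            class = "expansion_config")
}

#' Squared Euclidean distance transform in world mm
#'
#' For each voxel, the squared distance from its center to the nearest
#' foreground voxel center, honoring anisotropic voxel sizes exactly
#' (separable lower-envelope algorithm). All-background input gives `Inf`
#' everywhere.
#'
#' @param mask A [roi_mask()] or logical `volume_grid`.
#' @return Numeric array of squared distances (mm^2).
#' @export
distance_transform_sq <- function(mask) {
  stopifnot(inherits(mask, "volume_grid"))
  v <- mask$values
  if (!is.logical(v)) v <- array(v != 0, dim = mask$dims)
  edt_sq_cpp(v, mask$dims, mask$voxel_sizes)
}

#' Metric dilation of a binary mask
#'
#' A voxel belongs to the dilation iff its center lies within `radius` world
#' mm of some foreground voxel center (center-to-center Euclidean distance,
#' exact under anisotropic voxels).
#'
#' @param mask A [roi_mask()].
#' @param radius Dilation radius in mm (0 returns the mask unchanged).
#' @return The dilated [roi_mask()].
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(inherits(mask, "volume_grid"), radius >= 0)
  if (radius == 0) return(mask)
  d2 <- distance_transform_sq(mask)
  out <- mask
  out$values <- array(d2 <= radius * radius + 1e-9, dim = mask$dims)
  out
}

#' Threshold a WMPL map at an expansion path length
#'
#' Selects visited voxels whose path length is at most `epl` (inclusive;
#' zero included, fill excluded).
#'
#' @param w A [path_length_map()].
#' @param epl Threshold in mm (> 0).
#' @return A [roi_mask()] on the map's grid.
#' @export
threshold_wmpl <- function(w, epl) {
  stopifnot(inherits(w, "path_length_map"), epl > 0)
  fill <- attr(w, "fill")
  m <- w$values != fill & w$values >= 0 & w$values <= epl
  g <- volume_grid(array(m, dim = w$dims), w$voxel_sizes, w$affine,
                   w$axis_codes)
  roi_mask(g, role = "generic")
}

#' Build an anisotropic CTV from a WMPL map
#'
#' `((GTV union threshold_wmpl(w, epl)) dilated by radius r) intersect brain`.
#'
#' @param w A [path_length_map()].
#' @param gtv Nonempty GTV [roi_mask()], grid-aligned with `w`.
#' @param brain Brain [roi_mask()], grid-aligned with `w`.
#' @param epl EPL threshold in mm.
#' @param r Island-suppression dilation radius in mm (default 5).
#' @return The CTV as a [roi_mask()].
#' @export
build_anisotropic_ctv <- function(w, gtv, brain, epl, r = 5) {
  stopifnot(inherits(w, "path_length_map"))
  stop_if_misaligned(w, gtv, "WMPL and GTV grids")
  stop_if_misaligned(w, brain, "WMPL and brain grids")
  if (is_empty_mask(gtv)) stop("GTV mask is empty", call. = FALSE)
  u <- gtv
  u$values <- gtv$values | threshold_wmpl(w, epl)$values
  dil <- dilate_mask(u, r)
  dil$values <- dil$values & brain$values
  attr(dil, "role") <- "generic"
  dil
}

#' Build the isotropic control CTV
#'
#' Metric dilation of the GTV by `margin`, clipped to the brain.
#'
#' @param gtv Nonempty GTV [roi_mask()].
#' @param brain Brain [roi_mask()], grid-aligned.
#' @param margin Isotropic margin in mm (default 20; 0 gives GTV within
#'   brain).
#' @return The control CTV as a [roi_mask()].
#' @export
build_isotropic_ctv <- function(gtv, brain, margin = 20) {
  stop_if_misaligned(gtv, brain, "GTV and brain grids")
  if (is_empty_mask(gtv)) stop("GTV mask is empty", call. = FALSE)
  out <- if (margin > 0) dilate_mask(gtv, margin) else gtv
  out$values <- out$values & brain$values
  attr(out, "role") <- "generic"
  out
}

#' Build the full CTV family
#'
#' One anisotropic mask per configured EPL plus the isotropic control.
#'
#' @param w A [path_length_map()].
#' @param gtv,brain Grid-aligned [roi_mask()]s.
#' @param cfg An [expansion_config()].
#' @return An object of class `ctv_set`: list with `anisotropic` (named list
#'   of masks, one per EPL), `isotropic`, and `config`.
#' @export
build_ctv_set <- function(w, gtv, brain, cfg = expansion_config()) {
  stopifnot(inherits(cfg, "expansion_config"))
  aniso <- lapply(cfg$epl_list, function(epl)
    build_anisotropic_ctv(w, gtv, brain, epl, r = cfg$expansion_radius))
  names(aniso) <- paste0("epl_", cfg$epl_list, "mm")
  if (is_empty_mask(gtv)) stop("GTV mask is empty", call. = FALSE)
  iso <- dilate_mask(gtv, cfg$isotropic_margin)
  if (cfg$expand_isotropic) iso <- dilate_mask(iso, cfg$expansion_radius)
  if (cfg$clip_isotropic) iso$values <- iso$values & brain$values
  attr(iso, "role") <- "generic"
  structure(list(anisotropic = aniso, isotropic = iso, config = cfg),
            class = "ctv_set")
}

#' @export
print.ctv_set <- function(x, ...) {
  cat(sprintf("<ctv_set> %d anisotropic mask(s) (EPL %s mm) + isotropic %g mm\n",
              length(x$anisotropic),
              paste(x$config$epl_list, collapse = ", "),
              x$config$isotropic_margin))
  invisible(x)
}

#' World-mm^3 volume of a mask
#'
#' @param mask A [roi_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$values) * prod(mask$voxel_sizes)
}

#' Compare two target volumes
#'
#' Reports world-mm^3 volumes, the percent volume difference
#' `100 * (vol(a) - vol(b)) / vol(b)`, and — when a recurrence mask is
#' supplied and nonempty — the fraction of the recurrence covered by each
#' mask. An empty or missing recurrence yields `NA` coverage.
#'
#' @param a,b Grid-aligned [roi_mask()]s (e.g. anisotropic vs isotropic CTV).
#' @param recurrence Optional recurrence [roi_mask()].
#' @return A list of class `ctv_comparison` with elements `volume_a`,
#'   `volume_b`, `percent_difference`, `coverage_a`, `coverage_b`.
#' @export
compare_ctvs <- function(a, b, recurrence = NULL) {
  stop_if_misaligned(a, b, "comparison grids")
  va <- mask_volume(a)
  vb <- mask_volume(b)
  cov <- c(a = NA_real_, b = NA_real_)
  if (!is.null(recurrence) && !is_empty_mask(recurrence)) {
    stop_if_misaligned(a, recurrence, "mask and recurrence grids")
    vr <- sum(recurrence$values)
    cov["a"] <- sum(recurrence$values & a$values) / vr
    cov["b"] <- sum(recurrence$values & b$values) / vr
  }
  structure(list(volume_a = va, volume_b = vb,
                 percent_difference = 100 * (va - vb) / vb,
                 coverage_a = unname(cov["a"]),
                 coverage_b = unname(cov["b"])),
            class = "ctv_comparison")
}

#' @export
print.ctv_comparison <- function(x, ...) {
  cat(sprintf("<ctv_comparison> vol(a) = %.1f mm^3, vol(b) = %.1f mm^3 (%+.1f%%)\n",
              x$volume_a, x$volume_b, x$percent_difference))
  if (!is.na(x$coverage_a))
    cat(sprintf("  recurrence coverage: a %.1f%%, b %.1f%%\n",
                100 * x$coverage_a, 100 * x$coverage_b))
  invisible(x)
}
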