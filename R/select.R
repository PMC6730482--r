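#' @title Streamline targeting and outlier filtering
#' @description Selecting the GTV-connected subset of a whole-brain
#'   tractogram, and scoring streamlines with the Cluster Confidence Index
#'   (CCI): each streamline is resampled to a fixed number of equally spaced
#'   vertices, pairwise similarity is the minimum average direct-flip (MDF)
#'   distance, and a streamline's CCI sums inverse-MDF contributions from
#'   neighbors within a distance cap. Isolated outliers score near zero.
#' @name streamline-select
NULL

#' Select streamlines passing through an ROI
#'
#' Keeps exactly those polylines with at least one ROI-interior vertex
#' (vertex voxel membership via [point_to_voxel()]); order is preserved and
#' an empty result is allowed.
#'
#' @param s A [streamline_set()].
#' @param roi A nonempty [roi_mask()].
#' @param a The reconciling `tract_affine`.
#' @return The targeted [streamline_set()].
#' @export
target_streamlines <- function(s, roi, a) {
  stopifnot(inherits(s, "streamline_set"), inherits(roi, "roi_mask"))
  if (is_empty_mask(roi)) stop("target ROI is empty", call. = FALSE)
  hits <- vapply(s$polylines, function(p) {
    v <- point_to_voxel(p, a)
    inb <- !is.na(v[, 1])
    any(inb) && any(roi$values[v[inb, , drop = FALSE] + 1L])
  }, logical(1))
  message("targeting kept ", sum(hits), " of ", length(hits), " streamlines")
  out <- s
  out$polylines <- s$polylines[hits]
  out$header$n_streamlines <- sum(hits)
  out
}

#' Resample a polyline to n equally spaced vertices
#'
#' Equal spacing is in arc length; endpoints are preserved.
#'
#' @param p `m x 3` matrix of points.
#' @param n Number of output vertices (>= 2).
#' @return `n x 3` matrix.
#' @export
resample_polyline <- function(p, n) {
  stopifnot(nrow(p) >= 2L, n >= 2L)
  cl <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  ts <- seq(0, cl[length(cl)], length.out = n)
  cbind(approx(cl, p[, 1], xout = ts, ties = "ordered")$y,
        approx(cl, p[, 2], xout = ts, ties = "ordered")$y,
        approx(cl, p[, 3], xout = ts, ties = "ordered")$y)
}

#' Minimum average direct-flip distance between two resampled polylines
#'
#' Mean Euclidean distance between corresponding vertices, minimized over
#' the two traversal orientations of `b`. Symmetric and flip-invariant.
#'
#' @param a,b Matrices with the same number of rows (already resampled).
#' @return A nonnegative scalar (mm).
#' @export
mdf_distance <- function(a, b) {
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[nrow(b):1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' Cluster Confidence Index scores
#'
#' Each streamline is resampled to `subsample_n` equally spaced vertices;
#' for streamline i, `CCI_i = sum over j != i with 0 < MDF(i,j) <= max_dist
#' of (1 / MDF(i,j))^power`. Exact-duplicate pairs (MDF 0) are excluded from
#' the sum and counted. Defaults follow the standard reference
#' implementation of the index.
#'
#' @param s A [streamline_set()] with at least 2 streamlines.
#' @param subsample_n Resampling point count (default 12).
#' @param power Exponent on the inverse distance (default 1).
#' @param max_dist Neighborhood cap in mm (default 5).
#' @return Numeric scores (class `cci_scores`) with the parameters and the
#'   duplicate-pair count as attributes.
#' @export
cluster_confidence <- function(s, subsample_n = 12L, power = 1,
                               max_dist = 5) {
  stopifnot(inherits(s, "streamline_set"))
  k <- length(s$polylines)
  if (k < 2L)
    stop("cluster_confidence needs >= 2 streamlines; ",
         "skip CCI filtering for smaller sets", call. = FALSE)
  rs <- lapply(s$polylines, resample_polyline, n = subsample_n)
  scores <- numeric(k)
  n_dup <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- mdf_distance(rs[[i]], rs[[j]])
      if (d == 0) {
        n_dup <- n_dup + 1L
      } else if (d <= max_dist) {
        w <- (1 / d)^power
        scores[i] <- scores[i] + w
        scores[j] <- scores[j] + w
      }
    }
  }
  if (n_dup > 0L)
    message(n_dup, " duplicate streamline pair(s) excluded from CCI sums")
  structure(scores, class = "cci_scores",
            params = list(subsample_n = subsample_n, power = power,
                          max_dist = max_dist),
            n_duplicate_pairs = n_dup)
}

#' Filter streamlines by CCI score
#'
#' Keeps streamlines whose score is strictly greater than `threshold`.
#'
#' @param s A [streamline_set()].
#' @param scores Scores from [cluster_confidence()], aligned with `s`.
#' @param threshold Score cutoff (default 1).
#' @return The filtered [streamline_set()].
#' @export
filter_by_cci <- function(s, scores, threshold = 1) {
  stopifnot(inherits(s, "streamline_set"),
            length(scores) == length(s$polylines))
  keep <- as.numeric(scores) > threshold
  message("CCI filter kept ", sum(keep), " of ", length(keep),
          " streamlines (threshold ", threshold, ")")
  out <- s
  out$polylines <- s$polylines[keep]
  out$header$n_streamlines <- sum(keep)
  out
}
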