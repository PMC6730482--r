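#' @title TrackVis TRK streamline input/output
#' @description Reader and writer for the TrackVis TRK binary format
#'   (version 2, little-endian, 1000-byte header). Point coordinates are kept
#'   in the file's native space: voxel-size-scaled with corner origin, so the
#'   center of voxel `(i, j, k)` lies at `(i + 0.5) * voxel_size` along each
#'   header axis.
#' @name trk-io
NULL

TRK_HDR_SIZE <- 1000L

#' Construct a streamline header
#'
#' @param dims Grid dimensions (3 positive integers).
#' @param voxel_sizes Voxel sizes in mm (3 positive lengths).
#' @param voxel_order Three-letter orientation of the streamline grid axes
#'   (e.g. `"RAS"`, `"LPS"`).
#' @param n_streamlines Streamline count (maintained automatically by
#'   [streamline_set()] and the TRK I/O functions).
#' @param vox_to_ras Optional 4x4 voxel-to-world matrix carried in the header.
#' @return An object of class `streamline_header`.
#' @export
streamline_header <- function(dims, voxel_sizes, voxel_order = "RAS",
                              n_streamlines = 0L, vox_to_ras = NULL) {
  dims <- as.integer(dims)
  voxel_sizes <- as.numeric(voxel_sizes)
  if (length(dims) != 3L || any(dims <= 0L))
    stop("header dims must be 3 positive integers", call. = FALSE)
  if (length(voxel_sizes) != 3L || any(voxel_sizes <= 0))
    stop("header voxel_sizes must be 3 positive lengths", call. = FALSE)
  voxel_order <- validate_axis_codes(voxel_order)
  structure(
    list(dims = dims, voxel_sizes = voxel_sizes, voxel_order = voxel_order,
         n_streamlines = as.integer(n_streamlines),
         vox_to_ras = vox_to_ras),
    class = "streamline_header"
  )
}

#' Construct a streamline set
#'
#' Bundles a list of polylines (each an `n x 3` matrix of points, `n >= 2`,
#' coordinates in the TrackVis voxel-mm space described by `header`) with its
#' header. Consecutive duplicate points are removed with a message; polylines
#' left with fewer than 2 points are dropped with a warning.
#'
#' @param polylines List of numeric matrices with 3 columns.
#' @param header A [streamline_header()].
#' @param space_tag Label for the coordinate convention of the points.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(polylines, header, space_tag = "trackvis_voxmm") {
  stopifnot(inherits(header, "streamline_header"))
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("each polyline needs 3 columns", call. = FALSE)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  ndup <- 0L
  polylines <- lapply(polylines, function(p) {
    if (nrow(p) < 2L) return(p)
    keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
    ndup <<- ndup + sum(!keep)
    p[keep, , drop = FALSE]
  })
  if (ndup > 0)
    message("removed ", ndup, " consecutive duplicate streamline points")
  short <- vapply(polylines, nrow, integer(1)) < 2L
  if (any(short)) {
    warning("dropped ", sum(short), " degenerate streamline(s) with < 2 points",
            call. = FALSE)
    polylines <- polylines[!short]
  }
  header$n_streamlines <- length(polylines)
  structure(list(polylines = polylines, header = header,
                 space_tag = space_tag),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$polylines, nrow, integer(1))
  cat(sprintf("<streamline_set> %d streamlines (%s points each), %s, %s mm\n",
              length(x$polylines),
              if (length(np)) paste(range(np), collapse = "-") else "0",
              x$header$voxel_order,
              paste(signif(x$header$voxel_sizes, 4), collapse = " x ")))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$polylines)

read_chars <- function(raw) {
  nul <- which(raw == as.raw(0))
  end <- if (length(nul)) nul[1] - 1L else length(raw)
  if (end < 1L) "" else rawToChar(raw[seq_len(end)])
}

#' Read a TrackVis TRK file
#'
#' Parses a TRK version-2 file. Coordinates are preserved in the file's
#' native voxel-mm space. Per-point scalars and per-track properties, if
#' present, are skipped. A file declaring zero streamlines yields an empty
#' set with a warning; malformed headers and truncated payloads raise errors
#' naming the offending field.
#'
#' @param path Path to a `.trk` file.
#' @return A [streamline_set()].
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  hraw <- readBin(con, "raw", TRK_HDR_SIZE)
  if (length(hraw) < TRK_HDR_SIZE)
    stop("malformed TRK header: file shorter than 1000 bytes", call. = FALSE)
  rd <- function(off, what, n, size) {
    readBin(hraw[(off + 1L):length(hraw)], what, n = n, size = size,
            endian = "little")
  }
  id <- read_chars(hraw[1:6])
  if (!identical(substr(id, 1, 5), "TRACK"))
    stop("malformed TRK header: id_string is not 'TRACK'", call. = FALSE)
  dims <- rd(6L, integer(), 3L, 2L)
  voxel_sizes <- rd(12L, numeric(), 3L, 4L)
  n_scalars <- rd(36L, integer(), 1L, 2L)
  n_properties <- rd(238L, integer(), 1L, 2L)
  vox_to_ras <- matrix(rd(440L, numeric(), 16L, 4L), 4L, 4L, byrow = TRUE)
  voxel_order <- read_chars(hraw[949:952])
  n_count <- rd(988L, integer(), 1L, 4L)
  version <- rd(992L, integer(), 1L, 4L)
  hdr_size <- rd(996L, integer(), 1L, 4L)
  if (!identical(hdr_size, TRK_HDR_SIZE))
    stop("malformed TRK header: hdr_size = ", hdr_size, " (expected 1000)",
         call. = FALSE)
  if (!version %in% c(1L, 2L))
    stop("malformed TRK header: unsupported version ", version, call. = FALSE)
  if (any(dims <= 0L))
    stop("malformed TRK header: non-positive dim field", call. = FALSE)
  if (any(voxel_sizes <= 0))
    stop("malformed TRK header: non-positive voxel_size field", call. = FALSE)
  if (n_scalars < 0L || n_properties < 0L)
    stop("malformed TRK header: negative n_scalars/n_properties",
         call. = FALSE)
  if (voxel_order == "") voxel_order <- "LPS"  # TrackVis default
  if (all(vox_to_ras == 0)) vox_to_ras <- NULL

  polylines <- list()
  repeat {
    npts <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    if (npts < 0L)
      stop("malformed TRK payload: negative point count", call. = FALSE)
    nvals <- npts * (3L + n_scalars)
    pts <- readBin(con, numeric(), nvals, size = 4L, endian = "little")
    if (length(pts) < nvals)
      stop("truncated TRK file: streamline ", length(polylines) + 1L,
           " ends prematurely", call. = FALSE)
    if (n_properties > 0L) {
      pr <- readBin(con, numeric(), n_properties, size = 4L, endian = "little")
      if (length(pr) < n_properties)
        stop("truncated TRK file: missing track properties", call. = FALSE)
    }
    m <- matrix(pts, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    polylines[[length(polylines) + 1L]] <- m
  }
  if (n_count > 0L && n_count != length(polylines))
    stop("malformed TRK file: header declares ", n_count,
         " streamlines but payload holds ", length(polylines), call. = FALSE)
  if (length(polylines) == 0L)
    warning("TRK file contains no streamlines", call. = FALSE)
  hdr <- streamline_header(dims = dims, voxel_sizes = voxel_sizes,
                           voxel_order = voxel_order,
                           n_streamlines = length(polylines),
                           vox_to_ras = vox_to_ras)
  streamline_set(polylines, hdr)
}

#' Write a TrackVis TRK file
#'
#' Writes a [streamline_set()] as TRK version 2 (little-endian, no per-point
#' scalars or per-track properties). Coordinates are stored as 32-bit floats,
#' so a written-then-read set equals the float32 rounding of the input; a
#' second round trip is bit-exact.
#'
#' @param s A [streamline_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(s, path) {
  stopifnot(inherits(s, "streamline_set"))
  h <- s$header
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  wraw <- function(n) writeBin(raw(n), con)
  writeBin(charToRaw("TRACK"), con); wraw(1L)                  # id_string[6]
  writeBin(h$dims, con, size = 2L, endian = "little")          # dim[3]
  writeBin(h$voxel_sizes, con, size = 4L, endian = "little")   # voxel_size[3]
  writeBin(rep(0, 3), con, size = 4L, endian = "little")       # origin[3]
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  wraw(200L)                                                   # scalar_name
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  wraw(200L)                                                   # property_name
  m <- h$vox_to_ras %||% matrix(0, 4, 4)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little") # vox_to_ras
  wraw(444L)                                                   # reserved
  vo <- charToRaw(h$voxel_order)
  writeBin(c(vo, raw(4L - length(vo))), con)                   # voxel_order
  wraw(4L)                                                     # pad2
  writeBin(rep(0, 6), con, size = 4L, endian = "little")       # IOP[6]
  wraw(2L)                                                     # pad1
  wraw(6L)                                                     # invert/swap
  writeBin(length(s$polylines), con, size = 4L, endian = "little") # n_count
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(TRK_HDR_SIZE, con, size = 4L, endian = "little")    # hdr_size

  for (p in s$polylines) {
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
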