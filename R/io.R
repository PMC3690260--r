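#' Read and write MetaImage volumes
#'
#' Minimal MetaImage (.mhd header + .raw float32 payload) support, used for
#' both reconstruction volumes and projection stacks (stacks are stored as a
#' 3D image of size nv x nu x n_views with the geometry in a JSON sidecar).
#' Values are stored as little-endian IEEE float32, so a write/read cycle is
#' exact at float32 precision.
#'
#' @param vol A `cbct_volume`.
#' @param path Path to the `.mhd` header; the `.raw` file is written next to
#'   it.
#' @export
write_volume <- function(vol, path) {
  if (!grepl("\\.mhd$", path)) stop("path must end in .mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(vol$data)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           "ElementType = MET_FLOAT",
           sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (!length(ln)) stop("missing MetaImage key: ", key)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  if (get("ElementType") != "MET_FLOAT") stop("only MET_FLOAT is supported")
  d <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), " +")[[1]])
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = prod(d), size = 4L, endian = "little")
  if (length(vals) != prod(d)) stop("raw payload size does not match header")
  structure(list(data = array(vals, d), spacing = spacing, origin = origin),
            class = "cbct_volume")
}

#' Read and write projection stacks
#'
#' The image payload goes to MetaImage (see [write_volume()]) as a 3D
#' image of size nv x nu x n_views; the acquisition geometry goes to a
#' JSON sidecar (same basename, `.json`). Reading checks that the stack
#' page count matches the geometry's `n_views`.
#'
#' @param stack A `projection_stack`.
#' @param path Path ending in `.mhd`.
#' @export
write_projections <- function(stack, path) {
  vol <- structure(list(data = stack$data, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)), class = "cbct_volume")
  write_volume(vol, path)
  write_geometry(stack$geometry, sub("\\.mhd$", ".json", path))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  vol <- read_volume(path)
  geom <- read_geometry(sub("\\.mhd$", ".json", path))
  if (dim(vol$data)[3] != geom$n_views)
    stop(sprintf("stack has %d pages but geometry declares %d views",
                 dim(vol$data)[3], geom$n_views))
  structure(list(data = vol$data, geometry = geom),
            class = "projection_stack")
}

#' Read and write tracking results
#'
#' CSV with columns frame, a, b, c, u_vertex, v_vertex, n_inliers,
#' constrained.
#' @param track A `diaphragm_track` data frame from [track_sequence()].
#' @param path CSV path.
#' @export
write_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("diaphragm_track", "data.frame")
  df
}

#' Read and write respiration signals
#'
#' CSV with columns frame, t_s, r_mm, r_smoothed_mm.
#' @param signal A `respiration_signal`.
#' @param smoothed Optional smoothed counterpart (same length).
#' @param path CSV path.
#' @export
write_signal <- function(signal, path, smoothed = NULL) {
  df <- data.frame(frame = seq_along(signal$r) - 1L,
                   t_s = signal$timestamps, r_mm = signal$r,
                   r_smoothed_mm = if (is.null(smoothed)) NA_real_
                                   else smoothed$r)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path)
  structure(list(r = df$r_mm, z_ref = NA_real_, ref_index = NA_integer_,
                 timestamps = df$t_s), class = "respiration_signal")
}

#' Read and write triangulated point tracks
#'
#' CSV with columns frame, x, y, z, partner_frame.
#' @param points Data frame from [triangulate_sequence()].
#' @param path CSV path.
#' @export
write_points3d <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points3d
#' @export
read_points3d <- function(path) utils::read.csv(path)
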