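#' Construct a CT volume
#'
#' A `ct_volume` is the raw material every pipeline stage consumes: a 3D
#' integer voxel grid in shifted Hounsfield units (HU + 2048, range
#' \[0, 6144\]) with orientation `(X, Y, Z)`. Slices are taken along X (the
#' core depth axis); `(Y, Z)` are the in-slice rows and columns.
#'
#' @param voxels 3D integer array with dim `(X, Y, Z)`, values in
#'   \[0, 6144\] (shifted HU).
#' @param spacing numeric length 3: `(slice_thickness_mm, y_mm, z_mm)`.
#'   Default is the clinical-CT geometry used throughout: 0.25 mm slices,
#'   0.351 x 0.351 mm in-plane.
#' @param sample_id opaque label carried through annotation and reporting.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing = c(0.25, 0.351, 0.351),
                      sample_id = "unnamed") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all extents must be >= 1")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  storage.mode(voxels) <- "integer"
  if (anyNA(voxels)) stop("voxels must not contain NA")
  rng <- range(voxels)
  if (rng[1] < 0L || rng[2] > 6144L)
    stop("voxel values must lie in [0, 6144] (shifted HU); got [",
         rng[1], ", ", rng[2], "]")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 sample_id = as.character(sample_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume '%s': (X,Y,Z) = (%d, %d, %d), HU range [%d, %d]\n",
              x$sample_id, d[1], d[2], d[3],
              min(x$voxels), max(x$voxels)))
  cat(sprintf("  spacing: %.3f mm slices, %.3f x %.3f mm in-plane\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Shift raw Hounsfield units into the working range
#'
#' Adds the constant 2048 so the chosen scanner range \[-2048, 4096\] HU maps
#' onto \[0, 6144\], and clamps out-of-range values (stray scanner readings
#' must not abort a run). Monotone non-decreasing and total.
#'
#' @param raw_hu integer/numeric vector of raw HU readings.
#' @return integer vector in \[0, 6144\].
#' @export
shift_hu <- function(raw_hu) {
  as.integer(pmin(6144, pmax(0, round(raw_hu) + 2048)))
}

#' Crop a volume to its inner analysis region
#'
#' Returns the centered sub-volume with the requested extents, avoiding the
#' edge effects caused by the cylindrical core wall. The default target
#' `(400, 200, 200)` is the standard inner range for 640 x 512 x 512 scans.
#' Odd differences are split with the extra voxel on the high side (floor
#' division for the start offset).
#'
#' @param volume a `ct_volume`.
#' @param target_extents integer length 3, each `<=` the source extent.
#' @return the cropped `ct_volume` (spacing and sample_id preserved).
#' @export
crop_inner <- function(volume, target_extents = c(400L, 200L, 200L)) {
  stopifnot(inherits(volume, "ct_volume"))
  src <- dim(volume$voxels)
  tgt <- as.integer(target_extents)
  if (length(tgt) != 3L || any(tgt < 1L)) stop("target_extents must be 3 positive integers")
  if (any(tgt > src))
    stop("target extent exceeds source extent: (",
         paste(tgt, collapse = ","), ") vs (", paste(src, collapse = ","), ")")
  lo <- (src - tgt) %/% 2L
  v <- volume$voxels[lo[1] + seq_len(tgt[1]),
                     lo[2] + seq_len(tgt[2]),
                     lo[3] + seq_len(tgt[3]), drop = FALSE]
  ct_volume(v, spacing = volume$spacing, sample_id = volume$sample_id)
}

#' Write a volume as a raw integer voxel stream
#'
#' Fixture format for tests and synthetic data: headerless little-endian
#' int32 stream with X outermost (X slowest, Z fastest), plus a JSON sidecar
#' `<path>.json` recording extents, spacing and sample_id.
#'
#' @param volume a `ct_volume`.
#' @param file_path destination path for the voxel stream.
#' @export
write_raw_volume <- function(volume, file_path) {
  stopifnot(inherits(volume, "ct_volume"))
  con <- file(file_path, "wb")
  on.exit(close(con))
  # aperm to (Z,Y,X) so column-major flattening makes X outermost
  writeBin(as.integer(aperm(volume$voxels, c(3L, 2L, 1L))), con,
           size = 4L, endian = "little")
  jsonlite::write_json(list(extents = dim(volume$voxels),
                            spacing = volume$spacing,
                            sample_id = volume$sample_id,
                            dtype = "int32", order = "X_outermost"),
                       paste0(file_path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file_path)
}

#' Read a raw integer voxel stream
#'
#' @param file_path path written by [write_raw_volume()].
#' @param extents optional integer length 3 `(X, Y, Z)`; if missing, taken
#'   from the JSON sidecar.
#' @return a `ct_volume`.
#' @export
read_raw_volume <- function(file_path, extents = NULL) {
  side <- paste0(file_path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  if (is.null(extents)) {
    if (is.null(meta)) stop("no extents given and no sidecar found at ", side)
    extents <- meta$extents
  }
  extents <- as.integer(extents)
  n_expect <- prod(extents)
  n_bytes <- file.info(file_path)$size
  if (is.na(n_bytes) || n_bytes != 4 * n_expect)
    stop("file size (", n_bytes, " bytes) does not match declared extents (",
         paste(extents, collapse = "x"), " int32 = ", 4 * n_expect, " bytes)")
  con <- file(file_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n_expect, size = 4L, endian = "little")
  v <- aperm(array(v, dim = rev(extents)), c(3L, 2L, 1L))
  ct_volume(v,
            spacing = if (!is.null(meta)) meta$spacing else c(0.25, 0.351, 0.351),
            sample_id = if (!is.null(meta)) meta$sample_id else "raw")
}
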