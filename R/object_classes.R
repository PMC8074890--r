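#' Object-class scheme: partition of the shifted-HU range into bands
#'
#' The shifted Hounsfield range \[0, 6144\] is divided into contiguous
#' inclusive integer bands, each treated as one material category ("object
#' class"): low bands capture air-filled pores and organic matter, mid bands
#' the soil matrix, high bands stones. The default is six bands of width
#' 1024 — \[0,1023\], \[1024,2047\], ..., \[5120,6144\] — with the top band
#' absorbing 6144 so the clamped range is fully covered.
#'
#' @param breaks integer vector of band lower edges, starting at 0,
#'   strictly increasing; the last band runs to 6144.
#' @return an `object_class_scheme`: data.frame with columns `class`, `lo`,
#'   `hi`.
#' @export
object_class_scheme <- function(breaks = seq(0L, 5120L, by = 1024L)) {
  breaks <- as.integer(breaks)
  if (breaks[1] != 0L || is.unsorted(breaks, strictly = TRUE) ||
      breaks[length(breaks)] > 6144L)
    stop("breaks must start at 0, be strictly increasing, and stay <= 6144")
  hi <- c(breaks[-1] - 1L, 6144L)
  structure(data.frame(class = seq_along(breaks), lo = breaks, hi = hi),
            class = c("object_class_scheme", "data.frame"))
}

#' Classify shifted-HU values into object-class bands
#'
#' @param shifted_hu integer/numeric vector of values in \[0, 6144\].
#' @param scheme an [object_class_scheme()].
#' @return integer vector of 1-based class indices.
#' @export
classify_voxel <- function(shifted_hu, scheme = object_class_scheme()) {
  v <- as.integer(shifted_hu)
  if (anyNA(v) || any(v < 0L) || any(v > 6144L))
    stop("values must lie in [0, 6144]")
  findInterval(v, c(scheme$lo, 6145L), rightmost.closed = FALSE)
}

#' Binarize a volume for a selected object class
#'
#' Codes the selected class(es) as the solid phase: voxel value 1 iff its
#' class index is in `class_indices`, else 0 (void). Multi-band solids (e.g.
#' classes `{5, 6}` for all stones) are supported; the mask is the union of
#' the per-band masks.
#'
#' @param volume a `ct_volume` (or a bare integer array of shifted HU).
#' @param class_indices non-empty integer set of class indices.
#' @param scheme an [object_class_scheme()].
#' @return integer array of 0/1 with the same dim; attribute `solid_classes`
#'   records the selection.
#' @export
binarize <- function(volume, class_indices, scheme = object_class_scheme()) {
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  class_indices <- unique(as.integer(class_indices))
  if (length(class_indices) == 0L) stop("class_indices must be non-empty")
  if (any(!class_indices %in% scheme$class))
    stop("unknown class index: ",
         paste(setdiff(class_indices, scheme$class), collapse = ", "))
  sel <- scheme[scheme$class %in% class_indices, , drop = FALSE]
  m <- array(0L, dim = dim(v))
  for (i in seq_len(nrow(sel)))
    m[v >= sel$lo[i] & v <= sel$hi[i]] <- 1L
  attr(m, "solid_classes") <- sort(class_indices)
  m
}

#' Remove small solid clusters from a binary mask
#'
#' Connected clusters of the solid phase (value 1) with fewer than
#' `min_size` voxels are reassigned to void — the "root filter" that drops
#' fragments too small to matter structurally. Clusters of exactly
#' `min_size` voxels survive. Applied once on the full 3D mask so clusters
#' spanning slices are sized in 3D.
#'
#' @param mask 2D/3D integer array of 0/1 (solid = 1).
#' @param min_size minimum surviving cluster size in voxels; default 60.
#' @param connectivity 6 or 26 in 3D (4 or 8 in 2D); default 26/8, since
#'   diagonal grain contacts are common in granular media.
#' @return the trimmed mask (attributes preserved).
#' @export
trim_small_clusters <- function(mask, min_size = 60L, connectivity = 26L) {
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_size == 1L) return(mask)
  if (is.null(dim(mask))) stop("mask must have dim")
  lab <- .label_components(mask, as.integer(connectivity))
  n <- attr(lab, "n_components")
  if (n == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  kill <- which(sizes < min_size)
  if (length(kill)) {
    out <- mask
    out[lab %in% kill] <- 0L
    attributes(out) <- attributes(mask)
    return(out)
  }
  mask
}

#' Per-slice porosity of a binary slice
#'
#' Porosity in the wide sense: `Area(void) / (Area(void) + Area(solid))`,
#' the fraction of 0-coded pixels, whatever fills them (air, water, roots).
#'
#' @param slice 2D 0/1 array (or vector); must be non-empty.
#' @return porosity in \[0, 1\].
#' @export
slice_porosity <- function(slice) {
  n <- length(slice)
  if (n == 0L) stop("zero-size slice")
  sum(slice == 0L) / n
}

#' Porosity profile of a binary volume along the core axis
#'
#' @param mask 3D 0/1 array with slices along X (first dim).
#' @param spacing_mm slice thickness for the depth column; default 0.25.
#' @return a `porosity_profile`: data.frame with `slice_index` (0-based),
#'   `depth_mm`, `porosity`.
#' @export
porosity_profile <- function(mask, spacing_mm = 0.25) {
  stopifnot(length(dim(mask)) == 3L)
  nx <- dim(mask)[1]
  area <- prod(dim(mask)[2:3])
  solid <- rowSums(mask != 0L, dims = 1L)
  p <- 1 - solid / area
  structure(data.frame(slice_index = seq_len(nx) - 1L,
                       depth_mm = (seq_len(nx) - 1L) * spacing_mm,
                       porosity = p),
            solid_classes = attr(mask, "solid_classes"),
            class = c("porosity_profile", "data.frame"))
}

#' Surrogate annotation: per-slice porosity profile of selected classes
#'
#' The full annotation chain for one volume and one target:
#' [binarize()] with the target classes as solid, then
#' [trim_small_clusters()] on the 3D mask, then [porosity_profile()]. The
#' resulting profile is the automatically computed training annotation — no
#' manual labels anywhere.
#'
#' @param volume a `ct_volume`.
#' @param target_classes integer set of class indices defining the solid.
#' @param scheme an [object_class_scheme()].
#' @param trim_min_size cluster-size threshold; 1 disables trimming.
#' @param connectivity passed to [trim_small_clusters()].
#' @return a `porosity_profile` data.frame.
#' @export
annotate_volume <- function(volume, target_classes,
                            scheme = object_class_scheme(),
                            trim_min_size = 60L, connectivity = 26L) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- binarize(volume, target_classes, scheme)
  m <- trim_small_clusters(m, min_size = trim_min_size,
                           connectivity = connectivity)
  porosity_profile(m, spacing_mm = volume$spacing[1])
}

#' Write a porosity profile as CSV
#'
#' Columns: `slice_index`, `depth_mm`, `porosity`.
#' @param profile a `porosity_profile`.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("slice_index", "depth_mm",
                                              "porosity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot porosity-vs-depth curves
#'
#' Draws one curve per profile, mirroring the standard depth-profile figure
#' for the six object classes.
#'
#' @param profiles a named list of `porosity_profile`s (names used in the
#'   legend), or a single profile.
#' @param main plot title.
#' @export
plot_profiles <- function(profiles, main = "Porosity profile") {
  if (inherits(profiles, "porosity_profile")) profiles <- list(profiles)
  cols <- grDevices::hcl.colors(max(3L, length(profiles)), "Dark 3")
  graphics::plot(NULL, xlim = range(profiles[[1]]$depth_mm), ylim = c(0, 1),
                 xlab = "depth (mm)", ylab = "porosity", main = main)
  for (i in seq_along(profiles))
    graphics::lines(profiles[[i]]$depth_mm, profiles[[i]]$porosity,
                    col = cols[i], lwd = 1.5)
  if (!is.null(names(profiles)))
    graphics::legend("topright", legend = names(profiles),
                     col = cols[seq_along(profiles)], lwd = 1.5, cex = 0.8)
  invisible(NULL)
}
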