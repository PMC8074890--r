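# Seeded synthetic soil-core generator. Emulates what a clinical CT of an
# undisturbed core contains — a soil-matrix background with embedded
# low-HU pores and organic blobs, high-HU stones, and burrow-like tunnels —
# while keeping exact voxel-level material labels, so the ground-truth
# porosity of every object-class band is known by construction.

.default_materials <- function() {
  data.frame(
    name  = c("matrix", "pore", "organic", "dense_mineral", "stone",
              "coarse_stone"),
    hu_lo = c(2300L,  200L, 1200L, 3300L, 4200L, 5300L),
    hu_hi = c(2900L,  900L, 1900L, 3900L, 4900L, 6000L),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic soil core
#'
#' A `synthetic_spec` is a stated world: a material palette (name + HU
#' interval, each interval lying inside one object-class band of the default
#' scheme) and a shape inventory rasterized into a matrix-phase background.
#' Shape kinds: `sphere` (stones, isolated pores), `ellipsoid` (organic
#' blobs, dense mineral), `tunnel` (an axis-meandering cylinder running the
#' full core length, like a burrow). `depth` restricts a shape group to a
#' fraction range of the core axis, which is how depth heterogeneity (e.g.
#' an organic-rich topsoil over a stony subsoil) is emulated.
#'
#' Presets:
#' \describe{
#'   \item{heterogeneous}{all six materials, organic concentrated in the
#'     upper core and stones in the lower — profiles vary strongly with
#'     depth, like a layered forest soil.}
#'   \item{homogeneous}{pores only, uniform with depth — like a uniform
#'     sandy grassland core.}
#'   \item{organic_rich}{pores + many organic blobs, no stones.}
#'   \item{stony}{stones + dense mineral, few pores.}
#' }
#'
#' @param preset one of the presets above, or `"custom"` to use `shapes`
#'   as given.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @param extents integer `(X, Y, Z)`; default `(100, 64, 64)` desk scale.
#' @param materials data.frame with columns `name`, `hu_lo`, `hu_hi`.
#' @param shapes list of groups: `list(material=, kind=, n=, size=c(lo,hi),
#'   depth=c(lo,hi))`; only used with `preset = "custom"`.
#' @param jitter if TRUE (default) voxel HU is sampled uniformly within the
#'   material interval; if FALSE the interval midpoint is used.
#' @param sample_id label for the generated volume.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("heterogeneous", "homogeneous",
                                      "organic_rich", "stony", "custom"),
                           seed = 1L, extents = c(100L, 64L, 64L),
                           materials = .default_materials(), shapes = NULL,
                           jitter = TRUE, sample_id = NULL) {
  preset <- match.arg(preset)
  grp <- function(material, kind, n, size, depth = c(0, 1))
    list(material = material, kind = kind, n = n, size = size, depth = depth)
  if (preset != "custom") {
    shapes <- switch(preset,
      # organic bodies are deliberately coarser than resolved pores: at
      # clinical-CT resolution organic aggregates span many voxels while
      # visible pores are near the resolution limit, and that size contrast
      # is what lets a network separate the two materials sharing the
      # low-HU input channel
      heterogeneous = list(
        grp("pore", "sphere", 25L, c(1.5, 3)),
        grp("pore", "tunnel", 2L, c(1.5, 2.5)),
        grp("organic", "ellipsoid", 15L, c(4, 10), depth = c(0, 0.45)),
        grp("dense_mineral", "ellipsoid", 8L, c(2, 5), depth = c(0.4, 1)),
        grp("stone", "sphere", 12L, c(2, 6), depth = c(0.5, 1)),
        grp("coarse_stone", "sphere", 4L, c(2, 4), depth = c(0.6, 1))),
      homogeneous = list(
        grp("pore", "sphere", 25L, c(1.5, 3))),
      organic_rich = list(
        grp("pore", "sphere", 20L, c(1.5, 3)),
        grp("pore", "tunnel", 2L, c(1.5, 2.5)),
        grp("organic", "ellipsoid", 25L, c(4, 9))),
      stony = list(
        grp("pore", "sphere", 8L, c(1, 3)),
        grp("dense_mineral", "ellipsoid", 12L, c(3, 6)),
        grp("stone", "sphere", 18L, c(3, 7)),
        grp("coarse_stone", "sphere", 6L, c(2, 5))))
  }
  if (is.null(shapes)) shapes <- list()
  if (any(materials$hu_lo < 0L) || any(materials$hu_hi > 6144L) ||
      any(materials$hu_lo > materials$hu_hi))
    stop("material HU intervals must be ordered and inside [0, 6144]")
  for (g in shapes)
    if (!g$material %in% materials$name)
      stop("shape group references unknown material: ", g$material)
  structure(list(preset = preset, seed = as.integer(seed),
                 extents = as.integer(extents), materials = materials,
                 shapes = shapes, jitter = isTRUE(jitter),
                 sample_id = sample_id %||% sprintf("syn_%s_%d", preset, seed)),
            class = "synthetic_spec")
}

.rasterize_sphere <- function(labels, center, r, id) {
  d <- dim(labels)
  rng <- lapply(1:3, function(a)
    max(1L, floor(center[a] - r)):min(d[a], ceiling(center[a] + r)))
  dx2 <- (rng[[1]] - center[1])^2
  dy2 <- (rng[[2]] - center[2])^2
  dz2 <- (rng[[3]] - center[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  sub <- labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub[inside] <- id
  labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
  labels
}

.rasterize_ellipsoid <- function(labels, center, semi, id) {
  d <- dim(labels)
  rng <- lapply(1:3, function(a)
    max(1L, floor(center[a] - semi[a])):min(d[a], ceiling(center[a] + semi[a])))
  dx2 <- ((rng[[1]] - center[1]) / semi[1])^2
  dy2 <- ((rng[[2]] - center[2]) / semi[2])^2
  dz2 <- ((rng[[3]] - center[3]) / semi[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  sub <- labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub[inside] <- id
  labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
  labels
}

# burrow-like tunnel: a disc of radius r stamped at every slice, whose
# (Y,Z) centre performs a bounded random walk along X
.rasterize_tunnel <- function(labels, r, id) {
  d <- dim(labels)
  cy <- stats::runif(1, r + 1, d[2] - r)
  cz <- stats::runif(1, r + 1, d[3] - r)
  ys <- seq_len(d[2]); zs <- seq_len(d[3])
  for (x in seq_len(d[1])) {
    inside <- outer((ys - cy)^2, (zs - cz)^2, "+") <= r^2
    sl <- labels[x, , ]
    sl[inside] <- id
    labels[x, , ] <- sl
    cy <- min(max(cy + stats::rnorm(1, sd = 0.8), r + 1), d[2] - r)
    cz <- min(max(cz + stats::rnorm(1, sd = 0.8), r + 1), d[3] - r)
  }
  labels
}

#' Generate a synthetic soil-core volume with ground truth
#'
#' Deterministic for a fixed spec (seed included): shapes are rasterized in
#' declared order, later shapes overwriting earlier ones so each voxel has
#' exactly one material label; HU values are then drawn per voxel within
#' each material's interval (jitter never leaves the material's band, so
#' band classification of the volume reproduces the labels exactly).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `volume` (a `ct_volume`) and `truth` (a `ground_truth`:
#'   the label grid plus the material table with its object-class indices).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$extents
  mat <- spec$materials
  scheme <- object_class_scheme()
  classes <- lapply(seq_len(nrow(mat)), function(i)
    unique(classify_voxel(c(mat$hu_lo[i], mat$hu_hi[i]), scheme)))
  if (any(vapply(classes, length, 0L) > 2L))
    stop("material HU interval spans more than two bands")
  labels <- array(1L, dim = d)  # material 1 ("matrix") is the background
  local_seed(spec$seed, {
    for (g in spec$shapes) {
      id <- match(g$material, mat$name)
      for (j in seq_len(g$n)) {
        xlo <- 1 + g$depth[1] * (d[1] - 1); xhi <- 1 + g$depth[2] * (d[1] - 1)
        if (g$kind == "sphere") {
          r <- stats::runif(1, g$size[1], g$size[2])
          ctr <- c(stats::runif(1, xlo, xhi), stats::runif(1, 1, d[2]),
                   stats::runif(1, 1, d[3]))
          labels <- .rasterize_sphere(labels, ctr, r, id)
        } else if (g$kind == "ellipsoid") {
          semi <- stats::runif(3, g$size[1], g$size[2])
          ctr <- c(stats::runif(1, xlo, xhi), stats::runif(1, 1, d[2]),
                   stats::runif(1, 1, d[3]))
          labels <- .rasterize_ellipsoid(labels, ctr, semi, id)
        } else if (g$kind == "tunnel") {
          r <- stats::runif(1, g$size[1], g$size[2])
          labels <- .rasterize_tunnel(labels, r, id)
        } else stop("unknown shape kind: ", g$kind)
      }
    }
    vox <- array(0L, dim = d)
    for (i in seq_len(nrow(mat))) {
      idx <- which(labels == i)
      if (!length(idx)) next
      vox[idx] <- if (spec$jitter)
        as.integer(stats::runif(length(idx), mat$hu_lo[i], mat$hu_hi[i] + 1))
      else as.integer((mat$hu_lo[i] + mat$hu_hi[i]) %/% 2L)
    }
    volume <- ct_volume(vox, sample_id = spec$sample_id)
    truth <- structure(list(labels = labels,
                            materials = cbind(mat, id = seq_len(nrow(mat))),
                            classes = classes, extents = d),
                       class = "ground_truth")
  })
  list(volume = volume, truth = truth)
}

#' Exact porosity profile from ground-truth labels
#'
#' Computes the per-slice porosity of a class selection straight from the
#' material labels, bypassing the imaging pipeline entirely — the oracle
#' against which [annotate_volume()] (with trimming disabled) must agree
#' exactly.
#'
#' @param gt a `ground_truth` from [generate_volume()].
#' @param class_selection integer set of object-class indices (the solid).
#' @param spacing_mm slice thickness for the depth column.
#' @return a `porosity_profile` data.frame.
#' @export
ground_truth_profile <- function(gt, class_selection, spacing_mm = 0.25) {
  stopifnot(inherits(gt, "ground_truth"))
  class_selection <- unique(as.integer(class_selection))
  if (!length(class_selection) || any(!class_selection %in% 1:6))
    stop("class_selection must be a non-empty subset of 1..6")
  solid_ids <- integer(0)
  for (i in seq_along(gt$classes)) {
    cl <- gt$classes[[i]]
    inside <- cl %in% class_selection
    if (all(inside)) solid_ids <- c(solid_ids, i)
    else if (any(inside))
      stop("material '", gt$materials$name[i],
           "' spans the selection boundary; ground truth would be inexact")
  }
  solid <- array(gt$labels %in% solid_ids, dim = gt$extents)
  p <- 1 - rowSums(solid, dims = 1L) / prod(gt$extents[2:3])
  structure(data.frame(slice_index = seq_len(gt$extents[1]) - 1L,
                       depth_mm = (seq_len(gt$extents[1]) - 1L) * spacing_mm,
                       porosity = p),
            solid_classes = sort(class_selection),
            class = c("porosity_profile", "data.frame"))
}
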