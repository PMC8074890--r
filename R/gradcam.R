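# Grad-CAM for the scalar-output regression model. Classic grad-CAM
# differentiates a class score; with a (1x1x1) head the porosity output is
# differentiated directly. The heatmap is the ReLU of the gradient-weighted
# sum of a conv layer's activation maps, max-normalized and bilinearly
# upsampled to the input extents.

.bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ri <- if (h == 1L) rep(1, H) else (seq_len(H) - 1) * (h - 1) / (H - 1) + 1
  ci <- if (w == 1L) rep(1, W) else (seq_len(W) - 1) * (w - 1) / (W - 1) + 1
  r0 <- pmin(floor(ri), h - 1L); r0[h == 1L] <- 1L
  c0 <- pmin(floor(ci), w - 1L); c0[w == 1L] <- 1L
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

#' Grad-CAM heatmap for one input image
#'
#' Computes the gradient of the scalar porosity prediction with respect to
#' the target conv layer's (post-activation) maps, averages it spatially
#' into per-channel weights, forms the weighted sum of the activation maps,
#' zeroes negative values, normalizes by the maximum (an identically zero
#' map stays zero) and upsamples to the input size. Any conv layer can be
#' targeted; the default is the last one, whose maps carry the most
#' task-specific spatial evidence.
#'
#' @param model a trained `porosity_model`.
#' @param image a channel image `(H, W, C)` matching the model input.
#' @param target_layer conv layer name (e.g. `"conv2_2"`) or index in the
#'   layer list; default: last conv layer.
#' @return a `heat_map`: `(H, W)` matrix in \[0, 1\] with attributes
#'   `target_layer` and `prediction`.
#' @export
grad_cam <- function(model, image, target_layer = NULL) {
  stopifnot(inherits(model, "porosity_model"))
  if (length(dim(image)) != 3L || !all(dim(image) == model$input_dim))
    stop("image must be (", paste(model$input_dim, collapse = "x"), ")")
  conv_idx <- which(vapply(model$layers, function(l) l$type == "conv", TRUE))
  li <- if (is.null(target_layer)) {
    conv_idx[length(conv_idx)]
  } else if (is.character(target_layer)) {
    hit <- which(vapply(model$layers, function(l)
      identical(l$name, target_layer), TRUE))
    if (!length(hit)) stop("no layer named '", target_layer, "'")
    hit[1]
  } else as.integer(target_layer)
  if (!(li %in% conv_idx))
    stop("target layer must be a convolutional layer")
  x <- image; dim(x) <- c(1L, dim(image))
  fw <- .nn_forward(model, x, cache = TRUE)
  bw <- .nn_backward(model, fw, 1, stop_layer = li)
  A <- fw$acts[[li]]; dA <- bw$d_act
  d <- dim(A)  # (1, H', W', F)
  A <- array(A, d[-1]); dA <- array(dA, d[-1])
  wts <- apply(dA, 3L, mean)
  cam <- matrix(0, d[2], d[3])
  for (c in seq_len(d[4])) cam <- cam + wts[c] * A[, , c]
  cam[cam < 0] <- 0
  hm <- .bilinear_upsample(cam, dim(image)[1], dim(image)[2])
  hm[hm < 0] <- 0  # guard against fp wiggle in interpolation
  # normalize after upsampling so the delivered map peaks at exactly 1
  if (max(hm) > 0) hm <- hm / max(hm)
  structure(hm, class = c("heat_map", class(hm)),
            target_layer = model$layers[[li]]$name,
            prediction = fw$out)
}

#' Overlay a heatmap on its source image
#'
#' Alpha-blends a color-mapped heatmap over the grayscale slice (channel
#' mean of a channel image). Where the heatmap is zero the base image shows
#' through unchanged.
#'
#' @param heatmap a `heat_map` (values in \[0, 1\]).
#' @param image `(H, W)` grayscale or `(H, W, C)` channel image with the
#'   same spatial extents.
#' @param alpha maximum blend weight of the colormap (default 0.6).
#' @return `(H, W, 3)` RGB array in \[0, 1\].
#' @export
overlay <- function(heatmap, image, alpha = 0.6) {
  gray <- if (length(dim(image)) == 3L) apply(image, c(1, 2), mean) else image
  if (!all(dim(heatmap)[1:2] == dim(gray)))
    stop("heatmap and image extents differ")
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, "Inferno"))
  cols <- ramp(pmin(1, pmax(0, as.vector(heatmap)))) / 255
  a <- alpha * as.vector(heatmap)
  out <- array(0, dim = c(dim(gray), 3L))
  for (c in 1:3)
    out[, , c] <- (1 - a) * as.vector(gray) + a * cols[, c]
  out
}

#' Save an RGB array (e.g. an [overlay()] composite) as PNG
#' @param rgb `(H, W, 3)` array in \[0, 1\].
#' @param path output path.
#' @export
save_rgb_png <- function(rgb, path) {
  grDevices::png(path, width = dim(rgb)[2], height = dim(rgb)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(path)
}
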