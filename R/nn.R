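# VGG-style regression network: layer constructors, forward/backward engine,
# and the Adam update. Batches are [N, H, W, C] arrays; dense layers operate
# on [N, features] matrices. Convolutions are 3x3, same padding, stride 1;
# pooling is 2x2 max with stride 2 (odd trailing rows/columns are dropped,
# the standard valid-pooling convention).

.he_init <- function(nrow, ncol, fan_in, linear = FALSE) {
  sd <- sqrt((if (linear) 1 else 2) / fan_in)
  matrix(stats::rnorm(nrow * ncol, sd = sd), nrow, ncol)
}

.layer_conv <- function(name, c_in, filters, activation = "relu") {
  list(type = "conv", name = name, k = 3L, pad = 1L,
       W = .he_init(9L * c_in, filters, 9L * c_in),
       b = numeric(filters), activation = activation, trainable = TRUE)
}
.layer_dense <- function(name, n_in, n_out, activation = "relu") {
  list(type = "dense", name = name,
       W = .he_init(n_in, n_out, n_in, linear = activation == "linear"),
       b = numeric(n_out), activation = activation, trainable = TRUE)
}

.conv_widths <- function(scale) {
  switch(scale,
         mini = list(blocks = list(c(8L, 8L), c(16L, 16L)), dense = 64L),
         full = list(blocks = list(c(64L, 64L), c(128L, 128L),
                                   c(256L, 256L, 256L),
                                   c(512L, 512L, 512L),
                                   c(512L, 512L, 512L)),
                     dense = c(4096L, 4096L)),
         stop("unknown scale: ", scale))
}

#' Build an untrained convolutional regression model
#'
#' Constructs a VGG-style network — stacked 3x3 convolutions with max
#' pooling, then dense layers — whose head is a single linear unit, so the
#' scalar slice porosity can be the training target. `scale = "full"` is the
#' 16-layer reference topology (13 conv + 3 dense) with the 1000-way
#' classification layer replaced by one unit; `scale = "mini"` is a
#' 2-block desk-scale variant for CPU experiments.
#'
#' @param input_extents integer `(H, W)` or `(H, W, channels)`; channels
#'   default to 3 (the band-stacked input of [build_channel_image()]).
#' @param scale `"mini"` or `"full"`.
#' @param seed integer; weight initialisation is seeded and reproducible.
#' @return a `porosity_model`.
#' @export
build_model <- function(input_extents, scale = c("mini", "full"), seed = 1L) {
  scale <- match.arg(scale)
  input_extents <- as.integer(input_extents)
  if (length(input_extents) == 2L) input_extents <- c(input_extents, 3L)
  stopifnot(length(input_extents) == 3L)
  cfg <- .conv_widths(scale)
  depth <- length(cfg$blocks)
  hw <- input_extents[1:2]
  if (any(hw %/% 2L^depth < 1L))
    stop("input ", paste(hw, collapse = "x"),
         " too small for pooling depth ", depth)
  layers <- list()
  local_seed(seed, {
    c_in <- input_extents[3]
    for (b in seq_along(cfg$blocks)) {
      widths <- cfg$blocks[[b]]
      for (j in seq_along(widths)) {
        layers[[length(layers) + 1L]] <-
          .layer_conv(sprintf("conv%d_%d", b, j), c_in, widths[j])
        c_in <- widths[j]
      }
      layers[[length(layers) + 1L]] <- list(type = "maxpool",
                                            name = sprintf("pool%d", b))
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten", name = "flatten")
    n_in <- prod(hw %/% 2L^depth) * c_in
    for (j in seq_along(cfg$dense)) {
      layers[[length(layers) + 1L]] <-
        .layer_dense(sprintf("fc%d", j), n_in, cfg$dense[j])
      n_in <- cfg$dense[j]
    }
    layers[[length(layers) + 1L]] <-
      .layer_dense("output", n_in, 1L, activation = "linear")
  })
  structure(list(layers = layers, input_dim = input_extents, scale = scale,
                 seed = seed, metrics = NULL),
            class = "porosity_model")
}

#' @export
print.porosity_model <- function(x, ...) {
  cat(sprintf("porosity_model (scale=%s, input %s)\n", x$scale,
              paste(x$input_dim, collapse = "x")))
  for (l in x$layers) {
    np <- if (!is.null(l$W)) length(l$W) + length(l$b) else 0L
    cat(sprintf("  %-10s %-8s params=%-9d %s\n", l$name, l$type, np,
                if (isFALSE(l$trainable)) "frozen" else ""))
  }
  if (!is.null(x$metrics))
    cat(sprintf("  fitted: train RMSE %.5f / held-out RMSE %.5f\n",
                x$metrics$train_rmse, x$metrics$val_rmse))
  invisible(x)
}

#' Count parameters of a model
#' @param model a `porosity_model`.
#' @param trainable_only count only layers currently marked trainable.
#' @return integer parameter count.
#' @export
n_params <- function(model, trainable_only = FALSE) {
  sum(vapply(model$layers, function(l) {
    if (is.null(l$W)) return(0)
    if (trainable_only && isFALSE(l$trainable)) return(0)
    length(l$W) + length(l$b)
  }, 0))
}

# forward pass; returns list(out = N-vector, acts, pools) when cache = TRUE
.nn_forward <- function(model, x, cache = FALSE) {
  if (length(dim(x)) == 3L) {
    d <- dim(x); dim(x) <- c(1L, d)   # single image -> batch of 1
  }
  acts <- if (cache) vector("list", length(model$layers))
  pools <- if (cache) vector("list", length(model$layers))
  a <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    a <- switch(l$type,
      conv = {
        y <- .conv2d_forward(a, l$W, l$b, l$k, l$pad)
        if (l$activation == "relu") y[y < 0] <- 0
        y
      },
      maxpool = {
        mp <- .maxpool2_forward(a)
        if (cache) pools[[i]] <- list(argmax = mp$argmax, in_dim = dim(a))
        mp$Y
      },
      flatten = {
        d <- dim(a)
        if (cache) pools[[i]] <- list(in_dim = d)
        dim(a) <- c(d[1], prod(d[-1]))
        a
      },
      dense = {
        y <- sweep(a %*% l$W, 2L, l$b, "+")
        if (l$activation == "relu") y[y < 0] <- 0
        y
      },
      stop("unknown layer type"))
    if (cache) acts[[i]] <- a
  }
  out <- as.numeric(a)
  if (cache) list(out = out, input = x, acts = acts, pools = pools) else out
}

# backward pass from d(loss)/d(out). Returns per-layer grads; if
# stop_layer > 0, instead returns the gradient w.r.t. that layer's
# (post-activation) output as soon as it is reached.
.nn_backward <- function(model, fw, dout, stop_layer = 0L) {
  grads <- vector("list", length(model$layers))
  d <- matrix(dout, ncol = 1L)
  for (i in rev(seq_along(model$layers))) {
    if (i == stop_layer) return(list(d_act = d))
    l <- model$layers[[i]]
    a_prev <- if (i == 1L) fw$input else fw$acts[[i - 1L]]
    if (l$type == "dense") {
      if (l$activation == "relu") d <- d * (fw$acts[[i]] > 0)
      grads[[i]] <- list(dW = crossprod(a_prev, d), db = colSums(d))
      d <- d %*% t(l$W)
    } else if (l$type == "flatten") {
      dim(d) <- fw$pools[[i]]$in_dim
    } else if (l$type == "maxpool") {
      d <- .maxpool2_backward(d, fw$pools[[i]]$argmax, fw$pools[[i]]$in_dim)
    } else if (l$type == "conv") {
      if (l$activation == "relu") d <- d * (fw$acts[[i]] > 0)
      bw <- .conv2d_backward(a_prev, l$W, d, l$k, l$pad)
      grads[[i]] <- list(dW = bw$dW, db = bw$db)
      d <- bw$dX
    }
  }
  list(grads = grads)
}

.adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

.adam_step <- function(model, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(l$W) || isFALSE(l$trainable)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    l$W <- l$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    l$b <- l$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    model$layers[[i]] <- l
    state[[i]] <- s
  }
  list(model = model, state = state)
}

#' Predict porosity for new images
#'
#' Runs the forward pass; predictions are clipped into \[0, 1\] at inference
#' (the output unit itself is linear).
#'
#' @param object a `porosity_model`.
#' @param newdata a `training_dataset` or an image array (`[H,W,C]` or
#'   `[N,H,W,C]`).
#' @param clip clip predictions into \[0, 1\] (default TRUE).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return numeric vector of predicted porosities.
#' @export
predict.porosity_model <- function(object, newdata, clip = TRUE,
                                   batch_size = 64L, ...) {
  x <- if (inherits(newdata, "training_dataset")) newdata$x else newdata
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  n <- dim(x)[1]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    out[idx] <- .nn_forward(object, x[idx, , , , drop = FALSE])
  }
  if (clip) out <- pmin(1, pmax(0, out))
  out
}

#' Root mean squared error of a model on a dataset
#'
#' @param model a trained `porosity_model`.
#' @param dataset a non-empty `training_dataset`.
#' @return RMSE of predictions vs. surrogate targets.
#' @export
evaluate_rmse <- function(model, dataset) {
  stopifnot(inherits(dataset, "training_dataset"))
  if (length(dataset$y) == 0L) stop("empty dataset")
  p <- predict(model, dataset)
  sqrt(mean((p - dataset$y)^2))
}
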