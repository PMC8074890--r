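# Transfer learning: keep the convolutional stack constant, retrain only the
# dense head on a different surrogate target. Success here is the paper-style
# evidence that the conv stack learned a generalized representation of the
# soil structure rather than one target's shortcut.

#' Freeze the convolutional stack of a model
#'
#' Marks every convolutional layer non-trainable; the dense head stays
#' trainable. Weights themselves are untouched. Idempotent.
#'
#' @param model a `porosity_model` with at least one dense layer.
#' @return the model with conv layers frozen.
#' @export
freeze_conv <- function(model) {
  stopifnot(inherits(model, "porosity_model"))
  if (!any(vapply(model$layers, function(l) l$type == "dense", TRUE)))
    stop("model has no dense head")
  for (i in seq_along(model$layers))
    if (model$layers[[i]]$type == "conv")
      model$layers[[i]]$trainable <- FALSE
  model
}

# index of the flatten layer (boundary between conv stack and dense head)
.flatten_index <- function(model) {
  which(vapply(model$layers, function(l) l$type == "flatten", TRUE))[1]
}

# forward through the frozen conv stack only -> [N, features] matrix
.conv_features <- function(model, x, batch_size = 64L) {
  fi <- .flatten_index(model)
  stub <- model
  stub$layers <- model$layers[seq_len(fi)]
  n <- dim(x)[1]
  out <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    f <- .nn_forward(stub, x[idx, , , , drop = FALSE], cache = TRUE)
    feat <- f$acts[[fi]]
    if (is.null(out)) out <- matrix(0, n, ncol(feat))
    out[idx, ] <- feat
  }
  out
}

#' Retrain the dense head on a new surrogate target
#'
#' The conv stack must already be frozen ([freeze_conv()]); its weights are
#' bit-identical before and after. Because the frozen stack is a fixed
#' function, its features are precomputed once and only the dense head is
#' iterated, which is what makes transfer runs much cheaper than full
#' training. By default the dense head is re-initialised (seeded) before
#' training, so nothing carries over from the old target but the conv
#' representation; set `reinit_dense = FALSE` to warm-start instead.
#'
#' @param model a frozen `porosity_model`.
#' @param new_dataset `training_dataset` with the new target.
#' @param config a [train_config()]; `config$validation` is used for early
#'   stopping as in [train()].
#' @param reinit_dense re-initialise dense weights before training (default
#'   TRUE).
#' @return list with `model` and `history`, as [train()].
#' @export
transfer_train <- function(model, new_dataset, config = train_config(),
                           reinit_dense = TRUE) {
  stopifnot(inherits(model, "porosity_model"),
            inherits(new_dataset, "training_dataset"))
  conv_idx <- which(vapply(model$layers, function(l) l$type == "conv", TRUE))
  if (any(vapply(model$layers[conv_idx], function(l)
    !isFALSE(l$trainable), TRUE)))
    stop("conv stack is not frozen; call freeze_conv() first")
  if (!all(dim(new_dataset$x)[2:4] == model$input_dim))
    stop("dataset images (", paste(dim(new_dataset$x)[2:4], collapse = "x"),
         ") incompatible with model input (",
         paste(model$input_dim, collapse = "x"), ")")
  fi <- .flatten_index(model)
  dense_idx <- which(vapply(model$layers, function(l) l$type == "dense", TRUE))
  if (reinit_dense) {
    local_seed(config$seed, {
      for (i in dense_idx) {
        l <- model$layers[[i]]
        model$layers[[i]]$W <- .he_init(nrow(l$W), ncol(l$W), nrow(l$W),
                                        linear = l$activation == "linear")
        model$layers[[i]]$b <- numeric(length(l$b))
      }
    })
  }
  if (is.null(config$validation)) {
    sp <- split_dataset(new_dataset, 1 - config$validation_fraction,
                        seed = config$seed + 1L)
    tr <- sp$train; va <- sp$test
  } else {
    tr <- new_dataset; va <- config$validation
  }
  feat_tr <- .conv_features(model, tr$x)
  feat_va <- .conv_features(model, va$x)

  # dense-head-only model operating on the precomputed features
  head <- structure(list(layers = model$layers[dense_idx],
                         input_dim = ncol(feat_tr), scale = model$scale,
                         seed = model$seed, metrics = NULL),
                    class = "porosity_model")
  head_fw <- function(h, f) {
    a <- f
    for (l in h$layers) {
      a <- sweep(a %*% l$W, 2L, l$b, "+")
      if (l$activation == "relu") a[a < 0] <- 0
    }
    as.numeric(a)
  }
  head_rmse <- function(h, f, y)
    sqrt(mean((pmin(1, pmax(0, head_fw(h, f))) - y)^2))

  n <- nrow(feat_tr)
  state <- .adam_init(head)
  best <- list(rmse = Inf, layers = head$layers, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                     val_rmse = numeric(0))
  t_step <- 0L
  local_seed(config$seed + 7L, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample(n)
      for (s in seq(1L, n, by = config$batch_size)) {
        bi <- idx[s:min(n, s + config$batch_size - 1L)]
        f <- feat_tr[bi, , drop = FALSE]
        # manual forward with caches
        acts <- vector("list", length(head$layers))
        a <- f
        for (j in seq_along(head$layers)) {
          l <- head$layers[[j]]
          a <- sweep(a %*% l$W, 2L, l$b, "+")
          if (l$activation == "relu") a[a < 0] <- 0
          acts[[j]] <- a
        }
        resid <- as.numeric(a) - tr$y[bi]
        if (!all(is.finite(resid)))
          stop("non-finite loss in transfer training at epoch ", ep)
        d <- matrix(2 * resid / length(bi), ncol = 1L)
        grads <- vector("list", length(head$layers))
        for (j in rev(seq_along(head$layers))) {
          l <- head$layers[[j]]
          if (l$activation == "relu") d <- d * (acts[[j]] > 0)
          a_prev <- if (j == 1L) f else acts[[j - 1L]]
          grads[[j]] <- list(dW = crossprod(a_prev, d), db = colSums(d))
          d <- d %*% t(l$W)
        }
        t_step <- t_step + 1L
        upd <- .adam_step(head, grads, state, config$lr, t_step)
        head <- upd$model; state <- upd$state
      }
      tr_rmse <- head_rmse(head, feat_tr, tr$y)
      va_rmse <- head_rmse(head, feat_va, va$y)
      hist <- rbind(hist, data.frame(epoch = ep, train_rmse = tr_rmse,
                                     val_rmse = va_rmse))
      if (config$verbose)
        message(sprintf("transfer epoch %3d  train %.5f  val %.5f", ep,
                        tr_rmse, va_rmse))
      if (va_rmse < best$rmse - 1e-9)
        best <- list(rmse = va_rmse, layers = head$layers, epoch = ep)
      if (ep - best$epoch >= config$patience) break
    }
  })
  model$layers[dense_idx] <- best$layers
  model$metrics <- list(train_rmse = head_rmse(
                          structure(list(layers = best$layers),
                                    class = "porosity_model"),
                          feat_tr, tr$y)[1],
                        val_rmse = best$rmse, epochs_run = nrow(hist),
                        best_epoch = best$epoch)
  list(model = model, history = hist)
}
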