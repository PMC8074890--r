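# Surrogate-annotated training data and the training loop. Inputs are
# band-stacked slice images (channel 1 = object classes 1+2, channel 2 =
# 3+4, channel 3 = 5+6 — the "RGB" the reference topology expects); targets
# are trimmed per-slice porosities, computed automatically by the annotation
# chain. The whole dataset is a pure function of (volume, scheme, config).

.channel_pairs <- function(scheme) {
  n <- nrow(scheme)
  if (n %% 2L != 0L)
    stop("band-stacked images need an even number of object classes")
  split(scheme$class, rep(seq_len(n / 2L), each = 2L))
}

#' Band-stacked channel image of one slice
#'
#' Builds the 3-channel network input for one X-slice: each channel is the
#' union solid mask of two adjacent object-class bands (binary, the
#' default), or the HU value min-max scaled within the pair's range when
#' `mode = "hu"`.
#'
#' @param volume a `ct_volume`.
#' @param slice_index 1-based slice position along X.
#' @param scheme an [object_class_scheme()] with an even number of bands.
#' @param mode `"binary"` (default) or `"hu"`.
#' @return numeric array `(Y, Z, n_bands/2)` with values in \[0, 1\].
#' @export
build_channel_image <- function(volume, slice_index,
                                scheme = object_class_scheme(),
                                mode = c("binary", "hu")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  if (slice_index < 1L || slice_index > d[1])
    stop("slice_index out of range [1, ", d[1], "]")
  pairs <- .channel_pairs(scheme)
  sl <- volume$voxels[slice_index, , , drop = TRUE]
  img <- array(0, dim = c(d[2], d[3], length(pairs)))
  for (c in seq_along(pairs)) {
    lo <- scheme$lo[min(pairs[[c]])]; hi <- scheme$hi[max(pairs[[c]])]
    img[, , c] <- if (mode == "binary") (sl >= lo & sl <= hi) + 0
    else ifelse(sl >= lo & sl <= hi, (sl - lo) / (hi - lo), 0)
  }
  img
}

.training_dataset <- function(x, y, provenance, target_classes) {
  stopifnot(dim(x)[1] == length(y), all(y >= 0 & y <= 1))
  structure(list(x = x, y = y, provenance = provenance,
                 target_classes = target_classes),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(paste0("training_dataset: %d samples of %dx%dx%d, target = ",
                     "porosity of class {%s}\n"),
              d[1], d[2], d[3], d[4],
              paste(x$target_classes, collapse = ",")))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds a `training_dataset`.
#' @export
n_samples <- function(ds) length(ds$y)

#' Subset a training dataset by sample index
#' @param ds a `training_dataset`.
#' @param idx integer sample indices.
#' @export
dataset_subset <- function(ds, idx) {
  .training_dataset(ds$x[idx, , , , drop = FALSE], ds$y[idx],
                    ds$provenance[idx, , drop = FALSE], ds$target_classes)
}

#' Assemble a surrogate-annotated training dataset
#'
#' One sample per slice of every volume: input = [build_channel_image()],
#' target = the slice's trimmed porosity for `target_classes` from
#' [annotate_volume()], index-aligned. No manual annotation is involved at
#' any point.
#'
#' @param volumes a `ct_volume` or a list of them.
#' @param target_classes integer set of class indices defining the target's
#'   solid phase (e.g. `3`, or `c(5, 6)`).
#' @param scheme an [object_class_scheme()].
#' @param trim_min_size cluster filter threshold for the targets (1 = off).
#' @param connectivity cluster connectivity for trimming.
#' @param mode channel mode, see [build_channel_image()].
#' @return a `training_dataset`.
#' @export
assemble_dataset <- function(volumes, target_classes,
                             scheme = object_class_scheme(),
                             trim_min_size = 60L, connectivity = 26L,
                             mode = c("binary", "hu")) {
  mode <- match.arg(mode)
  if (inherits(volumes, "ct_volume")) volumes <- list(volumes)
  if (length(volumes) == 0L) stop("at least one volume required")
  pairs <- .channel_pairs(scheme)
  d1 <- dim(volumes[[1]]$voxels)
  n_tot <- sum(vapply(volumes, function(v) dim(v$voxels)[1], 0L))
  x <- array(0, dim = c(n_tot, d1[2], d1[3], length(pairs)))
  y <- numeric(n_tot)
  prov <- data.frame(sample_id = character(n_tot), slice_index = integer(n_tot))
  at <- 0L
  for (v in volumes) {
    d <- dim(v$voxels)
    if (any(d[2:3] != d1[2:3]))
      stop("all volumes must share (Y, Z) extents")
    rows <- at + seq_len(d[1])
    for (c in seq_along(pairs)) {
      lo <- scheme$lo[min(pairs[[c]])]; hi <- scheme$hi[max(pairs[[c]])]
      x[rows, , , c] <- if (mode == "binary")
        (v$voxels >= lo & v$voxels <= hi) + 0
      else ifelse(v$voxels >= lo & v$voxels <= hi,
                  (v$voxels - lo) / (hi - lo), 0)
    }
    prof <- annotate_volume(v, target_classes, scheme,
                            trim_min_size = trim_min_size,
                            connectivity = connectivity)
    y[rows] <- prof$porosity
    prov$sample_id[rows] <- v$sample_id
    prov$slice_index[rows] <- seq_len(d[1])
    at <- at + d[1]
  }
  .training_dataset(x, y, prov, sort(unique(as.integer(target_classes))))
}

#' Split a dataset into train and test parts
#'
#' Seeded random split at the slice level by default (80/20), with an
#' optional per-volume grouped split for leakage-free experiments.
#'
#' @param dataset a `training_dataset` with at least 2 samples.
#' @param train_fraction in (0, 1); default 0.8.
#' @param seed split seed.
#' @param by_volume if TRUE, whole volumes are assigned to one side.
#' @return list with `train` and `test` datasets (disjoint, exhaustive).
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L,
                          by_volume = FALSE) {
  stopifnot(inherits(dataset, "training_dataset"))
  n <- n_samples(dataset)
  if (n < 2L) stop("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  local_seed(seed, {
    if (by_volume) {
      ids <- unique(dataset$provenance$sample_id)
      n_tr <- max(1L, round(train_fraction * length(ids)))
      tr_ids <- sample(ids, n_tr)
      tr <- which(dataset$provenance$sample_id %in% tr_ids)
    } else {
      tr <- sample(n, round(train_fraction * n))
    }
    te <- setdiff(seq_len(n), tr)
  })
  list(train = dataset_subset(dataset, sort(tr)),
       test = dataset_subset(dataset, sort(te)))
}

#' Training configuration
#'
#' Desk-scale defaults: Adam at learning rate 1e-3, batches of 32, up to 80
#' epochs with early stopping at patience 10 on held-out RMSE (best weights
#' restored). The held-out set is `validation` if given, else a seeded
#' `validation_fraction` carved from the training data.
#'
#' @param epochs,batch_size,lr,patience,seed,validation_fraction see above.
#' @param validation optional `training_dataset` used for early stopping.
#' @param verbose print per-epoch RMSE.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = 32L, lr = 1e-3,
                         patience = 10L, seed = 1L, validation = NULL,
                         validation_fraction = 0.15, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed),
                 validation = validation,
                 validation_fraction = validation_fraction,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a regression model on surrogate porosity targets
#'
#' Minimises mean squared error between the scalar prediction and the
#' surrogate porosity by mini-batch Adam, with early stopping on held-out
#' RMSE. Only layers marked trainable are updated, so the same routine
#' drives both from-scratch training and dense-only transfer runs.
#'
#' @param model an untrained (or frozen) `porosity_model`.
#' @param dataset the training `training_dataset`.
#' @param config a [train_config()].
#' @return list with `model` (best weights restored, `metrics` filled) and
#'   `history` (data.frame: epoch, train_rmse, val_rmse).
#' @export
train <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "porosity_model"),
            inherits(dataset, "training_dataset"))
  if (is.null(config$validation)) {
    sp <- split_dataset(dataset, 1 - config$validation_fraction,
                        seed = config$seed + 1L)
    tr <- sp$train; va <- sp$test
  } else {
    tr <- dataset; va <- config$validation
  }
  n <- n_samples(tr)
  state <- .adam_init(model)
  best <- list(rmse = Inf, layers = model$layers, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                     val_rmse = numeric(0))
  t_step <- 0L
  local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample(n)
      sse <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        bi <- idx[s:min(n, s + config$batch_size - 1L)]
        xb <- tr$x[bi, , , , drop = FALSE]
        fw <- .nn_forward(model, xb, cache = TRUE)
        resid <- fw$out - tr$y[bi]
        if (!all(is.finite(resid)))
          stop("non-finite loss at epoch ", ep, " (batch starting ", s,
               "); predictions range ",
               paste(range(fw$out), collapse = " .. "),
               " - try a lower learning rate")
        sse <- sse + sum(resid^2)
        bw <- .nn_backward(model, fw, 2 * resid / length(bi))
        t_step <- t_step + 1L
        upd <- .adam_step(model, bw$grads, state, config$lr, t_step)
        model <- upd$model; state <- upd$state
      }
      tr_rmse <- sqrt(sse / n)  # running pre-update loss, the usual report
      va_rmse <- evaluate_rmse(model, va)
      hist <- rbind(hist, data.frame(epoch = ep, train_rmse = tr_rmse,
                                     val_rmse = va_rmse))
      if (config$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tr_rmse,
                        va_rmse))
      if (va_rmse < best$rmse - 1e-9)
        best <- list(rmse = va_rmse, layers = model$layers, epoch = ep)
      if (ep - best$epoch >= config$patience) break
    }
  })
  model$layers <- best$layers
  model$metrics <- list(train_rmse = evaluate_rmse(model, tr),
                        val_rmse = best$rmse, epochs_run = nrow(hist),
                        best_epoch = best$epoch)
  list(model = model, history = hist)
}
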