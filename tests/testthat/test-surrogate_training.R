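make_tiny_volume <- function(seed, extents = c(24L, 16L, 16L)) {
  generate_volume(synthetic_spec("heterogeneous", seed = seed,
                                 extents = extents))$volume
}

test_that("channel images stack band-pair union masks", {
  v <- make_tiny_volume(1)
  img <- build_channel_image(v, 3L)
  expect_identical(dim(img), c(16L, 16L, 3L))
  # channel c equals binarize with that channel's band pair
  pairs <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  for (c in 1:3)
    expect_equal(img[, , c],
                 binarize(v$voxels[3L, , , drop = FALSE], pairs[[c]])[1, , ] + 0)
  # band partition: channels sum to 1 at every pixel
  expect_true(all(apply(img, c(1, 2), sum) == 1))
  # constant-2500 slice lights only channel 2
  cv <- ct_volume(array(2500L, c(2, 6, 6)))
  ci <- build_channel_image(cv, 1L)
  expect_true(all(ci[, , 2] == 1) && all(ci[, , c(1, 3)] == 0))
  expect_error(build_channel_image(v, 99L), "out of range")
})

test_that("assemble_dataset pairs images with annotation targets, index-aligned", {
  vols <- list(make_tiny_volume(1), make_tiny_volume(2))
  ds <- assemble_dataset(vols, 2L, trim_min_size = 20L)
  expect_s3_class(ds, "training_dataset")
  expect_identical(n_samples(ds), 48L)
  expect_identical(dim(ds$x), c(48L, 16L, 16L, 3L))
  # targets equal annotate_volume output element-wise
  expected <- c(annotate_volume(vols[[1]], 2L, trim_min_size = 20L)$porosity,
                annotate_volume(vols[[2]], 2L, trim_min_size = 20L)$porosity)
  expect_equal(ds$y, expected)
  # inputs are reproducible bit-exactly (pure function of volume + scheme)
  ds2 <- assemble_dataset(vols, 2L, trim_min_size = 20L)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$y, ds2$y)
  expect_error(assemble_dataset(list(), 2L), "at least one")
})

test_that("split_dataset is seeded, disjoint and exhaustive", {
  ds <- assemble_dataset(make_tiny_volume(3), 3L, trim_min_size = 1L)
  sp <- split_dataset(ds, 0.8, seed = 7)
  expect_identical(n_samples(sp$train), 19L)  # round(0.8 * 24)
  expect_identical(n_samples(sp$test), 5L)
  sp2 <- split_dataset(ds, 0.8, seed = 7)
  expect_identical(sp$train$y, sp2$train$y)
  # union of splits = original multiset
  got <- sort(c(sp$train$provenance$slice_index, sp$test$provenance$slice_index))
  expect_identical(got, 1:24)
  expect_error(split_dataset(ds, 1.2), "train_fraction")
  # grouped split keeps volumes whole
  vols <- list(make_tiny_volume(4), make_tiny_volume(5))
  dsg <- assemble_dataset(vols, 3L, trim_min_size = 1L)
  spg <- split_dataset(dsg, 0.5, seed = 1, by_volume = TRUE)
  expect_length(unique(spg$train$provenance$sample_id), 1L)
})

test_that("build_model obeys the topology contracts", {
  m <- build_model(c(64, 64), "mini", seed = 3)
  types <- vapply(m$layers, `[[`, "", "type")
  expect_identical(sum(types == "conv"), 4L)
  expect_identical(m$layers[[length(m$layers)]]$activation, "linear")
  expect_identical(ncol(m$layers[[length(m$layers)]]$W), 1L)
  # seeded determinism
  m2 <- build_model(c(64, 64), "mini", seed = 3)
  expect_identical(m$layers, m2$layers)
  expect_false(identical(m$layers[[1]]$W,
                         build_model(c(64, 64), "mini", seed = 4)$layers[[1]]$W))
  # full scale: 13 conv + 3 dense, scalar head (built small to fit memory)
  f <- build_model(c(64, 64), "full", seed = 1)
  tf <- vapply(f$layers, `[[`, "", "type")
  expect_identical(sum(tf == "conv"), 13L)
  expect_identical(sum(tf == "dense"), 3L)
  expect_identical(ncol(f$layers[[length(f$layers)]]$W), 1L)
  expect_error(build_model(c(16, 16), "full"), "too small")
})

test_that("model output is one scalar per image and evaluate_rmse is the formula", {
  m <- build_model(c(8, 8), "mini", seed = 1)
  x <- array(stats::runif(3 * 8 * 8 * 3), c(3, 8, 8, 3))
  p <- predict(m, x, clip = FALSE)
  expect_length(p, 3L)
  ds <- structure(list(x = x, y = c(0.2, 0.5, 0.9),
                       provenance = data.frame(sample_id = "a",
                                               slice_index = 1:3),
                       target_classes = 3L),
                  class = "training_dataset")
  pc <- predict(m, ds)
  expect_equal(evaluate_rmse(m, ds), sqrt(mean((pc - ds$y)^2)))
  # perfect predictor: rmse 0 via a dataset whose targets are the predictions
  ds$y <- pc
  expect_equal(evaluate_rmse(m, ds), 0)
  ds0 <- ds; ds0$y <- numeric(0); ds0$x <- x[integer(0), , , , drop = FALSE]
  expect_error(evaluate_rmse(m, ds0), "empty")
})

test_that("whole-network gradients match numerical differentiation", {
  set.seed(4)
  m <- build_model(c(8, 8), "mini", seed = 2)
  x <- array(stats::runif(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  y <- c(0.3, 0.7)
  fw <- soilpore:::.nn_forward(m, x, cache = TRUE)
  bw <- soilpore:::.nn_backward(m, fw, 2 * (fw$out - y) / 2)
  loss <- function(model) {
    out <- soilpore:::.nn_forward(model, x)
    mean((out - y)^2)
  }
  eps <- 1e-6
  for (li in which(!vapply(m$layers, function(l) is.null(l$W), TRUE))) {
    ix <- sample(length(m$layers[[li]]$W), 4L)
    for (i in ix) {
      mp <- m; mp$layers[[li]]$W[i] <- mp$layers[[li]]$W[i] + eps
      mm <- m; mm$layers[[li]]$W[i] <- mm$layers[[li]]$W[i] - eps
      num <- (loss(mp) - loss(mm)) / (2 * eps)
      expect_equal(bw$grads[[li]]$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training recovers a constant target", {
  # optimization sanity at desk scale: a small pool of distinct images, each
  # seen in training, all labelled 0.5 - the fit must settle on the constant
  set.seed(9)
  pool <- array(stats::runif(10 * 8 * 8 * 3), c(10, 8, 8, 3))
  idx <- rep(1:10, each = 12)
  x <- pool[idx, , , , drop = FALSE]
  ds <- structure(list(x = x, y = rep(0.5, length(idx)),
                       provenance = data.frame(sample_id = "c",
                                               slice_index = seq_along(idx)),
                       target_classes = 1L),
                  class = "training_dataset")
  sp <- split_dataset(ds, 0.8, seed = 1)
  fit <- train(build_model(c(8, 8), "mini", seed = 1), sp$train,
               train_config(epochs = 40, batch_size = 16, lr = 2e-3,
                            patience = 40, seed = 1, validation = sp$test))
  expect_true(all(abs(predict(fit$model, sp$test) - 0.5) < 0.01))
})

test_that("a seeded training run is bit-reproducible", {
  ds <- assemble_dataset(make_tiny_volume(6), 2L, trim_min_size = 1L)
  sp <- split_dataset(ds, 0.8, seed = 2)
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 5,
                      validation = sp$test)
  f1 <- train(build_model(c(16, 16), "mini", seed = 9), sp$train, cfg)
  f2 <- train(build_model(c(16, 16), "mini", seed = 9), sp$train, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})
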