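# hand-buildable one-conv-layer model: conv(relu) -> flatten -> dense(linear)
hand_model <- function(Wc, bc, wd, bd, hw = c(8L, 8L)) {
  f <- ncol(Wc)
  structure(list(
    layers = list(
      list(type = "conv", name = "conv1_1", k = 3L, pad = 1L, W = Wc, b = bc,
           activation = "relu", trainable = TRUE),
      list(type = "flatten", name = "flatten"),
      list(type = "dense", name = "output", W = wd, b = bd,
           activation = "linear", trainable = TRUE)),
    input_dim = c(hw, nrow(Wc) / 9L), scale = "mini", seed = 1L,
    metrics = NULL), class = "porosity_model")
}

# brute-force same-padding 3x3 convolution, independent of the package kernel
conv_ref <- function(x, Wc, bc) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; F <- ncol(Wc)
  out <- array(0, c(H, W, F))
  for (f in seq_len(F)) for (h in 1:H) for (w in 1:W) {
    s <- bc[f]
    for (c in 1:Cin) for (kw in 1:3) for (kh in 1:3) {
      ih <- h + kh - 2; iw <- w + kw - 2
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        s <- s + x[ih, iw, c] * Wc[kh + 3 * (kw - 1) + 9 * (c - 1), f]
    }
    out[h, w, f] <- s
  }
  out
}

test_that("grad_cam equals the hand-computed weighted activation sum", {
  set.seed(12)
  Wc <- matrix(stats::rnorm(9 * 2, sd = 0.5), 9, 2)
  bc <- c(0.05, -0.05)
  wd <- matrix(stats::rnorm(8 * 8 * 2, sd = 0.2), ncol = 1)
  m <- hand_model(Wc, bc, wd, 0.1)
  x <- array(stats::runif(64), c(8, 8, 1))
  hm <- grad_cam(m, x, target_layer = "conv1_1")
  # oracle: A = relu(conv), dy/dA = dense weights reshaped (h, w, f)
  A <- pmax(conv_ref(x, Wc, bc), 0)
  dA <- array(wd, c(8, 8, 2))
  wts <- apply(dA, 3, mean)
  cam <- pmax(wts[1] * A[, , 1] + wts[2] * A[, , 2], 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  expect_equal(unclass(hm), cam, ignore_attr = TRUE, tolerance = 1e-10)
  expect_identical(attr(hm, "target_layer"), "conv1_1")
})

test_that("single map with uniform positive gradient reduces to the map itself", {
  Wc <- matrix(stats::rnorm(9, sd = 0.5), 9, 1)
  wd <- matrix(1, 64, 1)  # uniform positive gradient on the single map
  m <- hand_model(Wc, 0.1, wd, 0)
  x <- array(stats::runif(64), c(8, 8, 1))
  hm <- grad_cam(m, x)
  A <- pmax(conv_ref(x, Wc, 0.1), 0)[, , 1]
  expect_equal(unclass(hm), A / max(A), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("heatmaps are non-negative, max-normalized, scale-invariant", {
  set.seed(22)
  m <- build_model(c(16, 16), "mini", seed = 6)
  x <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  hm <- grad_cam(m, x)
  expect_true(all(hm >= 0))
  expect_true(max(hm) <= 1 + 1e-12)
  expect_true(max(hm) == 1 || all(hm == 0))
  expect_identical(dim(unclass(hm)), c(16L, 16L))
  # scaling the head by a positive constant leaves the map unchanged
  m2 <- m
  oi <- length(m2$layers)
  m2$layers[[oi]]$W <- 3.7 * m2$layers[[oi]]$W
  m2$layers[[oi]]$b <- 3.7 * m2$layers[[oi]]$b
  expect_equal(unclass(grad_cam(m2, x)), unclass(hm), tolerance = 1e-10,
               ignore_attr = TRUE)
  # any conv layer is selectable; non-conv layers are not
  hm1 <- grad_cam(m, x, target_layer = "conv1_1")
  expect_identical(dim(unclass(hm1)), c(16L, 16L))
  expect_error(grad_cam(m, x, target_layer = "flatten"), "convolutional")
  expect_error(grad_cam(m, x, target_layer = "nope"), "no layer")
})

test_that("an identically zero map is returned as-is, not normalized", {
  Wc <- matrix(0, 9, 1)
  m <- hand_model(Wc, -1, matrix(1, 64, 1), 0)  # relu kills everything
  hm <- grad_cam(m, array(stats::runif(64), c(8, 8, 1)))
  expect_true(all(hm == 0))
})

test_that("overlay blends and degenerates correctly", {
  img <- array(stats::runif(12 * 12 * 3), c(12, 12, 3))
  gray <- apply(img, c(1, 2), mean)
  zero <- matrix(0, 12, 12)
  comp0 <- overlay(zero, img)
  expect_identical(dim(comp0), c(12L, 12L, 3L))
  for (c in 1:3) expect_equal(comp0[, , c], gray)
  # saturated heatmap is dominated by the colormap's top color
  comp1 <- overlay(matrix(1, 12, 12), img, alpha = 1)
  top <- grDevices::colorRamp(grDevices::hcl.colors(256, "Inferno"))(1) / 255
  for (c in 1:3) expect_true(all(abs(comp1[, , c] - top[c]) < 1e-9))
  expect_error(overlay(matrix(0, 5, 5), img), "extents")
})

test_that("bilinear upsampling preserves corners and range", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- soilpore:::.bilinear_upsample(m, 8, 8)
  expect_identical(dim(up), c(8L, 8L))
  expect_equal(up[1, 1], 0); expect_equal(up[8, 8], 0)
  expect_equal(up[1, 8], 1); expect_equal(up[8, 1], 1)
  expect_true(all(up >= 0 & up <= 1))
  expect_identical(soilpore:::.bilinear_upsample(m, 2, 2), m)
})
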