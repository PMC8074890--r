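test_that("the default scheme is six 1024-wide bands covering [0, 6144]", {
  s <- object_class_scheme()
  expect_identical(s$lo, seq(0L, 5120L, by = 1024L))
  expect_identical(s$hi, c(seq(1023L, 5119L, by = 1024L), 6144L))
  # disjoint, contiguous, exhaustive
  expect_identical(s$lo[-1], s$hi[-6] + 1L)
})

test_that("classify_voxel matches a linear interval scan", {
  s <- object_class_scheme()
  expect_identical(classify_voxel(1500L), 2L)
  expect_identical(classify_voxel(c(0L, 6144L)), c(1L, 6L))
  expect_error(classify_voxel(-1L), "6144")
  expect_error(classify_voxel(6145L), "6144")
  set.seed(31)
  v <- sample(0:6144, 500L, replace = TRUE)
  scan <- vapply(v, function(x)
    which(x >= s$lo & x <= s$hi), 0L)  # brute-force interval scan
  expect_identical(classify_voxel(v), scan)
})

test_that("binarize codes the selected classes solid, incl. multi-band unions", {
  expect_identical(unique(as.vector(binarize(array(0L, c(2, 2, 2)), 1L))), 1L)
  expect_identical(unique(as.vector(binarize(array(2500L, c(2, 2, 2)), 3L))), 1L)
  expect_identical(unique(as.vector(binarize(array(2500L, c(2, 2, 2)), 2L))), 0L)
  expect_error(binarize(array(0L, c(2, 2, 2)), integer(0)), "non-empty")
  expect_error(binarize(array(0L, c(2, 2, 2)), 7L), "unknown")
  set.seed(8)
  vox <- array(sample(0:6144, 6^3, replace = TRUE), c(6, 6, 6))
  m56 <- binarize(vox, c(5L, 6L))
  expect_identical(as.vector(m56),
                   as.vector(pmax(binarize(vox, 5L), binarize(vox, 6L))))
})

test_that("six single-class masks partition every voxel", {
  set.seed(21)
  vox <- array(sample(0:6144, 5 * 7 * 6, replace = TRUE), c(5, 7, 6))
  masks <- lapply(1:6, function(k) binarize(vox, k))
  tot <- Reduce(`+`, masks)
  expect_true(all(tot == 1L))
})

test_that("trim_small_clusters honors the < min_size boundary", {
  m <- array(0L, c(8, 8, 8))
  expect_identical(trim_small_clusters(m, 60L), m)
  # a 4x5x3 block of exactly 60 voxels survives at min_size 60
  m60 <- array(0L, c(10, 10, 10)); m60[2:5, 2:6, 2:4] <- 1L
  expect_identical(trim_small_clusters(m60, 60L), m60)
  # one voxel fewer and the whole cluster goes
  m59 <- m60; m59[2, 2, 2] <- 0L
  expect_true(all(trim_small_clusters(m59, 60L) == 0L))
  expect_error(trim_small_clusters(m60, 60L, connectivity = 13L),
               "connectivity")
  expect_error(trim_small_clusters(m60, 0L), "min_size")
})

test_that("trimming matches the flood-fill oracle and is monotone", {
  set.seed(77)
  for (rep in 1:12) {
    dims <- sample(4:14, 3, replace = TRUE)
    m <- random_mask(dims, p_solid = stats::runif(1, 0.15, 0.5))
    for (conn in c(6L, 26L)) for (ms in c(2L, 9L)) {
      got <- trim_small_clusters(m, ms, conn)
      expect_identical(as.vector(got), as.vector(oracle_trim(m, ms, conn)))
      expect_lte(sum(got), sum(m))        # never adds solid
    }
    expect_identical(trim_small_clusters(m, 1L, 26L), m)  # identity at 1
  }
})

test_that("slice porosity is the void fraction", {
  expect_identical(slice_porosity(matrix(0L, 4, 4)), 1)
  expect_identical(slice_porosity(matrix(1L, 4, 4)), 0)
  set.seed(3)
  sl <- matrix(0L, 10, 10); sl[sample(100, 37)] <- 1L
  expect_identical(slice_porosity(sl), 0.63)
  expect_error(slice_porosity(integer(0)), "zero-size")
  # algebraic identity: porosity = 1 - mean(mask)
  for (rep in 1:5) {
    sl <- matrix(as.integer(stats::runif(48) < 0.4), 6, 8)
    expect_equal(slice_porosity(sl), 1 - mean(sl))
  }
})

test_that("porosity_profile is the per-slice porosity along X", {
  m <- array(0L, c(20, 4, 4)); m[1:10, , ] <- 1L
  p <- porosity_profile(m)
  expect_equal(p$porosity, c(rep(0, 10), rep(1, 10)))
  expect_equal(nrow(p), 20L)
  expect_equal(p$depth_mm, (0:19) * 0.25)
  expect_equal(porosity_profile(array(0L, c(3, 2, 2)))$porosity, rep(1, 3))
})

test_that("annotate_volume composes binarize -> trim -> profile", {
  g <- generate_volume(synthetic_spec("heterogeneous", seed = 6,
                                      extents = c(30L, 24L, 24L)))
  v <- g$volume
  # trim_min_size = 1 equals the untrimmed pipeline
  p1 <- annotate_volume(v, 2L, trim_min_size = 1L)
  expect_equal(p1$porosity, porosity_profile(binarize(v, 2L))$porosity)
  # union target equals the union-binarized profile
  p56 <- annotate_volume(v, c(5L, 6L), trim_min_size = 1L)
  expect_equal(p56$porosity, porosity_profile(binarize(v, c(5, 6)))$porosity)
  # trimming never decreases any slice's porosity
  p60 <- annotate_volume(v, 2L, trim_min_size = 60L)
  expect_true(all(p60$porosity >= p1$porosity - 1e-12))
  expect_true(all(p60$porosity >= 0 & p60$porosity <= 1))
})

test_that("profiles export as CSV with depth metadata", {
  g <- generate_volume(synthetic_spec("homogeneous", seed = 4,
                                      extents = c(8L, 10L, 10L)))
  p <- annotate_volume(g$volume, 3L, trim_min_size = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("slice_index", "depth_mm", "porosity"))
  expect_equal(back$porosity, p$porosity)
})
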