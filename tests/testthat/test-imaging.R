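test_that("pixel-to-micron conversion is the image-width ratio", {
  expect_equal(pxToUm(40, 1000, 250), 10)
  expect_equal(pxToUm(c(10, 20), 100, 50), c(5, 10))
  expect_equal(pxToUm(c(3, 7.5), 64, 64), c(3, 7.5))   # 1 um/px identity
  expect_error(pxToUm(1, 0, 250), "must be > 0")
  expect_error(pxToUm(1, 100, -1), "must be > 0")
})

test_that("Sauter mean matches hand computation and rejects bad input", {
  expect_equal(sauterMean(c(5, 5, 5)), 5)
  expect_equal(sauterMean(c(1, 2, 3)), 36 / 14)
  expect_error(sauterMean(numeric(0)), "at least one")
  expect_error(sauterMean(c(1, -2)), "> 0")
})

test_that("d32 dominates the arithmetic mean and scales linearly", {
  set.seed(99)
  for (i in 1:50) {
    d <- rlnorm(sample(2:80, 1), meanlog = runif(1, 0, 3),
                sdlog = runif(1, 0, 1))
    expect_gte(sauterMean(d), mean(d))
    c0 <- runif(1, 0.1, 10)
    expect_equal(sauterMean(c0 * d), c0 * sauterMean(d), tolerance = 1e-12)
    expect_equal(mean(c0 * d), c0 * mean(d), tolerance = 1e-12)
  }
  # equality holds only for monodisperse sets
  expect_gt(sauterMean(c(1, 1.0001)), mean(c(1, 1.0001)))
})

test_that("variation rate reproduces the study's derived columns", {
  expect_equal(variationRate(15.87, 28.56),
               list(difference = 12.69, ratePct = 100 * 12.69 / 15.87))
  v <- variationRate(11.24, 11.27)
  expect_equal(v$difference, 0.03)
  expect_equal(round(v$ratePct, 2), 0.27)
  expect_equal(variationRate(5, 5), list(difference = 0, ratePct = 0))
  expect_error(variationRate(0, 5), "> 0")
})

test_that("sizeSummary aggregates mean, d32 and count", {
  s <- sizeSummary(dropletSet(c(1, 2, 3), timepoint = "T5top"))
  expect_equal(s$mean_um, 2)
  expect_equal(s$d32_um, 36 / 14)
  expect_equal(s$n, 3L)
  expect_equal(s$timepoint, "T5top")
  expect_error(sizeSummary(dropletSet(numeric(0))), "empty")
})

test_that("detection returns nothing on featureless images", {
  expect_length(detectDroplets(matrix(0.7, 50, 50)), 0)
  expect_error(detectDroplets(matrix(numeric(0), 0, 0)), "empty")
})

test_that("a single rendered disk is recovered within a pixel", {
  mg <- generateMicrograph(micrographSpec(widthPx = 200L, widthUm = 50,
                                          nDroplets = 1L,
                                          meanlog = log(10), sdlog = 0,
                                          noiseSd = 0, seed = 2L))
  d <- detectDroplets(mg$image)
  expect_length(d, 1)
  expect_lt(abs(d - 40), 1)
})

test_that("border-touching objects are excluded", {
  img <- matrix(0.9, 80, 80)
  img[1:10, 35:45] <- 0.2            # touches the top border
  for (i in 30:50) for (j in 30:50)  # interior disk, r = 8
    if ((i - 40)^2 + (j - 40)^2 <= 64) img[i, j] <- 0.2
  d <- detectDroplets(img)
  expect_length(d, 1)
  expect_lt(abs(d - 16), 1.5)
})

test_that("the measurement pipeline recovers ground truth d32", {
  # noise-free: within 2%; default noise: within 5% (50 droplets, 10 seeds)
  errs <- vapply(1:10, function(s) {
    for (noise in c(0, 0.05)) {
      spec <- micrographSpec(nDroplets = 50L, noiseSd = noise, seed = s)
      mg <- generateMicrograph(spec)
      meas <- measureDroplets(mg$image, spec@widthUm)
      err <- abs(sauterMean(meas) - sauterMean(mg$truth$diameter_um)) /
        sauterMean(mg$truth$diameter_um)
      if (noise == 0) err0 <- err else err5 <- err
    }
    c(err0, err5)
  }, numeric(2))
  expect_lt(max(errs[1, ]), 0.02)
  expect_lt(max(errs[2, ]), 0.05)
})

test_that("droplet subsampling is seeded and caps the count", {
  d <- 1:100 + 0.5
  s1 <- subsampleDroplets(d, 50, seed = 1)
  s2 <- subsampleDroplets(d, 50, seed = 1)
  expect_identical(s1, s2)
  expect_length(s1, 50)
  expect_true(all(s1 %in% d))
  expect_identical(subsampleDroplets(d[1:30], 50), d[1:30])
})
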