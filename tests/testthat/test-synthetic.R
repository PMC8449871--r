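test_that("micrograph generator handles the empty and single-droplet cases", {
  blank <- generateMicrograph(micrographSpec(widthPx = 100L, widthUm = 25,
                                             nDroplets = 0L, noiseSd = 0))
  expect_equal(nrow(blank$truth), 0L)
  expect_equal(length(unique(as.vector(blank$image))), 1L)

  # one droplet of exactly 10 um on a 1000 px / 250 um frame is 40 px
  one <- generateMicrograph(micrographSpec(widthPx = 1000L, widthUm = 250,
                                           nDroplets = 1L,
                                           meanlog = log(10), sdlog = 0,
                                           noiseSd = 0, seed = 7L))
  expect_equal(one$truth$diameter_um, 10)
  expect_equal(one$truth$diameter_px, 40)
})

test_that("micrograph generation is deterministic under a fixed seed", {
  spec <- micrographSpec(widthPx = 300L, widthUm = 75, nDroplets = 12L,
                         noiseSd = 0.05, seed = 42L)
  a <- generateMicrograph(spec)
  b <- generateMicrograph(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("rendered droplet count matches an independent flood-fill oracle", {
  spec <- micrographSpec(widthPx = 500L, widthUm = 125, nDroplets = 50L,
                         meanlog = log(8), sdlog = 0.2, noiseSd = 0,
                         seed = 11L)
  mg <- generateMicrograph(spec)
  ff <- floodFillLabel(mg$image < 0.5)
  expect_equal(ff$n, 50L)
  # flood-fill areas reproduce the rendered diameters within 2% (pixelation)
  d_ff <- sort(2 * sqrt(ff$areas / pi))
  d_true <- sort(mg$truth$diameter_px)
  expect_lt(max(abs(d_ff - d_true) / d_true), 0.02)
  # and ground-truth d32 agrees with the flood-fill d32 within 2%
  scale <- spec@widthUm / spec@widthPx
  expect_lt(abs(sauterMean(d_ff * scale) -
                sauterMean(mg$truth$diameter_um)) /
              sauterMean(mg$truth$diameter_um), 0.02)
})

test_that("overlap-free placement fails loudly when the image is too full", {
  spec <- micrographSpec(widthPx = 60L, widthUm = 60, nDroplets = 40L,
                         meanlog = log(20), sdlog = 0, noiseSd = 0)
  expect_error(generateMicrograph(spec), "could not place droplet")
})

test_that("flow-curve generator matches hand-evaluated stresses", {
  grid <- c(0.05, 1, 4, 100)
  zero <- generateFlowCurve(flowCurveSpec(0, 0, 0.5, freqGrid = grid))
  expect_equal(stresses(zero), rep(0, 4))
  const <- generateFlowCurve(flowCurveSpec(2.35, 0, 0.5, freqGrid = grid))
  expect_equal(stresses(const), rep(2.35, 4))
  hb <- generateFlowCurve(flowCurveSpec(1, 1, 0.5, freqGrid = grid))
  expect_equal(stresses(hb)[3], 3)          # 1 + 1 * sqrt(4)
  # noise-free stress is non-decreasing in frequency when K >= 0
  expect_true(all(diff(stresses(hb)) >= 0))
  # determinism with noise
  s1 <- generateFlowCurve(flowCurveSpec(1, 0.1, 0.5, noiseSd = 0.05,
                                        seed = 3L))
  s2 <- generateFlowCurve(flowCurveSpec(1, 0.1, 0.5, noiseSd = 0.05,
                                        seed = 3L))
  expect_identical(stresses(s1), stresses(s2))
  expect_error(flowCurveSpec(1, 1, 0.5, freqGrid = numeric(0)), "non-empty")
})

test_that("noiseless simulated responses refit to the exact coefficients", {
  d <- builtinDesign()
  beta <- c(constant = 1.34, A = 0.0087, B = -0.065, D = -0.21, AE = 0.079)
  for (tr in c("log10", "sqrt", "identity")) {
    y <- generateDoeResponses(d, beta, transform = tr, noiseSd = 0)
    fit <- fitLinearModel(d, y, terms = c("A", "B", "D", "AE"),
                          transform = tr)
    ct <- coefTable(fit)
    got <- setNames(ct$estimate, ct$term)[names(beta)]
    expect_equal(unname(got), unname(beta), tolerance = 1e-8)
    expect_equal(unname(rSquared(fit)["raw"]), 1, tolerance = 1e-8)
  }
})

test_that("centre-point response under log10 is the back-transformed constant", {
  d <- builtinDesign()
  y <- generateDoeResponses(d, c(constant = 1.34), transform = "log10")
  expect_equal(y[d$label == "a/a/a/a/a"], rep(10^1.34, 3))
})

test_that("coefficient estimates are unbiased under transformed-scale noise", {
  d <- builtinDesign()
  beta <- c(constant = 1.3, A = 0.05, D = -0.2, E = -0.07)
  est <- vapply(seq_len(200), function(s) {
    y <- generateDoeResponses(d, beta, transform = "log10", noiseSd = 0.05,
                              seed = s)
    ct <- coefTable(fitLinearModel(d, y, terms = c("A", "D", "E"),
                                   transform = "log10"))
    setNames(ct$estimate, ct$term)[c("A", "D", "E")]
  }, numeric(3))
  bias <- rowMeans(est) - beta[c("A", "D", "E")]
  # MC error of the mean at sd 0.05/sqrt(21-ish effective runs), 200 reps
  expect_lt(max(abs(bias)), 0.004)
})

test_that("simulation rejects transform-domain violations", {
  d <- builtinDesign()
  expect_error(
    generateDoeResponses(d, c(constant = 0.1, D = 1), transform = "sqrt"),
    "squared back")
})
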