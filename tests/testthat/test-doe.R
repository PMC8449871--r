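test_that("factor coding maps endpoints, midpoints and is involutive", {
  ctr <- codeFactors(15, 0.75, 1, 15000, 12.5)
  expect_equal(unname(unlist(ctr)), rep(0, 5))
  expect_equal(codeFactors(20, 0, 0, 10000, 5)$A, 1)
  expect_equal(codeFactors(10, 0, 0, 10000, 5)$A, -1)
  expect_equal(codeFactors(10, 1.125, 0, 10000, 5)$B, 0.5)
  expect_error(codeFactors(25, 0, 0, 10000, 5), "out of range")

  set.seed(4)
  for (i in 1:20) {
    nat <- data.frame(oil_pct = runif(1, 10, 20),
                      starch_pct = runif(1, 0, 1.5),
                      caseinate_pct = runif(1, 0, 2),
                      stir_rpm = runif(1, 10000, 20000),
                      stir_min = runif(1, 5, 20))
    coded <- codeFactors(nat$oil_pct, nat$starch_pct, nat$caseinate_pct,
                         nat$stir_rpm, nat$stir_min)
    expect_equal(decodeFactors(coded), nat, tolerance = 1e-12)
  }
})

test_that("the built-in design reproduces the published 24 runs", {
  d <- builtinDesign()
  expect_equal(nrow(d), 24L)
  expect_equal(d$block, rep(1:3, each = 8))
  expect_equal(unname(unlist(d[d$run == 24, LETTERS[1:5]])), rep(1, 5))
  expect_equal(unname(unlist(d[d$run == 1, LETTERS[1:5]])),
               c(-1, -1, -1, 1, -1))
  expect_equal(d$label[d$run == 11], "M/m/m/M/M")
  expect_equal(d$label[d$run == 24], "M/M/M/M/M")
  # 3 centre points, all-zero coded, at runs 2, 9, 16
  ctr <- d$run[d$label == "a/a/a/a/a"]
  expect_equal(ctr, c(2L, 9L, 16L))
  expect_true(all(d[d$run %in% ctr, LETTERS[1:5]] == 0))
})

test_that("Box-Cox scan recovers known simulated transforms", {
  d <- builtinDesign()
  X <- doeModelMatrix(d, c("A", "B", "D"))
  set.seed(8)
  eta <- 1.2 + 0.3 * d$A - 0.4 * d$D + rnorm(24, 0, 0.05)
  scLog <- boxcoxScan(10^eta, X)
  expect_lt(abs(scLog$lambda), 0.25)
  expect_equal(scLog$name, "log10")
  yLin <- 20 + 3 * d$A - 4 * d$D + rnorm(24, 0, 0.3)
  expect_equal(boxcoxScan(yLin, X)$name, "identity")
})

test_that("Box-Cox objective is continuous across lambda = 0", {
  d <- builtinDesign()
  X <- doeModelMatrix(d, defaultTerms("s0"))
  y <- designTable()$size_t0_um
  sse <- function(l) boxcoxScan(y, X, lambdas = c(-2, l, 2))$grid$sse[2]
  expect_equal(sse(1e-6), sse(0), tolerance = 1e-6)
  expect_equal(sse(-1e-6), sse(0), tolerance = 1e-6)
})

test_that("Box-Cox scan agrees with the MASS profile-likelihood maximiser", {
  d <- designTable()
  X <- doeModelMatrix(d, defaultTerms("s0"))
  y <- d$size_t0_um
  sc <- boxcoxScan(y, X)
  b <- MASS::boxcox(y ~ X, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_equal(sc$lambda, b$x[which.max(b$y)], tolerance = 1e-8)
})

test_that("OLS coefficients match an explicit normal-equations oracle", {
  for (s in 1:5) {
    d <- randomCodedDesign(40L, seed = s)
    set.seed(100 + s)
    y <- 2 + d$A - 0.5 * d$B + 0.3 * d$A * d$E + rnorm(40, 0, 0.4)
    terms <- c("A", "B", "C", "AE")
    fit <- fitLinearModel(d, y, terms = terms, transform = "identity")
    X <- doeModelMatrix(d, terms)
    oracle <- normalEquationsFit(X, y)
    ct <- coefTable(fit)
    expect_equal(unname(setNames(ct$estimate, ct$term)[colnames(X)]),
                 unname(oracle[colnames(X)]), tolerance = 1e-8)
    expect_equal(ct$estimate[ct$term == "constant"],
                 unname(oracle["(Intercept)"]), tolerance = 1e-8)
    # t-values are estimate / se for every term
    expect_equal(ct$t, ct$estimate / ct$se, tolerance = 1e-12)
  }
})

test_that("closed-form PRESS equals explicit leave-one-out refits", {
  for (s in 1:3) {
    d <- randomCodedDesign(30L, seed = 10 + s)
    set.seed(200 + s)
    y <- 1 + 0.5 * d$D + rnorm(30)
    fit <- fitLinearModel(d, y, terms = c("A", "D"), transform = "identity")
    X <- doeModelMatrix(d, c("A", "D"))
    sst <- sum((y - mean(y))^2)
    expect_equal(unname(rSquared(fit)["predicted"]),
                 1 - explicitPress(X, y) / sst, tolerance = 1e-8)
    r2 <- rSquared(fit)
    expect_lte(r2[["predicted"]], r2[["raw"]])
    expect_lte(r2[["adjusted"]], r2[["raw"]])
  }
})

test_that("noiseless data give a perfect fit", {
  d <- builtinDesign()
  y <- 3 + d$A - 2 * d$B + 0.5 * d$D * d$E
  fit <- fitLinearModel(d, y, terms = c("A", "B", "DE"),
                        transform = "identity")
  expect_equal(unname(rSquared(fit)["raw"]), 1, tolerance = 1e-10)
})

test_that("aliased term sets raise an aliasing error", {
  dd <- builtinDesign()
  dd$B <- dd$A                     # B now aliased with A
  expect_error(fitLinearModel(dd, rnorm(24), terms = c("A", "B"),
                              transform = "identity"), "aliasing")
})

test_that("interactions pull their parent main effects into the model", {
  d <- builtinDesign()
  y <- 1 + d$A + d$E + 0.5 * d$A * d$E
  fit <- fitLinearModel(d, y, terms = "AE", transform = "identity")
  expect_setequal(modelTerms(fit), c("A", "E", "AE"))
  expect_equal(unname(rSquared(fit)["raw"]), 1, tolerance = 1e-10)
})

test_that("Pareto limits are ordered and flags respect them", {
  d <- designTable()
  fit <- fitLinearModel(d, response = "var")
  p <- effectPareto(fit, alpha = 0.05)
  expect_gte(attr(p, "bonferroniLimit"), attr(p, "tLimit"))
  p1 <- effectPareto(fit, alpha = 0.05, mEffects = 1)
  expect_equal(attr(p1, "bonferroniLimit"), attr(p1, "tLimit"))
  expect_true(all(abs(p$t[p$flag == "highly-significant"]) >=
                    attr(p, "bonferroniLimit")))
  expect_true(all(abs(p$t[p$flag == "none"]) < attr(p, "tLimit")))
  # the dominant factors (starch, caseinate, stirring speed and time)
  # exceed the Bonferroni limit for the variation rate; the small oil
  # effect (printed coefficient -0.29) does not clear the corrected limit
  mains <- p[p$term %in% LETTERS[1:5], ]
  expect_true(all(mains$flag[mains$term %in% c("B", "C", "D", "E")] ==
                    "highly-significant"))
})

test_that("pure-noise responses rarely cross the Bonferroni limit", {
  d <- builtinDesign()
  terms <- defaultTerms("s0")
  hits <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    fit <- fitLinearModel(d, rnorm(24), terms = terms,
                          transform = "identity")
    p <- effectPareto(fit, alpha = 0.05)
    any(p$flag == "highly-significant")
  }, logical(1))
  # FWER <= 0.05 plus 3 binomial standard errors at n = 200
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("predictions invert the transform and round-trip training data", {
  d <- designTable()
  fit <- fitLinearModel(d, response = "s0")
  ctr <- predictResponse(fit, c(A = 0, B = 0, C = 0, D = 0, E = 0))
  const <- coefTable(fit)$estimate[coefTable(fit)$term == "constant"]
  expect_equal(round(const, 2), 1.34)
  expect_equal(ctr, 10^const)
  expect_equal(round(10^1.34, 1), 21.9)   # the back-transformed constant
  # identity-transform prediction equals the linear predictor
  y <- 2 + d$A
  fitI <- fitLinearModel(d, y, terms = "A", transform = "identity")
  expect_equal(predictResponse(fitI, c(A = 1, B = 0, C = 0, D = 0, E = 0)),
               3, tolerance = 1e-10)
  # round trip: noiseless fit reproduces its training responses
  yy <- invertTransform(1 + 0.2 * d$A - 0.1 * d$D, "log10")
  fitL <- fitLinearModel(d, yy, terms = c("A", "D"), transform = "log10")
  pred <- vapply(seq_len(24), function(i)
    predictResponse(fitL, unlist(d[i, LETTERS[1:5]])), numeric(1))
  expect_equal(pred, yy, tolerance = 1e-8)
  expect_error(predictResponse(fit, c(A = 2, B = 0, C = 0, D = 0, E = 0)),
               "\\[-1, \\+1\\]")
})
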