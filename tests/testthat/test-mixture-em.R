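# EM fitting of (censored) Gaussian mixtures and selection of K.

test_that("mixture density follows the component decomposition", {
  p1 <- MixtureParams(1, 5000, 300, satThreshold = 65535)
  expect_equal(mixtureDensity(5000, p1), 1 / (300 * sqrt(2 * pi)))

  # censoring only alters the value at y = S
  pr <- MixtureParams(c(0.6, 0.4), c(2000, 60000), c(500, 5000))
  pc <- MixtureParams(c(0.6, 0.4), c(2000, 60000), c(500, 5000),
                      censoredLast = TRUE)
  yy <- c(1500, 2500, 55000, 65000)
  expect_equal(mixtureDensity(yy, pr), mixtureDensity(yy, pc))

  # three components evaluated at S: two pdfs plus the survival mass
  p3 <- MixtureParams(c(0.7, 0.1, 0.2), c(2000, 15000, 68000),
                      c(1000, 6000, 6000), censoredLast = TRUE)
  S <- 65535
  expect_equal(mixtureDensity(S, p3),
               0.7 * dnorm(S, 2000, 1000) + 0.1 * dnorm(S, 15000, 6000) +
                 0.2 * pnorm((S - 68000) / 6000, lower.tail = FALSE))
  expect_error(mixtureDensity(S + 1, p3), "cannot occur")
})

test_that("initialization partitions ordered pixels by the start weights", {
  m <- PixelMask(1:10, satThreshold = 100)
  init <- initializeMixture(m, 2, startWeights = c(0.8, 0.2))
  expect_equal(mixMeans(init), c(mean(1:8), mean(9:10)))
  expect_equal(mixWeights(init), c(0.8, 0.2))

  # documented defaults
  init3 <- initializeMixture(PixelMask(1:30, satThreshold = 100), 3)
  expect_equal(mixWeights(init3), c(0.7, 0.1, 0.2))
  expect_equal(mixWeights(initializeMixture(m, 2)), c(0.8, 0.2))

  # degenerate constant input: floored scales, strictly ordered means
  cm <- initializeMixture(PixelMask(rep(5, 12), satThreshold = 100), 2)
  expect_true(all(mixSds(cm) > 0))
  expect_lt(mixMeans(cm)[1], mixMeans(cm)[2])

  expect_error(initializeMixture(m, 2, startWeights = c(0.8, 0.4)),
               "sum to 1")
  expect_error(initializeMixture(PixelMask(1:5, satThreshold = 100), 2),
               "too few pixels")
})

test_that("responsibilities are posterior component probabilities", {
  m1 <- PixelMask(c(1, 2, 3), satThreshold = 100)
  expect_equal(eStep(m1, MixtureParams(1, 2, 1, satThreshold = 100)),
               matrix(1, 3, 1))

  # two identical components split responsibility evenly
  tie <- MixtureParams(c(0.5, 0.5), c(5, 5), c(2, 2), satThreshold = 100)
  expect_equal(eStep(m1, tie), matrix(0.5, 3, 2))

  # direct ratio evaluation at fixed parameters, censored last component
  mask <- PixelMask(c(800, 990, 1000), satThreshold = 1000)
  th <- MixtureParams(c(0.7, 0.3), c(850, 995), c(60, 20),
                      censoredLast = TRUE, satThreshold = 1000)
  z <- eStep(mask, th)
  f2 <- function(y) if (y >= 1000)
    pnorm((1000 - 995) / 20, lower.tail = FALSE) else dnorm(y, 995, 20)
  for (i in 1:3) {
    y <- c(800, 990, 1000)[i]
    num <- c(0.7 * dnorm(y, 850, 60), 0.3 * f2(y))
    expect_equal(z[i, ], num / sum(num), tolerance = 1e-12)
  }
  expect_equal(rowSums(z), rep(1, 3))
})

test_that("M-step recovers weighted closed forms and the censored solve", {
  set.seed(10)
  y <- c(rnorm(40, 10, 2), rnorm(20, 50, 5))
  mask <- PixelMask(y, satThreshold = 1000)
  hard <- cbind(rep(c(1, 0), c(40, 20)), rep(c(0, 1), c(40, 20)))
  up <- mStep(mask, hard)
  expect_equal(mixMeans(up), c(mean(y[1:40]), mean(y[41:60])))
  expect_equal(mixSds(up),
               c(sqrt(mean((y[1:40] - mean(y[1:40]))^2)),
                 sqrt(mean((y[41:60] - mean(y[41:60]))^2))))
  expect_equal(mixWeights(up), colMeans(hard))

  # soft responsibilities: weights are the column means (components are
  # re-sorted by mean, so match the expected order)
  set.seed(11)
  soft <- matrix(runif(120), 60, 2)
  soft <- soft / rowSums(soft)
  ord <- order(colSums(soft * y) / colSums(soft))
  expect_equal(mixWeights(mStep(mask, soft)), colMeans(soft)[ord])

  # censored last component agrees with the grid-search oracle
  set.seed(12)
  yv <- c(rnorm(18, 8000, 2000), pmin(rnorm(12, 64000, 6000), 65535))
  yv[19:30][1:5] <- 65535   # force ~40% of the bright block saturated
  cm <- PixelMask(yv, satThreshold = 65535)
  z <- cbind(rep(c(1, 0), c(18, 12)), rep(c(0, 1), c(18, 12)))
  upc <- mStep(cm, z, censoredLast = TRUE)
  g <- gridSearchCensNorm(yv, z[, 2], 65535, c(50000, 80000), c(500, 15000))
  expect_lt(abs(mixMeans(upc)[2] - g$mu), g$resMu)
  expect_lt(abs(mixSds(upc)[2] - g$sigma), g$resSigma)
})

test_that("EM fits satisfy the likelihood and identifiability contracts", {
  set.seed(13)
  y1 <- rnorm(300, 9000, 1500)
  m1 <- PixelMask(y1, satThreshold = 65535)
  f1 <- fitMixture(m1, 1)
  expect_equal(mixMeans(f1), mean(y1))
  expect_equal(mixSds(f1), sqrt(mean((y1 - mean(y1))^2)))
  expect_equal(f1@nParams, 2L)

  set.seed(14)
  y2 <- c(rnorm(350, 8000, 2000), rnorm(150, 40000, 5000))
  m2 <- PixelMask(y2, satThreshold = 65535)
  fr <- fitMixture(m2, 2, censored = FALSE)
  fc <- fitMixture(m2, 2, censored = TRUE)
  # no saturated pixel: the censored and regular fits coincide
  expect_equal(mixMeans(fc), mixMeans(fr), tolerance = 1e-6)
  expect_equal(mixSds(fc), mixSds(fr), tolerance = 1e-6)
  expect_equal(mixWeights(fc), mixWeights(fr), tolerance = 1e-6)
  expect_equal(fc@logLik, fr@logLik, tolerance = 1e-6)

  # EM guarantees: monotone likelihood, normalized responsibilities,
  # ordered means, 3K - 1 free parameters
  for (fit in list(fr, fc)) {
    expect_true(all(diff(fit@logLikTrace) >= -1e-8 * abs(fit@logLik)))
    expect_equal(rowSums(responsibilities(fit)), rep(1, 500))
    expect_true(all(diff(mixMeans(fit)) > 0))
    expect_equal(fit@nParams, 5L)
    expect_equal(AIC(fit), -2 * fit@logLik + 2 * 5)
    expect_equal(BIC(fit), -2 * fit@logLik + 5 * log(500))
  }
  expect_error(fitMixture(m2, 4), "K must be")
})

test_that("the relative-difference rule prefers the simplest close model", {
  expect_identical(censpot:::.pickK(c(1000.0, 999.5, 999.4), 0.001), 1L)
  expect_identical(censpot:::.pickK(c(1200, 999.5, 999.4), 0.001), 2L)
  expect_identical(censpot:::.pickK(c(1200, 1100, 999.4), 0.001), 3L)
  expect_identical(censpot:::.pickK(c(NA, 1100, 999.4), 0.001), 3L)
})

test_that("BIC selection identifies the true number of components", {
  # single normal: K = 1 in at least 95% of seeded replicates
  k1 <- vapply(1:100, function(s) {
    set.seed(s)
    m <- PixelMask(rnorm(400, 8000, 2000), satThreshold = 65535)
    nComponents(selectK(m))
  }, integer(1))
  expect_gte(mean(k1 == 1L), 0.95)

  # two well-separated components (10 sigma apart): K = 2
  k2 <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    y <- c(rnorm(320, 8000, 2000), rnorm(80, 28000, 2000))
    nComponents(selectK(PixelMask(y, satThreshold = 65535)))
  }, integer(1))
  expect_gte(mean(k2 == 2L), 0.95)
})

test_that("censored fits recover parameters that the regular model biases", {
  sc <- makeScenario(3, 0.4)
  truth <- c(sc@weights[1:2], sc@means, sc@sds)
  est_c <- matrix(NA_real_, 200, 8)
  est_r_mu3 <- numeric(200)
  set.seed(4242)
  seeds <- sample.int(1e6, 200)
  for (i in 1:200) {
    set.seed(seeds[i])
    mk <- simulateMask(sc)
    fc <- fitMixture(mk$censored, 3, censored = TRUE)
    fr <- fitMixture(mk$censored, 3, censored = FALSE)
    est_c[i, ] <- c(mixWeights(fc)[1:2], mixMeans(fc), mixSds(fc))
    est_r_mu3[i] <- mixMeans(fr)[3]
  }
  bias_c <- (colMeans(est_c) - truth) / truth
  expect_true(all(abs(bias_c) < 0.03))
  # the regular mixture underestimates the foreground mean on censored data
  expect_lt((mean(est_r_mu3) - sc@means[3]) / sc@means[3], -0.02)
})
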