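test_that("fold transform and circular mean follow vector arithmetic", {
  expect_equal(foldTransform(15, 6), 90)
  expect_equal(foldTransform(60, 6), 0)
  expect_equal(foldTransform(0, 4), 0)
  cm <- circMean(c(0, 90))
  expect_equal(cm$mean, 45)
  expect_equal(cm$R, cos(pi / 4))
  expect_equal(circMean(rep(33, 5))$R, 1)
  expect_equal(circMean(seq(0, 359, by = 30))$R, 0, tolerance = 1e-12)
})

test_that("V test is significant for concentrated samples, null for uniform ones", {
  pConc <- vTest(rep(40, 50), mu0 = 40)$p
  expect_lt(pConc, 1e-6)
  even <- seq(0, 354, by = 6)
  res <- vTest(even, mu0 = 0)
  expect_equal(res$V, 0, tolerance = 1e-9)
  expect_equal(res$p, 0.5, tolerance = 1e-6)
  ## von Mises power at the study's sample size: significant in > 90%
  ## of repetitions (kappa = 2, n = 38)
  set.seed(301)
  rejections <- mean(replicate(200, {
    u <- runif(38); w <- runif(38)
    ## von Mises sampler (Best-Fisher) at kappa = 2, mean 0
    kappa <- 2
    a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
    r0 <- (1 + b^2) / (2 * b)
    th <- vapply(seq_len(38), function(i) {
      repeat {
        z <- cos(pi * runif(1)); f <- (1 + r0 * z) / (r0 + z)
        c0 <- kappa * (r0 - f)
        if (c0 * (2 - c0) - runif(1) > 0 ||
            log(c0 / runif(1)) + 1 - c0 >= 0)
          return(sign(runif(1) - 0.5) * acos(f))
      }
    }, numeric(1))
    vTest((th * 180 / pi) %% 360, mu0 = 0)$p < 0.05
  }))
  expect_gt(rejections, 0.9)
})

test_that("Rayleigh test separates uniform from concentrated samples", {
  even <- seq(0, 354, by = 6)
  expect_gt(rayleighTest(even)$p, 0.99)
  expect_lt(rayleighTest(rep(100, 20))$p, 1e-6)
  ## null calibration: uniform samples give roughly uniform p-values
  set.seed(88)
  ps <- replicate(400, rayleighTest(runif(38, 0, 360))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("small-sample p-values agree with the brute-force oracle", {
  ## fixed samples of n <= 10; oracle tolerance 0.01
  samples <- list(c(10, 20, 35, 50, 300), c(0, 45, 90, 180, 270, 315),
                  c(5, 8, 12, 17, 23, 100, 200, 355))
  for (s in samples) {
    pv <- vTest(s, mu0 = 20)$p
    pOracle <- bruteForceCircP(s, rawV(20))
    expect_lt(abs(pv - pOracle), 0.01)
    pr <- rayleighTest(s)$p
    prOracle <- bruteForceCircP(s, rawR)
    expect_lt(abs(pr - prOracle), 0.01)
  }
})

test_that("type-I error of both tests is calibrated at alpha = 0.05", {
  set.seed(99)
  rejV <- mean(replicate(1000,
    vTest(runif(38, 0, 360), mu0 = 123)$p < 0.05))
  expect_gt(rejV, 0.035); expect_lt(rejV, 0.065)
  rejR <- mean(replicate(1000, rayleighTest(runif(38, 0, 360))$p < 0.05))
  expect_gt(rejR, 0.035); expect_lt(rejR, 0.065)
})

test_that("tests are invariant to global rotation with co-rotated mu0", {
  s <- c(12, 80, 95, 140, 200, 260, 300, 310, 340, 50, 66)
  base <- vTest(s, mu0 = 30)
  rot <- vTest((s + 111) %% 360, mu0 = (30 + 111) %% 360)
  expect_equal(base$V, rot$V, tolerance = 1e-9)
  expect_equal(base$p, rot$p, tolerance = 1e-9)
  expect_equal(rayleighTest(s)$p, rayleighTest((s + 200) %% 360)$p,
               tolerance = 1e-9)
})
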