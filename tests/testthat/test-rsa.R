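test_that("LSS recovers per-trial amplitudes from well-separated events", {
  ## two noiseless events with amplitudes 1 and 2, far apart
  tr <- 2; n <- 80
  tab <- data.frame(
    onset = c(20, 100, 22, 102), duration = c(2, 2, 2.5, 2.5),
    trial_type = rep(c("morph", "choice"), each = 2),
    run = 1L, theta_deg = c(10, 200, 10, 200), distance = 0.5,
    on_avatar = FALSE)
  tab <- tab[order(tab$onset), ]
  y <- makeRegressor(20, 2, 1, n, tr) + makeRegressor(100, 2, 2, n, tr)
  run <- boldRun(matrix(y, 1), tr = tr)
  pats <- lssEstimates(run, tab, driftCutoff = Inf)
  b <- patternMatrix(pats)[, 1]
  expect_equal(b[1], 1, tolerance = 1e-6)
  expect_equal(b[2], 2, tolerance = 1e-6)
  expect_equal(b[2] / b[1], 2, tolerance = 1e-6)
  ## single trial: target and nuisance collinear
  tab1 <- tab[tab$onset %in% c(20, 22), ]
  expect_error(lssEstimates(run, tab1), "at least 2 trials")
})

test_that("neural DSM is symmetric, zero-diagonal, with correlation bounds", {
  P <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))
  pats <- new("TrialPatterns", patterns = P,
              meta = data.frame(run = 1L, theta_deg = c(0, 10, 20)))
  D <- neuralDsm(pats)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D[1, 2], 0)            # identical rows
  expect_equal(D[1, 3], 2)            # perfectly anti-correlated rows
  Pbad <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4))
  patsBad <- new("TrialPatterns", patterns = Pbad,
                 meta = data.frame(run = 1L, theta_deg = c(0, 10)))
  expect_error(neuralDsm(patsBad), "trial 1")
})

test_that("model DSM folds angular differences by the periodicity", {
  expect_equal(modelDsm(c(10, 70), 6)[1, 2], 0)    # one period apart
  expect_equal(modelDsm(c(10, 40), 6)[1, 2], 30)   # maximal folded diff
  expect_equal(modelDsm(c(0, 100), 6)[1, 2], 20)   # 100 mod 60 -> 20
  ## invariant to adding a constant to all directions
  th <- c(3, 50, 111, 280)
  expect_equal(modelDsm(th, 6), modelDsm(th + 77, 6))
})

test_that("orientation-independent RSA detects generative hexadirectional structure", {
  expect_equal(
    rsaOrientationIndependent(modelDsm(c(0, 20, 40, 80), 6),
                              modelDsm(c(0, 20, 40, 80), 6))$rho, 1)
  ## generative patterns: similarity decays with folded angular distance
  genPatterns <- function(theta, nVox, noiseSd, seed) {
    set.seed(seed)
    A <- matrix(rnorm(2 * nVox), 2, nVox)
    M <- cbind(cos(6 * theta * pi / 180), sin(6 * theta * pi / 180)) %*% A
    M + matrix(rnorm(length(theta) * nVox, sd = noiseSd),
               length(theta), nVox)
  }
  theta <- seq(0, 355, by = 5)
  P <- genPatterns(theta, 40, 0.3, 42)
  pats <- new("TrialPatterns", patterns = P,
              meta = data.frame(run = 1L, theta_deg = theta))
  rsa <- rsaOrientationIndependent(neuralDsm(pats), modelDsm(theta, 6))
  expect_gt(rsa$rho, 0.3)
  ## pure-noise patterns give rho near zero
  P0 <- matrix(rnorm(length(theta) * 40), length(theta), 40)
  pats0 <- new("TrialPatterns", patterns = P0,
               meta = data.frame(run = 1L, theta_deg = theta))
  rsa0 <- rsaOrientationIndependent(neuralDsm(pats0), modelDsm(theta, 6))
  expect_lt(abs(rsa0$rho), 0.1)
})

test_that("orientation-dependent RSA separates aligned from misaligned patterns", {
  ## aligned trials share one pattern, misaligned trials an orthogonal one
  set.seed(9)
  phi <- 0
  theta <- rep(c(0, 60, 120, 30, 90, 150), each = 4)
  aligned <- classifyAlignment(theta, phi, 6)$aligned
  base1 <- rnorm(30); base2 <- rnorm(30)
  P <- t(vapply(seq_along(theta), function(i)
    (if (aligned[i]) base1 else base2) + rnorm(30, sd = 0.05),
    numeric(30)))
  pats <- new("TrialPatterns", patterns = P,
              meta = data.frame(run = 1L, theta_deg = theta))
  res <- rsaOrientationDependent(pats, phiByRun = phi, fold = 6)
  expect_gt(res$difference, 0.5)
  ## identical patterns give zero difference
  Psame <- matrix(rep(rnorm(30), length(theta)), nrow = length(theta),
                  byrow = TRUE) +
    matrix(rnorm(length(theta) * 30, sd = 1e-8), length(theta), 30)
  patsSame <- new("TrialPatterns", patterns = Psame,
                  meta = data.frame(run = 1L, theta_deg = theta))
  resSame <- rsaOrientationDependent(patsSame, phiByRun = phi, fold = 6)
  expect_lt(abs(resSame$difference), 1e-6)
  ## empty class errors
  expect_error(
    rsaOrientationDependent(
      new("TrialPatterns", patterns = P[1:4, ],
          meta = data.frame(run = 1L, theta_deg = rep(0, 4))),
      phiByRun = 0, fold = 6),
    "non-empty")
})

test_that("direction-label permutation centers both RSA statistics on zero", {
  set.seed(11)
  theta <- seq(0, 355, by = 15)
  P <- matrix(rnorm(length(theta) * 25), length(theta), 25)
  pats <- new("TrialPatterns", patterns = P,
              meta = data.frame(run = 1L, theta_deg = theta))
  nd <- neuralDsm(pats)
  rhos <- replicate(50, {
    thp <- sample(theta)
    rsaOrientationIndependent(nd, modelDsm(thp, 6))$rho
  })
  expect_lt(abs(mean(rhos)), 0.03)
})
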