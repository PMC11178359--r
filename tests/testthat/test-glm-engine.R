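test_that("regressor construction is linear and peaks at the HRF lag", {
  n <- 100; tr <- 2
  z <- makeRegressor(10, 2, 0, n, tr)
  expect_equal(z, rep(0, n))
  r1 <- makeRegressor(10, 2, 1, n, tr)
  r2 <- makeRegressor(10, 2, 2, n, tr)
  expect_equal(r2, 2 * r1)
  ## peak of a single short event occurs ~5 s after onset (HRF lag,
  ## computed from the kernel argmax)
  tt <- seq(0, 30, 0.01)
  hrfPeak <- tt[which.max(canonicalHrf(tt))]
  expect_equal(hrfPeak, 5, tolerance = 0.05)
  scanPeak <- (which.max(r1) - 1) * tr
  expect_lt(abs(scanPeak - (10 + hrfPeak)), 2 * tr)
  expect_error(makeRegressor(1000, 2, 1, n, tr), "beyond run end")
})

test_that("GLM1 design has the documented columns and centering behavior", {
  sub <- tinySubject(trials = 12, runs = 1)
  tab <- sub$trials[[1]]
  ns <- nScans(sub$runs[[1]])
  d <- buildGlm1Design(tab, fold = 6, nScans = ns, tr = 2)
  prov <- designProvenance(d)
  nDrift <- sum(prov$stage == "drift")
  expect_equal(ncol(designData(d)), 4 + nDrift + 1)
  expect_setequal(prov$label[prov$stage == "morph"],
                  c("morph", "morph_sin", "morph_cos"))
  ## theta = 15 deg, f = 6: pre-convolution (sin, cos) = (1, 0)
  expect_equal(sin(6 * 15 * pi / 180), 1)
  expect_equal(cos(6 * 15 * pi / 180), 0, tolerance = 1e-12)
  ## identical directions make the modulators degenerate
  tab2 <- tab
  tab2$theta_deg <- 33
  d2 <- buildGlm1Design(tab2, fold = 6, nScans = ns, tr = 2)
  expect_setequal(degenerateColumns(d2), c("morph_sin", "morph_cos"))
  expect_error(buildGlm1Design(tab, fold = 0, nScans = ns), "fold")
})

test_that("OLS recovers exact coefficients and rejects rank deficiency", {
  sub <- tinySubject(trials = 12, runs = 1)
  ns <- nScans(sub$runs[[1]])
  d <- buildGlm1Design(sub$trials[[1]], 6, nScans = ns, tr = 2)
  X <- designData(d)
  b <- seq_len(ncol(X))
  y <- as.numeric(X %*% b)
  fit <- fitOls(boldRun(matrix(y, nrow = 1), tr = 2), d)
  expect_equal(as.numeric(coefMatrix(fit)), b, tolerance = 1e-8)
  expect_equal(residVariance(fit), 0, tolerance = 1e-12)
  expect_equal(dfResidual(fit), ns - ncol(X))
  ## residuals orthogonal to the design; fitted + residuals = data
  sub2 <- tinySubject(trials = 12, runs = 1, seed = 21L)
  d2 <- buildGlm1Design(sub2$trials[[1]], 6,
                        nScans = nScans(sub2$runs[[1]]), tr = 2)
  X2 <- designData(d2)
  fit2 <- fitOls(sub2$runs[[1]], d2)
  Y <- t(boldData(sub2$runs[[1]]))
  res <- Y - X2 %*% t(coefMatrix(fit2))
  expect_lt(max(abs(crossprod(X2, res))), 1e-6)
  ## duplicated column triggers the rank check, naming the column
  dupProv <- rbind(designProvenance(d2),
                   data.frame(label = "morph_copy", stage = "morph",
                              modulator = NA, bin = NA,
                              degenerate = FALSE))
  dupX <- cbind(X2, morph_copy = X2[, "morph"])
  dDup <- new("DesignMatrix", matrix = dupX, frameTimes = d2@frameTimes,
              provenance = dupProv)
  expect_error(fitOls(sub2$runs[[1]], dDup), "morph")
})

test_that("noiseless hexadirectional data recover omega and phi through the quadrature identity", {
  omega <- 0.4; phiTrue <- 12
  sub <- simulateSubject(tinyConfig(nGrid = 2, omega = omega,
                                    phi = phiTrue, noiseSd = EPS_SD,
                                    trials = 24, runs = 1))
  fit <- fitGlm1All(sub)[[1]]
  qb <- quadratureBetas(fit)
  expect_equal(unname(qb$bCos[1]), omega * cos(6 * phiTrue * pi / 180),
               tolerance = 1e-4)
  expect_equal(unname(qb$bSin[1]), omega * sin(6 * phiTrue * pi / 180),
               tolerance = 1e-4)
  est <- estimateOrientation(fit)
  expect_equal(orientation(est), phiTrue, tolerance = 0.01)
})

test_that("F-to-Z conversion matches the F distribution quantiles", {
  ## the 95th percentile of F(2, 100) maps to Z = qnorm(0.95)
  f95 <- qf(0.95, 2, 100)
  sub <- tinySubject(trials = 12, runs = 1)
  d <- buildGlm1Design(sub$trials[[1]], 6, nScans = nScans(sub$runs[[1]]),
                       tr = 2)
  fit <- fitOls(sub$runs[[1]], d)
  ## synthetic check through the same transform the package applies
  expect_equal(qnorm(pf(f95, 2, 100)), qnorm(0.95), tolerance = 1e-10)
  ## median of the null F distribution maps to Z = 0
  fMed <- qf(0.5, 2, dfResidual(fit))
  expect_equal(qnorm(pf(fMed, 2, dfResidual(fit))), 0, tolerance = 1e-12)
  ## F = 0 is clipped to the configured floor, not -Inf
  res <- quadratureFTest(fit, zClip = 6)
  expect_true(all(is.finite(res$z)))
  expect_true(all(res$z >= -6 - 1e-9 & res$z <= 6 + 1e-9))
})

test_that("GLM2 partitions trials into 2f bins with correct alignment labels", {
  sub <- tinySubject(trials = 24, runs = 1)
  tab <- sub$trials[[1]]
  ns <- nScans(sub$runs[[1]])
  d <- buildGlm2Design(tab, phi = 10, fold = 6, nScans = ns, tr = 2)
  prov <- designProvenance(d)
  bins <- prov[!is.na(prov$bin), ]
  expect_equal(nrow(bins), 12)
  expect_equal(sum(bins$modulator == "aligned"), 6)
  expect_equal(sum(bins$modulator == "misaligned"), 6)
  ## every trial lands in exactly one bin column
  cls <- classifyAlignment(tab$theta_deg[tab$trial_type == "morph"], 10, 6)
  expect_true(all(cls$bin %in% 1:12))
})

test_that("GLM3 centers the distance modulator and rejects constant distance", {
  sub <- tinySubject(trials = 12, runs = 1)
  tab <- sub$trials[[1]]
  ns <- nScans(sub$runs[[1]])
  d <- buildGlm3Design(tab, nScans = ns, tr = 2)
  expect_true("morph_distance" %in% designProvenance(d)$label)
  tabC <- tab
  tabC$distance <- 0.5
  expect_error(buildGlm3Design(tabC, nScans = ns, tr = 2), "degenerate")
  ## distance-coding voxels give a positive t on the modulator
  vox <- voxelSpec(5, "distance", omega = 0, distSlope = 2, noiseSd = 0.3)
  cfg <- simConfig(runs = 1, trialsPerBlock = 24, voxels = vox, seed = 3L)
  sub2 <- simulateSubject(cfg)
  d2 <- buildGlm3Design(sub2$trials[[1]], nScans = nScans(sub2$runs[[1]]),
                        tr = 2)
  f2 <- fitOls(sub2$runs[[1]], d2)
  X <- designData(d2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- match("morph_distance", colnames(X))
  tvals <- coefMatrix(f2)[, j] / sqrt(residVariance(f2) * XtXinv[j, j])
  expect_true(all(tvals > 2))
})
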