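test_that("alignment classification follows the half-open 30-degree bins", {
  r <- classifyAlignment(c(10, 30, 196, 29, 15), 0, 6)
  expect_equal(r$aligned, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(r$center, c(0, 30, 210, 30, 30))  # 15 rounds up (half-open)
  ## 4-fold geometry: 45 deg offset is a trough
  r4 <- classifyAlignment(45, 0, 4)
  expect_false(r4$aligned)
})

test_that("orientation estimation maps averaged betas into the fundamental domain", {
  est0 <- estimateOrientation(list(bSin = 0, bCos = 1), fold = 6)
  expect_equal(orientation(est0), 0)
  est15 <- estimateOrientation(list(bSin = 1, bCos = 0), fold = 6)
  expect_equal(orientation(est15), 15)
  ## atan2 branch: (-1, 0) folds to 45
  vp <- voxelwiseOrientations(list(bSin = c(1, -1), bCos = c(0, 0)),
                              roiVoxels = 1:2, fold = 6)
  expect_equal(vp, c(15, 45))
  ## negative-angle results wrap into [0, 360/f)
  estNeg <- estimateOrientation(list(bSin = -1, bCos = 0), fold = 6)
  expect_equal(orientation(estNeg), 45)
  flagged <- estimateOrientation(list(bSin = 0, bCos = 0), fold = 6)
  expect_true(flagged@lowConfidence)
})

test_that("orientation estimator recovers the simulated orientation and is rotation-equivariant", {
  phiTrue <- 20
  sub <- tinySubject(nGrid = 30, omega = 0.3, phi = phiTrue, trials = 40,
                     runs = 1, seed = 12L)
  fit <- fitGlm1All(sub)[[1]]
  phiHat <- orientation(estimateOrientation(fit))
  err <- min(abs(phiHat - phiTrue), 60 - abs(phiHat - phiTrue))
  expect_lt(err, 2)
  ## rotating all trial directions by delta (relabelling the same data)
  ## shifts the estimated orientation by +delta mod 60
  delta <- 17
  cfg0 <- tinyConfig(nGrid = 5, omega = 0.3, phi = phiTrue,
                     noiseSd = EPS_SD, trials = 40, runs = 1, seed = 12L)
  sub0 <- simulateSubject(cfg0)
  fit0 <- fitGlm1All(sub0)[[1]]
  phi0 <- orientation(estimateOrientation(fit0))
  tab0 <- sub0$trials[[1]]
  tab0$theta_deg <- (tab0$theta_deg + delta) %% 360
  d0 <- buildGlm1Design(tab0, 6, nScans(sub0$runs[[1]]), 2)
  fitR <- fitOls(sub0$runs[[1]], d0)
  phiR <- orientation(estimateOrientation(fitR))
  expect_equal((phiR - phi0) %% 60, delta %% 60, tolerance = 0.05)
})

test_that("leave-one-run-out consistency is positive for grid signal and honest to held-out data", {
  sub <- tinySubject(nGrid = 20, omega = 0.3, trials = 40, runs = 3,
                     seed = 31L)
  res <- looConsistency(sub$runs, sub$trials, fold = 6)
  expect_s4_class(res, "ConsistencyResult")
  expect_equal(nrow(perRunContrasts(res)), 3)
  expect_gt(subjectContrast(res), 0)
  expect_equal(subjectContrast(res), mean(perRunContrasts(res)$contrast))
  ## cross-validation honesty: perturbing the held-out run's data leaves
  ## the orientation applied to it unchanged
  sub2 <- sub
  pert <- boldData(sub2$runs[[1]])
  pert[, ] <- pert + matrix(rnorm(length(pert), sd = 5), nrow(pert))
  sub2$runs[[1]] <- boldRun(pert, tr = 2, runIndex = 1L)
  res2 <- looConsistency(sub2$runs, sub2$trials, fold = 6)
  expect_equal(perRunContrasts(res2)$phi[1], perRunContrasts(res)$phi[1])
  expect_error(looConsistency(sub$runs[1], sub$trials[1]), "2 runs")
})

test_that("contrast arithmetic handles flat and structured bin patterns", {
  ## construct a GLM2 fit whose bin betas are known exactly
  sub <- tinySubject(nGrid = 1, omega = 0, trials = 24, runs = 1)
  d <- buildGlm2Design(sub$trials[[1]], phi = 0, fold = 6,
                       nScans = nScans(sub$runs[[1]]), tr = 2)
  X <- designData(d)
  prov <- designProvenance(d)
  occ <- !prov$degenerate
  b <- numeric(ncol(X))
  b[occ & prov$modulator %in% "aligned"] <- 1     # aligned bins 1, rest 0
  y <- as.numeric(X[, occ] %*% b[occ])
  fit <- fitOls(boldRun(matrix(y, 1), tr = 2), d)
  ct <- alignmentContrast(fit)
  expect_equal(ct$contrast, 1, tolerance = 1e-8)
  bAll <- numeric(ncol(X)); bAll[occ] <- 2        # all bins equal
  yAll <- as.numeric(X[, occ] %*% bAll[occ])
  fitAll <- fitOls(boldRun(matrix(yAll, 1), tr = 2), d)
  expect_equal(alignmentContrast(fitAll)$contrast, 0, tolerance = 1e-8)
})

test_that("group and covariate tests behave on degenerate and structured input", {
  g <- groupTest(c(2, 2, 2))
  expect_true(g$degenerate)
  expect_equal(g$t, Inf)
  expect_equal(groupTest(c(-1, 1, -2, 2), alternative = "two.sided")$t, 0)
  expect_error(groupTest(c(0, 0, 0)), "zero variance")
  ## covariate regression: perfect and recovered slopes
  set.seed(5)
  contrasts <- rnorm(30)
  ct <- suppressWarnings(covariateTest(contrasts, list(self = contrasts)))
  expect_equal(ct$r, 1, tolerance = 1e-12)
  cov2 <- rnorm(30)
  gen <- 0.5 + 2 * cov2 + rnorm(30, sd = 0.01)
  ct2 <- covariateTest(gen, list(x = cov2))
  expect_equal(ct2$slope, 2, tolerance = 0.05)
  expect_true(all(ct2$p_fdr >= ct2$p - 1e-15))
  expect_error(covariateTest(gen, list(k = rep(1, 30))), "constant")
})

test_that("a pure sixfold signal shows no consistency at control folds (specificity)", {
  ## single subject, strong signal, near-noiseless: sixfold contrast
  ## should dominate every control fold
  sub <- tinySubject(nGrid = 10, omega = 0.4, noiseSd = 0.05, trials = 40,
                     runs = 2, seed = 77L)
  res6 <- looConsistency(sub$runs, sub$trials, fold = 6)
  ctrl <- controlPeriodicities(sub$runs, sub$trials, folds = c(4, 5, 7, 8))
  expect_named(ctrl, c("fold4", "fold5", "fold7", "fold8"))
  for (cr in ctrl)
    expect_lt(subjectContrast(cr), subjectContrast(res6))
  expect_gt(subjectContrast(res6), 0)
})
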