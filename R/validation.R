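# Ground-truth validation studies: standardized simulations that
# exercise the full pipeline against known generating parameters. These
# back the package's recovery/calibration checks and are reusable for
# power exploration.

#' Grid-code recovery and consistency study
#'
#' Simulates \code{nSubjects} scanning sessions under the default task
#' conditions (4 runs x 80 trials, TR 2 s) with an ROI of hexadirectional
#' grid voxels whose true orientation is drawn uniformly from
#' [0, 60) degrees per subject, then runs the orientation-estimation and
#' leave-one-run-out consistency pipeline at the requested folds.
#'
#' @param nSubjects number of simulated subjects.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param folds periodicities to analyze (6 plus controls by default).
#' @param nVoxels grid voxels in the ROI.
#' @param omega modulation amplitude (default the package's calibrated
#'   effect size, per-voxel quadrature Z ~ 2).
#' @param noiseSd noise SD.
#' @param runs,trialsPerBlock task dimensions.
#' @return list with \code{perSubject} (data.frame: subject, phiTrue,
#'   medianAbsErrorDeg of the three-run orientation estimates) and
#'   \code{contrasts} (subject x fold matrix of consistency contrasts).
#' @export
gridCodeStudy <- function(nSubjects = 20, seed = 1L,
                          folds = c(4, 5, 6, 7, 8), nVoxels = 50,
                          omega = 0.15, noiseSd = 1, runs = 4,
                          trialsPerBlock = 80) {
  phiTrue <- withSeed(seed, stats::runif(nSubjects, 0, 60))
  contrasts <- matrix(NA_real_, nSubjects, length(folds),
                      dimnames = list(NULL, paste0("fold", folds)))
  perSubject <- data.frame(subject = seq_len(nSubjects), phiTrue = phiTrue,
                           medianAbsErrorDeg = NA_real_)
  for (s in seq_len(nSubjects)) {
    vox <- voxelSpec(nVoxels, "grid", omega = omega, phi = phiTrue[s],
                     noiseSd = noiseSd)
    cfg <- simConfig(runs = runs, trialsPerBlock = trialsPerBlock,
                     voxels = vox, seed = seed + 13L * s)
    sub <- simulateSubject(cfg)
    glm1 <- lapply(seq_len(runs), function(r) {
      d <- buildGlm1Design(sub$trials[[r]], fold = 6,
                           nScans = nScans(sub$runs[[r]]),
                           tr = repetitionTime(sub$runs[[r]]))
      fitOls(sub$runs[[r]], d)
    })
    errs <- vapply(seq_len(runs), function(r) {
      est <- setdiff(seq_len(runs), r)
      phiHat <- orientation(estimateOrientation(glm1[est]))
      d <- abs(phiHat - phiTrue[s]) %% 60
      min(d, 60 - d)
    }, numeric(1))
    perSubject$medianAbsErrorDeg[s] <- stats::median(errs)
    for (k in seq_along(folds))
      contrasts[s, k] <- subjectContrast(
        looConsistency(sub$runs, sub$trials, fold = folds[k]))
  }
  list(perSubject = perSubject, contrasts = contrasts)
}

#' Null calibration of the group consistency test
#'
#' Repeats a scaled-down version of the consistency analysis with zero
#' modulation amplitude (omega = 0): each repetition simulates
#' \code{nSubjects} subjects, runs the leave-one-run-out analysis at
#' fold 6 and applies the group one-sample test. Under the null the
#' rejection rate at \code{alpha} should match \code{alpha} up to
#' Monte-Carlo error.
#'
#' @param nReps repetitions.
#' @param nSubjects subjects per repetition.
#' @param seed master seed.
#' @param runs,trialsPerBlock,nVoxels scaled-down task dimensions.
#' @param alpha nominal level.
#' @return list with rejectionRate, pValues.
#' @export
nullCalibrationStudy <- function(nReps = 100, nSubjects = 8, seed = 1L,
                                 runs = 2, trialsPerBlock = 20,
                                 nVoxels = 8, alpha = 0.05) {
  ps <- vapply(seq_len(nReps), function(rep) {
    cons <- vapply(seq_len(nSubjects), function(s) {
      vox <- voxelSpec(nVoxels, "grid", omega = 0, noiseSd = 1)
      cfg <- simConfig(runs = runs, trialsPerBlock = trialsPerBlock,
                       voxels = vox,
                       seed = seed + 1009L * rep + 7L * s)
      sub <- simulateSubject(cfg)
      subjectContrast(looConsistency(sub$runs, sub$trials, fold = 6))
    }, numeric(1))
    groupTest(cons)$p
  }, numeric(1))
  list(rejectionRate = mean(ps < alpha), pValues = ps)
}

#' Calibration of the quadrature F-to-Z transform under the null
#'
#' Simulates one run of pure-noise voxels, applies the quadrature F test
#' and reports the empirical one-sided type-I error at \code{alpha} and
#' a Kolmogorov-Smirnov check of the Z statistics against the standard
#' normal (under white noise the F statistic is exactly F(2, df), so Z
#' should be exactly standard normal).
#'
#' @param nVoxels null voxels (default 2000).
#' @param seed seed.
#' @param trialsPerBlock trials in the simulated run.
#' @param alpha nominal level.
#' @return list with typeIRate, ksP, z.
#' @export
zCalibrationStudy <- function(nVoxels = 2000, seed = 1L,
                              trialsPerBlock = 80, alpha = 0.05) {
  vox <- voxelSpec(nVoxels, "noise", omega = 0, noiseSd = 1)
  cfg <- simConfig(runs = 1, trialsPerBlock = trialsPerBlock,
                   voxels = vox, seed = seed)
  sub <- simulateSubject(cfg)
  d <- buildGlm1Design(sub$trials[[1]], fold = 6,
                       nScans = nScans(sub$runs[[1]]), tr = 2)
  res <- quadratureFTest(fitOls(sub$runs[[1]], d))
  list(typeIRate = mean(res$z > stats::qnorm(1 - alpha)),
       ksP = stats::ks.test(res$z, "pnorm")$p.value, z = res$z)
}

## Generative multivoxel patterns with f-fold directional structure:
## voxel k responds g_k * cos(fold*(theta - phi)) + noise, with positive
## mean gains (neighboring voxels share orientation and response sign).
.genDirectionalPatterns <- function(theta, phi, nVox, noiseSd, fold = 6,
                                    gainMean = 1, gainSd = 0.3) {
  g <- stats::rnorm(nVox, gainMean, gainSd)
  tune <- cos(fold * deg2rad(theta - phi))
  outer(tune, g) + matrix(stats::rnorm(length(theta) * nVox,
                                       sd = noiseSd),
                          length(theta), nVox)
}

#' RSA validation study on generative directional patterns
#'
#' Simulates, per subject, single-trial multivoxel patterns over 4 runs
#' x 80 trial directions. With \code{signal = TRUE} patterns carry
#' sixfold directional tuning around a subject-specific orientation;
#' with \code{signal = FALSE} they are pure noise. Computes, per
#' subject, the orientation-independent statistic (Spearman correlation
#' between the neural DSM and the folded angular-difference model DSM)
#' and the orientation-dependent statistic (AA minus AM pattern
#' similarity, with each run's orientation estimated from the other
#' runs' patterns only).
#'
#' @param nSubjects subjects.
#' @param seed master seed.
#' @param signal generate hexadirectional structure (TRUE) or noise.
#' @param nVox voxels per pattern.
#' @param noiseSd pattern noise SD.
#' @param runs,trialsPerBlock task dimensions.
#' @return list with per-subject \code{rho}, \code{fisherZ},
#'   \code{aaMinusAm}.
#' @export
rsaStudy <- function(nSubjects = 20, seed = 1L, signal = TRUE, nVox = 40,
                     noiseSd = 1, runs = 4, trialsPerBlock = 80) {
  rho <- aaam <- numeric(nSubjects)
  sp <- socialSpace()
  for (s in seq_len(nSubjects)) {
    out <- withSeed(seed + 101L * s, {
      phiTrue <- stats::runif(1, 0, 60)
      av <- sampleAvatarLayout(sp, seed = seed + 101L * s + 1L)
      theta <- run <- NULL
      for (r in seq_len(runs)) {
        tab <- sampleRecallBlock(sp, av, nTrials = trialsPerBlock,
                                 seed = seed + 101L * s + 10L + r,
                                 run = r)
        th <- tab$theta_deg[tab$trial_type == "morph"]
        theta <- c(theta, th)
        run <- c(run, rep(r, length(th)))
      }
      P <- if (signal)
        .genDirectionalPatterns(theta, phiTrue, nVox, noiseSd)
      else matrix(stats::rnorm(length(theta) * nVox), length(theta), nVox)
      pats <- trialPatterns(P, data.frame(run = run, theta_deg = theta))
      indep <- rsaOrientationIndependent(neuralDsm(pats),
                                         modelDsm(theta, 6))
      ## out-of-run orientation estimates from per-voxel quadrature
      ## regression of the patterns on sin/cos(6 theta)
      phiByRun <- vapply(seq_len(runs), function(r) {
        i <- run != r
        X <- cbind(cos(6 * deg2rad(theta[i])), sin(6 * deg2rad(theta[i])))
        B <- stats::lm.fit(X, P[i, , drop = FALSE])$coefficients
        orientation(estimateOrientation(list(bSin = B[2, ],
                                             bCos = B[1, ]), fold = 6))
      }, numeric(1))
      names(phiByRun) <- as.character(seq_len(runs))
      dep <- rsaOrientationDependent(pats, phiByRun, fold = 6)
      c(indep$rho, dep$difference)
    })
    rho[s] <- out[1]; aaam[s] <- out[2]
  }
  list(rho = rho, fisherZ = atanh(rho), aaMinusAm = aaam)
}
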