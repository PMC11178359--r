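# Representational similarity analyses: least-squares-separate
# single-trial estimation, neural and model dissimilarity matrices, and
# the orientation-independent and orientation-dependent tests.

#' Least-squares-separate (LSS) single-trial pattern estimation
#'
#' For each trial a separate GLM is fit with one target regressor
#' modeling that trial's morph event and one nuisance regressor modeling
#' all remaining morph events, plus choice, drift and intercept columns;
#' the target beta is that trial's activity pattern. This stabilizes
#' single-trial estimates in fast event-related designs where
#' one-regressor-per-trial models become collinear.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param trials trial table for that run (>= 2 trials).
#' @param driftCutoff high-pass cutoff (s).
#' @param hrfParams HRF parameters.
#' @return A \linkS4class{TrialPatterns}, rows in trial-table (onset)
#'   order.
#' @export
lssEstimates <- function(run, trials, driftCutoff = 128,
                         hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                       c = 1 / 6)) {
  validateTrialTable(trials)
  morph <- morphEvents(trials)
  choice <- choiceEvents(trials)
  nT <- nrow(morph)
  if (nT < 2)
    stopf("LSS needs at least 2 trials (target and nuisance collinear)")
  ns <- nScans(run); tr <- repetitionTime(run)
  mk <- function(ev) makeRegressor(ev$onset, ev$duration,
                                   rep(1, nrow(ev)), ns, tr, hrfParams)
  choiceCol <- mk(choice)
  drift <- dctBasis(ns, tr, driftCutoff)
  Y <- t(boldData(run))
  pat <- matrix(NA_real_, nrow = nT, ncol = nVoxels(run))
  for (i in seq_len(nT)) {
    target <- mk(morph[i, , drop = FALSE])
    nuis <- mk(morph[-i, , drop = FALSE])
    X <- cbind(target = target, nuisance = nuis, choice = choiceCol,
               drift, intercept = 1)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stopf("LSS design rank-deficient at trial %d", i)
    pat[i, ] <- qr.coef(qrX, Y)[1, ]
  }
  trialPatterns(pat, data.frame(run = morph$run,
                                theta_deg = morph$theta_deg))
}

#' Neural dissimilarity matrix (1 - Pearson correlation)
#'
#' @param patterns a \linkS4class{TrialPatterns} (>= 2 voxels).
#' @return trial x trial dissimilarity matrix, symmetric with zero
#'   diagonal.
#' @export
neuralDsm <- function(patterns) {
  P <- patternMatrix(patterns)
  if (ncol(P) < 2)
    stopf("correlation needs at least 2 voxels")
  sds <- apply(P, 1, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance pattern row(s): trial %s",
          paste(which(sds == 0), collapse = ", "))
  D <- 1 - stats::cor(t(P))
  diag(D) <- 0
  D
}

#' Model dissimilarity matrix from trajectory directions
#'
#' Predicted dissimilarity between two trials is the angular difference
#' of their directions folded by the periodicity:
#' \code{min(m, 360/f - m)} with \code{m = |theta_i - theta_j| mod
#' (360/f)}, in [0, 180/f] degrees (0..30 for f = 6).
#'
#' @param theta trial directions, degrees.
#' @param fold periodicity f.
#' @return trial x trial model DSM (degrees).
#' @examples
#' modelDsm(c(10, 70), 6)[1, 2]  # 0: exactly one period apart
#' @export
modelDsm <- function(theta, fold = 6) {
  if (fold < 1) stopf("fold must be >= 1")
  per <- 360 / fold
  m <- abs(outer(theta, theta, "-")) %% per
  D <- pmin(m, per - m)
  diag(D) <- 0
  D
}

.lowerTri <- function(M) M[lower.tri(M)]

#' Orientation-independent RSA
#'
#' Spearman rank correlation between the off-diagonal (lower-triangle)
#' entries of the neural and model DSMs, with its Fisher Z transform.
#' Positive correlation means pattern similarity tracks the 60-degree
#' folded angular difference between trajectories, without reference to
#' any estimated grid orientation.
#'
#' @param neural neural DSM (from \code{\link{neuralDsm}}).
#' @param model model DSM (from \code{\link{modelDsm}}), same size.
#' @param excludeWithinRun optional integer run labels (one per trial):
#'   when supplied, within-run pairs are excluded from the correlation.
#' @return list with rho and fisherZ.
#' @export
rsaOrientationIndependent <- function(neural, model,
                                      excludeWithinRun = NULL) {
  if (!all(dim(neural) == dim(model)))
    stopf("neural and model DSM sizes differ")
  nv <- .lowerTri(neural); mv <- .lowerTri(model)
  if (!is.null(excludeWithinRun)) {
    same <- .lowerTri(outer(excludeWithinRun, excludeWithinRun, "=="))
    nv <- nv[!same]; mv <- mv[!same]
  }
  if (stats::sd(nv) == 0 || stats::sd(mv) == 0)
    stopf("constant DSM: correlation undefined")
  rho <- stats::cor(nv, mv, method = "spearman")
  list(rho = rho, fisherZ = atanh(rho))
}

#' Orientation-dependent RSA (AA minus AM pattern similarity)
#'
#' Trials are classified as aligned or misaligned to a putative grid
#' orientation (estimated out-of-sample, per run, by the same
#' leave-one-run-out procedure as the univariate analysis). The statistic
#' is the mean Pearson similarity among aligned-aligned (AA) trial pairs
#' minus the mean similarity between aligned-misaligned (AM) pairs.
#'
#' @param patterns a \linkS4class{TrialPatterns} spanning all runs.
#' @param phiByRun named numeric vector: putative orientation (degrees)
#'   per run label, each estimated without that run's data; or a single
#'   value applied to all trials.
#' @param fold periodicity f.
#' @param excludeWithinRun exclude within-run pairs (default FALSE:
#'   pooled over all pairs).
#' @return list with aa, am, difference, nAligned, nMisaligned.
#' @export
rsaOrientationDependent <- function(patterns, phiByRun, fold = 6,
                                    excludeWithinRun = FALSE) {
  meta <- patternMeta(patterns)
  phi <- if (length(phiByRun) == 1 && is.null(names(phiByRun)))
    rep(phiByRun, nrow(meta))
  else {
    key <- as.character(meta$run)
    if (!all(key %in% names(phiByRun)))
      stopf("phiByRun is missing run(s): %s",
            paste(setdiff(unique(key), names(phiByRun)), collapse = ", "))
    unname(phiByRun[key])
  }
  aligned <- classifyAlignment(meta$theta_deg, phi, fold)$aligned
  if (!any(aligned) || all(aligned))
    stopf("both aligned and misaligned trial classes must be non-empty")
  S <- stats::cor(t(patternMatrix(patterns)))
  pairMask <- function(cls1, cls2) {
    M <- outer(cls1, cls2, "&") | outer(cls2, cls1, "&")
    diag(M) <- FALSE
    if (excludeWithinRun)
      M <- M & outer(meta$run, meta$run, "!=")
    M & lower.tri(M)
  }
  aaM <- pairMask(aligned, aligned)
  amM <- pairMask(aligned, !aligned)
  if (!any(aaM) || !any(amM))
    stopf("no usable AA or AM pairs under the current settings")
  aa <- mean(S[aaM]); am <- mean(S[amM])
  list(aa = aa, am = am, difference = aa - am,
       nAligned = sum(aligned), nMisaligned = sum(!aligned))
}

#' Group-level test of per-subject RSA statistics
#'
#' One-sample t test across subjects on Fisher-Z-transformed Spearman
#' correlations (orientation-independent) or on AA-AM similarity
#' differences (orientation-dependent).
#'
#' @param values per-subject statistics.
#' @param alternative default "greater".
#' @return list with t, df, p, mean.
#' @export
rsaGroupTest <- function(values, alternative = c("greater", "two.sided",
                                                 "less")) {
  groupTest(values, alternative = match.arg(alternative))
}
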