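# Temporal signal-to-noise quality control and its relation to the
# hexagonal-modulation statistic.

#' Temporal signal-to-noise ratio (tSNR)
#'
#' Per voxel and run, \code{tSNR = mu / sigma} with mu the time-series
#' mean and sigma its standard deviation (computed on the raw series by
#' default; \code{detrend = TRUE} removes a linear trend first). The
#' per-voxel tSNR is the mean across runs; an ROI's tSNR is the mean
#' over its member voxels. Voxels with sigma = 0 in a run are undefined
#' (NA) for that run and excluded from aggregates.
#'
#' @param runs a \linkS4class{BoldRun} or list of them (same voxels).
#' @param roiVoxels optional ROI voxel indices for the ROI mean.
#' @param detrend remove a linear trend before computing sigma.
#' @return list with \code{voxel} (per-voxel tSNR averaged across runs),
#'   \code{perRun} (voxel x run matrix), \code{roiMean}.
#' @export
tsnr <- function(runs, roiVoxels = NULL, detrend = FALSE) {
  if (is(runs, "BoldRun")) runs <- list(runs)
  perRun <- vapply(runs, function(r) {
    if (nScans(r) < 2) stopf("tSNR needs at least 2 scans")
    Y <- boldData(r)
    mu <- rowMeans(Y)
    if (detrend) {
      tt <- seq_len(ncol(Y))
      Y <- Y - t(apply(Y, 1, function(y) stats::fitted(stats::lm(y ~ tt))))
      sg <- apply(Y, 1, stats::sd)
    } else sg <- apply(Y, 1, stats::sd)
    out <- mu / sg
    out[sg == 0] <- NA_real_
    out
  }, numeric(nVoxels(runs[[1]])))
  perRun <- matrix(perRun, nrow = nVoxels(runs[[1]]))
  voxel <- rowMeans(perRun)
  roiMean <- if (is.null(roiVoxels)) mean(voxel, na.rm = TRUE)
             else mean(voxel[roiVoxels], na.rm = TRUE)
  list(voxel = voxel, perRun = perRun, roiMean = roiMean)
}

#' Relationship between tSNR and the hexagonal-modulation statistic
#'
#' Two analyses: (1) across subjects, the Pearson correlation between
#' each subject's ROI-mean tSNR and ROI-mean modulation Z; (2) within
#' each subject, the per-voxel correlation between tSNR and Z, Fisher-Z
#' transformed, with a group-level two-sided Wilcoxon signed-rank test of
#' whether the participant-level correlations differ from zero.
#'
#' @param tsnrByVoxel list (one per subject) of per-voxel tSNR vectors.
#' @param zByVoxel list (one per subject) of per-voxel modulation Z
#'   vectors (matched voxels).
#' @return list with \code{across} (r, p, n) and \code{within}
#'   (perSubjectR, fisherZ, wilcoxonV, p).
#' @export
tsnrModulationRelation <- function(tsnrByVoxel, zByVoxel) {
  if (length(tsnrByVoxel) != length(zByVoxel))
    stopf("subject lists differ in length")
  n <- length(tsnrByVoxel)
  if (n < 2) stopf("need at least 2 subjects")
  withinR <- vapply(seq_len(n), function(i) {
    a <- tsnrByVoxel[[i]]; b <- zByVoxel[[i]]
    if (length(a) != length(b)) stopf("subject %d: voxel mismatch", i)
    ok <- is.finite(a) & is.finite(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stopf("subject %d: constant input", i)
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  fz <- atanh(pmin(pmax(withinR, -1 + 1e-12), 1 - 1e-12))
  wt <- stats::wilcox.test(fz, mu = 0, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  meanT <- vapply(tsnrByVoxel, function(v) mean(v, na.rm = TRUE),
                  numeric(1))
  meanZ <- vapply(zByVoxel, function(v) mean(v, na.rm = TRUE), numeric(1))
  if (stats::sd(meanT) == 0 || stats::sd(meanZ) == 0)
    stopf("constant subject-level means")
  ct <- stats::cor.test(meanT, meanZ)
  list(across = list(r = unname(ct$estimate), p = ct$p.value, n = n),
       within = list(perSubjectR = withinR, fisherZ = fz,
                     wilcoxonV = unname(wt$statistic), p = wt$p.value))
}
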