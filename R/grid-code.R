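# Grid-orientation estimation and the leave-one-run-out consistency
# analysis, with control periodicities and group-level statistics.

#' Classify trial directions by alignment to a grid orientation
#'
#' The offset \code{(theta - phi) mod 360} is assigned to the nearest of
#' the 2f bin centers \code{k * 360/(2f)} (half-open intervals
#' [center - w/2, center + w/2) with w = 360/(2f), so an offset exactly
#' halfway rounds up to the next center). Bins whose center is 0 modulo
#' 360/f degrees are aligned; centers at 360/(2f) modulo 360/f are
#' misaligned. For f = 6 this is 12 bins of 30 degrees: six aligned
#' (0 mod 60) and six misaligned (30 mod 60).
#'
#' @param theta trajectory directions, degrees.
#' @param phi grid orientation, degrees.
#' @param fold periodicity f (>= 1).
#' @return data.frame with per-trial \code{bin} (1..2f), \code{center}
#'   (degrees) and logical \code{aligned}.
#' @examples
#' classifyAlignment(c(10, 30, 196), 0, 6)$aligned  # TRUE FALSE FALSE
#' @export
classifyAlignment <- function(theta, phi, fold = 6) {
  if (fold < 1) stopf("fold must be >= 1")
  w <- 360 / (2 * fold)
  offset <- (theta - phi) %% 360
  bin0 <- floor((offset + w / 2) / w) %% (2 * fold)   # 0-based
  center <- bin0 * w
  data.frame(bin = as.integer(bin0) + 1L, center = center,
             aligned = center %% (360 / fold) == 0)
}

#' Estimate the grid orientation of an ROI
#'
#' Quadrature betas are averaged across the ROI voxels (and any number of
#' estimating runs), then \code{phi = atan2(mean(bSin), mean(bCos)) /
#' fold}, mapped into the fundamental domain [0, 360/fold) degrees. When
#' both averaged betas are near zero the direction is undefined; phi is
#' still returned but flagged low-confidence.
#'
#' @param betas list with \code{bSin}, \code{bCos} per voxel (from
#'   \code{\link{quadratureBetas}}), or a \linkS4class{GlmFit}; multiple
#'   estimating runs may be supplied as a list of such objects, in which
#'   case betas are averaged across runs first.
#' @param roiVoxels integer indices of the ROI voxels (default: all).
#' @param fold periodicity f.
#' @param sourceRuns integer labels of the estimating runs (metadata).
#' @param roi ROI label (metadata).
#' @param tol both |mean betas| below this flags low confidence.
#' @return An \linkS4class{OrientationEstimate}.
#' @export
estimateOrientation <- function(betas, roiVoxels = NULL, fold = 6,
                                sourceRuns = integer(), roi = "",
                                tol = 1e-10) {
  bs <- .collectQuadBetas(betas)
  fold <- if (!is.null(bs$fold)) bs$fold else fold
  bSin <- bs$bSin; bCos <- bs$bCos
  if (is.null(roiVoxels)) roiVoxels <- seq_along(bSin)
  if (!length(roiVoxels)) stopf("ROI contains no voxels")
  mS <- mean(bSin[roiVoxels]); mC <- mean(bCos[roiVoxels])
  low <- abs(mS) < tol && abs(mC) < tol
  phi <- (rad2deg(atan2(mS, mC)) / fold) %% (360 / fold)
  new("OrientationEstimate", phi = phi, fold = fold,
      sourceRuns = as.integer(sourceRuns), roi = roi,
      voxelPhi = numeric(), lowConfidence = low)
}

## Accept a GlmFit, a quadrature-beta list, or a list of either; average
## betas across multiple runs.
.collectQuadBetas <- function(betas) {
  one <- function(b) if (is(b, "GlmFit")) quadratureBetas(b) else b
  if (is(betas, "GlmFit") ||
      (is.list(betas) && !is.null(betas$bSin)))
    return(one(betas))
  parts <- lapply(betas, one)
  list(bSin = rowMeans(do.call(cbind, lapply(parts, `[[`, "bSin"))),
       bCos = rowMeans(do.call(cbind, lapply(parts, `[[`, "bCos"))),
       fold = parts[[1]]$fold)
}

#' Per-voxel putative grid orientations
#'
#' @param betas quadrature betas (list or \linkS4class{GlmFit}, possibly
#'   a list across runs as in \code{\link{estimateOrientation}}).
#' @param roiVoxels voxel indices (default all; at least 2).
#' @param fold periodicity.
#' @return numeric vector of per-voxel orientations, degrees in
#'   [0, 360/fold).
#' @export
voxelwiseOrientations <- function(betas, roiVoxels = NULL, fold = 6) {
  bs <- .collectQuadBetas(betas)
  fold <- if (!is.null(bs$fold)) bs$fold else fold
  if (is.null(roiVoxels)) roiVoxels <- seq_along(bs$bSin)
  if (length(roiVoxels) < 2) stopf("need at least 2 voxels")
  (rad2deg(atan2(bs$bSin[roiVoxels], bs$bCos[roiVoxels])) / fold) %%
    (360 / fold)
}

#' Aligned-minus-misaligned contrast from a GLM2 fit
#'
#' ROI-mean beta of each occupied alignment bin; contrast = mean over
#' occupied aligned bins minus mean over occupied misaligned bins
#' (weights +1/nAligned, -1/nMisaligned).
#'
#' @param fit a \linkS4class{GlmFit} of a GLM2 design.
#' @param roiVoxels voxel indices (default all).
#' @return list: contrast, alignedMean, misalignedMean, nAlignedBins,
#'   nMisalignedBins, binMeans (named vector).
#' @export
alignmentContrast <- function(fit, roiVoxels = NULL) {
  prov <- fit@design@provenance
  binCols <- which(!is.na(prov$bin))
  if (!length(binCols)) stopf("fit does not contain alignment bins")
  if (is.null(roiVoxels)) roiVoxels <- seq_len(nrow(fit@betas))
  occupied <- binCols[!prov$degenerate[binCols]]
  means <- colMeans(fit@betas[roiVoxels, occupied, drop = FALSE])
  aligned <- prov$modulator[occupied] == "aligned"
  if (!any(aligned) || all(aligned))
    return(list(contrast = NA_real_, alignedMean = NA_real_,
                misalignedMean = NA_real_,
                nAlignedBins = sum(aligned),
                nMisalignedBins = sum(!aligned), binMeans = means))
  aMean <- mean(means[aligned]); mMean <- mean(means[!aligned])
  list(contrast = aMean - mMean, alignedMean = aMean,
       misalignedMean = mMean, nAlignedBins = sum(aligned),
       nMisalignedBins = sum(!aligned),
       binMeans = stats::setNames(means, prov$label[occupied]))
}

#' Leave-one-run-out grid-orientation consistency analysis
#'
#' For each held-out run r: GLM1 (at the stated fold) is fit to each of
#' the remaining runs, quadrature betas are averaged across those
#' estimating runs and the ROI voxels to give the putative orientation
#' phi(-r); GLM2 is then built on run r with phi(-r) and fit, and the
#' aligned-minus-misaligned contrast computed over occupied bins. The
#' held-out run never contributes to the orientation used to test it. A
#' held-out run with no occupied aligned or no occupied misaligned bin is
#' excluded with a warning. The subject-level contrast is the mean over
#' evaluated runs.
#'
#' @param runs list of \linkS4class{BoldRun}s (>= 2).
#' @param trials list of per-run trial tables (same order).
#' @param roiVoxels integer ROI voxel indices (default: all voxels).
#' @param fold periodicity f.
#' @param driftCutoff,hrfParams passed to the design builders.
#' @param roi ROI label.
#' @return A \linkS4class{ConsistencyResult}.
#' @export
looConsistency <- function(runs, trials, roiVoxels = NULL, fold = 6,
                           driftCutoff = 128,
                           hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                         c = 1 / 6),
                           roi = "") {
  nR <- length(runs)
  if (nR < 2) stopf("leave-one-run-out needs at least 2 runs")
  if (length(trials) != nR)
    stopf("trials must have one table per run")
  ## GLM1 fits are reused across folds: fit each run once
  glm1 <- lapply(seq_len(nR), function(r) {
    d <- buildGlm1Design(trials[[r]], fold = fold,
                         nScans = nScans(runs[[r]]),
                         tr = repetitionTime(runs[[r]]),
                         driftCutoff = driftCutoff, hrfParams = hrfParams)
    fitOls(runs[[r]], d)
  })
  rows <- NULL
  for (r in seq_len(nR)) {
    est <- setdiff(seq_len(nR), r)
    phi <- estimateOrientation(glm1[est], roiVoxels = roiVoxels,
                               fold = fold, sourceRuns = est, roi = roi)
    d2 <- buildGlm2Design(trials[[r]], phi, nScans = nScans(runs[[r]]),
                          tr = repetitionTime(runs[[r]]),
                          driftCutoff = driftCutoff,
                          hrfParams = hrfParams)
    f2 <- fitOls(runs[[r]], d2)
    ct <- alignmentContrast(f2, roiVoxels)
    if (is.na(ct$contrast)) {
      warning(sprintf(
        "run %d excluded: no occupied %s bins", r,
        if (ct$nAlignedBins == 0) "aligned" else "misaligned"),
        call. = FALSE)
      next
    }
    rows <- rbind(rows, data.frame(
      run = r, phi = orientation(phi), alignedMean = ct$alignedMean,
      misalignedMean = ct$misalignedMean, contrast = ct$contrast,
      nAlignedBins = ct$nAlignedBins,
      nMisalignedBins = ct$nMisalignedBins))
  }
  if (is.null(rows)) stopf("no run could be evaluated")
  new("ConsistencyResult", perRun = rows,
      subjectContrast = mean(rows$contrast), fold = fold, roi = roi)
}

#' Consistency analysis at control periodicities
#'
#' Runs the identical leave-one-run-out pipeline at each control fold
#' (fourfold, fivefold, sevenfold and eightfold by default), with
#' fold-generalized bins of width 360/(2f) degrees. A signal that is
#' genuinely sixfold should show no consistency at these folds.
#'
#' @inheritParams looConsistency
#' @param folds integer vector of control periodicities.
#' @return Named list of \linkS4class{ConsistencyResult}, one per fold.
#' @export
controlPeriodicities <- function(runs, trials, roiVoxels = NULL,
                                 folds = c(4, 5, 7, 8),
                                 driftCutoff = 128,
                                 hrfParams = c(a1 = 6, b1 = 1, a2 = 16,
                                               b2 = 1, c = 1 / 6),
                                 roi = "") {
  res <- lapply(folds, function(f)
    looConsistency(runs, trials, roiVoxels, fold = f,
                   driftCutoff = driftCutoff, hrfParams = hrfParams,
                   roi = roi))
  names(res) <- paste0("fold", folds)
  res
}

#' Second-level one-sample (and paired) test of consistency contrasts
#'
#' One-sample t test of per-subject contrasts against zero. When
#' \code{paired} is supplied (e.g. a control fold's contrasts), a paired
#' t test of \code{contrasts - paired} is returned instead.
#'
#' @param contrasts per-subject contrast values (n >= 2).
#' @param paired optional second sample for a paired comparison.
#' @param alternative test direction, default "greater" (the consistency
#'   prediction is align > misalign).
#' @return list with t, df, p, mean, degenerate flag.
#' @export
groupTest <- function(contrasts, paired = NULL,
                      alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  x <- if (is.null(paired)) contrasts else contrasts - paired
  if (length(x) < 2) stopf("need at least 2 subjects")
  if (stats::sd(x) == 0) {
    if (mean(x) == 0) stopf("zero variance and zero mean: test undefined")
    return(list(t = Inf * sign(mean(x)), df = length(x) - 1,
                p = if (sign(mean(x)) > 0 || alternative == "two.sided") 0
                    else 1,
                mean = mean(x), degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = 0, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(x), degenerate = FALSE)
}

#' Regress subject contrasts on behavioral covariates
#'
#' Each covariate is tested in a separate simple regression of the
#' per-subject consistency contrasts on the covariate;
#' Benjamini-Hochberg FDR correction is applied across the tested
#' covariates.
#'
#' @param contrasts per-subject contrast values (n >= 3).
#' @param covariates named list or data.frame of per-subject covariates.
#' @return data.frame with covariate, slope, r, t, p, p_fdr.
#' @export
covariateTest <- function(contrasts, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(contrasts))
    stopf("covariates must have one row per subject")
  if (length(contrasts) < 3) stopf("need at least 3 subjects")
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (stats::sd(v) == 0) stopf("covariate '%s' is constant", nm)
    fit <- stats::lm(contrasts ~ v)
    s <- summary(fit)
    data.frame(covariate = nm, slope = unname(stats::coef(fit)[2]),
               r = stats::cor(contrasts, v),
               t = s$coefficients[2, "t value"],
               p = s$coefficients[2, "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Spherical ROI voxel indices on a 3D voxel grid
#'
#' Utility replacing peak-sphere ROI construction: returns the flattened
#' indices of voxels within \code{radius} (voxel units) of a center on a
#' grid of dimensions \code{dims}, using the same flattening order as
#' \code{\link{writeBoldRun}}.
#'
#' @param center length-3 voxel coordinate (1-based).
#' @param radius radius in voxel units.
#' @param dims length-3 grid dimensions.
#' @return integer voxel indices.
#' @export
sphereRoi <- function(center, radius, dims) {
  stopifnot(length(center) == 3, length(dims) == 3, radius >= 0)
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  which(d2 <= radius^2)
}
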