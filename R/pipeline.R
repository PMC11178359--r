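# End-to-end pipeline driver: simulate (optional) -> GLM1 localizer ->
# orientation/consistency at all requested folds -> GLM3 distance ->
# RSA -> circular stats -> QC, with a reproducibility stamp.

#' Run the full grid-code analysis pipeline on one subject
#'
#' Executes, for one subject's runs: the quadrature-filter localizer
#' (GLM1) with F-to-Z conversion; the leave-one-run-out consistency
#' analysis at fold 6 and the control periodicities; the
#' distance-modulation GLM (GLM3) t statistic; the LSS-based RSA tests
#' (orientation-independent and orientation-dependent); voxel-wise
#' orientation clustering (V test) and tSNR QC. When \code{subject} is
#' NULL a subject is simulated from \code{config}.
#'
#' @param subject list with \code{runs} and \code{trials} (as from
#'   \code{\link{simulateSubject}}), or NULL to simulate.
#' @param config a \linkS4class{SimConfig} (used when simulating, and
#'   for the seed stamp).
#' @param roiVoxels ROI voxel indices (default: all voxels).
#' @param folds periodicities to test; fold 6 is the hypothesis, the
#'   rest controls.
#' @param runRsa run the (slower) LSS/RSA stage.
#' @param driftCutoff high-pass cutoff (s).
#' @param outDir optional directory: results are written as TSV/JSON
#'   with a config-hash + seed stamp in every sidecar.
#' @return list bundle: quadrature (per-voxel F/Z, run-mean), consistency
#'   (per fold), distanceT, rsa, orientationTests, tsnr, stamp.
#' @export
runPipeline <- function(subject = NULL, config = simConfig(),
                        roiVoxels = NULL, folds = c(4, 5, 6, 7, 8),
                        runRsa = TRUE, driftCutoff = 128,
                        outDir = NULL) {
  if (is.null(subject)) subject <- simulateSubject(config)
  runs <- subject$runs
  trials <- subject$trials
  nR <- length(runs)

  ## GLM1 localizer: per-run fits, Z averaged across runs per voxel
  glm1 <- lapply(seq_len(nR), function(r) {
    d <- buildGlm1Design(trials[[r]], fold = 6, nScans = nScans(runs[[r]]),
                         tr = repetitionTime(runs[[r]]),
                         driftCutoff = driftCutoff)
    fitOls(runs[[r]], d)
  })
  zPerRun <- vapply(glm1, function(f) quadratureFTest(f)$z,
                    numeric(nVoxels(runs[[1]])))
  quad <- list(zByVoxel = rowMeans(zPerRun), perRun = zPerRun)

  ## consistency at all folds
  consistency <- lapply(folds, function(f)
    looConsistency(runs, trials, roiVoxels, fold = f,
                   driftCutoff = driftCutoff))
  names(consistency) <- paste0("fold", folds)

  ## GLM3 distance modulation: per-run t of the distance modulator,
  ## averaged over runs and (ROI) voxels
  distT <- vapply(seq_len(nR), function(r) {
    d <- buildGlm3Design(trials[[r]], nScans = nScans(runs[[r]]),
                         tr = repetitionTime(runs[[r]]),
                         driftCutoff = driftCutoff)
    f <- fitOls(runs[[r]], d)
    X <- designData(d)
    XtXinv <- chol2inv(chol(crossprod(X)))
    j <- match("morph_distance", colnames(X))
    tv <- f@betas[, j] / sqrt(f@sigma2 * XtXinv[j, j])
    mean(if (is.null(roiVoxels)) tv else tv[roiVoxels])
  }, numeric(1))

  ## orientation distribution tests per estimating set
  orientationTests <- lapply(seq_len(nR), function(r) {
    est <- setdiff(seq_len(nR), r)
    vph <- voxelwiseOrientations(glm1[est], roiVoxels = roiVoxels)
    roiPhi <- orientation(estimateOrientation(glm1[est],
                                              roiVoxels = roiVoxels))
    orientationClusteringTest(vph, roiPhi)$clustering
  })

  rsa <- NULL
  if (runRsa) {
    pats <- do.call(bindPatterns, lapply(seq_len(nR), function(r)
      lssEstimates(runs[[r]], trials[[r]], driftCutoff = driftCutoff)))
    if (!is.null(roiVoxels))
      pats <- trialPatterns(patternMatrix(pats)[, roiVoxels, drop = FALSE],
                            patternMeta(pats))
    meta <- patternMeta(pats)
    indep <- rsaOrientationIndependent(neuralDsm(pats),
                                       modelDsm(meta$theta_deg, 6))
    phiByRun <- vapply(seq_len(nR), function(r)
      orientation(estimateOrientation(glm1[setdiff(seq_len(nR), r)],
                                      roiVoxels = roiVoxels)),
      numeric(1))
    names(phiByRun) <- as.character(seq_len(nR))
    dep <- rsaOrientationDependent(pats, phiByRun, fold = 6)
    rsa <- list(independent = indep, dependent = dep)
  }

  qcRes <- tsnr(runs, roiVoxels = roiVoxels)

  stamp <- list(seed = config@seed,
                configHash = substr(digestConfig(config), 1, 16),
                timepoint = "deterministic")
  bundle <- list(quadrature = quad, consistency = consistency,
                 distanceT = distT, rsa = rsa,
                 orientationTests = orientationTests, tsnr = qcRes,
                 stamp = stamp)
  if (!is.null(outDir)) .writeBundle(bundle, trials, outDir)
  bundle
}

## Stable hash of the configuration (serialize -> sum of bytes in a
## simple rolling hash); enough to detect config drift in sidecars.
digestConfig <- function(config) {
  raw <- serialize(list(config@tr, config@runs, config@trialsPerBlock,
                        config@voxels, config@morphDuration,
                        config@choiceDuration, config@itiRange,
                        config@dRange, config@hrfParams, config@arCoef,
                        config@seed),
                   connection = NULL, ascii = TRUE)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2^31
  sprintf("%08x%08x", h, length(raw) %% 2^31)
}

.writeBundle <- function(bundle, trials, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cons <- do.call(rbind, lapply(names(bundle$consistency), function(nm) {
    cr <- bundle$consistency[[nm]]
    data.frame(fold = cr@fold, contrast = subjectContrast(cr))
  }))
  utils::write.table(cons, file.path(outDir, "consistency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (r in seq_along(trials))
    writeEvents(trials[[r]],
                file.path(outDir, sprintf("events_run%d.tsv", r)))
  jsonlite::write_json(
    c(bundle$stamp,
      list(distanceT = bundle$distanceT,
           meanZ = mean(bundle$quadrature$zByVoxel))),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized fields mirror the \code{\link{simConfig}} arguments plus
#' \code{folds}, \code{driftCutoff} and \code{outDir}; unknown fields
#' are an error.
#'
#' @param path YAML (.yml/.yaml) or JSON config file.
#' @return list with \code{config} (a \linkS4class{SimConfig}) and the
#'   analysis switches.
#' @export
readPipelineConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("tr", "runs", "trialsPerBlock", "morphDuration",
             "choiceDuration", "itiRange", "dRange", "arCoef", "seed",
             "folds", "driftCutoff", "outDir")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfgArgs <- vals[intersect(names(vals), c(
    "tr", "runs", "trialsPerBlock", "morphDuration", "choiceDuration",
    "itiRange", "dRange", "arCoef", "seed"))]
  list(config = do.call(simConfig, cfgArgs),
       folds = if (is.null(vals$folds)) c(4, 5, 6, 7, 8)
               else unlist(vals$folds),
       driftCutoff = if (is.null(vals$driftCutoff)) 128
                     else vals$driftCutoff,
       outDir = vals$outDir)
}
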