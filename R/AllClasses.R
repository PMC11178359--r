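#' @import methods
NULL

# ---------------------------------------------------------------------------
# SocialSpace -----------------------------------------------------------------

#' SocialSpace: a 2D unit-square cognitive map with landmark avatars
#'
#' The abstract space navigated in the task: a unit square whose first axis
#' is competence and second axis is trustworthiness, both on [0, 1]. Six
#' avatar landmarks live at designated center coordinates; per-participant
#' layouts jitter each avatar uniformly within a disc of
#' \code{jitterRadius} around its center. \code{popoutRadius} is the
#' detection radius within which an avatar "pops out" during exploration.
#'
#' @slot avatarCenters numeric 6x2 matrix of (competence, trustworthiness)
#'   center coordinates, all inside the unit square.
#' @slot jitterRadius numeric(1), map units (default 1/30).
#' @slot popoutRadius numeric(1), map units (default 0.01), strictly
#'   positive.
#' @name SocialSpace-class
#' @aliases SocialSpace-class
#' @exportClass SocialSpace
setClass("SocialSpace",
  representation(avatarCenters = "matrix",
                 jitterRadius = "numeric",
                 popoutRadius = "numeric"),
  validity = function(object) {
    msg <- NULL
    ac <- object@avatarCenters
    if (!is.numeric(ac) || ncol(ac) != 2)
      msg <- c(msg, "avatarCenters must be a numeric n x 2 matrix")
    else if (any(ac < 0 | ac > 1))
      msg <- c(msg, "all avatar centers must lie inside the unit square")
    if (length(object@jitterRadius) != 1 || object@jitterRadius < 0)
      msg <- c(msg, "jitterRadius must be a single value >= 0")
    if (length(object@popoutRadius) != 1 || object@popoutRadius <= 0)
      msg <- c(msg, "popoutRadius must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SocialSpace
#'
#' @param avatarCenters n x 2 matrix of avatar center coordinates; defaults
#'   to a six-landmark layout spread widely over the unit square.
#' @param jitterRadius radius (map units) of the sampling disc around each
#'   center; default 1/30.
#' @param popoutRadius avatar detection radius; default 0.01.
#' @return A \linkS4class{SocialSpace}.
#' @examples
#' sp <- socialSpace()
#' avatarCenters(sp)
#' @export
socialSpace <- function(avatarCenters = defaultAvatarCenters(),
                        jitterRadius = 1 / 30,
                        popoutRadius = 0.01) {
  new("SocialSpace", avatarCenters = avatarCenters,
      jitterRadius = jitterRadius, popoutRadius = popoutRadius)
}

#' Default six-avatar center layout
#'
#' Six (competence, trustworthiness) centers distinguishable on both axes
#' and spread widely across the unit square.
#'
#' @return 6 x 2 numeric matrix.
#' @export
defaultAvatarCenters <- function() {
  m <- matrix(c(0.15, 0.80,
                0.30, 0.25,
                0.45, 0.60,
                0.60, 0.15,
                0.75, 0.85,
                0.90, 0.45), ncol = 2, byrow = TRUE)
  dimnames(m) <- list(paste0("avatar", seq_len(nrow(m))),
                      c("competence", "trustworthiness"))
  m
}

#' @describeIn socialSpace Accessor for the avatar center matrix.
#' @param object,x a SocialSpace.
#' @export
avatarCenters <- function(object) object@avatarCenters

#' @describeIn socialSpace Accessor for the jitter radius.
#' @export
jitterRadius <- function(object) object@jitterRadius

#' @describeIn socialSpace Accessor for the pop-out radius.
#' @export
popoutRadius <- function(object) object@popoutRadius

setMethod("show", "SocialSpace", function(object) {
  cat("SocialSpace: unit square [0,1]^2 (competence x trustworthiness)\n",
      nrow(object@avatarCenters), " avatars; jitterRadius=",
      format(object@jitterRadius, digits = 4),
      ", popoutRadius=", object@popoutRadius, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# SimConfig ------------------------------------------------------------------

#' SimConfig: parameters of the synthetic BOLD experiment
#'
#' Defines the simulated scanner task (runs of the trajectory-recall task)
#' and the voxel signal model. Voxel kinds: \code{"grid"} voxels respond to
#' the morph stage with amplitude \code{baseline + omega * cos(f*(theta -
#' phi))}; \code{"distance"} voxels with \code{baseline + slope * d};
#' \code{"noise"} voxels carry baseline only. All voxels receive a common
#' choice-stage response, HRF convolution and additive Gaussian noise.
#'
#' @slot tr repetition time, seconds (2.0 as in the emulated acquisition).
#' @slot runs number of runs (4).
#' @slot trialsPerBlock trials per run (80).
#' @slot voxels data.frame with columns \code{kind}, \code{omega},
#'   \code{phi} (degrees, in [0, 360/fold)), \code{fold}, \code{noiseSd},
#'   \code{baseline}, \code{distSlope}, \code{choiceAmp}.
#' @slot morphDuration,choiceDuration seconds.
#' @slot itiRange length-2 numeric, uniform jittered inter-trial interval.
#' @slot dRange length-2 numeric, range of traveled distances.
#' @slot hrfParams named numeric vector of double-gamma HRF parameters.
#' @slot arCoef AR(1) noise coefficient (0 = white noise).
#' @slot seed integer master seed.
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(tr = "numeric", runs = "integer", trialsPerBlock = "integer",
                 voxels = "data.frame", morphDuration = "numeric",
                 choiceDuration = "numeric", itiRange = "numeric",
                 dRange = "numeric", hrfParams = "numeric",
                 arCoef = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    v <- object@voxels
    need <- c("kind", "omega", "phi", "fold", "noiseSd", "baseline",
              "distSlope", "choiceAmp")
    if (!all(need %in% names(v)))
      msg <- c(msg, paste("voxels needs columns:", paste(need, collapse = ", ")))
    else {
      if (any(v$omega < 0)) msg <- c(msg, "omega must be >= 0")
      if (any(v$noiseSd <= 0)) msg <- c(msg, "noiseSd must be > 0")
      if (any(v$fold < 1)) msg <- c(msg, "fold must be >= 1")
      if (any(v$phi < 0 | v$phi >= 360 / v$fold))
        msg <- c(msg, "phi must lie in [0, 360/fold) degrees")
      if (!all(v$kind %in% c("grid", "distance", "noise")))
        msg <- c(msg, "voxel kind must be grid, distance or noise")
    }
    if (object@tr <= 0) msg <- c(msg, "tr must be > 0")
    if (object@runs < 1) msg <- c(msg, "runs must be >= 1")
    if (length(object@itiRange) != 2 || diff(object@itiRange) < 0)
      msg <- c(msg, "itiRange must be increasing length-2")
    if (length(object@dRange) != 2 || any(object@dRange <= 0))
      msg <- c(msg, "dRange must be positive length-2")
    if (abs(object@arCoef) >= 1) msg <- c(msg, "|arCoef| must be < 1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SimConfig
#'
#' Defaults reproduce the emulated study conditions: TR 2 s, 4 runs of 80
#' trials, morph stage 2 s (1 s watched + 1 s imagined), choice stage
#' 2.5 s, jittered ITI uniform on [2, 6] s, traveled distance uniform on
#' [0.15, 0.85] map units. The default voxel population holds 50 grid
#' voxels with \code{omega = 0.15}, unit noise SD — an effect size at
#' which the per-voxel quadrature Z statistic (averaged over the four
#' runs) is approximately 2 — plus
#' distance-coding and pure-noise voxels.
#'
#' @param tr repetition time (s).
#' @param runs number of runs.
#' @param trialsPerBlock trials per run.
#' @param voxels voxel specification data.frame (see
#'   \linkS4class{SimConfig}); built with \code{\link{voxelSpec}}.
#' @param morphDuration,choiceDuration stage durations (s).
#' @param itiRange jittered inter-trial interval range (s).
#' @param dRange traveled-distance range (map units).
#' @param hrfParams double-gamma HRF parameters (see
#'   \code{\link{canonicalHrf}}).
#' @param arCoef AR(1) coefficient of the noise process (0 = white).
#' @param seed integer master seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(tr = 2, runs = 4, trialsPerBlock = 80,
                      voxels = defaultVoxelSpec(),
                      morphDuration = 2, choiceDuration = 2.5,
                      itiRange = c(2, 6), dRange = c(0.15, 0.85),
                      hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                    c = 1 / 6),
                      arCoef = 0, seed = 1L) {
  new("SimConfig", tr = tr, runs = as.integer(runs),
      trialsPerBlock = as.integer(trialsPerBlock), voxels = voxels,
      morphDuration = morphDuration, choiceDuration = choiceDuration,
      itiRange = itiRange, dRange = dRange, hrfParams = hrfParams,
      arCoef = arCoef, seed = as.integer(seed))
}

#' Voxel specifications for the simulator
#'
#' @param n number of voxels.
#' @param kind "grid", "distance" or "noise".
#' @param omega hexadirectional modulation amplitude (grid voxels).
#' @param phi true grid orientation, degrees in [0, 360/fold).
#' @param fold angular periodicity (6 = hexadirectional).
#' @param noiseSd additive Gaussian noise SD.
#' @param baseline morph-stage baseline amplitude.
#' @param distSlope distance-coding slope (distance voxels).
#' @param choiceAmp choice-stage amplitude.
#' @return data.frame of n voxel rows.
#' @export
voxelSpec <- function(n, kind = "grid", omega = 0.15, phi = 20, fold = 6,
                      noiseSd = 1, baseline = 1, distSlope = 0,
                      choiceAmp = 0.5) {
  data.frame(kind = rep(kind, n), omega = omega, phi = phi, fold = fold,
             noiseSd = noiseSd, baseline = baseline, distSlope = distSlope,
             choiceAmp = choiceAmp, stringsAsFactors = FALSE)
}

#' @describeIn voxelSpec Default mixed population: 50 grid voxels
#'   (omega 0.15, phi 20 deg), 20 distance voxels (slope 1), 30 noise
#'   voxels.
#' @export
defaultVoxelSpec <- function() {
  rbind(voxelSpec(50, "grid", omega = 0.15, phi = 20),
        voxelSpec(20, "distance", omega = 0, distSlope = 1),
        voxelSpec(30, "noise", omega = 0))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@runs, " run(s) x ", object@trialsPerBlock,
      " trials, TR=", object@tr, "s\n", sep = "")
  cat("  voxels: ", nrow(object@voxels), " (",
      paste(sprintf("%s=%d", names(table(object@voxels$kind)),
                    as.integer(table(object@voxels$kind))), collapse = ", "),
      ")\n  seed: ", object@seed, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# BoldRun --------------------------------------------------------------------

#' BoldRun: a voxel-by-time BOLD data matrix for one run
#'
#' @slot data numeric voxel x scan matrix, no missing values.
#' @slot tr repetition time in seconds.
#' @slot runIndex integer run label.
#' @name BoldRun-class
#' @exportClass BoldRun
setClass("BoldRun",
  representation(data = "matrix", tr = "numeric", runIndex = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
    if (anyNA(object@data)) msg <- c(msg, "data must not contain NA")
    if (length(object@tr) != 1 || object@tr <= 0)
      msg <- c(msg, "tr must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BoldRun
#'
#' @param data voxel x scan numeric matrix.
#' @param tr repetition time (s).
#' @param runIndex run label.
#' @return A \linkS4class{BoldRun}.
#' @export
boldRun <- function(data, tr = 2, runIndex = 1L) {
  new("BoldRun", data = as.matrix(data), tr = tr,
      runIndex = as.integer(runIndex))
}

#' @describeIn boldRun Number of scans (time points).
#' @param object a BoldRun.
#' @export
nScans <- function(object) ncol(object@data)

#' @describeIn boldRun Number of voxels.
#' @export
nVoxels <- function(object) nrow(object@data)

#' @describeIn boldRun The voxel x scan data matrix.
#' @export
boldData <- function(object) object@data

#' @describeIn boldRun Repetition time in seconds.
#' @export
repetitionTime <- function(object) object@tr

#' @describeIn boldRun Run index.
#' @export
runIndex <- function(object) object@runIndex

setMethod("show", "BoldRun", function(object) {
  cat("BoldRun: ", nVoxels(object), " voxels x ", nScans(object),
      " scans (TR=", object@tr, "s, run ", object@runIndex, ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# DesignMatrix ---------------------------------------------------------------

#' DesignMatrix: a scan-by-regressor GLM design with column provenance
#'
#' @slot matrix numeric scan x regressor matrix.
#' @slot frameTimes scan acquisition times, seconds.
#' @slot provenance data.frame (one row per column) with \code{label},
#'   \code{stage}, \code{modulator}, \code{bin} and \code{degenerate}
#'   fields; degenerate columns (all-zero after centering, or empty bins)
#'   are excluded from fitting and contrasts.
#' @name DesignMatrix-class
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(matrix = "matrix", frameTimes = "numeric",
                 provenance = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@matrix) != nrow(object@provenance))
      msg <- c(msg, "provenance must have one row per design column")
    if (nrow(object@matrix) != length(object@frameTimes))
      msg <- c(msg, "frameTimes must match the number of rows")
    if (anyDuplicated(object@provenance$label))
      msg <- c(msg, "duplicate column labels")
    if (is.null(msg)) TRUE else msg
  })

designMatrix <- function(mat, frameTimes, provenance) {
  colnames(mat) <- provenance$label
  new("DesignMatrix", matrix = mat, frameTimes = frameTimes,
      provenance = provenance)
}

#' @describeIn buildGlm1Design The numeric design matrix of a
#'   DesignMatrix object.
#' @param design a DesignMatrix.
#' @export
designData <- function(design) design@matrix

#' @describeIn buildGlm1Design Column provenance table of a DesignMatrix.
#' @export
designProvenance <- function(design) design@provenance

#' @describeIn buildGlm1Design Labels of columns flagged degenerate.
#' @export
degenerateColumns <- function(design)
  design@provenance$label[design@provenance$degenerate]

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix: ", nrow(object@matrix), " scans x ",
      ncol(object@matrix), " regressors\n  columns: ",
      paste(object@provenance$label, collapse = ", "), "\n", sep = "")
  dg <- degenerateColumns(object)
  if (length(dg))
    cat("  degenerate: ", paste(dg, collapse = ", "), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# GlmFit ---------------------------------------------------------------------

#' GlmFit: mass-univariate OLS estimates for one run
#'
#' @slot betas voxel x regressor matrix (NA for degenerate columns).
#' @slot sigma2 per-voxel residual variance.
#' @slot df residual degrees of freedom.
#' @slot design the \linkS4class{DesignMatrix} that was fit.
#' @name GlmFit-class
#' @exportClass GlmFit
setClass("GlmFit",
  representation(betas = "matrix", sigma2 = "numeric", df = "numeric",
                 design = "DesignMatrix"),
  validity = function(object) {
    if (object@df <= 0) "residual degrees of freedom must be > 0" else TRUE
  })

#' @describeIn fitOls Voxel x regressor coefficient matrix.
#' @param fit a GlmFit.
#' @export
coefMatrix <- function(fit) fit@betas

#' @describeIn fitOls Per-voxel residual variance.
#' @export
residVariance <- function(fit) fit@sigma2

#' @describeIn fitOls Residual degrees of freedom.
#' @export
dfResidual <- function(fit) fit@df

setMethod("show", "GlmFit", function(object) {
  cat("GlmFit: ", nrow(object@betas), " voxels x ", ncol(object@betas),
      " regressors, df=", object@df, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# OrientationEstimate ---------------------------------------------------------

#' OrientationEstimate: a putative grid orientation for one ROI and fold
#'
#' The orientation phi is the phase of the f-fold directional modulation,
#' defined on the fundamental domain [0, 360/f) degrees, estimated from
#' ROI-averaged quadrature betas as \code{atan2(mean(bSin), mean(bCos))/f}.
#'
#' @slot phi orientation in degrees, in [0, 360/f).
#' @slot fold periodicity f.
#' @slot sourceRuns integer vector of estimating runs.
#' @slot roi character ROI label.
#' @slot voxelPhi optional per-voxel orientations (degrees).
#' @slot lowConfidence TRUE when both averaged betas are ~0 (direction
#'   undefined).
#' @name OrientationEstimate-class
#' @exportClass OrientationEstimate
setClass("OrientationEstimate",
  representation(phi = "numeric", fold = "numeric", sourceRuns = "integer",
                 roi = "character", voxelPhi = "numeric",
                 lowConfidence = "logical"),
  validity = function(object) {
    if (object@phi < 0 || object@phi >= 360 / object@fold)
      "phi must lie in [0, 360/fold) degrees"
    else TRUE
  })

#' @describeIn estimateOrientation Orientation in degrees.
#' @param object an OrientationEstimate.
#' @export
orientation <- function(object) object@phi

#' @describeIn estimateOrientation The fold (periodicity).
#' @export
orientationFold <- function(object) object@fold

setMethod("show", "OrientationEstimate", function(object) {
  cat(sprintf("OrientationEstimate: phi=%.2f deg (fold %d, domain [0,%g))%s\n",
              object@phi, as.integer(object@fold), 360 / object@fold,
              if (object@lowConfidence) " [low confidence]" else ""))
})

# ---------------------------------------------------------------------------
# ConsistencyResult -----------------------------------------------------------

#' ConsistencyResult: leave-one-run-out grid-orientation consistency
#'
#' Per held-out run: the orientation estimated from the remaining runs,
#' the ROI-mean betas of aligned and misaligned trial bins, and their
#' contrast (aligned - misaligned, weights renormalized over occupied
#' bins). The subject-level contrast is the mean across held-out runs.
#'
#' @slot perRun data.frame with columns run, phi, alignedMean,
#'   misalignedMean, contrast, nAlignedBins, nMisalignedBins.
#' @slot subjectContrast mean contrast over evaluated runs.
#' @slot fold periodicity.
#' @slot roi ROI label.
#' @name ConsistencyResult-class
#' @exportClass ConsistencyResult
setClass("ConsistencyResult",
  representation(perRun = "data.frame", subjectContrast = "numeric",
                 fold = "numeric", roi = "character"),
  validity = function(object) {
    ok <- object@perRun$contrast
    if (length(ok) && !isTRUE(all.equal(object@subjectContrast,
                                        mean(ok, na.rm = TRUE))))
      "subjectContrast must equal the mean of per-run contrasts"
    else TRUE
  })

#' @describeIn looConsistency Subject-level mean contrast.
#' @param object a ConsistencyResult.
#' @export
subjectContrast <- function(object) object@subjectContrast

#' @describeIn looConsistency Per-held-out-run results table.
#' @export
perRunContrasts <- function(object) object@perRun

setMethod("show", "ConsistencyResult", function(object) {
  cat(sprintf(
    "ConsistencyResult (fold %d%s): subject contrast %.4f over %d run(s)\n",
    as.integer(object@fold),
    if (nzchar(object@roi)) paste0(", ROI ", object@roi) else "",
    object@subjectContrast, nrow(object@perRun)))
})

# ---------------------------------------------------------------------------
# TrialPatterns ---------------------------------------------------------------

#' TrialPatterns: trial-by-voxel single-trial activity estimates
#'
#' Rows are least-squares-separate (LSS) beta estimates, one per trial, in
#' trial-table order; \code{meta} carries the run and trajectory direction
#' of each trial.
#'
#' @slot patterns numeric trial x voxel matrix.
#' @slot meta data.frame with columns run and theta_deg (one row per
#'   trial).
#' @name TrialPatterns-class
#' @exportClass TrialPatterns
setClass("TrialPatterns",
  representation(patterns = "matrix", meta = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@patterns) != nrow(object@meta))
      msg <- c(msg, "meta must have one row per trial")
    if (anyNA(object@patterns)) msg <- c(msg, "patterns must be finite")
    if (!all(c("run", "theta_deg") %in% names(object@meta)))
      msg <- c(msg, "meta needs run and theta_deg columns")
    if (is.null(msg)) TRUE else msg
  })

trialPatterns <- function(patterns, meta)
  new("TrialPatterns", patterns = as.matrix(patterns), meta = meta)

#' @describeIn lssEstimates Trial x voxel pattern matrix.
#' @param object a TrialPatterns.
#' @export
patternMatrix <- function(object) object@patterns

#' @describeIn lssEstimates Per-trial metadata (run, theta_deg).
#' @export
patternMeta <- function(object) object@meta

setMethod("show", "TrialPatterns", function(object) {
  cat("TrialPatterns: ", nrow(object@patterns), " trials x ",
      ncol(object@patterns), " voxels\n", sep = "")
})

#' Combine TrialPatterns across runs
#'
#' @param ... TrialPatterns objects.
#' @return A single TrialPatterns with rows stacked in argument order.
#' @export
bindPatterns <- function(...) {
  xs <- list(...)
  trialPatterns(do.call(rbind, lapply(xs, patternMatrix)),
                do.call(rbind, lapply(xs, patternMeta)))
}
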