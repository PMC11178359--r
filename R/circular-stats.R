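# Circular statistics for grid orientations. Orientations live on
# [0, 360/f) degrees; the fold transform psi = f * phi maps them onto the
# full circle where standard circular tests apply.

#' Fold transform of orientations
#'
#' \code{psi = (fold * phi) mod 360} degrees: maps f-fold orientations
#' from their fundamental domain onto the full circle.
#'
#' @param phi orientations, degrees.
#' @param fold periodicity f (>= 1).
#' @return transformed angles, degrees in [0, 360).
#' @export
foldTransform <- function(phi, fold = 6) {
  if (fold < 1) stopf("fold must be >= 1")
  (fold * phi) %% 360
}

#' Circular mean direction and resultant length
#'
#' @param psi angles in degrees.
#' @return list with \code{mean} (degrees in [0, 360)) and \code{R}
#'   (mean resultant length in [0, 1]).
#' @export
circMean <- function(psi) {
  if (!length(psi)) stopf("empty angle sample")
  rad <- deg2rad(psi)
  C <- mean(cos(rad)); S <- mean(sin(rad))
  list(mean = rad2deg(atan2(S, C)) %% 360, R = sqrt(C^2 + S^2))
}

## Monte-Carlo null p-value for a circular statistic: fraction of
## uniform samples with statistic >= observed.
.mcCircP <- function(stat, n, statFun, nsim, seed) {
  withSeed(seed, {
    null <- replicate(nsim, statFun(stats::runif(n, 0, 360)))
    (1 + sum(null >= stat)) / (nsim + 1)
  })
}

#' V test for clustering around a hypothesized mean direction
#'
#' Tests uniformity against the alternative of clustering at a known
#' mean direction mu0: \code{V = n * R * cos(meanDir - mu0)}, with the
#' large-sample p-value \code{1 - pnorm(V * sqrt(2/n))}. For small
#' samples (\code{n < mcBelow}) the p-value is instead computed by
#' Monte-Carlo simulation of the null (uniform angles), which is exact up
#' to simulation error.
#'
#' @param psi angles in degrees (n >= 2).
#' @param mu0 hypothesized mean direction, degrees. In the grid-code
#'   application this is the fold-transformed ROI-mean orientation from
#'   the same estimating set.
#' @param mcBelow sample-size threshold under which the Monte-Carlo
#'   p-value is used (default 10).
#' @param nsim Monte-Carlo simulations.
#' @param mcSeed seed of the (self-contained) Monte-Carlo draw.
#' @return list with V, u (standardized statistic), p, n, method.
#' @export
vTest <- function(psi, mu0, mcBelow = 10, nsim = 100000L,
                  mcSeed = 104729L) {
  n <- length(psi)
  if (n < 2) stopf("V test needs at least 2 angles")
  vStat <- function(x) {
    cm <- circMean(x)
    length(x) * cm$R * cos(deg2rad(cm$mean - mu0))
  }
  V <- vStat(psi)
  u <- V * sqrt(2 / n)
  if (n < mcBelow) {
    p <- .mcCircP(V, n, vStat, nsim, mcSeed)
    method <- "monte-carlo"
  } else {
    p <- 1 - stats::pnorm(u)
    method <- "large-sample"
  }
  list(V = V, u = u, p = p, n = n, method = method)
}

#' Rayleigh test of circular uniformity
#'
#' \code{Z = n * R^2} with the standard small-sample-corrected p-value
#' approximation; for \code{n < mcBelow} a Monte-Carlo null p-value is
#' used instead.
#'
#' @param psi angles in degrees (n >= 2).
#' @param mcBelow threshold for the Monte-Carlo fallback (default 10).
#' @param nsim Monte-Carlo simulations.
#' @param mcSeed Monte-Carlo seed.
#' @return list with R (mean resultant length), Z, p, n, method.
#' @export
rayleighTest <- function(psi, mcBelow = 10, nsim = 100000L,
                         mcSeed = 104729L) {
  n <- length(psi)
  if (n < 2) stopf("Rayleigh test needs at least 2 angles")
  R <- circMean(psi)$R
  Z <- n * R^2
  if (n < mcBelow) {
    p <- .mcCircP(R, n, function(x) circMean(x)$R, nsim, mcSeed)
    method <- "monte-carlo"
  } else {
    p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                      (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                        (288 * n^2))
    p <- min(max(p, 0), 1)
    method <- "large-sample"
  }
  list(R = R, Z = Z, p = p, n = n, method = method)
}

#' Orientation-distribution tests for an ROI
#'
#' Convenience wrapper reproducing the two standard checks on grid
#' orientations: (1) within a participant, are voxel-wise orientations
#' clustered around the ROI-mean orientation (V test on fold-transformed
#' angles, mu0 = fold-transformed ROI orientation)? (2) across
#' participants, are ROI orientations uniformly distributed (Rayleigh
#' test)?
#'
#' @param voxelPhi per-voxel orientations, degrees in [0, 360/fold).
#' @param roiPhi the ROI-average orientation (degrees), used as mu0.
#' @param fold periodicity.
#' @return list with the V-test result (\code{clustering}) and the
#'   fold-transformed angles.
#' @export
orientationClusteringTest <- function(voxelPhi, roiPhi, fold = 6) {
  psi <- foldTransform(voxelPhi, fold)
  mu0 <- foldTransform(roiPhi, fold)
  list(clustering = vTest(psi, mu0), psi = psi, mu0 = mu0)
}
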