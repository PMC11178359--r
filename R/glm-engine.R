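# Mass-univariate GLM machinery: design construction (GLM1/GLM2/GLM3),
# OLS fitting, and the quadrature F test with F -> Z conversion.

.frameTimes <- function(nScans, tr) (seq_len(nScans) - 1L) * tr

## Assemble a DesignMatrix from task columns + drift + intercept.
.assembleDesign <- function(cols, provenance, nScans, tr, driftCutoff) {
  drift <- dctBasis(nScans, tr, driftCutoff)
  if (ncol(drift)) {
    cols <- cbind(cols, drift)
    provenance <- rbind(provenance,
      data.frame(label = colnames(drift), stage = "drift",
                 modulator = NA_character_, bin = NA_integer_,
                 degenerate = FALSE))
  }
  cols <- cbind(cols, intercept = rep(1, nScans))
  provenance <- rbind(provenance,
    data.frame(label = "intercept", stage = "intercept",
               modulator = NA_character_, bin = NA_integer_,
               degenerate = FALSE))
  designMatrix(cols, .frameTimes(nScans, tr), provenance)
}

.prov <- function(label, stage, modulator = NA_character_,
                  bin = NA_integer_, degenerate = FALSE)
  data.frame(label = label, stage = stage, modulator = modulator,
             bin = bin, degenerate = degenerate)

#' Build the quadrature-filter localizer design (GLM1)
#'
#' Columns: morph-stage main effect; morph x sin(f*theta) and
#' morph x cos(f*theta) parametric modulators (mean-centered across
#' trials before convolution, not serially orthogonalized); choice-stage
#' main effect; discrete-cosine drift; intercept. A joint F test on the
#' two modulators detects f-fold directional modulation regardless of the
#' grid orientation, since \code{omega*cos(f*(theta-phi)) =
#' omega*cos(f*phi)*cos(f*theta) + omega*sin(f*phi)*sin(f*theta)}.
#'
#' @param trials trial table for one run.
#' @param fold periodicity f (>= 1); default 6.
#' @param nScans scans in the run.
#' @param tr repetition time (s).
#' @param driftCutoff high-pass cutoff (s), default 128.
#' @param hrfParams HRF parameters.
#' @return A \linkS4class{DesignMatrix}. If all directions are equal the
#'   modulator columns are zero after centering and flagged degenerate.
#' @export
buildGlm1Design <- function(trials, fold = 6, nScans, tr = 2,
                            driftCutoff = 128,
                            hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                          c = 1 / 6)) {
  if (fold < 1) stopf("fold must be >= 1")
  validateTrialTable(trials)
  morph <- morphEvents(trials)
  choice <- choiceEvents(trials)
  s <- sin(fold * deg2rad(morph$theta_deg))
  c6 <- cos(fold * deg2rad(morph$theta_deg))
  sC <- s - mean(s)
  cC <- c6 - mean(c6)
  degenerate <- c(FALSE,
                  isTRUE(all.equal(max(abs(sC)), 0)),
                  isTRUE(all.equal(max(abs(cC)), 0)),
                  FALSE)
  mk <- function(amp, ev) makeRegressor(ev$onset, ev$duration, amp,
                                        nScans, tr, hrfParams)
  cols <- cbind(morph = mk(rep(1, nrow(morph)), morph),
                morph_sin = mk(sC, morph),
                morph_cos = mk(cC, morph),
                choice = mk(rep(1, nrow(choice)), choice))
  prov <- rbind(
    .prov("morph", "morph"),
    .prov("morph_sin", "morph", sprintf("sin(%d*theta)", fold),
          degenerate = degenerate[2]),
    .prov("morph_cos", "morph", sprintf("cos(%d*theta)", fold),
          degenerate = degenerate[3]),
    .prov("choice", "choice"))
  .assembleDesign(cols, prov, nScans, tr, driftCutoff)
}

#' Build the alignment-bin consistency design (GLM2)
#'
#' Trials are partitioned by the offset of their direction from the
#' putative grid orientation into 2f bins of width 360/(2f) degrees
#' (12 bins of 30 degrees for f = 6), each bin getting one morph-stage
#' regressor; bins whose center is 0 modulo 360/f degrees are the aligned
#' bins, the others misaligned. Empty bins yield all-zero columns flagged
#' degenerate (excluded from fitting; contrast weights renormalize over
#' occupied bins). Plus choice, drift and intercept columns.
#'
#' @param trials trial table for one run.
#' @param phi putative grid orientation (degrees in [0, 360/f)) or an
#'   \linkS4class{OrientationEstimate}.
#' @param fold periodicity f.
#' @inheritParams buildGlm1Design
#' @return A \linkS4class{DesignMatrix} whose bin columns carry their bin
#'   index (1..2f) and an \code{aligned} attribute in the provenance
#'   \code{modulator} field ("aligned"/"misaligned").
#' @export
buildGlm2Design <- function(trials, phi, fold = 6, nScans, tr = 2,
                            driftCutoff = 128,
                            hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                          c = 1 / 6)) {
  if (is(phi, "OrientationEstimate")) {
    fold <- orientationFold(phi)
    phi <- orientation(phi)
  }
  validateTrialTable(trials)
  morph <- morphEvents(trials)
  choice <- choiceEvents(trials)
  cls <- classifyAlignment(morph$theta_deg, phi, fold)
  nBins <- 2L * fold
  mk <- function(ev, amp) makeRegressor(ev$onset, ev$duration, amp,
                                        nScans, tr, hrfParams)
  cols <- matrix(0, nrow = nScans, ncol = nBins)
  prov <- NULL
  for (b in seq_len(nBins)) {
    sel <- cls$bin == b
    if (any(sel))
      cols[, b] <- mk(morph[sel, , drop = FALSE], rep(1, sum(sel)))
    aligned <- ((b - 1L) * (360 / nBins)) %% (360 / fold) == 0
    prov <- rbind(prov, .prov(sprintf("bin%02d", b), "morph",
                              if (aligned) "aligned" else "misaligned",
                              bin = b, degenerate = !any(sel)))
  }
  cols <- cbind(cols, choice = mk(choice, rep(1, nrow(choice))))
  prov <- rbind(prov, .prov("choice", "choice"))
  .assembleDesign(cols, prov, nScans, tr, driftCutoff)
}

#' Build the distance-modulation design (GLM3)
#'
#' Columns: morph main effect; morph x traveled-distance parametric
#' modulator (mean-centered before convolution); choice; drift;
#' intercept.
#'
#' @param trials trial table for one run.
#' @inheritParams buildGlm1Design
#' @return A \linkS4class{DesignMatrix}.
#' @export
buildGlm3Design <- function(trials, nScans, tr = 2, driftCutoff = 128,
                            hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                          c = 1 / 6)) {
  validateTrialTable(trials)
  morph <- morphEvents(trials)
  choice <- choiceEvents(trials)
  dC <- morph$distance - mean(morph$distance)
  if (isTRUE(all.equal(max(abs(dC)), 0)))
    stopf("all traveled distances are equal; distance modulator degenerate")
  mk <- function(amp, ev) makeRegressor(ev$onset, ev$duration, amp,
                                        nScans, tr, hrfParams)
  cols <- cbind(morph = mk(rep(1, nrow(morph)), morph),
                morph_distance = mk(dC, morph),
                choice = mk(rep(1, nrow(choice)), choice))
  prov <- rbind(.prov("morph", "morph"),
                .prov("morph_distance", "morph", "distance"),
                .prov("choice", "choice"))
  .assembleDesign(cols, prov, nScans, tr, driftCutoff)
}

#' Fit a design to a BOLD run by ordinary least squares
#'
#' Degenerate (flagged) columns are dropped before fitting and their
#' betas returned as NA. A rank-deficient design among the retained
#' columns is an error naming the collinear columns.
#'
#' @param run a \linkS4class{BoldRun} (or voxel x scan matrix).
#' @param design a \linkS4class{DesignMatrix} with rows matching the
#'   run's scans.
#' @return A \linkS4class{GlmFit}.
#' @export
fitOls <- function(run, design) {
  Y <- if (is(run, "BoldRun")) t(boldData(run)) else t(as.matrix(run))
  X <- designData(design)
  if (nrow(X) != nrow(Y))
    stopf("design has %d rows but run has %d scans", nrow(X), nrow(Y))
  keep <- !design@provenance$degenerate
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qrX$pivot[(qrX$rank + 1):ncol(Xk)]]
    stopf("design is rank-deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  df <- nrow(Xk) - ncol(Xk)
  if (df <= 0) stopf("no residual degrees of freedom")
  beta <- qr.coef(qrX, Y)
  res <- Y - Xk %*% beta
  sigma2 <- colSums(res^2) / df
  full <- matrix(NA_real_, nrow = ncol(Y), ncol = ncol(X),
                 dimnames = list(NULL, colnames(X)))
  full[, keep] <- t(beta)
  new("GlmFit", betas = full, sigma2 = as.numeric(sigma2), df = df,
      design = design)
}

#' Extract quadrature (sin/cos) betas from a GLM1 fit
#'
#' @param fit a \linkS4class{GlmFit} of a GLM1 design.
#' @return list with per-voxel \code{bSin}, \code{bCos} and the
#'   \code{fold} read off the design provenance.
#' @export
quadratureBetas <- function(fit) {
  prov <- fit@design@provenance
  si <- which(prov$label == "morph_sin")
  ci <- which(prov$label == "morph_cos")
  if (!length(si) || !length(ci))
    stopf("fit does not contain quadrature modulator columns")
  fold <- as.numeric(sub(".*\\((\\d+)\\*theta\\)", "\\1",
                         prov$modulator[si]))
  list(bSin = fit@betas[, si], bCos = fit@betas[, ci], fold = fold)
}

#' Joint F test of the quadrature modulators, with F to Z conversion
#'
#' Tests, per voxel, the null that both the sin and cos modulator betas
#' are zero (equivalently that the modulation amplitude omega is zero):
#' F with (2, df) degrees of freedom. F statistics are mapped to
#' Z statistics through the normal quantile of the F cumulative
#' probability, \code{Z = qnorm(pf(F, 2, df))}, with the probability
#' clipped away from 0 and 1 so Z stays finite.
#'
#' @param fit a \linkS4class{GlmFit} of a GLM1 design.
#' @param zClip clip bound: probabilities outside
#'   \code{[pnorm(-zClip), pnorm(zClip)]} are clipped (default 8.2,
#'   i.e. |Z| <= 8.2).
#' @return data.frame with per-voxel \code{F}, \code{z} and the test df.
#' @export
quadratureFTest <- function(fit, zClip = 8.2) {
  qb <- quadratureBetas(fit)
  if (anyNA(qb$bSin) || anyNA(qb$bCos))
    stopf("quadrature modulator columns were degenerate in this fit")
  prov <- fit@design@provenance
  keep <- !prov$degenerate
  X <- designData(fit@design)[, keep, drop = FALSE]
  XtXinv <- chol2inv(chol(crossprod(X)))
  idx <- match(c("morph_sin", "morph_cos"), colnames(X))
  M <- XtXinv[idx, idx]
  Minv <- solve(M)
  B <- cbind(qb$bSin, qb$bCos)
  quad <- rowSums((B %*% Minv) * B)
  Fv <- quad / (2 * fit@sigma2)
  p <- stats::pf(Fv, 2, fit@df)
  lim <- stats::pnorm(zClip)
  p <- pmin(pmax(p, 1 - lim), lim)
  data.frame(F = Fv, z = stats::qnorm(p), df1 = 2, df2 = fit@df)
}
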