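#' Canonical double-gamma hemodynamic response function
#'
#' \code{h(t) = g(t; a1, b1) - c * g(t; a2, b2)} with gamma densities
#' \code{g}, normalized to unit peak. Defaults (a1=6, b1=1, a2=16, b2=1,
#' c=1/6) give the standard response peaking ~5 s after the event with a
#' late undershoot.
#'
#' @param t time in seconds (vector).
#' @param params named numeric vector with entries a1, b1, a2, b2, c.
#' @return HRF values at \code{t}.
#' @examples
#' tt <- seq(0, 30, 0.1)
#' tt[which.max(canonicalHrf(tt))]  # ~5 s
#' @export
canonicalHrf <- function(t, params = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                       c = 1 / 6)) {
  h <- stats::dgamma(t, shape = params[["a1"]], rate = params[["b1"]]) -
    params[["c"]] *
      stats::dgamma(t, shape = params[["a2"]], rate = params[["b2"]])
  h[t < 0] <- 0
  peak <- stats::dgamma((params[["a1"]] - 1) / params[["b1"]],
                        shape = params[["a1"]], rate = params[["b1"]]) -
    params[["c"]] * stats::dgamma((params[["a1"]] - 1) / params[["b1"]],
                                  shape = params[["a2"]],
                                  rate = params[["b2"]])
  h / peak
}

## Internal time resolution (s) for boxcar construction / convolution.
.microDt <- 0.1

#' Build a convolved boxcar regressor
#'
#' Events are boxcars of the stated duration scaled by their amplitudes,
#' convolved with the HRF on a fine time grid and sampled at the scan
#' acquisition times \code{(0:(nScans-1)) * tr}.
#'
#' @param onsets event onsets (s).
#' @param durations event durations (s), recycled.
#' @param amplitudes event amplitudes, recycled (boxcar heights).
#' @param nScans number of scans in the run.
#' @param tr repetition time (s).
#' @param hrfParams HRF parameters passed to \code{\link{canonicalHrf}}.
#' @return numeric vector of length \code{nScans}.
#' @export
makeRegressor <- function(onsets, durations, amplitudes, nScans, tr,
                          hrfParams = c(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                        c = 1 / 6)) {
  if (any(durations <= 0)) stopf("durations must be > 0")
  runEnd <- nScans * tr
  if (any(onsets < 0) || any(onsets >= runEnd))
    stopf("event onset beyond run end (run covers [0, %g) s)", runEnd)
  k <- max(length(onsets), length(durations), length(amplitudes))
  onsets <- rep_len(onsets, k)
  durations <- rep_len(durations, k)
  amplitudes <- rep_len(amplitudes, k)
  dt <- .microDt
  n <- ceiling(runEnd / dt) + 1L
  x <- numeric(n)
  for (i in seq_len(k)) {
    i0 <- floor(onsets[i] / dt) + 1L
    i1 <- min(n, ceiling((onsets[i] + durations[i]) / dt))
    x[i0:i1] <- x[i0:i1] + amplitudes[i]  # overlapping events sum
  }
  hker <- canonicalHrf(seq(0, 32, by = dt), hrfParams)
  conv <- stats::convolve(x, rev(hker), type = "open")[seq_len(n)] * dt
  scanIdx <- round(((seq_len(nScans) - 1L) * tr) / dt) + 1L
  conv[scanIdx]
}

#' Discrete-cosine drift basis
#'
#' High-pass drift regressors: DCT components with period longer than
#' \code{cutoff} seconds (the standard 128 s default), unit-normalized,
#' excluding the constant.
#'
#' @param nScans number of scans.
#' @param tr repetition time (s).
#' @param cutoff high-pass cutoff period (s); \code{Inf} gives no drift
#'   columns.
#' @return nScans x K matrix (K may be 0).
#' @export
dctBasis <- function(nScans, tr, cutoff = 128) {
  K <- if (!is.finite(cutoff)) 0L else
    max(0L, as.integer(floor(2 * nScans * tr / cutoff)))
  if (K == 0L)
    return(matrix(numeric(0), nrow = nScans, ncol = 0))
  s <- seq_len(nScans) - 1L
  B <- vapply(seq_len(K), function(k)
    cos(pi * k * (2 * s + 1) / (2 * nScans)), numeric(nScans))
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  colnames(B) <- paste0("drift", seq_len(K))
  B
}
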