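## Angles are degrees at every user-facing interface; radians are used
## internally for trigonometry.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Absolute angular difference folded into [0, 180] degrees.
angDiff180 <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards. All generators in the
## package route their randomness through this so that they are pure
## functions of (arguments, seed).
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Required columns of a trial event table (BIDS-events-like layout:
## onset and duration lead).
.trialTableColumns <- c("onset", "duration", "trial_type", "run",
                        "theta_deg", "distance", "on_avatar")

#' Validate a trial event table
#'
#' A trial table is a plain \code{data.frame} with one row per event and
#' columns \code{onset}, \code{duration}, \code{trial_type} (\code{"morph"}
#' or \code{"choice"}), \code{run}, \code{theta_deg} (trajectory direction,
#' degrees in [0, 360)), \code{distance} (traveled Euclidean distance in
#' map units) and \code{on_avatar} (logical). Within each run, onsets must
#' be strictly increasing within a trial type and every morph event must
#' precede its choice event.
#'
#' @param trials data.frame of trial events.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   problem.
#' @export
validateTrialTable <- function(trials) {
  if (!is.data.frame(trials))
    stopf("trial table must be a data.frame")
  missing <- setdiff(.trialTableColumns, names(trials))
  if (length(missing))
    stopf("trial table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  if (any(!is.finite(trials$onset)) || any(!is.finite(trials$duration)))
    stopf("trial table onsets/durations must be finite")
  th <- trials$theta_deg
  if (any(th < 0 | th >= 360))
    stopf("theta_deg must lie in [0, 360)")
  for (r in unique(trials$run)) {
    for (tt in unique(trials$trial_type)) {
      o <- trials$onset[trials$run == r & trials$trial_type == tt]
      if (is.unsorted(o, strictly = TRUE))
        stopf("onsets not strictly increasing in run %s (%s events)", r, tt)
    }
    morph <- trials[trials$run == r & trials$trial_type == "morph", ]
    choice <- trials[trials$run == r & trials$trial_type == "choice", ]
    if (nrow(morph) == nrow(choice) && nrow(morph) > 0 &&
        any(morph$onset >= choice$onset))
      stopf("every morph event must precede its choice event (run %s)", r)
  }
  invisible(trials)
}

## Rows of a trial table that are morph events, ordered by onset.
morphEvents <- function(trials, run = NULL) {
  x <- trials[trials$trial_type == "morph", , drop = FALSE]
  if (!is.null(run)) x <- x[x$run == run, , drop = FALSE]
  x[order(x$onset), , drop = FALSE]
}

choiceEvents <- function(trials, run = NULL) {
  x <- trials[trials$trial_type == "choice", , drop = FALSE]
  if (!is.null(run)) x <- x[x$run == run, , drop = FALSE]
  x[order(x$onset), , drop = FALSE]
}
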