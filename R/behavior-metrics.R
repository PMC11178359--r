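# Behavioral map-formation indices: explore-task occupancy, collect-task
# precision, compare-task distance effects, recall accuracy.

#' Explore-task occupancy map
#'
#' Divides the unit square into a \code{gridSize} x \code{gridSize}
#' lattice of subregions (15 x 15 by default) and computes the fraction
#' of explore time spent in each. Cells are half-open with the top/right
#' edges closed at 1.0, so every sample falls in exactly one cell. The
#' edge fraction sums the outermost rows and columns. When
#' \code{avatars} are supplied, the time-at-avatars fraction is the
#' fraction of samples within \code{popoutRadius} of an avatar (the
#' pop-out / on-screen rule); alternatively an \code{at_avatar} logical
#' column in \code{samples} is used directly.
#'
#' @param samples data.frame with columns x, y in [0, 1] (and optionally
#'   at_avatar).
#' @param space a \linkS4class{SocialSpace} (supplies popoutRadius).
#' @param avatars optional avatar layout data.frame.
#' @param gridSize lattice size per axis (default 15).
#' @return list with \code{grid} (gridSize x gridSize fraction matrix,
#'   fractions summing to 1), \code{edgeFraction} and
#'   \code{avatarFraction} (NA when not computable).
#' @export
occupancyMap <- function(samples, space = socialSpace(), avatars = NULL,
                         gridSize = 15) {
  x <- samples$x; y <- samples$y
  if (any(x < 0 | x > 1 | y < 0 | y > 1))
    stopf("explore samples must lie in the unit square")
  cx <- pmin(floor(x * gridSize), gridSize - 1) + 1
  cy <- pmin(floor(y * gridSize), gridSize - 1) + 1
  grid <- matrix(0, gridSize, gridSize)
  for (i in seq_along(cx))
    grid[cx[i], cy[i]] <- grid[cx[i], cy[i]] + 1
  grid <- grid / length(cx)
  edge <- matrix(FALSE, gridSize, gridSize)
  edge[c(1, gridSize), ] <- TRUE
  edge[, c(1, gridSize)] <- TRUE
  avFrac <- NA_real_
  if (!is.null(samples$at_avatar))
    avFrac <- mean(samples$at_avatar)
  else if (!is.null(avatars)) {
    r <- popoutRadius(space)
    d2min <- rep(Inf, length(x))
    for (k in seq_len(nrow(avatars)))
      d2min <- pmin(d2min, (x - avatars$competence[k])^2 +
                      (y - avatars$trustworthiness[k])^2)
    avFrac <- mean(d2min <= r^2)
  }
  list(grid = grid, edgeFraction = sum(grid[edge]),
       avatarFraction = avFrac)
}

#' Collect-task precision metrics
#'
#' Per trial: the deviation of the first transition from the ideal
#' trajectory (absolute angular difference, in [0, 180] degrees, between
#' the first-transition direction and the direction from start to
#' target) and the Euclidean distance from the endpoint response to the
#' target. Summaries use the strict thresholds of the task: fraction of
#' trials with deviation < 15 degrees and with distance < 0.01 map
#' units, plus the mean transition count.
#'
#' @param trials data.frame with columns start_x, start_y,
#'   first_dir_deg, resp_x, resp_y, target_x, target_y and optionally
#'   n_transitions.
#' @return list with \code{perTrial} (deviation_deg, distance) and
#'   \code{summary} (pctDeviationUnder15, pctDistanceUnder001,
#'   meanTransitions).
#' @export
collectMetrics <- function(trials) {
  need <- c("start_x", "start_y", "first_dir_deg", "resp_x", "resp_y",
            "target_x", "target_y")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stopf("collect table missing column(s): %s",
          paste(missing, collapse = ", "))
  ideal <- rad2deg(atan2(trials$target_y - trials$start_y,
                         trials$target_x - trials$start_x)) %% 360
  dev <- angDiff180(trials$first_dir_deg, ideal)
  dist <- sqrt((trials$resp_x - trials$target_x)^2 +
                 (trials$resp_y - trials$target_y)^2)
  list(perTrial = data.frame(deviation_deg = dev, distance = dist),
       summary = list(
         pctDeviationUnder15 = mean(dev < 15),
         pctDistanceUnder001 = mean(dist < 0.01),
         meanTransitions = if (is.null(trials$n_transitions)) NA_real_
                           else mean(trials$n_transitions)))
}

#' Compare-task distance-effect indices
#'
#' Per-participant regression slopes of log response time and accuracy
#' on the task-relevant distance between the compared avatars (the
#' distance on the compared axis, or the expected-profit difference in
#' the cooperation block — the \code{distance} column is expected to
#' already follow the block rule, as produced by
#' \code{\link{simulateBehavior}} / \code{\link{compareTaskDistance}}).
#' A map-like representation predicts a negative log-RT slope and a
#' positive accuracy slope. The slopes are the exported covariate
#' indices.
#'
#' @param trials data.frame with columns block, distance, accuracy and
#'   rt (or log_rt).
#' @param block optional block label to subset (e.g. "cooperation").
#' @return list with rtSlope, accSlope, n, and the fitted models'
#'   summaries as \code{rtFit}, \code{accFit}.
#' @export
compareDistanceEffect <- function(trials, block = NULL) {
  if (!is.null(block)) trials <- trials[trials$block == block, ]
  if (!nrow(trials)) stopf("no trials in the requested block")
  d <- trials$distance
  if (length(unique(d)) < 2) stopf("constant task-relevant distance")
  logRt <- if (!is.null(trials$log_rt)) trials$log_rt else log(trials$rt)
  rtFit <- stats::lm(logRt ~ d)
  accFit <- stats::lm(trials$accuracy ~ d)
  list(rtSlope = unname(stats::coef(rtFit)[2]),
       accSlope = unname(stats::coef(accFit)[2]),
       n = nrow(trials), rtFit = rtFit, accFit = accFit)
}

#' Recall-task accuracy
#'
#' Fraction of correct responses, overall and (when a \code{session}
#' column is present) per session. Sessions below the 60% exclusion
#' threshold are flagged.
#'
#' @param responses data.frame with a logical/0-1 \code{correct} column
#'   and optionally \code{session}.
#' @param threshold exclusion threshold (default 0.6).
#' @return list with accuracy, bySession (or NULL), belowThreshold.
#' @export
recallAccuracy <- function(responses, threshold = 0.6) {
  if (is.null(responses$correct)) stopf("responses need a 'correct' column")
  acc <- mean(as.numeric(responses$correct))
  bySession <- NULL
  if (!is.null(responses$session)) {
    s <- tapply(as.numeric(responses$correct), responses$session, mean)
    bySession <- stats::setNames(as.numeric(s), names(s))
  }
  list(accuracy = acc, bySession = bySession,
       belowThreshold = acc < threshold)
}
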