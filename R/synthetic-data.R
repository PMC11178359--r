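# Synthetic task, BOLD and behavior generators. These emulate the
# trajectory-recall experiment on a 2D social value map so the analysis
# pipeline can be validated against known ground truth.

#' Expected profit in the investment game
#'
#' The investor's expected profit from an agent is
#' \code{investment * (1 + competence) * trustworthiness}: competence is
#' the profit rate (how much the agent multiplies the stake) and
#' trustworthiness the return rate (share of earnings returned).
#'
#' @param investment invested points (>= 0).
#' @param competence profit rate in [0, 1].
#' @param trustworthiness return rate in [0, 1].
#' @return Expected profit in points.
#' @examples
#' expectedProfit(1000, 0.5, 0.5)  # 750
#' @export
expectedProfit <- function(investment, competence, trustworthiness) {
  if (any(investment < 0)) stopf("investment must be >= 0")
  if (any(competence < 0 | competence > 1))
    stopf("competence must lie in [0, 1]")
  if (any(trustworthiness < 0 | trustworthiness > 1))
    stopf("trustworthiness must lie in [0, 1]")
  investment * (1 + competence) * trustworthiness
}

#' Hexadirectional (f-fold) response amplitude
#'
#' \code{omega * cos(f * (theta - phi))}: the directional modulation of
#' population activity expected from conjunctive grid x head-direction
#' coding, generalized to fold f.
#'
#' @param theta trajectory direction, degrees.
#' @param phi grid orientation, degrees.
#' @param omega amplitude (>= 0).
#' @param fold periodicity f (>= 1); 6 for the hexadirectional case.
#' @return Modulation amplitude.
#' @examples
#' hexadirectionalResponse(20, 20, 1, 6)       # 1 (aligned peak)
#' hexadirectionalResponse(50, 20, 1, 6)       # -1 (misaligned trough)
#' @export
hexadirectionalResponse <- function(theta, phi, omega, fold = 6) {
  stopifnot(fold >= 1, all(omega >= 0))
  omega * cos(fold * deg2rad(theta - phi))
}

#' Sample a per-participant avatar layout
#'
#' Each avatar is placed uniformly within a disc of the space's
#' \code{jitterRadius} around its center coordinate (positions clipped to
#' the unit square when \code{clip = TRUE}).
#'
#' @param space a \linkS4class{SocialSpace}.
#' @param seed integer seed (layouts are reproducible).
#' @param clip clip sampled positions to the unit square; if FALSE, a
#'   center closer than \code{jitterRadius} to the boundary is an error.
#' @return data.frame with columns competence, trustworthiness.
#' @export
sampleAvatarLayout <- function(space, seed = 1L, clip = TRUE) {
  centers <- avatarCenters(space)
  r <- jitterRadius(space)
  if (!clip) {
    near <- pmin(centers, 1 - centers) < r
    if (any(near))
      stopf("avatar center(s) within jitterRadius of the boundary: %s",
            paste(which(rowSums(near) > 0), collapse = ", "))
  }
  withSeed(seed, {
    n <- nrow(centers)
    rho <- r * sqrt(stats::runif(n))   # uniform over the disc
    ang <- stats::runif(n, 0, 2 * pi)
    pos <- centers + cbind(rho * cos(ang), rho * sin(ang))
    if (clip) pos <- pmin(pmax(pos, 0), 1)
    data.frame(competence = pos[, 1], trustworthiness = pos[, 2],
               row.names = rownames(centers))
  })
}

#' Sample one block (run) of the trajectory recall task
#'
#' Directions are sampled uniformly, one per equal-width bin of
#' [0, 360) degrees (\code{nTrials} bins), so the block covers every bin
#' exactly once. Half of the trials are constructed to terminate exactly
#' on an avatar location (the start is back-computed as
#' \code{end - d * (cos theta, sin theta)}); the other half terminate at
#' locations not associated with any avatar. Traveled distance is drawn
#' uniformly from \code{dRange}, resampled (up to \code{maxRetry} times)
#' when no start inside the unit square is feasible. Morph and choice
#' stages are scheduled with a jittered inter-trial interval.
#'
#' @param space a \linkS4class{SocialSpace}.
#' @param avatars avatar layout data.frame from
#'   \code{\link{sampleAvatarLayout}}.
#' @param nTrials trials in the block (default 80).
#' @param seed integer seed.
#' @param run run index recorded in the table.
#' @param dRange traveled-distance range (map units).
#' @param morphDuration,choiceDuration stage durations (s).
#' @param itiRange uniform jittered inter-trial interval (s).
#' @param startTime onset of the first trial (s).
#' @param maxRetry resampling budget per trial before erroring.
#' @return A trial table (see \code{\link{validateTrialTable}}) with two
#'   rows (morph, choice) per trial plus endpoint columns end_x, end_y.
#' @export
sampleRecallBlock <- function(space, avatars, nTrials = 80, seed = 1L,
                              run = 1L, dRange = c(0.15, 0.85),
                              morphDuration = 2, choiceDuration = 2.5,
                              itiRange = c(2, 6), startTime = 10,
                              maxRetry = 200L) {
  stopifnot(nTrials >= 2, nTrials %% 2 == 0)
  withSeed(seed, {
    binW <- 360 / nTrials
    theta <- (seq_len(nTrials) - 1) * binW + stats::runif(nTrials, 0, binW)
    theta <- sample(theta)                      # random trial order
    onAvatar <- sample(rep(c(TRUE, FALSE), nTrials / 2))
    d <- numeric(nTrials)
    endX <- endY <- numeric(nTrials)
    nav <- nrow(avatars)
    ## admissible distance interval so that start = end - d*u stays in
    ## the unit square (per-axis linear constraints intersected with
    ## dRange)
    feasibleD <- function(ex, ey, ux, uy) {
      lo <- dRange[1]; hi <- dRange[2]
      for (k in 1:2) {
        e <- if (k == 1) ex else ey
        u <- if (k == 1) ux else uy
        if (abs(u) > 1e-12) {
          b <- sort(c((e - 1) / u, e / u))
          lo <- max(lo, b[1]); hi <- min(hi, b[2])
        }
      }
      c(lo, hi)
    }
    for (i in seq_len(nTrials)) {
      ux <- cos(deg2rad(theta[i])); uy <- sin(deg2rad(theta[i]))
      if (onAvatar[i]) {
        ## pick uniformly among avatars admitting some distance in range
        cand <- sample.int(nav)
        ok <- FALSE
        for (a in cand) {
          ex <- avatars$competence[a]; ey <- avatars$trustworthiness[a]
          f <- feasibleD(ex, ey, ux, uy)
          if (f[2] > f[1]) {
            d[i] <- stats::runif(1, f[1], f[2])
            endX[i] <- ex; endY[i] <- ey
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stopf(paste("no avatar reachable with a trajectory of direction",
                      "%.1f deg and distance in [%g, %g]"),
                theta[i], dRange[1], dRange[2])
      } else {
        ok <- FALSE
        for (try in seq_len(maxRetry)) {
          di <- stats::runif(1, dRange[1], dRange[2])
          dx <- di * ux; dy <- di * uy
          sLo <- c(max(0, -dx), max(0, -dy))
          sHi <- c(min(1, 1 - dx), min(1, 1 - dy))
          if (all(sHi > sLo)) {
            sx <- stats::runif(1, sLo[1], sHi[1])
            sy <- stats::runif(1, sLo[2], sHi[2])
            d[i] <- di; endX[i] <- sx + dx; endY[i] <- sy + dy
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stopf("no feasible start for trial %d (theta=%.1f deg) after %d draws",
                i, theta[i], maxRetry)
      }
    }
    iti <- stats::runif(nTrials, itiRange[1], itiRange[2])
    morphOn <- numeric(nTrials)
    t0 <- startTime
    for (i in seq_len(nTrials)) {
      morphOn[i] <- t0
      t0 <- t0 + morphDuration + choiceDuration + iti[i]
    }
    choiceOn <- morphOn + morphDuration
    tab <- rbind(
      data.frame(onset = morphOn, duration = morphDuration,
                 trial_type = "morph", run = as.integer(run),
                 theta_deg = theta, distance = d, on_avatar = onAvatar,
                 end_x = endX, end_y = endY),
      data.frame(onset = choiceOn, duration = choiceDuration,
                 trial_type = "choice", run = as.integer(run),
                 theta_deg = theta, distance = d, on_avatar = onAvatar,
                 end_x = endX, end_y = endY))
    tab <- tab[order(tab$onset), ]
    rownames(tab) <- NULL
    validateTrialTable(tab)
    tab
  })
}

#' Simulate one BOLD run from a trial table
#'
#' Each voxel's neural event train is built from the trial table: during
#' the morph stage, grid voxels respond with amplitude \code{baseline +
#' omega * cos(fold * (theta - phi))}, distance voxels with
#' \code{baseline + distSlope * d}, noise voxels with baseline only; the
#' choice stage adds a response of amplitude \code{choiceAmp}. The train
#' is convolved with the canonical HRF, sampled at the repetition time,
#' and Gaussian noise of per-voxel SD is added (AR(1) when
#' \code{arCoef != 0}).
#'
#' @param trials a trial table for one run.
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer seed for the noise.
#' @param nScansOut number of scans; defaults to covering the last event
#'   plus 16 s.
#' @return A \linkS4class{BoldRun}.
#' @export
simulateRun <- function(trials, config, seed = config@seed,
                        nScansOut = NULL) {
  validateTrialTable(trials)
  tr <- config@tr
  lastEnd <- max(trials$onset + trials$duration)
  if (is.null(nScansOut))
    nScansOut <- ceiling((lastEnd + 16) / tr)
  nScansOut <- as.integer(nScansOut)
  if (nScansOut <= 0) stopf("nScans must be positive")
  if (nScansOut * tr < lastEnd)
    stopf("trial schedule (%.1f s) exceeds the run duration (%.1f s)",
          lastEnd, nScansOut * tr)
  morph <- morphEvents(trials)
  choice <- choiceEvents(trials)
  vox <- config@voxels
  nv <- nrow(vox)

  ## group voxels sharing the same morph amplitude profile to avoid
  ## redundant convolutions
  ampFor <- function(i) {
    base <- rep(vox$baseline[i], nrow(morph))
    if (vox$kind[i] == "grid")
      base + hexadirectionalResponse(morph$theta_deg, vox$phi[i],
                                     vox$omega[i], vox$fold[i])
    else if (vox$kind[i] == "distance")
      base + vox$distSlope[i] * morph$distance
    else base
  }
  key <- paste(vox$kind, vox$omega, vox$phi, vox$fold, vox$baseline,
               vox$distSlope, vox$choiceAmp)
  groups <- split(seq_len(nv), key)
  choiceRegUnit <- makeRegressor(choice$onset, choice$duration,
                                 rep(1, nrow(choice)), nScansOut, tr,
                                 config@hrfParams)
  clean <- matrix(0, nrow = nv, ncol = nScansOut)
  for (g in groups) {
    i <- g[1]
    sig <- makeRegressor(morph$onset, morph$duration, ampFor(i),
                         nScansOut, tr, config@hrfParams) +
      vox$choiceAmp[i] * choiceRegUnit
    clean[g, ] <- matrix(sig, nrow = length(g), ncol = nScansOut,
                         byrow = TRUE)
  }
  noise <- withSeed(seed, {
    eps <- matrix(stats::rnorm(nv * nScansOut), nv, nScansOut)
    if (config@arCoef != 0) {
      a <- config@arCoef
      for (tcol in 2:nScansOut)
        eps[, tcol] <- a * eps[, tcol - 1] + sqrt(1 - a^2) * eps[, tcol]
    }
    eps * vox$noiseSd
  })
  boldRun(clean + noise, tr = tr, runIndex = unique(trials$run)[1])
}

#' Simulate a whole scanning session for one subject
#'
#' Generates \code{runs} blocks of the recall task and the matching BOLD
#' runs under one \linkS4class{SimConfig}. Per-run seeds are derived
#' deterministically from \code{seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param space a \linkS4class{SocialSpace}.
#' @param seed master seed (defaults to the config seed).
#' @return list with elements \code{trials} (list of per-run trial
#'   tables), \code{runs} (list of \linkS4class{BoldRun}s), \code{avatars}
#'   and \code{config}.
#' @export
simulateSubject <- function(config = simConfig(), space = socialSpace(),
                            seed = config@seed) {
  avatars <- sampleAvatarLayout(space, seed = seed + 1000L)
  trials <- vector("list", config@runs)
  runs <- vector("list", config@runs)
  for (r in seq_len(config@runs)) {
    trials[[r]] <- sampleRecallBlock(
      space, avatars, nTrials = config@trialsPerBlock,
      seed = seed + 2000L + r, run = r, dRange = config@dRange,
      morphDuration = config@morphDuration,
      choiceDuration = config@choiceDuration, itiRange = config@itiRange)
    runs[[r]] <- simulateRun(trials[[r]], config, seed = seed + 3000L + r)
  }
  list(trials = trials, runs = runs, avatars = avatars, config = config)
}

#' Simulate behavioral task tables
#'
#' Generates the four behavioral tables the map-formation indices are
#' computed from: \code{explore} (location samples drawn from a mixture
#' concentrated at avatars versus uniform over the map), \code{collect}
#' (first-transition directions and endpoint responses with angular and
#' positional noise), \code{compare} (accuracy and response time as
#' functions of the task-relevant distance: log RT = intercept - slope *
#' distance + noise; accuracy logistic in distance), and \code{recall}
#' (correct/incorrect choices with a set accuracy).
#'
#' @param avatars avatar layout data.frame.
#' @param seed integer seed.
#' @param nExplore number of explore location samples.
#' @param avatarWeight mixture weight on the avatar-concentrated
#'   component, in [0, 1].
#' @param avatarSd SD of the Gaussian around each avatar (map units).
#' @param nCollect collect trials.
#' @param collectAngSd angular noise SD (degrees) of the first
#'   transition.
#' @param collectPosSd positional noise SD of the endpoint response.
#' @param rtIntercept,rtSlope,rtNoiseSd log-RT model parameters
#'   (\code{rtNoiseSd > 0}).
#' @param accIntercept,accSlope logistic accuracy model parameters.
#' @param investment stake used for the cooperation-block expected-profit
#'   distance.
#' @param nRepeats repetitions of each avatar pair per compare block.
#' @param recallAcc probability of a correct recall response.
#' @param nRecall recall trials.
#' @return list of data.frames: explore, collect, compare, recall.
#' @export
simulateBehavior <- function(avatars, seed = 1L, nExplore = 2000,
                             avatarWeight = 0.3, avatarSd = 0.03,
                             nCollect = 30, collectAngSd = 8,
                             collectPosSd = 0.005,
                             rtIntercept = 0.2, rtSlope = 0.5,
                             rtNoiseSd = 0.1,
                             accIntercept = 0.5, accSlope = 4,
                             investment = 1, nRepeats = 4,
                             recallAcc = 0.85, nRecall = 80) {
  if (rtNoiseSd <= 0) stopf("rtNoiseSd must be > 0")
  if (avatarWeight < 0 || avatarWeight > 1)
    stopf("avatarWeight must lie in [0, 1]")
  nav <- nrow(avatars)
  withSeed(seed, {
    ## explore: mixture of avatar-concentrated and uniform samples
    atAvatar <- stats::runif(nExplore) < avatarWeight
    idx <- sample.int(nav, nExplore, replace = TRUE)
    x <- ifelse(atAvatar,
                avatars$competence[idx] + stats::rnorm(nExplore, 0, avatarSd),
                stats::runif(nExplore))
    y <- ifelse(atAvatar,
                avatars$trustworthiness[idx] +
                  stats::rnorm(nExplore, 0, avatarSd),
                stats::runif(nExplore))
    explore <- data.frame(x = pmin(pmax(x, 0), 1),
                          y = pmin(pmax(y, 0), 1),
                          at_avatar = atAvatar)

    ## collect: noisy first transitions toward each target avatar
    tgt <- rep_len(seq_len(nav), nCollect)
    sx <- stats::runif(nCollect); sy <- stats::runif(nCollect)
    ideal <- rad2deg(atan2(avatars$trustworthiness[tgt] - sy,
                           avatars$competence[tgt] - sx)) %% 360
    firstDir <- (ideal + stats::rnorm(nCollect, 0, collectAngSd)) %% 360
    rx <- avatars$competence[tgt] + stats::rnorm(nCollect, 0, collectPosSd)
    ry <- avatars$trustworthiness[tgt] +
      stats::rnorm(nCollect, 0, collectPosSd)
    collect <- data.frame(target = tgt, start_x = sx, start_y = sy,
                          first_dir_deg = firstDir,
                          resp_x = rx, resp_y = ry,
                          target_x = avatars$competence[tgt],
                          target_y = avatars$trustworthiness[tgt],
                          n_transitions = 1 + stats::rpois(nCollect, 0.6))

    ## compare: all avatar pairs x blocks x repeats
    pairs <- utils::combn(nav, 2)
    blocks <- c("competence", "trustworthiness", "cooperation")
    compare <- do.call(rbind, lapply(blocks, function(b) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        dist <- compareTaskDistance(avatars[i, ], avatars[j, ], b,
                                    investment = investment)
        data.frame(block = b, avatar_i = i, avatar_j = j,
                   distance = dist,
                   rep = seq_len(nRepeats))
      }))
    }))
    compare$log_rt <- rtIntercept - rtSlope * compare$distance +
      stats::rnorm(nrow(compare), 0, rtNoiseSd)
    compare$rt <- exp(compare$log_rt)
    pAcc <- stats::plogis(accIntercept + accSlope * compare$distance)
    compare$accuracy <- as.integer(stats::runif(nrow(compare)) < pAcc)

    recall <- data.frame(trial = seq_len(nRecall),
                         correct = as.integer(stats::runif(nRecall) <
                                                recallAcc))
    list(explore = explore, collect = collect, compare = compare,
         recall = recall)
  })
}

#' Task-relevant distance between two avatars in the compare task
#'
#' For the competence and trustworthiness blocks, the distance on the
#' compared axis; for the cooperation block, the absolute difference in
#' expected profit (\code{\link{expectedProfit}}) at the given investment.
#'
#' @param a,b single-row avatar data.frames (competence,
#'   trustworthiness).
#' @param block "competence", "trustworthiness" or "cooperation".
#' @param investment stake for the cooperation block (default 1).
#' @return Nonnegative task-relevant distance.
#' @export
compareTaskDistance <- function(a, b, block, investment = 1) {
  switch(block,
    competence = abs(a$competence - b$competence),
    trustworthiness = abs(a$trustworthiness - b$trustworthiness),
    cooperation = abs(
      expectedProfit(investment, a$competence, a$trustworthiness) -
        expectedProfit(investment, b$competence, b$trustworthiness)),
    stopf("unknown compare block '%s'", block))
}
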