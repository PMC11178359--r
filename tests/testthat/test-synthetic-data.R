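test_that("expected profit follows the investment-game formula", {
  expect_equal(expectedProfit(1000, 0.5, 0.5), 750)
  expect_equal(expectedProfit(1000, 1.0, 0.0), 0)
  expect_equal(expectedProfit(1000, 1.0, 1.0), 2000)
  expect_error(expectedProfit(-1, 0.5, 0.5), "investment")
  expect_error(expectedProfit(10, 1.5, 0.5), "competence")
  expect_error(expectedProfit(10, 0.5, -0.1), "trustworthiness")
})

test_that("avatar layouts are jittered within the disc and reproducible", {
  sp <- socialSpace()
  a1 <- sampleAvatarLayout(sp, seed = 3)
  a2 <- sampleAvatarLayout(sp, seed = 3)
  expect_identical(a1, a2)
  d <- sqrt(rowSums((as.matrix(a1) - avatarCenters(sp))^2))
  expect_true(all(d <= 1 / 30 + 1e-12))
  expect_true(all(as.matrix(a1) >= 0 & as.matrix(a1) <= 1))
  ## degenerate disc puts avatars exactly at centers
  sp0 <- socialSpace(jitterRadius = 0)
  a0 <- sampleAvatarLayout(sp0, seed = 1)
  expect_equal(unname(as.matrix(a0)), unname(avatarCenters(sp0)))
})

test_that("recall blocks cover every direction bin once and split on-avatar half/half", {
  sp <- socialSpace()
  av <- sampleAvatarLayout(sp, seed = 1)
  for (n in c(4L, 80L)) {
    tab <- sampleRecallBlock(sp, av, nTrials = n, seed = 11)
    morph <- tab[tab$trial_type == "morph", ]
    expect_equal(nrow(morph), n)
    bins <- floor(morph$theta_deg / (360 / n))
    expect_setequal(bins, 0:(n - 1))          # one direction per bin
    expect_equal(sum(morph$on_avatar), n / 2) # half terminate on avatars
  }
  tab <- sampleRecallBlock(sp, av, nTrials = 80, seed = 11)
  expect_identical(tab, sampleRecallBlock(sp, av, nTrials = 80, seed = 11))
  validateTrialTable(tab)
  ## trajectory geometry: end = start + d*(cos, sin) stays in the square
  morph <- tab[tab$trial_type == "morph", ]
  sx <- morph$end_x - morph$distance * cos(morph$theta_deg * pi / 180)
  sy <- morph$end_y - morph$distance * sin(morph$theta_deg * pi / 180)
  expect_true(all(sx >= -1e-9 & sx <= 1 + 1e-9))
  expect_true(all(sy >= -1e-9 & sy <= 1 + 1e-9))
  ## on-avatar endpoints coincide with avatar locations
  onAv <- morph[morph$on_avatar, ]
  hit <- mapply(function(x, y)
    min((av$competence - x)^2 + (av$trustworthiness - y)^2), onAv$end_x,
    onAv$end_y)
  expect_true(all(hit < 1e-18))
})

test_that("hexadirectional response matches the cosine model", {
  expect_equal(hexadirectionalResponse(20, 20, 1, 6), 1)
  expect_equal(hexadirectionalResponse(50, 20, 1, 6), -1)
  expect_equal(hexadirectionalResponse(35, 20, 1, 6), 0, tolerance = 1e-12)
  ## fold generalization: 4-fold trough at 45 deg offset
  expect_equal(hexadirectionalResponse(45, 0, 1, 4), -1)
})

test_that("simulated runs are deterministic and morph amplitudes follow the signal model", {
  cfg <- tinyConfig(nGrid = 3, omega = 0.4, noiseSd = EPS_SD, trials = 12,
                    runs = 1)
  sp <- socialSpace()
  av <- sampleAvatarLayout(sp, seed = 2)
  tab <- sampleRecallBlock(sp, av, nTrials = 12, seed = 5)
  r1 <- simulateRun(tab, cfg, seed = 99)
  r2 <- simulateRun(tab, cfg, seed = 99)
  expect_identical(boldData(r1), boldData(r2))
  ## with noise ~ 0 the data equal the convolved closed-form amplitudes
  morph <- tab[tab$trial_type == "morph", ]
  choice <- tab[tab$trial_type == "choice", ]
  amp <- 1 + hexadirectionalResponse(morph$theta_deg, 20, 0.4, 6)
  expected <- makeRegressor(morph$onset, morph$duration, amp,
                            nScans(r1), 2) +
    0.5 * makeRegressor(choice$onset, choice$duration,
                        rep(1, nrow(choice)), nScans(r1), 2)
  expect_equal(boldData(r1)[1, ], expected, tolerance = 1e-6)
})

test_that("behavioral generator recovers its own parameters", {
  av <- sampleAvatarLayout(socialSpace(), seed = 4)
  ## near-noiseless compare table returns the generating log-RT slope
  beh <- simulateBehavior(av, seed = 8, rtSlope = 0.5, rtNoiseSd = 1e-9,
                          nRepeats = 8)
  eff <- compareDistanceEffect(beh$compare, block = "cooperation")
  expect_equal(eff$rtSlope, -0.5, tolerance = 1e-6)
  ## zero slope recovers ~0
  beh0 <- simulateBehavior(av, seed = 9, rtSlope = 0, rtNoiseSd = 0.05,
                           nRepeats = 8)
  eff0 <- compareDistanceEffect(beh0$compare, block = "competence")
  expect_lt(abs(eff0$rtSlope), 0.2)
  ## degenerate mixture puts all explore time at avatars
  beh1 <- simulateBehavior(av, seed = 10, avatarWeight = 1)
  occ <- occupancyMap(beh1$explore, socialSpace(), avatars = av)
  expect_equal(occ$avatarFraction, 1)
  expect_error(simulateBehavior(av, rtNoiseSd = 0), "rtNoiseSd")
})

test_that("cooperation-block distance uses the expected-profit difference", {
  a <- data.frame(competence = 0.8, trustworthiness = 0.5)
  b <- data.frame(competence = 0.4, trustworthiness = 0.5)
  expect_equal(compareTaskDistance(a, b, "cooperation", investment = 1),
               abs(1.8 * 0.5 - 1.4 * 0.5))
  expect_equal(compareTaskDistance(a, b, "competence"), 0.4)
  expect_error(compareTaskDistance(a, b, "nope"), "unknown")
})
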