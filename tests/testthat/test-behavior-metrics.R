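test_that("occupancy fractions sum to one and classify edges correctly", {
  ## all samples in one interior cell
  s <- data.frame(x = rep(0.5, 100), y = rep(0.5, 100))
  occ <- occupancyMap(s)
  expect_equal(sum(occ$grid), 1, tolerance = 1e-9)
  expect_equal(max(occ$grid), 1)
  expect_equal(occ$edgeFraction, 0)
  ## corner samples are all edge
  s2 <- data.frame(x = c(0.01, 0.99, 0.01, 0.99),
                   y = c(0.01, 0.01, 0.99, 0.99))
  expect_equal(occupancyMap(s2)$edgeFraction, 1)
  ## uniform samples approach the 56/225 edge-cell share of a 15x15 grid
  set.seed(14)
  s3 <- data.frame(x = runif(40000), y = runif(40000))
  occ3 <- occupancyMap(s3)
  expect_equal(sum(occ3$grid), 1, tolerance = 1e-9)
  expect_equal(occ3$edgeFraction, 56 / 225, tolerance = 0.02)
  ## boundary coordinate 1.0 falls in the last (closed-edge) cell
  occB <- occupancyMap(data.frame(x = 1, y = 1))
  expect_equal(occB$grid[15, 15], 1)
  expect_error(occupancyMap(data.frame(x = 1.2, y = 0)), "unit square")
})

test_that("collect metrics use strict thresholds and symmetric deviations", {
  tr <- data.frame(start_x = 0, start_y = 0, first_dir_deg = 45,
                   resp_x = 0.5, resp_y = 0.5, target_x = 0.5,
                   target_y = 0.5, n_transitions = 1)
  m <- collectMetrics(tr)
  expect_equal(m$perTrial$deviation_deg, 0)
  expect_equal(m$perTrial$distance, 0)
  expect_equal(m$summary$pctDeviationUnder15, 1)
  expect_equal(m$summary$pctDistanceUnder001, 1)
  ## deviation of exactly 15 degrees is NOT counted (strict <)
  tr15 <- tr; tr15$first_dir_deg <- 60
  expect_equal(collectMetrics(tr15)$perTrial$deviation_deg, 15)
  expect_equal(collectMetrics(tr15)$summary$pctDeviationUnder15, 0)
  ## clockwise and counterclockwise errors are symmetric
  trCw <- tr; trCw$first_dir_deg <- 45 - 20
  trCcw <- tr; trCcw$first_dir_deg <- 45 + 20
  expect_equal(collectMetrics(trCw)$perTrial$deviation_deg,
               collectMetrics(trCcw)$perTrial$deviation_deg)
  expect_error(collectMetrics(tr[, -1]), "missing column")
})

test_that("distance-effect slopes are recovered without bias", {
  av <- sampleAvatarLayout(socialSpace(), seed = 6)
  slopes <- replicate(20, {
    sd <- sample(1:1e6, 1)
    beh <- simulateBehavior(av, seed = sd, rtSlope = 0.4, rtNoiseSd = 0.1,
                            nRepeats = 4)
    compareDistanceEffect(beh$compare, block = "trustworthiness")$rtSlope
  })
  expect_equal(mean(slopes), -0.4, tolerance = 0.05)
  expect_error(compareDistanceEffect(
    data.frame(block = "a", distance = 1, accuracy = 1, rt = 1)),
    "constant")
})

test_that("recall accuracy is a plain proportion with the 60% exclusion flag", {
  expect_equal(recallAccuracy(data.frame(correct = rep(1, 10)))$accuracy, 1)
  expect_equal(recallAccuracy(data.frame(correct = rep(0, 10)))$accuracy, 0)
  r <- recallAccuracy(data.frame(correct = c(rep(1, 48), rep(0, 32))))
  expect_equal(r$accuracy, 0.6)
  expect_false(r$belowThreshold)  # threshold is strict <60%
  bySess <- recallAccuracy(data.frame(correct = c(1, 1, 0, 0),
                                      session = c("a", "a", "b", "b")))
  expect_equal(unname(bySess$bySession), c(1, 0))
})
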