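# Independent brute-force oracle: Monte-Carlo null distribution of a
# circular statistic under uniformity, written here from scratch (plain
# loops, its own seed), never calling the package's internals.
bruteForceCircP <- function(angles, statFun, nsim = 200000L, seed = 2468L) {
  obs <- statFun(angles)
  set.seed(seed)
  hits <- 0L
  n <- length(angles)
  for (i in seq_len(nsim)) {
    x <- runif(n, 0, 360)
    if (statFun(x) >= obs) hits <- hits + 1L
  }
  (1 + hits) / (nsim + 1)
}

## Raw V statistic toward a hypothesized direction (degrees in, degrees
## mu0), computed from first principles.
rawV <- function(mu0) function(x) {
  r <- x * pi / 180
  C <- mean(cos(r)); S <- mean(sin(r))
  length(x) * sqrt(C^2 + S^2) *
    cos(atan2(S, C) - mu0 * pi / 180)
}

## Raw mean resultant length.
rawR <- function(x) {
  r <- x * pi / 180
  sqrt(mean(cos(r))^2 + mean(sin(r))^2)
}
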