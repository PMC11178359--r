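# Shared fixtures: small simulated sessions used across test files.
# Everything is generated in code under fixed seeds.

tinySpace <- function() socialSpace()

## A reduced session for fast unit tests: fewer trials/voxels/runs than
## the emulated study, same structure.
tinyConfig <- function(nGrid = 10, omega = 0.15, phi = 20, fold = 6,
                       runs = 2, trials = 20, noiseSd = 1, seed = 7L,
                       extra = NULL) {
  vox <- voxelSpec(nGrid, "grid", omega = omega, phi = phi, fold = fold,
                   noiseSd = noiseSd)
  if (!is.null(extra)) vox <- rbind(vox, extra)
  simConfig(runs = runs, trialsPerBlock = trials, voxels = vox,
            seed = seed)
}

tinySubject <- function(...) simulateSubject(tinyConfig(...))

## GLM1 fits for every run of a subject.
fitGlm1All <- function(sub, fold = 6) {
  lapply(seq_along(sub$runs), function(r) {
    d <- buildGlm1Design(sub$trials[[r]], fold = fold,
                         nScans = nScans(sub$runs[[r]]),
                         tr = repetitionTime(sub$runs[[r]]))
    fitOls(sub$runs[[r]], d)
  })
}

## Noiseless-in-practice simulation: noise SD must be > 0, so use an SD
## far below the signal scale.
EPS_SD <- 1e-8
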