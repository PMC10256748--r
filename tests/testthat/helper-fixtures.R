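# Small in-code fixtures shared across tests. Everything is generated at
# test time; sizes are kept tiny (16x16, a handful of cases) so the whole
# suite stays fast.

tinySpecs <- function(nCases = 6L, shape = c(16L, 16L), shift = FALSE,
                      noise = 0.1) {
  list(
    taskSpec("tinyA", nCases, shape, intensityFg = c(0.75, 0.03),
             intensityBg = c(0.25, 0.03), noiseSigma = noise,
             roiFraction = 0.12),
    if (shift)
      taskSpec("tinyB", nCases, shape, intensityFg = c(0.25, 0.03),
               intensityBg = c(0.75, 0.03), noiseSigma = noise,
               roiFraction = 0.12)
    else
      taskSpec("tinyB", nCases, shape, intensityFg = c(0.75, 0.03),
               intensityBg = c(0.25, 0.03), noiseSigma = noise,
               roiFraction = 0.12))
}

tinyTasks <- function(nCases = 6L, shape = c(16L, 16L), shift = FALSE,
                      seed = 7L, noise = 0.1) {
  generateSequence(tinySpecs(nCases, shape, shift, noise), seed = seed)
}

tinyConfig <- function(method = "sequential", epochs = 2L, steps = 5L,
                       batch = 2L, lr = 0.05, seed = 3L, ...) {
  trainConfig(method, epochs = epochs, stepsPerEpoch = steps,
              batchSize = batch, learningRate = lr, seed = seed, ...)
}

# flat parameter view of body + all heads, for bitwise comparisons
modelParams <- function(model) {
  c(model@body, unlist(lapply(model@heads, identity), recursive = FALSE))
}
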