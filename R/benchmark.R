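# The packaged two-task forgetting/recovery benchmark: the standard
# behavioural experiment the documentation and the reproduction script
# run. Conditions: the high-shift preset pair (64 x 64, 30 cases/task,
# contrast inversion between tasks), 200 optimization steps per stage
# (10 epochs x 20 steps, batch 2, lr 0.05), repeated over run seeds.

#' Run the standard two-task forgetting benchmark
#'
#' Trains the high-shift task pair sequentially under each requested
#' strategy and reports, per run seed and method: task 1 test Dice right
#' after stage 1, task 1 test Dice after stage 2 (its drop is the amount
#' of forgetting), and the final-task Dice (its deficit versus sequential
#' training is plasticity loss). The EWC run uses a deliberately rigid
#' penalty weight (`ewcLambda = 40`) to expose the plasticity cost of
#' strong anchoring.
#'
#' @param seeds integer run seeds; results are reported per seed.
#' @param methods subset of `c("sequential", "rehearsal", "ewc")`.
#' @param dataSeed seed of the task-pair generation (the data is shared by
#'   all runs).
#' @param nCases,imageShape generator conditions.
#' @param epochs,stepsPerEpoch,batchSize,learningRate training budget.
#' @param rehearsalFraction buffer fraction for the rehearsal arm.
#' @param ewcLambda anchoring weight for the EWC arm.
#' @return data frame with one row per (seed, method).
#' @export
forgettingBenchmark <- function(seeds = 1:3,
                                methods = c("sequential", "rehearsal", "ewc"),
                                dataSeed = 1L, nCases = 30L,
                                imageShape = c(64L, 64L), epochs = 10L,
                                stepsPerEpoch = 20L, batchSize = 2L,
                                learningRate = 0.05,
                                rehearsalFraction = 0.25, ewcLambda = 40) {
  specs <- taskPreset("highshift_pair", nCases = nCases,
                      imageShape = imageShape)
  tasks <- generateSequence(specs, seed = dataSeed)
  rows <- list()
  for (seed in seeds) {
    for (m in methods) {
      mp <- switch(m, rehearsal = list(fraction = rehearsalFraction),
                   ewc = list(lambda = ewcLambda), list())
      cfg <- trainConfig(m, epochs = epochs, stepsPerEpoch = stepsPerEpoch,
                         batchSize = batchSize, learningRate = learningRate,
                         seed = seed, methodParams = mp)
      run <- trainSequence(tasks, cfg)
      p <- run$perf
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, method = m,
        task1AtStage1 = .aggDice(p, 1L, 1L),
        task1Final = .aggDice(p, 2L, 1L),
        task1Drop = .aggDice(p, 1L, 1L) - .aggDice(p, 2L, 1L),
        finalTaskDice = .aggDice(p, 2L, 2L),
        bwtTask1 = backwardTransfer(p, 1L))
    }
  }
  do.call(rbind, rows)
}
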