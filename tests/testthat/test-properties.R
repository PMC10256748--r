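# Property-style checks across modules: behaviour under controlled
# distribution shift, the rigidity/plasticity dial, and the null control.

test_that("all six training regimes run end to end on a task pair", {
  tasks <- tinyTasks(shift = TRUE)
  cfgs <- list(
    tinyConfig("sequential"),
    tinyConfig("rehearsal", methodParams = list(fraction = 0.25)),
    tinyConfig("ewc", methodParams = list(lambda = 0.4)),
    tinyConfig("lwf", headMode = "multi",
               methodParams = list(temperature = 8)),
    tinyConfig("rw", methodParams = list(lambda = 0.4, alpha = 0.9)),
    tinyConfig("mib", methodParams = list(alpha = 0.9)))
  for (cfg in cfgs) {
    run <- trainSequence(tasks, cfg, baseChannels = 4)
    expect_identical(nrow(run$trajectory),
                     2L * cfg@epochs * 2L, label = cfg@method)
    expect_true(all(run$trajectory$dice >= 0 & run$trajectory$dice <= 1),
                label = cfg@method)
    expect_true(all(is.finite(unlist(modelParams(run$model)))),
                label = cfg@method)
  }
})

test_that("widening the intensity gap does not improve cross-task Dice", {
  # a probe model trained on a bright-on-dark task, evaluated on targets
  # whose foreground mean slides towards (and past) the background's
  probeTask <- generateTask(
    taskSpec("probe", 10, c(32, 32), intensityFg = c(0.75, 0.03),
             intensityBg = c(0.25, 0.03), noiseSigma = 0.2), seed = 21)
  cfg <- trainConfig("sequential", epochs = 3L, stepsPerEpoch = 15L,
                     batchSize = 2L, learningRate = 0.05, seed = 1L)
  probe <- trainSequence(list(probeTask), cfg, baseChannels = 4)$model
  gaps <- c(0, 0.25, 0.5)                     # fg mean 0.75, 0.5, 0.25
  cross <- vapply(seq_along(gaps), function(i) {
    tgt <- generateTask(
      taskSpec("tgt", 8, c(32, 32), intensityFg = c(0.75 - gaps[i], 0.03),
               intensityBg = c(0.25, 0.03), noiseSigma = 0.2),
      seed = 22)
    contiseg:::.taskClassDice(probe, tgt, headId = activeHead(probe))$mean
  }, numeric(1L))
  # trend over three gap levels: non-increasing within a small slack
  expect_lte(cross[2], cross[1] + 0.02)
  expect_lte(cross[3], cross[2] + 0.02)
  expect_lt(cross[3], cross[1])
})

test_that("stronger anchoring pulls the body monotonically to its anchor", {
  tasks <- tinyTasks(shift = TRUE, nCases = 8L)
  dist <- function(lambda, seed) {
    cfg <- tinyConfig("ewc", epochs = 2L, steps = 10L, seed = seed,
                      methodParams = list(lambda = lambda))
    m <- buildModel(tasks[[1]], baseChannels = 4,
                    seed = contiseg:::.mixSeed(cfg@seed, 11L))
    s1 <- trainStage(m, tasks[[1]], cfg, stageIndex = 1L)
    anchor <- s1$state$store@tasks$tinyA$anchor
    m2 <- addHead(s1$model, "tinyB", headMode = "single")
    s2 <- trainStage(m2, tasks[[2]], cfg, s1$state, stageIndex = 2L)
    flat <- contiseg:::.flatParams(s2$model)
    sqrt(sum(vapply(names(anchor), function(nm)
      sum((flat[[nm]] - anchor[[nm]])^2), numeric(1L))))
  }
  lambdas <- c(0, 0.4, 4, 40)
  for (seed in 1:3) {
    d <- vapply(lambdas, dist, numeric(1L), seed = seed)
    for (k in 1:3) expect_lte(d[k + 1], d[k] * 1.001)
    expect_lt(d[4], d[1])                     # strong anchoring clearly binds
  }
})

test_that("an identical-distribution pair shows no systematic transfer", {
  specs <- list(
    taskSpec("nullA", 10, c(32, 32), noiseSigma = 0.2, roiFraction = 0.1),
    taskSpec("nullB", 10, c(32, 32), noiseSigma = 0.2, roiFraction = 0.1))
  tasks <- generateSequence(specs, seed = 31)
  bwts <- vapply(1:3, function(seed) {
    cfg <- trainConfig("sequential", epochs = 5L, stepsPerEpoch = 20L,
                       batchSize = 2L, learningRate = 0.05, seed = seed)
    backwardTransfer(trainSequence(tasks, cfg, baseChannels = 8)$perf, 1L)
  }, numeric(1L))
  expect_lt(mean(abs(bwts)), 0.1)
})

test_that("freezing the body protects task 1 under a high shift", {
  tasks <- tinyTasks(nCases = 8L, shape = c(32L, 32L), shift = TRUE,
                     noise = 0.2)
  d1 <- function(freeze, seed) {
    cfg <- trainConfig("sequential", epochs = 3L, stepsPerEpoch = 10L,
                       batchSize = 2L, learningRate = 0.05, seed = seed,
                       headMode = "multi", freezeBodyAfterFirst = freeze)
    p <- trainSequence(tasks, cfg, baseChannels = 4)$perf
    contiseg:::.aggDice(p, 2L, 1L)           # task 1 after stage 2
  }
  frozen <- vapply(1:3, d1, numeric(1L), freeze = TRUE)
  plastic <- vapply(1:3, d1, numeric(1L), freeze = FALSE)
  expect_gte(mean(frozen), mean(plastic))
})

test_that("the final report agrees with the trajectory's last epoch", {
  tasks <- tinyTasks(shift = TRUE)
  run <- trainSequence(tasks, tinyConfig(epochs = 3L, steps = 8L),
                       baseChannels = 4)
  rep <- evaluateFinal(run$model, tasks, headPolicy = "active")
  last <- subset(run$trajectory, stage == 2 & epoch == 3)
  repOrder <- rep$task[order(-rep$diceMean)]
  trajOrder <- last$task[order(-last$dice)]
  expect_identical(repOrder, trajOrder)
})
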