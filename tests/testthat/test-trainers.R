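# Continual strategies: loss-component oracles, reduction identities,
# buffer arithmetic, state immutability.

test_that("rehearsal buffers use rounded per-task fractions", {
  tasks <- tinyTasks(nCases = 10L)           # 8 train cases each
  buf <- rehearsalSample(tasks[1], fraction = 0.25, seed = 5)
  expect_length(buf@entries, 2L)             # round(0.25 * 8)
  expect_true(all(vapply(buf@entries, `[[`, character(1), "taskId") == "tinyA"))
  trainIds <- vapply(trainCases(tasks[[1]]), `[[`, character(1), "caseId")
  expect_true(all(vapply(buf@entries, `[[`, character(1), "caseId")
                  %in% trainIds))

  expect_length(rehearsalSample(tasks[1], fraction = 0, seed = 5)@entries, 0L)
  b1 <- rehearsalSample(tasks, fraction = 0.5, seed = 9)
  b2 <- rehearsalSample(tasks, fraction = 0.5, seed = 9)
  expect_identical(vapply(b1@entries, `[[`, character(1), "caseId"),
                   vapply(b2@entries, `[[`, character(1), "caseId"))
  expect_error(rehearsalSample(tasks, fraction = 1.2), "fraction")
})

test_that("reduced strategies are bitwise identical to sequential", {
  tasks <- tinyTasks(shift = TRUE)
  base <- trainSequence(tasks, tinyConfig("sequential"), baseChannels = 4)
  reduced <- list(
    rehearsal = tinyConfig("rehearsal", methodParams = list(fraction = 0)),
    ewc = tinyConfig("ewc", methodParams = list(lambda = 0)),
    rw = tinyConfig("rw", methodParams = list(lambda = 0, alpha = 0.9)))
  for (nm in names(reduced)) {
    run <- trainSequence(tasks, reduced[[nm]], baseChannels = 4)
    expect_identical(modelParams(run$model), modelParams(base$model),
                     label = paste(nm, "parameters"))
    expect_identical(run$trajectory$dice, base$trajectory$dice,
                     label = paste(nm, "trajectory"))
  }
})

test_that("training stages are deterministic under equal seeds", {
  tasks <- tinyTasks(shift = TRUE)
  cfg <- tinyConfig("sequential")
  a <- trainSequence(tasks, cfg, baseChannels = 4)
  b <- trainSequence(tasks, cfg, baseChannels = 4)
  expect_identical(modelParams(a$model), modelParams(b$model))
  expect_identical(a$trajectory, b$trajectory)
})

test_that("empirical Fisher matches the logistic closed form exactly", {
  # one-parameter logistic model p = sigmoid(w x); the Fisher expectation
  # over the model's label distribution is p(1-p)x^2. Feeding both label
  # outcomes per case, weighted by their model probabilities, must
  # reproduce it to numerical precision.
  w <- 0.7
  xs <- c(-2, -0.5, 1, 3)
  p <- 1 / (1 + exp(-w * xs))
  cases <- list(); weights <- numeric()
  for (i in seq_along(xs)) for (y in c(1, 0)) {
    cases[[length(cases) + 1L]] <- list(x = xs[i], y = y)
    weights <- c(weights, if (y == 1) p[i] else 1 - p[i])
  }
  gradFn <- function(cs) {
    pi <- 1 / (1 + exp(-w * cs$x))
    (cs$y - pi) * cs$x              # d log p(y) / d w
  }
  fisher <- empiricalFisher(gradFn, cases, weights = weights / 2)
  closed <- mean(p * (1 - p) * xs^2)
  expect_equal(fisher, closed, tolerance = 1e-12)
})

test_that("computeFisher is nonnegative and congruent with the parameters", {
  tasks <- tinyTasks()
  run <- trainSequence(tasks[1], tinyConfig(epochs = 1L), baseChannels = 4)
  Fi <- computeFisher(run$model, tasks[[1]], nSamples = 3)
  flat <- contiseg:::.flatParams(run$model)
  expect_setequal(names(Fi), names(flat))
  for (nm in names(Fi)) {
    expect_true(all(Fi[[nm]] >= 0))
    expect_identical(length(Fi[[nm]]), length(flat[[nm]]))
  }
  empty <- tasks[[1]]; empty@trainIdx <- integer(0); empty@testIdx <- seq_len(6)
  expect_error(computeFisher(run$model, empty), "empty sample")
})

test_that("the anchoring penalty reproduces its closed form", {
  store <- new("ImportanceStore",
               tasks = list(t1 = list(anchor = list(w = c(0, 0)),
                                      omega = list(w = c(1, 2)))))
  params <- list(w = c(1, 1))                 # delta = (1, 1)
  expect_equal(ewcPenalty(params, store, 0.4), 0.4 / 2 * (1 + 2))  # 0.6
  expect_equal(ewcPenalty(params, store, 0), 0)
  expect_equal(ewcPenalty(store@tasks$t1$anchor, store, 5), 0)
  # two anchors sum
  store@tasks$t2 <- list(anchor = list(w = c(1, 0)), omega = list(w = c(4, 0)))
  expect_equal(ewcPenalty(params, store, 1), 0.5 * (1 + 2) + 0.5 * (0 + 0))
  bad <- new("ImportanceStore",
             tasks = list(t1 = list(anchor = list(w = c(0, 0, 0)),
                                    omega = list(w = c(1, 1, 1)))))
  expect_error(ewcPenalty(params, bad, 1), "shape mismatch")
})

test_that("anchors never change after their task completes", {
  tasks <- tinyTasks(shift = TRUE)
  cfg <- tinyConfig("ewc", methodParams = list(lambda = 0.4))
  m <- buildModel(tasks[[1]], baseChannels = 4, seed = 1)
  s1 <- trainStage(m, tasks[[1]], cfg, stageIndex = 1L)
  anchor1 <- s1$state$store@tasks$tinyA
  m2 <- addHead(s1$model, "tinyB", headMode = "single")
  s2 <- trainStage(m2, tasks[[2]], cfg, s1$state, stageIndex = 2L)
  expect_identical(s2$state$store@tasks$tinyA, anchor1)
  expect_setequal(names(s2$state$store@tasks), c("tinyA", "tinyB"))
})

test_that("the online importance update follows its stated recursion", {
  g1 <- list(w = 2); g2 <- list(w = -1)
  th0 <- list(w = 0); th1 <- list(w = -0.1); th2 <- list(w = -0.05)
  xi <- 1e-3
  st <- rwUpdate(NULL, g1, th0, th1, alpha = 0.9, xi = xi)
  st <- rwUpdate(st, g2, th1, th2, alpha = 0.9, xi = xi)
  # hand-rolled two-step trace of the same recursion
  F1 <- 0.9 * 4; F2 <- 0.9 * 1 + 0.1 * F1
  s1 <- max(0, -2 * -0.1) / (F1 * 0.01 / 2 + xi)
  s2 <- s1 + max(0, 1 * 0.05) / (F2 * 0.0025 / 2 + xi)
  expect_equal(st$F$w, F2, tolerance = 1e-12)
  expect_equal(st$s$w, s2, tolerance = 1e-12)
  omega <- contiseg:::.rwOmega(st)
  expect_equal(omega$w, F2 + s2, tolerance = 1e-12)

  # alpha = 1: running Fisher equals the last squared gradient
  stA <- rwUpdate(NULL, g1, th0, th1, alpha = 1)
  stA <- rwUpdate(stA, g2, th1, th2, alpha = 1)
  expect_equal(stA$F$w, 1)
  # zero parameter motion leaves the path score unchanged
  stZ <- rwUpdate(NULL, g1, th0, th0, alpha = 0.5)
  expect_equal(stZ$s$w, 0)
  expect_error(rwUpdate(NULL, g1, th0, th1, alpha = 1.5), "alpha")
})

test_that("distillation losses satisfy their limits and oracles", {
  set.seed(20)
  Zs <- matrix(rnorm(10), 5, 2)
  Zt <- matrix(rnorm(10), 5, 2)

  # zero at equality: student logits equal, same temperature
  qT <- contiseg:::softmaxRows(Zs / 4)
  kd0 <- kdLoss(Zs, qT, temperature = 4)
  ent <- -16 * mean(rowSums(qT * log(qT)))
  expect_equal(kd0$loss, ent, tolerance = 1e-9)    # minimum = teacher entropy
  expect_equal(max(abs(kd0$dZ)), 0, tolerance = 1e-12)

  # T = 1 reduces to plain cross-entropy between softmax outputs
  q1 <- contiseg:::softmaxRows(Zt)
  kd1 <- kdLoss(Zs, q1, temperature = 1)
  ce <- -mean(rowSums(q1 * log(contiseg:::softmaxRows(Zs))))
  expect_equal(kd1$loss, ce, tolerance = 1e-9)

  # single-voxel, 2-class oracle recomputed independently
  st <- matrix(c(0, 2), 1, 2); te <- matrix(c(2, 0), 1, 2)
  kd <- kdLoss(st, contiseg:::softmaxRows(te / 2), temperature = 2)
  pT <- exp(st / 2) / sum(exp(st / 2))
  qT2 <- exp(te / 2) / sum(exp(te / 2))
  expect_equal(kd$loss, -4 * sum(qT2 * log(pT)), tolerance = 1e-6)
})

test_that("probability hardening follows p^(1/alpha) renormalized", {
  p <- c(0.9, 0.1)
  expect_equal(hardenProbs(p, 1), p, tolerance = 1e-12)      # identity
  h <- hardenProbs(p, 0.9)
  manual <- p^(1 / 0.9) / sum(p^(1 / 0.9))
  expect_equal(h, manual, tolerance = 1e-9)
  expect_gt(h[1], p[1])                                      # sharpened
  expect_error(hardenProbs(p, 0), "alpha")
})

test_that("background-modelling losses reduce to standard CE here", {
  set.seed(21)
  Z <- matrix(rnorm(12), 6, 2)
  y <- sample(0:1, 6, TRUE)
  ml <- mibLosses(Z, y, teacherLogits = NULL, alpha = 0.9)
  P <- contiseg:::softmaxRows(Z)
  expect_equal(ml$ce, -mean(log(P[cbind(1:6, y + 1)])), tolerance = 1e-9)
  expect_equal(ml$kd, 0)
  # KD at its minimum when the student equals the hardened teacher
  Zt <- matrix(rnorm(12), 6, 2)
  q <- hardenProbs(contiseg:::softmaxRows(Zt), 0.9)
  mlt <- mibLosses(log(q), y, teacherLogits = Zt, alpha = 0.9)
  expect_equal(mlt$kd, -mean(rowSums(q * log(q))), tolerance = 1e-9)
  expect_error(mibLosses(Z, y, alpha = -1), "alpha")
})

test_that("LwF trains only in multi-head mode and distils old heads", {
  tasks <- tinyTasks(shift = TRUE)
  expect_error(trainConfig("lwf", headMode = "single"), "multi")
  cfg <- tinyConfig("lwf", headMode = "multi",
                    methodParams = list(temperature = 2))
  run <- trainSequence(tasks, cfg, baseChannels = 4)
  expect_length(heads(run$model), 2L)
  # old head received gradient in the joint phase
  ref <- trainSequence(tasks, tinyConfig("sequential", headMode = "multi"),
                       baseChannels = 4)
  expect_false(identical(heads(run$model)$tinyA, heads(ref$model)$tinyA))
})
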