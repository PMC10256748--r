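# Metric formulas: Dice, backward/forward transfer, their relative forms,
# and the report/matrix plumbing built on them.

mkPerf <- function(dice, independent = NULL, order = NULL) {
  n <- dim(dice)[1]
  if (is.null(order)) order <- paste0("T", seq_len(n))
  if (is.null(independent))
    independent <- matrix(NA_real_, n, dim(dice)[3])
  dimnames(dice) <- list(stage = order, task = order,
                         class = seq_len(dim(dice)[3]))
  new("PerfMatrix", dice = dice, independent = independent, order = order)
}

test_that("Dice follows 2|AnB|/(|A|+|B|) with the both-empty convention", {
  a <- matrix(c(1L, 1L, 0L, 0L), 2)
  expect_equal(diceScore(a, a, 1), 1)                       # identical
  b <- matrix(c(0L, 0L, 1L, 1L), 2)
  expect_equal(diceScore(a, b, 1), 0)                       # disjoint

  # enumerated 4x4 grid: |A| = 4, |B| = 6, |A n B| = 3 -> 0.6
  A <- matrix(0L, 4, 4); A[c(1, 2, 3, 5)] <- 1L
  B <- matrix(0L, 4, 4); B[c(1, 2, 5, 8, 9, 10)] <- 1L
  stopifnot(sum(A) == 4, sum(B) == 6, sum(A & B) == 3)
  expect_equal(diceScore(A, B, 1), 2 * 3 / (4 + 6))

  z <- matrix(0L, 2, 2)
  expect_equal(diceScore(z, z, 1), 1)                       # both empty
  expect_equal(diceScore(z, a, 1), 0)                       # pred empty
  expect_error(diceScore(matrix(0L, 2, 2), matrix(0L, 2, 3), 1), "shape")
})

test_that("Dice is symmetric, bounded, and 1 iff the voxel sets agree", {
  set.seed(30)
  for (r in 1:20) {
    a <- array(sample(0:2, 64, TRUE), dim = c(8, 8))
    b <- array(sample(0:2, 64, TRUE), dim = c(8, 8))
    cl <- sample(1:2, 1)
    d1 <- diceScore(a, b, cl); d2 <- diceScore(b, a, cl)
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    if (d1 == 1) expect_identical(a == cl, b == cl)
  }
})

test_that("backward transfer reproduces hand-computed values", {
  d <- array(NA_real_, c(2, 2, 1))
  d[1, 1, ] <- 0.90; d[1, 2, ] <- 0.30
  d[2, 1, ] <- 0.80; d[2, 2, ] <- 0.95
  p <- mkPerf(d)
  expect_equal(backwardTransfer(p, 1), -0.10, tolerance = 1e-9)
  expect_equal(backwardTransfer(p, 1, relative = TRUE), 100 * -0.10 / 0.90,
               tolerance = 1e-9)                            # -11.1%
  expect_equal(backwardTransfer(p, 2), 0, tolerance = 1e-12)

  d[2, 1, ] <- 0.95; d[1, 1, ] <- 0.85
  expect_equal(backwardTransfer(mkPerf(d), 1), +0.10, tolerance = 1e-9)

  dm <- d; dm[1, 1, ] <- NA
  expect_error(backwardTransfer(mkPerf(dm), 1), "missing")
  dg <- d; dg[1, 1, ] <- 1e-5; dg[2, 1, ] <- 0
  expect_warning(out <- backwardTransfer(mkPerf(dg), 1, relative = TRUE),
                 "undefined")
  expect_true(is.na(out))
})

test_that("forward transfer compares against the independent reference", {
  d <- array(NA_real_, c(2, 2, 1))
  d[1, 1, ] <- 0.88; d[2, 2, ] <- 0.90; d[2, 1, ] <- 0.80; d[1, 2, ] <- 0.2
  ind <- matrix(c(0.92, 0.85), 2, 1)
  p <- mkPerf(d, independent = ind)
  expect_equal(forwardTransfer(p, 1), -0.04, tolerance = 1e-9)
  expect_equal(forwardTransfer(p, 1, relative = TRUE), 100 * -0.04 / 0.92,
               tolerance = 1e-9)                            # -4.3%
  expect_equal(forwardTransfer(p, 2), 0.05, tolerance = 1e-9)
  pNA <- mkPerf(d)
  expect_error(forwardTransfer(pNA, 1), "independent")
})

test_that("transfer metrics ignore the order of non-involved tasks", {
  set.seed(31)
  d <- array(runif(27, 0.2, 0.95), c(3, 3, 3))
  p <- mkPerf(d)
  b1 <- backwardTransfer(p, 1)
  # permute the entries of a non-involved task (task 3's column at
  # intermediate stage rows does not enter BWT of task 1)
  d2 <- d
  d2[2, 3, ] <- rev(d[2, 3, ])
  expect_equal(backwardTransfer(mkPerf(d2), 1), b1, tolerance = 1e-12)
})

test_that("the final report has one row per task and class", {
  tasks <- tinyTasks()
  run <- trainSequence(tasks, tinyConfig(epochs = 1L, steps = 3L),
                       baseChannels = 4)
  rep <- evaluateFinal(run$model, tasks)
  expect_identical(nrow(rep), 2L)                     # 2 tasks x 1 fg class
  expect_true(all(rep$diceMean >= 0 & rep$diceMean <= 1))
  expect_true(all(rep$nCases == 1L))
  multi <- addHead(run$model, "spare")
  expect_error(evaluateFinal(multi, list(tinyTasks(seed = 9L)[[1]])),
               "no head")
})

test_that("a one-task inter-task matrix equals the static test Dice", {
  task <- tinyTasks()[1]
  cfg <- tinyConfig(epochs = 1L, steps = 4L)
  M <- interTaskMatrix(task, cfg, baseChannels = 4)
  expect_identical(dim(M), c(1L, 1L))
  ref <- contiseg:::.independentModel(task[[1]], cfg, baseChannels = 4)
  d <- contiseg:::.taskClassDice(ref, task[[1]])$mean
  expect_equal(M[1, 1], mean(d), tolerance = 1e-12)
})
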