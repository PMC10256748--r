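# Experiment orchestration: persistence, determinism, ordering, method
# comparison and configuration files.

tinyExperiment <- function(outputDir, method = "sequential", order = NULL,
                           seed = 1L, mp = list()) {
  experimentConfig(tinySpecs(), order = order,
                   train = tinyConfig(method, methodParams = mp),
                   outputDir = outputDir, seed = seed)
}

test_that("runExperiment persists reports and reproduces them bitwise", {
  d1 <- tempfile("exp1-"); d2 <- tempfile("exp2-")
  r1 <- runExperiment(tinyExperiment(d1))
  expect_s4_class(r1$perf, "PerfMatrix")
  wanted <- c("trajectory.csv", "perf_matrix.csv", "final_report.csv",
              "summary.json", "provenance.json", "alignment_report.json",
              "task_tinyA_manifest.json")
  for (f in wanted) expect_true(file.exists(file.path(d1, f)), label = f)

  r2 <- runExperiment(tinyExperiment(d2))
  for (f in wanted) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("bitwise", f))
  }
  expect_identical(r1$digest, r2$digest)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("task order changes the run but not the per-task data", {
  dA <- tempfile(); dB <- tempfile()
  rA <- runExperiment(tinyExperiment(dA, order = c("tinyA", "tinyB")))
  rB <- runExperiment(tinyExperiment(dB, order = c("tinyB", "tinyA")))
  expect_identical(rA$perf@order, c("tinyA", "tinyB"))
  expect_identical(rB$perf@order, c("tinyB", "tinyA"))
  expect_false(identical(rA$summary, rB$summary))
  # same generated per-task data: the stored splits coincide
  mA <- jsonlite::read_json(file.path(dA, "task_tinyA_manifest.json"))
  mB <- jsonlite::read_json(file.path(dB, "task_tinyA_manifest.json"))
  expect_identical(mA$split, mB$split)
  expect_error(tinyExperiment(tempfile(), order = c("tinyA", "nope")),
               "permutation")
  unlink(c(dA, dB), recursive = TRUE)
})

test_that("experiments abort with the failing stage name", {
  cfg <- experimentConfig(
    tinySpecs(),
    mappings = list(tinyA = labelMapping(c("9" = 1), "tinyA"),
                    tinyB = identityMapping(1L, "tinyB")),
    train = tinyConfig(), outputDir = tempfile(), seed = 1L)
  expect_error(runExperiment(cfg), "stage 'align'")
})

test_that("compareMethods tabulates methods over a shared sequence", {
  cfgs <- list(tinyExperiment(tempfile(), "sequential"),
               tinyExperiment(tempfile(), "rehearsal",
                              mp = list(fraction = 0.5)))
  tab <- compareMethods(cfgs)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$method, c("sequential", "rehearsal"))
  expect_true(all(c("dice_tinyA", "dice_tinyB", "bwt_tinyA") %in% names(tab)))
  expect_true(is.integer(attr(tab, "best")) || is.numeric(attr(tab, "best")))

  single <- compareMethods(cfgs[1])
  expect_identical(nrow(single), 1L)

  # lossless CSV round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$dice_tinyA, tab$dice_tinyA, tolerance = 1e-12)
  expect_identical(back$method, tab$method)
  unlink(f)

  bad <- tinyExperiment(tempfile(), order = c("tinyB", "tinyA"))
  expect_error(compareMethods(list(cfgs[[1]], bad)), "share")
})

test_that("configurations round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 7",
    "order: [t1, t2]",
    "tasks:",
    "  - task_id: t1",
    "    n_cases: 6",
    "    image_shape: [16, 16]",
    "  - task_id: t2",
    "    n_cases: 6",
    "    image_shape: [16, 16]",
    "    label_scheme: [1, 2]",
    "mappings:",
    "  t1: {'1': 1}",
    "  t2: {'1': 1, '2': 0}",
    "train:",
    "  method: rehearsal",
    "  epochs: 2",
    "  steps_per_epoch: 3",
    "  batch_size: 2",
    "  method_params: {fraction: 0.25}"), f)
  cfg <- readExperimentConfig(f)
  expect_s4_class(cfg, "ExperimentConfig")
  expect_identical(cfg@seed, 7L)
  expect_identical(cfg@train@method, "rehearsal")
  expect_equal(cfg@train@methodParams$fraction, 0.25)
  expect_identical(cfg@order, c("t1", "t2"))
  expect_identical(cfg@mappings$t2@map, c("1" = 1L, "2" = 0L))
  unlink(f)
})
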