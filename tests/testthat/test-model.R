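# Model mechanics: construction, head replication, freezing, prediction,
# parameter-split soundness.

test_that("buildModel fixes the architecture from the first task", {
  ds <- tinyTasks()[[1]]
  m <- buildModel(ds, baseChannels = 4, seed = 2)
  expect_identical(names(heads(m)), "tinyA")
  expect_identical(archConfig(m)$nClasses, 2L)                # binary -> 2 channels
  expect_identical(ncol(heads(m)$tinyA[["seg_head.W"]]), 2L)
  m2 <- buildModel(ds, baseChannels = 4, seed = 2)
  expect_identical(m@body, m2@body)                           # deterministic init
  expect_identical(heads(m), heads(m2))
  m3 <- buildModel(ds, baseChannels = 4, seed = 3)
  expect_false(identical(m@body, m3@body))
  expect_error(buildModel(ds, nClasses = 1), "2 classes")
})

test_that("inputs of a different shape are resampled by the data path", {
  tasks <- tinyTasks()
  m <- buildModel(tasks[[1]], baseChannels = 4, seed = 1)
  big <- generateTask(taskSpec("big", 3, c(32, 32)), seed = 1)
  pred <- predictMask(m, big@cases[[1]]$image)
  expect_identical(dim(pred), c(32L, 32L))                    # model config unchanged
  expect_identical(archConfig(m)$imageShape, c(16L, 16L))
})

test_that("head replication copies values and predictions exactly", {
  tasks <- tinyTasks()
  m <- buildModel(tasks[[1]], baseChannels = 4, seed = 4)
  m2 <- addHead(m, "tinyB", headMode = "multi")
  expect_length(heads(m2), 2L)
  expect_identical(heads(m2)$tinyA, heads(m2)$tinyB)
  img <- tasks[[1]]@cases[[1]]$image
  expect_identical(predictMask(m2, img, "tinyA"), predictMask(m2, img, "tinyB"))
  expect_identical(activeHead(m2), "tinyB")
  expect_error(addHead(m2, "tinyB"), "already exists")
})

test_that("single-head mode re-keys instead of replicating", {
  tasks <- tinyTasks()
  m <- buildModel(tasks[[1]], baseChannels = 4, seed = 5)
  m1 <- addHead(m, "tinyB", headMode = "single")
  expect_length(heads(m1), 1L)
  expect_identical(names(heads(m1)), "tinyB")
  expect_identical(heads(m1)$tinyB, heads(m)$tinyA)
})

test_that("a frozen body is bitwise constant under training, heads move", {
  tasks <- tinyTasks()
  m <- buildModel(tasks[[1]], baseChannels = 4, seed = 6)
  m <- freezeBody(m)
  res <- trainStage(m, tasks[[1]], tinyConfig(epochs = 1L, steps = 3L))
  expect_identical(res$model@body, m@body)
  expect_false(identical(heads(res$model)$tinyA, heads(m)$tinyA))
})

test_that("training task i in multi-head mode never changes head j != i", {
  tasks <- tinyTasks(shift = TRUE)
  cfg <- tinyConfig(headMode = "multi", epochs = 1L, steps = 4L)
  m <- buildModel(tasks[[1]], baseChannels = 4,
                  seed = contiseg:::.mixSeed(cfg@seed, 11L))
  s1 <- trainStage(m, tasks[[1]], cfg, stageIndex = 1L)
  headA <- heads(s1$model)$tinyA
  m2 <- addHead(s1$model, "tinyB", headMode = "multi")
  s2 <- trainStage(m2, tasks[[2]], cfg, s1$state, stageIndex = 2L)
  expect_identical(heads(s2$model)$tinyA, headA)
})

test_that("every trainable parameter is in exactly one of body/head", {
  m <- buildModel(tinyTasks()[[1]], baseChannels = 4, seed = 7)
  flat <- contiseg:::.flatParams(m)
  headNms <- names(flat)[startsWith(names(flat), m@splitPoint)]
  expect_setequal(names(flat), c(names(m@body), headNms))
  expect_length(intersect(names(m@body), headNms), 0L)
  expect_setequal(contiseg:::.trainableNames(m), names(flat))
  expect_setequal(contiseg:::.trainableNames(freezeBody(m)), headNms)
})

test_that("arg-max decoding breaks score ties toward the lowest class", {
  Z <- rbind(c(0.5, 0.5, 0.1),      # tie between class 0 and 1 -> 0
             c(0.1, 0.9, 0.9),      # tie between class 1 and 2 -> 1
             c(0.2, 0.3, 0.9))      # clear winner -> 2
  out <- contiseg:::.argmaxMask(Z, c(3L, 1L))
  expect_identical(as.vector(out), c(0L, 1L, 2L))
})

test_that("prediction with an unknown head id errors in multi-head models", {
  tasks <- tinyTasks()
  m <- addHead(buildModel(tasks[[1]], baseChannels = 4, seed = 8), "tinyB")
  expect_error(predictMask(m, tasks[[1]]@cases[[1]]$image, "nope"), "no head")
})

test_that("checkpoints round-trip body, heads and provenance", {
  tasks <- tinyTasks()
  m <- addHead(buildModel(tasks[[1]], baseChannels = 4, seed = 9), "tinyB")
  f <- tempfile(fileext = ".rds")
  saveModel(m, f, provenance = list(order = c("tinyA", "tinyB")))
  back <- loadModel(f)
  expect_identical(back@body, m@body)
  expect_identical(heads(back), heads(m))
  expect_identical(attr(back, "provenance")$order, c("tinyA", "tinyB"))
  unlink(f)
})
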