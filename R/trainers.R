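# The six training regimes -- trivial sequential plus five continual
# strategies -- share one SGD loop; a strategy only adds (a) extra cases in
# the sampling pool (rehearsal), (b) extra gradient terms (EWC, RW, MiB,
# LwF distillation), or (c) a trainable-set schedule (LwF's staged phases).
#
# Determinism: every stage draws from a private RNG stream seeded by
# hash(run seed, stage index), so adding a method never perturbs the data
# stream of another, and reduced settings (rehearsal fraction 0, lambda 0)
# are bitwise identical to sequential training.

#' Sample a rehearsal memory buffer from previous tasks
#'
#' Draws uniformly without replacement from each previous task's train
#' split: `round(fraction * |train_j|)` cases per task (half away from
#' zero). Buffer cases join the current stage's training pool with equal
#' per-case sampling weight.
#'
#' @param previous list of previously seen [TaskDataset-class].
#' @param fraction proportion in [0, 1] of each train split to keep.
#' @param seed sampling seed (per-task streams derive from it and the task
#'   id).
#' @return a [MemoryBuffer-class].
#' @export
rehearsalSample <- function(previous, fraction = 0.25, seed = 1L) {
  if (fraction < 0 || fraction > 1)
    .stopUser("rehearsal fraction must lie in [0, 1]")
  entries <- list()
  for (ds in previous) {
    tr <- trainCases(ds)
    k <- as.integer(.roundHalfAway(fraction * length(tr)))
    if (k < 1L) next
    pick <- withSeed(.mixSeed(seed, .hashString(taskId(ds))),
                     sort(sample.int(length(tr), k)))
    for (i in pick) {
      cs <- tr[[i]]
      entries[[length(entries) + 1L]] <-
        list(taskId = taskId(ds), caseId = cs$caseId,
             image = cs$image, mask = cs$mask)
    }
  }
  new("MemoryBuffer", entries = entries, fraction = fraction,
      seed = as.integer(seed))
}

# dataset case -> list(x = (V,1) input matrix, y = 0-based label vector)
.poolEntry <- function(image, mask, arch) {
  x <- .caseInput(image, arch)
  m <- .resampleNearest(mask, arch$imageShape)
  y <- as.integer(as.vector(m))
  if (max(y) >= arch$nClasses)
    .stopUser("mask contains label ", max(y), " but the model has ",
              arch$nClasses, " classes; align labels first")
  list(x = x, y = y)
}

# mean foreground Dice of the current parameters on one task's test split
.valDice <- function(body, headsList, activeId, task, arch, geom) {
  hid <- if (taskId(task) %in% names(headsList)) taskId(task) else activeId
  hd <- headsList[[hid]]
  scores <- vapply(testCases(task), function(cs) {
    x <- .caseInput(cs$image, arch)
    Z <- headForward(hd, bodyForward(body, x, geom)$feat)
    pred <- .argmaxMask(Z, arch$imageShape)
    truth <- .resampleNearest(cs$mask, arch$imageShape)
    mean(vapply(seq_len(arch$nClasses - 1L),
                function(cl) diceScore(pred, truth, cl), numeric(1L)))
  }, numeric(1L))
  mean(scores)
}

#' Train one stage (one task) under a continual strategy
#'
#' Runs `epochs x stepsPerEpoch` SGD steps on the task's train split (plus
#' the rehearsal buffer, if any), applying the strategy in
#' `config@method`. After every epoch the mean foreground Dice on the test
#' split of *every* task in `valTasks` is recorded, giving the
#' multi-validation-set trajectory.
#'
#' @param model a [SegModel-class]; its active head is trained.
#' @param task the (aligned) [TaskDataset-class] of this stage.
#' @param config a [TrainConfig-class].
#' @param state method state carried across stages: a list with elements
#'   `store` ([ImportanceStore-class]), `teacher` (previous-boundary
#'   [SegModel-class] snapshot), `rw` (running Fisher/path state) and
#'   `buffer` ([MemoryBuffer-class]); NULL starts a fresh state.
#' @param stageIndex 1-based position of this stage in the sequence.
#' @param valTasks tasks whose validation performance is tracked each
#'   epoch; defaults to `list(task)`.
#' @return list with the updated `model`, `state`, and a `trajectory` data
#'   frame (stage, stageTask, epoch, task, dice).
#' @export
trainStage <- function(model, task, config, state = NULL, stageIndex = 1L,
                       valTasks = NULL) {
  stopifnot(is(model, "SegModel"), is(task, "TaskDataset"),
            is(config, "TrainConfig"))
  validObject(config)
  if (is.null(state))
    state <- list(store = new("ImportanceStore", tasks = list()),
                  teacher = NULL, rw = NULL, buffer = NULL)
  if (is.null(valTasks)) valTasks <- list(task)
  method <- config@method
  mp <- config@methodParams
  arch <- model@archConfig
  geom <- .getGeometry(arch$imageShape)
  K <- arch$nClasses

  if (method == "lwf" && stageIndex > 1L && is.null(state$teacher))
    .stopUser("lwf needs a teacher snapshot from the previous stage")
  if (method == "lwf" && config@headMode != "multi")
    .stopUser("lwf requires multi-head mode")
  if (method %in% c("ewc", "rw") && !is(state$store, "ImportanceStore"))
    .stopUser("method '", method, "' needs an ImportanceStore in the state")

  # ---- training pool ----
  pool <- lapply(trainCases(task), function(cs)
    .poolEntry(cs$image, cs$mask, arch))
  if (method == "rehearsal" && !is.null(state$buffer)) {
    for (e in state$buffer@entries)
      pool[[length(pool) + 1L]] <- .poolEntry(e$image, e$mask, arch)
  }
  nPool <- length(pool)

  # ---- strategy preparation ----
  theta <- .flatParams(model)
  headNms <- names(theta)[startsWith(names(theta), model@splitPoint)]
  bodyNms <- setdiff(names(theta), headNms)
  trainable <- .trainableNames(model)

  penalize <- character()
  lambda <- 0
  anchorA <- anchorB <- list()
  if (method %in% c("ewc", "rw") && length(state$store@tasks)) {
    lambda <- mp$lambda
    penalize <- intersect(trainable, names(state$store@tasks[[1L]]$anchor))
    if (config@headMode == "multi")
      penalize <- setdiff(penalize, headNms)    # heads are task-private
    # The quadratic anchoring term is applied as a proximal (implicit)
    # step, solving th = th' - lr*lambda*(B*th - A) for th, which is
    # unconditionally stable for any lambda. B and A are fixed per stage.
    for (nm in penalize) {
      B <- A <- state$store@tasks[[1L]]$anchor[[nm]] * 0
      for (tk in state$store@tasks) {
        if (!nm %in% names(tk$anchor)) next
        if (length(tk$anchor[[nm]]) != length(theta[[nm]]))
          .stopUser("shape mismatch between parameters and anchor '", nm, "'")
        B <- B + tk$omega[[nm]]
        A <- A + tk$omega[[nm]] * tk$anchor[[nm]]
      }
      anchorB[[nm]] <- B
      anchorA[[nm]] <- A
    }
  }

  teacherQ <- NULL
  if (method == "mib" && !is.null(state$teacher)) {
    tArch <- state$teacher@archConfig
    tGeom <- .getGeometry(tArch$imageShape)
    tHead <- state$teacher@heads[[state$teacher@activeHead]]
    teacherQ <- lapply(pool, function(pe) {
      Z <- headForward(tHead,
                       bodyForward(state$teacher@body, pe$x, tGeom)$feat)
      hardenProbs(softmaxRows(Z), mp$alpha)
    })
  }

  lwfActive <- method == "lwf" && stageIndex > 1L
  oldHeads <- list()
  lwfQ <- NULL
  warmEpochs <- 0L
  if (lwfActive) {
    Tmp <- mp$temperature
    oldIds <- setdiff(names(model@heads), model@activeHead)
    oldHeads <- model@heads[oldIds]
    tBody <- state$teacher@body
    # record the teacher's temperature-T outputs on the new task's train
    # images once, per old head (three-phase schedule, recording phase)
    lwfQ <- lapply(oldIds, function(oid) {
      th <- state$teacher@heads[[oid]]
      lapply(pool, function(pe) {
        Z <- headForward(th, bodyForward(tBody, pe$x, geom)$feat)
        softmaxRows(Z / Tmp)
      })
    })
    names(lwfQ) <- oldIds
    warmEpochs <- max(1L, as.integer(ceiling(0.1 * config@epochs)))
  }

  velocity <- paramZero(theta)
  vOld <- lapply(oldHeads, paramZero)
  rwState <- if (method == "rw") state$rw else NULL
  xi <- if (!is.null(mp$xi)) mp$xi else 1e-3

  stageSeed <- .mixSeed(config@seed, stageIndex)
  trajRows <- list()

  withSeed(stageSeed, {
    for (epoch in seq_len(config@epochs)) {
      warm <- lwfActive && epoch <= warmEpochs
      stepTrainable <- if (warm) intersect(trainable, headNms) else trainable
      for (step in seq_len(config@stepsPerEpoch)) {
        idx <- sample.int(nPool, config@batchSize,
                          replace = nPool < config@batchSize)
        gAcc <- NULL
        gOldAcc <- if (length(oldHeads)) lapply(oldHeads, paramZero) else list()
        for (i in idx) {
          pe <- pool[[i]]
          bf <- bodyForward(theta[bodyNms], pe$x, geom)
          Z <- headForward(theta[headNms], bf$feat)
          sl <- segLoss(Z, pe$y, K)
          dZ <- sl$dZ
          if (method == "mib" && !is.null(teacherQ)) {
            # distillation against the hardened teacher outputs; the
            # unbiased CE term reduces to the standard CE used in segLoss
            # because the label set is identical across tasks
            P <- softmaxRows(Z)
            dZ <- dZ + mp$kdWeight * (P - teacherQ[[i]]) / nrow(Z)
          }
          hb <- headBackward(theta[headNms], bf$feat, dZ)
          dFeat <- hb$dFeat
          if (lwfActive && !warm) {
            for (oid in names(oldHeads)) {
              zo <- headForward(oldHeads[[oid]], bf$feat)
              kd <- kdLoss(zo, lwfQ[[oid]][[i]], mp$temperature)
              ob <- headBackward(oldHeads[[oid]], bf$feat, kd$dZ)
              gOldAcc[[oid]] <- paramAxpy(1, ob$grads, gOldAcc[[oid]])
              dFeat <- dFeat + ob$dFeat
            }
          }
          g <- c(bodyBackward(theta[bodyNms], bf$cache, dFeat), hb$grads)
          gAcc <- if (is.null(gAcc)) g else paramAxpy(1, g, gAcc)
        }
        grads <- paramScale(gAcc, 1 / config@batchSize)
        if (length(gOldAcc))
          gOldAcc <- lapply(gOldAcc, paramScale, 1 / config@batchSize)
        if (method == "rw") before <- theta[stepTrainable]
        up <- sgdStep(theta, grads, velocity, config@learningRate,
                      config@momentum, stepTrainable)
        theta <- up$params
        velocity <- up$velocity
        if (lambda > 0 && length(penalize)) {
          lrl <- config@learningRate * lambda
          for (nm in penalize)
            theta[[nm]] <- (theta[[nm]] + lrl * anchorA[[nm]]) /
              (1 + lrl * anchorB[[nm]])
        }
        if (method == "rw") {
          rwState <- rwUpdate(rwState, grads[stepTrainable], before,
                              theta[stepTrainable], alpha = mp$alpha, xi = xi)
        }
        if (lwfActive && !warm && length(oldHeads)) {
          for (oid in names(oldHeads)) {
            upo <- sgdStep(oldHeads[[oid]], gOldAcc[[oid]], vOld[[oid]],
                           config@learningRate, config@momentum,
                           names(oldHeads[[oid]]))
            oldHeads[[oid]] <- upo$params
            vOld[[oid]] <- upo$velocity
          }
        }
      }
      # epoch boundary: track every validation set
      headsNow <- model@heads
      headsNow[[model@activeHead]] <- theta[headNms]
      for (oid in names(oldHeads)) headsNow[[oid]] <- oldHeads[[oid]]
      for (vt in valTasks) {
        trajRows[[length(trajRows) + 1L]] <- data.frame(
          stage = stageIndex, stageTask = taskId(task), epoch = epoch,
          task = taskId(vt),
          dice = .valDice(theta[bodyNms], headsNow, model@activeHead,
                          vt, arch, geom))
      }
    }
  })

  # ---- write back ----
  model <- .unflatten(model, theta)
  for (oid in names(oldHeads)) model@heads[[oid]] <- oldHeads[[oid]]

  # ---- post-stage state ----
  if (method == "ewc") {
    Fi <- computeFisher(model, task,
                        nSamples = min(10L, length(trainCases(task))),
                        seed = .mixSeed(stageSeed, 77L))
    state$store <- .storeAdd(state$store, taskId(task),
                             anchor = .flatParams(model), omega = Fi)
  } else if (method == "rw") {
    omega <- .rwOmega(rwState)
    anchor <- .flatParams(model)
    state$store <- .storeAdd(state$store, taskId(task),
                             anchor = anchor[names(omega)], omega = omega)
    state$rw <- NULL
  }
  state$teacher <- model
  state$buffer <- NULL

  list(model = model, state = state,
       trajectory = do.call(rbind, trajRows))
}

#' Train a model sequentially over an ordered task sequence
#'
#' Builds the model from the first task (its configuration is fixed for the
#' whole run), then trains one stage per task under the configured
#' strategy, replicating heads at task boundaries in multi-head mode,
#' sampling rehearsal buffers, and carrying method state. After each stage
#' the model is evaluated on every task's test split, filling the
#' performance matrix that backward/forward transfer are computed from.
#'
#' @param tasks ordered list of aligned [TaskDataset-class].
#' @param config a [TrainConfig-class].
#' @param baseChannels network width (first-level channels).
#' @param computeIndependent also train one static reference model per task
#'   (same architecture, same budget) to fill the independent row used by
#'   forward transfer.
#' @return list with `model`, `state`, `trajectory` (data frame),
#'   and `perf` (a [PerfMatrix-class]).
#' @export
trainSequence <- function(tasks, config, baseChannels = 8L,
                          computeIndependent = FALSE) {
  stopifnot(length(tasks) >= 1L)
  ids <- unname(vapply(tasks, taskId, character(1L)))
  names(tasks) <- ids
  model <- buildModel(tasks[[1L]], baseChannels = baseChannels,
                      seed = .mixSeed(config@seed, 11L))
  state <- NULL
  nCls <- model@archConfig$nClasses
  classes <- seq_len(nCls - 1L)
  dice <- array(NA_real_, dim = c(length(tasks), length(tasks), nCls - 1L),
                dimnames = list(stage = ids, task = ids, class = classes))
  traj <- list()
  for (s in seq_along(tasks)) {
    if (s > 1L) {
      model <- addHead(model, ids[s], headMode = config@headMode)
      if (config@freezeBodyAfterFirst) model <- freezeBody(model)
    }
    if (config@method == "rehearsal" && s > 1L) {
      buf <- rehearsalSample(tasks[seq_len(s - 1L)],
                             fraction = config@methodParams$fraction,
                             seed = .mixSeed(config@seed, 500L + s))
      if (is.null(state))
        state <- list(store = new("ImportanceStore", tasks = list()),
                      teacher = NULL, rw = NULL, buffer = buf)
      else state$buffer <- buf
    }
    res <- trainStage(model, tasks[[s]], config, state, stageIndex = s,
                      valTasks = tasks)
    model <- res$model
    state <- res$state
    traj[[s]] <- res$trajectory
    for (j in seq_along(tasks)) {
      dice[s, j, ] <- .taskClassDice(model, tasks[[j]])$mean
    }
  }
  independent <- matrix(NA_real_, length(tasks), nCls - 1L,
                        dimnames = list(ids, classes))
  if (computeIndependent) {
    for (j in seq_along(tasks)) {
      ref <- .independentModel(tasks[[j]], config, baseChannels)
      independent[j, ] <- .taskClassDice(ref, tasks[[j]])$mean
    }
  }
  perf <- new("PerfMatrix", dice = dice, independent = independent,
              order = ids)
  list(model = model, state = state, trajectory = do.call(rbind, traj),
       perf = perf)
}

# static reference model: same architecture/config family, trained with the
# same budget solely on one task
.independentModel <- function(task, config, baseChannels = 8L) {
  cfg <- trainConfig("sequential", epochs = config@epochs,
                     stepsPerEpoch = config@stepsPerEpoch,
                     batchSize = config@batchSize,
                     learningRate = config@learningRate,
                     momentum = config@momentum,
                     seed = .taskSeed(config@seed, taskId(task)),
                     headMode = "single")
  trainSequence(list(task), cfg, baseChannels = baseChannels)$model
}
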