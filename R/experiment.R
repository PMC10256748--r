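# Experiment orchestration: configuration, the generation -> alignment ->
# training -> evaluation pipeline, persistence and provenance.
#
# Reports are written as plain CSV/JSON with full precision, so an
# idempotent re-run with the same configuration reproduces every
# deterministic report file bitwise.

#' Construct an ExperimentConfig
#'
#' @param specs list of [TaskSpec-class], or character paths to task
#'   directories written by [writeTaskDataset()]; a single preset name
#'   (see [taskPreset()]) is also accepted.
#' @param mappings named list of [LabelMapping-class] per task; empty means
#'   identity mappings derived from each task's scheme.
#' @param order task ids in training order; defaults to the declared order.
#' @param train a [TrainConfig-class].
#' @param outputDir output directory.
#' @param seed global seed (data generation; the training seed lives in
#'   `train`).
#' @param computeIndependent train per-task static reference models.
#' @return a validated [ExperimentConfig-class].
#' @export
experimentConfig <- function(specs, mappings = list(), order = NULL,
                             train = trainConfig(), outputDir = tempfile("contiseg_"),
                             seed = 1L, computeIndependent = FALSE) {
  if (is.character(specs) && length(specs) == 1L &&
      specs %in% c("highshift_pair", "noshift_pair", "three_site")) {
    if (!length(mappings)) mappings <- presetMappings(specs)
    specs <- taskPreset(specs)
  }
  if (is(specs, "TaskSpec")) specs <- list(specs)
  ids <- vapply(specs, function(s)
    if (is.character(s)) jsonlite::read_json(file.path(s, "manifest.json"))$task_id
    else taskId(s), character(1L))
  if (is.null(order)) order <- ids
  cfg <- new("ExperimentConfig", specs = specs, mappings = mappings,
             order = as.character(order), train = train,
             outputDir = outputDir, seed = as.integer(seed),
             computeIndependent = computeIndependent)
  if (!setequal(cfg@order, ids) || length(cfg@order) != length(ids))
    .stopUser("order must be a permutation of the declared task ids: ",
              paste(ids, collapse = ", "))
  cfg
}

# FNV-1a over a string, reported as hex; used to fingerprint configurations
.fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.configDigest <- function(config) {
  js <- jsonlite::toJSON(list(
    tasks = lapply(config@specs, function(s) {
      if (is.character(s)) list(dir = s)
      else list(task_id = s@taskId, n_cases = s@nCases,
                image_shape = s@imageShape, intensity_fg = s@intensityFg,
                intensity_bg = s@intensityBg, noise_sigma = s@noiseSigma,
                shape_family = s@shapeFamily, label_scheme = s@labelScheme,
                roi_fraction = s@roiFraction)
    }),
    mappings = lapply(config@mappings, function(m)
      as.list(stats::setNames(as.integer(m@map), names(m@map)))),
    order = config@order,
    train = list(method = config@train@method, epochs = config@train@epochs,
                 steps = config@train@stepsPerEpoch,
                 batch = config@train@batchSize,
                 lr = config@train@learningRate,
                 momentum = config@train@momentum, seed = config@train@seed,
                 params = config@train@methodParams,
                 head_mode = config@train@headMode,
                 freeze = config@train@freezeBodyAfterFirst),
    seed = config@seed), auto_unbox = TRUE, digits = NA)
  .fnv1a(as.character(js))
}

.writeNum <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a full continual-learning experiment
#'
#' Executes all stages in order: task generation (or loading), label
#' alignment, sequential training under the configured strategy, and final
#' evaluation. Persists aligned task manifests, per-stage checkpoints, the
#' training trajectory, the performance matrix, a final report and a
#' machine-readable provenance block into the output directory. A re-run
#' with the same configuration reproduces all deterministic report files
#' bitwise. Any stage failure aborts with the stage name; partial
#' provenance is kept.
#'
#' @param config an [ExperimentConfig-class].
#' @param writeCheckpoints persist per-stage model checkpoints.
#' @return an `ExperimentRecord` list: `model`, `perf`, `trajectory`,
#'   `summary`, `alignment`, `files`, `digest`.
#' @export
runExperiment <- function(config, writeCheckpoints = TRUE) {
  stopifnot(is(config, "ExperimentConfig"))
  out <- config@outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  digest <- .configDigest(config)
  prov <- list(config_digest = digest, seed = config@seed,
               train_seed = config@train@seed,
               package_version = as.character(utils::packageVersion("contiseg")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               stages_completed = character())
  .writeNum(prov, file.path(out, "provenance.json"))
  stageName <- "setup"
  fail <- function(e) {
    .writeNum(prov, file.path(out, "provenance.json"))
    .stopUser("experiment stage '", stageName, "' failed: ",
              conditionMessage(e))
  }
  tryCatch({
    stageName <- "generate"
    tasks <- list()
    for (s in config@specs) {
      ds <- if (is.character(s)) readTaskDataset(s)
            else generateTask(s, seed = .taskSeed(config@seed, taskId(s)))
      tasks[[taskId(ds)]] <- ds
    }
    tasks <- tasks[config@order]
    prov$stages_completed <- c(prov$stages_completed, "generate")

    stageName <- "align"
    mappings <- config@mappings
    if (!length(mappings)) {
      mappings <- lapply(tasks, function(ts)
        identityMapping(labelScheme(ts), name = taskId(ts)))
    }
    mappings <- mappings[config@order]
    report <- validateAlignment(tasks, mappings)
    .writeNum(list(pass = report$pass, target_set = report$targetSet,
                   failures = report$failures),
              file.path(out, "alignment_report.json"))
    if (!report$pass)
      stop(paste(report$failures, collapse = "; "))
    aligned <- mapply(alignDataset, tasks, mappings, SIMPLIFY = FALSE)
    for (id in names(aligned)) {
      ds <- aligned[[id]]
      .writeNum(list(task_id = id, label_scheme = labelScheme(ds),
                     image_shape = imageShape(ds),
                     split = list(
                       train = vapply(trainCases(ds), `[[`, character(1L), "caseId"),
                       test = vapply(testCases(ds), `[[`, character(1L), "caseId"))),
                file.path(out, paste0("task_", id, "_manifest.json")))
    }
    prov$stages_completed <- c(prov$stages_completed, "align")

    stageName <- "train"
    run <- trainSequence(aligned, config@train,
                         computeIndependent = config@computeIndependent)
    if (writeCheckpoints) {
      dir.create(file.path(out, "checkpoints"), showWarnings = FALSE)
      saveModel(run$model, file.path(out, "checkpoints", "final.rds"),
                provenance = list(order = config@order,
                                  method = config@train@method,
                                  seed = config@train@seed,
                                  digest = digest))
    }
    utils::write.csv(run$trajectory, file.path(out, "trajectory.csv"),
                     row.names = FALSE)
    prov$stages_completed <- c(prov$stages_completed, "train")

    stageName <- "evaluate"
    perf <- run$perf
    long <- expand.grid(stage = perf@order, task = perf@order,
                        class = seq_len(dim(perf@dice)[3L]),
                        stringsAsFactors = FALSE)
    long$dice <- mapply(function(s, t, cl) perf@dice[s, t, cl],
                        long$stage, long$task, long$class)
    utils::write.csv(long, file.path(out, "perf_matrix.csv"),
                     row.names = FALSE)
    finalReport <- evaluateFinal(run$model, aligned,
                                 headPolicy = if (config@train@headMode == "multi")
                                   "per-task" else "active")
    utils::write.csv(finalReport, file.path(out, "final_report.csv"),
                     row.names = FALSE)

    n <- length(config@order)
    summary <- list(order = config@order, method = config@train@method)
    summary$tasks <- lapply(seq_len(n), function(i) {
      x <- list(task = config@order[i],
                dice_at_training = .aggDice(perf, i, i),
                dice_final = .aggDice(perf, n, i),
                bwt = backwardTransfer(perf, i),
                bwt_relative_pct = suppressWarnings(
                  backwardTransfer(perf, i, relative = TRUE)))
      if (config@computeIndependent) {
        x$dice_independent <- mean(perf@independent[i, ])
        x$fwt <- forwardTransfer(perf, i)
        x$fwt_relative_pct <- suppressWarnings(
          forwardTransfer(perf, i, relative = TRUE))
      }
      x
    })
    .writeNum(summary, file.path(out, "summary.json"))
    prov$stages_completed <- c(prov$stages_completed, "evaluate")
    .writeNum(prov, file.path(out, "provenance.json"))

    structure(list(model = run$model, perf = perf,
                   trajectory = run$trajectory, summary = summary,
                   alignment = report, digest = digest,
                   files = list.files(out, recursive = TRUE, full.names = TRUE),
                   outputDir = out),
              class = "ExperimentRecord")
  }, error = fail)
}

#' @export
print.ExperimentRecord <- function(x, ...) {
  cat("ExperimentRecord (", x$summary$method, "), digest ", x$digest, "\n",
      sep = "")
  for (t in x$summary$tasks)
    cat(sprintf("  %s: final Dice %.3f (at-training %.3f, BWT %+.3f)\n",
                t$task, t$dice_final, t$dice_at_training, t$bwt))
  invisible(x)
}

#' Compare continual-learning methods on a shared task sequence
#'
#' Runs one experiment per configuration (all configurations must share
#' tasks and order and differ only in method/method parameters) and
#' tabulates per-task final Dice plus backward/forward transfer, one row
#' per method. The best value of each numeric column is flagged in the
#' `"best"` attribute.
#'
#' @param configs list of [ExperimentConfig-class].
#' @return data frame of class `MethodComparison`.
#' @export
compareMethods <- function(configs) {
  if (!length(configs)) .stopUser("no configurations given")
  orders <- lapply(configs, function(c) c@order)
  if (!all(vapply(orders[-1], identical, logical(1L), orders[[1L]])))
    .stopUser("all configurations must share the same tasks and order")
  rows <- lapply(configs, function(cfg) {
    rec <- runExperiment(cfg, writeCheckpoints = FALSE)
    row <- list(method = cfg@train@method)
    for (t in rec$summary$tasks) {
      row[[paste0("dice_", t$task)]] <- t$dice_final
      row[[paste0("bwt_", t$task)]] <- t$bwt
      if (!is.null(t$fwt)) row[[paste0("fwt_", t$task)]] <- t$fwt
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1L))
  best <- vapply(names(tab)[num], function(cl) which.max(tab[[cl]]), integer(1L))
  attr(tab, "best") <- best
  class(tab) <- c("MethodComparison", class(tab))
  tab
}

#' Read an experiment configuration from YAML or JSON
#'
#' Top-level keys: `seed`, `output_dir`, `order`, `compute_independent`,
#' `preset` (or `tasks`, a list of task spec blocks or `{dir: ...}`
#' entries), `mappings` (task id -> raw-to-target map), and `train`
#' (`method`, `epochs`, `steps_per_epoch`, `batch_size`, `learning_rate`,
#' `momentum`, `seed`, `head_mode`, `freeze_body_after_first`,
#' `method_params`).
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return an [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- cfg$train
  if (is.null(tr)) tr <- list()
  train <- trainConfig(
    method = if (!is.null(tr$method)) tr$method else "sequential",
    epochs = if (!is.null(tr$epochs)) tr$epochs else 10L,
    stepsPerEpoch = if (!is.null(tr$steps_per_epoch)) tr$steps_per_epoch else 20L,
    batchSize = if (!is.null(tr$batch_size)) tr$batch_size else 4L,
    learningRate = if (!is.null(tr$learning_rate)) tr$learning_rate else 0.05,
    momentum = if (!is.null(tr$momentum)) tr$momentum else 0.9,
    seed = if (!is.null(tr$seed)) tr$seed else 1L,
    methodParams = if (!is.null(tr$method_params)) as.list(tr$method_params) else list(),
    headMode = if (!is.null(tr$head_mode)) tr$head_mode else "single",
    freezeBodyAfterFirst = isTRUE(tr$freeze_body_after_first))
  specs <- if (!is.null(cfg$preset)) cfg$preset else {
    lapply(seq_along(cfg$tasks), function(i) {
      tk <- if (is.data.frame(cfg$tasks)) as.list(cfg$tasks[i, ]) else cfg$tasks[[i]]
      if (!is.null(tk$dir)) return(tk$dir)
      taskSpec(taskId = tk$task_id,
               nCases = if (!is.null(tk$n_cases)) tk$n_cases else 30L,
               imageShape = if (!is.null(tk$image_shape)) unlist(tk$image_shape) else c(64L, 64L),
               intensityFg = if (!is.null(tk$intensity_fg)) unlist(tk$intensity_fg) else c(0.75, 0.03),
               intensityBg = if (!is.null(tk$intensity_bg)) unlist(tk$intensity_bg) else c(0.25, 0.03),
               noiseSigma = if (!is.null(tk$noise_sigma)) tk$noise_sigma else 0.05,
               shapeFamily = if (!is.null(tk$shape_family)) tk$shape_family else "ellipsoid",
               labelScheme = if (!is.null(tk$label_scheme)) unlist(tk$label_scheme) else 1L,
               roiFraction = if (!is.null(tk$roi_fraction)) tk$roi_fraction else 0.1)
    })
  }
  mappings <- list()
  if (!is.null(cfg$mappings)) {
    mappings <- lapply(names(cfg$mappings), function(id)
      labelMapping(unlist(cfg$mappings[[id]]), name = id))
    names(mappings) <- names(cfg$mappings)
  }
  experimentConfig(specs, mappings = mappings, order = cfg$order,
                   train = train,
                   outputDir = if (!is.null(cfg$output_dir)) cfg$output_dir
                               else tempfile("contiseg_"),
                   seed = if (!is.null(cfg$seed)) cfg$seed else 1L,
                   computeIndependent = isTRUE(cfg$compute_independent))
}
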