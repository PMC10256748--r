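# Continual-learning evaluation: Dice, backward/forward transfer (absolute
# and relative), inter-task matrices and final-model reports.

#' Dice coefficient of one class
#'
#' `2|A n B| / (|A| + |B|)` for the voxel sets of class `class` in the
#' prediction and the truth. When both sets are empty the score is defined
#' as 1 (perfect agreement on absence); an empty prediction against a
#' nonempty truth scores 0.
#'
#' @param pred,truth integer arrays of identical shape.
#' @param class class label whose overlap is measured.
#' @return proportion in [0, 1].
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' diceScore(a, a, 1)
#' @export
diceScore <- function(pred, truth, class = 1L) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    .stopUser("prediction and truth must share the same shape")
  A <- as.vector(pred) == class
  B <- as.vector(truth) == class
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0L) return(1)
  2 * sum(A & B) / (sa + sb)
}

# per-class mean and sd of test-split Dice for one task
.taskClassDice <- function(model, task, headId = NULL) {
  arch <- model@archConfig
  classes <- seq_len(arch$nClasses - 1L)
  if (is.null(headId))
    headId <- if (taskId(task) %in% names(model@heads)) taskId(task)
              else model@activeHead
  per <- vapply(testCases(task), function(cs) {
    pred <- predictMask(model, cs$image, taskId = headId)
    vapply(classes, function(cl) diceScore(pred, cs$mask, cl), numeric(1L))
  }, numeric(length(classes)))
  per <- matrix(per, nrow = length(classes))
  list(mean = rowMeans(per),
       sd = apply(per, 1L, stats::sd),
       n = ncol(per))
}

.aggDice <- function(perf, stage, task) {
  v <- perf@dice[stage, task, ]
  if (all(is.na(v))) NA_real_ else mean(v)
}

.relGuard <- 1e-3

.transfer <- function(value, reference, relative) {
  d <- value - reference
  if (!relative) return(d)
  if (is.na(reference) || abs(reference) < .relGuard) {
    warning("relative transfer undefined: reference performance below ",
            .relGuard, call. = FALSE)
    return(NA_real_)
  }
  100 * d / reference
}

#' Backward transfer of task i
#'
#' Difference between the final model's performance on task i and its
#' performance right after training on task i finished:
#' `BWT_i = F_final(T_i) - F_at_i(T_i)`. Negative values mean forgetting;
#' positive values mean training on later tasks improved task i. The
#' relative form divides by the at-training performance and is reported as
#' a percentage; if the reference Dice is below 1e-3 the relative value is
#' undefined (NA with a warning).
#'
#' @param perf a [PerfMatrix-class].
#' @param i task index or id.
#' @param relative report the relative change in percent.
#' @param finalStage stage regarded as final (defaults to the last).
#' @return signed scalar.
#' @export
backwardTransfer <- function(perf, i, relative = FALSE,
                             finalStage = length(perf@order)) {
  stopifnot(is(perf, "PerfMatrix"))
  if (is.character(i)) i <- match(i, perf@order)
  atI <- .aggDice(perf, i, i)
  fin <- .aggDice(perf, finalStage, i)
  if (is.na(atI) || is.na(fin))
    .stopUser("performance matrix is missing entries (", i, ",", i, ") or (",
              finalStage, ",", i, ")")
  .transfer(fin, atI, relative)
}

#' Forward transfer of task i
#'
#' Difference between the continual model's performance on task i right
#' after its own stage and an independent model trained solely on task i
#' with the same architecture and budget:
#' `FWT_i = F_at_i(T_i) - F_indep_i(T_i)`. Negative values signal loss of
#' plasticity. Relative form and guards as in [backwardTransfer()].
#'
#' @inheritParams backwardTransfer
#' @return signed scalar.
#' @export
forwardTransfer <- function(perf, i, relative = FALSE) {
  stopifnot(is(perf, "PerfMatrix"))
  if (is.character(i)) i <- match(i, perf@order)
  atI <- .aggDice(perf, i, i)
  indep <- mean(perf@independent[i, ])
  if (is.na(atI) || is.na(indep))
    .stopUser("performance matrix is missing the continual entry (", i, ",",
              i, ") or the independent reference for task ", i)
  .transfer(atI, indep, relative)
}

#' Inter-task performance matrix
#'
#' Trains one independent model per task (fixed seeds derived from the
#' config seed and task ids) and evaluates each on every task's test
#' split. The diagonal is in-distribution performance; off-diagonal
#' entries show how each static model transfers to the other domains.
#'
#' @param tasks list of aligned [TaskDataset-class] (>= 1).
#' @param config a [TrainConfig-class]; its method is ignored (static
#'   training).
#' @param baseChannels network width.
#' @return matrix `[trained-on, evaluated-on]` of mean foreground Dice,
#'   with per-class values in the `"perClass"` attribute.
#' @export
interTaskMatrix <- function(tasks, config, baseChannels = 8L) {
  ids <- vapply(tasks, taskId, character(1L))
  models <- lapply(tasks, .independentModel, config = config,
                   baseChannels = baseChannels)
  nCls <- models[[1L]]@archConfig$nClasses
  per <- array(NA_real_, c(length(tasks), length(tasks), nCls - 1L),
               dimnames = list(trainedOn = ids, evaluatedOn = ids,
                               class = seq_len(nCls - 1L)))
  for (a in seq_along(tasks)) for (b in seq_along(tasks)) {
    per[a, b, ] <- .taskClassDice(models[[a]], tasks[[b]],
                                  headId = models[[a]]@activeHead)$mean
  }
  out <- apply(per, c(1L, 2L), mean)
  attr(out, "perClass") <- per
  out
}

#' Final-model evaluation report
#'
#' Per-task, per-class test Dice of the final model state, as mean and
#' standard deviation over test cases (the std is over cases). In
#' multi-head mode the head matching each task is selected; a missing head
#' is an error unless `headPolicy = "active"`.
#'
#' @param model a trained [SegModel-class].
#' @param tasks list of aligned [TaskDataset-class].
#' @param headPolicy `"per-task"` (select each task's head) or `"active"`
#'   (always use the active head).
#' @return data frame with columns task, class, diceMean, diceSd, nCases.
#' @export
evaluateFinal <- function(model, tasks, headPolicy = c("per-task", "active")) {
  headPolicy <- match.arg(headPolicy)
  rows <- lapply(tasks, function(ts) {
    hid <- if (headPolicy == "active") model@activeHead else taskId(ts)
    if (headPolicy == "per-task" && length(model@heads) > 1L &&
        !hid %in% names(model@heads))
      .stopUser("no head stored for task '", hid, "'")
    if (!hid %in% names(model@heads)) hid <- model@activeHead
    d <- .taskClassDice(model, ts, headId = hid)
    data.frame(task = taskId(ts),
               class = seq_along(d$mean),
               diceMean = d$mean, diceSd = d$sd, nCases = d$n)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
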