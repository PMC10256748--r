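# Importance-based regularization: diagonal Fisher information (EWC) and
# the online Fisher + path-integral score (RW). Both feed the same
# quadratic penalty on divergence from per-task parameter anchors.

#' Diagonal empirical Fisher information from a gradient function
#'
#' Accumulates `mean_i w_i * g(case_i)^2` over cases, the diagonal of the
#' (empirical) Fisher information matrix. With unit weights and one case
#' per observed label this is the classical empirical Fisher; supplying one
#' case per possible label weighted by the model's own label probabilities
#' yields the exact expectation over the model distribution.
#'
#' @param gradFn function(case) returning a named list (or plain vector) of
#'   gradients of the per-case log-likelihood.
#' @param cases list of cases passed to `gradFn`.
#' @param weights optional nonnegative case weights; they are normalized to
#'   sum to the number of distinct unweighted observations only if you do
#'   so yourself -- the accumulator uses them as given and divides by their
#'   total.
#' @return gradients-shaped object of nonnegative importance values.
#' @export
empiricalFisher <- function(gradFn, cases, weights = NULL) {
  if (!length(cases)) .stopUser("empirical Fisher needs at least one case")
  if (is.null(weights)) weights <- rep(1, length(cases))
  if (length(weights) != length(cases) || any(weights < 0))
    .stopUser("weights must be nonnegative, one per case")
  acc <- NULL
  for (i in seq_along(cases)) {
    g <- gradFn(cases[[i]])
    sq <- if (is.list(g)) lapply(g, function(x) x^2) else g^2
    acc <- if (is.null(acc)) {
      if (is.list(sq)) lapply(sq, `*`, weights[i]) else sq * weights[i]
    } else if (is.list(sq)) {
      mapply(function(a, b) a + weights[i] * b, acc, sq, SIMPLIFY = FALSE)
    } else acc + weights[i] * sq
  }
  tot <- sum(weights)
  if (is.list(acc)) lapply(acc, `/`, tot) else acc / tot
}

#' Fisher importance of a trained segmentation model
#'
#' Empirical diagonal Fisher over sampled training cases: the gradient of
#' the log-likelihood of the model's own hard-predicted label map (the
#' one-hot prediction), squared and averaged. Elementwise nonnegative by
#' construction.
#'
#' @param model a trained [SegModel-class].
#' @param task the [TaskDataset-class] it was trained on.
#' @param nSamples number of train-split cases to use (at most `|train|`).
#' @param seed sampling seed.
#' @return named list of importance arrays congruent with
#'   `c(body, active head)` parameters.
#' @export
computeFisher <- function(model, task, nSamples = 10L, seed = 1L) {
  stopifnot(is(model, "SegModel"), is(task, "TaskDataset"))
  tr <- trainCases(task)
  if (!length(tr)) .stopUser("empty sample set: task has no train cases")
  nSamples <- min(as.integer(nSamples), length(tr))
  if (nSamples < 1L) .stopUser("nSamples must be >= 1")
  pick <- withSeed(seed, sort(sample.int(length(tr), nSamples)))
  arch <- model@archConfig
  geom <- .getGeometry(arch$imageShape)
  head <- model@heads[[model@activeHead]]
  gradFn <- function(cs) {
    x <- .caseInput(cs$image, arch)
    bf <- bodyForward(model@body, x, geom)
    Z <- headForward(head, bf$feat)
    P <- softmaxRows(Z)
    yhat <- max.col(Z, ties.method = "first")     # model's own prediction
    V <- nrow(Z)
    Tm <- matrix(0, V, arch$nClasses)
    Tm[cbind(seq_len(V), yhat)] <- 1
    dZ <- P - Tm                 # gradient of -sum_v log p(yhat_v)
    hb <- headBackward(head, bf$feat, dZ)
    c(bodyBackward(model@body, bf$cache, hb$dFeat), hb$grads)
  }
  empiricalFisher(gradFn, tr[pick])
}

#' Quadratic parameter-anchoring penalty
#'
#' `(lambda / 2) * sum_t sum_k omega_tk (theta_k - theta*_tk)^2`, summed
#' over all completed tasks' anchors in the store. Only parameter names
#' present in both `params` and an anchor contribute.
#'
#' @param params named list of current parameter values.
#' @param store an [ImportanceStore-class].
#' @param lambda penalty weight (>= 0).
#' @return scalar penalty value.
#' @export
ewcPenalty <- function(params, store, lambda) {
  stopifnot(is(store, "ImportanceStore"))
  if (lambda == 0 || !length(store@tasks)) return(0)
  total <- 0
  for (tk in store@tasks) {
    for (nm in intersect(names(params), names(tk$anchor))) {
      if (!identical(dim(params[[nm]]), dim(tk$anchor[[nm]])) ||
          length(params[[nm]]) != length(tk$anchor[[nm]]))
        .stopUser("shape mismatch between parameters and anchor '", nm, "'")
      total <- total + sum(tk$omega[[nm]] * (params[[nm]] - tk$anchor[[nm]])^2)
    }
  }
  lambda / 2 * total
}

#' One online importance update for the Riemannian walk
#'
#' Called after every optimization step. The running Fisher is an
#' exponential moving average of squared gradients,
#' `F <- alpha * g^2 + (1 - alpha) * F`; the path score accumulates the
#' loss decrease attributed to each parameter's motion, normalized by the
#' Riemannian path length and clipped at zero:
#' `s <- s + max(0, -g * dtheta) / (F * dtheta^2 / 2 + xi)`.
#' The total importance used in the quadratic penalty is `omega = F + s`.
#'
#' @param state list with elements `F` and `s` (or NULL to initialize).
#' @param gradients named list of this step's gradients.
#' @param paramsBefore,paramsAfter parameter values around the update.
#' @param alpha EMA coefficient in [0, 1].
#' @param xi damping constant of the path normalization.
#' @return the updated state.
#' @export
rwUpdate <- function(state, gradients, paramsBefore, paramsAfter,
                     alpha = 0.9, xi = 1e-3) {
  if (alpha < 0 || alpha > 1) .stopUser("alpha must lie in [0, 1]")
  if (is.null(state))
    state <- list(F = lapply(gradients, function(g) g * 0),
                  s = lapply(gradients, function(g) g * 0))
  for (nm in names(gradients)) {
    g <- gradients[[nm]]
    Fnew <- alpha * g^2 + (1 - alpha) * state$F[[nm]]
    state$F[[nm]] <- Fnew
    dtheta <- paramsAfter[[nm]] - paramsBefore[[nm]]
    inc <- pmax(0, -g * dtheta) / (Fnew * dtheta^2 / 2 + xi)
    state$s[[nm]] <- state$s[[nm]] + inc
  }
  state
}

.rwOmega <- function(state) {
  mapply(function(f, s) f + s, state$F, state$s, SIMPLIFY = FALSE)
}

.storeAdd <- function(store, taskId, anchor, omega) {
  store@tasks[[taskId]] <- list(anchor = anchor, omega = omega)
  store
}
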