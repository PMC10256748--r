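# Knowledge-distillation losses: temperature-scaled distillation (LwF) and
# the background-modelling segmentation loss (MiB) whose teacher
# probabilities are hardened before distillation.

#' Temperature-scaled knowledge-distillation loss
#'
#' Cross-entropy between teacher and student softened distributions,
#' `-T^2 * mean_v sum_c q_vc log p_vc` with `p = softmax(z_student / T)`
#' and `q` the teacher's temperature-T probabilities. The `T^2` factor
#' keeps gradient magnitudes comparable across temperatures; at `T = 1`
#' this is the plain cross-entropy between teacher and student softmax
#' outputs.
#'
#' @param studentLogits matrix (voxels x classes).
#' @param teacherProbs teacher probabilities at the same temperature
#'   (voxels x classes).
#' @param temperature distillation temperature T > 0.
#' @return list with `loss` and `dZ`, the gradient with respect to the
#'   student logits.
#' @export
kdLoss <- function(studentLogits, teacherProbs, temperature = 1) {
  if (temperature <= 0) .stopUser("temperature must be > 0")
  V <- nrow(studentLogits)
  P <- softmaxRows(studentLogits / temperature)
  loss <- -temperature^2 * mean(rowSums(teacherProbs * log(pmax(P, 1e-12))))
  dZ <- temperature * (P - teacherProbs) / V
  list(loss = loss, dZ = dZ)
}

#' Harden a probability vector
#'
#' Raises probabilities to the power `1/alpha` and renormalizes:
#' `p^(1/alpha) / sum(p^(1/alpha))`. With `alpha = 1` this is the identity;
#' `alpha < 1` sharpens the distribution towards its mode ("hardifies" the
#' teacher's soft labels).
#'
#' @param probs numeric vector or matrix of probabilities (rows sum to 1).
#' @param alpha hardening exponent parameter, > 0.
#' @return object of the same shape with renormalized rows.
#' @export
hardenProbs <- function(probs, alpha) {
  if (alpha <= 0) .stopUser("alpha must be > 0")
  if (is.matrix(probs)) {
    h <- probs^(1 / alpha)
    h / rowSums(h)
  } else {
    h <- probs^(1 / alpha)
    h / sum(h)
  }
}

#' Background-modelling loss components
#'
#' Returns the two terms of the background-modelling segmentation loss: a
#' modified (unbiased) cross-entropy and a distillation term against the
#' previous network's hardened soft outputs.
#'
#' The unbiased cross-entropy aggregates, for voxels labelled background,
#' the probability mass of background plus any classes *not* present in the
#' previous task's label set. The implementation is literal so the code
#' path generalizes; in the domain-incremental regime used throughout this
#' package the label set is identical across tasks, so the set of novel
#' classes is empty and the term reduces exactly to the standard
#' cross-entropy.
#'
#' @param studentLogits matrix (voxels x classes).
#' @param targets integer vector of 0-based class labels per voxel.
#' @param teacherLogits previous network's logits (voxels x classes), or
#'   NULL for the first stage (then `kd = 0`).
#' @param alpha hardening parameter in (0, 1]; the teacher's probabilities
#'   are raised to `1/alpha` and renormalized before distillation.
#' @param newClasses 0-based indices of classes that did not exist for the
#'   teacher (empty in the domain-incremental regime).
#' @return list with scalar `ce` and `kd` terms, plus gradients `dZce`,
#'   `dZkd` with respect to the student logits.
#' @export
mibLosses <- function(studentLogits, targets, teacherLogits = NULL,
                      alpha = 0.9, newClasses = integer()) {
  if (alpha <= 0) .stopUser("alpha must be > 0")
  V <- nrow(studentLogits)
  K <- ncol(studentLogits)
  P <- softmaxRows(studentLogits)
  ti <- cbind(seq_len(V), targets + 1L)

  if (length(newClasses)) {
    # q(bg) absorbs the novel classes for background-labelled voxels
    absorb <- c(1L, newClasses + 1L)
    pEff <- P[ti]
    bg <- targets == 0L
    pEff[bg] <- rowSums(P[bg, absorb, drop = FALSE])
    ce <- -mean(log(pmax(pEff, 1e-12)))
    dZce <- P / V
    # d(-log sum_absorb p)/dz = p - indicator(absorb)*p/sum for bg voxels
    Tm <- matrix(0, V, K)
    Tm[ti[!bg, , drop = FALSE]] <- 1
    for (j in absorb) Tm[bg, j] <- P[bg, j] / pEff[bg]
    dZce <- (P - Tm) / V
  } else {
    ce <- -mean(log(pmax(P[ti], 1e-12)))
    Tm <- matrix(0, V, K)
    Tm[ti] <- 1
    dZce <- (P - Tm) / V
  }

  if (is.null(teacherLogits)) {
    kd <- 0
    dZkd <- studentLogits * 0
  } else {
    q <- hardenProbs(softmaxRows(teacherLogits), alpha)
    kd <- -mean(rowSums(q * log(pmax(P, 1e-12))))
    dZkd <- (P - q) / V
  }
  list(ce = ce, kd = kd, dZce = dZce, dZkd = dZkd)
}
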