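# The compact U-Net-style network: three resolution levels, one 3^d
# convolution per level on both paths, instance normalization and leaky
# activations, average-pool down / nearest-neighbour up, additive skip
# concatenation, and a final 1x1 per-class projection ("seg_head").
#
# Parameters are a flat named list of numeric matrices/vectors. Everything
# whose name starts with the head prefix (default "seg_head") belongs to a
# task head; the rest is the shared body.

.channelPlan <- function(base, dims) {
  cin <- 1L
  c1 <- base; c2 <- 2L * base; c3 <- 4L * base
  list(cin = cin, c1 = c1, c2 = c2, c3 = c3,
       K = 3L^dims,
       enc1 = c(cin, c1), enc2 = c(c1, c2), bott = c(c2, c3),
       dec2 = c(c3 + c2, c2), dec1 = c(c2 + c1, c1))
}

.initConv <- function(cinK, cout) {
  matrix(stats::rnorm(cinK * cout, sd = sqrt(2 / cinK)), cinK, cout)
}

#' Initialize body parameters
#' @keywords internal
initBodyParams <- function(baseChannels, dims) {
  cp <- .channelPlan(baseChannels, dims)
  K <- cp$K
  p <- list()
  for (blk in c("enc1", "enc2", "bott", "dec2", "dec1")) {
    io <- cp[[blk]]
    p[[paste0(blk, ".conv.W")]] <- .initConv(K * io[1L], io[2L])
    p[[paste0(blk, ".conv.b")]] <- numeric(io[2L])
    p[[paste0(blk, ".norm.g")]] <- rep(1, io[2L])
    p[[paste0(blk, ".norm.b")]] <- numeric(io[2L])
  }
  p
}

#' Initialize head parameters (1x1 projection to class scores)
#' @keywords internal
initHeadParams <- function(baseChannels, nClasses) {
  list("seg_head.W" = matrix(stats::rnorm(baseChannels * nClasses,
                                          sd = sqrt(2 / baseChannels)),
                             baseChannels, nClasses),
       "seg_head.b" = numeric(nClasses))
}

.convBlockF <- function(X, p, blk, g) {
  cv <- convForward(X, p[[paste0(blk, ".conv.W")]], p[[paste0(blk, ".conv.b")]], g)
  nm <- cpp_inorm_lrelu_f(cv$Y, p[[paste0(blk, ".norm.g")]],
                          p[[paste0(blk, ".norm.b")]], .inormEps)
  list(Y = nm$Y, cols = cv$cols, Xhat = nm$Xhat, inv = nm$inv)
}

.convBlockB <- function(dY, cache, p, blk, g, Cin) {
  nb <- cpp_inorm_lrelu_b(dY, cache$Y, cache$Xhat, cache$inv,
                          p[[paste0(blk, ".norm.g")]])
  cb <- convBackward(nb$dX, cache$cols, p[[paste0(blk, ".conv.W")]], g, Cin)
  grads <- list(cb$dW, cb$db, nb$dGamma, nb$dBeta)
  names(grads) <- paste0(blk, c(".conv.W", ".conv.b", ".norm.g", ".norm.b"))
  list(dX = cb$dX, grads = grads)
}

#' Body forward pass
#'
#' @param params named list of body parameters
#' @param x numeric matrix (n_voxels, 1), voxels in column-major order
#' @param geom geometry from [buildGeometry()]
#' @return list with `feat` (n_voxels, base_channels) and a cache for backward
#' @keywords internal
bodyForward <- function(params, x, geom) {
  g1 <- geom$conv[[1L]]; g2 <- geom$conv[[2L]]; g3 <- geom$conv[[3L]]
  p1 <- geom$pool[[1L]]; p2 <- geom$pool[[2L]]
  e1 <- .convBlockF(x, params, "enc1", g1)
  d1 <- poolForward(e1$Y, p1)
  e2 <- .convBlockF(d1, params, "enc2", g2)
  d2 <- poolForward(e2$Y, p2)
  bt <- .convBlockF(d2, params, "bott", g3)
  u2 <- upForward(bt$Y, p2)
  c2 <- cbind(u2, e2$Y)
  o2 <- .convBlockF(c2, params, "dec2", g2)
  u1 <- upForward(o2$Y, p1)
  c1 <- cbind(u1, e1$Y)
  o1 <- .convBlockF(c1, params, "dec1", g1)
  list(feat = o1$Y,
       cache = list(e1 = e1, e2 = e2, bt = bt, o2 = o2, o1 = o1, geom = geom))
}

#' Body backward pass
#' @param dFeat gradient at the body output features
#' @return named list of body-parameter gradients
#' @keywords internal
bodyBackward <- function(params, cache, dFeat) {
  geom <- cache$geom
  g1 <- geom$conv[[1L]]; g2 <- geom$conv[[2L]]; g3 <- geom$conv[[3L]]
  p1 <- geom$pool[[1L]]; p2 <- geom$pool[[2L]]
  cp <- ncol(cache$e1$Y)            # base channels
  c2w <- ncol(cache$e2$Y)           # 2 * base
  c3w <- ncol(cache$bt$Y)           # 4 * base

  b1 <- .convBlockB(dFeat, cache$o1, params, "dec1", g1, c2w + cp)
  dU1 <- b1$dX[, seq_len(c2w), drop = FALSE]
  dE1skip <- b1$dX[, c2w + seq_len(cp), drop = FALSE]
  dO2 <- upBackward(dU1, p1)

  b2 <- .convBlockB(dO2, cache$o2, params, "dec2", g2, c3w + c2w)
  dU2 <- b2$dX[, seq_len(c3w), drop = FALSE]
  dE2skip <- b2$dX[, c3w + seq_len(c2w), drop = FALSE]
  dBt <- upBackward(dU2, p2)

  b3 <- .convBlockB(dBt, cache$bt, params, "bott", g3, c2w)
  dD2 <- b3$dX
  dE2 <- poolBackward(dD2, p2) + dE2skip

  b4 <- .convBlockB(dE2, cache$e2, params, "enc2", g2, cp)
  dD1 <- b4$dX
  dE1 <- poolBackward(dD1, p1) + dE1skip

  b5 <- .convBlockB(dE1, cache$e1, params, "enc1", g1, 1L)
  c(b5$grads, b4$grads, b3$grads, b2$grads, b1$grads)
}

headForward <- function(head, feat) {
  sweep(feat %*% head[["seg_head.W"]], 2L, head[["seg_head.b"]], `+`)
}

headBackward <- function(head, feat, dZ) {
  list(grads = list("seg_head.W" = crossprod(feat, dZ),
                    "seg_head.b" = colSums(dZ)),
       dFeat = dZ %*% t(head[["seg_head.W"]]))
}

# elementwise helpers over named parameter lists
paramZero <- function(params) lapply(params, function(p) p * 0)

paramAxpy <- function(a, x, y) {   # y + a*x, matched by name over names(x)
  for (nm in names(x)) y[[nm]] <- y[[nm]] + a * x[[nm]]
  y
}

paramScale <- function(x, a) lapply(x, function(p) p * a)

#' One SGD-with-momentum update restricted to `trainable` parameter names.
#' @keywords internal
sgdStep <- function(params, grads, velocity, lr, momentum, trainable) {
  for (nm in trainable) {
    v <- momentum * velocity[[nm]] + grads[[nm]]
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, velocity = velocity)
}
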