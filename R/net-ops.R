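# Low-level numeric primitives for the compact encoder-decoder network.
#
# Images live as matrices of shape (n_voxels, n_channels), voxels in
# column-major order of the spatial array. All spatial bookkeeping is
# precomputed once per image shape as integer index tables ("geometry"),
# so convolution, pooling and upsampling reduce to indexing + BLAS matmul.
# Adjoints are expressed as gathers (never scatters): the convolution
# input-gradient is an im2col of the output gradient against the flipped
# kernel, and average-pool / nearest-upsample are each other's transpose
# up to a constant.

#' @keywords internal
.linIndex <- function(coords, shape) {
  # coords: matrix (n, d) of 1-based coordinates; column-major linear index
  stride <- cumprod(c(1L, shape[-length(shape)]))
  as.integer(1 + as.vector((coords - 1) %*% stride))
}

# Neighbourhood (3^d) index table into a zero-padded copy of the image.
.convIndex <- function(shape) {
  d <- length(shape)
  padded <- shape + 2L
  inner <- as.matrix(do.call(expand.grid, lapply(shape, seq_len)))
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  K <- nrow(offsets)
  idx <- matrix(0L, nrow(inner), K)
  for (k in seq_len(K)) {
    nb <- sweep(inner + 1L, 2L, -offsets[k, ]) # inner+1 centers in padded frame
    idx[, k] <- .linIndex(nb, padded)
  }
  list(idxv = as.vector(idx), inner = .linIndex(inner + 1L, padded),
       nPad = prod(padded), K = K, V = nrow(inner))
}

# 2^d children of each coarse voxel (average pooling) and the parent of
# each fine voxel (nearest upsampling).
.poolIndex <- function(shape) {
  d <- length(shape)
  coarse <- shape %/% 2L
  cg <- as.matrix(do.call(expand.grid, lapply(coarse, seq_len)))
  offs <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  P <- matrix(0L, nrow(cg), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    P[, k] <- .linIndex(sweep(2L * cg - 1L, 2L, -offs[k, ]), shape)
  }
  fine <- as.matrix(do.call(expand.grid, lapply(shape, seq_len)))
  U <- .linIndex((fine + 1L) %/% 2L, coarse)
  list(P = P, U = U)
}

#' Precompute index tables for one image shape
#'
#' The network has three resolution levels, so every spatial extent must be
#' divisible by 4 and at least 4 voxels.
#' @keywords internal
buildGeometry <- function(shape) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L))
    stop("image shape must have 2 or 3 dimensions")
  if (any(shape < 4L) || any(shape %% 4L != 0L))
    stop("each spatial extent must be a multiple of 4 and >= 4, got [",
         paste(shape, collapse = ", "), "]")
  s1 <- shape; s2 <- s1 %/% 2L; s3 <- s2 %/% 2L
  list(shape = shape, dims = length(shape),
       conv = list(.convIndex(s1), .convIndex(s2), .convIndex(s3)),
       pool = list(.poolIndex(s1), .poolIndex(s2)),
       nVox = c(prod(s1), prod(s2), prod(s3)))
}

# ---- convolution (3^d kernel, zero padding, stride 1) ----

# X: (V, Cin) -> (V, K*Cin), columns ordered offset-fastest within channel
.im2col <- function(X, g) cpp_im2col(X, g$idxv, g$inner, g$nPad)

convForward <- function(X, W, b, g) {
  cols <- .im2col(X, g)
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, cols = cols)
}

# Cache of kernel-flip permutations, keyed by (K, Cin, Cout). Entry p maps
# Wflip[(k, cout), cin] = W[(flip(k), cin), cout]; the symmetric offset grid
# makes flip(k) = K + 1 - k.
.flipCache <- new.env(parent = emptyenv())

.flipPerm <- function(K, Cin, Cout) {
  key <- paste(K, Cin, Cout, sep = "x")
  p <- .flipCache[[key]]
  if (is.null(p)) {
    k <- rep(seq_len(K), times = Cout * Cin)
    co <- rep(rep(seq_len(Cout), each = K), times = Cin)
    ci <- rep(seq_len(Cin), each = K * Cout)
    p <- (co - 1L) * (K * Cin) + (ci - 1L) * K + (K + 1L - k)
    .flipCache[[key]] <- p
  }
  p
}

convBackward <- function(dY, cols, W, g, Cin) {
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  Cout <- ncol(dY)
  Wflip <- matrix(W[.flipPerm(g$K, Cin, Cout)], g$K * Cout, Cin)
  dX <- .im2col(dY, g) %*% Wflip
  list(dX = dX, dW = dW, db = db)
}

# ---- 2x average pooling / nearest-neighbour upsampling ----

poolForward <- function(X, p) {
  K <- ncol(p$P)
  Y <- X[p$P[, 1L], , drop = FALSE]
  for (k in 2:K) Y <- Y + X[p$P[, k], , drop = FALSE]
  Y / K
}

# adjoint of average pooling = replicate to children / K
poolBackward <- function(dY, p) dY[p$U, , drop = FALSE] / ncol(p$P)

upForward <- function(X, p) X[p$U, , drop = FALSE]

# adjoint of nearest upsampling = sum over children
upBackward <- function(dY, p) {
  K <- ncol(p$P)
  Y <- dY[p$P[, 1L], , drop = FALSE]
  for (k in 2:K) Y <- Y + dY[p$P[, k], , drop = FALSE]
  Y
}

# ---- instance normalization (per-channel, per-image) ----

.inormEps <- 1e-5

inormForward <- function(X, gamma, beta) {
  N <- nrow(X)
  m <- colMeans(X)
  Xc <- X - rep(m, each = N)
  v <- colMeans(Xc^2)
  inv <- 1 / sqrt(v + .inormEps)
  Xhat <- Xc * rep(inv, each = N)
  Y <- Xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(Y = Y, Xhat = Xhat, inv = inv)
}

inormBackward <- function(dY, cache, gamma) {
  Xhat <- cache$Xhat
  N <- nrow(Xhat)
  dXhat <- dY * rep(gamma, each = N)
  s1 <- colSums(dXhat) / N
  s2 <- colSums(dXhat * Xhat) / N
  dX <- (dXhat - rep(s1, each = N) - Xhat * rep(s2, each = N)) *
    rep(cache$inv, each = N)
  list(dX = dX, dGamma = colSums(dY * Xhat), dBeta = colSums(dY))
}

# ---- leaky ReLU (slope 0.01) ----

lreluForward <- function(X) {
  mult <- 0.01 + 0.99 * (X > 0)
  list(Y = X * mult, mult = mult)
}

lreluBackward <- function(dY, mult) dY * mult

# ---- softmax / losses ----

softmaxRows <- function(Z) {
  m <- Z[, 1L]
  for (k in seq_len(ncol(Z))[-1L]) m <- pmax(m, Z[, k])
  E <- exp(Z - m)
  E / rowSums(E)
}

# Composite segmentation loss: voxel-wise cross-entropy plus soft Dice over
# foreground classes. `target` is an integer vector of class ids (0-based).
# Returns the loss value and its gradient with respect to the logits.
segLoss <- function(Z, target, nClasses, diceSmooth = 1e-5) {
  V <- nrow(Z)
  P <- softmaxRows(Z)
  ti <- cbind(seq_len(V), target + 1L)
  ce <- -mean(log(pmax(P[ti], 1e-12)))
  Tm <- matrix(0, V, nClasses)
  Tm[ti] <- 1
  dZ <- (P - Tm) / V

  fg <- seq_len(nClasses - 1L) + 1L       # columns of foreground classes
  diceLoss <- 0
  dP <- matrix(0, V, nClasses)
  for (c in fg) {
    num <- 2 * sum(P[, c] * Tm[, c]) + diceSmooth
    den <- sum(P[, c]) + sum(Tm[, c]) + diceSmooth
    diceLoss <- diceLoss + (1 - num / den)
    dP[, c] <- -(2 * Tm[, c] * den - num) / den^2
  }
  nFg <- length(fg)
  diceLoss <- diceLoss / nFg
  dP <- dP / nFg
  # back through softmax: dZ += P * (dP - rowSums(dP * P))
  dZ <- dZ + P * (dP - rowSums(dP * P))
  list(loss = ce + diceLoss, ce = ce, dice = diceLoss, dZ = dZ)
}
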