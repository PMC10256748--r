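# Seeded generator of domain-shifted synthetic segmentation tasks.
#
# Each task stands in for one acquisition site: cases share anatomy (a
# parametric foreground shape) while intensity statistics, noise and label
# scheme differ between tasks. The intensity model is piecewise-constant
# class means + a smooth multiplicative bias field + additive Gaussian
# noise -- a minimal model of scanner shift.

.familyLabelsNeeded <- c(ellipsoid = 1L, bilobed = 2L, ring = 1L)

.unitVector <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

.randomRotation <- function(d) {
  if (d == 2L) {
    th <- stats::runif(1L, 0, pi)
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  } else {
    qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  }
}

# coords: (V, d) voxel coordinates; returns logical vector of voxels inside
# the rotated ellipsoid (or between radii fractions for a shell).
.insideEllipsoid <- function(coords, center, radii, rot, innerFrac = 0) {
  q <- sweep(coords, 2L, center) %*% rot
  r2 <- rowSums(sweep(q, 2L, radii, `/`)^2)
  if (innerFrac > 0) r2 <= 1 & r2 >= innerFrac^2 else r2 <= 1
}

.baseRadius <- function(targetVox, d) {
  if (d == 2L) sqrt(targetVox / pi) else (targetVox * 3 / (4 * pi))^(1 / 3)
}

.drawCenter <- function(shape, maxRadius, what) {
  margin <- maxRadius + 1
  lo <- rep(1 + margin, length(shape))
  hi <- shape - margin
  if (any(hi <= lo))
    .stopUser("shape parameters incompatible with image shape: ", what,
              " of radius ", format(round(maxRadius, 1)),
              " cannot fit inside [", paste(shape, collapse = " x "), "]")
  vapply(seq_along(shape), function(j) stats::runif(1L, lo[j], hi[j]),
         numeric(1L))
}

# Renders the mask of one case; draws all its random parameters from the
# current RNG stream.
.renderMask <- function(spec) {
  shape <- spec@imageShape
  d <- length(shape)
  V <- prod(shape)
  coords <- as.matrix(do.call(expand.grid, lapply(shape, seq_len)))
  mask <- integer(V)
  sp <- spec@shapeParams
  eccRange <- if (!is.null(sp$eccentricityRange)) sp$eccentricityRange else c(0.8, 1.25)
  jitter <- if (!is.null(sp$sizeJitter)) sp$sizeJitter else 0.15

  targetVox <- spec@roiFraction * V
  scale <- stats::runif(1L, 1 - jitter, 1 + jitter)
  labels <- spec@labelScheme
  need <- .familyLabelsNeeded[[spec@shapeFamily]]

  placeEllipsoid <- function(vox, label, innerFrac = 0, centerOffset = NULL,
                             refCenter = NULL, what = "structure") {
    r <- .baseRadius(vox, d)
    ecc <- exp(stats::runif(d, log(eccRange[1L]), log(eccRange[2L])))
    ecc <- ecc / prod(ecc)^(1 / d)            # volume-preserving eccentricity
    radii <- r * ecc
    rot <- .randomRotation(d)
    center <- if (is.null(refCenter)) .drawCenter(shape, max(radii), what)
              else refCenter + centerOffset
    inside <- .insideEllipsoid(coords, center, radii, rot, innerFrac)
    mask[inside] <<- label
    list(center = center, radius = r)
  }

  if (spec@shapeFamily == "ellipsoid") {
    placeEllipsoid(targetVox * scale, labels[1L], what = "ellipsoid ROI")
  } else if (spec@shapeFamily == "bilobed") {
    # two overlapping lobes (e.g. head/body of a bilobed structure)
    lobeVox <- 0.62 * targetVox * scale
    rl <- .baseRadius(lobeVox, d)
    dirv <- .unitVector(d)
    main <- placeEllipsoid(lobeVox, labels[1L], what = "bilobed ROI")
    placeEllipsoid(lobeVox, labels[2L], refCenter = main$center,
                   centerOffset = dirv * 1.1 * rl)
  } else {                                     # ring: annular shell
    innerFrac <- 0.55
    shellVox <- targetVox * scale / (1 - innerFrac^d)
    placeEllipsoid(shellVox, labels[1L], innerFrac = innerFrac,
                   what = "ring ROI")
  }

  extras <- labels[-seq_len(need)]
  for (lb in extras) {
    # small irrelevant structure (e.g. an adjacent organ) with its own label
    placeEllipsoid(0.2 * targetVox, lb, what = "distractor")
  }

  dim(mask) <- shape
  if (!any(mask == labels[1L]))
    .stopUser("generated ROI for task '", spec@taskId,
              "' is empty; roiFraction too small for this image shape")
  mask
}

.renderImage <- function(spec, mask) {
  shape <- spec@imageShape
  V <- prod(shape)
  sp <- spec@shapeParams
  amp <- if (!is.null(sp$biasFieldAmplitude)) sp$biasFieldAmplitude else 0.15
  fgMean <- stats::rnorm(1L, spec@intensityFg[1L], spec@intensityFg[2L])
  bgMean <- stats::rnorm(1L, spec@intensityBg[1L], spec@intensityBg[2L])
  img <- rep(bgMean, V)
  img[as.vector(mask) > 0L] <- fgMean

  # smooth multiplicative bias field: first-order polynomial in centered
  # normalized coordinates plus pairwise interactions
  u <- lapply(seq_along(shape), function(j) {
    g <- (seq_len(shape[j]) - 0.5) / shape[j] - 0.5
    a <- array(0, dim = shape)
    a[] <- g[slice.index(a, j)]
    a
  })
  field <- array(1, dim = shape)
  for (j in seq_along(u)) field <- field + stats::runif(1L, -amp, amp) * u[[j]]
  if (length(u) > 1L) {
    for (j in seq_len(length(u) - 1L)) for (k in seq((j + 1L), length(u))) {
      field <- field + stats::runif(1L, -amp, amp) * u[[j]] * u[[k]]
    }
  }
  img <- img * as.vector(field) + stats::rnorm(V, 0, spec@noiseSigma)
  dim(img) <- shape
  img
}

#' Generate one synthetic task
#'
#' Deterministic for a fixed `(spec, seed)`: two calls yield bitwise
#' identical datasets. Each case contains at least one foreground voxel and
#' the realized foreground fraction matches `roiFraction` up to the
#' generator's size jitter. A 20% test split (rounded half away from zero)
#' is drawn and stored with the dataset.
#'
#' @param spec a [TaskSpec-class].
#' @param seed integer seed.
#' @param testFraction fraction of cases held out for testing.
#' @return a [TaskDataset-class].
#' @examples
#' ds <- generateTask(taskSpec("siteA", nCases = 5, imageShape = c(32, 32)), seed = 1)
#' ds
#' @export
generateTask <- function(spec, seed, testFraction = 0.2) {
  stopifnot(is(spec, "TaskSpec"))
  validObject(spec)
  cases <- withSeed(seed, {
    lapply(seq_len(spec@nCases), function(i) {
      mask <- .renderMask(spec)
      img <- .renderImage(spec, mask)
      list(caseId = sprintf("%s_%03d", spec@taskId, i),
           image = img, mask = mask)
    })
  })
  ds <- new("TaskDataset", spec = spec, cases = cases,
            trainIdx = seq_len(spec@nCases), testIdx = integer())
  makeSplit(ds, testFraction, seed = .mixSeed(seed, 999331L))
}

#' Generate an ordered sequence of tasks
#'
#' Per-task seeds are tied to `(seed, taskId)`, so permuting the specs
#' permutes the outputs with identical per-task content.
#'
#' @param specs list of [TaskSpec-class] with distinct task ids.
#' @param seed integer sequence seed.
#' @param testFraction per-task test fraction.
#' @return list of [TaskDataset-class] in the given order.
#' @export
generateSequence <- function(specs, seed, testFraction = 0.2) {
  ids <- vapply(specs, taskId, character(1L))
  if (anyDuplicated(ids))
    .stopUser("duplicate task ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  out <- lapply(specs, function(sp) {
    generateTask(sp, seed = .taskSeed(seed, taskId(sp)),
                 testFraction = testFraction)
  })
  names(out) <- ids
  out
}

#' Draw (or re-draw) a train/test split
#'
#' The test side gets `round(testFraction * nCases)` cases, rounding half
#' away from zero; the split is stored inside the dataset so it stays
#' identical across all experiments that use it.
#'
#' @param dataset a [TaskDataset-class].
#' @param testFraction proportion in (0, 1).
#' @param seed integer seed.
#' @return the dataset with a new split.
#' @export
makeSplit <- function(dataset, testFraction = 0.2, seed = 1L) {
  stopifnot(is(dataset, "TaskDataset"))
  if (testFraction <= 0 || testFraction >= 1)
    .stopUser("testFraction must lie strictly between 0 and 1")
  n <- length(dataset@cases)
  nTest <- as.integer(.roundHalfAway(testFraction * n))
  if (nTest < 1L || nTest >= n)
    .stopUser("split would leave an empty train or test side (n = ", n,
              ", testFraction = ", testFraction, ")")
  testIdx <- withSeed(seed, sort(sample.int(n, nTest)))
  dataset@testIdx <- testIdx
  dataset@trainIdx <- setdiff(seq_len(n), testIdx)
  validObject(dataset)
  dataset
}
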