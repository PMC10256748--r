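# SegModel construction and multi-head bookkeeping.
#
# The architecture configuration (depth, channels, dimensionality, number
# of classes, input shape) is fixed from the FIRST task and never changes;
# later tasks with a different image shape are resampled by the data path.

.headNames <- c("seg_head.W", "seg_head.b")

#' Build a segmentation model from the first task
#'
#' The number of classes is the aligned label count of the first task plus
#' background. Initialization is deterministic under `seed`.
#'
#' @param firstTask an aligned [TaskDataset-class].
#' @param baseChannels channel width of the first level (doubled per level).
#' @param seed initialization seed.
#' @param nClasses override the class count (background included); defaults
#'   to `max(labelScheme) + 1` of the first task.
#' @param splitPoint parameter-name prefix of the head.
#' @return a [SegModel-class] with one head keyed by the first task.
#' @export
buildModel <- function(firstTask, baseChannels = 8L, seed = 1L,
                       nClasses = NULL, splitPoint = "seg_head") {
  stopifnot(is(firstTask, "TaskDataset"))
  shape <- imageShape(firstTask)
  dims <- length(shape)
  if (is.null(nClasses)) nClasses <- max(labelScheme(firstTask)) + 1L
  nClasses <- as.integer(nClasses)
  if (nClasses < 2L)
    .stopUser("a segmentation model needs at least 2 classes (got ",
              nClasses, ")")
  .getGeometry(shape)                     # fail early on unusable shapes
  params <- withSeed(seed, {
    body <- initBodyParams(as.integer(baseChannels), dims)
    head <- initHeadParams(as.integer(baseChannels), nClasses)
    list(body = body, head = head)
  })
  heads <- list(params$head)
  names(heads) <- taskId(firstTask)
  new("SegModel", body = params$body, heads = heads,
      splitPoint = splitPoint, activeHead = taskId(firstTask),
      bodyFrozen = FALSE,
      archConfig = list(depth = 3L, baseChannels = as.integer(baseChannels),
                        dims = dims, nClasses = nClasses,
                        imageShape = shape, initSeed = as.integer(seed)))
}

#' Replicate the active head for a new task
#'
#' In multi-head mode the new head is a value-copy of the currently active
#' head (so predictions with either head are identical at creation); in
#' single-head mode the single shared head is re-keyed to the new task.
#' The new head becomes active.
#'
#' @param model a [SegModel-class].
#' @param taskId id of the task about to start.
#' @param headMode `"multi"` (replicate) or `"single"` (re-key).
#' @return the updated model.
#' @export
addHead <- function(model, taskId, headMode = "multi") {
  stopifnot(is(model, "SegModel"))
  if (taskId %in% names(model@heads))
    .stopUser("head '", taskId, "' already exists")
  if (headMode == "single") {
    names(model@heads)[names(model@heads) == model@activeHead] <- taskId
  } else {
    model@heads[[taskId]] <- model@heads[[model@activeHead]]
  }
  model@activeHead <- taskId
  validObject(model)
  model
}

#' Freeze the shared body
#'
#' Subsequent training updates heads only; body parameters stay bitwise
#' constant.
#'
#' @param model a [SegModel-class].
#' @return the model with `bodyFrozen = TRUE`.
#' @export
freezeBody <- function(model) {
  stopifnot(is(model, "SegModel"))
  model@bodyFrozen <- TRUE
  model
}

# image array -> (V, 1) matrix at the architecture's input shape
.caseInput <- function(image, arch) {
  img <- .resampleNearest(image, arch$imageShape)
  matrix(as.vector(img), ncol = 1L)
}

.modelLogits <- function(model, image, headId) {
  arch <- model@archConfig
  geom <- .getGeometry(arch$imageShape)
  x <- .caseInput(image, arch)
  bf <- bodyForward(model@body, x, geom)
  headForward(model@heads[[headId]], bf$feat)
}

# arg-max decode with the documented tie rule: the lowest class index wins
.argmaxMask <- function(Z, shape) {
  cls <- max.col(Z, ties.method = "first") - 1L
  m <- as.integer(cls)
  dim(m) <- shape
  m
}

#' Predict a segmentation mask
#'
#' Runs the shared body plus the head selected for `taskId` and decodes the
#' per-voxel arg-max over class scores; score ties go to the lowest class
#' index. Task identity is assumed to be known at inference time. Inputs
#' whose shape differs from the architecture's are resampled to the model
#' grid and the predicted mask is resampled back.
#'
#' @param model a [SegModel-class].
#' @param image numeric array.
#' @param taskId head to use; defaults to the active head. In multi-head
#'   models an unknown id is an error.
#' @return integer mask of the same spatial shape as `image`.
#' @export
predictMask <- function(model, image, taskId = NULL) {
  stopifnot(is(model, "SegModel"))
  if (is.null(taskId)) taskId <- model@activeHead
  if (!taskId %in% names(model@heads)) {
    if (length(model@heads) == 1L) taskId <- names(model@heads)
    else .stopUser("no head for task '", taskId, "'; stored heads: ",
                   paste(names(model@heads), collapse = ", "))
  }
  Z <- .modelLogits(model, image, taskId)
  m <- .argmaxMask(Z, model@archConfig$imageShape)
  if (!identical(dim(image), dim(m))) m <- .resampleNearest(m, dim(image))
  m
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the body, all heads, the
#' architecture configuration, split point and training provenance (task
#' order, method, seeds).
#'
#' @param model a [SegModel-class].
#' @param path file path.
#' @param provenance optional list stored alongside the parameters.
#' @return `loadModel` returns the model; the provenance is attached as
#'   attribute `"provenance"`.
#' @export
saveModel <- function(model, path, provenance = list()) {
  stopifnot(is(model, "SegModel"))
  saveRDS(list(body = model@body, heads = model@heads,
               splitPoint = model@splitPoint, activeHead = model@activeHead,
               bodyFrozen = model@bodyFrozen, archConfig = model@archConfig,
               provenance = provenance), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  m <- new("SegModel", body = x$body, heads = x$heads,
           splitPoint = x$splitPoint, activeHead = x$activeHead,
           bodyFrozen = x$bodyFrozen, archConfig = x$archConfig)
  attr(m, "provenance") <- x$provenance
  m
}

# flat trainable parameter view: body (unless frozen) + active head.
# Head parameter names (seg_head.*) never collide with body names.
.flatParams <- function(model) {
  c(model@body, model@heads[[model@activeHead]])
}

.trainableNames <- function(model) {
  nm <- names(.flatParams(model))
  if (model@bodyFrozen) nm[startsWith(nm, model@splitPoint)] else nm
}

.unflatten <- function(model, theta) {
  hn <- names(theta)[startsWith(names(theta), model@splitPoint)]
  model@body <- theta[setdiff(names(theta), hn)]
  model@heads[[model@activeHead]] <- theta[hn]
  model
}

# checksum used in tests to assert bitwise constancy
.paramChecksum <- function(params) {
  sum(vapply(params, function(p) sum(p) + sum(p * seq_along(p)), numeric(1L)))
}
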