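# Core S4 containers. A task is one dataset/acquisition site treated as a
# training stage; a sequence of tasks is the substrate of a continual run.

#' TaskSpec: declarative description of one synthetic segmentation task
#'
#' A task emulates one "scanner domain": images share anatomy (a parametric
#' foreground shape) but differ in intensity statistics, noise and label
#' scheme. All generation derived from a spec is a pure function of
#' (spec, seed).
#'
#' @slot taskId short identifier, unique within a sequence.
#' @slot nCases number of cases (>= 2 so a nonempty split exists).
#' @slot imageShape integer vector of 2 or 3 voxel extents; each extent must
#'   be a positive multiple of 4 (three resolution levels).
#' @slot intensityFg,intensityBg `(mean, sd)` of the foreground/background
#'   class intensity in arbitrary units; the per-case class mean is drawn
#'   from this distribution, emulating scanner and patient variation.
#' @slot noiseSigma additive voxel-wise Gaussian noise scale, >= 0.
#' @slot shapeFamily one of `"ellipsoid"`, `"bilobed"` (two overlapping
#'   lobes, e.g. an anterior/posterior sub-structure pair), `"ring"`
#'   (annulus, e.g. a myocardium-like shell).
#' @slot labelScheme distinct positive integer labels present in raw masks;
#'   0 is reserved for background. Labels beyond those the shape family
#'   needs are rendered as small distractor structures (irrelevant tissue
#'   that alignment later maps to background).
#' @slot roiFraction target foreground fraction of the main structure,
#'   strictly inside (0, 0.5).
#' @slot shapeParams list of optional family parameters
#'   (`eccentricityRange`, `sizeJitter`, `biasFieldAmplitude`).
#' @export
setClass("TaskSpec",
  representation(taskId = "character", nCases = "integer",
                 imageShape = "integer", intensityFg = "numeric",
                 intensityBg = "numeric", noiseSigma = "numeric",
                 shapeFamily = "character", labelScheme = "integer",
                 roiFraction = "numeric", shapeParams = "list"))

setValidity("TaskSpec", function(object) {
  msg <- character()
  if (length(object@taskId) != 1L || !nzchar(object@taskId))
    msg <- c(msg, "taskId must be a single non-empty string")
  if (length(object@nCases) != 1L || object@nCases < 2L)
    msg <- c(msg, "nCases must be >= 2")
  if (!length(object@imageShape) %in% c(2L, 3L) ||
      any(object@imageShape < 4L) || any(object@imageShape %% 4L != 0L))
    msg <- c(msg, "imageShape must be 2 or 3 extents, each a multiple of 4")
  if (length(object@intensityFg) != 2L || object@intensityFg[2L] < 0)
    msg <- c(msg, "intensityFg must be (mean, sd) with sd >= 0")
  if (length(object@intensityBg) != 2L || object@intensityBg[2L] < 0)
    msg <- c(msg, "intensityBg must be (mean, sd) with sd >= 0")
  if (length(object@noiseSigma) != 1L || object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (!object@shapeFamily %in% c("ellipsoid", "bilobed", "ring"))
    msg <- c(msg, "shapeFamily must be ellipsoid, bilobed or ring")
  if (length(object@labelScheme) < 1L || any(object@labelScheme <= 0L) ||
      anyDuplicated(object@labelScheme))
    msg <- c(msg, "labelScheme must be distinct positive integers (0 is background)")
  if (length(object@roiFraction) != 1L || object@roiFraction <= 0 ||
      object@roiFraction >= 0.5)
    msg <- c(msg, "roiFraction must lie strictly in (0, 0.5)")
  if (object@shapeFamily == "bilobed" && length(object@labelScheme) < 2L)
    msg <- c(msg, "bilobed tasks need at least two labels (one per lobe)")
  if (length(msg)) msg else TRUE
})

#' Construct a TaskSpec
#'
#' @param taskId short identifier.
#' @param nCases number of cases.
#' @param imageShape 2 or 3 voxel extents (multiples of 4).
#' @param intensityFg,intensityBg `(mean, sd)` intensity of the two classes.
#' @param noiseSigma additive noise scale.
#' @param shapeFamily `"ellipsoid"`, `"bilobed"` or `"ring"`.
#' @param labelScheme raw positive integer labels.
#' @param roiFraction target foreground fraction in (0, 0.5).
#' @param shapeParams optional list of family parameters.
#' @return a validated [TaskSpec-class] object.
#' @examples
#' taskSpec("siteA", nCases = 10, imageShape = c(32, 32))
#' @export
taskSpec <- function(taskId, nCases = 30L, imageShape = c(64L, 64L),
                     intensityFg = c(0.75, 0.03), intensityBg = c(0.25, 0.03),
                     noiseSigma = 0.05, shapeFamily = "ellipsoid",
                     labelScheme = 1L, roiFraction = 0.1,
                     shapeParams = list()) {
  new("TaskSpec", taskId = as.character(taskId), nCases = as.integer(nCases),
      imageShape = as.integer(imageShape), intensityFg = as.numeric(intensityFg),
      intensityBg = as.numeric(intensityBg), noiseSigma = as.numeric(noiseSigma),
      shapeFamily = shapeFamily, labelScheme = as.integer(labelScheme),
      roiFraction = as.numeric(roiFraction), shapeParams = shapeParams)
}

#' TaskDataset: realized cases of one task with a persistent split
#'
#' @slot spec the generating [TaskSpec-class] (or a descriptive spec for
#'   externally loaded data).
#' @slot cases ordered list; each case is `list(caseId, image, mask)` where
#'   image is a dense numeric array and mask an integer array of the same
#'   spatial shape.
#' @slot trainIdx,testIdx disjoint 1-based case indices covering all cases;
#'   the split is stored with the dataset so every experiment sees the same
#'   partition.
#' @export
setClass("TaskDataset",
  representation(spec = "TaskSpec", cases = "list",
                 trainIdx = "integer", testIdx = "integer"))

setValidity("TaskDataset", function(object) {
  msg <- character()
  n <- length(object@cases)
  allIdx <- sort(c(object@trainIdx, object@testIdx))
  if (!identical(allIdx, seq_len(n)))
    msg <- c(msg, "train/test indices must partition the cases exactly once")
  allowed <- c(0L, object@spec@labelScheme)
  for (cs in object@cases) {
    if (!identical(dim(cs$image), dim(cs$mask))) {
      msg <- c(msg, "images and masks must share spatial shape")
      break
    }
    if (!all(unique(as.vector(cs$mask)) %in% allowed)) {
      msg <- c(msg, paste0("mask of case ", cs$caseId,
                           " contains labels outside the declared scheme"))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' LabelMapping: raw-to-target label remapping for one task
#'
#' Targets 0..K index the unified scheme; target 0 is background. Background
#' (raw 0) always maps to 0 and needs no entry.
#'
#' @slot map named integer vector; names are raw labels, values targets.
#' @slot name mapping label (usually the task id).
#' @export
setClass("LabelMapping",
  representation(map = "integer", name = "character"))

setValidity("LabelMapping", function(object) {
  msg <- character()
  raw <- suppressWarnings(as.integer(names(object@map)))
  if (length(object@map) && (anyNA(raw) || any(raw < 0L) || anyDuplicated(raw)))
    msg <- c(msg, "raw labels must be distinct nonnegative integers")
  if (length(object@map) && any(object@map < 0L))
    msg <- c(msg, "target labels must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMapping
#' @param map named vector or list, e.g. `c("1" = 1, "2" = 1)`.
#' @param name mapping label.
#' @return a [LabelMapping-class].
#' @examples
#' labelMapping(c("1" = 1, "2" = 0), name = "siteC")
#' @export
labelMapping <- function(map, name = "") {
  m <- as.integer(unlist(map))
  names(m) <- names(unlist(map))
  new("LabelMapping", map = m, name = as.character(name))
}

#' SegModel: shared body plus one-or-more task heads
#'
#' The body is the encoder-decoder trunk; a head is the final per-class
#' projection (all parameters whose name starts with the split point,
#' `"seg_head"` by default). Heads are architecturally interchangeable.
#' The architecture configuration is fixed from the first task and never
#' changes afterwards; inputs of a different spatial shape are resampled by
#' the data path.
#'
#' @slot body named list of body parameter arrays.
#' @slot heads named list (by task id) of head parameter lists.
#' @slot splitPoint parameter-name prefix delimiting the head.
#' @slot activeHead task id of the currently active head.
#' @slot bodyFrozen if TRUE, training updates heads only and the body is
#'   bitwise constant.
#' @slot archConfig list: `depth`, `baseChannels`, `dims`, `nClasses`,
#'   `imageShape`, `initSeed`.
#' @export
setClass("SegModel",
  representation(body = "list", heads = "list", splitPoint = "character",
                 activeHead = "character", bodyFrozen = "logical",
                 archConfig = "list"))

setValidity("SegModel", function(object) {
  msg <- character()
  if (!length(object@heads))
    msg <- c(msg, "a model needs at least one head")
  shapes <- lapply(object@heads, function(h) lapply(h, dim))
  if (length(shapes) > 1L && !all(vapply(shapes[-1L], identical, logical(1L),
                                         shapes[[1L]])))
    msg <- c(msg, "all heads must share identical parameter shapes")
  if (!object@activeHead %in% names(object@heads))
    msg <- c(msg, "activeHead must name an existing head")
  if (any(startsWith(names(object@body), object@splitPoint)))
    msg <- c(msg, "body must not contain head parameters")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: one training regime
#'
#' Holds the budget (epochs x steps), optimizer settings, the continual
#' strategy and its hyperparameters, and the head regime. Method parameter
#' defaults are the package defaults: rehearsal `fraction = 0.25`, EWC
#' `lambda = 0.4`, LwF `temperature = 8`, RW `lambda = 0.4, alpha = 0.9`,
#' MiB `alpha = 0.9, kdWeight = 1`.
#'
#' @slot epochs,stepsPerEpoch,batchSize integer training budget.
#' @slot learningRate,momentum SGD settings (fixed for the whole run).
#' @slot seed integer run seed; per-stage streams are derived from it.
#' @slot method one of `"sequential"`, `"rehearsal"`, `"ewc"`, `"lwf"`,
#'   `"rw"`, `"mib"`.
#' @slot methodParams named list of hyperparameters for the method.
#' @slot headMode `"single"` (one shared head) or `"multi"` (one per task).
#' @slot freezeBodyAfterFirst freeze the shared body after stage 1.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", stepsPerEpoch = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 momentum = "numeric", seed = "integer", method = "character",
                 methodParams = "list", headMode = "character",
                 freezeBodyAfterFirst = "logical"))

.clMethods <- c("sequential", "rehearsal", "ewc", "lwf", "rw", "mib")

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@stepsPerEpoch < 1L) msg <- c(msg, "stepsPerEpoch must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must be in [0, 1)")
  if (!object@method %in% .clMethods)
    msg <- c(msg, paste("method must be one of:", paste(.clMethods, collapse = ", ")))
  if (!object@headMode %in% c("single", "multi"))
    msg <- c(msg, "headMode must be 'single' or 'multi'")
  mp <- object@methodParams
  bad <- switch(object@method,
    rehearsal = is.null(mp$fraction) || mp$fraction < 0 || mp$fraction > 1,
    ewc = is.null(mp$lambda) || mp$lambda < 0,
    lwf = is.null(mp$temperature) || mp$temperature <= 0,
    rw = is.null(mp$lambda) || is.null(mp$alpha) ||
      mp$alpha < 0 || mp$alpha > 1,
    mib = is.null(mp$alpha) || mp$alpha <= 0,
    FALSE)
  if (isTRUE(bad))
    msg <- c(msg, paste0("methodParams incomplete or invalid for method '",
                         object@method, "'"))
  if (object@method == "lwf" && object@headMode != "multi")
    msg <- c(msg, "lwf requires headMode = 'multi' (it distils into task heads)")
  if (length(msg)) msg else TRUE
})

.defaultMethodParams <- function(method) {
  switch(method,
         rehearsal = list(fraction = 0.25),
         ewc = list(lambda = 0.4),
         lwf = list(temperature = 8),
         rw = list(lambda = 0.4, alpha = 0.9, xi = 1e-3),
         mib = list(alpha = 0.9, kdWeight = 1),
         list())
}

#' Construct a TrainConfig
#'
#' @param method continual strategy (see [TrainConfig-class]).
#' @param epochs,stepsPerEpoch,batchSize training budget per stage.
#' @param learningRate,momentum SGD settings.
#' @param seed run seed.
#' @param methodParams overrides merged over the method's defaults.
#' @param headMode `"single"` or `"multi"`.
#' @param freezeBodyAfterFirst freeze the shared body after the first stage.
#' @return a validated [TrainConfig-class].
#' @examples
#' trainConfig("rehearsal", epochs = 5, methodParams = list(fraction = 0.25))
#' @export
trainConfig <- function(method = "sequential", epochs = 10L,
                        stepsPerEpoch = 20L, batchSize = 4L,
                        learningRate = 0.05, momentum = 0.9, seed = 1L,
                        methodParams = list(), headMode = "single",
                        freezeBodyAfterFirst = FALSE) {
  mp <- utils::modifyList(.defaultMethodParams(method), methodParams)
  if (method == "lwf" && missing(headMode)) headMode <- "multi"
  new("TrainConfig", epochs = as.integer(epochs),
      stepsPerEpoch = as.integer(stepsPerEpoch),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      momentum = momentum, seed = as.integer(seed), method = method,
      methodParams = mp, headMode = headMode,
      freezeBodyAfterFirst = freezeBodyAfterFirst)
}

#' MemoryBuffer: rehearsal samples drawn from previous tasks
#'
#' Entries are drawn uniformly without replacement from the train splits of
#' previous tasks only; per task, `round(fraction * |train|)` cases
#' (half away from zero).
#'
#' @slot entries list of `list(taskId, caseId, image, mask)`.
#' @slot fraction sampled fraction per previous task.
#' @slot seed sampling seed.
#' @export
setClass("MemoryBuffer",
  representation(entries = "list", fraction = "numeric", seed = "integer"))

#' ImportanceStore: per-task parameter anchors and importance weights
#'
#' For each completed task, a value-copy of the parameters at the task
#' boundary (the anchor) and elementwise nonnegative importance weights
#' (diagonal Fisher information for EWC; Fisher + path score for RW).
#' Anchors never change after their task completes.
#'
#' @slot tasks named list (by task id) of `list(anchor, omega)`.
#' @export
setClass("ImportanceStore", representation(tasks = "list"))

#' PerfMatrix: per-stage, per-task, per-class Dice
#'
#' `dice[s, j, c]` is the mean test Dice for class c of the model state
#' after stage s on task j. The `independent` matrix holds the static
#' reference of a model trained solely on each task (the forward-transfer
#' baseline). Missing entries are NA.
#'
#' @slot dice 3-d array `[stage, task, class]` in [0, 1] or NA.
#' @slot independent matrix `[task, class]` or NA.
#' @slot order stage order (task ids).
#' @export
setClass("PerfMatrix",
  representation(dice = "array", independent = "matrix", order = "character"))

setValidity("PerfMatrix", function(object) {
  d <- object@dice
  ok <- is.na(d) | (d >= 0 & d <= 1)
  if (!all(ok)) return("dice entries must be in [0, 1] or NA")
  TRUE
})

#' ExperimentConfig: a full reproducible experiment
#'
#' @slot specs list of [TaskSpec-class] (or character directories of
#'   NIfTI tasks with manifests).
#' @slot mappings named list of [LabelMapping-class] per task (may be empty
#'   when schemes are already aligned).
#' @slot order task ids in training order (a permutation of the declared
#'   tasks; orderings matter).
#' @slot train the [TrainConfig-class].
#' @slot outputDir where reports and checkpoints are written.
#' @slot seed global seed; data generation and training streams derive
#'   from it.
#' @slot computeIndependent train per-task static reference models (needed
#'   for forward transfer and the inter-task matrix).
#' @export
setClass("ExperimentConfig",
  representation(specs = "list", mappings = "list", order = "character",
                 train = "TrainConfig", outputDir = "character",
                 seed = "integer", computeIndependent = "logical"))

# ---- show methods ----

setMethod("show", "TaskSpec", function(object) {
  cat("TaskSpec '", object@taskId, "': ", object@nCases, " cases, [",
      paste(object@imageShape, collapse = " x "), "] ",
      object@shapeFamily, ", labels {",
      paste(object@labelScheme, collapse = ","), "}, ROI ",
      format(object@roiFraction), "\n", sep = "")
  cat("  fg ~ N(", object@intensityFg[1L], ", ", object@intensityFg[2L],
      "), bg ~ N(", object@intensityBg[1L], ", ", object@intensityBg[2L],
      "), noise ", object@noiseSigma, "\n", sep = "")
})

setMethod("show", "TaskDataset", function(object) {
  cat("TaskDataset '", object@spec@taskId, "': ", length(object@cases),
      " cases (", length(object@trainIdx), " train / ",
      length(object@testIdx), " test), shape [",
      paste(object@spec@imageShape, collapse = " x "), "]\n", sep = "")
})

setMethod("show", "LabelMapping", function(object) {
  cat("LabelMapping '", object@name, "': ",
      paste(names(object@map), "->", object@map, collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "SegModel", function(object) {
  ac <- object@archConfig
  cat("SegModel: depth ", ac$depth, ", base ", ac$baseChannels,
      " channels, ", ac$nClasses, " classes, input [",
      paste(ac$imageShape, collapse = " x "), "]\n", sep = "")
  cat("  heads: ", paste(names(object@heads), collapse = ", "),
      " (active: ", object@activeHead, ")",
      if (object@bodyFrozen) " [body frozen]", "\n", sep = "")
})

setMethod("show", "TrainConfig", function(object) {
  mp <- object@methodParams
  cat("TrainConfig: ", object@method, ", ", object@epochs, " epochs x ",
      object@stepsPerEpoch, " steps, batch ", object@batchSize,
      ", lr ", object@learningRate, ", seed ", object@seed,
      ", heads ", object@headMode,
      if (object@freezeBodyAfterFirst) ", freeze body", "\n", sep = "")
  if (length(mp))
    cat("  params: ", paste(names(mp), unlist(mp), sep = "=", collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "PerfMatrix", function(object) {
  cat("PerfMatrix: ", dim(object@dice)[1L], " stages x ",
      dim(object@dice)[2L], " tasks x ", dim(object@dice)[3L],
      " classes\n", sep = "")
  print(round(apply(object@dice, c(1L, 2L), mean), 3))
})
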