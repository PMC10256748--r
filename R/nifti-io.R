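# Task persistence: one NIfTI image + one NIfTI mask per case plus a JSON
# manifest per task. The manifest (task id, label semantics, split, file
# list, generator spec) is the unit every other module consumes, so real
# volumetric datasets organized the same way plug in identically.

.asVolume <- function(arr) {
  # NIfTI is inherently 3-d; promote 2-d slices to (H, W, 1)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  arr
}

.fromVolume <- function(arr, shape) {
  array(as.vector(arr), dim = shape)   # strip NIfTI metadata attributes
}

#' Write a task to disk as NIfTI volumes plus a JSON manifest
#'
#' @param dataset a [TaskDataset-class].
#' @param dir output directory (created if missing). Existing case files
#'   are never silently overwritten unless `overwrite = TRUE`.
#' @param overwrite allow replacing an existing task directory.
#' @return the directory, invisibly.
#' @export
writeTaskDataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(is(dataset, "TaskDataset"))
  manifestPath <- file.path(dir, "manifest.json")
  if (file.exists(manifestPath) && !overwrite)
    .stopUser("manifest already exists in ", dir,
              " (use overwrite = TRUE to replace)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(dataset@cases, function(cs) {
    img <- paste0(cs$caseId, "_image.nii.gz")
    msk <- paste0(cs$caseId, "_mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(.asVolume(cs$image)),
                       file.path(dir, img))
    RNifti::writeNifti(RNifti::asNifti(.asVolume(cs$mask)),
                       file.path(dir, msk))
    list(case_id = cs$caseId, image = img, mask = msk)
  })
  spec <- dataset@spec
  manifest <- list(
    task_id = spec@taskId,
    image_shape = spec@imageShape,
    label_scheme = spec@labelScheme,
    spec = list(n_cases = spec@nCases, intensity_fg = spec@intensityFg,
                intensity_bg = spec@intensityBg, noise_sigma = spec@noiseSigma,
                shape_family = spec@shapeFamily, roi_fraction = spec@roiFraction),
    split = list(train = vapply(dataset@cases[dataset@trainIdx],
                                `[[`, character(1L), "caseId"),
                 test = vapply(dataset@cases[dataset@testIdx],
                               `[[`, character(1L), "caseId")),
    cases = files)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a task directory written by [writeTaskDataset()]
#'
#' Also reads externally prepared tasks: the manifest must list cases and a
#' split; generator fields absent from hand-written manifests fall back to
#' neutral defaults.
#'
#' @param dir task directory containing `manifest.json`.
#' @return a [TaskDataset-class].
#' @export
readTaskDataset <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    .stopUser("no manifest.json in ", dir)
  mf <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  shape <- as.integer(mf$image_shape)
  sp <- mf$spec
  spec <- taskSpec(
    taskId = mf$task_id,
    nCases = if (!is.null(sp$n_cases)) sp$n_cases else nrow(mf$cases),
    imageShape = shape,
    intensityFg = if (!is.null(sp$intensity_fg)) sp$intensity_fg else c(1, 0),
    intensityBg = if (!is.null(sp$intensity_bg)) sp$intensity_bg else c(0, 0),
    noiseSigma = if (!is.null(sp$noise_sigma)) sp$noise_sigma else 0,
    shapeFamily = if (!is.null(sp$shape_family)) sp$shape_family else "ellipsoid",
    labelScheme = as.integer(mf$label_scheme),
    roiFraction = if (!is.null(sp$roi_fraction)) sp$roi_fraction else 0.1)
  cases <- lapply(seq_len(nrow(mf$cases)), function(i) {
    row <- mf$cases[i, ]
    img <- .fromVolume(RNifti::readNifti(file.path(dir, row$image)), shape)
    msk <- .fromVolume(RNifti::readNifti(file.path(dir, row$mask)), shape)
    storage.mode(msk) <- "integer"
    list(caseId = row$case_id, image = img, mask = msk)
  })
  ids <- vapply(cases, `[[`, character(1L), "caseId")
  ds <- new("TaskDataset", spec = spec, cases = cases,
            trainIdx = match(mf$split$train, ids),
            testIdx = match(mf$split$test, ids))
  validObject(ds)
  ds
}
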