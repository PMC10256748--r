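# Label-scheme alignment: remap heterogeneous raw label schemes to one
# consistent scheme before any training. Alignment is a semantic act (which
# raw region corresponds to which target structure), so mappings are always
# explicit -- supplied in code or as JSON files -- and never inferred from
# label statistics. Trainers only ever see aligned data.

#' Remap the labels of one mask
#'
#' Applies `mapping` voxel-wise: raw label r becomes `mapping[r]`;
#' background (0) always maps to 0. Typical uses are merging two
#' sub-structure labels into one target label, or sending an irrelevant
#' structure to background.
#'
#' @param mask integer array.
#' @param mapping a [LabelMapping-class].
#' @param caseId optional case identifier used in error messages.
#' @return an integer array of the same shape.
#' @examples
#' m <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
#' alignMask(m, labelMapping(c("1" = 1, "2" = 1)))
#' @export
alignMask <- function(mask, mapping, caseId = NULL) {
  stopifnot(is(mapping, "LabelMapping"))
  raw <- sort(unique(as.vector(mask)))
  raw <- raw[raw != 0L]
  known <- as.integer(names(mapping@map))
  missing <- setdiff(raw, known)
  if (length(missing))
    .stopUser("unmapped label(s) ", paste(missing, collapse = ", "),
              " in mask", if (!is.null(caseId)) paste0(" of case ", caseId),
              " (mapping '", mapping@name, "')")
  lut <- integer(max(c(raw, known, 0L)) + 1L)       # lut[r + 1] = target
  lut[known + 1L] <- mapping@map
  out <- lut[as.vector(mask) + 1L]
  dim(out) <- dim(mask)
  out
}

#' Identity mapping for a label scheme
#' @param scheme integer raw labels.
#' @param name mapping label.
#' @return a [LabelMapping-class] mapping every label to itself.
#' @export
identityMapping <- function(scheme, name = "identity") {
  m <- as.integer(scheme)
  names(m) <- as.character(scheme)
  new("LabelMapping", map = m, name = name)
}

#' Align all masks of a dataset
#'
#' @param dataset a [TaskDataset-class].
#' @param mapping a [LabelMapping-class] covering the dataset's raw scheme.
#' @return the dataset with remapped masks and an updated label scheme.
#' @export
alignDataset <- function(dataset, mapping) {
  stopifnot(is(dataset, "TaskDataset"))
  dataset@cases <- lapply(dataset@cases, function(cs) {
    cs$mask <- alignMask(cs$mask, mapping, caseId = cs$caseId)
    cs
  })
  targets <- sort(unique(mapping@map[mapping@map > 0L]))
  dataset@spec@labelScheme <- as.integer(targets)
  validObject(dataset)
  dataset
}

#' Validate alignment across a task sequence
#'
#' Checks that, after applying each task's mapping, all tasks share the
#' identical target label set and that target labels form a contiguous set
#' {0..K}. Failures are carried in the report, not thrown.
#'
#' @param datasets list of [TaskDataset-class].
#' @param mappings list of [LabelMapping-class], one per task (recycled
#'   names are matched by task id when the list is named).
#' @return an `AlignmentReport` list with elements `pass`, `targetSet`,
#'   `perTask` (data frame of voxel counts per target class before/after),
#'   and `failures` (character).
#' @export
validateAlignment <- function(datasets, mappings) {
  if (length(mappings) != length(datasets))
    .stopUser("need exactly one mapping per task")
  ids <- vapply(datasets, taskId, character(1L))
  if (!is.null(names(mappings)) && all(nzchar(names(mappings))))
    mappings <- mappings[ids]

  failures <- character()
  targetSets <- vector("list", length(datasets))
  rows <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    mp <- mappings[[i]]
    raw <- labelScheme(ds)
    known <- as.integer(names(mp@map))
    missing <- setdiff(raw, known)
    if (length(missing)) {
      failures <- c(failures, paste0(
        "task '", ids[i], "': no mapping entry for label(s) ",
        paste(missing, collapse = ", ")))
      next
    }
    targets <- sort(unique(c(0L, mp@map[as.character(raw)])))
    targetSets[[i]] <- targets
    counts <- integer(0)
    remapped <- 0
    for (cs in ds@cases) {
      al <- alignMask(cs$mask, mp, caseId = cs$caseId)
      remapped <- remapped + sum(al != cs$mask)
      tb <- table(factor(as.vector(al), levels = targets))
      counts <- if (length(counts)) counts + as.integer(tb) else as.integer(tb)
    }
    rows[[ids[i]]] <- data.frame(task = unname(ids[i]), target = targets,
                                 voxels = counts, remappedVoxels = remapped)
  }
  targetSets <- targetSets[!vapply(targetSets, is.null, logical(1L))]
  unified <- if (length(targetSets)) targetSets[[1L]] else integer()
  if (length(targetSets) > 1L) {
    same <- all(vapply(targetSets[-1L], identical, logical(1L), unified))
    if (!same)
      failures <- c(failures, "tasks do not share an identical post-alignment label set")
  }
  if (length(unified) && !identical(unified, seq(0L, max(unified))))
    failures <- c(failures,
                  "post-alignment labels are not contiguous {0..K}")
  structure(list(pass = length(failures) == 0L,
                 targetSet = unified,
                 perTask = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 failures = failures),
            class = "AlignmentReport")
}

#' @export
print.AlignmentReport <- function(x, ...) {
  cat("AlignmentReport:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  unified target set: {", paste(x$targetSet, collapse = ","), "}\n")
  if (length(x$failures)) cat("  failures:\n   -",
                              paste(x$failures, collapse = "\n   - "), "\n")
  invisible(x)
}

#' Read / write label mappings as JSON
#'
#' File format: `{"task_id": "siteB", "map": {"1": 1, "2": 1}}`.
#'
#' @param path JSON file path.
#' @return `readLabelMapping` returns a [LabelMapping-class].
#' @export
readLabelMapping <- function(path) {
  j <- jsonlite::read_json(path)
  labelMapping(unlist(j$map), name = if (!is.null(j$task_id)) j$task_id else "")
}

#' @rdname readLabelMapping
#' @param mapping a [LabelMapping-class].
#' @export
writeLabelMapping <- function(mapping, path) {
  stopifnot(is(mapping, "LabelMapping"))
  jsonlite::write_json(
    list(task_id = mapping@name,
         map = as.list(stats::setNames(as.integer(mapping@map),
                                       names(mapping@map)))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
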