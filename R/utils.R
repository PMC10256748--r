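# Shared helpers: seeded evaluation without touching the caller's RNG
# stream, deterministic seed derivation, split rounding, nearest-neighbour
# resampling, and a geometry cache.

#' Evaluate an expression under a temporary RNG state
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit combination of a seed with an integer tag.
# Multipliers are kept small so every intermediate stays exact in doubles.
.mixSeed <- function(seed, tag) {
  as.integer(((seed %% 65521) * 31013 + (tag %% 65521) * 7919 + 17) %% 2147483629)
}

# 31-bit string hash, used to tie per-task seeds to task ids.
.hashString <- function(x) {
  h <- 5381
  for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2147480009
  as.integer(h)
}

.taskSeed <- function(seed, taskId) .mixSeed(seed, .hashString(taskId))

# Round half away from zero (fixed so splits are reproducible across
# platforms; base round() rounds half to even).
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Geometry tables are pure functions of the image shape; cache them.
.geomCache <- new.env(parent = emptyenv())

.getGeometry <- function(shape) {
  key <- paste(shape, collapse = "x")
  g <- .geomCache[[key]]
  if (is.null(g)) {
    g <- buildGeometry(shape)
    .geomCache[[key]] <- g
  }
  g
}

# Nearest-neighbour resampling of a dense array to a target spatial shape.
.resampleNearest <- function(arr, target) {
  src <- dim(arr)
  if (identical(as.integer(src), as.integer(target))) return(arr)
  if (length(src) != length(target))
    stop("cannot resample between different dimensionalities")
  idx <- lapply(seq_along(target), function(d) {
    pmin(src[d], pmax(1L, as.integer(ceiling(seq_len(target[d]) * src[d] / target[d]))))
  })
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

.stopUser <- function(...) stop(..., call. = FALSE)
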