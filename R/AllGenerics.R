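# Accessor generics for the core containers.

#' @rdname TaskSpec-class
#' @param object a contiseg object.
#' @export
setGeneric("taskId", function(object) standardGeneric("taskId"))

#' @rdname TaskSpec-class
#' @export
setGeneric("labelScheme", function(object) standardGeneric("labelScheme"))

#' @rdname TaskSpec-class
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))

#' @rdname TaskDataset-class
#' @param object a contiseg object.
#' @export
setGeneric("nCases", function(object) standardGeneric("nCases"))

#' @rdname TaskDataset-class
#' @export
setGeneric("trainCases", function(object) standardGeneric("trainCases"))

#' @rdname TaskDataset-class
#' @export
setGeneric("testCases", function(object) standardGeneric("testCases"))

#' @rdname SegModel-class
#' @param object a contiseg object.
#' @export
setGeneric("heads", function(object) standardGeneric("heads"))

#' @rdname SegModel-class
#' @export
setGeneric("activeHead", function(object) standardGeneric("activeHead"))

#' @rdname SegModel-class
#' @export
setGeneric("bodyFrozen", function(object) standardGeneric("bodyFrozen"))

#' @rdname SegModel-class
#' @export
setGeneric("archConfig", function(object) standardGeneric("archConfig"))

setMethod("taskId", "TaskSpec", function(object) object@taskId)
setMethod("taskId", "TaskDataset", function(object) object@spec@taskId)
setMethod("labelScheme", "TaskSpec", function(object) object@labelScheme)
setMethod("labelScheme", "TaskDataset", function(object) object@spec@labelScheme)
setMethod("imageShape", "TaskSpec", function(object) object@imageShape)
setMethod("imageShape", "TaskDataset", function(object) object@spec@imageShape)
setMethod("nCases", "TaskSpec", function(object) object@nCases)
setMethod("nCases", "TaskDataset", function(object) length(object@cases))
setMethod("trainCases", "TaskDataset",
          function(object) object@cases[object@trainIdx])
setMethod("testCases", "TaskDataset",
          function(object) object@cases[object@testIdx])
setMethod("heads", "SegModel", function(object) object@heads)
setMethod("activeHead", "SegModel", function(object) object@activeHead)
setMethod("bodyFrozen", "SegModel", function(object) object@bodyFrozen)
setMethod("archConfig", "SegModel", function(object) object@archConfig)
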