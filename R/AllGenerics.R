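#' Accessors for mmscape classes
#'
#' Small accessor generics for the package's S4 containers. Slots are never
#' accessed directly by user code.
#'
#' @param x an mmscape object.
#' @param ... passed to methods.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("svRecords", function(x) standardGeneric("svRecords"))

#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname accessors
#' @export
setGeneric("baselinePloidy", function(x) standardGeneric("baselinePloidy"))

#' @rdname accessors
#' @export
setGeneric("burdenLabel", function(x) standardGeneric("burdenLabel"))

#' @rdname accessors
#' @export
setGeneric("burdenEvidence", function(x) standardGeneric("burdenEvidence"))

#' @rdname accessors
#' @export
setGeneric("atomicIntervals", function(x) standardGeneric("atomicIntervals"))

#' @rdname accessors
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x, ...) standardGeneric("consensusMatrix"))

#' @rdname accessors
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))

#' @rdname accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))
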