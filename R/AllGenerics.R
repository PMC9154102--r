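#' @include AllClasses.R
NULL

#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @export
setGeneric("taxonIds", function(x, ...) standardGeneric("taxonIds"))

#' @export
setGeneric("membership", function(x, ...) standardGeneric("membership"))

#' @export
setGeneric("setSizes", function(x, ...) standardGeneric("setSizes"))

#' @export
setGeneric("setMembers", function(x, ...) standardGeneric("setMembers"))

#' @export
setGeneric("replaceZeros", function(x, pseudocount = 1e-5, ...)
    standardGeneric("replaceZeros"))

#' @export
setGeneric("closure", function(x, ...) standardGeneric("closure"))

#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @export
setGeneric("outputType", function(x, ...) standardGeneric("outputType"))

#' @export
setGeneric("nullModel", function(x, ...) standardGeneric("nullModel"))

#' @export
setGeneric("nullFamily", function(x, ...) standardGeneric("nullFamily"))

#' @export
setGeneric("isAdjusted", function(x, ...) standardGeneric("isAdjusted"))

#' @export
setGeneric("nullParameters", function(x, ...) standardGeneric("nullParameters"))

#' @export
setGeneric("nullDiagnostics", function(x, ...)
    standardGeneric("nullDiagnostics"))

#' @export
setGeneric("simCounts", function(x, ...) standardGeneric("simCounts"))

#' @export
setGeneric("simSets", function(x, ...) standardGeneric("simSets"))

#' @export
setGeneric("truthLabels", function(x, ...) standardGeneric("truthLabels"))

#' @export
setGeneric("groupLabels", function(x, ...) standardGeneric("groupLabels"))
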