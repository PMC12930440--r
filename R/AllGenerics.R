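#' @rdname DifferentialTable-class
#' @param object,x a \linkS4class{DifferentialTable}.
#' @export
setGeneric("analyteIds", function(x) standardGeneric("analyteIds"))

#' @rdname DifferentialTable-class
#' @export
setGeneric("log2FoldChange", function(x) standardGeneric("log2FoldChange"))

#' @rdname DifferentialTable-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname DifferentialTable-class
#' @export
setGeneric("adjPValues", function(x) standardGeneric("adjPValues"))

#' @rdname DifferentialTable-class
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname SignatureSet-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname SignatureSet-class
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname AnalyteUniverse-class
#' @export
setGeneric("universeIds", function(x) standardGeneric("universeIds"))
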