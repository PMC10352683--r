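#' @rdname genePanel
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname genePanel
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname genePanel
#' @export
setGeneric("nCarcinogens", function(x) standardGeneric("nCarcinogens"))

#' @rdname latticeAccessors
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname latticeAccessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname latticeAccessors
#' @export
setGeneric("classFractions", function(x) standardGeneric("classFractions"))

#' @rdname simResultAccessors
#' @export
setGeneric("timeSeries", function(x) standardGeneric("timeSeries"))

#' @rdname simResultAccessors
#' @export
setGeneric("eventRecord", function(x) standardGeneric("eventRecord"))

#' @rdname simResultAccessors
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @rdname lineageTable
#' @export
setGeneric("lineageTable", function(x, ...) standardGeneric("lineageTable"))

#' @rdname classifyClonality
#' @export
setGeneric("classifyClonality", function(x, ...)
  standardGeneric("classifyClonality"))
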