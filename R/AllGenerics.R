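#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname zscoreNormalize
#' @export
setGeneric("zscoreNormalize", function(x) standardGeneric("zscoreNormalize"))

#' @rdname rankGenes
#' @export
setGeneric("rankGenes", function(x, filter = c("snr", "ts", "pc"))
    standardGeneric("rankGenes"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("stepAccuracies", function(x) standardGeneric("stepAccuracies"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("finalAccuracy", function(x) standardGeneric("finalAccuracy"))
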