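#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionDataset: a two-class expression matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' continuous expression matrix (genes in rows, samples in columns) and a
#' binary class label per sample. Labels are canonicalized to the factor
#' levels \code{"0"} and \code{"1"} by the sorted order of the two observed
#' label strings; the original strings are kept in
#' \code{colData(x)$label_original}.
#'
#' Validity requires: all values finite; exactly two classes, each with at
#' least two samples; unique gene and sample identifiers.
#'
#' @seealso [ExpressionDataset()] for construction from a plain matrix,
#'   [readExpressionTable()] to load one from delimited text.
#' @name ExpressionDataset-class
#' @aliases ExpressionDataset-class
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(m))
            msg <- c(msg, "expression values must be numeric")
        else if (any(!is.finite(m)))
            msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    cls <- SummarizedExperiment::colData(object)$class
    if (is.null(cls)) {
        msg <- c(msg, "colData column 'class' is required")
    } else {
        tab <- table(cls)
        if (length(tab) != 2L)
            msg <- c(msg, sprintf("exactly two classes required, found %d",
                                  length(tab)))
        else if (any(tab < 2L))
            msg <- c(msg, "each class needs at least two samples")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' GeneRanking: one filter's ordered gene list
#'
#' Genes sorted by the filter's ranking key (raw score for the
#' signal-to-noise ratio, absolute value for the t-statistic and the
#' Pearson correlation) in non-increasing order; ties keep input gene
#' order. Produced by [rankGenes()].
#'
#' @slot filterName one of \code{"snr"}, \code{"ts"}, \code{"pc"}.
#' @slot ranking a \code{DataFrame} with columns \code{gene_id},
#'   \code{score}, \code{key} (the sort key) and \code{rank}.
#' @name GeneRanking-class
#' @exportClass GeneRanking
setClass("GeneRanking",
    representation(filterName = "character", ranking = "DataFrame"),
    validity = function(object) {
        msg <- character()
        if (!object@filterName %in% c("snr", "ts", "pc"))
            msg <- c(msg, "filterName must be one of 'snr', 'ts', 'pc'")
        need <- c("gene_id", "score", "key", "rank")
        if (!all(need %in% colnames(object@ranking)))
            msg <- c(msg, paste("ranking needs columns:",
                                paste(need, collapse = ", ")))
        else {
            if (anyDuplicated(object@ranking$gene_id))
                msg <- c(msg, "duplicate gene_id in ranking")
            k <- object@ranking$key
            if (length(k) > 1L && any(diff(k) > 0, na.rm = TRUE))
                msg <- c(msg, "ranking key must be non-increasing")
        }
        if (length(msg)) msg else TRUE
    })

#' FilteredUnion: merged top-N candidate set
#'
#' The deduplicated union of the per-filter top-N gene lists, ordered by
#' best rank across contributing filters (ties by mean contributing rank,
#' then input gene order), with per-filter rank provenance. Produced by
#' [unionTopN()].
#'
#' @slot geneIds ordered, deduplicated candidate gene ids.
#' @slot provenance named list: for each gene, a \code{data.frame} of
#'   \code{(filter, rank)} pairs that contributed it.
#' @slot N the per-filter top count used.
#' @name FilteredUnion-class
#' @exportClass FilteredUnion
setClass("FilteredUnion",
    representation(geneIds = "character", provenance = "list",
                   N = "integer"),
    validity = function(object) {
        msg <- character()
        if (anyDuplicated(object@geneIds))
            msg <- c(msg, "geneIds must be unique")
        if (!identical(sort(names(object@provenance)),
                       sort(object@geneIds)))
            msg <- c(msg, "provenance must be named by geneIds")
        if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
            msg <- c(msg, "N must be a positive integer")
        ok <- vapply(object@provenance,
                     function(p) any(p$rank <= object@N), logical(1))
        if (length(ok) && !all(ok))
            msg <- c(msg, "every gene must rank <= N in some filter")
        if (length(msg)) msg else TRUE
    })

#' RedundancyConfig: settings for the cross-entropy screen
#'
#' @slot threshold independence threshold T in [0, 1]; a candidate is
#'   admitted while its redundancy against the kept set stays strictly
#'   below T.
#' @slot binMethod \code{"equal_frequency"} or \code{"equal_width"}.
#' @slot nBins number of discretization bins; \code{NA} means automatic
#'   (\code{ceiling(sqrt(n_samples))}, floored at 2).
#' @slot aggregation \code{"pairwise_max"} (maximum pairwise normalized
#'   cross-entropy against the kept set) or \code{"joint"} (one joint
#'   normalized cross-entropy over kept set plus candidate).
#' @seealso [redundancyConfig()], [eliminateRedundant()]
#' @name RedundancyConfig-class
#' @exportClass RedundancyConfig
setClass("RedundancyConfig",
    representation(threshold = "numeric", binMethod = "character",
                   nBins = "integer", aggregation = "character"),
    validity = function(object) {
        msg <- character()
        Tt <- object@threshold
        if (length(Tt) != 1L || is.na(Tt) || Tt < 0 || Tt > 1)
            msg <- c(msg, "threshold must be a single value in [0, 1]")
        if (!object@binMethod %in% c("equal_frequency", "equal_width"))
            msg <- c(msg, "binMethod must be 'equal_frequency' or 'equal_width'")
        if (!is.na(object@nBins) && object@nBins < 2L)
            msg <- c(msg, "nBins must be >= 2 (or NA for automatic)")
        if (!object@aggregation %in% c("pairwise_max", "joint"))
            msg <- c(msg, "aggregation must be 'pairwise_max' or 'joint'")
        if (length(msg)) msg else TRUE
    })

#' ClassifierSpec: the wrapper's classification model
#'
#' @slot kind \code{"knn"}, \code{"svm_linear"} or \code{"naive_bayes"}.
#' @slot k neighbourhood size for KNN (ignored otherwise); odd by default
#'   so two-class votes cannot tie.
#' @seealso [classifierSpec()], [cvAccuracy()]
#' @name ClassifierSpec-class
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
    representation(kind = "character", k = "integer"),
    validity = function(object) {
        msg <- character()
        if (!object@kind %in% c("knn", "svm_linear", "naive_bayes"))
            msg <- c(msg, "kind must be 'knn', 'svm_linear' or 'naive_bayes'")
        if (object@kind == "knn" && (is.na(object@k) || object@k < 1L))
            msg <- c(msg, "k must be >= 1 for knn")
        if (length(msg)) msg else TRUE
    })

#' SelectionResult: output of the greedy wrapper / full pipeline
#'
#' @slot selectedGenes final subset R, in admission order.
#' @slot stepAccuracies cross-validated accuracy (percent) after each
#'   admission; strictly increasing by construction.
#' @slot finalAccuracy last entry of \code{stepAccuracies}.
#' @slot classifier the \linkS4class{ClassifierSpec} used.
#' @slot cvFolds number of cross-validation folds.
#' @slot seed integer seed that fixed fold assignment.
#' @slot provenance named list: per selected gene, the \code{(filter,
#'   rank)} provenance carried from the candidate union (empty when the
#'   wrapper was run on a bare gene list).
#' @slot config full pipeline configuration as a named list (empty when
#'   the wrapper was run standalone).
#' @slot stageSizes named integer vector with the gene counts of each
#'   pipeline stage (\code{genes}, \code{F}, \code{G}, \code{R}).
#' @name SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(selectedGenes = "character", stepAccuracies = "numeric",
                   finalAccuracy = "numeric", classifier = "ClassifierSpec",
                   cvFolds = "integer", seed = "integer",
                   provenance = "list", config = "list",
                   stageSizes = "integer"),
    validity = function(object) {
        msg <- character()
        a <- object@stepAccuracies
        if (length(a) != length(object@selectedGenes))
            msg <- c(msg, "one accuracy per selected gene required")
        if (length(a) > 1L && any(diff(a) <= 0))
            msg <- c(msg, "step accuracies must be strictly increasing")
        if (length(a) && !isTRUE(all.equal(object@finalAccuracy,
                                           a[length(a)])))
            msg <- c(msg, "finalAccuracy must equal the last step accuracy")
        if (any(a < 0 | a > 100))
            msg <- c(msg, "accuracies must lie in [0, 100]")
        if (length(msg)) msg else TRUE
    })

#' PipelineConfig: all pipeline settings in one validated object
#'
#' Defaults follow the method's published protocol: all three filters,
#' top-N of 50 per filter, independence threshold 0.5, equal-frequency
#' automatic binning, pairwise-max redundancy aggregation, KNN with k = 3,
#' stratified 10-fold cross-validation, z-score normalization on.
#'
#' @slot filters subset of \code{c("snr", "ts", "pc")}.
#' @slot topN per-filter top count N.
#' @slot redundancy a \linkS4class{RedundancyConfig}.
#' @slot classifier a \linkS4class{ClassifierSpec}.
#' @slot cvFolds fold count K (ignored when \code{cv = "loocv"}).
#' @slot cv \code{"kfold"} or \code{"loocv"}.
#' @slot strategy wrapper search strategy, \code{"best_first"} or
#'   \code{"scan"} (see [forwardSelect()]).
#' @slot normalize apply per-gene z-score normalization first.
#' @slot seed integer seed for fold assignment.
#' @seealso [pipelineConfig()], [runPipeline()]
#' @name PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(filters = "character", topN = "integer",
                   redundancy = "RedundancyConfig",
                   classifier = "ClassifierSpec", cvFolds = "integer",
                   cv = "character", strategy = "character",
                   normalize = "logical", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (!length(object@filters) ||
            !all(object@filters %in% c("snr", "ts", "pc")))
            msg <- c(msg, "filters must be a non-empty subset of snr/ts/pc")
        if (anyDuplicated(object@filters))
            msg <- c(msg, "duplicate filter names")
        if (is.na(object@topN) || object@topN < 1L)
            msg <- c(msg, "top_n must be a positive integer")
        if (!object@cv %in% c("kfold", "loocv"))
            msg <- c(msg, "cv must be 'kfold' or 'loocv'")
        if (!object@strategy %in% c("best_first", "scan"))
            msg <- c(msg, "strategy must be 'best_first' or 'scan'")
        if (object@cv == "kfold" && (is.na(object@cvFolds) ||
                                     object@cvFolds < 2L))
            msg <- c(msg, "cv_folds must be >= 2")
        if (length(msg)) msg else TRUE
    })
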