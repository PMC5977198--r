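#' Construct an ExpressionDataset
#'
#' Builds the package's central container from a plain numeric matrix and
#' a per-sample label vector. Any two distinct label values are accepted
#' and canonicalized to the factor levels \code{"0"} and \code{"1"} by
#' sorted order of the observed strings; the originals are retained in
#' \code{colData(x)$label_original}.
#'
#' @param exprs numeric matrix, genes in rows, samples in columns. Row
#'   and column names are used as gene/sample identifiers unless
#'   \code{geneIds}/\code{sampleIds} override them.
#' @param labels vector of length \code{ncol(exprs)} with exactly two
#'   distinct values, each observed at least twice.
#' @param geneIds,sampleIds optional identifier vectors.
#'
#' @return an \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' ds <- ExpressionDataset(m, rep(c("T", "N"), 5))
#' classLabels(ds)
#' @export
ExpressionDataset <- function(exprs, labels, geneIds = rownames(exprs),
                              sampleIds = colnames(exprs)) {
    exprs <- as.matrix(exprs)
    storage.mode(exprs) <- "double"
    if (is.null(geneIds))
        geneIds <- paste0("gene_", seq_len(nrow(exprs)))
    if (is.null(sampleIds))
        sampleIds <- paste0("sample_", seq_len(ncol(exprs)))
    if (length(labels) != ncol(exprs))
        stop("need one label per sample (", ncol(exprs), " samples, ",
             length(labels), " labels)")
    dimnames(exprs) <- list(as.character(geneIds), as.character(sampleIds))
    lab <- as.character(labels)
    lev <- sort(unique(lab))
    if (length(lev) != 2L)
        stop("exactly two distinct label values required, found ",
             length(lev), ": ", paste(lev, collapse = ", "))
    cls <- factor(match(lab, lev) - 1L, levels = c(0L, 1L))
    cd <- S4Vectors::DataFrame(class = cls, label_original = lab,
                               row.names = colnames(exprs))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(exprs = exprs), colData = cd)
    new("ExpressionDataset", se)
}

#' Accessors for ExpressionDataset
#'
#' \code{exprMatrix} returns the genes-by-samples numeric matrix;
#' \code{classLabels} the canonical two-level factor (\code{"0"} <
#' \code{"1"} in sorted order of the original label strings);
#' \code{geneIds} and \code{sampleIds} the identifier vectors.
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @return matrix, factor or character vector as described.
#' @name ExpressionDataset-accessors
#' @aliases exprMatrix classLabels geneIds sampleIds
NULL

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("exprMatrix", "ExpressionDataset", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("classLabels", "ExpressionDataset", function(x)
    SummarizedExperiment::colData(x)$class)

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

setMethod("show", "ExpressionDataset", function(object) {
    tab <- table(classLabels(object))
    cat("ExpressionDataset:", nrow(object), "genes x", ncol(object),
        "samples\n")
    orig <- split(SummarizedExperiment::colData(object)$label_original,
                  classLabels(object))
    cat(sprintf("  class 0 ('%s'): %d samples\n", orig[["0"]][1], tab[1]))
    cat(sprintf("  class 1 ('%s'): %d samples\n", orig[["1"]][1], tab[2]))
    invisible(NULL)
})

setMethod("show", "GeneRanking", function(object) {
    r <- object@ranking
    cat(sprintf("GeneRanking (%s): %d genes\n", object@filterName, nrow(r)))
    n <- min(5L, nrow(r))
    for (i in seq_len(n))
        cat(sprintf("  %4d  %-14s %.4g\n", r$rank[i], r$gene_id[i],
                    r$score[i]))
    if (nrow(r) > n) cat("  ...\n")
    invisible(NULL)
})

setMethod("show", "FilteredUnion", function(object) {
    cat(sprintf("FilteredUnion: %d candidate genes (top-%d per filter)\n",
                length(object@geneIds), object@N))
    n <- min(5L, length(object@geneIds))
    for (g in object@geneIds[seq_len(n)]) {
        p <- object@provenance[[g]]
        cat(sprintf("  %-14s %s\n", g,
                    paste(sprintf("%s#%d", p$filter, p$rank),
                          collapse = " ")))
    }
    if (length(object@geneIds) > n) cat("  ...\n")
    invisible(NULL)
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d gene(s), final CV accuracy %.2f%%\n",
                length(object@selectedGenes), object@finalAccuracy))
    cat(sprintf("  classifier: %s%s, %d-fold CV, seed %d\n",
                object@classifier@kind,
                if (object@classifier@kind == "knn")
                    sprintf(" (k=%d)", object@classifier@k) else "",
                object@cvFolds, object@seed))
    for (i in seq_along(object@selectedGenes))
        cat(sprintf("  step %d: + %-14s -> %.2f%%\n", i,
                    object@selectedGenes[i], object@stepAccuracies[i]))
    if (length(object@stageSizes))
        cat("  stages:", paste(names(object@stageSizes),
                               object@stageSizes, sep = "=",
                               collapse = " -> "), "\n")
    invisible(NULL)
})

#' Accessors for SelectionResult
#'
#' @param x a \linkS4class{SelectionResult}.
#' @return \code{selectedGenes}: character vector of the final subset in
#'   admission order; \code{stepAccuracies}: percent accuracy after each
#'   admission; \code{finalAccuracy}: the last of these.
#' @name SelectionResult-accessors
#' @aliases selectedGenes stepAccuracies finalAccuracy
NULL

#' @rdname SelectionResult-accessors
#' @export
setMethod("selectedGenes", "SelectionResult", function(x) x@selectedGenes)

#' @rdname SelectionResult-accessors
#' @export
setMethod("stepAccuracies", "SelectionResult", function(x)
    x@stepAccuracies)

#' @rdname SelectionResult-accessors
#' @export
setMethod("finalAccuracy", "SelectionResult", function(x) x@finalAccuracy)
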