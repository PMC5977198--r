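.inferSep <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression table with class labels
#'
#' Loads a CSV/TSV expression matrix (header row and identifier column
#' required) together with a binary class label per sample, and returns a
#' validated \linkS4class{ExpressionDataset}. Internally genes are always
#' stored as rows regardless of the file orientation; downstream results
#' do not depend on the orientation of the input file.
#'
#' Labels come either from a separate two-column delimited file
#' (\code{sample_id}, \code{label}; no header needed, one is tolerated) or
#' from a row (\code{genes_by_samples}) / column (\code{samples_by_genes})
#' of the expression table itself, named by \code{labels}.
#'
#' @param path path to the expression table. The delimiter is inferred
#'   from the extension (\code{.csv} is comma, anything else tab) unless
#'   \code{sep} overrides it.
#' @param orientation layout of the file: \code{"genes_by_samples"}
#'   (default, the common microarray layout) or \code{"samples_by_genes"}.
#' @param labels path to a label file, or the name of the label
#'   row/column inside the table.
#' @param sep optional delimiter override.
#'
#' @return an \linkS4class{ExpressionDataset}.
#' @seealso [writeExpressionTable()] for the inverse operation.
#' @export
readExpressionTable <- function(path,
                                orientation = c("genes_by_samples",
                                                "samples_by_genes"),
                                labels, sep = NULL) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .inferSep(path, sep)
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             row.names = 1, check.names = FALSE,
                             colClasses = "character",
                             comment.char = "", quote = "\"")
    if (anyDuplicated(rownames(raw)))
        stop("duplicate row identifiers: ",
             paste(unique(rownames(raw)[duplicated(rownames(raw))]),
                   collapse = ", "))
    if (anyDuplicated(colnames(raw)))
        stop("duplicate column identifiers: ",
             paste(unique(colnames(raw)[duplicated(colnames(raw))]),
                   collapse = ", "))

    labelVec <- NULL
    if (length(labels) == 1L && file.exists(labels)) {
        lt <- utils::read.table(labels, sep = .inferSep(labels),
                                header = FALSE, check.names = FALSE,
                                colClasses = "character")
        if (ncol(lt) < 2L)
            stop("label file must have two columns (sample_id, label)")
        # tolerate a header line
        if (identical(tolower(lt[1, 1]), "sample_id"))
            lt <- lt[-1, , drop = FALSE]
        labelVec <- stats::setNames(lt[[2]], lt[[1]])
    } else if (orientation == "genes_by_samples") {
        if (!labels %in% rownames(raw))
            stop("label row '", labels, "' not found in table")
        labelVec <- stats::setNames(unlist(raw[labels, ]), colnames(raw))
        raw <- raw[setdiff(rownames(raw), labels), , drop = FALSE]
    } else {
        if (!labels %in% colnames(raw))
            stop("label column '", labels, "' not found in table")
        labelVec <- stats::setNames(raw[[labels]], rownames(raw))
        raw <- raw[, setdiff(colnames(raw), labels), drop = FALSE]
    }

    m <- suppressWarnings(
        matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
               dimnames = dimnames(raw)))
    if (orientation == "samples_by_genes") m <- t(m)
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad)) {
        cells <- apply(utils::head(bad, 20), 1, function(ix)
            sprintf("gene '%s' / sample '%s'", rownames(m)[ix[1]],
                    colnames(m)[ix[2]]))
        stop("missing or non-numeric values at: ",
             paste(cells, collapse = "; "),
             if (nrow(bad) > 20) sprintf(" (and %d more)", nrow(bad) - 20)
             else "")
    }
    missing <- setdiff(colnames(m), names(labelVec))
    if (length(missing))
        stop("no label for sample(s): ", paste(missing, collapse = ", "))
    ExpressionDataset(m, labelVec[colnames(m)])
}

#' Write an expression table and its label file
#'
#' Writes the genes-by-samples matrix as delimited text (identifier
#' column + header row) and the original sample labels as a two-column
#' file, such that [readExpressionTable()] reproduces the dataset.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param path output path for the matrix; delimiter inferred from the
#'   extension as in [readExpressionTable()].
#' @param labelsPath output path for the label file (default:
#'   \code{<path>.labels.tsv}).
#' @param sep optional delimiter override.
#' @return invisibly, the two paths written.
#' @export
writeExpressionTable <- function(ds, path,
                                 labelsPath = paste0(path, ".labels.tsv"),
                                 sep = NULL) {
    stopifnot(is(ds, "ExpressionDataset"))
    sep <- .inferSep(path, sep)
    m <- exprMatrix(ds)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    lab <- SummarizedExperiment::colData(ds)$label_original
    utils::write.table(data.frame(sample_id = colnames(m), label = lab),
                       labelsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(c(path, labelsPath))
}

#' Per-gene z-score normalization
#'
#' Centers each gene to mean zero and scales it to unit sample standard
#' deviation (denominator n - 1) across all samples. Genes with zero
#' variance become all-zero, with a warning naming them. Normalization is
#' idempotent up to floating-point tolerance.
#'
#' Note this is computed once on the full dataset, before any
#' cross-validation, mirroring the published protocol; see the vignette
#' for a discussion of the train/test leakage this implies.
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @return a normalized \linkS4class{ExpressionDataset}.
#' @rdname zscoreNormalize
#' @export
setMethod("zscoreNormalize", "ExpressionDataset", function(x) {
    m <- exprMatrix(x)
    n <- ncol(m)
    mu <- rowMeans(m)
    ctr <- m - mu
    sdv <- sqrt(rowSums(ctr^2) / (n - 1))
    flat <- sdv == 0
    if (any(flat)) {
        warning(sum(flat), " zero-variance gene(s) set to all zeros: ",
                paste(utils::head(rownames(m)[flat], 5), collapse = ", "),
                if (sum(flat) > 5) ", ..." else "")
        sdv[flat] <- 1
    }
    out <- ctr / sdv
    out[flat, ] <- 0
    SummarizedExperiment::assay(x, "exprs") <- out
    x
})

.classifierAsList <- function(spec)
    list(kind = spec@kind,
         k = if (spec@kind == "knn") spec@k else NULL)

#' Write a machine- and human-readable selection report
#'
#' Writes a JSON report (selected genes, per-step accuracies, filter
#' provenance, complete configuration, seed, status flag) and a TSV gene
#' list next to it. An empty selection yields a valid report with zero
#' gene rows and \code{status = "empty"}.
#'
#' @param result a \linkS4class{SelectionResult}.
#' @param path path of the JSON report; the TSV gene list is written to
#'   the same path with extension \code{.tsv}.
#' @return invisibly, the JSON and TSV paths.
#' @seealso [readReport()]
#' @export
writeReport <- function(result, path) {
    stopifnot(is(result, "SelectionResult"))
    genes <- result@selectedGenes
    prov <- lapply(genes, function(g) {
        p <- result@provenance[[g]]
        if (is.null(p)) "" else
            paste(sprintf("%s#%d", p$filter, p$rank), collapse = ",")
    })
    rep <- list(
        status = if (length(genes)) "ok" else "empty",
        selected_genes = as.list(genes),
        step_accuracies = as.list(result@stepAccuracies),
        final_accuracy = if (length(genes)) result@finalAccuracy else NULL,
        provenance = stats::setNames(prov, genes),
        classifier = .classifierAsList(result@classifier),
        cv_folds = result@cvFolds,
        seed = result@seed,
        stage_sizes = as.list(result@stageSizes),
        config = result@config)
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    tsvPath <- sub("\\.json$", "", path)
    tsvPath <- paste0(tsvPath, ".tsv")
    df <- data.frame(step = seq_along(genes), gene_id = genes,
                     cv_accuracy_after = result@stepAccuracies,
                     filters = unlist(c(prov, list(character(0)))))
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, tsvPath))
}

#' Read back a JSON selection report
#'
#' @param path path written by [writeReport()].
#' @return the report as a named list; the \code{config} element
#'   round-trips exactly and can be fed to [pipelineConfig()] via
#'   \code{do.call} to replay a run.
#' @export
readReport <- function(path)
    jsonlite::read_json(path, simplifyVector = TRUE)
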