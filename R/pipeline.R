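#' Assemble a validated pipeline configuration
#'
#' Defaults reproduce the method's published experimental protocol:
#' z-score normalization, all three filters with top-N = 50 each,
#' redundancy threshold T = 0.5 with equal-frequency automatic binning
#' and pairwise-max aggregation, and a KNN (k = 3) wrapper under
#' stratified 10-fold cross-validation.
#'
#' @param filters character subset of \code{c("snr", "ts", "pc")}.
#' @param top_n per-filter top count N.
#' @param threshold redundancy threshold T in [0, 1].
#' @param binning \code{"equal_frequency"} or \code{"equal_width"}.
#' @param bins \code{"auto"} or an integer >= 2.
#' @param aggregation \code{"pairwise_max"} or \code{"joint"}.
#' @param classifier \code{"knn"}, \code{"svm"}/\code{"svm_linear"} or
#'   \code{"nb"}/\code{"naive_bayes"}.
#' @param knn_k neighbourhood size for KNN.
#' @param cv_folds fold count K.
#' @param cv \code{"kfold"} or \code{"loocv"}.
#' @param strategy wrapper search strategy, \code{"best_first"}
#'   (default) or \code{"scan"}; see [forwardSelect()].
#' @param normalize apply z-score normalization before filtering.
#' @param seed integer seed for fold assignment.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(filters = c("snr", "ts", "pc"), top_n = 50L,
                           threshold = 0.5,
                           binning = "equal_frequency", bins = "auto",
                           aggregation = "pairwise_max",
                           classifier = "knn", knn_k = 3L,
                           cv_folds = 10L, cv = "kfold",
                           strategy = "best_first",
                           normalize = TRUE, seed = 1L) {
    kind <- switch(as.character(classifier),
                   knn = "knn",
                   svm = , svm_linear = "svm_linear",
                   nb = , naive_bayes = "naive_bayes",
                   stop("unknown classifier: ", classifier))
    cfg <- new("PipelineConfig",
               filters = as.character(filters),
               topN = as.integer(top_n),
               redundancy = redundancyConfig(threshold = threshold,
                                             binMethod = binning,
                                             nBins = bins,
                                             aggregation = aggregation),
               classifier = classifierSpec(kind, k = knn_k),
               cvFolds = as.integer(cv_folds), cv = as.character(cv),
               strategy = as.character(strategy),
               normalize = isTRUE(normalize), seed = as.integer(seed))
    validObject(cfg)
    cfg
}

.configAsList <- function(cfg) {
    list(filters = cfg@filters, top_n = cfg@topN,
         threshold = cfg@redundancy@threshold,
         binning = cfg@redundancy@binMethod,
         bins = if (is.na(cfg@redundancy@nBins)) "auto"
                else cfg@redundancy@nBins,
         aggregation = cfg@redundancy@aggregation,
         classifier = cfg@classifier@kind, knn_k = cfg@classifier@k,
         cv_folds = cfg@cvFolds, cv = cfg@cv, strategy = cfg@strategy,
         normalize = cfg@normalize, seed = cfg@seed)
}

.configFromList <- function(lst) {
    lst <- lst[names(lst) %in% names(formals(pipelineConfig))]
    do.call(pipelineConfig, lst)
}

.stage <- function(name, expr)
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

#' Run the full gene-selection pipeline
#'
#' Executes the four stages in order on a two-class expression dataset:
#' per-gene z-score normalization (optional), univariate filter ranking
#' and top-N union (candidate set F), normalized cross-entropy
#' redundancy elimination (non-redundant set G), and greedy forward
#' wrapper selection under cross-validated accuracy (final subset R).
#' Stage sizes and timings are logged via \code{message()}; the stage
#' containment R \eqn{\subseteq} G \eqn{\subseteq} F \eqn{\subseteq}
#' genes is asserted on every run. Fully reproducible given the
#' configuration seed.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param verbose emit per-stage log messages (default TRUE).
#' @return a \linkS4class{SelectionResult} carrying the selected genes,
#'   per-step accuracies, filter provenance, the full configuration and
#'   the stage sizes.
#' @examples
#' sim <- simulateMicroarray(nSamples = 40, nGenes = 120, seed = 3)
#' res <- runPipeline(sim$dataset,
#'                    pipelineConfig(top_n = 20, seed = 3),
#'                    verbose = FALSE)
#' res
#' @export
runPipeline <- function(ds, config = pipelineConfig(), verbose = TRUE) {
    stopifnot(is(ds, "ExpressionDataset"), is(config, "PipelineConfig"))
    say <- function(...) if (verbose) message(...)
    t0 <- proc.time()[["elapsed"]]
    tick <- function() {
        dt <- proc.time()[["elapsed"]] - t0
        t0 <<- proc.time()[["elapsed"]]
        sprintf("%.2fs", dt)
    }
    nGenes <- nrow(ds)

    work <- .stage("normalize",
        if (config@normalize) zscoreNormalize(ds) else ds)
    say("normalize: ", nGenes, " genes, ", ncol(ds), " samples [",
        tick(), "]")

    rankings <- .stage("filter",
        lapply(config@filters, function(f) rankGenes(work, f)))
    fUnion <- .stage("union", unionTopN(rankings, config@topN))
    say("filter+union: |F| = ", length(fUnion@geneIds), " (top-",
        config@topN, " x ", length(config@filters), " filters) [",
        tick(), "]")

    G <- .stage("redundancy",
        eliminateRedundant(fUnion, work, config@redundancy))
    say("redundancy: |G| = ", length(G), " at T = ",
        config@redundancy@threshold, " [", tick(), "]")

    sel <- .stage("wrapper",
        forwardSelect(G, work, spec = config@classifier,
                      folds = config@cvFolds, seed = config@seed,
                      cv = config@cv, strategy = config@strategy))
    say("wrapper: |R| = ", length(sel@selectedGenes),
        ", final accuracy ", sprintf("%.2f", sel@finalAccuracy), "% [",
        tick(), "]")

    stopifnot(all(sel@selectedGenes %in% G),
              all(G %in% fUnion@geneIds),
              all(fUnion@geneIds %in% geneIds(ds)))

    sel@provenance <- fUnion@provenance[sel@selectedGenes]
    sel@config <- .configAsList(config)
    sel@stageSizes <- c(genes = nGenes, F = length(fUnion@geneIds),
                        G = length(G), R = length(sel@selectedGenes))
    validObject(sel)
    sel
}
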