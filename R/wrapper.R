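#' Specify the wrapper's classifier
#'
#' @param kind \code{"knn"} (k-nearest neighbours, Euclidean distance),
#'   \code{"svm_linear"} (support vector machine, linear kernel, cost 1)
#'   or \code{"naive_bayes"} (Gaussian naive Bayes).
#' @param k neighbourhood size for KNN; default 3, odd so a two-class
#'   vote cannot tie.
#' @return a \linkS4class{ClassifierSpec}.
#' @export
classifierSpec <- function(kind = c("knn", "svm_linear", "naive_bayes"),
                           k = 3L) {
    kind <- match.arg(kind)
    new("ClassifierSpec", kind = kind, k = as.integer(k))
}

# evaluate expr under a private RNG stream, leaving the caller's
# .Random.seed untouched
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    expr
}

# stratified fold assignment: within each class, samples are shuffled
# (seeded) and dealt round-robin into K folds
.makeFolds <- function(cls, folds, seed) {
    n <- length(cls)
    foldid <- integer(n)
    .withSeed(seed, {
        for (lev in levels(cls)) {
            idx <- sample(which(cls == lev))
            foldid[idx] <- rep_len(seq_len(folds), length(idx))
        }
    })
    foldid
}

# number of correctly classified samples over all held-out folds,
# as an exact integer count
.cvCorrect <- function(m, cls, genes, spec, foldid) {
    correct <- 0L
    X <- t(m[genes, , drop = FALSE])
    for (f in unique(foldid)) {
        test <- foldid == f
        xtr <- X[!test, , drop = FALSE]
        xte <- X[test, , drop = FALSE]
        ytr <- cls[!test]
        pred <- switch(spec@kind,
            knn = class::knn(xtr, xte, ytr,
                             k = min(spec@k, nrow(xtr))),
            svm_linear = {
                fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1,
                                  scale = FALSE)
                stats::predict(fit, xte)
            },
            naive_bayes = {
                fit <- e1071::naiveBayes(xtr, ytr)
                stats::predict(fit, xte)
            })
        correct <- correct + sum(as.character(pred) ==
                                 as.character(cls[test]))
    }
    correct
}

#' Cross-validated classification accuracy of a gene subset
#'
#' Stratified K-fold cross-validation: within each class, samples are
#' shuffled with the given seed and dealt round-robin into K folds, so
#' class proportions are preserved; accuracy is the pooled fraction of
#' correctly classified held-out samples, in percent. If a class has
#' fewer samples than K, the fold count is reduced to the smallest class
#' size with a warning. \code{cv = "loocv"} performs leave-one-out
#' cross-validation instead (the fold count is then n).
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param genes non-empty character vector of gene ids to use as
#'   features.
#' @param spec a \linkS4class{ClassifierSpec} (default KNN, k = 3).
#' @param folds fold count K (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @param cv \code{"kfold"} or \code{"loocv"}.
#' @return accuracy in percent, in [0, 100]; deterministic given seed.
#' @export
cvAccuracy <- function(ds, genes, spec = classifierSpec(), folds = 10L,
                       seed = 1L, cv = c("kfold", "loocv")) {
    cv <- match.arg(cv)
    stopifnot(is(ds, "ExpressionDataset"), is(spec, "ClassifierSpec"))
    genes <- as.character(genes)
    if (!length(genes)) stop("gene subset is empty")
    missing <- setdiff(genes, geneIds(ds))
    if (length(missing))
        stop("unknown gene id(s): ", paste(missing, collapse = ", "))
    cls <- classLabels(ds)
    foldid <- .resolveFolds(cls, folds, seed, cv)
    m <- exprMatrix(ds)
    100 * .cvCorrect(m, cls, genes, spec, foldid) / length(cls)
}

.resolveFolds <- function(cls, folds, seed, cv) {
    if (cv == "loocv") return(seq_along(cls))
    folds <- as.integer(folds)
    minClass <- min(table(cls))
    if (minClass < folds) {
        warning("smallest class has ", minClass, " samples; reducing ",
                "fold count from ", folds, " to ", minClass)
        folds <- minClass
    }
    .makeFolds(cls, folds, as.integer(seed))
}

#' Greedy forward selection scored by cross-validated accuracy
#'
#' Forward feature selection over an ordered candidate gene list G,
#' scored by cross-validated classification accuracy. Two search
#' strategies are available:
#' \describe{
#'   \item{\code{"best_first"} (default)}{standard greedy forward
#'     selection. First every single gene is evaluated and the best is
#'     admitted (ties go to the earlier position in G); then,
#'     repeatedly, every remaining candidate is evaluated joined to the
#'     current subset and the best is admitted iff it strictly improves
#'     accuracy. Stops when accuracy reaches 100 percent, no candidate
#'     strictly improves, or G is exhausted.}
#'   \item{\code{"scan"}}{the admit-on-improvement variant: after the
#'     best single gene is admitted, the remaining candidates are
#'     examined once, in G's order, and each one that strictly improves
#'     the current accuracy is admitted immediately. This follows lower
#'     accuracy gradients and therefore tends to admit more genes than
#'     best-first, which often saturates after very few admissions on
#'     small sample sets; see the vignette.}
#' }
#' Under either strategy improvement is decided on exact integer counts
#' of correctly classified samples, so floating-point equality never
#' enters the comparison, and the fold assignment is drawn once from
#' the seed and reused for every subset evaluation.
#'
#' @param G ordered character vector of candidate gene ids (typically
#'   the output of [eliminateRedundant()]).
#' @param strategy \code{"best_first"} or \code{"scan"}.
#' @inheritParams cvAccuracy
#' @return a \linkS4class{SelectionResult}; its per-step accuracies are
#'   strictly increasing and its final accuracy is at least the best
#'   single-gene accuracy.
#' @examples
#' sim <- simulateMicroarray(nSamples = 40, nGenes = 30,
#'                           nInformative = 2, seed = 2)
#' res <- forwardSelect(geneIds(sim$dataset), sim$dataset, seed = 2)
#' selectedGenes(res)
#' @export
forwardSelect <- function(G, ds, spec = classifierSpec(), folds = 10L,
                          seed = 1L, cv = c("kfold", "loocv"),
                          strategy = c("best_first", "scan")) {
    cv <- match.arg(cv)
    strategy <- match.arg(strategy)
    stopifnot(is(ds, "ExpressionDataset"), is(spec, "ClassifierSpec"))
    G <- as.character(G)
    if (!length(G)) stop("candidate gene list G is empty")
    cls <- classLabels(ds)
    n <- length(cls)
    foldid <- .resolveFolds(cls, folds, seed, cv)
    m <- exprMatrix(ds)

    evalSubset <- function(genes) .cvCorrect(m, cls, genes, spec, foldid)

    selected <- character(0)
    stepCorrect <- integer(0)
    best <- -1L
    remaining <- G
    if (strategy == "best_first") {
        repeat {
            cand <- vapply(remaining, function(g)
                evalSubset(c(selected, g)), integer(1),
                USE.NAMES = FALSE)
            top <- which.max(cand)   # ties -> earliest position in G
            if (cand[top] <= best) break
            best <- cand[top]
            selected <- c(selected, remaining[top])
            stepCorrect <- c(stepCorrect, best)
            remaining <- remaining[-top]
            if (best == n || !length(remaining)) break
        }
    } else {
        single <- vapply(G, function(g) evalSubset(g), integer(1),
                         USE.NAMES = FALSE)
        best <- max(single)
        selected <- G[which.max(single)]
        stepCorrect <- best
        for (g in G[-which.max(single)]) {
            if (best == n) break
            a <- evalSubset(c(selected, g))
            if (a > best) {
                best <- a
                selected <- c(selected, g)
                stepCorrect <- c(stepCorrect, best)
            }
        }
    }
    acc <- 100 * stepCorrect / n
    new("SelectionResult", selectedGenes = selected,
        stepAccuracies = acc, finalAccuracy = acc[length(acc)],
        classifier = spec,
        cvFolds = if (cv == "loocv") n else length(unique(foldid)),
        seed = as.integer(seed), provenance = list(), config = list(),
        stageSizes = integer(0))
}
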