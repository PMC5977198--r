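#' Univariate filter scores for one gene
#'
#' The three relevance filters used for gene ranking, each scoring one
#' gene's expression vector against the binary class label:
#'
#' \describe{
#'   \item{\code{snrScore}}{signal-to-noise ratio
#'     \eqn{|\mu_+ - \mu_-| / (\sigma_+ + \sigma_-)} with sample
#'     (n - 1) standard deviations. Non-negative; if both within-class
#'     standard deviations are zero the score is \code{Inf} when the
#'     class means differ (maximally discriminative by the formula's own
#'     logic) and \code{0} when they are equal.}
#'   \item{\code{tScore}}{Welch-style two-sample statistic
#'     \eqn{(\bar x_2 - \bar x_1) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}; the
#'     ranking key is its absolute value. Signed \code{Inf} when both
#'     variances vanish with distinct means, \code{0} when means are also
#'     equal.}
#'   \item{\code{pearsonScore}}{Pearson correlation between the gene and
#'     the \{0,1\}-encoded label; the ranking key is its absolute value.
#'     A zero-variance gene scores \code{0} with a warning (correlation
#'     undefined).}
#' }
#'
#' @param values numeric expression of one gene across samples.
#' @param labels binary labels, one per sample; coerced through
#'   factor levels so any two-value coding works. Each class must have at
#'   least two samples for \code{snrScore}/\code{tScore}.
#' @return a single numeric score.
#' @examples
#' snrScore(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))  # 1.5
#' @name filterScores
NULL

.splitClasses <- function(values, labels) {
    f <- as.factor(labels)
    if (nlevels(f) != 2L)
        stop("labels must have exactly two classes, found ", nlevels(f))
    split(as.numeric(values), f)
}

#' @rdname filterScores
#' @export
snrScore <- function(values, labels) {
    g <- .splitClasses(values, labels)
    if (any(lengths(g) < 2L))
        stop("each class needs >= 2 samples for snrScore")
    num <- abs(mean(g[[1]]) - mean(g[[2]]))
    den <- stats::sd(g[[1]]) + stats::sd(g[[2]])
    if (den == 0) return(if (num == 0) 0 else Inf)
    num / den
}

#' @rdname filterScores
#' @export
tScore <- function(values, labels) {
    g <- .splitClasses(values, labels)
    n <- lengths(g)
    if (any(n < 2L))
        stop("each class needs >= 2 samples for tScore")
    num <- mean(g[[2]]) - mean(g[[1]])
    den <- sqrt(stats::var(g[[1]]) / n[[1]] + stats::var(g[[2]]) / n[[2]])
    if (den == 0) return(if (num == 0) 0 else sign(num) * Inf)
    num / den
}

#' @rdname filterScores
#' @export
pearsonScore <- function(values, labels) {
    y <- as.integer(as.factor(labels)) - 1L
    if (length(unique(y)) != 2L)
        stop("labels must have exactly two classes")
    v <- as.numeric(values)
    if (stats::sd(v) == 0) {
        warning("zero-variance gene: Pearson correlation undefined, ",
                "scoring 0")
        return(0)
    }
    stats::cor(v, y)
}

# Vectorized scoring of all genes at once; row-wise arithmetic kept in
# matrix form so ranking a few thousand genes stays instantaneous.
.scoreAll <- function(m, cls, filter) {
    i0 <- cls == levels(cls)[1]
    m0 <- m[, i0, drop = FALSE]; m1 <- m[, !i0, drop = FALSE]
    n0 <- ncol(m0); n1 <- ncol(m1)
    mu0 <- rowMeans(m0); mu1 <- rowMeans(m1)
    v0 <- rowSums((m0 - mu0)^2) / (n0 - 1)
    v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
    if (filter == "snr") {
        num <- abs(mu0 - mu1); den <- sqrt(v0) + sqrt(v1)
        s <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
    } else if (filter == "ts") {
        num <- mu1 - mu0; den <- sqrt(v0 / n0 + v1 / n1)
        s <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf),
                    num / den)
    } else {
        y <- as.integer(cls) - 1L
        mu <- rowMeans(m); ctr <- m - mu
        sy <- y - mean(y)
        num <- as.vector(ctr %*% sy)
        den <- sqrt(rowSums(ctr^2) * sum(sy^2))
        flat <- den == 0
        if (any(flat))
            warning(sum(flat), " zero-variance gene(s) scored 0 under ",
                    "the Pearson filter")
        s <- ifelse(flat, 0, num / den)
    }
    unname(s)
}

#' Rank all genes of a dataset under one filter
#'
#' Scores every gene with the chosen filter and sorts by the ranking key
#' in decreasing order: the raw score for \code{"snr"} (already
#' non-negative), the absolute value for \code{"ts"} and \code{"pc"}
#' (two-class relevance is sign-symmetric). Ties are broken by ascending
#' position in the input, so rankings are deterministic; degenerate
#' zero-denominator genes carry an infinite key and rank first, among
#' themselves in input order.
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @param filter \code{"snr"}, \code{"ts"} or \code{"pc"}.
#' @return a \linkS4class{GeneRanking}.
#' @examples
#' ds <- simulateMicroarray(nSamples = 20, nGenes = 50, seed = 1)$dataset
#' rankGenes(ds, "snr")
#' @rdname rankGenes
#' @export
setMethod("rankGenes", "ExpressionDataset",
          function(x, filter = c("snr", "ts", "pc")) {
    filter <- match.arg(filter)
    m <- exprMatrix(x)
    s <- .scoreAll(m, classLabels(x), filter)
    key <- if (filter == "snr") s else abs(s)
    ord <- order(-key, seq_along(key))
    rk <- S4Vectors::DataFrame(gene_id = rownames(m)[ord],
                               score = s[ord], key = key[ord],
                               rank = seq_along(ord), index = ord)
    new("GeneRanking", filterName = filter, ranking = rk)
})

#' Export a ranking as a plain data.frame or TSV
#'
#' @param ranking a \linkS4class{GeneRanking}.
#' @param path optional path; when given, a TSV with columns
#'   \code{rank}, \code{gene_id}, \code{score} is written there.
#' @return the ranking as a \code{data.frame} (invisibly when writing).
#' @export
rankingTable <- function(ranking, path = NULL) {
    stopifnot(is(ranking, "GeneRanking"))
    df <- as.data.frame(ranking@ranking[, c("rank", "gene_id", "score")])
    if (!is.null(path)) {
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(df))
    }
    df
}

#' Merge per-filter top-N lists into the candidate set
#'
#' Takes the union of each filter's top-N genes and deduplicates it,
#' recording for every candidate which filters contributed it and at what
#' rank. Candidates are ordered by their best (minimum) rank across
#' contributing filters, ties by mean contributing rank, remaining ties
#' by input gene order — so the most relevant candidates are examined
#' first by the downstream redundancy screen. With L filters the union
#' size always lies in [N, L*N].
#'
#' @param rankings list of \linkS4class{GeneRanking} objects over the
#'   same gene universe.
#' @param N per-filter top count (positive, at most the gene count).
#' @return a \linkS4class{FilteredUnion}.
#' @export
unionTopN <- function(rankings, N) {
    if (is(rankings, "GeneRanking")) rankings <- list(rankings)
    stopifnot(length(rankings) >= 1L,
              all(vapply(rankings, is, logical(1), "GeneRanking")))
    N <- as.integer(N)
    if (is.na(N) || N < 1L) stop("top_n must be a positive integer")
    universe <- sort(rankings[[1]]@ranking$gene_id)
    for (r in rankings[-1])
        if (!identical(sort(r@ranking$gene_id), universe))
            stop("rankings cover different gene universes")
    if (N > length(universe))
        stop("top_n (", N, ") exceeds number of genes (",
             length(universe), ")")
    inputIdx <- stats::setNames(rankings[[1]]@ranking$index,
                                rankings[[1]]@ranking$gene_id)
    prov <- list()
    for (r in rankings) {
        top <- utils::head(r@ranking, N)
        for (i in seq_len(nrow(top))) {
            g <- top$gene_id[i]
            prov[[g]] <- rbind(prov[[g]],
                               data.frame(filter = r@filterName,
                                          rank = top$rank[i]))
        }
    }
    ids <- names(prov)
    best <- vapply(prov, function(p) min(p$rank), numeric(1))
    avg <- vapply(prov, function(p) mean(p$rank), numeric(1))
    pos <- inputIdx[ids]
    ids <- ids[order(best, avg, pos)]
    new("FilteredUnion", geneIds = ids, provenance = prov[ids], N = N)
}
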