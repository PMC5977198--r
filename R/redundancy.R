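#' Settings for the cross-entropy redundancy screen
#'
#' @param threshold independence threshold T in [0, 1]. A candidate gene
#'   is kept while its redundancy against the already-kept set is
#'   strictly below T; the published protocol uses 0.5 and reports
#'   insensitivity over roughly [0.4, 0.8].
#' @param binMethod \code{"equal_frequency"} (default; quantile cut
#'   points, robust to outliers and monotone transforms) or
#'   \code{"equal_width"}.
#' @param nBins bins per gene, or \code{"auto"} =
#'   \code{ceiling(sqrt(n_samples))} floored at 2.
#' @param aggregation how a candidate is compared against a set of kept
#'   genes: \code{"pairwise_max"} (default) takes the maximum pairwise
#'   normalized cross-entropy; \code{"joint"} evaluates one joint
#'   normalized cross-entropy over kept genes plus candidate. With tens
#'   of samples the joint plug-in entropy over many genes saturates
#'   (every sample lands in its own cell), which is why pairwise-max is
#'   the default; see the vignette.
#' @return a \linkS4class{RedundancyConfig}.
#' @export
redundancyConfig <- function(threshold = 0.5,
                             binMethod = c("equal_frequency",
                                           "equal_width"),
                             nBins = "auto",
                             aggregation = c("pairwise_max", "joint")) {
    binMethod <- match.arg(binMethod)
    aggregation <- match.arg(aggregation)
    nb <- if (identical(nBins, "auto")) NA_integer_ else as.integer(nBins)
    new("RedundancyConfig", threshold = as.numeric(threshold),
        binMethod = binMethod, nBins = nb, aggregation = aggregation)
}

.autoBins <- function(n) max(2L, as.integer(ceiling(sqrt(n))))

#' Discretize a continuous vector into bin symbols
#'
#' Maps each value to an integer bin index. Equal-frequency binning cuts
#' at the sample quantiles; equal-width binning cuts the observed range
#' into equal intervals. A value equal to a cut point is assigned to the
#' lower bin (right-closed intervals), deterministically. A constant
#' vector yields a single symbol under either scheme; under
#' equal-frequency binning any strictly monotone transform of the values
#' leaves the symbols unchanged.
#'
#' @param values finite numeric vector.
#' @param binMethod \code{"equal_frequency"} or \code{"equal_width"}.
#' @param nBins number of bins (at least 2, at most \code{length(values)})
#'   or \code{"auto"} for \code{ceiling(sqrt(n))}.
#' @return integer vector of bin indices (1-based).
#' @examples
#' discretize(c(1, 2, 3, 4), nBins = 2)  # 1 1 2 2
#' @export
discretize <- function(values, binMethod = c("equal_frequency",
                                             "equal_width"),
                       nBins = "auto") {
    binMethod <- match.arg(binMethod)
    values <- as.numeric(values)
    if (!length(values)) stop("empty input")
    if (any(!is.finite(values))) stop("values must be finite")
    n <- length(values)
    nb <- if (identical(nBins, "auto")) .autoBins(n) else as.integer(nBins)
    if (nb < 2L) stop("nBins must be >= 2")
    if (nb > n) stop("nBins (", nb, ") exceeds number of samples (", n, ")")
    breaks <- if (binMethod == "equal_frequency")
        stats::quantile(values, probs = seq(0, 1, length.out = nb + 1L),
                        names = FALSE)
    else
        seq(min(values), max(values), length.out = nb + 1L)
    breaks <- unique(breaks)
    if (length(breaks) < 2L) return(rep.int(1L, n))
    cut(values, breaks = breaks, include.lowest = TRUE, right = TRUE,
        labels = FALSE)
}

.symbolKey <- function(vecs) {
    # collapse one or more equal-length symbol vectors into one joint
    # symbol per observation
    if (length(vecs) == 1L) return(as.character(vecs[[1]]))
    do.call(paste, c(lapply(vecs, as.character), sep = "\r"))
}

#' Plug-in Shannon entropy of discrete vectors
#'
#' Maximum-likelihood ("plug-in") Shannon entropy of the empirical
#' distribution, in bits. Given several equal-length vectors with
#' \code{joint = TRUE}, the entropy of their empirical joint distribution
#' is returned; with \code{joint = FALSE}, the sum of the marginal
#' entropies.
#'
#' @param ... one or more vectors of discrete symbols (any atomic type),
#'   or a single list of such vectors.
#' @param joint if \code{TRUE} (default) compute the joint entropy,
#'   otherwise the sum of marginals.
#' @param base logarithm base (default 2, bits).
#' @return non-negative entropy value.
#' @examples
#' shannonEntropy(c(0, 0, 1, 1))            # 1 bit
#' shannonEntropy(c(0, 0, 1), c(0, 1, 0))   # joint entropy, log2(3)
#' @export
shannonEntropy <- function(..., joint = TRUE, base = 2) {
    vecs <- list(...)
    if (length(vecs) == 1L && is.list(vecs[[1]])) vecs <- vecs[[1]]
    if (!length(vecs) || any(!lengths(vecs)))
        stop("empty input")
    if (length(unique(lengths(vecs))) != 1L)
        stop("vectors must have equal length")
    ent1 <- function(x) {
        p <- tabulate(factor(x)) / length(x)
        p <- p[p > 0]
        -sum(p * log(p, base = base))
    }
    if (joint) ent1(.symbolKey(vecs))
    else sum(vapply(vecs, ent1, numeric(1)))
}

#' Normalized cross-entropy (normalized total correlation)
#'
#' The dependency measure used by the redundancy screen: for n discrete
#' variables with marginal plug-in entropies \eqn{H_1, \dots, H_n} and
#' joint entropy \eqn{H},
#' \deqn{\bar D_n = (H_1 + \dots + H_n - H) / ((n - 1) H),}
#' a normalization of the total correlation (multi-information). It lies
#' in [0, 1]: 0 for empirically independent variables (the joint
#' distribution factorizes), 1 for maximal dependence (e.g. a duplicated
#' non-constant variable). The logarithm base cancels in the ratio.
#'
#' When all variables are constant the joint entropy is zero and no
#' dependence is measurable; the value is defined as 0 with a warning.
#'
#' @param ... two or more equal-length vectors of discrete symbols, or a
#'   single list of them.
#' @return a value in [0, 1].
#' @examples
#' normalizedCrossEntropy(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0, independent
#' normalizedCrossEntropy(c(0, 1, 0, 1), c(0, 1, 0, 1))  # 1, duplicate
#' @export
normalizedCrossEntropy <- function(...) {
    vecs <- list(...)
    if (length(vecs) == 1L && is.list(vecs[[1]])) vecs <- vecs[[1]]
    n <- length(vecs)
    if (n < 2L) stop("need at least two variables")
    if (length(unique(lengths(vecs))) != 1L)
        stop("vectors must have equal length")
    H <- shannonEntropy(vecs, joint = TRUE)
    if (H == 0) {
        warning("all variables constant: joint entropy is zero, ",
                "no dependence measurable; returning 0")
        return(0)
    }
    Hi <- shannonEntropy(vecs, joint = FALSE)
    val <- (Hi - H) / ((n - 1) * H)
    # clamp tiny negative rounding residue
    min(max(val, 0), 1)
}

#' Redundancy of a candidate against a set of kept genes
#'
#' Under \code{"pairwise_max"} aggregation, the maximum pairwise
#' normalized cross-entropy between the candidate and each kept gene;
#' under \code{"joint"}, one joint normalized cross-entropy over kept
#' genes plus candidate. An empty kept set gives 0: a candidate is
#' always independent of nothing.
#'
#' @param keptSymbols list of discretized symbol vectors (possibly
#'   empty).
#' @param candidateSymbols discretized symbol vector of the candidate.
#' @param aggregation \code{"pairwise_max"} or \code{"joint"}.
#' @return redundancy value in [0, 1].
#' @export
redundancyAgainstSet <- function(keptSymbols, candidateSymbols,
                                 aggregation = c("pairwise_max",
                                                 "joint")) {
    aggregation <- match.arg(aggregation)
    if (!length(keptSymbols)) return(0)
    if (aggregation == "pairwise_max")
        max(vapply(keptSymbols, function(g)
            normalizedCrossEntropy(g, candidateSymbols), numeric(1)))
    else
        normalizedCrossEntropy(c(keptSymbols, list(candidateSymbols)))
}

#' Eliminate redundant genes from the candidate union
#'
#' Walks the candidate genes in the union's order (best filter rank
#' first). The working gene set starts empty; each candidate is admitted
#' iff its redundancy against the genes admitted so far is strictly
#' below the threshold T (the first candidate is therefore always
#' admitted). Expression values are discretized once, per gene, with the
#' configured scheme before any entropy is computed.
#'
#' @param x a \linkS4class{FilteredUnion} or a character vector of gene
#'   ids giving the processing order.
#' @param ds the \linkS4class{ExpressionDataset} holding the expression
#'   of every candidate.
#' @param config a \linkS4class{RedundancyConfig}.
#' @return character vector: the non-redundant gene set G, in admission
#'   order (never empty for a non-empty candidate list).
#' @examples
#' sim <- simulateMicroarray(nSamples = 30, nGenes = 30, seed = 1)
#' ds <- plantExactDuplicates(sim$dataset, geneIds(sim$dataset)[1], 2)
#' eliminateRedundant(geneIds(ds), ds, redundancyConfig())
#' @export
eliminateRedundant <- function(x, ds, config = redundancyConfig()) {
    stopifnot(is(config, "RedundancyConfig"), is(ds, "ExpressionDataset"))
    ids <- if (is(x, "FilteredUnion")) x@geneIds else as.character(x)
    if (!length(ids)) stop("candidate gene list is empty")
    missing <- setdiff(ids, geneIds(ds))
    if (length(missing))
        stop("candidate gene(s) absent from dataset: ",
             paste(utils::head(missing, 5), collapse = ", "))
    m <- exprMatrix(ds)
    nb <- if (is.na(config@nBins)) .autoBins(ncol(m)) else config@nBins
    sym <- lapply(ids, function(g)
        discretize(m[g, ], binMethod = config@binMethod, nBins = nb))
    names(sym) <- ids
    kept <- character(0)
    for (g in ids) {
        if (!length(kept)) {
            kept <- g
            next
        }
        d <- redundancyAgainstSet(sym[kept], sym[[g]],
                                  aggregation = config@aggregation)
        if (d < config@threshold) kept <- c(kept, g)
    }
    kept
}
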