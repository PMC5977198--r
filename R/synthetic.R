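#' Simulate a microarray-like two-class expression dataset
#'
#' Generates a seeded dataset with the structure typical of two-class
#' tumour microarray studies — a high-dimensional gene space, a small
#' sample count, a handful of class-informative genes, correlated
#' redundant copies of them, and a large background of uninformative
#' noise genes — so that every selection stage can be exercised with a
#' known ground truth.
#'
#' Informative genes are class-conditional Gaussians with unit variance
#' and a between-class mean shift of \code{effectSize} (so
#' \code{effectSize} is the standardized mean difference). Redundant
#' genes are a parent informative gene plus independent
#' \code{N(0, redundancyNoiseSd^2)} perturbation — near-duplicates, not
#' re-draws, so their discretized dependence on the parent is close to
#' maximal. Noise genes are independent standard normals. Gene order in
#' the matrix is shuffled (seeded) so no stage can exploit gene
#' position.
#'
#' @param nSamples number of samples (>= 4).
#' @param nGenes total number of genes.
#' @param nInformative number of class-informative genes.
#' @param nRedundantPerInformative redundant copies planted per
#'   informative gene.
#' @param effectSize standardized mean difference between classes for
#'   informative genes.
#' @param redundancyNoiseSd standard deviation of the perturbation added
#'   to redundant copies.
#' @param classBalance fraction of samples in class 1 (labels
#'   \code{"pos"}); the count is rounded.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a list with elements \code{dataset}
#'   (\linkS4class{ExpressionDataset}) and \code{truth} (a list with
#'   \code{informative_ids}, \code{redundant_ids},
#'   \code{redundant_parent} — a named vector mapping each redundant
#'   gene to its parent informative gene —, \code{noise_ids},
#'   \code{effect_size}, \code{redundancy_noise_sd}).
#' @examples
#' sim <- simulateMicroarray(nSamples = 20, nGenes = 100, seed = 1)
#' sim$dataset
#' sim$truth$informative_ids
#' @export
simulateMicroarray <- function(nSamples = 60L, nGenes = 500L,
                               nInformative = 5L,
                               nRedundantPerInformative = 4L,
                               effectSize = 2.0,
                               redundancyNoiseSd = 0.1,
                               classBalance = 0.5, seed = 1L) {
    nSamples <- as.integer(nSamples); nGenes <- as.integer(nGenes)
    nInformative <- as.integer(nInformative)
    nRed <- as.integer(nRedundantPerInformative)
    if (nSamples < 4L) stop("nSamples must be >= 4")
    if (nInformative * (1L + nRed) > nGenes)
        stop("nInformative * (1 + nRedundantPerInformative) exceeds ",
             "nGenes")
    nPos <- as.integer(round(nSamples * classBalance))
    if (nPos < 2L || nSamples - nPos < 2L)
        stop("classBalance leaves a class with fewer than 2 samples")
    labels <- rep(c("neg", "pos"), c(nSamples - nPos, nPos))
    shift <- ifelse(labels == "pos", effectSize, 0)

    .withSeed(as.integer(seed), {
        infIds <- sprintf("inf_%02d", seq_len(nInformative))
        inf <- t(vapply(infIds, function(g)
            stats::rnorm(nSamples, mean = shift),
            numeric(nSamples)))
        redIds <- character(0); redParent <- character(0)
        red <- matrix(0, nrow = 0, ncol = nSamples)
        if (nInformative && nRed) {
            for (p in infIds) {
                for (j in seq_len(nRed)) {
                    redIds <- c(redIds, sprintf("red_%s_%d", p, j))
                    redParent <- c(redParent, p)
                    red <- rbind(red, inf[p, ] +
                        stats::rnorm(nSamples, sd = redundancyNoiseSd))
                }
            }
        }
        nNoise <- nGenes - nInformative - length(redIds)
        noiseIds <- sprintf("noise_%04d", seq_len(nNoise))
        noise <- matrix(stats::rnorm(nNoise * nSamples), nrow = nNoise,
                        ncol = nSamples)
        m <- rbind(inf, red, noise)
        rownames(m) <- c(infIds, redIds, noiseIds)
        ord <- sample(nrow(m))
        m <- m[ord, , drop = FALSE]
        ds <- ExpressionDataset(
            m, labels, sampleIds = sprintf("s%03d", seq_len(nSamples)))
        truth <- list(informative_ids = infIds,
                      redundant_ids = redIds,
                      redundant_parent = stats::setNames(redParent,
                                                         redIds),
                      noise_ids = noiseIds,
                      effect_size = effectSize,
                      redundancy_noise_sd = redundancyNoiseSd)
        S4Vectors::metadata(ds)$truth <- truth
        list(dataset = ds, truth = truth)
    })
}

#' Append byte-identical copies of a gene
#'
#' Utility for exercising the redundancy screen: appends \code{nCopies}
#' exact copies of an existing gene's expression row, with ids
#' \code{<gene>_dup1}, \code{<gene>_dup2}, ... Zero copies returns the
#' dataset unchanged.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param geneId an existing gene id.
#' @param nCopies number of copies to append.
#' @return the augmented \linkS4class{ExpressionDataset}.
#' @export
plantExactDuplicates <- function(ds, geneId, nCopies) {
    stopifnot(is(ds, "ExpressionDataset"))
    nCopies <- as.integer(nCopies)
    if (nCopies == 0L) return(ds)
    m <- exprMatrix(ds)
    if (!geneId %in% rownames(m)) stop("unknown gene id: ", geneId)
    copies <- matrix(rep(m[geneId, ], nCopies), nrow = nCopies,
                     byrow = TRUE)
    rownames(copies) <- sprintf("%s_dup%d", geneId, seq_len(nCopies))
    out <- ExpressionDataset(
        rbind(m, copies),
        SummarizedExperiment::colData(ds)$label_original)
    S4Vectors::metadata(out) <- S4Vectors::metadata(ds)
    out
}
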