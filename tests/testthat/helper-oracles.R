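# Independent straight-from-formula oracles and tiny fixture builders.
# These deliberately avoid the package's vectorized code paths.

oracleSnr <- function(values, labels) {
    a <- values[labels == sort(unique(labels))[1]]
    b <- values[labels == sort(unique(labels))[2]]
    num <- abs(mean(a) - mean(b))
    den <- sd(a) + sd(b)
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

oracleT <- function(values, labels) {
    a <- values[labels == sort(unique(labels))[1]]
    b <- values[labels == sort(unique(labels))[2]]
    num <- mean(b) - mean(a)
    den <- sqrt(var(a) / length(a) + var(b) / length(b))
    if (den == 0) { if (num == 0) 0 else sign(num) * Inf } else num / den
}

oraclePc <- function(values, labels) {
    y <- as.integer(factor(labels)) - 1L
    num <- sum((values - mean(values)) * (y - mean(y)))
    den <- sqrt(sum((values - mean(values))^2) * sum((y - mean(y))^2))
    num / den
}

# plug-in entropy from an explicit contingency table
oracleEntropy <- function(x, base = 2) {
    p <- as.vector(table(x)) / length(x)
    p <- p[p > 0]
    -sum(p * log(p, base = base))
}

oracleDnbar <- function(vecs, base = 2) {
    joint <- apply(do.call(cbind, lapply(vecs, as.character)), 1,
                   paste, collapse = "|")
    H <- oracleEntropy(joint, base)
    Hi <- sum(vapply(vecs, oracleEntropy, numeric(1), base = base))
    (Hi - H) / ((length(vecs) - 1) * H)
}

# independent greedy forward-selection oracle: at each step evaluate
# every remaining candidate by KNN cross-validated accuracy (same fold
# assignment) and admit the best iff it strictly improves
oracleForward <- function(ds, G, folds, seed, k = 3) {
    cls <- classLabels(ds)
    foldid <- entroSelect:::.makeFolds(cls, as.integer(folds),
                                       as.integer(seed))
    m <- exprMatrix(ds)
    acc <- function(genes) {
        ok <- 0
        for (f in unique(foldid)) {
            te <- foldid == f
            pr <- class::knn(t(m[genes, !te, drop = FALSE]),
                             t(m[genes, te, drop = FALSE]),
                             cls[!te], k = k)
            ok <- ok + sum(pr == cls[te])
        }
        ok
    }
    R <- character(0); best <- -1; trace <- numeric(0)
    repeat {
        rem <- setdiff(G, R)
        if (!length(rem)) break
        scores <- vapply(rem, function(g) acc(c(R, g)), numeric(1))
        if (max(scores) <= best) break
        best <- max(scores)
        R <- c(R, rem[which.max(scores)])
        trace <- c(trace, 100 * best / length(cls))
        if (best == length(cls)) break
    }
    list(R = R, trace = trace)
}

# admit-on-improvement oracle: best single gene, then one ordered scan
# over the remaining candidates admitting each strict improvement
oracleScan <- function(ds, G, folds, seed, k = 3) {
    cls <- classLabels(ds)
    foldid <- entroSelect:::.makeFolds(cls, as.integer(folds),
                                       as.integer(seed))
    m <- exprMatrix(ds)
    acc <- function(genes) {
        ok <- 0
        for (f in unique(foldid)) {
            te <- foldid == f
            pr <- class::knn(t(m[genes, !te, drop = FALSE]),
                             t(m[genes, te, drop = FALSE]),
                             cls[!te], k = k)
            ok <- ok + sum(pr == cls[te])
        }
        ok
    }
    single <- vapply(G, acc, numeric(1))
    R <- G[which.max(single)]; best <- max(single)
    trace <- 100 * best / length(cls)
    for (g in setdiff(G, R)) {
        if (best == length(cls)) break
        a <- acc(c(R, g))
        if (a > best) {
            best <- a; R <- c(R, g)
            trace <- c(trace, 100 * best / length(cls))
        }
    }
    list(R = R, trace = trace)
}

# small deterministic two-class dataset: one perfectly separating gene,
# one constant gene, one fixed "noise" gene
toyDataset <- function() {
    m <- rbind(sep   = c(0, 0.1, 0.2, 1, 1.1, 1.2),
               flat  = rep(5, 6),
               noise = c(0.3, -0.2, 0.4, -0.1, 0.2, -0.3))
    colnames(m) <- paste0("s", 1:6)
    ExpressionDataset(m, c("A", "A", "A", "B", "B", "B"))
}

# build a full GeneRanking by hand over an explicit gene order
makeRanking <- function(filter, geneIdsInRankOrder, universeOrder) {
    n <- length(geneIdsInRankOrder)
    new("GeneRanking", filterName = filter,
        ranking = S4Vectors::DataFrame(
            gene_id = geneIdsInRankOrder,
            score = seq(n, 1), key = seq(n, 1), rank = seq_len(n),
            index = match(geneIdsInRankOrder, universeOrder)))
}
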