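test_that("filter scores reproduce hand-computed values and conventions", {
    # signal-to-noise ratio
    expect_equal(snrScore(c(0, 1, 2, 0, 1, 2), rep(c("p", "n"), each = 3)), 0)
    expect_equal(snrScore(c(1, 2, 3, 4, 5, 6), rep(c("p", "n"), each = 3)), 1.5)
    expect_identical(snrScore(c(2, 2, 5, 5), c("p", "p", "n", "n")), Inf)

    # t-statistic
    expect_equal(tScore(c(0, 2, 0, 2), c(1, 1, 2, 2)), 0)
    v <- c(0, 0, 2, 2, 3, 3, 5, 5)
    l <- rep(c(1, 2), each = 4)
    expect_equal(tScore(v, l), 3 / sqrt((4 / 3) / 4 + (4 / 3) / 4),
                 tolerance = 1e-12)
    expect_equal(tScore(v, 3 - l), -tScore(v, l))   # label swap negates
    expect_error(tScore(c(1, 2, 3), c("a", "b", "b")), ">= 2 samples")

    # Pearson correlation against the 0/1 label coding
    lab <- c("a", "a", "b", "b")
    expect_equal(pearsonScore(c(0, 0, 1, 1), lab), 1)
    expect_equal(pearsonScore(c(1, 1, 0, 0), lab), -1)
    expect_equal(pearsonScore(c(1, -1, 1, -1), lab), 0)
    expect_warning(z <- pearsonScore(c(3, 3, 3, 3), lab), "zero-variance")
    expect_equal(z, 0)
})

test_that("scores agree with straight-from-formula oracles on random instances", {
    set.seed(42)
    for (i in 1:100) {
        n <- sample(6:30, 1)
        labels <- c("u", "v", sample(c("u", "v"), n - 2, replace = TRUE))
        values <- rnorm(n, sd = runif(1, 0.1, 10))
        expect_equal(snrScore(values, labels), oracleSnr(values, labels),
                     tolerance = 1e-12)
        expect_equal(tScore(values, labels), oracleT(values, labels),
                     tolerance = 1e-12)
        expect_equal(pearsonScore(values, labels),
                     oraclePc(values, labels), tolerance = 1e-12)
    }
})

test_that("rankGenes sorts by the right key with deterministic tie-breaks", {
    ds <- toyDataset()
    for (f in c("snr", "ts", "pc")) {
        rk <- suppressWarnings(rankGenes(ds, f))
        ids <- rk@ranking$gene_id
        expect_identical(ids[1], "sep")     # perfect separator first
        expect_identical(ids[3], "flat")    # constant gene last
        expect_true(all(diff(rk@ranking$key) <= 0))
    }

    # byte-identical genes occupy adjacent ranks in input order
    m <- rbind(a = c(1, 2, 3, 4), twin1 = c(4, 3, 2, 1),
               twin2 = c(4, 3, 2, 1))
    colnames(m) <- paste0("s", 1:4)
    ds2 <- ExpressionDataset(m, c("x", "x", "y", "y"))
    rk2 <- rankGenes(ds2, "snr")
    i <- match(c("twin1", "twin2"), rk2@ranking$gene_id)
    expect_equal(i[2], i[1] + 1L)

    # sample order is irrelevant
    perm <- c(3, 1, 4, 2)
    dsP <- ExpressionDataset(m[, perm], c("x", "x", "y", "y")[perm])
    expect_identical(rankGenes(dsP, "ts")@ranking$gene_id,
                     rankGenes(ds2, "ts")@ranking$gene_id)

    # vectorized matrix scoring equals the per-gene scalar functions
    sim <- simulateMicroarray(nSamples = 20, nGenes = 30, seed = 9)
    mm <- exprMatrix(sim$dataset); cl <- classLabels(sim$dataset)
    rk3 <- rankGenes(sim$dataset, "pc")
    for (g in sample(rownames(mm), 5))
        expect_equal(rk3@ranking$score[rk3@ranking$gene_id == g],
                     pearsonScore(mm[g, ], cl), tolerance = 1e-12)
})

test_that("positive rescaling of one gene preserves the order of the others", {
    set.seed(7)
    for (rep in 1:10) {
        m <- matrix(rnorm(5 * 12), nrow = 5,
                    dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
        ds <- ExpressionDataset(m, rep(c("a", "b"), 6))
        m2 <- m; m2[3, ] <- m2[3, ] * runif(1, 0.1, 9)
        ds2 <- ExpressionDataset(m2, rep(c("a", "b"), 6))
        for (f in c("snr", "ts", "pc")) {
            r1 <- rankGenes(ds, f)@ranking
            r2 <- rankGenes(ds2, f)@ranking
            keep <- r1$gene_id != "g3"
            expect_identical(r1$gene_id[keep],
                             r2$gene_id[r2$gene_id != "g3"])
            # the rescaled gene's own scores are unchanged too: all
            # three statistics are scale-invariant
            expect_equal(r2$score[r2$gene_id == "g3"],
                         r1$score[r1$gene_id == "g3"], tolerance = 1e-9)
        }
    }
})

test_that("unionTopN merges, deduplicates and orders with provenance", {
    universe <- paste0("g", 1:5)
    r1 <- makeRanking("snr", c("g1", "g2", "g3", "g4", "g5"), universe)
    r2 <- makeRanking("ts",  c("g2", "g4", "g5", "g1", "g3"), universe)
    u <- unionTopN(list(r1, r2), N = 2)
    # best ranks: g1 -> 1 (mean 1), g2 -> 1 (mean 1.5), g4 -> 2
    expect_identical(u@geneIds, c("g1", "g2", "g4"))
    expect_identical(u@provenance$g2$filter, c("snr", "ts"))
    expect_equal(u@provenance$g2$rank, c(2, 1))

    # identical rankings: union collapses to N
    uSame <- unionTopN(list(r1, r1, r1), N = 3)
    expect_identical(uSame@geneIds, c("g1", "g2", "g3"))

    # disjoint top-N sets: union has L*N genes
    r3 <- makeRanking("pc", c("g4", "g5", "g1", "g2", "g3"), universe)
    uDisj <- unionTopN(list(r1, r3), N = 2)
    expect_length(uDisj@geneIds, 4)

    expect_error(unionTopN(list(r1), N = 0), "positive")
    expect_error(unionTopN(list(r1), N = 9), "exceeds")
})

test_that("union size always lies in [N, L*N]", {
    set.seed(13)
    for (rep in 1:20) {
        sim <- simulateMicroarray(nSamples = 16, nGenes = 40,
                                  nInformative = 3,
                                  nRedundantPerInformative = 2,
                                  seed = rep)
        rks <- lapply(c("snr", "ts", "pc"),
                      function(f) rankGenes(sim$dataset, f))
        N <- sample(3:15, 1)
        u <- unionTopN(rks, N)
        expect_gte(length(u@geneIds), N)
        expect_lte(length(u@geneIds), 3 * N)
        expect_true(all(vapply(u@provenance,
                               function(p) min(p$rank) <= N, logical(1))))
    }
})
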