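test_that("discretization follows quantile cuts with ties to the lower bin", {
    expect_equal(discretize(c(1, 2, 3, 4), nBins = 2), c(1, 1, 2, 2))
    expect_equal(discretize(rep(7, 5), nBins = 2), rep(1L, 5))
    expect_equal(discretize(rep(7, 5), binMethod = "equal_width",
                            nBins = 2), rep(1L, 5))
    # rank invariance under strictly monotone transforms
    set.seed(3)
    for (i in 1:20) {
        v <- rnorm(25)
        nb <- sample(2:5, 1)
        expect_identical(discretize(exp(v), nBins = nb),
                         discretize(v, nBins = nb))
        expect_identical(discretize(v^3, nBins = nb),
                         discretize(v, nBins = nb))
    }
    expect_error(discretize(1:3, nBins = 5), "exceeds")
})

test_that("plug-in entropy matches closed forms and the counting oracle", {
    expect_equal(shannonEntropy(rep("a", 9)), 0)
    expect_equal(shannonEntropy(c(1, 2, 3, 4)), 2)           # uniform
    expect_equal(shannonEntropy(c(0, 0, 1)),
                 -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3),
                 tolerance = 1e-12)
    expect_error(shannonEntropy(integer(0)), "empty")
    set.seed(8)
    for (i in 1:25) {
        x <- sample(1:4, 30, replace = TRUE)
        y <- sample(letters[1:3], 30, replace = TRUE)
        expect_equal(shannonEntropy(x), oracleEntropy(x),
                     tolerance = 1e-12)
        expect_equal(shannonEntropy(x, y),
                     oracleEntropy(paste(x, y)), tolerance = 1e-12)
        expect_equal(shannonEntropy(x, y, joint = FALSE),
                     oracleEntropy(x) + oracleEntropy(y),
                     tolerance = 1e-12)
    }
})

test_that("normalized cross-entropy hits its analytic anchors", {
    # empirically independent pair: joint = product of marginals
    expect_equal(normalizedCrossEntropy(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
    # duplicated non-constant variable: maximal dependence
    x <- c(0, 1, 0, 1, 2)
    expect_equal(normalizedCrossEntropy(x, x), 1)
    # all-constant input is degenerate by convention
    expect_warning(d0 <- normalizedCrossEntropy(c(1, 1), c(2, 2)),
                   "constant")
    expect_equal(d0, 0)
    expect_error(normalizedCrossEntropy(x), "two variables")
})

test_that("normalized cross-entropy is bounded, symmetric and base-free", {
    set.seed(21)
    for (i in 1:200) {
        k <- sample(2:4, 1)            # number of variables
        n <- sample(c(10, 30), 1)
        vecs <- replicate(k, sample(0:2, n, replace = TRUE),
                          simplify = FALSE)
        d <- normalizedCrossEntropy(vecs)
        expect_gte(d, 0); expect_lte(d, 1)
        expect_equal(d, oracleDnbar(vecs, base = 2), tolerance = 1e-12)
        # the log base cancels in the ratio
        expect_equal(oracleDnbar(vecs, base = exp(1)),
                     oracleDnbar(vecs, base = 2), tolerance = 1e-12)
        if (k == 2)
            expect_equal(normalizedCrossEntropy(vecs[[2]], vecs[[1]]), d,
                         tolerance = 1e-12)
    }
})

test_that("redundancy against a kept set follows both aggregation modes", {
    x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)   # independent pair
    expect_equal(redundancyAgainstSet(list(), x), 0)
    expect_equal(redundancyAgainstSet(list(x), x), 1)
    expect_equal(redundancyAgainstSet(list(x), x, "joint"), 1)
    # candidate duplicates one member of an independent pair
    expect_equal(redundancyAgainstSet(list(x, y), x), 1)
    # the joint mode matches a direct three-variable evaluation
    expect_equal(redundancyAgainstSet(list(x, y), x, "joint"),
                 oracleDnbar(list(x, y, x)), tolerance = 1e-12)
})

test_that("eliminateRedundant keeps the first gene and drops duplicates", {
    set.seed(2)
    base <- rnorm(30)
    m <- rbind(g1 = base, g1copy = base,
               g3 = rnorm(30))
    colnames(m) <- paste0("s", 1:30)
    ds <- ExpressionDataset(m, rep(c("a", "b"), 15))
    cfg <- redundancyConfig(threshold = 0.5)
    expect_identical(eliminateRedundant(c("g1", "g1copy", "g3"), ds, cfg),
                     c("g1", "g3"))
    # T = 1: everything except exact duplicates admitted
    expect_identical(
        eliminateRedundant(c("g1", "g1copy", "g3"), ds,
                           redundancyConfig(threshold = 1)),
        c("g1", "g3"))
    # T = 0: only the unconditional first admission
    expect_identical(
        eliminateRedundant(c("g1", "g1copy", "g3"), ds,
                           redundancyConfig(threshold = 0)),
        "g1")
    expect_error(redundancyConfig(threshold = 1.2), "0, 1")
    expect_error(eliminateRedundant(character(0), ds, cfg), "empty")
    expect_error(eliminateRedundant("nope", ds, cfg), "absent")
})

test_that("inserting an exact duplicate after its original never changes G", {
    set.seed(17)
    for (rep in 1:10) {
        sim <- simulateMicroarray(nSamples = 24, nGenes = 15,
                                  nInformative = 3,
                                  nRedundantPerInformative = 1,
                                  seed = rep)
        ids <- geneIds(sim$dataset)
        cfg <- redundancyConfig()
        g0 <- eliminateRedundant(ids, sim$dataset, cfg)
        # plant a duplicate of a random gene and splice it in later
        pick <- sample(ids, 1)
        ds2 <- plantExactDuplicates(sim$dataset, pick, 1)
        dupId <- paste0(pick, "_dup1")
        spots <- seq(match(pick, ids), length(ids))  # positions after pick
        after <- spots[sample.int(length(spots), 1)]
        order2 <- append(ids, dupId, after = after)
        g1 <- eliminateRedundant(order2, ds2, cfg)
        expect_identical(setdiff(g1, dupId), g0)
        expect_false(dupId %in% g1)
    }
})

test_that("|G| is non-decreasing in T on a graded-redundancy instance", {
    # genes built as increasingly noisy copies of one template, so that
    # raising T admits progressively more of them
    set.seed(5)
    tmpl <- rnorm(40)
    m <- rbind(t0 = tmpl,
               t1 = tmpl + rnorm(40, sd = 0.05),
               t2 = tmpl + rnorm(40, sd = 0.4),
               t3 = tmpl + rnorm(40, sd = 1.5),
               t4 = rnorm(40))
    colnames(m) <- paste0("s", 1:40)
    ds <- ExpressionDataset(m, rep(c("a", "b"), 20))
    sizes <- vapply(seq(0.1, 1, by = 0.1), function(Tt)
        length(eliminateRedundant(rownames(m), ds,
                                  redundancyConfig(threshold = Tt))),
        numeric(1))
    expect_true(all(diff(sizes) >= 0))
})
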