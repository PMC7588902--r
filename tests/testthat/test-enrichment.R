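test_that("gene ranking is deterministic with lexicographic tie-breaking", {
    rl <- rankGenes(c(A = 2, B = -1, C = 0.5))
    expect_identical(geneIds(rl), c("A", "C", "B"))
    expect_identical(unname(rankMetric(rl)), c(2, 0.5, -1))

    rl <- rankGenes(c(zed = 1, alpha = 1, mid = 1))
    expect_identical(geneIds(rl), c("alpha", "mid", "zed"))

    ## signed log10 p metric
    res <- S4Vectors::DataFrame(log2FC = c(1, -2), t = c(3, -4),
                                pValue = c(0.01, 0.001),
                                row.names = c("up1", "dn1"))
    dr <- new("DifferentialResults", res)
    rl <- rankGenes(dr, metric = "signed_logp")
    expect_equal(unname(rankMetric(rl)[c("up1", "dn1")]), c(2, -3))

    expect_error(rankGenes(c(A = 1, A = 2)), "duplicate")
    expect_error(rankGenes(c(A = NA_real_)), "finite")
})

test_that("extreme rankings force the enrichment score to +/- 1", {
    rl <- rankGenes(stats::setNames(10:1, LETTERS[1:10]))
    top <- enrichmentScore(rl, LETTERS[1:3], weightExponent = 0)
    expect_equal(top$es, 1, tolerance = 1e-12)
    expect_setequal(top$leadingEdge, LETTERS[1:3])

    bottom <- enrichmentScore(rl, LETTERS[8:10], weightExponent = 0)
    expect_equal(bottom$es, -1, tolerance = 1e-12)
    expect_setequal(bottom$leadingEdge, LETTERS[8:10])

    ## reversing the ranking negates the weight-0 score (exactly when
    ## the walk's two extrema do not tie in magnitude; a tie resolves
    ## to the positive side in both orientations by the declared rule)
    rev <- rankGenes(stats::setNames(1:10, LETTERS[1:10]))
    set.seed(4)
    for (i in 1:20) {
        mem <- sample(LETTERS[1:10], sample(2:5, 1))
        fwd <- enrichmentScore(rl, mem, weightExponent = 0)
        e2 <- enrichmentScore(rev, mem, weightExponent = 0)$es
        tied <- abs(max(fwd$runningSum) + min(fwd$runningSum)) < 1e-9
        if (tied) {
            expect_equal(abs(fwd$es), abs(e2), tolerance = 1e-12)
        } else {
            expect_equal(fwd$es, -e2, tolerance = 1e-12)
        }
    }

    expect_error(enrichmentScore(rl, c("zz")), "disjoint")
    expect_error(enrichmentScore(rl, LETTERS[1:10]), "whole ranked universe")
})

test_that("the running-sum score matches brute-force enumeration", {
    ## the worked case: hits at positions 2, 5, 9 of 10, weight 1
    metric <- c(5, 4, 3, 2.5, 2, 1, 0.5, -0.5, -1.5, -3)
    genes <- sprintf("g%02d", 1:10)
    rl <- rankGenes(stats::setNames(metric, genes))
    out <- enrichmentScore(rl, genes[c(2, 5, 9)], weightExponent = 1)
    expect_equal(out$es, oracleES(metric, c(2, 5, 9), 1),
                 tolerance = 1e-12)

    ## exhaustive: small universes x all subsets of size <= 3, both
    ## weight regimes
    set.seed(11)
    for (n in 5:8) {
        m <- sort(round(rnorm(n), 2), decreasing = TRUE)
        g <- sprintf("x%02d", seq_len(n))
        rlx <- rankGenes(stats::setNames(m, g))
        for (size in 1:3) {
            combs <- utils::combn(n, size)
            for (j in seq_len(ncol(combs))) {
                hit <- combs[, j]
                if (length(hit) == n) next
                for (alpha in c(0, 1)) {
                    expect_equal(
                        enrichmentScore(rlx, g[hit], alpha)$es,
                        oracleES(m, hit, alpha), tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("the enrichment engine agrees with an independent implementation", {
    skip_if_not_installed("fgsea")
    set.seed(9)
    for (i in 1:25) {
        n <- sample(20:200, 1)
        stats <- sort(rnorm(n), decreasing = TRUE)
        names(stats) <- sprintf("g%03d", seq_len(n))
        h <- sort(sample(n, sample(3:8, 1)))
        es1 <- enrichmentScore(rankGenes(stats), names(stats)[h],
                               weightExponent = 1)$es
        es2 <- fgsea::calcGseaStat(stats, selectedStats = h,
                                   gseaParam = 1)
        expect_equal(es1, es2, tolerance = 1e-12)
    }
})

test_that("permutation p-values are seeded, smoothed and powerful", {
    sim <- simulateOverexpression(SimulationParams(nGenes = 1000,
                                                   seed = 19))
    res <- callDifferential(sim$se, "vector", "overexpression")
    rl <- rankGenes(res)
    eff <- trueEffects(sim$truth)
    upPlanted <- names(eff)[eff > 0]

    g1 <- gseaPermutation(rl, GeneSet("up", members = upPlanted),
                          nPermutations = 1000, seed = 5)
    g2 <- gseaPermutation(rl, GeneSet("up", members = upPlanted),
                          nPermutations = 1000, seed = 5)
    expect_identical(enrichmentScoreValue(g1), enrichmentScoreValue(g2))
    expect_identical(pNominal(g1), pNominal(g2))
    expect_identical(nes(g1), nes(g2))

    ## a planted top block is decisively enriched
    expect_gt(enrichmentScoreValue(g1), 0)
    expect_lte(pNominal(g1), 0.01)
    expect_gt(nes(g1), 1)

    ## p is never zero (additive smoothing)
    expect_gt(pNominal(g1), 0)
    expect_error(gseaPermutation(rl, upPlanted, nPermutations = 50,
                                 seed = 1),
                 ">= 100")
})

test_that("hypergeometric over-representation matches the exact tail sum", {
    bg <- sprintf("G%02d", 1:20)
    term <- GeneSet("t", members = bg[1:5])
    out <- oraTest(bg[1:5], term, bg)
    expect_equal(out$pValue, oracleHyperTail(20, 5, 5, 5))

    ## the printed worked case: N=20, K=5, n=5, k=4
    query <- bg[c(1:4, 10)]
    out <- oraTest(query, term, bg)
    expect_identical(out$k, 4L)
    expect_equal(out$pValue, oracleHyperTail(20, 5, 5, 4),
                 tolerance = 1e-12)
    expect_equal(out$pValue, 76 / 15504, tolerance = 1e-12)

    ## zero overlap: p = 1
    out0 <- oraTest(bg[10:14], GeneSet("t0", members = bg[1:5]), bg)
    expect_identical(out0$pValue, 1)

    ## EASE subtracts one success
    oe <- oraTest(query, term, bg, ease = TRUE)
    expect_equal(oe$pValue, oracleHyperTail(20, 5, 5, 3),
                 tolerance = 1e-12)

    ## disjoint terms are skipped, not tested
    terms <- list(term, GeneSet("off", members = c("ZZZ1", "ZZZ2")))
    expect_message(outs <- oraTest(query, terms, bg), "skipped")
    expect_identical(outs$term, "t")

    expect_error(oraTest(c("NOPE"), term, bg), "subset")
    expect_error(oraTest(character(), term, bg), "non-empty")
})

test_that("BH q-values are monotone in p across terms", {
    set.seed(21)
    bg <- sprintf("G%03d", 1:200)
    query <- sample(bg, 30)
    terms <- lapply(1:15, function(i) {
        GeneSet(sprintf("t%02d", i), members = sample(bg, sample(10:40, 1)))
    })
    out <- oraTest(query, terms, bg)
    ord <- order(out$pValue)
    expect_true(all(diff(out$qValue[ord]) >= -1e-15))
    expect_true(all(out$qValue >= out$pValue - 1e-15))
})
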