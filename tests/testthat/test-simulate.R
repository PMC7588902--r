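test_that("every generator is a pure function of inputs and seed", {
    p <- SimulationParams(nGenes = 300, seed = 11)
    a <- simulateOverexpression(p)
    b <- simulateOverexpression(p)
    expect_identical(SummarizedExperiment::assay(a$se),
                     SummarizedExperiment::assay(b$se))
    expect_identical(trueEffects(a$truth), trueEffects(b$truth))

    c1 <- simulateCompanionStudy(a$truth, 0.5, 0.2, seed = 3)
    c2 <- simulateCompanionStudy(a$truth, 0.5, 0.2, seed = 3)
    expect_identical(c1, c2)

    p1 <- simulateProteome(a$truth, 0.7, 0.8, 0.1, seed = 4)
    p2 <- simulateProteome(a$truth, 0.7, 0.8, 0.1, seed = 4)
    expect_identical(p1$table, p2$table)

    t1 <- simulateTissuePanel(sprintf("G%02d", 1:20), nTissues = 2,
                              nDonors = 20, rWithin = 0.8, seed = 5)
    t2 <- simulateTissuePanel(sprintf("G%02d", 1:20), nTissues = 2,
                              nDonors = 20, rWithin = 0.8, seed = 5)
    expect_identical(SummarizedExperiment::assay(t1$panels[[1]]),
                     SummarizedExperiment::assay(t2$panels[[1]]))
    expect_identical(moduleAssignment(t1$truth),
                     moduleAssignment(t2$truth))

    ## the generator must not disturb the caller's RNG stream
    set.seed(99); before <- rnorm(1)
    set.seed(99); invisible(simulateOverexpression(p)); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("zero DE fraction plants nothing and invalid parameters are rejected", {
    sim <- simulateOverexpression(SimulationParams(nGenes = 100,
                                                   deFraction = 0,
                                                   seed = 2))
    expect_length(deGenes(sim$truth), 0)
    expect_warning(simulateCompanionStudy(sim$truth, 0.5, 0.1, seed = 1),
                   "no planted genes")

    expect_error(SimulationParams(effectMean = Inf), "finite")
    expect_error(SimulationParams(deFraction = 1.2), "\\[0, 1\\]")
    expect_error(SimulationParams(nGenes = 0), ">= 1")
    expect_error(simulateProteome(sim$truth, 1, 0, 0, seed = 1), "coverage")
    expect_error(simulateTissuePanel(letters, rWithin = 1, seed = 1),
                 "rWithin")
})

test_that("the noise-free limit reproduces planted fold changes exactly", {
    p <- SimulationParams(nGenes = 400, deFraction = 0.1,
                          replicateNoiseSd = 0, seed = 7)
    sim <- simulateOverexpression(p)
    m <- SummarizedExperiment::assay(sim$se)
    cond <- SummarizedExperiment::colData(sim$se)$condition
    lfc <- log2(rowMeans(m[, cond == "overexpression"]) /
                    rowMeans(m[, cond == "vector"]))
    eff <- trueEffects(sim$truth)
    expect_equal(unname(lfc[names(eff)]), unname(eff), tolerance = 1e-12)
    others <- setdiff(universeGenes(sim$truth), names(eff))
    expect_equal(unname(lfc[others]), rep(0, length(others)),
                 tolerance = 1e-12)
})

test_that("companion overlap fraction controls the significant-call overlap", {
    sim <- simulateOverexpression(SimulationParams(nGenes = 1000,
                                                   seed = 21))
    de <- deGenes(sim$truth)

    ## overlap 1, no fold-change noise: significant set equals the
    ## planted set and fold changes match exactly
    comp <- simulateCompanionStudy(sim$truth, 1, 0, seed = 1)
    sig <- significantGenes(comp)
    expect_setequal(intersect(sig, de), de)
    expect_equal(comp$log2FC[match(de, comp$gene)],
                 unname(trueEffects(sim$truth)), tolerance = 1e-12)

    ## overlap 0: no planted gene is called
    comp0 <- simulateCompanionStudy(sim$truth, 0, 0.1, seed = 2)
    expect_length(intersect(significantGenes(comp0), de), 0)

    ## overlap 0.3: recovered fraction stays within the binomial
    ## 99.9% envelope around 0.3 across seeds
    fr <- vapply(1:10, function(s) {
        cs <- simulateCompanionStudy(sim$truth, 0.3, 0.1, seed = s)
        length(intersect(significantGenes(cs), de)) / length(de)
    }, numeric(1))
    ci <- qbinom(c(5e-4, 1 - 5e-4), length(de), 0.3) / length(de)
    expect_true(all(fr >= ci[1] & fr <= ci[2]))
})

test_that("proteome coverage and attenuation behave as parameterized", {
    sim <- simulateOverexpression(SimulationParams(nGenes = 1000,
                                                   seed = 31))
    de <- deGenes(sim$truth)

    ## full-coverage noise-free proteome reproduces RNA effects exactly
    pr <- simulateProteome(sim$truth, 1, 1, 0, seed = 1)
    expect_setequal(pr$table$gene, universeGenes(sim$truth))
    expect_equal(pr$table$log2FC[match(de, pr$table$gene)],
                 unname(trueEffects(sim$truth)), tolerance = 1e-12)
    expect_identical(pr$truth@proteinAttenuation, 1)

    ## detected-gene count tracks coverage within the binomial envelope
    counts <- vapply(1:10, function(s) {
        nrow(simulateProteome(sim$truth, 1, 0.5, 0.1, seed = s)$table)
    }, numeric(1))
    ci <- qbinom(c(5e-4, 1 - 5e-4), 1000, 0.5)
    expect_true(all(counts >= ci[1] & counts <= ci[2]))
})

test_that("tissue panels carry the planted correlation structure", {
    genes <- sprintf("G%02d", 1:40)

    ## background-only panel: pairwise correlations hover near zero
    bg <- simulateTissuePanel(genes, nTissues = 1, nDonors = 100,
                              rWithin = 0.5, seed = 3,
                              coherentFraction = 0, antiFraction = 0)
    cm <- corValues(correlationMatrix(bg$panels[[1]]))
    expect_lt(mean(abs(cm[upper.tri(cm)])), 0.15)

    ## within-module correlation matches the calibration target
    ms <- vapply(1:5, function(s) {
        tp <- simulateTissuePanel(genes, nTissues = 1, nDonors = 200,
                                  rWithin = 0.9, seed = s)
        cmx <- correlationMatrix(tp$panels[[1]])
        mem <- moduleAssignment(tp$truth)[[1]][geneIds(cmx)]
        v <- corValues(cmx)[mem == "coherent", mem == "coherent"]
        mean(v[upper.tri(v)])
    }, numeric(1))
    expect_gt(mean(ms), 0.85)
    expect_lt(mean(ms), 0.95)

    ## membership is re-drawn per tissue
    tp <- simulateTissuePanel(genes, nTissues = 3, nDonors = 20,
                              rWithin = 0.8, seed = 17)
    mods <- moduleAssignment(tp$truth)
    expect_false(identical(mods[[1]], mods[[2]]) &&
                     identical(mods[[2]], mods[[3]]))
})
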