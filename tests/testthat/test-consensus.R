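## Hand-made differential tables for set-logic tests.
.sigTable <- function(up, down, none = character()) {
    data.frame(gene = c(up, down, none),
               log2FC = c(rep(1, length(up)), rep(-1, length(down)),
                          rep(0.01, length(none))),
               p = c(rep(0.001, length(up) + length(down)),
                     rep(0.9, length(none))))
}

test_that("cross-study intersection partitions the union of calls", {
    a <- .sigTable(up = c("g1", "g2", "g3", "g7"), down = "g4")
    b <- .sigTable(up = c("g2", "g3", "g5"), down = c("g4", "g6", "g7"))
    out <- intersectDE(a, b)
    expect_setequal(out$sharedUp, c("g2", "g3"))
    expect_setequal(out$sharedDown, "g4")
    ## g7 is discordant (up in A, down in B): kept study-specific
    expect_true("g7" %in% out$aOnly)
    expect_false("g7" %in% c(out$sharedUp, out$sharedDown, out$bOnly))
    ## the four sets partition the union of significant genes
    all <- c(out$sharedUp, out$sharedDown, out$aOnly, out$bOnly)
    expect_identical(anyDuplicated(all), 0L)
    expect_setequal(all, c("g1", "g2", "g3", "g4", "g5", "g6", "g7"))

    ## without the concordance requirement g7 is shared
    out2 <- intersectDE(a, b, requireSignConcordance = FALSE)
    expect_true("g7" %in% out2$sharedUp)

    ## matching is case-insensitive
    b2 <- .sigTable(up = c("G2", "g3"), down = character())
    out3 <- suppressWarnings(intersectDE(a, b2))
    expect_setequal(out3$sharedUp, c("g2", "g3"))

    ## disjoint studies warn but do not fail
    expect_warning(
        intersectDE(.sigTable("x1", character()),
                    .sigTable("y1", character())),
        "no shared")
})

test_that("fold-change regression matches the normal-equations oracle", {
    ## exact linearity
    cmp <- regressFoldChanges(c(1, 2, 3, 4), c(2, 4, 6, 8))
    expect_equal(regressionSlope(cmp), 2, tolerance = 1e-12)
    expect_equal(regressionIntercept(cmp), 0, tolerance = 1e-12)
    expect_equal(rSquared(cmp), 1, tolerance = 1e-12)

    ## ten fixed pairs vs the oracle
    set.seed(3)
    x <- round(rnorm(10, 0, 1.5), 3)
    y <- round(0.8 * x + rnorm(10, 0, 0.4), 3)
    cmp <- regressFoldChanges(x, y)
    o <- oracleOLS(x, y)
    expect_equal(regressionSlope(cmp), o$slope, tolerance = 1e-10)
    expect_equal(regressionIntercept(cmp), o$intercept, tolerance = 1e-10)
    expect_equal(rSquared(cmp), o$r2, tolerance = 1e-10)

    ## r^2 is symmetric in the two studies; the slope is not
    swap <- regressFoldChanges(y, x)
    expect_equal(rSquared(swap), rSquared(cmp), tolerance = 1e-12)

    ## independent noise: no concordance
    for (s in 1:3) {
        set.seed(s)
        r2 <- rSquared(regressFoldChanges(rnorm(500), rnorm(500)))
        expect_lt(r2, 0.05)
    }

    expect_error(regressFoldChanges(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
    expect_error(regressFoldChanges(c(1, 2), c(1, 2)), ">= 3")
})

test_that("consensus tiers nest and track protein evidence", {
    ## no protein table: protein tier empty but RNA tiers intact
    expect_message(buildConsensus(c("g1", "g2"), "g3", NULL),
                   "no protein table")
    cs <- suppressMessages(buildConsensus(c("g1", "g2"), "g3", NULL))
    expect_length(rnaProtein(cs), 0)
    expect_setequal(rnaUp(cs), c("g1", "g2"))
    expect_setequal(rnaDown(cs), "g3")

    ## protein evidence with sign concordance
    prot <- data.frame(gene = c("g1", "g2", "g3"),
                       log2FC = c(1.2, -0.5, -0.8),
                       p = c(0.01, 0.01, 0.2))
    cs <- buildConsensus(c("g1", "g2"), "g3", prot)
    ## g2 is protein-significant but discordant (RNA up, protein down);
    ## g3 concordant but not significant
    expect_setequal(rnaProtein(cs), "g1")
    expect_true(all(rnaProtein(cs) %in% c(rnaUp(cs), rnaDown(cs))))
    pv <- provenance(cs)
    expect_identical(pv$gene, c("g1", "g2", "g3"))
    expect_true(all(pv$proteinDetected))

    ## without the sign requirement g2 enters
    cs2 <- buildConsensus(c("g1", "g2"), "g3", prot,
                          requireProteinSignConcordance = FALSE)
    expect_setequal(rnaProtein(cs2), c("g1", "g2"))

    expect_error(buildConsensus(c("g1"), c("g1"), NULL), "overlap")
})

test_that("a fully concordant proteome promotes every shared gene", {
    sim <- simulateOverexpression(SimulationParams(nGenes = 800,
                                                   seed = 13))
    res <- callDifferential(sim$se, "vector", "overexpression")
    comp <- simulateCompanionStudy(sim$truth, 1, 0, seed = 2)
    inter <- intersectDE(res, comp)
    pr <- simulateProteome(sim$truth, 1, 1, 0, seed = 3)
    cs <- buildConsensus(inter$sharedUp, inter$sharedDown, pr$table)
    expect_setequal(rnaProtein(cs), c(rnaUp(cs), rnaDown(cs)))

    ## at half coverage, roughly half the shared genes are promoted
    fr <- vapply(1:10, function(s) {
        pr <- simulateProteome(sim$truth, 1, 0.5, 0, seed = s)
        csx <- buildConsensus(inter$sharedUp, inter$sharedDown, pr$table)
        length(rnaProtein(csx)) /
            length(c(rnaUp(csx), rnaDown(csx)))
    }, numeric(1))
    n <- length(c(rnaUp(cs), rnaDown(cs)))
    ci <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5) / n
    expect_true(all(fr >= ci[1] & fr <= ci[2]))
})

test_that("gene-set export writes GMT records losslessly", {
    cs <- buildConsensus(c("A", "B"), "C",
                         data.frame(gene = "A", log2FC = 2, p = 0.001))
    sets <- exportGeneSets(cs, "NRF2")
    expect_length(sets, 3)  # three non-empty tiers
    expect_named(sets, c("NRF2_RNA_up", "NRF2_RNA_down",
                         "NRF2_RNA_protein"))

    tf <- tempfile(fileext = ".gmt")
    writeGMT(sets, tf)
    lines <- readLines(tf)
    expect_identical(lines[1],
                     "NRF2_RNA_up\tconsensus tier RNA_up\tA\tB")
    back <- readGMT(tf)
    expect_identical(lapply(back, setMembers), lapply(sets, setMembers))

    ## empty tier is omitted with a message
    cs0 <- suppressMessages(buildConsensus("A", character(), NULL))
    expect_message(sets0 <- exportGeneSets(cs0, "X"), "empty")
    expect_named(sets0, "X_RNA_up")
})
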