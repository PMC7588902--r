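## Tissue panel shared by several blocks.
.panel3 <- function(nGenes = 30, nDonors = 100, seed = 1, nTissues = 1) {
    simulateTissuePanel(sprintf("G%02d", seq_len(nGenes)),
                        nTissues = nTissues, nDonors = nDonors,
                        rWithin = 0.9, seed = seed)
}

test_that("correlation matrices are exact: symmetry, diagonal, known pairs", {
    ## a gene against its own copy correlates exactly 1; y = -x exactly -1
    donors <- 20
    x <- 2^(10 + seq_len(donors) / 5)
    v <- rbind(a = x, a_copy = x, neg = 2^(20 - log2(x)),
               noise = 2^(10 + rnorm(donors, 0, 0.5)))
    se <- makeSE(v, rep("t", donors))
    cm <- correlationMatrix(se, minSamples = 10)
    vals <- corValues(cm)
    expect_equal(vals["a", "a_copy"], 1, tolerance = 1e-10)
    expect_lt(vals["a", "neg"], -0.99)
    expect_identical(vals, t(vals))       # exact, not approximate
    expect_true(all(diag(vals) == 1))
    expect_true(all(abs(vals) <= 1))

    ## zero-variance genes are dropped with a message
    v2 <- rbind(v, flat = rep(4, donors))
    expect_message(cm2 <- correlationMatrix(makeSE(v2, rep("t", donors)),
                                            minSamples = 10),
                   "zero-variance")
    expect_false("flat" %in% geneIds(cm2))

    ## donor floor is enforced
    expect_error(correlationMatrix(makeSE(v[, 1:5], rep("t", 5)),
                                   minSamples = 10), "minSamples")
})

test_that("clustering recovers planted modules and is seed-deterministic", {
    ## two perfectly separated blocks at k = 2
    tp2 <- simulateTissuePanel(sprintf("G%02d", 1:30), nTissues = 1,
                               nDonors = 150, rWithin = 0.9, seed = 3,
                               coherentFraction = 0.5, antiFraction = 0.5)
    cm2 <- correlationMatrix(tp2$panels[[1]])
    cl2 <- clusterCorrelationProfiles(cm2, k = 2, seed = 1)
    truth2 <- moduleAssignment(tp2$truth)[[1]][geneIds(cm2)]
    skip_if_not_installed("mclust")
    expect_equal(mclust::adjustedRandIndex(cl2, truth2), 1)

    ## three-group planted structure at k = 3
    tp <- .panel3(seed = 5)
    cm <- correlationMatrix(tp$panels[[1]])
    cl <- clusterCorrelationProfiles(cm, k = 3, seed = 2)
    truth <- moduleAssignment(tp$truth)[[1]][geneIds(cm)]
    expect_gte(mclust::adjustedRandIndex(cl, truth), 0.9)

    ## cluster 1 is the most internally coherent group
    v <- corValues(cm)
    intra <- vapply(1:3, function(k) {
        idx <- which(cl == k)
        s <- v[idx, idx]
        mean(s[upper.tri(s)])
    }, numeric(1))
    expect_identical(which.max(intra), 1L)

    ## determinism and the hierarchical alternative
    expect_identical(cl, clusterCorrelationProfiles(cm, k = 3, seed = 2))
    hcl <- clusterCorrelationProfiles(cm, k = 3, method = "hierarchical")
    expect_identical(sort(unique(unname(hcl))), 1:3)
    expect_gte(mclust::adjustedRandIndex(hcl, truth), 0.9)

    expect_error(clusterCorrelationProfiles(cm, k = nrow(v)), "smaller")
})

test_that("clustering is equivariant under gene-order permutation", {
    tp <- .panel3(seed = 7)
    cm <- correlationMatrix(tp$panels[[1]])
    cl <- clusterCorrelationProfiles(cm, k = 3, seed = 4)

    set.seed(1)
    perm <- sample(length(geneIds(cm)))
    vperm <- corValues(cm)[perm, perm]
    cmPerm <- new("CorrelationMatrix", values = vperm,
                  tissue = tissueLabel(cm), method = "pearson",
                  nSamples = 100L)
    clPerm <- clusterCorrelationProfiles(cmPerm, k = 3, seed = 4)
    expect_identical(clPerm, cl[perm])
})

test_that("coherence classes follow the core cluster and thresholds", {
    tp <- .panel3(seed = 9, nDonors = 200)
    cm <- correlationMatrix(tp$panels[[1]])
    cl <- clusterCorrelationProfiles(cm, k = 3, seed = 1)
    truth <- moduleAssignment(tp$truth)[[1]][geneIds(cm)]
    cls <- classifyCoherence(cm, cl)

    expect_true(all(cls[truth == "coherent"] == "correlated"))
    expect_true(all(cls[truth == "anti"] == "anti-correlated"))
    ## background genes sit near the lenient tauNeg boundary, so a
    ## small fraction crosses it by sampling noise of the mean
    ## correlation; the large majority must stay unclassified
    expect_gte(mean(cls[truth == "background"] == "unclassified"), 0.8)

    ## monotone in tauPos: raising it never adds "correlated" genes
    for (tau in c(0.1, 0.3, 0.5, 0.7)) {
        lo <- names(which(classifyCoherence(cm, cl, tauPos = tau)
                          == "correlated"))
        hi <- names(which(classifyCoherence(cm, cl, tauPos = tau + 0.2)
                          == "correlated"))
        expect_true(all(hi %in% lo))
    }

    ## all-singleton clustering cannot define a core
    v <- corValues(cm)[1:3, 1:3]
    cm3 <- new("CorrelationMatrix", values = v, tissue = "t",
               method = "pearson", nSamples = 100L)
    expect_warning(out <- classifyCoherence(cm3, stats::setNames(1:3,
                                                rownames(v))),
                   "singleton")
    expect_true(all(out == "unclassified"))
})

test_that("cross-tissue ordering uses the reference and exposes shuffling", {
    tp <- .panel3(seed = 11, nTissues = 3)
    results <- lapply(names(tp$panels), function(t) {
        cm <- correlationMatrix(tp$panels[[t]], tissue = t)
        cl <- clusterCorrelationProfiles(cm, k = 3, seed = 2)
        list(matrix = cm, labels = cl,
             classes = classifyCoherence(cm, cl))
    })
    names(results) <- names(tp$panels)

    res <- crossTissueOrder(results, reference = "brain")
    ord <- geneOrder(res)
    ## reference labels are sorted in the display order
    expect_true(!is.unsorted(unname(clusterLabels(res, "brain"))))
    ## every tissue's matrix is re-indexed to the same order
    for (t in names(tp$panels)) {
        expect_identical(rownames(corValues(res@matrices[[t]])), ord)
        expect_identical(names(clusterLabels(res, t)), ord)
    }
    ## assignment table covers gene x tissue exhaustively
    at <- assignmentTable(res)
    expect_identical(nrow(at), length(ord) * 3L)

    ## a single tissue is its own reference
    solo <- crossTissueOrder(results["brain"], reference = "brain")
    expect_identical(geneOrder(solo),
                     names(sort(clusterLabels(solo, "brain"))))

    ## identical labelings across tissues agree perfectly; re-drawn
    ## membership does not
    skip_if_not_installed("mclust")
    dup <- results[c("brain", "brain")]
    names(dup) <- c("brain", "copy")
    resDup <- crossTissueOrder(dup, reference = "brain")
    expect_equal(mclust::adjustedRandIndex(
        clusterLabels(resDup, "brain"), clusterLabels(resDup, "copy")), 1)
    ariAcross <- mclust::adjustedRandIndex(
        clusterLabels(res, "brain"), clusterLabels(res, "liver"))
    truthB <- moduleAssignment(tp$truth)$brain[ord]
    ariWithin <- mclust::adjustedRandIndex(clusterLabels(res, "brain"),
                                           truthB)
    expect_lt(ariAcross, ariWithin - 0.3)

    expect_error(crossTissueOrder(results, reference = "kidney"),
                 "absent")
})

test_that("the one-call analysis wrapper reproduces the stepwise result", {
    tp <- .panel3(seed = 13, nTissues = 2)
    res <- coexpressionAnalysis(tp$panels, k = 3, seed = 5,
                                reference = "brain")
    expect_s4_class(res, "CoexpressionResult")
    expect_identical(res@reference, "brain")
    cmB <- correlationMatrix(tp$panels$brain, tissue = "brain")
    clB <- clusterCorrelationProfiles(cmB, k = 3, seed = 5)
    expect_identical(unname(clusterLabels(res, "brain")[names(clB)]),
                     unname(clB))
})
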