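## Per-tissue correlation matrices, clustering of correlation profiles,
## coherence classification and cross-tissue ordering.

## Mean off-diagonal correlation among `idx` genes; 0 for singletons
## (no internal coherence evidence).
.meanIntraCor <- function(values, idx) {
    if (length(idx) < 2L) return(0)
    sub <- values[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
}

#' Gene-gene correlation matrix for one tissue
#'
#' Computes pairwise correlations between the log2(abundance + 1)
#' profiles of the requested genes across the donors of one tissue.
#' Genes absent from the matrix or with zero variance across donors are
#' dropped with a message. The result is exactly symmetric with unit
#' diagonal.
#'
#' @param se A \linkS4class{SummarizedExperiment} with assay
#'   \code{"abundance"} (genes x donors) for a single tissue.
#' @param geneSet Character vector of genes to correlate (default: all
#'   genes in the matrix).
#' @param method "pearson" (default) or "spearman".
#' @param minSamples Minimum donors required (default 10).
#' @param tissue Tissue label; defaults to the colData \code{tissue}
#'   column when present.
#' @return A \linkS4class{CorrelationMatrix}.
#' @examples
#' tp <- simulateTissuePanel(sprintf("G%02d", 1:20), nTissues = 1,
#'                           nDonors = 50, rWithin = 0.8, seed = 1)
#' correlationMatrix(tp$panels$brain)
#' @export
correlationMatrix <- function(se, geneSet = NULL,
                              method = c("pearson", "spearman"),
                              minSamples = 10L, tissue = NULL) {
    method <- match.arg(method)
    m <- SummarizedExperiment::assay(se, "abundance")
    if (ncol(m) < minSamples) {
        stop("fewer than minSamples = ", minSamples, " donors available")
    }
    if (is.null(tissue)) {
        cd <- SummarizedExperiment::colData(se)
        tissue <- if ("tissue" %in% colnames(cd)) {
            as.character(cd$tissue[1L])
        } else "tissue"
    }
    if (!is.null(geneSet)) {
        geneSet <- as.character(geneSet)
        missing <- setdiff(geneSet, rownames(m))
        if (length(missing) == length(geneSet)) {
            stop("none of the requested genes are present in the matrix")
        }
        if (length(missing)) {
            message(length(missing),
                    " requested gene(s) absent from the matrix; dropped")
        }
        m <- m[intersect(geneSet, rownames(m)), , drop = FALSE]
    }
    lg <- log2(m + 1)
    v <- apply(lg, 1L, stats::var)
    if (any(v == 0)) {
        message(sum(v == 0), " zero-variance gene(s) dropped")
        lg <- lg[v > 0, , drop = FALSE]
    }
    if (nrow(lg) < 2L) stop("fewer than 2 usable genes")
    cm <- stats::cor(t(lg), method = method)
    cm <- (cm + t(cm)) / 2          # enforce exact symmetry
    cm[cm > 1] <- 1
    cm[cm < -1] <- -1
    diag(cm) <- 1
    new("CorrelationMatrix", values = cm, tissue = tissue,
        method = method, nSamples = ncol(lg))
}

#' Cluster genes by their correlation profiles
#'
#' Each gene's feature vector is its row of the correlation matrix
#' (diagonal included; it is constant 1 and does not affect Euclidean
#' geometry between rows). k-means (default) keeps the best of
#' \code{nRestarts} random initializations; the hierarchical alternative
#' uses average linkage on Euclidean distances cut at k groups. Labels
#' are renumbered by descending mean intra-cluster correlation, so
#' cluster 1 is always the most internally coherent group. Clustering is
#' performed on the gene-ID-sorted matrix and mapped back, making the
#' result equivariant under permutations of the input gene order, and is
#' deterministic under \code{seed}.
#'
#' @param cmat A \linkS4class{CorrelationMatrix}.
#' @param k Number of groups (default 3), less than the number of genes.
#' @param method "kmeans" (default) or "hierarchical".
#' @param nRestarts Random k-means initializations (default 50).
#' @param seed Integer RNG seed (k-means only).
#' @return Named integer vector of cluster labels in input gene order.
#' @examples
#' tp <- simulateTissuePanel(sprintf("G%02d", 1:30), nTissues = 1,
#'                           nDonors = 100, rWithin = 0.9, seed = 1)
#' cm <- correlationMatrix(tp$panels$brain)
#' table(clusterCorrelationProfiles(cm, k = 3, seed = 1))
#' @export
clusterCorrelationProfiles <- function(cmat, k = 3L,
                                       method = c("kmeans",
                                                  "hierarchical"),
                                       nRestarts = 50L, seed = 1L) {
    stopifnot(is(cmat, "CorrelationMatrix"))
    method <- match.arg(method)
    k <- .assertCount(k, "k")
    nRestarts <- .assertCount(nRestarts, "nRestarts")
    genes <- rownames(cmat@values)
    if (k >= length(genes)) {
        stop("k must be smaller than the number of genes (", length(genes),
             ")")
    }
    ord <- order(genes, method = "radix")
    v <- cmat@values[ord, ord, drop = FALSE]
    labels <- if (method == "kmeans") {
        fit <- .withSeed(seed, stats::kmeans(v, centers = k,
                                             nstart = nRestarts,
                                             iter.max = 100L))
        fit$cluster
    } else {
        hc <- stats::hclust(stats::dist(v), method = "average")
        stats::cutree(hc, k = k)
    }
    ## renumber by descending mean intra-cluster correlation
    coherence <- vapply(seq_len(k), function(cl) {
        .meanIntraCor(v, which(labels == cl))
    }, numeric(1))
    remap <- integer(k)
    remap[order(-coherence)] <- seq_len(k)
    labels <- remap[labels]
    names(labels) <- rownames(v)
    labels[genes]
}

#' Classify genes as correlated or anti-correlated with the core cluster
#'
#' The core cluster is the one with the highest mean intra-cluster
#' correlation. A gene is "correlated" when its mean correlation to the
#' core-cluster genes (excluding itself) is at least \code{tauPos},
#' "anti-correlated" when it is at most \code{tauNeg}, and
#' "unclassified" otherwise.
#'
#' @param cmat A \linkS4class{CorrelationMatrix}.
#' @param labels Cluster labels from
#'   \code{\link{clusterCorrelationProfiles}} computed on \code{cmat}.
#' @param tauPos,tauNeg Correlation thresholds (defaults 0.3 and -0.1).
#' @return Named character vector (gene -> class) in the matrix's gene
#'   order.
#' @examples
#' tp <- simulateTissuePanel(sprintf("G%02d", 1:30), nTissues = 1,
#'                           nDonors = 100, rWithin = 0.9, seed = 1)
#' cm <- correlationMatrix(tp$panels$brain)
#' cl <- clusterCorrelationProfiles(cm, seed = 1)
#' table(classifyCoherence(cm, cl))
#' @export
classifyCoherence <- function(cmat, labels, tauPos = 0.3, tauNeg = -0.1) {
    stopifnot(is(cmat, "CorrelationMatrix"))
    v <- cmat@values
    genes <- rownames(v)
    if (!identical(sort(names(labels)), sort(genes))) {
        stop("labels must cover exactly the genes of the matrix")
    }
    if (tauNeg > tauPos) stop("tauNeg must not exceed tauPos")
    labels <- labels[genes]
    sizes <- table(labels)
    if (all(sizes == 1L)) {
        warning("all clusters are singletons; no core cluster defined")
        return(stats::setNames(rep("unclassified", length(genes)), genes))
    }
    coherence <- vapply(sort(unique(labels)), function(cl) {
        .meanIntraCor(v, which(labels == cl))
    }, numeric(1))
    core <- sort(unique(labels))[which.max(coherence)]
    coreIdx <- which(labels == core)
    cls <- vapply(seq_along(genes), function(i) {
        others <- setdiff(coreIdx, i)
        if (!length(others)) return("unclassified")
        mc <- mean(v[i, others])
        if (mc >= tauPos) "correlated"
        else if (mc <= tauNeg) "anti-correlated"
        else "unclassified"
    }, character(1))
    stats::setNames(cls, genes)
}

#' Order tissues by a reference tissue's clustering
#'
#' Takes per-tissue correlation matrices with their cluster labels (and
#' optionally coherence classes), restricts all tissues to the common
#' gene set, sorts genes by the reference tissue's clusters (by label,
#' then by decreasing mean correlation to the gene's own cluster), and
#' re-indexes every tissue's matrix to that display order.
#'
#' @param results Named list (by tissue); each element a list with
#'   \code{matrix} (a \linkS4class{CorrelationMatrix}), \code{labels}
#'   (named integer vector) and optionally \code{classes} (named
#'   character vector).
#' @param reference Tissue label present in \code{results}.
#' @return A \linkS4class{CoexpressionResult}; its
#'   \code{assignmentTable} lists each gene's cluster and coherence
#'   class per tissue.
#' @examples
#' tp <- simulateTissuePanel(sprintf("G%02d", 1:30), nTissues = 2,
#'                           nDonors = 100, rWithin = 0.9, seed = 1)
#' res <- lapply(tp$panels, function(p) {
#'     cm <- correlationMatrix(p)
#'     cl <- clusterCorrelationProfiles(cm, seed = 1)
#'     list(matrix = cm, labels = cl, classes = classifyCoherence(cm, cl))
#' })
#' crossTissueOrder(res, reference = "brain")
#' @export
crossTissueOrder <- function(results, reference) {
    if (is.null(names(results)) || anyDuplicated(names(results))) {
        stop("results must be a named per-tissue list")
    }
    if (!reference %in% names(results)) {
        stop("reference tissue '", reference, "' absent from results")
    }
    geneLists <- lapply(results, function(r) rownames(r$matrix@values))
    common <- Reduce(intersect, geneLists)
    if (length(common) < 2L) stop("fewer than 2 genes shared across tissues")
    dropped <- length(unique(unlist(geneLists))) - length(common)
    if (dropped > 0L) {
        message(dropped, " gene(s) not shared by all tissues; dropped")
    }
    ref <- results[[reference]]
    refLab <- ref$labels[common]
    refV <- ref$matrix@values[common, common, drop = FALSE]
    ## within-cluster: most representative (highest mean correlation to
    ## its own cluster) first; gene ID breaks ties
    ownCor <- vapply(seq_along(common), function(i) {
        idx <- setdiff(which(refLab == refLab[i]), i)
        if (!length(idx)) return(0)
        mean(refV[i, idx])
    }, numeric(1))
    ordIdx <- order(refLab, -ownCor, common, method = "radix")
    displayOrder <- common[ordIdx]
    matrices <- list()
    clusters <- list()
    classes <- list()
    rows <- list()
    for (t in names(results)) {
        r <- results[[t]]
        v <- r$matrix@values[displayOrder, displayOrder, drop = FALSE]
        matrices[[t]] <- new("CorrelationMatrix", values = v,
                             tissue = r$matrix@tissue,
                             method = r$matrix@method,
                             nSamples = r$matrix@nSamples)
        clusters[[t]] <- r$labels[displayOrder]
        classes[[t]] <- if (!is.null(r$classes)) {
            r$classes[displayOrder]
        } else {
            stats::setNames(rep(NA_character_, length(displayOrder)),
                            displayOrder)
        }
        rows[[t]] <- S4Vectors::DataFrame(
            gene = displayOrder, tissue = t,
            cluster = unname(clusters[[t]]),
            class = unname(classes[[t]]))
    }
    new("CoexpressionResult", matrices = matrices, clusters = clusters,
        classes = classes, reference = reference,
        geneOrder = displayOrder, assignments = do.call(rbind, rows))
}

#' Full co-expression coherence analysis of a tissue panel
#'
#' Convenience wrapper running \code{\link{correlationMatrix}},
#' \code{\link{clusterCorrelationProfiles}} and
#' \code{\link{classifyCoherence}} per tissue, then
#' \code{\link{crossTissueOrder}} against the reference tissue.
#'
#' @param panels Named list of per-tissue
#'   \linkS4class{SummarizedExperiment} objects.
#' @param geneSet Optional gene subset.
#' @param k,method,nRestarts,seed Passed to the clustering step; each
#'   tissue uses \code{seed} + its index - 1.
#' @param corMethod,minSamples Passed to the correlation step.
#' @param tauPos,tauNeg Passed to the classification step.
#' @param reference Reference tissue (default: first panel).
#' @return A \linkS4class{CoexpressionResult}.
#' @examples
#' tp <- simulateTissuePanel(sprintf("G%02d", 1:30), nTissues = 2,
#'                           nDonors = 100, rWithin = 0.9, seed = 1)
#' coexpressionAnalysis(tp$panels, seed = 1)
#' @export
coexpressionAnalysis <- function(panels, geneSet = NULL, k = 3L,
                                 method = "kmeans", nRestarts = 50L,
                                 seed = 1L, corMethod = "pearson",
                                 minSamples = 10L, tauPos = 0.3,
                                 tauNeg = -0.1,
                                 reference = names(panels)[1L]) {
    stopifnot(length(panels) >= 1L, !is.null(names(panels)))
    results <- list()
    for (i in seq_along(panels)) {
        t <- names(panels)[i]
        cm <- correlationMatrix(panels[[t]], geneSet = geneSet,
                                method = corMethod,
                                minSamples = minSamples, tissue = t)
        cl <- clusterCorrelationProfiles(cm, k = k, method = method,
                                         nRestarts = nRestarts,
                                         seed = seed + i - 1L)
        results[[t]] <- list(matrix = cm, labels = cl,
                             classes = classifyCoherence(cm, cl,
                                                         tauPos, tauNeg))
    }
    crossTissueOrder(results, reference)
}
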