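## Running-sum gene-set enrichment (ES, permutation null, NES) and
## hypergeometric over-representation analysis.

#' Rank genes for enrichment analysis
#'
#' Orders genes best-to-worst by a signed metric derived from a
#' differential result: the Welch t statistic, or the signed log10
#' p-value (\code{sign(log2FC) * -log10(p)}). Ties are broken
#' lexicographically by gene identifier so the ranking is deterministic.
#'
#' @param results A \linkS4class{DifferentialResults} object, or a named
#'   numeric vector of pre-computed metric values.
#' @param metric "t_stat" (default) or "signed_logp"; ignored for a
#'   pre-computed vector.
#' @return A \linkS4class{RankedList}.
#' @examples
#' rankGenes(c(A = 2, B = -1, C = 0.5))
#' @export
rankGenes <- function(results, metric = c("t_stat", "signed_logp")) {
    metric <- match.arg(metric)
    if (is(results, "DifferentialResults")) {
        vals <- switch(metric,
            t_stat = stats::setNames(results$t, rownames(results)),
            signed_logp = stats::setNames(
                sign(results$log2FC) *
                    -log10(pmax(results$pValue, .Machine$double.xmin)),
                rownames(results)))
    } else {
        vals <- results
        if (is.null(names(vals))) stop("metric vector must be named by gene")
    }
    if (!length(vals)) stop("no genes to rank")
    if (anyDuplicated(names(vals))) stop("duplicate genes in ranking input")
    if (any(!is.finite(vals))) stop("ranking metric must be finite")
    ord <- order(-vals, names(vals), method = "radix")
    new("RankedList", geneIds = names(vals)[ord],
        metric = unname(vals[ord]))
}

## Core running-sum statistic. hits: logical over ranking positions;
## w: |metric|^alpha. Hits increment by w/sum(w[hits]); misses decrement
## by 1/(N - Nhit). Returns the per-position running sum.
.runningSum <- function(hits, w) {
    nHit <- sum(hits)
    n <- length(hits)
    wHit <- sum(w[hits])
    inc <- rep.int(-1 / (n - nHit), n)
    if (wHit == 0) {
        ## all hit weights zero (e.g., hits sitting at metric 0 with
        ## weight > 0): fall back to equal hit increments
        inc[hits] <- 1 / nHit
    } else {
        inc[hits] <- w[hits] / wHit
    }
    cumsum(inc)
}

## Signed maximum deviation of a running sum. When the positive and
## negative extrema tie in magnitude (common on the weight-0 lattice,
## up to accumulation rounding) the positive side wins; the tolerance
## absorbs sub-ulp differences between accumulation orders.
.esFromRun <- function(run) {
    maxP <- max(run)
    minP <- min(run)
    if (maxP + minP >= -1e-12) maxP else minP
}

#' Running-sum enrichment score of a gene set
#'
#' Walks the ranked list: positions occupied by set members increment
#' the running sum by |metric|^weightExponent (normalized by the sum
#' over members), other positions decrement by 1/(N - Nhit). The
#' enrichment score is the signed maximum deviation; the leading edge
#' contains the member genes at or before the extremum (at or after it
#' for a negative score).
#'
#' @param ranked A \linkS4class{RankedList}.
#' @param geneSet A \linkS4class{GeneSet} (or character vector of
#'   members). Must overlap the ranked universe without covering it.
#' @param weightExponent Non-negative metric weighting; 0 gives the
#'   unweighted (Kolmogorov-Smirnov) form, 1 (default) the standard
#'   weighted form.
#' @return A list with \code{es}, \code{runningSum} (per-position) and
#'   \code{leadingEdge}.
#' @examples
#' rl <- rankGenes(c(A = 3, B = 2, C = 1, D = 0, E = -1, F = -2))
#' enrichmentScore(rl, c("A", "B"), weightExponent = 0)$es
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
    stopifnot(is(ranked, "RankedList"))
    members <- if (is(geneSet, "GeneSet")) geneSet@members else
        as.character(geneSet)
    .assertScalarNumber(weightExponent, "weightExponent", 0)
    hits <- ranked@geneIds %in% members
    if (!any(hits)) {
        stop("gene set is disjoint from the ranked universe")
    }
    if (all(hits)) {
        stop("gene set covers the whole ranked universe; ES undefined")
    }
    w <- abs(ranked@metric)^weightExponent
    run <- .runningSum(hits, w)
    es <- .esFromRun(run)
    i <- if (es >= 0) which.max(run) else which.min(run)
    lead <- if (es >= 0) {
        ranked@geneIds[hits & seq_along(hits) <= i]
    } else {
        ranked@geneIds[hits & seq_along(hits) >= i]
    }
    list(es = es, runningSum = run, leadingEdge = lead)
}

#' Permutation-based significance of an enrichment score
#'
#' Builds a null distribution by drawing random gene-label sets of the
#' same effective size from the ranked universe and recomputing the
#' running-sum score. The nominal p-value is sign-stratified and
#' additively smoothed, p = (1 + #\{same-signed null >= |observed|\}) /
#' (1 + #\{same-signed null\}), so it is never zero; the normalized
#' enrichment score divides the observed score by the mean |null score|
#' of the same sign. Gene-label (not phenotype) permutation is used:
#' with triplicate designs only 20 phenotype permutations exist, far too
#' few for the p-value resolution the method is quoted at.
#'
#' @param ranked A \linkS4class{RankedList}.
#' @param geneSet A \linkS4class{GeneSet} or character vector.
#' @param nPermutations At least 100 (default 1000).
#' @param weightExponent Passed to \code{\link{enrichmentScore}}.
#' @param seed Integer RNG seed; identical seeds give identical results.
#' @return An \linkS4class{EnrichmentResult}.
#' @examples
#' rl <- rankGenes(stats::setNames(10:1 / 2, LETTERS[1:10]))
#' gseaPermutation(rl, c("A", "B", "C"), nPermutations = 100, seed = 1)
#' @export
gseaPermutation <- function(ranked, geneSet, nPermutations = 1000L,
                            weightExponent = 1, seed = 1L) {
    nPermutations <- .assertCount(nPermutations, "nPermutations",
                                  min = 100L)
    obs <- enrichmentScore(ranked, geneSet, weightExponent)
    members <- if (is(geneSet, "GeneSet")) geneSet@members else
        as.character(geneSet)
    setName <- if (is(geneSet, "GeneSet")) geneSet@name else "geneSet"
    n <- length(ranked@geneIds)
    nHit <- sum(ranked@geneIds %in% members)
    w <- abs(ranked@metric)^weightExponent
    nullEs <- .withSeed(seed, {
        vapply(seq_len(nPermutations), function(i) {
            hits <- logical(n)
            hits[sample.int(n, nHit)] <- TRUE
            .esFromRun(.runningSum(hits, w))
        }, numeric(1))
    })
    sameSign <- if (obs$es >= 0) nullEs >= 0 else nullEs < 0
    nSame <- sum(sameSign)
    if (nSame == 0L) {
        warning("no same-signed null scores; p reported at the smoothing guard")
        p <- 1
        nesVal <- NA_real_
    } else {
        p <- (1 + sum(sameSign & abs(nullEs) >= abs(obs$es))) / (1 + nSame)
        nesVal <- obs$es / mean(abs(nullEs[sameSign]))
    }
    new("EnrichmentResult", setName = setName, es = obs$es,
        nes = nesVal, pNominal = p,
        nPermutations = nPermutations,
        leadingEdge = obs$leadingEdge, runningSum = obs$runningSum)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a query gene
#' set against a background universe with the one-sided hypergeometric
#' upper-tail probability, BH-adjusted across the supplied terms. Each
#' term is intersected with the background before testing; terms
#' disjoint from the background are skipped with a message. Matching is
#' case-insensitive.
#'
#' @param query Character vector, a subset of \code{background}.
#' @param terms List of \linkS4class{GeneSet} objects (or a single one).
#' @param background Character vector, the gene universe.
#' @param ease Apply the EASE correction (subtract 1 from the observed
#'   overlap before the tail probability); off by default.
#' @return A \linkS4class{DFrame} with columns \code{term}, \code{k}
#'   (overlap), \code{K} (term size in background), \code{n} (query
#'   size), \code{N} (background size), \code{pValue}, \code{qValue}.
#' @examples
#' bg <- sprintf("G%02d", 1:20)
#' oraTest(bg[1:5], GeneSet("t1", members = bg[c(1:4, 10)]), bg)
#' @export
oraTest <- function(query, terms, background, ease = FALSE) {
    if (is(terms, "GeneSet")) terms <- list(terms)
    query <- unique(.normGene(query))
    background <- unique(.normGene(background))
    if (!length(query) || !length(background)) {
        stop("query and background must be non-empty")
    }
    if (!all(query %in% background)) {
        stop("query must be a subset of the background universe")
    }
    N <- length(background)
    n <- length(query)
    rows <- lapply(terms, function(ts) {
        stopifnot(is(ts, "GeneSet"))
        tg <- intersect(unique(.normGene(ts@members)), background)
        if (!length(tg)) {
            message("term '", ts@name,
                    "' is disjoint from the background; skipped")
            return(NULL)
        }
        K <- length(tg)
        k <- length(intersect(tg, query))
        kAdj <- if (ease) max(k - 1L, 0L) else k
        p <- stats::phyper(kAdj - 1L, K, N - K, n, lower.tail = FALSE)
        S4Vectors::DataFrame(term = ts@name, k = k, K = K, n = n, N = N,
                             pValue = p)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("no testable terms")
    out <- do.call(rbind, rows)
    out$qValue <- stats::p.adjust(out$pValue, method = "BH")
    out
}
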