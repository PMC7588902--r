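## Welch differential testing, fold changes, significance calling, the
## active-transcriptome filter and the comparative-Ct qPCR utility.

## Vectorized Welch machinery over row-matched matrices of log-scale
## values. Both groups zero-variance: a variance floor of 1e-12 is
## applied and the gene flagged degenerate (equal means then give t = 0,
## p = 1; unequal means give the variance-floor result).
.welchRows <- function(ref, alt, varFloor = 1e-12) {
    a <- .rowMeansVars(ref)
    b <- .rowMeansVars(alt)
    degenerate <- a$var == 0 & b$var == 0
    v1 <- ifelse(degenerate, varFloor, a$var)
    v2 <- ifelse(degenerate, varFloor, b$var)
    se2 <- v1 / a$n + v2 / b$n
    t <- (b$mean - a$mean) / sqrt(se2)
    df <- se2^2 / ((v1 / a$n)^2 / (a$n - 1L) + (v2 / b$n)^2 / (b$n - 1L))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p, meanRef = a$mean, meanAlt = b$mean,
         degenerate = degenerate)
}

#' Welch (unequal-variance) two-sample t-test
#'
#' The per-gene test of the differential-expression path: unpooled
#' variances, Welch-Satterthwaite degrees of freedom, two-sided p from
#' the t distribution. When both groups have zero variance a variance
#' floor of 1e-12 is applied (equal means then yield t = 0, p = 1) and
#' the result is flagged degenerate.
#'
#' @param groupRef,groupAlt Numeric vectors of at least 2 finite values.
#' @return A list with \code{t} (alt minus ref in sign), \code{df},
#'   \code{p} and \code{degenerate}.
#' @examples
#' welchTTest(c(4.1, 4.8, 5.2), c(6.9, 7.3, 8.0))
#' @export
welchTTest <- function(groupRef, groupAlt) {
    if (length(groupRef) < 2L || length(groupAlt) < 2L ||
        any(!is.finite(groupRef)) || any(!is.finite(groupAlt))) {
        stop("each group needs >= 2 finite values")
    }
    w <- .welchRows(matrix(groupRef, nrow = 1L),
                    matrix(groupAlt, nrow = 1L))
    list(t = w$t, df = w$df, p = w$p, degenerate = w$degenerate)
}

#' Log2 fold change of two means
#'
#' \code{log2((meanAlt + pseudocount) / (meanRef + pseudocount))}.
#'
#' @param meanRef,meanAlt Non-negative mean abundances.
#' @param pseudocount Non-negative abundance added to both means; with
#'   both means and the pseudocount zero the ratio is undefined and the
#'   call is rejected.
#' @return Log2 fold change (alt over ref), vectorized over the means.
#' @examples
#' log2FoldChange(10, 40)            # 2
#' log2FoldChange(0, 8, pseudocount = 1)  # log2(9)
#' @export
log2FoldChange <- function(meanRef, meanAlt, pseudocount = 0) {
    if (any(meanRef < 0) || any(meanAlt < 0) || pseudocount < 0) {
        stop("means and pseudocount must be >= 0")
    }
    if (any(meanRef + pseudocount == 0 & meanAlt + pseudocount == 0)) {
        stop("log2 fold change undefined: both means and pseudocount are zero")
    }
    log2((meanAlt + pseudocount) / (meanRef + pseudocount))
}

#' Active-transcriptome filter
#'
#' Retains genes with any evidence of expression: maximum abundance
#' across all samples strictly greater than \code{minExpression}. Input
#' gene order is preserved.
#'
#' @param se A \linkS4class{SummarizedExperiment} with assay
#'   \code{"abundance"}.
#' @param minExpression Abundance floor (default 0).
#' @return Character vector of retained gene identifiers.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 50, seed = 1))
#' length(activeTranscriptomeFilter(sim$se))
#' @export
activeTranscriptomeFilter <- function(se, minExpression = 0) {
    m <- SummarizedExperiment::assay(se, "abundance")
    rownames(m)[apply(m, 1L, max) > minExpression]
}

#' Call differentially expressed genes between two conditions
#'
#' Applies the active-transcriptome filter, tests each remaining gene
#' with the Welch unequal-variance t-test on log2(abundance +
#' pseudocount), computes the log2 fold change of raw condition means
#' (pseudocounted), and calls significance with strict thresholds:
#' significant iff \code{p < pMax} and \code{|log2FC| > minAbsLog2FC}.
#' BH-adjusted q-values are reported as an informational column; the
#' primary decision rule uses raw p.
#'
#' @param se A \linkS4class{SummarizedExperiment} with assay
#'   \code{"abundance"} and a colData column naming each sample's group.
#' @param refGroup,altGroup Group labels (each with >= 2 replicates).
#' @param thresholds A \linkS4class{Thresholds} object.
#' @param groupColumn colData column holding group labels (default
#'   \code{"condition"}).
#' @return A \linkS4class{DifferentialResults} object, one row per
#'   active gene in input order.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 300, seed = 1))
#' res <- callDifferential(sim$se, "vector", "overexpression")
#' res
#' @export
callDifferential <- function(se, refGroup, altGroup,
                             thresholds = Thresholds(),
                             groupColumn = "condition") {
    stopifnot(is(thresholds, "Thresholds"))
    validObject(thresholds)
    cd <- SummarizedExperiment::colData(se)
    if (!groupColumn %in% colnames(cd)) {
        stop("design column '", groupColumn, "' not found")
    }
    groups <- as.character(cd[[groupColumn]])
    for (g in c(refGroup, altGroup)) {
        if (sum(groups == g) < 2L) {
            stop("group '", g, "' absent from design or has < 2 replicates")
        }
    }
    m <- SummarizedExperiment::assay(se, "abundance")
    keep <- activeTranscriptomeFilter(se, thresholds@minExpression)
    m <- m[keep, , drop = FALSE]
    refM <- m[, groups == refGroup, drop = FALSE]
    altM <- m[, groups == altGroup, drop = FALSE]
    pc <- thresholds@pseudocount
    w <- .welchRows(log2(refM + pc), log2(altM + pc))
    meanRef <- rowMeans(refM)
    meanAlt <- rowMeans(altM)
    lfc <- log2FoldChange(meanRef, meanAlt, pc)
    sig <- w$p < thresholds@pMax & abs(lfc) > thresholds@minAbsLog2FC
    direction <- ifelse(!sig, "none", ifelse(lfc > 0, "up", "down"))
    out <- S4Vectors::DataFrame(
        meanRef = unname(meanRef), meanAlt = unname(meanAlt),
        log2FC = unname(lfc), t = unname(w$t), df = unname(w$df),
        pValue = unname(w$p),
        qValue = unname(stats::p.adjust(w$p, method = "BH")),
        significant = unname(sig), direction = unname(direction),
        degenerate = unname(w$degenerate), row.names = keep)
    res <- new("DifferentialResults", out)
    metadata(res) <- list(refGroup = refGroup, altGroup = altGroup,
                          thresholds = thresholds)
    res
}

#' Significant genes from a differential result
#'
#' @param res A \linkS4class{DifferentialResults} object or a
#'   data.frame-like table with columns \code{log2FC} and \code{p} (a
#'   companion-study table), in which case \code{thresholds} is applied.
#' @param direction "up", "down" or "any".
#' @param thresholds Used only for plain tables.
#' @return Character vector of gene identifiers.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 300, seed = 1))
#' res <- callDifferential(sim$se, "vector", "overexpression")
#' head(significantGenes(res, "up"))
#' @export
significantGenes <- function(res, direction = c("any", "up", "down"),
                             thresholds = Thresholds()) {
    direction <- match.arg(direction)
    if (is(res, "DifferentialResults")) {
        keep <- res$significant
        if (direction != "any") keep <- keep & res$direction == direction
        return(rownames(res)[keep])
    }
    stopifnot(all(c("gene", "log2FC", "p") %in% colnames(res)))
    sig <- res$p < thresholds@pMax &
        abs(res$log2FC) > thresholds@minAbsLog2FC
    if (direction == "up") sig <- sig & res$log2FC > 0
    if (direction == "down") sig <- sig & res$log2FC < 0
    as.character(res$gene[sig])
}

#' Comparative-Ct (delta-delta-Ct) relative abundance
#'
#' qPCR quantification: per condition, delta-Ct = mean(target Ct) -
#' mean(reference Ct); delta-delta-Ct subtracts the control condition's
#' delta-Ct; relative abundance = 2^(-delta-delta-Ct), so the control
#' maps to 1.
#'
#' @param ctTarget,ctReference Named lists mapping condition label to a
#'   numeric vector of replicate threshold cycles; the two lists must
#'   share condition names.
#' @param controlLabel The control condition (must be present).
#' @return Named numeric vector of relative abundances per condition.
#' @examples
#' deltaDeltaCt(list(control = 20, treated = 18),
#'              list(control = 15, treated = 15), "control")
#' @export
deltaDeltaCt <- function(ctTarget, ctReference, controlLabel) {
    if (!identical(sort(names(ctTarget)), sort(names(ctReference)))) {
        stop("target and reference must cover the same conditions")
    }
    if (!controlLabel %in% names(ctTarget)) {
        stop("control condition '", controlLabel, "' not found")
    }
    conds <- names(ctTarget)
    dCt <- vapply(conds, function(cn) {
        mean(ctTarget[[cn]]) - mean(ctReference[[cn]])
    }, numeric(1))
    ddCt <- dCt - dCt[[controlLabel]]
    2^(-ddCt)
}
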