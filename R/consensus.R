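## Cross-study consensus: DE-set intersection, fold-change concordance
## regression and tiered consensus construction.

## Match genes case-insensitively; returns indices of `query` in `ref`.
.matchGenes <- function(query, ref) match(.normGene(query), .normGene(ref))

#' Intersect significant calls of two studies
#'
#' Partitions the union of significant genes into shared and
#' study-specific sets. With \code{requireSignConcordance} (the
#' default), a gene enters a shared set only when both studies call it
#' in the same direction; discordant genes are assigned to the
#' study-specific sets. Gene identity is matched on upper-cased symbols.
#'
#' @param studyA A \linkS4class{DifferentialResults} object.
#' @param studyB A data.frame with columns \code{gene}, \code{log2FC},
#'   \code{p} (companion-study differential table).
#' @param requireSignConcordance Require matching direction (default
#'   TRUE).
#' @param thresholds \linkS4class{Thresholds} applied to
#'   \code{studyB}'s table (and used only there; \code{studyA} carries
#'   its own calls).
#' @return A list with character vectors \code{sharedUp},
#'   \code{sharedDown}, \code{aOnly}, \code{bOnly}; the four sets
#'   partition the union of significant genes (symbols as in study A
#'   where shared).
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 300, seed = 1))
#' res <- callDifferential(sim$se, "vector", "overexpression")
#' comp <- simulateCompanionStudy(sim$truth, 1, 0, seed = 2)
#' lengths(intersectDE(res, comp))
#' @export
intersectDE <- function(studyA, studyB, requireSignConcordance = TRUE,
                        thresholds = Thresholds()) {
    aUp <- significantGenes(studyA, "up", thresholds)
    aDown <- significantGenes(studyA, "down", thresholds)
    bUp <- significantGenes(studyB, "up", thresholds)
    bDown <- significantGenes(studyB, "down", thresholds)
    nAUp <- .normGene(aUp); nADown <- .normGene(aDown)
    nBUp <- .normGene(bUp); nBDown <- .normGene(bDown)
    if (requireSignConcordance) {
        sharedUp <- aUp[nAUp %in% nBUp]
        sharedDown <- aDown[nADown %in% nBDown]
    } else {
        bAll <- c(nBUp, nBDown)
        sharedUp <- aUp[nAUp %in% bAll]
        sharedDown <- aDown[nADown %in% bAll]
    }
    shared <- .normGene(c(sharedUp, sharedDown))
    aOnly <- c(aUp, aDown)[!.normGene(c(aUp, aDown)) %in% shared]
    bOnly <- c(bUp, bDown)[!.normGene(c(bUp, bDown)) %in%
                               c(shared, nAUp, nADown)]
    ## discordant genes significant in both studies stay study-specific
    ## on the A side; keep them out of bOnly too so the four sets
    ## partition the union
    bOnly <- bOnly[!.normGene(bOnly) %in% .normGene(aOnly)]
    if (!length(shared)) {
        warning("no shared significant genes between the two studies")
    }
    list(sharedUp = sharedUp, sharedDown = sharedDown,
         aOnly = aOnly, bOnly = bOnly)
}

#' Ordinary least-squares fold-change concordance
#'
#' Regresses study B's log2 fold changes on study A's over the shared
#' genes (free intercept, via \code{stats::lm}) and reports the squared
#' Pearson correlation. r-squared is invariant to swapping the studies;
#' the slope is not.
#'
#' @param lfcA,lfcB Aligned numeric vectors (>= 3 values).
#' @param genes Optional gene identifiers aligned to the fold changes.
#' @return A \linkS4class{StudyComparison} object.
#' @examples
#' regressFoldChanges(c(1, 2, 3, 4), c(2.1, 3.9, 6.2, 7.8))
#' @export
regressFoldChanges <- function(lfcA, lfcB, genes = NULL) {
    if (length(lfcA) != length(lfcB)) stop("fold changes must be aligned")
    if (length(lfcA) < 3L) stop("need >= 3 shared genes")
    if (any(!is.finite(lfcA)) || any(!is.finite(lfcB))) {
        stop("fold changes must be finite")
    }
    if (stats::var(lfcA) == 0) {
        stop("zero variance in study A fold changes; slope undefined")
    }
    fit <- stats::lm(lfcB ~ lfcA)
    r2 <- if (stats::var(lfcB) == 0) 1 else stats::cor(lfcA, lfcB)^2
    if (is.null(genes)) genes <- sprintf("gene%d", seq_along(lfcA))
    new("StudyComparison", sharedGenes = as.character(genes),
        lfcA = as.numeric(lfcA), lfcB = as.numeric(lfcB),
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        rSquared = r2)
}

#' Build tiered consensus gene sets
#'
#' Combines the cross-study shared sets with protein-level evidence:
#' \code{rnaUp}/\code{rnaDown} are copied from the shared sets;
#' \code{rnaProtein} restricts their union to genes whose protein
#' p-value is below \code{pMax} (and, by default, whose protein fold
#' change matches the RNA direction). Per-gene provenance is recorded.
#'
#' @param sharedUp,sharedDown Character vectors from
#'   \code{\link{intersectDE}}.
#' @param proteinTable data.frame with columns \code{gene},
#'   \code{log2FC}, \code{p}, or NULL (then \code{rnaProtein} is empty
#'   and flagged).
#' @param thresholds \linkS4class{Thresholds}; protein significance uses
#'   the same \code{pMax} as RNA.
#' @param requireProteinSignConcordance Require protein fold-change sign
#'   to match the RNA direction (default TRUE).
#' @return A \linkS4class{ConsensusSets} object.
#' @examples
#' prov <- buildConsensus(c("NQO1", "HMOX1"), c("MAP2"),
#'     data.frame(gene = c("NQO1", "MAP2"), log2FC = c(1.2, -0.8),
#'                p = c(0.001, 0.04)))
#' rnaProtein(prov)
#' @export
buildConsensus <- function(sharedUp, sharedDown, proteinTable = NULL,
                           thresholds = Thresholds(),
                           requireProteinSignConcordance = TRUE) {
    sharedUp <- as.character(sharedUp)
    sharedDown <- as.character(sharedDown)
    if (length(intersect(.normGene(sharedUp), .normGene(sharedDown)))) {
        stop("sharedUp and sharedDown overlap")
    }
    genes <- c(sharedUp, sharedDown)
    rnaDir <- rep(c("up", "down"),
                  c(length(sharedUp), length(sharedDown)))
    protDetected <- rep(FALSE, length(genes))
    protLfc <- rep(NA_real_, length(genes))
    protP <- rep(NA_real_, length(genes))
    if (is.null(proteinTable) || nrow(proteinTable) == 0L) {
        if (is.null(proteinTable)) {
            message("no protein table supplied; rnaProtein tier is empty")
        }
    } else {
        stopifnot(all(c("gene", "log2FC", "p") %in% colnames(proteinTable)))
        idx <- .matchGenes(genes, proteinTable$gene)
        protDetected <- !is.na(idx)
        protLfc[protDetected] <- proteinTable$log2FC[idx[protDetected]]
        protP[protDetected] <- proteinTable$p[idx[protDetected]]
    }
    protSig <- protDetected & !is.na(protP) & protP < thresholds@pMax
    if (requireProteinSignConcordance) {
        signMatch <- ifelse(rnaDir == "up", protLfc > 0, protLfc < 0)
        protSig <- protSig & !is.na(signMatch) & signMatch
    }
    prov <- S4Vectors::DataFrame(
        gene = genes, rnaDirection = rnaDir,
        proteinDetected = protDetected, proteinLog2FC = protLfc,
        proteinP = protP, inRnaProtein = protSig)
    new("ConsensusSets", rnaUp = sharedUp, rnaDown = sharedDown,
        rnaProtein = genes[protSig], provenance = prov)
}

#' Export consensus tiers as gene-set records
#'
#' One \linkS4class{GeneSet} per non-empty tier (\code{<name>_RNA_up},
#' \code{<name>_RNA_down}, \code{<name>_RNA_protein}); empty tiers are
#' omitted with a message. Writing the result with
#' \code{\link{writeGMT}} and reading it back is lossless.
#'
#' @param sets A \linkS4class{ConsensusSets} object.
#' @param collectionName Prefix for the tier names.
#' @return A list of \linkS4class{GeneSet} records.
#' @examples
#' cs <- buildConsensus(c("NQO1"), character(), NULL)
#' exportGeneSets(cs, "NRF2_consensus")
#' @export
exportGeneSets <- function(sets, collectionName) {
    stopifnot(is(sets, "ConsensusSets"))
    tiers <- list(RNA_up = sets@rnaUp, RNA_down = sets@rnaDown,
                  RNA_protein = sets@rnaProtein)
    out <- list()
    for (tier in names(tiers)) {
        members <- tiers[[tier]]
        nm <- paste(collectionName, tier, sep = "_")
        if (!length(members)) {
            message("tier '", nm, "' is empty; omitted from export")
            next
        }
        out[[nm]] <- GeneSet(nm, paste("consensus tier", tier), members)
    }
    out
}
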