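#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' Parameters for the overexpression simulation
#'
#' Bundles the knobs of the two-condition (empty vector vs NRF transgene
#' overexpression) simulation: the number of genes, replicates per
#' condition, the fraction of genes carrying a planted differential
#' effect, the distribution of those effects, the baseline abundance
#' distribution, and the per-cell replicate noise. Abundances are
#' simulated on the log2 scale and exponentiated to RPKM-like values, so
#' all location/scale parameters are in log2 units.
#'
#' @slot nGenes integer, number of genes simulated.
#' @slot nReplicates integer, biological replicates per condition.
#' @slot deFraction numeric in [0,1], fraction of genes with a planted
#'   differential effect.
#' @slot effectMean,effectSd numeric, mean and sd (log2 units) of the
#'   magnitude of planted effects; signs are Bernoulli(0.5).
#' @slot baselineLogMean,baselineLogSd numeric, mean and sd of per-gene
#'   baseline log2 abundance.
#' @slot replicateNoiseSd numeric, sd (log2 units) of i.i.d. per-cell
#'   measurement noise.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationParams",
    slots = c(
        nGenes = "integer",
        nReplicates = "integer",
        deFraction = "numeric",
        effectMean = "numeric",
        effectSd = "numeric",
        baselineLogMean = "numeric",
        baselineLogSd = "numeric",
        replicateNoiseSd = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character()
    num <- c(deFraction = object@deFraction, effectMean = object@effectMean,
             effectSd = object@effectSd,
             baselineLogMean = object@baselineLogMean,
             baselineLogSd = object@baselineLogSd,
             replicateNoiseSd = object@replicateNoiseSd)
    if (any(!is.finite(num))) {
        msg <- c(msg, "all numeric parameters must be finite")
    }
    if (length(object@nGenes) != 1L || is.na(object@nGenes) ||
        object@nGenes < 1L) {
        msg <- c(msg, "nGenes must be a count >= 1")
    }
    if (length(object@nReplicates) != 1L || is.na(object@nReplicates) ||
        object@nReplicates < 1L) {
        msg <- c(msg, "nReplicates must be a count >= 1")
    }
    if (!is.na(object@deFraction) &&
        (object@deFraction < 0 || object@deFraction > 1)) {
        msg <- c(msg, "deFraction must lie in [0, 1]")
    }
    sds <- c(object@effectSd, object@baselineLogSd, object@replicateNoiseSd)
    if (any(is.finite(sds) & sds < 0)) {
        msg <- c(msg, "all sd parameters must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationParams-class
#' @param nGenes,nReplicates,deFraction,effectMean,effectSd Simulation
#'   knobs; see slot documentation.
#' @param baselineLogMean,baselineLogSd,replicateNoiseSd,seed Simulation
#'   knobs; see slot documentation.
#' @return A validated \code{SimulationParams} object.
#' @examples
#' SimulationParams(nGenes = 100, seed = 7)
#' @export
SimulationParams <- function(nGenes = 5000L, nReplicates = 3L,
                             deFraction = 0.1, effectMean = 1.5,
                             effectSd = 0.25, baselineLogMean = 5,
                             baselineLogSd = 2, replicateNoiseSd = 0.25,
                             seed = 1L) {
    new("SimulationParams",
        nGenes = .assertCount(nGenes, "nGenes"),
        nReplicates = .assertCount(nReplicates, "nReplicates"),
        deFraction = .assertScalarNumber(deFraction, "deFraction", 0, 1),
        effectMean = .assertScalarNumber(effectMean, "effectMean"),
        effectSd = .assertScalarNumber(effectSd, "effectSd", 0),
        baselineLogMean = .assertScalarNumber(baselineLogMean,
                                              "baselineLogMean"),
        baselineLogSd = .assertScalarNumber(baselineLogSd, "baselineLogSd",
                                            0),
        replicateNoiseSd = .assertScalarNumber(replicateNoiseSd,
                                               "replicateNoiseSd", 0),
        seed = .assertCount(seed, "seed", min = 0L))
}

#' Planted ground truth of a simulation
#'
#' Records what the synthetic-data generator planted so downstream
#' recovery can be scored: the simulated gene universe, the genes with
#' true differential effects and their signed log2 magnitudes, the
#' RNA-to-protein attenuation slope (once a proteome has been simulated),
#' and per-tissue co-expression module membership (once a tissue panel
#' has been simulated).
#'
#' @slot universe character, all simulated gene identifiers.
#' @slot deGenes character, genes with planted effects (subset of
#'   universe).
#' @slot effects named numeric, signed true log2 effects (names =
#'   deGenes).
#' @slot proteinAttenuation numeric, RNA-to-protein slope (NA until a
#'   proteome is simulated).
#' @slot moduleAssignment list of named character vectors, one per
#'   tissue, mapping gene -> {"coherent", "anti", "background"}.
#' @export
setClass("SyntheticTruth",
    slots = c(
        universe = "character",
        deGenes = "character",
        effects = "numeric",
        proteinAttenuation = "numeric",
        moduleAssignment = "list"
    ),
    prototype = prototype(proteinAttenuation = NA_real_,
                          moduleAssignment = list())
)

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (anyDuplicated(object@universe)) {
        msg <- c(msg, "universe has duplicated gene identifiers")
    }
    if (!all(object@deGenes %in% object@universe)) {
        msg <- c(msg, "deGenes must be a subset of the simulated universe")
    }
    if (length(object@effects) != length(object@deGenes) ||
        (length(object@deGenes) > 0L &&
         !identical(names(object@effects), object@deGenes))) {
        msg <- c(msg, "effects must be named by and aligned to deGenes")
    }
    if (length(object@proteinAttenuation) != 1L ||
        (!is.na(object@proteinAttenuation) &&
         !is.finite(object@proteinAttenuation))) {
        msg <- c(msg, "proteinAttenuation must be a single finite value or NA")
    }
    if (length(msg)) msg else TRUE
})

#' Significance thresholds for differential calling
#'
#' The decision rule applied to each gene: significant iff
#' \code{p < pMax} and \code{|log2FC| > minAbsLog2FC} (both strict).
#' Defaults follow the overexpression study design: p < 0.05 and
#' |log2 fold change| > 0.075, with a pseudocount of 1 added before any
#' log transform and an active-transcriptome floor of 0 (a gene is kept
#' when its maximum abundance exceeds the floor in at least one sample).
#'
#' @slot pMax numeric in (0,1], raw p-value cutoff (strict).
#' @slot minAbsLog2FC numeric >= 0, absolute log2 fold-change cutoff
#'   (strict).
#' @slot minExpression numeric >= 0, active-transcriptome abundance floor.
#' @slot pseudocount numeric >= 0, added to abundances before logs and
#'   to means before the fold-change ratio.
#' @export
setClass("Thresholds",
    slots = c(
        pMax = "numeric",
        minAbsLog2FC = "numeric",
        minExpression = "numeric",
        pseudocount = "numeric"
    )
)

setValidity("Thresholds", function(object) {
    msg <- character()
    if (!is.finite(object@pMax) || object@pMax <= 0 || object@pMax > 1) {
        msg <- c(msg, "pMax must lie in (0, 1]")
    }
    if (!is.finite(object@minAbsLog2FC) || object@minAbsLog2FC < 0) {
        msg <- c(msg, "minAbsLog2FC must be >= 0")
    }
    if (!is.finite(object@minExpression) || object@minExpression < 0) {
        msg <- c(msg, "minExpression must be >= 0")
    }
    if (!is.finite(object@pseudocount) || object@pseudocount < 0) {
        msg <- c(msg, "pseudocount must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname Thresholds-class
#' @param pMax,minAbsLog2FC,minExpression,pseudocount See slot
#'   documentation.
#' @return A validated \code{Thresholds} object.
#' @examples
#' Thresholds()
#' @export
Thresholds <- function(pMax = 0.05, minAbsLog2FC = 0.075,
                       minExpression = 0, pseudocount = 1) {
    new("Thresholds", pMax = pMax, minAbsLog2FC = minAbsLog2FC,
        minExpression = minExpression, pseudocount = pseudocount)
}

#' Per-gene differential-expression results
#'
#' A \linkS4class{DFrame} subclass with one row per active gene and
#' columns \code{meanRef}, \code{meanAlt}, \code{log2FC}, \code{t},
#' \code{df}, \code{pValue}, \code{qValue} (BH-adjusted, informational),
#' \code{significant}, \code{direction} ("up"/"down"/"none") and
#' \code{degenerate} (both groups zero-variance; tested with a variance
#' floor). The thresholds and group labels used are kept in
#' \code{metadata()}.
#'
#' @export
setClass("DifferentialResults", contains = "DFrame")

#' A ranked gene list for enrichment analysis
#'
#' Genes ordered best-to-worst by a signed ranking metric; ties are
#' broken lexicographically by gene identifier so the ordering is
#' deterministic.
#'
#' @slot geneIds character, ordered gene identifiers (no duplicates).
#' @slot metric numeric, non-increasing metric values aligned to
#'   \code{geneIds}.
#' @export
setClass("RankedList",
    slots = c(geneIds = "character", metric = "numeric")
)

setValidity("RankedList", function(object) {
    msg <- character()
    if (length(object@geneIds) != length(object@metric)) {
        msg <- c(msg, "geneIds and metric must be aligned")
    }
    if (anyDuplicated(object@geneIds)) {
        msg <- c(msg, "duplicate gene identifiers in ranking")
    }
    if (any(!is.finite(object@metric))) {
        msg <- c(msg, "metric values must be finite")
    }
    if (is.unsorted(-object@metric)) {
        msg <- c(msg, "metric must be non-increasing")
    }
    if (length(msg)) msg else TRUE
})

#' A named gene set
#'
#' @slot name character, set identifier (GMT column 1).
#' @slot description character, free-text description (GMT column 2).
#' @slot members character, unique, non-empty member gene identifiers.
#' @export
setClass("GeneSet",
    slots = c(name = "character", description = "character",
              members = "character")
)

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name)) {
        msg <- c(msg, "name must be a single non-empty string")
    }
    if (length(object@members) == 0L) {
        msg <- c(msg, "members must be non-empty")
    }
    if (anyDuplicated(object@members)) {
        msg <- c(msg, "members must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name,description,members See slot documentation.
#' @return A validated \code{GeneSet}.
#' @examples
#' GeneSet("oxidative_stress", members = c("NQO1", "HMOX1", "GCLM"))
#' @export
GeneSet <- function(name, description = "", members) {
    new("GeneSet", name = as.character(name),
        description = as.character(description),
        members = as.character(members))
}

#' Cross-study fold-change comparison
#'
#' Ordinary least-squares comparison of per-gene log2 fold changes
#' between two studies (or between RNA and protein), over the genes
#' shared by both. \code{rSquared} is the squared Pearson correlation;
#' \code{slope}/\code{intercept} come from the free-intercept fit of
#' \code{lfcB} on \code{lfcA} (so the slope, unlike r-squared, depends on
#' which study plays the explanatory role).
#'
#' @slot sharedGenes character, genes entering the regression.
#' @slot lfcA,lfcB numeric, aligned log2 fold changes.
#' @slot slope,intercept,rSquared numeric scalars.
#' @export
setClass("StudyComparison",
    slots = c(sharedGenes = "character", lfcA = "numeric", lfcB = "numeric",
              slope = "numeric", intercept = "numeric",
              rSquared = "numeric")
)

setValidity("StudyComparison", function(object) {
    msg <- character()
    n <- length(object@sharedGenes)
    if (length(object@lfcA) != n || length(object@lfcB) != n) {
        msg <- c(msg, "lfcA/lfcB must be aligned to sharedGenes")
    }
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1 + 1e-12)) {
        msg <- c(msg, "rSquared must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Tiered consensus gene sets
#'
#' The tiered output of the cross-study/cross-platform consensus: genes
#' significantly up (down) in both RNA studies in the same direction, and
#' the higher-confidence subset whose protein levels are also
#' significantly altered. Tiers are nested by construction:
#' \code{rnaProtein} is a subset of \code{rnaUp} union \code{rnaDown},
#' and \code{rnaUp}/\code{rnaDown} are disjoint.
#'
#' @slot rnaUp,rnaDown,rnaProtein character gene sets.
#' @slot provenance DFrame, one row per consensus gene recording its
#'   per-study directions and protein evidence.
#' @export
setClass("ConsensusSets",
    slots = c(rnaUp = "character", rnaDown = "character",
              rnaProtein = "character", provenance = "DFrame")
)

setValidity("ConsensusSets", function(object) {
    msg <- character()
    if (length(intersect(object@rnaUp, object@rnaDown))) {
        msg <- c(msg, "rnaUp and rnaDown must be disjoint")
    }
    if (!all(object@rnaProtein %in% c(object@rnaUp, object@rnaDown))) {
        msg <- c(msg, "rnaProtein must be a subset of rnaUp U rnaDown")
    }
    if (length(msg)) msg else TRUE
})

#' Gene-set enrichment result
#'
#' The weighted running-sum enrichment score of one gene set against a
#' ranked list, with its gene-label permutation null: nominal p-value
#' (additively smoothed, sign-stratified), normalized enrichment score
#' (ES divided by the mean |null ES| of the same sign) and the
#' leading-edge members.
#'
#' @slot setName character.
#' @slot es numeric in [-1, 1].
#' @slot nes numeric (NA when no same-signed null draws exist).
#' @slot pNominal numeric in (0, 1].
#' @slot nPermutations integer.
#' @slot leadingEdge character.
#' @slot runningSum numeric, per-position running enrichment statistic.
#' @export
setClass("EnrichmentResult",
    slots = c(setName = "character", es = "numeric", nes = "numeric",
              pNominal = "numeric", nPermutations = "integer",
              leadingEdge = "character", runningSum = "numeric")
)

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (!is.finite(object@es) || abs(object@es) > 1 + 1e-12) {
        msg <- c(msg, "es must lie in [-1, 1]")
    }
    if (!is.finite(object@pNominal) || object@pNominal <= 0 ||
        object@pNominal > 1) {
        msg <- c(msg, "pNominal must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Per-tissue gene-gene correlation matrix
#'
#' Pairwise correlations of log2(abundance + 1) across donors of one
#' tissue, exactly symmetric with unit diagonal.
#'
#' @slot values numeric matrix with gene identifiers as dimnames.
#' @slot tissue character label.
#' @slot method "pearson" or "spearman".
#' @slot nSamples integer, donors used.
#' @export
setClass("CorrelationMatrix",
    slots = c(values = "matrix", tissue = "character", method = "character",
              nSamples = "integer")
)

setValidity("CorrelationMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v) || is.null(rownames(v)) ||
        !identical(rownames(v), colnames(v))) {
        msg <- c(msg, "values must be square with matching gene dimnames")
    } else {
        if (!identical(v, t(v))) {
            msg <- c(msg, "values must be exactly symmetric")
        }
        if (any(diag(v) != 1)) {
            msg <- c(msg, "diagonal must be exactly 1")
        }
        if (any(abs(v) > 1)) {
            msg <- c(msg, "correlations must lie in [-1, 1]")
        }
    }
    if (!object@method %in% c("pearson", "spearman")) {
        msg <- c(msg, "method must be 'pearson' or 'spearman'")
    }
    if (length(msg)) msg else TRUE
})

#' Multi-tissue co-expression coherence result
#'
#' Per-tissue correlation matrices re-indexed to a reference tissue's
#' cluster-sorted gene order, per-tissue cluster labels and coherence
#' classes, and the long-format assignment table.
#'
#' @slot matrices list of \linkS4class{CorrelationMatrix}, one per
#'   tissue, all in the shared display order.
#' @slot clusters list of named integer vectors (gene -> cluster), one
#'   per tissue.
#' @slot classes list of named character vectors (gene ->
#'   correlated/anti-correlated/unclassified), one per tissue.
#' @slot reference character, the ordering tissue.
#' @slot geneOrder character, shared display order of genes.
#' @slot assignments DFrame with columns gene, tissue, cluster, class.
#' @export
setClass("CoexpressionResult",
    slots = c(matrices = "list", clusters = "list", classes = "list",
              reference = "character", geneOrder = "character",
              assignments = "DFrame")
)

setValidity("CoexpressionResult", function(object) {
    msg <- character()
    tis <- names(object@matrices)
    if (is.null(tis) || anyDuplicated(tis)) {
        msg <- c(msg, "matrices must be a named list (unique tissues)")
    }
    if (!identical(names(object@clusters), tis) ||
        !identical(names(object@classes), tis)) {
        msg <- c(msg, "clusters/classes must align with matrices by tissue")
    }
    if (!(object@reference %in% tis)) {
        msg <- c(msg, "reference tissue missing from matrices")
    }
    for (t in tis) {
        lab <- object@clusters[[t]]
        if (!identical(sort(names(lab)), sort(object@geneOrder))) {
            msg <- c(msg, sprintf(
                "tissue '%s': every gene must have exactly one cluster label",
                t))
        }
    }
    if (length(msg)) msg else TRUE
})
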