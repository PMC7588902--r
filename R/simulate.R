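#' Simulate a two-condition overexpression experiment
#'
#' Generates an RPKM-like gene x sample abundance matrix for an empty
#' vector condition and a transgene overexpression condition, with a
#' known fraction of genes carrying planted log2 effects. Per gene and
#' sample, abundance = 2^(baseline + condition effect + noise) where
#' baseline ~ N(baselineLogMean, baselineLogSd), the condition effect is
#' the gene's signed true effect in overexpression samples (0 otherwise,
#' and 0 for non-planted genes), and noise ~ N(0, replicateNoiseSd)
#' i.i.d. per cell. Effect magnitudes are N(effectMean, effectSd) with
#' Bernoulli(0.5) signs, mirroring a study that reports both up- and
#' downregulated target sets.
#'
#' @param params A \linkS4class{SimulationParams} object.
#' @return A list with elements \code{se} (a
#'   \linkS4class{SummarizedExperiment} with assay \code{"abundance"} and
#'   colData columns \code{condition} ("vector"/"overexpression") and
#'   \code{replicate}) and \code{truth} (a \linkS4class{SyntheticTruth}).
#'   Identical \code{params} (including seed) give bit-identical output.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 200, seed = 1))
#' sim$truth
#' @export
simulateOverexpression <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    n <- params@nGenes
    r <- params@nReplicates
    genes <- sprintf("G%05d", seq_len(n))
    .withSeed(params@seed, {
        baseline <- stats::rnorm(n, params@baselineLogMean,
                                 params@baselineLogSd)
        nDE <- round(params@deFraction * n)
        deIdx <- if (nDE > 0L) sort(sample.int(n, nDE)) else integer()
        eff <- numeric(0)
        effects <- numeric(n)
        if (nDE > 0L) {
            eff <- stats::rnorm(nDE, params@effectMean, params@effectSd) *
                sample(c(-1, 1), nDE, replace = TRUE)
            effects[deIdx] <- eff
        }
        condition <- rep(c("vector", "overexpression"), each = r)
        shift <- outer(effects, as.numeric(condition == "overexpression"))
        noise <- matrix(stats::rnorm(n * 2L * r, 0,
                                     params@replicateNoiseSd),
                        nrow = n)
        values <- 2^(baseline + shift + noise)
        samples <- paste0(rep(c("vector_", "overexpr_"), each = r),
                          rep(seq_len(r), 2L))
        dimnames(values) <- list(genes, samples)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(abundance = values),
            colData = S4Vectors::DataFrame(
                condition = condition,
                replicate = rep(seq_len(r), 2L),
                row.names = samples))
        truth <- new("SyntheticTruth", universe = genes,
                     deGenes = genes[deIdx],
                     effects = stats::setNames(eff, genes[deIdx]))
        list(se = se, truth = truth)
    })
}

#' Simulate a companion study's differential-expression table
#'
#' Emulates an independent profiling study of the same perturbation
#' (e.g., an inducible system in a different cell line) as a full
#' (gene, log2FC, p) table over the simulated universe. A fraction
#' \code{overlapFraction} of the planted genes is reported significant
#' with log2FC = true effect + N(0, fcNoiseSd); the remaining planted
#' genes keep their (noisy) fold change but draw p ~ Uniform(0.05, 1),
#' so the overlap fraction exactly controls the significant-call
#' overlap. A decoy fraction of null genes is reported as study-specific
#' significant calls; other null genes draw p ~ Uniform(0, 1) with
#' near-zero fold changes.
#'
#' @param truth A \linkS4class{SyntheticTruth} from
#'   \code{\link{simulateOverexpression}}.
#' @param overlapFraction Fraction in [0, 1] of planted genes the
#'   companion study detects.
#' @param fcNoiseSd Sd (log2 units) of fold-change noise added to true
#'   effects.
#' @param seed Integer RNG seed.
#' @param decoyFraction Fraction of null genes reported as spurious
#'   study-specific significant calls (default 0.02).
#' @return A data.frame with columns \code{gene}, \code{log2FC},
#'   \code{p}, one row per universe gene; deterministic under
#'   \code{seed}.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 200, seed = 1))
#' head(simulateCompanionStudy(sim$truth, 0.3, 0.2, seed = 2))
#' @export
simulateCompanionStudy <- function(truth, overlapFraction, fcNoiseSd,
                                   seed, decoyFraction = 0.02) {
    stopifnot(is(truth, "SyntheticTruth"))
    .assertScalarNumber(overlapFraction, "overlapFraction", 0, 1)
    .assertScalarNumber(fcNoiseSd, "fcNoiseSd", 0)
    .assertScalarNumber(decoyFraction, "decoyFraction", 0, 1)
    universe <- truth@universe
    de <- truth@deGenes
    if (length(de) == 0L) {
        warning("truth contains no planted genes; companion table is null-only")
    }
    .withSeed(seed, {
        lfc <- stats::setNames(numeric(length(universe)), universe)
        p <- stats::setNames(numeric(length(universe)), universe)
        nulls <- setdiff(universe, de)
        ## null genes: calibrated p, negligible fold change
        lfc[nulls] <- stats::rnorm(length(nulls), 0, 0.02)
        p[nulls] <- stats::runif(length(nulls))
        if (length(de)) {
            nOv <- round(overlapFraction * length(de))
            ov <- if (nOv > 0L) sample(de, nOv) else character()
            miss <- setdiff(de, ov)
            if (length(ov)) {
                lfc[ov] <- truth@effects[ov] +
                    stats::rnorm(length(ov), 0, fcNoiseSd)
                ## p implied by the reported effect size, capped so a
                ## detected gene is always a significant call
                p[ov] <- pmin(2 * stats::pnorm(-abs(lfc[ov]) / 0.2),
                              0.049)
                p[ov] <- pmax(p[ov], .Machine$double.xmin)
            }
            if (length(miss)) {
                lfc[miss] <- truth@effects[miss] +
                    stats::rnorm(length(miss), 0, fcNoiseSd)
                p[miss] <- stats::runif(length(miss), 0.05, 1)
            }
        }
        nDecoy <- round(decoyFraction * length(nulls))
        if (nDecoy > 0L) {
            decoys <- sample(nulls, nDecoy)
            lfc[decoys] <- sample(c(-1, 1), nDecoy, replace = TRUE) *
                (0.1 + abs(stats::rnorm(nDecoy, 0.4, 0.2)))
            p[decoys] <- stats::runif(nDecoy) * 0.05
        }
        data.frame(gene = universe, log2FC = unname(lfc), p = unname(p),
                   stringsAsFactors = FALSE)
    })
}

#' Simulate a quantitative proteome table
#'
#' Emulates TMT-style protein quantification of the same perturbation: a
#' random \code{coverage} fraction of the universe is detected; detected
#' planted genes get protein log2FC = attenuation x RNA effect +
#' N(0, noiseSd) with a p-value implied by that effect size; detected
#' null genes get near-zero fold changes with p ~ Uniform(0, 1).
#'
#' @param truth A \linkS4class{SyntheticTruth}; its
#'   \code{proteinAttenuation} slot is filled in the returned copy.
#' @param attenuation Finite slope relating protein to RNA log2 effects.
#' @param coverage Fraction in (0, 1] of genes detected at the protein
#'   level.
#' @param noiseSd Sd (log2 units) of protein fold-change noise.
#' @param seed Integer RNG seed.
#' @return A list with \code{table} (data.frame \code{gene},
#'   \code{log2FC}, \code{p}; detected genes only) and \code{truth} (the
#'   updated \linkS4class{SyntheticTruth}).
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 200, seed = 1))
#' pr <- simulateProteome(sim$truth, attenuation = 0.7, coverage = 0.8,
#'                        noiseSd = 0.1, seed = 3)
#' head(pr$table)
#' @export
simulateProteome <- function(truth, attenuation, coverage, noiseSd, seed) {
    stopifnot(is(truth, "SyntheticTruth"))
    .assertScalarNumber(attenuation, "attenuation")
    .assertScalarNumber(coverage, "coverage", 0, 1, strict_lower = TRUE)
    .assertScalarNumber(noiseSd, "noiseSd", 0)
    universe <- truth@universe
    .withSeed(seed, {
        detected <- sort(sample(universe, round(coverage * length(universe))))
        de <- intersect(detected, truth@deGenes)
        nulls <- setdiff(detected, de)
        lfc <- stats::setNames(numeric(length(detected)), detected)
        p <- stats::setNames(numeric(length(detected)), detected)
        if (length(de)) {
            lfc[de] <- attenuation * truth@effects[de] +
                stats::rnorm(length(de), 0, noiseSd)
            ## implied-test p: effect over a nominal measurement scale
            s0 <- max(noiseSd, 0.05)
            p[de] <- pmax(2 * stats::pnorm(-abs(lfc[de]) / s0),
                          .Machine$double.xmin)
        }
        if (length(nulls)) {
            lfc[nulls] <- stats::rnorm(length(nulls), 0, noiseSd)
            p[nulls] <- stats::runif(length(nulls))
        }
        truth@proteinAttenuation <- attenuation
        validObject(truth)
        list(table = data.frame(gene = detected, log2FC = unname(lfc),
                                p = unname(p), stringsAsFactors = FALSE),
             truth = truth)
    })
}

#' Simulate a multi-tissue expression panel with correlation modules
#'
#' For each tissue, partitions the supplied gene set into a coherent
#' module (loading +lambda on a shared donor-level latent factor), an
#' anti module (loading -antiLoading x lambda) and background (loading
#' 0), then simulates donor-level log2 expression as
#' baseline + loading x factor + N(0, noiseSd) and exponentiates to
#' RPKM-like abundance. lambda = noiseSd x sqrt(rWithin / (1 - rWithin))
#' so the expected pairwise correlation within the coherent module is
#' rWithin. Module membership is re-drawn independently per tissue, so
#' cross-tissue assignments differ. Baselines are N(10, 0.5) per gene
#' and tissue (well-expressed genes, keeping the log2(x + 1) transform
#' used downstream effectively linear).
#'
#' @param geneSet Character vector of gene identifiers.
#' @param nTissues Number of tissues (default 3; the first three are
#'   labeled brain, liver, heart).
#' @param nDonors Donors per tissue (>= 3).
#' @param rWithin Target within-module correlation, in (0, 1).
#' @param antiLoading Non-negative multiplier of the anti module's
#'   (negated) loading; default 0.6, so the anti module is internally
#'   less tightly coupled than the coherent core.
#' @param noiseSd Sd of donor-level log2 noise (default 1).
#' @param seed Integer RNG seed.
#' @param coherentFraction,antiFraction Fractions of the gene set
#'   assigned to the coherent and anti modules (defaults 0.4 and 0.3;
#'   the remainder is background).
#' @return A list with \code{panels} (named list of
#'   \linkS4class{SummarizedExperiment}, assay \code{"abundance"},
#'   colData columns \code{tissue} and \code{donor}) and \code{truth}
#'   (a \linkS4class{SyntheticTruth} whose \code{moduleAssignment} maps
#'   gene -> module per tissue).
#' @examples
#' tp <- simulateTissuePanel(sprintf("G%02d", 1:30), nTissues = 2,
#'                           nDonors = 50, rWithin = 0.9, seed = 1)
#' table(moduleAssignment(tp$truth)$brain)
#' @export
simulateTissuePanel <- function(geneSet, nTissues = 3L, nDonors = 200L,
                                rWithin = 0.9, antiLoading = 0.6,
                                noiseSd = 1, seed = 1L,
                                coherentFraction = 0.4,
                                antiFraction = 0.3) {
    geneSet <- as.character(geneSet)
    if (anyDuplicated(geneSet)) stop("geneSet has duplicated identifiers")
    nTissues <- .assertCount(nTissues, "nTissues")
    nDonors <- .assertCount(nDonors, "nDonors", min = 3L)
    .assertScalarNumber(rWithin, "rWithin", 0, 1, strict_lower = TRUE,
                        strict_upper = TRUE)
    .assertScalarNumber(antiLoading, "antiLoading", 0)
    .assertScalarNumber(noiseSd, "noiseSd", 0)
    .assertScalarNumber(coherentFraction, "coherentFraction", 0, 1)
    .assertScalarNumber(antiFraction, "antiFraction", 0, 1)
    if (coherentFraction + antiFraction > 1) {
        stop("coherentFraction + antiFraction must be <= 1")
    }
    nG <- length(geneSet)
    tissues <- c("brain", "liver", "heart",
                 sprintf("tissue%d", seq_len(max(0L, nTissues - 3L)) + 3L))
    tissues <- tissues[seq_len(nTissues)]
    lambda <- noiseSd * sqrt(rWithin / (1 - rWithin))
    .withSeed(seed, {
        panels <- list()
        modules <- list()
        for (t in tissues) {
            nCo <- round(coherentFraction * nG)
            nAn <- round(antiFraction * nG)
            nAn <- min(nAn, nG - nCo)
            member <- sample(c(rep("coherent", nCo), rep("anti", nAn),
                               rep("background", nG - nCo - nAn)))
            names(member) <- geneSet
            loading <- c(coherent = lambda, anti = -antiLoading * lambda,
                         background = 0)[member]
            baseline <- stats::rnorm(nG, 10, 0.5)
            f <- stats::rnorm(nDonors)
            eps <- matrix(stats::rnorm(nG * nDonors, 0, noiseSd),
                          nrow = nG)
            logExpr <- baseline + outer(unname(loading), f) + eps
            values <- 2^logExpr
            donors <- sprintf("%s_donor%03d", t, seq_len(nDonors))
            dimnames(values) <- list(geneSet, donors)
            panels[[t]] <- SummarizedExperiment::SummarizedExperiment(
                assays = list(abundance = values),
                colData = S4Vectors::DataFrame(
                    tissue = rep(t, nDonors),
                    donor = donors, row.names = donors))
            modules[[t]] <- member
        }
        truth <- new("SyntheticTruth", universe = geneSet,
                     deGenes = character(), effects = numeric(),
                     moduleAssignment = modules)
        list(panels = panels, truth = truth)
    })
}
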