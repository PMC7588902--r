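## Pipeline configuration (validated YAML/list) and the umbrella
## runPipeline() driver tying simulate -> de -> consensus -> enrichment
## -> coexpression together with a reproducibility manifest.

.configSchema <- list(
    seeds = c("simulation", "companion", "proteome", "tissue", "gsea",
              "coexpression"),
    simulation = c("nGenes", "nReplicates", "deFraction", "effectMean",
                   "effectSd", "baselineLogMean", "baselineLogSd",
                   "replicateNoiseSd"),
    companion = c("overlapFraction", "fcNoiseSd", "decoyFraction"),
    proteome = c("attenuation", "coverage", "noiseSd"),
    thresholds = c("pMax", "minAbsLog2FC", "minExpression", "pseudocount"),
    enrichment = c("metric", "weightExponent", "nPermutations"),
    tissue = c("nTissues", "nDonors", "rWithin", "antiLoading", "noiseSd",
               "maxGenes"),
    coexpression = c("k", "method", "nRestarts", "corMethod",
                     "minSamples", "tauPos", "tauNeg", "reference")
)

#' Default pipeline configuration
#'
#' The default simulation-backed configuration: a triplicate
#' two-condition experiment of 5000 genes with 10% planted effects
#' (magnitude 1.5 +/- 0.25 log2 units, replicate noise 0.25), a
#' companion study detecting 30% of planted genes, an attenuated
#' (slope 0.7) proteome covering 80% of genes, and a three-tissue panel
#' of 200 donors with within-module correlation 0.9. Thresholds default
#' to p < 0.05 and |log2FC| > 0.075.
#'
#' @return A nested named list accepted by \code{\link{runPipeline}}.
#' @examples
#' str(defaultPipelineConfig(), max.level = 1)
#' @export
defaultPipelineConfig <- function() {
    list(
        seeds = list(simulation = 101L, companion = 102L, proteome = 103L,
                     tissue = 104L, gsea = 105L, coexpression = 106L),
        simulation = list(nGenes = 5000L, nReplicates = 3L,
                          deFraction = 0.1, effectMean = 1.5,
                          effectSd = 0.25, baselineLogMean = 5,
                          baselineLogSd = 2, replicateNoiseSd = 0.25),
        companion = list(overlapFraction = 0.3, fcNoiseSd = 0.2,
                         decoyFraction = 0.02),
        proteome = list(attenuation = 0.7, coverage = 0.8, noiseSd = 0.1),
        thresholds = list(pMax = 0.05, minAbsLog2FC = 0.075,
                          minExpression = 0, pseudocount = 1),
        enrichment = list(metric = "t_stat", weightExponent = 1,
                          nPermutations = 1000L),
        tissue = list(nTissues = 3L, nDonors = 200L, rWithin = 0.9,
                      antiLoading = 0.6, noiseSd = 1, maxGenes = 60L),
        coexpression = list(k = 3L, method = "kmeans", nRestarts = 50L,
                            corMethod = "pearson", minSamples = 10L,
                            tauPos = 0.3, tauNeg = -0.1,
                            reference = "brain")
    )
}

#' Validate a pipeline configuration
#'
#' Merges the supplied (possibly partial) configuration over the
#' defaults, rejects unknown sections or keys, and checks value ranges
#' before any stage runs.
#'
#' @param config Nested named list (e.g. from
#'   \code{\link{readPipelineConfig}}); missing entries take defaults.
#' @return The validated, fully populated configuration.
#' @examples
#' validatePipelineConfig(list(thresholds = list(pMax = 0.01)))$thresholds
#' @export
validatePipelineConfig <- function(config = list()) {
    if (!is.list(config)) stop("config must be a list")
    unknown <- setdiff(names(config), names(.configSchema))
    if (length(unknown)) {
        stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    }
    full <- defaultPipelineConfig()
    for (sec in names(config)) {
        bad <- setdiff(names(config[[sec]]), .configSchema[[sec]])
        if (length(bad)) {
            stop("unknown key(s) in section '", sec, "': ",
                 paste(bad, collapse = ", "))
        }
        full[[sec]][names(config[[sec]])] <- config[[sec]]
    }
    ## range checks; constructors re-validate at run time too
    do.call(SimulationParams, c(full$simulation,
                                list(seed = full$seeds$simulation)))
    do.call(Thresholds, full$thresholds)
    .assertScalarNumber(full$companion$overlapFraction, "overlapFraction",
                        0, 1)
    .assertScalarNumber(full$companion$fcNoiseSd, "fcNoiseSd", 0)
    .assertScalarNumber(full$proteome$coverage, "coverage", 0, 1,
                        strict_lower = TRUE)
    .assertScalarNumber(full$proteome$attenuation, "attenuation")
    .assertScalarNumber(full$tissue$rWithin, "rWithin", 0, 1,
                        strict_lower = TRUE, strict_upper = TRUE)
    .assertCount(full$enrichment$nPermutations, "nPermutations",
                 min = 100L)
    .assertCount(full$coexpression$k, "k")
    if (!full$enrichment$metric %in% c("t_stat", "signed_logp")) {
        stop("enrichment metric must be 't_stat' or 'signed_logp'")
    }
    if (!full$coexpression$method %in% c("kmeans", "hierarchical")) {
        stop("coexpression method must be 'kmeans' or 'hierarchical'")
    }
    for (s in names(full$seeds)) {
        .assertCount(full$seeds[[s]], paste0("seeds$", s), min = 0L)
    }
    full
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path; its entries override the defaults of
#'   \code{\link{defaultPipelineConfig}} and are validated.
#' @return The validated configuration list.
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeLines("thresholds:\n  pMax: 0.01", tf)
#' readPipelineConfig(tf)$thresholds$pMax
#' @export
readPipelineConfig <- function(path) {
    validatePipelineConfig(yaml::read_yaml(path))
}

.writeTable <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
}

.deTable <- function(res) {
    data.frame(gene = rownames(res), meanRef = res$meanRef,
               meanAlt = res$meanAlt, log2FC = res$log2FC, t = res$t,
               df = res$df, p = res$pValue, q = res$qValue,
               significant = res$significant, direction = res$direction,
               stringsAsFactors = FALSE)
}

#' Run the full simulation-backed analysis pipeline
#'
#' Executes, in order: synthetic-data generation (overexpression
#' experiment, companion study, proteome, tissue panel), differential
#' calling, consensus construction with concordance regressions,
#' enrichment (running-sum GSEA of the consensus tiers plus
#' over-representation of the consensus genes against planted-truth and
#' random control terms), and multi-tissue co-expression coherence. All
#' randomness flows from the per-stage seeds in the configuration, so a
#' rerun with the same configuration reproduces every output
#' bit-identically; a JSON manifest records the configuration, seeds,
#' per-stage outputs and the MD5 hash of every file written.
#'
#' @param config Configuration list (see
#'   \code{\link{defaultPipelineConfig}}); validated before any stage
#'   runs.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the manifest, the in-memory stage
#'   results (\code{truth}, \code{de}, \code{consensus},
#'   \code{comparisons}, \code{enrichment}, \code{ora},
#'   \code{coexpression}) and the manifest path.
#' @examples
#' \donttest{
#' cfg <- validatePipelineConfig(list(
#'     simulation = list(nGenes = 400L),
#'     tissue = list(nDonors = 50L, maxGenes = 30L),
#'     enrichment = list(nPermutations = 100L)))
#' out <- runPipeline(cfg, tempfile("pipe"))
#' names(out$manifest$stages)
#' }
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir) {
    config <- validatePipelineConfig(config)
    if (!dir.exists(outdir)) {
        dir.create(outdir, recursive = TRUE)
    }
    pth <- function(f) file.path(outdir, f)
    stages <- list()

    ## -- simulate ----------------------------------------------------
    params <- do.call(SimulationParams,
                      c(config$simulation,
                        list(seed = config$seeds$simulation)))
    sim <- simulateOverexpression(params)
    companion <- simulateCompanionStudy(
        sim$truth, config$companion$overlapFraction,
        config$companion$fcNoiseSd, seed = config$seeds$companion,
        decoyFraction = config$companion$decoyFraction)
    prot <- simulateProteome(
        sim$truth, config$proteome$attenuation, config$proteome$coverage,
        config$proteome$noiseSd, seed = config$seeds$proteome)
    truth <- prot$truth
    writeExpression(sim$se, pth("expression.tsv"), pth("design.tsv"))
    .writeTable(companion, pth("companion_de.tsv"))
    .writeTable(prot$table, pth("proteome.tsv"))
    jsonlite::write_json(
        list(universe = truth@universe, deGenes = truth@deGenes,
             effects = as.list(truth@effects),
             proteinAttenuation = truth@proteinAttenuation),
        pth("truth.json"), auto_unbox = TRUE, digits = NA)
    stages$simulate <- c("expression.tsv", "design.tsv",
                         "companion_de.tsv", "proteome.tsv", "truth.json")

    ## -- differential expression ------------------------------------
    thr <- do.call(Thresholds, config$thresholds)
    de <- callDifferential(sim$se, "vector", "overexpression", thr)
    .writeTable(.deTable(de), pth("de_results.tsv"))
    stages$de <- "de_results.tsv"

    ## -- consensus ---------------------------------------------------
    inter <- intersectDE(de, companion, thresholds = thr)
    shared <- c(inter$sharedUp, inter$sharedDown)
    comparisons <- list()
    if (length(shared) >= 3L) {
        idxB <- .matchGenes(shared, companion$gene)
        comparisons$crossStudy <- regressFoldChanges(
            de[shared, "log2FC"], companion$log2FC[idxB], genes = shared)
    }
    cons <- buildConsensus(inter$sharedUp, inter$sharedDown, prot$table,
                           thr)
    pv <- cons@provenance
    protShared <- pv$gene[pv$proteinDetected]
    if (length(protShared) >= 3L) {
        comparisons$rnaProtein <- regressFoldChanges(
            de[protShared, "log2FC"],
            pv$proteinLog2FC[pv$proteinDetected], genes = protShared)
    }
    sets <- exportGeneSets(cons, "consensus")
    writeGMT(sets, pth("consensus_sets.gmt"))
    .writeTable(as.data.frame(pv), pth("consensus_provenance.tsv"))
    jsonlite::write_json(
        lapply(comparisons, function(cc) {
            list(n = length(cc@sharedGenes), slope = cc@slope,
                 intercept = cc@intercept, rSquared = cc@rSquared)
        }), pth("comparison_stats.json"), auto_unbox = TRUE, digits = NA)
    stages$consensus <- c("consensus_sets.gmt", "consensus_provenance.tsv",
                          "comparison_stats.json")

    ## -- enrichment --------------------------------------------------
    ranked <- rankGenes(de, config$enrichment$metric)
    writeRNK(ranked, pth("ranking.rnk"))
    gsea <- list()
    for (i in seq_along(sets)) {
        gsea[[names(sets)[i]]] <- gseaPermutation(
            ranked, sets[[i]],
            nPermutations = config$enrichment$nPermutations,
            weightExponent = config$enrichment$weightExponent,
            seed = config$seeds$gsea + i - 1L)
    }
    gseaTab <- do.call(rbind, lapply(gsea, function(g) {
        data.frame(set = g@setName,
                   size = length(intersect(
                       sets[[g@setName]]@members, ranked@geneIds)),
                   es = g@es, nes = g@nes, p_nominal = g@pNominal,
                   leading_edge = paste(g@leadingEdge, collapse = ","),
                   stringsAsFactors = FALSE)
    }))
    .writeTable(gseaTab, pth("gsea_results.tsv"))
    ## ORA of the consensus genes against planted truth + size-matched
    ## random control terms drawn from the universe
    background <- rownames(de)
    query <- intersect(c(cons@rnaUp, cons@rnaDown), background)
    ora <- NULL
    if (length(query) && length(truth@deGenes)) {
        terms <- list(GeneSet("planted_de", "planted differential genes",
                              truth@deGenes))
        nCtl <- 5L
        ctl <- .withSeed(config$seeds$gsea + 1000L, {
            lapply(seq_len(nCtl), function(i) {
                GeneSet(sprintf("random_control_%d", i), "random control",
                        sample(background,
                               min(length(truth@deGenes),
                                   length(background))))
            })
        })
        ora <- oraTest(query, c(terms, ctl), background)
        .writeTable(as.data.frame(ora), pth("ora_results.tsv"))
        stages$enrichment <- c("ranking.rnk", "gsea_results.tsv",
                               "ora_results.tsv")
    } else {
        stages$enrichment <- c("ranking.rnk", "gsea_results.tsv")
    }

    ## -- coexpression ------------------------------------------------
    consGenes <- sort(c(cons@rnaUp, cons@rnaDown))
    tissueGenes <- utils::head(consGenes, config$tissue$maxGenes)
    if (length(tissueGenes) < config$coexpression$k + 2L) {
        ## consensus too small to cluster; fall back to planted genes
        tissueGenes <- utils::head(sort(truth@deGenes),
                                   config$tissue$maxGenes)
    }
    panel <- simulateTissuePanel(
        tissueGenes, nTissues = config$tissue$nTissues,
        nDonors = config$tissue$nDonors, rWithin = config$tissue$rWithin,
        antiLoading = config$tissue$antiLoading,
        noiseSd = config$tissue$noiseSd, seed = config$seeds$tissue)
    ref <- config$coexpression$reference
    if (!ref %in% names(panel$panels)) ref <- names(panel$panels)[1L]
    coex <- coexpressionAnalysis(
        panel$panels, k = config$coexpression$k,
        method = config$coexpression$method,
        nRestarts = config$coexpression$nRestarts,
        seed = config$seeds$coexpression,
        corMethod = config$coexpression$corMethod,
        minSamples = config$coexpression$minSamples,
        tauPos = config$coexpression$tauPos,
        tauNeg = config$coexpression$tauNeg, reference = ref)
    coexFiles <- character()
    for (t in names(coex@matrices)) {
        f <- sprintf("correlation_%s.tsv", t)
        v <- coex@matrices[[t]]@values
        .writeTable(data.frame(gene = rownames(v), v,
                               check.names = FALSE,
                               stringsAsFactors = FALSE), pth(f))
        coexFiles <- c(coexFiles, f)
        tf <- sprintf("tissue_%s.tsv", t)
        writeExpression(panel$panels[[t]], pth(tf))
        coexFiles <- c(coexFiles, tf)
    }
    .writeTable(as.data.frame(coex@assignments), pth("assignments.tsv"))
    jsonlite::write_json(
        lapply(panel$truth@moduleAssignment, as.list),
        pth("tissue_truth.json"), auto_unbox = TRUE, digits = NA)
    stages$coexpression <- c(coexFiles, "assignments.tsv",
                             "tissue_truth.json")

    ## -- manifest ----------------------------------------------------
    allFiles <- sort(unique(unlist(stages)))
    hashes <- tools::md5sum(file.path(outdir, allFiles))
    names(hashes) <- allFiles
    manifest <- list(
        package = "nrfscope",
        version = as.character(utils::packageVersion("nrfscope")),
        config = config,
        stages = stages,
        md5 = as.list(hashes))
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(manifest = manifest,
                   manifestPath = pth("manifest.json"),
                   truth = truth, tissueTruth = panel$truth, de = de,
                   consensus = cons, comparisons = comparisons,
                   enrichment = gsea, ora = ora, coexpression = coex))
}
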