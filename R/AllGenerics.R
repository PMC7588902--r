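## Accessor generics and show methods. Slot access from user code should
## go through these.

#' @name nrfscope-accessors
#' @title Accessors for nrfscope result objects
#' @description Small accessor family for the package's S4 classes; each
#'   returns the slot content documented on the class page.
#' @param x An nrfscope S4 object.
#' @param ... Additional arguments (unused).
#' @return The requested component.
#' @examples
#' gs <- GeneSet("s", members = c("A", "B"))
#' setMembers(gs)
NULL

#' @rdname nrfscope-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("rankMetric", function(x, ...) standardGeneric("rankMetric"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("setName", function(x, ...) standardGeneric("setName"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("setMembers", function(x, ...) standardGeneric("setMembers"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("universeGenes", function(x, ...) standardGeneric("universeGenes"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("deGenes", function(x, ...) standardGeneric("deGenes"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("trueEffects", function(x, ...) standardGeneric("trueEffects"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("moduleAssignment",
           function(x, ...) standardGeneric("moduleAssignment"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("rnaUp", function(x, ...) standardGeneric("rnaUp"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("rnaDown", function(x, ...) standardGeneric("rnaDown"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("rnaProtein", function(x, ...) standardGeneric("rnaProtein"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("sharedGenes", function(x, ...) standardGeneric("sharedGenes"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("regressionSlope",
           function(x, ...) standardGeneric("regressionSlope"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("regressionIntercept",
           function(x, ...) standardGeneric("regressionIntercept"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("rSquared", function(x, ...) standardGeneric("rSquared"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("enrichmentScoreValue",
           function(x, ...) standardGeneric("enrichmentScoreValue"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("nes", function(x, ...) standardGeneric("nes"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("pNominal", function(x, ...) standardGeneric("pNominal"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("leadingEdge", function(x, ...) standardGeneric("leadingEdge"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("runningSum", function(x, ...) standardGeneric("runningSum"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("corValues", function(x, ...) standardGeneric("corValues"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("tissueLabel", function(x, ...) standardGeneric("tissueLabel"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("coherenceClasses",
           function(x, ...) standardGeneric("coherenceClasses"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("geneOrder", function(x, ...) standardGeneric("geneOrder"))
#' @rdname nrfscope-accessors
#' @export
setGeneric("assignmentTable",
           function(x, ...) standardGeneric("assignmentTable"))

#' @rdname nrfscope-accessors
setMethod("geneIds", "RankedList", function(x, ...) x@geneIds)
#' @rdname nrfscope-accessors
setMethod("geneIds", "CorrelationMatrix",
          function(x, ...) rownames(x@values))
#' @rdname nrfscope-accessors
setMethod("rankMetric", "RankedList", function(x, ...) {
    stats::setNames(x@metric, x@geneIds)
})
#' @rdname nrfscope-accessors
setMethod("setName", "GeneSet", function(x, ...) x@name)
#' @rdname nrfscope-accessors
setMethod("setName", "EnrichmentResult", function(x, ...) x@setName)
#' @rdname nrfscope-accessors
setMethod("setMembers", "GeneSet", function(x, ...) x@members)
#' @rdname nrfscope-accessors
setMethod("universeGenes", "SyntheticTruth", function(x, ...) x@universe)
#' @rdname nrfscope-accessors
setMethod("deGenes", "SyntheticTruth", function(x, ...) x@deGenes)
#' @rdname nrfscope-accessors
setMethod("trueEffects", "SyntheticTruth", function(x, ...) x@effects)
#' @rdname nrfscope-accessors
setMethod("moduleAssignment", "SyntheticTruth",
          function(x, ...) x@moduleAssignment)
#' @rdname nrfscope-accessors
setMethod("rnaUp", "ConsensusSets", function(x, ...) x@rnaUp)
#' @rdname nrfscope-accessors
setMethod("rnaDown", "ConsensusSets", function(x, ...) x@rnaDown)
#' @rdname nrfscope-accessors
setMethod("rnaProtein", "ConsensusSets", function(x, ...) x@rnaProtein)
#' @rdname nrfscope-accessors
setMethod("provenance", "ConsensusSets", function(x, ...) x@provenance)
#' @rdname nrfscope-accessors
setMethod("sharedGenes", "StudyComparison", function(x, ...) x@sharedGenes)
#' @rdname nrfscope-accessors
setMethod("regressionSlope", "StudyComparison", function(x, ...) x@slope)
#' @rdname nrfscope-accessors
setMethod("regressionIntercept", "StudyComparison",
          function(x, ...) x@intercept)
#' @rdname nrfscope-accessors
setMethod("rSquared", "StudyComparison", function(x, ...) x@rSquared)
#' @rdname nrfscope-accessors
setMethod("enrichmentScoreValue", "EnrichmentResult", function(x, ...) x@es)
#' @rdname nrfscope-accessors
setMethod("nes", "EnrichmentResult", function(x, ...) x@nes)
#' @rdname nrfscope-accessors
setMethod("pNominal", "EnrichmentResult", function(x, ...) x@pNominal)
#' @rdname nrfscope-accessors
setMethod("leadingEdge", "EnrichmentResult", function(x, ...) x@leadingEdge)
#' @rdname nrfscope-accessors
setMethod("runningSum", "EnrichmentResult", function(x, ...) x@runningSum)
#' @rdname nrfscope-accessors
setMethod("corValues", "CorrelationMatrix", function(x, ...) x@values)
#' @rdname nrfscope-accessors
setMethod("tissueLabel", "CorrelationMatrix", function(x, ...) x@tissue)
#' @rdname nrfscope-accessors
#' @param tissue Optional tissue label selecting one tissue's vector.
setMethod("clusterLabels", "CoexpressionResult",
          function(x, tissue = NULL, ...) {
    if (is.null(tissue)) x@clusters else x@clusters[[tissue]]
})
#' @rdname nrfscope-accessors
setMethod("coherenceClasses", "CoexpressionResult",
          function(x, tissue = NULL, ...) {
    if (is.null(tissue)) x@classes else x@classes[[tissue]]
})
#' @rdname nrfscope-accessors
setMethod("geneOrder", "CoexpressionResult", function(x, ...) x@geneOrder)
#' @rdname nrfscope-accessors
setMethod("assignmentTable", "CoexpressionResult",
          function(x, ...) x@assignments)

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@nGenes, "genes x",
        2L * object@nReplicates, "samples;",
        sprintf("DE fraction %.3g, effect %.3g +/- %.3g (log2),",
                object@deFraction, object@effectMean, object@effectSd),
        sprintf("noise sd %.3g, seed %d\n",
                object@replicateNoiseSd, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@universe), "genes,",
        length(object@deGenes), "with planted effects")
    if (!is.na(object@proteinAttenuation)) {
        cat(sprintf("; protein attenuation %.3g",
                    object@proteinAttenuation))
    }
    if (length(object@moduleAssignment)) {
        cat(";", length(object@moduleAssignment), "tissue module maps")
    }
    cat("\n")
})

setMethod("show", "Thresholds", function(object) {
    cat(sprintf(
        "Thresholds: p < %g and |log2FC| > %g (strict); min expression %g, pseudocount %g\n",
        object@pMax, object@minAbsLog2FC, object@minExpression,
        object@pseudocount))
})

setMethod("show", "DifferentialResults", function(object) {
    md <- metadata(object)
    cat("DifferentialResults:", nrow(object), "active genes")
    if (!is.null(md$refGroup)) {
        cat(sprintf(" (%s vs %s)", md$altGroup, md$refGroup))
    }
    cat(";", sum(object$significant), "significant (",
        sum(object$direction == "up"), "up /",
        sum(object$direction == "down"), "down )\n")
    callNextMethod()
})

setMethod("show", "RankedList", function(object) {
    n <- length(object@geneIds)
    cat("RankedList of", n, "genes; metric range [",
        sprintf("%.3g", min(object@metric)), ",",
        sprintf("%.3g", max(object@metric)), "]\n")
})

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet", object@name, "(", length(object@members), "members )\n")
})

setMethod("show", "StudyComparison", function(object) {
    cat(sprintf(
        "StudyComparison: n = %d shared genes; slope %.4g, intercept %.4g, r^2 = %.4g\n",
        length(object@sharedGenes), object@slope, object@intercept,
        object@rSquared))
})

setMethod("show", "ConsensusSets", function(object) {
    cat("ConsensusSets:", length(object@rnaUp), "RNA up,",
        length(object@rnaDown), "RNA down,",
        length(object@rnaProtein), "RNA+Protein\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult '%s': ES = %.4g, NES = %.4g, p = %.4g (%d permutations), %d leading-edge genes\n",
        object@setName, object@es, object@nes, object@pNominal,
        object@nPermutations, length(object@leadingEdge)))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf(
        "CorrelationMatrix (%s): %d genes, %s, n = %d samples\n",
        object@tissue, nrow(object@values), object@method,
        object@nSamples))
})

setMethod("show", "CoexpressionResult", function(object) {
    cat("CoexpressionResult:", length(object@geneOrder), "genes x",
        length(object@matrices), "tissues; reference:", object@reference,
        "\n")
    for (t in names(object@classes)) {
        cl <- object@classes[[t]]
        cat(sprintf("  %s: %d correlated, %d anti-correlated, %d unclassified\n",
                    t, sum(cl == "correlated"),
                    sum(cl == "anti-correlated"),
                    sum(cl == "unclassified")))
    }
})
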