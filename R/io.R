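## Readers and writers for the pipeline's plain-text formats: expression
## TSV (+ design TSV), GMT, RNK. TSV (tab-separated, UTF-8, unquoted) is
## the canonical dialect; CSV is accepted on read by extension.

.sepForPath <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix (and design) from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Non-numeric cells, ragged rows and duplicated gene
#' identifiers are rejected with their location. Values must be finite
#' and non-negative.
#'
#' @param path Expression table path (TSV, or CSV by extension).
#' @param designPath Optional design table path with a \code{sample}
#'   column plus grouping columns (e.g. \code{condition},
#'   \code{replicate} or \code{tissue}, \code{donor}); every sample of
#'   the matrix must be present.
#' @return A \linkS4class{SummarizedExperiment} with assay
#'   \code{"abundance"}; the design becomes its colData.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 10, seed = 1))
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(sim$se, tf)
#' readExpression(tf)
#' @export
readExpression <- function(path, designPath = NULL) {
    sep <- .sepForPath(path)
    lines <- readLines(path)
    if (length(lines) < 2L) stop("expression file has no data rows: ", path)
    fields <- strsplit(lines, sep, fixed = TRUE)
    header <- fields[[1L]]
    nCol <- length(header)
    samples <- header[-1L]
    if (!length(samples)) stop("no sample columns in header")
    body <- fields[-1L]
    widths <- lengths(body)
    if (any(widths != nCol)) {
        bad <- which(widths != nCol)[1L]
        stop("ragged row at line ", bad + 1L, ": expected ", nCol,
             " fields, found ", widths[bad])
    }
    genes <- vapply(body, `[[`, character(1), 1L)
    if (anyDuplicated(genes)) {
        d <- genes[duplicated(genes)][1L]
        stop("duplicated gene identifier '", d, "' (line ",
             which(genes == d)[2L] + 1L, ")")
    }
    values <- matrix(NA_real_, nrow = length(genes), ncol = nCol - 1L,
                     dimnames = list(genes, samples))
    for (i in seq_along(body)) {
        v <- suppressWarnings(as.numeric(body[[i]][-1L]))
        if (anyNA(v)) {
            j <- which(is.na(v))[1L]
            stop("non-numeric value '", body[[i]][j + 1L], "' at line ",
                 i + 1L, ", column ", j + 1L)
        }
        values[i, ] <- v
    }
    if (any(!is.finite(values)) || any(values < 0)) {
        stop("expression values must be finite and non-negative")
    }
    cd <- S4Vectors::DataFrame(row.names = samples)
    if (!is.null(designPath)) {
        design <- utils::read.table(designPath, header = TRUE,
                                    sep = .sepForPath(designPath),
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE)
        if (!"sample" %in% colnames(design)) {
            stop("design table needs a 'sample' column")
        }
        missing <- setdiff(samples, design$sample)
        if (length(missing)) {
            stop("samples missing from design: ",
                 paste(missing, collapse = ", "))
        }
        design <- design[match(samples, design$sample), , drop = FALSE]
        cd <- S4Vectors::DataFrame(
            design[, setdiff(colnames(design), "sample"), drop = FALSE],
            row.names = samples)
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values), colData = cd)
}

#' Write an expression matrix (and design) as TSV
#'
#' @param se A \linkS4class{SummarizedExperiment} with assay
#'   \code{"abundance"}.
#' @param path Output TSV path (first column \code{gene}, header =
#'   sample identifiers).
#' @param designPath Optional path for the design TSV (column
#'   \code{sample} plus the colData columns).
#' @return Invisibly, \code{path}.
#' @examples
#' sim <- simulateOverexpression(SimulationParams(nGenes = 10, seed = 1))
#' writeExpression(sim$se, tempfile(fileext = ".tsv"))
#' @export
writeExpression <- function(se, path, designPath = NULL) {
    m <- SummarizedExperiment::assay(se, "abundance")
    ## full double precision so write -> read round-trips exactly
    ch <- matrix(sprintf("%.17g", m), nrow = nrow(m),
                 dimnames = dimnames(m))
    df <- data.frame(gene = rownames(m), ch, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    if (!is.null(designPath)) {
        cd <- SummarizedExperiment::colData(se)
        dd <- data.frame(sample = rownames(cd), as.data.frame(cd),
                         check.names = FALSE, stringsAsFactors = FALSE)
        utils::write.table(dd, designPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
    }
    invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per tab-separated line: name, description, members. Lines
#' with fewer than 3 fields are rejected with their line number;
#' duplicate members are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return A named list of \linkS4class{GeneSet} objects.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeGMT(list(GeneSet("s1", "demo", c("A", "B"))), tf)
#' readGMT(tf)
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L) {
            stop("GMT line ", i, " has fewer than 3 fields")
        }
        members <- f[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members)) {
            stop("GMT line ", i, " has an empty member list")
        }
        if (anyDuplicated(members)) {
            warning("GMT line ", i, " ('", f[1L],
                    "'): duplicate members deduplicated")
            members <- unique(members)
        }
        sets[[f[1L]]] <- GeneSet(f[1L], f[2L], members)
    }
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets A list of \linkS4class{GeneSet} objects (or a single
#'   one).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @examples
#' writeGMT(GeneSet("s1", "demo", c("A", "B")),
#'          tempfile(fileext = ".gmt"))
#' @export
writeGMT <- function(sets, path) {
    if (is(sets, "GeneSet")) sets <- list(sets)
    lines <- vapply(sets, function(s) {
        paste(c(s@name, s@description, s@members), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a ranked gene list in RNK format
#'
#' Two tab-separated columns (gene, score), no header required; a
#' header line whose second field is non-numeric is skipped. The genes
#' are ranked by descending score with lexicographic tie-breaking.
#'
#' @param path RNK file path.
#' @return A \linkS4class{RankedList}.
#' @examples
#' tf <- tempfile(fileext = ".rnk")
#' writeRNK(rankGenes(c(A = 2, B = -1)), tf)
#' readRNK(tf)
#' @export
readRNK <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (length(f) && length(f[[1L]]) == 2L &&
        is.na(suppressWarnings(as.numeric(f[[1L]][2L])))) {
        f <- f[-1L]
    }
    if (any(lengths(f) != 2L)) {
        stop("RNK line ", which(lengths(f) != 2L)[1L],
             " does not have exactly 2 fields")
    }
    genes <- vapply(f, `[[`, character(1), 1L)
    scores <- as.numeric(vapply(f, `[[`, character(1), 2L))
    if (anyNA(scores)) stop("non-numeric score in RNK file")
    rankGenes(stats::setNames(scores, genes))
}

#' Write a ranked gene list in RNK format
#'
#' @param ranked A \linkS4class{RankedList}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @examples
#' writeRNK(rankGenes(c(A = 2, B = -1)), tempfile(fileext = ".rnk"))
#' @export
writeRNK <- function(ranked, path) {
    stopifnot(is(ranked, "RankedList"))
    writeLines(sprintf("%s\t%.17g", ranked@geneIds, ranked@metric), path)
    invisible(path)
}
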