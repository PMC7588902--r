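## Independent oracles used to validate the package's own
## implementations. Each is coded from the definition, not from the
## package source.

## Welch-Satterthwaite from the textbook formulas.
oracleWelch <- function(x, y) {
    m1 <- sum(x) / length(x)
    m2 <- sum(y) / length(y)
    v1 <- sum((x - m1)^2) / (length(x) - 1)
    v2 <- sum((y - m2)^2) / (length(y) - 1)
    a <- v1 / length(x)
    b <- v2 / length(y)
    t <- (m2 - m1) / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (length(x) - 1) + b^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Brute-force running-sum enrichment score: walk every position,
## track both extrema explicitly; positive wins magnitude near-ties
## (the same declared tie rule as the implementation, applied to an
## independently accumulated walk).
oracleES <- function(metric, hitPositions, alpha) {
    n <- length(metric)
    isHit <- seq_len(n) %in% hitPositions
    wsum <- sum(abs(metric[hitPositions])^alpha)
    run <- 0
    hi <- -Inf
    lo <- Inf
    for (i in seq_len(n)) {
        if (isHit[i]) {
            if (wsum == 0) {
                run <- run + 1 / length(hitPositions)
            } else {
                run <- run + abs(metric[i])^alpha / wsum
            }
        } else {
            run <- run - 1 / (n - length(hitPositions))
        }
        if (run > hi) hi <- run
        if (run < lo) lo <- run
    }
    if (hi + lo >= -1e-12) hi else lo
}

## Exact hypergeometric upper tail by direct combinatorial summation.
oracleHyperTail <- function(N, K, n, k) {
    i <- k:min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## OLS by the normal equations, plus r^2 from the correlation formula.
oracleOLS <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    sxy <- sum(x * y); sxx <- sum(x^2); syy <- sum(y^2)
    slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    intercept <- sy / n - slope * sx / n
    r <- (n * sxy - sx * sy) /
        sqrt((n * sxx - sx^2) * (n * syy - sy^2))
    list(slope = slope, intercept = intercept, r2 = r^2)
}

## Jaccard index of two gene sets.
jaccard <- function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
}

## Small SummarizedExperiment builder for hand-made fixtures.
makeSE <- function(values, condition) {
    if (is.null(rownames(values))) {
        rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
    }
    if (is.null(colnames(values))) {
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values),
        colData = S4Vectors::DataFrame(condition = condition,
                                       row.names = colnames(values)))
}
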