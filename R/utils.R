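## Internal helpers shared across modules.

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards. All stochastic operations in the package flow
## through this so that every op is a pure function of (inputs, seed).
.withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
        stop("'seed' must be a single finite integer")
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    }
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(as.integer(seed))
    force(expr)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
        stop("'", name, "' must be a single finite number")
    }
    lo_ok <- if (strict_lower) x > lower else x >= lower
    hi_ok <- if (strict_upper) x < upper else x <= upper
    if (!lo_ok || !hi_ok) {
        stop("'", name, "' must lie in ",
             if (strict_lower) "(" else "[", lower, ", ", upper,
             if (strict_upper) ")" else "]")
    }
    invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x != round(x) || x < min) {
        stop("'", name, "' must be an integer >= ", min)
    }
    invisible(as.integer(x))
}

## Case-normalized gene identity used for cross-table matching; original
## casing is preserved in all outputs.
.normGene <- function(x) toupper(trimws(as.character(x)))

## Row-wise means and unbiased variances for a numeric matrix; the basis
## of the vectorized Welch test.
.rowMeansVars <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    v <- rowSums((m - mu)^2) / (n - 1L)
    list(mean = mu, var = v, n = n)
}
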