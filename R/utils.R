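# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise sample variance (divisor k-1) of a numeric matrix
.rowVar <- function(m) {
    k <- ncol(m)
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (k - 1)
}

# Dirichlet(alpha) draws, one simplex vector per row
.rdirichlet <- function(n, alpha) {
    g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
    g / rowSums(g)
}

.assertProb <- function(x, name, open = TRUE) {
    if (open) {
        if (any(x <= 0 | x >= 1))
            stop(name, " must lie strictly in (0, 1)", call. = FALSE)
    } else if (any(x < 0 | x > 1)) {
        stop(name, " must lie in [0, 1]", call. = FALSE)
    }
    invisible(x)
}

# append one stage to a QcReport carried in metadata
.addQcStep <- function(object, step, axis, threshold, n_input, n_removed) {
    qc <- metadata(object)$qc %||% new("QcReport")
    qc@steps <- rbind(qc@steps, data.frame(step = step, axis = axis,
        threshold = threshold, n_input = as.integer(n_input),
        n_removed = as.integer(n_removed),
        n_retained = as.integer(n_input - n_removed),
        stringsAsFactors = FALSE))
    validObject(qc)
    metadata(object)$qc <- qc
    object
}
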