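#' LD-thin a genotype matrix
#'
#' Greedy pruning in position order: each SNP is dropped if its genotype
#' squared correlation with any retained SNP within \code{window} base pairs
#' on the same chromosome exceeds \code{r2_max}. The survivors are then
#' down-sampled pseudo-randomly (driven by the session RNG; seed it for
#' reproducibility) to \code{target_n}. If pruning leaves fewer than
#' \code{target_n} SNPs, all survivors are returned with a warning.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param target_n number of SNPs to keep after down-sampling.
#' @param r2_max maximum tolerated genotype r^2 between retained SNPs.
#' @param window pruning window in base pairs.
#' @return the thinned \linkS4class{GenotypeExperiment}.
#' @export
thinGenotypes <- function(ge, target_n, r2_max = 0.2, window = 100000L) {
    if (target_n > nrow(ge))
        stop("target_n exceeds the SNP count", call. = FALSE)
    chrom <- as.character(seqnames(rowRanges(ge)))
    pos <- start(rowRanges(ge))
    ord <- order(chrom, pos)
    dos <- dosage(ge)
    kept <- integer()
    kept_chrom <- character(); kept_pos <- integer()
    for (i in ord) {
        near <- kept[kept_chrom[seq_along(kept)] == chrom[i] &
                     abs(kept_pos[seq_along(kept)] - pos[i]) <= window]
        drop <- FALSE
        if (length(near)) {
            r <- suppressWarnings(cor(dos[i, ], t(dos[near, , drop = FALSE]),
                use = "pairwise.complete.obs"))
            drop <- any(r^2 > r2_max, na.rm = TRUE)
        }
        if (!drop) {
            kept <- c(kept, i)
            kept_chrom <- c(kept_chrom, chrom[i])
            kept_pos <- c(kept_pos, pos[i])
        }
    }
    if (length(kept) < target_n) {
        warning("LD pruning left ", length(kept),
                " SNPs, fewer than target_n; returning all of them")
        return(ge[sort(kept), ])
    }
    keep <- sort(sample(kept, target_n))
    ge[keep, ]
}

#' Principal component analysis of a sample-by-feature matrix
#'
#' Eigen-decomposition (via SVD) of the standardized data. In
#' \code{"genotype"} mode each SNP column of dosages is centered by twice
#' its allele frequency estimate and scaled by the binomial standard
#' deviation sqrt(p(1-p)) — the smartPCA convention. In
#' \code{"quantitative"} mode columns are z-scored. Missing entries are
#' column-mean imputed for the decomposition only; constant columns are
#' dropped with a flag. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param x matrix with samples in rows and features in columns, or a
#'   \linkS4class{GenotypeExperiment} / \linkS4class{OmicsExperiment}
#'   (transposed internally).
#' @param mode "genotype" or "quantitative"; chosen automatically from the
#'   object class when omitted.
#' @return A \linkS4class{PcaResult}.
#' @export
runPca <- function(x, mode = c("quantitative", "genotype")) {
    if (is(x, "GenotypeExperiment")) {
        if (missing(mode)) mode <- "genotype"
        m <- t(dosage(x))
    } else if (is(x, "SummarizedExperiment")) {
        if (missing(mode)) mode <- "quantitative"
        m <- t(assay(x))
    } else {
        m <- as.matrix(x)
    }
    mode <- match.arg(mode)
    # column-mean imputation, decomposition only
    if (anyNA(m)) {
        mu <- colMeans(m, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- mu[idx[, 2L]]
    }
    if (mode == "genotype") {
        p_hat <- colMeans(m) / 2
        keep <- p_hat > 0 & p_hat < 1
        center <- 2 * p_hat
        scale_ <- sqrt(p_hat * (1 - p_hat))
    } else {
        center <- colMeans(m)
        scale_ <- apply(m, 2L, sd)
        keep <- scale_ > 0
    }
    dropped <- colnames(m)[!keep] %||% character()
    z <- sweep(sweep(m[, keep, drop = FALSE], 2L, center[keep]),
               2L, scale_[keep], `/`)
    sv <- svd(z)
    rank <- min(nrow(z) - 1L, ncol(z))
    d <- sv$d[seq_len(rank)]
    scores <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(d, rank)
    loadings <- sv$v[, seq_len(rank), drop = FALSE]
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(rank)) {
        i_max <- which.max(abs(loadings[, j]))
        if (loadings[i_max, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    rownames(scores) <- rownames(m)
    rownames(loadings) <- colnames(z)
    colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(rank))
    ve <- d^2 / sum(sv$d^2)
    new("PcaResult", scores = scores, loadings = loadings,
        varianceExplained = ve, mode = mode,
        dropped = as.character(dropped))
}

#' Components needed to reach a cumulative variance target
#'
#' @param result a \linkS4class{PcaResult}.
#' @param target fraction of total variance in (0, 1].
#' @return smallest number of leading components whose cumulative variance
#'   explained reaches \code{target}.
#' @examples
#' # fractions (0.5, 0.3, 0.2): 2 components reach 80%, 3 reach 90%
#' @export
cumulativeVariance <- function(result, target) {
    if (target <= 0 || target > 1)
        stop("target must lie in (0, 1]", call. = FALSE)
    cum <- cumsum(result@varianceExplained)
    idx <- which(cum >= target - 1e-12)
    if (!length(idx)) length(cum) else idx[1L]
}
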