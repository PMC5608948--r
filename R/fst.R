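#' Wright's F_ST across k populations
#'
#' For a variant with per-population frequencies p_1..p_k the statistic is
#' \deqn{F_{ST} = \frac{(k-1)\,\sigma^2}{k\,\bar p\,(1-\bar p)}}
#' where \eqn{\sigma^2} is the sample variance (divisor k-1) of the
#' frequencies and \eqn{\bar p} their mean. The (k-1)/k factor bounds the
#' statistic at 1 for a fixed difference. Variants monomorphic across all
#' populations (\eqn{\bar p} of 0 or 1) are assigned F_ST 0 by convention.
#'
#' @param freqs numeric vector of k frequencies in [0, 1], or a
#'   variants-by-population matrix for a vectorized computation.
#' @return numeric F_ST in [0, 1], one value per variant.
#' @examples
#' wrightFst(c(0.118, 0.263, 0.900))  # 0.471
#' wrightFst(c(0, 0, 1))              # 1
#' @export
wrightFst <- function(freqs) {
    if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L)
    if (ncol(freqs) < 2L) stop("need at least 2 populations", call. = FALSE)
    .assertProb(freqs, "frequencies", open = FALSE)
    k <- ncol(freqs)
    p_bar <- rowMeans(freqs)
    sigma2 <- .rowVar(freqs)
    denom <- k * p_bar * (1 - p_bar)
    fst <- ifelse(denom == 0, 0, (k - 1) * sigma2 / denom)
    unname(fst)
}

#' Full per-variant F_ST statistics
#'
#' Computes, for each row of a frequency table, the F_ST together with its
#' components (sample variance, mean frequency), a monomorphic flag, and the
#' population pair driving the differentiation.
#'
#' @param freqs variants-by-population frequency matrix (column names are the
#'   population labels).
#' @param null_fst optional genome-wide null F_ST distribution; when supplied
#'   an empirical p-value column is added via [empiricalPvalue()].
#' @return data.frame with columns variant, one frequency column per
#'   population, sigma2, p_bar, fst, monomorphic, driving_pair and (when a
#'   null is given) p_empirical.
#' @export
fstTable <- function(freqs, null_fst = NULL) {
    freqs <- as.matrix(freqs)
    k <- ncol(freqs)
    pops <- colnames(freqs) %||% paste0("pop", seq_len(k))
    colnames(freqs) <- pops
    p_bar <- rowMeans(freqs)
    out <- data.frame(variant = rownames(freqs) %||%
        paste0("v", seq_len(nrow(freqs))), stringsAsFactors = FALSE)
    for (p in pops) out[[paste0("freq_", p)]] <- freqs[, p]
    out$sigma2 <- .rowVar(freqs)
    out$p_bar <- p_bar
    out$fst <- wrightFst(freqs)
    out$monomorphic <- p_bar == 0 | p_bar == 1
    out$driving_pair <- if (k == 3L) drivingPair(freqs) else NA_character_
    if (!is.null(null_fst)) out$p_empirical <- empiricalPvalue(out$fst, null_fst)
    rownames(out) <- NULL
    out
}

#' Per-population allele frequencies from genotypes
#'
#' Frequencies are computed from non-missing chromosomes only:
#' p_i = sum(dosage) / (2 * non-missing N_i) within each population. A
#' population with no called genotype at a variant leaves that frequency
#' \code{NA} and flags the variant (it is excluded from F_ST downstream).
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @return list with \code{freq} (variants-by-population frequency matrix),
#'   \code{n_chrom} (matrix of non-missing chromosome counts 2*N_i) and
#'   \code{incomplete} (logical flag per variant: some population had no
#'   data).
#' @export
frequenciesFromGenotypes <- function(ge) {
    pop <- population(ge)
    dos <- dosage(ge)
    pops <- levels(pop)
    freq <- n_chrom <- matrix(NA_real_, nrow(dos), length(pops),
        dimnames = list(rownames(dos), pops))
    for (p in pops) {
        d <- dos[, pop == p, drop = FALSE]
        n_called <- rowSums(!is.na(d))
        n_chrom[, p] <- 2 * n_called
        freq[, p] <- ifelse(n_called == 0, NA_real_,
                            rowSums(d, na.rm = TRUE) / (2 * n_called))
    }
    list(freq = freq, n_chrom = n_chrom,
         incomplete = rowSums(is.na(freq)) > 0)
}

#' One-vs-rest frequency table for classical HLA alleles
#'
#' Each distinct classical allele observed at a locus is treated as the
#' alternate allele of a biallelic variant: its per-population frequency is
#' the count of that allele over the total called allele count (2 per sample
#' with both alleles called; missing calls, NA or "", are excluded from the
#' denominator). Each row can then be fed to [wrightFst()].
#'
#' @param hla data.frame with columns sample, locus, allele1, allele2.
#' @param population named vector or factor of population labels indexed by
#'   sample ID, or a vector aligned with the rows of \code{hla}.
#' @return variants-by-population frequency matrix, rownames
#'   "locus:allele"; attribute \code{"n_chrom"} holds the per-population
#'   called-allele counts per locus.
#' @export
hlaOneVsRest <- function(hla, population) {
    if (!is.null(names(population))) {
        pop <- factor(population[hla$sample])
    } else {
        if (length(population) != nrow(hla))
            stop("population must be named by sample or aligned with rows",
                 call. = FALSE)
        pop <- factor(population)
    }
    pops <- levels(pop)
    long <- rbind(
        data.frame(locus = hla$locus, allele = hla$allele1, pop = pop),
        data.frame(locus = hla$locus, allele = hla$allele2, pop = pop))
    long <- long[!is.na(long$allele) & long$allele != "", , drop = FALSE]
    denom <- table(long$locus, long$pop)  # called alleles per locus x pop
    counts <- table(paste(long$locus, long$allele, sep = ":"), long$pop)
    loci <- sub(":.*$", "", rownames(counts))
    freq <- matrix(0, nrow(counts), length(pops),
                   dimnames = list(rownames(counts), pops))
    for (p in pops) freq[, p] <- counts[, p] / denom[loci, p]
    attr(freq, "n_chrom") <- unclass(denom)
    freq
}

# pairwise (k = 2) F_ST for all three pairs of a 3-column frequency matrix
.pairwiseFst3 <- function(freqs) {
    pair <- function(a, b) {
        pb <- (freqs[, a] + freqs[, b]) / 2
        s2 <- (freqs[, a] - pb)^2 + (freqs[, b] - pb)^2  # divisor k-1 = 1
        denom <- 2 * pb * (1 - pb)
        ifelse(denom == 0, 0, s2 / denom)
    }
    cbind(p12 = pair(1L, 2L), p13 = pair(1L, 3L), p23 = pair(2L, 3L))
}

#' Population pair driving a variant's differentiation
#'
#' Attribution rule: the pair with the largest two-population F_ST (the k = 2
#' version of the same formula applied to that pair). Ties are broken by the
#' fixed pair order (1,2), (1,3), (2,3) in the supplied population order;
#' variants with all frequencies equal return "none".
#'
#' @param freqs vector of 3 frequencies or a variants-by-3 matrix; column
#'   names are the population labels.
#' @return character vector of pair labels like "Chinese-Indian", or "none".
#' @examples
#' drivingPair(matrix(c(0.118, 0.263, 0.900), 1,
#'     dimnames = list(NULL, c("Chinese", "Malay", "Indian"))))
#' @export
drivingPair <- function(freqs) {
    if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L)
    if (ncol(freqs) != 3L)
        stop("driving-pair attribution requires exactly 3 populations",
             call. = FALSE)
    pops <- colnames(freqs) %||% paste0("pop", 1:3)
    labels <- c(paste(pops[1], pops[2], sep = "-"),
                paste(pops[1], pops[3], sep = "-"),
                paste(pops[2], pops[3], sep = "-"))
    pw <- .pairwiseFst3(freqs)
    best <- max.col(pw, ties.method = "first")
    out <- labels[best]
    out[pw[cbind(seq_len(nrow(pw)), best)] == 0] <- "none"
    out
}

#' Empirical p-value against a genome-wide null
#'
#' The fraction of the null distribution strictly exceeding the observed
#' value: P = #\{null > observed\} / #null. An observed value at or above the
#' null maximum gives exactly 0 (no pseudocount, matching the definition);
#' set \code{add_one = TRUE} for the conservative (count+1)/(total+1)
#' variant. Values below 1e-4 are conventionally flagged as strong
#' pharmacogenomic differentiation candidates.
#'
#' @param observed numeric vector of observed F_ST values.
#' @param null numeric vector, the genome-wide null F_ST distribution.
#' @param add_one apply the +1 pseudocount correction (default FALSE).
#' @return numeric vector of empirical p-values in [0, 1].
#' @examples
#' empiricalPvalue(0.25, c(0.1, 0.2, 0.3, 0.4))  # 0.5
#' @export
empiricalPvalue <- function(observed, null, add_one = FALSE) {
    null <- null[!is.na(null)]
    if (!length(null)) stop("null distribution is empty", call. = FALSE)
    sn <- sort(null)
    # #{null > obs} = n - #{null <= obs}
    exceed <- length(sn) - findInterval(observed, sn)
    if (add_one) (exceed + 1) / (length(sn) + 1) else exceed / length(sn)
}
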