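#' Remove SNPs with high missingness
#'
#' SNPs whose missing-genotype fraction is strictly greater than
#' \code{max_miss} (default 5\%) are removed; a SNP exactly at the threshold
#' is retained.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param max_miss maximum tolerated missing fraction, in [0, 1].
#' @return the filtered object, with the stage appended to [qcReport()].
#' @export
filterSnpMissingness <- function(ge, max_miss = 0.05) {
    .assertProb(max_miss, "max_miss", open = FALSE)
    miss <- rowMeans(is.na(dosage(ge)))
    keep <- miss <= max_miss
    out <- ge[keep, ]
    .addQcStep(out, "snp_missingness", "snp", max_miss, nrow(ge), sum(!keep))
}

#' Remove samples with high missingness
#'
#' Samples missing strictly more than \code{max_miss} (default 2\%) of their
#' genotypes are removed.
#'
#' @inheritParams filterSnpMissingness
#' @param max_miss maximum tolerated missing fraction per sample.
#' @return the filtered object, with the stage appended to [qcReport()].
#' @export
filterSampleMissingness <- function(ge, max_miss = 0.02) {
    .assertProb(max_miss, "max_miss", open = FALSE)
    miss <- colMeans(is.na(dosage(ge)))
    keep <- miss <= max_miss
    out <- ge[, keep]
    .addQcStep(out, "sample_missingness", "sample", max_miss, ncol(ge),
               sum(!keep))
}

#' Remove samples by explicit exclusion list
#'
#' Duplicate/related samples and ethnicity-discordant samples are removed by
#' user-supplied ID lists (no genetic inference is performed here).
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param ids sample IDs to drop.
#' @param reason label recorded in the QC report.
#' @export
excludeSamples <- function(ge, ids, reason = "exclusion_list") {
    keep <- !colnames(ge) %in% ids
    out <- ge[, keep]
    .addQcStep(out, reason, "sample", NA_real_, ncol(ge), sum(!keep))
}

# conditional distribution of the heterozygote count given allele counts,
# by the numerically stable mid-out recurrence; returns probs indexed by
# het = first_het, first_het + 2, ...
.hweHetDist <- function(n, n_a) {
    # n diploid samples, n_a copies of the A allele (n_a <= n assumed by caller)
    het_max <- min(n_a, 2L * n - n_a)
    parity <- n_a %% 2L
    hets <- seq.int(parity, het_max, by = 2L)
    probs <- numeric(length(hets))
    # start from the mode-ish midpoint
    mid <- round(n_a * (2 * n - n_a) / (2 * n))
    if (mid %% 2L != parity) mid <- mid + 1L
    if (mid > het_max) mid <- het_max
    i_mid <- match(mid, hets)
    probs[i_mid] <- 1
    # downward: P(h-2)/P(h) = h(h-1) / (4 * homA(h-2+... ) ) use standard ratio
    if (i_mid > 1L) for (i in seq(i_mid, 2L)) {
        h <- hets[i]
        homA <- (n_a - h) / 2
        homB <- (n - homA - h)
        probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (homA + 1) * (homB + 1))
    }
    # upward: P(h+2)/P(h) = 4*homA*homB / ((h+2)(h+1))
    if (i_mid < length(hets)) for (i in seq(i_mid, length(hets) - 1L)) {
        h <- hets[i]
        homA <- (n_a - h) / 2
        homB <- n - homA - h
        probs[i + 1L] <- probs[i] * 4 * homA * homB / ((h + 2) * (h + 1))
    }
    probs <- probs / sum(probs)
    names(probs) <- hets
    probs
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' total probability of heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Monomorphic variants return
#' p = 1 by convention. All three count arguments are vectorized.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts
#'   (reference homozygotes, heterozygotes, alternate homozygotes).
#' @return numeric p-value(s) in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # balanced, p = 1 region
#' hweExactTest(50, 0, 50)    # extreme heterozygote deficit, p << 1e-3
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
    n_hom_ref <- as.integer(n_hom_ref); n_het <- as.integer(n_het)
    n_hom_alt <- as.integer(n_hom_alt)
    if (any(n_hom_ref < 0 | n_het < 0 | n_hom_alt < 0, na.rm = TRUE))
        stop("genotype counts must be non-negative", call. = FALSE)
    n <- n_hom_ref + n_het + n_hom_alt
    if (any(n < 1, na.rm = TRUE))
        stop("at least one genotype is required", call. = FALSE)
    # fold to the minor allele; p depends only on (n, n_minor, het)
    n_a <- pmin(2L * n_hom_alt + n_het, 2L * n_hom_ref + n_het)
    out <- numeric(length(n))
    out[] <- NA_real_
    mono <- !is.na(n_a) & n_a == 0L
    out[mono] <- 1
    todo <- which(!mono & !is.na(n_a))
    if (length(todo)) {
        key <- paste(n[todo], n_a[todo])
        for (grp in split(todo, key)) {
            probs <- .hweHetDist(n[grp[1L]], n_a[grp[1L]])
            hets <- as.integer(names(probs))
            # two-sided: sum of probabilities <= P(observed) (with slack for
            # floating-point ties, as in the standard exact-test convention)
            p_two <- vapply(probs,
                function(p0) sum(probs[probs <= p0 * (1 + 1e-12)]), 0)
            out[grp] <- pmin(1, p_two[match(n_het[grp], hets)])
        }
    }
    unname(out)
}

#' Remove SNPs departing from Hardy-Weinberg equilibrium
#'
#' [hweExactTest()] is applied within each population; a SNP is removed if
#' its p-value falls below \code{p_threshold} in any one population
#' (\code{mode = "any"}, the default) or in all of them
#' (\code{mode = "all"}).
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param p_threshold removal threshold (default 1e-3).
#' @param mode aggregation over populations, "any" or "all".
#' @return the filtered object, with the stage appended to [qcReport()].
#' @export
filterHwe <- function(ge, p_threshold = 1e-3, mode = c("any", "all")) {
    mode <- match.arg(mode)
    pop <- population(ge)
    dos <- dosage(ge)
    fail <- matrix(FALSE, nrow(dos), nlevels(pop))
    for (j in seq_len(nlevels(pop))) {
        d <- dos[, pop == levels(pop)[j], drop = FALSE]
        p <- hweExactTest(rowSums(d == 0, na.rm = TRUE),
                          rowSums(d == 1, na.rm = TRUE),
                          rowSums(d == 2, na.rm = TRUE))
        fail[, j] <- p < p_threshold
    }
    drop <- if (mode == "any") rowSums(fail) > 0 else rowSums(fail) == ncol(fail)
    out <- ge[!drop, ]
    .addQcStep(out, paste0("hwe_", mode), "snp", p_threshold, nrow(ge),
               sum(drop))
}

#' Filter features or samples by call rate or missingness
#'
#' Two boundary conventions are supported, matching how such filters are
#' usually stated: \code{criterion = "call_rate"} removes rows/columns whose
#' call rate is less than or equal to the threshold (e.g. miRNAs at a 90\%
#' call-rate rule, where exactly 90\% is removed), and
#' \code{criterion = "missingness"} removes those whose missing fraction is
#' strictly greater than the threshold (e.g. clinical variables at a 20\%
#' missingness rule, where exactly 20\% is retained).
#'
#' @param x matrix or \linkS4class{OmicsExperiment} (features in rows).
#' @param threshold fraction in [0, 1].
#' @param axis apply to "feature" rows or "sample" columns.
#' @param criterion "call_rate" (remove \eqn{\le} threshold) or
#'   "missingness" (remove \eqn{>} threshold).
#' @return the filtered object; for an \linkS4class{OmicsExperiment} the
#'   stage is appended to [qcReport()].
#' @export
filterCallRate <- function(x, threshold, axis = c("feature", "sample"),
                           criterion = c("call_rate", "missingness")) {
    axis <- match.arg(axis)
    criterion <- match.arg(criterion)
    .assertProb(threshold, "threshold", open = FALSE)
    m <- if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
    frac_called <- if (axis == "feature") rowMeans(!is.na(m)) else
        colMeans(!is.na(m))
    keep <- if (criterion == "call_rate") frac_called > threshold else
        (1 - frac_called) <= threshold
    out <- if (axis == "feature") x[keep, ] else x[, keep]
    if (is(out, "SummarizedExperiment"))
        out <- .addQcStep(out, paste(criterion, axis, sep = "_"), axis,
                          threshold, length(keep), sum(!keep))
    out
}

#' Merge two genotyping arrays
#'
#' Samples are restricted to those present on both arrays. For SNPs present
#' on both, the copy with the lower missing fraction is retained; ties keep
#' the first input.
#'
#' @param ge1,ge2 \linkS4class{GenotypeExperiment}s sharing sample IDs.
#' @return merged \linkS4class{GenotypeExperiment}.
#' @export
mergeArrays <- function(ge1, ge2) {
    shared <- intersect(colnames(ge1), colnames(ge2))
    if (!length(shared)) stop("no shared samples to merge", call. = FALSE)
    ge1 <- ge1[, shared]; ge2 <- ge2[, shared]
    overlap <- intersect(rownames(ge1), rownames(ge2))
    m1 <- rowMeans(is.na(dosage(ge1[overlap, ])))
    m2 <- rowMeans(is.na(dosage(ge2[overlap, ])))
    from2 <- overlap[m2 < m1]  # ties keep the first input
    keep1 <- setdiff(rownames(ge1), from2)
    keep2 <- c(setdiff(rownames(ge2), overlap), from2)
    out <- BiocGenerics::rbind(ge1[keep1, ], ge2[keep2, ])
    new("GenotypeExperiment", out)
}

#' Genotype concordance between two matrices
#'
#' Per-SNP fraction of agreeing genotypes over shared samples and SNPs,
#' counting only pairs where both calls are non-missing.
#'
#' @param ge1,ge2 \linkS4class{GenotypeExperiment}s.
#' @return named numeric vector of concordance per shared SNP (NA when no
#'   comparable pair exists).
#' @export
genotypeConcordance <- function(ge1, ge2) {
    shared_s <- intersect(colnames(ge1), colnames(ge2))
    shared_v <- intersect(rownames(ge1), rownames(ge2))
    if (!length(shared_s) || !length(shared_v))
        stop("no shared sample/SNP pairs", call. = FALSE)
    d1 <- dosage(ge1[shared_v, shared_s])
    d2 <- dosage(ge2[shared_v, shared_s])
    both <- !is.na(d1) & !is.na(d2)
    agree <- rowSums(both & d1 == d2, na.rm = TRUE)
    total <- rowSums(both)
    setNames(ifelse(total == 0, NA_real_, agree / total), shared_v)
}
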