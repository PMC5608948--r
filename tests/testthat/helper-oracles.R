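# Independent oracles used across tests. Each recomputes a quantity by a
# route different from the package implementation.

# HWE exact test by direct enumeration: log-factorial pmf of the
# heterozygote count conditional on allele counts, two-sided sum of
# probabilities not exceeding the observed one.
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
    n <- n_hom_ref + n_het + n_hom_alt
    n_a <- 2L * n_hom_alt + n_het          # alt allele count (unfolded)
    if (n_a == 0L || n_a == 2L * n) return(1)
    hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
    logp <- lfactorial(n) + hets * log(2) + lfactorial(n_a) +
        lfactorial(2L * n - n_a) - lfactorial(2L * n) -
        lfactorial((n_a - hets) / 2) - lfactorial(hets) -
        lfactorial(n - (n_a - hets) / 2 - hets)
    probs <- exp(logp - max(logp))
    probs <- probs / sum(probs)
    p0 <- probs[match(n_het, hets)]
    min(1, sum(probs[probs <= p0 * (1 + 1e-12)]))
}

# distribution of the heterozygote count for one (n, n_a), by the same
# direct log-factorial route (used by the exhaustive comparison)
oracle_hwe_dist <- function(n, n_a) {
    hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
    logp <- lfactorial(n) + hets * log(2) + lfactorial(n_a) +
        lfactorial(2L * n - n_a) - lfactorial(2L * n) -
        lfactorial((n_a - hets) / 2) - lfactorial(hets) -
        lfactorial(n - (n_a - hets) / 2 - hets)
    probs <- exp(logp - max(logp))
    names(probs) <- hets
    probs / sum(probs)
}

# classical one-way ANOVA F by explicit sums of squares
oracle_oneway_F <- function(y, g) {
    g <- factor(g)
    k <- nlevels(g); n <- length(y)
    grand <- mean(y)
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    F <- (ssb / (k - 1)) / (ssw / (n - k))
    list(F = F, p = pf(F, k - 1, n - k, lower.tail = FALSE))
}

# squared Pearson correlation from the covariance formula, complete cases
oracle_r2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    (sxy^2) / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# small deterministic genotype fixture with a known missingness pattern
make_genotype_fixture <- function(n_snps = 20L, n_samples = 30L, seed = 11L) {
    set.seed(seed)
    d <- matrix(as.numeric(sample(0:2, n_snps * n_samples, replace = TRUE)),
                n_snps, n_samples)
    d[sample(length(d), round(0.05 * length(d)))] <- NA
    dimnames(d) <- list(sprintf("snp%03d", seq_len(n_snps)),
                        sprintf("S%03d", seq_len(n_samples)))
    genotypeExperiment(d, chrom = rep("chr1", n_snps),
        pos = seq_len(n_snps) * 1000L,
        population = rep(c("Chinese", "Malay", "Indian"),
                         length.out = n_samples))
}

# feature-by-sample omics fixture with three balanced groups
make_omics_fixture <- function(n_feat = 10L, n_per_group = 20L, seed = 3L,
                               shift = NULL, platform = "expression") {
    set.seed(seed)
    n <- 3L * n_per_group
    pop <- rep(c("Chinese", "Malay", "Indian"), each = n_per_group)
    y <- matrix(rnorm(n_feat * n, mean = 10), n_feat, n,
        dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                        sprintf("S%03d", seq_len(n))))
    if (!is.null(shift))
        y[1L, pop == "Indian"] <- y[1L, pop == "Indian"] + shift
    omicsExperiment(y, population = pop, platform = platform,
        sex = rep_len(c("F", "M"), n), batch = rep_len(c("b1", "b2", "b3"), n))
}

# block-structured correlation matrix: n_blocks blocks of size block_size
# at within-block r2 = hi, everything else at lo
make_block_corr <- function(n_blocks = 3L, block_size = 4L, n_extra = 5L,
                            hi = 0.95, lo = 0.1) {
    K <- n_blocks * block_size + n_extra
    feats <- sprintf("L%03d", seq_len(K))
    r2 <- matrix(lo, K, K, dimnames = list(feats, feats))
    for (b in seq_len(n_blocks)) {
        idx <- (b - 1L) * block_size + seq_len(block_size)
        r2[idx, idx] <- hi
    }
    diag(r2) <- 1
    new("CorrelationMatrix", r2 = r2, n_pairs = matrix(50L, K, K),
        population = "fixture")
}
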