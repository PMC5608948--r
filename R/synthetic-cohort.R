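#' Create a synthetic cohort design
#'
#' Parameter object for [simulateCohort()]. Defaults emulate a three-population
#' Singapore-style cohort: 122 Chinese, 120 Malays and 122 Indians, SNP
#' differentiation around F = 0.01 (genome-wide pairwise differentiation of
#' one to a few percent), multi-allelic HLA-like loci with Dirichlet
#' frequencies, and log2-scale lipid concentrations in correlated blocks at
#' the r^2 = 0.8 tagging threshold with planted 1.5-SD group shifts.
#'
#' @param n_per_pop integer sample counts per population.
#' @param pop_labels population labels, same length as \code{n_per_pop}.
#' @param n_snps number of biallelic SNPs.
#' @param fst_target Balding-Nichols divergence F, scalar or one per
#'   population, in (0, 1).
#' @param n_hla_loci,alleles_per_locus layout of the multi-allelic loci.
#' @param n_lipids,n_expression,n_mirna feature counts per platform.
#' @param n_blocks number of correlated lipid blocks.
#' @param block_r2 within-block pairwise squared-correlation target.
#' @param n_diff_features features per platform given a true group shift.
#' @param effect_size group shift in within-group SD units.
#' @param missing_rate per-entry missingness probability.
#' @param snp_stride base pairs between consecutive SNPs.
#' @param snps_per_chrom SNPs per synthetic chromosome.
#' @param seed integer seed; fixed seed gives a byte-identical cohort.
#' @return A \linkS4class{CohortDesign}.
#' @examples
#' design <- cohortDesign(n_snps = 500L, seed = 7L)
#' design
#' @export
cohortDesign <- function(n_per_pop = c(122L, 120L, 122L),
                         pop_labels = c("Chinese", "Malay", "Indian"),
                         n_snps = 2000L, fst_target = 0.01,
                         n_hla_loci = 2L, alleles_per_locus = 6L,
                         n_lipids = 60L, n_expression = 200L, n_mirna = 100L,
                         n_blocks = 5L, block_r2 = 0.8,
                         n_diff_features = 10L, effect_size = 1.5,
                         missing_rate = 0.01, snp_stride = 10000L,
                         snps_per_chrom = 1000L, seed = 1L) {
    new("CohortDesign", n_per_pop = as.integer(n_per_pop),
        pop_labels = as.character(pop_labels), n_snps = as.integer(n_snps),
        fst_target = fst_target, n_hla_loci = as.integer(n_hla_loci),
        alleles_per_locus = as.integer(alleles_per_locus),
        n_lipids = as.integer(n_lipids),
        n_expression = as.integer(n_expression), n_mirna = as.integer(n_mirna),
        n_blocks = as.integer(n_blocks), block_r2 = block_r2,
        n_diff_features = as.integer(n_diff_features),
        effect_size = effect_size, missing_rate = missing_rate,
        snp_stride = as.integer(snp_stride),
        snps_per_chrom = as.integer(snps_per_chrom), seed = as.integer(seed))
}

#' Balding-Nichols population allele frequencies
#'
#' Draws, for each locus and each population, an allele frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral frequency p. Under this
#' model the expected apportionment of frequency variance between populations
#' equals F, so the divergence parameter maps directly onto the expected
#' per-locus F_ST.
#'
#' @param p_ancestral vector of ancestral allele frequencies, each in (0, 1).
#' @param F divergence parameter, scalar or one value per population,
#'   strictly inside (0, 1); 0 and 1 are rejected as degenerate.
#' @param pop_labels labels for the populations (default three populations).
#' @return matrix of per-population frequencies, loci in rows, populations in
#'   columns (named by \code{pop_labels}).
#' @examples
#' set.seed(1)
#' simulateBNFrequencies(c(0.2, 0.5), F = 0.05)
#' @export
simulateBNFrequencies <- function(p_ancestral, F,
                                  pop_labels = c("Chinese", "Malay", "Indian")) {
    .assertProb(p_ancestral, "p_ancestral")
    .assertProb(F, "F")
    k <- length(pop_labels)
    if (length(F) == 1L) F <- rep(F, k)
    if (length(F) != k)
        stop("F must be scalar or one value per population", call. = FALSE)
    n <- length(p_ancestral)
    out <- matrix(NA_real_, n, k, dimnames = list(names(p_ancestral), pop_labels))
    for (j in seq_len(k)) {
        scale <- (1 - F[j]) / F[j]
        out[, j] <- rbeta(n, p_ancestral * scale, (1 - p_ancestral) * scale)
    }
    out
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Within each population, dosages at each SNP are drawn Binomial(2, p) from
#' that population's allele frequency; missingness is applied uniformly at
#' random. Positions are laid out at a fixed stride along synthetic
#' chromosomes, so 100-kb windows hold a deterministic number of SNPs.
#'
#' @param freqs loci-by-population frequency matrix, e.g. from
#'   [simulateBNFrequencies()]; all entries must be in [0, 1].
#' @param n_per_pop samples per population (same column order as
#'   \code{freqs}).
#' @param missing_rate per-entry missingness probability.
#' @param snp_stride,snps_per_chrom position layout.
#' @param sex optional per-sample sex factor (generated balanced if NULL).
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
simulateGenotypes <- function(freqs, n_per_pop, missing_rate = 0,
                              snp_stride = 10000L, snps_per_chrom = 1000L,
                              sex = NULL) {
    .assertProb(freqs, "frequencies", open = FALSE)
    k <- ncol(freqs)
    n_snps <- nrow(freqs)
    pops <- colnames(freqs) %||% paste0("pop", seq_len(k))
    n_total <- sum(n_per_pop)
    dos <- matrix(NA_real_, n_snps, n_total)
    col0 <- 0L
    for (j in seq_len(k)) {
        nj <- n_per_pop[j]
        dos[, col0 + seq_len(nj)] <-
            rbinom(n_snps * nj, size = 2L, prob = rep(freqs[, j], nj))
        col0 <- col0 + nj
    }
    if (missing_rate > 0)
        dos[runif(length(dos)) < missing_rate] <- NA_real_
    rownames(dos) <- rownames(freqs) %||% sprintf("snp%05d", seq_len(n_snps))
    colnames(dos) <- sprintf("S%03d", seq_len(n_total))
    chrom_idx <- (seq_len(n_snps) - 1L) %/% snps_per_chrom
    within <- (seq_len(n_snps) - 1L) %% snps_per_chrom
    genotypeExperiment(dos,
        chrom = paste0("chr", chrom_idx + 1L),
        pos = within * snp_stride + 1L,
        population = rep(pops, n_per_pop),
        sex = sex %||% rep_len(c("F", "M"), n_total))
}

#' Simulate a multi-allelic (HLA-like) locus
#'
#' Two alleles per sample are drawn independently within each population from
#' that population's allele-frequency simplex.
#'
#' @param allele_freqs alleles-by-population matrix; each column must sum
#'   to 1 (tolerance 1e-8). Rownames are the allele labels.
#' @param n_per_pop samples per population (column order of
#'   \code{allele_freqs}).
#' @param locus locus label.
#' @return data.frame with columns sample, locus, allele1, allele2.
#' @export
simulateMultiallelicLocus <- function(allele_freqs, n_per_pop,
                                      locus = "HLA_A") {
    allele_freqs <- as.matrix(allele_freqs)
    if (any(abs(colSums(allele_freqs) - 1) > 1e-8))
        stop("each population's allele frequencies must sum to 1",
             call. = FALSE)
    if (any(allele_freqs < 0))
        stop("allele frequencies must be non-negative", call. = FALSE)
    alleles <- rownames(allele_freqs) %||%
        paste0(locus, "*", sprintf("%02d", seq_len(nrow(allele_freqs))))
    pops <- colnames(allele_freqs) %||% paste0("pop", seq_len(ncol(allele_freqs)))
    draw <- function(j, n) alleles[sample.int(length(alleles), 2L * n,
        replace = TRUE, prob = allele_freqs[, j])]
    out <- lapply(seq_along(n_per_pop), function(j) {
        n <- n_per_pop[j]
        a <- matrix(draw(j, n), ncol = 2L)
        data.frame(pop_idx = j, allele1 = a[, 1L], allele2 = a[, 2L],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    data.frame(sample = sprintf("S%03d", seq_len(sum(n_per_pop))),
               locus = locus, allele1 = out$allele1, allele2 = out$allele2,
               stringsAsFactors = FALSE)
}

#' Simulate a quantitative omics platform
#'
#' Features are drawn on the log2 scale as Gaussian noise around per-feature
#' baselines, with additive sex and batch/plate effects. For the lipid
#' platform the first \code{n_blocks} blocks of features share a latent
#' factor: each member is factor*sqrt(r) + noise*sqrt(1-r) with
#' r = sqrt(block_r2), which yields within-block pairwise squared
#' correlations of approximately \code{block_r2}. The first
#' \code{n_diff_features} features receive an additive shift of
#' \code{effect_size} within-group SDs in one population (rotating over
#' populations), recorded in the returned truth.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param platform one of "lipid", "expression", "mirna".
#' @return list with elements \code{experiment} (an
#'   \linkS4class{OmicsExperiment}) and \code{truth} (data.frame of planted
#'   shifts plus, for lipids, the block membership).
#' @export
simulateQuantPlatform <- function(design,
                                  platform = c("lipid", "expression", "mirna")) {
    platform <- match.arg(platform)
    if (design@block_r2 >= 1)
        stop("block_r2 must be < 1", call. = FALSE)
    n_feat <- switch(platform, lipid = design@n_lipids,
        expression = design@n_expression, mirna = design@n_mirna)
    n_per_pop <- design@n_per_pop
    n <- sum(n_per_pop)
    pop <- factor(rep(design@pop_labels, n_per_pop),
                  levels = design@pop_labels)
    sex <- factor(rep_len(c("F", "M"), n))
    batch <- factor(rep_len(paste0("b", 1:3), n))
    prefix <- switch(platform, lipid = "lip", expression = "tx", mirna = "mir")
    feats <- sprintf("%s%04d", prefix, seq_len(n_feat))

    baseline <- runif(n_feat, 2, 15)
    y <- matrix(rnorm(n_feat * n), n_feat, n,
                dimnames = list(feats, sprintf("S%03d", seq_len(n))))

    blocks <- NULL
    if (platform == "lipid" && design@n_blocks > 0L) {
        # latent-factor blocks: pairwise correlation sqrt(block_r2)
        r <- sqrt(design@block_r2)
        block_size <- max(2L, n_feat %/% (2L * design@n_blocks))
        blocks <- data.frame(feature = character(), block = integer(),
                             stringsAsFactors = FALSE)
        for (b in seq_len(design@n_blocks)) {
            idx <- (b - 1L) * block_size + seq_len(block_size)
            idx <- idx[idx <= n_feat]
            if (length(idx) < 2L) next
            f <- rnorm(n)
            y[idx, ] <- sqrt(r) * matrix(f, length(idx), n, byrow = TRUE) +
                sqrt(1 - r) * y[idx, ]
            blocks <- rbind(blocks, data.frame(feature = feats[idx],
                block = b, stringsAsFactors = FALSE))
        }
    }

    # covariate effects, per feature; kept modest (0.2 SD) so they perturb
    # but do not dominate the within-group variance or wash out the block
    # correlation structure
    sex_eff <- rnorm(n_feat, 0, 0.2)
    batch_eff <- matrix(rnorm(n_feat * nlevels(batch), 0, 0.2),
                        n_feat, nlevels(batch))
    y <- y + baseline +
        outer(sex_eff, as.numeric(sex == "M")) +
        batch_eff[, as.integer(batch)]

    shifts <- data.frame(feature = character(), population = character(),
                         shift = numeric(), stringsAsFactors = FALSE)
    if (design@n_diff_features > 0L) {
        n_diff <- min(design@n_diff_features, n_feat)
        for (i in seq_len(n_diff)) {
            target <- design@pop_labels[(i - 1L) %% length(design@pop_labels) + 1L]
            y[i, pop == target] <- y[i, pop == target] + design@effect_size
            shifts <- rbind(shifts, data.frame(feature = feats[i],
                population = target, shift = design@effect_size,
                stringsAsFactors = FALSE))
        }
    }
    if (design@missing_rate > 0)
        y[runif(length(y)) < design@missing_rate] <- NA_real_

    oe <- omicsExperiment(y, population = pop, platform = platform,
                          sex = sex, batch = batch)
    list(experiment = oe,
         truth = list(shifts = shifts, blocks = blocks,
                      sex_effect = sex_eff))
}

#' Simulate a complete three-population cohort
#'
#' Runs the full generator under \code{design@seed}: ancestral SNP
#' frequencies Uniform(0.05, 0.95), Balding-Nichols population frequencies at
#' \code{fst_target}, HWE genotypes with missingness, Dirichlet(1,...,1)
#' multi-allelic HLA-like loci, and the three quantitative platforms. The
#' same seed reproduces the cohort exactly.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' cohort <- simulateCohort(cohortDesign(n_snps = 200L, n_lipids = 20L,
#'     n_expression = 20L, n_mirna = 20L, seed = 42L))
#' cohort
#' @export
simulateCohort <- function(design) {
    validObject(design)
    set.seed(design@seed)
    p_anc <- runif(design@n_snps, 0.05, 0.95)
    freqs <- simulateBNFrequencies(p_anc, design@fst_target,
                                   design@pop_labels)
    rownames(freqs) <- sprintf("snp%05d", seq_len(design@n_snps))
    ge <- simulateGenotypes(freqs, design@n_per_pop, design@missing_rate,
                            design@snp_stride, design@snps_per_chrom)

    hla <- do.call(rbind, lapply(seq_len(design@n_hla_loci), function(l) {
        locus <- paste0("HLA_", LETTERS[l])
        af <- t(.rdirichlet(length(design@pop_labels),
                            rep(1, design@alleles_per_locus)))
        dimnames(af) <- list(
            paste0(locus, "*", sprintf("%02d", seq_len(design@alleles_per_locus))),
            design@pop_labels)
        simulateMultiallelicLocus(af, design@n_per_pop, locus)
    }))

    lip <- simulateQuantPlatform(design, "lipid")
    expr <- simulateQuantPlatform(design, "expression")
    mir <- simulateQuantPlatform(design, "mirna")

    truth <- list(
        snp_frequencies = freqs, fst_target = design@fst_target,
        lipid = lip$truth, expression = expr$truth, mirna = mir$truth)
    new("SyntheticCohort", design = design, genotypes = ge, hla = hla,
        lipids = lip$experiment, expression = expr$experiment,
        mirna = mir$experiment, truth = truth)
}
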