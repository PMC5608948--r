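test_that("design validation rejects out-of-range parameters", {
    expect_error(cohortDesign(fst_target = 0), "fst_target")
    expect_error(cohortDesign(fst_target = 1), "fst_target")
    expect_error(cohortDesign(block_r2 = 1.2), "block_r2")
    expect_error(cohortDesign(missing_rate = 1), "missing_rate")
    expect_error(cohortDesign(n_snps = 0L), "positive")
})

test_that("Balding-Nichols frequencies respect the no-divergence limit", {
    expect_error(simulateBNFrequencies(c(0, 0.5), 0.01), "p_ancestral")
    expect_error(simulateBNFrequencies(0.5, 0), "F")
    expect_error(simulateBNFrequencies(0.5, 1), "F")
    set.seed(1)
    p <- runif(500, 0.1, 0.9)
    f <- simulateBNFrequencies(p, 1e-6)
    expect_gte(mean(abs(f - p) < 1e-2), 0.99)
    # determinism under a fixed seed
    set.seed(9); a <- simulateBNFrequencies(p, 0.05)
    set.seed(9); b <- simulateBNFrequencies(p, 0.05)
    expect_identical(a, b)
})

test_that("simulated divergence maps onto the F_ST scale", {
    set.seed(2)
    p <- runif(10000, 0.05, 0.95)
    f <- simulateBNFrequencies(p, 0.01)
    m <- mean(wrightFst(f))
    expect_gte(m, 0.005)
    expect_lte(m, 0.02)
})

test_that("mean F_ST is monotone in the divergence parameter", {
    set.seed(3)
    p <- runif(3000, 0.05, 0.95)
    means <- vapply(c(0.001, 0.01, 0.05, 0.1), function(F)
        mean(wrightFst(simulateBNFrequencies(p, F))), 0)
    expect_true(all(diff(means) > 0))
})

test_that("genotype simulation honors frequencies, HWE and missingness", {
    freqs <- matrix(c(0, 0.3, 1), 1, 3,
        dimnames = list("s1", c("A", "B", "C")))
    set.seed(4)
    ge <- simulateGenotypes(freqs, c(50, 10000, 50))
    dos <- dosage(ge)
    pop <- population(ge)
    expect_true(all(dos[, pop == "A"] == 0))
    expect_true(all(dos[, pop == "C"] == 2))
    # sample frequency within 3 binomial SEs of the target
    p_hat <- mean(dos[, pop == "B"]) / 2
    se <- sqrt(0.3 * 0.7 / (2 * 10000))
    expect_lt(abs(p_hat - 0.3), 3 * se)
    expect_false(anyNA(dos))        # missing_rate 0
    set.seed(5)
    ge2 <- simulateGenotypes(matrix(0.5, 20, 3), c(30, 30, 30),
                             missing_rate = 0.2)
    miss <- mean(is.na(dosage(ge2)))
    expect_gt(miss, 0.1); expect_lt(miss, 0.3)
})

test_that("multi-allelic locus simulation matches its simplex inputs", {
    af <- matrix(c(1, 0, 0, 1, 0, 0), 3, 2,
        dimnames = list(c("X*01", "X*02", "X*03"), c("A", "B")))
    set.seed(6)
    tab <- simulateMultiallelicLocus(af, c(10, 10), locus = "X")
    expect_true(all(tab$allele1 == "X*01" & tab$allele2 == "X*01"))
    expect_error(simulateMultiallelicLocus(af * 2, c(5, 5)), "sum to 1")
    # observed one-vs-rest frequencies within 3 SEs of simulated
    set.seed(7)
    af2 <- t(matrix(c(.5, .3, .2, .1, .6, .3), 2, 3, byrow = TRUE))
    dimnames(af2) <- list(c("Y*01", "Y*02", "Y*03"), c("A", "B"))
    n <- 4000L
    tab2 <- simulateMultiallelicLocus(af2, c(n, n), locus = "Y")
    pop <- rep(c("A", "B"), each = n)
    for (j in c("A", "B")) {
        obs <- c(tab2$allele1[pop == j], tab2$allele2[pop == j])
        for (al in rownames(af2)) {
            p <- af2[al, j]
            se <- sqrt(p * (1 - p) / (2 * n))
            expect_lt(abs(mean(obs == al) - p), 3 * se + 1e-9)
        }
    }
})

test_that("quantitative platform realizes the block correlation target", {
    design <- cohortDesign(n_per_pop = c(100L, 100L, 100L), n_lipids = 40L,
        n_blocks = 4L, block_r2 = 0.9, n_diff_features = 0L,
        missing_rate = 0, seed = 8L)
    set.seed(design@seed)
    sim <- simulateQuantPlatform(design, "lipid")
    truth <- sim$truth
    y <- SummarizedExperiment::assay(sim$experiment, "log2")
    r2s <- unlist(lapply(split(truth$blocks$feature, truth$blocks$block),
        function(members) {
            r <- cor(t(y[members, ]))^2
            r[upper.tri(r)]
        }))
    expect_gte(median(r2s), 0.8)
    expect_lte(median(r2s), 0.95)
})

test_that("planted shifts are recorded exactly in the truth", {
    design <- cohortDesign(n_snps = 100L, n_lipids = 20L, n_expression = 30L,
        n_mirna = 10L, n_diff_features = 6L, seed = 10L)
    cohort <- simulateCohort(design)
    truth <- cohortTruth(cohort)
    for (pl in c("lipid", "expression", "mirna")) {
        shifts <- truth[[pl]]$shifts
        expect_equal(nrow(shifts), 6L)
        expect_true(all(shifts$shift == design@effect_size))
        expect_true(all(shifts$shift != 0))
    }
})

test_that("a fixed seed reproduces the cohort exactly", {
    design <- cohortDesign(n_snps = 80L, n_lipids = 12L, n_expression = 12L,
                           n_mirna = 8L, seed = 123L)
    a <- simulateCohort(design)
    b <- simulateCohort(design)
    expect_identical(dosage(a@genotypes), dosage(b@genotypes))
    expect_identical(a@hla, b@hla)
    expect_identical(SummarizedExperiment::assay(a@lipids),
                     SummarizedExperiment::assay(b@lipids))
    expect_identical(cohortTruth(a), cohortTruth(b))
})

test_that("cohort platforms share one sample set with consistent covariates", {
    cohort <- simulateCohort(cohortDesign(n_snps = 60L, n_lipids = 10L,
        n_expression = 10L, n_mirna = 10L, seed = 2L))
    ids <- colnames(cohort@genotypes)
    expect_identical(colnames(cohort@lipids), ids)
    expect_identical(colnames(cohort@mirna), ids)
    expect_setequal(unique(cohort@hla$sample), ids)
    expect_equal(as.character(population(cohort@lipids)),
                 as.character(population(cohort@genotypes)))
})
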