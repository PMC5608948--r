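test_that("wrightFst reproduces the printed pharmacogenomic SNP values", {
    # VKORC1/ADH/ABCB5 frequency triplets and their published F_ST
    triplets <- list(
        c(0.118, 0.263, 0.900), c(0.118, 0.273, 0.900),
        c(0.118, 0.263, 0.868), c(0.109, 0.272, 0.822),
        c(0.179, 0.272, 0.865), c(0.038, 0.165, 0.670))
    expected <- c(0.471, 0.466, 0.434, 0.387, 0.375, 0.361)
    got <- vapply(triplets, wrightFst, 0)
    # the published values were computed from unrounded frequencies; from the
    # printed 3-dp frequencies the first row lands at 0.47153, so agreement is
    # to the half-unit of the printed precision plus that input-rounding
    # propagation
    expect_true(all(abs(got - expected) <= 0.0006))
    expect_true(all(abs(got[-1] - expected[-1]) <= 0.0005))
})

test_that("wrightFst reproduces the drug-associated HLA allele values", {
    triplets <- list(
        c(0.074, 0.124, 0.038),  # B*15:02
        c(0.102, 0.030, 0.008),  # B*13:01
        c(0.046, 0.043, 0.029),  # B*38:02
        c(0.000, 0.009, 0.075))  # B*57:01
    expected <- c(0.017, 0.036, 0.001, 0.041)
    got <- vapply(triplets, wrightFst, 0)
    expect_true(all(abs(got - expected) <= 0.0005))
})

test_that("wrightFst handles degenerate and boundary inputs", {
    expect_equal(wrightFst(c(0.3, 0.3, 0.3)), 0)
    expect_equal(wrightFst(c(0, 0, 1)), 1)
    expect_equal(wrightFst(c(0, 0, 0)), 0)   # monomorphic convention
    expect_equal(wrightFst(c(1, 1, 1)), 0)
    expect_error(wrightFst(0.5), "2 populations")
    expect_error(wrightFst(c(-0.1, 0.5, 0.5)), "frequencies")
})

test_that("F_ST lies in [0,1] and is invariant under allele relabeling", {
    set.seed(42)
    p <- matrix(runif(3e5), ncol = 3)
    fst <- wrightFst(p)
    expect_true(all(fst >= 0 & fst <= 1))
    expect_equal(wrightFst(1 - p), fst, tolerance = 1e-12)
})

test_that("frequenciesFromGenotypes matches brute-force counting", {
    ge <- make_genotype_fixture()
    fq <- frequenciesFromGenotypes(ge)
    dos <- dosage(ge)
    pop <- population(ge)
    for (p in levels(pop)) {
        d <- dos[, pop == p, drop = FALSE]
        for (i in seq_len(nrow(d))) {
            called <- d[i, !is.na(d[i, ])]
            expect_equal(fq$freq[i, p], sum(called) / (2 * length(called)))
            expect_equal(fq$n_chrom[i, p], 2 * length(called))
        }
    }
    # trivial cases
    ge2 <- genotypeExperiment(rbind(snp1 = c(2, 2, 0), snp2 = c(2, 1, 0)),
        chrom = c("chr1", "chr1"), pos = c(1L, 2L),
        population = c("A", "A", "B"))
    fq2 <- frequenciesFromGenotypes(ge2)
    expect_equal(unname(fq2$freq["snp1", "A"]), 1)       # all dosage 2
    expect_equal(unname(fq2$freq["snp2", "A"]), 0.75)
    # all-missing population flags the variant
    ge3 <- genotypeExperiment(matrix(c(NA, NA, 1, 1), 1, 4),
        chrom = "chr1", pos = 1L, population = c("A", "A", "B", "B"))
    expect_true(frequenciesFromGenotypes(ge3)$incomplete)
})

test_that("HLA one-vs-rest frequencies behave like biallelic variants", {
    hla <- data.frame(
        sample = c("s1", "s2", "s3", "s4"),
        locus = "HLA_B",
        allele1 = c("B*57:01", "B*15:02", "B*15:02", "B*15:02"),
        allele2 = c("B*15:02", "B*15:02", "B*15:02", "B*57:01"),
        stringsAsFactors = FALSE)
    pop <- setNames(c("A", "A", "B", "B"), hla$sample)
    freq <- hlaOneVsRest(hla, pop)
    expect_equal(unname(freq["HLA_B:B*57:01", "A"]), 1 / 4)
    expect_equal(unname(freq["HLA_B:B*57:01", "B"]), 1 / 4)
    # per-population frequencies across alleles at one locus sum to 1
    expect_equal(unname(colSums(freq)), c(1, 1))
    # missing calls excluded from the denominator
    hla$allele2[1] <- NA
    freq2 <- hlaOneVsRest(hla, pop)
    expect_equal(unname(freq2["HLA_B:B*57:01", "A"]), 1 / 3)
})

test_that("driving pair is the maximal pairwise F_ST with fixed tie-break", {
    labels <- c("Chinese", "Malay", "Indian")
    m <- matrix(c(0.118, 0.263, 0.900), 1, dimnames = list(NULL, labels))
    # brute-force all three pairwise k=2 F_ST values
    pw <- vapply(list(c(1, 2), c(1, 3), c(2, 3)),
        function(ij) wrightFst(m[, ij]), 0)
    expect_equal(which.max(pw), 2L)
    expect_equal(drivingPair(m), "Chinese-Indian")
    expect_equal(drivingPair(matrix(c(0.5, 0.5, 0.5), 1,
        dimnames = list(NULL, labels))), "none")
    # tie between pairs (1,2) and (1,3): first in fixed order wins
    expect_equal(drivingPair(matrix(c(0.1, 0.5, 0.5), 1,
        dimnames = list(NULL, labels))), "Chinese-Malay")
})

test_that("empirical p-values use the strict-exceedance fraction", {
    null <- c(0.1, 0.2, 0.3, 0.4)
    expect_equal(empiricalPvalue(0.25, null), 0.5)
    expect_equal(empiricalPvalue(0.4, null), 0)    # >= max: strict inequality
    expect_equal(empiricalPvalue(0.5, null), 0)
    expect_equal(empiricalPvalue(0.05, null), 1)
    expect_error(empiricalPvalue(0.2, numeric(0)), "empty")
    # non-increasing in the observed value
    obs <- sort(runif(50))
    p <- empiricalPvalue(obs, runif(1000))
    expect_true(all(diff(p) <= 0))
    # +1 pseudocount mode
    expect_equal(empiricalPvalue(0.5, null, add_one = TRUE), 1 / 5)
})

test_that("fstTable assembles components consistently", {
    set.seed(7)
    freqs <- matrix(runif(30), 10, 3,
        dimnames = list(paste0("v", 1:10), c("Chinese", "Malay", "Indian")))
    ft <- fstTable(freqs, null_fst = runif(100))
    k <- 3
    expect_equal(ft$fst, (k - 1) * ft$sigma2 / (k * ft$p_bar * (1 - ft$p_bar)))
    expect_equal(ft$p_bar, rowMeans(freqs), ignore_attr = TRUE)
    expect_equal(ft$sigma2, apply(freqs, 1, var), ignore_attr = TRUE)
    expect_true(all(ft$p_empirical >= 0 & ft$p_empirical <= 1))
})
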