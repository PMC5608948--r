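test_that("SNP missingness filter uses a strict > rule", {
    d <- matrix(0, 10, 100, dimnames = list(sprintf("snp%02d", 1:10),
        sprintf("S%03d", 1:100)))
    d[1, 1:6] <- NA   # 6% missing: removed at 5%
    d[2, 1:5] <- NA   # exactly 5%: retained
    ge <- genotypeExperiment(d, chrom = rep("chr1", 10), pos = 1:10 * 100L,
        population = rep("A", 100))
    out <- filterSnpMissingness(ge, 0.05)
    expect_false("snp01" %in% rownames(out))
    expect_true("snp02" %in% rownames(out))
    st <- qcSteps(qcReport(out))
    expect_equal(st$n_removed, 1L)
    expect_equal(st$n_removed + st$n_retained, st$n_input)
})

test_that("sample missingness filter matches brute-force counting", {
    ge <- make_genotype_fixture(n_snps = 50L, n_samples = 40L, seed = 2L)
    out <- filterSampleMissingness(ge, 0.02)
    expected <- colnames(ge)[colMeans(is.na(dosage(ge))) <= 0.02]
    expect_equal(colnames(out), expected)
    # complete matrix: everyone retained
    d <- matrix(1, 3, 5)
    ge2 <- genotypeExperiment(d, chrom = rep("chr1", 3), pos = 1:3,
        population = rep("A", 5))
    expect_equal(ncol(filterSampleMissingness(ge2)), 5L)
})

test_that("random-mask fixtures survive filters exactly as brute force", {
    ge <- make_genotype_fixture(n_snps = 60L, n_samples = 50L, seed = 9L)
    for (thr in c(0.0, 0.03, 0.1)) {
        out <- filterSnpMissingness(ge, thr)
        expect_equal(nrow(out), sum(rowMeans(is.na(dosage(ge))) <= thr))
    }
})

test_that("HWE exact test matches the enumeration oracle", {
    cases <- list(c(25, 50, 25), c(50, 0, 50), c(3, 1, 0), c(10, 5, 2),
                  c(0, 1, 0), c(7, 0, 1), c(60, 20, 20))
    for (cs in cases) {
        expect_equal(hweExactTest(cs[1], cs[2], cs[3]),
                     oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-12)
    }
    # extreme heterozygote deficit is far below any QC threshold
    expect_lt(hweExactTest(50, 0, 50), 1e-3)
    # monomorphic convention
    expect_equal(hweExactTest(10, 0, 0), 1)
    expect_equal(hweExactTest(0, 0, 10), 1)
    expect_error(hweExactTest(-1, 2, 3), "non-negative")
    expect_error(hweExactTest(0, 0, 0), "at least one")
})

test_that("HWE filter removes variants failing in any population", {
    # population B grossly out of HWE, A in HWE
    dA <- c(rep(0, 25), rep(1, 50), rep(2, 25))
    dB <- c(rep(0, 50), rep(2, 50))
    d <- rbind(snpbad = c(dA, dB), snpok = c(dA, dA))
    colnames(d) <- sprintf("S%03d", seq_len(ncol(d)))
    ge <- genotypeExperiment(d, chrom = c("chr1", "chr1"), pos = c(1L, 2L),
        population = rep(c("A", "B"), each = 100))
    out <- filterHwe(ge, 1e-3, mode = "any")
    expect_equal(rownames(out), "snpok")
    out_all <- filterHwe(ge, 1e-3, mode = "all")
    expect_equal(nrow(out_all), 2L)  # fails in B only
})

test_that("call-rate filter honors both boundary conventions", {
    m <- matrix(rnorm(10 * 20), 10, 20,
        dimnames = list(sprintf("f%02d", 1:10), sprintf("S%02d", 1:20)))
    m[1, 1:2] <- NA   # call rate 0.90 exactly
    m[2, 1:3] <- NA   # call rate 0.85
    m[3, 1:4] <- NA   # missingness 0.20 exactly
    m[4, 1:6] <- NA   # missingness 0.30
    # miRNA rule: call rate <= 0.9 removed, so f01, f02, f03 and f04 go
    out <- filterCallRate(m, 0.9, "feature", "call_rate")
    expect_equal(rownames(out), rownames(m)[-(1:4)])
    # clinical rule: missingness > 0.2 removed, so f03 (exactly 20%) stays
    # while f04 (30%) goes
    out2 <- filterCallRate(m, 0.2, "feature", "missingness")
    expect_true(all(c("f01", "f02", "f03") %in% rownames(out2)))
    expect_false("f04" %in% rownames(out2))
    # survivor set equals hand enumeration on a random mask
    set.seed(5)
    m2 <- matrix(rnorm(200), 10, 20)
    m2[sample(200, 40)] <- NA
    out3 <- filterCallRate(m2, 0.85, "feature", "call_rate")
    expect_equal(nrow(out3), sum(rowMeans(!is.na(m2)) > 0.85))
})

test_that("filter composition equals sequential application", {
    ge <- make_genotype_fixture(n_snps = 40L, n_samples = 60L, seed = 21L)
    a <- filterSnpMissingness(filterSampleMissingness(ge, 0.1), 0.07)
    b1 <- filterSampleMissingness(ge, 0.1)
    b2 <- filterSnpMissingness(b1, 0.07)
    expect_identical(dosage(a), dosage(b2))
    st <- qcSteps(qcReport(a))
    expect_equal(st$step, c("sample_missingness", "snp_missingness"))
    expect_true(all(st$n_removed + st$n_retained == st$n_input))
})

test_that("array merge keeps the copy with least missingness, ties first", {
    d1 <- rbind(a = c(0, 1), b = c(NA, 1))
    colnames(d1) <- c("s1", "s2")
    d2 <- rbind(b = c(2, 2), c = c(1, 1))
    colnames(d2) <- c("s1", "s2")
    ge1 <- genotypeExperiment(d1, chrom = c("chr1", "chr1"), pos = c(1L, 2L),
        population = c("A", "A"))
    ge2 <- genotypeExperiment(d2, chrom = c("chr1", "chr1"), pos = c(2L, 3L),
        population = c("A", "A"))
    merged <- mergeArrays(ge1, ge2)
    expect_setequal(rownames(merged), c("a", "b", "c"))
    # b has 1 missing on array 1, none on array 2: array 2 wins
    expect_equal(unname(dosage(merged)["b", ]), c(2, 2))
    # tie: both complete -> first input kept
    d1ok <- d1; d1ok[] <- c(0, 1, 0, 1)  # b becomes (1, 1) with no missing
    ge1b <- genotypeExperiment(d1ok, chrom = c("chr1", "chr1"),
        pos = c(1L, 2L), population = c("A", "A"))
    merged2 <- mergeArrays(ge1b, ge2)
    expect_equal(unname(dosage(merged2)["b", ]), c(1, 1))
})

test_that("genotype concordance counts non-missing agreements", {
    d1 <- matrix(c(0, 1, 2, NA, 1, 1), 2, 3,
        dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
    d2 <- matrix(c(0, 1, 1, 1, 1, 0), 2, 3,
        dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
    ge1 <- genotypeExperiment(d1, chrom = c("chr1", "chr1"), pos = c(1L, 2L),
        population = rep("A", 3))
    ge2 <- genotypeExperiment(d2, chrom = c("chr1", "chr1"), pos = c(1L, 2L),
        population = rep("A", 3))
    cc <- genotypeConcordance(ge1, ge2)
    expect_equal(unname(cc["a"]), 2 / 3)   # s1 agrees, s2 differs, s3 agrees
    expect_equal(unname(cc["b"]), 1 / 2)   # s1 missing, s2 agrees, s3 differs
})

test_that("VCF round trip preserves the dosage matrix", {
    ge <- make_genotype_fixture(n_snps = 25L, n_samples = 20L, seed = 4L)
    path <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(ge, path)
    pop <- setNames(as.character(population(ge)), colnames(ge))
    back <- readGenotypeVcf(path, pop)
    expect_identical(dosage(back), dosage(ge))
    expect_equal(as.character(population(back)), as.character(population(ge)))
    # GT semantics
    lines <- readLines(path)
    expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
    # dosage TSV round trip too
    tsv <- tempfile(fileext = ".tsv")
    writeDosageTsv(ge, tsv)
    back2 <- readDosageTsv(tsv, pop)
    expect_equal(unname(dosage(back2)), unname(dosage(ge)))
})

test_that("multi-allelic VCF records are rejected with a message", {
    ge <- make_genotype_fixture(n_snps = 3L, n_samples = 4L, seed = 8L)
    path <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(ge, path)
    lines <- readLines(path)
    body <- which(!startsWith(lines, "#"))[1]
    f <- strsplit(lines[body], "\t")[[1]]
    f[5] <- "G,T"
    lines[body] <- paste(f, collapse = "\t")
    writeLines(lines, path)
    pop <- setNames(as.character(population(ge)), colnames(ge))
    expect_error(readGenotypeVcf(path, pop), "multi-allelic")
})

test_that("sample exclusion lists act as QC stages", {
    ge <- make_genotype_fixture(n_snps = 5L, n_samples = 10L)
    out <- excludeSamples(ge, c("S001", "S003"), reason = "duplicates")
    expect_equal(ncol(out), 8L)
    expect_equal(qcSteps(qcReport(out))$step, "duplicates")
})
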