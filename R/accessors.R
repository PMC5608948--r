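#' Construct a GenotypeExperiment
#'
#' @param dosage SNP-by-sample matrix of alternate-allele dosages in
#'   \{0, 1, 2, NA\}; rownames are SNP IDs, colnames sample IDs.
#' @param chrom,pos chromosome and 1-based position per SNP.
#' @param population per-sample population labels.
#' @param ref,alt allele labels per SNP.
#' @param sex optional per-sample sex factor.
#' @return A \linkS4class{GenotypeExperiment}.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'     dimnames = list(c("snp1", "snp2"), c("s1", "s2")))
#' ge <- genotypeExperiment(d, chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'     population = c("Chinese", "Malay"))
#' @export
genotypeExperiment <- function(dosage, chrom, pos, population,
                               ref = NULL, alt = NULL, sex = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("snp", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
    rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L))
    names(rr) <- rownames(dosage)
    if (!is.null(ref)) S4Vectors::mcols(rr)$ref <- ref
    if (!is.null(alt)) S4Vectors::mcols(rr)$alt <- alt
    cd <- DataFrame(population = factor(population), row.names = colnames(dosage))
    if (!is.null(sex)) cd$sex <- factor(sex)
    new("GenotypeExperiment", SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr, colData = cd))
}

#' Construct an OmicsExperiment
#'
#' @param log2mat feature-by-sample matrix on the log2 scale.
#' @param population per-sample population labels.
#' @param platform platform label ("lipid", "expression", "mirna", ...).
#' @param sex,batch optional per-sample covariate factors.
#' @return An \linkS4class{OmicsExperiment}.
#' @export
omicsExperiment <- function(log2mat, population, platform = "quantitative",
                            sex = NULL, batch = NULL) {
    log2mat <- as.matrix(log2mat)
    if (is.null(rownames(log2mat)))
        rownames(log2mat) <- paste0("feature", seq_len(nrow(log2mat)))
    if (is.null(colnames(log2mat)))
        colnames(log2mat) <- paste0("sample", seq_len(ncol(log2mat)))
    cd <- DataFrame(population = factor(population), row.names = colnames(log2mat))
    if (!is.null(sex)) cd$sex <- factor(sex)
    if (!is.null(batch)) cd$batch <- factor(batch)
    oe <- new("OmicsExperiment", SummarizedExperiment(
        assays = list(log2 = log2mat), colData = cd))
    metadata(oe)$platform <- platform
    oe
}

#' @rdname dosage
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Extract the dosage matrix
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @return SNP-by-sample numeric matrix in \{0, 1, 2, NA\}.
#' @export
setMethod("dosage", "GenotypeExperiment", function(x) assay(x, "dosage"))

#' @rdname population
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' Per-sample population labels
#'
#' @param x a \linkS4class{GenotypeExperiment} or \linkS4class{OmicsExperiment}.
#' @return factor of population labels, one per sample.
#' @export
setMethod("population", "SummarizedExperiment",
    function(x) colData(x)$population)

#' @rdname qcReport
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' Accumulated QC report
#'
#' @param x an object whose filters record into \code{metadata(x)$qc}.
#' @return the \linkS4class{QcReport} (empty if no filter has run).
#' @export
setMethod("qcReport", "SummarizedExperiment", function(x) {
    qc <- metadata(x)$qc
    if (is.null(qc)) new("QcReport") else qc
})

#' @rdname qcSteps
#' @export
setGeneric("qcSteps", function(x) standardGeneric("qcSteps"))

#' QC stages as a data.frame
#' @param x a \linkS4class{QcReport}.
#' @export
setMethod("qcSteps", "QcReport", function(x) x@steps)

#' @rdname tagCounts
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' Tagging bookkeeping counts
#'
#' @param x a \linkS4class{TagReport}.
#' @return named numeric vector with \code{K} (features), \code{n_tags},
#'   \code{n_tagged} (cluster members excluding their tags),
#'   \code{n_singletons} and \code{n_representative} = K − n_tagged.
#' @export
setMethod("tagCounts", "TagReport", function(x) {
    role <- x@assignments$role
    K <- length(role)
    n_tags <- sum(role == "tag")
    n_tagged <- sum(role == "tagged")
    n_single <- sum(role == "singleton")
    c(K = K, n_tags = n_tags, n_tagged = n_tagged, n_singletons = n_single,
      n_representative = K - n_tagged)
})

#' @rdname tagAssignments
#' @export
setGeneric("tagAssignments", function(x) standardGeneric("tagAssignments"))

#' Per-feature tag assignments
#' @param x a \linkS4class{TagReport}.
#' @export
setMethod("tagAssignments", "TagReport", function(x) x@assignments)

#' @rdname pcaScores
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname pcaLoadings
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname varianceExplained
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' Sample scores of a PCA
#' @param x a \linkS4class{PcaResult}.
#' @export
setMethod("pcaScores", "PcaResult", function(x) x@scores)

#' Feature loadings of a PCA
#' @param x a \linkS4class{PcaResult}.
#' @export
setMethod("pcaLoadings", "PcaResult", function(x) x@loadings)

#' Variance explained per component
#' @param x a \linkS4class{PcaResult}.
#' @export
setMethod("varianceExplained", "PcaResult", function(x) x@varianceExplained)

setMethod("show", "QcReport", function(object) {
    s <- object@steps
    cat("QcReport with", nrow(s), "stage(s)\n")
    if (nrow(s)) print(s, row.names = FALSE)
})

setMethod("show", "TagReport", function(object) {
    ct <- tagCounts(object)
    cat(sprintf(
        "TagReport [%s] threshold r^2 > %g: K=%d, %d tags covering %d members, %d singletons, %d representative\n",
        object@population, object@threshold, ct["K"], ct["n_tags"],
        ct["n_tagged"], ct["n_singletons"], ct["n_representative"]))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix [%s]: %d features, %d undefined entries\n",
        object@population, nrow(object@r2), sum(is.na(object@r2))))
})

setMethod("show", "PcaResult", function(object) {
    ve <- object@varianceExplained
    cat(sprintf("PcaResult (%s mode): %d samples x %d components\n",
        object@mode, nrow(object@scores), ncol(object@scores)))
    cat("  variance explained (first 5):",
        paste(sprintf("%.3f", head(ve, 5)), collapse = " "), "\n")
    if (length(object@dropped))
        cat("  dropped constant columns:", length(object@dropped), "\n")
})

setMethod("show", "CohortDesign", function(object) {
    cat("CohortDesign:", sum(object@n_per_pop), "samples (",
        paste(object@n_per_pop, collapse = "/"), ") in populations",
        paste(object@pop_labels, collapse = ", "), "\n")
    cat(sprintf("  %d SNPs (F=%s), %d HLA-like loci, %d/%d/%d lipid/expr/miRNA features, seed %d\n",
        object@n_snps, paste(signif(object@fst_target, 3), collapse = "/"),
        object@n_hla_loci, object@n_lipids, object@n_expression,
        object@n_mirna, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", ncol(object@genotypes), "samples,",
        nrow(object@genotypes), "SNPs,", nrow(object@lipids), "lipids,",
        nrow(object@expression), "transcripts,", nrow(object@mirna), "miRNAs\n")
})

#' @rdname cohortPlatform
#' @export
setGeneric("cohortPlatform", function(x, platform) standardGeneric("cohortPlatform"))

#' Extract one platform from a synthetic cohort
#'
#' @param x a \linkS4class{SyntheticCohort}.
#' @param platform one of "genotype", "hla", "lipid", "expression", "mirna".
#' @export
setMethod("cohortPlatform", "SyntheticCohort", function(x, platform) {
    switch(match.arg(platform,
            c("genotype", "hla", "lipid", "expression", "mirna")),
        genotype = x@genotypes, hla = x@hla, lipid = x@lipids,
        expression = x@expression, mirna = x@mirna)
})

#' @rdname cohortTruth
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' Simulation ground truth of a synthetic cohort
#' @param x a \linkS4class{SyntheticCohort}.
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
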