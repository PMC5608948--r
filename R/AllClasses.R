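#' @import methods
#' @importFrom stats var sd quantile anova as.formula complete.cases cor
#'   lm model.matrix model.frame terms coef p.adjust pf predict rbeta rbinom
#'   rgamma rnorm runif setNames dbinom
#' @importFrom utils read.delim write.table head modifyList combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData rowRanges
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom BiocGenerics rbind
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' Genotype dosage container
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a SNP-by-sample matrix of
#' alternate-allele dosages (0, 1, 2 or \code{NA} for missing), genomic
#' positions as \code{rowRanges}, and per-sample metadata (at minimum a
#' \code{population} factor) in \code{colData}. Quality-control history
#' accumulates as a \linkS4class{QcReport} in \code{metadata(x)$qc}.
#'
#' @seealso [genotypeExperiment()], [dosage()], [qcReport()]
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

#' Quantitative omics container
#'
#' A \linkS4class{SummarizedExperiment} holding a feature-by-sample matrix of
#' log2-scale measurements (assay \code{"log2"}) with sample covariates
#' (population, and optionally sex and batch/plate factors) in \code{colData}
#' and the platform label in \code{metadata(x)$platform}.
#'
#' @seealso [omicsExperiment()], [platformContrast()], [pairwiseR2()]
#' @export
setClass("OmicsExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- NULL
    if (!"dosage" %in% names(assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        if (!all(d %in% c(0, 1, 2) | is.na(d)))
            msg <- c(msg, "dosages must be in {0, 1, 2, NA}")
    }
    if (!"population" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample IDs must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "SNP IDs must be unique")
    if (is.null(msg)) TRUE else msg
})

setValidity("OmicsExperiment", function(object) {
    msg <- NULL
    if (!"log2" %in% names(assays(object)))
        msg <- c(msg, "assay 'log2' is required")
    if (!"population" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature IDs must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Quality-control report
#'
#' Ordered record of filter stages applied to a genotype or omics object. Each
#' stage stores the filter name, the axis it acted on, the threshold, and the
#' input/removed/retained counts; the class validity enforces the conservation
#' identity removed + retained = input at every stage.
#'
#' @slot steps data.frame with columns \code{step}, \code{axis},
#'   \code{threshold}, \code{n_input}, \code{n_removed}, \code{n_retained}.
#' @export
setClass("QcReport", representation(steps = "data.frame"),
    prototype(steps = data.frame(step = character(), axis = character(),
        threshold = numeric(), n_input = integer(), n_removed = integer(),
        n_retained = integer(), stringsAsFactors = FALSE)))

setValidity("QcReport", function(object) {
    s <- object@steps
    need <- c("step", "axis", "threshold", "n_input", "n_removed", "n_retained")
    if (!all(need %in% names(s)))
        return(paste("steps must have columns:", paste(need, collapse = ", ")))
    if (nrow(s) && any(s$n_removed + s$n_retained != s$n_input))
        return("n_removed + n_retained must equal n_input at every stage")
    TRUE
})

#' Lipid tagging report
#'
#' Partition of the features of one population's correlation matrix into tags,
#' tagged members and singletons, produced by [selectTags()]. The counts
#' satisfy n_representative = n_tags + n_singletons = K − n_tagged, where
#' n_tagged counts cluster members other than their tag.
#'
#' @slot population population label the correlations were computed in.
#' @slot threshold squared-correlation threshold used.
#' @slot assignments data.frame with one row per feature: \code{feature},
#'   \code{role} (tag/tagged/singleton), \code{tag} (its representative, or
#'   itself for tags and singletons), \code{r2_to_tag}.
#' @export
setClass("TagReport", representation(population = "character",
    threshold = "numeric", assignments = "data.frame"))

setValidity("TagReport", function(object) {
    a <- object@assignments
    need <- c("feature", "role", "tag", "r2_to_tag")
    if (!all(need %in% names(a)))
        return(paste("assignments must have columns:", paste(need, collapse = ", ")))
    if (!all(a$role %in% c("tag", "tagged", "singleton")))
        return("role must be tag, tagged or singleton")
    if (anyDuplicated(a$feature)) return("features must partition (no duplicates)")
    bad <- a$role == "tagged" &
        (!a$tag %in% a$feature[a$role == "tag"] |
         (!is.na(a$r2_to_tag) & a$r2_to_tag <= object@threshold))
    if (any(bad)) return("every tagged feature needs an above-threshold tag")
    TRUE
})

#' Pairwise squared-correlation matrix
#'
#' Within-population feature-by-feature squared Pearson correlations on the
#' log2 scale, with the complete-case sample count behind every pair.
#'
#' @slot r2 symmetric matrix of squared correlations with unit diagonal;
#'   \code{NA} marks pairs involving a zero-variance feature.
#' @slot n_pairs matrix of complete-case sample counts per pair.
#' @slot population population label.
#' @export
setClass("CorrelationMatrix", representation(r2 = "matrix",
    n_pairs = "matrix", population = "character"))

setValidity("CorrelationMatrix", function(object) {
    r2 <- object@r2
    if (nrow(r2) != ncol(r2)) return("r2 must be square")
    ok <- r2[!is.na(r2)]
    if (length(ok) && (min(ok) < -1e-8 || max(ok) > 1 + 1e-8))
        return("r2 values must lie in [0, 1]")
    if (max(abs(r2 - t(r2)), na.rm = TRUE) > 1e-8) return("r2 must be symmetric")
    TRUE
})

#' Principal component analysis result
#'
#' @slot scores sample-by-component score matrix.
#' @slot loadings feature-by-component loading matrix (orthonormal columns).
#' @slot varianceExplained fraction of total variance per component,
#'   non-increasing, summing to 1 at full rank.
#' @slot mode standardization applied: \code{"genotype"} (center by twice the
#'   allele frequency, scale by the binomial SD) or \code{"quantitative"}
#'   (column z-score).
#' @slot dropped IDs of constant columns removed before decomposition.
#' @export
setClass("PcaResult", representation(scores = "matrix", loadings = "matrix",
    varianceExplained = "numeric", mode = "character", dropped = "character"))

setValidity("PcaResult", function(object) {
    v <- object@varianceExplained
    if (length(v)) {
        if (any(v < -1e-12)) return("varianceExplained must be non-negative")
        if (any(diff(v) > 1e-8)) return("varianceExplained must be non-increasing")
        if (sum(v) > 1 + 1e-6) return("varianceExplained must sum to <= 1")
    }
    TRUE
})

#' Synthetic cohort design
#'
#' Parameters of the three-population synthetic cohort generator. Defaults
#' mirror the cohort the analysis is designed for: 122/120/122 Chinese, Malay
#' and Indian samples, a divergence parameter of 0.01 matching genome-wide
#' pairwise differentiation of one to a few percent, lipid blocks correlated
#' at the tagging threshold r^2 = 0.8, and planted group shifts of 1.5
#' within-group standard deviations.
#'
#' @slot n_per_pop integer sample counts per population.
#' @slot pop_labels ordered population labels (k = 3 by default).
#' @slot n_snps number of simulated biallelic SNPs.
#' @slot fst_target Balding-Nichols divergence parameter F in (0, 1).
#' @slot n_hla_loci,alleles_per_locus multi-allelic (HLA-like) loci layout.
#' @slot n_lipids,n_expression,n_mirna feature counts per quantitative platform.
#' @slot n_blocks number of correlated lipid blocks.
#' @slot block_r2 within-block pairwise squared-correlation target in (0, 1).
#' @slot n_diff_features features per platform receiving a true group shift.
#' @slot effect_size group mean shift in within-group SD units.
#' @slot missing_rate per-entry missingness probability in [0, 1).
#' @slot snp_stride base-pair spacing of consecutive SNPs (fixed stride, so
#'   100-kb windows hold a deterministic number of SNPs).
#' @slot snps_per_chrom SNPs placed on each synthetic chromosome.
#' @slot seed integer seed; a fixed seed yields a byte-identical cohort.
#' @seealso [cohortDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign", representation(
    n_per_pop = "integer", pop_labels = "character", n_snps = "integer",
    fst_target = "numeric", n_hla_loci = "integer",
    alleles_per_locus = "integer", n_lipids = "integer",
    n_expression = "integer", n_mirna = "integer", n_blocks = "integer",
    block_r2 = "numeric", n_diff_features = "integer", effect_size = "numeric",
    missing_rate = "numeric", snp_stride = "integer",
    snps_per_chrom = "integer", seed = "integer"))

setValidity("CohortDesign", function(object) {
    msg <- NULL
    if (length(object@n_per_pop) != length(object@pop_labels))
        msg <- c(msg, "n_per_pop and pop_labels lengths differ")
    counts <- c(object@n_per_pop, object@n_snps, object@n_hla_loci,
        object@alleles_per_locus, object@n_lipids, object@n_expression,
        object@n_mirna, object@n_blocks, object@snp_stride,
        object@snps_per_chrom)
    if (any(counts <= 0)) msg <- c(msg, "all counts must be positive")
    if (any(object@fst_target <= 0 | object@fst_target >= 1))
        msg <- c(msg, "fst_target must lie in (0, 1)")
    if (object@block_r2 <= 0 || object@block_r2 >= 1)
        msg <- c(msg, "block_r2 must lie in (0, 1)")
    if (object@missing_rate < 0 || object@missing_rate >= 1)
        msg <- c(msg, "missing_rate must lie in [0, 1)")
    if (object@n_diff_features < 0) msg <- c(msg, "n_diff_features must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic multi-omics cohort
#'
#' Bundle of the simulated platforms sharing one sample set: genotypes (a
#' \linkS4class{GenotypeExperiment}), an HLA-like multi-allelic table, and
#' lipid / expression / miRNA \linkS4class{OmicsExperiment}s, plus a
#' \code{truth} list recording what was planted (per-feature group shifts,
#' lipid block membership, the divergence parameter).
#'
#' @slot design the generating \linkS4class{CohortDesign}.
#' @slot genotypes \linkS4class{GenotypeExperiment}.
#' @slot hla data.frame with columns sample, locus, allele1, allele2.
#' @slot lipids,expression,mirna \linkS4class{OmicsExperiment} per platform.
#' @slot truth list of simulation ground truth.
#' @export
setClass("SyntheticCohort", representation(design = "CohortDesign",
    genotypes = "GenotypeExperiment", hla = "data.frame",
    lipids = "OmicsExperiment", expression = "OmicsExperiment",
    mirna = "OmicsExperiment", truth = "list"))

setValidity("SyntheticCohort", function(object) {
    ids <- colnames(object@genotypes)
    same <- function(x) identical(sort(colnames(x)), sort(ids))
    if (!same(object@lipids) || !same(object@expression) || !same(object@mirna))
        return("sample sets must be consistent across platforms")
    if (!all(object@hla$sample %in% ids))
        return("HLA samples must come from the cohort sample set")
    TRUE
})
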