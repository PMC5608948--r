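#' Pipeline configuration
#'
#' Assembles the default thresholds of every stage into one list; any entry
#' can be overridden, or loaded from a YAML/JSON file.
#'
#' @param ... overrides of the defaults.
#' @param file optional YAML or JSON config file whose entries are applied
#'   before \code{...}.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(..., file = NULL) {
    cfg <- list(
        seed = 1L,
        snp_miss = 0.05,      # SNP missingness > 5% removed
        sample_miss = 0.02,   # sample missingness > 2% removed
        hwe_p = 1e-3,         # HWE exact p < 1e-3 in any population removed
        callrate = 0.9,       # miRNA call rate <= 90% removed
        var_miss = 0.2,       # clinical/feature missingness > 20% removed
        window = 100000L,     # window size for the region scan
        high_quantile = 0.01, # top 1% of F_ST defines "high"
        emp_p = 1e-4,         # empirical p flag threshold
        tag_r2 = 0.8,         # tagging threshold
        alpha = 0.05,         # significance level (Bonferroni-corrected)
        pca_components = 10L)
    if (!is.null(file)) {
        loaded <- if (grepl("\\.json$", file))
            jsonlite::read_json(file, simplifyVector = TRUE)
        else yaml::read_yaml(file)
        cfg <- modifyList(cfg, loaded)
    }
    modifyList(cfg, list(...))
}

#' Run the analysis pipeline on a synthetic cohort
#'
#' End-to-end wiring of the stages: simulate a cohort, apply the QC cascade
#' to every platform, compute per-SNP F_ST with empirical p-values against
#' the genome-wide null, run the binomial window scan, the per-platform
#' group contrasts, lipid tagging per population, and PCAs. Every stage
#' writes TSV artifacts into \code{output_dir} and is recorded in a JSON
#' manifest (inputs, thresholds, seed, package version, output files).
#'
#' @param config list from [pipelineConfig()].
#' @param stage one of "simulate", "qc", "fst", "scan", "contrast", "tag",
#'   "pca", "all". Stages other than "simulate" run on the (re)simulated
#'   cohort, so a fixed seed makes every artifact reproducible.
#' @param output_dir directory for artifacts (created if needed).
#' @param design optional \linkS4class{CohortDesign}; defaults to
#'   \code{cohortDesign(seed = config$seed)}.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), stage = "all",
                        output_dir = tempfile("popdiverge_"),
                        design = NULL) {
    stage <- match.arg(stage, c("simulate", "qc", "fst", "scan", "contrast",
                                "tag", "pca", "all"))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    design <- design %||% cohortDesign(seed = as.integer(config$seed))
    manifest <- list(seed = config$seed, thresholds = config,
                     stages = list(), outputs = character())
    emit <- function(name, writer) {
        path <- file.path(output_dir, name)
        writer(path)
        manifest$outputs <<- c(manifest$outputs, name)
        path
    }
    results <- list()

    cohort <- simulateCohort(design)
    results$cohort <- cohort
    manifest$stages$simulate <- list(
        n_samples = ncol(cohort@genotypes), n_snps = nrow(cohort@genotypes))
    if (stage %in% c("simulate", "all")) {
        emit("genotypes.vcf", function(p) writeGenotypeVcf(cohort@genotypes, p))
        emit("dosages.tsv", function(p) writeDosageTsv(cohort@genotypes, p))
        emit("hla.tsv", function(p) write.table(cohort@hla, p, sep = "\t",
            quote = FALSE, row.names = FALSE))
        for (pl in c("lipid", "expression", "mirna")) {
            oe <- cohortPlatform(cohort, pl)
            emit(paste0(pl, "_matrix.tsv"), function(p) write.table(
                data.frame(feature = rownames(oe), assay(oe, "log2"),
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
        }
        emit("covariates.tsv", function(p) write.table(
            data.frame(sample = colnames(cohort@lipids),
                       as.data.frame(colData(cohort@lipids))),
            p, sep = "\t", quote = FALSE, row.names = FALSE))
        if (stage == "simulate")
            return(invisible(.finishManifest(manifest, output_dir, results)))
    }

    ge <- filterSampleMissingness(cohort@genotypes, config$sample_miss)
    ge <- filterSnpMissingness(ge, config$snp_miss)
    ge <- filterHwe(ge, config$hwe_p)
    mirna <- filterCallRate(cohort@mirna, config$callrate, "feature",
                            "call_rate")
    results$genotypes_qc <- ge
    results$mirna_qc <- mirna
    manifest$stages$qc <- list(
        genotype = as.list(qcSteps(qcReport(ge))),
        mirna = as.list(qcSteps(qcReport(mirna))))
    if (stage %in% c("qc", "all"))
        emit("qc_report.tsv", function(p) writeQcReport(qcReport(ge), p))
    if (stage == "qc")
        return(invisible(.finishManifest(manifest, output_dir, results)))

    if (stage %in% c("fst", "scan", "all")) {
        fq <- frequenciesFromGenotypes(ge)
        usable <- !fq$incomplete
        ft <- fstTable(fq$freq[usable, , drop = FALSE])
        ft$p_empirical <- empiricalPvalue(ft$fst, ft$fst)
        ft$flagged <- ft$p_empirical < config$emp_p
        results$fst <- ft
        manifest$stages$fst <- list(n_variants = nrow(ft),
            mean_fst = mean(ft$fst))
        emit("fst.tsv", function(p) write.table(ft, p, sep = "\t",
            quote = FALSE, row.names = FALSE))
        hla_freq <- hlaOneVsRest(cohort@hla,
            setNames(as.character(population(ge)), colnames(ge)))
        results$fst_hla <- fstTable(hla_freq)
        emit("fst_hla.tsv", function(p) write.table(results$fst_hla, p,
            sep = "\t", quote = FALSE, row.names = FALSE))

        rr <- rowRanges(ge)[usable]
        scan <- scanRegions(ft$fst, as.character(seqnames(rr)), start(rr),
            high_quantile = config$high_quantile, alpha = config$alpha,
            window_size = config$window, driving_pair = ft$driving_pair)
        results$scan <- scan
        manifest$stages$scan <- list(n_windows = nrow(scan$windows),
            n_regions = nrow(scan$regions))
        emit("windows.tsv", function(p) write.table(scan$windows, p,
            sep = "\t", quote = FALSE, row.names = FALSE))
        emit("regions.bed", function(p) writeRegionsBed(scan$regions, p))
    }
    if (stage %in% c("fst", "scan"))
        return(invisible(.finishManifest(manifest, output_dir, results)))

    if (stage %in% c("contrast", "all")) {
        results$contrast <- list()
        for (pl in c("lipid", "expression", "mirna")) {
            oe <- if (pl == "mirna") mirna else cohortPlatform(cohort, pl)
            ct <- platformContrast(oe, alpha = config$alpha)
            results$contrast[[pl]] <- ct
            manifest$stages[[paste0("contrast_", pl)]] <- list(
                m = attr(ct, "m"), n_significant = sum(ct$significant))
            emit(paste0("contrast_", pl, ".tsv"), function(p) write.table(
                ct, p, sep = "\t", quote = FALSE, row.names = FALSE))
        }
    }
    if (stage == "contrast")
        return(invisible(.finishManifest(manifest, output_dir, results)))

    if (stage %in% c("tag", "all")) {
        reports <- lapply(design@pop_labels, function(p)
            selectTags(pairwiseR2(cohort@lipids, p), config$tag_r2))
        results$tags <- reports
        summ <- tagSummary(reports)
        manifest$stages$tag <- as.list(setNames(summ$n_representative,
                                                summ$population))
        emit("tag_summary.tsv", function(p) write.table(summ, p, sep = "\t",
            quote = FALSE, row.names = FALSE))
        for (i in seq_along(reports))
            emit(paste0("tags_", design@pop_labels[i], ".tsv"),
                 function(p) write.table(tagAssignments(reports[[i]]), p,
                     sep = "\t", quote = FALSE, row.names = FALSE))
    }
    if (stage == "tag")
        return(invisible(.finishManifest(manifest, output_dir, results)))

    if (stage %in% c("pca", "all")) {
        results$pca <- list(
            genotype = runPca(ge, mode = "genotype"),
            lipid = runPca(cohort@lipids))
        for (nm in names(results$pca)) {
            pr <- results$pca[[nm]]
            k <- min(config$pca_components, ncol(pcaScores(pr)))
            emit(paste0("pca_", nm, "_scores.tsv"), function(p) write.table(
                data.frame(sample = rownames(pcaScores(pr)),
                           pcaScores(pr)[, seq_len(k), drop = FALSE]),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
        }
        manifest$stages$pca <- lapply(results$pca, function(pr)
            list(pc1_variance = varianceExplained(pr)[1L]))
    }
    invisible(.finishManifest(manifest, output_dir, results))
}

.finishManifest <- function(manifest, output_dir, results) {
    manifest$package_version <-
        as.character(utils::packageVersion("popDiverge"))
    path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
    list(results = results, manifest = manifest, output_dir = output_dir)
}
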