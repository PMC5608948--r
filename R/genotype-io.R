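#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) and maps diploid GT calls to
#' alternate-allele dosages: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. ->
#' missing. Phased separators are accepted. Multi-allelic records are
#' rejected with a message naming the variants.
#'
#' @param path VCF file.
#' @param population per-sample population labels: a named vector indexed by
#'   sample ID, or a two-column file (sample, population) given as a path.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
readGenotypeVcf <- function(path, population) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                  dimnames = dimnames(vcfR::getFIX(v)))
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
        stop("multi-allelic records are not supported: ",
             paste(head(fix[multi, "ID"], 5L), collapse = ", "),
             call. = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    gt_clean <- gsub("\\|", "/", gt)
    dos[gt_clean == "0/0"] <- 0
    dos[gt_clean %in% c("0/1", "1/0")] <- 1
    dos[gt_clean == "1/1"] <- 2
    bad <- !is.na(gt_clean) & !gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
    if (any(bad))
        stop("unsupported GT value(s): ",
             paste(unique(gt_clean[bad])[1:min(5, sum(bad))], collapse = ", "),
             call. = FALSE)
    if (is.character(population) && length(population) == 1L &&
        file.exists(population)) {
        tab <- read.delim(population, stringsAsFactors = FALSE)
        population <- setNames(tab[[2L]], tab[[1L]])
    }
    pop <- if (!is.null(names(population)))
        population[colnames(dos)] else population
    genotypeExperiment(dos, chrom = fix[, "CHROM"],
        pos = as.integer(fix[, "POS"]), population = pop,
        ref = fix[, "REF"], alt = fix[, "ALT"])
}

#' Write genotypes as a minimal VCF v4.2
#'
#' Emits the nine fixed columns plus per-sample GT fields (0/0, 0/1, 1/1,
#' ./.). Alleles default to A/G when the object carries none.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param path output file.
#' @export
writeGenotypeVcf <- function(ge, path) {
    rr <- rowRanges(ge)
    mc <- S4Vectors::mcols(rr)
    ref <- if ("ref" %in% names(mc)) mc$ref else rep("A", nrow(ge))
    alt <- if ("alt" %in% names(mc)) mc$alt else rep("G", nrow(ge))
    dos <- dosage(ge)
    gt <- matrix("./.", nrow(dos), ncol(dos))
    gt[!is.na(dos) & dos == 0] <- "0/0"
    gt[!is.na(dos) & dos == 1] <- "0/1"
    gt[!is.na(dos) & dos == 2] <- "1/1"
    body <- cbind(as.character(seqnames(rr)), start(rr), rownames(ge),
                  ref, alt, ".", "PASS", ".", "GT", gt)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(ge)), collapse = "\t")), con)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read a dosage matrix from TSV
#'
#' Expects samples as rows: a first column of sample IDs, then one column
#' per SNP, missing encoded as \code{NA}.
#'
#' @param path dosage TSV.
#' @param population per-sample labels (named vector or path, as in
#'   [readGenotypeVcf()]).
#' @param chrom,pos optional SNP coordinates; defaults place SNPs at a 10-kb
#'   stride on one synthetic chromosome.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
readDosageTsv <- function(path, population, chrom = NULL, pos = NULL) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- tab[[1L]]
    m <- t(as.matrix(tab[, -1L, drop = FALSE]))  # SNP x sample
    colnames(m) <- ids
    if (is.character(population) && length(population) == 1L &&
        file.exists(population)) {
        lab <- read.delim(population, stringsAsFactors = FALSE)
        population <- setNames(lab[[2L]], lab[[1L]])
    }
    pop <- if (!is.null(names(population))) population[ids] else population
    genotypeExperiment(m,
        chrom = chrom %||% rep("chr1", nrow(m)),
        pos = pos %||% ((seq_len(nrow(m)) - 1L) * 10000L + 1L),
        population = pop)
}

#' Write a dosage matrix as TSV (samples as rows)
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param path output file.
#' @export
writeDosageTsv <- function(ge, path) {
    m <- t(dosage(ge))
    out <- data.frame(sample = rownames(m), m, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a QC report as TSV or JSON
#'
#' @param qc a \linkS4class{QcReport}.
#' @param path output file; format chosen by extension (.json or .tsv).
#' @export
writeQcReport <- function(qc, path) {
    if (grepl("\\.json$", path)) {
        jsonlite::write_json(qcSteps(qc), path, dataframe = "rows",
                             auto_unbox = TRUE, digits = NA, na = "null")
    } else {
        write.table(qcSteps(qc), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}
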