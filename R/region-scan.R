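#' Assign SNPs to non-overlapping windows
#'
#' A SNP at 1-based position pos on a chromosome falls in window index
#' floor((pos - 1) / window_size); windows tile each chromosome as 0-based
#' half-open intervals [i*W, (i+1)*W) without overlap.
#'
#' @param chrom chromosome per SNP.
#' @param pos 1-based position per SNP (positive integers).
#' @param window_size window width in base pairs (default 100 kb).
#' @return data.frame with columns chrom, window (0-based index), start, end
#'   (0-based half-open window interval), one row per SNP.
#' @examples
#' assignWindows(c("chr1", "chr1"), c(100000, 100001))  # windows 0 and 1
#' @export
assignWindows <- function(chrom, pos, window_size = 100000L) {
    pos <- as.numeric(pos)
    if (any(pos < 1)) stop("positions must be positive (1-based)", call. = FALSE)
    w <- floor((pos - 1) / window_size)
    data.frame(chrom = as.character(chrom), window = as.integer(w),
               start = w * window_size, end = (w + 1) * window_size,
               stringsAsFactors = FALSE)
}

#' Binomial over-representation tail probability
#'
#' Upper-tail probability P(X >= n_high) for X ~ Binomial(n_snps, q),
#' computed by exact summation of the probability mass function. Used to
#' quantify enrichment of high-F_ST SNPs in a genomic window against the
#' genome-wide background fraction q.
#'
#' @param n_snps number of SNPs in the window (vectorized).
#' @param n_high number of high-F_ST SNPs among them.
#' @param q background probability that a SNP is high-F_ST, in (0, 1).
#' @return tail probability in [0, 1]; \code{n_high = 0} gives exactly 1.
#' @examples
#' binomialTail(10, 3, 0.1)   # 0.0702
#' binomialTail(10, 10, 0.5)  # 2^-10
#' @export
binomialTail <- function(n_snps, n_high, q) {
    .assertProb(q, "q")
    if (any(n_high < 0 | n_high > n_snps))
        stop("need 0 <= n_high <= n_snps", call. = FALSE)
    n_snps <- as.integer(n_snps); n_high <- as.integer(n_high)
    mapply(function(n, x, qq) {
        if (x == 0L) return(1)
        sum(dbinom(x:n, n, qq))
    }, n_snps, n_high, q)
}

#' Window scan for regions enriched in high-F_ST SNPs
#'
#' Tiles each chromosome into non-overlapping windows, calls a SNP "high"
#' when its F_ST exceeds the (1 - high_quantile) quantile of the genome-wide
#' distribution, and tests every occupied window for over-representation
#' with the exact binomial tail at the realized genome-wide high fraction q.
#' A window is significant when its tail probability falls below
#' alpha / (number of occupied windows) (Bonferroni); runs of adjacent
#' significant windows on a chromosome are merged into regions. Each
#' window's driving pair is the majority driving pair of its high-F_ST SNPs.
#'
#' @param fst per-SNP F_ST values.
#' @param chrom,pos per-SNP chromosome and 1-based position.
#' @param high_quantile upper tail fraction defining "high" F_ST
#'   (default 0.01, the top 1\%).
#' @param alpha family-wise significance level before Bonferroni
#'   (default 0.05).
#' @param window_size window width in bp (default 100 kb).
#' @param driving_pair optional per-SNP driving-pair labels, majority-voted
#'   per window.
#' @return list with \code{windows} (per occupied window: chrom, window,
#'   start, end, n_snps, n_high, q, p, significant, driving_pair),
#'   \code{regions} (merged significant windows as 0-based half-open
#'   intervals with n_windows and min p), \code{threshold} (the F_ST cut)
#'   and \code{q}.
#' @export
scanRegions <- function(fst, chrom, pos, high_quantile = 0.01, alpha = 0.05,
                        window_size = 100000L, driving_pair = NULL) {
    ok <- !is.na(fst)
    fst <- fst[ok]; chrom <- chrom[ok]; pos <- pos[ok]
    if (!is.null(driving_pair)) driving_pair <- driving_pair[ok]
    wa <- assignWindows(chrom, pos, window_size)
    key <- paste(wa$chrom, wa$window)
    if (length(unique(key)) < 2L)
        stop("need at least 2 occupied windows to scan", call. = FALSE)
    cut <- quantile(fst, 1 - high_quantile, names = FALSE)
    high <- fst > cut
    q <- mean(high)
    if (q <= 0)
        stop("no SNP exceeds the high-F_ST threshold; nothing to scan",
             call. = FALSE)

    idx <- split(seq_along(fst), key)
    windows <- do.call(rbind, lapply(idx, function(i) {
        dp <- NA_character_
        if (!is.null(driving_pair) && any(high[i])) {
            tab <- sort(table(driving_pair[i][high[i]]), decreasing = TRUE)
            dp <- names(tab)[1L]
        }
        data.frame(chrom = wa$chrom[i[1L]], window = wa$window[i[1L]],
                   start = wa$start[i[1L]], end = wa$end[i[1L]],
                   n_snps = length(i), n_high = sum(high[i]),
                   driving_pair = dp, stringsAsFactors = FALSE)
    }))
    windows$q <- q
    windows$p <- binomialTail(windows$n_snps, windows$n_high, q)
    n_tested <- nrow(windows)
    windows$significant <- windows$p < alpha / n_tested
    windows <- windows[order(windows$chrom, windows$window), ]
    rownames(windows) <- NULL

    regions <- .mergeAdjacentWindows(windows[windows$significant, ])
    list(windows = windows, regions = regions, threshold = cut, q = q,
         n_tested = n_tested)
}

# maximal runs of adjacent significant windows on one chromosome
.mergeAdjacentWindows <- function(sig) {
    if (!nrow(sig))
        return(data.frame(chrom = character(), start = numeric(),
            end = numeric(), n_windows = integer(), min_p = numeric(),
            stringsAsFactors = FALSE))
    sig <- sig[order(sig$chrom, sig$window), ]
    new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 diff(sig$window) != 1L)
    run <- cumsum(new_run)
    do.call(rbind, lapply(split(sig, run), function(s) {
        data.frame(chrom = s$chrom[1L], start = min(s$start),
                   end = max(s$end), n_windows = nrow(s), min_p = min(s$p),
                   stringsAsFactors = FALSE)
    }))
}

#' Write significant regions as BED
#'
#' 0-based half-open intervals, one line per merged region.
#'
#' @param regions the \code{regions} element of a [scanRegions()] result.
#' @param path output file.
#' @export
writeRegionsBed <- function(regions, path) {
    bed <- data.frame(chrom = regions$chrom,
                      start = format(regions$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(regions$end, scientific = FALSE,
                                   trim = TRUE),
                      name = sprintf("region_%d", seq_len(nrow(regions))),
                      score = ifelse(regions$min_p <= 0, 1000,
                          pmin(1000, round(-10 * log10(regions$min_p)))))
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
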