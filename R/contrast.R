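#' Covariate-adjusted ANOVA for one feature
#'
#' Tests the null hypothesis that the mean level of a feature is identical
#' across the population groups, adjusting for covariates, via the partial
#' F-test comparing \code{y ~ population + covariates} against
#' \code{y ~ covariates}. With no interaction terms this equals the Type-III
#' test for the population factor. Samples with missing \code{y} are dropped
#' featurewise.
#'
#' @param y numeric feature vector (log2 scale for omics platforms).
#' @param population factor of group labels.
#' @param covariates optional data.frame of covariate factors (and/or
#'   numeric covariates) aligned with \code{y}.
#' @return list with \code{statistic} (F), \code{p_value}, \code{df},
#'   \code{fit} (the full \code{lm}), \code{n} used; or NULL-statistic with
#'   \code{skipped = TRUE} when a population has fewer than 2 observations.
#' @export
anovaFeature <- function(y, population, covariates = NULL) {
    population <- factor(population)
    dat <- data.frame(y = y, population = population)
    cov_names <- character()
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        cov_names <- names(covariates)
        dat <- cbind(dat, covariates)
    }
    dat <- dat[!is.na(dat$y), , drop = FALSE]
    dat$population <- droplevels(dat$population)
    tab <- table(dat$population)
    if (nlevels(population) != length(tab) || any(tab < 2L))
        return(list(statistic = NA_real_, p_value = NA_real_, fit = NULL,
                    n = nrow(dat), skipped = TRUE))
    rhs_cov <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
    full <- lm(as.formula(paste("y ~ population +", rhs_cov)), data = dat)
    .checkCollinearity(full, cov_names)
    reduced <- lm(as.formula(paste("y ~", rhs_cov)), data = dat)
    an <- anova(reduced, full)
    list(statistic = an$F[2L], p_value = an$`Pr(>F)`[2L],
         df = c(an$Df[2L], an$Res.Df[2L]), fit = full, n = nrow(dat),
         skipped = FALSE)
}

# error naming the covariate(s) aliased with the population factor
.checkCollinearity <- function(fit, cov_names) {
    if (!any(is.na(coef(fit)))) return(invisible())
    bad <- names(coef(fit))[is.na(coef(fit))]
    hit <- cov_names[vapply(cov_names, function(cn)
        any(startsWith(bad, cn)), TRUE)]
    stop("collinear design: covariate(s) ",
         paste(unique(c(hit, bad)), collapse = ", "),
         " aliased with the model", call. = FALSE)
}

#' Least-squares means per population
#'
#' Model-predicted group means with every other factor balanced: the fitted
#' model is evaluated on the grid of all factor-level combinations (with any
#' continuous covariate held at its mean) and predictions are averaged
#' within each population level. In a balanced design this reduces to the
#' raw group means.
#'
#' @param fit an \code{lm} fit containing a \code{population} term, e.g.
#'   from [anovaFeature()].
#' @param factor_name name of the grouping factor (default "population").
#' @return named numeric vector of least-squares means, one per level.
#' @export
leastSquaresMeans <- function(fit, factor_name = "population") {
    mf <- model.frame(fit)
    vars <- attr(terms(fit), "term.labels")
    grid_vars <- lapply(setNames(vars, vars), function(v) {
        x <- mf[[v]]
        if (is.factor(x) || is.character(x)) levels(factor(x)) else mean(x)
    })
    grid <- expand.grid(grid_vars, stringsAsFactors = TRUE)
    pred <- predict(fit, newdata = grid)
    if (anyNA(pred))
        stop("unestimable factor level in least-squares means", call. = FALSE)
    lsm <- tapply(pred, grid[[factor_name]], mean)
    setNames(as.numeric(lsm), names(lsm))
}

#' Fold change between two least-squares means
#'
#' For log2-scale data, log2 FC(a - b) = lsm_a - lsm_b, so the natural-scale
#' fold change is FC = 2^(lsm_a - lsm_b).
#'
#' @param lsm_a,lsm_b least-squares means on the log2 scale.
#' @return fold-change ratio (unitless).
#' @examples
#' foldChange(17.52, 18.04)  # 0.70: the group at lsm_a runs ~30% lower
#' @export
foldChange <- function(lsm_a, lsm_b) {
    if (!all(is.finite(lsm_a)) || !all(is.finite(lsm_b)))
        stop("least-squares means must be finite", call. = FALSE)
    2^(lsm_a - lsm_b)
}

#' Per-feature group contrasts for one platform
#'
#' Runs [anovaFeature()] on every feature of a platform matrix, applies a
#' within-platform Bonferroni correction (m = number of features actually
#' tested), computes least-squares means per population, all ordered
#' pairwise fold changes, and attributes each feature to the population pair
#' with the largest absolute lsm difference (ties broken by the fixed pair
#' order).
#'
#' @param oe an \linkS4class{OmicsExperiment} (post-QC).
#' @param covariates covariate column names of \code{colData(oe)} to adjust
#'   for (default the intersection of c("sex", "batch") with what is
#'   present). Samples with a missing covariate are dropped platform-wide.
#' @param alpha significance level on the Bonferroni-corrected p-value.
#' @return data.frame with one row per feature: feature, n, F statistic,
#'   p_raw, p_bonferroni, lsm_<pop> per population, fc_<a>_<b> per ordered
#'   pair, driving_pair, significant, skipped.
#' @export
platformContrast <- function(oe, covariates = NULL, alpha = 0.05) {
    if (!nrow(oe)) stop("empty platform matrix", call. = FALSE)
    cd <- as.data.frame(colData(oe))
    if (is.null(covariates))
        covariates <- intersect(c("sex", "batch"), names(cd))
    keep <- rep(TRUE, ncol(oe))
    for (cv in covariates) keep <- keep & !is.na(cd[[cv]])
    oe_use <- oe[, keep]
    cd <- cd[keep, , drop = FALSE]
    y <- assay(oe_use, "log2")
    pop <- factor(cd$population)
    pops <- levels(pop)
    covs <- if (length(covariates)) cd[covariates] else NULL

    pairs <- utils::combn(pops, 2L)
    res <- lapply(seq_len(nrow(y)), function(i) {
        af <- anovaFeature(y[i, ], pop, covs)
        lsm <- rep(NA_real_, length(pops))
        names(lsm) <- pops
        if (!af$skipped) lsm[] <- leastSquaresMeans(af$fit)[pops]
        c(list(feature = rownames(y)[i], n = af$n, statistic = af$statistic,
               p_raw = af$p_value, skipped = af$skipped), as.list(lsm))
    })
    out <- data.frame(feature = vapply(res, `[[`, "", "feature"),
        n = vapply(res, `[[`, 0, "n"),
        statistic = vapply(res, `[[`, 0, "statistic"),
        p_raw = vapply(res, `[[`, 0, "p_raw"),
        skipped = vapply(res, `[[`, TRUE, "skipped"),
        stringsAsFactors = FALSE)
    for (p in pops) out[[paste0("lsm_", p)]] <- vapply(res, `[[`, 0, p)

    m <- sum(!out$skipped)
    out$p_bonferroni <- pmin(1, m * out$p_raw)
    for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        out[[paste0("fc_", a, "_", b)]] <-
            2^(out[[paste0("lsm_", a)]] - out[[paste0("lsm_", b)]])
        out[[paste0("fc_", b, "_", a)]] <-
            2^(out[[paste0("lsm_", b)]] - out[[paste0("lsm_", a)]])
    }
    lsm_mat <- as.matrix(out[paste0("lsm_", pops)])
    diffs <- abs(lsm_mat[, paste0("lsm_", pairs[1L, ]), drop = FALSE] -
                 lsm_mat[, paste0("lsm_", pairs[2L, ]), drop = FALSE])
    best <- max.col(replace(diffs, is.na(diffs), -Inf), ties.method = "first")
    out$driving_pair <- paste(pairs[1L, best], pairs[2L, best], sep = "-")
    out$driving_pair[out$skipped] <- NA_character_
    out$significant <- !out$skipped & out$p_bonferroni < alpha
    attr(out, "m") <- m
    attr(out, "covariates") <- covariates
    out
}
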