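#' Within-population pairwise squared correlations
#'
#' Squared Pearson correlation between every pair of features, computed on
#' log2 values within a single population using pairwise complete
#' observations. Zero-variance features get \code{NA} rows/columns and are
#' forced to singletons downstream.
#'
#' @param x an \linkS4class{OmicsExperiment} or a feature-by-sample matrix.
#' @param population population to subset to (required when \code{x} carries
#'   several); NULL uses all samples.
#' @param min_n minimum complete-case pairs per correlation (default 3);
#'   pairs below it are \code{NA}.
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
pairwiseR2 <- function(x, population = NULL, min_n = 3L) {
    if (is(x, "SummarizedExperiment")) {
        if (!is.null(population)) {
            keep <- as.character(colData(x)$population) == population
            x <- x[, keep]
        }
        m <- assay(x, "log2")
    } else {
        m <- as.matrix(x)
    }
    if (ncol(m) < min_n)
        stop("need at least ", min_n, " samples", call. = FALSE)
    tm <- t(m)  # samples x features
    n_pairs <- crossprod(!is.na(tm) * 1L)
    r <- suppressWarnings(cor(tm, use = "pairwise.complete.obs"))
    r2 <- r^2
    r2[n_pairs < min_n] <- NA_real_
    # zero-variance features: undefined correlations, but self-r2 is 1
    diag(r2) <- 1
    new("CorrelationMatrix", r2 = r2, n_pairs = n_pairs,
        population = population %||% "all")
}

#' Greedy selection of tagging features
#'
#' Builds the above-threshold adjacency from a squared-correlation matrix
#' and greedily covers it: repeatedly pick the feature with the most
#' not-yet-covered neighbors above the threshold (ties resolved by larger
#' mean r^2 to those neighbors, then lexicographic feature ID) as a tag; its
#' uncovered above-threshold neighbors become tagged by it. Features left
#' with no above-threshold neighbor are singletons: they represent
#' themselves. With \code{mode = "transitive"} the above-threshold graph's
#' connected components are covered instead (one tag per component, the
#' member with the highest degree).
#'
#' @param corr a \linkS4class{CorrelationMatrix} (e.g. from [pairwiseR2()]).
#' @param threshold squared-correlation threshold; tagging requires
#'   r^2 strictly above it (default 0.8).
#' @param mode "direct" (default): every tagged feature must itself exceed
#'   the threshold with its tag; "transitive": cluster by graph
#'   connectivity.
#' @return A \linkS4class{TagReport}.
#' @examples
#' r2 <- matrix(c(1, .9, .5, .9, 1, .9, .5, .9, 1), 3,
#'     dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' cm <- new("CorrelationMatrix", r2 = r2,
#'     n_pairs = matrix(10L, 3, 3), population = "demo")
#' tagCounts(selectTags(cm))  # B tags A and C
#' @export
selectTags <- function(corr, threshold = 0.8, mode = c("direct", "transitive")) {
    mode <- match.arg(mode)
    r2 <- corr@r2
    feats <- rownames(r2) %||% paste0("f", seq_len(nrow(r2)))
    dimnames(r2) <- list(feats, feats)
    adj <- !is.na(r2) & r2 > threshold
    diag(adj) <- FALSE

    role <- setNames(rep("singleton", length(feats)), feats)
    tag_of <- setNames(feats, feats)       # singletons/tags represent themselves
    r2_to_tag <- setNames(rep(NA_real_, length(feats)), feats)

    if (mode == "transitive") {
        comp <- .connectedComponents(adj)
        for (members in comp) {
            if (length(members) < 2L) next
            deg <- rowSums(adj[members, members, drop = FALSE])
            mean_r2 <- rowMeans(r2[members, members, drop = FALSE],
                                na.rm = TRUE)
            ord <- order(-deg, -mean_r2, members)
            tag <- members[ord[1L]]
            rest <- setdiff(members, tag)
            role[tag] <- "tag"; role[rest] <- "tagged"
            tag_of[rest] <- tag
            r2_to_tag[rest] <- r2[rest, tag]
        }
    } else {
        uncovered <- setNames(rep(TRUE, length(feats)), feats)
        repeat {
            cand <- feats[uncovered]
            deg <- vapply(cand, function(f)
                sum(adj[f, ] & uncovered), 0L)
            if (!length(deg) || max(deg) == 0L) break
            top <- cand[deg == max(deg)]
            if (length(top) > 1L) {
                mr <- vapply(top, function(f) {
                    nb <- adj[f, ] & uncovered
                    mean(r2[f, nb])
                }, 0)
                top <- top[order(-mr, top)]
            }
            tag <- top[1L]
            members <- feats[adj[tag, ] & uncovered]
            role[tag] <- "tag"
            role[members] <- "tagged"
            tag_of[members] <- tag
            r2_to_tag[members] <- r2[members, tag]
            uncovered[c(tag, members)] <- FALSE
        }
    }
    new("TagReport", population = corr@population, threshold = threshold,
        assignments = data.frame(feature = feats, role = unname(role[feats]),
            tag = unname(tag_of[feats]), r2_to_tag = unname(r2_to_tag[feats]),
            stringsAsFactors = FALSE))
}

# connected components of a logical adjacency matrix (BFS)
.connectedComponents <- function(adj) {
    feats <- rownames(adj)
    seen <- setNames(rep(FALSE, length(feats)), feats)
    comps <- list()
    for (f in feats) {
        if (seen[f]) next
        queue <- f; members <- character()
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            if (seen[v]) next
            seen[v] <- TRUE
            members <- c(members, v)
            queue <- c(queue, feats[adj[v, ] & !seen])
        }
        comps[[length(comps) + 1L]] <- sort(members)
    }
    comps
}

#' Representative-set bookkeeping
#'
#' If n_tags tagging features represent a set of n_cluster_members features
#' (a count that includes the tags themselves), the whole panel of K
#' features is summarized by K - (n_cluster_members - n_tags)
#' representatives: the tags plus every feature outside the clusters.
#'
#' @param K total number of features.
#' @param n_cluster_members features inside multi-feature clusters,
#'   including their tags.
#' @param n_tags number of tagging features.
#' @return number of representative features.
#' @examples
#' tagBookkeeping(282, 71, 29)  # 240
#' @export
tagBookkeeping <- function(K, n_cluster_members, n_tags) {
    if (any(n_tags > n_cluster_members))
        stop("n_tags cannot exceed n_cluster_members", call. = FALSE)
    K - (n_cluster_members - n_tags)
}

#' Summarize tagging reports across populations
#'
#' @param reports list of \linkS4class{TagReport}s (one per population).
#' @return data.frame with one row per population (K, n_tags, n_tagged,
#'   n_singletons, n_representative, and the count of tags shared with every
#'   other population's tag set; empty overlap column with one report).
#' @export
tagSummary <- function(reports) {
    if (is(reports, "TagReport")) reports <- list(reports)
    tab <- do.call(rbind, lapply(reports, function(r) {
        ct <- tagCounts(r)
        data.frame(population = r@population, K = ct[["K"]],
            n_tags = ct[["n_tags"]], n_tagged = ct[["n_tagged"]],
            n_singletons = ct[["n_singletons"]],
            n_representative = ct[["n_representative"]],
            stringsAsFactors = FALSE)
    }))
    tag_sets <- lapply(reports, function(r)
        r@assignments$feature[r@assignments$role == "tag"])
    tab$tags_shared_all <- if (length(reports) > 1L)
        length(Reduce(intersect, tag_sets)) else NA_integer_
    rownames(tab) <- NULL
    tab
}
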