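#' Descriptive statistics with a 95% t confidence interval
#'
#' One descriptive row per group: n, mean, 95% CI bounds, SD, min, max. The
#' interval uses the t distribution (mean +/- t[0.975, n-1] * sd / sqrt(n)),
#' which is essential for the very small healthy groups typical of
#' retrospective DAT SPECT cohorts.
#'
#' @param x numeric sample with at least 2 values.
#' @return A one-row data.frame: n, mean, ci_low, ci_high, sd, min, max.
#' @examples
#' describeSample(c(1, 2, 3))
#' @export
describeSample <- function(x) {
    x <- as.numeric(x)
    n <- length(x)
    if (n < 2L) stop("descriptive statistics require n >= 2", call. = FALSE)
    m <- mean(x)
    s <- sd(x)
    half <- qt(0.975, n - 1) * s / sqrt(n)
    data.frame(n = n, mean = m, ci_low = m - half, ci_high = m + half,
               sd = s, min = min(x), max = max(x))
}

.checkGroups <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need a list of at least two groups", call. = FALSE)
    if (any(vapply(groups, length, 0L) == 0L))
        stop("all groups must be non-empty", call. = FALSE)
    lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on k - 1 degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups list of two or more numeric samples.
#' @return list(statistic, df, p_value).
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskalWallis <- function(groups) {
    groups <- .checkGroups(groups)
    kt <- kruskal.test(groups)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = unname(kt$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided U test using the tie-corrected normal approximation (no
#' continuity correction, so that for two groups it agrees with the
#' Kruskal-Wallis chi-square on 1 df). The returned U counts the pairs with
#' `a > b` plus half the tied pairs.
#'
#' @param a,b numeric samples.
#' @return list(U, p_value).
#' @export
mannWhitneyU <- function(a, b) {
    if (!length(a) || !length(b))
        stop("both samples must be non-empty", call. = FALSE)
    wt <- suppressWarnings(wilcox.test(as.numeric(a), as.numeric(b),
                                       exact = FALSE, correct = FALSE))
    list(U = unname(wt$statistic), p_value = unname(wt$p.value))
}

#' Dunn's post hoc test with Bonferroni adjustment
#'
#' Pairwise follow-up to the Kruskal-Wallis test on the pooled ranks:
#' \eqn{z = (\bar R_i - \bar R_j) / SE} with the pooled, tie-corrected
#' standard error
#' \eqn{SE = \sqrt{(N(N+1)/12 - \sum(t^3 - t)/(12(N-1)))(1/n_i + 1/n_j)}}.
#' Two-sided p-values are multiplied by the number of pairs and capped at 1.
#'
#' @param groups named list of two or more numeric samples.
#' @return data.frame with one row per unordered pair: group1, group2, z,
#'   p_value (unadjusted), p_adjusted.
#' @examples
#' dunnBonferroni(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
dunnBonferroni <- function(groups) {
    groups <- .checkGroups(groups)
    k <- length(groups)
    if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
    pooled <- unlist(groups, use.names = FALSE)
    N <- length(pooled)
    r <- rank(pooled)
    idx <- rep(seq_len(k), times = vapply(groups, length, 0L))
    meanRank <- tapply(r, idx, mean)
    n <- vapply(groups, length, 0L)
    ties <- table(pooled)
    tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
    pairs <- utils::combn(k, 2)
    nPairs <- ncol(pairs)
    out <- lapply(seq_len(nPairs), function(p) {
        i <- pairs[1, p]; j <- pairs[2, p]
        se <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / n[i] + 1 / n[j]))
        z <- if (se > 0) (meanRank[[i]] - meanRank[[j]]) / se else 0
        praw <- 2 * pnorm(-abs(z))
        data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
                   z = z, p_value = praw,
                   p_adjusted = min(1, praw * nPairs),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Group statistics report for a feature table
#'
#' For every feature: per-stage descriptive statistics, the Kruskal-Wallis
#' test across stages, and the Dunn-Bonferroni pairwise table. This is the
#' tabular analysis stage of the pipeline.
#'
#' @param features a feature data.frame from [featureFrame()].
#' @param featureNames which feature columns to analyse.
#' @return A named list, one entry per feature, each with elements
#'   `descriptives` (per stage), `kruskal_wallis` and `dunn_bonferroni`.
#' @export
groupStatsReport <- function(features, featureNames = .FEATURES) {
    stopifnot(all(featureNames %in% names(features)))
    stages <- levels(factor(features$stage, levels = .STAGES))
    out <- lapply(featureNames, function(f) {
        groups <- split(features[[f]], factor(features$stage,
                                              levels = .STAGES))
        groups <- groups[vapply(groups, length, 0L) > 0L]
        desc <- lapply(groups, describeSample)
        list(descriptives = do.call(rbind, c(desc, make.row.names = TRUE)),
             kruskal_wallis = kruskalWallis(groups),
             dunn_bonferroni = dunnBonferroni(groups))
    })
    names(out) <- featureNames
    out
}
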