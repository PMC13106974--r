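#' Summarise per-cell masses by group
#'
#' Arithmetic mean, SD and median of `mass_fg` per group. Cells flagged
#' BELOW_LOD can be excluded (`includeBelowLod = FALSE`), mirroring the two
#' defensible treatments of undetected cells.
#'
#' @param measurements measurements data.frame with `group`, `mass_fg` and
#'   `flags` columns.
#' @param includeBelowLod keep cells flagged BELOW_LOD (default TRUE).
#' @return data.frame with one row per group: `group`, `n_cells`,
#'   `mean_fg`, `sd_fg`, `median_fg`. Errors when nothing survives the
#'   filter.
#' @export
summarizeGroups <- function(measurements, includeBelowLod = TRUE) {
    m <- measurements
    if (!"flags" %in% names(m)) m$flags <- ""
    if (!includeBelowLod)
        m <- m[!grepl("BELOW_LOD", m$flags, fixed = TRUE), , drop = FALSE]
    m <- m[is.finite(m$mass_fg), , drop = FALSE]
    if (nrow(m) == 0L)
        stop("no measurements left after filtering")
    groups <- sort(unique(m$group))
    out <- lapply(groups, function(g) {
        x <- m$mass_fg[m$group == g]
        data.frame(group = g, n_cells = length(x), mean_fg = mean(x),
                   sd_fg = if (length(x) > 1L) stats::sd(x) else 0,
                   median_fg = stats::median(x))
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-sided Mann-Whitney comparison of two groups
#'
#' Reports the Mann-Whitney U statistic (number of (a, b) pairs with
#' a > b), the two-sided p value — exact when `min(n_a, n_b) <= 8` and the
#' data carry no ties, the normal approximation with tie and continuity
#' correction otherwise — and the fold change of means, `mean(b)/mean(a)`.
#'
#' @param a,b numeric vectors of per-cell masses (fg) for the two groups.
#' @param groupA,groupB group labels carried into the result.
#' @return data.frame with `group_a`, `group_b`, `n_a`, `n_b`, `U`,
#'   `p_value` and `fold_change_of_means`.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))
#' @export
compareGroups <- function(a, b, groupA = "a", groupB = "b") {
    a <- as.numeric(a); b <- as.numeric(b)
    stopifnot(length(a) >= 1L, length(b) >= 1L)
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- min(length(a), length(b)) <= 8L && !ties
    wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                             exact = exact, correct = TRUE)
    data.frame(group_a = groupA, group_b = groupB,
               n_a = length(a), n_b = length(b),
               U = unname(wt$statistic), p_value = wt$p.value,
               fold_change_of_means = mean(b) / mean(a))
}

#' All pairwise group comparisons of a measurement table
#'
#' Runs [compareGroups()] on every unordered pair of groups. No
#' multiplicity correction is applied by default; `adjust = "holm"` adds a
#' Holm-adjusted column.
#'
#' @inheritParams summarizeGroups
#' @param adjust "none" (default) or "holm".
#' @return data.frame of comparisons (possibly zero rows with one group).
#' @export
compareAllGroups <- function(measurements, includeBelowLod = TRUE,
                             adjust = c("none", "holm")) {
    adjust <- match.arg(adjust)
    m <- measurements
    if (!"flags" %in% names(m)) m$flags <- ""
    if (!includeBelowLod)
        m <- m[!grepl("BELOW_LOD", m$flags, fixed = TRUE), , drop = FALSE]
    m <- m[is.finite(m$mass_fg), , drop = FALSE]
    groups <- sort(unique(m$group))
    if (length(groups) < 2L)
        return(data.frame(group_a = character(), group_b = character(),
                          n_a = integer(), n_b = integer(), U = numeric(),
                          p_value = numeric(),
                          fold_change_of_means = numeric()))
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    out <- do.call(rbind, c(lapply(pairs, function(p)
        compareGroups(m$mass_fg[m$group == p[1L]],
                      m$mass_fg[m$group == p[2L]],
                      groupA = p[1L], groupB = p[2L])),
        list(make.row.names = FALSE)))
    if (adjust == "holm")
        out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
    out
}
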