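#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test: exact p by enumeration when the pooled sample has
#' at most 20 observations and no ties, otherwise the normal approximation
#' with tie and continuity correction (the standard [stats::wilcox.test()]
#' branches).
#'
#' @param a,b numeric vectors (each nonempty).
#' @param group_a,group_b labels for reporting.
#' @return One-row data frame: `group_a`, `group_b`, `statistic` (rank-sum W
#'   of group a), `p_two_sided`, `n_a`, `n_b`, `direction`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, group_a = "a", group_b = "b") {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  dir <- if (wt$statistic > length(a) * length(b) / 2) "a>b"
  else if (wt$statistic < length(a) * length(b) / 2) "a<b" else "equal"
  data.frame(group_a = group_a, group_b = group_b,
             statistic = unname(wt$statistic),
             p_two_sided = wt$p.value, n_a = length(a), n_b = length(b),
             direction = dir, stringsAsFactors = FALSE)
}

#' Contrast dN, dS and omega between structural classes
#'
#' Pools per-gene pairwise rate estimates within each class label (only pairs
#' whose label is given; cross-class pairs should simply be absent from
#' `grouping`) and runs all pairwise label contrasts for each metric by
#' [wilcoxon_rank_sum()].
#'
#' @param estimates data frame of rate estimates ([ml_pairwise_rates()] rows).
#' @param grouping named character vector: taxon-pair string (`"a:b"`) ->
#'   class label.
#' @param metrics which columns to contrast.
#' @return Data frame: contrast, metric, statistic, p_two_sided, n_a, n_b,
#'   direction.
#' @export
compare_rate_groups <- function(estimates, grouping,
                                metrics = c("dS", "dN", "omega")) {
  labs <- unique(unname(grouping))
  if (length(labs) < 2L) stop("need at least two class labels")
  est <- estimates[estimates$pair %in% names(grouping), , drop = FALSE]
  est$label <- unname(grouping[est$pair])
  for (l in labs) {
    if (sum(est$label == l) == 0L) stop("no estimates for label ", l)
  }
  out <- list()
  for (i in seq_len(length(labs) - 1L)) {
    for (j in seq(i + 1L, length(labs))) {
      for (m in metrics) {
        va <- est[[m]][est$label == labs[i]]
        vb <- est[[m]][est$label == labs[j]]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        cmp <- wilcoxon_rank_sum(va, vb, labs[i], labs[j])
        cmp$metric <- m
        cmp$contrast <- paste(labs[i], "vs", labs[j])
        out[[length(out) + 1L]] <- cmp
      }
    }
  }
  res <- do.call(rbind, out)
  res[, c("contrast", "metric", "statistic", "p_two_sided", "n_a", "n_b",
          "direction")]
}

#' Partition genes by membership in a rearranged region
#'
#' Two-way labeling (inside/outside a named inversion) for use as a
#' [compare_rate_groups()] grouping at the gene level.
#'
#' @param genes character vector of gene names.
#' @param inside_set genes inside the region (must be a subset of `genes`).
#' @return Named character vector gene -> `"inside"`/`"outside"`.
#' @export
partition_by_region <- function(genes, inside_set) {
  unknown <- setdiff(inside_set, genes)
  if (length(unknown) > 0L) {
    stop("inside_set contains unknown genes: ",
         paste(unknown, collapse = ", "))
  }
  stats::setNames(ifelse(genes %in% inside_set, "inside", "outside"), genes)
}
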