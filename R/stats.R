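## Group comparisons and tabulation. The rank tests wrap stats::wilcox.test
## with an explicit exactness policy; tabulation reproduces the printed
## count-(percentage) layout of the co-culture tables.

group_comparison <- function(scope, a_name, b_name, test, statistic, p, na, nb) {
  data.frame(scope = scope, group_a = a_name, group_b = b_name, test = test,
             statistic = statistic, p_value = p, n_a = na, n_b = nb,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test (within-experiment comparison)
#'
#' Two-sided rank-sum comparison of two cell groups within one experiment.
#' The exact null distribution is used when both samples have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @param a_name,b_name labels for the report row.
#' @return one-row data.frame (scope, groups, test, U statistic, two-sided
#'   p, sample sizes).
#' @export
mann_whitney <- function(a, b, a_name = "A", b_name = "B") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 8 && length(b) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  group_comparison("within", a_name, b_name, "Mann-Whitney U",
                   unname(ht$statistic), min(1, ht$p.value),
                   length(a), length(b))
}

#' Wilcoxon signed-rank test (across-experiment paired comparison)
#'
#' Two-sided signed-rank test on paired differences — typically the
#' per-co-culture medians of two cell groups across experiments, pairs with
#' a missing group dropped listwise. Zero differences are dropped
#' (Wilcoxon's convention); the exact distribution is used for at most 15
#' non-zero differences without ties.
#'
#' @param d numeric vector of paired differences, or supply `x` and `y`.
#' @param x,y optional paired samples (then `d = x - y`).
#' @param a_name,b_name labels for the report row.
#' @return one-row data.frame as in [mann_whitney()].
#' @export
wilcoxon_signed_rank <- function(d = NULL, x = NULL, y = NULL,
                                 a_name = "A", b_name = "B") {
  if (is.null(d)) {
    keep <- !is.na(x) & !is.na(y)
    d <- x[keep] - y[keep]
  }
  d <- d[!is.na(d)]
  n_pairs <- length(d)
  d <- d[d != 0]
  if (length(d) < 1) stop("all paired differences are zero")
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- length(d) <= 15 && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = TRUE))
  group_comparison("across", a_name, b_name, "Wilcoxon signed-rank",
                   unname(ht$statistic), min(1, ht$p.value),
                   n_pairs, n_pairs)
}

#' Paired t-test
#'
#' Standard paired t statistic with two-sided p; used for the across-
#' experiment comparisons of normalized nuclear 5mc.
#'
#' @param x,y paired samples (pairs with a missing value dropped).
#' @param a_name,b_name labels for the report row.
#' @return one-row data.frame as in [mann_whitney()].
#' @export
paired_t <- function(x, y, a_name = "A", b_name = "B") {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(x - y) == 0)
    stop("zero variance of paired differences; t statistic undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  group_comparison("across", a_name, b_name, "paired t",
                   unname(ht$statistic), ht$p.value, length(x), length(y))
}

## ---- tabulation -------------------------------------------------------

fmt_count_pct <- function(n, pct) {
  ifelse(n == 0, "0 (0%)", sprintf("%d (%.1f%%)", n, pct))
}

#' Tabulate co-cultured cells by Cartesian-plot group
#'
#' Counts and one-decimal percentages (rounded half away from zero,
#' denominator = all co-cultured cells) per classification group, in the
#' published column order from the fibroblast pole to the cancer-cell
#' pole, plus control cell counts and the co-culture total.
#'
#' @param counts named integer vector of per-group counts (names from
#'   [CARTESIAN_GROUPS]; absent groups count 0), or a classified
#'   data.frame with a `group` column.
#' @param n_control_green,n_control_red control cell counts for the outer
#'   columns.
#' @return one-row data.frame mixing formatted "n (p%)" cells and totals.
#' @export
tabulate_groups <- function(counts, n_control_green = NA, n_control_red = NA) {
  counts <- as_group_counts(counts, CARTESIAN_GROUPS)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 1) else counts * 0
  cells <- fmt_count_pct(counts, pct)
  names(cells) <- names(counts)
  data.frame(control_fibroblasts = n_control_red,
             indist_red = cells[["indist_red"]],
             red_some_green = cells[["red_some_green"]],
             uncertain = cells[["uncertain"]],
             green_some_red = cells[["green_some_red"]],
             indist_green = cells[["indist_green"]],
             unclassified = cells[["unclassified"]],
             total_cocultured = total,
             control_cancer_cells = n_control_green,
             stringsAsFactors = FALSE)
}

#' Tabulate co-cultured cells by Exchange-Unit domain
#'
#' Counts and one-decimal percentages per EU domain, in ascending EU order
#' from the `EU=-50` singleton to the `EU=50` singleton. The singleton
#' domain counts equal the corresponding indistinguishable-group counts of
#' [tabulate_groups()] by construction.
#'
#' @param counts named integer vector of per-domain counts (names from
#'   [EU_DOMAINS]), or a classified data.frame with an `eu_domain` column.
#' @return one-row data.frame of formatted "n (p%)" cells plus the total.
#' @export
tabulate_eu <- function(counts) {
  counts <- as_group_counts(counts, EU_DOMAINS)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 1) else counts * 0
  out <- as.data.frame(as.list(fmt_count_pct(counts, pct)),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(counts)
  out$total_cocultured <- total
  out
}

as_group_counts <- function(counts, levels) {
  if (is.data.frame(counts)) {
    col <- if ("eu_domain" %in% names(counts) &&
               identical(levels, EU_DOMAINS)) "eu_domain" else "group"
    f <- factor(as.character(counts[[col]]), levels = levels)
    counts <- table(f)
  }
  out <- stats::setNames(integer(length(levels)), levels)
  counts <- unlist(counts)
  if (is.null(names(counts)) && length(counts) == length(levels))
    names(counts) <- levels
  bad <- setdiff(names(counts), levels)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  out[names(counts)] <- as.integer(counts)
  out
}

#' Pairwise comparisons of a phenotype across classification groups
#'
#' Within one experiment: Mann-Whitney U between every pair of occupied
#' cell groups (controls included as pseudo-groups) for a chosen phenotype
#' column. No multiple-testing correction is applied by default, matching
#' the raw-threshold reporting convention; `p_adjust = "holm"` is
#' available.
#'
#' @param fit a [cartesian_transfer()] fit.
#' @param phenotype `"circularity"`, `"area"` or `"cnf_norm"`.
#' @param by `"group"` or `"eu_domain"`.
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @param min_n smallest group size entering a comparison.
#' @return data.frame of comparison rows.
#' @export
compare_groups <- function(fit, phenotype = "circularity",
                           by = c("group", "eu_domain"),
                           p_adjust = "none", min_n = 2) {
  by <- match.arg(by)
  if (!phenotype %in% c("circularity", "area", "cnf_norm"))
    stop("unknown phenotype: ", phenotype)
  f <- fit$cells[[by]]
  samples <- split(fit$cells[[phenotype]], f, drop = FALSE)
  samples$control_green <- fit$control_green[[phenotype]]
  samples$control_red <- fit$control_red[[phenotype]]
  samples <- Filter(function(v) sum(!is.na(v)) >= min_n, samples)
  nm <- names(samples)
  if (length(nm) < 2) return(group_comparison(character(0), character(0),
                                              character(0), character(0),
                                              numeric(0), numeric(0),
                                              integer(0), integer(0))[0, ])
  rows <- list()
  for (i in seq_len(length(nm) - 1))
    for (j in seq(i + 1, length(nm)))
      rows[[length(rows) + 1]] <-
        mann_whitney(samples[[i]], samples[[j]], nm[i], nm[j])
  out <- do.call(rbind, rows)
  if (p_adjust != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
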