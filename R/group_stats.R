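# ---- nonparametric comparison layer -----------------------------------------
# Paired Wilcoxon signed-rank for longitudinal (BL vs FUP6) comparisons,
# Mann-Whitney for two independent groups, Kruskal-Wallis with Dunn's post
# hoc for multiple groups, and Benjamini-Hochberg step-up adjustment.
# Exact p-values are used in the tie-free small-sample regime (signed-rank
# n <= 25; Mann-Whitney n_a + n_b <= 12), tie-corrected normal
# approximations (no continuity correction) otherwise — fixed switchover
# rules so results are deterministic.

.tier <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "#" else ""
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; with no remaining differences a degenerate
#' result (p = 1) is returned. Exact two-sided p-values in the tie-free
#' regime with n <= 25 remaining pairs, tie-corrected normal approximation
#' otherwise.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return data.frame: `method`, `statistic`, `p_value`, `n`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (!length(d))
    return(data.frame(method = "wilcoxon_signed_rank", statistic = NA_real_,
                      p_value = 1, n = 0L, exact = TRUE,
                      stringsAsFactors = FALSE))
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- !ties && length(d) <= 25
  res <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = use_exact,
                                             correct = FALSE))
  data.frame(method = "wilcoxon_signed_rank",
             statistic = unname(res$statistic),
             p_value = min(res$p.value, 1), n = length(d), exact = use_exact,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test for two independent groups
#'
#' Exact two-sided p-value by enumeration in the tie-free regime with
#' `n_a + n_b <= 12`, tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return data.frame: `method`, `statistic` (U), `p_value`, `n_a`, `n_b`,
#'   `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && (length(a) + length(b)) <= 12
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                             correct = FALSE))
  data.frame(method = "mann_whitney", statistic = unname(res$statistic),
             p_value = min(res$p.value, 1), n_a = length(a), n_b = length(b),
             exact = use_exact, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected H statistic with chi-square p-value; pairwise Dunn z-tests
#' on mean ranks with the usual tie correction, adjusted by Bonferroni-style
#' multiplication over the number of comparisons.
#'
#' @param groups named list of >= 3 nonempty numeric vectors.
#' @return list with `omnibus` (method, statistic, p_value, df) and
#'   `pairwise` (group_a, group_b, z, p_value, adjusted_p).
#' @export
kruskal_wallis_dunn <- function(groups) {
  if (length(groups) < 3)
    stop("need >= 3 groups; use mann_whitney_u for two groups")
  stopifnot(all(lengths(groups) > 0))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  rk <- rank(x)
  N <- length(x)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  mean_rank <- tapply(rk, g, mean)
  n_i <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  n_cmp <- ncol(pairs)
  pw <- lapply(seq_len(n_cmp), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[ga] + 1 / n_i[gb]))
    z <- (mean_rank[ga] - mean_rank[gb]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = ga, group_b = gb, z = unname(z),
               p_value = unname(p), adjusted_p = unname(min(p * n_cmp, 1)),
               stringsAsFactors = FALSE)
  })
  list(omnibus = data.frame(method = "kruskal_wallis",
                            statistic = unname(kw$statistic),
                            p_value = kw$p.value,
                            df = unname(kw$parameter), stringsAsFactors = FALSE),
       pairwise = do.call(rbind, pw))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run a declared comparison plan over a tidy metrics table
#'
#' Each plan entry names a metric, a test and the grouping: `paired`
#' (signed-rank, pairing by `subject` across `timepoint`), `two_group`
#' (Mann-Whitney on a two-level `group_col`) or `multi_group`
#' (Kruskal-Wallis + Dunn over a `group_col`). Significance tiers follow the
#' usual convention (`#` p<0.1, `*` p<0.05, `**` p<0.01, `***` p<0.001).
#'
#' @param metrics tidy data.frame with at least `metric`, `value` and the
#'   grouping columns each entry references.
#' @param plan list of entries: `list(metric=, test=, group_col=, subset=)`
#'   (`subset` optional: restrict to one `cell_subset`).
#' @param global_bh also add a BH adjustment across all plan cells,
#'   default FALSE (the per-test behavior of the original figures).
#' @return data.frame: one row per plan cell with `metric`, `cell_subset`,
#'   `test`, `statistic`, `p_value`, `tier` (and `adjusted_p` if
#'   `global_bh`).
#' @export
run_comparison_plan <- function(metrics, plan, global_bh = FALSE) {
  if (!length(plan))
    return(data.frame(metric = character(0), cell_subset = character(0),
                      test = character(0), statistic = numeric(0),
                      p_value = numeric(0), tier = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(plan, function(entry) {
    df <- metrics[metrics$metric == entry$metric, , drop = FALSE]
    if (!is.null(entry$subset))
      df <- df[df$cell_subset == entry$subset, , drop = FALSE]
    need <- switch(entry$test, paired = c("subject", "timepoint"),
                   entry$group_col)
    if (any(!need %in% names(df)))
      stop("plan references absent column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    res <- switch(entry$test,
      paired = {
        wide <- stats::reshape(df[, c("subject", "timepoint", "value")],
                               idvar = "subject", timevar = "timepoint",
                               direction = "wide")
        wide <- wide[stats::complete.cases(wide), , drop = FALSE]
        wilcoxon_signed_rank(wide[[2]], wide[[3]])
      },
      two_group = {
        lv <- sort(unique(df[[entry$group_col]]))
        if (length(lv) != 2) stop("two_group test needs exactly 2 levels")
        mann_whitney_u(df$value[df[[entry$group_col]] == lv[1]],
                       df$value[df[[entry$group_col]] == lv[2]])
      },
      multi_group = {
        kruskal_wallis_dunn(split(df$value, df[[entry$group_col]]))$omnibus
      },
      stop("unknown test: ", entry$test))
    data.frame(metric = entry$metric,
               cell_subset = if (is.null(entry$subset)) NA_character_ else entry$subset,
               test = entry$test, statistic = res$statistic,
               p_value = res$p_value, tier = .tier(res$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (global_bh) out$adjusted_p <- benjamini_hochberg(out$p_value)
  out
}
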