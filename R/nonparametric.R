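#' Kruskal-Wallis omnibus test with pairwise Wilcoxon / BH follow-up
#'
#' The study's non-parametric route for outcomes that resist
#' transformation: a tie-corrected Kruskal-Wallis test across all groups,
#' then all pairwise two-sided Wilcoxon rank-sum tests with
#' Benjamini-Hochberg step-up adjustment over the pairwise family. The
#' rank-sum tests use the tie-corrected normal approximation without
#' continuity correction, so with two groups the omnibus and pairwise
#' p-values agree.
#'
#' @param table observation table with columns `value` and `group`.
#' @return A list with `kw_statistic`, `kw_df`, `kw_p` and a tibble
#'   `pairwise` (`group1`, `group2`, `w_statistic`, `p_raw`, `p_bh`).
#' @export
#' @examples
#' tb <- generate_table(table_spec(group_effects = c(a = 0, b = 1, c = 0),
#'                                 seed = 9))$table
#' kruskal_wallis_wilcoxon_bh(tb)$kw_p
kruskal_wallis_wilcoxon_bh <- function(table) {
  if (!all(c("value", "group") %in% names(table))) {
    rlang::abort("table must have `value` and `group` columns.",
                 class = "enspff_validation_error")
  }
  g <- factor(table$group)
  g <- droplevels(g)
  counts <- table(g)
  if (nlevels(g) < 2L || any(counts == 0)) {
    rlang::abort("need >= 2 groups, each with >= 1 observation.",
                 class = "enspff_validation_error")
  }
  kw <- stats::kruskal.test(table$value, g)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(p) {
    x <- table$value[g == p[1]]
    y <- table$value[g == p[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    c(w = unname(wt$statistic), p = wt$p.value)
  })
  p_raw <- unname(res["p", ])
  pairwise <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    w_statistic = unname(res["w", ]), p_raw = p_raw,
    p_bh = stats::p.adjust(p_raw, method = "BH")
  )
  list(kw_statistic = unname(kw$statistic), kw_df = unname(kw$parameter),
       kw_p = kw$p.value, pairwise = pairwise)
}

#' Dose-response regression of intensity on fibril dose
#'
#' Ordinary least-squares fit of a response (e.g. mean fibril-tag intensity
#' per image) on administered dose in micrograms, summarised by slope,
#' intercept, adjusted R-squared and the slope's p-value — the form of the
#' study's overall dose-dependence check across the 1--6 ug dose ladder.
#'
#' @param table data frame with columns `dose` (ug) and `value`.
#' @return A list with `slope`, `intercept`, `r_squared`, `adj_r_squared`,
#'   `p_value`, `n` and the fitted `lm` object as `model`.
#' @export
dose_response <- function(table) {
  if (!all(c("dose", "value") %in% names(table))) {
    rlang::abort("table must have `dose` and `value` columns.",
                 class = "enspff_validation_error")
  }
  if (length(unique(table$dose)) < 3L) {
    rlang::abort("need at least three distinct doses.",
                 class = "enspff_validation_error")
  }
  fit <- stats::lm(value ~ dose, data = table)
  s <- summary(fit)
  list(slope = unname(coef(fit)["dose"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       r_squared = s$r.squared,
       adj_r_squared = s$adj.r.squared,
       p_value = s$coefficients["dose", "Pr(>|t|)"],
       n = nrow(table), model = fit)
}
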