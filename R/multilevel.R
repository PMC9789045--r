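#' Fit the general linear model (no random effects)
#'
#' The simplest candidate in the model ladder: group fixed effects on the
#' (optionally transformed) outcome, ordinary least squares.
#'
#' @param table observation table with columns `value` and `group` (factor
#'   or character).
#' @param outcome_transform optional [transform_spec()] applied to `value`.
#' @return A `model_fit_result` (see [fit_multilevel()]).
#' @export
fit_glm <- function(table, outcome_transform = NULL) {
  dat <- prepare_model_data(table, outcome_transform)
  model <- stats::lm(.value ~ group, data = dat)
  new_model_fit(model, "glm", dat, n_varcomp = 0L,
                log_likelihood = as.numeric(stats::logLik(model)),
                transform = outcome_transform)
}

#' Fit a multilevel (mixed-effects) model
#'
#' Group fixed effects with nested random intercepts for experimental
#' replicate (2-level model) or replicate and well within replicate
#' (3-level model), fitted by maximum likelihood so that log-likelihoods
#' are comparable across the candidate ladder in [select_model()].
#'
#' @param table observation table with columns `value`, `group`,
#'   `replicate`, and `well` for the 3-level model.
#' @param outcome_transform optional [transform_spec()] applied to `value`.
#' @param levels `"replicate_only"` (2-level) or `"replicate_and_well"`
#'   (3-level).
#' @return An object of class `model_fit_result`: elements `model` (the
#'   fitted lme4/lm/glmmTMB object), `model_kind`, `fixed_effects` (tibble),
#'   `random_effect_variances`, `log_likelihood`, `n_varcomp`, `transform`
#'   and `data`.
#' @export
#' @examples
#' tb <- generate_table(table_spec(seed = 4))$table
#' fit <- fit_multilevel(tb, levels = "replicate_and_well")
#' fit$random_effect_variances
fit_multilevel <- function(table, outcome_transform = NULL,
                           levels = c("replicate_only", "replicate_and_well")) {
  levels <- match.arg(levels)
  dat <- prepare_model_data(table, outcome_transform)
  if (nlevels(dat$group) < 2L) {
    rlang::abort("need at least two groups.", class = "enspff_validation_error")
  }
  if (length(unique(dat$replicate)) < 2L) {
    rlang::abort("need at least two replicate clusters.",
                 class = "enspff_validation_error")
  }
  form <- .value ~ group + (1 | replicate)
  n_varcomp <- 1L
  if (levels == "replicate_and_well") {
    no_well_structure <- is.null(dat$well) ||
      !any(stats::ave(seq_len(nrow(dat)), dat$replicate,
                      FUN = function(i) length(unique(dat$well[i]))) > 1) ||
      length(unique(dat$well)) >= nrow(dat)  # one observation per well
    if (no_well_structure) {
      rlang::warn("no usable well structure within replicates; dropping the well level.")
    } else {
      form <- .value ~ group + (1 | replicate) + (1 | well)
      n_varcomp <- 2L
    }
  }
  model <- lme4::lmer(form, data = dat, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(model))
  varcomps <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                              vc$grp[vc$grp != "Residual"])
  new_model_fit(model, if (n_varcomp == 2L) "lmm3" else "lmm2", dat,
                n_varcomp = n_varcomp,
                log_likelihood = as.numeric(stats::logLik(model)),
                transform = outcome_transform,
                random_effect_variances = varcomps,
                residual_variance = vc$vcov[vc$grp == "Residual"])
}

prepare_model_data <- function(table, outcome_transform = NULL) {
  if (!all(c("value", "group") %in% names(table))) {
    rlang::abort("table must have `value` and `group` columns.",
                 class = "enspff_validation_error")
  }
  if (any(is.na(table$value))) {
    table <- table[!is.na(table$value), , drop = FALSE]
  }
  dat <- as.data.frame(table)
  dat$group <- if (is.factor(dat$group)) droplevels(dat$group) else factor(dat$group)
  dat$.value <- if (!is.null(outcome_transform)) {
    as.numeric(apply_transform(dat$value, outcome_transform))
  } else {
    dat$value
  }
  dat
}

new_model_fit <- function(model, kind, data, n_varcomp, log_likelihood,
                          transform = NULL, random_effect_variances = numeric(0),
                          residual_variance = NULL) {
  s <- if (inherits(model, "glmmTMB")) summary(model)$coefficients$cond
       else summary(model)$coefficients
  fe <- tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                       se = unname(s[, 2]))
  structure(
    list(model = model, model_kind = kind, fixed_effects = fe,
         random_effect_variances = random_effect_variances,
         residual_variance = residual_variance,
         log_likelihood = log_likelihood, n_varcomp = n_varcomp,
         transform = transform, data = data),
    class = "model_fit_result"
  )
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat(sprintf("<model_fit_result> %s, logLik = %.3f, %d variance component(s)\n",
              x$model_kind, x$log_likelihood, x$n_varcomp))
  invisible(x)
}

#' Select the simplest adequate model by likelihood ratio
#'
#' Walks an ordered ladder of nested candidates — general linear model
#' first, then increasingly rich multilevel models — and returns the
#' simplest candidate whose likelihood-ratio test against the general
#' linear model is significant. Because the null value of a random-intercept
#' variance sits on the boundary of its parameter space, the reference
#' distribution is the conventional 50:50 chi-square mixture
#' (`0.5 * chisq(q - 1) + 0.5 * chisq(q)` for `q` extra variance
#' components). If no candidate improves, the general linear model is kept;
#' exactly tied log-likelihoods therefore favour the simplest model.
#'
#' @param fits list of `model_fit_result`s ordered from simplest; the first
#'   must be the GLM (`n_varcomp = 0`) and all must be ML fits of the same
#'   data.
#' @param alpha significance level of the LRT (default 0.05).
#' @return the chosen `model_fit_result`, with attributes
#'   `"selection_table"` (tibble of candidates, LRT statistics, p-values)
#'   and `"selected_index"`.
#' @export
select_model <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 1)
  nvc <- vapply(fits, function(f) f$n_varcomp, integer(1))
  if (nvc[1] != 0L || is.unsorted(nvc, strictly = TRUE)) {
    rlang::abort("candidates must be ordered from the GLM upward (nested).",
                 class = "enspff_validation_error")
  }
  ns <- vapply(fits, function(f) nrow(f$data), integer(1))
  if (length(unique(ns)) != 1L) {
    rlang::abort("candidates must be fitted on identical data.",
                 class = "enspff_validation_error")
  }
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  stat <- 2 * (ll - ll[1])
  q <- nvc
  pval <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)[-1]) {
    s <- max(stat[i], 0)
    p_hi <- stats::pchisq(s, df = q[i], lower.tail = FALSE)
    p_lo <- if (q[i] - 1L == 0L) as.numeric(s <= 0)
            else stats::pchisq(s, df = q[i] - 1L, lower.tail = FALSE)
    pval[i] <- 0.5 * p_lo + 0.5 * p_hi
  }
  chosen <- 1L
  for (i in seq_along(fits)[-1]) {
    if (!is.na(pval[i]) && pval[i] < alpha) {
      chosen <- i
      break
    }
  }
  sel <- fits[[chosen]]
  attr(sel, "selection_table") <- tibble::tibble(
    model_kind = vapply(fits, function(f) f$model_kind, character(1)),
    n_varcomp = nvc, log_likelihood = ll, lrt_stat = stat, p_value = pval)
  attr(sel, "selected_index") <- chosen
  sel
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' Estimated marginal group means of a fitted model and all pairwise
#' differences with Tukey (studentized-range / multivariate-t) adjustment;
#' the unadjusted p-value is reported alongside. For the zero-inflated
#' count model, contrasts are taken on the log-mean (conditional-model)
#' scale; when the model carries a `stimulus` factor the contrasts are of
#' stimulus within group.
#'
#' @param fit a `model_fit_result`.
#' @return A list with tibbles `emmeans` (per-group estimates) and
#'   `contrasts` (`contrast`, `estimate`, `se`, `df`, `p_tukey`,
#'   `p_unadjusted`); both empty when only one group is present.
#' @export
emmeans_contrasts <- function(fit) {
  stopifnot(inherits(fit, "model_fit_result"))
  dat <- fit$data
  has_stim <- "stimulus" %in% names(dat) &&
    length(unique(dat$stimulus)) > 1L
  if (nlevels(factor(dat$group)) < 2L && !has_stim) {
    return(list(emmeans = tibble::tibble(), contrasts = tibble::tibble()))
  }
  spec <- if (has_stim) ~ stimulus | group else ~ group
  em <- emmeans::emmeans(fit$model, spec, data = dat)
  tuk <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  p_col <- intersect(c("p.value"), names(tuk))
  contrasts <- tibble::tibble(
    contrast = as.character(tuk$contrast),
    group = if (has_stim) as.character(tuk$group) else NA_character_,
    estimate = tuk$estimate, se = tuk$SE,
    df = if ("df" %in% names(tuk)) tuk$df else NA_real_,
    p_tukey = tuk[[p_col]], p_unadjusted = raw[[p_col]]
  )
  list(emmeans = tibble::as_tibble(as.data.frame(em)), contrasts = contrasts)
}
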