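#' Zero-inflated negative-binomial log-likelihood (closed form)
#'
#' `log L = sum log( pi * 1[y = 0] + (1 - pi) * NB(y; mu, theta) )`, the
#' mixture of a structural-zero point mass and a negative binomial with
#' mean `mu` and dispersion `theta` (variance `mu + mu^2 / theta`). Used to
#' validate the fitted model's likelihood against an independent sum.
#'
#' @param y non-negative integer counts.
#' @param mu NB mean (scalar or vector).
#' @param theta dispersion > 0.
#' @param pi zero-inflation probability in `[0, 1]`.
#' @return total log-likelihood.
#' @export
zinb_loglik <- function(y, mu, theta, pi) {
  if (any(y < 0) || any(y != floor(y))) {
    rlang::abort("counts must be non-negative integers.",
                 class = "enspff_validation_error")
  }
  dens <- (1 - pi) * stats::dnbinom(y, size = theta, mu = mu) +
    pi * as.numeric(y == 0)
  sum(log(dens))
}

#' Fit the zero-inflated negative-binomial multilevel count model
#'
#' The study's electrophysiology model: spike counts per recording window
#' modelled as zero-inflated negative binomial with a log link on the
#' count mean, an intercept-only (logit-scale) zero-inflation component,
#' culture day as a fixed covariate, a group-by-stimulus interaction when a
#' stimulus factor is present, and nested random intercepts for
#' experimental replicate and electrode. Fitted by maximum likelihood with
#' the Laplace approximation (via glmmTMB).
#'
#' @param table observation table of counts: columns `value`, `group`, and
#'   optionally `day`, `stimulus`, `replicate`, `unit` (electrode).
#' @param include_day include `day` as a fixed covariate when it varies.
#' @param random_levels grouping columns given random intercepts (those
#'   present with >= 2 levels are used; the rest are dropped).
#' @param zero_inflated if `FALSE`, fit a plain NB mixed model (used e.g.
#'   for distributional-limit checks).
#' @return A `model_fit_result` (see [fit_multilevel()]) with extra
#'   elements `theta` (NB dispersion) and `zero_inflation_prob`.
#' @export
#' @examples
#' \donttest{
#' tb <- generate_table(table_spec(family = "zinb", seed = 11))$table
#' fit <- fit_zinb(tb)
#' fit$zero_inflation_prob
#' }
fit_zinb <- function(table, include_day = TRUE,
                     random_levels = c("replicate", "unit"),
                     zero_inflated = TRUE) {
  dat <- as.data.frame(table)
  if (!all(c("value", "group") %in% names(dat))) {
    rlang::abort("table must have `value` and `group` columns.",
                 class = "enspff_validation_error")
  }
  if (any(dat$value < 0) || any(dat$value != floor(dat$value))) {
    rlang::abort("outcome must be non-negative integer counts.",
                 class = "enspff_validation_error")
  }
  if (all(dat$value == 0)) {
    rlang::abort("all counts are zero; the count component is degenerate.",
                 class = "enspff_degenerate_fit_error")
  }
  dat$group <- factor(dat$group)

  fixed <- if (nlevels(dat$group) >= 2L) "group" else "1"
  if ("stimulus" %in% names(dat) && length(unique(dat$stimulus)) > 1L) {
    dat$stimulus <- factor(dat$stimulus)
    fixed <- "group * stimulus"
  }
  if (include_day && "day" %in% names(dat) && length(unique(dat$day)) > 1L) {
    fixed <- paste(fixed, "+ day")
  }
  rterms <- character(0)
  for (lv in random_levels) {
    if (lv %in% names(dat) && length(unique(dat[[lv]])) > 1L) {
      rterms <- c(rterms, paste0("(1 | ", lv, ")"))
    }
  }
  form <- stats::as.formula(
    paste("value ~", paste(c(fixed, rterms), collapse = " + ")))

  model <- glmmTMB::glmmTMB(
    form, data = dat, family = glmmTMB::nbinom2,
    ziformula = if (zero_inflated) ~1 else ~0)

  conv <- model$fit$convergence
  if (!is.null(conv) && conv != 0) {
    rlang::warn(paste0("ZINB fit did not converge cleanly (code ", conv,
                       "); max |gradient| = ",
                       format(max(abs(model$fit$objective_gr %||% NA)))))
  }

  vc <- glmmTMB::VarCorr(model)$cond
  varcomps <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  zi_prob <- if (zero_inflated) {
    stats::plogis(glmmTMB::fixef(model)$zi[["(Intercept)"]])
  } else 0

  fit <- new_model_fit(model, "zinb_glmm", dat,
                       n_varcomp = length(varcomps),
                       log_likelihood = as.numeric(stats::logLik(model)),
                       random_effect_variances = varcomps)
  fit$theta <- glmmTMB::sigma(model)
  fit$zero_inflation_prob <- zi_prob
  fit
}
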