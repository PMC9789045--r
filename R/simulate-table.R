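#' Specification of a hierarchical outcome table
#'
#' Describes the nested sampling design the study's statistics assume:
#' experimental groups measured across experimental replicates, wells within
#' replicates, and imaging/recording units within wells, with random
#' intercepts at the replicate and well levels. Outcomes are either
#' continuous (Gaussian residuals on the — possibly transformed — analysis
#' scale) or zero-inflated negative-binomial counts (spike counts), where
#' group effects act on the log mean.
#'
#' @param group_effects named numeric vector: true group-level means
#'   (continuous family) or log-mean linear-predictor values (zinb family).
#' @param n_replicates experimental replicates per group.
#' @param wells_per_replicate wells (or electrodes grouping level) per
#'   replicate.
#' @param units_per_well images or electrodes per well.
#' @param replicate_sd,well_sd random-intercept SDs (on the analysis scale
#'   for continuous outcomes, the log-mean scale for counts).
#' @param residual_sd residual SD (continuous family only).
#' @param family `"continuous"` or `"zinb"`.
#' @param theta negative-binomial dispersion (zinb; var = mu + mu^2/theta).
#' @param zero_inflation structural-zero probability in `[0, 1]` (zinb).
#' @param days numeric vector of culture days; each well-unit is observed on
#'   every day (day enters as a covariate, not a random level).
#' @param day_effect additive effect per unit day on the linear predictor.
#' @param seed RNG seed.
#' @return An object of class `table_spec`.
#' @seealso [generate_table()]
#' @export
table_spec <- function(group_effects = c(control = 0, dosed = 1),
                       n_replicates = 3L,
                       wells_per_replicate = 3L,
                       units_per_well = 5L,
                       replicate_sd = 0.5,
                       well_sd = 0.25,
                       residual_sd = 1,
                       family = c("continuous", "zinb"),
                       theta = 1.5,
                       zero_inflation = 0.3,
                       days = 21,
                       day_effect = 0,
                       seed = 1L) {
  family <- match.arg(family)
  if (n_replicates < 1L || wells_per_replicate < 1L || units_per_well < 1L) {
    rlang::abort("design counts must be positive integers.",
                 class = "enspff_validation_error")
  }
  if (zero_inflation < 0 || zero_inflation > 1) {
    rlang::abort("zero_inflation must lie in [0, 1].",
                 class = "enspff_validation_error")
  }
  if (theta <= 0) {
    rlang::abort("theta (NB dispersion) must be > 0.",
                 class = "enspff_validation_error")
  }
  if (is.null(names(group_effects)) || any(!nzchar(names(group_effects)))) {
    rlang::abort("group_effects must be a named vector.",
                 class = "enspff_validation_error")
  }
  structure(
    list(group_effects = group_effects, n_replicates = as.integer(n_replicates),
         wells_per_replicate = as.integer(wells_per_replicate),
         units_per_well = as.integer(units_per_well),
         replicate_sd = replicate_sd, well_sd = well_sd,
         residual_sd = residual_sd, family = family, theta = theta,
         zero_inflation = zero_inflation, days = days,
         day_effect = day_effect, seed = as.integer(seed)),
    class = "table_spec"
  )
}

#' Generate a hierarchical outcome table with known parameters
#'
#' Draws a tidy observation table under the nested design of a
#' [table_spec()]. Replicates are crossed with groups (each group has its
#' own replicates, as in the study where every experiment contributed wells
#' to every condition). For the `zinb` family, counts are drawn as
#' a `zero_inflation` point mass at zero mixed with negative-binomial counts
#' whose log mean is the linear predictor.
#'
#' @param spec a [table_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{table}{tibble with columns `group`, `replicate`, `well`, `unit`,
#'     `day`, `value`.}
#'   \item{truth}{the spec's true parameters, for recovery tests.}
#' }
#' @export
#' @examples
#' tb <- generate_table(table_spec(seed = 2))
#' nrow(tb$table)
generate_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  withr::with_seed(spec$seed, generate_table_impl(spec))
}

generate_table_impl <- function(spec) {
  groups <- names(spec$group_effects)
  grid <- expand.grid(
    unit = seq_len(spec$units_per_well),
    well = seq_len(spec$wells_per_replicate),
    replicate = seq_len(spec$n_replicates),
    group = groups,
    day = spec$days,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )

  rep_key <- interaction(grid$group, grid$replicate, drop = TRUE)
  well_key <- interaction(grid$group, grid$replicate, grid$well, drop = TRUE)
  b_rep <- rnorm(nlevels(rep_key), 0, spec$replicate_sd)
  b_well <- rnorm(nlevels(well_key), 0, spec$well_sd)

  eta <- spec$group_effects[grid$group] +
    b_rep[as.integer(rep_key)] + b_well[as.integer(well_key)] +
    spec$day_effect * (grid$day - min(spec$days))

  value <- if (spec$family == "continuous") {
    eta + rnorm(nrow(grid), 0, spec$residual_sd)
  } else {
    mu <- exp(eta)
    y <- rnbinom(nrow(grid), size = spec$theta, mu = mu)
    zero <- rbinom(nrow(grid), 1, spec$zero_inflation)
    ifelse(zero == 1, 0L, y)
  }

  tbl <- tibble::tibble(
    group = factor(grid$group, levels = groups),
    replicate = paste0(grid$group, "_R", grid$replicate),
    well = paste0(grid$group, "_R", grid$replicate, "_W", grid$well),
    unit = paste0(grid$group, "_R", grid$replicate, "_W", grid$well,
                  "_U", grid$unit),
    day = grid$day,
    value = as.numeric(value)
  )
  list(table = tbl, truth = unclass(spec))
}

#' Closed-form zero probability of a zero-inflated negative binomial
#'
#' `P(Y = 0) = pi + (1 - pi) * (theta / (theta + mu))^theta`.
#'
#' @param mu negative-binomial mean.
#' @param theta dispersion.
#' @param pi zero-inflation probability.
#' @return probability of observing a zero.
#' @export
zinb_zero_prob <- function(mu, theta, pi) {
  pi + (1 - pi) * (theta / (theta + mu))^theta
}
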