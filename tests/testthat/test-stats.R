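test_that("Box-Cox closed forms: lambda = 1 affine identity and lambda -> 0 log limit", {
  y <- c(0.5, 1, 2, 10, 100)
  z1 <- apply_transform(y, transform_spec("boxcox", lambda = 1))
  expect_equal(as.numeric(z1), y - 1)
  zeps <- apply_transform(y, transform_spec("boxcox", lambda = 1e-6))
  expect_equal(as.numeric(zeps), log(y), tolerance = 1e-8)
})

test_that("root and log transforms invert exactly and reject bad domains", {
  y <- c(0, 1, 16, 81)
  sp <- transform_spec("root", root_order = 4L)
  expect_equal(invert_transform(apply_transform(y, sp), sp), y)
  spl <- transform_spec("log", offset = 0.5)
  expect_equal(invert_transform(apply_transform(y, spl), spl), y)
  err <- tryCatch(apply_transform(c(1, 0, 2), transform_spec("log")),
                  error = identity)
  expect_s3_class(err, "enspff_domain_error")
  expect_match(conditionMessage(err), "2")   # names the offending row
})

test_that("profile-likelihood lambda estimation recovers the generating exponent", {
  lambda_true <- 0.5
  ests <- vapply(1:30, function(s) {
    withr::with_seed(s, {
      z <- rnorm(2000, 8, 2)
      y <- (lambda_true * z + 1)^(1 / lambda_true)
      estimate_boxcox_lambda(y)
    })
  }, numeric(1))
  expect_gte(mean(abs(ests - lambda_true) <= 0.15), 0.9)
})

test_that("our Box-Cox profile agrees with MASS::boxcox's maximiser", {
  skip_if_not_installed("MASS")
  withr::with_seed(2, y <- rlnorm(500, 1, 0.4))
  ours <- estimate_boxcox_lambda(y)
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  ref <- bc$x[which.max(bc$y)]
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("with no cluster variance, mixed fixed effects collapse to OLS", {
  tb <- generate_table(table_spec(group_effects = c(a = 0, b = 2),
                                  replicate_sd = 0, well_sd = 0,
                                  residual_sd = 1, n_replicates = 4L,
                                  units_per_well = 8L, seed = 14))$table
  fit_mm <- fit_multilevel(tb, levels = "replicate_and_well")
  fit_ols <- fit_glm(tb)
  expect_true(all(fit_mm$random_effect_variances <= 0.05))
  expect_equal(fit_mm$fixed_effects$estimate, fit_ols$fixed_effects$estimate,
               tolerance = 1e-6)
})

test_that("group-effect recovery in the three-level model (spot check)", {
  # full 100-seed recovery lives in the acceptance tests
  ests <- vapply(1:10, function(s) {
    tb <- generate_table(table_spec(group_effects = c(ctrl = 0, dosed = 2),
                                    n_replicates = 6L, wells_per_replicate = 4L,
                                    units_per_well = 10L, replicate_sd = 1,
                                    well_sd = 0.5, residual_sd = 1,
                                    seed = s))$table
    fit <- fit_multilevel(tb, levels = "replicate_and_well")
    fit$fixed_effects$estimate[2]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 0.3)
})

test_that("balanced two-group contrast equals the difference of cluster-mean means", {
  tb <- generate_table(table_spec(group_effects = c(a = 1, b = 3),
                                  n_replicates = 4L, wells_per_replicate = 1L,
                                  units_per_well = 6L, replicate_sd = 0.8,
                                  well_sd = 0, residual_sd = 1,
                                  seed = 5))$table
  fit <- fit_multilevel(tb, levels = "replicate_only")
  cl_means <- tapply(tb$value, list(tb$replicate, tb$group), mean)
  want <- mean(cl_means[, "b"], na.rm = TRUE) - mean(cl_means[, "a"], na.rm = TRUE)
  ct <- emmeans_contrasts(fit)$contrasts
  expect_equal(-ct$estimate[1], want, tolerance = 1e-6)
})

test_that("model selection walks the ladder and breaks ties toward the GLM", {
  tb <- generate_table(table_spec(group_effects = c(a = 0, b = 1),
                                  replicate_sd = 1.5, well_sd = 0,
                                  residual_sd = 1, n_replicates = 6L,
                                  units_per_well = 10L, seed = 3))$table
  fits <- list(fit_glm(tb), fit_multilevel(tb, levels = "replicate_only"),
               fit_multilevel(tb, levels = "replicate_and_well"))
  sel <- select_model(fits)
  st <- attr(sel, "selection_table")
  expect_s3_class(st, "tbl_df")
  expect_true(all(st$lrt_stat >= -1e-6))           # LRT non-negative
  expect_true(all(diff(st$log_likelihood) >= -1e-6)) # richer model never worse
  expect_identical(sel$model_kind, "lmm2")         # strong replicate variance

  # exactly tied log-likelihoods: simplest candidate wins
  f1 <- fit_glm(tb)
  f2 <- fit_multilevel(tb, levels = "replicate_only")
  f2$log_likelihood <- f1$log_likelihood
  expect_identical(select_model(list(f1, f2))$model_kind, "glm")

  expect_error(select_model(list(f2, f1)), class = "enspff_validation_error")
})

test_that("Tukey adjustment with two groups equals the unadjusted contrast", {
  tb <- generate_table(table_spec(group_effects = c(a = 0, b = 0.5),
                                  seed = 8))$table
  ct <- emmeans_contrasts(fit_glm(tb))$contrasts
  expect_equal(ct$p_tukey, ct$p_unadjusted, tolerance = 1e-6)
})

test_that("Tukey-adjusted p-values never fall below unadjusted ones", {
  for (s in 1:5) {
    tb <- generate_table(table_spec(
      group_effects = c(a = 0, b = 0.3, c = 0.1, d = 0), seed = s))$table
    ct <- emmeans_contrasts(fit_glm(tb))$contrasts
    expect_true(all(ct$p_tukey >= ct$p_unadjusted - 1e-12))
  }
})

test_that("four-group Tukey contrasts keep family-wise error near nominal under the null", {
  n_sim <- 200
  any_sig <- vapply(seq_len(n_sim), function(s) {
    tb <- generate_table(table_spec(
      group_effects = c(a = 0, b = 0, c = 0, d = 0),
      n_replicates = 2L, wells_per_replicate = 2L, units_per_well = 4L,
      replicate_sd = 0, well_sd = 0, residual_sd = 1, seed = s))$table
    any(emmeans_contrasts(fit_glm(tb))$contrasts$p_tukey < 0.05)
  }, logical(1))
  fwe <- mean(any_sig)
  expect_lte(fwe, 0.07 + 2 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("Kruskal-Wallis with two groups matches the tie-corrected Wilcoxon p", {
  withr::with_seed(12, {
    tb <- tibble::tibble(
      value = c(rnorm(15), rnorm(12, 0.8)),
      group = rep(c("a", "b"), c(15, 12)))
  })
  res <- kruskal_wallis_wilcoxon_bh(tb)
  expect_equal(res$kw_p, res$pairwise$p_raw[1], tolerance = 1e-6)
})

test_that("BH step-up matches the hand-computed adjustment", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up by hand: p_(i) * m / i, cummin from the largest
  expect_equal(stats::p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.04))
  # and through the pairwise pipeline on four groups
  withr::with_seed(3, {
    tb <- tibble::tibble(value = rnorm(60),
                         group = rep(c("a", "b", "c", "d"), 15))
  })
  res <- kruskal_wallis_wilcoxon_bh(tb)
  expect_equal(res$pairwise$p_bh,
               stats::p.adjust(res$pairwise$p_raw, "BH"))
  expect_true(all(res$pairwise$p_bh <= 1))
})

test_that("identical samples across groups give null p-values; empty groups error", {
  tb <- tibble::tibble(value = rep(c(1, 2, 3, 4, 5), 3),
                       group = rep(c("a", "b", "c"), each = 5))
  res <- kruskal_wallis_wilcoxon_bh(tb)
  expect_true(all(res$pairwise$p_bh >= 0.99))
  expect_error(
    kruskal_wallis_wilcoxon_bh(tibble::tibble(value = 1, group = factor("a", levels = c("a", "b")))),
    class = "enspff_validation_error")
})

test_that("closed-form ZINB log-likelihood matches glmmTMB's fitted likelihood", {
  tb <- generate_table(table_spec(group_effects = c(g = log(4)),
                                  n_replicates = 1L, wells_per_replicate = 1L,
                                  units_per_well = 300L, replicate_sd = 0,
                                  well_sd = 0, family = "zinb", theta = 1.5,
                                  zero_inflation = 0.3, seed = 6))$table
  # intercept-only, no random effects: our closed form at the fitted
  # parameters must equal the optimiser's reported log-likelihood
  fit <- suppressWarnings(
    fit_zinb(tb, include_day = FALSE, random_levels = character(0)))
  mu_hat <- exp(fit$fixed_effects$estimate[1])
  ours <- zinb_loglik(tb$value, mu_hat, fit$theta, fit$zero_inflation_prob)
  expect_equal(ours, fit$log_likelihood, tolerance = 1e-6)

  # and the brute-force sum definition agrees term by term
  by_hand <- sum(log(0.3 * (tb$value == 0) +
                       0.7 * dnbinom(tb$value, size = 1.5, mu = 4)))
  expect_equal(zinb_loglik(tb$value, 4, 1.5, 0.3), by_hand, tolerance = 1e-10)
})

test_that("without zero inflation and low dispersion the ZINB approaches Poisson", {
  tb <- generate_table(table_spec(group_effects = c(a = log(3), b = log(6)),
                                  n_replicates = 1L, wells_per_replicate = 1L,
                                  units_per_well = 400L, replicate_sd = 0,
                                  well_sd = 0, family = "zinb", theta = 1e4,
                                  zero_inflation = 0, seed = 7))$table
  fit <- suppressWarnings(
    fit_zinb(tb, include_day = FALSE, random_levels = character(0),
             zero_inflated = FALSE))
  pois <- glm(value ~ group, data = tb, family = poisson())
  expect_equal(fit$fixed_effects$estimate, unname(coef(pois)),
               tolerance = 0.005)
})

test_that("an all-zero count table is rejected as degenerate", {
  tb <- generate_table(table_spec(family = "zinb", zero_inflation = 1,
                                  seed = 2))$table
  expect_error(fit_zinb(tb), class = "enspff_degenerate_fit_error")
  expect_error(fit_zinb(dplyr::mutate(tb, value = value + 0.5)),
               class = "enspff_validation_error")
})

test_that("ZINB recovery of effect and inflation probability (spot check)", {
  # full 100-seed benchmark lives in the acceptance tests
  res <- vapply(1:5, function(s) {
    tb <- generate_table(table_spec(
      group_effects = c(ctrl = 1, dosed = 1.7), n_replicates = 6L,
      wells_per_replicate = 20L, units_per_well = 1L, replicate_sd = 0.3,
      well_sd = 0, family = "zinb", theta = 1.5, zero_inflation = 0.3,
      days = c(18, 20, 22), seed = s))$table
    fit <- suppressWarnings(fit_zinb(tb, random_levels = c("replicate", "unit")))
    c(fit$fixed_effects$estimate[grep("dosed", fit$fixed_effects$term)],
      fit$zero_inflation_prob)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.7), 0.15)
  expect_lt(abs(mean(res[2, ]) - 0.3), 0.05)
})

test_that("dose-response regression: exact fit, null behaviour and validation", {
  exact <- tibble::tibble(dose = c(1, 2, 4, 6), value = 3 + 2 * c(1, 2, 4, 6))
  res <- suppressWarnings(dose_response(exact))  # lm warns on a perfect fit
  expect_equal(res$adj_r_squared, 1)
  expect_equal(res$slope, 2)

  null_r2 <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      tb <- tibble::tibble(dose = rep(c(1, 2, 4, 6), 25), value = rnorm(100))
    })
    dose_response(tb)$adj_r_squared
  }, numeric(1))
  expect_lt(abs(mean(null_r2)), 0.02)

  expect_error(dose_response(tibble::tibble(dose = 1, value = 2)),
               class = "enspff_validation_error")
})

test_that("dose ladder slope recovery under noise", {
  slopes <- vapply(1:30, function(s) {
    withr::with_seed(s, {
      d <- rep(c(1, 2, 4, 6), each = 10)
      tb <- tibble::tibble(dose = d, value = 1 + 2 * d + rnorm(40))
    })
    dose_response(tb)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 2), 0.2)
})
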