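#' Imaging-arm pipeline configuration
#'
#' Describes a full in-silico imaging experiment: per-group aggregate-channel
#' intensity effects with replicate/well random variation, the nested design
#' (replicates, wells, images per well), the synthetic-scene geometry, the
#' segmentation parameters and the statistical block.
#'
#' @param group_effects named vector: additive shift (uint8) of the analysed
#'   channel's foreground level per group.
#' @param n_replicates,wells_per_replicate,images_per_well nested design.
#' @param replicate_sd,well_sd SDs (uint8) of random intensity offsets at
#'   the replicate and well level.
#' @param scene_args list of [scene_spec()] overrides (geometry, noise).
#' @param seg segmentation parameters, a [seg_params()].
#' @param channel channel whose mean intensity is the outcome.
#' @param compartment compartment in which the outcome is measured.
#' @param metrics_channels channels quantified into the metrics table
#'   (default: the outcome channel only; pass all roles for a full table).
#' @param outcome_transform [transform_spec()] for the statistical layer.
#' @param seed base RNG seed; all per-image seeds derive from it.
#' @param out_dir optional output directory.
#' @return a `pipeline_config` list.
#' @export
imaging_config <- function(group_effects = c(control = 0, dosed = 10),
                           n_replicates = 3L, wells_per_replicate = 2L,
                           images_per_well = 2L,
                           replicate_sd = 3, well_sd = 1.5,
                           scene_args = list(image_shape = c(128L, 128L),
                                             n_somas = 2L,
                                             soma_radius_px = c(10, 14)),
                           seg = seg_params(nucleus_dilation_radius_px = 6L),
                           channel = "ASYN_AGG", compartment = "neuron",
                           metrics_channels = channel,
                           outcome_transform = transform_spec("boxcox",
                                                              offset = 0.5),
                           seed = 1L, out_dir = NULL) {
  structure(
    list(arm = "imaging", group_effects = group_effects,
         n_replicates = as.integer(n_replicates),
         wells_per_replicate = as.integer(wells_per_replicate),
         images_per_well = as.integer(images_per_well),
         replicate_sd = replicate_sd, well_sd = well_sd,
         scene_args = scene_args, seg = seg, channel = channel,
         compartment = compartment, metrics_channels = metrics_channels,
         outcome_transform = outcome_transform,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 10007 + i * 7919) %% 2147483629)
}

#' Run the imaging arm: simulate, segment, quantify, model
#'
#' Generates one synthetic scene per image of the nested design (group
#' intensity effects plus replicate/well random offsets on the analysed
#' channel), segments each into morphology compartments, quantifies the
#' outcome channel, and fits the statistical ladder (GLM, 2-level and
#' 3-level multilevel models) with likelihood-ratio selection and
#' Tukey-adjusted pairwise contrasts. Failures are isolated per image and
#' recorded in the manifest; the run fails only if every image fails.
#'
#' @param config an [imaging_config()].
#' @return A list: `metrics` (per-image tidy metrics), `table` (outcome
#'   table), `fits`, `selected` (chosen `model_fit_result`), `contrasts`,
#'   and `manifest`.
#' @export
run_imaging <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), config$arm == "imaging")
  groups <- names(config$group_effects)
  warnings <- character(0)
  rows <- list()
  metrics <- list()
  idx <- 0L

  base_levels <- scene_spec()$channel_levels
  ch_fg <- base_levels[[config$channel]][1]
  ch_bg <- base_levels[[config$channel]][2]

  offsets <- withr::with_seed(derive_seed(config$seed, 0L), {
    list(
      rep = matrix(rnorm(length(groups) * config$n_replicates, 0,
                         config$replicate_sd),
                   nrow = length(groups)),
      well = array(rnorm(length(groups) * config$n_replicates *
                           config$wells_per_replicate, 0, config$well_sd),
                   dim = c(length(groups), config$n_replicates,
                           config$wells_per_replicate))
    )
  })

  for (gi in seq_along(groups)) {
    for (r in seq_len(config$n_replicates)) {
      for (w in seq_len(config$wells_per_replicate)) {
        for (im in seq_len(config$images_per_well)) {
          idx <- idx + 1L
          image_id <- sprintf("%s_R%d_W%d_I%d", groups[gi], r, w, im)
          res <- tryCatch({
            fg <- ch_fg + config$group_effects[gi] +
              offsets$rep[gi, r] + offsets$well[gi, r, w]
            fg <- min(max(fg, ch_bg + 1), 255)
            levels <- base_levels
            levels[[config$channel]] <- c(fg, ch_bg)
            sargs <- utils::modifyList(
              list(channel_levels = levels, seed = derive_seed(config$seed, idx)),
              config$scene_args)
            sargs$channel_levels <- levels
            spec <- do.call(scene_spec, sargs)
            sc <- generate_scene(spec)
            masks <- build_masks(sc$image, config$seg)
            m <- compartment_metrics(sc$image, masks, image_id = image_id,
                                     channels = config$metrics_channels)
            outcome <- m$mean_intensity[m$compartment == config$compartment &
                                          m$channel == config$channel]
            list(metrics = m, outcome = outcome)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            warnings <- c(warnings, paste0(image_id, ": ", conditionMessage(res)))
            next
          }
          metrics[[length(metrics) + 1L]] <-
            dplyr::mutate(res$metrics, group = groups[gi],
                          replicate = paste0(groups[gi], "_R", r),
                          well = paste0(groups[gi], "_R", r, "_W", w))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            group = groups[gi], replicate = paste0(groups[gi], "_R", r),
            well = paste0(groups[gi], "_R", r, "_W", w), unit = image_id,
            day = NA_real_, value = res$outcome)
        }
      }
    }
  }

  if (length(rows) == 0L) {
    rlang::abort("all images failed; see manifest warnings.",
                 class = "enspff_pipeline_error")
  }
  table <- dplyr::bind_rows(rows)
  table <- table[!is.na(table$value), , drop = FALSE]
  metrics <- dplyr::bind_rows(metrics)

  fits <- list(fit_glm(table, config$outcome_transform),
               fit_multilevel(table, config$outcome_transform,
                              "replicate_only"))
  fit3 <- suppressWarnings(
    fit_multilevel(table, config$outcome_transform, "replicate_and_well"))
  if (fit3$n_varcomp == 2L) fits <- c(fits, list(fit3))
  selected <- select_model(fits)
  # selection compares ML log-likelihoods; estimation and contrasts use a
  # REML refit of the winner, whose variance estimates are unbiased in the
  # few-replicate designs this pipeline targets
  inference <- selected
  if (selected$model_kind != "glm") {
    inference$model <- update(selected$model, REML = TRUE)
  }
  contrasts <- emmeans_contrasts(inference)

  manifest <- make_manifest(config, warnings,
                            outputs = list(metrics = metrics, table = table))
  out <- list(metrics = metrics, table = table, fits = fits,
              selected = selected, contrasts = contrasts$contrasts,
              emmeans = contrasts$emmeans, manifest = manifest)
  maybe_write_outputs(out, config$out_dir)
  out
}

#' MEA-arm pipeline configuration
#'
#' Describes a full in-silico electrophysiology experiment: per-group
#' baseline firing rates, per-stimulus rate multipliers (the differential
#' stimulus response the interaction contrast must recover), the nested
#' design, trace synthesis parameters and detection settings.
#'
#' @param baseline_rate_hz named vector of spontaneous firing rates per
#'   group.
#' @param stimulus_response named list: for each group, a named vector of
#'   multiplicative rate factors per stimulus (stimuli not listed run at
#'   the baseline rate).
#' @param silent_prob probability an electrode is structurally silent
#'   (fires no spikes), generating the zero inflation.
#' @param n_replicates,electrodes_per_replicate,days nested design; each
#'   electrode is recorded once per day and stimulus.
#' @param replicate_sd SD of log-rate random offsets per replicate.
#' @param duration_s,sampling_rate_hz,noise_sd,spike_amplitude_uv trace
#'   synthesis parameters (see [trace_spec()]).
#' @param k_sd,window_s detection threshold multiplier and counting window.
#' @param seed base RNG seed.
#' @param out_dir optional output directory.
#' @return a `pipeline_config` list.
#' @export
mea_config <- function(baseline_rate_hz = c(control = 0.2, dosed = 0.2),
                       stimulus_response = list(
                         control = c(dopamine = 2),
                         dosed = c(dopamine = 1)),
                       silent_prob = 0.3,
                       n_replicates = 3L, electrodes_per_replicate = 8L,
                       days = 20, replicate_sd = 0.2,
                       duration_s = 30, sampling_rate_hz = 12500,
                       noise_sd = 5, spike_amplitude_uv = -50,
                       k_sd = 5, window_s = NULL,
                       seed = 1L, out_dir = NULL) {
  structure(
    list(arm = "mea", baseline_rate_hz = baseline_rate_hz,
         stimulus_response = stimulus_response, silent_prob = silent_prob,
         n_replicates = as.integer(n_replicates),
         electrodes_per_replicate = as.integer(electrodes_per_replicate),
         days = days, replicate_sd = replicate_sd,
         duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         noise_sd = noise_sd, spike_amplitude_uv = spike_amplitude_uv,
         k_sd = k_sd, window_s = window_s %||% duration_s,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

#' Run the MEA arm: simulate, filter, detect, count, model
#'
#' Synthesises one voltage trace per electrode, day and stimulus (group- and
#' stimulus-dependent Poisson firing, a fraction of structurally silent
#' electrodes), band-passes and threshold-detects spikes, counts them in the
#' recording window, calls bursts, and fits the zero-inflated
#' negative-binomial multilevel model with Tukey-adjusted
#' stimulus-within-group contrasts. Failures are isolated per electrode.
#'
#' @param config an [mea_config()].
#' @return A list: `summary` (per-recording spike counts and burst flags),
#'   `fit` (the ZINB `model_fit_result`, or `NULL` with a warning recorded
#'   when the count component is degenerate), `contrasts`, and `manifest`.
#' @export
run_mea <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), config$arm == "mea")
  groups <- names(config$baseline_rate_hz)
  stimuli <- unique(c("spontaneous",
                      unlist(lapply(config$stimulus_response, names))))
  warnings <- character(0)
  rows <- list()
  idx <- 0L

  state <- withr::with_seed(derive_seed(config$seed, 0L), {
    n_el <- length(groups) * config$n_replicates *
      config$electrodes_per_replicate
    list(rep_offsets = matrix(rnorm(length(groups) * config$n_replicates,
                                    0, config$replicate_sd),
                              nrow = length(groups)),
         silent = matrix(runif(n_el) < config$silent_prob,
                         nrow = length(groups) * config$n_replicates))
  })

  for (gi in seq_along(groups)) {
    for (r in seq_len(config$n_replicates)) {
      for (e in seq_len(config$electrodes_per_replicate)) {
        el_row <- (gi - 1L) * config$n_replicates + r
        is_silent <- state$silent[el_row, e]
        for (day in config$days) {
          for (stim in stimuli) {
            idx <- idx + 1L
            eid <- sprintf("%s_R%d_E%d", groups[gi], r, e)
            res <- tryCatch({
              mult <- 1
              if (stim != "spontaneous") {
                mult <- config$stimulus_response[[groups[gi]]][stim]
                if (is.na(mult) || is.null(mult)) mult <- 1
              }
              rate <- if (is_silent) 0 else
                config$baseline_rate_hz[gi] * mult *
                  exp(state$rep_offsets[gi, r])
              spec <- trace_spec(
                sampling_rate_hz = config$sampling_rate_hz,
                duration_s = config$duration_s, noise_sd = config$noise_sd,
                spike_rate_hz = rate,
                spike_amplitude_uv = config$spike_amplitude_uv,
                seed = derive_seed(config$seed, idx))
              tr <- generate_trace(spec)
              filt <- bandpass(tr$trace)
              train <- detect_spikes(filt, k_sd = config$k_sd)
              tibble::tibble(
                electrode_id = eid, group = groups[gi],
                replicate = paste0(groups[gi], "_R", r), unit = eid,
                day = day, stimulus = stim,
                value = count_spikes(train, config$window_s),
                bursting = detect_bursts(train)$bursting)
            }, error = function(err) err)
            if (inherits(res, "error")) {
              warnings <- c(warnings, paste0(eid, " ", stim, ": ",
                                             conditionMessage(res)))
              next
            }
            rows[[length(rows) + 1L]] <- res
          }
        }
      }
    }
  }

  if (length(rows) == 0L) {
    rlang::abort("all electrodes failed; see manifest warnings.",
                 class = "enspff_pipeline_error")
  }
  summary_tbl <- dplyr::bind_rows(rows)

  fit <- tryCatch(fit_zinb(summary_tbl), error = function(e) e)
  contrasts <- tibble::tibble()
  if (inherits(fit, "error")) {
    warnings <- c(warnings, paste0("zinb: ", conditionMessage(fit)))
    fit <- NULL
  } else {
    contrasts <- emmeans_contrasts(fit)$contrasts
  }

  manifest <- make_manifest(config, warnings,
                            outputs = list(summary = summary_tbl))
  out <- list(summary = summary_tbl, fit = fit, contrasts = contrasts,
              manifest = manifest)
  maybe_write_outputs(out, config$out_dir)
  out
}

make_manifest <- function(config, warnings, outputs) {
  list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("enspff")),
    timestamp = format(Sys.time(), tz = "UTC"),
    output_checksums = lapply(outputs, rlang::hash),
    warnings = warnings
  )
}

maybe_write_outputs <- function(out, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$metrics)) {
    utils::write.csv(out$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$summary)) {
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$contrasts) && nrow(out$contrasts) > 0) {
    utils::write.csv(out$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(NULL)
}

#' Read a pipeline configuration from YAML
#'
#' Builds an [imaging_config()] or [mea_config()] from a YAML file whose
#' top-level `arm` field selects the pipeline arm; remaining fields override
#' the corresponding constructor defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  arm <- y$arm %||% "imaging"
  y$arm <- NULL
  for (nm in c("group_effects", "baseline_rate_hz")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  if (!is.null(y$stimulus_response)) {
    y$stimulus_response <- lapply(y$stimulus_response, unlist)
  }
  if (identical(arm, "imaging")) do.call(imaging_config, y)
  else do.call(mea_config, y)
}
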