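test_that("noiseless scene construction places exact two-level channels", {
  sp <- scene_spec(image_shape = c(128L, 128L), n_somas = 1L,
                   soma_radius_px = c(15, 15), noise_sd = 0,
                   channel_levels = list(DAPI = c(180, 8), B3T = c(200, 10),
                                         ASYN_AGG = c(60, 10),
                                         PFF_TAG = c(240, 8)),
                   seed = 3)
  sc <- generate_scene(sp)
  b3t <- get_channel(sc$image, "B3T")
  expect_true(all(b3t[sc$truth$neuron_mask] == 200))
  expect_true(all(b3t[!sc$truth$neuron_mask] == 10))
  dapi <- get_channel(sc$image, "DAPI")
  expect_true(all(dapi[sc$truth$soma_mask & dapi > 100] == 180))
  # nuclei centres inside the soma mask
  cen <- round(sc$truth$nuclei_centers)
  expect_true(all(sc$truth$soma_mask[cbind(cen[, 1], cen[, 2])]))
})

test_that("empty scene (no somas) is all background with empty masks", {
  sc <- generate_scene(scene_spec(image_shape = c(64L, 64L), n_somas = 0L,
                                  noise_sd = 0, seed = 1))
  expect_false(any(sc$truth$soma_mask))
  expect_false(any(sc$truth$neurite_mask))
  expect_equal(unique(as.vector(get_channel(sc$image, "B3T"))), 10)
})

test_that("scene generation is bit-exact under a fixed seed and masks are disjoint", {
  for (seed in c(7, 21)) {
    a <- generate_scene(scene_spec(image_shape = c(96L, 96L), n_somas = 2L,
                                   soma_radius_px = c(10, 14), seed = seed))
    b <- generate_scene(scene_spec(image_shape = c(96L, 96L), n_somas = 2L,
                                   soma_radius_px = c(10, 14), seed = seed))
    expect_identical(a$image$pixels, b$image$pixels)
    expect_identical(a$truth$soma_mask, b$truth$soma_mask)
    expect_false(any(a$truth$soma_mask & a$truth$neurite_mask))
    expect_identical(a$truth$neuron_mask,
                     a$truth$soma_mask | a$truth$neurite_mask)
  }
})

test_that("ground-truth compartment means equal brute-force means of the clean image", {
  sc <- generate_scene(scene_spec(image_shape = c(96L, 96L), n_somas = 2L,
                                  soma_radius_px = c(10, 14), seed = 5))
  masks <- list(whole = matrix(TRUE, 96, 96), neuron = sc$truth$neuron_mask,
                soma = sc$truth$soma_mask, neurite = sc$truth$neurite_mask)
  for (ci in seq_along(sc$image$channel_roles)) {
    plane <- sc$truth$clean[, , ci]
    for (comp in names(masks)) {
      m <- masks[[comp]]
      brute <- if (any(m)) {
        acc <- 0; k <- 0
        for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
          if (m[i, j]) { acc <- acc + plane[i, j]; k <- k + 1 }
        }
        acc / k
      } else NA_real_
      expect_equal(
        sc$truth$compartment_means[sc$image$channel_roles[ci], comp], brute)
    }
  }
})

test_that("scene spec validation rejects inverted levels and impossible placement", {
  expect_error(scene_spec(channel_levels = list(B3T = c(10, 200))),
               class = "enspff_validation_error")
  expect_error(
    generate_scene(scene_spec(image_shape = c(64L, 64L), n_somas = 30L,
                              soma_radius_px = c(14, 16), seed = 1)),
    class = "enspff_placement_error")
})

test_that("noiseless trace is the spike template at the embedded time, zero elsewhere", {
  sp <- trace_spec(sampling_rate_hz = 10000, duration_s = 3, noise_sd = 0,
                   spike_times_s = 1.0, spike_amplitude_uv = -50, seed = 1)
  tr <- generate_trace(sp)
  x <- tr$trace$samples
  expect_length(x, 30000)
  expect_equal(tr$spike_times_s, 1.0)
  expect_equal(min(x), -50)                        # negative lobe depth exact
  expect_equal(which.min(x), round(1.0 * 10000) + 1) # centred at the spike time
  far <- abs(seq_along(x) - 10001) > 200
  expect_true(all(x[far] == 0))
})

test_that("Poisson spike counts match the specified rate within Monte-Carlo error", {
  rate <- 5; dur <- 60; n_seeds <- 100
  counts <- vapply(seq_len(n_seeds), function(s) {
    length(generate_trace(trace_spec(sampling_rate_hz = 8000, duration_s = dur,
                                     noise_sd = 1, spike_rate_hz = rate,
                                     seed = s))$spike_times_s)
  }, numeric(1))
  mu <- rate * dur
  se <- sqrt(mu / n_seeds)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("trace spec validation rejects bad durations and positive amplitudes", {
  expect_error(trace_spec(duration_s = 0), class = "enspff_validation_error")
  expect_error(trace_spec(spike_amplitude_uv = 50),
               class = "enspff_validation_error")
  expect_error(trace_spec(spike_times_s = c(1, 400), duration_s = 300),
               class = "enspff_validation_error")
})

test_that("degenerate-noise continuous tables reproduce group means exactly", {
  tb <- generate_table(table_spec(group_effects = c(a = 2, b = 5),
                                  replicate_sd = 0, well_sd = 0,
                                  residual_sd = 0, seed = 1))
  expect_equal(unique(tb$table$value[tb$table$group == "a"]), 2)
  expect_equal(unique(tb$table$value[tb$table$group == "b"]), 5)
  expect_equal(nrow(tb$table), 2 * 3 * 3 * 5)
})

test_that("total zero inflation gives all-zero counts", {
  tb <- generate_table(table_spec(family = "zinb", zero_inflation = 1,
                                  seed = 2))
  expect_true(all(tb$table$value == 0))
})

test_that("ZINB zero fraction matches the closed-form mixture probability", {
  mu <- 5; theta <- 1.5; pi <- 0.4
  tb <- generate_table(table_spec(group_effects = c(g = log(mu)),
                                  n_replicates = 10L, wells_per_replicate = 10L,
                                  units_per_well = 100L,
                                  replicate_sd = 0, well_sd = 0,
                                  family = "zinb", theta = theta,
                                  zero_inflation = pi, seed = 4))
  p0 <- zinb_zero_prob(mu, theta, pi)
  n <- nrow(tb$table)
  expect_equal(n, 10000)
  obs <- mean(tb$table$value == 0)
  expect_lt(abs(obs - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("table generation is deterministic and validates its spec", {
  a <- generate_table(table_spec(seed = 9))
  b <- generate_table(table_spec(seed = 9))
  expect_identical(a$table, b$table)
  expect_error(table_spec(zero_inflation = 1.2),
               class = "enspff_validation_error")
  expect_error(table_spec(theta = 0), class = "enspff_validation_error")
  expect_error(table_spec(n_replicates = 0), class = "enspff_validation_error")
})
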