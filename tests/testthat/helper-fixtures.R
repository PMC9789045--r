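# Small fixture builders shared across test files.

# Random uint8 image with the four standard channels.
random_image <- function(h = 16, w = 16, seed = 1,
                         roles = c("DAPI", "B3T", "ASYN_AGG", "PFF_TAG")) {
  withr::with_seed(seed, {
    px <- array(sample(0:255, h * w * length(roles), replace = TRUE),
                dim = c(h, w, length(roles)))
    multichannel_image(px, roles)
  })
}

# Two-level (foreground/background) noiseless image from a mask.
two_level_image <- function(mask, fg = 200, bg = 10,
                            roles = c("DAPI", "B3T")) {
  px <- array(bg, dim = c(dim(mask), length(roles)))
  for (i in seq_along(roles)) {
    plane <- matrix(bg, nrow(mask), ncol(mask))
    plane[mask] <- fg
    px[, , i] <- plane
  }
  multichannel_image(px, roles)
}

# Random sorted spike train with bursty clumps mixed in.
random_spike_train <- function(seed, n_range = c(0, 40), t_max = 10) {
  withr::with_seed(seed, {
    n <- sample(n_range[1]:n_range[2], 1)
    base <- runif(n, 0, t_max)
    # add occasional tight clumps so burst windows actually occur
    if (n > 4 && runif(1) < 0.6) {
      centre <- runif(1, 0, t_max - 0.2)
      base <- c(base, centre + cumsum(runif(sample(3:6, 1), 0.005, 0.04)))
    }
    sort(base)
  })
}

# Brute-force burst oracle: mark every spike contained in ANY subwindow of
# >= n consecutive spikes spanning <= span_s, then report maximal marked runs.
burst_oracle <- function(times, n = 4L, span_s = 0.1) {
  k <- length(times)
  marked <- logical(k)
  if (k >= n) {
    for (i in seq_len(k)) {
      for (j in i:k) {
        if (j - i + 1L >= n && times[j] - times[i] <= span_s) {
          marked[i:j] <- TRUE
        }
        if (times[j] - times[i] > span_s) break
      }
    }
  }
  if (!any(marked)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          n_spikes = integer(0)))
  }
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  tibble::tibble(start_s = times[starts[runs]], end_s = times[ends[runs]],
                 n_spikes = as.integer(ends[runs] - starts[runs] + 1L))
}
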