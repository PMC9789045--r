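#' Specification of a synthetic immunofluorescence scene
#'
#' Describes a four-channel synthetic micrograph with known ground truth:
#' somas are disks with a concentric nucleus, neurites are smooth random-walk
#' polylines of fixed width emanating from soma boundaries, and the
#' preformed-fibril tag channel carries bright puncta. Channel intensities
#' are two-level (foreground/background, uint8 units) with additive Gaussian
#' noise and optional Poisson shot noise on the signal.
#'
#' Default levels approximate a well-stained 8-bit acquisition: strong
#' beta-3-tubulin and nuclear signal over a dim background, a weaker diffuse
#' aggregate channel, and sparse bright fibril-tag puncta.
#'
#' @param image_shape integer pair, image height and width in pixels.
#' @param n_somas number of somas to place (0 allowed).
#' @param soma_radius_px length-2 range of soma radii, pixels.
#' @param neurites_per_soma length-2 integer range of neurites per soma.
#' @param neurite_width_px neurite width, pixels (odd widths render
#'   symmetrically).
#' @param channel_levels named list mapping each channel role to
#'   `c(foreground, background)` means in uint8 units; foreground must
#'   exceed background.
#' @param pff_puncta list with `n` (count), `radius_px` and `intensity`
#'   (uint8) describing fibril-tag puncta placed inside the neuron
#'   morphology.
#' @param noise_sd Gaussian noise standard deviation, uint8 units.
#' @param poisson if `TRUE`, pixel values are Poisson-resampled (shot noise)
#'   before Gaussian noise is added.
#' @param nucleus_radius_frac nucleus radius as a fraction of its soma's
#'   radius.
#' @param seed RNG seed; fixes the output bit-exactly.
#'
#' @return An object of class `scene_spec`.
#' @seealso [generate_scene()]
#' @export
scene_spec <- function(image_shape = c(512L, 512L),
                       n_somas = 8L,
                       soma_radius_px = c(18, 28),
                       neurites_per_soma = c(2L, 4L),
                       neurite_width_px = 5L,
                       channel_levels = list(
                         DAPI     = c(180, 8),
                         B3T      = c(200, 10),
                         ASYN_AGG = c(60, 10),
                         PFF_TAG  = c(240, 8)
                       ),
                       pff_puncta = list(n = 30L, radius_px = 2L, intensity = 240),
                       noise_sd = 15,
                       poisson = FALSE,
                       nucleus_radius_frac = 0.5,
                       seed = 1L) {
  spec <- structure(
    list(image_shape = as.integer(image_shape), n_somas = as.integer(n_somas),
         soma_radius_px = soma_radius_px,
         neurites_per_soma = as.integer(neurites_per_soma),
         neurite_width_px = as.integer(neurite_width_px),
         channel_levels = channel_levels, pff_puncta = pff_puncta,
         noise_sd = noise_sd, poisson = isTRUE(poisson),
         nucleus_radius_frac = nucleus_radius_frac, seed = as.integer(seed)),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (length(spec$image_shape) != 2L || any(spec$image_shape < 8L)) {
    rlang::abort("image_shape must be two integers >= 8.",
                 class = "enspff_validation_error")
  }
  if (spec$n_somas < 0L) {
    rlang::abort("n_somas must be >= 0.", class = "enspff_validation_error")
  }
  for (role in names(spec$channel_levels)) {
    lv <- spec$channel_levels[[role]]
    if (length(lv) != 2L || lv[1] <= lv[2]) {
      rlang::abort(paste0("channel '", role,
                          "': foreground mean must exceed background mean."),
                   class = "enspff_validation_error")
    }
    if (any(lv < 0) || any(lv > 255)) {
      rlang::abort(paste0("channel '", role, "': levels must lie in [0, 255]."),
                   class = "enspff_validation_error")
    }
  }
  p <- spec$pff_puncta
  if (p$intensity < 0 || p$intensity > 255) {
    rlang::abort("puncta intensity must lie in [0, 255].",
                 class = "enspff_validation_error")
  }
  if (spec$noise_sd < 0) {
    rlang::abort("noise_sd must be >= 0.", class = "enspff_validation_error")
  }
  invisible(spec)
}

# Set pixels of a disk of radius r centred at (row, col) to TRUE.
stamp_disk <- function(mask, row, col, r) {
  h <- nrow(mask); w <- ncol(mask)
  rr <- max(1L, floor(row - r)):min(h, ceiling(row + r))
  cc <- max(1L, floor(col - r)):min(w, ceiling(col + r))
  if (length(rr) == 0 || length(cc) == 0) return(mask)
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  mask[rr, cc] <- mask[rr, cc] | (d2 <= r^2)
  mask
}

# Random-walk neurite polyline stamped as a fixed-width band.
stamp_neurite <- function(mask, row0, col0, heading, width, h, w, n_steps,
                          step_len = 2, turn_sd = 0.22) {
  r <- max(0L, (width - 1L) %/% 2L)
  row <- row0; col <- col0
  for (i in seq_len(n_steps)) {
    mask <- stamp_disk(mask, row, col, r)
    heading <- heading + rnorm(1, 0, turn_sd)
    row <- row + step_len * sin(heading)
    col <- col + step_len * cos(heading)
    if (row < 1 || row > h || col < 1 || col > w) break
  }
  mask
}

#' Generate a ground-truthed synthetic micrograph
#'
#' Renders the scene described by a [scene_spec()]: a noiseless four-channel
#' image is constructed first (nuclei on DAPI, soma-plus-neurite morphology
#' on B3T and the aggregate channel, puncta on the fibril-tag channel), then
#' optional Poisson shot noise and additive Gaussian noise are applied and
#' values are clipped to `[0, 255]`. The returned ground truth carries the
#' exact soma/neurite masks, nuclei centres, the noiseless image, and the
#' per-compartment noiseless mean of every channel.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{image}{a [multichannel_image()] (noisy, uint8 scale).}
#'   \item{truth}{a list of class `scene_ground_truth`: `soma_mask`,
#'     `neurite_mask`, `neuron_mask`, `nuclei_centers` (matrix of
#'     row/col/radius), `puncta_mask`, `clean` (noiseless H x W x C array)
#'     and `compartment_means` (channel x compartment matrix).}
#' }
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(image_shape = c(96, 96), n_somas = 2,
#'                                 seed = 3))
#' sum(sc$truth$soma_mask & sc$truth$neurite_mask) # disjoint compartments
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  roles <- names(spec$channel_levels)

  soma_mask <- matrix(FALSE, h, w)
  neurite_raw <- matrix(FALSE, h, w)
  nuclei_mask <- matrix(FALSE, h, w)
  centers <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("row", "col", "radius")))

  placed <- matrix(numeric(0), ncol = 3) # row, col, radius
  if (spec$n_somas > 0L) {
    for (s in seq_len(spec$n_somas)) {
      r <- runif(1, spec$soma_radius_px[1], spec$soma_radius_px[2])
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        row <- runif(1, r + 1, h - r)
        col <- runif(1, r + 1, w - r)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - row)^2 + (placed[, 2] - col)^2) >
                (placed[, 3] + r + 2))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        rlang::abort(
          "could not place non-overlapping somas; reduce n_somas or radii.",
          class = "enspff_placement_error")
      }
      placed <- rbind(placed, c(row, col, r))
      soma_mask <- stamp_disk(soma_mask, row, col, r)
      rn <- spec$nucleus_radius_frac * r
      nuclei_mask <- stamp_disk(nuclei_mask, row, col, rn)
      centers <- rbind(centers, c(row, col, rn))

      n_neur <- sample(spec$neurites_per_soma[1]:spec$neurites_per_soma[2], 1)
      for (k in seq_len(n_neur)) {
        ang <- runif(1, 0, 2 * pi)
        start_row <- row + (r + 1) * sin(ang)
        start_col <- col + (r + 1) * cos(ang)
        n_steps <- sample(40:90, 1)
        neurite_raw <- stamp_neurite(neurite_raw, start_row, start_col, ang,
                                     spec$neurite_width_px, h, w, n_steps)
      }
    }
  }
  neurite_mask <- neurite_raw & !soma_mask
  neuron_mask <- soma_mask | neurite_mask

  # puncta restricted to the neuron morphology (uptaken fibrils)
  puncta_mask <- matrix(FALSE, h, w)
  n_puncta <- spec$pff_puncta$n
  inside <- which(neuron_mask)
  if (n_puncta > 0L && length(inside) > 0L) {
    at <- sample(inside, min(n_puncta, length(inside)),
                 replace = length(inside) < n_puncta)
    for (idx in at) {
      row <- ((idx - 1L) %% h) + 1L
      col <- ((idx - 1L) %/% h) + 1L
      puncta_mask <- stamp_disk(puncta_mask, row, col, spec$pff_puncta$radius_px)
    }
  }

  clean <- array(0, dim = c(h, w, length(roles)))
  for (i in seq_along(roles)) {
    lv <- spec$channel_levels[[roles[i]]]
    plane <- matrix(lv[2], h, w)
    fg <- switch(roles[i],
                 DAPI = nuclei_mask,
                 B3T = neuron_mask,
                 ASYN_AGG = neuron_mask,
                 PFF_TAG = matrix(FALSE, h, w))
    plane[fg] <- lv[1]
    if (roles[i] == "PFF_TAG") plane[puncta_mask] <- spec$pff_puncta$intensity
    clean[, , i] <- plane
  }

  noisy <- clean
  if (spec$poisson) {
    noisy[] <- rpois(length(noisy), lambda = as.vector(noisy))
  }
  if (spec$noise_sd > 0) {
    noisy <- noisy + rnorm(length(noisy), 0, spec$noise_sd)
  }
  noisy <- round(pmin(pmax(noisy, 0), 255))

  comp_masks <- list(whole = matrix(TRUE, h, w), neuron = neuron_mask,
                     soma = soma_mask, neurite = neurite_mask)
  means <- matrix(NA_real_, length(roles), length(comp_masks),
                  dimnames = list(roles, names(comp_masks)))
  for (i in seq_along(roles)) {
    for (j in seq_along(comp_masks)) {
      m <- comp_masks[[j]]
      means[i, j] <- if (any(m)) mean(clean[, , i][m]) else NA_real_
    }
  }

  truth <- structure(
    list(soma_mask = soma_mask, neurite_mask = neurite_mask,
         neuron_mask = neuron_mask, nuclei_centers = centers,
         puncta_mask = puncta_mask, clean = clean,
         compartment_means = means),
    class = "scene_ground_truth"
  )
  list(image = multichannel_image(noisy, roles), truth = truth)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`; equals 1 when both masks are empty (perfect
#' agreement on absence).
#'
#' @param a,b logical matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
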