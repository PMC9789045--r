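#' Mean channel intensity within a mask
#'
#' Arithmetic mean of a channel's pixels restricted to a compartment mask,
#' reported on the uint8 scale (0--255). The mean of an empty compartment is
#' undefined and returned as `NA` (never coerced to 0), matching how images
#' with no detected morphology are handled downstream.
#'
#' @param image a [multichannel_image()].
#' @param channel channel role.
#' @param mask logical mask of the image's shape.
#' @return mean intensity, or `NA_real_` for an empty mask.
#' @export
mean_intensity <- function(image, channel, mask) {
  chan <- get_channel(image, channel)
  check_mask_shape(chan, mask)
  if (!any(mask)) return(NA_real_)
  mean(chan[mask])
}

#' Elevated-area fraction within a mask
#'
#' Fraction of a compartment's pixels whose intensity strictly exceeds a
#' threshold — the study's complementary "area of elevated signal" metric.
#' The threshold rule is either a fixed uint8 cut-off or a per-region Otsu
#' threshold computed from the masked pixels; the rule actually applied is
#' attached as attributes for provenance.
#'
#' @param image a [multichannel_image()].
#' @param channel channel role.
#' @param mask logical mask.
#' @param rule `"otsu"` or `list(fixed = t)` with t in uint8 units.
#' @return fraction in `[0, 1]` with attributes `"rule"` and `"threshold"`;
#'   `NA_real_` for an empty mask.
#' @export
elevated_area_fraction <- function(image, channel, mask, rule = "otsu") {
  chan <- get_channel(image, channel)
  check_mask_shape(chan, mask)
  if (!any(mask)) return(NA_real_)
  vals <- chan[mask]
  if (identical(rule, "otsu")) {
    t <- otsu_threshold(vals)
    rule_name <- "otsu"
  } else if (is.list(rule) && !is.null(rule$fixed)) {
    t <- rule$fixed
    rule_name <- "fixed"
  } else {
    rlang::abort("rule must be \"otsu\" or list(fixed = t).",
                 class = "enspff_validation_error")
  }
  frac <- sum(vals > t) / length(vals)
  attr(frac, "rule") <- rule_name
  attr(frac, "threshold") <- t
  frac
}

#' Maximum channel intensity of an image
#'
#' The study's maximum-intensity-pixel assessment: the brightest pixel of a
#' channel over the whole image.
#'
#' @param image a [multichannel_image()].
#' @param channel channel role.
#' @return maximum intensity, uint8 scale.
#' @export
max_intensity <- function(image, channel) {
  max(get_channel(image, channel))
}

check_mask_shape <- function(chan, mask) {
  if (!is.logical(mask) || !identical(dim(chan), dim(mask))) {
    rlang::abort("mask must be a logical matrix matching the image shape.",
                 class = "enspff_validation_error")
  }
}

#' Count nuclei in the DAPI channel
#'
#' Self-contained nuclei counter: threshold the DAPI channel, discard
#' components below `min_nucleus_area_px`, split touching nuclei by a
#' distance-transform watershed, and count the resulting objects. Centroids
#' are reported in (row, col) pixel coordinates.
#'
#' @param image a [multichannel_image()] with a `DAPI` channel.
#' @param params a [seg_params()] (threshold rule and minimum nucleus area).
#' @return A list of class `nuclei_result`: `count` and `centroids`
#'   (count x 2 matrix).
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(image_shape = c(128, 128), n_somas = 3,
#'                                 noise_sd = 0, seed = 5))
#' count_nuclei(sc$image)$count
count_nuclei <- function(image, params = seg_params()) {
  chan <- get_channel(image, "DAPI")
  th <- threshold_channel(chan, params)
  mask <- remove_small_objects(th$mask, params$min_nucleus_area_px)
  if (!any(mask)) {
    return(structure(list(count = 0L,
                          centroids = matrix(numeric(0), ncol = 2,
                                             dimnames = list(NULL, c("row", "col")))),
                     class = "nuclei_result"))
  }
  dm <- EBImage::distmap(mask * 1)
  lab <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  lab[!mask] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  cent <- t(vapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  colnames(cent) <- c("row", "col")
  structure(list(count = length(ids), centroids = cent),
            class = "nuclei_result")
}

#' Growth-cone activity metrics
#'
#' Filopodial activity is the sum of extension and retraction events per
#' minute of observation; the normalised form divides by the filopodia
#' count (undefined — `NA` — for a growth cone with no filopodia).
#'
#' @param filopodia_count number of filopodia on the growth cone.
#' @param extension_events,retraction_events event counts over the
#'   observation window.
#' @param observation_minutes observation duration, minutes (> 0).
#' @return A list with `activity_per_min` and
#'   `activity_per_filopodium_per_min`.
#' @export
#' @examples
#' growth_cone_metrics(4, 3, 2, 5) # 1 event/min, 0.25 per filopodium
growth_cone_metrics <- function(filopodia_count, extension_events,
                                retraction_events, observation_minutes) {
  counts <- c(filopodia_count, extension_events, retraction_events)
  if (any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("event and filopodia counts must be non-negative integers.",
                 class = "enspff_validation_error")
  }
  if (observation_minutes <= 0) {
    rlang::abort("observation_minutes must be > 0.",
                 class = "enspff_validation_error")
  }
  activity <- (extension_events + retraction_events) / observation_minutes
  normalised <- if (filopodia_count > 0) activity / filopodia_count else NA_real_
  list(activity_per_min = activity,
       activity_per_filopodium_per_min = normalised)
}

#' Per-compartment metrics table for one image
#'
#' Applies [mean_intensity()], [elevated_area_fraction()] and
#' [max_intensity()] to every compartment x channel combination of a mask
#' set, in the tidy layout the statistical layer consumes.
#'
#' @param image a [multichannel_image()].
#' @param masks a `morphology_masks` object from [build_masks()].
#' @param image_id identifier copied into every row.
#' @param channels channel roles to quantify (default: all present).
#' @param elevated_rule rule passed to [elevated_area_fraction()].
#' @return tibble with columns `image_id`, `compartment`, `channel`,
#'   `mean_intensity`, `elevated_fraction`, `max_intensity`, `n_pixels`.
#' @export
compartment_metrics <- function(image, masks, image_id = "img",
                                channels = image$channel_roles,
                                elevated_rule = "otsu") {
  validate_masks(masks)
  comps <- c("whole", "neuron", "soma", "neurite")
  rows <- list()
  for (comp in comps) {
    m <- masks[[comp]]
    for (ch in channels) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_id = image_id, compartment = comp, channel = ch,
        mean_intensity = mean_intensity(image, ch, m),
        elevated_fraction = as.numeric(elevated_area_fraction(image, ch, m,
                                                              elevated_rule)),
        max_intensity = max_intensity(image, ch),
        n_pixels = sum(m)
      )
    }
  }
  dplyr::bind_rows(rows)
}
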