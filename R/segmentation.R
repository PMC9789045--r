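#' Segmentation parameters
#'
#' Parameters of the morphology-mask construction: the thresholding rule for
#' the beta-3-tubulin and DAPI channels, disk-shaped structuring-element
#' radii for morphological cleanup, minimum object sizes, and the nucleus
#' dilation that seeds the soma region. All are recorded in the provenance
#' of every mask set so a run can be reproduced from its outputs.
#'
#' @param threshold_method `"otsu"` (per-image Otsu threshold) or `"fixed"`.
#' @param fixed_threshold uint8 threshold used when `threshold_method` is
#'   `"fixed"`; pixels strictly above it are foreground.
#' @param opening_radius_px disk radius of the morphological opening applied
#'   to the neuron mask (removes noise specks); 0 disables.
#' @param closing_radius_px disk radius of the closing applied before the
#'   opening (bridges small gaps in neurites); 0 disables.
#' @param min_object_area_px connected components of the neuron mask smaller
#'   than this are removed.
#' @param nucleus_dilation_radius_px disk radius by which thresholded nuclei
#'   are dilated to form the soma seed.
#' @param min_nucleus_area_px nuclei components smaller than this are
#'   discarded before dilation.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(threshold_method = c("otsu", "fixed"),
                       fixed_threshold = 100,
                       opening_radius_px = 1L,
                       closing_radius_px = 2L,
                       min_object_area_px = 64L,
                       nucleus_dilation_radius_px = 11L,
                       min_nucleus_area_px = 30L) {
  threshold_method <- match.arg(threshold_method)
  if (fixed_threshold < 0 || fixed_threshold > 255) {
    rlang::abort("fixed_threshold must lie in [0, 255].",
                 class = "enspff_validation_error")
  }
  radii <- c(opening_radius_px, closing_radius_px, nucleus_dilation_radius_px)
  if (any(radii < 0)) {
    rlang::abort("structuring-element radii must be >= 0.",
                 class = "enspff_validation_error")
  }
  structure(
    list(threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         opening_radius_px = as.integer(opening_radius_px),
         closing_radius_px = as.integer(closing_radius_px),
         min_object_area_px = as.integer(min_object_area_px),
         nucleus_dilation_radius_px = as.integer(nucleus_dilation_radius_px),
         min_nucleus_area_px = as.integer(min_nucleus_area_px)),
    class = "seg_params"
  )
}

disc_kernel <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

# Threshold a uint8 channel; returns list(mask, threshold, saturated_flag).
threshold_channel <- function(channel, params) {
  constant <- diff(range(channel)) == 0
  t <- if (params$threshold_method == "fixed") params$fixed_threshold
       else otsu_threshold(as.vector(channel))
  list(mask = channel > t, threshold = t, constant_channel = constant)
}

remove_small_objects <- function(mask, min_area) {
  if (min_area <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.matrix(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Segment the neuron morphology from the beta-3-tubulin channel
#'
#' Threshold (Otsu by default), then morphological closing and opening with
#' disk structuring elements, then removal of small connected components.
#' With all radii zero and `min_object_area_px <= 1` the result is the exact
#' level set of the threshold.
#'
#' @param image a [multichannel_image()] with a `B3T` channel.
#' @param params a [seg_params()].
#' @return logical H x W mask. The applied threshold is attached as
#'   attribute `"threshold"`; attribute `"constant_channel"` flags a
#'   degenerate (constant, e.g. saturated) channel.
#' @export
segment_neuron <- function(image, params = seg_params()) {
  chan <- get_channel(image, "B3T")
  th <- threshold_channel(chan, params)
  mask <- th$mask
  if (th$constant_channel) {
    rlang::warn("B3T channel is constant; thresholding is degenerate.")
  }
  if (params$closing_radius_px > 0 && any(mask)) {
    mask <- as.matrix(EBImage::closing(mask * 1,
                                       disc_kernel(params$closing_radius_px))) > 0.5
  }
  if (params$opening_radius_px > 0 && any(mask)) {
    mask <- as.matrix(EBImage::opening(mask * 1,
                                       disc_kernel(params$opening_radius_px))) > 0.5
  }
  mask <- remove_small_objects(mask, params$min_object_area_px)
  attr(mask, "threshold") <- th$threshold
  attr(mask, "constant_channel") <- th$constant_channel
  mask
}

#' Segment the soma compartment
#'
#' Nuclei seed the somas: the DAPI channel is thresholded, small components
#' are discarded, the surviving nuclei are dilated by a disk, and the result
#' is intersected with the neuron mask — which guarantees soma ⊆ neuron.
#'
#' @param image a [multichannel_image()] with a `DAPI` channel.
#' @param neuron logical neuron mask of the same shape.
#' @param params a [seg_params()].
#' @return logical H x W soma mask with attribute `"threshold"`.
#' @export
segment_soma <- function(image, neuron, params = seg_params()) {
  chan <- get_channel(image, "DAPI")
  if (!identical(dim(chan), dim(neuron))) {
    rlang::abort("neuron mask shape must match the image.",
                 class = "enspff_validation_error")
  }
  th <- threshold_channel(chan, params)
  nuclei <- remove_small_objects(th$mask, params$min_nucleus_area_px)
  if (params$nucleus_dilation_radius_px > 0 && any(nuclei)) {
    nuclei <- as.matrix(EBImage::dilate(
      nuclei * 1, disc_kernel(params$nucleus_dilation_radius_px))) > 0.5
  }
  soma <- nuclei & neuron
  attr(soma, "threshold") <- th$threshold
  soma
}

#' Derive the neurite compartment
#'
#' Neurites are the neuron morphology minus the somas, making
#' whole/neuron/soma/neurite a consistent compartment system.
#'
#' @param neuron,soma logical masks of equal shape with `soma ⊆ neuron`.
#' @return logical neurite mask (`neuron & !soma`).
#' @export
derive_neurite <- function(neuron, soma) {
  if (!identical(dim(neuron), dim(soma))) {
    rlang::abort("neuron and soma masks must have the same shape.",
                 class = "enspff_validation_error")
  }
  neuron & !soma
}

#' Build the full morphology mask set
#'
#' Composes [segment_neuron()], [segment_soma()] and [derive_neurite()] and
#' records the parameters used. The returned object satisfies the
#' compartment invariants: `soma ⊆ neuron`, `neurite ⊆ neuron`,
#' `soma ∩ neurite = ∅`, `soma ∪ neurite = neuron`.
#'
#' @param image a [multichannel_image()] with `DAPI` and `B3T` channels.
#' @param params a [seg_params()].
#' @return An object of class `morphology_masks`: logical masks `whole`,
#'   `neuron`, `soma`, `neurite`, plus `provenance` (parameters, applied
#'   thresholds, degenerate-channel warnings).
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(image_shape = c(96, 96), n_somas = 2,
#'                                 noise_sd = 5, seed = 1))
#' m <- build_masks(sc$image)
#' all(m$soma | m$neurite) == all(m$neuron)
build_masks <- function(image, params = seg_params()) {
  neuron <- segment_neuron(image, params)
  soma <- segment_soma(image, neuron, params)
  neurite <- derive_neurite(neuron, soma)
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  masks <- structure(
    list(
      whole = matrix(TRUE, h, w),
      neuron = structure(as.logical(neuron), dim = dim(neuron)),
      soma = structure(as.logical(soma), dim = dim(soma)),
      neurite = neurite,
      provenance = list(
        params = unclass(params),
        neuron_threshold = attr(neuron, "threshold"),
        soma_threshold = attr(soma, "threshold"),
        degenerate_b3t = isTRUE(attr(neuron, "constant_channel"))
      )
    ),
    class = "morphology_masks"
  )
  validate_masks(masks)
  masks
}

#' Assert the compartment set-algebra invariants of a mask set
#'
#' @param masks a `morphology_masks` object.
#' @return `masks`, invisibly; aborts if any invariant is violated.
#' @export
validate_masks <- function(masks) {
  stopifnot(inherits(masks, "morphology_masks"))
  with(masks, {
    if (!all(whole)) rlang::abort("whole mask must cover every pixel.")
    if (any(soma & !neuron)) rlang::abort("soma must be a subset of neuron.")
    if (any(neurite & !neuron)) rlang::abort("neurite must be a subset of neuron.")
    if (any(soma & neurite)) rlang::abort("soma and neurite must be disjoint.")
    if (!identical(unname(soma | neurite), unname(neuron))) {
      rlang::abort("soma and neurite must partition the neuron mask.")
    }
  })
  invisible(masks)
}

#' @export
print.morphology_masks <- function(x, ...) {
  cat(sprintf(
    "<morphology_masks> %d x %d px | neuron %d px, soma %d px, neurite %d px\n",
    nrow(x$neuron), ncol(x$neuron), sum(x$neuron), sum(x$soma), sum(x$neurite)))
  invisible(x)
}
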