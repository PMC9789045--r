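#' Multi-channel fluorescence micrograph
#'
#' Container for an 8-bit multi-channel fluorescence image. Pixels are stored
#' as an H x W x C numeric array on the uint8 scale (0--255); each channel is
#' tagged with its biological role: nuclear stain (`DAPI`), beta-3 tubulin
#' neuronal marker (`B3T`), aggregated alpha-synuclein immunostain
#' (`ASYN_AGG`) or the fluorescent preformed-fibril tag (`PFF_TAG`).
#'
#' @param pixels numeric array, H x W x C (or H x W for a single channel),
#'   values in `[0, 255]`.
#' @param channel_roles character vector of length C; each a role from
#'   `DAPI`, `B3T`, `ASYN_AGG`, `PFF_TAG`.
#' @param pixel_size_um optional pixel edge length in micrometres.
#'
#' @return An object of class `multichannel_image` with elements `pixels`,
#'   `channel_roles` and `pixel_size_um`.
#' @export
#' @examples
#' px <- array(runif(16 * 16 * 2, 0, 255), dim = c(16, 16, 2))
#' img <- multichannel_image(px, c("DAPI", "B3T"))
#' dim(get_channel(img, "B3T"))
multichannel_image <- function(pixels, channel_roles, pixel_size_um = NULL) {
  if (length(dim(pixels)) == 2L) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  if (length(dim(pixels)) != 3L) {
    rlang::abort("`pixels` must be an H x W x C array.", class = "enspff_validation_error")
  }
  if (dim(pixels)[3] != length(channel_roles)) {
    rlang::abort("channel count must equal the number of channel roles.",
                 class = "enspff_validation_error")
  }
  bad <- setdiff(channel_roles, CHANNEL_ROLES)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")),
                 class = "enspff_channel_error")
  }
  if (anyDuplicated(channel_roles)) {
    rlang::abort("channel roles must be unique.", class = "enspff_validation_error")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    rlang::abort("pixel values must be finite and within [0, 255].",
                 class = "enspff_validation_error")
  }
  structure(
    list(pixels = pixels, channel_roles = as.character(channel_roles),
         pixel_size_um = pixel_size_um),
    class = "multichannel_image"
  )
}

#' Extract one channel of a multi-channel image
#'
#' @param image a [multichannel_image()].
#' @param role channel role to extract (`"DAPI"`, `"B3T"`, `"ASYN_AGG"` or
#'   `"PFF_TAG"`).
#' @return numeric H x W matrix on the uint8 scale.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "multichannel_image"))
  idx <- match(role, image$channel_roles)
  if (is.na(idx)) {
    rlang::abort(paste0("channel role '", role, "' not present in image."),
                 class = "enspff_channel_error")
  }
  image$pixels[, , idx]
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multichannel_image> %d x %d px, channels: %s\n",
              d[1], d[2], paste(x$channel_roles, collapse = ", ")))
  invisible(x)
}

#' Write / read a multi-channel image as multi-page TIFF
#'
#' One 8-bit TIFF page per channel; channel roles (and pixel size) go to a
#' JSON sidecar `<path>.json` so the file round-trips losslessly.
#'
#' @param image a [multichannel_image()].
#' @param path TIFF file path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a [multichannel_image()].
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  pages <- lapply(seq_along(image$channel_roles), function(i) {
    image$pixels[, , i] / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(channel_roles = image$channel_roles,
         pixel_size_um = image$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) px[, , i] <- round(pages[[i]] * 255)
  multichannel_image(px, meta$channel_roles,
                     pixel_size_um = meta$pixel_size_um)
}

#' Write / read a binary mask as single-page TIFF
#'
#' @param mask logical matrix.
#' @param path TIFF file path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0.5
}
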