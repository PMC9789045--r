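#' Otsu threshold of uint8 intensities
#'
#' Between-class-variance-maximising threshold of a sample of 0--255
#' intensities, computed on a 256-bin histogram. Implemented as a vector
#' routine so the same rule can be applied to a whole channel or to the
#' pixels inside an arbitrary mask (e.g. the elevated-area rule restricted
#' to the neuron compartment).
#'
#' @param values numeric vector of intensities in `[0, 255]`.
#' @return The threshold t (a value in `[0, 255)`); pixels with intensity
#'   strictly greater than t are foreground.
#' @export
#' @examples
#' x <- c(rnorm(500, 20, 5), rnorm(500, 200, 5))
#' otsu_threshold(x) # separates the two modes
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    rlang::abort("cannot compute an Otsu threshold of an empty sample.",
                 class = "enspff_validation_error")
  }
  bins <- pmin(pmax(floor(values), 0), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                    # class-0 probability up to bin t
  mu <- cumsum(p * (0:255))             # first moment up to bin t
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254 (foreground = bins > t)
  w0 <- omega[1:255]
  sigma_b <- (mu_t * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  if (all(sigma_b == -Inf)) return(0)   # constant image: everything > 0 is fg
  which.max(sigma_b) - 1
}
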