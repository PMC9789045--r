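#' Variance-stabilising transform specification
#'
#' The study analyses skewed intensity and activity outcomes on a
#' transformed scale: Box-Cox with a profile-likelihood-estimated exponent,
#' a plain log, or an integer root (4th or 6th root in the figures). Zeros
#' on the uint8 scale are handled by an additive offset applied before the
#' transform; the offset travels with the specification object, so every
#' transform is invertible.
#'
#' @param kind `"boxcox"`, `"log"` or `"root"`.
#' @param lambda Box-Cox exponent; `NULL` (default) estimates it by profile
#'   maximum likelihood on a grid when the transform is applied.
#' @param root_order integer root order (>= 2), e.g. 4 or 6.
#' @param offset value added to the data before transforming (default 0;
#'   0.5 is the conventional choice for uint8 data containing zeros).
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("boxcox", "log", "root"),
                           lambda = NULL, root_order = 4L, offset = 0) {
  kind <- match.arg(kind)
  if (kind == "root" && (root_order < 2 || root_order != floor(root_order))) {
    rlang::abort("root_order must be an integer >= 2.",
                 class = "enspff_validation_error")
  }
  structure(list(kind = kind, lambda = lambda,
                 root_order = as.integer(root_order), offset = offset),
            class = "transform_spec")
}

# exponents within 1e-5 of zero are treated as the log limit, where the
# generic formula loses precision to cancellation
boxcox_value <- function(y, lambda) {
  if (abs(lambda) < 1e-5) log(y) else (y^lambda - 1) / lambda
}

#' Profile-likelihood estimate of the Box-Cox exponent
#'
#' Maximises the Box-Cox profile log-likelihood
#' `-n/2 log(sigma2_hat(lambda)) + (lambda - 1) * sum(log y)` over a grid,
#' where `sigma2_hat` is the ML residual variance of the transformed data
#' about its mean.
#'
#' @param y positive data.
#' @param grid candidate exponents (default `seq(-2, 2, by = 0.01)`).
#' @return the maximising exponent.
#' @export
estimate_boxcox_lambda <- function(y, grid = seq(-2, 2, by = 0.01)) {
  if (any(y <= 0)) {
    rlang::abort("Box-Cox requires strictly positive data.",
                 class = "enspff_domain_error")
  }
  slog <- sum(log(y))
  n <- length(y)
  ll <- vapply(grid, function(l) {
    z <- boxcox_value(y, l)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (l - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}

#' Apply a variance-stabilising transform
#'
#' @param values numeric outcomes.
#' @param spec a [transform_spec()].
#' @return transformed values; for Box-Cox the exponent used (fixed or
#'   estimated) is attached as attribute `"lambda"`.
#' @export
#' @examples
#' apply_transform(c(1, 8, 27), transform_spec("root", root_order = 3))
#' attr(apply_transform(rlnorm(200), transform_spec("boxcox")), "lambda")
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  y <- values + spec$offset
  if (spec$kind %in% c("boxcox", "log") && any(y <= 0)) {
    bad <- which(y <= 0)
    rlang::abort(
      paste0(spec$kind, " transform needs positive values after offset; ",
             "offending rows: ", paste(utils::head(bad, 10), collapse = ", "),
             if (length(bad) > 10) ", ..." else ""),
      class = "enspff_domain_error")
  }
  if (spec$kind == "root" && any(y < 0)) {
    rlang::abort("root transform needs non-negative values after offset.",
                 class = "enspff_domain_error")
  }
  out <- switch(spec$kind,
    log = log(y),
    root = y^(1 / spec$root_order),
    boxcox = {
      lambda <- spec$lambda %||% estimate_boxcox_lambda(y)
      z <- boxcox_value(y, lambda)
      attr(z, "lambda") <- lambda
      z
    })
  out
}

#' Invert a transform
#'
#' @param transformed transformed values.
#' @param spec the [transform_spec()] used (for Box-Cox, `lambda` must be
#'   the fixed or estimated exponent).
#' @param lambda Box-Cox exponent override (e.g. the `"lambda"` attribute
#'   returned by [apply_transform()]).
#' @return values on the original scale.
#' @export
invert_transform <- function(transformed, spec, lambda = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  z <- as.numeric(transformed)
  y <- switch(spec$kind,
    log = exp(z),
    root = z^spec$root_order,
    boxcox = {
      l <- lambda %||% spec$lambda %||% attr(transformed, "lambda")
      if (is.null(l)) {
        rlang::abort("Box-Cox inversion needs the lambda that was applied.",
                     class = "enspff_validation_error")
      }
      if (abs(l) < 1e-5) exp(z) else (l * z + 1)^(1 / l)
    })
  y - spec$offset
}
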