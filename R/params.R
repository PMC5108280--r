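#' Invasion-model constants
#'
#' The seven constants of the three-probability invasion model:
#'
#' * `alpha` — ceiling of the establishment probability (dimensionless,
#'   in (0, 1]); reached when donor and recipient environments match.
#' * `beta` — distance-sigmoid steepness (dimensionless, > 0).
#' * `gamma` — distance-sigmoid scale, units km^beta (> 0); the sigmoid
#'   midpoint sits at `gamma^(1/beta)` km.
#' * `lambda` — per-volume inoculation rate (1/m^3, > 0).
#' * `mu` — en-route mortality rate (1/day, >= 0).
#' * `sigma_t` — temperature tolerance scale (degrees C, > 0).
#' * `sigma_s` — salinity tolerance scale (ppt, > 0).
#'
#' The defaults are documented placeholders, NOT the calibrated constants
#' of the source shipping model (which are not public): they give a
#' distance-sigmoid midpoint of 1000 km and order-of-magnitude plausible
#' introduction/establishment scales. Every function that consumes them
#' treats the parameter set as mandatory configuration; results obtained
#' with the defaults are flagged `non_canonical` in pipeline reports.
#'
#' @param alpha,beta,gamma,lambda,mu,sigma_t,sigma_s Model constants, see
#'   above.
#' @return A named list of class `model_params`.
#' @export
#' @examples
#' p <- model_params()
#' p_nonindigenous(1000, p) # 0.5 at the sigmoid midpoint
model_params <- function(alpha = 2e-4, beta = 4, gamma = 1000^4,
                         lambda = 3e-5, mu = 0.02,
                         sigma_t = 2, sigma_s = 10) {
  stopifnot(
    alpha > 0, alpha <= 1,
    beta > 0, gamma > 0,
    lambda > 0, mu >= 0,
    sigma_t > 0, sigma_s > 0
  )
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         mu = mu, sigma_t = sigma_t, sigma_s = sigma_s),
    class = "model_params",
    non_canonical = missing(alpha) && missing(beta) && missing(gamma) &&
      missing(lambda) && missing(mu) && missing(sigma_t) && missing(sigma_s)
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Invasion model constants:\n")
  cat(sprintf(
    "  alpha=%g  beta=%g  gamma=%g km^beta  lambda=%g /m^3  mu=%g /day  sigma_t=%g C  sigma_s=%g ppt\n",
    x$alpha, x$beta, x$gamma, x$lambda, x$mu, x$sigma_t, x$sigma_s
  ))
  if (isTRUE(attr(x, "non_canonical"))) {
    cat("  [NON-CANONICAL placeholder defaults - supply calibrated values]\n")
  }
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  do.call(model_params, as.list(x))
}
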