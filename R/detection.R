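#' Detection function model
#'
#' A perpendicular-distance detection function for binned strip-transect
#' data: half-normal `g(y) = exp(-y^2 / (2 sigma^2))` or hazard-rate
#' `g(y) = 1 - exp(-(y / sigma)^(-shape))`, together with the distance
#' cutpoints that define the intervals.
#'
#' @param form `"half_normal"` or `"hazard_rate"`.
#' @param sigma Scale parameter in meters, > 0.
#' @param shape Hazard-rate shape, > 1 (so that detection at the line is
#'   certain); ignored for the half-normal.
#' @param cutpoints Distance cutpoints in meters, from 0 to the strip
#'   half-width.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(form = c("half_normal", "hazard_rate"), sigma,
                            shape = NULL, cutpoints = c(0, 4 / 3, 8 / 3, 4)) {
  form <- match.arg(form)
  check_positive(sigma, "sigma")
  if (form == "hazard_rate") {
    stop_if(is.null(shape) || shape <= 1,
            "hazard-rate `shape` must be > 1")
  }
  stop_if(any(diff(cutpoints) <= 0) || cutpoints[1] != 0,
          "`cutpoints` must be strictly increasing and start at 0")
  structure(list(form = form, sigma = sigma, shape = shape,
                 cutpoints = cutpoints, w = cutpoints[length(cutpoints)]),
            class = "detection_model")
}

#' Evaluate a detection function
#'
#' @param model A [detection_model()].
#' @param y Perpendicular distances (meters), `>= 0`.
#' @return Detection probabilities `g(y)` in `(0, 1]`, with `g(0) = 1`.
#' @export
detection_g <- function(model, y) {
  stop_if(any(y < 0), "`y` must be >= 0")
  switch(model$form,
         half_normal = exp(-y^2 / (2 * model$sigma^2)),
         hazard_rate = ifelse(y == 0, 1,
                              1 - exp(-(y / model$sigma)^(-model$shape))))
}

# integral of g over [a, b]; closed form (error function) for the
# half-normal, adaptive quadrature for the hazard rate
g_integral <- function(model, a, b) {
  if (model$form == "half_normal") {
    s <- model$sigma
    s * sqrt(pi / 2) * (pracma::erf(b / (s * sqrt(2))) -
                          pracma::erf(a / (s * sqrt(2))))
  } else {
    mapply(function(lo, hi)
      stats::integrate(function(y) detection_g(model, y), lo, hi,
                       rel.tol = 1e-10, abs.tol = 1e-12)$value,
      a, b)
  }
}

#' Distance-interval detection probabilities
#'
#' Probability that a pellet group, uniform in distance across the strip,
#' falls in interval `k` and is detected:
#' `pi_k = \int_{c_{k-1}}^{c_k} g(y) dy / w`. Their sum is the overall
#' within-strip detection probability `P_a`.
#'
#' @param model A [detection_model()].
#' @return Numeric vector `pi_k`, one entry per interval.
#' @export
bin_probabilities <- function(model) {
  cp <- model$cutpoints
  g_integral(model, cp[-length(cp)], cp[-1]) / model$w
}

#' Effective strip half-width
#'
#' `mu = \int_0^w g(y) dy = w * P_a`: the half-width that, searched
#' perfectly, would yield the same expected number of detections as the
#' actual imperfect search of the strip.
#'
#' @param model A [detection_model()].
#' @return Effective half-width in meters, `<= w`.
#' @export
effective_half_width <- function(model) {
  g_integral(model, 0, model$w)
}

#' Conventional (Horvitz-Thompson style) dung density estimate
#'
#' A design-based cross-check for the integrated likelihood:
#' `D = n / (2 * mu * L)` with `mu` the effective half-width and `L` the
#' total line length. The CV combines Poisson count variance with (if
#' `sigma_se` is given) a delta-method term for the detection scale.
#'
#' @param n_retained Number of retained (non-midden) pellet events.
#' @param total_line_length Summed transect length in meters.
#' @param model A [detection_model()].
#' @param sigma_se Optional standard error of the detection scale.
#' @return A list with `density` (per m^2), `cv`, and `mu`.
#' @export
ht_density <- function(n_retained, total_line_length, model,
                       sigma_se = NULL) {
  stop_if(n_retained < 0, "`n_retained` must be >= 0")
  check_positive(total_line_length, "total_line_length")
  mu <- effective_half_width(model)
  d <- n_retained / (2 * mu * total_line_length)
  cv2 <- if (n_retained > 0) 1 / n_retained else NA_real_
  if (!is.null(sigma_se) && n_retained > 0) {
    # delta method on mu(sigma): numeric derivative
    h <- 1e-5 * model$sigma
    m2 <- model; m2$sigma <- model$sigma + h
    dmu <- (effective_half_width(m2) - mu) / h
    cv2 <- cv2 + (dmu * sigma_se / mu)^2
  }
  list(density = d, cv = sqrt(cv2), mu = mu)
}
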