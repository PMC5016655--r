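#' Dung-to-animal conversion rates
#'
#' Bundles the defecation rate and the mean pellet-group persistence time
#' that link standing pellet-group density to animal density. The decay
#' time may be given as a range (e.g. 490-520 days), in which case the
#' midpoint is used and the half-range is treated as two standard errors
#' unless an SE is supplied.
#'
#' @param defecation Pellet groups per animal per day.
#' @param decay_days Mean persistence time in days (ignored when
#'   `decay_range` is given).
#' @param defecation_se,decay_se Optional standard errors.
#' @param decay_range Optional length-2 vector (low, high) of decay days.
#' @return A list of class `conversion_rates`.
#' @export
conversion_rates <- function(defecation, decay_days = NULL,
                             defecation_se = 0, decay_se = NULL,
                             decay_range = NULL) {
  check_positive(defecation, "defecation")
  if (!is.null(decay_range)) {
    stop_if(length(decay_range) != 2 || any(decay_range <= 0),
            "`decay_range` must be two positive numbers")
    decay_days <- mean(decay_range)
    if (is.null(decay_se)) decay_se <- diff(range(decay_range)) / 4
  }
  check_positive(decay_days, "decay_days")
  structure(list(defecation = defecation, decay_days = decay_days,
                 defecation_se = defecation_se,
                 decay_se = decay_se %||% 0),
            class = "conversion_rates")
}

#' Convert pellet-group density to animal density
#'
#' Inverts the steady-state relation: `D_animal = D_dung / (r * T)` with
#' defecation rate `r` and mean decay time `T`.
#'
#' @param dung_density Pellet-group density (any area unit).
#' @param rates A [conversion_rates()].
#' @return Animal density in the same area unit.
#' @export
dung_to_animal <- function(dung_density, rates) {
  check_positive(rates$defecation, "defecation")
  check_positive(rates$decay_days, "decay_days")
  stop_if(any(dung_density < 0), "`dung_density` must be >= 0")
  dung_density / (rates$defecation * rates$decay_days)
}

#' Abundance with confidence interval
#'
#' `N = D_animal * area`. The default CI combines the CVs of the dung
#' density, the defecation rate and the decay time under independence on
#' the log scale (lognormal delta method); a seeded parametric bootstrap
#' (independent lognormal draws for the three components) is available as a
#' cross-check.
#'
#' @param animal_density Animals per unit area.
#' @param area Area in squared units matching the density.
#' @param density_cv CV of the dung-density estimate.
#' @param rates Optional [conversion_rates()] contributing rate CVs.
#' @param method `"delta"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param level Confidence level.
#' @return A list with `N`, `ci` (length 2), `cv` and `method`.
#' @export
abundance_estimate <- function(animal_density, area, density_cv = 0,
                               rates = NULL,
                               method = c("delta", "bootstrap"),
                               n_boot = 10000, seed = 1L, level = 0.95) {
  method <- match.arg(method)
  check_positive(area, "area")
  stop_if(animal_density < 0, "`animal_density` must be >= 0")
  N <- animal_density * area
  cv_r <- if (!is.null(rates)) rates$defecation_se / rates$defecation else 0
  cv_t <- if (!is.null(rates)) rates$decay_se / rates$decay_days else 0
  cv <- sqrt(density_cv^2 + cv_r^2 + cv_t^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delta" || N == 0) {
    if (cv > 0 && N > 0) {
      c_mult <- exp(z * sqrt(log(1 + cv^2)))
      ci <- c(N / c_mult, N * c_mult)
    } else ci <- c(N, N)
  } else {
    set.seed(seed)
    draw <- function(mean, cvx) {
      if (cvx == 0) return(rep(mean, n_boot))
      sd_log <- sqrt(log(1 + cvx^2))
      stats::rlnorm(n_boot, log(mean) - sd_log^2 / 2, sd_log)
    }
    nb <- draw(N, density_cv) * draw(1, cv_r)^-1 * draw(1, cv_t)^-1
    ci <- unname(stats::quantile(nb, c((1 - level) / 2,
                                       1 - (1 - level) / 2)))
  }
  list(N = N, ci = ci, cv = cv, method = method)
}
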