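#' Parameter-recovery experiment
#'
#' Repeatedly simulates surveys from a scenario, fits a given integrated
#' model to each, and summarizes estimator bias and Wald confidence-interval
#' coverage against the scenario's true parameter values. Confidence
#' intervals for the variance parameters are formed on the log scale and
#' back-transformed.
#'
#' @param scenario A [simulation_scenario()]; its first species is used.
#' @param spec An [integrated_spec()] matching the generator's density
#'   model.
#' @param n_reps Number of simulation replicates.
#' @param seed Root seed; replicate seeds derive from it.
#' @param options [fit_options()] for each fit.
#' @param level Nominal CI level.
#' @return A list with `estimates` (reps x parameters), `truth`, `summary`
#'   (per parameter: mean estimate, bias, Monte-Carlo SE of the bias,
#'   coverage), and `n_converged`.
#' @export
parameter_recovery <- function(scenario, spec, n_reps = 200, seed = 1L,
                               options = fit_options(n_starts = 1),
                               level = 0.95) {
  sp <- names(scenario$species)[1]
  pars <- scenario$species[[sp]]
  truth <- c("(Intercept)" = pars$beta0, pars$beta,
             log_sigma_b = log(pars$sigma_b),
             log_sigma_det = log(pars$sigma_det))
  seeds <- split_seed(seed, n_reps)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ds <- simulate_survey(scenario, seed = seeds[r])
    fit <- tryCatch(fit_integrated(ds, spec, options),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || is.null(fit$vcov)) next
    th <- fit$theta
    se <- sqrt(diag(fit$vcov))
    common <- intersect(names(truth), names(th))
    cov_flags <- abs(th[common] - truth[common]) <= z * se[common]
    rows[[r]] <- list(theta = th[common], covered = cov_flags)
  }
  rows <- Filter(Negate(is.null), rows)
  stop_if(length(rows) == 0, "no replicate converged")
  est <- do.call(rbind, lapply(rows, function(x) x$theta))
  covered <- do.call(rbind, lapply(rows, function(x) x$covered))
  common <- colnames(est)
  summary <- data.frame(
    parameter = common,
    truth = truth[common],
    mean_estimate = colMeans(est),
    bias = colMeans(est) - truth[common],
    mc_se = apply(est, 2, stats::sd) / sqrt(nrow(est)),
    coverage = colMeans(covered),
    row.names = NULL)
  list(estimates = est, truth = truth[common], summary = summary,
       n_converged = nrow(est))
}

#' Density round-trip experiment
#'
#' Simulates surveys at a known animal density (via the steady-state dung
#' relation), fits the global null integrated model to each replicate,
#' converts the fitted marginal dung density back to animal density, and
#' summarizes recovery.
#'
#' @param animal_density_km2 True animal density (per km^2).
#' @param rates A [conversion_rates()].
#' @param scenario Base scenario; the first species' intercept is reset so
#'   that the marginal dung density matches the steady-state value, and its
#'   covariate effects are cleared.
#' @param n_reps,seed,options As in [parameter_recovery()].
#' @return A list with `estimates` (per-rep animal densities per km^2),
#'   `truth`, `mean`, and `mc_se`.
#' @export
density_roundtrip <- function(animal_density_km2, rates,
                              scenario = simulation_scenario(),
                              n_reps = 200, seed = 1L,
                              options = fit_options(n_starts = 1)) {
  d_dung_km2 <- steady_state_dung_density(animal_density_km2,
                                          rates$defecation,
                                          rates$decay_days)
  sp <- names(scenario$species)[1]
  pars <- scenario$species[[sp]]
  # set the intercept so the *marginal* dung density is the steady state
  pars$beta <- stats::setNames(numeric(0), character(0))
  pars$beta0 <- log(d_dung_km2 / 1e6) - pars$sigma_b^2 / 2
  scenario$species <- stats::setNames(list(pars), sp)
  spec <- integrated_spec(sp, ~1)
  seeds <- split_seed(seed, n_reps)
  out <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    ds <- simulate_survey(scenario, seed = seeds[r])
    fit <- tryCatch(fit_integrated(ds, spec, options),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    d_dung_hat <- mean(predict_density(fit, type = "marginal")$density)
    out[r] <- dung_to_animal(d_dung_hat, rates) * 1e6
  }
  est <- out[!is.na(out)]
  list(estimates = est, truth = animal_density_km2, mean = mean(est),
       mc_se = stats::sd(est) / sqrt(length(est)))
}
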