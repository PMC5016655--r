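#' Specify an integrated detection-plus-density model
#'
#' An integrated model jointly describes (i) pellet-group density on the log
#' scale as a linear function of transect covariates plus a wadi-system
#' random intercept, and (ii) a global detection function over the distance
#' intervals. Both parts are estimated simultaneously from the binned
#' perpendicular-distance counts.
#'
#' @param species `"oryx"`, `"gazelle"`, or `"combined"`. Combined models
#'   stack both species' counts per transect, share the wadi-system random
#'   effect and the detection function, and may include `species` as a
#'   categorical predictor in `formula`.
#' @param formula Right-hand-side formula for the density model, e.g.
#'   `~ rock_cover + richness`; `~ 1` is the global null (intercept and
#'   random effect only).
#' @param detection `"half_normal"` or `"hazard_rate"`.
#' @return An object of class `integrated_spec`.
#' @export
integrated_spec <- function(species = c("oryx", "gazelle", "combined"),
                            formula = ~1,
                            detection = c("half_normal", "hazard_rate")) {
  species <- match.arg(species)
  detection <- match.arg(detection)
  stop_if(!inherits(formula, "formula") || length(formula) != 2,
          "`formula` must be a one-sided formula such as ~ rock_cover")
  vars <- all.vars(formula)
  stop_if(anyDuplicated(vars) > 0, "duplicated predictor in formula")
  structure(list(species = species, formula = formula,
                 detection = detection,
                 label = paste(deparse(formula[[2]]), collapse = "")),
            class = "integrated_spec")
}

# Assemble the fitting blocks: model matrix X (one row per transect, or per
# transect x species for combined fits), counts matrix (rows x bins),
# exposure 2L, wadi-system index, cutpoints.
prepare_integrated_data <- function(dataset, spec) {
  cutpoints <- dataset$config$cutpoints
  keep <- filter_middens(dataset$events)$events
  sp_levels <- if (spec$species == "combined") c("oryx", "gazelle")
  else spec$species
  keep <- keep[keep$species %in% sp_levels, , drop = FALSE]
  binned <- bin_distances(keep, cutpoints,
                          transect_ids = dataset$transects$transect_id,
                          species = sp_levels)
  K <- length(cutpoints) - 1L
  cells <- unique(binned[, c("transect_id", "species")])
  # one row per (transect, species), one column per distance interval
  counts <- t(vapply(seq_len(nrow(cells)), function(i) {
    sel <- binned$transect_id == cells$transect_id[i] &
      binned$species == cells$species[i]
    binned$count[sel][order(binned$bin[sel])]
  }, numeric(K)))

  cov <- dataset$covariates[match(cells$transect_id,
                                  dataset$covariates$transect_id), ,
                            drop = FALSE]
  cov$species <- factor(cells$species, levels = SPECIES_LEVELS)
  cov$habitat <- factor(cov$habitat, levels = c("plain", "wadi"))
  cov$wadi_system <- factor(cov$wadi_system)

  vars <- all.vars(spec$formula)
  missing <- setdiff(vars, names(cov))
  stop_if(length(missing) > 0,
          sprintf("formula term(s) not in covariate table: %s",
                  paste(missing, collapse = ", ")))
  trm <- stats::terms(spec$formula, data = cov)
  X <- stats::model.matrix(trm, data = cov)

  tr <- dataset$transects[match(cells$transect_id,
                                dataset$transects$transect_id), ]
  list(X = X, counts = counts, expo = 2 * tr$length_m,
       sys = as.integer(cov$wadi_system),
       n_sys = nlevels(cov$wadi_system),
       transect_id = cells$transect_id, species = cells$species,
       cutpoints = cutpoints, w = cutpoints[length(cutpoints)],
       terms = trm, cov = cov)
}

# marginal log-likelihood contribution of one wadi system, integrating the
# shared random intercept b by mode-centered (adaptive) Gauss-Hermite
# quadrature; collapses to sufficient scalars because lambda_jk(b) =
# lambda0_jk * exp(b)
ll_one_system <- function(A, B, C, sigma_b, gh) {
  h <- function(b) C + A * b - B * exp(b) - b^2 / (2 * sigma_b^2) -
    log(sigma_b) - 0.5 * log(2 * pi)
  # Newton for the mode of h (strictly concave)
  b <- 0
  for (it in 1:100) {
    g1 <- A - B * exp(b) - b / sigma_b^2
    g2 <- -B * exp(b) - 1 / sigma_b^2
    step <- g1 / g2
    b <- b - step
    if (abs(step) < 1e-12) break
  }
  tau <- 1 / sqrt(B * exp(b) + 1 / sigma_b^2)
  nodes <- b + sqrt(2) * tau * gh$x
  log(sqrt(2) * tau) + logsumexp(log(gh$w) + gh$x^2 +
                                   vapply(nodes, h, numeric(1)))
}

ll_from_blocks <- function(counts, lam0, sys, n_sys, sigma_b, gh,
                           random = TRUE) {
  stop_if(any(!is.finite(lam0)) || any(lam0 <= 0),
          "non-finite or non-positive expected count")
  if (!random) {
    return(sum(counts * log(lam0) - lam0 - lgamma(counts + 1)))
  }
  ll <- 0
  for (s in seq_len(n_sys)) {
    idx <- sys == s
    A <- sum(counts[idx, , drop = FALSE])
    B <- sum(lam0[idx, , drop = FALSE])
    C <- sum(counts[idx, , drop = FALSE] * log(lam0[idx, , drop = FALSE]) -
               lgamma(counts[idx, , drop = FALSE] + 1))
    ll <- ll + ll_one_system(A, B, C, sigma_b, gh)
  }
  ll
}

unpack_theta <- function(theta, p, random, det_free) {
  beta <- theta[seq_len(p)]
  i <- p
  sigma_b <- if (random) exp(theta[(i <- i + 1)]) else 0
  sigma_det <- if (det_free) exp(theta[(i <- i + 1)]) else NA_real_
  list(beta = beta, sigma_b = sigma_b, sigma_det = sigma_det)
}

ll_theta <- function(theta, prep, spec, gh, random = TRUE,
                     sigma_det_fixed = NULL, shape = NULL) {
  p <- ncol(prep$X)
  det_free <- is.null(sigma_det_fixed)
  pars <- unpack_theta(theta, p, random, det_free)
  sigma_det <- if (det_free) pars$sigma_det else sigma_det_fixed
  dm <- detection_model(spec$detection, sigma_det,
                        shape = shape %||% 2,
                        cutpoints = prep$cutpoints)
  I <- g_integral(dm, prep$cutpoints[-length(prep$cutpoints)],
                  prep$cutpoints[-1])
  eta <- drop(prep$X %*% pars$beta)
  lam0 <- (prep$expo * exp(eta)) %o% I
  if (any(!is.finite(lam0)))
    stop(sprintf("non-finite expected count at transect %s",
                 prep$transect_id[which(!is.finite(rowSums(lam0)))[1]]),
         call. = FALSE)
  ll_from_blocks(prep$counts, lam0, prep$sys, prep$n_sys, pars$sigma_b, gh,
                 random = random)
}

#' Integrated log-likelihood
#'
#' Evaluates the joint log-likelihood of binned pellet counts under a
#' Poisson density model with log link and wadi-system random intercept,
#' multiplied through by the detection-function integrals over the distance
#' intervals. The random intercept is integrated out per wadi system with
#' mode-centered adaptive Gauss-Hermite quadrature.
#'
#' The expected count of transect `j` in interval `k` given the system
#' effect `b` is `lambda_jk(b) = 2 L_j * exp(beta0 + x_j' beta + b) * I_k`,
#' with `I_k` the integral of the detection function over interval `k`.
#'
#' @param dataset A `survey_dataset`.
#' @param spec An [integrated_spec()].
#' @param theta Parameter vector `(beta, log sigma_b, log sigma_det)`.
#' @param nodes Number of Gauss-Hermite nodes.
#' @return The log-likelihood (a scalar).
#' @export
integrated_loglik <- function(dataset, spec, theta, nodes = 15) {
  prep <- prepare_integrated_data(dataset, spec)
  gh <- pracma::gaussHermite(nodes)
  unname(ll_theta(theta, prep, spec, gh))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 ll + 2k + 2k(k+1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Effective sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  stop_if(n <= k + 1, "AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fitting options for the integrated model
#'
#' @param n_starts Number of optimizer starts (first from data-driven
#'   initial values, the rest jittered).
#' @param seed Seed for the start jitter.
#' @param nodes Gauss-Hermite nodes for the random-effect integral.
#' @param aicc_n Effective-sample-size convention for AICc: `"units"`
#'   (count units: transects, or transect x species rows for combined fits)
#'   or `"bins"` (units times distance intervals).
#' @param sigma_det_fixed Optional fixed detection scale (meters); when
#'   given, the detection parameter is not estimated and the model reduces
#'   to a Poisson mixed model with a known detection offset.
#' @param random Set `FALSE` to drop the wadi-system random effect.
#' @param hazard_shape Shape for hazard-rate detection fits.
#' @return A list of options.
#' @export
fit_options <- function(n_starts = 5, seed = 1L, nodes = 15,
                        aicc_n = c("units", "bins"),
                        sigma_det_fixed = NULL, random = TRUE,
                        hazard_shape = 2) {
  list(n_starts = n_starts, seed = as.integer(seed), nodes = nodes,
       aicc_n = match.arg(aicc_n), sigma_det_fixed = sigma_det_fixed,
       random = random, hazard_shape = hazard_shape)
}

# data-driven starting values: detection scale from pooled bin proportions,
# coefficients from a fixed-effects Poisson GLM with detection offset
start_values <- function(prep, spec, options) {
  pooled <- colSums(prep$counts)
  obj <- function(ls) {
    dm <- detection_model(spec$detection, exp(ls),
                          shape = options$hazard_shape,
                          cutpoints = prep$cutpoints)
    pr <- bin_probabilities(dm)
    -sum(pooled * log(pr / sum(pr)))
  }
  ls0 <- if (sum(pooled) > 0)
    stats::optimize(obj, c(log(0.1), log(50)))$minimum else log(1)
  dm <- detection_model(spec$detection, exp(ls0),
                        shape = options$hazard_shape,
                        cutpoints = prep$cutpoints)
  I_tot <- sum(g_integral(dm, prep$cutpoints[-length(prep$cutpoints)],
                          prep$cutpoints[-1]))
  off <- log(prep$expo * I_tot)
  beta0 <- tryCatch(
    stats::glm.fit(prep$X, rowSums(prep$counts),
                   family = stats::poisson(), offset = off)$coefficients,
    error = function(e) c(log(max(mean(rowSums(prep$counts)), 0.5)) -
                            mean(off), rep(0, ncol(prep$X) - 1)))
  beta0[!is.finite(beta0)] <- 0
  list(beta = beta0, log_sigma_b = log(0.3), log_sigma_det = ls0)
}

#' Fit an integrated detection-plus-density model
#'
#' Maximum-likelihood estimation of all parameters (density coefficients,
#' random-effect SD, detection scale) jointly, by box-constrained
#' quasi-Newton optimization on transformed parameters with multiple
#' starts. Standard errors come from the inverse observed Hessian at the
#' optimum.
#'
#' @param dataset A `survey_dataset`.
#' @param spec An [integrated_spec()].
#' @param options A [fit_options()] list.
#' @return An object of class `integrated_fit` with elements `estimates`
#'   (named vector: coefficients plus `sigma_b`, `sigma_det`), `vcov` (on
#'   the internal scale: coefficients, `log_sigma_b`, `log_sigma_det`),
#'   `loglik`, `k`, `n_effective`, `aicc`, `converged`, and `diagnostics`.
#' @export
fit_integrated <- function(dataset, spec, options = fit_options()) {
  prep <- prepare_integrated_data(dataset, spec)
  stop_if(nrow(prep$X) < 2, "need at least 2 transects")
  stop_if(sum(prep$counts) == 0 && is.null(options$sigma_det_fixed),
          "all counts are zero: detection scale not estimable")
  gh <- pracma::gaussHermite(options$nodes)
  det_free <- is.null(options$sigma_det_fixed)
  p <- ncol(prep$X)

  sv <- start_values(prep, spec, options)
  theta0 <- c(sv$beta,
              if (options$random) sv$log_sigma_b,
              if (det_free) sv$log_sigma_det)
  npar <- length(theta0)
  lower <- c(rep(-Inf, p),
             if (options$random) log(1e-3),
             if (det_free) log(0.05))
  upper <- c(rep(Inf, p),
             if (options$random) log(20),
             if (det_free) log(1e3))

  nll <- function(th) {
    v <- tryCatch(
      -ll_theta(th, prep, spec, gh, random = options$random,
                sigma_det_fixed = options$sigma_det_fixed,
                shape = options$hazard_shape),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  set.seed(options$seed)
  starts <- list(theta0)
  if (options$n_starts > 1) {
    for (i in seq_len(options$n_starts - 1))
      starts[[i + 1]] <- theta0 + stats::rnorm(npar, 0, 0.3)
  }
  # balance parameter scales (interaction columns can be orders of
  # magnitude larger than the intercept)
  col_scale <- pmax(apply(abs(prep$X), 2, max), 1)
  parscale <- c(1 / col_scale, rep(1, npar - p))
  fits <- lapply(starts, function(st) {
    st <- pmin(pmax(st, lower + 0.01), upper - 0.01)
    f <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = 500, factr = 1e7,
                                              parscale = parscale)),
                  error = function(e) NULL)
    if (!is.null(f) && f$convergence != 0) {
      # polish with a derivative-free pass, then one more bounded pass
      g <- tryCatch(stats::optim(f$par, nll, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                parscale = parscale,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(g) && g$value <= f$value) {
        g$par <- pmin(pmax(g$par, lower), upper)
        f2 <- tryCatch(stats::optim(g$par, nll, method = "L-BFGS-B",
                                    lower = lower, upper = upper,
                                    control = list(maxit = 500,
                                                   factr = 1e7,
                                                   parscale = parscale)),
                       error = function(e) NULL)
        f <- if (!is.null(f2) && f2$value <= g$value) f2 else {
          g$convergence <- 0L
          g
        }
      }
    }
    f
  })
  fits <- Filter(Negate(is.null), fits)
  stop_if(length(fits) == 0, "all optimizer starts failed")
  vals <- vapply(fits, function(f) f$value, numeric(1))
  # ties broken by lowest parameter norm for determinism
  best_val <- min(vals)
  tied <- which(vals <= best_val + 1e-8)
  norms <- vapply(fits[tied], function(f) sum(f$par^2), numeric(1))
  best <- fits[[tied[which.min(norms)]]]

  theta_hat <- best$par
  ll_hat <- -best$value
  converged <- best$convergence == 0

  H <- tryCatch(stats::optimHess(theta_hat, nll), error = function(e) NULL)
  vc <- NULL
  hess_cond <- NA_real_
  if (!is.null(H)) {
    hess_cond <- tryCatch(kappa(H), error = function(e) NA_real_)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)) {
      warning("singular or indefinite Hessian; standard errors unavailable",
              call. = FALSE)
      vc <- NULL
    }
  }
  grad_norm <- max(abs(numeric_grad(nll, theta_hat)))

  pars <- unpack_theta(theta_hat, p, options$random, det_free)
  est <- c(pars$beta,
           sigma_b = if (options$random) pars$sigma_b else 0,
           sigma_det = if (det_free) pars$sigma_det
           else options$sigma_det_fixed)
  names(est)[seq_len(p)] <- colnames(prep$X)

  k <- p + as.integer(options$random) + as.integer(det_free)
  n_eff <- switch(options$aicc_n,
                  units = nrow(prep$X),
                  bins = length(prep$counts))
  aicc_val <- if (converged) aicc(ll_hat, k, n_eff) else NA_real_
  if (!converged)
    warning("optimizer did not converge; AICc withheld", call. = FALSE)
  boundary <- options$random && pars$sigma_b < 2e-3

  theta_names <- c(colnames(prep$X),
                   if (options$random) "log_sigma_b",
                   if (det_free) "log_sigma_det")
  if (!is.null(vc)) dimnames(vc) <- list(theta_names, theta_names)

  structure(list(
    spec = spec, estimates = est, theta = stats::setNames(theta_hat,
                                                          theta_names),
    vcov = vc, loglik = ll_hat, k = k, n_effective = n_eff,
    aicc = aicc_val, converged = converged,
    diagnostics = list(gradient_norm = grad_norm,
                       hessian_condition = hess_cond,
                       sigma_b_boundary = boundary,
                       n_starts = length(fits),
                       start_spread = diff(range(-vals))),
    prep = prep, options = options), class = "integrated_fit")
}

numeric_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.integrated_fit <- function(x, ...) {
  cat(sprintf("Integrated model [%s]: ~ %s\n", x$spec$species,
              x$spec$label))
  cat(sprintf("  logLik %.3f | k = %d | AICc %.3f%s\n", x$loglik, x$k,
              x$aicc, if (x$converged) "" else " (NOT converged)"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Coefficient table of an integrated fit
#'
#' @param object An `integrated_fit`.
#' @param ... Unused.
#' @return Data frame with estimate, SE (delta scale for variance
#'   parameters), and Wald 95% confidence limits (log-scale for the sigmas,
#'   back-transformed).
#' @export
coef_table <- function(object, ...) {
  th <- object$theta
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov))
  else rep(NA_real_, length(th))
  lo <- th - 1.96 * se
  hi <- th + 1.96 * se
  est <- th
  is_log <- grepl("^log_sigma", names(th))
  est[is_log] <- exp(est[is_log])
  lo[is_log] <- exp(lo[is_log])
  hi[is_log] <- exp(hi[is_log])
  data.frame(term = sub("^log_", "", names(th)), estimate = est,
             se_internal = se, ci_lo = lo, ci_hi = hi,
             row.names = NULL)
}

#' Predict pellet-group density per transect
#'
#' Returns fitted dung (pellet-group) density per square meter, either
#' marginal over the wadi-system random effect (lognormal mean correction
#' `exp(sigma_b^2 / 2)`) or conditional on `b = 0`.
#'
#' @param object An `integrated_fit`.
#' @param newdata Optional covariate data frame; defaults to the fitted
#'   transects.
#' @param type `"marginal"` or `"conditional"`.
#' @param ... Unused.
#' @return Data frame with `transect_id` (if available), `log_density`,
#'   `density`, and `se_log` (delta-method SE of the linear predictor).
#' @export
predict_density <- function(object, newdata = NULL,
                            type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  prep <- object$prep
  if (is.null(newdata)) {
    X <- prep$X
    ids <- prep$transect_id
  } else {
    vars <- all.vars(object$spec$formula)
    missing <- setdiff(vars, names(newdata))
    stop_if(length(missing) > 0,
            sprintf("missing covariate(s) in newdata: %s",
                    paste(missing, collapse = ", ")))
    if ("habitat" %in% names(newdata) && !is.factor(newdata$habitat))
      newdata$habitat <- factor(newdata$habitat, levels = c("plain", "wadi"))
    if ("species" %in% names(newdata) && !is.factor(newdata$species))
      newdata$species <- factor(newdata$species, levels = SPECIES_LEVELS)
    X <- stats::model.matrix(stats::delete.response(prep$terms),
                             data = newdata)
    ids <- newdata$transect_id %||% rep(NA_character_, nrow(X))
  }
  p <- ncol(prep$X)
  beta <- object$theta[seq_len(p)]
  eta <- drop(X %*% beta)
  if (type == "marginal") eta <- eta + object$estimates[["sigma_b"]]^2 / 2
  se_log <- if (!is.null(object$vcov))
    sqrt(rowSums((X %*% object$vcov[seq_len(p), seq_len(p)]) * X))
  else rep(NA_real_, length(eta))
  data.frame(transect_id = ids, log_density = eta, density = exp(eta),
             se_log = se_log, row.names = NULL)
}
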