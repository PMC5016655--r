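#' Build the candidate model set
#'
#' Follows the two-stage rule used for the field study: fit all univariate
#' density models (plus the global null), rank them by AICc, then form all
#' pairwise combinations of the `top_m` best univariate predictors, each
#' both with and without its two-way interaction.
#'
#' @param dataset A `survey_dataset`.
#' @param predictors Character vector of registered predictor names.
#' @param top_m How many of the best univariate predictors enter the
#'   multivariate stage.
#' @param species Response species (`"oryx"`, `"gazelle"` or `"combined"`).
#' @param interactions Include interaction variants of the pairs.
#' @param options [fit_options()] used for the univariate screening fits.
#' @return A list with `specs` (list of [integrated_spec()]; null first,
#'   then univariate, then multivariate) and `univariate` (screening table
#'   with predictor and AICc).
#' @export
build_candidates <- function(dataset, predictors, top_m = 2,
                             species = "oryx", interactions = TRUE,
                             options = fit_options()) {
  stop_if(anyDuplicated(predictors) > 0, "duplicate predictor names")
  stop_if(top_m < 1, "`top_m` must be >= 1")
  if (top_m > length(predictors)) {
    warning("`top_m` exceeds number of predictors; clamped", call. = FALSE)
    top_m <- length(predictors)
  }
  null_spec <- integrated_spec(species, ~1)
  uni_specs <- lapply(predictors, function(p)
    integrated_spec(species, stats::as.formula(paste("~", p))))
  uni_aicc <- vapply(uni_specs, function(sp) {
    f <- tryCatch(fit_integrated(dataset, sp, options),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) NA_real_ else f$aicc
  }, numeric(1))
  ord <- order(uni_aicc)
  top <- predictors[ord][seq_len(top_m)]
  multi <- list()
  if (top_m >= 2) {
    pairs <- utils::combn(sort(top), 2, simplify = FALSE)
    for (pr in pairs) {
      multi[[length(multi) + 1]] <-
        integrated_spec(species,
                        stats::as.formula(paste("~", pr[1], "+", pr[2])))
      if (interactions)
        multi[[length(multi) + 1]] <-
          integrated_spec(species,
                          stats::as.formula(paste("~", pr[1], "*", pr[2])))
    }
  }
  specs <- c(list(null_spec), uni_specs, multi)
  labels <- vapply(specs, function(s) s$label, character(1))
  specs <- specs[!duplicated(labels)]
  list(specs = specs,
       univariate = data.frame(predictor = predictors, aicc = uni_aicc)[
         order(uni_aicc), ])
}

#' Fit a set of candidate models
#'
#' @param dataset A `survey_dataset`.
#' @param specs List of [integrated_spec()] objects.
#' @param options [fit_options()].
#' @return A `model_set`: list with `fits` and `table` (see
#'   [model_table()]).
#' @export
fit_candidates <- function(dataset, specs, options = fit_options()) {
  fits <- lapply(specs, function(sp)
    tryCatch(fit_integrated(dataset, sp, options), error = function(e) {
      warning(sprintf("fit failed for ~ %s: %s", sp$label,
                      conditionMessage(e)), call. = FALSE)
      NULL
    }))
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  ms <- structure(list(fits = fits), class = "model_set")
  ms$table <- model_table(ms)
  ms
}

#' AICc differences
#'
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector of AICc values (or a `model_set`).
#' @return Nonnegative differences, zero for the best model.
#' @export
delta_aicc <- function(aicc_values) {
  if (inherits(aicc_values, "model_set"))
    aicc_values <- vapply(aicc_values$fits, function(f) f$aicc, numeric(1))
  stop_if(any(!is.finite(aicc_values)), "all AICc values must be finite")
  aicc_values - min(aicc_values)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`: the relative
#' probability of each candidate being the best model in the set.
#'
#' @param delta Vector of AICc differences.
#' @return Weights summing to one.
#' @export
akaike_weights <- function(delta) {
  stop_if(any(!is.finite(delta)), "deltas must be finite")
  x <- exp(-delta / 2)
  x / sum(x)
}

#' Confidence set of best-ranked models
#'
#' With models ranked by descending weight, the confidence set is the
#' smallest prefix whose cumulative weight reaches `level`; the model that
#' first attains the threshold is included.
#'
#' @param weights Akaike weights sorted in descending order.
#' @param level Cumulative-weight threshold in `(0, 1]`.
#' @return Logical membership flags (same order as `weights`).
#' @export
confidence_set <- function(weights, level = 0.95) {
  stop_if(level <= 0 || level > 1, "`level` must be in (0, 1]")
  stop_if(is.unsorted(rev(weights)), "`weights` must be sorted descending")
  cum <- cumsum(weights)
  m <- which(cum >= level - 1e-12)[1]
  if (is.na(m)) m <- length(weights)
  seq_along(weights) <= m
}

#' Ranked model-selection table
#'
#' One row per fitted candidate, ranked by AICc (ties broken by ascending
#' `k`, then model label), with `delta_aicc`, Akaike `weight`, cumulative
#' weight and confidence-set membership — the layout of a standard
#' candidate-set table.
#'
#' @param model_set A `model_set` from [fit_candidates()].
#' @param level Confidence-set level.
#' @return A data frame.
#' @export
model_table <- function(model_set, level = 0.95) {
  fits <- model_set$fits
  ok <- vapply(fits, function(f) f$converged && is.finite(f$aicc),
               logical(1))
  fits <- fits[ok]
  stop_if(length(fits) == 0, "no converged fits")
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  k <- vapply(fits, function(f) f$k, integer(1))
  lab <- vapply(fits, function(f) f$spec$label, character(1))
  ord <- order(a, k, lab)
  a <- a[ord]; k <- k[ord]; lab <- lab[ord]
  d <- delta_aicc(a)
  w <- akaike_weights(d)
  inset <- confidence_set(w, level)
  data.frame(rank = seq_along(a), model = lab, k = k, aicc = a,
             delta_aicc = d, weight = w, cum_weight = cumsum(w),
             in_confidence_set = inset, fit_index = ord, row.names = NULL)
}

spec_terms <- function(fit) {
  attr(stats::terms(fit$spec$formula), "term.labels")
}

# does the model contain `predictor` as a main effect or inside an
# interaction term?
contains_predictor <- function(fit, predictor) {
  any(vapply(strsplit(spec_terms(fit), ":", fixed = TRUE),
             function(parts) predictor %in% parts, logical(1)))
}

#' Per-predictor importance (summed Akaike weights)
#'
#' For each predictor, the sum of the Akaike weights of every candidate
#' model containing it (as a main effect or within an interaction).
#'
#' @param model_set A `model_set`.
#' @return Named numeric vector sorted descending.
#' @export
predictor_importance <- function(model_set) {
  tab <- model_table(model_set)
  fits <- model_set$fits[tab$fit_index]
  preds <- unique(unlist(lapply(fits, function(f)
    unlist(strsplit(spec_terms(f), ":", fixed = TRUE)))))
  imp <- vapply(preds, function(p)
    sum(tab$weight[vapply(fits, contains_predictor, logical(1), p)]),
    numeric(1))
  sort(imp, decreasing = TRUE)
}

#' Model-averaged coefficient
#'
#' Averages a predictor's main-effect coefficient over the candidate set,
#' weighted by Akaike weights. `mode = "subset"` renormalizes the weights
#' over the models containing the predictor; `mode = "full"` lets models
#' without the predictor contribute a coefficient of zero. The
#' unconditional SE follows the standard model-averaging variance
#' `sqrt(sum w_i (se_i^2 + (b_i - bbar)^2))`.
#'
#' @param model_set A `model_set`.
#' @param predictor Predictor name.
#' @param mode `"subset"` or `"full"`.
#' @return A one-row data frame with `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   and the summed weight of contributing models.
#' @export
model_average <- function(model_set, predictor,
                          mode = c("subset", "full")) {
  mode <- match.arg(mode)
  tab <- model_table(model_set)
  fits <- model_set$fits[tab$fit_index]
  has <- vapply(fits, function(f)
    predictor %in% colnames(f$prep$X), logical(1))
  stop_if(!any(has), sprintf("predictor `%s` absent from all models",
                             predictor))
  b <- ifelse(has, vapply(fits, function(f)
    if (predictor %in% names(f$estimates))
      f$estimates[[predictor]] else 0, numeric(1)), 0)
  se <- ifelse(has, vapply(fits, function(f) {
    if (!is.null(f$vcov) && predictor %in% rownames(f$vcov))
      sqrt(f$vcov[predictor, predictor]) else 0
  }, numeric(1)), 0)
  w <- tab$weight
  if (mode == "subset") {
    w <- w[has] / sum(w[has])
    b <- b[has]; se <- se[has]
  }
  bbar <- sum(w * b)
  se_u <- sqrt(sum(w * (se^2 + (b - bbar)^2)))
  data.frame(predictor = predictor, mode = mode, estimate = bbar,
             se = se_u, ci_lo = bbar - 1.96 * se_u,
             ci_hi = bbar + 1.96 * se_u,
             sum_weight = sum(tab$weight[has]), row.names = NULL)
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("Candidate model set: %d fitted models\n", length(x$fits)))
  print(x$table[, c("rank", "model", "k", "aicc", "delta_aicc", "weight",
                    "in_confidence_set")], digits = 4)
  invisible(x)
}
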