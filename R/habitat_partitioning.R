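#' Ward hierarchical clustering of transects
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances of (optionally z-scored) transect covariates: the
#' "animal's-eye" a posteriori habitat classification.
#'
#' @param covariates Numeric matrix or data frame (rows = transects).
#' @param k Number of habitat clusters, `2 <= k <= n`.
#' @param standardize Z-score columns first (constant columns are dropped
#'   with a warning).
#' @return A list with `assignment` (integer cluster labels, named by row),
#'   `hclust` (the dendrogram object with merge heights) and `k`.
#' @export
ward_cluster <- function(covariates, k, standardize = TRUE) {
  X <- as.matrix(covariates)
  stop_if(!is.numeric(X), "`covariates` must be numeric")
  stop_if(anyNA(X), "`covariates` must be complete (no missing values)")
  stop_if(k < 2 || k > nrow(X), "`k` must be in [2, n]")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping constant covariate(s): %s",
                      paste(colnames(X)[sds == 0], collapse = ", ")),
              call. = FALSE)
      X <- X[, sds > 0, drop = FALSE]
    }
    X <- scale(X)
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  list(assignment = stats::cutree(hc, k = k), hclust = hc, k = k)
}

#' Choose the number of habitat clusters by silhouette
#'
#' @param covariates As in [ward_cluster()].
#' @param k_range Candidate cluster numbers.
#' @param standardize Passed through.
#' @return The `k` maximizing the mean silhouette width.
#' @export
choose_k_silhouette <- function(covariates, k_range = 2:8,
                                standardize = TRUE) {
  X <- as.matrix(covariates)
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  d <- stats::dist(X)
  hc <- stats::hclust(d, method = "ward.D2")
  k_range <- k_range[k_range < nrow(X)]
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean_silhouette(cl, as.matrix(d))
  }, numeric(1))
  k_range[which.max(sil)]
}

# mean silhouette width for a labelled partition given a distance matrix
mean_silhouette <- function(labels, dmat) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(dmat[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(dmat[i, labels == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Manly standardized selection ratios
#'
#' Raw selection ratios `w_i = use_i / a_i` (use per unit availability) are
#' normalized to `B_i = w_i / sum_j w_j`: the probability that the species
#' would select habitat `i` were all habitats equally available.
#'
#' @param use Nonnegative use intensities per habitat (densities or
#'   counts).
#' @param availability Availability proportions (summing to 1); defaults to
#'   equal availability.
#' @return Named vector `B` summing to 1.
#' @export
selection_ratio <- function(use, availability = NULL) {
  stop_if(any(use < 0), "`use` must be >= 0")
  stop_if(all(use == 0), "all-zero use: selection undefined")
  availability <- availability %||% rep(1 / length(use), length(use))
  stop_if(length(availability) != length(use),
          "`availability` and `use` lengths differ")
  stop_if(any(availability <= 0), "`availability` must be > 0")
  availability <- availability / sum(availability)
  w <- use / availability
  B <- w / sum(w)
  names(B) <- names(use)
  B
}

#' Key resource area flags
#'
#' A habitat is a key resource area when its standardized selection ratio
#' reaches the threshold (`>=`, so a ratio of exactly 0.5 qualifies).
#'
#' @param B Standardized selection ratios.
#' @param threshold Flagging threshold.
#' @return Logical vector.
#' @export
key_resource_flags <- function(B, threshold = 0.5) {
  B >= threshold
}

#' Shannon-Wiener diversity of habitat use
#'
#' `H' = -sum B_i log(B_i)`, treating the standardized selection ratios as
#' proportions of habitat use; zero entries contribute zero.
#'
#' @param B Standardized selection ratios (must sum to 1).
#' @param base Logarithm base (natural log by default).
#' @return The diversity index.
#' @export
shannon_diversity <- function(B, base = exp(1)) {
  stop_if(abs(sum(B) - 1) > 1e-9, "`B` must sum to 1")
  stop_if(any(B < 0), "`B` must be >= 0")
  nz <- B[B > 0]
  -sum(nz * log(nz) / log(base))
}

#' Two-species habitat partitioning index
#'
#' Per habitat: the fold-ratio between the denser and the sparser species
#' (with a small-epsilon guard when one density is zero) and the signed
#' density difference (oryx minus gazelle).
#'
#' @param d_oryx,d_gazelle Nonnegative densities per habitat.
#' @param eps Guard for zero denominators.
#' @return Data frame with `ratio`, `difference`, and `ratio_defined`
#'   (FALSE where both densities are zero).
#' @export
partition_index <- function(d_oryx, d_gazelle, eps = 1e-9) {
  stop_if(any(d_oryx < 0) || any(d_gazelle < 0), "densities must be >= 0")
  hi <- pmax(d_oryx, d_gazelle)
  lo <- pmin(d_oryx, d_gazelle)
  defined <- hi > 0
  ratio <- ifelse(defined, hi / pmax(lo, eps), NA_real_)
  data.frame(ratio = ratio, difference = d_oryx - d_gazelle,
             ratio_defined = defined)
}

#' Wilcoxon rank-sum test with midranks and exact enumeration
#'
#' Computes the Mann-Whitney statistic `W` (rank sum of `x` minus its
#' minimum) using midranks for ties, so half-integer values of `W` can
#' occur. For combined sample sizes up to `exact_max` the two-sided p-value
#' is exact, by full enumeration of all assignments of the pooled values to
#' the two groups, counting assignments at least as far from the null mean
#' of `W` as observed. For larger samples a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Maximum `length(x) + length(y)` for enumeration.
#' @return A list with `statistic` (W), `p_value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  stop_if(length(x) == 0 || length(y) == 0, "samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)              # midranks
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  EW <- nx * ny / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, nx)
    stats_all <- apply(combs, 2, function(idx)
      sum(r[idx]) - nx * (nx + 1) / 2)
    p <- mean(abs(stats_all - EW) >= abs(W - EW) - 1e-12)
    method <- "exact enumeration (midranks)"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    varW <- nx * ny / 12 * (n + 1 - tie_term)
    z <- (abs(W - EW) - 0.5) / sqrt(varW)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
    p <- min(p, 1)
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = W, p_value = p, method = method)
}

#' Habitat partition summary for a survey
#'
#' Combines a transect-to-habitat assignment with per-species per-habitat
#' densities into the selection summary: standardized selection ratios, key
#' resource flags, Shannon-Wiener diversity of habitat use, and the
#' two-species partitioning index.
#'
#' @param assignment Named vector (by transect id) of habitat labels.
#' @param density Data frame with columns `transect_id`, `species`,
#'   `density`.
#' @param availability Optional named availability proportions per habitat;
#'   defaults to the proportion of transects per habitat.
#' @param shannon_base Logarithm base for `H'`.
#' @return A list with `habitats` (per-habitat table: mean density per
#'   species, `B_` ratios, key flags, partition index) and `diversity`
#'   (named `H'` per species).
#' @export
habitat_partition <- function(assignment, density, availability = NULL,
                              shannon_base = exp(1)) {
  habs <- sort(unique(as.character(assignment)))
  species <- unique(density$species)
  avail <- if (is.null(availability)) {
    tab <- table(factor(as.character(assignment), levels = habs))
    as.numeric(tab) / sum(tab)
  } else {
    stop_if(!all(habs %in% names(availability)),
            "`availability` must name every habitat")
    as.numeric(availability[habs] / sum(availability[habs]))
  }
  dens <- sapply(species, function(sp) {
    vapply(habs, function(h) {
      ids <- names(assignment)[as.character(assignment) == h]
      mean(density$density[density$species == sp &
                             density$transect_id %in% ids])
    }, numeric(1))
  })
  dens <- matrix(dens, nrow = length(habs),
                 dimnames = list(habs, species))
  B <- apply(dens, 2, selection_ratio, availability = avail)
  out <- data.frame(habitat = habs, availability = avail,
                    n_transects = as.integer(table(factor(
                      as.character(assignment), levels = habs))))
  for (sp in species) {
    out[[paste0("density_", sp)]] <- dens[, sp]
    out[[paste0("B_", sp)]] <- B[, sp]
    out[[paste0("key_", sp)]] <- key_resource_flags(B[, sp])
  }
  if (all(c("oryx", "gazelle") %in% species)) {
    pi_tab <- partition_index(dens[, "oryx"], dens[, "gazelle"])
    out$partition_ratio <- pi_tab$ratio
    out$density_difference <- pi_tab$difference
  }
  div <- vapply(species, function(sp)
    shannon_diversity(B[, sp], base = shannon_base), numeric(1))
  rownames(out) <- NULL
  list(habitats = out, diversity = div)
}

#' Wadi/plain covariate contrasts
#'
#' Compares each transect-level covariate between the two a priori habitat
#' classes with the midrank Wilcoxon rank-sum test.
#'
#' @param covariates Transect covariate table including a `habitat` column.
#' @param vars Covariate columns to test (all numeric predictors by
#'   default).
#' @return Data frame with per-variable wadi and plain means, `W` and the
#'   two-sided p-value.
#' @export
habitat_contrasts <- function(covariates, vars = NULL) {
  stop_if(!"habitat" %in% names(covariates), "need a `habitat` column")
  if (is.null(vars)) {
    vars <- setdiff(names(covariates)[vapply(covariates, is.numeric,
                                             logical(1))],
                    c("north_south", "east_west"))
  }
  wadi <- as.character(covariates$habitat) == "wadi"
  rows <- lapply(vars, function(v) {
    ts <- wilcoxon_rank_sum(covariates[[v]][wadi],
                            covariates[[v]][!wadi])
    data.frame(variable = v, mean_wadi = mean(covariates[[v]][wadi]),
               mean_plain = mean(covariates[[v]][!wadi]),
               W = ts$statistic, p_value = ts$p_value)
  })
  do.call(rbind, rows)
}
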