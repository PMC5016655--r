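# Small deterministic fixtures built in code; no data files.

tiny_transects <- function(n_pairs = 2, n_systems = 1) {
  rows <- list()
  sys <- rep_len(seq_len(n_systems), n_pairs)
  for (p in seq_len(n_pairs)) {
    for (hab in c("wadi", "plain")) {
      rows[[length(rows) + 1]] <- data.frame(
        transect_id = sprintf("T%02d_%s", p, hab),
        pair_id = sprintf("P%02d", p),
        wadi_system = sprintf("W%d", sys[p]), habitat = hab,
        length_m = 200, half_width_m = 4,
        north_south = (p - 1) / n_pairs, east_west = 0.1 * p,
        predator_scats = p %% 3)
    }
  }
  do.call(rbind, rows)
}

tiny_quadrats <- function(transects, seed = 1, n_quadrats = 11) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(transects)), function(i) {
    wadi <- transects$habitat[i] == "wadi"
    data.frame(
      transect_id = transects$transect_id[i],
      quadrat_idx = seq_len(n_quadrats),
      rock_pct = pmax(0, rnorm(n_quadrats, if (wadi) 10 else 40, 4)),
      litter_pct = pmax(0, rnorm(n_quadrats, if (wadi) 10 else 3, 2)),
      herb_pct = pmax(0, rnorm(n_quadrats, if (wadi) 25 else 5, 4)),
      shrub_pct = pmax(0, rnorm(n_quadrats, 8, 2)),
      tree_pct = pmax(0, rnorm(n_quadrats, 2, 1)),
      herb_height_cm = pmax(0, rnorm(n_quadrats, if (wadi) 18 else 8, 3)),
      shrub_height_cm = pmax(0, rnorm(n_quadrats, 40, 8)),
      tree_height_cm = 120,
      richness = 3L,
      species_list = c("a;b;c", "b;c;d")[1 + (seq_len(n_quadrats) %% 2)],
      nonwoody_wet_g = 10, nonwoody_dry_g = 4, woody_g = 2)
  }))
}

tiny_events <- function(transects, n = 40, seed = 1, species = "oryx",
                        midden_frac = 0) {
  set.seed(seed)
  data.frame(
    transect_id = sample(transects$transect_id, n, replace = TRUE),
    species = sample(species, n, replace = TRUE),
    distance_m = round(runif(n, 0, 4), 3),
    n_pellets = 10L + rpois(n, 10),
    is_midden = as.integer(runif(n) < midden_frac))
}

tiny_dataset <- function(n_pairs = 2, n_systems = 1, n_events = 40,
                         seed = 1, species = "oryx", midden_frac = 0) {
  tr <- tiny_transects(n_pairs, n_systems)
  survey_dataset(tiny_events(tr, n_events, seed, species, midden_frac),
                 tr, tiny_quadrats(tr, seed))
}

# one-species scenario used by the recovery and round-trip experiments:
# one covariate effect of 0.2, sigma_b = 0.3, sigma_det = 1.5 m
recovery_scenario <- function() {
  simulation_scenario(species = list(
    oryx = list(beta0 = -5.0, beta = c(richness = 0.2), sigma_b = 0.3,
                sigma_det = 1.5, midden_rate = 0.02)))
}

fast_options <- function(...) fit_options(n_starts = 1, ...)

# total within-cluster sum of squares for a labelled partition
wss2 <- function(X, labels) {
  sum(vapply(unique(labels), function(l) {
    Y <- X[labels == l, , drop = FALSE]
    sum(scale(Y, scale = FALSE)^2)
  }, numeric(1)))
}
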