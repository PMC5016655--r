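#' Simulation scenario for a paired wadi/plain pellet survey
#'
#' Defines the study conditions emulated by the synthetic generator: 18
#' wadi/plain transect pairs spread over 8 wadi systems, 200 x 8 m strips
#' with three equal distance intervals, 11 vegetation quadrats per transect,
#' species-specific log-linear covariate effects on pellet-group density, a
#' shared wadi-system random effect, a global half-normal detection function
#' per species, midden contamination, and the defecation/decay rates that
#' link pellet-group density to animal density at steady state.
#'
#' Default covariate effects mirror the direction of the field system: oryx
#' density increases with plant species richness and decreases with rock
#' cover; gazelle density decreases with litter cover and herbaceous height.
#' Intercepts are calibrated so that a default survey yields on the order of
#' 600 oryx and 130 gazelle retained pellet events.
#'
#' @param n_pairs Number of wadi/plain transect pairs.
#' @param n_wadi_systems Number of wadi systems (random-effect levels).
#' @param length_m,half_width_m Strip geometry in meters.
#' @param cutpoints Distance cutpoints in meters.
#' @param species Named list of per-species parameter lists with elements
#'   `beta0` (log pellet-group density per m^2 at zero covariates), `beta`
#'   (named covariate effects), `sigma_b` (random-effect SD), `sigma_det`
#'   (half-normal detection scale, m) and `midden_rate` (fraction of
#'   recorded events that are middens).
#' @param rates Named list per species: `defecation` (pellet groups per
#'   animal per day) and `decay_days` (mean pellet-group persistence, days).
#' @param landscape Covariate generator parameters; see
#'   [default_landscape_params()].
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(
    n_pairs = 18L, n_wadi_systems = 8L, length_m = 200, half_width_m = 4,
    cutpoints = c(0, 4 / 3, 8 / 3, 4),
    species = list(
      oryx = list(beta0 = -4.53,
                  beta = c(richness = 0.208, rock_cover = -0.031),
                  sigma_b = 0.3, sigma_det = 1.5, midden_rate = 12 / 640),
      gazelle = list(beta0 = -4.33,
                     beta = c(litter_cover = -0.073, herb_height = -0.053),
                     sigma_b = 0.3, sigma_det = 1.5,
                     midden_rate = 53 / 185)),
    rates = list(oryx = list(defecation = 16, decay_days = 505),
                 gazelle = list(defecation = 7, decay_days = 505)),
    landscape = default_landscape_params()) {
  for (sp in names(species)) {
    p <- species[[sp]]
    stop_if(p$sigma_det <= 0, "sigma_det must be > 0")
    stop_if(p$sigma_b < 0, "sigma_b must be >= 0")
    stop_if(p$midden_rate < 0 || p$midden_rate >= 1,
            "midden_rate must be in [0, 1)")
  }
  for (sp in names(rates)) {
    check_positive(rates[[sp]]$defecation, "defecation")
    check_positive(rates[[sp]]$decay_days, "decay_days")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 n_wadi_systems = as.integer(n_wadi_systems),
                 length_m = length_m, half_width_m = half_width_m,
                 cutpoints = cutpoints, species = species, rates = rates,
                 landscape = landscape),
            class = "simulation_scenario")
}

#' Default covariate-generator parameters
#'
#' Transect-level target means and SDs for each vegetation predictor, by
#' habitat. Wadi transects carry denser, taller and richer vegetation and
#' lower rock cover than the adjoining plain; `within_sd` controls
#' quadrat-to-quadrat scatter around the transect target.
#'
#' @return A list with per-habitat parameter tables and auxiliary settings.
#' @export
default_landscape_params <- function() {
  # rows: mean/sd per habitat; covers %, heights cm, masses g
  tab <- function(wadi_mean, wadi_sd, plain_mean, plain_sd, lo, hi) {
    list(wadi = c(mean = wadi_mean, sd = wadi_sd),
         plain = c(mean = plain_mean, sd = plain_sd),
         range = c(lo, hi))
  }
  list(
    rock_pct = tab(15, 5, 40, 10, 0, 100),
    litter_pct = tab(10, 3, 3, 1.5, 0, 100),
    herb_pct = tab(30, 8, 5, 3, 0, 100),
    shrub_pct = tab(15, 5, 4, 2, 0, 100),
    tree_pct = tab(5, 2, 0.5, 0.5, 0, 100),
    herb_height_cm = tab(18, 5, 8, 3, 0, 200),
    shrub_height_cm = tab(60, 15, 30, 10, 0, 99),
    tree_height_cm = tab(150, 30, 120, 15, 101, 600),
    nonwoody_dry_g = tab(8, 3, 2, 1, 0.05, 500),
    woody_g = tab(5, 2, 1, 0.5, 0, 500),
    water_frac = tab(0.55, 0.05, 0.40, 0.05, 0.05, 0.95),
    richness = tab(8, 2, 5, 1.5, 1, 40),
    within_sd_frac = 0.35,       # quadrat scatter as fraction of target
    predator_scat_mean = 38 / 36, # Poisson mean scats per transect
    species_pool = sprintf("sp%02d", 1:40)
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate the transect landscape and vegetation quadrats
#'
#' Generates paired wadi/plain transects allocated across wadi systems, with
#' geographic gradient scores, predator scat counts, and 11 vegetation
#' quadrats per transect drawn around habitat-specific transect targets
#' (wadis more vegetated, plains rockier).
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed.
#' @return A list with `transects` and `quadrats` data frames following the
#'   survey CSV schemas.
#' @export
simulate_landscape <- function(scenario, seed) {
  set.seed(seed)
  lp <- scenario$landscape
  np <- scenario$n_pairs
  ns <- scenario$n_wadi_systems
  systems <- sort(rep_len(seq_len(ns), np))
  sys_ns <- stats::runif(ns, -1, 1)   # north-south position per system
  sys_ew <- stats::runif(ns, -1, 1)

  rows <- list(); qrows <- list()
  for (p in seq_len(np)) {
    for (hab in c("wadi", "plain")) {
      tid <- sprintf("T%02d_%s", p, hab)
      sys <- systems[p]
      # transect-level targets
      tgt <- vapply(
        c("rock_pct", "litter_pct", "herb_pct", "shrub_pct", "tree_pct",
          "herb_height_cm", "shrub_height_cm", "tree_height_cm",
          "nonwoody_dry_g", "woody_g", "water_frac"),
        function(v) {
          pr <- lp[[v]][[hab]]
          rtrunc_norm(1, pr["mean"], pr["sd"], lp[[v]]$range[1],
                      lp[[v]]$range[2])
        }, numeric(1))
      rich_pr <- lp$richness[[hab]]
      rich <- max(1L, round(stats::rnorm(1, rich_pr["mean"], rich_pr["sd"])))
      rich <- min(rich, length(lp$species_pool))
      spp <- sample(lp$species_pool, rich)

      rows[[tid]] <- data.frame(
        transect_id = tid, pair_id = sprintf("P%02d", p),
        wadi_system = sprintf("W%d", sys), habitat = hab,
        length_m = scenario$length_m, half_width_m = scenario$half_width_m,
        north_south = round(sys_ns[sys] + stats::rnorm(1, 0, 0.05), 4),
        east_west = round(sys_ew[sys] + stats::rnorm(1, 0, 0.05), 4),
        predator_scats = stats::rpois(1, lp$predator_scat_mean))

      nq <- 11L
      wsd <- lp$within_sd_frac
      qv <- function(v) {
        pr <- lp[[v]]
        rtrunc_norm(nq, tgt[v], pmax(wsd * tgt[v], 0.2), pr$range[1],
                    pr$range[2])
      }
      # every selected species appears in >= 1 quadrat so pooled richness
      # equals the transect target
      ql <- replicate(nq, character(0), simplify = FALSE)
      for (s in spp) {
        hit <- sample.int(nq, min(nq, 1 + stats::rpois(1, 2)))
        for (h in hit) ql[[h]] <- c(ql[[h]], s)
      }
      dry <- qv("nonwoody_dry_g")
      wet <- dry / (1 - rtrunc_norm(nq, tgt["water_frac"], 0.03, 0.05, 0.95))
      tree_p <- qv("tree_pct")
      tree_h <- ifelse(tree_p > 0.05, qv("tree_height_cm"), 0)
      qrows[[tid]] <- data.frame(
        transect_id = tid, quadrat_idx = seq_len(nq),
        rock_pct = qv("rock_pct"), litter_pct = qv("litter_pct"),
        herb_pct = qv("herb_pct"), shrub_pct = qv("shrub_pct"),
        tree_pct = tree_p, herb_height_cm = qv("herb_height_cm"),
        shrub_height_cm = qv("shrub_height_cm"), tree_height_cm = tree_h,
        richness = vapply(ql, length, integer(1)),
        species_list = vapply(ql, paste, character(1), collapse = ";"),
        nonwoody_wet_g = round(wet, 3), nonwoody_dry_g = round(dry, 3),
        woody_g = round(qv("woody_g"), 3))
    }
  }
  transects <- do.call(rbind, rows)
  quadrats <- do.call(rbind, qrows)
  rownames(transects) <- rownames(quadrats) <- NULL
  num <- vapply(quadrats, is.numeric, logical(1))
  quadrats[num] <- lapply(quadrats[num], function(x) round(x, 3))
  list(transects = transects, quadrats = quadrats)
}

#' Steady-state pellet-group density
#'
#' At steady state, standing pellet-group density equals animal density
#' times the defecation rate times the mean time to decay:
#' `D_dung = D_animal * r * T`.
#'
#' @param animal_density Animals per unit area.
#' @param defecation_rate Pellet groups per animal per day.
#' @param decay_days Mean pellet-group persistence in days.
#' @return Pellet-group density in the same area unit as `animal_density`.
#' @export
steady_state_dung_density <- function(animal_density, defecation_rate,
                                      decay_days) {
  check_positive(animal_density, "animal_density")
  check_positive(defecation_rate, "defecation_rate")
  check_positive(decay_days, "decay_days")
  animal_density * defecation_rate * decay_days
}

#' Simulate pellet events on a landscape
#'
#' For each transect and species, latent pellet groups are Poisson with mean
#' `2 w L * D_dung`, where `log D_dung = beta0 + x' beta + b_system`;
#' perpendicular distances are uniform on `[0, w]`; detection thins events
#' with the half-normal probability `g(y)`. Middens are appended at the
#' species' midden rate with distance-independent (uniform) placement, so
#' that the midden filter is consequential.
#'
#' @param landscape Output of [simulate_landscape()] (or a list with
#'   `transects` and `quadrats`).
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed.
#' @param covariates Optional precomputed transect covariate table; computed
#'   from the quadrats when omitted.
#' @return An events data frame following the survey CSV schema.
#' @export
simulate_pellets <- function(landscape, scenario, seed, covariates = NULL) {
  set.seed(seed)
  tr <- landscape$transects
  if (is.null(covariates)) {
    covariates <- aggregate_quadrats(landscape$quadrats)
  }
  cov <- covariates[match(tr$transect_id, covariates$transect_id), ,
                    drop = FALSE]
  w <- scenario$half_width_m
  sys_levels <- unique(tr$wadi_system)
  out <- list()
  for (sp in names(scenario$species)) {
    pars <- scenario$species[[sp]]
    b <- stats::rnorm(length(sys_levels), 0, pars$sigma_b)
    names(b) <- sys_levels
    xb <- rep(0, nrow(tr))
    for (v in names(pars$beta)) {
      stop_if(!v %in% names(cov), sprintf("unknown covariate `%s`", v))
      xb <- xb + pars$beta[[v]] * cov[[v]]
    }
    log_d <- pars$beta0 + xb + b[tr$wadi_system]
    lambda <- 2 * w * tr$length_m * exp(log_d)   # latent groups per transect
    for (i in seq_len(nrow(tr))) {
      n_lat <- stats::rpois(1, lambda[i])
      if (n_lat > 0) {
        y <- stats::runif(n_lat, 0, w)
        keep <- stats::runif(n_lat) < detection_g(
          detection_model("half_normal", pars$sigma_det,
                          cutpoints = scenario$cutpoints), y)
        y <- y[keep]
      } else y <- numeric(0)
      n_det <- length(y)
      n_mid <- if (pars$midden_rate > 0 && n_det > 0)
        stats::rpois(1, n_det * pars$midden_rate / (1 - pars$midden_rate))
      else 0L
      if (n_det + n_mid > 0) {
        out[[length(out) + 1L]] <- data.frame(
          transect_id = tr$transect_id[i], species = sp,
          distance_m = round(c(y, stats::runif(n_mid, 0, w)), 4),
          n_pellets = 10L + stats::rpois(n_det + n_mid, 15),
          is_midden = rep(c(0L, 1L), c(n_det, n_mid)))
      }
    }
  }
  ev <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(transect_id = character(0), species = character(0),
               distance_m = numeric(0), n_pellets = integer(0),
               is_midden = integer(0))
  rownames(ev) <- NULL
  ev
}

#' Simulate a complete survey dataset
#'
#' Convenience wrapper: [simulate_landscape()] then [simulate_pellets()],
#' assembled into a validated [survey_dataset()].
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer root seed (split internally between landscape and
#'   pellet stages).
#' @return A `survey_dataset`. The scenario and seed are attached as
#'   attributes for provenance.
#' @export
simulate_survey <- function(scenario = simulation_scenario(), seed = 1L) {
  seeds <- split_seed(seed, 2)
  land <- simulate_landscape(scenario, seeds[1])
  cov <- aggregate_quadrats(land$quadrats)
  ev <- simulate_pellets(land, scenario, seeds[2], covariates = cov)
  ds <- survey_dataset(ev, land$transects, land$quadrats,
                       survey_config(cutpoints = scenario$cutpoints))
  attr(ds, "scenario") <- scenario
  attr(ds, "seed") <- seed
  ds
}
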