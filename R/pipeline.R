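#' Default predictor registry
#'
#' The transect-level predictors available to the density models: habitat
#' class, the two geographic gradient scores, predator scat count, and the
#' vegetation covariates from the quadrat aggregation. The wadi-system
#' identity is handled as the model's random effect, not a fixed predictor.
#'
#' @param combined Include `species` (for combined two-species fits).
#' @return Character vector of predictor names.
#' @export
predictor_registry <- function(combined = FALSE) {
  c("habitat", "north_south", "east_west", "rock_cover", "litter_cover",
    "herb_cover", "shrub_cover", "tree_cover", "herb_height",
    "shrub_height", "tree_height", "nonwoody_biomass", "woody_biomass",
    "water_content", "richness", "predator_scats",
    if (combined) "species")
}

#' Pipeline configuration
#'
#' Everything the end-to-end analysis needs: input data (CSV paths or a
#' simulation scenario), the candidate-set rule, model-averaging and
#' confidence-set settings, dung-to-animal conversion rates, habitat
#' availability, clustering settings, and the root seed. The configuration
#' round-trips through YAML via [yaml::as.yaml()] for provenance.
#'
#' @param events_path,transects_path,quadrats_path CSV paths; leave `NULL`
#'   to simulate from `scenario`.
#' @param scenario A [simulation_scenario()] used when no paths are given.
#' @param species Response species to analyze.
#' @param predictors Predictor registry.
#' @param top_m Univariate predictors entering the multivariate stage.
#' @param level Confidence-set level.
#' @param averaging_mode Model-averaging mode (`"subset"` or `"full"`).
#' @param rates Named list of [conversion_rates()] per species (`NULL`
#'   skips the conversion stage).
#' @param area_m2 Study-area size in square meters (default 3800 ha).
#' @param availability Optional a priori availability (named, wadi/plain).
#' @param cluster_k Number of a posteriori habitats (`NULL`: silhouette
#'   choice over 2..8).
#' @param seed Root seed; all stage seeds derive from it.
#' @param fit [fit_options()] shared by all fits.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(events_path = NULL, transects_path = NULL,
                            quadrats_path = NULL,
                            scenario = simulation_scenario(),
                            species = c("oryx", "gazelle"),
                            predictors = predictor_registry(),
                            top_m = 2, level = 0.95,
                            averaging_mode = "subset",
                            rates = list(
                              oryx = conversion_rates(16, 505),
                              gazelle = conversion_rates(7, 505)),
                            area_m2 = 3.8e7,
                            availability = NULL, cluster_k = NULL,
                            seed = 1L, fit = fit_options()) {
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(bundle, name, fun) {
  res <- tryCatch(fun(), error = function(e)
    structure(conditionMessage(e), class = "stage_error"))
  if (inherits(res, "stage_error")) {
    bundle$manifest$errors[[name]] <- unclass(res)
  } else {
    bundle[[name]] <- res
    bundle$manifest$stages <- c(bundle$manifest$stages, name)
  }
  bundle
}

#' Run the full analysis pipeline
#'
#' Executes the workflow end to end: load or simulate the survey, exclude
#' middens, bin distances, fit the candidate model sets per species, rank
#' and average models, convert fitted dung density to animal density and
#' abundance, and produce the a priori and a posteriori habitat
#' partitioning summaries. Deterministic given `config$seed`. A failing
#' stage is recorded in the manifest and later stages that do not depend on
#' it still run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A report bundle (list) with elements `dataset`, `bookkeeping`,
#'   `models` (per species: model table, importance, averaged
#'   coefficients), `abundance`, `apriori`, `contrasts`, `aposteriori`, and
#'   `manifest` (stages run, errors, seed, config provenance).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  seeds <- split_seed(config$seed, 4)
  bundle <- list(manifest = list(stages = character(0), errors = list(),
                                 seed = config$seed,
                                 package_version =
                                   as.character(utils::packageVersion(
                                     "dungdist"))))

  bundle <- run_stage(bundle, "dataset", function() {
    if (!is.null(config$events_path)) {
      load_survey(config$events_path, config$transects_path,
                  config$quadrats_path)
    } else {
      simulate_survey(config$scenario, seed = seeds[1])
    }
  })
  if (is.null(bundle$dataset)) return(finish_bundle(bundle, out_dir))
  ds <- bundle$dataset

  bundle <- run_stage(bundle, "bookkeeping", function()
    filter_middens(ds$events)$bookkeeping)

  bundle <- run_stage(bundle, "models", function() {
    opts <- config$fit
    opts$seed <- seeds[2]
    out <- list()
    for (sp in config$species) {
      preds <- setdiff(config$predictors, "species")
      cand <- build_candidates(ds, preds, top_m = config$top_m,
                               species = sp, options = opts)
      ms <- fit_candidates(ds, cand$specs, options = opts)
      imp <- predictor_importance(ms)
      major <- names(imp)[seq_len(min(3, length(imp)))]
      avg <- do.call(rbind, lapply(major, function(p)
        tryCatch(model_average(ms, p, mode = config$averaging_mode),
                 error = function(e) NULL)))
      out[[sp]] <- list(model_set = ms,
                        table = model_table(ms, level = config$level),
                        importance = imp, averaged = avg)
    }
    out
  })

  bundle <- run_stage(bundle, "abundance", function() {
    if (is.null(config$rates)) return(NULL)
    rows <- lapply(config$species, function(sp) {
      if (!sp %in% names(config$rates)) return(NULL)
      best <- best_fit(bundle$models[[sp]])
      pred <- predict_density(best, type = "marginal")
      d_dung <- mean(pred$density)
      cv <- mean(pred$se_log)
      d_animal <- dung_to_animal(d_dung, config$rates[[sp]])
      ab <- abundance_estimate(d_animal, config$area_m2, density_cv = cv,
                               rates = config$rates[[sp]])
      data.frame(species = sp, dung_density_m2 = d_dung,
                 animal_density_km2 = d_animal * 1e6,
                 N = ab$N, ci_lo = ab$ci[1], ci_hi = ab$ci[2], cv = ab$cv)
    })
    do.call(rbind, rows)
  })
  if (is.null(bundle$abundance) &&
      !"abundance" %in% names(bundle$manifest$errors))
    bundle$manifest$notes <- c(bundle$manifest$notes %||% character(0),
                               "no conversion rates: abundance skipped")

  bundle <- run_stage(bundle, "apriori", function() {
    assign <- stats::setNames(ds$transects$habitat,
                              ds$transects$transect_id)
    dens <- species_density_table(bundle$models, config$species)
    avail <- config$availability %||%
      stats::setNames(rep(0.5, 2), c("plain", "wadi"))
    habitat_partition(assign, dens, availability = avail)
  })

  bundle <- run_stage(bundle, "contrasts", function()
    habitat_contrasts(ds$covariates))

  bundle <- run_stage(bundle, "aposteriori", function() {
    num <- intersect(predictor_registry(), names(ds$covariates))
    num <- num[vapply(ds$covariates[num], is.numeric, logical(1))]
    X <- as.matrix(ds$covariates[, num])
    rownames(X) <- ds$covariates$transect_id
    k <- config$cluster_k %||% choose_k_silhouette(X)
    cl <- ward_cluster(X, k = k)
    assign <- stats::setNames(LETTERS[cl$assignment],
                              rownames(X))
    dens <- species_density_table(bundle$models, config$species)
    part <- habitat_partition(assign, dens)
    list(k = k, assignment = assign, partition = part,
         merge_heights = cl$hclust$height)
  })

  finish_bundle(bundle, out_dir)
}

best_fit <- function(model_entry) {
  tab <- model_entry$table
  model_entry$model_set$fits[[tab$fit_index[1]]]
}

species_density_table <- function(models, species) {
  do.call(rbind, lapply(species, function(sp) {
    pred <- predict_density(best_fit(models[[sp]]), type = "marginal")
    data.frame(transect_id = pred$transect_id, species = sp,
               density = pred$density)
  }))
}

finish_bundle <- function(bundle, out_dir) {
  class(bundle) <- "pipeline_bundle"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write pipeline artifacts to disk
#'
#' Emits the ranked model tables (TSV), the abundance table (TSV), the
#' habitat summaries (TSV), the bookkeeping log (TSV), and a JSON manifest
#' with config provenance.
#'
#' @param bundle A `pipeline_bundle`.
#' @param out_dir Output directory.
#' @return Invisibly, the output directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE,
    quote = FALSE)
  if (!is.null(bundle$bookkeeping)) tsv(bundle$bookkeeping,
                                        "bookkeeping.tsv")
  for (sp in names(bundle$models %||% list())) {
    tab <- bundle$models[[sp]]$table
    tsv(tab[, setdiff(names(tab), "fit_index")],
        sprintf("models_%s.tsv", sp))
    if (!is.null(bundle$models[[sp]]$averaged))
      tsv(bundle$models[[sp]]$averaged,
          sprintf("averaged_coefficients_%s.tsv", sp))
  }
  if (!is.null(bundle$abundance)) tsv(bundle$abundance, "abundance.tsv")
  if (!is.null(bundle$apriori)) tsv(bundle$apriori$habitats,
                                    "habitats_apriori.tsv")
  if (!is.null(bundle$contrasts)) tsv(bundle$contrasts, "contrasts.tsv")
  if (!is.null(bundle$aposteriori))
    tsv(bundle$aposteriori$partition$habitats, "habitats_aposteriori.tsv")
  manifest <- bundle$manifest
  if (!is.null(bundle$apriori))
    manifest$diversity_apriori <- as.list(bundle$apriori$diversity)
  if (!is.null(bundle$aposteriori))
    manifest$diversity_aposteriori <-
      as.list(bundle$aposteriori$partition$diversity)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
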