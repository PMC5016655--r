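#' Survey configuration
#'
#' Bundles the fixed design constants of a pellet-group strip-transect survey:
#' the distance cutpoints that define the perpendicular-distance intervals,
#' the expected number of vegetation quadrats per transect, and how
#' per-quadrat plant species richness is rolled up to the transect level.
#'
#' @param cutpoints Numeric vector of strictly increasing distance cutpoints
#'   in meters, starting at 0 and ending at the strip half-width. The default
#'   splits a 4 m half-strip into three equal intervals.
#' @param n_quadrats Expected number of vegetation quadrats per transect.
#' @param richness One of `"pooled"` (distinct species across the transect's
#'   quadrats, requires a `species_list` column) or `"mean"` (mean of the
#'   per-quadrat richness counts).
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(cutpoints = c(0, 4 / 3, 8 / 3, 4),
                          n_quadrats = 11L,
                          richness = c("pooled", "mean")) {
  richness <- match.arg(richness)
  stop_if(length(cutpoints) < 2 || any(diff(cutpoints) <= 0) ||
            cutpoints[1] != 0,
          "`cutpoints` must be strictly increasing and start at 0")
  structure(list(cutpoints = cutpoints, n_quadrats = as.integer(n_quadrats),
                 richness = richness),
            class = "survey_config")
}

SPECIES_LEVELS <- c("oryx", "gazelle")

events_schema <- c("transect_id", "species", "distance_m", "n_pellets",
                   "is_midden")
transects_schema <- c("transect_id", "pair_id", "wadi_system", "habitat",
                      "length_m", "half_width_m", "north_south", "east_west",
                      "predator_scats")
quadrats_schema <- c("transect_id", "quadrat_idx", "rock_pct", "litter_pct",
                     "herb_pct", "shrub_pct", "tree_pct", "herb_height_cm",
                     "shrub_height_cm", "tree_height_cm", "richness",
                     "nonwoody_wet_g", "nonwoody_dry_g", "woody_g")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          sprintf("%s: missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  invisible(df)
}

#' Load a pellet-group survey from CSV files
#'
#' Reads the three survey tables (pellet events, transects, vegetation
#' quadrats), validates them against the expected schemas, checks referential
#' integrity and unit bounds, and aggregates quadrats into transect-level
#' covariates.
#'
#' @param events_path,transects_path,quadrats_path Paths to CSV files. See
#'   the package vignette for the column layout.
#' @param config A [survey_config()].
#' @return A `survey_dataset`: a list with elements `events`, `transects`,
#'   `quadrats`, `covariates` (transect-level predictor table) and `config`.
#' @export
load_survey <- function(events_path, transects_path, quadrats_path,
                        config = survey_config()) {
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  transects <- utils::read.csv(transects_path, stringsAsFactors = FALSE)
  quadrats <- utils::read.csv(quadrats_path, stringsAsFactors = FALSE)
  survey_dataset(events, transects, quadrats, config)
}

#' Assemble and validate a survey dataset
#'
#' @param events,transects,quadrats Data frames following the CSV schemas.
#' @param config A [survey_config()].
#' @return A validated `survey_dataset`.
#' @export
survey_dataset <- function(events, transects, quadrats,
                           config = survey_config()) {
  check_schema(events, events_schema, "events")
  check_schema(transects, transects_schema, "transects")
  check_schema(quadrats, quadrats_schema, "quadrats")

  stop_if(anyDuplicated(transects$transect_id) > 0,
          "transects: duplicated transect_id")
  bad_sp <- setdiff(unique(events$species), SPECIES_LEVELS)
  stop_if(length(bad_sp) > 0,
          sprintf("events: unknown species label(s): %s",
                  paste(bad_sp, collapse = ", ")))
  bad_hab <- setdiff(unique(transects$habitat), c("wadi", "plain"))
  stop_if(length(bad_hab) > 0,
          sprintf("transects: unknown habitat label(s): %s",
                  paste(bad_hab, collapse = ", ")))
  stop_if(any(transects$length_m <= 0) || any(transects$half_width_m <= 0),
          "transects: length_m and half_width_m must be > 0")

  orphan <- setdiff(events$transect_id, transects$transect_id)
  stop_if(length(orphan) > 0,
          sprintf("events reference unknown transect(s): %s",
                  paste(unique(orphan), collapse = ", ")))
  orphan_q <- setdiff(quadrats$transect_id, transects$transect_id)
  stop_if(length(orphan_q) > 0,
          sprintf("quadrats reference unknown transect(s): %s",
                  paste(unique(orphan_q), collapse = ", ")))

  w <- transects$half_width_m[match(events$transect_id,
                                    transects$transect_id)]
  bad <- which(events$distance_m < 0 | events$distance_m > w)
  stop_if(length(bad) > 0,
          sprintf("events: distance_m outside [0, half_width] at row(s): %s",
                  paste(bad, collapse = ", ")))
  stop_if(any(events$n_pellets < 10),
          "events: n_pellets < 10 violates the pellet-event definition")

  cover_cols <- c("rock_pct", "litter_pct", "herb_pct", "shrub_pct",
                  "tree_pct")
  for (cc in cover_cols)
    stop_if(any(quadrats[[cc]] < 0 | quadrats[[cc]] > 100),
            sprintf("quadrats: %s outside [0, 100]", cc))
  stop_if(any(quadrats$nonwoody_dry_g > quadrats$nonwoody_wet_g + 1e-9),
          "quadrats: nonwoody_dry_g exceeds nonwoody_wet_g")

  nq <- table(quadrats$transect_id)
  short <- names(nq)[nq != config$n_quadrats]
  if (length(short) > 0)
    warning(sprintf(
      "quadrats: %d transect(s) do not have %d quadrats (e.g. %s); proceeding",
      length(short), config$n_quadrats, short[1]), call. = FALSE)

  events$is_midden <- as.logical(events$is_midden)
  covariates <- aggregate_quadrats(quadrats, richness = config$richness)
  covariates <- merge(
    transects[, c("transect_id", "pair_id", "wadi_system", "habitat",
                  "north_south", "east_west", "predator_scats")],
    covariates, by = "transect_id", sort = TRUE)

  structure(list(events = events, transects = transects, quadrats = quadrats,
                 covariates = covariates, config = config),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Pellet-group survey dataset\n")
  cat(sprintf("  transects: %d (%d pairs, %d wadi systems)\n",
              nrow(x$transects), length(unique(x$transects$pair_id)),
              length(unique(x$transects$wadi_system))))
  cat(sprintf("  pellet events: %d recorded (%d middens)\n",
              nrow(x$events), sum(x$events$is_midden)))
  for (sp in unique(x$events$species)) {
    idx <- x$events$species == sp
    cat(sprintf("    %s: %d recorded, %d middens\n", sp, sum(idx),
                sum(x$events$is_midden[idx])))
  }
  invisible(x)
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [load_survey()]; writes `events.csv`, `transects.csv` and
#' `quadrats.csv` into `dir`.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "transects.csv", "quadrats.csv"))
  ev <- dataset$events
  ev$is_midden <- as.integer(ev$is_midden)
  utils::write.csv(ev, paths[1], row.names = FALSE)
  utils::write.csv(dataset$transects, paths[2], row.names = FALSE)
  utils::write.csv(dataset$quadrats, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Exclude middens from the event record
#'
#' Middens (territorial fecal clusters) reflect territory marking rather than
#' resource use and are removed before any density analysis. Returns the
#' retained events together with a per-species bookkeeping table.
#'
#' @param events Event data frame with an `is_midden` flag.
#' @return A list with `events` (non-midden rows) and `bookkeeping`, a data
#'   frame with columns `species`, `recorded`, `middens`, `retained` (plus a
#'   `combined` row).
#' @export
filter_middens <- function(events) {
  stop_if(!"is_midden" %in% names(events), "events lack an `is_midden` flag")
  is_mid <- as.logical(events$is_midden)
  species <- intersect(SPECIES_LEVELS, unique(events$species))
  rows <- lapply(species, function(sp) {
    idx <- events$species == sp
    data.frame(species = sp, recorded = sum(idx),
               middens = sum(idx & is_mid),
               retained = sum(idx & !is_mid))
  })
  bk <- do.call(rbind, c(rows, list(data.frame(
    species = "combined", recorded = nrow(events), middens = sum(is_mid),
    retained = sum(!is_mid)))))
  list(events = events[!is_mid, , drop = FALSE], bookkeeping = bk)
}

#' Bin perpendicular distances into distance intervals
#'
#' Assigns each retained pellet event to a distance interval using half-open
#' intervals `[c_{k-1}, c_k)`, with the last interval closed at the strip
#' half-width, and tabulates counts per transect and species. Transects or
#' species with no events get explicit zero counts when `transect_ids` /
#' `species` are supplied.
#'
#' @param events Retained (non-midden) event data frame.
#' @param cutpoints Strictly increasing cutpoints from 0 to the half-width.
#' @param transect_ids Optional vector of all transect ids for which zero
#'   rows must appear.
#' @param species Optional vector of species levels to complete.
#' @return A data frame with columns `transect_id`, `species`, `bin`
#'   (integer interval index), `count`; cutpoints stored as an attribute.
#' @export
bin_distances <- function(events, cutpoints = c(0, 4 / 3, 8 / 3, 4),
                          transect_ids = NULL, species = NULL) {
  stop_if(any(diff(cutpoints) <= 0) || cutpoints[1] != 0,
          "`cutpoints` must be strictly increasing and start at 0")
  w <- cutpoints[length(cutpoints)]
  stop_if(nrow(events) > 0 &&
            (any(events$distance_m < 0) || any(events$distance_m > w)),
          "event distance outside [0, half-width]")
  k <- length(cutpoints) - 1L
  transect_ids <- transect_ids %||% sort(unique(events$transect_id))
  species <- species %||% sort(unique(events$species))
  grid <- expand.grid(transect_id = transect_ids, species = species,
                      bin = seq_len(k), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    # right-open bins; fold the exact boundary y == w into the last bin
    idx <- findInterval(events$distance_m, cutpoints,
                        rightmost.closed = TRUE)
    cnt <- stats::aggregate(
      list(count = rep(1L, nrow(events))),
      list(transect_id = events$transect_id, species = events$species,
           bin = idx), sum)
    grid <- merge(grid, cnt,
                  by = c("transect_id", "species", "bin"), all.x = TRUE)
    grid$count[is.na(grid$count)] <- 0L
  } else {
    grid$count <- 0L
  }
  grid <- grid[order(grid$transect_id, grid$species, grid$bin), ]
  rownames(grid) <- NULL
  attr(grid, "cutpoints") <- cutpoints
  grid
}

#' Aggregate vegetation quadrats to transect-level covariates
#'
#' Cover and height predictors are means over a transect's quadrats; biomass
#' predictors are means of the clipped subquadrat masses; plant water content
#' is computed from the summed nonwoody wet and dry masses; richness is
#' either the pooled count of distinct species over the transect (default,
#' requires a `species_list` column with `;`-separated names) or the mean of
#' the per-quadrat richness counts.
#'
#' @param quadrats Quadrat data frame.
#' @param richness `"pooled"` or `"mean"`.
#' @return One row per transect with the vegetation predictors:
#'   `rock_cover`, `litter_cover`, `herb_cover`, `shrub_cover`, `tree_cover`,
#'   `herb_height`, `shrub_height`, `tree_height`, `nonwoody_biomass`,
#'   `woody_biomass`, `water_content`, `richness`.
#' @export
aggregate_quadrats <- function(quadrats, richness = c("pooled", "mean")) {
  richness <- match.arg(richness)
  check_schema(quadrats, quadrats_schema, "quadrats")
  if (richness == "pooled" && !"species_list" %in% names(quadrats)) {
    warning("no `species_list` column; falling back to mean richness",
            call. = FALSE)
    richness <- "mean"
  }
  split_q <- split(quadrats, quadrats$transect_id)
  rows <- lapply(split_q, function(q) {
    wet <- sum(q$nonwoody_wet_g)
    dry <- sum(q$nonwoody_dry_g)
    if (wet > 0 && dry == 0)
      warning(sprintf(
        "transect %s: all-zero dry mass with nonzero wet mass (water 100%%)",
        q$transect_id[1]), call. = FALSE)
    wc <- if (wet > 0) 100 * (wet - dry) / wet else 0
    rich <- if (richness == "pooled") {
      spp <- unlist(strsplit(q$species_list, ";", fixed = TRUE))
      length(unique(spp[nzchar(spp)]))
    } else {
      mean(q$richness)
    }
    data.frame(
      transect_id = q$transect_id[1],
      rock_cover = mean(q$rock_pct), litter_cover = mean(q$litter_pct),
      herb_cover = mean(q$herb_pct), shrub_cover = mean(q$shrub_pct),
      tree_cover = mean(q$tree_pct), herb_height = mean(q$herb_height_cm),
      shrub_height = mean(q$shrub_height_cm),
      tree_height = mean(q$tree_height_cm),
      nonwoody_biomass = mean(q$nonwoody_dry_g),
      woody_biomass = mean(q$woody_g),
      water_content = wc, richness = rich)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
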