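#' Loaders for the packaged reference tables
#'
#' Plain-text reference tables ship with the package: 2018 simulation
#' confusion-matrix counts, GM(1,1)/Markov predicted-vs-actual area pairs
#' for 2015 and 2018, observed/forecast/simulated class areas, and a
#' reported ESV series. They are inputs for the worked examples and the
#' reproduction script.
#'
#' @return `load_reported_confusion()`: square count matrix (simulated x
#'   actual). `load_reported_predictions()`: data frame (class, code,
#'   year, model, predicted_km2, actual_km2). `load_reported_areas()`:
#'   data frame (class, code, source, year, area_km2).
#'   `load_reported_esv()`: class-by-year matrix in 10^7 USD.
#' @name reported_tables
NULL

extdata <- function(f)
  system.file("extdata", f, package = "lucesv", mustWork = TRUE)

#' @rdname reported_tables
#' @export
load_reported_confusion <- function() {
  tab <- utils::read.csv(extdata("confusion_matrix_2018.csv"),
                         check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}

#' @rdname reported_tables
#' @export
load_reported_predictions <- function()
  utils::read.csv(extdata("demand_predictions.csv"))

#' @rdname reported_tables
#' @export
load_reported_areas <- function()
  utils::read.csv(extdata("landuse_areas.csv"))

#' @rdname reported_tables
#' @export
load_reported_esv <- function() {
  tab <- utils::read.csv(extdata("esv_reported.csv"))
  m <- as.matrix(tab[, grep("^y", names(tab))])
  dimnames(m) <- list(as.character(tab$code), sub("^y", "", colnames(m)))
  m
}

#' Read and validate a pipeline configuration file
#'
#' YAML with a fixed schema; unknown keys are an error (silent typos would
#' corrupt scenarios), and any referenced file must exist.
#'
#' @param path Path to a YAML file. Recognized keys: `seed`, `grid_shape`,
#'   `cell_area`, `autocorrelation_scale`, `class_fractions`,
#'   `trend_rates`, `years`, `noise_sd`, `rules_file`,
#'   `neighborhood_size`, `max_iterations`, `demand_tolerance`,
#'   `inertia_floor`, `hidden_units`, `epochs`, `sample_fraction`,
#'   `protection_floor_km2`, `out_dir`.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "grid_shape", "cell_area", "autocorrelation_scale",
             "class_fractions", "trend_rates", "years", "noise_sd",
             "rules_file", "neighborhood_size", "max_iterations",
             "demand_tolerance", "inertia_floor", "hidden_units", "epochs",
             "sample_fraction", "protection_floor_km2", "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$rules_file) && !file.exists(cfg$rules_file))
    stop("rules file does not exist: ", cfg$rules_file)
  cfg
}

#' Run the full synthetic scenario pipeline
#'
#' Executes the framework end to end on a seeded synthetic scenario:
#' (1) generate a landscape and evolve it twice under the conversion
#' rules to obtain three dated maps; (2) forecast per-class demand with
#' GM(1,1) (with posterior-difference grading) and with a Markov chain
#' estimated from the first map pair, and compare the two on the last
#' dated map; (3) train the neural-network suitability model on driving
#' factors and allocate the validation demand with the constrained CA,
#' assessing the simulated map against the held-out map by sampled
#' confusion matrix; (4) allocate the GM-forecast demand for the horizon
#' year; (5) value first-year and horizon landscapes with the corrected
#' equivalent-factor model and report the trend. A single seed fans out
#' to fixed per-stage child seeds, so the whole run is deterministic.
#'
#' @param spec A [scenario_spec()].
#' @param params A [ca_params()]; its seed is overridden by `seed`.
#' @param hidden_units,epochs ANN settings (see
#'   [train_suitability_ann()]).
#' @param sample_fraction Training-sample fraction of cells (default
#'   0.02).
#' @param evolve_fraction Fraction of cells changed per map step (default
#'   0.03).
#' @param horizon GM forecast steps beyond the series (default 2).
#' @param seed Global seed; stage seeds are derived by fixed offsets.
#' @param out_dir Optional directory: writes the rasters, demand,
#'   iteration log, confusion matrix, accuracy table and ESV report as
#'   plain-text files plus a `run_info.yaml` sidecar with the seed.
#' @return List of class `lucesv_run` with the stage artifacts:
#'   `maps` (t1/t2/t3), `gm_fits`, `gm_accuracy`, `transition_matrix`,
#'   `comparison`, `demand`, `suitability`, `validation` (ca result +
#'   confusion matrix), `allocation` (horizon ca result), `esv`
#'   (factors, base/revised results, report).
#' @export
run_pipeline <- function(spec = scenario_spec(),
                         params = ca_params(),
                         hidden_units = 12, epochs = 300,
                         sample_fraction = 0.02,
                         evolve_fraction = 0.03,
                         horizon = 2,
                         seed = spec$seed,
                         out_dir = NULL) {
  spec$seed <- as.integer(seed)
  params$seed <- as.integer(seed + 40L)
  rules <- ecological_rules()
  n_cells <- prod(spec$grid_shape)
  n_changes <- round(evolve_fraction * n_cells)

  # --- maps -----------------------------------------------------------------
  t1 <- generate_landscape(spec)
  mask <- (t1$grid == 5L) * 1  # water is the restricted zone
  t2 <- evolve_landscape(t1, rules, n_changes, seed = seed + 10L, mask = mask)
  t3 <- evolve_landscape(t2, rules, n_changes, seed = seed + 11L, mask = mask)

  # --- demand ---------------------------------------------------------------
  series <- generate_area_series(spec)
  gm_fits <- apply(series$area, 1, gm11, simplify = FALSE)
  gm_acc <- lapply(gm_fits, posterior_difference_test)
  gm_forecast <- vapply(gm_fits, function(f) predict(f, horizon)[horizon],
                        numeric(1))
  P <- estimate_transition_matrix(t1, t2)
  # model comparison on the held-out last map: GM refit without the last
  # year vs one Markov step from the middle map
  n_yr <- length(spec$years)
  gm_hold <- apply(series$area[, -n_yr, drop = FALSE], 1, gm11,
                   simplify = FALSE)
  pred_gm <- vapply(gm_hold, function(f) predict(f, 1), numeric(1))
  actual_t3 <- class_areas(t3)
  pred_mk <- predict_markov(class_areas(t2), P, steps = 1)
  # GM worked on the tabular series; put both on the map's total area
  pred_gm_scaled <- pred_gm * sum(actual_t3) / sum(series$area[, n_yr])
  comparison <- compare_models(pred_gm_scaled, pred_mk, actual_t3)

  # demand for the horizon: GM growth ratios applied to the latest map's
  # composition, so targets stay consistent with the frozen water zone
  growth_ratio <- gm_forecast / series$area[, n_yr]
  demand_h <- build_demand(class_areas(t3) * growth_ratio,
                           spec$cell_area, n_cells,
                           fold_unused_into_builtup = TRUE, unit = "ha")

  # --- suitability ----------------------------------------------------------
  factors <- generate_driving_factors(t2, seed = seed + 20L)
  factors <- normalize_stack(factors)
  train <- sample_training(t2, factors,
                           n = max(50L, round(sample_fraction * n_cells)),
                           strategy = "uniform", seed = seed + 21L)
  model <- train_suitability_ann(train, hidden_units = hidden_units,
                                 epochs = epochs, seed = seed + 22L)
  suit <- predict(model, factors)

  # --- validation run: reproduce the held-out map's composition -------------
  mask2 <- (t2$grid == 5L) * 1
  val_counts <- class_counts(t3)
  val_demand <- val_counts[rownames(rules$allow)]
  val_demand["7"] <- val_demand["7"] + val_counts["8"]
  val_params <- params
  val_params$seed <- as.integer(seed + 41L)
  val <- run_allocation(t2, suit, rules, mask = mask2, demand = val_demand,
                        params = val_params)
  cells <- sample_cells(val$map, 0.01, seed = seed + 30L)
  cm <- assess_accuracy(actual = t3$grid[cells],
                        simulated = val$map$grid[cells])
  cm_full <- assess_accuracy(actual = as.vector(t3$grid),
                             simulated = as.vector(val$map$grid))

  # --- horizon allocation ---------------------------------------------------
  alloc <- run_allocation(t3, suit, rules, mask = (t3$grid == 5L) * 1,
                          demand = demand_h, params = params)

  # --- ESV ------------------------------------------------------------------
  soc <- generate_socioeconomic_series(spec$years, seed = seed + 50L)
  cf_of_year <- function(y) {
    r <- soc[soc$year == y & soc$scope == "region", ]
    n <- soc[soc$year == y & soc$scope == "nation", ]
    correction_factors(r$grain_yield, n$grain_yield, r$engel, n$engel,
                       r$pgdp, n$pgdp, r$urbanization, n$urbanization,
                       r$pop_density, n$pop_density)
  }
  cf_first <- cf_of_year(spec$years[1])
  cf_last <- cf_of_year(spec$years[n_yr])
  esv_first <- revised_esv(class_areas(t1), factors = cf_first, unit = "ha")
  esv_horizon <- revised_esv(class_areas(alloc$map), factors = cf_last,
                             unit = "ha")
  esv_mat <- cbind(esv_first$by_class, esv_horizon$by_class)
  colnames(esv_mat) <- c(as.character(spec$years[1]), "horizon")
  cat_mat <- cbind(esv_first$by_category, esv_horizon$by_category)
  colnames(cat_mat) <- colnames(esv_mat)
  report <- esv_report(esv_mat / 1e7, cat_mat / 1e7)

  out <- structure(list(maps = list(t1 = t1, t2 = t2, t3 = t3),
                        gm_fits = gm_fits, gm_accuracy = gm_acc,
                        transition_matrix = P, comparison = comparison,
                        demand = demand_h, suitability = suit,
                        validation = list(ca = val, confusion = cm,
                                          confusion_full = cm_full),
                        allocation = alloc,
                        esv = list(factors_first = cf_first,
                                   factors_last = cf_last,
                                   first = esv_first, horizon = esv_horizon,
                                   report = report),
                        seed = seed),
                   class = "lucesv_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.lucesv_run <- function(x, ...) {
  cat("Synthetic land-use/ESV pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  validation: OA %.2f%%, kappa %.4f (1%% sample of %d cells)\n",
              100 * x$validation$confusion$overall_accuracy,
              x$validation$confusion$kappa, x$validation$confusion$n))
  cat(sprintf("  horizon allocation: %s in %d sweeps\n",
              if (x$allocation$converged) "converged" else "not converged",
              x$allocation$sweeps))
  cat(sprintf("  total ESV growth over the run: %.2f%%\n",
              x$esv$report$growth[["total"]]))
  invisible(x)
}

# write every artifact as plain text so two runs can be compared by checksum
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_raster(run$maps$t1, p("map_t1.asc"))
  write_raster(run$maps$t3, p("map_t3.asc"))
  write_raster(run$validation$ca$map, p("map_validation.asc"))
  write_raster(run$allocation$map, p("map_horizon.asc"))
  utils::write.csv(data.frame(class = names(run$demand),
                              cells = as.integer(run$demand)),
                   p("demand.csv"), row.names = FALSE)
  utils::write.csv(run$allocation$log, p("allocation_log.csv"),
                   row.names = FALSE)
  utils::write.csv(run$comparison$table, p("model_comparison.csv"),
                   row.names = FALSE)
  acc <- data.frame(class = names(run$gm_accuracy),
                    C = vapply(run$gm_accuracy, `[[`, 0, "C"),
                    P = vapply(run$gm_accuracy, `[[`, 0, "P"),
                    level = vapply(run$gm_accuracy, `[[`, 0L, "level"))
  utils::write.csv(acc, p("gm_accuracy.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$validation$confusion$counts),
                   p("confusion_sampled.csv"))
  esv <- run$esv$report
  utils::write.csv(data.frame(class = rownames(esv$esv), round(esv$esv, 6),
                              check.names = FALSE),
                   p("esv_by_class.csv"), row.names = FALSE)
  f <- run$esv$factors_last
  utils::write.csv(data.frame(factor = c("Q", "Pw", "Pv", "D", "S"),
                              value = c(f$Q, f$Pw, f$Pv, f$D, f$S)),
                   p("correction_factors.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = run$seed,
                        package_version =
                          as.character(utils::packageVersion("lucesv"))),
                   p("run_info.yaml"))
  invisible(out_dir)
}
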