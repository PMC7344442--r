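#' Estimate a Markov transition matrix from two dated land-use maps
#'
#' Cross-tabulates per-cell transitions between two aligned rasters:
#' `P[i, j]` is the fraction of class-`i` cells at the first date found in
#' class `j` at the second. Classes absent at the first date get identity
#' rows so the matrix stays row-stochastic.
#'
#' @param map_t1,map_t2 Aligned `land_raster` objects sharing a legend.
#' @return Row-stochastic matrix of class `transition_matrix`, rows/cols
#'   named by class code.
#' @export
estimate_transition_matrix <- function(map_t1, map_t2) {
  stopifnot(inherits(map_t1, "land_raster"), inherits(map_t2, "land_raster"))
  if (!identical(dim(map_t1$grid), dim(map_t2$grid)))
    stop("rasters are not aligned (different grid dimensions)")
  if (!identical(map_t1$legend, map_t2$legend))
    stop("rasters use different legends")
  codes <- names(map_t1$legend)
  tab <- table(factor(as.vector(map_t1$grid), levels = codes),
               factor(as.vector(map_t2$grid), levels = codes))
  P <- unclass(tab / ifelse(rowSums(tab) == 0, 1, rowSums(tab)))
  empty <- rowSums(tab) == 0
  if (any(empty)) diag(P)[empty] <- 1
  structure(matrix(P, nrow(P), ncol(P), dimnames = dimnames(tab)),
            class = c("transition_matrix", "matrix"))
}

check_stochastic <- function(P, tol = 1e-9) {
  if (any(P < -tol) || any(P > 1 + tol) ||
      any(abs(rowSums(P) - 1) > tol))
    stop("matrix is not row-stochastic")
  invisible(TRUE)
}

#' Project class areas with a Markov chain
#'
#' Advances the state row vector `S` through a row-stochastic transition
#' matrix: `S_{t+k} = S_t P^k`. Total area is conserved exactly because
#' each row of `P` sums to one.
#'
#' @param S Nonnegative per-class area vector (order matching `P`).
#' @param P Row-stochastic transition matrix.
#' @param steps Number of steps (>= 1).
#' @return Projected area vector with the names of `S` (or of `P`'s rows).
#' @export
predict_markov <- function(S, P, steps = 1) {
  if (steps < 1) stop("`steps` must be >= 1")
  P <- as.matrix(P)
  if (length(S) != nrow(P) || nrow(P) != ncol(P))
    stop("dimensions of S and P disagree")
  if (any(S < 0)) stop("areas must be nonnegative")
  check_stochastic(P)
  out <- matrix(S, nrow = 1)
  for (i in seq_len(steps)) out <- out %*% P
  stats::setNames(as.numeric(out),
                  if (!is.null(names(S))) names(S) else rownames(P))
}

#' Compare two demand forecasts against observed areas
#'
#' Computes, per class, the relative difference
#' `d = (predicted - actual) / actual * 100` for each model, the accuracy
#' gap `|d_b| - |d_a|`, and flags the model with the smaller mean `|d|` as
#' selected. Classes with zero actual area get `NA` differences.
#'
#' @param pred_a,pred_b Named forecast vectors for models A and B (same
#'   classes).
#' @param actual Observed areas (same classes and unit).
#' @param models Length-2 character labels, default `c("gm11", "markov")`.
#' @return List of class `demand_comparison`: `table` (data frame with
#'   class, actual, per-model prediction and difference, gap) and
#'   `selected` (model label).
#' @export
compare_models <- function(pred_a, pred_b, actual,
                           models = c("gm11", "markov")) {
  if (length(pred_a) != length(actual) || length(pred_b) != length(actual))
    stop("forecast and actual vectors must cover the same classes")
  d_a <- ifelse(actual == 0, NA_real_, (pred_a - actual) / actual * 100)
  d_b <- ifelse(actual == 0, NA_real_, (pred_b - actual) / actual * 100)
  tab <- data.frame(class = if (!is.null(names(actual))) names(actual)
                            else as.character(seq_along(actual)),
                    actual = as.numeric(actual),
                    pred_a = as.numeric(pred_a), diff_a = d_a,
                    pred_b = as.numeric(pred_b), diff_b = d_b,
                    gap = abs(d_b) - abs(d_a))
  names(tab)[3:6] <- c(paste0("pred_", models[1]), paste0("diff_", models[1]),
                       paste0("pred_", models[2]), paste0("diff_", models[2]))
  sel <- models[which.min(c(mean(abs(d_a), na.rm = TRUE),
                            mean(abs(d_b), na.rm = TRUE)))]
  structure(list(table = tab, selected = sel), class = "demand_comparison")
}

#' @export
print.demand_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  cat("selected model:", x$selected, "\n")
  invisible(x)
}

#' Convert an area forecast into integer cell-count demand targets
#'
#' Turns per-class forecast areas into whole-cell targets by
#' largest-remainder rounding (so the targets sum exactly to the grid's
#' cell count), optionally folds the unused-land class into built-up land
#' (the urbanization assumption that residual unused land is absorbed by
#' construction), and can enforce a cultivated-land protection floor on
#' paddy plus unirrigated field.
#'
#' @param forecast Positive per-class areas, named by class code.
#' @param cell_area Hectares per cell.
#' @param n_cells Total number of (data) cells on the grid.
#' @param fold_unused_into_builtup Fold class 8 into class 7 (default TRUE
#'   when class "8" is present).
#' @param protection_floor Optional minimum combined area for classes 1
#'   and 2, in the same unit as `forecast`.
#' @param unit Unit of `forecast` (and of the floor): `"ha"` or `"km2"`.
#' @return Integer vector of cell targets named by class code, summing to
#'   `n_cells`.
#' @export
build_demand <- function(forecast, cell_area, n_cells,
                         fold_unused_into_builtup = "8" %in% names(forecast),
                         protection_floor = NULL,
                         unit = c("ha", "km2")) {
  unit <- match.arg(unit)
  if (any(forecast < 0)) stop("forecast areas must be nonnegative")
  if (is.null(names(forecast)))
    names(forecast) <- as.character(seq_along(forecast))
  f <- forecast
  if (unit == "km2") f <- f * 100
  if (fold_unused_into_builtup && "8" %in% names(f)) {
    if (!"7" %in% names(f)) stop("no built-up class ('7') to fold into")
    f["7"] <- f["7"] + f["8"]
    f <- f[names(f) != "8"]
  }
  if (!is.null(protection_floor)) {
    floor_ha <- if (unit == "km2") protection_floor * 100 else protection_floor
    cult <- sum(f[names(f) %in% c("1", "2")])
    if (cult < floor_ha)
      stop("cultivated-land protection floor violated: paddy + unirrigated ",
           "field forecast ", signif(cult, 8), " ha is below the floor of ",
           signif(floor_ha, 8), " ha")
  }
  raw <- f / sum(f) * n_cells
  base <- floor(raw)
  rem <- n_cells - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (sum(base) != n_cells) stop("demand targets exceed grid capacity")
  stats::setNames(as.integer(base), names(f))
}
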