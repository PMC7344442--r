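#' Specification for a synthetic landscape scenario
#'
#' Bundles the parameters of the synthetic-data generators: grid geometry,
#' legend size, target class shares, per-class annual area trends, the
#' observation years and the seed. The defaults describe a provincial-scale
#' mosaic dominated by cultivated land with a slowly expanding built-up
#' class, mirroring the structure the downstream models assume
#' (near-exponential class-area trajectories, spatially contiguous
#' patches).
#'
#' @param grid_shape Integer vector `(rows, cols)`.
#' @param n_classes Number of land-use classes (default 8; codes 1..8 per
#'   [land_legend()]).
#' @param cell_area Hectares per cell.
#' @param autocorrelation_scale Gaussian smoothing length in cells; larger
#'   values give larger contiguous patches.
#' @param class_fractions Target area shares, summing to 1.
#' @param trend_rates Per-class annual multiplicative area rates (all > 0).
#' @param years Strictly increasing integer years (>= 4 for grey-model
#'   fitting downstream).
#' @param noise_sd Standard deviation of the lognormal multiplicative
#'   noise on the area series (capped at 1% per draw).
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(grid_shape = c(100, 100),
                          n_classes = 8,
                          cell_area = 1,
                          autocorrelation_scale = 5,
                          class_fractions = c(0.29, 0.25, 0.22, 0.06,
                                              0.05, 0.01, 0.11, 0.01),
                          trend_rates = c(0.996, 0.996, 1.000, 0.999,
                                          1.002, 0.995, 1.012, 0.990),
                          years = c(1995, 2000, 2005, 2010, 2015),
                          noise_sd = 0.003,
                          seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1))
  if (length(class_fractions) != n_classes)
    stop("`class_fractions` must have one entry per class")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must sum to 1")
  if (any(class_fractions < 0)) stop("`class_fractions` must be nonnegative")
  if (length(trend_rates) != n_classes)
    stop("`trend_rates` must have one entry per class")
  if (any(trend_rates <= 0)) stop("all `trend_rates` must be > 0")
  if (is.unsorted(years, strictly = TRUE))
    stop("`years` must be strictly increasing")
  structure(list(grid_shape = as.integer(grid_shape),
                 n_classes = as.integer(n_classes),
                 cell_area = cell_area,
                 autocorrelation_scale = autocorrelation_scale,
                 class_fractions = class_fractions,
                 trend_rates = trend_rates,
                 years = as.integer(years),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# 1-D convolution with edge replication, then applied over rows and columns;
# used to turn white noise into a spatially autocorrelated field.
conv1d <- function(v, k) {
  h <- (length(k) - 1L) %/% 2L
  vp <- c(rep(v[1], h), v, rep(v[length(v)], h))
  out <- stats::filter(vp, k, sides = 2)
  as.numeric(out[(h + 1):(h + length(v))])
}

smooth_field <- function(nr, nc, scale) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale <= 0) return(m)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  m <- apply(m, 2, conv1d, k = k)
  m <- t(apply(m, 1, conv1d, k = k))
  (m - mean(m)) / stats::sd(as.vector(m))
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' Draws one smoothed Gaussian random field per class and assigns each
#' cell the class whose field (plus a per-class offset) is largest; the
#' offsets are calibrated iteratively so realised class shares match
#' `spec$class_fractions`. The result has contiguous same-class patches,
#' like a real land-use map, and is deterministic for a fixed seed.
#'
#' @param spec A [scenario_spec()].
#' @return A [land_raster()] whose class shares match the target fractions
#'   to within about two percentage points.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  n <- nr * nc
  frac <- spec$class_fractions
  tiny <- which(frac > 0 & round(frac * n) < 1)
  if (length(tiny))
    stop("grid too small to realize class ", tiny[1], " (",
         land_legend()[as.character(tiny[1])], "): target share ",
         frac[tiny[1]], " is under one cell")
  set.seed(spec$seed)
  k <- spec$n_classes
  fields <- lapply(seq_len(k), function(i)
    smooth_field(nr, nc, spec$autocorrelation_scale))
  score <- vapply(fields, as.vector, numeric(n))  # n x k
  delta <- rep(0, k)
  delta[frac == 0] <- -Inf
  assign_cells <- function(delta) {
    max.col(sweep(score, 2, delta, "+"), ties.method = "first")
  }
  eta <- 3
  cl <- assign_cells(delta)
  for (it in seq_len(300)) {
    got <- tabulate(cl, nbins = k) / n
    err <- frac - got
    if (max(abs(err)) < 0.005) break
    delta[frac > 0] <- delta[frac > 0] + eta * err[frac > 0]
    eta <- eta * 0.99
    cl <- assign_cells(delta)
  }
  land_raster(matrix(cl, nr, nc), cell_area = spec$cell_area,
              legend = land_legend()[seq_len(k)])
}

#' Join-count statistic of same-class adjacency
#'
#' Counts rook-adjacent cell pairs sharing a class, together with the
#' expectation under random labelling with the observed shares. Used to
#' check that generated landscapes are genuinely autocorrelated.
#'
#' @param x A `land_raster`.
#' @return List with `observed`, `expected` and `n_pairs`.
#' @export
join_count <- function(x) {
  g <- x$grid
  same_h <- sum(g[, -ncol(g)] == g[, -1], na.rm = TRUE)
  same_v <- sum(g[-nrow(g), ] == g[-1, ], na.rm = TRUE)
  n_pairs <- nrow(g) * (ncol(g) - 1) + (nrow(g) - 1) * ncol(g)
  p <- class_counts(x) / sum(class_counts(x))
  list(observed = same_h + same_v,
       expected = n_pairs * sum(p^2),
       n_pairs = n_pairs)
}

#' Generate synthetic driving-factor layers
#'
#' Produces a stack emulating the usual drivers of land-use change:
#' smooth continuous fields (economic intensity, elevation, climate),
#' Euclidean-distance surfaces to seeded linear/point features (transport,
#' rivers, settlements), and small-integer multi-class layers (slope and
#' soil classes). The default 5 + 6 + 5 split gives the customary 16
#' layers. All layers share the landscape grid.
#'
#' @param landscape A `land_raster` defining the grid.
#' @param n_continuous,n_distance,n_multiclass Layer counts (all >= 0).
#' @param seed Integer seed.
#' @return A [factor_stack()] with `n_continuous + n_distance +
#'   n_multiclass` layers.
#' @export
generate_driving_factors <- function(landscape, n_continuous = 5,
                                     n_distance = 6, n_multiclass = 5,
                                     seed = 1L) {
  stopifnot(inherits(landscape, "land_raster"),
            n_continuous >= 0, n_distance >= 0, n_multiclass >= 0)
  nr <- nrow(landscape$grid); nc <- ncol(landscape$grid)
  set.seed(seed)
  cont_names <- c("gdp", "population_density", "dem", "temperature",
                  "rainfall")
  dist_names <- c("dist_railway", "dist_expressway", "dist_highway",
                  "dist_river", "dist_town", "dist_rural_settlement")
  mc_names <- c("slope_class", "soil_sand", "soil_silt", "soil_clay",
                "soil_erosion")
  pick_names <- function(base, n)
    if (n <= length(base)) base[seq_len(n)] else
      c(base, paste0(base[1], "_", seq_len(n - length(base))))
  layers <- list(); kind <- character(0)
  for (nm in pick_names(cont_names, n_continuous)) {
    layers[[nm]] <- smooth_field(nr, nc, max(2, nr / 20))
    kind <- c(kind, "continuous")
  }
  rowi <- matrix(seq_len(nr), nr, nc)
  coli <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (nm in pick_names(dist_names, n_distance)) {
    n_feat <- sample(3:12, 1)
    fr <- sample.int(nr, n_feat, replace = TRUE)
    fc <- sample.int(nc, n_feat, replace = TRUE)
    d <- matrix(Inf, nr, nc)
    for (j in seq_len(n_feat))
      d <- pmin(d, sqrt((rowi - fr[j])^2 + (coli - fc[j])^2))
    layers[[nm]] <- d
    kind <- c(kind, "continuous")
  }
  for (nm in pick_names(mc_names, n_multiclass)) {
    f <- smooth_field(nr, nc, max(2, nr / 15))
    brk <- stats::quantile(f, probs = seq(0, 1, length.out = 6))
    layers[[nm]] <- matrix(as.numeric(cut(f, breaks = brk,
                                          include.lowest = TRUE)), nr, nc)
    kind <- c(kind, "multi-class")
  }
  factor_stack(layers, kind = kind)
}

#' Generate a per-class area time series
#'
#' Areas follow `area_0 * rate^(year - year_0)` with bounded lognormal
#' multiplicative noise (each factor within 1% of 1), then each year is
#' proportionally rescaled so the landscape total is conserved. With zero
#' noise and `renormalize = FALSE` the series is exactly geometric, the
#' regime in which the grey model is exact.
#'
#' @param spec A [scenario_spec()] with at least 4 years.
#' @param renormalize Rescale each year to the year-0 total (default TRUE).
#' @return An `area_series`: list with `years`, `area` (class x year
#'   matrix, rows named by code) and `unit` (`"ha"`).
#' @export
generate_area_series <- function(spec, renormalize = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(spec$years) < 4)
    stop("at least 4 years are required: the GM(1,1) grey model needs >= 4 ",
         "observations")
  set.seed(spec$seed + 1L)
  total <- prod(spec$grid_shape) * spec$cell_area
  a0 <- spec$class_fractions * total
  t_rel <- spec$years - spec$years[1]
  area <- vapply(t_rel, function(t) {
    noise <- exp(pmin(pmax(stats::rnorm(spec$n_classes, 0, spec$noise_sd),
                           log(0.99)), log(1.01)))
    if (spec$noise_sd == 0) noise <- rep(1, spec$n_classes)
    a0 * spec$trend_rates^t * noise
  }, numeric(spec$n_classes))
  if (renormalize)
    area <- sweep(area, 2, total / colSums(area), "*")
  rownames(area) <- as.character(seq_len(spec$n_classes))
  colnames(area) <- as.character(spec$years)
  structure(list(years = spec$years, area = area, unit = "ha"),
            class = "area_series")
}

#' Generate paired regional/national socio-economic series
#'
#' Emits, for each year, the statistics feeding the ESV correction
#' factors: Engel coefficient (fraction in (0,1)), per-capita GDP (USD),
#' urbanization rate (fraction), population density (persons/km^2, > 1),
#' grain yield (kg/ha) and grain price (USD/kg), for both the study region
#' and the nation. Trends are smooth (falling Engel, rising GDP and
#' urbanization) with small seeded noise; all regional/national ratios
#' stay within [0.2, 5].
#'
#' @param years Integer years (non-empty).
#' @param seed Integer seed.
#' @return Data frame with columns `year`, `scope` ("region"/"nation"),
#'   `engel`, `pgdp`, `urbanization`, `pop_density`, `grain_yield`,
#'   `grain_price`.
#' @export
generate_socioeconomic_series <- function(years, seed = 1L) {
  if (!length(years)) stop("`years` must be non-empty")
  set.seed(seed + 2L)
  t_rel <- years - years[1]
  jitter1 <- function(sd) exp(stats::rnorm(length(years), 0, sd))
  mk <- function(scope, engel0, pgdp0, urb0, dens, yield0, price0) {
    data.frame(
      year = years, scope = scope,
      engel = pmin(0.95, pmax(0.05,
               engel0 * 0.99^t_rel * jitter1(0.01))),
      pgdp = pgdp0 * 1.06^t_rel * jitter1(0.02),
      urbanization = pmin(0.95, urb0 * 1.01^t_rel * jitter1(0.01)),
      pop_density = dens * 1.004^t_rel * jitter1(0.005),
      grain_yield = yield0 * 1.005^t_rel * jitter1(0.01),
      grain_price = price0 * 1.01^t_rel * jitter1(0.01))
  }
  out <- rbind(mk("region", 0.42, 9000, 0.52, 450, 4800, 0.38),
               mk("nation", 0.45, 8000, 0.55, 145, 5500, 0.38))
  rownames(out) <- NULL
  out
}

#' Evolve a landscape by a known number of rule-permitted changes
#'
#' Flips exactly `n_changes` distinct cells to a different, rule-permitted
#' class, never touching masked cells. The pair (input, output) has a known
#' change ledger (attached as attribute `change_ledger`), which makes it a
#' ground truth for transition-matrix estimation and CA validation.
#'
#' @param landscape A `land_raster`.
#' @param rules A [transition_rules()] permission matrix; cells whose class
#'   is absent from the rules are treated as unchangeable.
#' @param n_changes Number of cells to change.
#' @param seed Integer seed.
#' @param mask Optional logical/0-1 matrix; TRUE/1 cells are frozen.
#' @return A `land_raster` differing from the input in exactly `n_changes`
#'   cells.
#' @export
evolve_landscape <- function(landscape, rules, n_changes, seed = 1L,
                             mask = NULL) {
  stopifnot(inherits(landscape, "land_raster"),
            inherits(rules, "transition_rules"), n_changes >= 0)
  g <- landscape$grid
  codes <- as.integer(rownames(rules$allow))
  # cells with at least one permitted off-diagonal target
  can_change <- matrix(FALSE, nrow(g), ncol(g))
  for (i in seq_along(codes)) {
    targets <- codes[rules$allow[i, ] == 1 & codes != codes[i]]
    if (length(targets))
      can_change[!is.na(g) & g == codes[i]] <- TRUE
  }
  if (!is.null(mask)) can_change[mask == 1] <- FALSE
  idx <- which(can_change)
  if (n_changes > length(idx))
    stop("n_changes (", n_changes, ") exceeds the ", length(idx),
         " changeable cells")
  set.seed(seed + 3L)
  chosen <- if (n_changes > 0) sample(idx, n_changes) else integer(0)
  ledger <- data.frame(cell = chosen, from = g[chosen],
                       to = rep(NA_integer_, length(chosen)))
  for (j in seq_along(chosen)) {
    i <- match(g[chosen[j]], codes)
    targets <- codes[rules$allow[i, ] == 1 & codes != codes[i]]
    ledger$to[j] <- if (length(targets) == 1) targets else sample(targets, 1)
  }
  g[chosen] <- ledger$to
  out <- land_raster(g, cell_area = landscape$cell_area,
                     legend = landscape$legend)
  attr(out, "change_ledger") <- ledger
  out
}
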