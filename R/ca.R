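#' Conversion-rules permission matrix
#'
#' A binary from-class x to-class matrix: `allow[i, j] = 1` permits
#' conversion of class i cells to class j during allocation. The diagonal
#' must be all ones (a class may always persist).
#'
#' @param allow Square 0/1 matrix with identical row/column class codes as
#'   dimnames.
#' @param class_names Optional character vector of class names (same
#'   order).
#' @return An object of class `transition_rules`.
#' @export
transition_rules <- function(allow, class_names = NULL) {
  allow <- as.matrix(allow)
  if (nrow(allow) != ncol(allow)) stop("rules matrix must be square")
  if (!all(allow %in% c(0, 1))) stop("rules matrix entries must be 0 or 1")
  if (any(diag(allow) != 1))
    stop("rules diagonal must be all 1: every class may persist")
  if (is.null(rownames(allow)))
    dimnames(allow) <- list(as.character(seq_len(nrow(allow))),
                            as.character(seq_len(nrow(allow))))
  if (all(allow == diag(nrow(allow))))
    warning("identity-only rules: no change is possible")
  structure(list(allow = allow, class_names = class_names),
            class = "transition_rules")
}

#' @export
print.transition_rules <- function(x, ...) {
  cat("Conversion rules (", nrow(x$allow), " classes):\n", sep = "")
  print(x$allow)
  invisible(x)
}

#' Load a conversion-rules matrix from CSV
#'
#' The CSV has a header row and a first column of class names, with 0/1
#' entries. Names are matched (case-insensitively) against the canonical
#' legend to recover class codes.
#'
#' @param path CSV file path.
#' @return A [transition_rules()] object with codes as dimnames.
#' @export
load_rules <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- trimws(as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("rules CSV is not square: ", nrow(m), " rows vs ", ncol(m),
         " class columns")
  cn <- trimws(colnames(m))
  if (!setequal(tolower(nm), tolower(cn)))
    stop("rules CSV row and column class names differ; missing column(s): ",
         paste(setdiff(tolower(nm), tolower(cn)), collapse = ", "))
  m <- m[, match(tolower(nm), tolower(cn)), drop = FALSE]
  if (!all(m %in% c(0, 1))) stop("rules CSV has non-binary entries")
  leg <- land_legend()
  codes <- names(leg)[match(tolower(nm), tolower(leg))]
  if (any(is.na(codes)))
    stop("unknown class name(s) in rules CSV: ",
         paste(nm[is.na(codes)], collapse = ", "))
  storage.mode(m) <- "numeric"
  dimnames(m) <- list(codes, codes)
  transition_rules(m, class_names = nm)
}

#' The packaged ecological-optimization conversion rules
#'
#' Loads the shipped scenario fixture: water is fully frozen, the
#' high-value classes (forest, grass, wet land) may not convert to the
#' low-value ones (cultivated and built-up land), cultivated and built-up
#' land are unrestricted.
#'
#' @return A [transition_rules()] over classes 1-7.
#' @export
ecological_rules <- function() {
  load_rules(system.file("extdata", "rules_ecological_optimization.csv",
                         package = "lucesv", mustWork = TRUE))
}

#' CA engine parameters
#'
#' @param neighborhood_size Odd window size >= 3 (cells), default 7.
#' @param max_iterations Maximum sweeps, default 200.
#' @param demand_tolerance Allowed per-class gap in cells; default
#'   `NULL` means 0.1% of the grid's data cells.
#' @param inertia_floor Lower clamp on the adaptive inertia, default 0.01.
#' @param neighborhood_epsilon Additive constant on the neighborhood
#'   fraction so absent-but-demanded classes can seed (default 0.01).
#' @param seed Integer seed for visiting order and roulette draws.
#' @return An object of class `ca_params`.
#' @export
ca_params <- function(neighborhood_size = 7, max_iterations = 200,
                      demand_tolerance = NULL, inertia_floor = 0.01,
                      neighborhood_epsilon = 0.01, seed = 1L) {
  if (neighborhood_size < 3 || neighborhood_size %% 2 == 0)
    stop("`neighborhood_size` must be odd and >= 3")
  stopifnot(max_iterations >= 1, inertia_floor > 0)
  structure(list(neighborhood_size = as.integer(neighborhood_size),
                 max_iterations = as.integer(max_iterations),
                 demand_tolerance = demand_tolerance,
                 inertia_floor = inertia_floor,
                 neighborhood_epsilon = neighborhood_epsilon,
                 seed = as.integer(seed)),
            class = "ca_params")
}

# truncated box sum via integral images; h is the half-width
box_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  a <- pmax(1L, seq_len(nr) - h); b <- pmin(nr, seq_len(nr) + h)
  roww <- cs[b + 1L, , drop = FALSE] - cs[a, , drop = FALSE]
  cs2 <- cbind(0, t(apply(roww, 1, cumsum)))
  a2 <- pmax(1L, seq_len(nc) - h); b2 <- pmin(nc, seq_len(nc) + h)
  cs2[, b2 + 1L, drop = FALSE] - cs2[, a2, drop = FALSE]
}

#' Neighborhood density of a class
#'
#' Per cell, the fraction of cells of class `cls` within the square Moore
#' window of side `neighborhood_size`, excluding the center cell; at the
#' edges the truncated window is used.
#'
#' @param landuse A `land_raster`.
#' @param cls Class code (integer or string).
#' @param params A [ca_params()] (only `neighborhood_size` is used).
#' @return Matrix in `[0, 1]` aligned to the grid.
#' @export
neighborhood_effect <- function(landuse, cls, params = ca_params()) {
  g <- landuse$grid
  h <- (params$neighborhood_size - 1L) %/% 2L
  ind <- (!is.na(g) & g == as.integer(cls)) * 1
  ones <- matrix(1, nrow(g), ncol(g))
  (box_sum(ind, h) - ind) / (box_sum(ones, h) - 1)
}

#' Adaptive inertia update
#'
#' Updates one class's inertia from the last two demand gaps
#' `D = demand - allocated`. The gap improving (or unchanged) in absolute
#' value leaves inertia alone; a worsening over-allocation
#' (`D_prev < D_prev2 < 0`) shrinks it by `D_prev2 / D_prev`; a worsening
#' under-allocation (`0 < D_prev2 < D_prev`) grows it by
#' `D_prev / D_prev2`. Zero denominators leave it unchanged and the
#' result is clamped at `inertia_floor`.
#'
#' @param inertia_prev Previous inertia coefficient.
#' @param demand Demand target (cells) for the class.
#' @param allocated_prev,allocated_prev2 Cells allocated after the last
#'   and second-to-last sweeps.
#' @param inertia_floor Lower clamp (> 0).
#' @param iteration Current sweep number; sweeps before the third return 1.
#' @return Updated inertia coefficient (>= `inertia_floor`).
#' @export
adaptive_inertia <- function(inertia_prev, demand, allocated_prev,
                             allocated_prev2, inertia_floor = 0.01,
                             iteration = 3) {
  if (iteration < 3) return(1)
  d1 <- demand - allocated_prev
  d2 <- demand - allocated_prev2
  out <- if (abs(d1) <= abs(d2)) inertia_prev
  else if (d1 < d2 && d2 < 0) {
    if (d1 == 0) inertia_prev else inertia_prev * d2 / d1
  } else if (d1 > d2 && d2 > 0) {
    if (d2 == 0) inertia_prev else inertia_prev * d1 / d2
  } else inertia_prev
  max(out, inertia_floor)
}

#' Combined per-cell conversion probabilities
#'
#' The competition score of class j at a cell is the product of its
#' suitability probability, its neighborhood density, its current inertia
#' and the rule permission from the cell's current class; scores are
#' renormalized per cell into a distribution. Frozen cells get a point
#' mass on their current class, as does any cell whose scores are all
#' zero.
#'
#' @param suit A `suitability_stack` (from [predict.suitability_model()]).
#' @param neigh Named list of neighborhood matrices, one per class code.
#' @param inertia Named numeric vector of per-class inertia coefficients.
#' @param rules A [transition_rules()].
#' @param current The current `land_raster`.
#' @param mask Optional 0/1 matrix of frozen cells.
#' @return Named list of per-class probability matrices summing to 1 per
#'   cell.
#' @export
combined_probability <- function(suit, neigh, inertia, rules, current,
                                 mask = NULL) {
  codes <- rownames(rules$allow)
  g <- current$grid
  cur_idx <- match(as.character(g), codes)
  score <- lapply(codes, function(j) {
    allow_vec <- rules$allow[, j][cur_idx]
    allow_vec[is.na(allow_vec)] <- 0
    s <- suit$p[[j]] * neigh[[j]] * inertia[[j]] *
      matrix(allow_vec, nrow(g), ncol(g))
    s[is.na(s)] <- 0
    s
  })
  names(score) <- codes
  tot <- Reduce(`+`, score)
  fixed <- (tot == 0)
  if (!is.null(mask)) fixed <- fixed | (mask == 1)
  out <- lapply(codes, function(j) {
    p <- score[[j]] / ifelse(tot == 0, 1, tot)
    # degenerate cells keep their class; frozen cells are a point mass
    p[fixed] <- as.numeric(g[fixed] == as.integer(j))
    p[is.na(g)] <- NA
    p
  })
  names(out) <- codes
  out
}

#' Roulette-wheel class selection
#'
#' Samples a class with probability proportional to its score.
#'
#' @param distribution Nonnegative named vector summing to 1 (after
#'   normalization).
#' @return The selected class code (character).
#' @export
roulette_select <- function(distribution) {
  if (any(distribution < 0) || sum(distribution) <= 0)
    stop("distribution must be nonnegative with positive mass")
  names(distribution)[sample.int(length(distribution), 1,
                                 prob = distribution)]
}

# max-flow feasibility on the permission digraph: can surplus classes supply
# every deficit through permitted conversions of unfrozen cells? Chains
# across sweeps (A -> B while B -> C) are legal, so permitted class-to-class
# edges carry unbounded flow; only the surplus a class can shed (limited to
# its unfrozen cells) and each deficit bound the flow.
check_feasible <- function(counts, demand, rules, movable) {
  codes <- names(demand)
  surplus <- pmax(counts - demand, 0)
  deficit <- pmax(demand - counts, 0)
  if (sum(deficit) == 0) return(invisible(TRUE))
  supply <- pmin(surplus, movable)
  k <- length(codes)
  big <- sum(deficit)
  edges <- c(); caps <- c()
  for (i in seq_len(k)) if (supply[i] > 0) {
    edges <- c(edges, 1, i + 2)
    caps <- c(caps, supply[i])
  }
  for (j in seq_len(k)) if (deficit[j] > 0) {
    edges <- c(edges, j + 2, 2)
    caps <- c(caps, deficit[j])
  }
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j && rules$allow[codes[i], codes[j]] == 1) {
      edges <- c(edges, i + 2, j + 2)
      caps <- c(caps, big)
    }
  g <- igraph::make_graph(edges, n = 2 + k, directed = TRUE)
  fl <- igraph::max_flow(g, source = 1, target = 2, capacity = caps)
  if (fl$value < sum(deficit))
    stop("infeasible demand: permitted conversions can supply only ",
         fl$value, " of the ", sum(deficit), " cells of total deficit")
  # per-edge flows double as class-to-class conversion budgets
  plan <- matrix(0, k, k, dimnames = list(codes, codes))
  el <- matrix(edges, ncol = 2, byrow = TRUE)
  inner <- el[, 1] > 2 & el[, 2] > 2
  plan[el[inner, , drop = FALSE] - 2] <- round(fl$flow[inner])
  invisible(plan)
}

#' Allocate demanded class areas with the constrained cellular automaton
#'
#' Iterative competitive allocation. A max-flow feasibility check on the
#' permission matrix first proves the demand reachable and yields
#' class-to-class conversion budgets (net numbers of cells each class must
#' pass to each permitted neighbour class, including transshipment chains
#' such as cultivated -> forest while forest -> water). Each sweep then
#' recomputes neighborhood densities, visits cells of donor classes in a
#' seeded random order and draws each cell's next class by roulette from
#' the product of suitability, neighborhood density and class inertia over
#' the budgeted, rule-permitted targets plus the current class; the
#' per-class inertia is updated from the evolving demand gaps after every
#' sweep. Stops when every class is within `demand_tolerance` cells of
#' its target (exact once all budgets are spent) or after
#' `max_iterations` sweeps. Frozen cells never change; cell count is
#' conserved at every sweep; no transition forbidden from a cell's
#' initial class can occur, even through chains.
#'
#' @param initial A `land_raster`. Cells whose class is absent from the
#'   rules (e.g. residual unused land after the demand fold-in) are
#'   relabelled to `absorb_unknown_into` before iterating.
#' @param suit A `suitability_stack` covering the rules' classes.
#' @param rules A [transition_rules()].
#' @param mask Optional 0/1 matrix of frozen cells (1 = frozen).
#' @param demand Named integer cell targets summing to the grid's data
#'   cells.
#' @param params A [ca_params()].
#' @param absorb_unknown_into Class code for relabelling out-of-rules
#'   cells (default "7", built-up land); NULL to treat them as an error.
#' @return List of class `ca_result`: `map` (final `land_raster`), `log`
#'   (data frame: sweep, class, allocated, target, inertia), `converged`,
#'   `sweeps`.
#' @export
run_allocation <- function(initial, suit, rules, mask = NULL, demand,
                           params = ca_params(),
                           absorb_unknown_into = "7") {
  stopifnot(inherits(initial, "land_raster"),
            inherits(rules, "transition_rules"))
  codes <- rownames(rules$allow)
  if (!setequal(names(demand), codes))
    stop("demand classes must match the rules' classes")
  demand <- demand[codes]
  g <- initial$grid
  unknown <- !is.na(g) & !(as.character(g) %in% codes)
  if (any(unknown)) {
    if (is.null(absorb_unknown_into))
      stop("initial map contains classes outside the rules")
    g[unknown] <- as.integer(absorb_unknown_into)
  }
  n_data <- sum(!is.na(g))
  if (sum(demand) != n_data)
    stop("demand must sum to the number of data cells (", n_data, ")")
  frozen <- if (is.null(mask)) matrix(FALSE, nrow(g), ncol(g)) else mask == 1
  for (j in codes) {
    nfroz <- sum(frozen & g == as.integer(j), na.rm = TRUE)
    if (demand[j] < nfroz)
      stop("demand for class ", j, " (", demand[j],
           ") is below its frozen cell count (", nfroz, ")")
  }
  tol <- if (is.null(params$demand_tolerance))
    max(1, round(0.001 * n_data)) else params$demand_tolerance
  counts <- stats::setNames(
    vapply(codes, function(j) sum(g == as.integer(j), na.rm = TRUE), 0L),
    codes)
  movable <- stats::setNames(
    vapply(codes, function(j)
      sum(g == as.integer(j) & !frozen, na.rm = TRUE), 0L), codes)
  plan <- check_feasible(counts, demand, rules, movable)
  set.seed(params$seed)
  inertia <- stats::setNames(rep(1, length(codes)), codes)
  eps <- params$neighborhood_epsilon
  work <- land_raster(g, cell_area = initial$cell_area,
                      legend = initial$legend)
  log_rows <- list()
  hist_alloc <- list(counts, counts)
  converged <- all(abs(counts - demand) <= tol)
  sweep_i <- 0L
  suit_cell <- vapply(codes, function(j) as.vector(suit$p[[j]]),
                      numeric(length(g)))
  budget <- plan  # remaining class-to-class conversion budgets
  while (!converged && sum(budget) > 0 && sweep_i < params$max_iterations) {
    sweep_i <- sweep_i + 1L
    neigh <- lapply(codes, function(j)
      neighborhood_effect(work, j, params) + eps)
    names(neigh) <- codes
    neigh_cell <- vapply(codes, function(j) as.vector(neigh[[j]]),
                         numeric(length(g)))
    gv <- work$grid
    donors <- codes[rowSums(budget) > 0]
    cand <- which(!is.na(gv) & !frozen & as.character(gv) %in% donors)
    cand <- cand[sample.int(length(cand))]
    for (cell in cand) {
      i <- as.character(gv[cell])
      # targets must be permitted both from the current class (budget) and
      # from the cell's initial class, so no forbidden transition can arise
      # through a chain of conversions
      open <- codes[budget[i, ] > 0 &
                      rules$allow[as.character(g[cell]), ] == 1]
      if (!length(open)) next
      pool <- c(i, open)
      w <- suit_cell[cell, pool] * neigh_cell[cell, pool] * inertia[pool]
      if (sum(w) <= 0) next
      pick <- pool[sample.int(length(pool), 1, prob = w)]
      if (pick != i) {
        gv[cell] <- as.integer(pick)
        counts[i] <- counts[i] - 1L
        counts[pick] <- counts[pick] + 1L
        budget[i, pick] <- budget[i, pick] - 1
      }
    }
    work$grid <- gv
    # inertia update from the two previous sweeps' gaps
    for (j in codes)
      inertia[j] <- adaptive_inertia(inertia[j], demand[j],
                                     hist_alloc[[2]][j], hist_alloc[[1]][j],
                                     params$inertia_floor,
                                     iteration = sweep_i)
    hist_alloc <- list(hist_alloc[[2]], counts)
    log_rows[[sweep_i]] <- data.frame(sweep = sweep_i, class = codes,
                                      allocated = as.integer(counts),
                                      target = as.integer(demand),
                                      inertia = as.numeric(inertia))
    converged <- all(abs(counts - demand) <= tol)
  }
  structure(list(map = work,
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(sweep = integer(), class = character(),
                                       allocated = integer(),
                                       target = integer(),
                                       inertia = numeric()),
                 converged = converged, sweeps = sweep_i),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("CA allocation:", x$sweeps, "sweeps,",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (nrow(x$log)) {
    last <- x$log[x$log$sweep == max(x$log$sweep), ]
    print(last[, c("class", "allocated", "target", "inertia")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Uniform random cell sample
#'
#' @param raster A `land_raster`.
#' @param fraction Sampling fraction in (0, 1]; sample size is
#'   `round(fraction * data cells)`.
#' @param seed Integer seed.
#' @return Sorted vector of sampled cell indices (without replacement).
#' @export
sample_cells <- function(raster, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  ok <- which(!is.na(raster$grid))
  n <- round(fraction * length(ok))
  set.seed(seed)
  if (n >= length(ok)) ok else sort(sample(ok, n))
}

#' Confusion matrix, overall accuracy and kappa
#'
#' Cross-tabulates simulated against actual labels (rows = simulated,
#' columns = actual, the layout of standard map-accuracy tables) and
#' derives overall accuracy (trace over total), the kappa coefficient
#' `(p_o - p_e) / (1 - p_e)` with chance agreement
#' `p_e = sum(row_i * col_i) / N^2`, and per-class user's (row) and
#' producer's (column) accuracies. Either pass two label vectors or a
#' ready count matrix.
#'
#' @param actual,simulated Equal-length label vectors (ignored when
#'   `counts` is given).
#' @param counts Optional square count matrix (simulated x actual).
#' @return List of class `confusion_matrix`: `counts`, `overall_accuracy`
#'   (fraction), `kappa`, `users_accuracy`, `producers_accuracy`, `n`.
#' @export
assess_accuracy <- function(actual = NULL, simulated = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(actual) || is.null(simulated) || !length(actual))
      stop("empty input: provide label vectors or a count matrix")
    if (length(actual) != length(simulated))
      stop("label vectors differ in length")
    lev <- sort(unique(c(actual, simulated)))
    counts <- table(factor(simulated, levels = lev),
                    factor(actual, levels = lev))
    counts <- matrix(counts, nrow(counts), dimnames = dimnames(counts))
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("count matrix must be square")
  N <- sum(counts)
  if (N == 0) stop("empty input: no observations")
  po <- sum(diag(counts)) / N
  pe <- sum(rowSums(counts) * colSums(counts)) / N^2
  structure(list(counts = counts,
                 overall_accuracy = po,
                 kappa = (po - pe) / (1 - pe),
                 users_accuracy = diag(counts) / rowSums(counts),
                 producers_accuracy = diag(counts) / colSums(counts),
                 n = N),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = simulated, cols = actual), n =", x$n, "\n")
  print(x$counts)
  cat(sprintf("overall accuracy: %.2f%%   kappa: %.4f\n",
              100 * x$overall_accuracy, x$kappa))
  invisible(x)
}
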