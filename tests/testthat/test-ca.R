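test_that("rules constructor validates structure", {
  expect_error(transition_rules(matrix(1, 2, 3)), "square")
  expect_error(transition_rules(matrix(2, 2, 2)), "0 or 1")
  m <- matrix(1, 2, 2); diag(m) <- c(1, 0)
  expect_error(transition_rules(m), "diagonal")
  expect_warning(transition_rules(diag(3)), "identity")
})

test_that("the packaged ecological rules freeze water and protect forest", {
  r <- ecological_rules()
  expect_identical(dim(r$allow), c(7L, 7L))
  # water (5) converts to nothing else
  expect_identical(unname(r$allow["5", ]), c(0, 0, 0, 0, 1, 0, 0))
  # forest (3) may persist or go to water and wet land only
  expect_identical(unname(r$allow["3", ]), c(0, 0, 1, 0, 1, 1, 0))
  # built-up land (7) only from cultivated or itself
  expect_identical(unname(r$allow[, "7"]), c(1, 1, 0, 0, 0, 0, 1))
  expect_true(all(diag(r$allow) == 1))
})

test_that("neighborhood density matches hand counts on a 3x3 window", {
  g <- matrix(2L, 5, 5); g[3, 3] <- 1L; g[3, 4] <- 1L
  ls <- land_raster(g, legend = c("1" = "a", "2" = "b"))
  p <- ca_params(neighborhood_size = 3)
  ne <- neighborhood_effect(ls, 1, p)
  # center cell: 8 neighbours, one of class 1
  expect_equal(ne[3, 3], 1 / 8)
  # cell (3,4): 8 neighbours, one of class 1 (the center)
  expect_equal(ne[3, 4], 1 / 8)
  # corner cell (1,1): 3 neighbours, none of class 1
  expect_equal(ne[1, 1], 0)
  # cell (2,3): 8 neighbours, two of class 1
  expect_equal(ne[2, 3], 2 / 8)
  # complementary classes always sum to 1
  ne2 <- neighborhood_effect(ls, 2, p)
  expect_true(all(abs(ne + ne2 - 1) < 1e-12))
})

test_that("truncated windows are used at the edges", {
  g <- matrix(1L, 4, 4)
  ls <- land_raster(g, legend = c("1" = "a"))
  ne <- neighborhood_effect(ls, 1, ca_params(neighborhood_size = 3))
  expect_true(all(ne == 1))
  g[1, 1] <- NA
  ne2 <- neighborhood_effect(land_raster(g, legend = c("1" = "a")), 1,
                             ca_params(neighborhood_size = 3))
  # (1,2) has 5 neighbours, 4 of class 1
  expect_equal(ne2[1, 2], 4 / 5)
})

test_that("adaptive inertia follows the three-case rule", {
  # early sweeps: identity
  expect_identical(adaptive_inertia(0.7, 10, 4, 2, iteration = 2), 1)
  # gap improving in absolute value: unchanged
  expect_identical(adaptive_inertia(0.7, 10, 8, 4, iteration = 5), 0.7)
  # worsening over-allocation: D1 = -6 < D2 = -2 < 0, shrink by d2/d1 = 1/3
  expect_equal(adaptive_inertia(0.9, 10, 16, 12, iteration = 5), 0.3)
  # worsening under-allocation: 0 < D2 = 2 < D1 = 6, grow by d1/d2 = 3
  expect_equal(adaptive_inertia(0.5, 10, 4, 8, iteration = 5), 1.5)
  # floor clamp
  expect_identical(adaptive_inertia(0.012, 10, 16, 12,
                                    inertia_floor = 0.01, iteration = 5),
                   0.01)
})

test_that("combined probabilities honor the rules and normalize", {
  codes <- c("1", "2", "3")
  allow <- matrix(1, 3, 3, dimnames = list(codes, codes))
  allow["1", "3"] <- 0
  rules <- transition_rules(allow)
  g <- matrix(c(1L, 2L, 3L, 1L), 2, 2)
  cur <- land_raster(g, legend = stats::setNames(letters[1:3], codes))
  suit <- uniform_suitability(1:3, 2, 2)
  neigh <- lapply(codes, function(j) matrix(0.5, 2, 2)); names(neigh) <- codes
  inertia <- stats::setNames(rep(1, 3), codes)
  p <- combined_probability(suit, neigh, inertia, rules, cur)
  tot <- Reduce(`+`, p)
  expect_true(all(abs(tot - 1) < 1e-12))
  # forbidden 1 -> 3 transition has probability zero at class-1 cells
  expect_identical(p[["3"]][1, 1], 0)
  expect_identical(p[["3"]][2, 2], 0)
  # symmetric inputs split mass evenly among the permitted classes
  expect_equal(p[["1"]][1, 1], 0.5)
  expect_equal(p[["2"]][1, 2], 1 / 3)
})

test_that("frozen and all-zero cells keep a point mass on their class", {
  codes <- c("1", "2")
  rules <- all_allowed_rules(2)
  g <- matrix(c(1L, 2L, 1L, 2L), 2, 2)
  cur <- land_raster(g, legend = c("1" = "a", "2" = "b"))
  suit <- uniform_suitability(1:2, 2, 2)
  suit$p[["1"]][2, 2] <- 0; suit$p[["2"]][2, 2] <- 0  # all-zero cell
  neigh <- list("1" = matrix(0.5, 2, 2), "2" = matrix(0.5, 2, 2))
  mask <- matrix(0, 2, 2); mask[1, 1] <- 1
  p <- combined_probability(suit, neigh, c("1" = 1, "2" = 1), rules, cur, mask)
  expect_identical(p[["1"]][1, 1], 1)  # frozen class-1 cell
  expect_identical(p[["2"]][1, 1], 0)
  expect_identical(p[["2"]][2, 2], 1)  # all-zero class-2 cell persists
})

test_that("roulette selection is unbiased at known weights", {
  set.seed(12)
  draws <- replicate(1e5, roulette_select(c(a = 0.5, b = 0.3, c = 0.2)))
  f <- table(draws) / 1e5
  expect_true(abs(f[["a"]] - 0.5) < 0.01)
  expect_true(abs(f[["b"]] - 0.3) < 0.01)
  expect_error(roulette_select(c(a = 0, b = 0)), "positive mass")
})

test_that("allocation meets demand exactly and conserves cells", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(60, 60), seed = 10L))
  rules <- all_allowed_rules(7)
  # build a reachable demand by nudging counts between classes
  g <- ls$grid; g[g == 8L] <- 7L
  ls7 <- land_raster(g, cell_area = ls$cell_area)
  cnt <- vapply(as.character(1:7),
                function(j) sum(g == as.integer(j)), 0L)
  demand <- cnt + c(-40L, 25L, 15L, 0L, 0L, 0L, 0L)
  names(demand) <- as.character(1:7)
  suit <- uniform_suitability(1:7, 60, 60)
  res <- run_allocation(ls7, suit, rules, demand = demand,
                        params = ca_params(demand_tolerance = 0, seed = 3L))
  expect_true(res$converged)
  final <- vapply(as.character(1:7),
                  function(j) sum(res$map$grid == as.integer(j)), 0L)
  expect_identical(final, demand)
  expect_identical(sum(final), sum(cnt))
})

test_that("frozen cells never change during allocation", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(40, 40), seed = 12L))
  g <- ls$grid; g[g == 8L] <- 7L
  ls7 <- land_raster(g, cell_area = ls$cell_area)
  mask <- matrix(0, 40, 40); mask[g == 5L] <- 1
  cnt <- vapply(as.character(1:7), function(j) sum(g == as.integer(j)), 0L)
  names(cnt) <- as.character(1:7)
  demand <- cnt
  demand["1"] <- demand["1"] - 30L; demand["3"] <- demand["3"] + 30L
  res <- run_allocation(ls7, uniform_suitability(1:7, 40, 40),
                        all_allowed_rules(7), mask = mask, demand = demand,
                        params = ca_params(demand_tolerance = 0, seed = 4L))
  expect_identical(res$map$grid[mask == 1], g[mask == 1])
})

test_that("no forbidden transition occurs, even through chains", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(50, 50), seed = 14L))
  g <- ls$grid; g[g == 8L] <- 7L
  ls7 <- land_raster(g, cell_area = ls$cell_area)
  rules <- ecological_rules()
  cnt <- vapply(as.character(1:7), function(j) sum(g == as.integer(j)), 0L)
  names(cnt) <- as.character(1:7)
  demand <- cnt
  demand["1"] <- demand["1"] - 25L
  demand["3"] <- demand["3"] + 15L
  demand["7"] <- demand["7"] + 10L
  res <- run_allocation(ls7, uniform_suitability(1:7, 50, 50), rules,
                        demand = demand,
                        params = ca_params(demand_tolerance = 0, seed = 5L))
  expect_true(res$converged)
  changed <- which(res$map$grid != g)
  for (cell in changed)
    expect_identical(rules$allow[as.character(g[cell]),
                                 as.character(res$map$grid[cell])], 1)
})

test_that("infeasible demand is rejected with the deficit size", {
  # ecological rules: water (5) can only come from classes that may convert
  # to it; freeze everything except water so no supply exists
  g <- matrix(rep(c(1L, 5L), each = 8), 4, 4)
  ls <- land_raster(g, legend = stats::setNames(land_legend()[1:7],
                                                as.character(1:7)))
  rules <- ecological_rules()
  cnt <- stats::setNames(vapply(as.character(1:7),
                                function(j) sum(g == as.integer(j)), 0L),
                         as.character(1:7))
  demand <- cnt; demand["1"] <- cnt["1"] - 4L; demand["7"] <- 4L
  mask <- matrix(1, 4, 4)  # all frozen: nothing movable
  expect_error(run_allocation(ls, uniform_suitability(1:7, 4, 4), rules,
                              mask = mask, demand = demand),
               "below its frozen cell count|infeasible")
  # unfrozen but demand for a class no donor may reach: wet land (6) may
  # only persist or become water, so a forest deficit cannot be supplied
  g2 <- matrix(rep(c(5L, 6L), each = 8), 4, 4)
  ls2 <- land_raster(g2, legend = stats::setNames(land_legend()[1:7],
                                                  as.character(1:7)))
  cnt2 <- stats::setNames(vapply(as.character(1:7),
                                 function(j) sum(g2 == as.integer(j)), 0L),
                          as.character(1:7))
  d2 <- cnt2; d2["6"] <- cnt2["6"] - 2L; d2["3"] <- 2L
  expect_error(run_allocation(ls2, uniform_suitability(1:7, 4, 4), rules,
                              demand = d2),
               "infeasible")
})

test_that("allocation is deterministic for a fixed seed", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(40, 40), seed = 16L))
  g <- ls$grid; g[g == 8L] <- 7L
  ls7 <- land_raster(g, cell_area = ls$cell_area)
  cnt <- stats::setNames(vapply(as.character(1:7),
                                function(j) sum(g == as.integer(j)), 0L),
                         as.character(1:7))
  demand <- cnt; demand["1"] <- demand["1"] - 20L
  demand["7"] <- demand["7"] + 20L
  run1 <- run_allocation(ls7, uniform_suitability(1:7, 40, 40),
                         all_allowed_rules(7), demand = demand,
                         params = ca_params(seed = 9L))
  run2 <- run_allocation(ls7, uniform_suitability(1:7, 40, 40),
                         all_allowed_rules(7), demand = demand,
                         params = ca_params(seed = 9L))
  expect_identical(run1$map$grid, run2$map$grid)
})

test_that("cell sampling is reproducible and sized correctly", {
  ls <- tiny_raster(rep(1:2, 50), nr = 10, nc = 10)
  s <- sample_cells(ls, 0.25, seed = 3L)
  expect_identical(length(s), 25L)
  expect_identical(s, sample_cells(ls, 0.25, seed = 3L))
  expect_identical(sample_cells(ls, 1), which(!is.na(ls$grid)))
  expect_error(sample_cells(ls, 0), "fraction")
})

test_that("identical maps give accuracy 1 and kappa 1", {
  lab <- sample(1:5, 200, replace = TRUE)
  cm <- assess_accuracy(lab, lab)
  expect_identical(cm$overall_accuracy, 1)
  expect_identical(cm$kappa, 1)
  expect_true(all(cm$users_accuracy == 1))
})

test_that("kappa matches the brute-force marginal computation", {
  set.seed(23)
  for (i in 1:15) {
    k <- sample(2:10, 1)
    counts <- matrix(stats::rpois(k * k, 20), k, k)
    cm <- assess_accuracy(counts = counts)
    expect_equal(cm$kappa, kappa_bruteforce(counts), tolerance = 1e-12)
    expect_equal(cm$overall_accuracy, sum(diag(counts)) / sum(counts))
  }
})

test_that("degenerate confusion inputs fail clearly", {
  expect_error(assess_accuracy(integer(), integer()), "empty")
  expect_error(assess_accuracy(1:3, 1:2), "length")
  expect_error(assess_accuracy(counts = matrix(1, 2, 3)), "square")
})
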