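test_that("min-max normalization maps known values and is idempotent", {
  fs <- factor_stack(list(a = matrix(c(2, 4, 6, 10), 2, 2),
                          b = matrix(5, 2, 2),
                          c = matrix(c(0, NA, 1, 2), 2, 2)))
  nz <- normalize_stack(fs)
  expect_equal(nz$layers$a, matrix(c(0, 0.25, 0.5, 1), 2, 2))
  expect_equal(nz$layers$b, matrix(0.5, 2, 2))
  expect_equal(nz$layers$c, matrix(c(0, NA, 0.5, 1), 2, 2))
  expect_equal(normalize_stack(nz)$layers, nz$layers)
})

test_that("normalization rejects all-NA and non-finite layers", {
  expect_error(normalize_stack(factor_stack(list(x = matrix(NA_real_, 2, 2)))),
               "nodata")
  expect_error(normalize_stack(factor_stack(list(x = matrix(c(1, Inf, 2, 3),
                                                            2, 2)))),
               "non-finite")
})

test_that("uniform sampling returns aligned factor rows and labels", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(30, 30), seed = 4L))
  fs <- normalize_stack(generate_driving_factors(ls, seed = 5L))
  tr <- sample_training(ls, fs, n = 120, seed = 8L)
  expect_identical(nrow(tr$x), 120L)
  expect_identical(length(tr$y), 120L)
  expect_identical(colnames(tr$x), names(fs$layers))
  # rows really are the factor values at the sampled cells
  for (r in c(1L, 60L, 120L))
    expect_equal(unname(tr$x[r, "dem"]), fs$layers$dem[tr$cells[r]])
  expect_identical(tr$y, ls$grid[tr$cells])
  # deterministic
  expect_identical(sample_training(ls, fs, 120, seed = 8L)$cells, tr$cells)
})

test_that("stratified sampling matches class proportions within one cell", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(50, 50), seed = 4L))
  fs <- normalize_stack(generate_driving_factors(ls, seed = 5L))
  n <- 500
  tr <- sample_training(ls, fs, n, strategy = "stratified", seed = 9L)
  cnt <- table(factor(tr$y, levels = sort(unique(as.vector(ls$grid)))))
  share <- class_counts(ls) / sum(class_counts(ls))
  expect_true(all(abs(as.numeric(cnt) - share[names(cnt)] * n) <= 1))
})

test_that("sampling more cells than exist fails", {
  ls <- tiny_raster(rep(1:2, 8))
  fs <- factor_stack(list(a = matrix(stats::runif(16), 4, 4)))
  expect_error(sample_training(ls, fs, 17), "exceeds")
})

test_that("the ANN separates a linearly separable problem", {
  tr <- separable_training(400)
  mod <- train_suitability_ann(tr, hidden_units = 4, epochs = 200, seed = 2L)
  fs <- factor_stack(list(a = matrix(tr$x[, 1], 20, 20),
                          b = matrix(tr$x[, 2], 20, 20)))
  suit <- predict(mod, fs)
  pred <- ifelse(suit$p[["1"]] > suit$p[["2"]], 1L, 2L)
  acc <- mean(as.vector(pred) == tr$y)
  expect_gte(acc, 0.95)
})

test_that("shuffled labels give near-chance accuracy", {
  tr <- separable_training(400)
  set.seed(7); tr$y <- sample(tr$y)
  mod <- train_suitability_ann(tr, hidden_units = 4, epochs = 200, seed = 2L)
  fs <- factor_stack(list(a = matrix(tr$x[, 1], 20, 20),
                          b = matrix(tr$x[, 2], 20, 20)))
  suit <- predict(mod, fs)
  pred <- ifelse(suit$p[["1"]] > suit$p[["2"]], 1L, 2L)
  acc <- mean(as.vector(pred) == tr$y)
  expect_lt(acc, 0.70)
})

test_that("predicted class probabilities sum to one and NA propagates", {
  ls <- generate_landscape(scenario_spec(grid_shape = c(25, 25), seed = 3L))
  fs <- normalize_stack(generate_driving_factors(ls, seed = 4L))
  tr <- sample_training(ls, fs, 300, seed = 5L)
  mod <- train_suitability_ann(tr, hidden_units = 6, epochs = 150, seed = 6L)
  fs$layers[[1]][1, 1] <- NA   # nodata introduced at prediction time
  suit <- predict(mod, fs)
  tot <- Reduce(`+`, suit$p)
  expect_true(is.na(tot[1, 1]))
  expect_true(all(abs(tot[-1] - 1) < 1e-8))
  expect_true(all(vapply(suit$p, function(m) all(m[-1] >= 0 & m[-1] <= 1),
                         logical(1))))
})

test_that("training is deterministic for a fixed seed", {
  tr <- separable_training(200)
  m1 <- train_suitability_ann(tr, hidden_units = 3, epochs = 60, seed = 5L)
  m2 <- train_suitability_ann(tr, hidden_units = 3, epochs = 60, seed = 5L)
  expect_identical(m1$net$wts, m2$net$wts)
})

test_that("rank AUC equals the brute-force pair count", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    # integer scores force ties
    score <- sample(1:6, n, replace = TRUE)
    label <- sample(c(0, 1), n, replace = TRUE)
    if (sum(label) == 0 || sum(label) == n) next
    expect_equal(auc_rank(score, label), auc_bruteforce(score, label))
  }
  expect_identical(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(auc_rank(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_error(auc_rank(1:3, c(1, 1, 1)), "positive and negative")
})

test_that("logistic screen scores an uninformative factor near 0.5", {
  set.seed(41)
  g <- matrix(sample(1:2, 2500, replace = TRUE), 50, 50)
  ls <- land_raster(g, legend = c("1" = "a", "2" = "b"))
  fs <- factor_stack(list(noise = matrix(stats::runif(2500), 50, 50)))
  sc <- screen_factors_logistic(ls, fs, 1, sample_fraction = 1, seed = 2L)
  expect_true(abs(sc$roc_auc - 0.5) < 0.05)
  expect_false(sc$separation)
})

test_that("a perfect indicator factor reaches AUC 1 with separation", {
  g <- matrix(rep(c(1L, 2L), each = 50), 10, 10)
  ls <- land_raster(g, legend = c("1" = "a", "2" = "b"))
  ind <- matrix(as.numeric(g == 1L), 10, 10)
  fs <- factor_stack(list(indicator = ind))
  sc <- screen_factors_logistic(ls, fs, 1, sample_fraction = 1, seed = 1L)
  expect_identical(sc$roc_auc, 1)
  expect_true(sc$separation)
  expect_true(sc$usable)
})

test_that("screening an absent class fails clearly", {
  ls <- tiny_raster(rep(1L, 16))
  fs <- factor_stack(list(a = matrix(stats::runif(16), 4, 4)))
  expect_error(screen_factors_logistic(ls, fs, 5), "absent")
})
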