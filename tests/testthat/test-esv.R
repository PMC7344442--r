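test_that("the unit equivalent value is one seventh of the grain value", {
  expect_equal(unit_equivalent_value(2, c(7000, 4900)), 2 * 5950 / 7)
  # anchoring identity: the price solving Ea = 262.34 at the reference
  # yield reproduces the anchor exactly
  p <- 7 * 262.34 / 4798.71
  expect_equal(unit_equivalent_value(p, 4798.71), 262.34)
  expect_error(unit_equivalent_value(-1, 100), "positive")
  expect_error(unit_equivalent_value(2, numeric()), "at least one")
})

test_that("the grain-yield factor is the plain ratio", {
  expect_identical(grain_yield_factor(6000, 5000), 1.2)
  expect_error(grain_yield_factor(0, 5000), "positive")
})

test_that("willingness to pay matches the logistic closed forms", {
  # E = 1/3 puts the growth curve exactly at its midpoint 0.5
  L <- function(E) 1 / (1 + exp(-(1 / E - 3)))
  expect_equal(L(1 / 3), 0.5)
  expect_equal(willingness_to_pay(1 / 3, 1 / 3), 1)
  # region at E = 0.25, nation at E = 0.5: the ratio collapses to e
  expect_equal(willingness_to_pay(0.25, 0.5), exp(1))
  # richer region (smaller Engel) always pays more willingly
  expect_gt(willingness_to_pay(0.3, 0.4), 1)
  expect_error(willingness_to_pay(1.2, 0.4), "fractions")
  expect_error(willingness_to_pay(0.4, 0), "fractions")
})

test_that("ability to pay and the development factor compose", {
  expect_equal(ability_to_pay(2, 1, 3, 2), 3)
  expect_identical(development_factor(2, 3), 6)
  expect_error(ability_to_pay(1, 1, 0, 1), "positive")
})

test_that("the scarcity factor is the log-density ratio", {
  expect_equal(scarcity_factor(exp(2), exp(1)), 2)
  expect_equal(scarcity_factor(150, 150), 1)
  expect_error(scarcity_factor(0.5, 150), "exceed 1")
})

test_that("identical regional and national inputs give unit factors", {
  cf <- correction_factors(5500, 5500, 0.32, 0.32, 60000, 60000,
                           0.55, 0.55, 400, 400)
  for (f in c("Q", "Pw", "Pv", "D", "S"))
    expect_equal(cf[[f]], 1)
  # and the composition identity D = Pw * Pv always holds
  cf2 <- correction_factors(6000, 5000, 0.28, 0.33, 70000, 60000,
                            0.6, 0.55, 450, 150)
  expect_equal(cf2$D, cf2$Pw * cf2$Pv)
})

test_that("the coefficient table has the documented shape", {
  vc <- esv_coefficients()
  expect_identical(dim(vc$vc), c(11L, 8L))
  expect_setequal(colnames(vc$vc), as.character(1:8))
  expect_setequal(unique(unname(vc$categories)),
                  c("provisioning", "regulating", "supporting", "cultural"))
  # built-up land carries a net-negative coefficient total
  expect_lt(sum(vc$vc[, "7"]), 0)
  # water and wet land are the highest-value classes
  expect_gt(sum(vc$vc[, "5"]), sum(vc$vc[, "3"]))
  expect_gt(sum(vc$vc[, "6"]), sum(vc$vc[, "3"]))
})

test_that("base ESV is the area-weighted coefficient total", {
  vc <- esv_coefficients()
  a <- c("3" = 100, "5" = 10)
  res <- base_esv(a, vc)
  expect_equal(unname(res$by_class["3"]), 100 * sum(vc$vc[, "3"]))
  expect_equal(res$total, sum(res$by_class))
  # category breakdown partitions the total exactly
  expect_equal(sum(res$by_category), res$total)
  # km2 input scales by 100
  res_km <- base_esv(a, vc, unit = "km2")
  expect_equal(res_km$total, res$total * 100)
  expect_error(base_esv(c("9" = 1), vc), "unknown class")
  expect_error(base_esv(c("3" = -1), vc), "nonnegative")
})

test_that("base ESV is linear in areas", {
  vc <- esv_coefficients()
  a <- c("1" = 20, "3" = 50, "6" = 5)
  b <- c("1" = 10, "3" = 15, "6" = 30)
  expect_equal(base_esv(a + b, vc)$total,
               base_esv(a, vc)$total + base_esv(b, vc)$total)
  expect_equal(base_esv(3 * a, vc)$total, 3 * base_esv(a, vc)$total)
})

test_that("revised ESV scales the base result by Q * D * S exactly", {
  vc <- esv_coefficients()
  cf <- correction_factors(6000, 5000, 0.28, 0.33, 70000, 60000,
                           0.6, 0.55, 450, 150)
  a <- c("1" = 40, "3" = 60, "5" = 10, "7" = 25)
  base <- base_esv(a, vc)
  rev <- revised_esv(a, vc, cf)
  k <- cf$Q * cf$D * cf$S
  expect_equal(rev$total, base$total * k)
  expect_equal(rev$by_class, base$by_class * k)
  expect_equal(rev$by_category, base$by_category * k)
})

test_that("growth rates match hand calculations", {
  expect_equal(growth_rate(100, 136.9), 36.9)
  expect_equal(growth_rate(200, 150), -25)
  expect_error(growth_rate(0, 5), "zero base")
})

test_that("the ESV report derives proportions, totals and growth", {
  m <- rbind("1" = c(40, 44), "3" = c(60, 92))
  colnames(m) <- c("2015", "2030")
  rep <- esv_report(m)
  expect_equal(unname(rep$totals), c(100, 136))
  expect_equal(unname(rep$proportions[, 1]), c(40, 60))
  expect_equal(unname(rep$growth["1"]), 10)
  expect_equal(unname(rep$growth["3"]), 160 / 3)
  expect_equal(unname(rep$growth["total"]), 36)
  # category growth follows the same first-to-last rule
  cats <- rbind(provisioning = c(10, 14.039), regulating = c(90, 121.961))
  rep2 <- esv_report(m, cats)
  expect_equal(unname(rep2$category_growth["provisioning"]), 40.39)
  expect_error(esv_report(m[, 1, drop = FALSE]), "2 years")
})

test_that("negative class values reduce the total and its proportion", {
  m <- rbind("5" = c(120, 120), "7" = c(-20, -40))
  colnames(m) <- c("a", "b")
  rep <- esv_report(m)
  expect_equal(unname(rep$totals), c(100, 80))
  expect_lt(rep$proportions["7", 1], 0)
})
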