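#' Ecosystem-service value coefficient table
#'
#' Loads the packaged per-hectare value coefficients (USD/ha/yr): 11
#' ecosystem services (grouped into provisioning, regulating, supporting
#' and cultural categories) by the 8 land-use classes. The table is the
#' regional equivalent-factor table anchored at a unit equivalent value of
#' 262.34 USD/ha.
#'
#' @param path Optional CSV path; defaults to the packaged fixture.
#' @return List of class `esv_coefficients`: `vc` (11 x 8 matrix, columns
#'   named by class code), `services`, `categories` (service -> category).
#' @export
esv_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "esv_coefficients.csv",
                        package = "lucesv", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  vc <- as.matrix(tab[, -(1:2)])
  rownames(vc) <- tab$service
  leg <- land_legend()
  codes <- names(leg)[match(tolower(colnames(vc)), tolower(leg))]
  if (any(is.na(codes)))
    stop("unknown class column(s) in coefficient table: ",
         paste(colnames(vc)[is.na(codes)], collapse = ", "))
  colnames(vc) <- codes
  structure(list(vc = vc, services = tab$service,
                 categories = stats::setNames(tab$category, tab$service)),
            class = "esv_coefficients")
}

#' @export
print.esv_coefficients <- function(x, ...) {
  cat("ESV coefficients (USD/ha/yr), ", nrow(x$vc), " services x ",
      ncol(x$vc), " classes\n", sep = "")
  print(round(x$vc, 2))
  cat("column totals:\n")
  print(round(colSums(x$vc), 2))
  invisible(x)
}

#' Unit value of the equivalent factor
#'
#' One-seventh of the economic value of the mean annual grain yield on one
#' hectare of average farmland: `Ea = (1/7) * p * mean(yields)`.
#'
#' @param price Average grain price (USD/kg, > 0).
#' @param yields Crop yields (kg/ha, all > 0; one value per crop).
#' @return `Ea` in USD/ha.
#' @export
unit_equivalent_value <- function(price, yields) {
  if (!length(yields)) stop("at least one crop yield is required")
  if (price <= 0 || any(yields <= 0))
    stop("grain price and yields must be positive")
  price * mean(yields) / 7
}

#' Grain-yield correction factor
#'
#' `Q = GA / GN`: regional over national average grain yield.
#'
#' @param GA,GN Regional and national grain yields (kg/ha, > 0).
#' @return Dimensionless factor.
#' @export
grain_yield_factor <- function(GA, GN) {
  if (GN <= 0 || GA <= 0) stop("grain yields must be positive")
  GA / GN
}

#' Willingness-to-pay factor from Engel coefficients
#'
#' The socio-economic development stage is scored by a Peal (logistic)
#' growth curve of the Engel coefficient, `L(E) = 1 / (1 + exp(-(1/E - 3)))`,
#' and the factor is the regional-to-national ratio of stages,
#' `Pw = L(EL_A) / L(EL_N)`. Engel coefficients are fractions in (0, 1).
#'
#' @param EL_A,EL_N Regional and national Engel coefficients (fractions).
#' @return `Pw`, dimensionless.
#' @export
willingness_to_pay <- function(EL_A, EL_N) {
  for (e in c(EL_A, EL_N))
    if (e <= 0 || e >= 1)
      stop("Engel coefficients must be fractions in (0, 1), got ", e)
  L <- function(E) 1 / (1 + exp(-(1 / E - 3)))
  L(EL_A) / L(EL_N)
}

#' Ability-to-pay factor
#'
#' `Pv = (pGDP_A / pGDP_N) * (U_A / U_N)`: the product of the regional-to-
#' national ratios of per-capita GDP and urbanization rate.
#'
#' @param pGDPA,pGDPN Regional and national per-capita GDP (> 0).
#' @param UA,UN Regional and national urbanization rates (> 0).
#' @return `Pv`, dimensionless.
#' @export
ability_to_pay <- function(pGDPA, pGDPN, UA, UN) {
  if (min(pGDPA, pGDPN, UA, UN) <= 0)
    stop("GDP and urbanization inputs must be positive")
  (pGDPA / pGDPN) * (UA / UN)
}

#' Socio-economic development correction factor
#'
#' `D = Pw * Pv`.
#'
#' @param Pw Willingness to pay ([willingness_to_pay()]).
#' @param Pv Ability to pay ([ability_to_pay()]).
#' @return `D`, dimensionless.
#' @export
development_factor <- function(Pw, Pv) {
  stopifnot(Pw > 0, Pv > 0)
  Pw * Pv
}

#' Resource-scarcity correction factor
#'
#' `S = ln(PA) / ln(PN)`: population density proxies the demand pressure
#' on ecological resources. Densities must exceed 1 person/km^2 so both
#' logarithms are positive.
#'
#' @param PA,PN Regional and national population densities (persons/km^2,
#'   > 1).
#' @return `S`, dimensionless.
#' @export
scarcity_factor <- function(PA, PN) {
  if (PA <= 1 || PN <= 1)
    stop("population densities must exceed 1 person/km^2 ",
         "(log-ratio undefined otherwise)")
  log(PA) / log(PN)
}

#' Bundle the three correction factors
#'
#' Convenience constructor computing Q, Pw, Pv, D and S from the raw
#' regional/national statistics. With identical regional and national
#' inputs every factor is exactly 1.
#'
#' @param GA,GN Grain yields (kg/ha).
#' @param EL_A,EL_N Engel coefficients (fractions in (0, 1)).
#' @param pGDPA,pGDPN Per-capita GDP.
#' @param UA,UN Urbanization rates.
#' @param PA,PN Population densities (persons/km^2, > 1).
#' @return List of class `correction_factors` with `Q`, `Pw`, `Pv`, `D`,
#'   `S`.
#' @export
correction_factors <- function(GA, GN, EL_A, EL_N, pGDPA, pGDPN,
                               UA, UN, PA, PN) {
  Pw <- willingness_to_pay(EL_A, EL_N)
  Pv <- ability_to_pay(pGDPA, pGDPN, UA, UN)
  structure(list(Q = grain_yield_factor(GA, GN),
                 Pw = Pw, Pv = Pv,
                 D = development_factor(Pw, Pv),
                 S = scarcity_factor(PA, PN)),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("Correction factors: Q = %.4f, Pw = %.4f, Pv = %.4f, ",
              x$Q, x$Pw, x$Pv),
      sprintf("D = %.4f, S = %.4f\n", x$D, x$S), sep = "")
  invisible(x)
}

#' Base ecosystem-service value of a class-area vector
#'
#' `ESV = sum_i A_i * VC_i` with `A_i` the class areas (converted to ha)
#' and `VC_i` the per-class coefficient column totals; the per-category
#' breakdown sums the same products over each category's services.
#'
#' @param areas Nonnegative areas named by class code.
#' @param vc An [esv_coefficients()] table.
#' @param unit Unit of `areas`: `"ha"` or `"km2"`.
#' @return List of class `esv_result`: `by_class` (USD), `by_category`
#'   (USD), `total` (USD).
#' @export
base_esv <- function(areas, vc = esv_coefficients(), unit = c("ha", "km2")) {
  unit <- match.arg(unit)
  if (any(areas < 0)) stop("areas must be nonnegative")
  if (is.null(names(areas))) names(areas) <- colnames(vc$vc)[seq_along(areas)]
  unknown <- setdiff(names(areas), colnames(vc$vc))
  if (length(unknown))
    stop("unknown class code(s): ", paste(unknown, collapse = ", "))
  a_ha <- if (unit == "km2") areas * 100 else areas
  cls <- names(areas)
  by_class <- colSums(vc$vc[, cls, drop = FALSE]) * a_ha
  per_service <- vc$vc[, cls, drop = FALSE] %*% a_ha
  by_category <- tapply(as.numeric(per_service),
                        vc$categories[rownames(per_service)], sum)
  structure(list(by_class = by_class,
                 by_category = by_category[c("provisioning", "regulating",
                                             "supporting", "cultural")],
                 total = sum(by_class)),
            class = "esv_result")
}

#' Revised (regionally corrected) ecosystem-service value
#'
#' `ESV = sum_i A_i * VC_i * Q * D * S`: the base value scaled uniformly
#' by the product of the grain-yield, socio-economic development and
#' resource-scarcity correction factors.
#'
#' @param areas Nonnegative areas named by class code.
#' @param vc An [esv_coefficients()] table.
#' @param factors A [correction_factors()] object.
#' @param unit Unit of `areas`.
#' @return An `esv_result`, equal to `Q * D * S` times the base result.
#' @export
revised_esv <- function(areas, vc = esv_coefficients(), factors,
                        unit = c("ha", "km2")) {
  stopifnot(inherits(factors, "correction_factors"))
  k <- factors$Q * factors$D * factors$S
  if (k <= 0) stop("correction factors must be positive")
  base <- base_esv(areas, vc, unit)
  structure(list(by_class = base$by_class * k,
                 by_category = base$by_category * k,
                 total = base$total * k),
            class = "esv_result")
}

#' @export
print.esv_result <- function(x, ...) {
  cat("ESV (10^7 USD):\n")
  print(round(x$by_class / 1e7, 2))
  cat("by category (10^7 USD):\n")
  print(round(x$by_category / 1e7, 2))
  cat(sprintf("total: %.2f x 10^7 USD\n", x$total / 1e7))
  invisible(x)
}

#' Relative growth rate between two values, in percent
#'
#' `(later - earlier) / earlier * 100`.
#'
#' @param earlier,later Values in the same unit.
#' @return Percent growth (negative for decline).
#' @export
growth_rate <- function(earlier, later) {
  if (earlier == 0) stop("growth rate undefined for a zero base value")
  (later - earlier) / earlier * 100
}

#' Multi-year ESV trend report
#'
#' From a class-by-year ESV matrix, derives per-class proportions of each
#' year's total (percent; negative allowed for built-up land), total and
#' per-class growth rates between the first and last year (or any pair),
#' and optional category shares.
#'
#' @param esv_by_year Numeric matrix, classes in rows (named by code),
#'   years in columns (named), in any fixed monetary unit (conventionally
#'   10^7 USD).
#' @param category_by_year Optional category-by-year matrix in the same
#'   unit.
#' @return List of class `esv_report`: `esv`, `proportions` (percent),
#'   `totals`, `growth` (per class plus `total`, first to last year),
#'   `category_growth` (if supplied).
#' @export
esv_report <- function(esv_by_year, category_by_year = NULL) {
  esv_by_year <- as.matrix(esv_by_year)
  if (ncol(esv_by_year) < 2) stop("at least 2 years are required")
  totals <- colSums(esv_by_year)
  prop <- sweep(esv_by_year, 2, totals, "/") * 100
  prop[, totals == 0] <- NA
  first <- 1; last <- ncol(esv_by_year)
  growth <- c(apply(esv_by_year, 1, function(v)
    if (v[first] == 0) NA_real_ else growth_rate(v[first], v[last])),
    total = unname(growth_rate(totals[first], totals[last])))
  out <- list(esv = esv_by_year, proportions = prop, totals = totals,
              growth = growth)
  if (!is.null(category_by_year)) {
    category_by_year <- as.matrix(category_by_year)
    out$category_growth <- apply(category_by_year, 1, function(v)
      if (v[first] == 0) NA_real_ else growth_rate(v[first], v[last]))
  }
  structure(out, class = "esv_report")
}

#' @export
print.esv_report <- function(x, ...) {
  cat("ESV by class and year:\n")
  print(round(x$esv, 2))
  cat("proportions (% of yearly total):\n")
  print(round(x$proportions, 2))
  cat("growth first -> last year (%):\n")
  print(round(x$growth, 2))
  invisible(x)
}
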