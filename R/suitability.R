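#' Min-max normalize every layer of a factor stack
#'
#' Rescales each layer to `[0, 1]`; constant layers map to 0.5 everywhere
#' and nodata (NA) cells are propagated unchanged. The operation is
#' idempotent.
#'
#' @param raw A [factor_stack()].
#' @return A `factor_stack` with all layers in `[0, 1]`.
#' @export
normalize_stack <- function(raw) {
  stopifnot(inherits(raw, "factor_stack"))
  layers <- lapply(names(raw$layers), function(nm) {
    m <- raw$layers[[nm]]
    if (all(is.na(m))) stop("layer '", nm, "' is entirely nodata")
    rng <- range(m, na.rm = TRUE)
    if (any(!is.finite(rng)))
      stop("layer '", nm, "' contains non-finite values")
    if (rng[1] == rng[2]) {
      m[!is.na(m)] <- 0.5
      m
    } else (m - rng[1]) / (rng[2] - rng[1])
  })
  names(layers) <- names(raw$layers)
  factor_stack(layers, kind = unname(raw$kind))
}

#' Sample training cells for the suitability model
#'
#' Draws `n` cells without replacement, either uniformly or stratified
#' with per-class counts proportional to class areas (largest-remainder
#' rounding). Each row pairs the cell's factor vector with its class
#' label.
#'
#' @param landuse A `land_raster`.
#' @param factors An aligned [factor_stack()].
#' @param n Number of cells (<= number of data cells).
#' @param strategy `"uniform"` or `"stratified"`.
#' @param seed Integer seed.
#' @return List of class `training_set`: `x` (n x layers matrix), `y`
#'   (integer class codes), `cells` (sampled cell indices),
#'   `layer_names`.
#' @export
sample_training <- function(landuse, factors, n,
                            strategy = c("uniform", "stratified"),
                            seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(landuse, "land_raster"), inherits(factors, "factor_stack"))
  if (!identical(dim(landuse$grid), dim(factors$layers[[1]])))
    stop("factors are not aligned to the land-use grid")
  ok <- which(!is.na(landuse$grid))
  if (n > length(ok)) stop("n exceeds the number of data cells")
  set.seed(seed)
  if (strategy == "uniform") {
    cells <- if (n == length(ok)) ok else sort(sample(ok, n))
  } else {
    lab <- landuse$grid[ok]
    cnt <- table(lab)
    raw <- cnt / sum(cnt) * n
    take <- floor(raw)
    rem <- n - sum(take)
    if (rem > 0) {
      extra <- order(raw - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    cells <- integer(0)
    for (k in seq_along(cnt)) {
      pool <- ok[lab == names(cnt)[k]]
      nk <- min(take[k], length(pool))
      if (nk < take[k])
        warning("class ", names(cnt)[k], " has fewer cells than its quota")
      cells <- c(cells, if (nk == length(pool)) pool else sample(pool, nk))
    }
    cells <- sort(cells)
  }
  x <- vapply(factors$layers, function(m) m[cells], numeric(length(cells)))
  if (is.null(dim(x))) x <- matrix(x, nrow = length(cells))
  colnames(x) <- names(factors$layers)
  structure(list(x = x, y = landuse$grid[cells], cells = cells,
                 layer_names = names(factors$layers)),
            class = "training_set")
}

#' Train the neural-network suitability model
#'
#' Fits a single-hidden-layer feed-forward classifier (softmax output, so
#' per-cell class probabilities sum to one) mapping normalized driving
#' factors to land-use class membership. Training is deterministic given
#' the seed, which fixes both the weight initialization and any sampling.
#'
#' @param train A [sample_training()] result with at least 2 classes.
#' @param hidden_units Hidden-layer width (default 12).
#' @param epochs Maximum optimizer iterations (default 300).
#' @param seed Integer seed.
#' @return List of class `suitability_model`: the fitted `nnet` object,
#'   the class codes and the expected layer names.
#' @export
train_suitability_ann <- function(train, hidden_units = 12, epochs = 300,
                                  seed = 1L) {
  stopifnot(inherits(train, "training_set"))
  classes <- sort(unique(train$y))
  if (length(classes) < 2)
    stop("training set is degenerate: only one class present")
  set.seed(seed)
  y <- factor(train$y, levels = classes)
  net <- nnet::nnet(train$x, nnet::class.ind(y), size = hidden_units,
                    softmax = TRUE, maxit = epochs, trace = FALSE,
                    MaxNWts = 100000)
  structure(list(net = net, classes = classes,
                 layer_names = train$layer_names),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat("ANN suitability model:", length(x$layer_names), "factors ->",
      x$net$n[2], "hidden units ->", length(x$classes), "classes\n")
  invisible(x)
}

#' Predict per-class occurrence probabilities over the full grid
#'
#' @param object A [train_suitability_ann()] model.
#' @param factors A [factor_stack()] with the layers (names and order)
#'   used in training.
#' @param ... Unused.
#' @return List of class `suitability_stack`: `p` is a named list of
#'   probability matrices (one per class code) whose per-cell values sum
#'   to 1; nodata cells (NA in any layer) carry NA.
#' @export
predict.suitability_model <- function(object, factors, ...) {
  stopifnot(inherits(factors, "factor_stack"))
  missing <- setdiff(object$layer_names, names(factors$layers))
  if (length(missing))
    stop("factor stack is missing layers: ", paste(missing, collapse = ", "))
  d <- dim(factors$layers[[1]])
  x <- vapply(object$layer_names, function(nm) as.vector(factors$layers[[nm]]),
              numeric(prod(d)))
  ok <- stats::complete.cases(x)
  pr <- matrix(NA_real_, prod(d), length(object$classes))
  pr[ok, ] <- stats::predict(object$net, x[ok, , drop = FALSE])
  p <- lapply(seq_along(object$classes), function(j) matrix(pr[, j], d[1], d[2]))
  names(p) <- as.character(object$classes)
  structure(list(p = p, classes = object$classes), class = "suitability_stack")
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param score Numeric scores.
#' @param label Logical or 0/1 vector (TRUE/1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("AUC needs both positive and negative cases")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screen driving factors with binary logistic regression and ROC
#'
#' Fits a class-versus-rest logistic regression of cell membership on the
#' (sampled) factor values and scores it by the rank-statistic ROC area.
#' Following the usual reading of the ROC rule, any model with AUC >= 0.5
#' is considered usable. Complete separation is reported as AUC 1 with a
#' `separation` flag rather than an error.
#'
#' @param landuse A `land_raster`.
#' @param factors An aligned, normalized [factor_stack()].
#' @param target_class Class code (integer or string) present on the map.
#' @param sample_fraction Fraction of cells used for the fit (default 0.02,
#'   uniform without replacement; 1 fits on the full grid).
#' @param seed Integer seed.
#' @return List of class `factor_screen`: `class`, `intercept`,
#'   `coefficients` (per factor), `roc_auc`, `usable`, `separation`.
#' @export
screen_factors_logistic <- function(landuse, factors, target_class,
                                    sample_fraction = 0.02, seed = 1L) {
  stopifnot(inherits(landuse, "land_raster"), inherits(factors, "factor_stack"))
  target_class <- as.integer(target_class)
  ok <- which(!is.na(landuse$grid))
  if (!any(landuse$grid[ok] == target_class))
    stop("target class ", target_class, " is absent from the map")
  set.seed(seed)
  n <- max(2L, round(sample_fraction * length(ok)))
  cells <- if (n >= length(ok)) ok else sort(sample(ok, n))
  x <- vapply(factors$layers, function(m) m[cells], numeric(length(cells)))
  if (is.null(dim(x))) x <- matrix(x, nrow = length(cells))
  colnames(x) <- names(factors$layers)
  y <- as.integer(landuse$grid[cells] == target_class)
  dat <- data.frame(y = y, x, check.names = TRUE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  score <- stats::fitted(fit)
  auc <- if (all(y == 1) || all(y == 0)) NA_real_ else auc_rank(score, y)
  if (any(y == 1) && any(y == 0) &&
      min(score[y == 1]) > max(score[y == 0])) {
    # the fit ranks every positive above every negative: complete separation
    sep <- TRUE
    auc <- 1
  }
  cf <- stats::coef(fit)
  structure(list(class = target_class,
                 intercept = unname(cf[1]),
                 coefficients = cf[-1],
                 roc_auc = auc,
                 usable = !is.na(auc) && auc >= 0.5,
                 separation = sep),
            class = "factor_screen")
}

#' @export
print.factor_screen <- function(x, ...) {
  cat(sprintf("Logistic screen, class %d: intercept %.4f, ROC %.4f%s%s\n",
              x$class, x$intercept, x$roc_auc,
              if (x$usable) " (usable)" else " (rejected)",
              if (x$separation) " [complete separation]" else ""))
  invisible(x)
}
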