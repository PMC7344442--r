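#' Fit a GM(1,1) grey prediction model
#'
#' The first-order, one-variable grey model fits an exponential trend to a
#' short positive time series through its accumulated (AGO) sequence.
#' With observations `x0(1..n)`, the accumulated series is
#' `x1 = cumsum(x0)` and the background values are
#' `z1(k) = (x1(k) + x1(k-1)) / 2`. The development coefficient `a` and
#' grey input `b` solve the least-squares problem
#' `x0(k) = -a z1(k) + b` for `k = 2..n` (ordinary least squares via the
#' normal equations). The restored (fitted) series is
#' `xhat0(1) = x0(1)` and
#' `xhat0(k) = (x0(1) - b/a) (1 - exp(a)) exp(-a (k - 1))` for `k >= 2`;
#' as `a -> 0` this tends to the constant `b`, which is used when `a` is
#' numerically zero.
#'
#' @param x Numeric vector of at least 4 strictly positive observations,
#'   equally spaced in time.
#' @return An object of class `gm11` with components `a`, `b`, `x` (the
#'   data), `fitted` (restored series, same length as `x`), `residuals`
#'   (`x - fitted`) and `unstable` (TRUE when `|a| >= 2`, where the model
#'   is considered unreliable).
#' @seealso [predict.gm11()], [posterior_difference_test()]
#' @examples
#' fit <- gm11(100 * 1.05^(0:5))
#' coef(fit)
#' predict(fit, horizon = 2)
#' @export
gm11 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("GM(1,1) needs at least 4 observations, got ", n)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("GM(1,1) is undefined for nonpositive or non-finite values")
  x1 <- cumsum(x)
  z1 <- (x1[-1] + x1[-n]) / 2
  B <- cbind(-z1, 1)
  Y <- x[-1]
  ab <- solve(crossprod(B), crossprod(B, Y))
  a <- ab[1]; b <- ab[2]
  k <- 2:n
  fitted <- c(x[1],
              if (abs(a) < 1e-12) rep(b, n - 1)
              else (x[1] - b / a) * (1 - exp(a)) * exp(-a * (k - 1)))
  unstable <- abs(a) >= 2
  if (unstable)
    warning("|a| >= 2: the GM(1,1) model is unstable for this series")
  structure(list(a = a, b = b, x = x, fitted = fitted,
                 residuals = x - fitted, unstable = unstable),
            class = "gm11")
}

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey model\n")
  cat(sprintf("  development coefficient a = %.6g\n", x$a))
  cat(sprintf("  grey input            b = %.6g\n", x$b))
  cat(sprintf("  n = %d observations%s\n", length(x$x),
              if (x$unstable) "  [unstable: |a| >= 2]" else ""))
  invisible(x)
}

#' @export
summary.gm11 <- function(object, ...) {
  acc <- posterior_difference_test(object)
  cat("GM(1,1) grey model\n")
  cat(sprintf("  a = %.6g, b = %.6g, n = %d\n", object$a, object$b,
              length(object$x)))
  cat(sprintf("  posterior difference ratio C = %.4f\n", acc$C))
  cat(sprintf("  small error possibility  P = %.4f\n", acc$P))
  cat(sprintf("  accuracy level: %d%s\n", acc$level,
              if (acc$level == 4) " (unqualified)" else ""))
  invisible(acc)
}

#' @export
coef.gm11 <- function(object, ...) c(a = object$a, b = object$b)

#' @export
fitted.gm11 <- function(object, ...) object$fitted

#' @export
residuals.gm11 <- function(object, ...) object$residuals

#' Forecast from a fitted GM(1,1) model
#'
#' Extends the restored-series formula beyond the sample.
#'
#' @param object A fitted [gm11()] model.
#' @param horizon Number of steps ahead (>= 1).
#' @param ... Unused.
#' @return Numeric vector of `horizon` forecast values.
#' @export
predict.gm11 <- function(object, horizon = 1, ...) {
  if (horizon < 1) stop("`horizon` must be >= 1")
  n <- length(object$x)
  k <- (n + 1):(n + horizon)
  a <- object$a; b <- object$b
  if (abs(a) < 1e-12) return(rep(b, horizon))
  (object$x[1] - b / a) * (1 - exp(a)) * exp(-a * (k - 1))
}

#' Posterior difference test of a GM(1,1) fit
#'
#' Grades prediction accuracy by the posterior difference ratio
#' `C = S2 / S1` (residual standard deviation over data standard
#' deviation, both population, 1/n form) and the small error possibility
#' `P`, the fraction of residuals within `0.6745 * S1` of the mean
#' residual. The grade combines the two indicators conservatively (the
#' worse band wins):
#'
#' | level | C       | P       |
#' |-------|---------|---------|
#' | 1     | < 0.35  | > 0.95  |
#' | 2     | < 0.50  | > 0.80  |
#' | 3     | < 0.65  | > 0.70  |
#' | 4     | otherwise (unqualified) |
#'
#' A zero-variance input series is perfectly predictable; it is reported
#' as level 1 with `C = 0`.
#'
#' @param fit A fitted [gm11()] model.
#' @return List of class `gm11_accuracy` with `C`, `P`, `level`.
#' @export
posterior_difference_test <- function(fit) {
  stopifnot(inherits(fit, "gm11"))
  x <- fit$x; e <- fit$residuals
  n <- length(x)
  S1 <- sqrt(sum((x - mean(x))^2) / n)
  if (S1 == 0)
    return(structure(list(C = 0, P = 1, level = 1L),
                     class = "gm11_accuracy"))
  S2 <- sqrt(sum((e - mean(e))^2) / n)
  C <- S2 / S1
  P <- mean(abs(e - mean(e)) < 0.6745 * S1)
  c_level <- if (C < 0.35) 1L else if (C < 0.50) 2L else if (C < 0.65) 3L else 4L
  p_level <- if (P > 0.95) 1L else if (P > 0.80) 2L else if (P > 0.70) 3L else 4L
  structure(list(C = C, P = P, level = max(c_level, p_level)),
            class = "gm11_accuracy")
}

#' @export
print.gm11_accuracy <- function(x, ...) {
  cat(sprintf("Posterior difference test: C = %.4f, P = %.4f, level %d%s\n",
              x$C, x$P, x$level,
              if (x$level == 4) " (unqualified)" else ""))
  invisible(x)
}
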