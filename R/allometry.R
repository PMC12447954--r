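#' Body mass predicted from body length
#'
#' Classical power-law relation between body mass and body length in the
#' cgs system, `P = 0.021 * L^3.03`, with `L` in cm and the result in
#' grams. The relation is stated for *body* length; endocast lengths are a
#' different quantity, so this function is exposed for completeness but is
#' never used by the package to fill missing body masses.
#'
#' @param L body length in cm; must be positive.
#' @return predicted body mass in grams.
#' @export
#' @examples
#' body_mass_from_length(10) # about 22.5 g
body_mass_from_length <- function(L) {
  if (!is.numeric(L) || any(is.na(L)) || any(L <= 0)) {
    stop("L must be positive", call. = FALSE)
  }
  0.021 * L^3.03
}

#' Fit a power law on log-log axes
#'
#' The package's central fitting function: ordinary least squares of
#' `log10(y)` on `log10(x)`, the linear form of the power law
#' `y = b * x^alpha`. Used for brain-body allometry (`E` on `P`) and for
#' surface-volume scaling (`S` on `E`). The slope is base-invariant; the
#' intercept is reported in log10 units alongside the back-transformed
#' coefficient.
#'
#' OLS (not reduced major axis) is the default estimator, matching the
#' bivariate-regression practice of classical paleoneurology; a reduced
#' major axis slope is available with `method = "rma"`.
#'
#' @param x,y positive numeric vectors of equal length (at least 2 pairs;
#'   `x` must not be constant).
#' @param method `"ols"` (default) or `"rma"`.
#' @param xlab,ylab axis names used in printing.
#' @return an object of class `"loglog_fit"`: a list with `slope`,
#'   `intercept` (log10 b), `coefficient` (b), `r` (Pearson correlation of
#'   the log pairs), `n`, `method` and the underlying `lm` fit (`model`,
#'   OLS only).
#' @seealso [predict.loglog_fit()], [eq_quotient()], [fit_surface_volume()]
#' @export
#' @examples
#' p <- c(10, 100, 1000)
#' f <- loglog_fit(p, 0.12 * p^(2 / 3))
#' coef(f) # slope 2/3, intercept log10(0.12)
loglog_fit <- function(x, y, method = c("ols", "rma"), xlab = "x", ylab = "y") {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("all values must be positive for a log-log fit", call. = FALSE)
  }
  lx <- log10(x); ly <- log10(y)
  if (diff(range(lx)) == 0) {
    stop("degenerate fit: all x values identical", call. = FALSE)
  }
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- if (diff(range(ly)) == 0) 1 else unname(stats::cor(lx, ly))
  if (method == "rma") {
    slope <- sign(r) * stats::sd(ly) / stats::sd(lx)
    intercept <- mean(ly) - slope * mean(lx)
    fit <- NULL
  }
  structure(list(slope = slope, intercept = intercept,
                 coefficient = 10^intercept, r = r, n = length(x),
                 method = method, model = fit, xlab = xlab, ylab = ylab),
            class = "loglog_fit")
}

#' Fit the brain-body allometry of a specimen table
#'
#' Convenience wrapper fitting `log10(E)` on `log10(P)` over the rows of a
#' specimen table with both endocranial volume and body mass present; the
#' number of dropped rows is reported via the `"dropped"` attribute.
#'
#' @param records a specimen table.
#' @inheritParams loglog_fit
#' @return a `"loglog_fit"` object.
#' @export
fit_brain_body <- function(records, method = c("ols", "rma")) {
  keep <- !is.na(records$E_ml) & !is.na(records$P_g)
  fit <- loglog_fit(records$P_g[keep], records$E_ml[keep], method = method,
                    xlab = "body mass P (g)", ylab = "brain volume E (ml)")
  attr(fit, "dropped") <- sum(!keep)
  fit
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s, log10 axes): %s ~ %s\n",
              toupper(x$method), x$ylab, x$xlab))
  cat(sprintf("  slope (exponent) = %.4f\n", x$slope))
  cat(sprintf("  intercept        = %.4f  (coefficient %.4g)\n",
              x$intercept, x$coefficient))
  cat(sprintf("  r = %.4f, n = %d\n", x$r, x$n))
  invisible(x)
}

#' @export
coef.loglog_fit <- function(object, ...) {
  c(intercept_log10 = object$intercept, slope = object$slope)
}

#' @export
summary.loglog_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$model)) {
    cat("\n")
    print(summary(object$model))
  }
  invisible(object)
}

#' Predict from a log-log power-law fit
#'
#' @param object a `"loglog_fit"`.
#' @param newx values of the predictor on its natural scale.
#' @param log10 return predictions as log10 values instead of the natural
#'   scale.
#' @param ... unused.
#' @return predicted response values.
#' @export
predict.loglog_fit <- function(object, newx, log10 = FALSE, ...) {
  ly <- object$intercept + object$slope * base::log10(newx)
  if (log10) ly else 10^ly
}

#' @export
residuals.loglog_fit <- function(object, ...) {
  if (is.null(object$model)) stop("residuals unavailable for RMA fits", call. = FALSE)
  stats::residuals(object$model)
}

#' Encephalization quotient
#'
#' The quotient of observed brain size over the size expected from body
#' mass under the reference allometry `E = b * P^alpha`:
#' `EQ = E / (b * P^alpha)`. The default reference uses the classical
#' intercept `b = 0.12` with the theoretical exponent `alpha` equal to the
#' exact fraction 2/3 (never a decimal truncation). All quantities are in
#' the cgs convention, `E` in ml and `P` in grams; the quotient is
#' meaningless under any other unit system, which the `units` tag guards.
#'
#' @param E endocranial (brain) volume, ml. Vectorized.
#' @param P body mass, g. Vectorized.
#' @param b reference intercept (default 0.12).
#' @param alpha reference exponent (default `2/3`).
#' @param units unit convention tag; only `"cgs"` is accepted.
#' @return a data frame with columns `expected_E` (ml) and `eq`.
#' @export
#' @examples
#' eq_quotient(97.85, 15000)$eq # about 1.34
eq_quotient <- function(E, P, b = 0.12, alpha = 2 / 3, units = "cgs") {
  units <- match.arg(units, "cgs")
  if (any(is.na(E)) || any(is.na(P)) || any(E <= 0) || any(P <= 0) || b <= 0) {
    stop("E, P and b must be positive", call. = FALSE)
  }
  expected <- b * P^alpha
  data.frame(expected_E = expected, eq = E / expected)
}

#' Recover the reference intercept from printed quotients
#'
#' Back-solves `b = E / (EQ * P^alpha)` on every row with volume, body
#' mass and a printed quotient, and returns the median. On the packaged
#' measurement table this recovers the classical 0.12, pinning the
#' reference the printed quotient column was computed with.
#'
#' @param records a specimen table; at least 10 complete rows required.
#' @param alpha reference exponent (default `2/3`).
#' @return the recovered intercept (dimensionless).
#' @export
derive_b <- function(records, alpha = 2 / 3) {
  keep <- !is.na(records$E_ml) & !is.na(records$P_g) & !is.na(records$EQ) &
    records$E_ml > 0 & records$P_g > 0 & records$EQ > 0
  if (sum(keep) < 10) {
    stop("need at least 10 rows with E, P and a printed EQ", call. = FALSE)
  }
  stats::median(records$E_ml[keep] /
                  (records$EQ[keep] * records$P_g[keep]^alpha))
}
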