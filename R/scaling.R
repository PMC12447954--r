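#' Surface-area-versus-volume scaling fit
#'
#' Power-law fit of endocast (or cortical) surface area on endocast
#' volume: OLS of `log10(S)` on `log10(E)`. A smooth 3D body scales its
#' surface with volume to the power 2/3; mammalian cortical surfaces
#' scale with an exponent well above 2/3 because larger brains are
#' disproportionately convoluted. The geometric reference exponent 2/3 is
#' carried in the result for comparison.
#'
#' @param E endocast/brain volumes, ml (positive, at least 3 pairs).
#' @param S surface areas, cm^2.
#' @return an object of classes `"scaling_fit"` and `"loglog_fit"`; the
#'   `exponent` and `coefficient` elements alias the slope and
#'   back-transformed intercept, and `geometric_reference_exponent` is
#'   2/3.
#' @export
#' @examples
#' v <- c(1, 8, 27)
#' f <- fit_surface_volume(v, (36 * pi)^(1 / 3) * v^(2 / 3)) # spheres
#' f$exponent
fit_surface_volume <- function(E, S) {
  keep <- !is.na(E) & !is.na(S)
  if (sum(keep) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  fit <- loglog_fit(E[keep], S[keep], xlab = "volume E (ml)",
                    ylab = "surface S (cm2)")
  fit$exponent <- fit$slope
  fit$geometric_reference_exponent <- 2 / 3
  class(fit) <- c("scaling_fit", class(fit))
  fit
}

#' Two-thirds-pinned scaling reference
#'
#' Fits only the coefficient of `S = c * E^(2/3)` to a dataset (the
#' exponent is pinned at the geometric value), by the least-squares
#' intercept in log10 space: `c = 10^mean(log10 S - (2/3) log10 E)`. This
#' is the smooth-scaling trend of the dataset itself, against which
#' convolutedness is measured; it is invariant to the ordering or
#' relabeling of the data.
#'
#' @param E volumes, ml (positive).
#' @param S surface areas, cm^2 (positive).
#' @return an object of class `"scaling_reference"` with `exponent`
#'   (2/3), `coefficient` and `n`.
#' @export
geometric_reference <- function(E, S) {
  keep <- !is.na(E) & !is.na(S)
  E <- E[keep]; S <- S[keep]
  if (length(E) < 1) stop("no complete pairs", call. = FALSE)
  if (any(E <= 0) || any(S <= 0)) stop("E and S must be positive", call. = FALSE)
  structure(list(exponent = 2 / 3,
                 coefficient = 10^mean(log10(S) - (2 / 3) * log10(E)),
                 n = length(E)),
            class = "scaling_reference")
}

#' @export
print.scaling_reference <- function(x, ...) {
  cat(sprintf("2/3-pinned scaling reference: S = %.4g * E^(2/3), n = %d\n",
              x$coefficient, x$n))
  invisible(x)
}

#' Convolutedness index
#'
#' Ratio of an observed surface area to the area predicted by a
#' 2/3-pinned reference at the same volume:
#' `S / (c * E^(2/3))`. Values above 1 mean the surface is more folded
#' than the dataset's smooth-scaling trend; the index is linear in `S`
#' and, because fitted exponents exceed 2/3, it increases with brain size
#' across a mammalian dataset.
#'
#' @param S surface area, cm^2. Vectorized.
#' @param E volume, ml. Vectorized.
#' @param reference a `"scaling_reference"` from [geometric_reference()].
#' @return the dimensionless index.
#' @export
convolutedness_index <- function(S, E, reference) {
  if (!inherits(reference, "scaling_reference")) {
    stop("reference must be a fitted scaling_reference", call. = FALSE)
  }
  if (any(S <= 0, na.rm = TRUE) || any(E <= 0, na.rm = TRUE)) {
    stop("S and E must be positive", call. = FALSE)
  }
  S / (reference$coefficient * E^(2 / 3))
}
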