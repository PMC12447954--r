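#' Neocorticalization percentage
#'
#' The neocortical surface ratio: neocortex area over the endocast surface
#' area excluding the olfactory bulbs, as a percentage,
#' `100 * NC / (S - OB)`. Olfactory bulbs are excluded because they are
#' frequently broken or absent on natural endocasts. Invariant under a
#' common rescaling of both areas; always in (0, 100].
#'
#' @param NC neocortical surface area, cm^2. Vectorized.
#' @param S_minus_OB endocast surface area excluding olfactory bulbs,
#'   cm^2. Vectorized.
#' @return neocorticalization in percent.
#' @export
#' @examples
#' pct_neocortex(10.17, 23.53) # about 43.22
pct_neocortex <- function(NC, S_minus_OB) {
  if (any(is.na(NC)) || any(is.na(S_minus_OB)) ||
      any(NC <= 0) || any(S_minus_OB <= 0)) {
    stop("NC and S_minus_OB must be positive", call. = FALSE)
  }
  if (any(NC > S_minus_OB)) {
    stop("NC exceeds S_minus_OB: mis-paired measurements", call. = FALSE)
  }
  100 * NC / S_minus_OB
}

# Per-row neocorticalization, preferring the recomputed ratio over the
# printed column (avoids propagating printed-cell errors); falls back to
# the printed value when NC or S-OB is missing.
recomputed_pct_nc <- function(records) {
  pct <- rep(NA_real_, nrow(records))
  ok <- !is.na(records$NC_cm2) & !is.na(records$S_minus_OB_cm2) &
    records$NC_cm2 > 0 & records$S_minus_OB_cm2 > 0 &
    records$NC_cm2 <= records$S_minus_OB_cm2
  pct[ok] <- 100 * records$NC_cm2[ok] / records$S_minus_OB_cm2[ok]
  pct[!ok] <- records$pctNC[!ok]
  pct
}

#' Neocorticalization trend through geologic time
#'
#' Ordinary least squares of neocorticalization (percent) on geologic age
#' (Ma, negative = past) over the rows of a specimen table with both
#' quantities available. Recomputed percentages are preferred over the
#' printed column; the printed value is used only where the areas are
#' missing. A positive slope means neocortex gained surface share toward
#' the present.
#'
#' @param records a specimen table.
#' @param predict_at ages (Ma) at which to evaluate the fitted line;
#'   default `c(0, -60)`.
#' @param exclude_failed drop rows whose printed percentage fails
#'   validation at the 0.05-point tolerance (default `FALSE`).
#' @param exclude_recent_Ma if non-`NULL`, drop fossil-section rows
#'   younger than this many Ma (e.g. `1` removes sub-1-Ma tar-pit
#'   material, which can skew the present-day end of the trend); extant
#'   rows at age 0 are kept.
#' @return an object of class `"nc_trend"`: `slope` (percentage points
#'   per Ma), `intercept` (percent at age 0), `r`, `n`, `predictions`
#'   (data frame of `age_Ma`, `pct`), and the underlying `lm` fit.
#' @export
#' @examples
#' tr <- nc_trend(read_specimens("table1_mammals"))
#' tr$slope * 10 # points of neocortex gained per 10 Ma
nc_trend <- function(records, predict_at = c(0, -60), exclude_failed = FALSE,
                     exclude_recent_Ma = NULL) {
  pct <- recomputed_pct_nc(records)
  keep <- !is.na(pct) & !is.na(records$age_Ma)
  if (exclude_failed) {
    rep <- validate_specimens(records)
    bad <- unique(rep$row[rep$check == "pctNC" & rep$status == "fail"])
    keep[bad] <- FALSE
  }
  if (!is.null(exclude_recent_Ma)) {
    keep <- keep & !(records$section %in% "fossil" &
                       abs(records$age_Ma) < exclude_recent_Ma &
                       records$age_Ma < 0)
  }
  if (sum(keep) < 3) stop("need at least 3 rows with %NC and age", call. = FALSE)
  age <- records$age_Ma[keep]
  y <- pct[keep]
  fit <- stats::lm(y ~ age)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(
    slope = slope, intercept = intercept,
    r = unname(stats::cor(age, y)), n = sum(keep),
    predictions = data.frame(age_Ma = predict_at,
                             pct = intercept + slope * predict_at),
    model = fit), class = "nc_trend")
}

#' @export
print.nc_trend <- function(x, ...) {
  cat("Neocorticalization trend vs geologic age\n")
  cat(sprintf("  slope = %.3f %%-points per Ma (%.2f per 10 Ma)\n",
              x$slope, 10 * x$slope))
  cat(sprintf("  intercept at 0 Ma = %.2f %%, r = %.3f, n = %d\n",
              x$intercept, x$r, x$n))
  if (nrow(x$predictions)) {
    cat("  predictions:\n")
    print.data.frame(x$predictions, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.nc_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict neocorticalization at given ages
#' @param object an `"nc_trend"` fit.
#' @param age_Ma ages in Ma (negative = past).
#' @param ... unused.
#' @return predicted percentages, exactly on the fitted line.
#' @export
predict.nc_trend <- function(object, age_Ma, ...) {
  object$intercept + object$slope * age_Ma
}

#' Neocorticalization profile against encephalization
#'
#' Bins specimens by encephalization quotient (equal-width bins) and
#' averages neocorticalization per bin, summarizing how neocortical
#' expansion saturates: the profile climbs with EQ and plateaus around
#' 80% once EQ reaches about 2. Quotients are recomputed from `E` and `P`
#' under the reference (`b`, `alpha`), falling back to the printed column
#' when either is missing; percentages are recomputed as in [nc_trend()].
#'
#' The plateau is operationalized as the smallest bin edge beyond which
#' successive occupied-bin means change by less than `plateau_tol`
#' percentage points.
#'
#' @param records a specimen table.
#' @param bin_width width of the EQ bins (default 0.5).
#' @param plateau_tol plateau tolerance in percentage points (default 2).
#' @param b,alpha reference allometry for the quotients.
#' @return an object of class `"nc_eq_profile"`: `bin_edges`,
#'   `bin_means`, `bin_counts`, `max_pct` (maximum specimen percentage)
#'   and `eq_at_plateau`.
#' @export
nc_eq_profile <- function(records, bin_width = 0.5, plateau_tol = 2,
                          b = 0.12, alpha = 2 / 3) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  pct <- recomputed_pct_nc(records)
  eq <- rep(NA_real_, nrow(records))
  ok <- !is.na(records$E_ml) & !is.na(records$P_g) &
    records$E_ml > 0 & records$P_g > 0
  if (any(ok)) {
    eq[ok] <- eq_quotient(records$E_ml[ok], records$P_g[ok],
                          b = b, alpha = alpha)$eq
  }
  eq[!ok] <- records$EQ[!ok]
  keep <- !is.na(pct) & !is.na(eq) & eq > 0
  if (sum(keep) < 3) stop("need at least 3 rows with %NC and EQ", call. = FALSE)
  eq <- eq[keep]; pct <- pct[keep]
  edges <- seq(0, bin_width * ceiling(max(eq) / bin_width), by = bin_width)
  bin <- findInterval(eq, edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0] <- 1 # eq exactly 0 cannot occur (eq > 0), guard anyway
  means <- tapply(pct, factor(bin, levels = seq_len(length(edges) - 1)), mean)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  occupied <- which(counts > 0)
  occ_means <- as.numeric(means[occupied])
  plateau <- NA_real_
  if (length(occupied) >= 2) {
    diffs <- abs(diff(occ_means))
    for (k in seq_along(diffs)) {
      if (all(diffs[k:length(diffs)] < plateau_tol)) {
        plateau <- edges[occupied[k]]
        break
      }
    }
    if (is.na(plateau) && length(occupied) >= 1) plateau <- NA_real_
  } else {
    plateau <- edges[occupied[1]]
  }
  if (length(occupied) == 1) plateau <- edges[occupied[1]]
  structure(list(bin_edges = edges, bin_means = as.numeric(means),
                 bin_counts = counts, max_pct = max(pct),
                 eq_at_plateau = plateau, n = sum(keep)),
            class = "nc_eq_profile")
}

#' @export
print.nc_eq_profile <- function(x, ...) {
  cat("Neocorticalization vs encephalization profile\n")
  cat(sprintf("  n = %d specimens, max %%NC = %.2f\n", x$n, x$max_pct))
  cat(sprintf("  plateau beyond EQ = %s\n",
              ifelse(is.na(x$eq_at_plateau), "none detected",
                     format(x$eq_at_plateau))))
  occ <- x$bin_counts > 0
  df <- data.frame(eq_bin = sprintf("(%g, %g]", utils::head(x$bin_edges, -1)[occ],
                                    x$bin_edges[-1][occ]),
                   mean_pct = round(x$bin_means[occ], 2),
                   n = x$bin_counts[occ])
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
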