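#' Within-species variation summary
#'
#' Mean, sample standard deviation and coefficient of variation of a set
#' of repeated measurements of one variable on conspecific specimens. The
#' SD uses the sample (n-1) denominator — the definition that reproduces
#' the published intra-species statistics for the *Bathygenys reevesi*
#' series. The CV (`sd/mean`) is scale-invariant and is also reported as
#' a percentage.
#'
#' @param values at least two positive measurements.
#' @param variable variable name carried into the summary.
#' @return a one-row data frame of class `"cv_summary"` with columns
#'   `variable`, `n`, `mean`, `sd`, `cv`, `cv_pct`.
#' @export
#' @examples
#' cv_summary(read_bathygenys()$E_ml, "E_ml")
cv_summary <- function(values, variable = deparse(substitute(values))) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values) # n-1 denominator
  out <- data.frame(variable = variable, n = length(values), mean = m,
                    sd = s, cv = s / m, cv_pct = 100 * s / m,
                    stringsAsFactors = FALSE)
  class(out) <- c("cv_summary", "data.frame")
  out
}

#' Variation summaries for several variables of a specimen set
#'
#' One [cv_summary()] per named column, each computed over the records
#' where that column is present.
#'
#' @param records a data frame of conspecific specimens (e.g. from
#'   [read_bathygenys()]).
#' @param variables column names to summarize.
#' @return a data frame of class `"cv_summary"`, one row per variable.
#' @export
#' @examples
#' variation_table(read_bathygenys(), c("E_ml", "S_cm2", "nc_cm2", "nc_over_S"))
variation_table <- function(records, variables) {
  absent <- setdiff(variables, names(records))
  if (length(absent)) {
    stop("variable(s) not present in the records: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(variables, function(v) cv_summary(records[[v]], v))
  out <- do.call(rbind, rows)
  class(out) <- c("cv_summary", "data.frame")
  out
}

#' @export
print.cv_summary <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 6)
  df$sd <- signif(df$sd, 6)
  df$cv <- signif(df$cv, 4)
  df$cv_pct <- round(df$cv_pct, 1) # percentages reported to 1 decimal
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
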