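#' @title Specimen measurement tables
#' @name specimen_table
#' @description
#' A specimen table holds one row per endocast or brain with the classical
#' cgs measurement set: total surface area `S_cm2`, olfactory-bulb surface
#' area `OB_cm2`, surface area excluding the bulbs `S_minus_OB_cm2`,
#' neocortical surface area `NC_cm2` (all cm^2), endocast length `L_cm`
#' (cm), geologic age `age_Ma` (millions of years, negative = past, 0 =
#' extant), endocranial volume `E_ml` (ml, numerically equal to grams of
#' brain), body mass `P_g` (g), and the derived columns `pctNC`
#' (neocorticalization, percent) and `EQ` (encephalization quotient re the
#' 2/3 reference). Identification columns are `species`, `specimen_id`,
#' `section` (one of `"fossil"`, `"living_nonprimate"`, `"living_primate"`)
#' and `taxon`. Blank cells are `NA`; an olfactory-bulb area of exactly 0
#' means the bulbs were absent from the cast and is distinct from `NA`
#' (cell blank).
NULL

.specimen_columns <- c(
  "species", "specimen_id", "section", "taxon",
  "S_cm2", "OB_cm2", "S_minus_OB_cm2", "NC_cm2", "L_cm",
  "age_Ma", "E_ml", "P_g", "pctNC", "EQ"
)
.specimen_numeric <- .specimen_columns[5:14]
.specimen_sections <- c("fossil", "living_nonprimate", "living_primate")

#' Path to a packaged measurement-table fixture
#'
#' Two plain-text fixtures ship with the package, both verbatim
#' transcriptions of published digitized-endocast measurement tables:
#' `"table1_mammals"`, 158 recoverable rows of fossil and living mammals
#' (the published table announces 118 fossil + 22 living non-primate + 19
#' living primate specimens; one fossil row could not be recovered from the
#' available text, so the transcription carries 117 fossil rows), and
#' `"table2_bathygenys"`, eight *Bathygenys reevesi* endocasts measured for
#' within-species variation (columns `E_ml`, `S_cm2`, `nc_cm2`,
#' `nc_over_S`).
#'
#' @param name fixture name, with or without the `.csv` extension.
#' @return absolute path to the fixture file.
#' @export
#' @examples
#' basename(paleo_fixture("table1_mammals"))
paleo_fixture <- function(name) {
  name <- sub("\\.csv$", "", name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "paleoneuro")
  if (!nzchar(path)) {
    stop("no packaged fixture named '", name, "'", call. = FALSE)
  }
  path
}

#' Read a specimen measurement table
#'
#' Parses a comma-separated measurement table with the standard header
#' (see [specimen_table]) into a specimen table. Blank cells become `NA`,
#' thousands separators are stripped (`"15,000"` reads as 15000), and no
#' row is ever silently dropped. Ages of fossil-section rows printed with a
#' positive sign are normalized to negative (the convention is millions of
#' years *ago*); each normalization is recorded in the
#' `"age_normalized"` attribute.
#'
#' @param path path to a CSV file, or the name of a packaged fixture
#'   (e.g. `"table1_mammals"`).
#' @param section_map optional named character vector mapping species to
#'   sections, used only when the file has no `section` column.
#' @param normalize_age normalize positive fossil ages to negative
#'   (default `TRUE`).
#' @return a `data.frame` of class `"specimen_table"`, one row per data
#'   row of the file, in file order.
#' @export
#' @examples
#' tab <- read_specimens("table1_mammals")
#' table(tab$section)
read_specimens <- function(path, section_map = NULL, normalize_age = TRUE) {
  if (!file.exists(path)) {
    path <- paleo_fixture(path)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  have_section <- "section" %in% names(raw)
  required <- setdiff(.specimen_columns, if (!have_section) "section")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("malformed header: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    species = trimws(raw$species),
                    specimen_id = trimws(raw$specimen_id))
  if (have_section) {
    out$section <- trimws(raw$section)
  } else if (!is.null(section_map)) {
    out$section <- unname(section_map[out$species])
  } else {
    out$section <- NA_character_
  }
  bad <- !(out$section %in% .specimen_sections) & !is.na(out$section)
  if (any(bad)) {
    stop("unknown section label(s): ", paste(unique(out$section[bad]), collapse = ", "),
         call. = FALSE)
  }
  out$taxon <- trimws(raw$taxon)
  for (col in .specimen_numeric) {
    cell <- gsub(",", "", trimws(raw[[col]]))
    val <- suppressWarnings(as.numeric(cell))
    broken <- nzchar(cell) & is.na(val)
    if (any(broken)) {
      i <- which(broken)[1L]
      stop("non-numeric value '", cell[i], "' in column ", col, ", row ", i,
           call. = FALSE)
    }
    val[!nzchar(cell)] <- NA_real_
    out[[col]] <- val
  }
  normalized <- integer(0)
  if (normalize_age) {
    flip <- which(out$section == "fossil" & !is.na(out$age_Ma) & out$age_Ma > 0)
    if (length(flip)) {
      out$age_Ma[flip] <- -out$age_Ma[flip]
      normalized <- flip
      message("normalized ", length(flip), " positive fossil age(s) to negative: row(s) ",
              paste(flip, collapse = ", "))
    }
  }
  attr(out, "age_normalized") <- normalized
  class(out) <- c("specimen_table", "data.frame")
  out
}

#' Write a specimen measurement table
#'
#' Writes the standard comma-separated schema; `NA` cells are written
#' blank. Re-reading the file reproduces the records value-for-value.
#'
#' @param x a specimen table (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(x, path) {
  stopifnot(all(.specimen_columns %in% names(x)))
  utils::write.csv(as.data.frame(x)[, .specimen_columns], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read the within-species variation fixture
#'
#' Loads the eight-specimen *Bathygenys reevesi* series used for
#' within-species variation statistics. Columns: endocast volume `E_ml`,
#' endocast surface area `S_cm2` (the specimens lack olfactory bulbs, so
#' this is also the bulb-free surface), neocortical area `nc_cm2`, and the
#' neocortex-to-surface ratio `nc_over_S`.
#'
#' @param path path to a CSV in the same layout; defaults to the packaged
#'   fixture.
#' @return a data frame with one row per specimen.
#' @export
#' @examples
#' bat <- read_bathygenys()
#' nrow(bat)
read_bathygenys <- function(path = paleo_fixture("table2_bathygenys")) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "specimen_id", "E_ml", "S_cm2", "nc_cm2", "nc_over_S")
                %in% names(out)))
  out
}

#' Validate a specimen table
#'
#' Recomputes the derived columns of each record and reports, never
#' raises, inconsistencies. Per record the checks are:
#' \describe{
#'   \item{`positive`}{every present area/length/volume/mass is > 0 (an
#'     olfactory-bulb area of 0 is allowed: bulbs absent from the cast).}
#'   \item{`additivity`}{when `S`, `OB` and `S-OB` are all present,
#'     `|S - OB - (S-OB)| <= 0.05` cm^2.}
#'   \item{`pctNC`}{when `NC` and `S-OB` are present, the recomputed
#'     `100 * NC / (S-OB)` agrees with the printed `pctNC` within
#'     `tolerance_pct` points.}
#'   \item{`EQ`}{when `E` and `P` are present, the recomputed quotient
#'     under (`b`, `alpha`), rounded to 2 decimals, agrees with the
#'     printed `EQ` within `tolerance_eq`.}
#' }
#' A check whose inputs are missing is reported as `"skipped_missing"`.
#' Validation never mutates the records.
#'
#' @param records a specimen table from [read_specimens()].
#' @param tolerance_pct tolerance for the neocorticalization check, in
#'   percentage points (default 0.05).
#' @param tolerance_eq tolerance for the quotient check after rounding to
#'   2 decimals (default 0.01).
#' @param b,alpha reference allometry for the quotient check; defaults
#'   are the classical `b = 0.12` and the theoretical exponent `2/3`.
#' @return a data frame of class `"validation_report"` with columns
#'   `row`, `species`, `specimen_id`, `check`, `status` (`"pass"`,
#'   `"fail"` or `"skipped_missing"`), `recomputed`, `reported`, `detail`.
#' @export
#' @examples
#' rep <- validate_specimens(read_specimens("table1_mammals"))
#' subset(rep, status == "fail" & check == "pctNC")
validate_specimens <- function(records, tolerance_pct = 0.05,
                               tolerance_eq = 0.01, b = 0.12, alpha = 2 / 3) {
  n <- nrow(records)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    checks <- list()
    measured <- c(S = r$S_cm2, OB = r$OB_cm2, S_minus_OB = r$S_minus_OB_cm2,
                  NC = r$NC_cm2, L = r$L_cm, E = r$E_ml, P = r$P_g)
    nonpos <- names(measured)[!is.na(measured) & measured <= 0 &
                                names(measured) != "OB"]
    nonpos <- c(nonpos, if (!is.na(r$OB_cm2) && r$OB_cm2 < 0) "OB")
    checks$positive <- list(
      status = if (length(nonpos)) "fail" else "pass",
      recomputed = NA_real_, reported = NA_real_,
      detail = if (length(nonpos)) paste("nonpositive:", paste(nonpos, collapse = ","))
               else "")
    if (!is.na(r$S_cm2) && !is.na(r$OB_cm2) && !is.na(r$S_minus_OB_cm2)) {
      gap <- r$S_cm2 - r$OB_cm2 - r$S_minus_OB_cm2
      checks$additivity <- list(
        status = if (abs(gap) > 0.05) "fail" else "pass",
        recomputed = r$S_cm2 - r$OB_cm2, reported = r$S_minus_OB_cm2,
        detail = sprintf("S - OB - (S-OB) = %.2f", gap))
    } else {
      checks$additivity <- list(status = "skipped_missing",
                                recomputed = NA_real_, reported = NA_real_,
                                detail = "")
    }
    if (!is.na(r$NC_cm2) && !is.na(r$S_minus_OB_cm2) && !is.na(r$pctNC) &&
        r$NC_cm2 > 0 && r$S_minus_OB_cm2 > 0) {
      pct <- 100 * r$NC_cm2 / r$S_minus_OB_cm2
      checks$pctNC <- list(
        status = if (abs(pct - r$pctNC) > tolerance_pct + 1e-9) "fail" else "pass",
        recomputed = pct, reported = r$pctNC,
        detail = sprintf("recomputed %.2f vs printed %.2f", pct, r$pctNC))
    } else {
      checks$pctNC <- list(status = "skipped_missing",
                           recomputed = NA_real_, reported = NA_real_,
                           detail = "")
    }
    if (!is.na(r$E_ml) && !is.na(r$P_g) && !is.na(r$EQ) &&
        r$E_ml > 0 && r$P_g > 0) {
      q <- round(eq_quotient(r$E_ml, r$P_g, b = b, alpha = alpha)$eq, 2)
      checks$EQ <- list(
        status = if (abs(q - r$EQ) > tolerance_eq + 1e-9) "fail" else "pass",
        recomputed = q, reported = r$EQ,
        detail = sprintf("recomputed %.2f vs printed %.2f", q, r$EQ))
    } else {
      checks$EQ <- list(status = "skipped_missing",
                        recomputed = NA_real_, reported = NA_real_,
                        detail = "")
    }
    res[[i]] <- data.frame(
      row = i, species = r$species, specimen_id = r$specimen_id,
      check = names(checks),
      status = vapply(checks, `[[`, "", "status"),
      recomputed = vapply(checks, `[[`, 0, "recomputed"),
      reported = vapply(checks, `[[`, 0, "reported"),
      detail = vapply(checks, `[[`, "", "detail"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  x <- as.data.frame(x)
  tab <- table(x$check, x$status)
  cat("Specimen validation report:", length(unique(x$row)), "records\n")
  print(tab)
  fails <- x[x$status == "fail", c("row", "species", "check", "detail")]
  if (nrow(fails)) {
    cat("\nFailing checks:\n")
    print.data.frame(fails, row.names = FALSE)
  }
  invisible(x)
}
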