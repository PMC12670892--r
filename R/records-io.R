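#' Default column mapping for ANC register extracts
#'
#' Maps the internal field names to the CSV column names of a register
#' extract. Override individual entries to read extracts with different
#' headers. `record_id` is optional in the file; identifiers are generated
#' when the column is absent.
#'
#' @param ... Named overrides, e.g. `n_contacts = "total_anc"`.
#' @return Named character vector (internal field -> CSV column).
#' @export
anc_columns <- function(...) {
  defaults <- c(
    record_id = "record_id", country = "country", clinic_id = "clinic_id",
    year = "year", n_contacts = "n_contacts",
    ga_first = "ga_first_weeks", ga_last = "ga_last_weeks"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) abort(sprintf("Unknown column mapping field(s): %s", toString(bad)))
    defaults[names(overrides)] <- overrides
  }
  defaults
}

# numeric coercion for register cells: "", "NA" -> missing; unparseable ->
# missing + warning count; fractional GA handled by the caller
parse_register_numeric <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "NA", "na", "N/A")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  list(value = out, n_unparseable = sum(!is.na(x) & is.na(out)))
}

#' Read an ANC register extract
#'
#' Reads a comma-delimited, UTF-8 register extract (header row required) into
#' a tibble of one row per pregnancy. Numeric cells that cannot be parsed
#' become missing values and are counted in the parse report; gestational
#' ages with fractional weeks are floored to completed weeks (the obstetric
#' "completed weeks" convention) and flagged.
#'
#' @param path Path to the CSV file.
#' @param columns Column mapping from [anc_columns()].
#' @return A tibble with columns `record_id`, `country`, `clinic_id`, `year`,
#'   `n_contacts`, `ga_first`, `ga_last`, carrying a `parse_report` attribute
#'   retrievable with [parse_report()].
#' @seealso [filter_descriptive()], [filter_window()]
#' @export
read_anc_register <- function(path, columns = anc_columns()) {
  if (!file.exists(path)) abort(sprintf("Register file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) abort(sprintf("Register file is empty: %s", path))
  mandatory <- setdiff(names(columns), "record_id")
  missing_cols <- columns[mandatory][!columns[mandatory] %in% names(raw)]
  if (length(missing_cols)) {
    abort(sprintf("Register file %s is missing mandatory column(s): %s",
                  path, toString(missing_cols)))
  }
  if (nrow(raw) == 0) abort(sprintf("Register file has a header but no data rows: %s", path))

  ids <- if (columns[["record_id"]] %in% names(raw)) {
    raw[[columns[["record_id"]]]]
  } else {
    sprintf("row%06d", seq_len(nrow(raw)))
  }

  report <- list()
  num <- function(field) {
    p <- parse_register_numeric(raw[[columns[[field]]]])
    if (p$n_unparseable > 0) {
      report[[length(report) + 1]] <<- tibble(field = field, issue = "unparseable",
                                              n = p$n_unparseable)
    }
    p$value
  }
  n_contacts <- num("n_contacts")
  year <- num("year")
  ga_first <- num("ga_first")
  ga_last <- num("ga_last")

  for (field in c("ga_first", "ga_last")) {
    v <- get(field)
    frac <- sum(!is.na(v) & v != floor(v))
    if (frac > 0) {
      report[[length(report) + 1]] <- tibble(field = field, issue = "floored_fractional_weeks", n = frac)
    }
    assign(field, floor(v))
  }

  clinic <- trimws(raw[[columns[["clinic_id"]]]])
  clinic[clinic %in% c("", "NA")] <- NA_character_

  records <- tibble(
    record_id = as.character(ids),
    country = trimws(raw[[columns[["country"]]]]),
    clinic_id = clinic,
    year = as.integer(year),
    n_contacts = as.integer(n_contacts),
    ga_first = as.integer(ga_first),
    ga_last = as.integer(ga_last)
  )
  attr(records, "parse_report") <- if (length(report)) bind_rows(report) else
    tibble(field = character(), issue = character(), n = integer())
  records
}

#' Retrieve the parse or exclusion report attached to a tibble
#'
#' @param x A tibble returned by [read_anc_register()].
#' @return The parse-report tibble (field, issue, n).
#' @export
parse_report <- function(x) {
  attr(x, "parse_report") %||%
    tibble(field = character(), issue = character(), n = integer())
}

#' Retrieve the exclusion tally attached to a filtered tibble
#'
#' @param x A tibble returned by [filter_descriptive()] or [filter_window()].
#' @return A tibble (reason, n) whose counts sum, together with the retained
#'   row count, to the input size.
#' @export
exclusion_tally <- function(x) {
  attr(x, "exclusion_tally") %||%
    tibble(reason = character(), n = integer())
}

descriptive_reasons <- c("missing_contact_count", "contacts_gt_16",
                         "missing_clinic", "single_contact_ga_mismatch")
window_reasons <- c("missing_ga_window", "last_before_first_window")

#' Descriptive-analysis exclusion filter
#'
#' Applies the register exclusion rules for the descriptive analysis of
#' contact counts: records are dropped when the contact count was not
#' recorded (or is non-positive), when more than 16 contacts were recorded
#' (outliers not representative of typical health-seeking patterns), when
#' the clinic was not recorded, or when a single contact was recorded but
#' different GAs were entered under first and last contact. Each excluded
#' record is attributed to exactly one reason, the first matching in that
#' fixed order; precedence affects only the tally, never the retained set.
#'
#' @param records A tibble of register records, as from [read_anc_register()].
#' @return The retained records, with an `exclusion_tally` attribute
#'   (see [exclusion_tally()]) including a `retained_descriptive` row.
#' @export
filter_descriptive <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  hit <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  hit(is.na(records$n_contacts) | records$n_contacts < 1, "missing_contact_count")
  hit(records$n_contacts > 16, "contacts_gt_16")
  hit(is.na(records$clinic_id), "missing_clinic")
  hit(records$n_contacts == 1 & !is.na(records$ga_first) & !is.na(records$ga_last) &
        records$ga_first != records$ga_last, "single_contact_ga_mismatch")

  retained <- records[is.na(reason), , drop = FALSE]
  counts <- unname(vapply(descriptive_reasons,
                          function(r) sum(reason == r, na.rm = TRUE), integer(1)))
  tally <- tibble(
    reason = c(descriptive_reasons, "retained_descriptive"),
    n = c(counts, nrow(retained))
  )
  attr(retained, "exclusion_tally") <- tally
  attr(retained, "parse_report") <- attr(records, "parse_report")
  retained
}

#' Window-analysis exclusion filter
#'
#' On top of the descriptive filter, the GA-window analysis additionally
#' requires both endpoint GAs: records are dropped when the GA is missing
#' for either first or last contact, or when the GA at last contact is lower
#' than at first contact (a data extraction error). Equality of the two GAs
#' is permitted.
#'
#' @param records A tibble that already passed [filter_descriptive()].
#' @return The retained records with an `exclusion_tally` attribute
#'   including a `retained_window` row.
#' @export
filter_window <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  miss <- is.na(records$ga_first) | is.na(records$ga_last)
  reason[miss] <- "missing_ga_window"
  rev_ga <- !miss & records$ga_last < records$ga_first
  reason[is.na(reason) & rev_ga] <- "last_before_first_window"

  retained <- records[is.na(reason), , drop = FALSE]
  counts <- unname(vapply(window_reasons,
                          function(r) sum(reason == r, na.rm = TRUE), integer(1)))
  tally <- tibble(
    reason = c(window_reasons, "retained_window"),
    n = c(counts, nrow(retained))
  )
  attr(retained, "exclusion_tally") <- tally
  attr(retained, "parse_report") <- attr(records, "parse_report")
  retained
}

#' Per-country data accounting
#'
#' Summarises how many records each country contributes after filtering and
#' appends a grand total, mirroring the data-accounting narrative of a
#' multi-country register study.
#'
#' @param x Either a tibble of retained records (counted per country) or a
#'   tibble with columns `country` and `retained` (pre-computed counts).
#' @return A tibble (country, retained) with a final `total` row.
#' @examples
#' data_accounting(tibble::tibble(
#'   country = c("BD", "GM", "NP", "NG", "TZ", "UG"),
#'   retained = c(33950, 20918, 9645, 41065, 6332, 11957)
#' ))
#' @export
data_accounting <- function(x) {
  counts <- if (all(c("country", "retained") %in% names(x))) {
    tibble(country = as.character(x$country), retained = as.numeric(x$retained))
  } else if ("country" %in% names(x)) {
    x %>% count(.data$country, name = "retained") %>%
      mutate(country = as.character(.data$country))
  } else {
    abort("data_accounting() needs a `country` column.")
  }
  counts <- arrange(counts, .data$country)
  bind_rows(counts, tibble(country = "total", retained = sum(counts$retained)))
}

#' Write an exclusion tally as CSV
#'
#' @param tally A tibble (reason, n), optionally with a `stratum` column.
#' @param path Output CSV path.
#' @param stratum Stratum label used when the tally has no `stratum` column.
#' @return `path`, invisibly.
#' @export
write_exclusion_tally <- function(tally, path, stratum = "overall") {
  out <- if ("stratum" %in% names(tally)) tally else mutate(tally, stratum = stratum)
  readr::write_csv(select(out, "stratum", "reason", "n"), path)
  invisible(path)
}
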