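# ---- file-based pipeline: simulate -> analyze -> report --------------------

#' Read a pipeline run configuration
#'
#' YAML or JSON; unspecified fields fall back to the defaults of
#' [run_full_analysis()] (all four standard windows, all three strategies,
#' both weightings, all groupings, seed 1).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file.
#' @return A named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(
    windows = names(anc_windows()),
    strategies = c("random", "even", "none"),
    weightings = c("pooled", "normalized"),
    groupings = c("overall", "country", "clinic", "year",
                  "contact_group_2way", "contact_group_3way"),
    seed = 1L, n_draws = NULL, rounding = 1L
  )
  utils::modifyList(defaults, as.list(cfg))
}

#' Simulate a cohort to disk
#'
#' Writes `cohort.csv` (register schema), `truth.csv` (record_id, week: one
#' row per true contact) and `manifest.json` (seed and a parameter hash) to
#' `out_dir`.
#'
#' @param params A `cohort_params` object, or a preset name for
#'   [cohort_preset()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer cohort seed.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(params = "six-country", out_dir, seed = 1L) {
  if (is.character(params)) params <- cohort_preset(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(params, seed = seed)
  if (nrow(sim$records) == 0) warn("Simulated cohort is empty; writing header-only files.")
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    truth = file.path(out_dir, "truth.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  out <- sim$records
  names(out)[names(out) == "ga_first"] <- "ga_first_weeks"
  names(out)[names(out) == "ga_last"] <- "ga_last_weeks"
  readr::write_csv(out, paths$cohort, na = "")
  readr::write_csv(sim$truth, paths$truth)
  jsonlite::write_json(
    list(seed = seed, n_records = nrow(sim$records),
         countries = names(params), params_hash = rlang::hash(params)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Analyze a register extract to disk
#'
#' Reads the cohort CSV, applies the exclusion filters, runs
#' [run_full_analysis()], and writes `exclusions.csv`, `reachability.csv`,
#' `contact_counts.csv`, `ga_distributions.csv`, `gains.csv`,
#' `accounting.csv` and a full-precision `bundle.json`. Per-stage record
#' counts are reported via `message()`.
#'
#' @param input Path to a register CSV in the [read_anc_register()] schema.
#' @param out_dir Output directory (created if needed).
#' @param config A config list from [read_run_config()] (or `NULL` for
#'   defaults).
#' @return Invisibly, the `anc_analysis` object.
#' @export
run_analyze <- function(input, out_dir, config = NULL) {
  config <- utils::modifyList(read_run_config_defaults(), as.list(config %||% list()))
  records <- read_anc_register(input)
  message(sprintf("stage=read records=%d", nrow(records)))
  ana <- run_full_analysis(records,
                           windows = config$windows, strategies = config$strategies,
                           weightings = config$weightings, groupings = config$groupings,
                           seed = config$seed, n_draws = config$n_draws)
  message(sprintf("stage=filter_descriptive records=%d", ana$n_descriptive))
  message(sprintf("stage=filter_window records=%d", ana$n_window))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ana$exclusions, file.path(out_dir, "exclusions.csv"))
  readr::write_csv(ana$reachability, file.path(out_dir, "reachability.csv"))
  readr::write_csv(ana$contact_counts, file.path(out_dir, "contact_counts.csv"))
  readr::write_csv(ana$ga_distributions, file.path(out_dir, "ga_distributions.csv"))
  readr::write_csv(ana$gains, file.path(out_dir, "gains.csv"))
  readr::write_csv(ana$accounting, file.path(out_dir, "accounting.csv"))
  jsonlite::write_json(
    list(n_input = ana$n_input, n_descriptive = ana$n_descriptive,
         n_window = ana$n_window, seed = ana$seed,
         reachability = ana$reachability, gains = ana$gains),
    file.path(out_dir, "bundle.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ana)
}

read_run_config_defaults <- function() {
  list(windows = names(anc_windows()),
       strategies = c("random", "even", "none"),
       weightings = c("pooled", "normalized"),
       groupings = c("overall", "country", "clinic", "year",
                     "contact_group_2way", "contact_group_3way"),
       seed = 1L, n_draws = NULL, rounding = 1L)
}

fmt1 <- function(x, digits = 1) sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))

md_table <- function(df, digits = 1) {
  fmt_cell <- function(v) {
    if (is.numeric(v) && !all(v == floor(v), na.rm = TRUE)) fmt1(v, digits) else as.character(v)
  }
  cells <- as.data.frame(lapply(df, fmt_cell), check.names = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a human-readable analysis report
#'
#' Builds a markdown summary from the CSV outputs of [run_analyze()]:
#' contact-count distribution by country, GA medians/IQRs, reachability per
#' window and strategy, and percentage gains between contact groups.
#' Percentages are rounded to one decimal place, half-up; empty strata were
#' already omitted upstream and are footnoted as such.
#'
#' @param results_dir Directory holding the [run_analyze()] outputs.
#' @param path Output file (default `report.md` inside `results_dir`).
#' @return The report text, invisibly; the file is written as a side effect.
#' @export
run_report <- function(results_dir, path = file.path(results_dir, "report.md")) {
  need <- file.path(results_dir, c("reachability.csv", "contact_counts.csv",
                                   "ga_distributions.csv", "gains.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) abort(sprintf("Missing analysis outputs: %s", toString(missing)))
  reach <- readr::read_csv(need[1], show_col_types = FALSE)
  counts <- readr::read_csv(need[2], show_col_types = FALSE)
  gas <- readr::read_csv(need[3], show_col_types = FALSE)
  gains <- readr::read_csv(need[4], show_col_types = FALSE)

  counts_tab <- counts %>%
    filter(.data$grouping %in% c("overall", "country")) %>%
    mutate(dplyr::across(dplyr::starts_with("share_"), ~ 100 * .x)) %>%
    select("stratum", "weighting", "n", "median", "q1", "q3",
           "share_1", "share_2", "share_3", "share_ge4", "share_ge8")
  reach_tab <- reach %>%
    filter(.data$grouping == "overall") %>%
    mutate(percent = 100 * .data$proportion) %>%
    select("window", "strategy", "weighting", "n", "percent")
  gains_tab <- gains %>%
    mutate(p_low = 100 * .data$p_low, p_high = 100 * .data$p_high) %>%
    select("window", "strategy", "weighting", "p_low", "p_high", "gain_pct_points")

  txt <- paste(
    "# ANC reachability report", "",
    "## Number of ANC contacts per pregnancy", "",
    md_table(counts_tab), "",
    "## Gestational age at first and last contact (weeks)", "",
    md_table(gas), "",
    "## Reachability by GA window (%)", "",
    md_table(reach_tab), "",
    "## Percentage-point gain, 1-3 vs >=4 contacts", "",
    md_table(gains_tab), "",
    "Strata with no records are omitted from all tables.", "",
    sep = "\n")
  writeLines(txt, path)
  invisible(txt)
}
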