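#' Run the full reachability analysis
#'
#' Orchestrates the published analysis end-to-end on a tibble of parsed
#' register records: applies the descriptive and window exclusion filters
#' (recording the tallies), then computes reachability for every requested
#' window x strategy x grouping x weighting combination, contact-count and
#' GA distribution summaries, and percentage gains between the 1--3 and >=4
#' contact groups. Deterministic: identical `(records, config, seed)` give
#' identical output.
#'
#' @param records Parsed register records (e.g. from [read_anc_register()]
#'   or [simulate_cohort()]); filtering is applied internally.
#' @param windows Named list or character vector of GA windows
#'   (default [anc_windows()]).
#' @param strategies Subset of `c("random", "even", "none")`.
#' @param weightings Subset of `c("pooled", "normalized")`.
#' @param groupings Subset of the groupings of [reach_by_stratum()].
#' @param seed Integer seed (used only in Monte-Carlo mode).
#' @param n_draws If non-`NULL`, the random strategy uses Monte-Carlo
#'   estimation with this many draws per record instead of the exact
#'   closed-form probability.
#' @return An `anc_analysis` object: a list with tibbles `reachability`,
#'   `contact_counts`, `ga_distributions`, `gains`, `exclusions`,
#'   `accounting`, plus the record counts at each stage. Supports [tidy()],
#'   [glance()], [autoplot()] and `print()`.
#' @export
run_full_analysis <- function(records,
                              windows = anc_windows(),
                              strategies = c("random", "even", "none"),
                              weightings = c("pooled", "normalized"),
                              groupings = c("overall", "country", "clinic", "year",
                                            "contact_group_2way", "contact_group_3way"),
                              seed = 1L, n_draws = NULL) {
  if (is.character(windows)) windows <- setNames(as.list(windows), windows)
  windows <- lapply(windows, as_ga_window)
  if (is.null(names(windows)) || any(names(windows) == "")) {
    names(windows) <- vapply(windows, format, character(1))
  }
  strategies <- match.arg(strategies, several.ok = TRUE)
  weightings <- match.arg(weightings, several.ok = TRUE)
  if (!length(windows) || !length(strategies)) abort("Need at least one window and one strategy.")

  n_input <- nrow(records)
  desc <- filter_descriptive(records)
  desc_tally <- exclusion_tally(desc)
  win <- filter_window(desc)
  win_tally <- exclusion_tally(win)
  exclusions <- bind_rows(
    mutate(desc_tally, stage = "descriptive"),
    mutate(win_tally, stage = "window")
  ) %>% select("stage", "reason", "n")

  if (nrow(win) == 0) {
    warn("No records remain after filtering; returning an empty analysis bundle.")
  }

  grid <- tidyr::expand_grid(window = names(windows), strategy = strategies,
                             weighting = weightings, grouping = groupings)
  reach <- purrr::pmap(grid, function(window, strategy, weighting, grouping) {
    if (nrow(win) == 0) return(NULL)
    reach_by_stratum(win, windows[[window]], strategy, grouping, weighting,
                     n_draws = n_draws, seed = seed)
  }) %>% bind_rows()

  contact_counts <- if (nrow(desc) > 0) {
    bind_rows(lapply(weightings, function(wt) {
      bind_rows(contact_count_summary(desc, "overall", wt),
                contact_count_summary(desc, "country", wt))
    }))
  } else tibble()

  ga_distributions <- if (nrow(win) > 0) {
    grp3 <- as.character(contact_group_3way(win$n_contacts))
    present <- c("all", intersect(c("1", "2-3", ">=4"), unique(grp3)))
    tidyr::expand_grid(group = present,
                       endpoint = c("first", "last"), weighting = weightings) %>%
      purrr::pmap(function(group, endpoint, weighting) {
        ga_summary(win, group, endpoint, weighting)
      }) %>% bind_rows()
  } else tibble()

  gains <- if (nrow(win) > 0 && "contact_group_2way" %in% groupings) {
    wide <- reach %>%
      filter(.data$grouping == "contact_group_2way") %>%
      tidyr::pivot_wider(id_cols = c("window", "strategy", "weighting"),
                         names_from = "stratum", values_from = "proportion")
    if (all(c("1-3", ">=4") %in% names(wide))) {
      wide %>%
        filter(!is.na(.data$`1-3`) & !is.na(.data$`>=4`)) %>%
        mutate(gain_pct_points = percentage_gain(.data$`1-3`, .data$`>=4`)) %>%
        rename(p_low = "1-3", p_high = ">=4")
    } else tibble()
  } else tibble()

  accounting <- if (nrow(win) > 0) data_accounting(win) else
    tibble(country = "total", retained = 0)

  structure(list(
    reachability = reach,
    contact_counts = contact_counts,
    ga_distributions = ga_distributions,
    gains = gains,
    exclusions = exclusions,
    accounting = accounting,
    n_input = n_input, n_descriptive = nrow(desc), n_window = nrow(win),
    windows = vapply(windows, format, character(1)),
    strategies = strategies, weightings = weightings, groupings = groupings,
    seed = seed, n_draws = n_draws
  ), class = "anc_analysis")
}

#' @export
print.anc_analysis <- function(x, ...) {
  cat("<anc_analysis>\n")
  cat(sprintf("  records: %d input -> %d descriptive -> %d window\n",
              x$n_input, x$n_descriptive, x$n_window))
  cat(sprintf("  windows: %s | strategies: %s\n",
              toString(x$windows), toString(x$strategies)))
  ov <- x$reachability %>%
    filter(.data$grouping == "overall", .data$weighting == x$weightings[1])
  if (nrow(ov)) {
    cat(sprintf("  overall reachability (%s):\n", x$weightings[1]))
    for (i in seq_len(nrow(ov))) {
      cat(sprintf("    %-5s %-6s %5.1f%%\n", ov$window[i], ov$strategy[i],
                  100 * ov$proportion[i]))
    }
  }
  invisible(x)
}

#' Tidy an analysis bundle
#'
#' @param x An `anc_analysis` object.
#' @param ... Unused.
#' @return The reachability tibble, one row per (window, strategy,
#'   weighting, grouping, stratum).
#' @method tidy anc_analysis
#' @export
tidy.anc_analysis <- function(x, ...) x$reachability

#' One-row summary of an analysis bundle
#'
#' @param x An `anc_analysis` object.
#' @param ... Unused.
#' @return One-row tibble with stage record counts and grid dimensions.
#' @method glance anc_analysis
#' @export
glance.anc_analysis <- function(x, ...) {
  tibble(n_input = x$n_input, n_descriptive = x$n_descriptive, n_window = x$n_window,
         n_windows = length(x$windows), n_strategies = length(x$strategies),
         n_estimates = nrow(x$reachability))
}

#' Plot reachability estimates
#'
#' Bar chart of the proportion reached per GA window, faceted by strategy,
#' for one grouping/weighting slice of the analysis.
#'
#' @param object An `anc_analysis` object.
#' @param grouping,weighting Slice to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anc_analysis
#' @export
autoplot.anc_analysis <- function(object, grouping = "overall",
                                  weighting = object$weightings[1], ...) {
  df <- object$reachability %>%
    filter(.data$grouping == .env$grouping, .data$weighting == .env$weighting)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$proportion,
                                   fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~strategy) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "GA window (weeks)", y = "Reached for vaccination",
                  fill = grouping,
                  title = sprintf("ANC reachability by GA window (%s)", weighting)) +
    ggplot2::theme_minimal()
}

#' Plot the contact-count distribution
#'
#' Stacked shares of women attending 1, 2, 3 and >=4 times, per country.
#'
#' @param analysis An `anc_analysis` object.
#' @param weighting Which weighting slice to display.
#' @return A ggplot object.
#' @export
plot_contact_counts <- function(analysis, weighting = "pooled") {
  df <- analysis$contact_counts %>%
    filter(.data$weighting == .env$weighting, .data$grouping %in% c("country", "overall")) %>%
    tidyr::pivot_longer(dplyr::all_of(c("share_1", "share_2", "share_3", "share_ge4")),
                        names_to = "category", values_to = "share") %>%
    mutate(category = factor(.data$category,
                             levels = c("share_1", "share_2", "share_3", "share_ge4"),
                             labels = c("1", "2", "3", ">=4")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$share,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Share of pregnancies", fill = "ANC contacts",
                  title = "Number of ANC contacts per pregnancy") +
    ggplot2::theme_minimal()
}
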