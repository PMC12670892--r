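# ---- weighted quantiles ----------------------------------------------------

#' Weighted sample quantiles
#'
#' Cumulative-weight inversion with linear interpolation: sorted values are
#' placed at midpoint positions \eqn{p_i = (c_i - w_i/2)/W} of the cumulative
#' weight, and quantiles are read off by linear interpolation between
#' adjacent order statistics (clamped at the extremes). With equal weights
#' this reduces to the familiar linear-interpolation sample quantile, e.g.
#' the median of 12, 14, 20, 24 is 17.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, recycled to `length(x)`.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, `NA` when no positive-weight values.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = c(0.25, 0.5, 0.75)) {
  stopifnot(all(probs >= 0 & probs <= 1))
  w <- rep_len(w, length(x))
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(rep(NA_real_, length(probs)))
  o <- order(x); x <- x[o]; w <- w[o]
  if (length(x) == 1) return(rep(x, length(probs)))
  p <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

# ---- per-record reach values ----------------------------------------------

#' Per-record window-reach values
#'
#' The quantity averaged into every reachability estimate: under the random
#' strategy the exact per-record reach probability (or a Monte-Carlo
#' estimate when `n_draws` is given); under `none`/`even` the 0/1 indicator
#' of whether the deterministic schedule touches the window.
#'
#' @param records Tibble past [filter_window()].
#' @param window A [ga_window()].
#' @param strategy `"none"`, `"even"` or `"random"`.
#' @param n_draws If non-`NULL` with `strategy = "random"`, use Monte-Carlo
#'   estimation with this many draws per record.
#' @param seed Cohort seed for Monte-Carlo mode; per-record substreams are
#'   derived from the record's row index.
#' @return Numeric vector, one value in `[0, 1]` per record.
#' @export
record_reach_values <- function(records, window, strategy = c("random", "even", "none"),
                                n_draws = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  w <- as_ga_window(window)
  if (strategy == "random") {
    if (is.null(n_draws)) {
      return(prob_reach_random(records$ga_first, records$ga_last, records$n_contacts, w))
    }
    if (is.null(seed)) abort("Monte-Carlo mode needs a seed.")
    return(purrr::map_dbl(seq_len(nrow(records)), function(i) {
      mc_reach_random(records[i, ], w, n_draws = n_draws, seed = derive_seed(seed, i))
    }))
  }
  purrr::map_dbl(seq_len(nrow(records)), function(i) {
    wk <- if (strategy == "none") schedule_none(records[i, ]) else schedule_even(records[i, ])
    as.numeric(reached(wk, w))
  })
}

# ---- stratifications -------------------------------------------------------

contact_group_3way <- function(k) {
  factor(dplyr::case_when(k == 1 ~ "1", k <= 3 ~ "2-3", TRUE ~ ">=4"),
         levels = c("1", "2-3", ">=4"))
}

contact_group_2way <- function(k) {
  factor(ifelse(k <= 3, "1-3", ">=4"), levels = c("1-3", ">=4"))
}

stratum_labels <- function(records, grouping) {
  switch(grouping,
    overall = rep("overall", nrow(records)),
    country = as.character(records$country),
    clinic = as.character(records$clinic_id),
    year = as.character(records$year),
    contact_group_2way = as.character(contact_group_2way(records$n_contacts)),
    contact_group_3way = as.character(contact_group_3way(records$n_contacts)),
    abort(sprintf("Unknown grouping: %s", grouping))
  )
}

#' Reachability by stratum
#'
#' The central estimator: the proportion of women with at least one ANC
#' contact inside a GA window, per stratum. Under `pooled` weighting the
#' proportion is the plain mean of per-record reach values in the stratum
#' (each individual weighted equally); under `normalized` weighting each
#' country contributes equally to the stratum estimate (the mean of
#' country-specific stratum means, identically the inverse-probability-
#' weighted mean with weights proportional to 1/country-size). Strata with
#' no records are omitted.
#'
#' @inheritParams record_reach_values
#' @param grouping One of `"overall"`, `"country"`, `"clinic"`, `"year"`,
#'   `"contact_group_2way"`, `"contact_group_3way"`.
#' @param weighting `"pooled"` or `"normalized"`.
#' @return Tibble (window, strategy, weighting, grouping, stratum, n,
#'   proportion).
#' @export
reach_by_stratum <- function(records, window, strategy = c("random", "even", "none"),
                             grouping = "overall", weighting = c("pooled", "normalized"),
                             n_draws = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  weighting <- match.arg(weighting)
  w <- as_ga_window(window)
  df <- tibble(
    stratum = stratum_labels(records, grouping),
    country = as.character(records$country),
    value = record_reach_values(records, w, strategy, n_draws = n_draws, seed = seed)
  )
  df <- filter(df, !is.na(.data$stratum))
  est <- if (weighting == "pooled") {
    df %>% group_by(.data$stratum) %>%
      summarise(n = dplyr::n(), proportion = mean(.data$value), .groups = "drop")
  } else {
    df %>% group_by(.data$stratum, .data$country) %>%
      summarise(n = dplyr::n(), p = mean(.data$value), .groups = "drop_last") %>%
      summarise(n = sum(.data$n), proportion = mean(.data$p), .groups = "drop")
  }
  est %>%
    mutate(window = format(w), strategy = .env$strategy, weighting = .env$weighting,
           grouping = .env$grouping) %>%
    select("window", "strategy", "weighting", "grouping", "stratum", "n", "proportion")
}

#' Combine country-level estimates
#'
#' Two ways of combining country proportions into one figure: `pooled` sums
#' country-level data (each individual equal weight,
#' \eqn{\sum p_i n_i / \sum n_i}) and `normalized` applies inverse
#' probability weighting so each country counts equally (the unweighted mean
#' of country estimates). The two agree when all cohort sizes are equal.
#'
#' @param country_estimates Tibble with columns `country`, `proportion`, `n`
#'   (each `n >= 1`).
#' @param mode `"pooled"` or `"normalized"`.
#' @return Single combined proportion.
#' @examples
#' d <- tibble::tibble(country = c("A", "B"), proportion = c(0.6, 0.8), n = c(1000, 10))
#' combine_countries(d, "pooled")      # 608/1010
#' combine_countries(d, "normalized")  # 0.7
#' @export
combine_countries <- function(country_estimates, mode = c("pooled", "normalized")) {
  mode <- match.arg(mode)
  if (nrow(country_estimates) == 0) abort("No country estimates to combine.")
  stopifnot(all(country_estimates$n >= 1))
  if (mode == "pooled") {
    sum(country_estimates$proportion * country_estimates$n) / sum(country_estimates$n)
  } else {
    mean(country_estimates$proportion)
  }
}

# per-individual weights: equal under pooled; proportional to 1/(country
# cohort size) under normalized, so each country carries equal total weight
individual_weights <- function(records, weighting) {
  if (weighting == "pooled") return(rep(1, nrow(records)))
  sizes <- table(records$country)
  1 / as.numeric(sizes[as.character(records$country)])
}

#' Contact-count distribution summary
#'
#' Median/IQR of the number of ANC contacts plus category shares at 1, 2, 3,
#' >=4 and >=8 contacts (the WHO-recommended schedule), per stratum. Under
#' `normalized` weighting each individual carries weight proportional to
#' 1/(country cohort size); quantiles use [weighted_quantile()].
#'
#' @param records Tibble past [filter_descriptive()].
#' @param grouping Stratification (see [reach_by_stratum()]).
#' @param weighting `"pooled"` or `"normalized"`.
#' @return Tibble (grouping, stratum, weighting, n, median, q1, q3, share_1,
#'   share_2, share_3, share_ge4, share_ge8).
#' @export
contact_count_summary <- function(records, grouping = "overall",
                                  weighting = c("pooled", "normalized")) {
  weighting <- match.arg(weighting)
  df <- tibble(
    stratum = stratum_labels(records, grouping),
    k = records$n_contacts,
    w = individual_weights(records, weighting)
  ) %>% filter(!is.na(.data$stratum), !is.na(.data$k))
  df %>%
    group_by(.data$stratum) %>%
    summarise(
      n = dplyr::n(),
      median = weighted_quantile(.data$k, .data$w, 0.5),
      q1 = weighted_quantile(.data$k, .data$w, 0.25),
      q3 = weighted_quantile(.data$k, .data$w, 0.75),
      share_1 = sum(.data$w[.data$k == 1]) / sum(.data$w),
      share_2 = sum(.data$w[.data$k == 2]) / sum(.data$w),
      share_3 = sum(.data$w[.data$k == 3]) / sum(.data$w),
      share_ge4 = sum(.data$w[.data$k >= 4]) / sum(.data$w),
      share_ge8 = sum(.data$w[.data$k >= 8]) / sum(.data$w),
      .groups = "drop"
    ) %>%
    mutate(grouping = .env$grouping, weighting = .env$weighting, variable = "n_contacts") %>%
    select("variable", "grouping", "stratum", "weighting", dplyr::everything())
}

#' GA-at-contact distribution summary
#'
#' Median/IQR of the GA at first or last contact, within a contact-count
#' group (`all`, `1`, `2-3`, `>=4`).
#'
#' @param records Tibble past [filter_window()].
#' @param contact_group `"all"`, `"1"`, `"2-3"` or `">=4"`.
#' @param endpoint `"first"` or `"last"`.
#' @param weighting `"pooled"` or `"normalized"`.
#' @return One-row tibble (variable, contact_group, weighting, n, median,
#'   q1, q3); zero rows (with a warning) when the group is empty.
#' @export
ga_summary <- function(records, contact_group = c("all", "1", "2-3", ">=4"),
                       endpoint = c("first", "last"),
                       weighting = c("pooled", "normalized")) {
  contact_group <- match.arg(contact_group)
  endpoint <- match.arg(endpoint)
  weighting <- match.arg(weighting)
  keep <- if (contact_group == "all") rep(TRUE, nrow(records)) else
    as.character(contact_group_3way(records$n_contacts)) == contact_group
  sub <- records[keep & !is.na(keep), , drop = FALSE]
  variable <- paste0("ga_", endpoint)
  if (nrow(sub) == 0) {
    warn(sprintf("Empty contact group %s for %s.", contact_group, variable))
    return(tibble(variable = character(), contact_group = character(),
                  weighting = character(), n = integer(),
                  median = double(), q1 = double(), q3 = double()))
  }
  x <- if (endpoint == "first") sub$ga_first else sub$ga_last
  w <- individual_weights(sub, weighting)
  q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
  tibble(variable = variable, contact_group = contact_group, weighting = weighting,
         n = nrow(sub), median = q[2], q1 = q[1], q3 = q[3])
}

#' Percentage-point gain between contact-frequency groups
#'
#' The gain in window reachability from attending ANC more often, expressed
#' in absolute percentage points: `(high - low) * 100`. Matches the printed
#' arithmetic of figure-style comparisons (e.g. 66.9% to 94.1% is a 27.2%
#' increase); it is not a relative ratio. May be negative.
#'
#' @param estimate_low_contacts,estimate_high_contacts Proportions in
#'   `[0, 1]` for the low- (1--3) and high- (>=4) contact groups.
#' @return Gain in percentage points.
#' @export
percentage_gain <- function(estimate_low_contacts, estimate_high_contacts) {
  stopifnot(all(estimate_low_contacts >= 0 & estimate_low_contacts <= 1),
            all(estimate_high_contacts >= 0 & estimate_high_contacts <= 1))
  (estimate_high_contacts - estimate_low_contacts) * 100
}
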