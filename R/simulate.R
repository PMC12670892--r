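# ---- synthetic multi-country ANC cohorts ----------------------------------
#
# The generator emulates the statistical structure the estimator assumes:
# per-country contact-count distributions (single-contact-dominant vs
# 4+-contact-dominant), earlier first contact and later last contact among
# women with more contacts, register truncation of <4-contact records at
# some clinics, and the specific data errors the exclusion filters target.
# It also emits the ground-truth full schedule of every pregnancy, which a
# real register never observes, so estimator bias can be measured.

#' Parameters for one synthetic country cohort
#'
#' @param country Country code (e.g. `"BD"`).
#' @param n_records Number of pregnancies to simulate.
#' @param clinic_ids Character vector of clinic codes.
#' @param year_range Integer vector of calendar years (sampled uniformly).
#' @param count_probs Probability vector over contact counts 1..16 (must sum
#'   to 1 within 1e-9).
#' @param ga_first_mean,ga_first_sd Mean/sd (weeks) of the first-contact GA,
#'   one value per contact-count group (1, 2--3, >=4); the GA is a
#'   discretized normal truncated to weeks 4--40. Women with more contacts
#'   should be given lower means (earlier booking).
#' @param gap_base,gap_per_contact The gap `ga_last - ga_first` is Poisson
#'   with mean `gap_base + gap_per_contact * (k - 1)` for `k >= 2` contacts
#'   (0 for `k = 1`), truncated so `ga_last <= 42`.
#' @param placement Law for the `k - 2` interior true contacts on
#'   `{ga_first..ga_last}`: `"uniform"`, `"early"` (clustered near the first
#'   contact) or `"late"` (clustered near the last).
#' @param truncation_below_4 Probability that a record with fewer than 4
#'   contacts is absent from the register (emulates clinics that only
#'   document from the fourth contact onward).
#' @param error_rates Named list of per-record error-injection rates (see
#'   [error_rates()]); at most one error is injected per record so expected
#'   exclusion tallies stay closed-form.
#' @return A `country_params` list.
#' @export
country_params <- function(country, n_records, clinic_ids = paste0(country, 1:4),
                           year_range = 2019:2022,
                           count_probs,
                           ga_first_mean = c(24, 20, 16), ga_first_sd = c(8, 8, 7),
                           gap_base = 2, gap_per_contact = 3.2,
                           placement = c("uniform", "early", "late"),
                           truncation_below_4 = 0,
                           error_rates = ancreach::error_rates()) {
  placement <- match.arg(placement)
  count_probs <- as.numeric(count_probs)
  if (length(count_probs) != 16) abort("count_probs must cover counts 1..16.")
  if (abs(sum(count_probs) - 1) > 1e-9) abort("count_probs must sum to 1 (within 1e-9).")
  if (any(count_probs < 0)) abort("count_probs must be non-negative.")
  rates <- unlist(error_rates)
  if (any(rates < 0) || sum(rates) > 1) abort("error rates must be in [0,1] and sum to <= 1.")
  if (truncation_below_4 < 0 || truncation_below_4 > 1) abort("truncation_below_4 must be a probability.")
  if (n_records < 0) abort("n_records must be >= 0.")
  structure(list(
    country = country, n_records = as.integer(n_records), clinic_ids = clinic_ids,
    year_range = as.integer(year_range), count_probs = count_probs,
    ga_first_mean = ga_first_mean, ga_first_sd = ga_first_sd,
    gap_base = gap_base, gap_per_contact = gap_per_contact,
    placement = placement, truncation_below_4 = truncation_below_4,
    error_rates = as.list(rates)
  ), class = "country_params")
}

#' Default per-record error-injection rates
#'
#' Each rate is the probability that a simulated register row carries the
#' corresponding data error (at most one per record): contact count not
#' recorded, a GA endpoint not recorded, first/last GA swapped at
#' extraction, one recorded contact with two different GAs, or an outlier
#' count above 16.
#'
#' @param missing_count,missing_ga,swapped_ga,single_contact_mismatch,count_gt_16
#'   Probabilities in `[0, 1]` summing to at most 1.
#' @return Named list of rates.
#' @export
error_rates <- function(missing_count = 0.01, missing_ga = 0.02,
                        swapped_ga = 0.005, single_contact_mismatch = 0.003,
                        count_gt_16 = 0.001) {
  list(missing_count = missing_count, missing_ga = missing_ga,
       swapped_ga = swapped_ga, single_contact_mismatch = single_contact_mismatch,
       count_gt_16 = count_gt_16)
}

#' Contact-count probability vector on 1..16
#'
#' Convenience constructor for [country_params()]: explicit shares at 1, 2
#' and 3 contacts and a Poisson-shaped tail over 4..16 centred at
#' `tail_mode`, normalised so the whole vector sums to 1.
#'
#' @param p1,p2,p3 Shares of pregnancies with exactly 1, 2, 3 contacts.
#' @param tail_mode Location (contacts) of the mode of the >=4 tail.
#' @return Probability vector of length 16.
#' @export
count_probs_16 <- function(p1, p2, p3, tail_mode = 5) {
  tail <- stats::dpois(0:12, lambda = max(tail_mode - 4, 0.1))
  tail <- tail / sum(tail) * (1 - p1 - p2 - p3)
  p <- c(p1, p2, p3, tail)
  stopifnot(length(p) == 16, abs(sum(p) - 1) < 1e-9)
  p
}

#' Shipped six-country cohort presets
#'
#' Illustrative parameter sets loosely matched to the contact-count
#' heterogeneity seen across ANC registers in Bangladesh, The Gambia, Nepal,
#' Nigeria, Tanzania and Uganda: a single-contact-dominant country (BD-like,
#' single-contact share about 0.52), a 4+-dominant country with register
#' truncation below 4 contacts at half its clinics (NP-like), an
#' early-booking country (TZ-like), and intermediate patterns. They are
#' synthetic fixtures for exercising the pipeline, not reconstructions of
#' any study population.
#'
#' @param name `"six-country"` (about 2,500 records, sizes proportional to a
#'   realistic multi-country register extract) or `"six-country-small"`
#'   (100 records per country).
#' @return A `cohort_params` list of [country_params()] blocks.
#' @export
cohort_preset <- function(name = c("six-country", "six-country-small")) {
  name <- match.arg(name)
  sizes <- if (name == "six-country") {
    c(BD = 679, GM = 418, NP = 193, NG = 821, TZ = 127, UG = 239)
  } else {
    c(BD = 100, GM = 100, NP = 100, NG = 100, TZ = 100, UG = 100)
  }
  blocks <- list(
    country_params("BD", sizes[["BD"]],
                   count_probs = count_probs_16(0.52, 0.15, 0.12, tail_mode = 4.5),
                   ga_first_mean = c(26, 22, 18), gap_per_contact = 2.5),
    country_params("GM", sizes[["GM"]],
                   count_probs = count_probs_16(0.14, 0.16, 0.18, tail_mode = 5)),
    country_params("NP", sizes[["NP"]],
                   count_probs = count_probs_16(0.004, 0.03, 0.08, tail_mode = 5.5),
                   ga_first_mean = c(22, 19, 15), gap_per_contact = 3.6,
                   truncation_below_4 = 0.5),
    country_params("NG", sizes[["NG"]],
                   count_probs = count_probs_16(0.06, 0.12, 0.16, tail_mode = 5.5)),
    country_params("TZ", sizes[["TZ"]],
                   count_probs = count_probs_16(0.05, 0.12, 0.17, tail_mode = 5),
                   ga_first_mean = c(18, 14, 11), ga_first_sd = c(7, 6, 5)),
    country_params("UG", sizes[["UG"]],
                   count_probs = count_probs_16(0.10, 0.15, 0.18, tail_mode = 5))
  )
  structure(setNames(blocks, vapply(blocks, `[[`, character(1), "country")),
            class = "cohort_params")
}

#' Bundle country parameter blocks into cohort parameters
#'
#' @param ... [country_params()] blocks.
#' @return A `cohort_params` list, named by country.
#' @export
cohort_params <- function(...) {
  blocks <- list(...)
  if (!length(blocks)) abort("Need at least one country_params block.")
  ok <- vapply(blocks, inherits, logical(1), "country_params")
  if (!all(ok)) abort("All arguments must be country_params objects.")
  structure(setNames(blocks, vapply(blocks, `[[`, character(1), "country")),
            class = "cohort_params")
}

# truncated discretized normal on integer weeks [lo, hi] via inverse CDF
rtruncnorm_int <- function(n, mean, sd, lo = 4, hi = 40) {
  plo <- pnorm(lo - 0.5, mean, sd); phi <- pnorm(hi + 0.5, mean, sd)
  x <- round(qnorm(runif(n, plo, phi), mean, sd))
  pmin(pmax(x, lo), hi)
}

place_interior <- function(u, f, l, placement) {
  if (u == 0) return(integer(0))
  support <- f:l
  if (length(support) == 1 || placement == "uniform") {
    return(support[1 + floor(runif(u) * length(support))])
  }
  off <- seq_along(support) - 1
  wts <- switch(placement,
    early = 0.65^off,
    late = 0.65^rev(off)
  )
  sample(support, u, replace = TRUE, prob = wts)
}

simulate_country <- function(par, seed) {
  set.seed(as.integer(seed))
  n <- par$n_records
  if (n == 0) {
    return(list(records = tibble(record_id = character(), country = character(),
                                 clinic_id = character(), year = integer(),
                                 n_contacts = integer(), ga_first = integer(),
                                 ga_last = integer()),
                truth = tibble(record_id = character(), week = integer())))
  }
  k <- sample.int(16, n, replace = TRUE, prob = par$count_probs)
  grp <- as.integer(contact_group_3way(k))           # 1, 2, 3 for groups 1 / 2-3 / >=4
  f <- rtruncnorm_int(n, par$ga_first_mean[grp], par$ga_first_sd[grp])
  gap <- ifelse(k == 1, 0L, rpois(n, par$gap_base + par$gap_per_contact * (pmin(k, 10) - 1)))
  l <- pmin(f + gap, 42L)

  # ground truth: all k contact weeks per pregnancy
  ids <- sprintf("%s-%06d", par$country, seq_len(n))
  interior <- purrr::map(seq_len(n), function(i) {
    place_interior(max(0L, k[i] - 2L), f[i], l[i], par$placement)
  })
  truth <- tibble(
    record_id = rep(ids, pmax(k, 1)),
    week = as.integer(unlist(purrr::map(seq_len(n), function(i) {
      if (k[i] == 1) f[i] else sort(c(f[i], interior[[i]], l[i]))
    })))
  )

  rec <- tibble(
    record_id = ids, country = par$country,
    clinic_id = sample(par$clinic_ids, n, replace = TRUE),
    year = sample(par$year_range, n, replace = TRUE),
    n_contacts = as.integer(k), ga_first = as.integer(f), ga_last = as.integer(l)
  )

  # register truncation: records with <4 contacts may never enter the register
  if (par$truncation_below_4 > 0) {
    drop <- rec$n_contacts < 4 & runif(n) < par$truncation_below_4
    rec <- rec[!drop, , drop = FALSE]
    truth <- truth[truth$record_id %in% rec$record_id, , drop = FALSE]
  }

  # error injection: at most one error per surviving record
  rates <- unlist(par$error_rates)
  if (sum(rates) > 0 && nrow(rec) > 0) {
    pick <- sample(c(names(rates), "none"), nrow(rec), replace = TRUE,
                   prob = c(rates, 1 - sum(rates)))
    for (i in which(pick != "none")) {
      rec[i, ] <- inject_error(rec[i, ], pick[i])
    }
  }
  list(records = rec, truth = truth)
}

# mutate one record to carry one specific register error
inject_error <- function(row, type) {
  switch(type,
    missing_count = { row$n_contacts <- NA_integer_; row },
    missing_ga = {
      if (runif(1) < 0.5) row$ga_first <- NA_integer_ else row$ga_last <- NA_integer_
      row
    },
    swapped_ga = {
      # guarantee ga_last < ga_first with n_contacts >= 2 so the record is
      # always caught by the window filter's last-before-first rule, never
      # the descriptive single-contact rule (keeps the expected tally
      # exactly n * rate)
      if (row$n_contacts == 1L) row$n_contacts <- 2L
      if (row$ga_first == row$ga_last) row$ga_last <- pmax(row$ga_last - 1L, 0L)
      if (row$ga_first == row$ga_last) row$ga_first <- row$ga_first + 1L
      tmp <- row$ga_first; row$ga_first <- max(row$ga_first, row$ga_last)
      row$ga_last <- min(tmp, row$ga_last)
      row
    },
    single_contact_mismatch = {
      row$n_contacts <- 1L
      if (row$ga_first == row$ga_last) row$ga_last <- pmin(row$ga_last + 2L, 42L)
      if (row$ga_first == row$ga_last) row$ga_first <- row$ga_first - 2L
      row
    },
    count_gt_16 = { row$n_contacts <- 17L + as.integer(floor(runif(1) * 4)); row },
    abort(sprintf("Unknown error type %s", type))
  )
}

#' Simulate a multi-country ANC cohort
#'
#' Draws one register row per pregnancy (contact count, GA at first and last
#' contact, clinic, year) together with the ground-truth full contact
#' schedule, then applies register truncation and error injection. Country
#' blocks use seed substreams derived from the cohort seed and the block
#' index, so adding a country does not perturb the others.
#'
#' @param params A `cohort_params` object ([cohort_preset()] or
#'   [cohort_params()]).
#' @param seed Integer cohort seed; output is fully reproducible.
#' @return A list with `records` (register tibble in the [read_anc_register()]
#'   schema) and `truth` (long tibble record_id/week, all true contacts of
#'   every simulated pregnancy, before truncation-surviving records' error
#'   injection).
#' @export
simulate_cohort <- function(params, seed = 1L) {
  if (!inherits(params, "cohort_params")) abort("params must be a cohort_params object.")
  out <- purrr::imap(unname(as.list(params)), function(par, i) {
    simulate_country(par, derive_seed(seed, i * 1000))
  })
  list(
    records = bind_rows(purrr::map(out, "records")),
    truth = bind_rows(purrr::map(out, "truth"))
  )
}

#' True reachability from ground-truth schedules
#'
#' The validation oracle: the fraction of simulated pregnancies with at
#' least one true contact inside the window. A real register cannot compute
#' this (only first/last GAs are observed); the generator's ground truth
#' can.
#'
#' @param truth Long tibble (record_id, week) from [simulate_cohort()].
#' @param window A [ga_window()].
#' @return Proportion in `[0, 1]`.
#' @export
true_reachability <- function(truth, window) {
  if (nrow(truth) == 0) abort("Empty truth set.")
  w <- as_ga_window(window)
  truth %>%
    group_by(.data$record_id) %>%
    summarise(hit = any(.data$week >= w$lo & .data$week <= w$hi), .groups = "drop") %>%
    pull("hit") %>% mean()
}

#' Expected exclusion tallies for a synthetic cohort
#'
#' Closed-form expectations for the exclusion-reason tallies of
#' [filter_descriptive()] and [filter_window()] applied to a cohort drawn
#' from `params`: each reason's expectation is (expected records surviving
#' truncation) x (its injection rate), which is exact because errors are
#' injected mutually exclusively after truncation.
#'
#' @param params A `cohort_params` object.
#' @return Tibble (reason, expected), including expected retained counts.
#' @export
expected_exclusions <- function(params) {
  per <- purrr::map(unname(as.list(params)), function(par) {
    p_lt4 <- sum(par$count_probs[1:3])
    n_eff <- par$n_records * (1 - par$truncation_below_4 * p_lt4)
    r <- par$error_rates
    tibble(
      reason = c("missing_contact_count", "contacts_gt_16", "missing_clinic",
                 "single_contact_ga_mismatch", "missing_ga_window",
                 "last_before_first_window", "n_records_in_register"),
      expected = n_eff * c(r$missing_count, r$count_gt_16, 0,
                           r$single_contact_mismatch, r$missing_ga, r$swapped_ga, 1)
    )
  })
  tot <- bind_rows(per) %>%
    group_by(.data$reason) %>%
    summarise(expected = sum(.data$expected), .groups = "drop")
  n_reg <- tot$expected[tot$reason == "n_records_in_register"]
  excl <- tot$expected[tot$reason != "n_records_in_register"]
  bind_rows(tot, tibble(reason = "retained_window", expected = n_reg - sum(excl)))
}
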