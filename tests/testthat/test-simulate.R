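test_that("cohort simulation is reproducible and respects its parameter contracts", {
  params <- cohort_preset("six-country-small")
  s1 <- simulate_cohort(params, seed = 9)
  s2 <- simulate_cohort(params, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1$records, simulate_cohort(params, seed = 10)$records))
  expect_setequal(unique(s1$records$country), c("BD", "GM", "NP", "NG", "TZ", "UG"))

  # truth matches the emitted clean records: k contacts spanning [first, last]
  clean <- cohort_params(country_params("CL", 300, count_probs = count_probs_16(0.2, 0.2, 0.2),
                                        error_rates = error_rates(0, 0, 0, 0, 0)))
  sim <- simulate_cohort(clean, seed = 5)
  expect_equal(nrow(filter_descriptive(sim$records)), 300)
  expect_equal(nrow(filter_window(filter_descriptive(sim$records))), 300)
  truth_stats <- sim$truth |>
    dplyr::group_by(record_id) |>
    dplyr::summarise(k = dplyr::n(), f = min(week), l = max(week), .groups = "drop") |>
    dplyr::inner_join(sim$records, by = "record_id")
  expect_equal(truth_stats$k, truth_stats$n_contacts)
  expect_equal(truth_stats$f, truth_stats$ga_first)
  expect_equal(truth_stats$l, truth_stats$ga_last)
  expect_true(all(truth_stats$ga_first <= truth_stats$ga_last &
                    truth_stats$ga_last <= 42))
})

test_that("parameter validation rejects malformed generator configs", {
  expect_error(country_params("XX", 10, count_probs = rep(0.1, 10)), "1..16")
  expect_error(country_params("XX", 10, count_probs = rep(0.07, 16)), "sum to 1")
  expect_error(country_params("XX", 10, count_probs = count_probs_16(0.2, 0.2, 0.2),
                              truncation_below_4 = 1.5), "probability")
  expect_error(country_params("XX", 10, count_probs = count_probs_16(0.2, 0.2, 0.2),
                              error_rates = error_rates(missing_count = 0.9, missing_ga = 0.9)),
               "sum")
  expect_error(cohort_params(list(not = "params")), "country_params")
})

test_that("register truncation removes sub-4-contact records and biases reach upward", {
  base <- function(tr) cohort_params(country_params(
    "TR", 4000, count_probs = count_probs_16(0.3, 0.2, 0.15),
    truncation_below_4 = tr, error_rates = error_rates(0, 0, 0, 0, 0)))
  full <- simulate_cohort(base(0), seed = 33)
  trunc <- simulate_cohort(base(1), seed = 33)
  expect_true(all(trunc$records$n_contacts >= 4))
  expect_lt(nrow(trunc$records), nrow(full$records))

  w <- ga_window(24, 36)
  est <- function(sim) mean(prob_reach_random(sim$records$ga_first, sim$records$ga_last,
                                              sim$records$n_contacts, w))
  # dropping low-contact women inflates apparent reachability
  expect_gt(est(trunc), est(full))
})

test_that("simulated contact-count shares track the configured probabilities", {
  p <- count_probs_16(0.3, 0.2, 0.15, tail_mode = 5)
  sim <- simulate_cohort(cohort_params(country_params(
    "MF", 5000, count_probs = p, error_rates = error_rates(0, 0, 0, 0, 0))), seed = 17)
  k <- sim$records$n_contacts
  n <- length(k)
  for (cat in list(c(1, 1), c(2, 2), c(3, 3), c(4, 16), c(8, 16))) {
    target <- sum(p[cat[1]:cat[2]])
    share <- mean(k >= cat[1] & k <= cat[2])
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(share - target), 3 * se + 1e-9)
  }
})

test_that("more contacts mean earlier first and later last contact on average", {
  sim <- simulate_cohort(cohort_preset("six-country"), seed = 2)
  recs <- filter_window(filter_descriptive(sim$records))
  by_grp <- recs |>
    dplyr::mutate(grp = dplyr::case_when(n_contacts == 1 ~ 1L,
                                         n_contacts <= 3 ~ 2L, TRUE ~ 3L)) |>
    dplyr::group_by(grp) |>
    dplyr::summarise(first = mean(ga_first), last = mean(ga_last), .groups = "drop") |>
    dplyr::arrange(grp)
  expect_true(all(diff(by_grp$first) < 0))
  expect_true(all(diff(by_grp$last) > 0))
})

test_that("true reachability oracle counts schedules touching the window", {
  truth <- tibble::tibble(record_id = rep(c("a", "b"), each = 3),
                          week = c(10, 30, 40, 5, 10, 15))
  expect_equal(true_reachability(truth, ga_window(24, 36)), 0.5)
  expect_equal(true_reachability(truth, ga_window(0, 23)), 1)
  expect_equal(true_reachability(truth, ga_window(41, 42)), 0)
  expect_error(true_reachability(truth[0, ], ga_window(24, 36)), "Empty")
})

test_that("expected exclusion tallies match injected error rates", {
  rates <- error_rates(missing_count = 0.1, missing_ga = 0, swapped_ga = 0,
                       single_contact_mismatch = 0, count_gt_16 = 0)
  par <- cohort_params(country_params("EE", 1000, count_probs = count_probs_16(0.2, 0.2, 0.2),
                                      error_rates = rates))
  exp_tally <- expected_exclusions(par)
  expect_equal(exp_tally$expected[exp_tally$reason == "missing_contact_count"], 100)

  zero <- cohort_params(country_params("EE", 1000, count_probs = count_probs_16(0.2, 0.2, 0.2),
                                       error_rates = error_rates(0, 0, 0, 0, 0)))
  zt <- expected_exclusions(zero)
  excl <- zt$expected[!zt$reason %in% c("retained_window", "n_records_in_register")]
  expect_true(all(excl == 0))
  expect_equal(zt$expected[zt$reason == "retained_window"], 1000)

  # swapped-GA errors surface as last-before-first exclusions, binomially
  swp <- cohort_params(country_params("SW", 2000, count_probs = count_probs_16(0.2, 0.2, 0.2),
                                      error_rates = error_rates(0, 0, 0.05, 0, 0)))
  sim <- simulate_cohort(swp, seed = 71)
  tally <- exclusion_tally(filter_window(filter_descriptive(sim$records)))
  observed <- tally$n[tally$reason == "last_before_first_window"]
  expect_lt(abs(observed - 100), 3 * sqrt(2000 * 0.05 * 0.95))
})
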