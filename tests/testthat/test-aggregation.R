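test_that("stratum reachability averages per-record reach values", {
  w <- ga_window(24, 36)
  two <- dplyr::bind_rows(rec(4, 10, 40, id = "a"), rec(2, 28, 40, id = "b"))
  est <- reach_by_stratum(two, w, "random", "overall", "pooled")
  expect_equal(est$proportion, (637 / 961 + 1) / 2)   # mean of oracle values
  expect_equal(est$n, 2L)

  outside <- dplyr::bind_rows(rec(3, 5, 12, id = "a"), rec(2, 38, 40, id = "b"))
  est0 <- reach_by_stratum(outside, w, "none")
  expect_equal(est0$proportion, 0)

  expect_error(reach_by_stratum(two, w, "random", "bogus"), "grouping")
})

test_that("empty strata are omitted and groupings partition the records", {
  records <- random_records(120, seed = 3)
  w <- ga_window(24, 36)
  for (g in c("country", "clinic", "year", "contact_group_2way", "contact_group_3way")) {
    est <- reach_by_stratum(records, w, "even", g)
    expect_true(all(est$n > 0))
    expect_equal(sum(est$n), nrow(records))
  }
})

test_that("pooled and normalized country combination follow their formulas", {
  d <- tibble::tibble(country = c("A", "B"), proportion = c(0.6, 0.8), n = c(1000, 10))
  expect_equal(combine_countries(d, "normalized"), 0.7)
  expect_equal(combine_countries(d, "pooled"), 608 / 1010)
  eq <- tibble::tibble(country = c("A", "B"), proportion = c(0.5, 0.5), n = c(50, 500))
  expect_equal(combine_countries(eq, "pooled"), 0.5)
  expect_equal(combine_countries(eq, "normalized"), 0.5)
  one <- tibble::tibble(country = "A", proportion = 0.42, n = 7)
  expect_equal(combine_countries(one, "pooled"), 0.42)
  expect_equal(combine_countries(one, "normalized"), 0.42)
  expect_error(combine_countries(one[0, ], "pooled"), "No country")
})

test_that("normalized stratum estimates equal inverse-probability-weighted means", {
  records <- random_records(400, seed = 13)
  w <- ga_window(28, 36)
  vals <- record_reach_values(records, w, "random")
  wts <- 1 / as.numeric(table(records$country)[records$country])
  est <- reach_by_stratum(records, w, "random", "overall", "normalized")
  expect_equal(est$proportion, sum(vals * wts) / sum(wts), tolerance = 1e-12)
  # and the pooled overall estimate ignores country labels entirely
  pooled <- reach_by_stratum(records, w, "random", "overall", "pooled")
  expect_equal(pooled$proportion, mean(vals), tolerance = 1e-15)
})

test_that("weighted quantiles invert cumulative weight with interpolation", {
  expect_equal(weighted_quantile(c(12, 14, 20, 24), probs = 0.5), 17)
  expect_equal(weighted_quantile(c(1, 2, 3, 4, 5), probs = 0.5), 3)
  expect_equal(weighted_quantile(7, probs = c(0.25, 0.5, 0.75)), c(7, 7, 7))
  # weight mass dominates: the median lands next to the heavily weighted value
  expect_lt(weighted_quantile(c(1, 10), w = c(99, 1), probs = 0.5), 1.1)
  expect_equal(weighted_quantile(c(1, 10), w = c(1, 1), probs = 0.5), 5.5)
  # equal-weight case stays within the sample hull and is monotone in p
  q <- weighted_quantile(c(3, 9, 1, 5), probs = c(0.1, 0.5, 0.9))
  expect_true(all(diff(q) >= 0) && min(q) >= 1 && max(q) <= 9)
})

test_that("contact-count summary computes shares and weighted medians", {
  records <- dplyr::bind_rows(
    rec(1, 10, 10, id = "a"), rec(2, 10, 20, id = "b"), rec(3, 10, 25, id = "c"),
    rec(4, 10, 30, id = "d"), rec(5, 10, 33, id = "e")
  )
  s <- contact_count_summary(records)
  expect_equal(s$median, 3)
  expect_equal(s$share_ge4, 0.4)
  expect_equal(s$share_1 + s$share_2 + s$share_3 + s$share_ge4, 1)

  # two countries of very different size: normalization balances them
  big <- random_records(0, seed = 1)
  a <- dplyr::bind_rows(lapply(1:1000, function(i) rec(1, 10, 10, id = paste0("a", i), country = "A")))
  b <- dplyr::bind_rows(lapply(1:10, function(i) rec(8, 10, 36, id = paste0("b", i), country = "B")))
  ab <- dplyr::bind_rows(a, b)
  norm <- contact_count_summary(ab, weighting = "normalized")
  expect_equal(norm$share_1, 0.5)
  expect_equal(norm$share_ge8, 0.5)
  pooled <- contact_count_summary(ab, weighting = "pooled")
  expect_equal(pooled$share_1, 1000 / 1010)
})

test_that("GA summaries stratify by contact group and flag empty groups", {
  records <- dplyr::bind_rows(
    rec(1, 10, 10, id = "a"), rec(1, 18, 18, id = "b"), rec(1, 26, 26, id = "c")
  )
  s <- ga_summary(records, "all", "first")
  expect_equal(s$median, 18)
  one <- ga_summary(rec(2, 14, 30), "2-3", "last")
  expect_equal(c(one$median, one$q1, one$q3), c(30, 30, 30))
  expect_warning(empty <- ga_summary(records, ">=4", "first"), "Empty")
  expect_equal(nrow(empty), 0)
})

test_that("percentage gain is an absolute percentage-point difference", {
  expect_equal(round(percentage_gain(0.669, 0.941), 1), 27.2)
  expect_equal(round(percentage_gain(0.526, 0.843), 1), 31.7)
  expect_equal(percentage_gain(0.5, 0.5), 0)
  expect_lt(percentage_gain(0.8, 0.7), 0)
  expect_error(percentage_gain(-0.1, 0.5))
})

test_that("full analysis bundle is deterministic and self-consistent", {
  params <- cohort_preset("six-country-small")
  sim <- simulate_cohort(params, seed = 21)
  a1 <- run_full_analysis(sim$records, seed = 21)
  a2 <- run_full_analysis(sim$records, seed = 21)
  expect_identical(a1$reachability, a2$reachability)
  expect_identical(a1$gains, a2$gains)
  expect_s3_class(tidy(a1), "tbl_df")
  expect_equal(glance(a1)$n_input, nrow(sim$records))
  expect_equal(glance(a1)$n_estimates, nrow(a1$reachability))

  # nesting of windows at every stratum, every strategy/weighting
  nested <- a1$reachability |>
    dplyr::filter(window %in% c("24-36", "28-36", "32-36")) |>
    tidyr::pivot_wider(id_cols = c("strategy", "weighting", "grouping", "stratum"),
                       names_from = "window", values_from = "proportion")
  expect_true(all(nested$`32-36` <= nested$`28-36` + 1e-12))
  expect_true(all(nested$`28-36` <= nested$`24-36` + 1e-12))

  # strategy dominance per stratum
  dom <- a1$reachability |>
    tidyr::pivot_wider(id_cols = c("window", "weighting", "grouping", "stratum"),
                       names_from = "strategy", values_from = "proportion")
  expect_true(all(dom$none <= dom$even + 1e-12))
  expect_true(all(dom$none <= dom$random + 1e-12))

  # one-record cohort: every overall estimate equals the per-record value
  single <- rec(4, 10, 40, id = "solo", country = "AA")
  a3 <- run_full_analysis(single, groupings = "overall")
  r <- a3$reachability |> dplyr::filter(window == "24-36", strategy == "random")
  expect_true(all(abs(r$proportion - 637 / 961) < 1e-12))

  expect_warning(a0 <- run_full_analysis(single[0, ]), "No records")
  expect_equal(nrow(a0$reachability), 0)
})

test_that("analysis plots build without error", {
  sim <- simulate_cohort(cohort_preset("six-country-small"), seed = 4)
  a <- run_full_analysis(sim$records, groupings = c("overall", "country", "contact_group_2way"))
  p1 <- autoplot(a)
  p2 <- plot_contact_counts(a)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
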