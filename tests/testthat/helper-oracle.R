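# Independent brute-force oracle for the random-interpolation reach
# probability: enumerate all m^(k-2) equally likely placements of the k-2
# unobserved contacts on the integer weeks {f..l} and count the placements
# (together with the fixed endpoints) that touch the window. Rational by
# construction: returns hits / m^u.
enum_reach_random <- function(f, l, k, lo, hi) {
  stopifnot(l >= f, k >= 1, hi >= lo)
  inside <- function(w) w >= lo & w <= hi
  if (inside(f) || inside(l)) return(1)
  u <- max(0L, k - 2L)
  if (u == 0L) return(0)
  support <- f:l
  grid <- as.matrix(expand.grid(rep(list(support), u)))
  hits <- sum(rowSums(grid >= lo & grid <= hi) > 0)
  hits / nrow(grid)
}

# quick record constructor for tests
rec <- function(k, f, l, id = "r1", country = "XX", clinic = "XX1", year = 2020) {
  tibble::tibble(record_id = id, country = country, clinic_id = clinic,
                 year = year, n_contacts = as.integer(k),
                 ga_first = as.integer(f), ga_last = as.integer(l))
}

# cohort of random valid window-analysis records for property tests
random_records <- function(n, seed, countries = c("AA", "BB", "CC")) {
  set.seed(seed)
  f <- sample(0:40, n, replace = TRUE)
  gap <- sample(0:25, n, replace = TRUE)
  tibble::tibble(
    record_id = sprintf("p%05d", seq_len(n)),
    country = sample(countries, n, replace = TRUE),
    clinic_id = paste0(sample(countries, n, replace = TRUE), 1),
    year = sample(2019:2022, n, replace = TRUE),
    n_contacts = sample(1:16, n, replace = TRUE),
    ga_first = f,
    ga_last = pmin(f + gap, 42L)
  ) |>
    dplyr::mutate(ga_last = ifelse(n_contacts == 1, ga_first, ga_last))
}

write_cohort_csv <- function(records, path) {
  out <- records
  names(out)[names(out) == "ga_first"] <- "ga_first_weeks"
  names(out)[names(out) == "ga_last"] <- "ga_last_weeks"
  readr::write_csv(out, path, na = "")
  path
}
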