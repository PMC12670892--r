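# ---- per-record contact schedules -----------------------------------------
#
# Registers record only k (total contacts), f (GA at first contact) and l
# (GA at last contact). A schedule reconstructs all k contact weeks under one
# of three assumptions:
#   none   - only the observed endpoints,
#   even   - equal spacing between f and l,
#   random - the k-2 unobserved contacts i.i.d. uniform on the closed integer
#            week set {f, ..., l}, with replacement (several contacts may fall
#            in the same week).
# Contacts live on an integer weekly grid; nothing is imputed outside [f, l].

as_record <- function(record) {
  k <- as.integer(record[["n_contacts"]])
  f <- as.integer(record[["ga_first"]])
  l <- as.integer(record[["ga_last"]])
  if (is.na(k) || is.na(f) || is.na(l)) abort("Record has missing n_contacts/ga_first/ga_last; apply filter_window() first.")
  if (l < f) abort("Record has ga_last < ga_first; apply filter_window() first.")
  list(k = k, f = f, l = l)
}

#' Contact schedule without interpolation
#'
#' The conservative strategy: only the observed first and last contacts.
#'
#' @param record A one-row data frame or named list with `n_contacts`,
#'   `ga_first`, `ga_last` (already past [filter_window()]).
#' @return Sorted integer vector of contact GA weeks (length 1 if
#'   `n_contacts == 1`, else 2).
#' @export
schedule_none <- function(record) {
  r <- as_record(record)
  if (r$k == 1) r$f else c(r$f, r$l)
}

#' Contact schedule under even interpolation
#'
#' Places the `k` contacts at equal spacing between first and last contact.
#' Interior positions are rounded half-up to integer weeks; the endpoints are
#' never rounded.
#'
#' @inheritParams schedule_none
#' @return Sorted integer vector of `n_contacts` GA weeks.
#' @export
schedule_even <- function(record) {
  r <- as_record(record)
  if (r$k == 1) return(r$f)
  pos <- r$f + (r$l - r$f) * (seq_len(r$k) - 1) / (r$k - 1)
  wk <- as.integer(round_half_up(pos))
  wk[1] <- r$f; wk[r$k] <- r$l
  wk
}

#' Contact schedule under uniform random interpolation
#'
#' Keeps the observed endpoints and draws the `k - 2` unobserved contacts
#' i.i.d. uniformly, with replacement, over the closed integer week set
#' `{ga_first, ..., ga_last}`. Reproducible given `seed`.
#'
#' @inheritParams schedule_none
#' @param seed Integer seed for this record's draw.
#' @return Sorted integer vector of `n_contacts` GA weeks containing both
#'   endpoints.
#' @export
schedule_random <- function(record, seed = NULL) {
  r <- as_record(record)
  if (r$k == 1) return(r$f)
  u <- r$k - 2
  interior <- if (u == 0) integer(0) else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    r$f + as.integer(floor(runif(u) * (r$l - r$f + 1)))
  }
  sort(c(r$f, interior, r$l))
}

#' Interpolate schedules for a cohort
#'
#' Builds one contact schedule per record and returns them in long form.
#' For the random strategy each record uses a substream derived from the
#' cohort seed and the record's row index, so results do not depend on
#' processing order.
#'
#' @param records Tibble past [filter_window()].
#' @param strategy One of `"none"`, `"even"`, `"random"`.
#' @param seed Cohort-level integer seed (random strategy only).
#' @return Long tibble (record_id, week, strategy), one row per contact.
#' @export
interpolate_schedules <- function(records, strategy = c("random", "even", "none"),
                                  seed = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "random" && is.null(seed)) abort("The random strategy needs a seed.")
  weeks <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    switch(strategy,
      none = schedule_none(rec),
      even = schedule_even(rec),
      random = schedule_random(rec, seed = derive_seed(seed, i))
    )
  })
  tibble(
    record_id = rep(records$record_id, lengths(weeks)),
    week = as.integer(unlist(weeks)),
    strategy = strategy
  )
}

#' Does a schedule reach a GA window?
#'
#' @param weeks Integer vector of contact GA weeks.
#' @param window A [ga_window()] (or anything [as_ga_window()] accepts).
#' @return `TRUE` iff at least one week falls inside the closed window.
#' @export
reached <- function(weeks, window) {
  w <- as_ga_window(window)
  any(weeks >= w$lo & weeks <= w$hi)
}

#' Exact reach probability under random interpolation
#'
#' For a record with `k` contacts, first contact at `f` and last at `l`
#' weeks, the probability that at least one contact falls inside the window
#' when the `k - 2` unobserved contacts are i.i.d. uniform on the `m = l - f
#' + 1` integer weeks of `{f..l}`. With `w` of those weeks inside the
#' window, the probability is 1 if an endpoint is inside, 0 if `k <= 2` and
#' both endpoints are outside, and otherwise
#' \deqn{1 - \left(\frac{m - w}{m}\right)^{k-2}.}
#' This is the variance-free equivalent of averaging infinitely many random
#' draws; [mc_reach_random()] is the Monte-Carlo counterpart.
#'
#' All arguments are vectorised over records.
#'
#' @param ga_first,ga_last,n_contacts Integer vectors describing records that
#'   passed [filter_window()].
#' @param window A single [ga_window()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' prob_reach_random(10, 40, 4, ga_window(24, 36)) # 1 - (18/31)^2 = 637/961
#' @export
prob_reach_random <- function(ga_first, ga_last, n_contacts, window) {
  w <- as_ga_window(window)
  f <- as.integer(ga_first); l <- as.integer(ga_last); k <- as.integer(n_contacts)
  if (any(is.na(f) | is.na(l) | is.na(k))) abort("Missing f/l/k; apply filter_window() first.")
  if (any(l < f)) abort("ga_last < ga_first encountered; apply filter_window() first.")
  endpoint_in <- (f >= w$lo & f <= w$hi) | (l >= w$lo & l <= w$hi)
  m <- l - f + 1
  ov <- pmax(0L, pmin(l, w$hi) - pmax(f, w$lo) + 1L)
  u <- pmax(0L, k - 2L)
  p <- 1 - ((m - ov) / m)^u
  p[u == 0L] <- 0                           # k <= 2: no unobserved contacts to place
  p[endpoint_in] <- 1
  p
}

#' Monte-Carlo reach probability under random interpolation
#'
#' Estimates the per-record reach probability by averaging the reach
#' indicator over `n_draws` independent random schedules; a validation mode
#' for [prob_reach_random()] and an exact replication of a draw-based
#' analysis.
#'
#' @inheritParams schedule_none
#' @param window A [ga_window()].
#' @param n_draws Number of independent schedules (`>= 1`).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return Estimated probability in `[0, 1]`.
#' @export
mc_reach_random <- function(record, window, n_draws = 10000, seed = 1) {
  r <- as_record(record)
  w <- as_ga_window(window)
  if (n_draws < 1) abort("n_draws must be >= 1.")
  endpoint_in <- (r$f >= w$lo & r$f <= w$hi) || (r$l >= w$lo && r$l <= w$hi)
  if (endpoint_in) return(1)
  u <- max(0L, r$k - 2L)
  if (u == 0L) return(0)
  set.seed(as.integer(seed))
  draws <- matrix(r$f + floor(runif(n_draws * u) * (r$l - r$f + 1)), nrow = n_draws)
  mean(apply(draws, 1, function(x) any(x >= w$lo & x <= w$hi)))
}
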