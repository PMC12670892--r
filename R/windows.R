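#' Gestational-age windows
#'
#' A GA window is a closed interval of completed gestational weeks during
#' which a maternal vaccine could be administered, e.g. 24--36 weeks for the
#' licensed maternal RSV vaccine. Membership is closed on both ends: week
#' `w` is inside iff `lo <= w <= hi`.
#'
#' @param lo,hi Integer completed weeks, `0 <= lo <= hi`.
#' @return A `ga_window` object.
#' @examples
#' ga_window(24, 36)
#' as_ga_window("28-36")
#' @export
ga_window <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (is.na(lo) || is.na(hi)) abort("GA window bounds must be integers.")
  if (lo < 0) abort("GA window lower bound must be >= 0.")
  if (hi < lo) abort(sprintf("Invalid GA window: hi (%d) < lo (%d).", hi, lo))
  structure(list(lo = lo, hi = hi), class = "ga_window")
}

#' @export
print.ga_window <- function(x, ...) {
  cat(sprintf("<ga_window %d-%d weeks>\n", x$lo, x$hi))
  invisible(x)
}

#' @export
format.ga_window <- function(x, ...) sprintf("%d-%d", x$lo, x$hi)

#' Coerce to a GA window
#'
#' Accepts a `ga_window`, a `"lo-hi"` string (e.g. `"24-36"`), or a length-2
#' numeric vector.
#'
#' @param x Object to coerce.
#' @return A `ga_window`.
#' @export
as_ga_window <- function(x) {
  if (inherits(x, "ga_window")) return(x)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(trimws(x), "-", fixed = TRUE)[[1]]
    if (length(parts) != 2 || anyNA(suppressWarnings(as.integer(parts)))) {
      abort(sprintf("Cannot parse GA window from %s; expected \"lo-hi\".", deparse(x)))
    }
    return(ga_window(as.integer(parts[1]), as.integer(parts[2])))
  }
  if (is.numeric(x) && length(x) == 2) return(ga_window(x[1], x[2]))
  abort("Cannot coerce to ga_window.")
}

#' Standard vaccination GA windows
#'
#' The four windows examined in the analysis: 0--23 weeks (e.g. tetanus and
#' other early-gestation vaccines) and the late-gestation windows 24--36,
#' 28--36 and 32--36 weeks relevant to RSV/GBS maternal immunization.
#'
#' @return A named list of [ga_window()] objects.
#' @export
anc_windows <- function() {
  list(
    "0-23"  = ga_window(0, 23),
    "24-36" = ga_window(24, 36),
    "28-36" = ga_window(28, 36),
    "32-36" = ga_window(32, 36)
  )
}
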