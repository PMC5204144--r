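# Internal helpers shared across the pipeline.

#' Convert calendar dates to decimal years
#'
#' Census arithmetic throughout the package uses decimal years so that
#' interval lengths are simple differences. Leap-year subtleties are ignored;
#' the resulting error (< 0.3%) is far below diameter-measurement noise.
#'
#' @param x a `Date`, an ISO-8601 date string (`"2004-07-15"`), or a numeric
#'   vector already in decimal years (returned unchanged).
#' @return numeric vector of decimal years.
#' @examples
#' decimal_year("2000-07-02") # ~ 2000.5
#' @export
decimal_year <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  d <- as.Date(x)
  if (anyNA(d) && !anyNA(x)) {
    abort("dates must be ISO-8601 strings, Date objects, or decimal years")
  }
  yr <- as.integer(format(d, "%Y"))
  start <- as.Date(paste0(yr, "-01-01"))
  yr + as.numeric(d - start) / 365.25
}

# 95th percentile with the h = (n-1)p + 1 linear-interpolation definition
# (stats::quantile type 7, the common scientific default).
pctl95 <- function(x) unname(quantile(x, 0.95, type = 7, names = FALSE))

# standard error of the mean; NA for fewer than two values
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
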