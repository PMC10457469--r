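#' Convert linear power to decibels
#'
#' Power expressed in microvolt squared per hertz is mapped to decibels
#' relative to 1 uV^2/Hz, i.e. `10 * log10(power)`.
#'
#' @param power Numeric vector of non-negative power values (uV^2/Hz).
#' @return Numeric vector in dB.
#' @seealso [db_to_power()]
#' @export
#' @examples
#' power_to_db(1)   # 0 dB
#' power_to_db(2)   # +3.0103 dB
power_to_db <- function(power) {
  10 * log10(power)
}

#' Convert decibels back to linear power
#'
#' @param db Numeric vector in dB relative to 1 uV^2/Hz.
#' @return Numeric vector of power values (uV^2/Hz).
#' @export
db_to_power <- function(db) {
  10^(db / 10)
}

## deterministic child-seed derivation; stays well below .Machine$integer.max
derive_seed <- function(base_seed, index, stream = 0L) {
  base <- (as.numeric(base_seed) %% 1e6)
  as.integer((base * 1009 + index * 7919 + stream * 104729) %% 2147483629)
}

## percentile summary used throughout model comparison (type-7 linear
## interpolation between order statistics)
cv_percentiles <- function(x) {
  quantile(x, probs = c(0.025, 0.25, 0.75, 0.975), type = 7, names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
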