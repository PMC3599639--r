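#' Round to whole dollars (halves away from zero)
#'
#' Display rounding used throughout the package: commercial rounding to the
#' nearest dollar with ties going away from zero, matching how the published
#' tables present whole-dollar figures. All internal chaining keeps full
#' precision; this function is applied only when a value is presented.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep (default 0, whole dollars).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_usd(2390.41)   # 2390
#' round_usd(-59443.43) # -59443
round_usd <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format dollars in publication style
#'
#' Whole dollars with thousands separators; negative amounts (net savings)
#' are rendered in parentheses, e.g. `($59,443)`.
#'
#' @param x Numeric vector of dollar amounts.
#' @return Character vector.
#' @export
#' @examples
#' format_usd(c(124094, -59443))
format_usd <- function(x) {
  r <- round_usd(x)
  s <- formatC(abs(r), format = "f", digits = 0, big.mark = ",")
  out <- ifelse(r < 0, paste0("($", s, ")"), paste0("$", s))
  out[is.na(x)] <- NA_character_
  out
}

# largest-remainder apportionment of n units over probabilities p;
# deterministic tie-break by index so quota fills are reproducible
quota_counts <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# truncated normal draws by inverse-CDF; used for adherence sampling
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
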