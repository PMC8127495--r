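# Internal helpers: condition classes, log-space arithmetic, p-value parsing.

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "pleioscan_config_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "pleioscan_data_error", ...)
}

abort_contract <- function(msg, ...) {
  rlang::abort(msg, class = "pleioscan_contract_error", ...)
}

#' Log-sum-exp
#'
#' Numerically stable `log(sum(exp(x)))`; `-Inf` elements contribute zero.
#' @param x numeric vector of log-scale values.
#' @return a single numeric value.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Parse p-values into natural-log representation
#'
#' Accepts numeric vectors or character vectors in plain or scientific
#' notation. Values such as `"1e-350"` that underflow a double are parsed from
#' the mantissa/exponent so their log is exact to double precision. Returns
#' `NA` for values that are missing, non-numeric, `<= 0`, or `> 1`.
#'
#' @param x numeric or character vector of p-values.
#' @return numeric vector of natural-log p-values (`NA` where unparseable).
#' @examples
#' parse_log_p(c("0.05", "1e-350", "NA"))
#' @export
parse_log_p <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(!is.na(x) & x > 0 & x <= 1, log(x), NA_real_)
    return(as.numeric(out))
  }
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  sci <- grepl("^[+-]?[0-9]*\\.?[0-9]+[eE][+-]?[0-9]+$", x)
  plain <- !sci & grepl("^[+-]?[0-9]*\\.?[0-9]+$", x)
  if (any(sci)) {
    mant <- as.numeric(sub("[eE].*$", "", x[sci]))
    expo <- as.numeric(sub("^.*[eE]", "", x[sci]))
    lp <- log(mant) + expo * log(10)
    lp[!(mant > 0) | lp > 0] <- NA_real_
    out[sci] <- lp
  }
  if (any(plain)) {
    v <- as.numeric(x[plain])
    out[plain] <- ifelse(v > 0 & v <= 1, log(v), NA_real_)
  }
  out
}

#' Format natural-log p-values for output
#'
#' Serializes p-values from their log representation. Values below double
#' underflow are printed in scientific notation (never as `0`).
#'
#' @param log_p numeric vector of natural-log p-values.
#' @param digits significant digits for the mantissa.
#' @return character vector.
#' @examples
#' format_log_p(c(log(0.05), -1000))
#' @export
format_log_p <- function(log_p, digits = 15L) {
  vapply(log_p, function(lp) {
    if (is.na(lp)) return(NA_character_)
    if (lp == -Inf) return("0e+00")  # true zero only by explicit request
    l10 <- lp / log(10)
    if (l10 > -300) {
      format(exp(lp), digits = digits, scientific = l10 < -4)
    } else {
      e <- floor(l10)
      m <- 10^(l10 - e)
      # guard against mantissa rounding to 10
      if (m >= 10 - 5e-16) {
        m <- m / 10
        e <- e + 1
      }
      sprintf("%.*ge%+03d", as.integer(digits), m, as.integer(e))
    }
  }, character(1))
}

# BH step-up and Bonferroni in log space, so adjusted values of p ~ 1e-200
# survive. m defaults to length(log_p) but can be overridden (e.g. to correct
# against a historical catalog-wide number of comparisons).
adjust_log_p <- function(log_p, m = length(log_p)) {
  n <- length(log_p)
  if (n == 0L) {
    return(tibble::tibble(log_p = numeric(), log_p_bh = numeric(),
                          log_p_bonferroni = numeric()))
  }
  if (m < n) abort_contract("`m` must be at least the number of p-values.")
  ord <- order(log_p)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  bh <- log_p + log(m) - log(ranks)
  # enforce step-up monotonicity: cumulative min from the largest p downwards
  bh_sorted <- bh[ord]
  bh_sorted <- rev(cummin(rev(bh_sorted)))
  bh[ord] <- bh_sorted
  bh <- pmin(bh, 0)
  bonf <- pmin(log_p + log(m), 0)
  tibble::tibble(log_p = log_p, log_p_bh = bh, log_p_bonferroni = bonf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
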