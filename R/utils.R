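# shared internal helpers

# round half away from zero at d decimals (presentation rounding for posteriors
# and percentages; base round() is round-half-even)
round_half_up <- function(x, d = 3) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_fertscreen <- function(..., class = "fertscreen_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

fmt_pct <- function(num, den, d = 2) {
  sprintf(paste0("%.", d, "f%% (%d/%d)"), round_half_up(100 * num / den, d), num, den)
}

#' Numerator/denominator rate summary
#'
#' Container used throughout the package for rates that must stay auditable as
#' count pairs (carrier frequencies, fertilization rates, detachment rates, ...).
#' The percentage is presentation only; comparisons and tests always use the
#' counts.
#'
#' @param numerator,denominator Non-negative integer counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @param label Short description of what is being counted.
#' @return An object of class `"rate_summary"` with fields `numerator`,
#'   `denominator`, `rate` (fraction) and `label`.
#' @examples
#' rate_summary(16, 55, "PLCZ1 carriers")
#' @export
rate_summary <- function(numerator, denominator, label = "") {
  if (!is_count(numerator) || !is_count(denominator)) {
    stop_fertscreen("rate_summary needs non-negative integer counts")
  }
  if (denominator == 0) stop_fertscreen("rate_summary: zero denominator")
  if (numerator > denominator) {
    stop_fertscreen("rate_summary: numerator exceeds denominator (", numerator,
                    "/", denominator, ")")
  }
  structure(
    list(numerator = as.integer(numerator), denominator = as.integer(denominator),
         rate = numerator / denominator, label = label),
    class = "rate_summary"
  )
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(if (nzchar(x$label)) paste0(x$label, ": ") else "",
      fmt_pct(x$numerator, x$denominator), "\n", sep = "")
  invisible(x)
}

#' @export
format.rate_summary <- function(x, ...) fmt_pct(x$numerator, x$denominator)
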