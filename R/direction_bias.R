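#' Tally direction calls by event type
#'
#' Counts, per event type, how many significant calls point in the
#' canonical drug direction: skipping for SE, retention for RI.
#'
#' @param calls output of [call_dysregulated()] (must carry a `direction`
#'   column).
#' @param comparison optional label copied to the output.
#' @return data.frame with one row per event type: `event_type`,
#'   `n_toward`, `n_total`, `comparison`.
#' @export
tabulate_directions <- function(calls, comparison = "") {
  if (nrow(calls) > 0 &&
      (is.null(calls$direction) || anyNA(calls$direction)))
    .stopf("calls must carry direction labels")
  out <- data.frame(event_type = c("SE", "RI"),
                    n_toward = c(sum(calls$event_type == "SE" &
                                       calls$direction == "more-skipped"),
                                 sum(calls$event_type == "RI" &
                                       calls$direction == "more-retained")),
                    n_total = c(sum(calls$event_type == "SE"),
                                sum(calls$event_type == "RI")),
                    comparison = comparison, stringsAsFactors = FALSE)
  out
}

#' One-sided exact binomial direction test
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim Binomial(n, 1/2)}, computed by log-space summation of the
#' binomial PMF (no normal approximation). Tests whether significant calls
#' are skewed toward one direction beyond a fair coin.
#'
#' @param n_toward observed calls in the hypothesized direction.
#' @param n_total all calls (>= 1).
#' @param alternative `"greater"` (default, one-sided as published) or
#'   `"two.sided"` (doubled smaller tail, capped at 1).
#' @return The p value.
#' @export
binomial_direction_test <- function(n_toward, n_total,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_total < 1 || n_toward < 0 || n_toward > n_total ||
      n_toward != round(n_toward) || n_total != round(n_total))
    .stopf("invalid counts: need 0 <= n_toward <= n_total, n_total >= 1")
  upper_tail <- function(k, n) {
    if (k <= 0) return(1)
    exp(.logsumexp(lchoose(n, k:n) - n * log(2)))
  }
  p_up <- min(1, upper_tail(n_toward, n_total))
  if (alternative == "greater") return(p_up)
  p_down <- min(1, upper_tail(n_total - n_toward, n_total))
  min(1, 2 * min(p_up, p_down))
}

#' Direction-bias summary for a comparison
#'
#' Tallies calls by event type and attaches the one-sided exact binomial
#' p value per type.
#'
#' @param calls output of [call_dysregulated()].
#' @param comparison label for the output.
#' @return data.frame with `event_type`, `n_toward`, `n_total`, `p_value`.
#' @export
direction_bias_test <- function(calls, comparison = "") {
  tal <- tabulate_directions(calls, comparison)
  tal$p_value <- vapply(seq_len(nrow(tal)), function(i)
    if (tal$n_total[i] >= 1)
      binomial_direction_test(tal$n_toward[i], tal$n_total[i]) else NA_real_,
    numeric(1))
  tal
}
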