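#' Two-group beta-binomial likelihood-ratio test for one event
#'
#' Fits inclusion counts of both replicate groups with a beta-binomial model
#' sharing one overdispersion parameter. The alternative allows each group
#' its own mean; the null constrains the means equal. The statistic
#' \eqn{2(\ell_{alt}-\ell_{null})} is referred to a chi-square with 1 df
#' (the dispersion is profiled, not tested). `delta_psi` is the difference
#' of per-replicate PSI means, group A minus group B, before any
#' orientation convention is applied (see [orient_delta()]).
#'
#' @param inclusionA,skippingA,inclusionB,skippingB per-replicate integer
#'   count vectors.
#' @param inc_norm,skip_norm effective junction counts used for PSI.
#' @param rho fixed overdispersion, typically the pooled estimate of
#'   [estimate_common_rho()]. When `NULL` (standalone use) rho is profiled
#'   per event under each model; the pooled route is better calibrated at
#'   few replicates and is what [compare_conditions()] uses.
#' @return List with `delta_psi`, `lrt_statistic`, `p_value` (`NA` when a
#'   group has fewer than two replicates with informative reads).
#' @export
betabinomial_lrt <- function(inclusionA, skippingA, inclusionB, skippingB,
                             inc_norm = 1L, skip_norm = 1L, rho = NULL) {
  totA <- inclusionA + skippingA
  totB <- inclusionB + skippingB
  okA <- totA > 0; okB <- totB > 0
  psiA <- compute_psi(inclusionA[okA], skippingA[okA], inc_norm, skip_norm)
  psiB <- compute_psi(inclusionB[okB], skippingB[okB], inc_norm, skip_norm)
  dpsi <- if (any(okA) && any(okB)) mean(psiA) - mean(psiB) else NA_real_
  if (sum(okA) < 2 || sum(okB) < 2)
    return(list(delta_psi = dpsi, lrt_statistic = NA_real_,
                p_value = NA_real_))
  kA <- inclusionA[okA]; nA <- totA[okA]
  kB <- inclusionB[okB]; nB <- totB[okB]
  k <- c(kA, kB); n <- c(nA, nB)
  g <- c(rep("A", length(kA)), rep("B", length(kB)))
  if (is.null(rho)) {
    ll1 <- .bb_profile_rho(k, n, g)$loglik
    ll0 <- .bb_profile_rho(k, n, rep("0", length(k)))$loglik
  } else {
    ll1 <- .bb_groups_loglik(k, n, g, rho)
    ll0 <- .bb_groups_loglik(k, n, rep("0", length(k)), rho)
  }
  stat <- max(0, 2 * (ll1 - ll0))
  list(delta_psi = dpsi, lrt_statistic = stat,
       p_value = max(stats::pchisq(stat, df = 1, lower.tail = FALSE),
                     .Machine$double.xmin))
}

#' Apply a reporting orientation to a raw PSI difference
#'
#' Raw differences are computed as group A minus group B with A the
#' first-named (perturbed) condition. Published convention reports
#' baseline-minus-perturbed, so that a positive value means the event was
#' spliced in more often in the baseline (e.g. vehicle) samples — i.e.
#' perturbation-induced skipping is positive.
#'
#' @param delta_psi_raw numeric, \eqn{\Psi_A - \Psi_B}.
#' @param orientation `"B_minus_A"` (default; baseline-minus-perturbed) or
#'   `"A_minus_B"`.
#' @return Oriented delta PSI with an `orientation` attribute.
#' @export
orient_delta <- function(delta_psi_raw, orientation = c("B_minus_A", "A_minus_B")) {
  orientation <- match.arg(orientation)
  out <- if (orientation == "B_minus_A") -delta_psi_raw else delta_psi_raw
  attr(out, "orientation") <- orientation
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled step-up procedure: with m non-missing p values and
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value is
#' \eqn{\min_{j \ge i} (m/j) p_{(j)}}, capped at 1. Missing entries are
#' excluded from m and stay missing.
#'
#' @param p_values numeric vector with entries in (0, 1\] or `NA`.
#' @return Adjusted FDR vector of the same length.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p <= 0 | p > 1)) .stopf("p values must be in (0,1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m == 0) return(out)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * (m / (m:1))))
  out[ok] <- q[order(o)]
  out
}

#' Re-adjust FDR on the events passing a filter
#'
#' Post-filter multiple-testing: BH is recomputed on exactly the surviving
#' subset; discarded events are dropped (they carry no FDR).
#'
#' @param results data.frame with at least `event_id` and `p_value`.
#' @param keep logical vector over rows (or character event ids) defining
#'   the filter.
#' @return The surviving rows with a recomputed `fdr` column.
#' @export
filter_then_readjust <- function(results, keep) {
  if (is.character(keep)) keep <- results$event_id %in% keep
  out <- results[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no events pass the filter; empty result")
    out$fdr <- numeric(0)
    return(out)
  }
  out$fdr <- bh_adjust(out$p_value)
  out
}

#' Run the beta-binomial test for every event between two conditions
#'
#' @param table a `JunctionCountTable` (usually pre-filtered with
#'   [filter_expressed()]).
#' @param condition_a,condition_b condition labels; `condition_a` is the
#'   perturbed condition, `condition_b` the baseline.
#' @param orientation passed to [orient_delta()]; the default reports
#'   baseline-minus-perturbed.
#' @param readjust if `TRUE` (default) BH-adjust p values over the tested
#'   (non-missing) events.
#' @param rho fixed overdispersion; by default pooled across events with
#'   [estimate_common_rho()] from the two compared groups.
#' @return data.frame of class `ComparisonResult` with columns `event_id`,
#'   `event_type`, `delta_psi` (oriented), `lrt_statistic`, `p_value`,
#'   `fdr`, `orientation`, `comparison`.
#' @export
compare_conditions <- function(table, condition_a, condition_b,
                               orientation = "B_minus_A", readjust = TRUE,
                               rho = NULL) {
  sa <- table$samples$condition == condition_a
  sb <- table$samples$condition == condition_b
  if (!any(sa) || !any(sb)) .stopf("empty condition in comparison")
  ne <- nrow(table$events)
  if (is.null(rho)) {
    use <- sa | sb
    rho <- estimate_common_rho(table$inclusion[, use, drop = FALSE],
                               table$skipping[, use, drop = FALSE],
                               table$samples$condition[use])
  }
  dpsi <- stat <- pval <- rep(NA_real_, ne)
  for (i in seq_len(ne)) {
    r <- betabinomial_lrt(table$inclusion[i, sa], table$skipping[i, sa],
                          table$inclusion[i, sb], table$skipping[i, sb],
                          table$events$inc_junction_count[i],
                          table$events$skip_junction_count[i], rho = rho)
    dpsi[i] <- r$delta_psi; stat[i] <- r$lrt_statistic; pval[i] <- r$p_value
  }
  res <- data.frame(
    event_id = table$events$event_id,
    event_type = table$events$event_type,
    delta_psi = as.numeric(orient_delta(dpsi, orientation)),
    lrt_statistic = stat, p_value = pval,
    fdr = if (readjust) bh_adjust(pval) else NA_real_,
    orientation = orientation,
    comparison = paste0(condition_a, "_vs_", condition_b),
    stringsAsFactors = FALSE)
  class(res) <- c("ComparisonResult", "data.frame")
  res
}

#' Call dysregulated events at FDR and |delta PSI| thresholds
#'
#' Strict inequalities on both criteria: `fdr < fdr_max` and
#' `|delta_psi| > min_abs_dpsi`. Each call is labelled by direction under
#' the baseline-minus-perturbed orientation: for SE, positive delta PSI is
#' `more-skipped`; for RI, negative delta PSI (more retention in the
#' perturbed samples) is `more-retained`.
#'
#' Presets: human CD34+ analysis used FDR < 0.05 and |dPSI| > 0.10; the
#' mouse bone-marrow analysis FDR < 0.10 and |dPSI| > 0.01.
#'
#' @param results a `ComparisonResult` data.frame.
#' @param fdr_max,min_abs_dpsi thresholds in (0,1).
#' @return The called subset with a `direction` label column.
#' @export
call_dysregulated <- function(results, fdr_max = 0.05, min_abs_dpsi = 0.10) {
  if (fdr_max <= 0 || fdr_max >= 1 || min_abs_dpsi < 0 || min_abs_dpsi >= 1)
    .stopf("thresholds out of range")
  ok <- !is.na(results$fdr) & results$fdr < fdr_max &
    !is.na(results$delta_psi) & abs(results$delta_psi) > min_abs_dpsi
  out <- results[ok, , drop = FALSE]
  out$direction <- ifelse(out$event_type == "SE",
                          ifelse(out$delta_psi > 0, "more-skipped", "more-included"),
                          ifelse(out$delta_psi < 0, "more-retained", "more-removed"))
  out
}

#' Threshold presets for dysregulation calling
#' @param preset `"human-cd34"` (FDR < 0.05, |dPSI| > 0.10) or `"mouse-bm"`
#'   (FDR < 0.10, |dPSI| > 0.01).
#' @return List with `fdr_max` and `min_abs_dpsi`.
#' @export
threshold_preset <- function(preset = c("human-cd34", "mouse-bm")) {
  preset <- match.arg(preset)
  switch(preset,
         "human-cd34" = list(fdr_max = 0.05, min_abs_dpsi = 0.10),
         "mouse-bm" = list(fdr_max = 0.10, min_abs_dpsi = 0.01))
}
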