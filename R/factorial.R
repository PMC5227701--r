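#' Validate a 2x2 factorial design
#'
#' @param samples data.frame with `sample_id`, `genotype` (WT/MT),
#'   `treatment` (Veh/Drug).
#' @param min_per_cell minimum samples per cell (default 2, required for
#'   replicate-aware testing).
#' @return The samples data.frame with a `condition` column, class
#'   `FactorialDesign`.
#' @export
factorial_design <- function(samples, min_per_cell = 2) {
  samples$condition <- paste(samples$genotype, samples$treatment, sep = ".")
  tab <- table(factor(samples$condition, levels = condition_levels()))
  if (any(tab < min_per_cell))
    .stopf("incomplete factorial design: cell(s) %s have < %d samples",
           paste(names(tab)[tab < min_per_cell], collapse = ", "), min_per_cell)
  class(samples) <- c("FactorialDesign", "data.frame")
  samples
}

# the five comparisons: (perturbed A, baseline B, label)
.five_comparisons <- function() list(
  drug_in_WT = c(A = "WT.Drug", B = "WT.Veh"),
  drug_in_MT = c(A = "MT.Drug", B = "MT.Veh"),
  mut_in_Veh = c(A = "MT.Veh", B = "WT.Veh"),
  mut_in_Drug = c(A = "MT.Drug", B = "WT.Drug"),
  cumulative = c(A = "MT.Drug", B = "WT.Veh"))

#' Run the five factorial delta-PSI comparisons
#'
#' The four context-restricted comparisons — drug vs vehicle within each
#' genotype and mutant vs WT within each treatment — plus the cumulative
#' comparison (MT,Drug) vs (WT,Veh). Each comparison is tested per event
#' with [betabinomial_lrt()] and BH-adjusted separately within the
#' comparison. All delta PSI values are reported baseline-minus-perturbed
#' (skipping-positive), so the cumulative effect decomposes exactly as
#' dPSI(cumulative) = dPSI(mut|Veh) + dPSI(drug|MT)
#'                  = dPSI(drug|WT) + dPSI(mut|Drug).
#'
#' @param table a `JunctionCountTable` whose samples cover all four cells.
#' @return List of class `FiveComparisonSet`: five `ComparisonResult`
#'   data.frames (named `drug_in_WT`, `drug_in_MT`, `mut_in_Veh`,
#'   `mut_in_Drug`, `cumulative`) plus `psi_means` (events x 4 condition
#'   means).
#' @export
run_five_comparisons <- function(table) {
  tab <- table(factor(table$samples$condition, levels = condition_levels()))
  if (any(tab == 0)) .stopf("missing factorial cell: %s",
                            paste(names(tab)[tab == 0], collapse = ", "))
  # one pooled overdispersion for all five comparisons, estimated on the
  # four-cell means model
  rho <- estimate_common_rho(table$inclusion, table$skipping,
                             table$samples$condition)
  cmp <- lapply(.five_comparisons(), function(ab)
    compare_conditions(table, ab[["A"]], ab[["B"]], rho = rho))
  structure(c(cmp, list(psi_means = condition_psi_means(table))),
            class = "FiveComparisonSet")
}

#' Cumulative delta PSI from the four condition means
#'
#' The cumulative effect of mutation plus drug relative to the WT, vehicle
#' baseline, on the skipping-positive orientation:
#' \eqn{\Delta\Psi_{cum} = \Psi(WT,Veh) - \Psi(MT,Drug)}. It equals the sum
#' of either decomposition path of context comparisons exactly.
#'
#' @param psi_means numeric vector or matrix with names/colnames
#'   `WT.Veh`, `WT.Drug`, `MT.Veh`, `MT.Drug`.
#' @return Cumulative delta PSI (`NA` where a mean is missing).
#' @export
cumulative_delta <- function(psi_means) {
  if (is.matrix(psi_means) || is.data.frame(psi_means))
    return(psi_means[, "WT.Veh"] - psi_means[, "MT.Drug"])
  psi_means[["WT.Veh"]] - psi_means[["MT.Drug"]]
}

#' Concordance regression of perturbation effects across genotypes
#'
#' Ordinary least squares of the drug effect in mutant cells on the drug
#' effect in WT cells (or any two matched effect vectors), over events
#' significant in both comparisons. Reports the slope (attenuation), R
#' squared and the overall F-test p value.
#'
#' @param effect_wt,effect_mt matched numeric vectors (e.g. delta PSI or
#'   log2 fold changes).
#' @param through_origin force a no-intercept fit (default `FALSE`).
#' @return List of class `ConcordanceResult`: `slope`, `intercept`,
#'   `r_squared`, `f_test_p`, `n_events`.
#' @export
concordance_regression <- function(effect_wt, effect_mt,
                                   through_origin = FALSE) {
  ok <- is.finite(effect_wt) & is.finite(effect_mt)
  x <- effect_wt[ok]; y <- effect_mt[ok]
  if (length(x) < 3) .stopf("need >= 3 events for concordance regression")
  if (stats::sd(x) < 1e-12) .stopf("degenerate (zero-variance) predictor")
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  # suppress the "essentially perfect fit" warning on degenerate exact input
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  structure(list(
    slope = unname(stats::coef(fit)[["x"]]),
    intercept = if (through_origin) 0 else unname(stats::coef(fit)[[1]]),
    r_squared = sm$r.squared,
    f_test_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                lower.tail = FALSE)),
    n_events = length(x)), class = "ConcordanceResult")
}

#' Drug/mutation interaction test on the logit-PSI scale
#'
#' Beta-binomial regression of inclusion counts on genotype and treatment
#' with logit link and shared overdispersion, comparing the additive model
#' (mut + drug) with the model adding a mut:drug product term, by
#' likelihood ratio (chi-square, 1 df). A positive interaction coefficient
#' on logit PSI means super-additive inclusion (the sign separates synergy
#' from antagonism relative to the additive expectation).
#'
#' @param inclusion,skipping per-sample integer count vectors for one event.
#' @param is_mut,is_drug 0/1 sample indicators.
#' @param rho fixed overdispersion, typically pooled across events with
#'   [estimate_common_rho()]; `NULL` profiles it per event on the
#'   cell-means model.
#' @return List with `p_value`, `effect_sign`, `lrt_statistic`,
#'   `interaction_coef` (`NA` on degenerate input).
#' @export
interaction_lrt <- function(inclusion, skipping, is_mut, is_drug,
                            rho = NULL) {
  tot <- inclusion + skipping
  ok <- tot > 0
  cells <- paste(is_mut, is_drug)
  if (length(unique(cells[ok])) < 4 || sum(ok) < 5)
    return(list(p_value = NA_real_, effect_sign = NA_real_,
                lrt_statistic = NA_real_, interaction_coef = NA_real_))
  k <- inclusion[ok]; n <- tot[ok]
  m <- is_mut[ok]; d <- is_drug[ok]
  if (is.null(rho)) rho <- .bb_profile_rho(k, n, cells[ok])$rho
  # the interaction model is the saturated cell-means model: its profile
  # splits by cell, and the interaction coefficient is the logit-scale
  # difference-of-differences of the fitted cell means
  mus <- numeric(0)
  ll1 <- 0
  for (cl in c("0 0", "0 1", "1 0", "1 1")) {
    i <- cells[ok] == cl
    f <- .bb_profile_mu(k[i], n[i], rho)
    ll1 <- ll1 + f$loglik
    mus[cl] <- .clamp(f$mu, 1e-9, 1 - 1e-9)
  }
  b_int <- stats::qlogis(mus[["1 1"]]) - stats::qlogis(mus[["1 0"]]) -
    stats::qlogis(mus[["0 1"]]) + stats::qlogis(mus[["0 0"]])
  # additive null: 3 coefficients at fixed rho
  nll0 <- function(b) {
    mu <- stats::plogis(b[1] + b[2] * m + b[3] * d)
    -.bb_loglik(k, n, mu, rho)
  }
  b_start <- c(stats::qlogis(mus[["0 0"]]),
               stats::qlogis(mus[["1 0"]]) - stats::qlogis(mus[["0 0"]]),
               stats::qlogis(mus[["0 1"]]) - stats::qlogis(mus[["0 0"]]))
  fit0 <- stats::optim(b_start, nll0, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
  fit0b <- stats::optim(fit0$par, nll0, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
  ll0 <- -min(fit0$value, fit0b$value)
  stat <- max(0, 2 * (ll1 - ll0))
  list(p_value = max(stats::pchisq(stat, df = 1, lower.tail = FALSE),
                     .Machine$double.xmin),
       effect_sign = unname(sign(b_int)),
       lrt_statistic = stat,
       interaction_coef = unname(b_int))
}

#' Interaction screen over all events
#'
#' Runs [interaction_lrt()] per event and BH-adjusts the resulting p values.
#'
#' @param table a `JunctionCountTable` covering all four cells.
#' @return data.frame with `event_id`, `p_value`, `fdr`, `effect_sign`,
#'   `interaction_coef`.
#' @export
interaction_screen <- function(table) {
  im <- as.integer(table$samples$genotype == "MT")
  id <- as.integer(table$samples$treatment == "Drug")
  rho <- estimate_common_rho(table$inclusion, table$skipping,
                             table$samples$condition)
  ne <- nrow(table$events)
  p <- sgn <- coefi <- rep(NA_real_, ne)
  for (i in seq_len(ne)) {
    r <- interaction_lrt(table$inclusion[i, ], table$skipping[i, ], im, id,
                         rho = rho)
    p[i] <- r$p_value; sgn[i] <- r$effect_sign; coefi[i] <- r$interaction_coef
  }
  data.frame(event_id = table$events$event_id, p_value = p,
             fdr = bh_adjust(p), effect_sign = sgn,
             interaction_coef = coefi, stringsAsFactors = FALSE)
}

#' Classify events from the five comparisons
#'
#' Labels, per event: `drug_concordant` — the drug effect passes thresholds
#' in both genotypes with the same sign; `drug_discordant` — passes in both
#' with opposite signs; `cumulative_exacerbated` — drug-concordant and
#' |cumulative dPSI| exceeds |dPSI(drug|WT)|; `trajectory_eligible` — all
#' five comparisons pass (strict inequalities); `interaction_significant` —
#' from the interaction screen at `interaction_fdr_max`.
#'
#' @param five a `FiveComparisonSet`.
#' @param fdr_max,min_abs_dpsi per-comparison thresholds (mouse preset
#'   defaults: 0.10 and 0.01).
#' @param interactions optional result of [interaction_screen()].
#' @param interaction_fdr_max FDR threshold for interaction calls (0.10).
#' @return data.frame, one row per event, with logical label columns and
#'   the five oriented delta PSI values.
#' @export
classify_events <- function(five, fdr_max = 0.10, min_abs_dpsi = 0.01,
                            interactions = NULL, interaction_fdr_max = 0.10) {
  stopifnot(inherits(five, "FiveComparisonSet"))
  pass <- function(r) !is.na(r$fdr) & r$fdr < fdr_max &
    !is.na(r$delta_psi) & abs(r$delta_psi) > min_abs_dpsi
  dW <- five$drug_in_WT; dM <- five$drug_in_MT
  both <- pass(dW) & pass(dM)
  same_sign <- sign(dW$delta_psi) == sign(dM$delta_psi)
  cum <- five$cumulative
  out <- data.frame(
    event_id = dW$event_id,
    event_type = dW$event_type,
    dpsi_drug_WT = dW$delta_psi, dpsi_drug_MT = dM$delta_psi,
    dpsi_mut_Veh = five$mut_in_Veh$delta_psi,
    dpsi_mut_Drug = five$mut_in_Drug$delta_psi,
    dpsi_cumulative = cum$delta_psi,
    drug_concordant = both & same_sign,
    drug_discordant = both & !same_sign,
    cumulative_exacerbated = both & same_sign &
      abs(cum$delta_psi) > abs(dW$delta_psi),
    trajectory_eligible = pass(dW) & pass(dM) & pass(five$mut_in_Veh) &
      pass(five$mut_in_Drug) & pass(cum),
    stringsAsFactors = FALSE)
  if (!is.null(interactions)) {
    m <- match(out$event_id, interactions$event_id)
    out$interaction_significant <- !is.na(interactions$fdr[m]) &
      interactions$fdr[m] < interaction_fdr_max
    out$interaction_sign <- interactions$effect_sign[m]
  }
  out
}

#' Per-event trajectory relative to the WT, vehicle baseline
#'
#' For each eligible event, the delta PSI of every condition relative to
#' (WT,Veh) on the skipping-positive orientation:
#' baseline 0, then \eqn{\Psi(WT,Veh) - \Psi(cond)} for the other cells.
#' Events are split by the sign of the cumulative effect (increased
#' skipping vs increased inclusion).
#'
#' @param five a `FiveComparisonSet`.
#' @param eligible character event ids (typically the
#'   `trajectory_eligible` calls from [classify_events()]).
#' @return data.frame with columns `event_id`, `WT.Veh` (all 0), `WT.Drug`,
#'   `MT.Veh`, `MT.Drug`, `group` (`"skipping"`/`"inclusion"`).
#' @export
trajectory_table <- function(five, eligible) {
  stopifnot(inherits(five, "FiveComparisonSet"))
  pm <- five$psi_means
  idx <- match(eligible, rownames(pm))
  base <- pm[idx, "WT.Veh"]
  out <- data.frame(
    event_id = eligible,
    WT.Veh = 0,
    WT.Drug = base - pm[idx, "WT.Drug"],
    MT.Veh = base - pm[idx, "MT.Veh"],
    MT.Drug = base - pm[idx, "MT.Drug"],
    stringsAsFactors = FALSE)
  out$group <- ifelse(out$MT.Drug >= 0, "skipping", "inclusion")
  out
}
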