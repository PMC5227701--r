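#' Configuration for the factorial splicing/expression simulator
#'
#' Builds and validates the generative model's parameters. Defaults emulate a
#' five-replicate-per-condition bone-marrow experiment: 4,000 events (80%
#' skipped exon, 20% retained intron), 1,000 genes, negative-binomial event
#' coverage with mean 60, beta-binomial replicate overdispersion, logit-scale
#' additive mutation and drug effects with a minority of interacting events,
#' a drug-effect bias toward exon skipping / intron retention, and a T/C
#' dichotomy at the -3 intronic acceptor position for mutation-sensitive
#' exons.
#'
#' @param n_events,n_genes positive integers.
#' @param replicates_per_condition integer >= 2 (default 5).
#' @param baseline_psi_alpha,baseline_psi_beta beta prior on the baseline PSI.
#' @param frac_mut_sensitive,frac_drug_sensitive,frac_interacting proportions
#'   in \[0,1\]; `frac_interacting` must not exceed the smaller sensitivity
#'   fraction (interacting events are both mutation- and drug-sensitive).
#' @param beta_mut,beta_drug,beta_int logit-scale effect magnitudes; per-event
#'   magnitudes are jittered uniformly within 50--150% and signs drawn per
#'   event (see `skip_bias_drug`).
#' @param skip_bias_drug probability that a drug-sensitive event's effect is
#'   in the canonical drug direction (more skipping for SE, more retention
#'   for RI); default 0.6, matching an observed 388/657 skipping skew.
#' @param coverage_mean,coverage_dispersion negative-binomial total-count
#'   model per event per sample (variance = mu + dispersion * mu^2).
#' @param bb_overdispersion beta-binomial intra-class correlation in \[0,1).
#' @param expr_log2fc_mut,expr_log2fc_drug gene-level effect magnitudes.
#' @param frac_de_genes proportion of genes differentially expressed per
#'   factor.
#' @param nb_gene_dispersion gene-level negative-binomial dispersion.
#' @param motif_t_minus3_sensitive,motif_t_minus3_background probability of a
#'   T at the -3 acceptor position for mutation-sensitive vs other events.
#' @param context_window integer pair (intronic length, exonic length) of the
#'   acceptor context window.
#' @param frac_se proportion of events that are skipped exons.
#' @param seed integer RNG seed.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_events = 4000, n_genes = 1000,
                              replicates_per_condition = 5,
                              baseline_psi_alpha = 2, baseline_psi_beta = 2,
                              frac_mut_sensitive = 0.15,
                              frac_drug_sensitive = 0.15,
                              frac_interacting = 0.01,
                              beta_mut = 1.5, beta_drug = 1.5, beta_int = 1.5,
                              skip_bias_drug = 0.6,
                              coverage_mean = 60, coverage_dispersion = 0.15,
                              bb_overdispersion = 0.05,
                              expr_log2fc_mut = 2, expr_log2fc_drug = 2,
                              frac_de_genes = 0.1, nb_gene_dispersion = 0.05,
                              motif_t_minus3_sensitive = 0.8,
                              motif_t_minus3_background = 0.25,
                              context_window = c(20L, 3L),
                              frac_se = 0.8, seed = 1L) {
  cfg <- as.list(environment())
  props <- c("frac_mut_sensitive", "frac_drug_sensitive", "frac_interacting",
             "skip_bias_drug", "frac_de_genes", "frac_se",
             "motif_t_minus3_sensitive", "motif_t_minus3_background")
  for (p in props)
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      .stopf("invalid parameter: %s must be in [0,1]", p)
  if (frac_interacting > min(frac_mut_sensitive, frac_drug_sensitive))
    .stopf("invalid parameter: frac_interacting exceeds min(frac_mut_sensitive, frac_drug_sensitive)")
  if (n_events < 1 || n_genes < 1) .stopf("invalid parameter: need >= 1 events and genes")
  if (replicates_per_condition < 2)
    .stopf("invalid parameter: replicates_per_condition must be >= 2")
  if (coverage_mean <= 0 || coverage_dispersion <= 0 || nb_gene_dispersion <= 0)
    .stopf("invalid parameter: coverage and dispersion parameters must be > 0")
  if (baseline_psi_alpha <= 0 || baseline_psi_beta <= 0)
    .stopf("invalid parameter: beta prior parameters must be > 0")
  if (bb_overdispersion < 0 || bb_overdispersion >= 1)
    .stopf("invalid parameter: bb_overdispersion must be in [0,1)")
  for (p in c("beta_mut", "beta_drug", "beta_int", "expr_log2fc_mut", "expr_log2fc_drug"))
    if (!is.finite(cfg[[p]])) .stopf("invalid parameter: %s must be finite", p)
  if (length(context_window) != 2 || any(context_window < 1))
    .stopf("invalid parameter: context_window must be two positive lengths")
  cfg$context_window <- as.integer(context_window)
  structure(cfg, class = "SimulationConfig")
}

#' Condition-level true PSI under the logit-additive model
#'
#' \eqn{\Psi = \mathrm{logit}^{-1}(\beta_0 + \beta_{mut} m + \beta_{drug} d +
#' \beta_{int} m d)} for genotype indicator \eqn{m} and treatment indicator
#' \eqn{d}. With `beta_int = 0` the mutation and drug effects are exactly
#' additive on the logit scale.
#'
#' @param beta0,beta_mut,beta_drug,beta_int finite reals (vectorized).
#' @param is_mut,is_drug 0/1 indicators.
#' @return PSI in \[0,1\].
#' @export
logit_psi_model <- function(beta0, beta_mut, beta_drug, beta_int,
                            is_mut, is_drug) {
  if (!all(is.finite(c(beta0, beta_mut, beta_drug, beta_int))))
    .stopf("invalid parameter: coefficients must be finite")
  stats::plogis(beta0 + beta_mut * is_mut + beta_drug * is_drug +
                  beta_int * is_mut * is_drug)
}

#' Draw beta-binomial inclusion/skipping counts
#'
#' Inclusion ~ beta-binomial(total, psi, rho) where `rho` is the intra-class
#' correlation; `rho = 0` degenerates to a plain binomial. Skipping is the
#' complement, so inclusion + skipping = total always.
#'
#' @param psi success probability in \[0,1\] (vectorized).
#' @param total non-negative integer totals.
#' @param rho overdispersion in \[0,1).
#' @return List with integer vectors `inclusion` and `skipping`.
#' @export
sample_event_counts <- function(psi, total, rho = 0) {
  if (any(rho < 0) || any(rho >= 1))
    .stopf("invalid parameter: rho must be in [0,1)")
  if (any(psi < 0) || any(psi > 1)) .stopf("invalid parameter: psi must be in [0,1]")
  if (any(total < 0)) .stopf("invalid parameter: total must be >= 0")
  n <- max(length(psi), length(total))
  psi <- rep_len(psi, n); total <- rep_len(total, n)
  if (all(rho == 0)) {
    p <- psi
  } else {
    a <- psi * (1 - rho) / rho
    b <- (1 - psi) * (1 - rho) / rho
    p <- ifelse(psi <= 0, 0, ifelse(psi >= 1, 1, stats::rbeta(n, a, b)))
    p[rho == 0] <- psi[rho == 0]
  }
  inc <- stats::rbinom(n, total, p)
  list(inclusion = inc, skipping = total - inc)
}

#' Draw one splice-acceptor context sequence
#'
#' Fixed-length sequence over \{A,C,G,T\} spanning `context_window[1]`
#' intronic and `context_window[2]` exonic bases around a 3' splice acceptor.
#' The canonical AG dinucleotide is planted at intronic positions -2,-1; the
#' -3 base is T with the sensitivity-dependent probability, otherwise drawn
#' uniformly from A/C/G; remaining positions are uniform background.
#'
#' @param is_mut_sensitive logical flag.
#' @param config a `SimulationConfig`.
#' @return Character string of length `sum(context_window)`.
#' @export
simulate_acceptor_sequence <- function(is_mut_sensitive, config) {
  iw <- config$context_window[1]; ew <- config$context_window[2]
  len <- iw + ew
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  p_t <- if (is_mut_sensitive) config$motif_t_minus3_sensitive
         else config$motif_t_minus3_background
  # intronic position -k maps to string index iw - k + 1
  if (iw >= 3)
    s[iw - 2] <- if (stats::runif(1) < p_t) "T" else sample(c("A", "C", "G"), 1)
  s[iw - 1] <- "A"
  s[iw] <- "G"
  paste(s, collapse = "")
}

#' Simulate a complete factorial splicing + expression dataset
#'
#' Generates, from a single RNG stream seeded by `config$seed`, (1) per-event
#' truth: baseline PSI, sensitivity flags, signed logit-scale coefficients;
#' (2) inclusion/skipping counts per sample with negative-binomial totals and
#' beta-binomial replicate noise, on the read scale implied by each event's
#' effective junction counts; (3) per-gene negative-binomial expression
#' counts with planted log2 fold changes and per-sample size factors; (4)
#' per-event 3' acceptor context sequences with the -3 T dichotomy.
#'
#' Draw order (fixed for reproducibility): event annotations, truth
#' coefficients, event totals, event counts, gene truth, gene counts,
#' acceptor sequences.
#'
#' @param config a `SimulationConfig`.
#' @return List of class `SyntheticDataset` with elements `junction_counts`
#'   (a `JunctionCountTable`), `gene_counts` (matrix), `samples`,
#'   `truth_events`, `truth_genes`, `size_factors_true`,
#'   `acceptor_sequences` (named character vector), `config`.
#' @export
simulate_factorial_experiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ne <- config$n_events; ng <- config$n_genes
  reps <- config$replicates_per_condition

  samples <- data.frame(
    sample_id = paste0(rep(c("WT_Veh", "WT_Drug", "MT_Veh", "MT_Drug"),
                           each = reps), "_", seq_len(reps)),
    genotype = rep(c("WT", "WT", "MT", "MT"), each = reps),
    treatment = rep(c("Veh", "Drug", "Veh", "Drug"), each = reps),
    stringsAsFactors = FALSE)
  is_mut <- as.integer(samples$genotype == "MT")
  is_drug <- as.integer(samples$treatment == "Drug")
  ns <- nrow(samples)

  # -- event annotations --------------------------------------------------
  ev_id <- sprintf("EV%05d", seq_len(ne))
  ev_type <- ifelse(stats::runif(ne) < config$frac_se, "SE", "RI")
  gene_of <- sample(ng, ne, replace = TRUE)
  strand <- sample(c("+", "-"), ne, replace = TRUE)
  # non-overlapping 1-kb slots on one synthetic chromosome
  slot <- (seq_len(ne) - 1L) * 1000L
  coord <- matrix(NA_integer_, ne, 4)
  se <- ev_type == "SE"
  coord[se, 1] <- slot[se] + 100L          # upstream exon end
  coord[se, 2] <- slot[se] + 300L          # cassette start
  coord[se, 3] <- slot[se] + 420L          # cassette end
  coord[se, 4] <- slot[se] + 700L          # downstream exon start
  coord[!se, 1] <- slot[!se] + 200L        # intron start
  coord[!se, 2] <- slot[!se] + 500L        # intron end
  events <- data.frame(
    event_id = ev_id, gene_id = sprintf("G%04d", gene_of),
    event_type = ev_type, chrom = "chrS",
    coord1 = coord[, 1], coord2 = coord[, 2],
    coord3 = coord[, 3], coord4 = coord[, 4],
    strand = strand,
    inc_junction_count = ifelse(se, 2L, 1L),
    skip_junction_count = 1L,
    stringsAsFactors = FALSE)

  # -- per-event truth ----------------------------------------------------
  psi0 <- .clamp(stats::rbeta(ne, config$baseline_psi_alpha,
                              config$baseline_psi_beta), 0.02, 0.98)
  beta0 <- stats::qlogis(psi0)
  interacting <- stats::runif(ne) < config$frac_interacting
  mut_sensitive <- (stats::runif(ne) < config$frac_mut_sensitive) | interacting
  drug_sensitive <- (stats::runif(ne) < config$frac_drug_sensitive) | interacting
  # canonical drug direction on PSI: SE -> skipping (PSI down), RI ->
  # retention (PSI up); drawn toward it with probability skip_bias_drug
  canon <- ifelse(se, -1, 1)
  toward <- stats::runif(ne) < config$skip_bias_drug
  sign_drug <- ifelse(toward, canon, -canon)
  sign_mut <- ifelse(stats::runif(ne) < 0.5, -1, 1)
  sign_int <- ifelse(stats::runif(ne) < 0.5, -1, 1)
  jit <- function() stats::runif(ne, 0.5, 1.5)
  b_mut <- ifelse(mut_sensitive, sign_mut * config$beta_mut * jit(), 0)
  b_drug <- ifelse(drug_sensitive, sign_drug * config$beta_drug * jit(), 0)
  b_int <- ifelse(interacting, sign_int * config$beta_int * jit(), 0)

  psi_true <- sapply(seq_len(ns), function(j)
    logit_psi_model(beta0, b_mut, b_drug, b_int, is_mut[j], is_drug[j]))

  # -- junction counts ----------------------------------------------------
  totals <- matrix(stats::rnbinom(ne * ns, mu = config$coverage_mean,
                                  size = 1 / config$coverage_dispersion),
                   ne, ns)
  # read-level inclusion probability given length normalization:
  # p = nI*psi / (nI*psi + nS*(1-psi)) so that compute_psi() recovers psi
  nI <- events$inc_junction_count; nS <- events$skip_junction_count
  p_read <- (nI * psi_true) / (nI * psi_true + nS * (1 - psi_true))
  inc <- matrix(0L, ne, ns)
  for (j in seq_len(ns)) {
    cts <- sample_event_counts(p_read[, j], totals[, j],
                               config$bb_overdispersion)
    inc[, j] <- cts$inclusion
  }
  skip <- totals - inc

  truth_events <- data.frame(
    event_id = ev_id, event_type = ev_type, psi_baseline = psi0,
    beta_mut = b_mut, beta_drug = b_drug, beta_int = b_int,
    mut_sensitive = mut_sensitive, drug_sensitive = drug_sensitive,
    interacting = interacting,
    drug_direction = ifelse(drug_sensitive,
                            ifelse(sign_drug == canon, "canonical", "reverse"),
                            "none"),
    stringsAsFactors = FALSE)
  cond <- paste(samples$genotype, samples$treatment, sep = ".")
  for (cc in condition_levels())
    truth_events[[paste0("psi_", cc)]] <- psi_true[, match(cc, cond)]

  # -- gene expression ----------------------------------------------------
  gene_id <- sprintf("G%04d", seq_len(ng))
  base_mean <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1)
  de_mut <- stats::runif(ng) < config$frac_de_genes
  de_drug <- stats::runif(ng) < config$frac_de_genes
  lfc_mut <- ifelse(de_mut, ifelse(stats::runif(ng) < 0.5, -1, 1) *
                      config$expr_log2fc_mut, 0)
  lfc_drug <- ifelse(de_drug, ifelse(stats::runif(ng) < 0.5, -1, 1) *
                       config$expr_log2fc_drug, 0)
  sf_true <- stats::runif(ns, 0.7, 1.4)
  mu_gene <- outer(base_mean, rep(1, ns)) *
    2^(outer(lfc_mut, is_mut) + outer(lfc_drug, is_drug))
  mu_gene <- sweep(mu_gene, 2, sf_true, `*`)
  gene_counts <- matrix(stats::rnbinom(ng * ns, mu = mu_gene,
                                       size = 1 / config$nb_gene_dispersion),
                        ng, ns, dimnames = list(gene_id, samples$sample_id))
  truth_genes <- data.frame(gene_id = gene_id, base_mean = base_mean,
                            log2fc_mut = lfc_mut, log2fc_drug = lfc_drug,
                            stringsAsFactors = FALSE)

  # -- acceptor contexts --------------------------------------------------
  seqs <- vapply(seq_len(ne), function(i)
    simulate_acceptor_sequence(mut_sensitive[i], config), character(1))
  names(seqs) <- ev_id

  structure(list(
    junction_counts = junction_count_table(events, samples, inc, skip),
    gene_counts = gene_counts, samples = samples,
    truth_events = truth_events, truth_genes = truth_genes,
    size_factors_true = stats::setNames(sf_true, samples$sample_id),
    acceptor_sequences = seqs, config = config),
    class = "SyntheticDataset")
}
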