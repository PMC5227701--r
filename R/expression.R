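#' Median-of-ratios size factors
#'
#' DESeq-style normalization: per sample, the median of count ratios to the
#' geometric-mean pseudo-reference, computed over genes with no zero count
#' in any sample.
#'
#' @param counts non-negative integer matrix (genes x samples).
#' @return Positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok))
    .stopf("no gene has nonzero counts in every sample; add a pseudocount upstream")
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(x) exp(stats::median(x - ref)))
  stats::setNames(sf, colnames(counts))
}

# IRLS fit of an NB GLM with log link, known dispersion, offset log(sf)
.nb_irls <- function(y, X, disp, offset, beta0 = NULL, maxit = 50) {
  if (is.null(beta0)) {
    mu0 <- mean(y) + 0.1
    beta0 <- c(log(mu0) - mean(offset), rep(0, ncol(X) - 1))
  }
  beta <- beta0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- .clamp(exp(eta), 1e-10, 1e12)
    w <- mu / (1 + disp * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    new <- fit$coefficients
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  eta <- drop(X %*% beta) + offset
  mu <- .clamp(exp(eta), 1e-10, 1e12)
  ll <- sum(stats::dnbinom(y, size = 1 / disp, mu = mu, log = TRUE))
  w <- mu / (1 + disp * mu)
  xtwx <- crossprod(X * sqrt(w))
  list(beta = beta, mu = mu, loglik = ll, xtwx = xtwx)
}

.DISP_FLOOR <- 1e-8

# Cox-Reid adjusted profile likelihood estimate of the NB dispersion under
# the full design, the small-sample correction used by the field's NB tools
.nb_dispersion_cr <- function(y, X, offset) {
  apl <- function(ldisp) {
    disp <- exp(ldisp)
    f <- .nb_irls(y, X, disp, offset)
    if (is.null(f)) return(-1e10)
    f$loglik - 0.5 * determinant(f$xtwx, logarithm = TRUE)$modulus[1]
  }
  opt <- stats::optimize(function(l) -apl(l), interval = c(log(.DISP_FLOOR), 4))
  max(exp(opt$minimum), .DISP_FLOOR)
}

#' Negative-binomial GLM test for one gene
#'
#' Simplified DESeq2-style analysis for a two-group contrast: NB GLM with
#' log link and size-factor offsets; per-gene dispersion estimated by
#' Cox-Reid adjusted profile likelihood under the full model (floor 1e-8,
#' no empirical-Bayes shrinkage across genes), then held fixed while the
#' full and reduced mean models are compared by likelihood ratio
#' (chi-square, 1 df).
#'
#' @param counts integer count vector over the samples of both groups.
#' @param group 0/1 indicator (1 = group A, the numerator of the fold
#'   change).
#' @param size_factors positive per-sample normalization factors.
#' @return List with `log2_fold_change`, `lrt_statistic`, `p_value`,
#'   `dispersion`, `base_mean` (`NA`s for all-zero or degenerate genes).
#' @export
nb_glm_gene_test <- function(counts, group, size_factors) {
  if (sum(group == 1) < 2 || sum(group == 0) < 2)
    .stopf("need >= 2 replicates per group")
  miss <- list(log2_fold_change = NA_real_, lrt_statistic = NA_real_,
               p_value = NA_real_, dispersion = NA_real_,
               base_mean = mean(counts / size_factors))
  if (all(counts == 0)) return(miss)
  offset <- log(size_factors)
  X1 <- cbind(1, group)
  X0 <- matrix(1, length(counts), 1)
  disp <- tryCatch(.nb_dispersion_cr(counts, X1, offset),
                   error = function(e) NA_real_)
  if (is.na(disp)) return(miss)
  f1 <- .nb_irls(counts, X1, disp, offset)
  f0 <- .nb_irls(counts, X0, disp, offset)
  if (is.null(f1) || is.null(f0)) return(miss)
  stat <- max(0, 2 * (f1$loglik - f0$loglik))
  list(log2_fold_change = f1$beta[2] / log(2),
       lrt_statistic = stat,
       p_value = max(stats::pchisq(stat, df = 1, lower.tail = FALSE),
                     .Machine$double.xmin),
       dispersion = disp,
       base_mean = mean(counts / size_factors))
}

#' Gene-level differential expression for one contrast
#'
#' Runs [nb_glm_gene_test()] for every gene between two conditions of the
#' factorial design and BH-adjusts the p values.
#'
#' @param counts genes x samples integer matrix.
#' @param samples sample sheet with `sample_id`, `genotype`, `treatment`.
#' @param condition_a,condition_b condition labels (`"WT.Drug"` etc.);
#'   `condition_a` is the fold-change numerator.
#' @param size_factors optional; estimated from all samples if missing.
#' @return data.frame of class `GeneDEResult`: `gene_id`, `base_mean`,
#'   `log2_fold_change`, `lrt_statistic`, `p_value`, `fdr`, `comparison`.
#' @export
de_contrast <- function(counts, samples, condition_a, condition_b,
                        size_factors = NULL) {
  cond <- paste(samples$genotype, samples$treatment, sep = ".")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  use <- cond %in% c(condition_a, condition_b)
  if (sum(cond == condition_a) < 2 || sum(cond == condition_b) < 2)
    .stopf("need >= 2 replicates per compared group")
  grp <- as.integer(cond[use] == condition_a)
  sf <- size_factors[use]
  cts <- counts[, use, drop = FALSE]
  res <- lapply(seq_len(nrow(cts)), function(i)
    nb_glm_gene_test(cts[i, ], grp, sf))
  out <- data.frame(
    gene_id = rownames(counts),
    base_mean = vapply(res, `[[`, numeric(1), "base_mean"),
    log2_fold_change = vapply(res, `[[`, numeric(1), "log2_fold_change"),
    lrt_statistic = vapply(res, `[[`, numeric(1), "lrt_statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out$comparison <- paste0(condition_a, "_vs_", condition_b)
  class(out) <- c("GeneDEResult", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' Strict thresholds, as published for the human analysis: FDR < 0.05 and
#' |log2 fold change| > 1.
#'
#' @param results a `GeneDEResult` data.frame.
#' @param fdr_max,min_abs_log2fc thresholds (strict inequalities).
#' @return Called subset with an `up`/`down` `direction` column.
#' @export
call_de_genes <- function(results, fdr_max = 0.05, min_abs_log2fc = 1) {
  ok <- !is.na(results$fdr) & results$fdr < fdr_max &
    !is.na(results$log2_fold_change) &
    abs(results$log2_fold_change) > min_abs_log2fc
  out <- results[ok, , drop = FALSE]
  out$direction <- ifelse(out$log2_fold_change > 0, "up", "down")
  out
}

#' Concordance of drug-induced expression changes across genotypes
#'
#' Shared implementation with [concordance_regression()]: OLS of the
#' mutant-genotype log2 fold changes on the WT ones over genes significant
#' in both drug contrasts.
#'
#' @param log2fc_wt,log2fc_mt matched numeric vectors.
#' @param through_origin force a no-intercept fit.
#' @return A `ConcordanceResult` (see [concordance_regression()]).
#' @export
expression_concordance <- function(log2fc_wt, log2fc_mt,
                                   through_origin = FALSE) {
  concordance_regression(log2fc_wt, log2fc_mt, through_origin)
}

#' Log-normalized expression matrix for heatmaps and PCA
#'
#' log2(count / size factor + 1); a plain stand-in for a regularized log
#' transform.
#'
#' @param counts genes x samples matrix.
#' @param size_factors optional, estimated if missing.
#' @return Numeric matrix.
#' @export
normalized_log_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  log2(sweep(as.matrix(counts), 2, size_factors, `/`) + 1)
}
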