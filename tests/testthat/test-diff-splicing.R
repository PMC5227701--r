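test_that("betabinomial_lrt: identical groups give zero signal", {
  inc <- c(12L, 18L, 15L, 20L, 10L); skp <- c(28L, 22L, 25L, 20L, 30L)
  r <- betabinomial_lrt(inc, skp, inc, skp)
  expect_equal(r$delta_psi, 0)
  expect_lte(r$lrt_statistic, 1e-6)
  expect_gt(r$p_value, 0.99)
})

test_that("betabinomial_lrt: antisymmetric delta, symmetric p, relabel-invariant", {
  set.seed(31)
  incA <- rbinom(5, 60, 0.7); skpA <- 60 - incA
  incB <- rbinom(5, 60, 0.4); skpB <- 60 - incB
  r1 <- betabinomial_lrt(incA, skpA, incB, skpB)
  r2 <- betabinomial_lrt(incB, skpB, incA, skpA)
  expect_equal(r1$delta_psi, -r2$delta_psi, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
  o <- c(3, 1, 5, 2, 4)
  r3 <- betabinomial_lrt(incA[o], skpA[o], incB, skpB)
  expect_equal(r1$lrt_statistic, r3$lrt_statistic, tolerance = 1e-8)
  # degenerate input: < 2 informative replicates
  r4 <- betabinomial_lrt(c(5L, 0L), c(5L, 0L), incB, skpB)
  expect_true(is.na(r4$p_value))
})

test_that("the comparison workflow has power for a strong effect", {
  ne <- 500
  psi <- null_psi(ne, 0.2)
  psi[, "MT.Drug"] <- 0.8
  tab <- make_sampled_table(psi, reps = 5, total_mean = 60, rho = 0.05,
                            seed = 77)
  res <- compare_conditions(tab, "MT.Drug", "WT.Veh")
  expect_gte(mean(res$p_value < 1e-4, na.rm = TRUE), 0.95)
  # delta reported baseline-minus-perturbed: 0.2 - 0.8 < 0
  expect_lt(median(res$delta_psi), -0.55)
})

test_that("orient_delta applies the declared sign convention", {
  # vehicle 0.7, drug 0.5; raw = perturbed(A=drug) - baseline(B=vehicle)
  raw <- 0.5 - 0.7
  expect_equal(as.numeric(orient_delta(raw, "B_minus_A")), 0.2)
  expect_equal(as.numeric(orient_delta(raw, "A_minus_B")), -0.2)
  expect_equal(as.numeric(orient_delta(0)), 0)
  expect_error(orient_delta(0.1, "sideways"), "arg")
})

test_that("bh_adjust matches the step-up formula and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_true(all(q >= p))             # BH can only increase p
    expect_true(all(q <= 1))
    expect_equal(q, p.adjust(p, "BH"))   # independent reference
    # brute-force step-up: min over j with p_j >= p_i of m p_j / rank_j
    m <- length(p); r <- rank(p, ties.method = "first")
    brute <- vapply(seq_len(m), function(i)
      min(1, min((m * p / r)[r >= r[i]])), numeric(1))
    expect_equal(q, brute, tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), "0,1")
  # missing entries excluded from m
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_equal(q, c(0.02, NA, 0.04))
})

test_that("filter_then_readjust recomputes BH on exactly the survivors", {
  set.seed(9)
  res <- data.frame(event_id = sprintf("E%02d", 1:40),
                    p_value = runif(40)^1.5)
  keep <- runif(40) < 0.5
  out <- filter_then_readjust(res, keep)
  expect_equal(nrow(out), sum(keep))
  expect_equal(out$fdr, p.adjust(res$p_value[keep], "BH"))
  # keep everything -> plain BH; keep one -> fdr equals raw p
  expect_equal(filter_then_readjust(res, rep(TRUE, 40))$fdr,
               p.adjust(res$p_value, "BH"))
  one <- filter_then_readjust(res, c(TRUE, rep(FALSE, 39)))
  expect_equal(one$fdr, one$p_value)
  expect_warning(filter_then_readjust(res, rep(FALSE, 40)), "no events")
})

test_that("call_dysregulated uses strict thresholds and labels directions", {
  res <- data.frame(event_id = c("a", "b", "c", "d"),
                    event_type = c("SE", "SE", "RI", "RI"),
                    delta_psi = c(0.2, -0.2, -0.3, 0.3),
                    p_value = 1e-5, fdr = c(0.05, 0.01, 0.01, 0.01),
                    stringsAsFactors = FALSE)
  out <- call_dysregulated(res, fdr_max = 0.05, min_abs_dpsi = 0.10)
  expect_false("a" %in% out$event_id)  # fdr == threshold, strict
  expect_equal(out$direction[out$event_id == "b"], "more-included")
  expect_equal(out$direction[out$event_id == "c"], "more-retained")
  expect_equal(out$direction[out$event_id == "d"], "more-removed")
  expect_equal(nrow(call_dysregulated(res[0, ], 0.05, 0.1)), 0L)
  res$delta_psi <- c(0.1, 0.1, 0.1, 0.1)
  expect_equal(nrow(call_dysregulated(res, 0.5, 0.10)), 0L)  # strict on dPSI
})

test_that("calling recovers planted effects with controlled FDR", {
  ne <- 500; n_true <- 50
  psi <- null_psi(ne, 0.5)
  psi[seq_len(n_true), "MT.Drug"] <- 0.8   # dPSI = 0.3 vs WT.Veh baseline
  tab <- make_sampled_table(psi, seed = 41)
  res <- compare_conditions(tab, "MT.Drug", "WT.Veh")
  calls <- call_dysregulated(res, fdr_max = 0.10, min_abs_dpsi = 0.01)
  hits <- calls$event_id %in% sprintf("E%04d", seq_len(n_true))
  recall <- sum(hits) / n_true
  emp_fdr <- if (nrow(calls)) sum(!hits) / nrow(calls) else 0
  expect_gte(recall, 0.8)
  expect_lte(emp_fdr, 1.5 * 0.10)
})
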