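test_that("extract_context recovers planted windows on both strands", {
  set.seed(61)
  cfg <- simulation_config(n_events = 10, n_genes = 5,
                           motif_t_minus3_sensitive = 1)
  ctx <- replicate(20, simulate_acceptor_sequence(TRUE, cfg))
  strands <- rep(c("+", "-"), 10)
  types <- rep(c("SE", "SE", "RI", "RI"), 5)
  pg <- plant_genome(ctx, strands, types)
  got <- extract_contexts(pg$events, pg$genome)
  expect_equal(unname(got), ctx)
  expect_true(all(nchar(got) == 23))
  # planted T at -3 (index 18) and AG at -2,-1 (indices 19,20), both strands
  expect_true(all(substr(got, 18, 20) == "TAG"))
  # same planted context recovered identically regardless of strand
  pg2 <- plant_genome(rep(ctx[1], 2), c("+", "-"), c("SE", "SE"))
  got2 <- extract_contexts(pg2$events, pg2$genome)
  expect_equal(got2[[1]], got2[[2]])
  # out-of-bounds window is missing with a warning
  ev <- pg$events[1, ]; ev$coord2 <- 5L
  expect_warning(res <- extract_context(ev, pg$genome), "out of bounds")
  expect_true(is.na(res))
})

test_that("build_pfm frequencies and information content", {
  pfm1 <- build_pfm("ACGT", intronic_len = 2)
  expect_equal(unname(pfm1$freq[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(pfm1$info_content), rep(2, 4))
  expect_equal(pfm1$positions, c(-2L, -1L, 0L, 1L))
  # uniform position -> IC 0; 75/25 two-base position -> 1.1887 bits
  seqs <- c("AA", "CA", "GA", "TA", "AA", "CA", "GA", "TA")
  pfm2 <- build_pfm(seqs, intronic_len = 2)
  expect_equal(unname(pfm2$info_content[1]), 0, tolerance = 1e-12)
  seqs3 <- c(rep("A", 6), rep("C", 2))
  pfm3 <- build_pfm(seqs3, intronic_len = 1)
  expect_equal(unname(pfm3$info_content[1]), 2 - 0.811278124459,
               tolerance = 1e-9)
  expect_true(all(abs(colSums(pfm2$freq) - 1) < 1e-9))
  expect_true(all(pfm2$info_content >= 0 & pfm2$info_content <= 2))
  expect_error(build_pfm(c("AC", "ACG")), "ragged")
})

test_that("position_enrichment_test matches exact hypergeometric enumeration", {
  # identical sets: no signal
  s <- c("TTT", "TCT", "TAT")
  r0 <- position_enrichment_test(s, s, position = -1, intronic_len = 3)
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$p_value, 1)
  # frozen 2x2 example: (8,2 / 2,8)
  dys <- c(rep("T", 8), rep("A", 2)); ctl <- c(rep("T", 2), rep("A", 8))
  r <- position_enrichment_test(dys, ctl, position = 0, intronic_len = 0)
  expect_equal(r$odds_ratio, 16)
  expect_equal(r$p_value, 0.0230141375652, tolerance = 1e-9)
  # Haldane correction when a cell is zero
  rz <- position_enrichment_test(rep("T", 5), rep("A", 5),
                                 position = 0, intronic_len = 0)
  expect_equal(rz$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
  # enumeration oracle over random tables with margins <= 30
  set.seed(71)
  for (i in 1:25) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    a <- sample(0:n1, 1); cc <- sample(0:n2, 1)
    d1 <- c(rep("T", a), rep("A", n1 - a))
    c1 <- c(rep("T", cc), rep("A", n2 - cc))
    r <- position_enrichment_test(d1, c1, position = 0, intronic_len = 0)
    # two-sided Fisher p: sum of hypergeometric PMFs <= observed PMF
    K <- a + cc; N <- n1 + n2
    pmf <- dhyper(max(0, K - n2):min(K, n1), n1, n2, K)
    obs <- dhyper(a, n1, n2, K)
    brute <- sum(pmf[pmf <= obs * (1 + 1e-7)])
    expect_equal(r$p_value, brute, tolerance = 1e-7)
  }
})

test_that("select_context_sets picks disjoint sets and matches a re-filter", {
  set.seed(81)
  res <- data.frame(event_id = sprintf("E%03d", 1:300),
                    event_type = "SE",
                    delta_psi = runif(300, -0.4, 0.4),
                    p_value = runif(300),
                    stringsAsFactors = FALSE)
  res$fdr <- bh_adjust(res$p_value)
  res$delta_psi[1:30] <- res$delta_psi[1:30] / 1000  # near-zero changes
  sets <- suppressWarnings(
    select_context_sets(res, fdr_max = 0.6, min_abs_dpsi = 0.10,
                        ctrl_fdr_min = 0.5, ctrl_max_abs_dpsi = 0.001))
  expect_length(intersect(sets$dysregulated, sets$control), 0)
  dys_brute <- res$event_id[res$fdr < 0.6 & abs(res$delta_psi) > 0.10]
  ctrl_brute <- setdiff(res$event_id[res$fdr > 0.5 &
                                       abs(res$delta_psi) < 0.001], dys_brute)
  expect_setequal(sets$dysregulated, dys_brute)
  expect_setequal(sets$control, ctrl_brute)
  # impossible thresholds give two empty sets, with a warning for controls
  expect_warning(
    empty <- select_context_sets(res, fdr_max = 1e-9, min_abs_dpsi = 0.99,
                                 ctrl_fdr_min = 0.999999,
                                 ctrl_max_abs_dpsi = 1e-9), "empty control")
  expect_length(empty$dysregulated, 0)
  expect_length(empty$control, 0)
  # published-methods variant: changed but non-significant controls
  alt <- select_context_sets(res, control = "changed-but-nonsig",
                             ctrl_max_abs_dpsi = 0.01)
  expect_true(all(abs(res$delta_psi[match(alt$control, res$event_id)]) > 0.01))
})
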