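# FiveComparisonSet built by hand for rule checks
fake_five <- function(dW, dM, mV, mD, cum, fdr = 0.001, type = "SE") {
  ne <- length(dW)
  mk <- function(d) data.frame(event_id = sprintf("E%03d", seq_len(ne)),
                               event_type = type, delta_psi = d,
                               p_value = fdr, fdr = fdr,
                               stringsAsFactors = FALSE)
  structure(list(drug_in_WT = mk(dW), drug_in_MT = mk(dM),
                 mut_in_Veh = mk(mV), mut_in_Drug = mk(mD),
                 cumulative = mk(cum),
                 psi_means = NULL), class = "FiveComparisonSet")
}

test_that("factorial_design validates cell coverage", {
  s <- data.frame(sample_id = letters[1:8],
                  genotype = rep(c("WT", "MT"), each = 4),
                  treatment = rep(c("Veh", "Drug"), 4))
  expect_s3_class(factorial_design(s), "FactorialDesign")
  expect_error(factorial_design(s[s$treatment == "Veh" | s$genotype == "WT", ]),
               "incomplete factorial")
})

test_that("cumulative_delta: worked example, zero case, path identity", {
  pm <- c(WT.Veh = 0.8, WT.Drug = 0.612, MT.Veh = 0.595, MT.Drug = 0.391)
  expect_equal(cumulative_delta(pm), 0.409, tolerance = 1e-12)
  d_mut_veh <- pm[["WT.Veh"]] - pm[["MT.Veh"]]     # 0.205
  d_drug_mt <- pm[["MT.Veh"]] - pm[["MT.Drug"]]    # 0.204
  d_drug_wt <- pm[["WT.Veh"]] - pm[["WT.Drug"]]    # 0.188
  d_mut_drug <- pm[["WT.Drug"]] - pm[["MT.Drug"]]
  expect_equal(cumulative_delta(pm), d_mut_veh + d_drug_mt, tolerance = 1e-15)
  expect_equal(cumulative_delta(pm), d_drug_wt + d_mut_drug, tolerance = 1e-15)
  expect_equal(cumulative_delta(rep(0.4, 4) |>
                                  setNames(condition_levels())), 0)
  pm_na <- pm; pm_na[["MT.Drug"]] <- NA
  expect_true(is.na(cumulative_delta(pm_na)))
})

test_that("run_five_comparisons satisfies exact path additivity", {
  psi <- null_psi(40, 0.5)
  psi[1:10, "MT.Veh"] <- 0.3; psi[1:10, "MT.Drug"] <- 0.25
  psi[11:20, "WT.Drug"] <- 0.7; psi[11:20, "MT.Drug"] <- 0.8
  tab <- make_sampled_table(psi, seed = 17)
  five <- run_five_comparisons(tab)
  cum <- five$cumulative$delta_psi
  path1 <- five$mut_in_Veh$delta_psi + five$drug_in_MT$delta_psi
  path2 <- five$drug_in_WT$delta_psi + five$mut_in_Drug$delta_psi
  expect_true(all(abs(cum - path1) < 1e-12))
  expect_true(all(abs(cum - path2) < 1e-12))
  # cumulative delta recomputable from the condition means
  expect_equal(cum, unname(cumulative_delta(five$psi_means)),
               tolerance = 1e-12)
})

test_that("concordance_regression: exact, null and attenuated cases", {
  x <- seq(-0.3, 0.3, length.out = 50)
  r <- concordance_regression(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  set.seed(19)
  rn <- concordance_regression(rnorm(500), rnorm(500))
  expect_lt(rn$r_squared, 0.05)
  x <- runif(600, -0.4, 0.4)
  y <- 0.75 * x + rnorm(600, 0, 0.02)
  ra <- concordance_regression(x, y)
  expect_gt(ra$slope, 0.70); expect_lt(ra$slope, 0.80)
  expect_lt(ra$f_test_p, 2.2e-16)
  expect_error(concordance_regression(rep(0.1, 10), rnorm(10)), "degenerate")
  expect_error(concordance_regression(1:2, 1:2), ">= 3")
  ro <- concordance_regression(x, y, through_origin = TRUE)
  expect_equal(ro$intercept, 0)
})

test_that("interaction_lrt: non-negative statistic, label-swap invariance, power", {
  set.seed(23)
  im <- rep(c(0L, 0L, 1L, 1L), each = 5)
  id <- rep(c(0L, 1L, 0L, 1L), each = 5)
  tot <- rnbinom(20, mu = 60, size = 10)
  psi <- plogis(0 + 0.8 * im - 0.5 * id + 1.5 * im * id)
  cts <- sample_event_counts(psi, tot, 0.05)
  r <- interaction_lrt(cts$inclusion, cts$skipping, im, id)
  expect_gte(r$lrt_statistic, 0)
  # swapping both factor labels simultaneously leaves the test unchanged
  r2 <- interaction_lrt(cts$inclusion, cts$skipping, 1L - im, 1L - id)
  expect_equal(r$p_value, r2$p_value, tolerance = 1e-4)
  # degenerate: missing cell
  r3 <- interaction_lrt(cts$inclusion[1:10], cts$skipping[1:10],
                        im[1:10], id[1:10])
  expect_true(is.na(r3$p_value))
  # strong planted interaction is detected most of the time
  hits <- 0
  for (i in 1:30) {
    tot <- rnbinom(20, mu = 60, size = 10)
    psi <- plogis(0 + 0.5 * im + 0.5 * id + 1.8 * im * id)
    cts <- sample_event_counts(psi, tot, 0.05)
    r <- interaction_lrt(cts$inclusion, cts$skipping, im, id)
    hits <- hits + (r$p_value < 0.05 && r$effect_sign > 0)
  }
  expect_gte(hits / 30, 0.7)
})

test_that("classify_events applies the concordance and cumulative rules", {
  five <- fake_five(dW = c(0.188, 0.2, 0.2, 0.005),
                    dM = c(0.204, -0.2, 0.2, 0.3),
                    mV = c(0.205, 0.0, 0.0, 0.1),
                    mD = c(0.221, 0.0, 0.0, 0.1),
                    cum = c(0.409, 0.0, 0.15, 0.3))
  cls <- classify_events(five, fdr_max = 0.10, min_abs_dpsi = 0.01)
  # worked example: concordant and exacerbated, trajectory-eligible
  expect_true(cls$drug_concordant[1])
  expect_true(cls$cumulative_exacerbated[1])
  expect_true(cls$trajectory_eligible[1])
  # discordant: both pass, opposite signs
  expect_true(cls$drug_discordant[2])
  expect_false(cls$cumulative_exacerbated[2])
  # concordant but cumulative below the WT drug effect
  expect_true(cls$drug_concordant[3])
  expect_false(cls$cumulative_exacerbated[3])
  # dPSI below threshold in one drug comparison
  expect_false(cls$drug_concordant[4])
  # all-null event gets no labels
  fiven <- fake_five(0, 0, 0, 0, 0, fdr = 0.9)
  clsn <- classify_events(fiven, 0.10, 0.01)
  expect_false(any(clsn$drug_concordant | clsn$drug_discordant |
                     clsn$cumulative_exacerbated | clsn$trajectory_eligible))
})

test_that("trajectory_table is baseline-anchored and recomputable from means", {
  psi <- null_psi(30, 0.6)
  psi[1:5, "WT.Drug"] <- 0.4; psi[1:5, "MT.Veh"] <- 0.4
  psi[1:5, "MT.Drug"] <- 0.2
  tab <- make_sampled_table(psi, total_mean = 200, rho = 0.01, seed = 29)
  five <- run_five_comparisons(tab)
  elig <- five$drug_in_WT$event_id[1:5]
  tr <- trajectory_table(five, elig)
  expect_true(all(tr$WT.Veh == 0))
  pm <- five$psi_means[elig, ]
  for (cc in c("WT.Drug", "MT.Veh", "MT.Drug"))
    expect_equal(tr[[cc]], unname(pm[, "WT.Veh"] - pm[, cc]),
                 tolerance = 1e-12)
  expect_true(all(tr$group == "skipping"))
})
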