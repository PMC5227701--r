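# Beta-binomial likelihood machinery shared by the two-group splicing test
# and the factorial interaction test. Parameterized by the mean mu and the
# intra-class correlation rho: a = mu(1-rho)/rho, b = (1-mu)(1-rho)/rho.
#
# Fitting strategy: for fixed rho the single-group profile over mu is a
# reliable 1-d optimization, and group means are separable, so model fits
# are built from nested 1-d profiles rather than a joint simplex search.
# Per-event profiling of rho at 5 replicates per group is noticeably
# anticonservative, so the table-level workflows estimate one rho shared
# across events by Cox-Reid adjusted profile likelihood on the cell-means
# model and hold it fixed in every event's LRT (see the methods vignette).

.RHO_FLOOR <- 1e-6
.RHO_CEIL <- 0.99

# summed log-likelihood of counts k of n at mean mu (scalar or
# per-observation vector) and intra-class correlation rho
.bb_loglik <- function(k, n, mu, rho) {
  mu <- .clamp(mu, 1e-9, 1 - 1e-9)
  if (rho < .RHO_FLOOR) return(sum(stats::dbinom(k, n, mu, log = TRUE)))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# profile the mean of one group at fixed rho; returns loglik and mu-hat
.bb_profile_mu <- function(k, n, rho) {
  o <- stats::optimize(function(t) -.bb_loglik(k, n, stats::plogis(t), rho),
                       interval = c(-15, 15), tol = 1e-8)
  list(loglik = -o$objective, mu = stats::plogis(o$minimum))
}

# profile loglik of a grouped model (one mean per group) at fixed rho,
# optionally with the Cox-Reid adjustment -0.5 log I(mu_g) per group
.bb_groups_loglik <- function(k, n, grp, rho, cox_reid = FALSE) {
  ll <- 0
  for (g in unique(grp)) {
    i <- grp == g
    f <- .bb_profile_mu(k[i], n[i], rho)
    ll <- ll + f$loglik
    if (cox_reid) {
      mu <- .clamp(f$mu, 1e-6, 1 - 1e-6)
      info <- mu * (1 - mu) * sum(n[i] / (1 + (n[i] - 1) * rho))
      ll <- ll - 0.5 * log(info)
    }
  }
  ll
}

# ML of rho for one event's grouped model (boundary rho = 0 considered)
.bb_profile_rho <- function(k, n, grp) {
  o <- stats::optimize(function(lr) -.bb_groups_loglik(k, n, grp, exp(lr)),
                       interval = c(log(.RHO_FLOOR), log(.RHO_CEIL)),
                       tol = 1e-6)
  ll0 <- .bb_groups_loglik(k, n, grp, 0)
  if (ll0 > -o$objective) list(rho = 0, loglik = ll0)
  else list(rho = exp(o$minimum), loglik = -o$objective)
}

#' Pooled beta-binomial overdispersion across events
#'
#' Estimates a single intra-class correlation shared by all events by
#' maximizing the Cox-Reid adjusted profile log-likelihood of the
#' cell-means model (one mean per condition group per event), summed over
#' events. The adjustment removes most of the downward small-sample bias of
#' plain profile ML. At large tables a deterministic, evenly spaced subset
#' of events (default up to 300) is used.
#'
#' @param inclusion,skipping events x samples count matrices.
#' @param groups per-sample group labels (the condition cells).
#' @param max_events number of events used for estimation.
#' @return The pooled rho estimate (scalar in \[0, 0.99\]).
#' @export
estimate_common_rho <- function(inclusion, skipping, groups,
                                max_events = 300) {
  ne <- nrow(inclusion)
  idx <- unique(round(seq(1, ne, length.out = min(ne, max_events))))
  tot <- inclusion + skipping
  obj <- function(rho) {
    s <- 0
    for (i in idx) {
      ok <- tot[i, ] > 0
      if (sum(ok) < 3) next
      s <- s + .bb_groups_loglik(inclusion[i, ok], tot[i, ok],
                                 groups[ok], rho, cox_reid = TRUE)
    }
    s
  }
  o <- stats::optimize(function(lr) -obj(exp(lr)),
                       interval = c(log(1e-5), log(0.5)), tol = 1e-4)
  rho <- exp(o$minimum)
  if (obj(.RHO_FLOOR) > -o$objective) rho <- .RHO_FLOOR
  rho
}
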