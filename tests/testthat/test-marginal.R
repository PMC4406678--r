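make_marginal_fixture <- function(seed = 60, n = 60, n_probes = 30) {
  set.seed(seed)
  age <- runif(n, 20, 70)
  status <- rep(c("case", "control"), length.out = n)
  accel <- rnorm(n, 0, 2)
  beta <- matrix(runif(n_probes * n, 0.2, 0.8), n_probes, n,
                 dimnames = list(sprintf("cg%04d", seq_len(n_probes)),
                                 sprintf("s%03d", seq_len(n))))
  # planted structure: probe 1 tracks acceleration, probe 2 is shifted in
  # cases, probe 3 is constant
  beta[1, ] <- 0.5 + 0.05 * accel + rnorm(n, 0, 0.01)
  beta[2, ] <- 0.4 + 0.1 * (status == "case") + rnorm(n, 0, 0.01)
  beta[3, ] <- 0.42
  beta[beta < 0] <- 0; beta[beta > 1] <- 1
  ann <- data.frame(sample_id = colnames(beta), age = age, status = status,
                    stringsAsFactors = FALSE)
  cohort <- methylation_cohort(beta, ann)
  accel_df <- data.frame(sample_id = colnames(beta), acceleration = accel,
                         stringsAsFactors = FALSE)
  list(cohort = cohort, accel = accel_df, status = status)
}

test_that("marginal statistics follow both sign conventions", {
  fx <- make_marginal_fixture()
  ms <- marginal_cpg_stats(fx$cohort, fx$accel)
  expect_gt(ms$signed_logp_accel[1], -log10(0.05))   # tracks acceleration
  expect_gt(ms$signed_logp_status[2], -log10(0.05))  # hyper in cases
  # zero-variance probe: all statistics zero, flagged, no error
  expect_true(ms$zero_variance[3])
  expect_equal(ms$signed_logp_accel[3], 0)
  expect_equal(ms$r_age[3], 0)

  # negating acceleration flips every acceleration sign
  neg <- fx$accel; neg$acceleration <- -neg$acceleration
  ms_neg <- marginal_cpg_stats(fx$cohort, neg)
  expect_equal(ms_neg$signed_logp_accel, -ms$signed_logp_accel,
               tolerance = 1e-10)
  # swapping case/control labels flips every status sign
  sw <- fx$cohort
  sw$annotations$status <- ifelse(sw$annotations$status == "case",
                                  "control", "case")
  ms_sw <- marginal_cpg_stats(sw, fx$accel)
  expect_equal(ms_sw$signed_logp_status, -ms$signed_logp_status,
               tolerance = 1e-10)
})

test_that("signed values are finite and capped", {
  fx <- make_marginal_fixture()
  # an effectively perfect acceleration proxy would have p under the floor
  fx$cohort$beta[4, ] <- pmin(pmax(0.5 + 0.1 *
    scale(fx$accel$acceleration)[, 1], 0), 1)
  ms <- marginal_cpg_stats(fx$cohort, fx$accel, cap = 300)
  expect_true(all(is.finite(ms$signed_logp_accel)))
  expect_true(all(abs(ms$signed_logp_accel) <= 300))
})

test_that("clock CpGs are flagged by training age-correlation sign", {
  cfg <- synthetic_config(seed = 61, clock_size = 20L, cell_types = 0L,
                          n_background_probes = 50L, n_cases = 15L,
                          n_controls = 25L)
  co <- generate_cohort(cfg)
  ck <- attr(co, "truth")$clock
  pred <- predict_dnam_age(co, ck)
  acc <- compute_age_acceleration(pred, co$annotations)
  ms <- marginal_cpg_stats(co, acc, clock = ck)
  truth_b <- attr(ck, "truth")$b
  in_clock <- ms$probe_id %in% names(ck$weights)
  expect_true(all(ms$clock_flag[!in_clock] == "non_clock"))
  flagged <- ms$clock_flag[match(names(truth_b), ms$probe_id)]
  expect_equal(flagged, ifelse(truth_b > 0, "clock_pos", "clock_neg"),
               ignore_attr = TRUE)
})

test_that("P-components are uniform under fully permuted labels", {
  set.seed(62)
  fx <- make_marginal_fixture(seed = 62, n = 50, n_probes = 200)
  # break the planted structure by permuting acceleration and status
  perm <- sample(nrow(fx$accel))
  accel_perm <- fx$accel
  accel_perm$acceleration <- accel_perm$acceleration[perm]
  co <- fx$cohort
  co$annotations$status <- co$annotations$status[sample(50)]
  ms <- marginal_cpg_stats(co, accel_perm)
  keep <- !ms$zero_variance & ms$probe_id != "cg0001"
  p_acc <- 10^(-abs(ms$signed_logp_accel[keep]))
  expect_gt(stats::ks.test(p_acc, "punif")$p.value, 0.01)
})

test_that("quadrant classification keys on both axes at alpha", {
  stats_df <- data.frame(
    probe_id = paste0("p", 1:5),
    signed_logp_accel = c(2, -2, 0.5, 2, -3),
    signed_logp_status = c(3, 4, 3, -0.2, -2),
    stringsAsFactors = FALSE)
  q <- classify_quadrants(stats_df, alpha = 0.05)
  expect_equal(q, c("upper-right", "upper-left", "nonsignificant",
                    "nonsignificant", "lower-left"))
  expect_error(classify_quadrants(stats_df, alpha = 1.2), "alpha")
})

test_that("planted concordant CpGs land in the upper-right quadrant", {
  cfg <- synthetic_config(seed = 63)
  co <- generate_cohort(cfg)
  truth <- attr(co, "truth")
  pred <- predict_dnam_age(co, truth$clock)
  acc <- compute_age_acceleration(pred, co$annotations)
  ms <- marginal_cpg_stats(co, acc, clock = truth$clock)
  q <- classify_quadrants(ms, alpha = 0.05)
  hit <- q[match(truth$planted_probes, ms$probe_id)]
  expect_gte(sum(hit == "upper-right"), 8)
})

test_that("preservation correlation: identity, null, and monotonicity", {
  fx <- make_marginal_fixture(seed = 64, n_probes = 100)
  ms <- marginal_cpg_stats(fx$cohort, fx$accel)
  expect_equal(preservation_correlation(ms, ms), 1.0)

  # independent null stats: correlation ~ 0 within 2/sqrt(n)
  set.seed(64)
  msB <- ms
  msB$signed_logp_accel <- sample(ms$signed_logp_accel)
  r0 <- preservation_correlation(ms, msB)
  expect_lt(abs(r0), 2 / sqrt(nrow(ms)) + 0.1)

  # sharing a growing fraction of signal raises r monotonically
  set.seed(65)
  base_sig <- rnorm(100, 0, 3)
  mkstats <- function(signal) data.frame(
    probe_id = sprintf("cg%04d", 1:100),
    signed_logp_accel = signal + rnorm(100, 0, 1),
    stringsAsFactors = FALSE)
  sA <- mkstats(base_sig)
  rs <- vapply(c(0, 0.5, 1), function(frac) {
    keep <- seq_len(100 * frac)
    sig_b <- rnorm(100, 0, 3)
    sig_b[keep] <- base_sig[keep]
    preservation_correlation(sA, mkstats(sig_b))
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_error(preservation_correlation(sA[1:5, ], sA[1:5, ]), "shared")
})

test_that("Stouffer combination: identity, z*sqrt(k), integration oracle", {
  one <- stouffer_meta(1.3)
  expect_equal(one$combined_z, 1.3)
  four <- stouffer_meta(rep(1.96, 4))
  expect_equal(four$combined_z, 3.92, tolerance = 1e-10)

  set.seed(66)
  for (i in 1:5) {
    z <- rnorm(4); w <- runif(4, 0.5, 2)
    res <- stouffer_meta(z, w)
    # oracle: combined z is standard normal under the null; two-sided tail
    # probability by direct numeric integration of the density
    p_int <- 2 * stats::integrate(stats::dnorm, abs(res$combined_z), Inf,
                                  rel.tol = 1e-12)$value
    expect_equal(res$combined_p, p_int, tolerance = 1e-8)
  }
  expect_error(stouffer_meta(c(NA, NA)), "finite")
  expect_error(stouffer_meta(1, weights = -1), "positive")
})

test_that("inverse-variance pooling matches the WLS oracle", {
  # two equal estimates with equal SEs pool to the same estimate, SE/sqrt(2)
  m <- fixed_effects_meta(c(4, 4), c(1.2, 1.2))
  expect_equal(m$estimate, 4)
  expect_equal(m$se, 1.2 / sqrt(2), tolerance = 1e-12)
  # single input: identity
  m1 <- fixed_effects_meta(3.74593, 1.37252)
  expect_equal(m1$estimate, 3.74593)
  expect_equal(m1$se, 1.37252)

  set.seed(67)
  for (i in 1:5) {
    est <- rnorm(3, 5, 2); se <- runif(3, 0.5, 2)
    res <- fixed_effects_meta(est, se)
    wls <- stats::lm(est ~ 1, weights = 1 / se^2)
    expect_equal(res$estimate, unname(stats::coef(wls)[1]),
                 tolerance = 1e-10)
    expect_equal(res$se, 1 / sqrt(sum(1 / se^2)), tolerance = 1e-12)
  }
  expect_error(fixed_effects_meta(1, 0), "SE")

  # secondary summary: unweighted mean of per-dataset years
  my <- fixed_effects_meta(c(4, 9, 4), c(1.4, 1.2, 1.1),
                           years = c(3.9, 11.5, 4.6))
  expect_equal(my$mean_years, mean(c(3.9, 11.5, 4.6)))
})

test_that("meta-analyses are invariant to dataset order", {
  set.seed(68)
  z <- rnorm(5); w <- runif(5, 0.5, 2); perm <- sample(5)
  expect_equal(stouffer_meta(z, w)$combined_z,
               stouffer_meta(z[perm], w[perm])$combined_z, tolerance = 1e-12)
  est <- rnorm(5); se <- runif(5, 0.5, 2)
  expect_equal(fixed_effects_meta(est, se)$estimate,
               fixed_effects_meta(est[perm], se[perm])$estimate,
               tolerance = 1e-12)
})
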