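test_that("controls on an exact line give zero residuals, case its offset", {
  d <- exact_line_data(offset = 5)
  acc <- compute_age_acceleration(d$pred, d$ann)
  expect_equal(acc$acceleration[acc$status == "control"], rep(0, 4),
               tolerance = 1e-10)
  expect_equal(acc$acceleration[acc$status == "case"], 5, tolerance = 1e-10)
  cf <- attr(acc, "control_fit")
  expect_equal(cf$slope, 1.1, tolerance = 1e-10)
  expect_equal(cf$intercept, 10, tolerance = 1e-10)
  expect_equal(cf$r, 1, tolerance = 1e-10)
})

test_that("control residuals have mean zero and zero age correlation", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    ann <- data.frame(sample_id = paste0("s", 1:n), age = runif(n, 10, 80),
                      status = sample(c("case", "control"), n, TRUE),
                      stringsAsFactors = FALSE)
    if (sum(ann$status == "control") < 3) ann$status[1:3] <- "control"
    pred <- data.frame(sample_id = ann$sample_id,
                       dnam_age = 5 + ann$age + rnorm(n, 0, 3),
                       stringsAsFactors = FALSE)
    acc <- compute_age_acceleration(pred, ann)
    ctl <- acc$status == "control"
    expect_lt(abs(mean(acc$acceleration[ctl])), 1e-10)
    expect_lt(abs(cor(acc$acceleration[ctl], acc$age[ctl])), 1e-10)
  }
})

test_that("relabelling a case as control re-anchors the regression", {
  d <- exact_line_data(offset = 8)
  ann2 <- d$ann
  ann2$status[ann2$sample_id == "k1"] <- "control"
  acc2 <- compute_age_acceleration(d$pred, ann2)
  ctl <- acc2$status == "control"
  expect_lt(abs(mean(acc2$acceleration[ctl])), 1e-10)
  # and the new control set includes the former case
  expect_equal(sum(ctl), 5)
})

test_that("degenerate control sets are hard errors", {
  d <- exact_line_data()
  ann <- d$ann; ann$status[1:2] <- "case"
  expect_error(compute_age_acceleration(d$pred, ann), ">= 3 control")
  ann2 <- d$ann; ann2$age[ann2$status == "control"] <- 30
  expect_error(compute_age_acceleration(d$pred, ann2), "age variance")
})

test_that("acceleration is translation-equivariant in dnam_age", {
  d <- exact_line_data(offset = 3)
  acc1 <- compute_age_acceleration(d$pred, d$ann)
  pred2 <- d$pred; pred2$dnam_age <- pred2$dnam_age + 12.5
  acc2 <- compute_age_acceleration(pred2, d$ann)
  expect_equal(acc1$acceleration, acc2$acceleration, tolerance = 1e-10)
})

test_that("non-case control definition includes other-disease samples", {
  d <- exact_line_data()
  ann <- d$ann
  ann$status[ann$sample_id == "c4"] <- "other-disease"
  acc_strict <- compute_age_acceleration(d$pred, ann, controls = "control")
  expect_equal(attr(acc_strict, "control_fit")$n_controls, 3)
  acc_wide <- compute_age_acceleration(d$pred, ann, controls = "non_case")
  expect_equal(attr(acc_wide, "control_fit")$n_controls, 4)
})

test_that("multivariate fit recovers noiseless coefficients exactly", {
  set.seed(30)
  n <- 50
  age <- runif(n, 10, 80)
  ds <- rep(c(1, 0), length.out = n)
  dnam <- 2 + 0.8 * age + 4 * ds
  fit <- fit_multivariate(dnam, age, ds)
  est <- fit$terms$estimate
  names(est) <- fit$terms$term
  expect_equal(unname(est["Chronological age"]), 0.8, tolerance = 1e-8)
  expect_equal(unname(est["DS"]), 4, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(31)
  age <- runif(30, 20, 60)
  ds <- rep(0:1, 15)
  dnam <- age + ds + rnorm(30)
  expect_error(fit_multivariate(dnam, age, ds,
                                covariates = data.frame(age_copy = age)),
               "age_copy")
})

test_that("Wald P is uniform under permuted null status labels", {
  set.seed(32)
  n <- 60
  age <- runif(n, 20, 70)
  pvals <- replicate(400, {
    ds <- sample(rep(0:1, each = n / 2))
    dnam <- 3 + age + rnorm(n, 0, 2)   # no status effect
    fit <- fit_multivariate(dnam, age, ds)
    fit$terms$p[fit$terms$term == "DS"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("years-of-acceleration ratio and its guards", {
  expect_equal(years_of_acceleration(fit_from_coefs(0.9, 0)), 0)
  expect_error(years_of_acceleration(fit_from_coefs(0, 1)), "zero")
  # invariant to rescaling dnam_age by a positive constant
  set.seed(33)
  age <- runif(40, 20, 70)
  ds <- rep(0:1, 20)
  dnam <- 1 + age + 5 * ds + rnorm(40)
  f1 <- fit_multivariate(dnam, age, ds)
  f2 <- fit_multivariate(3.7 * dnam, age, ds)
  expect_equal(years_of_acceleration(f1), years_of_acceleration(f2),
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis wrapper: statistic, ties, degenerate input", {
  kw <- suppressWarnings(kruskal_wallis(list(a = c(1, 2, 3),
                                             b = c(4, 5, 6))))
  expect_equal(kw$statistic, 3.857142857, tolerance = 1e-8)
  expect_equal(kw$df, 1L)
  # identical groups: H = 0, p = 1 by convention
  kw0 <- suppressWarnings(kruskal_wallis(list(a = rep(2, 4), b = rep(2, 4))))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  expect_warning(kruskal_wallis(list(a = 1:3, b = 4:6)), "< 5 observations")
  expect_error(kruskal_wallis(list(a = 1:10)), ">= 2")
  # group summaries
  kw2 <- kruskal_wallis(list(g1 = 1:6, g2 = 7:12))
  expect_equal(unname(kw2$group_means), c(3.5, 9.5))
})

test_that("chi-square P tracks the exact permutation oracle in the tail", {
  # spec's worked example, mid-p convention for the discrete null
  expect_lt(abs(suppressWarnings(
    kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6))))$p -
      kw_perm_midp(1:6, rep(1:2, each = 3))), 0.02)
  # complete separation at (4,4)
  expect_lt(abs(suppressWarnings(
    kruskal_wallis(list(a = 1:4, b = 5:8)))$p -
      kw_perm_midp(1:8, rep(1:2, each = 4))), 0.02)
})

test_that("stratified runs refit the control line per stratum", {
  # one stratum: identical to the unstratified analysis
  d <- exact_line_data(offset = 5)
  ann <- d$ann; ann$region <- "ctx"
  suppressWarnings({
    res <- run_stratified(d$pred, ann, "region", min_size = 2)
    base <- compute_age_acceleration(d$pred, d$ann)
  })
  expect_equal(res$ctx$acceleration$acceleration, base$acceleration)

  # two strata with different control slopes: each mean-zero in controls
  set.seed(34)
  mk <- function(region, slope, n = 12) {
    age <- runif(n, 20, 70)
    data.frame(sample_id = paste0(region, 1:n), age = age,
               status = rep(c("control", "case"), length.out = n),
               region = region,
               dnam_age = slope * age + rnorm(n, 0, 2),
               stringsAsFactors = FALSE)
  }
  dd <- rbind(mk("cb", 0.7), mk("fl", 1.3))
  suppressWarnings(
    res2 <- run_stratified(dd[c("sample_id", "dnam_age")],
                           dd[c("sample_id", "age", "status", "region")],
                           "region"))
  for (st in c("cb", "fl")) {
    acc <- res2[[st]]$acceleration
    expect_lt(abs(mean(acc$acceleration[acc$status == "control"])), 1e-10)
  }

  # small strata are skipped with a reason
  ann_small <- dd[c("sample_id", "age", "status", "region")]
  ann_small$region[1:3] <- "tiny"
  expect_message(
    res3 <- suppressWarnings(
      run_stratified(dd[c("sample_id", "dnam_age")], ann_small, "region")),
    "skipped")
  expect_true(!is.null(res3$tiny$skipped))
})

test_that("region-specific injected acceleration is found only there", {
  set.seed(35)
  mk_region <- function(region, delta, n_case = 12, n_ctrl = 12) {
    n <- n_case + n_ctrl
    age <- runif(n, 30, 70)
    status <- rep(c("case", "control"), c(n_case, n_ctrl))
    data.frame(sample_id = paste0(region, 1:n), age = age, status = status,
               region = region,
               dnam_age = age + delta * (status == "case") +
                 rnorm(n, 0, 1.5),
               stringsAsFactors = FALSE)
  }
  dd <- rbind(mk_region("affected", 8), mk_region("spared", 0))
  suppressWarnings(
    res <- run_stratified(dd[c("sample_id", "dnam_age")],
                          dd[c("sample_id", "age", "status", "region")],
                          "region"))
  expect_lt(res$affected$group_test$p, 0.01)
  expect_gt(res$spared$group_test$p, 0.05)
})
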