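signed_logp <- function(p, sign, floor = 1e-300, cap = 300) {
  p <- pmax(p, floor)
  val <- -log10(p)
  sign * pmin(val, cap)
}

#' Per-CpG marginal statistics
#'
#' For every probe in the cohort computes: the Pearson correlation with
#' chronological age; the signed `-log10 P` of the Pearson correlation test
#' against epigenetic age acceleration (two-sided, t reference; sign of the
#' correlation); and the signed `-log10 P` of a two-sided Wilcoxon rank-sum
#' comparison of cases versus controls (positive when the probe is
#' hypermethylated in cases). P-values are floored at 1e-300 and signed
#' values capped at +/-300 so they are always finite. Zero-variance probes
#' get all statistics 0 and are flagged. Clock CpGs are labelled by the sign
#' of their training-set age correlation when the clock carries that
#' annotation.
#'
#' @param cohort A [methylation_cohort()].
#' @param accelerations An `acceleration_result` from
#'   [compute_age_acceleration()].
#' @param clock Optional [clock_model()] with an `age_cor` annotation.
#' @param cap Cap for the absolute signed value (default 300).
#' @return Data frame of class `marginal_stats`: `probe_id`, `r_age`,
#'   `signed_logp_accel`, `signed_logp_status`, `clock_flag`
#'   (`clock_pos` / `clock_neg` / `non_clock`), `zero_variance`.
#' @export
marginal_cpg_stats <- function(cohort, accelerations, clock = NULL,
                               cap = 300) {
  beta <- cohort$beta
  ann <- cohort$annotations
  acc <- accelerations$acceleration[match(colnames(beta),
                                          accelerations$sample_id)]
  if (anyNA(acc)) stop("accelerations missing for some cohort samples")
  age <- ann$age
  is_case <- ann$status == "case"
  is_ctrl <- ann$status == "control"

  n_probe <- nrow(beta)
  r_age <- numeric(n_probe)
  slp_accel <- numeric(n_probe)
  slp_status <- numeric(n_probe)
  zero_var <- logical(n_probe)
  n <- ncol(beta)
  for (i in seq_len(n_probe)) {
    v <- beta[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0) {
      zero_var[i] <- TRUE
      next
    }
    r_age[i] <- stats::cor(v[ok], age[ok])
    # Pearson correlation test vs acceleration, t reference
    r <- stats::cor(v[ok], acc[ok])
    df <- sum(ok) - 2L
    if (is.na(r) || abs(r) >= 1) {
      p_acc <- 1e-300
    } else {
      tt <- r * sqrt(df / (1 - r^2))
      p_acc <- 2 * stats::pt(-abs(tt), df)
    }
    slp_accel[i] <- signed_logp(p_acc, sign(r), cap = cap)
    ca <- v[is_case & ok]; co <- v[is_ctrl & ok]
    if (length(ca) > 0L && length(co) > 0L) {
      wt <- suppressWarnings(stats::wilcox.test(ca, co, exact = FALSE))
      d <- mean(ca) - mean(co)
      slp_status[i] <- signed_logp(wt$p.value, sign(d), cap = cap)
    }
  }
  flag <- rep("non_clock", n_probe)
  if (!is.null(clock) && !is.null(clock$age_cor)) {
    ac <- clock$age_cor[rownames(beta)]
    flag[!is.na(ac) & ac > 0] <- "clock_pos"
    flag[!is.na(ac) & ac < 0] <- "clock_neg"
  }
  out <- data.frame(probe_id = rownames(beta), r_age = r_age,
                    signed_logp_accel = slp_accel,
                    signed_logp_status = slp_status,
                    clock_flag = flag, zero_variance = zero_var,
                    stringsAsFactors = FALSE)
  class(out) <- c("marginal_stats", class(out))
  out
}

#' Classify probes into significance quadrants
#'
#' Probes significant on both signed axes at the uncorrected threshold
#' `alpha` are labelled by their sign pair; a probe hypermethylated in cases
#' with a positive acceleration correlation lands in `"upper-right"`. All
#' other probes are `"nonsignificant"`.
#'
#' @param stats A `marginal_stats` data frame.
#' @param alpha Uncorrected P-value threshold in (0, 1); default 0.05.
#' @return Character vector of quadrant labels, one per probe:
#'   `upper-right`, `upper-left`, `lower-right`, `lower-left`,
#'   `nonsignificant`.
#' @export
classify_quadrants <- function(stats, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  thr <- -log10(alpha)
  x <- stats$signed_logp_accel
  y <- stats$signed_logp_status
  lab <- rep("nonsignificant", nrow(stats))
  sig <- abs(x) > thr & abs(y) > thr
  lab[sig & x > 0 & y > 0] <- "upper-right"
  lab[sig & x < 0 & y > 0] <- "upper-left"
  lab[sig & x > 0 & y < 0] <- "lower-right"
  lab[sig & x < 0 & y < 0] <- "lower-left"
  lab
}

#' Cross-dataset preservation of a marginal statistic
#'
#' Pearson correlation of a chosen signed statistic across the probes shared
#' by two marginal-stats tables — the degree to which per-CpG associations
#' replicate between datasets.
#'
#' @param statsA,statsB `marginal_stats` data frames.
#' @param field Column to correlate (default `"signed_logp_accel"`).
#' @return Correlation (numeric scalar).
#' @export
preservation_correlation <- function(statsA, statsB,
                                     field = "signed_logp_accel") {
  shared <- intersect(statsA$probe_id, statsB$probe_id)
  if (length(shared) < 10L)
    stop("need >= 10 shared probes, got ", length(shared))
  a <- statsA[[field]][match(shared, statsA$probe_id)]
  b <- statsB[[field]][match(shared, statsB$probe_id)]
  stats::cor(a, b)
}

#' Stouffer weighted z-score meta-analysis
#'
#' Combines per-dataset z-scores as `sum(w_i z_i) / sqrt(sum(w_i^2))` with a
#' two-sided normal P. Missing z-scores are dropped (with their weights); a
#' single input is returned unchanged.
#'
#' @param z Numeric vector of z-scores (one per dataset).
#' @param weights Positive weights; default equal. Use `sqrt(n)` per dataset
#'   for the sample-size-weighted variant.
#' @return Object of class `meta_result` with `combined_z`, `combined_p`,
#'   `method = "stouffer"`, `per_dataset_inputs`.
#' @export
stouffer_meta <- function(z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(z))
  stopifnot(length(weights) == length(z))
  if (any(weights <= 0, na.rm = TRUE)) stop("weights must be positive")
  ok <- is.finite(z)
  if (!any(ok)) stop("no finite z-scores to combine")
  z <- z[ok]; w <- weights[ok]
  cz <- sum(w * z) / sqrt(sum(w^2))
  structure(list(combined_z = cz,
                 combined_p = 2 * stats::pnorm(-abs(cz)),
                 method = "stouffer",
                 per_dataset_inputs = data.frame(z = z, weight = w)),
            class = "meta_result")
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-dataset coefficient estimates with weights `1/SE^2`:
#' pooled estimate `sum(w e) / sum(w)`, pooled SE `1/sqrt(sum(w))`, Wald P.
#' When per-dataset years-of-acceleration values are supplied their
#' unweighted mean is reported as a secondary summary.
#'
#' @param estimates Numeric vector of per-dataset estimates.
#' @param ses Positive standard errors, same length.
#' @param years Optional per-dataset years-of-acceleration values.
#' @return Object of class `meta_result` with `estimate`, `se`, `combined_z`,
#'   `combined_p`, `mean_years`, `method = "inverse_variance"`,
#'   `per_dataset_inputs`.
#' @export
fixed_effects_meta <- function(estimates, ses, years = NULL) {
  stopifnot(length(estimates) == length(ses))
  if (length(estimates) < 1L) stop("need >= 1 estimate")
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("every SE must be finite and > 0")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- est / se
  structure(list(estimate = est, se = se, combined_z = z,
                 combined_p = 2 * stats::pnorm(-abs(z)),
                 mean_years = if (is.null(years)) NA_real_ else mean(years),
                 method = "inverse_variance",
                 per_dataset_inputs = data.frame(estimate = estimates,
                                                 se = ses)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s, %d dataset(s))\n", x$method,
              nrow(x$per_dataset_inputs)))
  if (x$method == "inverse_variance") {
    cat(sprintf("  pooled estimate %.4g (SE %.4g), z = %.3f, p = %.3g\n",
                x$estimate, x$se, x$combined_z, x$combined_p))
    if (is.finite(x$mean_years))
      cat(sprintf("  unweighted mean years-of-acceleration: %.1f\n",
                  x$mean_years))
  } else {
    cat(sprintf("  combined z = %.3f, p = %.3g\n", x$combined_z,
                x$combined_p))
  }
  invisible(x)
}

#' Scatter plot of marginal statistics
#'
#' Signed `-log10 P` for acceleration on the x-axis against signed
#' `-log10 P` for case status on the y-axis; clock CpGs coloured red
#' (positive training age correlation) and blue (negative), others grey;
#' dashed lines mark the uncorrected `alpha` threshold on both axes.
#'
#' @param x A `marginal_stats` data frame.
#' @param alpha Threshold drawn on both axes (default 0.05).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.marginal_stats <- function(x, alpha = 0.05, ...) {
  col <- c(non_clock = "grey50", clock_pos = "red",
           clock_neg = "blue")[x$clock_flag]
  graphics::plot(x$signed_logp_accel, x$signed_logp_status, col = col,
                 pch = 16, cex = 0.6,
                 xlab = "signed -log10 P (age acceleration)",
                 ylab = "signed -log10 P (case status)", ...)
  thr <- -log10(alpha)
  graphics::abline(v = c(-thr, thr), h = c(-thr, thr), col = "red",
                   lty = 2)
  invisible(x)
}
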