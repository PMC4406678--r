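#' Control-anchored epigenetic age acceleration
#'
#' Regresses DNAm age on chronological age over the control samples by
#' ordinary least squares and defines, for every sample (case and control),
#' acceleration as the vertical distance to that control regression line. By
#' construction the control accelerations have mean zero and are uncorrelated
#' with chronological age; a positive value marks a sample whose DNAm age is
#' higher than expected for its chronological age.
#'
#' @param predictions Data frame from [predict_dnam_age()] (needs
#'   `sample_id`, `dnam_age`).
#' @param annotations Data frame with `sample_id`, `age`, `status`.
#' @param controls Which samples anchor the regression: `"control"` (default;
#'   other-disease samples excluded), `"non_case"` (controls plus
#'   other-disease), or a logical/character vector selecting samples directly.
#' @return Data frame of class `acceleration_result` with columns
#'   `sample_id`, `age`, `status`, `dnam_age`, `acceleration` (years) and an
#'   attribute `control_fit` = list(slope, intercept, r, r2, n_controls).
#' @export
compute_age_acceleration <- function(predictions, annotations,
                                     controls = c("control", "non_case")) {
  d <- merge(annotations, predictions, by = "sample_id", sort = FALSE)
  d <- d[match(predictions$sample_id, d$sample_id), , drop = FALSE]
  if (is.character(controls) && length(controls) > 1L &&
      all(controls %in% c("control", "non_case")))
    controls <- controls[1L]
  if (is.character(controls) && length(controls) == 1L &&
      controls %in% c("control", "non_case")) {
    is_ctrl <- if (controls == "control") d$status == "control"
               else d$status != "case"
  } else if (is.logical(controls)) {
    stopifnot(length(controls) == nrow(d))
    is_ctrl <- controls
  } else {
    is_ctrl <- d$sample_id %in% controls
  }
  ctl <- d[is_ctrl, , drop = FALSE]
  if (nrow(ctl) < 3L)
    stop("need >= 3 control samples to anchor the regression, got ",
         nrow(ctl))
  if (stats::sd(ctl$age) == 0)
    stop("zero age variance among controls; regression undefined")
  fit <- stats::lm(dnam_age ~ age, data = ctl)
  co <- stats::coef(fit)
  accel <- d$dnam_age - (co[[1L]] + co[[2L]] * d$age)
  out <- data.frame(sample_id = d$sample_id, age = d$age, status = d$status,
                    dnam_age = d$dnam_age, acceleration = accel,
                    stringsAsFactors = FALSE)
  attr(out, "control_fit") <- list(
    slope = unname(co[[2L]]), intercept = unname(co[[1L]]),
    r = stats::cor(ctl$age, ctl$dnam_age),
    r2 = stats::cor(ctl$age, ctl$dnam_age)^2, n_controls = nrow(ctl))
  class(out) <- c("acceleration_result", class(out))
  out
}

#' Multivariate regression of DNAm age on age and case status
#'
#' Fits `dnam_age ~ chronological age + status (+ covariates)` by least
#' squares, with status coded 1 for cases and 0 otherwise, and reports
#' classical standard errors and two-sided Wald P-values (normal reference).
#' The ratio of the status and age coefficients is the years-of-acceleration
#' summary ([years_of_acceleration()]).
#'
#' @param dnam_age Numeric vector of DNAm ages (years).
#' @param age Numeric vector of chronological ages (years).
#' @param status Case indicator: logical, 0/1 numeric, or a factor/character
#'   where `"case"` marks cases.
#' @param covariates Optional data frame (or named list) of extra numeric
#'   covariates, e.g. sex indicator, per-sample mean beta, cell proportions.
#' @return Object of class `regression_fit`: list with `terms` (data frame
#'   term/estimate/se/p), `r2`, `n`, `sigma`, `years_of_acceleration`.
#' @export
fit_multivariate <- function(dnam_age, age, status, covariates = NULL) {
  ds <- encode_status(status)
  X <- cbind(`(Intercept)` = 1, `Chronological age` = age, DS = ds)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    stopifnot(nrow(cv) == length(dnam_age))
    X <- cbind(X, as.matrix(cv))
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    aliased <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, dnam_age)
  n <- length(dnam_age); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  est <- fit$coefficients
  pval <- 2 * stats::pnorm(-abs(est / se))
  tss <- sum((dnam_age - mean(dnam_age))^2)
  out <- list(terms = data.frame(term = colnames(X), estimate = unname(est),
                                 se = unname(se), p = unname(pval),
                                 stringsAsFactors = FALSE),
              r2 = 1 - rss / tss, n = n, sigma = sqrt(sigma2))
  class(out) <- "regression_fit"
  out$years_of_acceleration <- tryCatch(years_of_acceleration(out),
                                        error = function(e) NA_real_)
  out
}

encode_status <- function(status) {
  if (is.logical(status)) return(as.numeric(status))
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1))) stop("numeric status must be 0/1")
    return(as.numeric(status))
  }
  as.numeric(as.character(status) == "case")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit (n = %d, R-squared = %.3f)\n", x$n, x$r2))
  tt <- x$terms
  tt$estimate <- signif(tt$estimate, 6)
  tt$se <- signif(tt$se, 4)
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  if (is.finite(x$years_of_acceleration))
    cat(sprintf("Age acceleration for cases: %.1f years\n",
                x$years_of_acceleration))
  invisible(x)
}

#' Years-of-acceleration ratio
#'
#' Expresses the case effect on the chronological-year scale as the ratio of
#' the case-status coefficient to the age coefficient from a multivariate
#' regression of DNAm age. Full precision is returned; round to one decimal
#' only when reporting.
#'
#' @param fit A `regression_fit` (or `mixed_model_fit`) containing terms
#'   `"Chronological age"` and `"DS"`.
#' @return The ratio beta_DS / beta_age, in years.
#' @export
years_of_acceleration <- function(fit) {
  terms <- if (inherits(fit, "mixed_model_fit")) fit$fixed_terms else fit$terms
  b_age <- terms$estimate[terms$term == "Chronological age"]
  b_ds <- terms$estimate[terms$term == "DS"]
  if (length(b_age) != 1L || length(b_ds) != 1L)
    stop("fit must contain terms 'Chronological age' and 'DS'")
  if (b_age == 0) stop("age coefficient is zero; ratio undefined")
  b_ds / b_age
}

#' Nonparametric group comparison of accelerations (Kruskal-Wallis)
#'
#' Midrank-based Kruskal-Wallis test with tie correction and a chi-square
#' upper-tail P (df = number of groups - 1), plus per-group mean and standard
#' error of the values. When every observation is identical the statistic is
#' 0 and P is 1 (no discrimination, not an error). A warning is logged when
#' any group has fewer than 5 observations (chi-square approximation
#' questionable).
#'
#' @param values_by_group Named list of numeric vectors, one per group; or a
#'   numeric vector plus a `groups` factor.
#' @param groups Optional grouping factor when `values_by_group` is a vector.
#' @return Object of class `group_test_result`: list with `statistic` (H),
#'   `df`, `p`, `group_means`, `group_ses`, `group_ns`.
#' @export
kruskal_wallis <- function(values_by_group, groups = NULL) {
  if (!is.null(groups)) {
    values_by_group <- split(as.numeric(values_by_group), groups)
  }
  values_by_group <- values_by_group[lengths(values_by_group) > 0L]
  k <- length(values_by_group)
  if (k < 2L) stop("need >= 2 nonempty groups")
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("group", seq_len(k))
  if (any(lengths(values_by_group) < 5L))
    warning("group(s) with < 5 observations; P-value approximation is crude")
  x <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), lengths(values_by_group)),
              levels = names(values_by_group))
  if (length(unique(x)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- suppressWarnings(stats::kruskal.test(x, g))
    H <- unname(kt$statistic); p <- kt$p.value
  }
  means <- vapply(values_by_group, mean, numeric(1))
  ses <- vapply(values_by_group,
                function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
  structure(list(statistic = H, df = k - 1L, p = p,
                 group_means = means, group_ses = ses,
                 group_ns = lengths(values_by_group)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  print(data.frame(group = names(x$group_means),
                   n = unname(x$group_ns),
                   mean = signif(unname(x$group_means), 4),
                   se = signif(unname(x$group_ses), 3)), row.names = FALSE)
  invisible(x)
}

#' Stratified acceleration analysis
#'
#' Re-runs the control-anchored acceleration analysis independently within
#' each level of a stratifying annotation (e.g. brain region): the control
#' regression is refit per stratum, so control accelerations are mean-zero
#' within every stratum. Strata smaller than `min_size` are skipped with a
#' logged reason.
#'
#' @param predictions Data frame from [predict_dnam_age()].
#' @param annotations Sample annotations including `stratum_field`.
#' @param stratum_field Name of the annotation column to stratify by.
#' @param min_size Minimum stratum size (default 6); smaller strata skipped.
#' @param controls Passed to [compute_age_acceleration()].
#' @return Named list, one element per analysed stratum: list with
#'   `acceleration` (an `acceleration_result`) and `group_test`
#'   (a `group_test_result` of acceleration by status, when >= 2 status
#'   groups are present). Skipped strata appear with a `skipped` reason.
#' @export
run_stratified <- function(predictions, annotations, stratum_field,
                           min_size = 6L, controls = "control") {
  if (!stratum_field %in% names(annotations))
    stop("stratum field not in annotations: ", stratum_field)
  strata <- split(annotations, annotations[[stratum_field]])
  out <- list()
  for (nm in names(strata)) {
    ann_s <- strata[[nm]]
    if (nrow(ann_s) < min_size) {
      message(sprintf("stratum '%s' skipped: %d samples < min_size %d",
                      nm, nrow(ann_s), min_size))
      out[[nm]] <- list(skipped = sprintf("n = %d < %d", nrow(ann_s),
                                          min_size))
      next
    }
    pred_s <- predictions[predictions$sample_id %in% ann_s$sample_id, ,
                          drop = FALSE]
    res <- tryCatch({
      acc <- compute_age_acceleration(pred_s, ann_s, controls = controls)
      gt <- NULL
      if (length(unique(droplevels(factor(acc$status)))) >= 2L) {
        gt <- suppressWarnings(
          kruskal_wallis(split(acc$acceleration, droplevels(factor(acc$status)))))
      }
      list(acceleration = acc, group_test = gt)
    }, error = function(e) list(skipped = conditionMessage(e)))
    out[[nm]] <- res
  }
  out
}
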