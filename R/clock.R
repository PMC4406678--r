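#' Construct a linear DNAm clock
#'
#' A linear clock predicts a transformed age score as
#' `intercept + sum_p weight_p * beta_p` and maps the score back to years
#' through [inverse_transform_age()]. `adult_age` parameterises the
#' calibration transform (log-linear below `adult_age`, linear above).
#'
#' @param weights Named numeric vector, probe id -> weight (per beta unit).
#' @param intercept Intercept on the transformed-age scale.
#' @param adult_age Calibration knot in years (> 0); default 20.
#' @param name Clock name used in reports.
#' @param gold_means Optional named vector of gold-standard mean beta values
#'   in `[0, 1]`, the first imputation tier for missing probes.
#' @param age_cor Optional named vector of training-set age correlations per
#'   clock CpG (used to colour clock CpGs in marginal plots).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(weights, intercept, adult_age = 20, name = "clock",
                        gold_means = NULL, age_cor = NULL) {
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("weights must be uniquely named by probe id")
  if (!is.finite(adult_age) || adult_age <= 0)
    stop("adult_age must be > 0")
  if (!is.null(gold_means)) {
    if (any(gold_means < 0 | gold_means > 1, na.rm = TRUE))
      stop("gold_means must lie in [0,1]")
  }
  structure(list(weights = weights, intercept = intercept,
                 adult_age = adult_age, name = name,
                 gold_means = gold_means, age_cor = age_cor),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model '%s': %d CpGs, intercept %.4g, adult_age %g\n",
              x$name, length(x$weights), x$intercept, x$adult_age))
  invisible(x)
}

#' Calibrated age transform
#'
#' Maps chronological age (years) to the scale on which the clock is linear:
#' `log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, and
#' `(age - adult_age) / (adult_age + 1)` above. Continuous, strictly
#' increasing, and zero exactly at `age = adult_age`.
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @param adult_age Calibration knot in years (> 0).
#' @return Transformed ages (unitless).
#' @export
transform_age <- function(age, adult_age = 20) {
  if (any(!is.finite(age)) || any(age < 0)) stop("age must be >= 0 and finite")
  if (adult_age <= 0) stop("adult_age must be > 0")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse of the calibrated age transform
#'
#' Exact functional inverse of [transform_age()] on its image; negative
#' scores map through the exponential branch, so the result is bounded below
#' by `-1`.
#'
#' @param t Transformed age score(s).
#' @param adult_age Calibration knot in years (> 0).
#' @return Ages in years.
#' @export
inverse_transform_age <- function(t, adult_age = 20) {
  if (adult_age <= 0) stop("adult_age must be > 0")
  ifelse(t <= 0,
         exp(t + log(adult_age + 1)) - 1,
         t * (adult_age + 1) + adult_age)
}

#' Complete the clock-probe submatrix of a cohort
#'
#' Extracts the clock probes from the cohort and fills missing cells (probes
#' absent from the array, or individual missing values) by a three-tier rule:
#' the clock's gold-standard mean when available, else the cohort-wide mean of
#' that probe, else 0.5. A clock is declared inapplicable when more than half
#' of its probes are entirely absent from the cohort.
#'
#' @param cohort A [methylation_cohort()] (or bare beta matrix).
#' @param clock A [clock_model()].
#' @return List with `beta` (clock probes x samples, complete),
#'   `report` (counts filled per tier: `gold`, `cohort_mean`, `default`) and
#'   `n_imputed_per_sample`.
#' @export
impute_missing_probes <- function(cohort, clock) {
  beta <- if (inherits(cohort, "methylation_cohort")) cohort$beta else cohort
  probes <- names(clock$weights)
  absent <- setdiff(probes, rownames(beta))
  if (length(absent) > length(probes) / 2)
    stop(sprintf(paste0("clock inapplicable: %d of %d clock probes absent ",
                        "from the cohort (> 50%%)"),
                 length(absent), length(probes)))
  sub <- matrix(NA_real_, length(probes), ncol(beta),
                dimnames = list(probes, colnames(beta)))
  present <- intersect(probes, rownames(beta))
  sub[present, ] <- beta[present, , drop = FALSE]

  report <- c(gold = 0L, cohort_mean = 0L, default = 0L)
  miss <- which(is.na(sub), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    cohort_means <- rowMeans(sub, na.rm = TRUE)  # NaN for all-missing probes
    for (i in seq_len(nrow(miss))) {
      p <- probes[miss[i, 1L]]
      gm <- if (!is.null(clock$gold_means)) clock$gold_means[p] else NA_real_
      if (!is.na(gm)) {
        sub[miss[i, 1L], miss[i, 2L]] <- gm
        report["gold"] <- report["gold"] + 1L
      } else if (is.finite(cohort_means[miss[i, 1L]])) {
        sub[miss[i, 1L], miss[i, 2L]] <- cohort_means[miss[i, 1L]]
        report["cohort_mean"] <- report["cohort_mean"] + 1L
      } else {
        sub[miss[i, 1L], miss[i, 2L]] <- 0.5
        report["default"] <- report["default"] + 1L
      }
    }
  }
  n_per_sample <- integer(ncol(sub))
  names(n_per_sample) <- colnames(sub)
  if (nrow(miss) > 0L) {
    tb <- table(factor(miss[, 2L], levels = seq_len(ncol(sub))))
    n_per_sample[] <- as.integer(tb)
  }
  list(beta = sub, report = report, n_imputed_per_sample = n_per_sample)
}

#' Predict DNAm age for every sample in a cohort
#'
#' Computes, per sample, the linear clock score on the transformed scale and
#' maps it to years through [inverse_transform_age()]. Missing clock probes
#' are completed by [impute_missing_probes()] first. Probes in the cohort
#' that are not in the clock have no effect.
#'
#' @param cohort A [methylation_cohort()] (or bare beta matrix).
#' @param clock A [clock_model()].
#' @return Data frame with one row per sample, in cohort order:
#'   `sample_id`, `dnam_age` (years), `n_imputed_probes`, `mean_beta`
#'   (cohort-wide mean beta per sample, exported for use as a covariate),
#'   `clock_name`.
#' @export
predict_dnam_age <- function(cohort, clock) {
  beta_full <- if (inherits(cohort, "methylation_cohort")) cohort$beta else cohort
  imp <- impute_missing_probes(cohort, clock)
  w <- clock$weights[rownames(imp$beta)]
  score <- clock$intercept + as.vector(crossprod(imp$beta, w))
  data.frame(sample_id = colnames(imp$beta),
             dnam_age = inverse_transform_age(score, clock$adult_age),
             n_imputed_probes = unname(imp$n_imputed_per_sample),
             mean_beta = unname(colMeans(beta_full, na.rm = TRUE)),
             clock_name = clock$name,
             stringsAsFactors = FALSE)
}
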