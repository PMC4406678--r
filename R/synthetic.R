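#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the study cohorts this pipeline is built
#' for: a blood-sized case/control cohort (30 cases, 60 controls) with ages
#' spanning 20-80 years, a 353-CpG linear clock, an injected case
#' acceleration of 6.6 years, transformed-scale noise equivalent to roughly
#' 2 years of prediction error above the calibration knot, a 6-cell-type
#' blood mixture with case shifts (fewer CD4T/B, more NK), 29 sibships for
#' the family design, and 10 planted case-associated CpGs among 1000
#' background probes.
#'
#' @param n_controls,n_cases,n_other Sample counts per group.
#' @param age_range Two-element vector, years.
#' @param delta Injected case acceleration in years (cases' clock CpGs are
#'   generated at effective age `age + delta`).
#' @param clock_size Number of clock CpGs.
#' @param n_background_probes Non-clock probes (the first
#'   `n_planted_ds_cpgs` of them carry a planted case signal).
#' @param noise_sd_transformed SD of per-sample additive noise on the
#'   transformed age scale (0.095 corresponds to ~2 years above the knot
#'   for `adult_age = 20`).
#' @param adult_age Calibration knot passed to the generated clock.
#' @param cell_types Number of cell types (0 disables mixtures).
#' @param mixture_concentration Dirichlet concentration scale for mixing
#'   weights (larger = less spread).
#' @param composition_shift Named per-cell-type additive shift applied to
#'   case mixing weights before renormalisation (`NULL` = default blood-like
#'   shift).
#' @param n_signature_probes Probes in the generated signature matrix.
#' @param n_sibships Sibships for the family design.
#' @param between_sibship_sd,within_sibship_sd Year-scale SDs of the shared
#'   sibship age offset and of individual noise in the sibship design.
#' @param n_planted_ds_cpgs Background CpGs given a case effect.
#' @param planted_effect_beta Case mean-beta shift of planted CpGs (in
#'   (-0.5, 0.5)).
#' @param planted_accel_slope Beta units per year of acceleration signal in
#'   planted CpGs (makes planted CpGs concordant: hyper in cases and
#'   positively correlated with acceleration).
#' @param background_noise_sd Beta-scale measurement noise SD for
#'   background/signature probes.
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_controls = 60L, n_cases = 30L, n_other = 0L,
                             age_range = c(20, 80), delta = 6.6,
                             clock_size = 353L,
                             n_background_probes = 1000L,
                             noise_sd_transformed = 0.095,
                             adult_age = 20,
                             cell_types = 6L,
                             mixture_concentration = 30,
                             composition_shift = NULL,
                             n_signature_probes = 600L,
                             n_sibships = 29L,
                             between_sibship_sd = 3,
                             within_sibship_sd = 2,
                             n_planted_ds_cpgs = 10L,
                             planted_effect_beta = 0.1,
                             planted_accel_slope = 0.004,
                             background_noise_sd = 0.02,
                             seed = 1L) {
  n_planted_ds_cpgs <- min(n_planted_ds_cpgs, n_background_probes)
  cfg <- as.list(environment())
  stopifnot(n_controls >= 0, n_cases >= 0, n_other >= 0,
            length(age_range) == 2L, age_range[1L] < age_range[2L],
            clock_size >= 1L, noise_sd_transformed >= 0,
            between_sibship_sd >= 0, within_sibship_sd >= 0,
            background_noise_sd >= 0,
            abs(planted_effect_beta) < 0.5)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic linear clock with exact ground truth
#'
#' Each clock CpG's expected beta is an affine function of transformed age,
#' `beta_j(t) = a_j + b_j t`, with slopes of mixed signs centred so the curve
#' stays inside `[0.02, 0.98]` over the configured age range. Weights are
#' `w_j = b_j / sum(b^2)` and the intercept `-sum(w_j a_j)`, so the noiseless
#' linear predictor returns the transformed age exactly and the clock inverts
#' its own construction. The per-CpG training age correlation annotation is
#' the sign of `b_j`.
#'
#' @param clock_size Number of clock CpGs.
#' @param adult_age Calibration knot (years).
#' @param age_range Age range (years) the curves must cover.
#' @param slope_range Absolute slope range in beta per transformed-age unit;
#'   `NULL` (default) picks a feasible range from `age_range`. Slopes whose
#'   curves would exit `[0.02, 0.98]` over the range are an error.
#' @param seed Integer seed.
#' @return A [clock_model()] with attribute `truth` = list(a, b) giving the
#'   per-CpG affine coefficients.
#' @export
generate_clock <- function(clock_size = 353L, adult_age = 20,
                           age_range = c(20, 80), slope_range = NULL,
                           seed = 1L) {
  stopifnot(clock_size >= 1L)
  set.seed(seed)
  t_lo <- transform_age(age_range[1L], adult_age)
  t_hi <- transform_age(age_range[2L], adult_age)
  h <- (t_hi - t_lo) / 2
  t_mid <- (t_hi + t_lo) / 2
  if (is.null(slope_range)) slope_range <- c(0.2, 0.9) * 0.48 / h
  if (max(slope_range) * h > 0.48)
    stop(sprintf(paste0("infeasible clipping: max slope %.3g over half-range",
                        " %.3g exits [0.02, 0.98]"), max(slope_range), h))
  sgn <- rep(c(1, -1), length.out = clock_size)
  b <- sgn * stats::runif(clock_size, slope_range[1L], slope_range[2L])
  a <- 0.5 - b * t_mid
  w <- b / sum(b^2)
  intercept <- -sum(w * a)
  probes <- sprintf("cgS%05d", seq_len(clock_size))
  names(w) <- names(a) <- names(b) <- probes
  gold_ref_age <- min(max(45, age_range[1L]), age_range[2L])
  gold <- a + b * transform_age(gold_ref_age, adult_age)
  clock <- clock_model(weights = w, intercept = intercept,
                       adult_age = adult_age, name = "synthetic-clock",
                       gold_means = gold,
                       age_cor = stats::setNames(sgn, probes))
  attr(clock, "truth") <- list(a = a, b = b)
  clock
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic cell-type signature matrix
#'
#' Random probe-by-cell-type mean beta values, uniform on `[0.05, 0.95]`;
#' columns are well separated with overwhelming probability, which is what
#' the constrained projection needs.
#'
#' @param n_probes Number of signature probes.
#' @param cell_types Number of cell types (named like blood leukocyte
#'   fractions when <= 6).
#' @param seed Integer seed.
#' @return A `signature_matrix` (probes x cell types).
#' @export
generate_signature <- function(n_probes = 600L, cell_types = 6L, seed = 1L) {
  set.seed(seed)
  blood <- c("CD4T", "CD8T", "B", "NK", "Mono", "Gran")
  cts <- if (cell_types <= 6L) blood[seq_len(cell_types)]
         else c(blood, paste0("CT", seq_len(cell_types - 6L)))
  m <- matrix(stats::runif(n_probes * cell_types, 0.05, 0.95),
              n_probes, cell_types,
              dimnames = list(sprintf("cgC%05d", seq_len(n_probes)), cts))
  validate_signature_matrix(m)
}

default_composition_shift <- function(cell_types) {
  shift <- stats::setNames(rep(0, length(cell_types)), cell_types)
  if ("CD4T" %in% cell_types) shift["CD4T"] <- -0.05
  if ("B" %in% cell_types) shift["B"] <- -0.03
  if ("NK" %in% cell_types) shift["NK"] <- 0.08
  shift
}

#' Generate a synthetic methylation cohort with known ground truth
#'
#' Builds a [methylation_cohort()] whose every feature is known: ages drawn
#' uniformly from `age_range`; cases' clock CpGs generated at effective age
#' `age + delta` (acceleration injected on the chronological-year scale);
#' per-sample additive noise on the transformed scale, back-propagated to
#' beta space through the clock construction (so year-scale error is
#' age-dependent below the calibration knot); optional cell-type mixtures
#' with a case composition shift; planted case-associated background CpGs
#' that are both hypermethylated in cases and positively correlated with
#' acceleration; and, under the sibship design, a shared per-sibship
#' year-scale age offset plus individual noise.
#'
#' @param config A [synthetic_config()].
#' @param design `"case_control"` (default) or `"sibship"` (each sibship:
#'   one case, one unaffected sibling, one mother — all sharing the sibship
#'   offset).
#' @return A `methylation_cohort` with attribute `truth`: list with
#'   `clock` (the generating [clock_model()]), `true_age`, `effective_age`,
#'   `noise_t`, `status`, `planted_probes`, `signature`, `mixtures`
#'   (cell types x samples, columns sum to 1, when mixtures enabled),
#'   `sibship_offsets` (sibship design only).
#' @export
generate_cohort <- function(config = synthetic_config(),
                            design = c("case_control", "sibship")) {
  design <- match.arg(design)
  cfg <- config
  set.seed(cfg$seed)
  clock <- generate_clock(cfg$clock_size, cfg$adult_age, cfg$age_range,
                          seed = cfg$seed + 1L)
  truth_ab <- attr(clock, "truth")

  if (design == "case_control") {
    n <- cfg$n_controls + cfg$n_cases + cfg$n_other
    if (n < 1L) stop("empty cohort")
    status <- c(rep("control", cfg$n_controls), rep("case", cfg$n_cases),
                rep("other-disease", cfg$n_other))
    age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])
    sibship <- rep("unknown", n)
    sib_off <- NULL
  } else {
    ns <- cfg$n_sibships
    if (ns < 2L) stop("sibship design needs >= 2 sibships")
    n <- 3L * ns
    status <- rep(c("case", "control", "control"), ns)   # DS, sib, mother
    fam_age <- stats::runif(ns, max(cfg$age_range[1L], 9), 50)
    age <- as.vector(rbind(fam_age,
                           fam_age + stats::runif(ns, -5, 5),
                           fam_age + 25))
    sibship <- rep(sprintf("fam%03d", seq_len(ns)), each = 3L)
    sib_off <- stats::rnorm(ns, 0, cfg$between_sibship_sd)
  }
  is_case <- status == "case"

  eff_age <- age + ifelse(is_case, cfg$delta, 0)
  if (design == "sibship") {
    eff_age <- eff_age + rep(sib_off, each = 3L) +
      stats::rnorm(n, 0, cfg$within_sibship_sd)
  }
  if (any(eff_age < 0))
    stop("delta/offsets push effective age below 0")
  noise_t <- stats::rnorm(n, 0, cfg$noise_sd_transformed)
  t_eff <- transform_age(eff_age, cfg$adult_age) + noise_t

  clip01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  # clock CpG block: beta = a + b * (t + noise), exactly invertible at noise 0
  beta_clock <- clip01(outer(truth_ab$a, rep(1, n)) +
                         outer(truth_ab$b, t_eff))
  rownames(beta_clock) <- names(clock$weights)

  blocks <- list(beta_clock)
  signature <- NULL; mixtures <- NULL
  if (cfg$cell_types > 0L) {
    signature <- generate_signature(cfg$n_signature_probes, cfg$cell_types,
                                    seed = cfg$seed + 2L)
    k <- ncol(signature)
    base <- rep(1 / k, k)
    shift <- cfg$composition_shift
    if (is.null(shift)) shift <- default_composition_shift(colnames(signature))
    mixtures <- vapply(seq_len(n), function(i) {
      w <- rdirichlet1(base * cfg$mixture_concentration)
      if (is_case[i]) {
        w <- w + shift[colnames(signature)]
        w <- pmax(w, 0.005)
        w <- w / sum(w)
      }
      w
    }, numeric(k))
    rownames(mixtures) <- colnames(signature)
    colnames(mixtures) <- NULL
    beta_sig <- clip01(signature %*% mixtures +
                         matrix(stats::rnorm(nrow(signature) * n, 0,
                                             cfg$background_noise_sd),
                                nrow(signature), n))
    rownames(beta_sig) <- rownames(signature)
    blocks <- c(blocks, list(beta_sig))
  }
  planted <- character(0)
  if (cfg$n_background_probes > 0L) {
    base_mean <- stats::runif(cfg$n_background_probes, 0.1, 0.9)
    bg <- outer(base_mean, rep(1, n)) +
      matrix(stats::rnorm(cfg$n_background_probes * n, 0,
                          cfg$background_noise_sd),
             cfg$n_background_probes, n)
    rownames(bg) <- sprintf("cgB%05d", seq_len(cfg$n_background_probes))
    if (cfg$n_planted_ds_cpgs > 0L) {
      planted <- rownames(bg)[seq_len(cfg$n_planted_ds_cpgs)]
      # acceleration signal on the year scale: per-sample transformed noise
      # back-converted (~ (adult_age+1) * noise above the knot) plus delta
      accel_years <- (cfg$adult_age + 1) * noise_t +
        ifelse(is_case, cfg$delta, 0)
      plant_sig <- outer(rep(1, cfg$n_planted_ds_cpgs),
                         cfg$planted_effect_beta * as.numeric(is_case) +
                           cfg$planted_accel_slope * accel_years)
      bg[seq_len(cfg$n_planted_ds_cpgs), ] <-
        bg[seq_len(cfg$n_planted_ds_cpgs), ] + plant_sig
    }
    blocks <- c(blocks, list(clip01(bg)))
  }

  beta <- do.call(rbind, blocks)
  sample_ids <- sprintf("s%03d", seq_len(n))
  colnames(beta) <- sample_ids
  if (!is.null(mixtures)) colnames(mixtures) <- sample_ids
  ann <- data.frame(sample_id = sample_ids, age = age,
                    status = factor(status, levels = c("case", "control",
                                                       "other-disease")),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    tissue = "whole blood", region = "unknown",
                    sibship = sibship, dataset_id = "synthetic",
                    stringsAsFactors = FALSE)
  cohort <- methylation_cohort(beta, ann)
  attr(cohort, "truth") <- list(clock = clock, true_age = age,
                                effective_age = eff_age, noise_t = noise_t,
                                status = status, planted_probes = planted,
                                signature = signature, mixtures = mixtures,
                                sibship_offsets = sib_off, config = cfg)
  cohort
}

#' Simulate year-scale sibship data for the mixed model
#'
#' Lightweight generator for the random-intercept model alone:
#' `dnam_age = intercept + slope * age + effect * status + u_sibship + e`,
#' with `u ~ N(0, between_sd^2)` shared within sibship and
#' `e ~ N(0, within_sd^2)`. Each sibship is a discordant pair (one case, one
#' control) of similar ages.
#'
#' @param n_sibships Number of sibships (discordant pairs).
#' @param effect Case effect in years.
#' @param between_sd,within_sd SDs of the sibship intercept and residual.
#' @param slope,intercept Fixed-effect truth (defaults 1 and 0).
#' @param age_range Age range for the sibship base age.
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `dnam_age`, `age`, `status`, `sibship`
#'   with attribute `truth`.
#' @export
simulate_sibship_data <- function(n_sibships = 29L, effect = 3.86,
                                  between_sd = 3, within_sd = 2,
                                  slope = 1, intercept = 0,
                                  age_range = c(9, 60), seed = 1L) {
  set.seed(seed)
  ns <- n_sibships
  fam_age <- stats::runif(ns, age_range[1L], age_range[2L])
  age <- as.vector(rbind(fam_age, fam_age + stats::runif(ns, -5, 5)))
  age <- pmax(age, 0)
  status <- rep(c("case", "control"), ns)
  u <- rep(stats::rnorm(ns, 0, between_sd), each = 2L)
  e <- stats::rnorm(2L * ns, 0, within_sd)
  dnam <- intercept + slope * age + effect * (status == "case") + u + e
  out <- data.frame(sample_id = sprintf("p%04d", seq_len(2L * ns)),
                    dnam_age = dnam, age = age, status = status,
                    sibship = rep(sprintf("fam%03d", seq_len(ns)), each = 2L),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(effect = effect, slope = slope,
                             intercept = intercept, between_sd = between_sd,
                             within_sd = within_sd)
  out
}

#' Write a synthetic cohort to disk in the package's file formats
#'
#' Emits the beta matrix (TSV), the sample sheet (CSV), the generating clock
#' file (CSV), the signature matrix when present (CSV), and a ground-truth
#' JSON sidecar — exactly the artifacts the readers in this package consume.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(cohort, "truth")
  paths <- list(beta = file.path(dir, "beta.tsv"),
                sheet = file.path(dir, "samples.csv"),
                clock = file.path(dir, "clock.csv"),
                truth = file.path(dir, "truth.json"))
  write_beta_matrix(cohort$beta, paths$beta)
  write_sample_sheet(cohort$annotations, paths$sheet)
  if (!is.null(truth$clock)) write_clock_file(truth$clock, paths$clock)
  if (!is.null(truth$signature)) {
    paths$signature <- file.path(dir, "signature.csv")
    sig <- truth$signature
    utils::write.csv(data.frame(probe_id = rownames(sig),
                                as.data.frame(unclass(sig)),
                                check.names = FALSE),
                     paths$signature, row.names = FALSE, quote = FALSE)
  }
  side <- list(true_age = truth$true_age,
               effective_age = truth$effective_age,
               status = truth$status,
               planted_probes = truth$planted_probes)
  if (!is.null(truth$mixtures)) side$mixtures <- truth$mixtures
  jsonlite::write_json(side, paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
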