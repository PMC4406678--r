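#' Build and validate a pipeline configuration
#'
#' @param beta Path to the beta matrix file.
#' @param sheet Path to the sample sheet.
#' @param clock Path to the clock coefficient file.
#' @param signature Optional path to a cell-type signature matrix; enables
#'   the composition and mediation stages.
#' @param output_dir Directory for result tables and the run manifest.
#' @param controls Control definition for the anchoring regression
#'   (`"control"` or `"non_case"`).
#' @param stratify_by Optional annotation column for a stratified re-run.
#' @param covariates Character vector of extra covariates for the
#'   multivariate model; supported: `"sex"`, `"mean_beta"`,
#'   `"cell_proportions"` (requires `signature`).
#' @param alpha Uncorrected significance threshold for quadrant calls.
#' @param seed Integer seed for the stochastic stages (mediation bootstrap).
#' @param status_aliases Optional extra status aliases for the sample sheet.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(beta, sheet, clock, signature = NULL,
                            output_dir = ".", controls = "control",
                            stratify_by = NULL, covariates = character(0),
                            alpha = 0.05, seed = 1L,
                            status_aliases = NULL) {
  cfg <- as.list(environment())
  for (f in c("beta", "sheet", "clock")) {
    if (!is.character(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("validation: ", f, " file not found: ", cfg[[f]],
           call. = FALSE)
  }
  if (!is.null(signature) && !file.exists(signature))
    stop("validation: signature file not found: ", signature, call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("validation: alpha must be in (0,1)")
  class(cfg) <- "pipeline_config"
  cfg
}

write_result_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full acceleration analysis pipeline
#'
#' Executes the analysis graph on a conforming set of input files: DNAm age
#' prediction, control-anchored acceleration, nonparametric group test,
#' multivariate regression (plus covariate variants), the sibship
#' random-intercept model when sibship labels are present, cell-composition
#' estimation and mediation when a signature is supplied, optional
#' stratified re-analysis, and per-CpG marginal statistics with quadrant
#' calls. All result tables are written as CSV under `output_dir` together
#' with a JSON run manifest (package version, seed, parameters, per-stage
#' status). Outputs are a pure function of the input files, the
#' configuration and the seed.
#'
#' @param config A [pipeline_config()].
#' @return A run report (named list of stage results) invisibly; the CSVs
#'   and `manifest.json` land in `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  manifest <- list(package = "epiaccel",
                   version = as.character(utils::packageVersion("epiaccel")),
                   seed = config$seed, alpha = config$alpha,
                   controls = config$controls,
                   covariates = config$covariates,
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("stage '%s' failed [E_STAGE_%s]: %s", name,
                   toupper(name), conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    report[[name]] <<- res
    res
  }

  cohort <- stage("read", read_cohort(config$beta, config$sheet,
                                      status_aliases = config$status_aliases))
  clock <- stage("clock", read_clock_file(config$clock))
  pred <- stage("predict", predict_dnam_age(cohort, clock))
  write_result_csv(pred, config$output_dir, "predictions")

  ann <- cohort$annotations
  accel <- stage("accelerate",
                 compute_age_acceleration(pred, ann,
                                          controls = config$controls))
  write_result_csv(as.data.frame(accel), config$output_dir, "acceleration")

  stage("group_test", {
    gt <- suppressWarnings(
      kruskal_wallis(split(accel$acceleration, droplevels(ann$status))))
    write_result_csv(data.frame(H = gt$statistic, df = gt$df, p = gt$p),
                     config$output_dir, "group_test")
    gt
  })

  comp <- NULL
  if (!is.null(config$signature)) {
    sig <- stage("signature", read_signature_matrix(config$signature))
    comp <- stage("cells", estimate_cell_composition(cohort, sig))
    write_result_csv(comp, config$output_dir, "cell_composition")
    stage("cell_tests", {
      ct <- test_composition_differences(comp, ann$status, accel)
      write_result_csv(ct, config$output_dir, "cell_tests")
      ct
    })
    stage("mediation", {
      cts <- setdiff(names(comp), c("sample_id", "residual_norm"))
      med <- mediation_test(ann$status, comp[[cts[1L]]],
                            accel$acceleration, seed = config$seed)
      write_result_csv(
        data.frame(mediator = cts[1L], total = med$total_effect,
                   direct = med$direct_effect,
                   indirect = med$indirect_effect, sobel_z = med$sobel_z,
                   sobel_p = med$sobel_p, ci_lo = med$bootstrap_ci[1L],
                   ci_hi = med$bootstrap_ci[2L],
                   note = "simplified product-of-coefficients, not full SEM"),
        config$output_dir, "mediation")
      med
    })
  }

  stage("multivariate", {
    covs <- NULL
    if (length(config$covariates)) {
      covs <- data.frame(row.names = seq_len(nrow(ann)))
      if ("sex" %in% config$covariates)
        covs$sex <- as.numeric(ann$sex == "F")
      if ("mean_beta" %in% config$covariates)
        covs$mean_beta <- pred$mean_beta
      if ("cell_proportions" %in% config$covariates) {
        if (is.null(comp))
          stop("cell_proportions covariate requires a signature")
        cts <- setdiff(names(comp), c("sample_id", "residual_norm"))
        # drop one proportion: they sum to 1 and would be collinear
        for (ct in cts[-length(cts)]) covs[[ct]] <- comp[[ct]]
      }
      if (!ncol(covs)) covs <- NULL
    }
    fit <- fit_multivariate(pred$dnam_age, ann$age, ann$status,
                            covariates = covs)
    tab <- fit$terms
    tab$r2 <- fit$r2
    tab$years_of_acceleration <- fit$years_of_acceleration
    write_result_csv(tab, config$output_dir, "multivariate")
    fit
  })

  if (any(ann$sibship != "unknown")) {
    stage("family", {
      keep <- ann$sibship != "unknown"
      fit <- fit_random_intercept(pred$dnam_age[keep], ann$age[keep],
                                  ann$status[keep], ann$sibship[keep])
      tab <- fit$fixed_terms
      tab$sigma2_between <- fit$sigma2_between
      tab$sigma2_within <- fit$sigma2_within
      write_result_csv(tab, config$output_dir, "family_model")
      fit
    })
  }

  if (!is.null(config$stratify_by)) {
    stage("stratified", run_stratified(pred, ann, config$stratify_by,
                                       controls = config$controls))
  }

  stage("marginal", {
    ms <- marginal_cpg_stats(cohort, accel, clock = clock)
    ms$quadrant <- classify_quadrants(ms, config$alpha)
    write_result_csv(ms, config$output_dir, "marginal_stats")
    ms
  })

  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
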