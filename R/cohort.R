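#' Construct a methylation cohort
#'
#' Bundles a probe-by-sample beta matrix with per-sample annotations and
#' validates the joint invariants: beta values in `[0, 1]` or missing, unique
#' probe and sample identifiers, and a one-to-one correspondence between
#' matrix columns and annotation rows (annotations are reordered to match the
#' matrix if needed).
#'
#' @param beta Numeric matrix, probes x samples, with dimnames.
#' @param annotations Data frame with a `sample_id` column matching
#'   `colnames(beta)`; see [read_sample_sheet()] for the expected columns.
#' @return An object of class `methylation_cohort`: a list with elements
#'   `beta` and `annotations`.
#' @export
methylation_cohort <- function(beta, annotations) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids in beta matrix")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("beta values outside [0,1]")
  if (!is.data.frame(annotations) || !"sample_id" %in% names(annotations))
    stop("annotations must be a data.frame with a sample_id column")
  if (!setequal(annotations$sample_id, colnames(beta)))
    stop("annotation sample_ids do not match beta matrix columns")
  annotations <- annotations[match(colnames(beta), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  if ("age" %in% names(annotations)) {
    if (any(!is.finite(annotations$age)) || any(annotations$age < 0))
      stop("age must be finite and non-negative")
  }
  structure(list(beta = beta, annotations = annotations),
            class = "methylation_cohort")
}

#' @export
print.methylation_cohort <- function(x, ...) {
  a <- x$annotations
  cat(sprintf("methylation_cohort: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  if ("status" %in% names(a)) {
    tab <- table(a$status)
    cat("  status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if ("age" %in% names(a))
    cat(sprintf("  age: mean %.1f (range %.1f-%.1f)\n",
                mean(a$age), min(a$age), max(a$age)))
  invisible(x)
}

#' Read a cohort from a beta matrix and sample sheet on disk
#'
#' @param beta_path Path to the beta matrix (see [read_beta_matrix()]).
#' @param sheet_path Path to the sample sheet (see [read_sample_sheet()]).
#' @param orientation_hint Passed to [read_beta_matrix()]; the sample sheet's
#'   ids resolve `"auto"` orientation.
#' @param status_aliases Passed to [read_sample_sheet()].
#' @return A [methylation_cohort()].
#' @export
read_cohort <- function(beta_path, sheet_path, orientation_hint = "auto",
                        status_aliases = NULL) {
  ann <- read_sample_sheet(sheet_path, status_aliases = status_aliases)
  beta <- read_beta_matrix(beta_path, orientation_hint = orientation_hint,
                           sample_ids = ann$sample_id)
  methylation_cohort(beta, ann)
}
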