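#' Solve a simplex-constrained least-squares projection
#'
#' Minimises `||y - S w||^2` subject to `w >= 0` and `sum(w) = 1`. The
#' optimum of this convex quadratic program lies on some face of the simplex
#' and is the equality-constrained minimiser over that face's affine hull, so
#' the solver enumerates all faces (zero-sets of coordinates), solves the
#' equality-constrained problem on each via its KKT system, and returns the
#' feasible solution with the smallest objective — exact for the small
#' numbers of cell types used in methylation deconvolution.
#'
#' @param y Numeric response vector (one sample's beta values).
#' @param S Numeric matrix, probes x cell types.
#' @return List with `w` (named weights on the simplex) and `objective`.
#' @keywords internal
simplex_lsq <- function(y, S) {
  k <- ncol(S)
  if (k > 15L) stop("face-enumeration solver limited to <= 15 cell types")
  StS <- crossprod(S)
  Sty <- crossprod(S, y)
  yty <- sum(y^2)
  best <- NULL
  for (code in seq_len(2^k) - 1L) {
    free <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) == 0L)
    if (length(free) == 0L) next
    kk <- length(free)
    K <- rbind(cbind(2 * StS[free, free, drop = FALSE], rep(1, kk)),
               c(rep(1, kk), 0))
    rhs <- c(2 * Sty[free], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    wf <- sol[seq_len(kk)]
    if (any(wf < -1e-9)) next
    w <- numeric(k); w[free] <- pmax(wf, 0)
    w <- w / sum(w)
    obj <- yty - 2 * sum(w * Sty) + as.numeric(t(w) %*% StS %*% w)
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(w = w, objective = obj)
  }
  if (is.null(best)) stop("no feasible solution found (singular signature?)")
  names(best$w) <- colnames(S)
  best
}

#' Estimate cell-type proportions by constrained projection
#'
#' For each sample, projects its beta profile onto the convex hull of the
#' signature matrix columns: proportions are the minimiser of
#' `||y - S w||^2` over the probability simplex (`w >= 0`, `sum(w) = 1`),
#' computed over the probes shared between cohort and signature. Probes
#' missing in a given sample are dropped for that sample.
#'
#' @param cohort A [methylation_cohort()] or bare beta matrix.
#' @param signature Signature matrix (probes x cell types), e.g. from
#'   [read_signature_matrix()] or [generate_signature()].
#' @return Data frame of class `cell_composition`: `sample_id`, one column
#'   per cell type (fractions summing to 1), `residual_norm`.
#' @export
estimate_cell_composition <- function(cohort, signature) {
  beta <- if (inherits(cohort, "methylation_cohort")) cohort$beta else cohort
  shared <- intersect(rownames(beta), rownames(signature))
  k <- ncol(signature)
  if (length(shared) < 10L * k)
    stop(sprintf("only %d probes shared with the signature; need >= %d",
                 length(shared), 10L * k))
  S <- signature[shared, , drop = FALSE]
  B <- beta[shared, , drop = FALSE]
  res <- lapply(seq_len(ncol(B)), function(j) {
    y <- B[, j]
    ok <- !is.na(y)
    if (sum(ok) < 10L * k)
      stop("sample ", colnames(B)[j], " has too few non-missing shared probes")
    sol <- simplex_lsq(y[ok], S[ok, , drop = FALSE])
    c(sol$w, residual_norm = sqrt(max(sol$objective, 0)))
  })
  out <- data.frame(sample_id = colnames(B),
                    do.call(rbind, res),
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("cell_composition", class(out))
  out
}

#' Reference-free latent-factor adjustment
#'
#' Adjusts the DNAm-age association model for latent cell-mixture structure
#' without a signature matrix. Probe loadings are taken from the top-k
#' singular vectors of the beta matrix residualised on the full design
#' (intercept, age, status); the per-sample surrogate scores are then obtained
#' by projecting the beta matrix residualised on age alone onto those
#' loadings, so that mixture variation aligned with case status is retained
#' in the scores and can absorb a confounded status effect. The association
#' model `dnam_age ~ age + status + scores` is then refit. With `k = 0` the
#' result is exactly the unadjusted [fit_multivariate()].
#'
#' @param beta Probe x sample matrix (or [methylation_cohort()]).
#' @param dnam_age Numeric vector of DNAm ages.
#' @param age Numeric vector of chronological ages.
#' @param status Case indicator.
#' @param k Number of latent factors (0 <= k < min(n - 3, 20)).
#' @return List with `fit` (adjusted `regression_fit`), `unadjusted_fit`,
#'   `scores` (n x k matrix), `k`.
#' @export
reference_free_adjust <- function(beta, dnam_age, age, status, k) {
  if (inherits(beta, "methylation_cohort")) beta <- beta$beta
  n <- ncol(beta)
  ds <- encode_status(status)
  max_k <- min(n - 3L, 20L)
  if (k < 0L || k >= max_k)
    stop("k must satisfy 0 <= k < ", max_k)
  unadj <- fit_multivariate(dnam_age, age, status)
  if (k == 0L)
    return(list(fit = unadj, unadjusted_fit = unadj,
                scores = matrix(numeric(0), n, 0), k = 0L))

  B <- beta
  B[is.na(B)] <- mean(B, na.rm = TRUE)
  X_full <- cbind(1, age, ds)
  X_age <- cbind(1, age)
  resid_on <- function(M, X) {
    # rows of M are probes; residualise each probe profile on X
    M - t(X %*% solve(crossprod(X), crossprod(X, t(M))))
  }
  R_full <- resid_on(B, X_full)
  sv <- svd(R_full, nu = k, nv = 0)
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  R_age <- resid_on(B, X_age)
  scores <- crossprod(R_age, loadings)            # n x k
  colnames(scores) <- paste0("latent", seq_len(k))
  fit <- fit_multivariate(dnam_age, age, status,
                          covariates = as.data.frame(scores))
  list(fit = fit, unadjusted_fit = unadj, scores = scores, k = k)
}

#' Test cell-composition differences between status groups
#'
#' Runs a Kruskal-Wallis test per cell type on the estimated proportions by
#' status group and, when accelerations are supplied, the Pearson correlation
#' of each proportion with epigenetic age acceleration.
#'
#' @param compositions A `cell_composition` data frame from
#'   [estimate_cell_composition()].
#' @param status Status vector aligned with `compositions` rows (or a
#'   data frame with `sample_id` and `status`).
#' @param acceleration Optional `acceleration_result` (or numeric vector
#'   aligned with rows).
#' @return Data frame, one row per cell type: `cell_type`, `H`, `p`,
#'   per-group means, and when acceleration is given `cor_accel`,
#'   `cor_accel_p`.
#' @export
test_composition_differences <- function(compositions, status,
                                         acceleration = NULL) {
  cell_types <- setdiff(names(compositions),
                        c("sample_id", "residual_norm"))
  if (is.data.frame(status)) {
    status <- status$status[match(compositions$sample_id, status$sample_id)]
  }
  g <- droplevels(factor(status))
  accel <- NULL
  if (!is.null(acceleration)) {
    accel <- if (is.data.frame(acceleration)) {
      acceleration$acceleration[match(compositions$sample_id,
                                      acceleration$sample_id)]
    } else acceleration
  }
  rows <- lapply(cell_types, function(ct) {
    v <- compositions[[ct]]
    kw <- suppressWarnings(kruskal_wallis(split(v, g)))
    row <- data.frame(cell_type = ct, H = kw$statistic, p = kw$p,
                      stringsAsFactors = FALSE)
    for (lev in names(kw$group_means))
      row[[paste0("mean_", lev)]] <- kw$group_means[[lev]]
    if (!is.null(accel)) {
      if (stats::sd(v) == 0) {
        row$cor_accel <- 0; row$cor_accel_p <- 1
      } else {
        ct_test <- stats::cor.test(v, accel)
        row$cor_accel <- unname(ct_test$estimate)
        row$cor_accel_p <- ct_test$p.value
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Simplified mediation test (product of coefficients)
#'
#' Tests whether a mediator (e.g. a cell-type proportion) transmits the
#' effect of case status on age acceleration, using the linear
#' product-of-coefficients decomposition: path `a` from regressing the
#' mediator on status, path `b` from regressing acceleration on mediator and
#' status; indirect effect `a*b` with a Sobel z test and a seeded percentile
#' bootstrap CI. For nested linear models the identity
#' `total = direct + indirect` holds exactly. This is a deliberate
#' simplification of a full structural-equation mediation model.
#'
#' @param status Case indicator.
#' @param mediator Numeric mediator vector.
#' @param acceleration Numeric outcome vector (years).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (required).
#' @return Object of class `mediation_result`: `total_effect`,
#'   `direct_effect`, `indirect_effect` (years), `sobel_z`, `sobel_p`,
#'   `bootstrap_ci` (percentile 2.5/97.5), `n_boot`.
#' @export
mediation_test <- function(status, mediator, acceleration, n_boot = 1000L,
                           seed) {
  if (missing(seed)) stop("seed must be supplied")
  ds <- encode_status(status)
  n <- length(ds)
  if (n < 20L) stop("need n >= 20 for the mediation test")
  if (stats::sd(mediator) == 0) stop("degenerate mediator (zero variance)")

  paths <- function(ds, m, y) {
    fa <- stats::lm(m ~ ds)
    fb <- stats::lm(y ~ m + ds)
    sa <- summary(fa)$coefficients
    sb <- summary(fb)$coefficients
    c(a = sa["ds", 1L], se_a = sa["ds", 2L],
      b = sb["m", 1L], se_b = sb["m", 2L],
      direct = sb["ds", 1L])
  }
  ph <- paths(ds, mediator, acceleration)
  total <- unname(stats::coef(stats::lm(acceleration ~ ds))[2L])
  indirect <- unname(ph["a"] * ph["b"])
  denom <- sqrt(ph["a"]^2 * ph["se_b"]^2 + ph["b"]^2 * ph["se_a"]^2)
  z <- if (indirect == 0) 0 else unname(indirect / denom)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    ii <- sample.int(n, replace = TRUE)
    if (length(unique(ds[ii])) < 2L || stats::sd(mediator[ii]) == 0)
      return(NA_real_)
    p <- paths(ds[ii], mediator[ii], acceleration[ii])
    unname(p["a"] * p["b"])
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(total_effect = total, direct_effect = unname(ph["direct"]),
                 indirect_effect = indirect, sobel_z = z,
                 sobel_p = 2 * stats::pnorm(-abs(z)),
                 bootstrap_ci = ci, n_boot = n_boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("mediation_result (product-of-coefficients; simplified linear",
      "decomposition, not a full SEM)\n")
  cat(sprintf("  total %.3f = direct %.3f + indirect %.3f years\n",
              x$total_effect, x$direct_effect, x$indirect_effect))
  cat(sprintf("  Sobel z = %.3f (p = %.3g); bootstrap 95%% CI [%.3f, %.3f]\n",
              x$sobel_z, x$sobel_p, x$bootstrap_ci[1L], x$bootstrap_ci[2L]))
  invisible(x)
}
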