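# Shared fixture builders; everything is generated in code at test time.

# tiny 3-probe x 2-sample beta matrix file; one NA cell
write_tiny_beta <- function(path, sep = "\t", na_cell = TRUE) {
  lines <- c(paste(c("ID_REF", "s1", "s2"), collapse = sep),
             paste(c("cg0001", "0.10", "0.90"), collapse = sep),
             paste(c("cg0002", if (na_cell) "NA" else "0.40", "0.50"),
                   collapse = sep),
             paste(c("cg0003", "0.25", "0.75"), collapse = sep))
  writeLines(lines, path)
  path
}

write_tiny_sheet <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- c("s1,43,DS,F,blood",
              "s2,50,control,M,blood")
  }
  writeLines(c("sample_id,age,status,sex,tissue", rows), path)
  path
}

write_tiny_clock <- function(path, adult_age_line = TRUE,
                             n_intercepts = 1L) {
  lines <- character(0)
  if (adult_age_line) lines <- c(lines, "#adult_age=20", "#name=tiny")
  lines <- c(lines, "probe_id,weight",
             rep("(Intercept),0.5", n_intercepts),
             "cg0001,2.0")
  writeLines(lines, path)
  path
}

# cohort whose controls lie exactly on dnam_age = 10 + 1.1 * age,
# with one case offset vertically by `offset` years
exact_line_data <- function(offset = 5) {
  ann <- data.frame(sample_id = c("c1", "c2", "c3", "c4", "k1"),
                    age = c(20, 30, 40, 50, 35),
                    status = c("control", "control", "control", "control",
                               "case"),
                    stringsAsFactors = FALSE)
  pred <- data.frame(sample_id = ann$sample_id,
                     dnam_age = 10 + 1.1 * ann$age +
                       c(0, 0, 0, 0, offset),
                     stringsAsFactors = FALSE)
  list(pred = pred, ann = ann)
}

# minimal regression_fit carrying just the two named terms, for ratio tests
fit_from_coefs <- function(beta_age, beta_ds) {
  structure(list(terms = data.frame(
    term = c("(Intercept)", "Chronological age", "DS"),
    estimate = c(0, beta_age, beta_ds),
    se = c(1, 1, 1), p = c(1, 1, 1), stringsAsFactors = FALSE),
    r2 = NA_real_, n = NA_integer_), class = "regression_fit")
}

# exact permutation mid-p for a two-group Kruskal-Wallis statistic
kw_perm_midp <- function(x, g) {
  n <- length(x)
  sizes <- table(g)
  idx <- utils::combn(n, sizes[[1L]])
  Hof <- function(a1) {
    gg <- rep(2L, n); gg[a1] <- 1L
    suppressWarnings(kruskal_wallis(split(x, gg)))$statistic
  }
  Hobs <- suppressWarnings(kruskal_wallis(split(x, g)))$statistic
  Hs <- apply(idx, 2L, Hof)
  mean(Hs > Hobs + 1e-12) + 0.5 * mean(abs(Hs - Hobs) <= 1e-12)
}
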