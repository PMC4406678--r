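#' Read a probe-by-sample beta-value matrix
#'
#' Parses a delimited text file of methylation beta values in the
#' GEO-series-matrix-like dialect: first column holds probe identifiers
#' (header cell `ID_REF` or blank), remaining columns are samples. The
#' delimiter (comma or tab) is auto-detected from the header line. Values
#' that are non-numeric or fall outside `[0, 1]` are set to missing; the
#' number of such cells is reported in a warning and stored in the
#' `n_invalid` attribute.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation_hint One of `"auto"`, `"probes_in_rows"`,
#'   `"samples_in_rows"`. Under `"auto"`, the orientation is decided by
#'   matching header tokens against `sample_ids` when supplied, otherwise
#'   probes-in-rows is assumed.
#' @param sample_ids Optional character vector of known sample identifiers
#'   (e.g. from a sample sheet), used only to resolve `"auto"` orientation.
#' @return A numeric matrix, probes in rows and samples in columns, with
#'   `dimnames` set, carrying attribute `n_invalid`.
#' @export
read_beta_matrix <- function(path,
                             orientation_hint = c("auto", "probes_in_rows",
                                                  "samples_in_rows"),
                             sample_ids = NULL) {
  orientation_hint <- match.arg(orientation_hint)
  if (!file.exists(path)) stop("beta matrix file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty beta matrix file: ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty beta matrix in ", path)

  ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(body) <- ids

  orient <- orientation_hint
  if (orient == "auto") {
    orient <- "probes_in_rows"
    if (!is.null(sample_ids)) {
      hits_cols <- sum(colnames(body) %in% sample_ids)
      hits_rows <- sum(ids %in% sample_ids)
      if (hits_rows > hits_cols) orient <- "samples_in_rows"
    }
  }
  if (orient == "samples_in_rows") body <- t(body)

  if (anyDuplicated(rownames(body))) {
    dup <- rownames(body)[duplicated(rownames(body))][1L]
    stop("duplicate probe id in beta matrix: ", dup)
  }

  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  # non-numeric strings other than recognised missing tokens, and values
  # outside [0,1], are invalidated rather than clipped
  missing_token <- is.na(body) | body %in% c("", "NA", "NaN", "na", "nan")
  dim(missing_token) <- dim(body)
  invalid <- (is.na(num) & !missing_token) |
    (!is.na(num) & (num < 0 | num > 1))
  n_invalid <- sum(invalid)
  num[invalid] <- NA_real_
  if (n_invalid > 0L) {
    warning(sprintf("%d beta value(s) non-numeric or outside [0,1] set to NA",
                    n_invalid))
  }
  attr(num, "n_invalid") <- n_invalid
  num
}

#' Default status alias map
#'
#' Maps raw status strings (case-insensitively) onto the canonical vocabulary
#' `case` / `control` / `other-disease`. Extensible: supply extra aliases to
#' [read_sample_sheet()] for cohorts with additional disease groups (e.g.
#' Alzheimer's disease samples alongside trisomy-21 cases).
#'
#' @return Named list of character vectors of lower-case aliases.
#' @export
default_status_aliases <- function() {
  list(case            = c("case", "ds", "trisomy21", "t21"),
       control         = c("control", "ctl", "ctrl", "healthy"),
       `other-disease` = c("other", "other-disease", "ad", "alzheimer"))
}

#' Read a sample annotation sheet
#'
#' Delimited text with a header; required columns `sample_id`, `age`,
#' `status`; optional `sex`, `tissue`, `region`, `sibship`, `dataset_id`
#' (absent or empty optional fields are filled with `"unknown"`).
#'
#' @param path Path to a CSV/TSV sample sheet.
#' @param status_aliases Alias map as returned by [default_status_aliases()];
#'   user entries are merged over the defaults.
#' @return A `data.frame` with one row per sample: `sample_id` (character),
#'   `age` (numeric years), `status` (factor with levels case, control,
#'   other-disease) and the optional character columns.
#' @export
read_sample_sheet <- function(path, status_aliases = NULL) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- c("sample_id", "age", "status")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop("sample sheet missing required column(s): ",
                         paste(miss, collapse = ", "))

  age <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age)) {
    bad <- which(is.na(age))[1L]
    stop("non-numeric age in sample sheet row ", bad,
         " (sample_id ", raw$sample_id[bad], ")")
  }
  if (any(age < 0)) stop("negative age in sample sheet")

  aliases <- default_status_aliases()
  if (!is.null(status_aliases)) {
    for (nm in names(status_aliases)) {
      aliases[[nm]] <- unique(c(aliases[[nm]], tolower(status_aliases[[nm]])))
    }
  }
  lut <- stats::setNames(rep(names(aliases), lengths(aliases)),
                         unlist(aliases))
  status <- lut[tolower(raw$status)]
  if (anyNA(status)) {
    bad <- unique(raw$status[is.na(status)])
    stop("unrecognised status value(s): ", paste(bad, collapse = ", "),
         "; extend status_aliases")
  }

  out <- data.frame(sample_id = raw$sample_id, age = age,
                    status = factor(status, levels = c("case", "control",
                                                       "other-disease")),
                    stringsAsFactors = FALSE)
  for (opt in c("sex", "tissue", "region", "sibship", "dataset_id")) {
    v <- if (opt %in% names(raw)) raw[[opt]] else rep("unknown", nrow(raw))
    v[is.na(v) | v == ""] <- "unknown"
    out[[opt]] <- v
  }
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id in sample sheet")
  out
}

#' Read a clock coefficient file
#'
#' CSV with columns `probe_id`, `weight` and optionally `gold_mean` (gold
#' standard mean beta used for imputation) and `age_cor` (training-set age
#' correlation used for clock-CpG colouring). The intercept row uses
#' `probe_id` `"(Intercept)"` (exactly one required). Header metadata lines
#' `#adult_age=<years>` and `#name=<string>` are honoured; `adult_age`
#' defaults to 20 when absent.
#'
#' @param path Path to a clock CSV file.
#' @return A [clock_model()] object.
#' @export
read_clock_file <- function(path) {
  if (!file.exists(path)) stop("clock file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  adult_age <- 20
  name <- "clock"
  for (m in meta) {
    kv <- sub("^#", "", m)
    if (grepl("^adult_age=", kv)) adult_age <- as.numeric(sub("^adult_age=", "", kv))
    if (grepl("^name=", kv)) name <- sub("^name=", "", kv)
  }
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  if (!all(c("probe_id", "weight") %in% names(tab)))
    stop("clock file needs columns probe_id, weight")
  is_int <- tab$probe_id == "(Intercept)"
  if (sum(is_int) != 1L)
    stop("clock file must contain exactly one (Intercept) row, found ",
         sum(is_int))
  intercept <- as.numeric(tab$weight[is_int])
  probes <- tab[!is_int, , drop = FALSE]
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe id in clock file: ",
         probes$probe_id[duplicated(probes$probe_id)][1L])
  gm <- if ("gold_mean" %in% names(probes))
    stats::setNames(as.numeric(probes$gold_mean), probes$probe_id) else NULL
  ac <- if ("age_cor" %in% names(probes))
    stats::setNames(as.numeric(probes$age_cor), probes$probe_id) else NULL
  clock_model(weights = stats::setNames(as.numeric(probes$weight),
                                        probes$probe_id),
              intercept = intercept, adult_age = adult_age, name = name,
              gold_means = gm, age_cor = ac)
}

#' Read a cell-type signature matrix
#'
#' CSV, probes in rows (first column `probe_id`), one column of mean beta
#' values per cell type. Missing values are not allowed; at least two cell
#' types and ten probes per cell type are required.
#'
#' @param path Path to a signature CSV.
#' @return Numeric matrix, probes x cell types, class `signature_matrix`.
#' @export
read_signature_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  validate_signature_matrix(m)
}

validate_signature_matrix <- function(m) {
  if (anyNA(m)) stop("signature matrix contains missing values")
  if (ncol(m) < 2L) stop("signature matrix needs >= 2 cell types")
  if (nrow(m) < 10L * ncol(m))
    stop("signature matrix needs >= 10 probes per cell type")
  if (any(m < 0 | m > 1)) stop("signature values must lie in [0,1]")
  class(m) <- c("signature_matrix", class(m))
  m
}

fmt10 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Write a beta matrix
#'
#' Writes probes x samples with header `ID_REF` followed by sample ids;
#' numeric values at 10 significant digits so that a write-then-read round
#' trip is value-identical.
#'
#' @param beta Numeric matrix, probes x samples, with dimnames.
#' @param path Output file.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @export
write_beta_matrix <- function(beta, path, sep = "\t") {
  df <- data.frame(ID_REF = rownames(beta),
                   apply(beta, 2L, fmt10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("ID_REF", colnames(beta))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet
#' @param annotations Data frame as returned by [read_sample_sheet()].
#' @param path Output CSV file.
#' @export
write_sample_sheet <- function(annotations, path) {
  out <- annotations
  out$status <- as.character(out$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a clock coefficient file
#' @param clock A [clock_model()].
#' @param path Output CSV file.
#' @export
write_clock_file <- function(clock, path) {
  hdr <- c(sprintf("#adult_age=%s", fmt10(clock$adult_age)),
           sprintf("#name=%s", clock$name))
  cols <- c("probe_id", "weight")
  rows <- data.frame(probe_id = c("(Intercept)", names(clock$weights)),
                     weight = fmt10(c(clock$intercept, unname(clock$weights))),
                     stringsAsFactors = FALSE)
  if (!is.null(clock$gold_means)) {
    rows$gold_mean <- c("", fmt10(unname(
      clock$gold_means[names(clock$weights)])))
    cols <- c(cols, "gold_mean")
  }
  if (!is.null(clock$age_cor)) {
    rows$age_cor <- c("", fmt10(unname(clock$age_cor[names(clock$weights)])))
    cols <- c(cols, "age_cor")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows[, cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
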