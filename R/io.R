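## io_core: beta matrices, clock coefficient tables, sample metadata.
##
## A beta matrix is a plain numeric matrix, probes in rows, with rownames =
## probe ids and colnames = sample ids; NA marks a missing measurement. All
## readers validate on the way in; nothing is imputed at read time.

INTERCEPT_ROW <- "(Intercept)"

#' Construct and validate a beta matrix
#'
#' A beta matrix holds methylation proportions (beta values) in `[0, 1]`,
#' probes in rows and samples in columns.  Missing measurements are `NA`;
#' they are never imputed here (imputation is an explicit policy of
#' [predict_dnam_age()]).
#'
#' @param values Numeric matrix of beta values.
#' @param probe_ids,sample_ids Optional character vectors overriding
#'   `rownames(values)` / `colnames(values)`.
#' @return The validated matrix with dimnames set.
#' @examples
#' beta_matrix(matrix(c(0.1, 0.9, 0.5, 0.5), 2,
#'             dimnames = list(c("cgA", "cgB"), c("s1", "s2"))))
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("beta values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("beta matrix needs probe ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  .check_unique(probe_ids, "probe id")
  .check_unique(sample_ids, "sample id")
  dimnames(values) <- list(probe_ids, sample_ids)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
      probe_ids[bad[1, 1]], sample_ids[bad[1, 2]],
      values[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  values
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s(s): %s", what,
                 paste(head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

.sniff_sep <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) "\t" else ","
}

#' Read a beta matrix from delimited text
#'
#' The file must have one header row of identifiers and one identifier
#' column.  Empty cells and `NA` become missing values.  The delimiter is
#' sniffed from the extension (`.csv` comma, `.tsv`/`.txt` tab) unless
#' given explicitly.
#'
#' @param path File path.
#' @param orientation `"probes_in_rows"` (default, array convention) or
#'   `"samples_in_rows"`; the latter is transposed on read.
#' @param delimiter Optional field separator overriding the sniffed one.
#' @return A validated beta matrix (probes in rows).
#' @seealso [write_beta_matrix()], [beta_matrix()]
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_in_rows",
                                             "samples_in_rows"),
                             delimiter = NULL) {
  orientation <- match.arg(orientation)
  sep <- .sniff_sep(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    storage.mode(m) <- "double"
  }
  if (orientation == "samples_in_rows") m <- t(m)
  beta_matrix(m)
}

#' Write a beta matrix to delimited text
#'
#' Values are printed at fixed precision so that write-then-read
#' round-trips are stable to the printed number of decimals.
#'
#' @param x Beta matrix (probes in rows).
#' @param path Output path; delimiter sniffed from the extension.
#' @param digits Printed decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, digits = 6) {
  x <- beta_matrix(x)
  sep <- .sniff_sep(path)
  out <- format(round(x, digits), nsmall = digits, trim = TRUE,
                scientific = FALSE)
  out[is.na(x)] <- "NA"
  df <- data.frame(probe_id = rownames(x), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define an epigenetic clock
#'
#' A clock is an intercept plus per-probe coefficients, together with the
#' calibration that maps the linear score to years: either the anchored
#' log-linear transform of [transform_age()] (multi-tissue clock style,
#' anchor 20 years) or the identity (blood clock style, score already in
#' years).
#'
#' @param name Label for the clock.
#' @param intercept Scalar intercept, in transformed-age units.
#' @param coefficients Named numeric vector, names are probe ids.
#' @param calibration `"identity"`, or a list
#'   `list(kind = "anchored_log_linear", anchor_years = A)`.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, coefficients,
                             calibration = "identity") {
  if (is.character(calibration)) {
    calibration <- list(kind = match.arg(calibration,
                                         c("identity",
                                           "anchored_log_linear")))
  }
  stopifnot(is.list(calibration),
            calibration$kind %in% c("identity", "anchored_log_linear"))
  if (calibration$kind == "anchored_log_linear") {
    if (is.null(calibration$anchor_years) || calibration$anchor_years <= 0) {
      stop("anchored_log_linear calibration needs anchor_years > 0",
           call. = FALSE)
    }
  }
  if (!is.numeric(intercept) || length(intercept) != 1 ||
      !is.finite(intercept)) {
    stop("intercept must be a finite scalar", call. = FALSE)
  }
  coefficients <- unlist(coefficients)
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
      stop("coefficients must be named by probe id", call. = FALSE)
    }
    .check_unique(names(coefficients), "probe id")
    if (any(!is.finite(coefficients))) {
      stop("all coefficients must be finite", call. = FALSE)
    }
  }
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, calibration = calibration),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cal <- if (x$calibration$kind == "identity") "identity" else
    sprintf("anchored log-linear (anchor %g y)", x$calibration$anchor_years)
  cat(sprintf("<clock_definition> %s: %d probes, intercept %.4g, %s calibration\n",
              x$name, length(x$coefficients), x$intercept, cal))
  invisible(x)
}

#' Read a clock coefficient table
#'
#' Reads the conventional supplementary-table CSV dialect: two columns
#' `probe_id`, `coefficient`, with the intercept encoded as a reserved
#' `"(Intercept)"` row.  Two bundled clocks are available by name:
#' \describe{
#'   \item{`"horvath2013"`}{353-probe multi-tissue clock layout with
#'     anchored log-linear calibration (anchor 20 years).}
#'   \item{`"hannum2013"`}{71-probe blood clock layout with identity
#'     calibration.}
#' }
#' The bundled tables are *synthetic stand-ins* (see
#' `system.file("extdata", package = "clockbias")`, filenames carry
#' `_synthetic`): the published coefficient values are third-party
#' supplementary data, so the bundled tables instead reproduce the clocks'
#' documented structure — probe counts (353 and 71), an intersection of
#' exactly 6 probe ids including cg22736354 and cg06493994, the absolute
#' coefficient range 5.9e-6 to 3.07 for the multi-tissue table, and the
#' named high-influence probe ids.  They exercise every code path a real
#' coefficient table would; for real-data work drop in the published CSVs.
#'
#' @param source Builtin name (`"horvath2013"`, `"hannum2013"`) or a file
#'   path.
#' @param calibration Calibration for file sources (ignored for builtins);
#'   default identity.  See [clock_definition()].
#' @param name Optional clock label for file sources.
#' @return A [clock_definition()].
#' @export
read_clock_definition <- function(source, calibration = "identity",
                                  name = NULL) {
  builtin <- c(horvath2013 = "horvath2013_synthetic_coefficients.csv",
               hannum2013 = "hannum2013_synthetic_coefficients.csv")
  if (source %in% names(builtin)) {
    path <- system.file("extdata", builtin[[source]], package = "clockbias",
                        mustWork = TRUE)
    calibration <- if (source == "horvath2013") {
      list(kind = "anchored_log_linear", anchor_years = 20)
    } else {
      "identity"
    }
    name <- source
  } else {
    path <- source
    if (!file.exists(path)) {
      stop(sprintf("clock source '%s' is neither a builtin name nor a file",
                   source), call. = FALSE)
    }
    if (is.null(name)) name <- basename(path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "coefficient")
  if (!all(need %in% names(df))) {
    stop("clock table needs columns probe_id, coefficient", call. = FALSE)
  }
  .check_unique(df$probe_id, "probe row")
  is_int <- df$probe_id == INTERCEPT_ROW
  if (sum(is_int) != 1) {
    stop(sprintf("clock table must contain exactly one '%s' row",
                 INTERCEPT_ROW), call. = FALSE)
  }
  coefs <- setNames(as.numeric(df$coefficient[!is_int]),
                    df$probe_id[!is_int])
  clock_definition(name = name,
                   intercept = as.numeric(df$coefficient[is_int]),
                   coefficients = coefs, calibration = calibration)
}

#' Write a clock coefficient table
#'
#' Inverse of [read_clock_definition()] for file sources (the calibration
#' is not serialized; pass it again on read).
#'
#' @param clock A [clock_definition()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clock_definition <- function(clock, path) {
  stopifnot(inherits(clock, "clock_definition"))
  df <- data.frame(
    probe_id = c(INTERCEPT_ROW, names(clock$coefficients)),
    coefficient = c(clock$intercept, unname(clock$coefficients)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Delimited text with a header containing at least `sample_id` and
#' `chronological_age` (years).  An optional `group` column must contain
#' only `case`/`control` (or missing).  All other columns are preserved as
#' phenotypes (e.g. `braak_stage`, `amyloid`, `tissue`, `sex`).
#'
#' @param path File path; delimiter sniffed from the extension.
#' @param delimiter Optional explicit separator.
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path, delimiter = NULL) {
  sep <- .sniff_sep(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_sample_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df Data frame with `sample_id` and `chronological_age` columns.
#' @return The validated data frame (sample_id coerced to character).
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "chronological_age")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns sample_id and chronological_age",
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  .check_unique(df$sample_id, "sample id")
  age <- df$chronological_age
  if (!is.numeric(age)) stop("chronological_age must be numeric",
                             call. = FALSE)
  bad <- which(!is.na(age) & (age < 0 | !is.finite(age)))
  if (length(bad) > 0) {
    stop(sprintf("negative or non-finite chronological_age for sample '%s'",
                 df$sample_id[bad[1]]), call. = FALSE)
  }
  if ("group" %in% names(df)) {
    ok <- is.na(df$group) | df$group %in% c("case", "control")
    if (!all(ok)) {
      stop(sprintf("group must be 'case' or 'control' (sample '%s')",
                   df$sample_id[which(!ok)[1]]), call. = FALSE)
    }
  }
  df
}

#' Align a beta matrix with sample metadata
#'
#' Restricts both objects to their shared sample ids, in lexicographic id
#' order (so the result does not depend on input ordering, and applying
#' the alignment twice is a no-op).
#'
#' @param betas Beta matrix (samples in columns).
#' @param metadata Metadata data frame with a `sample_id` column.
#' @return `list(betas = , metadata = )`, both restricted and ordered by
#'   sorted shared sample id.
#' @export
align_samples <- function(betas, metadata) {
  metadata <- validate_sample_metadata(metadata)
  shared <- sort(intersect(colnames(betas), metadata$sample_id))
  if (length(shared) == 0) {
    stop("no shared sample ids between beta matrix and metadata",
         call. = FALSE)
  }
  list(betas = betas[, shared, drop = FALSE],
       metadata = metadata[match(shared, metadata$sample_id), ,
                           drop = FALSE])
}
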