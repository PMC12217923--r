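# Simple-regression QSPR models P = A + b * TI and their diagnostics.

.property_names <- c("boiling_point", "melting_point", "enthalpy",
                     "flash_point", "molar_refractivity", "polarizability",
                     "surface_tension", "molar_volume")

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return The sample correlation coefficient, in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Upper-tail probability of the F distribution
#'
#' `P(F[df1, df2] > f)`, the p-value attached to a regression F statistic.
#'
#' @param f observed F statistic (non-negative).
#' @param df1,df2 positive integer degrees of freedom.
#' @return Probability in `[0, 1]`; `1` at `f = 0`.
#' @export
f_upper_tail_p <- function(f, df1, df2) {
  stopifnot(all(f >= 0), df1 >= 1, df2 >= 1)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Fit the simple linear QSPR model P = A + b * TI
#'
#' Ordinary least squares of a physicochemical property on a topological
#' index, with the diagnostics conventionally reported for such models:
#' Pearson r, R-squared, the F statistic on (1, n - 2) degrees of freedom,
#' its p-value, and the standard error of estimate
#' `SEE = sqrt(RSS / (n - 2))`.  Significance is declared at p < 0.05.
#'
#' @param ti numeric vector of index values (the predictor).
#' @param p numeric vector of property values (the response).
#' @return An object of class `qspr_fit`: a list with fields `n`,
#'   `intercept`, `slope`, `pearson_r`, `r_squared`, `f_stat`, `p_value`,
#'   `see` and `significant`.
#' @examples
#' fit <- fit_simple_regression(c(1, 2, 3, 4), c(5.1, 6.9, 9.1, 10.9))
#' fit$slope
#' @export
fit_simple_regression <- function(ti, p) {
  stopifnot(is.numeric(ti), is.numeric(p))
  if (length(ti) != length(p)) stop("'ti' and 'p' must have equal length")
  n <- length(ti)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(ti) || anyNA(p)) stop("missing values not allowed")
  if (stats::var(ti) == 0) stop("degenerate fit: zero variance in the index")
  fit <- stats::lm(p ~ ti)
  coefs <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((p - mean(p))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  r <- if (stats::var(p) > 0) stats::cor(ti, p) else 0
  fstat <- if (rss > 0) r2 * (n - 2) / (1 - r2) else Inf
  pval <- f_upper_tail_p(fstat, 1L, n - 2L)
  structure(
    list(n = n,
         intercept = unname(coefs[1L]),
         slope = unname(coefs[2L]),
         pearson_r = r,
         r_squared = r2,
         f_stat = fstat,
         p_value = pval,
         see = sqrt(rss / (n - 2)),
         significant = pval < 0.05),
    class = "qspr_fit")
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<qspr_fit> P = %.4f + %.4f TI  (n = %d)\n",
           "  r = %.4f  R^2 = %.4f  F = %.4f  p = %.4f  SEE = %.4f  %s\n"),
    x$intercept, x$slope, x$n, x$pearson_r, x$r_squared, x$f_stat, x$p_value,
    x$see, if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Build the full QSPR report from index and property tables
#'
#' Fits one simple regression per (index, property) pair and assembles the
#' correlation, SEE and fit tables.  A failed cell (e.g. a constant index
#' column) is recorded as `NA` without aborting the rest of the report.
#'
#' @param index_table data frame with a `drug` column and one numeric column
#'   per topological index.
#' @param property_table data frame with a `drug` column and one numeric
#'   column per property.
#' @return An object of class `qspr_report`: a list with `correlation` and
#'   `see` matrices (index rows, property columns), a nested `fits` list
#'   (`fits[[index]][[property]]`, each a [fit_simple_regression()] result
#'   or `NULL` on failure), `n`, `drugs`, and the index/property names.
#' @export
qspr_report_from_tables <- function(index_table, property_table) {
  stopifnot(is.data.frame(index_table), is.data.frame(property_table))
  if (!"drug" %in% names(index_table) || !"drug" %in% names(property_table)) {
    stop("both tables need a 'drug' column")
  }
  only_idx <- setdiff(index_table$drug, property_table$drug)
  only_prop <- setdiff(property_table$drug, index_table$drug)
  if (length(only_idx) || length(only_prop)) {
    stop("drug names do not match between tables; unmatched: ",
         paste(c(only_idx, only_prop), collapse = ", "))
  }
  property_table <- property_table[match(index_table$drug, property_table$drug), ]
  idx_names <- setdiff(names(index_table), "drug")
  prop_names <- setdiff(names(property_table), "drug")
  n <- nrow(index_table)
  if (n < 3L) stop("need at least 3 drugs to fit the QSPR models")
  if (n < 10L) {
    warning("only ", n, " drugs: QSPR fits will have low statistical power")
  }
  corr <- see <- matrix(NA_real_, length(idx_names), length(prop_names),
                        dimnames = list(idx_names, prop_names))
  fits <- stats::setNames(vector("list", length(idx_names)), idx_names)
  for (ix in idx_names) {
    fits[[ix]] <- stats::setNames(vector("list", length(prop_names)), prop_names)
    for (pp in prop_names) {
      cell <- tryCatch(
        fit_simple_regression(index_table[[ix]], property_table[[pp]]),
        error = function(e) NULL)
      fits[[ix]][[pp]] <- cell
      if (!is.null(cell)) {
        corr[ix, pp] <- cell$pearson_r
        see[ix, pp] <- cell$see
      }
    }
  }
  structure(
    list(correlation = corr, see = see, fits = fits, n = n,
         drugs = index_table$drug, index_names = idx_names,
         property_names = prop_names),
    class = "qspr_report")
}

#' Build the QSPR report from drug fixtures
#'
#' Convenience wrapper around [qspr_report_from_tables()].  With
#' `indices = "published"` the regressions run on the published index table
#' carried by the fixtures (the dataset the original statistical analysis
#' consumed); with `indices = "computed"` each structure is parsed and its
#' index set computed from scratch.
#'
#' @param fixtures a list of fixtures from [load_drug_fixtures()].
#' @param indices `"published"` or `"computed"`.
#' @return A `qspr_report`; see [qspr_report_from_tables()].
#' @examples
#' \donttest{
#' rep <- build_qspr_report(load_drug_fixtures())
#' rep$correlation["detour", "molar_refractivity"]
#' }
#' @export
build_qspr_report <- function(fixtures, indices = c("published", "computed")) {
  indices <- match.arg(indices)
  stopifnot(is.list(fixtures), length(fixtures) >= 3L)
  drugs <- vapply(fixtures, function(f) f$name, character(1))
  if (indices == "published") {
    idx_rows <- lapply(fixtures, function(f) as.list(f$expected_indices))
  } else {
    idx_rows <- lapply(fixtures, function(f) {
      s <- compute_index_set(parse_smiles(f$structure, f$name))
      s[.index_names]
    })
  }
  index_table <- cbind(data.frame(drug = drugs, stringsAsFactors = FALSE),
                       do.call(rbind, lapply(idx_rows, as.data.frame)))
  property_table <- cbind(data.frame(drug = drugs, stringsAsFactors = FALSE),
                          do.call(rbind, lapply(fixtures, function(f)
                            as.data.frame(as.list(f$properties)))))
  qspr_report_from_tables(index_table, property_table)
}

#' @export
print.qspr_report <- function(x, ...) {
  cat(sprintf("<qspr_report> %d drugs, %d indices x %d properties\n",
              x$n, length(x$index_names), length(x$property_names)))
  cat("Correlation coefficients:\n")
  print(round(x$correlation, 4))
  invisible(x)
}

#' Flatten a QSPR report into one row per (index, property) fit
#'
#' @param x a `qspr_report`.
#' @param ... unused.
#' @return A data frame with columns `index`, `property`, `n`, `intercept`,
#'   `slope`, `pearson_r`, `r_squared`, `f_stat`, `p_value`, `see`,
#'   `significant`.
#' @export
as.data.frame.qspr_report <- function(x, ...) {
  rows <- list()
  for (ix in x$index_names) {
    for (pp in x$property_names) {
      f <- x$fits[[ix]][[pp]]
      rows[[length(rows) + 1L]] <- data.frame(
        index = ix, property = pp,
        n = if (is.null(f)) NA_integer_ else f$n,
        intercept = if (is.null(f)) NA_real_ else f$intercept,
        slope = if (is.null(f)) NA_real_ else f$slope,
        pearson_r = if (is.null(f)) NA_real_ else f$pearson_r,
        r_squared = if (is.null(f)) NA_real_ else f$r_squared,
        f_stat = if (is.null(f)) NA_real_ else f$f_stat,
        p_value = if (is.null(f)) NA_real_ else f$p_value,
        see = if (is.null(f)) NA_real_ else f$see,
        significant = if (is.null(f)) NA else f$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
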