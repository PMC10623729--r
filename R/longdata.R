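#' Long-format longitudinal dataset
#'
#' Standardises a long-format table (one row per subject-visit) into the
#' container used by every estimation and simulation function: columns are
#' renamed internally to `id`, `time`, `y` plus any covariates, rows with a
#' missing outcome or time are dropped (with a count warning), and rows are
#' sorted by subject and time.
#'
#' @param data a data.frame in long format.
#' @param id,outcome,time names of the subject identifier, outcome and
#'   timescale columns. Time may be negative (e.g. years before death) or
#'   positive, but must be numeric.
#' @param covariates character vector of covariate column names to carry
#'   along (subject-level; if time-varying, the first value per subject is
#'   used when covariates enter a model).
#' @return an object of class `long_data`: a data.frame with columns
#'   `id`, `time`, `y` and the covariates, plus attributes recording the
#'   original column names.
#' @export
long_data <- function(data, id = "ID", outcome, time, covariates = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("long_data: input has no rows")
  for (col in c(id, outcome, time, covariates)) {
    if (!col %in% names(data)) {
      stop("long_data: column '", col, "' not found in the data")
    }
  }
  tval <- data[[time]]
  yval <- data[[outcome]]
  if (!is.numeric(tval)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(tval)))))
    stop("long_data: time column '", time, "' is not numeric (e.g. rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ")")
  }
  if (!is.numeric(yval)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(yval)))))
    stop("long_data: outcome column '", outcome, "' is not numeric (e.g. rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ")")
  }
  keep <- is.finite(tval) & is.finite(yval)
  if (any(!keep)) {
    warning("long_data: dropped ", sum(!keep),
            " row(s) with missing outcome or time")
  }
  out <- data.frame(id = data[[id]][keep], time = tval[keep], y = yval[keep],
                    stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- data[[cv]][keep]
  if (nrow(out) == 0L) stop("long_data: no usable rows after removing missing values")
  out <- out[order(out$id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("long_data", "data.frame"),
            id_col = id, outcome_col = outcome, time_col = time,
            covariates = as.character(covariates %||% character()))
}

#' Read a long-format CSV file
#'
#' Thin wrapper around [utils::read.csv()] followed by [long_data()]
#' validation and sorting.
#'
#' @inheritParams long_data
#' @param path path to a comma-separated file with a header row.
#' @return a [long_data()] object.
#' @export
read_long_csv <- function(path, id = "ID", outcome, time, covariates = NULL) {
  if (!file.exists(path)) stop("read_long_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_long_csv: '", path, "' contains no data rows")
  long_data(df, id = id, outcome = outcome, time = time,
            covariates = covariates)
}

#' Write a long-format dataset to CSV
#'
#' Writes the dataset with its original column names (`ID,time,outcome[,...]`
#' style header).
#'
#' @param data a [long_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  stopifnot(inherits(data, "long_data"))
  df <- as.data.frame(data)
  names(df)[1:3] <- c(attr(data, "id_col"), attr(data, "time_col"),
                      attr(data, "outcome_col"))
  # conventional column order: id, time-varying outcome after time
  df <- df[, c(1L, 2L, 3L, seq_len(ncol(df))[-(1:3)]), drop = FALSE]
  # 17 significant digits so that doubles survive the text round trip
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17,
                                               format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only subjects with a minimum number of observations
#'
#' Inclusion filter used by the simulation designs (e.g. at least 4
#' observations per subject). Idempotent; preserves row order.
#'
#' @param data a [long_data()] object or plain data.frame with an `id`
#'   column.
#' @param min_obs minimum number of rows a subject must have to be kept.
#' @return the filtered dataset, same class as the input.
#' @export
apply_inclusion_filter <- function(data, min_obs = 4L) {
  stopifnot(min_obs >= 1L)
  counts <- table(data$id)
  keep_ids <- names(counts)[counts >= min_obs]
  out <- data[as.character(data$id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.long_data <- function(x, ...) {
  n <- length(unique(x$id))
  cat("Longitudinal dataset: ", n, " subjects, ", nrow(x), " observations\n",
      sep = "")
  cat("  time range: [", format(min(x$time), digits = 4), ", ",
      format(max(x$time), digits = 4), "]  outcome range: [",
      format(min(x$y), digits = 4), ", ", format(max(x$y), digits = 4),
      "]\n", sep = "")
  cv <- attr(x, "covariates")
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# summary helpers used by reports and generators ----

subject_summaries <- function(data) {
  ids <- unique(data$id)
  first <- tapply(data$time, data$id, min)[as.character(ids)]
  last <- tapply(data$time, data$id, max)[as.character(ids)]
  nobs <- tapply(data$time, data$id, length)[as.character(ids)]
  data.frame(id = ids, first = as.numeric(first), last = as.numeric(last),
             followup = as.numeric(last - first), n_obs = as.integer(nobs))
}

#' Mean follow-up duration
#'
#' Average, across subjects, of the span from first to last visit.
#'
#' @param data a [long_data()] object.
#' @return a list with `mean` and `sd` of per-subject follow-up (time
#'   units) and `n` subjects.
#' @export
followup_summary <- function(data) {
  s <- subject_summaries(data)
  list(mean = mean(s$followup), sd = stats::sd(s$followup), n = nrow(s))
}
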