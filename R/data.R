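#' Construct a survival dataset
#'
#' Bundles follow-up times, event indicators and a covariate table into the
#' container used by every fitting routine in the package. Times are in the
#' study's time unit (weeks for a withdrawal trial), events are coded
#' \code{1} = event observed, \code{0} = censored; any other coding must be
#' mapped before construction.
#'
#' @param time numeric vector of nonnegative follow-up times.
#' @param event integer/numeric vector in \{0, 1\}, same length as \code{time}.
#' @param covariates data frame (or matrix) of numeric covariates, one row
#'   per subject. May be omitted for covariate-free analyses.
#' @return An object of class \code{survival_dataset}: a list with elements
#'   \code{time}, \code{event}, \code{covariates} (data frame) and \code{n}.
#' @examples
#' ds <- survival_dataset(c(1, 2, 3), c(1, 0, 1),
#'                        data.frame(trt = c(0, 1, 1)))
#' ds$n
#' @export
survival_dataset <- function(time, event, covariates = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event))
    stop("`time` and `event` must have the same length")
  if (length(time) < 1L)
    stop("dataset must contain at least one subject")
  if (anyNA(time) || anyNA(event))
    stop("missing values in `time` or `event`")
  if (any(time < 0))
    stop("all follow-up times must be nonnegative")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)")
  n <- length(time)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(n))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("`covariates` must have one row per subject")
    if (ncol(covariates) > 0) {
      if (anyNA(covariates))
        stop("missing values in covariates")
      if (!all(vapply(covariates, is.numeric, logical(1))))
        stop("all covariates must be numeric")
    }
  }
  structure(list(time = time, event = event,
                 covariates = covariates, n = n),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: %d subjects, %d events (%.1f%%), %d covariate(s)\n",
              x$n, sum(x$event), 100 * mean(x$event), ncol(x$covariates)))
  if (ncol(x$covariates) > 0)
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a survival dataset by row index
#' @param ds a \code{survival_dataset}.
#' @param idx integer or logical index vector.
#' @return The \code{survival_dataset} restricted to the selected subjects.
#' @export
subset_dataset <- function(ds, idx) {
  survival_dataset(ds$time[idx], ds$event[idx],
                   ds$covariates[idx, , drop = FALSE])
}

#' Read a survival table from CSV
#'
#' Reads a comma-separated table (header mandatory, decimal point, UTF-8)
#' with one row per subject and maps the named columns onto a
#' \code{\link{survival_dataset}}. Rows with missing values in any mapped
#' column are dropped with a message reporting the count.
#'
#' @param path path to the CSV file.
#' @param time_col name of the follow-up time column.
#' @param event_col name of the event indicator column (must be coded 0/1).
#' @param covariate_cols character vector of covariate column names;
#'   \code{NULL} (default) takes every remaining column.
#' @return A \code{survival_dataset}, with attribute \code{"dropped"} giving
#'   the number of incomplete rows removed.
#' @export
read_survival_csv <- function(path, time_col = "time", event_col = "event",
                              covariate_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(raw), c(time_col, event_col))
  needed <- c(time_col, event_col, covariate_cols)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop("mapped column(s) not present in file: ",
         paste(missing_cols, collapse = ", "))
  sub <- raw[, needed, drop = FALSE]
  complete <- stats::complete.cases(sub)
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(sprintf("read_survival_csv: dropped %d incomplete row(s)", dropped))
    sub <- sub[complete, , drop = FALSE]
  }
  if (nrow(sub) == 0) stop("no complete rows in file")
  ev <- sub[[event_col]]
  bad_ev <- which(!(ev %in% c(0, 1)))
  if (length(bad_ev) > 0)
    stop(sprintf("event column '%s' has value outside {0,1} at row(s): %s",
                 event_col, paste(utils::head(bad_ev, 5), collapse = ", ")))
  tm <- sub[[time_col]]
  if (any(tm < 0))
    stop(sprintf("negative time in column '%s'", time_col))
  ds <- survival_dataset(tm, ev, sub[, covariate_cols, drop = FALSE])
  attr(ds, "dropped") <- dropped
  ds
}

#' Write a survival dataset to CSV
#' @param ds a \code{survival_dataset}.
#' @param path output file path.
#' @param time_col,event_col column names to use in the file.
#' @return \code{path}, invisibly.
#' @export
write_survival_csv <- function(ds, path, time_col = "time", event_col = "event") {
  out <- data.frame(ds$time, ds$event)
  names(out) <- c(time_col, event_col)
  out <- cbind(out, ds$covariates)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sanity-check a survival dataset
#'
#' Runs non-fatal diagnostic checks and collects them in a report: absence of
#' observed events, constant covariate columns, and heavy event-time ties
#' (more than half of all events share a single time).
#'
#' @param ds a \code{survival_dataset}.
#' @return An object of class \code{validation_report}: list with character
#'   vectors \code{errors} and \code{warnings}.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  errors <- character(0)
  warnings <- character(0)
  if (sum(ds$event) == 0)
    warnings <- c(warnings, "no observed events")
  if (ncol(ds$covariates) > 0) {
    const <- vapply(ds$covariates, function(v) length(unique(v)) == 1L, logical(1))
    for (nm in names(ds$covariates)[const])
      warnings <- c(warnings, sprintf("constant covariate '%s'", nm))
  }
  ev_times <- ds$time[ds$event == 1]
  if (length(ev_times) > 1) {
    tab <- table(ev_times)
    if (max(tab) > length(ev_times) / 2)
      warnings <- c(warnings, "heavy ties: one time holds most events")
  }
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$errors) == 0 && length(x$warnings) == 0) {
    cat("Dataset validation: clean\n")
  } else {
    for (e in x$errors) cat("ERROR:", e, "\n")
    for (w in x$warnings) cat("warning:", w, "\n")
  }
  invisible(x)
}

## ---- right-continuous step functions -------------------------------------

#' Right-continuous step function
#'
#' Minimal container for the nondecreasing cumulative-hazard estimates and
#' the nonincreasing survival curves handled by the package. Evaluation is
#' right-continuous; left of the first knot the function equals
#' \code{left_value} (0 for a cumulative hazard, 1 for a survival curve).
#'
#' @param knots strictly increasing numeric vector of jump locations.
#' @param values function values at (and right of) each knot.
#' @param left_value value left of the first knot.
#' @param zero_tail logical; marks that the associated uncured survival is
#'   constrained to 0 beyond the last knot (identifiability device).
#' @param tail_value optional value returned strictly beyond the last knot
#'   (e.g. the cure plateau of a population survival curve); \code{NULL}
#'   keeps the last knot's value (finite extension).
#' @return An object of class \code{cure_stepfun}.
#' @export
cure_stepfun <- function(knots, values, left_value = 0, zero_tail = FALSE,
                         tail_value = NULL) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) != length(values))
    stop("`knots` and `values` must have equal length")
  if (is.unsorted(knots, strictly = TRUE))
    stop("`knots` must be strictly increasing")
  structure(list(knots = knots, values = values,
                 left_value = left_value, zero_tail = zero_tail,
                 tail_value = tail_value),
            class = "cure_stepfun")
}

#' Evaluate a step function
#' @param sf a \code{cure_stepfun}.
#' @param t numeric vector of evaluation points.
#' @return Numeric vector of values, right-continuous in \code{t}.
#' @export
stepfun_eval <- function(sf, t) {
  if (length(sf$knots) == 0) return(rep(sf$left_value, length(t)))
  idx <- findInterval(t, sf$knots)
  out <- ifelse(idx == 0, sf$left_value, sf$values[pmax(idx, 1L)])
  if (!is.null(sf$tail_value))
    out[t > sf$knots[length(sf$knots)]] <- sf$tail_value
  as.numeric(out)
}

#' @export
print.cure_stepfun <- function(x, ...) {
  cat(sprintf("Step function: %d knot(s)", length(x$knots)))
  if (length(x$knots) > 0)
    cat(sprintf(" on [%g, %g], values %g .. %g",
                min(x$knots), max(x$knots),
                x$values[1], x$values[length(x$values)]))
  if (x$zero_tail) cat(" [zero tail]")
  cat("\n")
  invisible(x)
}

#' Export a step function as a two-column CSV
#' @param sf a \code{cure_stepfun}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_stepfun_csv <- function(sf, path) {
  utils::write.csv(data.frame(time = sf$knots, value = sf$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kaplan-Meier estimate of the event or censoring distribution
#'
#' Product-limit estimate of the survival function, delegated to
#' \code{survival::survfit}. With \code{of = "censoring"} the roles of event
#' and censoring are reversed (reverse Kaplan-Meier), which estimates the
#' censoring distribution needed when simulating critical values for the
#' follow-up test.
#'
#' @param ds a \code{survival_dataset}.
#' @param of \code{"event"} (default) or \code{"censoring"}.
#' @return A \code{cure_stepfun} with knots at the distinct failure times of
#'   the chosen kind and values equal to the estimated survival probability;
#'   equals 1 left of the first knot.
#' @export
kaplan_meier <- function(ds, of = c("event", "censoring")) {
  stopifnot(inherits(ds, "survival_dataset"))
  of <- match.arg(of)
  status <- if (of == "event") ds$event else 1 - ds$event
  sf <- survival::survfit(survival::Surv(ds$time, status) ~ 1,
                          conf.type = "none")
  jump <- sf$n.event > 0
  if (!any(jump))
    return(cure_stepfun(numeric(0), numeric(0), left_value = 1))
  cure_stepfun(sf$time[jump], sf$surv[jump], left_value = 1)
}
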