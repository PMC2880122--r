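## Maller-Zhou q_n test of sufficient follow-up.
##
## Estimating a cure fraction is only meaningful if follow-up extends well
## past the bulk of the event-time distribution. The q_n statistic is the
## fraction of subjects with an uncensored time in the interval
## (2 t* - t_max, t*], where t* is the largest uncensored time and t_max
## the largest observed time: a long event-free plateau after the last
## event (t_max >> t*) widens the interval and captures many events,
## giving a large q_n, which supports sufficient follow-up.

#' The q_n statistic of sufficient follow-up
#'
#' @param ds a \code{\link{survival_dataset}} with at least one event.
#' @return An object of class \code{qn_result}: \code{qn} = N/n, \code{N}
#'   (uncensored times in the interval), \code{t_star}, \code{t_max} and
#'   \code{interval}. Critical values and a verdict can be added with
#'   \code{\link{qn_critical_values}}.
#' @examples
#' ds <- survival_dataset(c(1, 2, 3, 10), c(1, 1, 1, 0))
#' qn_statistic(ds)$qn   # 0.75
#' @export
qn_statistic <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  ev_times <- ds$time[ds$event == 1]
  if (length(ev_times) == 0) stop("no events: q_n undefined")
  t_star <- max(ev_times)
  t_max <- max(ds$time)
  lo <- 2 * t_star - t_max
  N <- sum(ev_times > lo & ev_times <= t_star)
  if (t_star == t_max) N <- 0L   # empty half-open interval (t*, t*]
  structure(list(qn = N / ds$n, N = as.integer(N), n = ds$n,
                 t_star = t_star, t_max = t_max,
                 interval = c(lo, t_star),
                 critical_values = NULL, B = NULL, level = NULL,
                 verdict = "indeterminate"),
            class = "qn_result")
}

#' Simulated critical values and verdict for the q_n test
#'
#' Simulates datasets of the observed size from the fitted parametric cure
#' model (cured with probability \code{c}, otherwise Weibull latency), with
#' censoring times drawn from the reverse Kaplan-Meier estimate of the
#' observed censoring distribution. The critical point at level \code{l}
#' is the empirical \code{l}-quantile of the simulated q_n values; follow-up
#' is judged sufficient when the observed q_n reaches the critical point at
#' the requested level.
#'
#' @param ds the observed \code{\link{survival_dataset}}.
#' @param cure_fit a \code{\link{fit_parametric_cure}} result, or a list
#'   with elements \code{c}, \code{mu} and \code{rho}.
#' @param B simulation replicates (default 1000).
#' @param levels quantile levels for the critical points.
#' @param level level at which the verdict is formed.
#' @param seed integer seed.
#' @return The \code{qn_result} for \code{ds}, completed with
#'   \code{critical_values}, \code{B} and \code{verdict}
#'   (\code{"sufficient"} or \code{"insufficient"}).
#' @export
qn_critical_values <- function(ds, cure_fit, B = 1000,
                               levels = c(0.90, 0.94, 0.95, 0.96),
                               level = 0.95, seed) {
  res <- qn_statistic(ds)
  if (sum(ds$event == 0) == 0)
    stop("no censored subjects: censoring distribution is degenerate")
  if (!missing(seed)) set.seed(as.integer(seed))
  cc <- cure_fit$c; mu <- cure_fit$mu; rho <- cure_fit$rho %||% 1
  stopifnot(cc >= 0, cc <= 1, mu > 0, rho > 0)
  cens_draw <- censoring_sampler(ds)
  n <- ds$n
  qn_sim <- vapply(seq_len(B), function(b) {
    eta <- stats::rbinom(n, 1L, 1 - cc)
    t_lat <- rep(Inf, n)
    if (any(eta == 1))
      t_lat[eta == 1] <- (-log(stats::runif(sum(eta == 1))) / mu)^(1 / rho)
    cens <- cens_draw(n)
    time <- pmin(t_lat, cens)
    event <- as.numeric(t_lat <= cens & eta == 1)
    if (sum(event) == 0) return(0)
    sim <- survival_dataset(time, event)
    qn_statistic(sim)$qn
  }, numeric(1))
  crit <- stats::quantile(qn_sim, probs = levels, names = FALSE, type = 1)
  res$critical_values <- stats::setNames(crit, paste0(levels * 100, "%"))
  res$B <- B
  res$level <- level
  crit_at <- stats::quantile(qn_sim, probs = level, names = FALSE, type = 1)
  res$verdict <- if (res$qn >= crit_at) "sufficient" else "insufficient"
  res
}

## Sampler from the reverse Kaplan-Meier censoring estimate: a discrete
## distribution on the observed censoring times; any mass the estimate
## leaves beyond its last jump is placed at the largest observed time.
censoring_sampler <- function(ds) {
  km <- kaplan_meier(ds, of = "censoring")
  t_max <- max(ds$time)
  if (length(km$knots) == 0) return(function(n) rep(t_max, n))
  surv <- km$values
  pmass <- diff(c(1, surv)) * -1          # jump sizes at the knots
  pts <- km$knots
  rem <- surv[length(surv)]
  if (rem > 1e-12) {
    pts <- c(pts, t_max)
    pmass <- c(pmass, rem)
  }
  pmass <- pmass / sum(pmass)
  function(n) pts[sample.int(length(pts), n, replace = TRUE, prob = pmass)]
}

#' @export
print.qn_result <- function(x, ...) {
  cat(sprintf("q_n test of sufficient follow-up\n"))
  cat(sprintf("  q_n = %.5f (N = %d of n = %d)\n", x$qn, x$N, x$n))
  cat(sprintf("  t* = %g, t_max = %g, interval (%g, %g]\n",
              x$t_star, x$t_max, x$interval[1], x$interval[2]))
  if (!is.null(x$critical_values)) {
    cat(sprintf("  critical points (B = %d):\n", x$B))
    print(round(x$critical_values, 5))
    cat(sprintf("  verdict at %.0f%% level: %s\n", 100 * x$level, x$verdict))
  }
  invisible(x)
}

#' Serialize a q_n result to JSON
#' @param x a \code{qn_result}.
#' @param path optional output file.
#' @return JSON string.
#' @export
qn_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(
    list(qn = x$qn, N = x$N, n = x$n, t_star = x$t_star, t_max = x$t_max,
         interval = x$interval, critical_values = as.list(x$critical_values),
         B = x$B, verdict = x$verdict),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  as.character(js)
}
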