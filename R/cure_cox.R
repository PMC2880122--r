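## Semiparametric Cox cure regression.
##
## Mixture model: subject i is cured with probability
##   c_i = expit(alpha' X_i)            (logistic incidence, intercept in X)
## and, if uncured, follows a proportional-hazards latency
##   S_i(t) = exp(-exp(beta' Z_i) Lambda0(t))
## with nonparametric baseline cumulative hazard Lambda0. The observed-data
## ("marginal full") log-likelihood is maximized by EM: the E-step computes
## posterior uncure weights for censored subjects; the M-step fits a
## fractional-response logistic model for alpha, a weighted Cox partial
## likelihood for beta, and a weighted Breslow baseline. Positive alpha
## coefficients raise the CURE probability.

## Build (X, Z) designs from covariate names; X always carries an intercept.
design_matrices <- function(ds, incidence_covs, latency_covs) {
  miss <- setdiff(c(incidence_covs, latency_covs), names(ds$covariates))
  if (length(miss) > 0)
    stop("covariate(s) not in dataset: ", paste(miss, collapse = ", "))
  X <- cbind("(Intercept)" = rep(1, ds$n),
             as.matrix(ds$covariates[, incidence_covs, drop = FALSE]))
  Z <- as.matrix(ds$covariates[, latency_covs, drop = FALSE])
  list(X = X, Z = Z)
}

#' Cure probability under the logistic incidence model
#'
#' @param alpha incidence coefficients, intercept first.
#' @param x covariate vector including the leading 1, or a matrix with one
#'   row per subject.
#' @return The cure probability \code{expit(alpha' x)}; a positive
#'   coefficient raises the probability of never experiencing the event.
#'   Numerically exact 0/1 for linear predictors beyond +-700.
#' @examples
#' incidence_prob(c(1.571, 1.177, -0.122), c(1, 1, 10))
#' @export
incidence_prob <- function(alpha, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(alpha)) stop("dimension mismatch")
    stats::plogis(drop(x %*% alpha))
  } else {
    if (length(x) != length(alpha)) stop("dimension mismatch")
    stats::plogis(sum(alpha * x))
  }
}

#' Survival function of an uncured subject
#'
#' @param beta latency coefficients (may be length 0).
#' @param baseline a \code{\link{cure_stepfun}} cumulative hazard.
#' @param z covariate vector matching \code{beta}.
#' @param t nonnegative evaluation time(s).
#' @return \code{exp(-exp(beta' z) * Lambda0(t))}; 0 beyond the last event
#'   time when the baseline carries the zero-tail constraint.
#' @export
uncured_survival <- function(beta, baseline, z, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  lp <- if (length(beta) > 0) sum(beta * z) else 0
  s <- exp(-exp(lp) * stepfun_eval(baseline, t))
  if (isTRUE(baseline$zero_tail) && length(baseline$knots) > 0)
    s[t > max(baseline$knots)] <- 0
  s
}

## Vectorized uncured survival at each subject's own time.
uncured_survival_all <- function(beta, baseline, Z, time) {
  lp <- if (ncol(Z) > 0) drop(Z %*% beta) else rep(0, length(time))
  s <- exp(-exp(lp) * stepfun_eval(baseline, time))
  if (isTRUE(baseline$zero_tail) && length(baseline$knots) > 0)
    s[time > max(baseline$knots) + 1e-12] <- 0
  s
}

#' Observed-data log-likelihood of the Cox cure model
#'
#' Boag-type mixture likelihood: events contribute the uncured density
#' (baseline jump times hazard multiplier times uncured survival) and the
#' probability of being uncured; censored subjects contribute
#' \code{c + (1 - c) S(T)}.
#'
#' @param alpha,beta coefficient vectors.
#' @param baseline \code{\link{cure_stepfun}} cumulative hazard with a jump
#'   at every distinct event time of \code{ds}.
#' @param ds a \code{\link{survival_dataset}}.
#' @param incidence_covs,latency_covs covariate names for the two designs.
#' @return The log-likelihood (finite scalar).
#' @export
observed_loglik <- function(alpha, beta, baseline, ds,
                            incidence_covs = character(0),
                            latency_covs = character(0)) {
  d <- design_matrices(ds, incidence_covs, latency_covs)
  ci <- incidence_prob(alpha, d$X)
  ev <- ds$event == 1
  if (any(ev)) {
    ev_times <- ds$time[ev]
    idx <- match_knot(baseline, ev_times)
    if (anyNA(idx))
      stop("baseline has no jump at event time(s): ",
           paste(utils::head(unique(ev_times[is.na(idx)]), 5), collapse = ", "))
    jumps <- baseline_jumps(baseline)[idx]
  }
  lp <- if (ncol(d$Z) > 0) drop(d$Z %*% beta) else rep(0, ds$n)
  Lam <- stepfun_eval(baseline, ds$time)
  ll <- 0
  if (any(ev))
    ll <- ll + sum(log(pmax(1 - ci[ev], 1e-300)) + log(pmax(jumps, 1e-300)) +
                     lp[ev] - exp(lp[ev]) * Lam[ev])
  if (any(!ev)) {
    S <- uncured_survival_all(beta, baseline, d$Z, ds$time)[!ev]
    ll <- ll + sum(log(pmax(ci[!ev] + (1 - ci[!ev]) * S, 1e-300)))
  }
  ll
}

match_knot <- function(sf, t) {
  idx <- findInterval(t, sf$knots)
  ok <- idx >= 1 & abs(t - sf$knots[pmax(idx, 1L)]) < 1e-9
  ifelse(ok, idx, NA_integer_)
}

baseline_jumps <- function(sf) diff(c(sf$left_value, sf$values))

#' E-step: posterior probability of being uncured
#'
#' Events are known uncured (weight 1); a censored subject's weight is the
#' conditional probability of eventual failure given survival to its
#' censoring time, \code{(1-c) S(T) / (c + (1-c) S(T))}.
#'
#' @inheritParams observed_loglik
#' @return Weight vector in \[0, 1\], equal to 1 wherever the event occurred.
#' @export
e_step <- function(alpha, beta, baseline, ds,
                   incidence_covs = character(0),
                   latency_covs = character(0)) {
  d <- design_matrices(ds, incidence_covs, latency_covs)
  ci <- incidence_prob(alpha, d$X)
  S <- uncured_survival_all(beta, baseline, d$Z, ds$time)
  e_step_weights(ds$event, ci, S)
}

## shared by the semiparametric and parametric models
e_step_weights <- function(event, ci, S) {
  num <- (1 - ci) * S
  den <- ci + num
  w <- ifelse(den > 0, num / den, 0)  # 0/0 (c = 1, S = 0): cured by continuity
  w[event == 1] <- 1
  unname(pmin(pmax(w, 0), 1))
}

#' M-step for the incidence coefficients
#'
#' Newton-Raphson maximization of the fractional-response logistic
#' log-likelihood \code{sum((1-w) log c + w log(1-c))} with
#' \code{c = expit(X alpha)}. Divergent coefficients (separation in the
#' weighted response) are capped at |20| with a warning.
#'
#' @param w uncure weights from the E-step.
#' @param X incidence design matrix including the intercept column.
#' @param fixed_intercept if non-\code{NULL}, the intercept is held at this
#'   value and only the remaining coefficients are maximized.
#' @param init starting coefficient vector (warm start); within the EM this
#'   is the current alpha, which also guarantees the M-step never decreases
#'   the objective.
#' @return Coefficient vector \code{alpha}, with attribute \code{"capped"}
#'   if the |20| cap was hit.
#' @export
m_step_incidence <- function(w, X, fixed_intercept = NULL,
                             init = rep(0, ncol(X))) {
  q <- ncol(X)
  free <- seq_len(q)
  offset <- rep(0, nrow(X))
  alpha <- pmin(pmax(init, -20), 20)
  if (!is.null(fixed_intercept)) {
    alpha[1] <- fixed_intercept
    offset <- X[, 1] * fixed_intercept
    free <- setdiff(free, 1L)
  }
  if (length(free) == 0) return(alpha)
  y <- 1 - w    # "success" = cured
  capped <- FALSE
  obj <- function(a) {
    eta <- offset + drop(X[, free, drop = FALSE] %*% a)
    sum(y * stats::plogis(eta, log.p = TRUE) +
          (1 - y) * stats::plogis(-eta, log.p = TRUE))
  }
  for (iter in 1:100) {
    eta <- offset + drop(X[, free, drop = FALSE] %*% alpha[free])
    c_hat <- stats::plogis(eta)
    grad <- drop(crossprod(X[, free, drop = FALSE], y - c_hat))
    if (sqrt(sum(grad^2)) < 1e-9) break
    Wd <- pmax(c_hat * (1 - c_hat), 1e-12)
    H <- crossprod(X[, free, drop = FALSE] * Wd, X[, free, drop = FALSE])
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    ## project onto the |20| box, halving until the objective cannot drop
    f0 <- obj(alpha[free])
    cand <- pmin(pmax(alpha[free] + step, -20), 20)
    for (h in 1:30) {
      if (obj(cand) >= f0 - 1e-12) break
      step <- step / 2
      cand <- pmin(pmax(alpha[free] + step, -20), 20)
    }
    if (obj(cand) < f0 - 1e-12) break   # no improving step inside the box
    moved <- max(abs(cand - alpha[free]))
    if (any(abs(cand) >= 20 - 1e-8)) capped <- TRUE
    alpha[free] <- cand
    if (moved < 1e-12) break
  }
  if (capped) warning("incidence coefficients diverged; capped at |20|")
  attr(alpha, "capped") <- capped
  alpha
}

#' M-step for the latency coefficients
#'
#' Newton-Raphson maximization of the weighted Cox partial likelihood in
#' which E-step weights discount censored subjects' contributions to the
#' risk sets (Breslow tie handling). With unit weights this is the standard
#' Cox partial likelihood.
#'
#' @param w uncure weights (1 for events).
#' @param ds a \code{\link{survival_dataset}}.
#' @param Z latency design matrix (no intercept); may have zero columns.
#' @param init starting coefficient vector.
#' @return Coefficient vector \code{beta}; degenerate coordinates (no
#'   information, e.g. an all-zero covariate or a single subject at risk)
#'   are reported as 0 with a warning, and monotone likelihoods are capped
#'   at |20| with a warning.
#' @export
m_step_latency <- function(w, ds, Z, init = rep(0, ncol(Z))) {
  p <- ncol(Z)
  if (p == 0) return(numeric(0))
  if (sum(ds$event) == 0) stop("no events: latency coefficients undefined")
  beta <- init
  capped <- FALSE
  for (iter in 1:100) {
    gh <- wpl_grad_hess(beta, w, ds$time, ds$event, Z)
    dinfo <- diag(gh$H)
    active <- which(dinfo > 1e-10)
    if (length(active) == 0) {
      if (any(abs(beta) > 0)) beta <- rep(0, p)
      warning("partial likelihood carries no information; beta set to 0")
      break
    }
    degen <- setdiff(seq_len(p), active)
    if (length(degen) > 0 && iter == 1) {
      beta[degen] <- 0
      warning("no information for latency coefficient(s) ",
              paste(colnames(Z)[degen], collapse = ", "), "; set to 0")
    }
    g <- gh$g[active]
    if (sqrt(sum(g^2)) < 1e-9) break
    step <- tryCatch(solve(gh$H[active, active, drop = FALSE], g),
                     error = function(e) g / max(dinfo[active]))
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    ## project onto the |20| box; step-halving keeps the partial
    ## likelihood from decreasing
    f0 <- weighted_partial_loglik(beta, w, ds$time, ds$event, Z)
    cand <- beta
    cand[active] <- pmin(pmax(beta[active] + step, -20), 20)
    for (h in 1:30) {
      if (weighted_partial_loglik(cand, w, ds$time, ds$event, Z) >=
          f0 - 1e-12) break
      step <- step / 2
      cand[active] <- pmin(pmax(beta[active] + step, -20), 20)
    }
    if (weighted_partial_loglik(cand, w, ds$time, ds$event, Z) <
        f0 - 1e-12) break
    if (any(abs(cand[active]) >= 20 - 1e-8)) capped <- TRUE
    moved <- max(abs(cand - beta))
    beta <- cand
    if (moved < 1e-12) break
  }
  if (capped) warning("latency coefficients diverged (monotone likelihood); capped at |20|")
  beta
}

## Gradient and (negative-curvature) Hessian of the weighted log partial
## likelihood; returns H = observed information (positive semidefinite).
wpl_grad_hess <- function(beta, w, time, event, Z) {
  p <- ncol(Z)
  lp <- drop(Z %*% beta)
  r <- w * exp(lp)
  ord <- order(time, decreasing = TRUE)   # accumulate risk sets from above
  Zo <- Z[ord, , drop = FALSE]
  ro <- r[ord]
  S0 <- cumsum(ro)
  S1 <- apply(Zo * ro, 2, cumsum)
  if (p == 1) S1 <- matrix(S1, ncol = 1)
  ## S2 as p x p running sums
  g <- rep(0, p); H <- matrix(0, p, p)
  to <- time[ord]; eo <- event[ord]
  ## handle ties: all subjects with T_j >= t are at risk; since sorted
  ## descending, positions 1..k where to[k] >= t. For an event at position i,
  ## risk set is all positions j with to[j] >= to[i]; with descending sort and
  ## ties that is 1..last index of the tie block.
  lens <- rle(to)$lengths
  tie_end <- rep(cumsum(lens), lens)
  S2_run <- matrix(0, p, p)
  k <- 0L
  S2_at <- vector("list", length(to))
  for (i in seq_along(to)) {
    zi <- Zo[i, ]
    S2_run <- S2_run + ro[i] * tcrossprod(zi)
    S2_at[[i]] <- S2_run
  }
  for (i in seq_along(to)) {
    if (eo[i] != 1) next
    k <- tie_end[i]
    s0 <- S0[k]
    if (s0 <= 0) stop("risk-set weight sum is zero at an event time")
    s1 <- S1[k, ]
    zbar <- s1 / s0
    g <- g + (Zo[i, ] - zbar)
    H <- H + S2_at[[k]] / s0 - tcrossprod(zbar)
  }
  list(g = g, H = H)
}

## Weighted log partial likelihood.
weighted_partial_loglik <- function(beta, w, time, event, Z) {
  lp <- if (ncol(Z) > 0) drop(Z %*% beta) else rep(0, length(time))
  r <- w * exp(lp)
  ord <- order(time, decreasing = TRUE)
  to <- time[ord]
  S0 <- cumsum(r[ord])
  lens <- rle(to)$lengths
  tie_end <- rep(cumsum(lens), lens)
  ev <- event[ord] == 1
  sum(lp[ord][ev] - log(S0[tie_end[ev]]))
}

#' Weighted Breslow estimate of the baseline cumulative hazard
#'
#' Jump at each distinct event time t of \code{d(t) / sum_(T_j >= t) w_j
#' exp(beta' Z_j)}, with \code{d(t)} the event count at t. E-step weights
#' discount censored subjects in the risk sets.
#'
#' @inheritParams m_step_latency
#' @param beta latency coefficients.
#' @param zero_tail mark the returned baseline with the zero-tail
#'   constraint (uncured survival 0 beyond the last event time).
#' @return A \code{\link{cure_stepfun}} with knots at distinct event times.
#' @export
breslow_estimate <- function(beta, w, ds, Z = NULL, zero_tail = TRUE,
                             latency_covs = character(0)) {
  if (is.null(Z)) Z <- design_matrices(ds, character(0), latency_covs)$Z
  if (sum(ds$event) == 0) stop("no events: baseline hazard undefined")
  lp <- if (ncol(Z) > 0) drop(Z %*% beta) else rep(0, ds$n)
  r <- w * exp(lp)
  ev_times <- sort(unique(ds$time[ds$event == 1]))
  jumps <- vapply(ev_times, function(t) {
    denom <- sum(r[ds$time >= t - 1e-12])
    if (denom <= 0) stop("risk-set weight sum is zero at an event time")
    sum(ds$event == 1 & abs(ds$time - t) < 1e-12) / denom
  }, numeric(1))
  cure_stepfun(ev_times, cumsum(jumps), left_value = 0, zero_tail = zero_tail)
}

#' Control options for the Cox cure EM
#'
#' @param n_starts number of EM starts. Start 0 is the naive pair (logistic
#'   regression of 1-event on X, standard Cox fit on Z); the others perturb
#'   it uniformly within +-2 naive standard errors, guarding against the
#'   EM's sensitivity to starting values.
#' @param max_iter maximum EM iterations per start.
#' @param tol_loglik relative log-likelihood convergence tolerance.
#' @param tol_coef maximum absolute coefficient change tolerance.
#' @param zero_tail impose the zero-tail identifiability constraint.
#' @param fix_alpha_intercept hold the incidence intercept at this value
#'   (e.g. -20 forces the cure fraction to ~0, recovering standard Cox).
#' @param init optional list with \code{alpha} and \code{beta} overriding
#'   start 0.
#' @param se_method \code{"hessian"}, \code{"bootstrap"} or \code{"none"}.
#' @param boot_B bootstrap replicates when \code{se_method = "bootstrap"}.
#' @return A list of class \code{cure_cox_control}.
#' @export
cure_cox_control <- function(n_starts = 20, max_iter = 1000,
                             tol_loglik = 1e-7, tol_coef = 1e-6,
                             zero_tail = TRUE, fix_alpha_intercept = NULL,
                             init = NULL, se_method = c("hessian", "bootstrap", "none"),
                             boot_B = 200) {
  structure(list(n_starts = n_starts, max_iter = max_iter,
                 tol_loglik = tol_loglik, tol_coef = tol_coef,
                 zero_tail = zero_tail, fix_alpha_intercept = fix_alpha_intercept,
                 init = init, se_method = match.arg(se_method), boot_B = boot_B),
            class = "cure_cox_control")
}

#' Fit the semiparametric Cox cure regression by multi-start EM
#'
#' Alternates the E-step (posterior uncure weights) with M-steps for the
#' logistic incidence coefficients, the weighted Cox partial-likelihood
#' latency coefficients, and the weighted Breslow baseline, until the
#' observed-data log-likelihood and the coefficients stabilize. Because the
#' EM can converge to different stationary points depending on its start,
#' several perturbed starts are run and the solution with the highest
#' log-likelihood is kept.
#'
#' @param ds a \code{\link{survival_dataset}} with at least one event.
#' @param incidence_covs names of covariates for the cured-incidence model
#'   (the intercept is always included).
#' @param latency_covs names of covariates for the uncured-latency model.
#' @param control a \code{\link{cure_cox_control}} list.
#' @return An object of class \code{cure_cox_fit}: coefficients
#'   \code{alpha}, \code{beta}, \code{baseline} (Breslow cumulative hazard),
#'   \code{weights}, \code{loglik}, \code{aic}, \code{se}, per-iteration
#'   \code{trace} of the best start, \code{converged}, \code{n_starts}.
#' @examples
#' sim <- simulate_sertraline_like(seed = 1)
#' fit <- fit_cure_cox(sim$dataset, "trt", c("gender"),
#'                     control = cure_cox_control(n_starts = 2,
#'                                                se_method = "none"))
#' fit$alpha
#' @export
fit_cure_cox <- function(ds, incidence_covs = character(0),
                         latency_covs = character(0),
                         control = cure_cox_control()) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (sum(ds$event) == 0) stop("no events: cure model is not identifiable")
  d <- design_matrices(ds, incidence_covs, latency_covs)
  q <- ncol(d$X); p <- ncol(d$Z)

  naive <- naive_start(ds, d, control)
  starts <- make_starts(naive, control, q, p)

  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    res <- run_em_once(s$alpha, s$beta, ds, d, incidence_covs, latency_covs,
                       control)
    if (res$converged) n_conv <- n_conv + 1L
    if (is.null(best) ||
        (is.finite(res$loglik) && res$loglik > best$loglik + 1e-12))
      best <- res
  }
  if (n_conv == 0L)
    stop(sprintf("EM failed to converge in all %d start(s); best loglik %.6f after %d iterations",
                 length(starts), best$loglik, length(best$trace)))

  attr(best$alpha, "capped") <- NULL
  names(best$alpha) <- colnames(d$X)
  if (p > 0) names(best$beta) <- colnames(d$Z)
  fit <- structure(list(alpha = best$alpha, beta = best$beta,
                        baseline = best$baseline, weights = best$w,
                        loglik = best$loglik,
                        aic = -2 * best$loglik + 2 * (q + p),
                        se = NULL, trace = best$trace,
                        converged = best$converged,
                        n_starts = length(starts),
                        incidence_covs = incidence_covs,
                        latency_covs = latency_covs,
                        control = control, n = ds$n),
                   class = "cure_cox_fit")
  if (control$se_method != "none")
    fit$se <- tryCatch(
      covariance_and_se(fit, ds, method = control$se_method, B = control$boot_B),
      error = function(e) {
        warning("standard errors unavailable: ", conditionMessage(e))
        NULL
      })
  fit
}

naive_start <- function(ds, d, control) {
  q <- ncol(d$X); p <- ncol(d$Z)
  alpha0 <- rep(0, q); alpha_se <- rep(0.5, q)
  gl <- tryCatch(suppressWarnings(
    stats::glm.fit(d$X, 1 - ds$event, family = stats::binomial())),
    error = function(e) NULL)
  if (!is.null(gl) && all(is.finite(gl$coefficients))) {
    alpha0 <- pmin(pmax(gl$coefficients, -20), 20)
    vc <- tryCatch(chol2inv(chol(crossprod(d$X * pmax(gl$weights, 1e-8), d$X))),
                   error = function(e) NULL)
    if (!is.null(vc)) alpha_se <- pmin(sqrt(pmax(diag(vc), 1e-8)), 2)
  }
  beta0 <- rep(0, p); beta_se <- rep(0.5, p)
  if (p > 0) {
    cx <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(ds$time, ds$event) ~ d$Z,
                      ties = "breslow")),
      error = function(e) NULL)
    if (!is.null(cx) && all(is.finite(stats::coef(cx)))) {
      beta0 <- stats::coef(cx)
      se <- sqrt(diag(cx$var))
      if (all(is.finite(se))) beta_se <- pmin(se, 2)
    }
  }
  if (!is.null(control$init)) {
    if (!is.null(control$init$alpha)) alpha0 <- control$init$alpha
    if (!is.null(control$init$beta)) beta0 <- control$init$beta
  }
  if (!is.null(control$fix_alpha_intercept))
    alpha0[1] <- control$fix_alpha_intercept
  list(alpha = alpha0, alpha_se = alpha_se, beta = beta0, beta_se = beta_se)
}

make_starts <- function(naive, control, q, p) {
  starts <- list(list(alpha = naive$alpha, beta = naive$beta))
  if (control$n_starts > 1 && is.null(control$init)) {
    ## deterministic near-zero-cure start: covers the standard-Cox boundary
    ## ridge where the cure fraction vanishes
    a_nc <- c(-6, rep(0, q - 1))
    if (!is.null(control$fix_alpha_intercept))
      a_nc[1] <- control$fix_alpha_intercept
    starts <- c(starts, list(list(alpha = a_nc, beta = naive$beta)))
  }
  if (control$n_starts > length(starts)) {
    for (k in seq_len(control$n_starts - length(starts))) {
      a <- naive$alpha + stats::runif(q, -2, 2) * naive$alpha_se
      b <- if (p > 0) naive$beta + stats::runif(p, -2, 2) * naive$beta_se
           else numeric(0)
      if (!is.null(control$fix_alpha_intercept))
        a[1] <- control$fix_alpha_intercept
      starts <- c(starts, list(list(alpha = a, beta = b)))
    }
  }
  starts
}

run_em_once <- function(alpha, beta, ds, d, incidence_covs, latency_covs,
                        control) {
  ## initialize the baseline at the start's own weight/Breslow fixed point
  ## (an EM over the baseline alone, so the starting likelihood equals the
  ## profile likelihood of the starting coefficients)
  baseline <- breslow_estimate(beta, rep(1, ds$n), ds, Z = d$Z,
                               zero_tail = control$zero_tail)
  for (k in 1:50) {
    ci <- incidence_prob(alpha, d$X)
    S <- uncured_survival_all(beta, baseline, d$Z, ds$time)
    w0 <- e_step_weights(ds$event, ci, S)
    new_bl <- breslow_estimate(beta, w0, ds, Z = d$Z,
                               zero_tail = control$zero_tail)
    done <- max(abs(new_bl$values - baseline$values)) < 1e-10
    baseline <- new_bl
    if (done) break
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  w <- rep(1, ds$n)
  for (iter in seq_len(control$max_iter)) {
    ci <- incidence_prob(alpha, d$X)
    S <- uncured_survival_all(beta, baseline, d$Z, ds$time)
    w <- e_step_weights(ds$event, ci, S)
    alpha_new <- suppressWarnings(
      m_step_incidence(w, d$X, fixed_intercept = control$fix_alpha_intercept,
                       init = alpha))
    beta_new <- suppressWarnings(m_step_latency(w, ds, d$Z, init = beta))
    baseline <- breslow_estimate(beta_new, w, ds, Z = d$Z,
                                 zero_tail = control$zero_tail)
    ll <- observed_loglik(alpha_new, beta_new, baseline, ds,
                          incidence_covs, latency_covs)
    trace <- c(trace, ll)
    dcoef <- max(abs(c(alpha_new - alpha, beta_new - beta)), 0)
    alpha <- alpha_new; beta <- beta_new
    if (abs(ll - ll_old) / (abs(ll) + 1) < control$tol_loglik &&
        dcoef < control$tol_coef) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(alpha = alpha, beta = beta, baseline = baseline, w = w,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

#' @export
print.cure_cox_fit <- function(x, ...) {
  cat("Cox cure regression fit\n")
  cat(sprintf("  n = %d, loglik = %.4f, AIC = %.4f, converged: %s\n",
              x$n, x$loglik, x$aic, x$converged))
  cat("  Cured incidence (logistic, positive = more likely cured):\n")
  print(round(x$alpha, 4))
  if (length(x$beta) > 0) {
    cat("  Uncured latency (Cox PH):\n")
    print(round(x$beta, 4))
  } else cat("  Uncured latency: baseline only\n")
  if (!is.null(x$se)) {
    cat("  Standard errors:\n")
    print(round(x$se, 4))
  }
  invisible(x)
}

#' Akaike information criterion for a fitted cure model
#'
#' \code{AIC = -2 loglik + 2k}, where \code{k} counts regression
#' coefficients only (the nonparametric baseline is excluded) -- the
#' convention under which published (log-likelihood, AIC) pairs for these
#' models reproduce arithmetically.
#'
#' @param object a \code{cure_cox_fit}, a \code{param_cure_fit}, or a bare
#'   numeric log-likelihood.
#' @param k number of regression parameters; required when \code{object} is
#'   numeric, ignored otherwise.
#' @return The AIC value.
#' @examples
#' model_aic(-81.603, k = 11)   # 185.206
#' @export
model_aic <- function(object, k = NULL) {
  if (inherits(object, "cure_cox_fit")) {
    k <- length(object$alpha) + length(object$beta)
    ll <- object$loglik
  } else if (inherits(object, "param_cure_fit")) {
    k <- if (object$family == "weibull") 3 else 2
    ll <- object$loglik
  } else if (is.numeric(object) && length(object) == 1) {
    if (is.null(k)) stop("k required for a bare log-likelihood")
    ll <- object
  } else stop("unsupported object")
  if (!is.finite(ll)) stop("log-likelihood is not finite")
  -2 * ll + 2 * k
}

#' Best-subset covariate search by AIC
#'
#' Enumerates admissible assignments of candidate covariates to the
#' incidence and latency components, fits each model, and ranks by AIC.
#' With \code{guidelines = TRUE} the variable-selection guidelines for
#' cure-incidence-first analyses apply: the treatment indicator is always in
#' the incidence model, the latency set is small (at most
#' \code{latency_cap} covariates), and no covariate appears in both
#' components. With guidelines off, every covariate may independently enter
#' neither, either, or both components.
#'
#' @param ds a \code{\link{survival_dataset}}.
#' @param candidates character vector of candidate covariate names.
#' @param treatment name of the treatment covariate (required when
#'   \code{guidelines = TRUE}).
#' @param guidelines logical.
#' @param latency_cap maximum latency-set size under the guidelines.
#' @param control \code{\link{cure_cox_control}} for the individual fits.
#' @return An object of class \code{subset_search_result}: data frame
#'   \code{models} (incidence set, latency set, loglik, aic), index
#'   \code{best}, and \code{guideline_version}.
#' @export
best_subset_search <- function(ds, candidates, treatment = NULL,
                               guidelines = TRUE, latency_cap = 2,
                               control = cure_cox_control(n_starts = 3,
                                                          se_method = "none")) {
  if (length(candidates) == 0) stop("candidate covariate set is empty")
  if (guidelines && (is.null(treatment) || !(treatment %in% candidates)))
    stop("guidelines require `treatment` to name a candidate covariate")
  specs <- enumerate_subset_models(candidates, treatment, guidelines,
                                   latency_cap)
  rows <- lapply(specs, function(sp) {
    fit <- tryCatch(fit_cure_cox(ds, sp$incidence, sp$latency, control),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(incidence = paste(sp$incidence, collapse = "+"),
               latency = paste(sp$latency, collapse = "+"),
               loglik = fit$loglik, aic = fit$aic,
               stringsAsFactors = FALSE)
  })
  models <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(models) || nrow(models) == 0) stop("no model could be fitted")
  models <- models[order(models$aic), , drop = FALSE]
  rownames(models) <- NULL
  structure(list(models = models, best = 1L,
                 guideline_version = if (guidelines) "incidence-first-v1" else "off",
                 specs = specs),
            class = "subset_search_result")
}

## Enumerate (incidence set, latency set) pairs under the active rules.
enumerate_subset_models <- function(candidates, treatment, guidelines,
                                    latency_cap) {
  specs <- list()
  if (guidelines) {
    others <- setdiff(candidates, treatment)
    dispositions <- c("none", "incidence", "latency")
    grid <- expand.grid(rep(list(dispositions), length(others)),
                        stringsAsFactors = FALSE)
    if (length(others) == 0) grid <- data.frame(row.names = 1)
    for (r in seq_len(nrow(grid))) {
      assign <- if (length(others) > 0) unlist(grid[r, ]) else character(0)
      inc <- c(treatment, others[assign == "incidence"])
      lat <- others[assign == "latency"]
      if (length(lat) > latency_cap) next
      specs <- c(specs, list(list(incidence = inc, latency = lat)))
    }
  } else {
    dispositions <- c("none", "incidence", "latency", "both")
    grid <- expand.grid(rep(list(dispositions), length(candidates)),
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      assign <- unlist(grid[r, ])
      inc <- candidates[assign %in% c("incidence", "both")]
      lat <- candidates[assign %in% c("latency", "both")]
      specs <- c(specs, list(list(incidence = inc, latency = lat)))
    }
  }
  specs
}

#' @export
print.subset_search_result <- function(x, ...) {
  cat(sprintf("Best-subset search (%s): %d models\n",
              x$guideline_version, nrow(x$models)))
  print(utils::head(x$models, 5))
  invisible(x)
}

#' Standard errors for a Cox cure regression fit
#'
#' \code{method = "hessian"}: numerical observed information of the profile
#' log-likelihood in \code{(alpha, beta)}, with the baseline jumps profiled
#' out (re-estimated by the weight/Breslow fixed point at each perturbed
#' coefficient value). \code{method = "bootstrap"}: nonparametric resampling
#' of subjects with refitting, SE = replicate standard deviation.
#'
#' @param fit a converged \code{cure_cox_fit}.
#' @param ds the dataset the fit was computed from.
#' @param method \code{"hessian"} or \code{"bootstrap"}.
#' @param B bootstrap replicates.
#' @param seed optional seed for the bootstrap.
#' @return Named vector of standard errors for \code{(alpha, beta)}.
#' @export
covariance_and_se <- function(fit, ds, method = c("hessian", "bootstrap"),
                              B = 200, seed = NULL) {
  method <- match.arg(method)
  d <- design_matrices(ds, fit$incidence_covs, fit$latency_covs)
  q <- ncol(d$X); p <- ncol(d$Z)
  nm <- c(colnames(d$X), colnames(d$Z))
  if (method == "hessian") {
    theta_hat <- c(fit$alpha, fit$beta)
    pl <- function(theta) {
      profile_loglik_theta(theta[seq_len(q)],
                           if (p > 0) theta[q + seq_len(p)] else numeric(0),
                           ds, d, fit)
    }
    H <- pracma::hessian(pl, theta_hat)
    info <- -H
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > 1e12)
      stop(sprintf("observed information is singular or ill-conditioned (condition number %.3g)",
                   max(ev) / max(min(ev), 1e-300)))
    se <- sqrt(diag(solve(info)))
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ctrl <- fit$control
    ctrl$n_starts <- 1
    ctrl$se_method <- "none"
    ctrl$init <- list(alpha = fit$alpha, beta = fit$beta)
    reps <- matrix(NA_real_, B, q + p)
    for (b in seq_len(B)) {
      idx <- sample.int(ds$n, replace = TRUE)
      for (try in 1:10) {
        if (sum(ds$event[idx]) > 0) break
        idx <- sample.int(ds$n, replace = TRUE)
      }
      bfit <- tryCatch(
        fit_cure_cox(subset_dataset(ds, idx), fit$incidence_covs,
                     fit$latency_covs, ctrl),
        error = function(e) NULL)
      if (!is.null(bfit)) reps[b, ] <- c(bfit$alpha, bfit$beta)
    }
    se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  }
  stats::setNames(se, nm)
}

## Profile observed log-likelihood at (alpha, beta): iterate the
## weight/Breslow fixed point for the baseline, then evaluate.
profile_loglik_theta <- function(alpha, beta, ds, d, fit, max_iter = 100,
                                 tol = 1e-10) {
  baseline <- fit$baseline
  for (i in seq_len(max_iter)) {
    ci <- incidence_prob(alpha, d$X)
    S <- uncured_survival_all(beta, baseline, d$Z, ds$time)
    w <- e_step_weights(ds$event, ci, S)
    new_bl <- breslow_estimate(beta, w, ds, Z = d$Z,
                               zero_tail = fit$control$zero_tail)
    if (max(abs(new_bl$values - baseline$values)) < tol) {
      baseline <- new_bl
      break
    }
    baseline <- new_bl
  }
  observed_loglik(alpha, beta, baseline, ds,
                  fit$incidence_covs, fit$latency_covs)
}

#' Adjusted population survival curve
#'
#' Marginal relapse-free survival for a displayed covariate profile,
#' averaged over the empirical joint distribution of the adjustment
#' covariates: \code{S_pop(t) = mean_k [ c(x_k) + (1 - c(x_k)) S_u(t | z_k)
#' ]}, where each subject k contributes its own adjustment covariate values
#' while the displayed covariates are fixed at \code{profile}. With the
#' zero-tail constraint the curve levels off at the average cure
#' probability.
#'
#' @param fit a \code{cure_cox_fit}.
#' @param profile named list/vector of values for the displayed covariates.
#' @param adjust_over names of covariates averaged over their empirical
#'   joint distribution in \code{ds}.
#' @param ds the dataset supplying the adjustment distribution.
#' @return A \code{\link{cure_stepfun}} starting at 1 (left of the first
#'   event time), nonincreasing.
#' @export
predict_population_survival <- function(fit, profile = list(),
                                        adjust_over = character(0), ds) {
  needed <- setdiff(union(fit$incidence_covs, fit$latency_covs), adjust_over)
  miss <- setdiff(needed, names(profile))
  if (length(miss) > 0)
    stop("profile missing covariate(s): ", paste(miss, collapse = ", "))
  n_adj <- if (length(adjust_over) > 0) ds$n else 1L
  covs <- ds$covariates[rep_len(seq_len(ds$n), n_adj), , drop = FALSE]
  if (length(adjust_over) == 0 && nrow(covs) >= 1)
    covs <- covs[1, , drop = FALSE]
  for (nm in names(profile)) covs[[nm]] <- profile[[nm]]
  X <- cbind(1, as.matrix(covs[, fit$incidence_covs, drop = FALSE]))
  Z <- as.matrix(covs[, fit$latency_covs, drop = FALSE])
  ci <- incidence_prob(fit$alpha, X)
  lp <- if (ncol(Z) > 0) drop(Z %*% fit$beta) else rep(0, nrow(covs))
  knots <- fit$baseline$knots
  Lam <- fit$baseline$values
  vals <- vapply(seq_along(knots), function(j) {
    S <- exp(-exp(lp) * Lam[j])
    mean(ci + (1 - ci) * S)
  }, numeric(1))
  zt <- isTRUE(fit$baseline$zero_tail)
  cure_stepfun(knots, vals, left_value = 1, zero_tail = zt,
               tail_value = if (zt) mean(ci) else NULL)
}
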