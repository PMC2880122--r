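# Independent oracles and fixture builders shared across the suite.
# Every oracle here is written from the defining formula, not by calling
# the implementation path it checks.

# Standard Cox log partial likelihood (Breslow ties), direct from the
# definition: sum over events of lp_i - log(sum of exp(lp_j) over the
# risk set T_j >= T_i).
oracle_cox_partial_loglik <- function(beta, time, event, Z) {
  lp <- drop(as.matrix(Z) %*% beta)
  ll <- 0
  for (i in which(event == 1))
    ll <- ll + lp[i] - log(sum(exp(lp[time >= time[i]])))
  ll
}

# 1-D golden-section maximization of the Cox partial likelihood.
oracle_cox_1d <- function(time, event, z, lower = -5, upper = 5) {
  stats::optimize(function(b) oracle_cox_partial_loglik(b, time, event,
                                                        cbind(z)),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# Profile observed log-likelihood of the semiparametric cure model at fixed
# (alpha, beta): the baseline is profiled by the weight/Breslow fixed point.
oracle_profile_lf <- function(alpha, beta, ds, inc, lat, zero_tail = TRUE) {
  w <- rep(1, ds$n)
  Z <- as.matrix(ds$covariates[, lat, drop = FALSE])
  bl <- breslow_estimate(beta, w, ds, Z = Z, zero_tail = zero_tail)
  for (k in 1:200) {
    w_new <- e_step(alpha, beta, bl, ds, inc, lat)
    bl_new <- breslow_estimate(beta, w_new, ds, Z = Z, zero_tail = zero_tail)
    if (max(abs(bl_new$values - bl$values)) < 1e-12 &&
        max(abs(w_new - w)) < 1e-12) { bl <- bl_new; w <- w_new; break }
    bl <- bl_new; w <- w_new
  }
  observed_loglik(alpha, beta, bl, ds, inc, lat)
}

# Dense grid maximum of the profile likelihood over (alpha0, alpha1, beta).
oracle_grid_max_semiparam <- function(ds, inc, lat, a0_grid, a1_grid, b_grid,
                                      zero_tail = TRUE) {
  best <- -Inf
  for (a0 in a0_grid) for (a1 in a1_grid) for (b in b_grid) {
    lf <- oracle_profile_lf(c(a0, a1), b, ds, inc, lat, zero_tail)
    if (lf > best) best <- lf
  }
  best
}

# Dense grid maximum of the parametric (exponential) cure likelihood over
# transformed parameters (logit c, log mu), rho fixed at 1.
oracle_grid_max_param <- function(ds, lc_grid, lm_grid) {
  best <- -Inf
  for (lc in lc_grid) for (lm in lm_grid) {
    cc <- stats::plogis(lc); mu <- exp(lm)
    S <- exp(-mu * ds$time)
    f <- mu * S
    ll <- sum(ifelse(ds$event == 1,
                     log(pmax((1 - cc) * f, 1e-300)),
                     log(pmax(cc + (1 - cc) * S, 1e-300))))
    if (ll > best) best <- ll
  }
  best
}

# All pruned subtrees of a cure_tree, each as a sorted vector of leaf ids.
# A pruned subtree keeps the root and, for every kept internal node, either
# keeps both children-subtrees or collapses the node to a leaf.
oracle_enumerate_subtrees <- function(tree, id = tree$root_id) {
  node <- tree$nodes[[as.character(id)]]
  if (is.null(node$children)) return(list(id))
  left <- oracle_enumerate_subtrees(tree, node$children[1])
  right <- oracle_enumerate_subtrees(tree, node$children[2])
  out <- list(id)  # collapsed at this node
  for (l in left) for (r in right) out <- c(out, list(sort(c(l, r))))
  out
}

# Penalized cost of a leaf set: sum of leaf deviances + gamma * #leaves.
oracle_leafset_cost <- function(tree, leaves, gamma) {
  R <- vapply(leaves, function(id)
    -2 * tree$nodes[[as.character(id)]]$fit$loglik / tree$n_root, numeric(1))
  sum(R) + gamma * length(leaves)
}

# Deterministic small dataset with a binary covariate, mixed events.
fixture_small <- function(n = 10, seed = 1) {
  set.seed(seed)
  trt <- rep(c(0, 1), length.out = n)
  time <- round(stats::rexp(n, 0.3), 2) + 0.05
  event <- stats::rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[1] <- 1
  survival_dataset(time, event, data.frame(trt = trt))
}

# Two-region partitioned fixture used by the tree tests.
fixture_two_region <- function(n = 400, seed = 1, c1 = 0.85, c2 = 0.2,
                               mu = 0.15, tau = 16, noise = TRUE) {
  spec <- list(g = list(dist = "bernoulli", p = 0.5))
  if (noise) spec$hamd <- list(dist = "uniform_int", min = 0, max = 10)
  simulate_partitioned_dataset(
    list(list(condition = function(r) r$g == 0, c = c1, mu = mu),
         list(condition = function(r) r$g == 1, c = c2, mu = mu)),
    n = n, covariate_spec = spec, censoring = list(tau = tau), seed = seed)
}
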