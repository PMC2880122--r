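test_that("incidence probability is the (numerically stable) expit", {
  expect_equal(incidence_prob(0, 1), 0.5)
  expect_equal(incidence_prob(c(-700), 1), 0)
  expect_equal(incidence_prob(c(700), 1), 1)
  # published-style coefficients: intercept 1.571, treatment 1.177,
  # baseline severity -0.122, profile (treated, score 10)
  expect_equal(incidence_prob(c(1.571, 1.177, -0.122), c(1, 1, 10)),
               1 / (1 + exp(-1.528)), tolerance = 1e-12)
  expect_error(incidence_prob(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("uncured survival follows exp(-exp(bz) * Lambda0(t))", {
  bl <- cure_stepfun(c(1, 2), c(0.5, log(2)))
  expect_equal(uncured_survival(numeric(0), bl, numeric(0), 0.5), 1)
  expect_equal(uncured_survival(0, bl, 0, 2), 0.5)
  expect_equal(uncured_survival(log(2), bl, 1, 2), 0.25)
  blz <- cure_stepfun(c(1, 2), c(0.5, log(2)), zero_tail = TRUE)
  expect_equal(uncured_survival(0, blz, 0, 3), 0)
  expect_error(uncured_survival(0, bl, 0, -1), "nonnegative")
})

test_that("observed log-likelihood reproduces hand computations", {
  # everyone censored, cure certain: each subject contributes log(1) = 0
  ds0 <- survival_dataset(c(1, 2), c(0, 0))
  bl0 <- cure_stepfun(1, 0.5)
  expect_equal(observed_loglik(700, numeric(0), bl0, ds0), 0)

  # one event at t=1, no cure, baseline jump 1: log(1) - 1 = -1
  ds1 <- survival_dataset(1, 1)
  bl1 <- cure_stepfun(1, 1)
  expect_equal(observed_loglik(-700, numeric(0), bl1, ds1), -1)

  # an event time with no baseline jump is a specification error
  expect_error(observed_loglik(0, numeric(0), cure_stepfun(2, 1), ds1),
               "no jump")
})

test_that("with cure off the likelihood is the Cox-Breslow profile loglik", {
  ds <- fixture_small(n = 10, seed = 3)
  beta <- 0.4
  Z <- as.matrix(ds$covariates)
  bl <- breslow_estimate(beta, rep(1, ds$n), ds, Z = Z)
  lf <- observed_loglik(-700, beta, bl, ds, character(0), "trt")
  # independent identity: Breslow-profiled full loglik = partial loglik +
  # sum over distinct event times of d_t log d_t - D
  pl <- oracle_cox_partial_loglik(beta, ds$time, ds$event, Z)
  d_t <- table(ds$time[ds$event == 1])
  extra <- sum(d_t * log(d_t)) - sum(ds$event)
  expect_equal(lf, pl + extra, tolerance = 1e-10)
})

test_that("E-step weights are the posterior uncure probabilities", {
  ds <- survival_dataset(c(1, 2, 3), c(1, 0, 0))
  bl <- cure_stepfun(1, 0)          # Lambda = 0 -> S = 1 everywhere
  w <- e_step(0, numeric(0), bl, ds)   # c = 0.5
  expect_equal(w, c(1, 0.5, 0.5))
  w2 <- e_step(-700, numeric(0), bl, ds)  # c = 0 -> w = 1
  expect_equal(w2, c(1, 1, 1))
  # c = 1, S = 0: 0/0 handled as cured (w = 0)
  blz <- cure_stepfun(0.5, 5, zero_tail = TRUE)
  ds2 <- survival_dataset(c(0.5, 3), c(1, 0))
  w3 <- e_step(700, numeric(0), blz, ds2)
  expect_equal(w3[2], 0)
  expect_equal(w3[1], 1)   # events always weight 1
})

test_that("incidence M-step solves the fractional logistic problem", {
  X <- cbind(rep(1, 8))
  a1 <- m_step_incidence(rep(0.5, 8), X)
  expect_equal(as.numeric(a1), 0, tolerance = 1e-7)
  # intercept-only MLE is logit(mean(1 - w))
  a2 <- m_step_incidence(rep(0.75, 8), X)
  expect_equal(as.numeric(a2), stats::qlogis(0.25), tolerance = 1e-6)
  # all uncured: chat -> 0, divergence flagged and capped
  expect_warning(a3 <- m_step_incidence(rep(1, 8), X), "capped")
  expect_equal(as.numeric(a3), -20)
  expect_true(attr(a3, "capped"))
  # with a covariate, matches glm on 0/1 responses
  set.seed(8)
  x <- stats::rbinom(60, 1, 0.5)
  y <- stats::rbinom(60, 1, stats::plogis(0.5 - x))
  Xd <- cbind(1, x)
  af <- m_step_incidence(1 - y, Xd)
  gf <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(as.numeric(af), as.numeric(stats::coef(gf)), tolerance = 1e-5)
})

test_that("latency M-step with unit weights equals the Cox estimate", {
  ds <- survival_dataset(c(1, 2, 3, 4, 5, 6, 7, 8),
                         c(1, 1, 0, 1, 1, 0, 1, 1),
                         data.frame(trt = c(0, 1, 0, 1, 1, 0, 0, 1)))
  Z <- as.matrix(ds$covariates)
  b <- m_step_latency(rep(1, ds$n), ds, Z)
  b_or <- oracle_cox_1d(ds$time, ds$event, ds$covariates$trt)
  expect_equal(as.numeric(b), b_or, tolerance = 1e-4)

  # all-zero covariate column: no information, coefficient 0
  ds2 <- survival_dataset(ds$time, ds$event, data.frame(z = rep(0, ds$n)))
  expect_warning(b0 <- m_step_latency(rep(1, ds$n), ds2,
                                      as.matrix(ds2$covariates)),
                 "no information|set to 0")
  expect_equal(as.numeric(b0), 0)

  # single event with a single subject at risk: constant partial likelihood
  ds3 <- survival_dataset(c(5, 1, 2), c(1, 0, 0), data.frame(z = c(1, 0, 1)))
  expect_warning(b3 <- m_step_latency(rep(1, 3), ds3,
                                      as.matrix(ds3$covariates)),
                 "no information")
  expect_equal(as.numeric(b3), 0)

  expect_error(m_step_latency(rep(1, 3), survival_dataset(1:3, c(0, 0, 0),
                                                          data.frame(z = 1:3)),
                              cbind(1:3)), "no events")
})

test_that("Breslow estimator matches hand-computed jumps", {
  # one event among 5 at risk, beta = 0, w = 1: single jump 1/5
  ds1 <- survival_dataset(c(1, 2, 3, 4, 5), c(1, 0, 0, 0, 0))
  bl1 <- breslow_estimate(numeric(0), rep(1, 5), ds1,
                          Z = matrix(nrow = 5, ncol = 0))
  expect_equal(bl1$knots, 1)
  expect_equal(bl1$values, 1/5)

  # events at t=1 (5 at risk) and t=2 (3 at risk): Lambda(2) = 1/5 + 1/3
  ds2 <- survival_dataset(c(1, 1.5, 2, 2.5, 3), c(1, 0, 1, 0, 0))
  bl2 <- breslow_estimate(numeric(0), rep(1, 5), ds2,
                          Z = matrix(nrow = 5, ncol = 0))
  expect_equal(stepfun_eval(bl2, 2), 1/5 + 1/3)

  # halving censored subjects' weights doubles their risk-set discount
  w <- ifelse(ds2$event == 1, 1, 0.5)
  bl3 <- breslow_estimate(numeric(0), w, ds2,
                          Z = matrix(nrow = 5, ncol = 0))
  expect_equal(bl3$values, cumsum(c(1 / (2 + 3 * 0.5), 1 / (1 + 2 * 0.5))))
})

test_that("EM fit recovers simulated truth and traces ascend", {
  sim <- simulate_cure_dataset(
    n = 500, covariate_spec = list(x = list(dist = "bernoulli", p = 0.5)),
    alpha = c(0.5, 1.0),
    latency = list(family = "exponential", mu = 0.15, beta = -0.8,
                   latency_covs = "x"),
    censoring = list(tau = 20), seed = 31)
  fit <- fit_cure_cox(sim$dataset, "x", "x",
                      control = cure_cox_control(n_starts = 2,
                                                 se_method = "hessian"))
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_true(all(fit$weights[sim$dataset$event == 1] == 1))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 3)
  # truth within 3 SEs
  est <- c(fit$alpha, fit$beta)
  expect_true(all(abs(est - c(0.5, 1.0, -0.8)) < 3 * fit$se + 0.2))
  expect_error(fit_cure_cox(survival_dataset(1:3, c(0, 0, 0),
                                             data.frame(x = 1:3)), "x", "x"),
               "no events")
})

test_that("AIC uses the regression-parameter count convention", {
  expect_equal(model_aic(-81.603, k = 11), 185.206)
  expect_equal(model_aic(-177.499, k = 6), 366.998)
  expect_equal(model_aic(-5, k = 0), 10)
  expect_error(model_aic(-5), "k required")
})

test_that("best-subset enumeration honours the selection guidelines", {
  specs_on <- curecart:::enumerate_subset_models(
    c("trt", "a"), treatment = "trt", guidelines = TRUE, latency_cap = 2)
  # one extra covariate: dispositions none / incidence / latency = 3 models,
  # treatment always in incidence
  expect_length(specs_on, 3)
  expect_true(all(vapply(specs_on, function(s) "trt" %in% s$incidence,
                         logical(1))))
  expect_true(all(vapply(specs_on,
                         function(s) length(intersect(s$incidence, s$latency)) == 0,
                         logical(1))))

  # guidelines off, 2 candidates: 4 dispositions each = 16 models
  specs_off <- curecart:::enumerate_subset_models(
    c("a", "b"), treatment = NULL, guidelines = FALSE, latency_cap = 2)
  expect_length(specs_off, 16)

  # latency cap prunes combinations
  specs_cap <- curecart:::enumerate_subset_models(
    c("trt", "a", "b", "c"), treatment = "trt", guidelines = TRUE,
    latency_cap = 1)
  expect_true(all(vapply(specs_cap, function(s) length(s$latency) <= 1,
                         logical(1))))
  expect_error(best_subset_search(fixture_small(), character(0)), "empty")
})

test_that("best-subset search ranks models by AIC on simulated data", {
  sim <- simulate_cure_dataset(
    n = 400,
    covariate_spec = list(trt = list(dist = "bernoulli", p = 0.5),
                          b = list(dist = "normal", mean = 0, sd = 1)),
    alpha = c(0.3, 1.5), incidence_covs = "trt",
    latency = list(family = "exponential", mu = 0.2, beta = 1.0,
                   latency_covs = "b"),
    censoring = list(tau = 16), seed = 17)
  res <- best_subset_search(sim$dataset, c("trt", "b"), treatment = "trt",
                            control = cure_cox_control(n_starts = 1,
                                                       se_method = "none"))
  expect_equal(res$models$aic, sort(res$models$aic))
  expect_equal(res$best, 1L)
  # the generating structure (trt in incidence, b in latency) should win
  expect_equal(res$models$latency[1], "b")
})

test_that("standard errors scale and fail informatively when singular", {
  sim <- simulate_cure_dataset(
    n = 300, covariate_spec = list(x = list(dist = "bernoulli", p = 0.5)),
    alpha = c(0.5, 0.8),
    latency = list(family = "exponential", mu = 0.2, beta = -0.5,
                   latency_covs = "x"),
    censoring = list(tau = 16), seed = 41)
  fit <- fit_cure_cox(sim$dataset, "x", "x",
                      control = cure_cox_control(n_starts = 1,
                                                 se_method = "none"))
  se1 <- covariance_and_se(fit, sim$dataset, method = "hessian")
  expect_true(all(is.finite(se1)) && all(se1 > 0))

  # duplicating every subject should shrink SEs by about 1/sqrt(2)
  ds2 <- subset_dataset(sim$dataset, rep(seq_len(sim$dataset$n), 2))
  fit2 <- fit_cure_cox(ds2, "x", "x",
                       control = cure_cox_control(n_starts = 1,
                                                  se_method = "none"))
  se2 <- covariance_and_se(fit2, ds2, method = "hessian")
  expect_true(all(abs(se2 / se1 - 1 / sqrt(2)) < 0.1 * 1 / sqrt(2)))

  # a constant-zero covariate gives a singular information matrix
  ds3 <- survival_dataset(sim$dataset$time, sim$dataset$event,
                          cbind(sim$dataset$covariates,
                                z0 = rep(0, sim$dataset$n)))
  fit3 <- suppressWarnings(
    fit_cure_cox(ds3, "x", c("x", "z0"),
                 control = cure_cox_control(n_starts = 1, se_method = "none")))
  expect_error(covariance_and_se(fit3, ds3, method = "hessian"),
               "singular|ill-conditioned")
})

test_that("bootstrap and hessian SEs agree to within 25 percent", {
  sim <- simulate_cure_dataset(
    n = 1000, covariate_spec = list(x = list(dist = "bernoulli", p = 0.5)),
    alpha = c(0.5, 0.8),
    latency = list(family = "exponential", mu = 0.2, beta = -0.5,
                   latency_covs = "x"),
    censoring = list(tau = 16), seed = 43)
  fit <- fit_cure_cox(sim$dataset, "x", "x",
                      control = cure_cox_control(n_starts = 1,
                                                 se_method = "none"))
  se_h <- covariance_and_se(fit, sim$dataset, method = "hessian")
  se_b <- covariance_and_se(fit, sim$dataset, method = "bootstrap", B = 60,
                            seed = 9)
  expect_true(all(abs(se_h / se_b - 1) < 0.25))
})

test_that("population survival curves start at 1, decrease, and level off", {
  sim <- simulate_sertraline_like(seed = 51)
  fit <- fit_cure_cox(sim$dataset, c("trt", "hamd_dp"),
                      c("gender", "complication"),
                      control = cure_cox_control(n_starts = 1,
                                                 se_method = "none"))
  curve <- predict_population_survival(
    fit, profile = list(trt = 1, hamd_dp = 8),
    adjust_over = c("gender", "complication"), ds = sim$dataset)
  expect_equal(stepfun_eval(curve, 0), 1)
  grid <- seq(0, 20, length.out = 100)
  vals <- stepfun_eval(curve, grid)
  expect_true(all(diff(vals) <= 1e-12))
  # beyond the last event (zero tail) the curve equals the cure probability
  curve0 <- predict_population_survival(fit, profile = list(trt = 1, hamd_dp = 8,
                                                            gender = 0,
                                                            complication = 0),
                                        ds = sim$dataset)
  expect_equal(stepfun_eval(curve0, max(curve0$knots) + 1),
               incidence_prob(fit$alpha, c(1, 1, 8)), tolerance = 1e-12)
  expect_error(predict_population_survival(fit, profile = list(trt = 1),
                                           ds = sim$dataset), "missing")
})
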