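# Shared small classification instance with a real signal
make_logistic_instance <- function(n = 50, p = 2, seed = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(x = x, y = y)
}

test_that("penalty-dominated limit zeroes all weights", {
  inst <- make_logistic_instance()
  fit <- fit_elastic_net_logistic(inst$x, inst$y, enet_hp(1e6, 0.5))
  expect_true(all(fit$weights == 0))
  p <- predict_positive_probability(fit, inst$x)
  expect_equal(p, rep(mean(inst$y), length(p)), tolerance = 1e-3)
})

test_that("unpenalized fit matches the maximum-likelihood oracle", {
  inst <- make_logistic_instance()
  fit <- fit_elastic_net_logistic(inst$x, inst$y, enet_hp(0, 0.5),
                                  thresh = 1e-12)
  oracle <- glm(inst$y ~ inst$x, family = binomial())
  expect_equal(unname(fit$weights), unname(coef(oracle)[-1]),
               tolerance = 1e-3)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-3)
})

test_that("penalized objective at the optimum matches a dense grid search", {
  set.seed(9)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  alpha <- 0.1; l1 <- 0.5
  fit <- fit_elastic_net_logistic(x, y, enet_hp(alpha, l1),
                                  fit_intercept = FALSE, thresh = 1e-12)
  # brute-force search over w in [-5, 5]^2, step 0.01
  w1 <- seq(-5, 5, by = 0.01)
  eta <- outer(x[, 1], w1) # n x length(w1)
  best <- Inf
  for (w2 in w1) {
    e <- eta + x[, 2] * w2
    nll <- colMeans(pmax(e, 0) + log1p(exp(-abs(e))) - outer(y, rep(1, ncol(e))) * e)
    pen <- alpha * (l1 * (abs(w1) + abs(w2)) + 0.5 * (1 - l1) * (w1^2 + w2^2))
    best <- min(best, min(nll + pen))
  }
  achieved <- logistic_objective(fit$weights, 0, x, y, alpha, l1)
  expect_lte(achieved, best * 1.01)
  expect_equal(achieved, best, tolerance = 0.01)
  expect_equal(achieved, fit$trace$objective, tolerance = 1e-12)
})

test_that("positive-probability prediction is the closed-form sigmoid", {
  model <- structure(list(weights = c(f1 = 0, f2 = 0), intercept = 0),
                     class = "fitted_linear_model")
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(predict_positive_probability(model, x), rep(0.5, 5))

  model$weights <- c(f1 = log(3), f2 = 0)
  x1 <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(predict_positive_probability(model, x1), 0.75)

  # complement identity: P(y=1) + P(y=0) = 1 exactly
  set.seed(10)
  model$weights <- c(f1 = 2.7, f2 = -1.1); model$intercept <- 0.3
  xx <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  p1 <- predict_positive_probability(model, xx)
  m_neg <- model; m_neg$weights <- -m_neg$weights; m_neg$intercept <- -0.3
  p0 <- predict_positive_probability(m_neg, xx)
  expect_equal(p1 + p0, rep(1, 20))

  expect_error(predict_positive_probability(model, matrix(0, 2, 3)),
               "3 columns")
})

test_that("regularization path and sparsity behave as expected", {
  inst <- make_logistic_instance(n = 100, p = 50, seed = 11)
  alphas <- c(1e-4, 1e-3, 0.01, 0.1, 1, 10)
  l1_norms <- vapply(alphas, function(a) {
    sum(abs(fit_elastic_net_logistic(inst$x, inst$y, enet_hp(a, 0.5))$weights))
  }, 0)
  expect_true(all(diff(l1_norms) <= 1e-6)) # non-increasing in alpha

  lasso <- fit_elastic_net_logistic(inst$x, inst$y, enet_hp(0.05, 1))
  ridge <- fit_elastic_net_logistic(inst$x, inst$y, enet_hp(0.05, 0))
  expect_gt(sum(lasso$weights == 0), sum(ridge$weights == 0))

  # optimizer progress: objective at the optimum never exceeds w = 0
  fit <- fit_elastic_net_logistic(inst$x, inst$y, enet_hp(0.05, 0.5))
  at_zero <- logistic_objective(rep(0, 50), fit$intercept, inst$x, inst$y,
                                0.05, 0.5)
  expect_lte(fit$trace$objective, at_zero + 1e-8)
})

test_that("covariate-only logistic fit reproduces per-type base rates", {
  b <- small_bundle(n = 1600, seed = 71, p = 10)
  clin <- b$clinical
  cov <- build_covariates(clin, clin$sample_id)
  y <- b$mutation[, "G1"]
  fit <- fit_elastic_net_logistic(cov, y, enet_hp(1e-4, 0))
  p <- predict_positive_probability(fit, cov)
  for (ct in unique(clin$cancer_type)) {
    sel <- clin$cancer_type == ct
    expect_lt(abs(mean(p[sel]) - mean(y[sel])), 0.01)
  }
})

test_that("single-class labels and width mismatches are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_elastic_net_logistic(x, rep(1, 10), enet_hp(0.1, 0.5)),
               "single class")
  expect_error(fit_elastic_net_logistic(x, c(rep(0, 5), rep(2, 5)),
                                        enet_hp(0.1, 0.5)), "0/1")
})

test_that("Cox: penalty-dominated limit, sign recovery, scalar oracle", {
  set.seed(12)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tm <- rexp(n, exp(x[, 1]))
  ev <- rbinom(n, 1, 0.8)
  big <- fit_elastic_net_cox(x, tm, ev, enet_hp(1e6, 0.5))
  expect_true(all(big$weights == 0))
  sc <- predict_risk_score(big, x)
  expect_equal(concordance_index(sc, tm, ev), 0.5) # all ties -> 0.5

  # planted-sign recovery, gamma = 1, n = 500
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    xs <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "f1"))
    tms <- rexp(500, exp(1 * xs[, 1]))
    evs <- rbinom(500, 1, 0.7)
    f <- fit_elastic_net_cox(xs, tms, evs, enet_hp(0.01, 0.5))
    if (f$weights["f1"] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9)

  # two samples, one event, one covariate: match the 1-D oracle
  x2 <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "f1"))
  tm2 <- c(1, 2); ev2 <- c(1, 0)
  f2 <- fit_elastic_net_cox(x2, tm2, ev2, enet_hp(0.1, 0), thresh = 1e-12)
  oracle <- optimize(function(w) cox_objective(w, x2, tm2, ev2, 0.1, 0),
                     c(-10, 10), tol = 1e-10)
  expect_equal(unname(f2$weights["f1"]), oracle$minimum, tolerance = 1e-4)

  expect_error(fit_elastic_net_cox(x, tm, rep(0, n), enet_hp(0.1, 0.5)),
               "no events")
  expect_error(fit_elastic_net_cox(x, tm - max(tm) - 1, ev,
                                   enet_hp(0.1, 0.5)), "> 0")
})

test_that("risk scores are linear and invariant to zero-weight columns", {
  model <- structure(list(weights = c(f1 = 0.5, f2 = -2)),
                     class = "cox_model")
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  s <- predict_risk_score(model, x)
  expect_equal(predict_risk_score(model, 3 * x), 3 * s) # linearity
  model3 <- structure(list(weights = c(f1 = 0.5, f2 = -2, pad = 0)),
                      class = "cox_model")
  x3 <- cbind(x, pad = rnorm(10))
  expect_equal(order(predict_risk_score(model3, x3)), order(s))
  expect_error(predict_risk_score(model, x3), "weights")
})

test_that("Breslow partial likelihood matches survival::coxph at the MLE", {
  set.seed(13)
  n <- 60
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  tm <- round(rexp(n, exp(0.7 * x[, 1])), 2) + 0.01 # induce some ties
  ev <- rbinom(n, 1, 0.7)
  cph <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "breslow")
  ours <- cox_neg_log_partial_likelihood(coef(cph), x, tm, ev,
                                         mean_scale = FALSE)
  expect_equal(ours, -cph$loglik[2], tolerance = 1e-8)
})
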