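#' Elastic-net hyperparameters
#'
#' `alpha` is the overall penalty strength and `l1_ratio` the L1 fraction of
#' the penalty (sometimes written lambda in the mutation-prediction
#' literature; note this is the *inverse* of the glmnet naming, where the
#' strength is called lambda and the mixing parameter alpha).
#'
#' @param alpha overall penalty strength, >= 0; 0 means unpenalized.
#' @param l1_ratio L1 fraction in [0, 1]; 1 = lasso, 0 = ridge.
#' @return list of class `enet_hp`.
#' @export
enet_hp <- function(alpha, l1_ratio) {
  if (alpha < 0) stop("enet_hp: 'alpha' must be >= 0")
  if (l1_ratio < 0 || l1_ratio > 1) stop("enet_hp: 'l1_ratio' must be in [0, 1]")
  structure(list(alpha = alpha, l1_ratio = l1_ratio), class = "enet_hp")
}

# Extract the plain numeric matrix (predictors + covariates) and the indices
# of covariate columns from either a feature_matrix or a raw matrix.
as_model_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) {
    list(x = X$matrix, covariate = which(X$provenance == "covariate"))
  } else {
    list(x = as.matrix(X), covariate = integer())
  }
}

# glmnet needs >= 2 columns; pad 1-column designs with an all-zero column
# (its weight is identically 0) and strip it afterwards.
pad_columns <- function(x) {
  if (ncol(x) >= 2) return(list(x = x, padded = FALSE))
  pad <- base::matrix(0, nrow(x), 1, dimnames = list(rownames(x), ".pad"))
  list(x = cbind(x, pad), padded = TRUE)
}

#' Penalized logistic-regression objective
#'
#' The objective minimized by [fit_elastic_net_logistic()]: the mean
#' negative log-likelihood of the labels plus
#' `alpha * (l1_ratio * ||w||_1 + (1 - l1_ratio) / 2 * ||w||_2^2)`.
#' The intercept is unpenalized. (Stated on the mean-likelihood scale;
#' the sum-likelihood form differs only by rescaling alpha by n.)
#'
#' @param weights,intercept model parameters.
#' @param X numeric matrix, `y` 0/1 labels.
#' @param alpha,l1_ratio elastic-net hyperparameters.
#' @param penalty_weights per-column penalty factors (default 1).
#' @return scalar objective value.
#' @export
logistic_objective <- function(weights, intercept, X, y, alpha, l1_ratio,
                               penalty_weights = rep(1, length(weights))) {
  eta <- as.numeric(X %*% weights + intercept)
  # log(1 + exp(eta)) - y * eta, computed stably
  nll <- mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
  pen <- alpha * (l1_ratio * sum(penalty_weights * abs(weights)) +
                  0.5 * (1 - l1_ratio) * sum(penalty_weights * weights^2))
  nll + pen
}

#' Fit elastic-net logistic regression
#'
#' Minimizes the penalized negative log-likelihood of
#' [logistic_objective()] via coordinate descent (glmnet), with the overall
#' strength `hp$alpha` mapped to glmnet's lambda and `hp$l1_ratio` to
#' glmnet's alpha. The intercept is unpenalized; covariate columns (from a
#' `feature_matrix`) are penalized like predictors unless
#' `penalize_covariates = FALSE`. Deterministic given the inputs.
#'
#' @param X a `feature_matrix` or numeric matrix (assumed standardized; no
#'   internal rescaling is applied).
#' @param y 0/1 labels with at least one sample of each class.
#' @param hp an [enet_hp()].
#' @param penalize_covariates penalize covariate columns (default TRUE).
#' @param fit_intercept include an unpenalized intercept (default TRUE).
#' @param thresh glmnet convergence threshold.
#' @return list of class `fitted_linear_model`: `weights` (named), `intercept`,
#'   `hyperparams`, `trace` (objective value at the optimum, converged flag).
#' @export
fit_elastic_net_logistic <- function(X, y, hp, penalize_covariates = TRUE,
                                     fit_intercept = TRUE, thresh = 1e-9) {
  mm <- as_model_matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("fit_elastic_net_logistic: y must be 0/1")
  if (length(unique(y)) < 2) {
    stop("fit_elastic_net_logistic: y contains a single class")
  }
  if (anyNA(mm$x)) stop("fit_elastic_net_logistic: X contains missing values")
  pf <- rep(1, ncol(mm$x))
  if (!penalize_covariates) pf[mm$covariate] <- 0
  pad <- pad_columns(mm$x)
  pfp <- if (pad$padded) c(pf, 1) else pf
  lam_path <- unique(sort(hp$alpha * c(64, 16, 4, 1), decreasing = TRUE))
  if (hp$alpha == 0) lam_path <- c(0.25, 0.05, 0)
  fit <- glmnet::glmnet(pad$x, y, family = "binomial", alpha = hp$l1_ratio,
                        lambda = lam_path, standardize = FALSE,
                        intercept = fit_intercept, penalty.factor = pfp,
                        thresh = thresh, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = hp$alpha))
  intercept <- cf[1]
  weights <- cf[-1]
  if (pad$padded) weights <- weights[-length(weights)]
  names(weights) <- colnames(mm$x)
  obj <- logistic_objective(weights, intercept, mm$x, y, hp$alpha,
                            hp$l1_ratio, pf)
  structure(list(weights = weights, intercept = intercept, hyperparams = hp,
                 trace = list(objective = obj,
                              converged = fit$npasses < 1e6,
                              npasses = fit$npasses)),
            class = "fitted_linear_model")
}

#' Predicted probability of a positive label
#'
#' `P(y = 1 | x) = 1 / (1 + exp(-(w'x + b)))`; the probability of class 0 is
#' its complement.
#'
#' @param model a `fitted_linear_model`.
#' @param X new data (feature_matrix or matrix) with matching width.
#' @return numeric vector of probabilities.
#' @export
predict_positive_probability <- function(model, X) {
  x <- as_model_matrix(X)$x
  if (ncol(x) != length(model$weights)) {
    stop("predict_positive_probability: X has ", ncol(x),
         " columns but the model has ", length(model$weights), " weights")
  }
  as.numeric(stats::plogis(x %*% model$weights + model$intercept))
}

#' Negative log partial likelihood (Breslow ties)
#'
#' @param weights coefficient vector.
#' @param X numeric matrix, `times` > 0, `events` 0/1.
#' @param mean_scale divide by n (the scale used by the penalized
#'   objective; default TRUE).
#' @return scalar.
#' @export
cox_neg_log_partial_likelihood <- function(weights, X, times, events,
                                           mean_scale = TRUE) {
  eta <- as.numeric(X %*% weights)
  ord <- order(times)
  eta <- eta[ord]; times <- times[ord]; events <- events[ord]
  # cumulative risk-set sums from the largest time down
  risk <- rev(cumsum(rev(exp(eta))))
  ll <- 0
  for (tt in unique(times[events == 1])) {
    d <- which(times == tt & events == 1)
    # Breslow: each tied event uses the full risk set at tt
    rs <- risk[match(tt, times)]
    ll <- ll + sum(eta[d]) - length(d) * log(rs)
  }
  nll <- -ll
  if (mean_scale) nll <- nll / length(times)
  nll
}

#' Penalized Cox objective
#'
#' Mean-scaled negative log partial likelihood (Breslow) plus the same
#' elastic-net penalty as [logistic_objective()].
#' @inheritParams logistic_objective
#' @param times,events survival outcome.
#' @export
cox_objective <- function(weights, X, times, events, alpha, l1_ratio,
                          penalty_weights = rep(1, length(weights))) {
  cox_neg_log_partial_likelihood(weights, X, times, events) +
    alpha * (l1_ratio * sum(penalty_weights * abs(weights)) +
             0.5 * (1 - l1_ratio) * sum(penalty_weights * weights^2))
}

#' Fit an elastic-net Cox model
#'
#' Minimizes [cox_objective()] (penalized partial likelihood, Breslow ties)
#' via glmnet's coxnet path. Risk scores are the linear predictor `w'x`;
#' higher scores mean higher predicted hazard.
#'
#' @inheritParams fit_elastic_net_logistic
#' @param times positive survival/censoring times.
#' @param events 0/1 event indicators with at least one event.
#' @return list of class `cox_model`: `weights`, `hyperparams`, `trace`.
#' @export
fit_elastic_net_cox <- function(X, times, events, hp,
                                penalize_covariates = TRUE, thresh = 1e-9) {
  mm <- as_model_matrix(X)
  if (any(times <= 0)) stop("fit_elastic_net_cox: times must be > 0")
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) stop("fit_elastic_net_cox: events must be 0/1")
  if (sum(events) == 0) stop("fit_elastic_net_cox: no events observed")
  pf <- rep(1, ncol(mm$x))
  if (!penalize_covariates) pf[mm$covariate] <- 0
  pad <- pad_columns(mm$x)
  pfp <- if (pad$padded) c(pf, 1) else pf
  lam_path <- unique(sort(hp$alpha * c(64, 16, 4, 1), decreasing = TRUE))
  if (hp$alpha == 0) lam_path <- c(0.25, 0.05, 0)
  fit <- tryCatch(
    glmnet::glmnet(pad$x, survival::Surv(times, events), family = "cox",
                   alpha = hp$l1_ratio, lambda = lam_path,
                   standardize = FALSE, penalty.factor = pfp,
                   thresh = thresh, maxit = 1e6),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    weights <- as.numeric(stats::coef(fit, s = hp$alpha))
    if (pad$padded) weights <- weights[-length(weights)]
  } else {
    # degenerate instances (very few samples/events) that coxnet cannot
    # initialize: minimize the penalized objective directly
    obj <- function(w) cox_objective(w, mm$x, times, events, hp$alpha,
                                     hp$l1_ratio, pf)
    if (ncol(mm$x) == 1) {
      weights <- stats::optimize(function(w) obj(w), c(-30, 30),
                                 tol = 1e-10)$minimum
    } else {
      start <- rep(0, ncol(mm$x))
      method <- if (hp$l1_ratio == 0) "BFGS" else "Nelder-Mead"
      weights <- stats::optim(start, obj, method = method,
                              control = list(maxit = 5000,
                                             reltol = 1e-12))$par
    }
    fit <- list(npasses = 0L)
  }
  names(weights) <- colnames(mm$x)
  obj <- cox_objective(weights, mm$x, times, events, hp$alpha, hp$l1_ratio, pf)
  structure(list(weights = weights, hyperparams = hp,
                 trace = list(objective = obj,
                              converged = fit$npasses < 1e6,
                              npasses = fit$npasses)),
            class = "cox_model")
}

#' Linear risk score of a Cox model
#'
#' Returns `w'x` per sample; by contract a higher score predicts a higher
#' hazard, i.e. shorter survival.
#'
#' @param model a `cox_model`.
#' @param X new data with matching width.
#' @return numeric vector of risk scores.
#' @export
predict_risk_score <- function(model, X) {
  x <- as_model_matrix(X)$x
  if (ncol(x) != length(model$weights)) {
    stop("predict_risk_score: X has ", ncol(x),
         " columns but the model has ", length(model$weights), " weights")
  }
  as.numeric(x %*% model$weights)
}

#' Serialize a fitted model to JSON
#'
#' Writes column ids, weights, hyperparameters and the optimizer trace to a
#' JSON document, mirroring released coefficient/hyperparameter resources.
#'
#' @param model a `fitted_linear_model` or `cox_model`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(class = class(model)[1],
              columns = names(model$weights),
              weights = unname(model$weights),
              intercept = model$intercept,
              hyperparams = unclass(model$hyperparams),
              trace = model$trace)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
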