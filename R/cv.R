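#' Build stratified cross-validation splits
#'
#' Samples are assigned to folds within joint (cancer type, sample type)
#' strata so every train/test combination preserves the cohort's cancer-type
#' and sample-type proportions. Strata smaller than `n_folds` are merged
#' into their cancer type's largest stratum before assignment. Replicates
#' use distinct child seeds derived from `seed`.
#'
#' @param clinical data.frame with `sample_id`, `cancer_type`, `sample_type`.
#' @param included_samples sample ids to split.
#' @param seed integer seed.
#' @param n_folds folds per replicate (default 4).
#' @param n_replicates replicates (default 2).
#' @return list of class `split_plan`: `assignments` is a list of length
#'   `n_replicates`, each a named integer vector (sample -> fold in
#'   1..n_folds).
#' @export
make_cv_splits <- function(clinical, included_samples, seed,
                           n_folds = 4, n_replicates = 2) {
  rownames(clinical) <- clinical$sample_id
  clin <- clinical[included_samples, , drop = FALSE]
  if (nrow(clin) < n_folds) {
    stop("make_cv_splits: fewer samples (", nrow(clin),
         ") than folds (", n_folds, ")")
  }
  stratum <- paste(clin$cancer_type, clin$sample_type, sep = "|")
  counts <- table(stratum)
  small <- names(counts)[counts < n_folds]
  if (length(small)) {
    for (s in small) {
      ct <- sub("\\|.*$", "", s)
      in_type <- setdiff(names(counts)[startsWith(names(counts),
                                                  paste0(ct, "|"))], small)
      target <- if (length(in_type)) {
        in_type[which.max(counts[in_type])]
      } else {
        # whole cancer type is small: merge into the global largest stratum
        names(counts)[which.max(counts)]
      }
      stratum[stratum == s] <- target
    }
  }
  assignments <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rng <- local_rng(child_seed(seed, "cv_replicate", r))
    fold <- integer(nrow(clin))
    for (s in unique(stratum)) {
      members <- which(stratum == s)
      members <- members[sample.int(length(members))]
      # random fold rotation so the +1-sized folds vary across strata
      fold[members] <- rep(sample.int(n_folds), length.out = length(members))
    }
    rng()
    names(fold) <- clin$sample_id
    assignments[[r]] <- fold
  }
  structure(list(n_folds = n_folds, n_replicates = n_replicates,
                 strata = stats::setNames(stratum, clin$sample_id),
                 assignments = assignments, seed = seed),
            class = "split_plan")
}

#' Permute labels within cancer types, separately in train and test
#'
#' The permuted-label null must preserve the class balance of the true
#' labels within every cancer type, separately on the training and test
#' side of a split. Each (cancer type x train/test) cell receives a uniform
#' random permutation of its own labels, so per-cell positive counts are
#' preserved exactly.
#'
#' @param labels named 0/1 vector.
#' @param cancer_types named character vector (sample -> cancer type).
#' @param train_set,test_set sample ids of the split.
#' @param seed integer seed.
#' @return named 0/1 vector, same names/order as `labels`.
#' @export
permute_labels_stratified <- function(labels, cancer_types, train_set,
                                      test_set, seed) {
  rng <- local_rng(child_seed(seed, "permute"))
  on.exit(rng(), add = TRUE)
  out <- labels
  for (part in list(train_set, test_set)) {
    ct <- cancer_types[part]
    for (type in unique(ct)) {
      cell <- part[ct == type]
      out[cell] <- labels[cell][sample.int(length(cell))]
    }
  }
  out
}

# Fit one glmnet path over the alpha (strength) grid at fixed l1_ratio and
# return predicted scores on newx for every alpha. Returns NULL when the
# response is degenerate (single class / no events).
fit_score_path <- function(x, y, l1_ratio, alphas, family, pf = NULL) {
  if (is.null(pf)) pf <- rep(1, ncol(x))
  pad <- pad_columns(x)
  if (pad$padded) pf <- c(pf, 1)
  lam <- sort(unique(alphas), decreasing = TRUE)
  if (min(lam) > 0) lam <- c(max(lam) * 4, lam) # warm-up knot
  fit <- tryCatch(
    glmnet::glmnet(pad$x, y, family = family, alpha = l1_ratio, lambda = lam,
                   standardize = FALSE, penalty.factor = pf,
                   thresh = 1e-7, maxit = 1e5),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  function(newx) {
    newpad <- pad_columns(newx)$x
    s <- stats::predict(fit, newx = newpad, s = alphas, type = "link")
    colnames(s) <- as.character(alphas)
    s
  }
}

# Inner k-fold split of a sample set, stratified by the precomputed strata.
inner_folds <- function(samples, strata, k, seed) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  st <- strata[samples]
  fold <- integer(length(samples))
  for (s in unique(st)) {
    members <- which(st == s)
    members <- members[sample.int(length(members))]
    fold[members] <- rep(sample.int(k), length.out = length(members))
  }
  names(fold) <- samples
  fold
}

#' Nested grid search over elastic-net hyperparameters for one outer fold
#'
#' Scores every (alpha, l1_ratio) pair by mean AUPR over `n_inner` inner
#' stratified folds of the outer-training set (classification) or by mean
#' c-index (Cox), picks the argmax with ties broken toward smaller alpha
#' then larger l1_ratio, refits on the full outer-training set, and
#' evaluates once on the outer test set.
#'
#' @param x numeric matrix (all samples).
#' @param y named 0/1 labels (classification) or a data.frame with `time`,
#'   `event` rownamed by sample (Cox).
#' @param train_set,test_set sample ids.
#' @param strata named stratum vector (from a `split_plan`).
#' @param grids list with `alpha` and `l1_ratio` numeric vectors.
#' @param family `"binomial"` or `"cox"`.
#' @param n_inner inner folds (default 3).
#' @param seed integer seed for the inner splits.
#' @param pf penalty factors (default all 1).
#' @return list: `alpha`, `l1_ratio`, `metrics` (named vector), `n_test_positives`
#'   (or `n_test_events`), `inner_scores` (alpha x l1_ratio matrix), or NULL
#'   when the outer test set is degenerate (with a warning).
#' @export
nested_grid_search <- function(x, y, train_set, test_set, strata, grids,
                               family = c("binomial", "cox"), n_inner = 3,
                               seed = 1, pf = NULL) {
  family <- match.arg(family)
  stopifnot(length(grids$alpha) >= 1, length(grids$l1_ratio) >= 1)
  ifold <- inner_folds(train_set, strata, n_inner,
                       child_seed(seed, "inner"))
  score <- base::matrix(NA_real_, length(grids$alpha), length(grids$l1_ratio),
                        dimnames = list(as.character(grids$alpha),
                                        as.character(grids$l1_ratio)))
  acc <- array(NA_real_, c(length(grids$alpha), length(grids$l1_ratio), n_inner))
  for (f in seq_len(n_inner)) {
    itr <- names(ifold)[ifold != f]
    ite <- names(ifold)[ifold == f]
    resp <- make_response(y, itr, family)
    if (is.null(resp)) {
      warning("nested_grid_search: inner fold ", f,
              " skipped (degenerate training response)")
      next
    }
    test_ok <- inner_test_ok(y, ite, family)
    if (!test_ok) {
      warning("nested_grid_search: inner fold ", f,
              " skipped (degenerate test response)")
      next
    }
    for (j in seq_along(grids$l1_ratio)) {
      path <- fit_score_path(x[itr, , drop = FALSE], resp,
                             grids$l1_ratio[j], grids$alpha, family, pf)
      if (is.null(path)) next
      s <- path(x[ite, , drop = FALSE])
      for (a in seq_along(grids$alpha)) {
        acc[a, j, f] <- inner_metric(s[, a], y, ite, family)
      }
    }
  }
  score[] <- apply(acc, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  if (all(is.na(score))) {
    stop("nested_grid_search: all inner folds degenerate")
  }
  best <- which(score == max(score, na.rm = TRUE), arr.ind = TRUE)
  # ties: smaller alpha, then larger l1_ratio
  best <- best[order(grids$alpha[best[, 1]], -grids$l1_ratio[best[, 2]]), ,
               drop = FALSE][1, ]
  hp <- enet_hp(grids$alpha[best[1]], grids$l1_ratio[best[2]])

  resp <- make_response(y, train_set, family)
  if (is.null(resp)) stop("nested_grid_search: degenerate outer training set")
  if (!inner_test_ok(y, test_set, family)) {
    warning("nested_grid_search: outer test set degenerate; fold dropped")
    return(NULL)
  }
  xtr <- x[train_set, , drop = FALSE]
  xte <- x[test_set, , drop = FALSE]
  if (family == "binomial") {
    model <- fit_elastic_net_logistic(xtr, resp, hp, thresh = 1e-7)
    p <- predict_positive_probability(model, xte)
    metrics <- compute_metrics(p, y[test_set])
    n_extra <- c(n_test_positives = sum(y[test_set] == 1))
  } else {
    model <- fit_elastic_net_cox(xtr, y[train_set, "time"],
                                 y[train_set, "event"], hp, thresh = 1e-7)
    sc <- predict_risk_score(model, xte)
    metrics <- c(cindex = concordance_index(sc, y[test_set, "time"],
                                            y[test_set, "event"]))
    n_extra <- c(n_test_events = sum(y[test_set, "event"] == 1))
  }
  list(alpha = hp$alpha, l1_ratio = hp$l1_ratio, metrics = metrics,
       n_extra = n_extra, inner_scores = score, model = model)
}

make_response <- function(y, samples, family) {
  if (family == "binomial") {
    v <- y[samples]
    if (length(unique(v)) < 2) return(NULL)
    v
  } else {
    d <- y[samples, , drop = FALSE]
    if (sum(d$event) == 0) return(NULL)
    survival::Surv(d$time, d$event)
  }
}

inner_test_ok <- function(y, samples, family) {
  if (family == "binomial") {
    length(unique(y[samples])) == 2
  } else {
    sum(y[samples, "event"]) > 0 && any(y[samples, "time"] >
                                          min(y[samples, "time"]))
  }
}

inner_metric <- function(scores, y, samples, family) {
  tryCatch({
    if (family == "binomial") {
      unname(compute_metrics(scores, y[samples])["aupr"])
    } else {
      concordance_index(scores, y[samples, "time"], y[samples, "event"])
    }
  }, error = function(e) NA_real_)
}
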