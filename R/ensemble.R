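# The consensus ensemble: six member classifiers (regularized logistic
# regression, k-nearest neighbours, kernel SVM, random forest, gradient
# boosted trees, single-hidden-layer feed-forward net), each tuned by seeded
# random search with stratified k-fold cross-validation maximizing
# precision (subject to a recall floor that rules out the degenerate
# predict-nothing optimum), then refitted on the full training data.  A
# compound is consensus-positive when at least `vote_threshold` members
# call it active (default: unanimous, 6 of 6).

MEMBER_ALGORITHMS <- c("logistic_linear", "k_nearest_neighbor", "kernel_svm",
                       "random_forest", "gradient_boosted_trees",
                       "feedforward_net")

#' Tuning configuration for ensemble members
#'
#' @param n_trials random-search trials per member (default 300).
#' @param cv_folds stratified cross-validation folds (default 10).
#' @param objective tuning objective: `"precision"` (default, with the
#'   recall floor), `"average_precision"`, or `"roc_auc"`.
#' @param recall_floor minimum mean CV recall a trial must reach before its
#'   precision is compared (default 0.25).
#' @param seed integer seed controlling search sampling, folds and member
#'   fitting.
#' @return A `tuning_config` list.
#' @export
tuning_config <- function(n_trials = 300L, cv_folds = 10L,
                          objective = c("precision", "average_precision",
                                        "roc_auc"),
                          recall_floor = 0.25, seed = 1L) {
  stopifnot(n_trials >= 1, cv_folds >= 2)
  structure(list(n_trials = as.integer(n_trials),
                 cv_folds = as.integer(cv_folds),
                 objective = match.arg(objective),
                 recall_floor = recall_floor, seed = as.integer(seed)),
            class = "tuning_config")
}

# --- hyperparameter search spaces ------------------------------------------

runif1 <- function(lo, hi) stats::runif(1, lo, hi)
logunif1 <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
pick1 <- function(v) v[[sample.int(length(v), 1)]]

sample_params <- function(algorithm) {
  switch(algorithm,
    logistic_linear = list(alpha = runif1(0, 1),
                           lambda = logunif1(1e-4, 10)),
    k_nearest_neighbor = list(k = sample(3:31, 1)),
    kernel_svm = list(kernel = pick1(c("radial", "linear")),
                      cost = logunif1(0.01, 100),
                      gamma = logunif1(1e-4, 0.1)),
    random_forest = list(num_trees = sample(100:200, 1),
                         mtry_frac = runif1(0.02, 0.3),
                         min_node_size = pick1(c(1, 3, 5, 10))),
    gradient_boosted_trees = list(nrounds = sample(40:150, 1),
                                  eta = logunif1(0.02, 0.3),
                                  max_depth = sample(2:6, 1),
                                  subsample = runif1(0.5, 1),
                                  colsample_bytree = runif1(0.3, 1)),
    feedforward_net = list(size = pick1(c(2L, 4L, 8L)),
                           decay = logunif1(1e-4, 1e-1),
                           maxit = 100L,
                           screen_k = 256L),
    stop("unknown algorithm: ", algorithm))
}

# scale-sensitive members: z-score for margin/gradient learners; range
# ([0,1] min-max) for k-nearest neighbours, where z-scoring sparse binary
# fingerprint bits would let rare bits dominate the Euclidean distance
scaler_type <- function(algorithm) {
  switch(algorithm,
    logistic_linear = , kernel_svm = , feedforward_net = "standardize",
    k_nearest_neighbor = "range",
    "none")
}

fit_scaler <- function(X, type = "standardize") {
  if (type == "range") {
    lo <- apply(X, 2, min)
    span <- apply(X, 2, max) - lo
    span[span == 0 | is.na(span)] <- 1
    list(type = "range", lo = lo, span = span)
  } else {
    mu <- colMeans(X)
    sdev <- apply(X, 2, stats::sd)
    sdev[sdev == 0 | is.na(sdev)] <- 1
    list(type = "standardize", mu = mu, sd = sdev)
  }
}

apply_scaler <- function(scaler, X) {
  if (scaler$type == "range") {
    sweep(sweep(X, 2, scaler$lo, "-"), 2, scaler$span, "/")
  } else {
    sweep(sweep(X, 2, scaler$mu, "-"), 2, scaler$sd, "/")
  }
}

# --- member fitting ---------------------------------------------------------

# `cv = TRUE` skips the SVM Platt-scaling fit during cross-validation (the
# CV score then uses the logistic-squashed decision value, which crosses
# 0.5 exactly at the class boundary); the final refit always carries the
# full probability model.
fit_member <- function(algorithm, X, y01, params, seed = 1L, cv = FALSE) {
  set.seed(seed)
  scaler <- NULL
  stype <- scaler_type(algorithm)
  if (stype != "none") {
    scaler <- fit_scaler(X, stype)
    X <- apply_scaler(scaler, X)
  }
  yfac <- factor(ifelse(y01 == 1, "active", "inactive"),
                 levels = c("inactive", "active"))
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0); n <- length(y01)
  w1 <- n / (2 * n1); w0 <- n / (2 * n0)   # balanced class weights
  fit <- switch(algorithm,
    logistic_linear = glmnet::glmnet(
      X, yfac, family = "binomial", alpha = params$alpha,
      lambda = params$lambda, weights = ifelse(y01 == 1, w1, w0),
      standardize = FALSE),
    k_nearest_neighbor = caret::knn3(X, yfac, k = params$k),
    kernel_svm = e1071::svm(
      X, yfac, kernel = params$kernel, cost = params$cost,
      gamma = params$gamma, probability = !cv, scale = FALSE,
      class.weights = c(inactive = w0, active = w1)),
    random_forest = ranger::ranger(
      x = X, y = yfac, probability = TRUE,
      num.trees = params$num_trees,
      mtry = max(1L, floor(params$mtry_frac * ncol(X))),
      min.node.size = params$min_node_size,
      class.weights = c(inactive = w0, active = w1),
      seed = seed, num.threads = 1),
    gradient_boosted_trees = {
      dtr <- xgboost::xgb.DMatrix(X, label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta, max_depth = params$max_depth,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      scale_pos_weight = n0 / n1,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = params$nrounds, verbose = 0)
    },
    feedforward_net = NULL,  # handled below (feature screen + net)
    stop("unknown algorithm: ", algorithm))
  subset_idx <- NULL
  if (algorithm == "feedforward_net") {
    # univariate screen to the top-k columns by absolute two-sample
    # t statistic (full-batch BFGS scales quadratically in the weight
    # count, so the net trains on a compact supervised subset)
    k <- min(params$screen_k %||% 256L, ncol(X))
    X1 <- X[y01 == 1, , drop = FALSE]; X0 <- X[y01 == 0, , drop = FALSE]
    m1 <- colMeans(X1); m0 <- colMeans(X0)
    v1 <- (colSums(X1^2) - nrow(X1) * m1^2) / max(nrow(X1) - 1, 1)
    v0 <- (colSums(X0^2) - nrow(X0) * m0^2) / max(nrow(X0) - 1, 1)
    tstat <- abs(m1 - m0) / sqrt(v1 / max(n1, 2) + v0 / max(n0, 2) + 1e-12)
    subset_idx <- order(tstat, decreasing = TRUE)[seq_len(k)]
    subset_idx <- sort(subset_idx)
    fit <- nnet::nnet(
      X[, subset_idx, drop = FALSE], y01, size = params$size,
      decay = params$decay, maxit = params$maxit, MaxNWts = 100000,
      trace = FALSE, weights = ifelse(y01 == 1, w1, w0), entropy = TRUE)
  }
  list(algorithm = algorithm, params = params, fit = fit, scaler = scaler,
       subset_idx = subset_idx, feature_names = colnames(X))
}

# P(active) for one fitted member
`%||%` <- function(a, b) if (is.null(a)) b else a

member_prob <- function(member, X) {
  if (!is.null(member$scaler)) X <- apply_scaler(member$scaler, X)
  if (!is.null(member$subset_idx)) X <- X[, member$subset_idx, drop = FALSE]
  alg <- member$algorithm
  p <- switch(alg,
    logistic_linear = as.numeric(stats::predict(member$fit, X, type = "response")),
    k_nearest_neighbor = stats::predict(member$fit, X, type = "prob")[, "active"],
    kernel_svm = {
      if (is.null(member$fit$compprob) || !member$fit$compprob) {
        # CV fit without a probability model: squash the decision value
        dvm <- attr(stats::predict(member$fit, X, decision.values = TRUE),
                    "decision.values")
        sgn <- if (colnames(dvm)[1] == "active/inactive") 1 else -1
        stats::plogis(sgn * dvm[, 1])
      } else {
        pr <- stats::predict(member$fit, X, probability = TRUE)
        attr(pr, "probabilities")[, "active"]
      }
    },
    random_forest = stats::predict(member$fit, data = X,
                                   num.threads = 1)$predictions[, "active"],
    gradient_boosted_trees = as.numeric(stats::predict(
      member$fit, xgboost::xgb.DMatrix(X))),
    feedforward_net = as.numeric(stats::predict(member$fit, X)),
    stop("unknown algorithm: ", alg))
  unname(p)
}

# stratified fold assignment, reproducible for a seed
stratified_folds <- function(y01, k, seed) {
  set.seed(seed)
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

trial_score <- function(obj, precision, recall, auc, ap, floor) {
  switch(obj,
    precision = if (is.na(recall) || recall < floor)
      (if (is.na(recall)) 0 else recall) - 1 else
        (if (is.na(precision)) 0 else precision),
    average_precision = if (is.na(ap)) -1 else ap,
    roc_auc = if (is.na(auc)) -1 else auc)
}

#' Tune and fit one ensemble member
#'
#' Seeded random search over the member's hyperparameter space: each trial
#' is scored by stratified k-fold cross-validation on the training data and
#' the best trial's parameters are refitted on the full training set.
#'
#' @param algorithm one of
#'   `"logistic_linear"`, `"k_nearest_neighbor"`, `"kernel_svm"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`, `"feedforward_net"`.
#' @param X training feature matrix.
#' @param y training labels.
#' @param tuning a [tuning_config()].
#' @return list with the fitted `member`, `best_params`, `best_score` and
#'   the full `trial_log` (one row per trial: parameters, mean CV
#'   precision/recall/AUC/AP and the objective score).
#' @export
tune_and_fit_member <- function(algorithm, X, y, tuning = tuning_config()) {
  algorithm <- match.arg(algorithm, MEMBER_ALGORITHMS)
  y01 <- as_binary_label(y)
  if (length(unique(y01)) < 2) stop("training data must contain both classes")
  seed0 <- tuning$seed + match(algorithm, MEMBER_ALGORITHMS) * 1000L
  set.seed(seed0)
  trials <- lapply(seq_len(tuning$n_trials), function(i) sample_params(algorithm))
  folds <- stratified_folds(y01, tuning$cv_folds, seed0)
  log_rows <- vector("list", tuning$n_trials)
  scores <- numeric(tuning$n_trials)
  for (t in seq_len(tuning$n_trials)) {
    params <- trials[[t]]
    pred <- rep(NA_real_, length(y01))
    for (f in seq_len(tuning$cv_folds)) {
      tr <- folds != f
      if (length(unique(y01[tr])) < 2) next
      m <- tryCatch(suppressWarnings(
        fit_member(algorithm, X[tr, , drop = FALSE], y01[tr],
                   params, seed = seed0 + f, cv = TRUE)),
        error = function(e) NULL)
      if (is.null(m)) next
      pred[!tr] <- tryCatch(member_prob(m, X[!tr, , drop = FALSE]),
                            error = function(e) NA_real_)
    }
    ok <- !is.na(pred)
    if (!any(ok)) {
      scores[t] <- -2
      log_rows[[t]] <- c(params, list(precision = NA, recall = NA,
                                      roc_auc = NA, average_precision = NA,
                                      score = -2))
      next
    }
    mets <- classification_metrics(y01[ok], as.integer(pred[ok] >= 0.5),
                                   scores = pred[ok])
    scores[t] <- trial_score(tuning$objective, mets$precision, mets$recall,
                             mets$roc_auc, mets$average_precision,
                             tuning$recall_floor)
    log_rows[[t]] <- c(params, list(precision = mets$precision,
                                    recall = mets$recall,
                                    roc_auc = mets$roc_auc,
                                    average_precision = mets$average_precision,
                                    score = scores[t]))
  }
  best <- which.max(scores)  # first maximum: deterministic tie-break
  member <- fit_member(algorithm, X, y01, trials[[best]], seed = seed0)
  list(member = member, best_params = trials[[best]],
       best_score = scores[best],
       trial_log = do.call(rbind, lapply(log_rows, function(r)
         as.data.frame(r, stringsAsFactors = FALSE))))
}

# --- the ensemble -----------------------------------------------------------

#' Fit the six-member consensus ensemble
#'
#' Tunes and fits all six member classifiers on a feature matrix from
#' [featurize()] and combines them under vote-threshold consensus.  The
#' default threshold 6 (unanimity) accepts a compound only when every
#' member predicts it active, which minimizes false positives at some cost
#' in recall.
#'
#' @param x feature matrix (rows = compounds).
#' @param y activity labels (`"active"`/`"inactive"`, logical, or 0/1).
#' @param members algorithms to include (default: all six).
#' @param tuning a [tuning_config()].
#' @param vote_threshold consensus threshold in 1..length(members)
#'   (default: all members).
#' @param verbose print per-member progress.
#' @return A `frag_ensemble` object with `members` (fitted member list),
#'   `tuning_logs`, `vote_threshold`, `feature_schema` and the tuning
#'   seed; see [predict.frag_ensemble()].
#' @export
frag_ensemble <- function(x, y, members = MEMBER_ALGORITHMS,
                          tuning = tuning_config(), vote_threshold = NULL,
                          verbose = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == length(as_binary_label(y)))
  members <- match.arg(members, MEMBER_ALGORITHMS, several.ok = TRUE)
  if (is.null(vote_threshold)) vote_threshold <- length(members)
  stopifnot(vote_threshold >= 1, vote_threshold <= length(members))
  fitted <- list(); logs <- list()
  for (alg in members) {
    if (verbose) message("tuning ", alg, " (", tuning$n_trials, " trials, ",
                         tuning$cv_folds, "-fold CV)")
    res <- tune_and_fit_member(alg, x, y, tuning)
    fitted[[alg]] <- res$member
    logs[[alg]] <- res$trial_log
  }
  structure(list(members = fitted, tuning_logs = logs,
                 vote_threshold = as.integer(vote_threshold),
                 feature_schema = colnames(x), tuning = tuning,
                 n_train = nrow(x),
                 class_balance = table(as_binary_label(y))),
            class = "frag_ensemble")
}

check_schema <- function(object, X) {
  sch <- object$feature_schema
  if (is.null(colnames(X))) {
    if (ncol(X) != length(sch))
      stop("feature matrix has ", ncol(X), " columns; model expects ",
           length(sch))
    return(X)
  }
  if (!identical(colnames(X), sch)) {
    bad <- which(colnames(X) != sch)[1]
    stop("feature schema mismatch at column ", bad, ": '",
         colnames(X)[bad], "' vs expected '", sch[bad], "'")
  }
  X
}

#' Predict from a consensus ensemble
#'
#' @param object a [frag_ensemble()].
#' @param newdata feature matrix matching the training schema.
#' @param type `"votes"` (number of members voting active, 0..6),
#'   `"consensus"` (logical, votes >= threshold), `"prob"` (mean member
#'   probability), or `"member_prob"` (matrix of per-member
#'   probabilities).
#' @param threshold vote threshold for `"consensus"` (default: the model's).
#' @param ... unused.
#' @return vector (or matrix for `"member_prob"`) aligned with rows of
#'   `newdata`.
#' @export
predict.frag_ensemble <- function(object, newdata,
                                  type = c("votes", "consensus", "prob",
                                           "member_prob"),
                                  threshold = NULL, ...) {
  type <- match.arg(type)
  X <- check_schema(object, newdata)
  probs <- vapply(object$members, function(m) member_prob(m, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) probs <- matrix(probs, nrow = 1,
                                    dimnames = list(NULL, names(object$members)))
  votes <- as.integer(rowSums(probs >= 0.5))
  switch(type,
    votes = votes,
    consensus = consensus_classify(
      votes, if (is.null(threshold)) object$vote_threshold else threshold),
    prob = unname(rowMeans(probs)),
    member_prob = probs)
}

#' Consensus decision from vote counts
#'
#' @param votes integer votes per compound (0..number of members).
#' @param threshold required votes.
#' @return logical: `votes >= threshold`.
#' @export
consensus_classify <- function(votes, threshold) {
  stopifnot(threshold >= 1)
  votes >= threshold
}

#' @export
print.frag_ensemble <- function(x, ...) {
  cat("<frag_ensemble: ", length(x$members), " members, vote threshold ",
      x$vote_threshold, ">\n", sep = "")
  cat("trained on ", x$n_train, " compounds (",
      paste(rev(x$class_balance), collapse = " active / "),
      " inactive); tuning: ", x$tuning$n_trials, " trials, ",
      x$tuning$cv_folds, "-fold CV, objective ", x$tuning$objective,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.frag_ensemble <- function(object, ...) {
  best <- do.call(rbind, lapply(names(object$members), function(alg) {
    lg <- object$tuning_logs[[alg]]
    b <- lg[which.max(lg$score), c("precision", "recall", "score")]
    data.frame(member = alg, b, row.names = NULL)
  }))
  cat("Best cross-validated trial per member:\n")
  print(best)
  invisible(best)
}

#' Stratified train/test split
#'
#' @param X feature matrix.
#' @param y labels.
#' @param fraction training fraction (default 0.9).
#' @param seed split seed.
#' @return list with `train` and `test`, each holding `x`, `y`, `idx`.
#' @export
split_train_test <- function(X, y, fraction = 0.9, seed = 1L) {
  y01 <- as_binary_label(y)
  stopifnot(nrow(X) == length(y01), nrow(X) >= 10)
  if (length(unique(y01)) < 2) stop("input has a single class")
  set.seed(seed)
  test_idx <- integer(0)
  for (cls in c(0, 1)) {
    idx <- which(y01 == cls)
    n_test <- round(length(idx) * (1 - fraction))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(X)), test_idx)
  list(train = list(x = X[train_idx, , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(x = X[test_idx, , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

#' Evaluate a model or member on labelled data
#'
#' For an ensemble, the decision is vote-threshold consensus and the curve
#' score is the vote fraction; for a single member, the decision is
#' probability >= 0.5 and the score is the probability.
#'
#' @param object a `frag_ensemble` or a fitted member from its `members`
#'   list.
#' @param X feature matrix.
#' @param y_true labels.
#' @param threshold optional vote threshold override (ensemble only).
#' @return An `eval_metrics` object (see [classification_metrics()]).  The
#'   unanimous-consensus false-positive count never exceeds any single
#'   member's (checked on every call).
#' @export
evaluate <- function(object, X, y_true, threshold = NULL) {
  yt <- as_binary_label(y_true)
  if (inherits(object, "frag_ensemble")) {
    votes <- predict(object, X, type = "votes")
    thr <- if (is.null(threshold)) object$vote_threshold else threshold
    pred <- as.integer(consensus_classify(votes, thr))
    mets <- classification_metrics(yt, pred, scores = votes / length(object$members))
    if (thr == length(object$members)) {
      # provable dominance: unanimous positives = intersection of member
      # positive sets, so ensemble FPs cannot exceed any member's
      probs <- predict(object, X, type = "member_prob")
      member_fp <- vapply(seq_len(ncol(probs)), function(j)
        sum(yt == 0 & probs[, j] >= 0.5), 0L)
      stopifnot(mets$fp <= min(member_fp))
    }
    mets
  } else {
    p <- member_prob(object, X)
    classification_metrics(yt, as.integer(p >= 0.5), scores = p)
  }
}

#' False-positive rate on an assumed-inactive pool by vote threshold
#'
#' The pool (e.g. a random commercial-directory sample) is taken to contain
#' no true actives, so every consensus positive is a false positive.
#'
#' @param model a `frag_ensemble`.
#' @param negatives feature matrix of the pool.
#' @param thresholds vote thresholds to tabulate (default 1..members).
#' @return data.frame with `threshold`, `n_passed`, `fpr` (non-increasing
#'   in threshold).
#' @export
negative_pool_fpr <- function(model, negatives, thresholds = NULL) {
  stopifnot(inherits(model, "frag_ensemble"))
  if (nrow(negatives) == 0) stop("empty negative pool")
  if (is.null(thresholds)) thresholds <- seq_along(model$members)
  votes <- predict(model, negatives, type = "votes")
  data.frame(
    threshold = thresholds,
    n_passed = vapply(thresholds, function(t) sum(votes >= t), 0L),
    fpr = vapply(thresholds, function(t) mean(votes >= t), 0))
}

#' Save / load a fitted ensemble
#'
#' The archive stores hyperparameters, fitted member parameters, the
#' feature schema and tuning provenance.
#'
#' @param model a `frag_ensemble`.
#' @param path file path.
#' @return `load_ensemble` returns the `frag_ensemble`.
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "frag_ensemble"))
  if (!is.null(model$members$gradient_boosted_trees)) {
    m <- model$members$gradient_boosted_trees
    m$fit_raw <- xgboost::xgb.save.raw(m$fit)
    m$fit <- NULL
    model$members$gradient_boosted_trees <- m
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  model <- readRDS(path)
  if (!is.null(model$members$gradient_boosted_trees$fit_raw)) {
    m <- model$members$gradient_boosted_trees
    m$fit <- xgboost::xgb.load.raw(m$fit_raw)
    m$fit_raw <- NULL
    model$members$gradient_boosted_trees <- m
  }
  model
}
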