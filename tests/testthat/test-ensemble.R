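# Ensemble members, tuning, consensus voting and evaluation metrics.

test_that("stratified splitting is exhaustive, proportional and seeded", {
  set.seed(3)
  X <- matrix(rnorm(1000 * 5), 1000, 5)
  y <- rep(c("active", "inactive"), c(100, 900))
  sp <- split_train_test(X, y, fraction = 0.9, seed = 21)
  expect_equal(nrow(sp$train$x), 900)
  expect_equal(nrow(sp$test$x), 100)
  expect_setequal(c(sp$train$idx, sp$test$idx), 1:1000)
  # stratification: 10% actives overall -> 10 +/- 1 actives in the test set
  expect_lte(abs(sum(sp$test$y == "active") - 10), 1)
  sp2 <- split_train_test(X, y, fraction = 0.9, seed = 21)
  expect_identical(sp$test$idx, sp2$test$idx)
  expect_error(split_train_test(X, rep("active", 1000), 0.9, 1),
               "single class")
})

test_that("tuning selects the only trial and is seed-deterministic", {
  d <- noisy_data()
  tun <- tuning_config(n_trials = 1, cv_folds = 3, seed = 5)
  r <- tune_and_fit_member("logistic_linear", d$x, d$y, tun)
  expect_identical(r$best_params, r$member$params)
  expect_equal(nrow(r$trial_log), 1)

  tun2 <- tuning_config(n_trials = 4, cv_folds = 3, seed = 8)
  ra <- tune_and_fit_member("random_forest", d$x, d$y, tun2)
  rb <- tune_and_fit_member("random_forest", d$x, d$y, tun2)
  expect_identical(ra$best_params, rb$best_params)
  expect_equal(ra$trial_log$score, rb$trial_log$score)
})

test_that("a tuned linear member separates linearly separable data perfectly", {
  d <- separable_data()
  tun <- tuning_config(n_trials = 5, cv_folds = 4, seed = 2)
  r <- tune_and_fit_member("logistic_linear", d$x, d$y, tun)
  expect_equal(r$best_score, 1.0)      # CV precision 1 at the recall floor
  m <- evaluate(r$member, d$x, d$y)
  expect_equal(m$precision, 1.0)
})

test_that("every member algorithm fits, predicts probabilities and is seeded", {
  d <- noisy_data()
  for (alg in fragfocus:::MEMBER_ALGORITHMS) {
    set.seed(1)
    p <- fragfocus:::sample_params(alg)
    m1 <- fragfocus:::fit_member(alg, d$x, d$y, p, seed = 3)
    m2 <- fragfocus:::fit_member(alg, d$x, d$y, p, seed = 3)
    pr1 <- fragfocus:::member_prob(m1, d$x)
    pr2 <- fragfocus:::member_prob(m2, d$x)
    expect_true(all(pr1 >= 0 & pr1 <= 1), info = alg)
    expect_equal(pr1, pr2, info = alg)
  }
})

test_that("votes, consensus and vote-threshold monotonicity behave as sets", {
  d <- noisy_data(n = 90)
  tun <- tuning_config(n_trials = 2, cv_folds = 3, seed = 4)
  ens <- frag_ensemble(d$x, d$y, tuning = tun)
  votes <- predict(ens, d$x, type = "votes")
  expect_true(all(votes >= 0 & votes <= 6))
  probs <- predict(ens, d$x, type = "member_prob")
  expect_equal(votes, as.integer(rowSums(probs >= 0.5)))
  # consensus thresholds nest
  sets <- lapply(1:6, function(t) which(consensus_classify(votes, t)))
  for (t in 2:6) expect_true(all(sets[[t]] %in% sets[[t - 1]]))
  # boundary examples
  expect_true(consensus_classify(6L, 6L))
  expect_true(consensus_classify(4L, 4L))
  expect_false(consensus_classify(5L, 6L))
})

test_that("metric identities hold exactly and match the confusion counts", {
  m <- classification_metrics(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 0))
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$precision, 0.75)  # tp / (tp + fp)
  # identities to machine precision on a random confusion
  set.seed(10)
  yt <- rbinom(500, 1, 0.3); yp <- rbinom(500, 1, 0.4)
  m2 <- classification_metrics(yt, yp)
  expect_equal(m2$precision, m2$tp / (m2$tp + m2$fp), tolerance = 1e-12)
  expect_equal(m2$recall, m2$tp / (m2$tp + m2$fn), tolerance = 1e-12)
  expect_equal(m2$accuracy, (m2$tp + m2$tn) / 500, tolerance = 1e-12)
  expect_equal(m2$fpr, m2$fp / (m2$fp + m2$tn), tolerance = 1e-12)
})

test_that("ROC AUC and average precision behave at the reference points", {
  # perfect scores
  m <- classification_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                              scores = c(.1, .2, .8, .9))
  expect_equal(m$roc_auc, 1.0)
  expect_equal(m$average_precision, 1.0)
  # random scores on balanced labels: AUC ~ 0.5 (Monte-Carlo band)
  set.seed(77)
  y <- rep(c(0, 1), 5000)
  s <- runif(10000)
  m2 <- classification_metrics(y, as.integer(s >= 0.5), scores = s)
  expect_lt(abs(m2$roc_auc - 0.5), 0.02)
  # AP cross-check against a direct rank-sum computation
  set.seed(78)
  y3 <- rbinom(200, 1, 0.3); s3 <- runif(200)
  o <- order(s3, decreasing = TRUE)
  hits <- y3[o]
  ap_direct <- sum((cumsum(hits) / seq_along(hits)) * hits) / sum(hits)
  m3 <- classification_metrics(y3, as.integer(s3 >= .5), scores = s3)
  expect_equal(m3$average_precision, ap_direct, tolerance = 1e-12)
})

test_that("unanimous consensus false positives never exceed any member's", {
  d <- noisy_data(n = 100, shift = 0.8, seed = 12)
  tun <- tuning_config(n_trials = 2, cv_folds = 3, seed = 6)
  ens <- frag_ensemble(d$x, d$y, tuning = tun)
  holdout <- noisy_data(n = 80, shift = 0.8, seed = 13)
  mets <- evaluate(ens, holdout$x, holdout$y)  # asserts dominance internally
  probs <- predict(ens, holdout$x, type = "member_prob")
  member_fp <- vapply(seq_len(6), function(j)
    sum(holdout$y == 0 & probs[, j] >= 0.5), 0L)
  expect_lte(mets$fp, min(member_fp))
})

test_that("negative-pool FPR is non-increasing in the vote threshold", {
  d <- noisy_data(n = 90, seed = 14)
  tun <- tuning_config(n_trials = 2, cv_folds = 3, seed = 7)
  ens <- frag_ensemble(d$x, d$y, tuning = tun)
  pool <- matrix(rnorm(60 * 10), 60, 10,
                 dimnames = list(NULL, colnames(d$x)))
  tab <- negative_pool_fpr(ens, pool)
  expect_equal(tab$threshold, 1:6)
  expect_true(all(diff(tab$fpr) <= 0))
  expect_equal(tab$fpr, tab$n_passed / 60)
  # threshold-6 fpr cannot exceed any member's fpr on the pool
  probs <- predict(ens, pool, type = "member_prob")
  expect_lte(tab$fpr[6], min(colMeans(probs >= 0.5)))
  expect_error(negative_pool_fpr(ens, pool[0, , drop = FALSE]), "empty")
})

test_that("ensembles survive a save/load round trip", {
  d <- noisy_data(n = 80, seed = 15)
  tun <- tuning_config(n_trials = 1, cv_folds = 3, seed = 9)
  ens <- frag_ensemble(d$x, d$y, tuning = tun)
  f <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens, f)
  back <- load_ensemble(f)
  expect_equal(predict(back, d$x, type = "votes"),
               predict(ens, d$x, type = "votes"))
  expect_identical(back$feature_schema, ens$feature_schema)
})

test_that("schema mismatches are rejected with the offending column named", {
  d <- noisy_data(n = 80, seed = 16)
  tun <- tuning_config(n_trials = 1, cv_folds = 3, seed = 10)
  ens <- frag_ensemble(d$x, d$y, tuning = tun)
  bad <- d$x
  colnames(bad)[3] <- "wrong"
  expect_error(predict(ens, bad), "wrong")
})
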