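test_that("feature table matches the block-40 coefficients per participant", {
  co <- generate_cohort(master_seed = 12L)
  tab <- build_feature_table(co)
  expect_equal(dim(tab), c(76L, 15L))
  expect_setequal(names(tab),
                  c(subspace_features("complete"), "Learner"))
  expect_equal(sum(tab$Learner == 0L), 14L)
  # definitional identity with block_series at block size 40
  id <- co$participants$participant_id[5]
  tr <- co$trials[co$trials$participant_id == id, ]
  expect_equal(as.numeric(tab[id, paste0("sens_", c("1_to_40", "41_to_80",
                                                    "81_to_120", "121_to_160",
                                                    "161_to_200", "201_to_240"))]),
               as.numeric(block_series(tr, "sensitivity", 40L)))
  # an all-correct participant scores 1 everywhere
  perfect <- learner_profile(hit_prob = c(1, 1, 1), cr_prob = c(1, 1, 1))
  pp <- simulate_participant(perfect, 1, "left", seed = 2L, id = "PX")
  co1 <- list(participants = data.frame(participant_id = "PX", config = 1,
                                        button = "left", label = "L"),
              trials = cbind(data.frame(participant_id = "PX", config = 1,
                                        button = "left", label = "L"),
                             pp$trials))
  t1 <- build_feature_table(co1)
  expect_true(all(t1[, 1:12] == 1))
  # missing trials are reported with the participant id
  broken <- co
  broken$trials <- co$trials[-1, ]
  expect_error(build_feature_table(broken), "P001")
})

test_that("feature subspaces are nested prefixes plus the design factors", {
  expect_setequal(subspace_features("upto_40"),
                  c("sens_1_to_40", "spec_1_to_40", "TargetConf", "Button"))
  expect_length(subspace_features("upto_200"), 12L)
  expect_length(subspace_features("complete"), 14L)
  for (k in 1:4) {
    a <- subspace_features(paste0("upto_", 40 * k))
    b <- subspace_features(paste0("upto_", 40 * (k + 1)))
    expect_true(all(a %in% b))
  }
  expect_error(subspace_features("upto_30"))
  co <- generate_cohort(master_seed = 13L)
  tab <- build_feature_table(co)
  sel <- subspace_select(tab, "upto_80")
  expect_equal(ncol(sel), 6L)
  expect_false("Learner" %in% names(sel))
})

test_that("class weights follow the negative/positive ratio", {
  w <- compute_weights(rep(c(1L, 0L), c(62L, 14L)))
  expect_equal(unique(w[1:62]), 14 / 62)
  expect_equal(unique(w[63:76]), 1)
  expect_equal(round(unique(w[1:62]), 3), 0.226) # printed as 0.225 after truncation
  expect_equal(unique(compute_weights(c(1, 1, 0, 0))), 1)
  expect_equal(compute_weights(c(1, rep(0, 99)))[1], 99)
  expect_error(compute_weights(rep(1, 5)), "both classes")
})

test_that("balanced accuracy equals the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0.5)
  y <- rep(c(1, 0), c(10, 10))
  p <- c(rep(1, 5), rep(0, 5), rep(0, 8), rep(1, 2))
  expect_equal(balanced_accuracy(y, p), 0.65)
  # randomized confusion-matrix oracle
  set.seed(51)
  for (i in 1:200) {
    yt <- sample(0:1, 30, replace = TRUE)
    if (length(unique(yt)) < 2) next
    yp <- sample(0:1, 30, replace = TRUE)
    recalls <- c(mean(yp[yt == 1] == 1), mean(yp[yt == 0] == 0))
    expect_equal(balanced_accuracy(yt, yp), mean(recalls))
  }
  expect_error(balanced_accuracy(rep(1, 4), rep(1, 4)), "both classes")
})

test_that("classifier is deterministic, ranks a planted signal first, and is
           invariant to weight scaling", {
  set.seed(52)
  n <- 80
  X <- data.frame(
    signal = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
    noise1 = rnorm(n), noise2 = rnorm(n),
    TargetConf = factor(sample(1:4, n, TRUE), levels = 1:4),
    Button = factor(sample(c("left", "right"), n, TRUE),
                    levels = c("left", "right"))
  )
  y <- rep(c(0L, 1L), each = n / 2)
  m1 <- train_classifier(X, y, seed = 7L, nrounds = 100L)
  m2 <- train_classifier(X, y, seed = 7L, nrounds = 100L)
  expect_identical(predict(m1, X, type = "prob"), predict(m2, X, type = "prob"))
  expect_equal(m1$importance$feature[1], "signal")
  expect_equal(sum(m1$importance$score), 100)
  # multiplying all weights by a constant leaves predictions unchanged
  w <- compute_weights(y)
  m3 <- train_classifier(X, y, weights = 5 * w, seed = 7L, nrounds = 100L)
  m4 <- train_classifier(X, y, weights = w, seed = 7L, nrounds = 100L)
  expect_equal(predict(m3, X, type = "prob"), predict(m4, X, type = "prob"),
               tolerance = 1e-6)
})

test_that("stratified folds preserve the class ratio within one instance", {
  co <- generate_cohort(master_seed = 14L)
  tab <- build_feature_table(co)
  rep5 <- stratified_cv(tab, "upto_40", k = 5L, seed = 1L, nrounds = 50L)
  expect_length(rep5$fold_scores, 5L)
  expect_equal(rep5$mean, mean(rep5$fold_scores))
  fold <- audlearn:::stratified_folds(tab$Learner, 5L, 99L)
  for (f in 1:5) {
    n1 <- sum(tab$Learner == 1L & fold == f)
    n0 <- sum(tab$Learner == 0L & fold == f)
    expect_true(abs(n1 - 62 / 5) < 1)
    expect_true(abs(n0 - 14 / 5) < 1)
  }
  expect_error(stratified_cv(tab, "upto_40", k = 20L), "smaller k")
})

test_that("strongly separated cohorts are classified almost perfectly while
           permuted labels are at chance", {
  # planted separation: mean over several seeded cohorts
  accs <- vapply(1:5, function(s) {
    co <- strong_separation_cohort(master_seed = s)
    tab <- build_feature_table(co)
    stratified_cv(tab, "complete", seed = s, nrounds = 150L)$mean
  }, numeric(1))
  expect_gt(mean(accs), 0.9)

  # label permutation: chance-level balanced accuracy
  co <- generate_cohort(master_seed = 15L)
  tab <- build_feature_table(co)
  set.seed(53)
  null_accs <- vapply(1:8, function(i) {
    tp <- tab
    tp$Learner <- sample(tp$Learner)
    stratified_cv(tp, "complete", seed = i, nrounds = 150L)$mean
  }, numeric(1))
  expect_gt(mean(null_accs), 0.35)
  expect_lt(mean(null_accs), 0.65)

  # complete feature space does at least as well as the first block alone
  better <- vapply(1:5, function(s) {
    co <- strong_separation_cohort(master_seed = 100L + s)
    tab <- build_feature_table(co)
    full <- stratified_cv(tab, "complete", seed = s, nrounds = 150L)$mean
    first <- stratified_cv(tab, "upto_40", seed = s, nrounds = 150L)$mean
    full >= first
  }, logical(1))
  expect_gte(mean(better), 0.6)
})
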