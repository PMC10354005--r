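test_that("CV plans are stratified, generation-seeded and reproducible", {
  y <- c(rep(1L, 35), rep(0L, 54))
  plan <- make_cv_plan(y, k = 10, base_seed = 3, generation = 0)
  expect_identical(sort(unlist(plan$folds)), seq_along(y))
  pos_per_fold <- vapply(plan$folds, function(f) sum(y[f]), 0L)
  expect_true(all(pos_per_fold %in% 3:4))
  neg_per_fold <- vapply(plan$folds, function(f) sum(y[f] == 0L), 0L)
  expect_true(all(neg_per_fold %in% 5:6))

  plan2 <- make_cv_plan(y, 10, 3, 0)
  expect_identical(plan$folds, plan2$folds)
  plan3 <- make_cv_plan(y, 10, 3, 1)
  expect_false(identical(plan$folds, plan3$folds))

  expect_error(make_cv_plan(c(rep(1L, 4), rep(0L, 40)), k = 10), "use k <=")
})

test_that("classification metrics reproduce the worked confusion matrix", {
  # TP=3, FN=1, TN=4, FP=2
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.6)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-10)
  expect_equal(m$balanced_accuracy, (0.75 + 2 / 3) / 2)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-10)
  expect_equal(m$f2, 0.71428571, tolerance = 1e-6)

  perfect <- classification_metrics(y_true, y_true, y_true)
  for (k in c("accuracy", "precision", "recall", "f1", "f2",
              "balanced_accuracy", "auc", "wgm"))
    expect_equal(perfect[[k]], 1, info = k)

  allpos <- classification_metrics(y_true, rep(1, 10))
  expect_equal(allpos$precision, 0.4)   # prevalence
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$specificity, 0)
})

test_that("metrics agree with an independent oracle on random vectors", {
  set.seed(21)
  for (r in 1:100) {
    n <- sample(5:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    m <- classification_metrics(y, pred)
    o <- oracle_metrics(y, pred)
    for (k in names(o)) expect_equal(m[[k]], o[[k]], info = k)
  }
})

test_that("rank-based AUC equals the concordant-pair fraction", {
  set.seed(22)
  for (r in 1:30) {
    n <- sample(5:80, 1)
    y <- sample(0:1, n, replace = TRUE)
    s <- round(runif(n), 1)       # coarse scores force midrank ties
    expect_equal(auc_score(y, s), oracle_auc(y, s))
  }
  expect_identical(auc_score(rep(1, 5), runif(5)), 0)  # one class absent
})

test_that("the weighted geometric mean follows its closed form", {
  expect_equal(wgm(0.75, 2 / 3, 0.5), sqrt(0.5), tolerance = 1e-12)
  expect_identical(wgm(0, 0.9, 0.5), 0)
  expect_identical(wgm(0.9, 0, 0.5), 0)
  expect_identical(wgm(0.37, 0.9, 1), 0.37)
  expect_identical(wgm(0.9, 0.37, 0), 0.37)
})

test_that("complexity objectives follow their linear formulas", {
  expect_identical(feature_complexity(0, 100), 1)
  expect_identical(feature_complexity(100, 100), 0)
  expect_equal(feature_complexity(9, 13239), 1 - 9 / 13239)
  expect_identical(split_complexity(0), 1)
  expect_identical(split_complexity(256), 0)
  expect_identical(split_complexity(128), 0.5)
  expect_identical(split_complexity(1000), 0)  # floored at 0
})

test_that("overall scores are plain and weighted means of the objectives", {
  obj <- setNames(rep(0.6, 10), objective_names())
  sc <- overall_scores(obj)
  expect_equal(sc$overall, 0.6)
  expect_equal(sc$weighted_overall, 0.6)

  onehot <- setNames(c(1, rep(0, 9)), objective_names())
  expect_equal(overall_scores(onehot)$overall, 0.1)

  w <- rep(0, 10); w[which(objective_names() == "auc")] <- 1
  obj2 <- setNames(seq(0.1, 1, by = 0.1), objective_names())
  expect_equal(overall_scores(obj2, w)$weighted_overall, obj2[["auc"]])

  expect_error(overall_scores(obj, rep(0, 10)), "positive sum")
})

test_that("fold training stops early and retains the best iteration", {
  set.seed(23)
  n <- 80
  y <- sample(0:1, n, replace = TRUE)
  x <- ifelse(y == 1, runif(n, 0.3, 2), runif(n, -2, -0.3))
  X <- cbind(x, rnorm(n))            # separable on feature 1 with a margin
  tr <- 1:60; val <- 61:80
  spec <- structure(list(params = list(eta = 0.3, max_depth = 2, gamma = 0,
                                       min_child_weight = 1, lambda = 1,
                                       alpha = 0, scale_pos_weight = 1),
                         max_rounds = 500L, patience = 50L),
                    class = "eb_model_spec")
  res <- train_fold(X[tr, ], y[tr], X[val, ], y[val], spec)
  expect_lte(res$rounds_trained, res$best_iteration + 50L)
  expect_gte(res$total_splits, 1)
  expect_equal(auc_score(y[val], res$pred_prob), 1, tolerance = 0.05)

  # single-class training split is a degenerate fold
  expect_null(train_fold(X[1:10, ], rep(1L, 10), X[val, ], y[val], spec))

  # a depth-1 model retained for one round has exactly one split
  spec1 <- spec
  spec1$params$max_depth <- 1
  spec1$max_rounds <- 1L; spec1$patience <- 1L
  res1 <- train_fold(X[tr, ], y[tr], X[val, ], y[val], spec1)
  expect_identical(res1$best_iteration, 1L)
  expect_identical(res1$total_splits, 1L)
})

test_that("solution evaluation handles degenerate and informative masks", {
  ds <- small_signal_dataset(n = 60, p = 15, n_inf = 3, effect = 1.5,
                             seed = 31)
  idx <- build_prescreen_index(ds, k_max = 10)
  plan <- make_cv_plan(ds$y, 5, 1, 0)
  ch <- random_chromosome(15, k_max = 10, seed = 32)

  # empty mask: zero classification metrics, maximal simplicity
  empty <- ch; empty$mask <- rep(FALSE, 15)
  sol <- evaluate_solution(empty, ds, idx, plan)
  expect_identical(unname(sol$objectives),
                   c(rep(0, 8), 1, 1))
  expect_true(sol$degenerate)

  # chromosome masking exactly the planted features scores well
  good <- ch; good$mask <- rep(FALSE, 15); good$mask[1:3] <- TRUE
  good$fs_method <- "none"
  sol2 <- evaluate_solution(good, ds, idx, plan)
  expect_gt(sol2$objectives[["auc"]], 0.8)
  expect_identical(sol2$active, 1:3)
  expect_equal(sol2$objectives[["feature_complexity"]], 1 - 3 / 15)

  # determinism under the same plan
  sol3 <- evaluate_solution(good, ds, idx, plan)
  expect_identical(sol3$objectives, sol2$objectives)

  # degenerate flag mirrors single-class pooled predictions
  expect_identical(sol2$degenerate,
                   length(unique(sol2$oof$label)) <= 1L)
})

test_that("planted-signal chromosomes reach high AUC across seeds", {
  hits <- 0L
  for (s in 1:10) {
    ds <- small_signal_dataset(n = 200, p = 30, n_inf = 5, effect = 1.0,
                               seed = 400 + s)
    idx <- build_prescreen_index(ds, k_max = 10)
    plan <- make_cv_plan(ds$y, 10, s, 0)
    ch <- random_chromosome(30, k_max = 10, seed = s)
    ch$mask <- rep(FALSE, 30); ch$mask[1:5] <- TRUE; ch$fs_method <- "none"
    sol <- evaluate_solution(ch, ds, idx, plan)
    if (sol$objectives[["auc"]] > 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("objective vectors stay in [0,1] for random chromosomes", {
  ds <- small_signal_dataset(n = 40, p = 12, n_inf = 2, effect = 1,
                             seed = 41)
  idx <- build_prescreen_index(ds, k_max = 8)
  plan <- make_cv_plan(ds$y, 5, 2, 0)
  pop <- init_population(12, 60, k_max = 8, seed = 42)
  for (ch in pop) {
    sol <- evaluate_solution(ch, ds, idx, plan)
    expect_true(all(sol$objectives >= 0 & sol$objectives <= 1))
    expect_equal(sol$overall, mean(sol$objectives), tolerance = 1e-12)
  }
})
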