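test_that("ANOVA F scores match the one-way oracle and cap degenerate cases", {
  X <- cbind(c(1, 2, 3, 4, 5, 6),       # F computed below
             c(1, 1, 1, 1, 1, 1),       # constant -> 0
             c(0, 0, 0, 1, 1, 1))       # equals y -> sentinel
  y <- c(0, 0, 0, 1, 1, 1)
  f <- score_kbest(X, y)
  expect_equal(f[1], 13.5)              # {1,2,3} vs {4,5,6}, t^2 = 13.5
  expect_equal(f[1], unname(t.test(X[y == 0, 1], X[y == 1, 1],
                                   var.equal = TRUE)$statistic^2))
  expect_identical(f[2], 0)
  expect_identical(f[3], 1e12)

  # feature with identical group distributions -> zero between-group variance
  X2 <- cbind(c(5, 7, 9, 5, 7, 9))
  expect_identical(score_kbest(X2, y), 0)
})

test_that("Wilcoxon rank sums match exact enumeration and are monotone", {
  X <- cbind(c(1, 2, 3, 4))
  y <- c(1, 1, 0, 0)
  res <- score_wilcoxon(X, y)
  expect_equal(res$p_value[1], 1 / 3)   # C(4,2) = 6 assignments, 2 extreme

  # permutation-symmetric input: all values tied -> p = 1
  null <- score_wilcoxon(cbind(rep(2, 8)), rep(c(0, 1), 4))
  expect_equal(null$p_value[1], 1)

  # the positive-group rank sum is monotone in an upward shift, and a
  # fully separating shift attains the minimal achievable p-value
  set.seed(42)
  for (r in 1:5) {
    x <- rnorm(8)
    yv <- rep(c(0, 1), 4)
    w0 <- score_wilcoxon(cbind(x), yv)$statistic
    w1 <- score_wilcoxon(cbind(x + yv * 2), yv)$statistic
    expect_gte(w1, w0)
    p0 <- score_wilcoxon(cbind(x), yv)$p_value
    p_sep <- score_wilcoxon(cbind(x + yv * 100), yv)$p_value
    expect_lte(p_sep, p0 + 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation agrees with wilcox.test", {
  set.seed(7)
  X <- matrix(rnorm(120), 60, 2)
  y <- rep(c(0, 1), 30)
  res <- score_wilcoxon(X, y, exact_limit = 1)   # force the approximation
  for (j in 1:2) {
    ref <- wilcox.test(X[y == 1, j], X[y == 0, j], exact = FALSE,
                       correct = TRUE)$p.value
    expect_equal(res$p_value[j], ref, tolerance = 1e-10)
  }
})

test_that("mutual information matches the plug-in formula", {
  # empirical independence with product-form counts
  a <- rep(c(1, 1, 2, 2), each = 25)
  b <- rep(c(1, 2, 1, 2), each = 25)
  expect_equal(mutual_information(a, b), 0)

  # identical balanced binary variables: MI = entropy = 1 bit
  z <- rep(c(0, 1), 50)
  expect_equal(mutual_information(z, z), 1)

  # joint counts [[30,10],[10,30]]: plug-in value 1 - H(0.25)
  a2 <- rep(c(1, 1, 2, 2), c(30, 10, 10, 30))
  b2 <- rep(c(1, 2, 1, 2), c(30, 10, 10, 30))
  expect_equal(mutual_information(a2, b2), oracle_mi(a2, b2))
  expect_equal(mutual_information(a2, b2), 0.1887219, tolerance = 1e-6)

  # symmetry and non-negativity on random draws
  set.seed(3)
  for (r in 1:20) {
    u <- sample(1:3, 30, replace = TRUE)
    v <- sample(1:4, 30, replace = TRUE)
    expect_equal(mutual_information(u, v), mutual_information(v, u))
    expect_gte(mutual_information(u, v), 0)
  }
})

test_that("JMI greedy selection follows its stated criterion", {
  set.seed(11)
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  strong <- y + sample(0:1, n, TRUE, prob = c(0.8, 0.2))
  weak <- y + sample(0:2, n, TRUE)
  D <- cbind(strong, strong, weak)  # duplicated strong feature

  # k = 1: the single feature with maximal MI(f; y), lowest index on tie
  expect_identical(select_jmi(D, y, 1, disc = structure(D,
    n_levels = apply(D, 2, max)))[1], 1L)

  # the duplicate is not chosen second: its pair with feature 1 adds the
  # same joint information while the weak feature has positive gain
  disc <- discretize_features(D, n_bins = 4)
  sel <- select_jmi(D, y, 2, disc = disc)
  o <- oracle_jmi(apply(disc, 2, identity), y, 2)
  expect_identical(sel, as.integer(o))

  # k = p exhausts all features
  expect_setequal(select_jmi(D, y, 3), 1:3)
})

test_that("mRMR rejects redundant duplicates and matches brute force", {
  set.seed(12)
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  f1 <- y + sample(0:1, n, TRUE, prob = c(0.75, 0.25))
  f2 <- f1                               # exact duplicate of the best pick
  f3 <- y + sample(0:2, n, TRUE)
  f4 <- sample(0:1, n, TRUE)
  D <- cbind(f1, f2, f3, f4)
  disc <- discretize_features(D, n_bins = 4)

  expect_identical(select_mrmr(D, y, 1, disc = disc)[1],
                   select_jmi(D, y, 1, disc = disc)[1])
  sel <- select_mrmr(D, y, 3, disc = disc)
  expect_false(sel[2] == 2L)  # duplicate has criterion <= 0 at step 2
  expect_identical(sel, as.integer(oracle_mrmr(apply(disc, 2, identity), y, 3)))
})

test_that("greedy filters equal exhaustive oracles on random tables", {
  set.seed(99)
  for (r in 1:10) {
    p <- sample(3:6, 1)
    n <- 30
    D <- matrix(sample(0:2, n * p, TRUE), n, p)
    y <- sample(0:1, n, TRUE)
    if (length(unique(y)) < 2) next
    disc <- discretize_features(D)
    k <- sample(1:3, 1)
    expect_identical(select_jmi(D, y, k, disc = disc),
                     as.integer(oracle_jmi(apply(disc, 2, identity), y, k)))
    expect_identical(select_mrmr(D, y, k, disc = disc),
                     as.integer(oracle_mrmr(apply(disc, 2, identity), y, k)))
  }
})

test_that("the prescreen index is complete, deterministic and valid", {
  ds <- small_signal_dataset(n = 50, p = 10, n_inf = 2, seed = 5)
  idx <- build_prescreen_index(ds, k_max = 5)
  expect_length(idx$rankings$jmi, 5L)
  expect_length(idx$rankings$mrmr, 5L)
  expect_length(idx$rankings$kbest, 10L)
  expect_length(idx$rankings$wilcoxon, 10L)
  for (r in idx$rankings) {
    expect_identical(anyDuplicated(r), 0L)
    expect_true(all(r >= 1 & r <= 10))
  }
  idx2 <- build_prescreen_index(ds, k_max = 5)
  expect_identical(idx$rankings, idx2$rankings)
})

test_that("planted signals surface in the F-statistic top ranks", {
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    ds <- small_signal_dataset(n = 80, p = 40, n_inf = 3, effect = 1.0,
                               seed = 1000 + s)
    top5 <- order(-score_kbest(ds$X, ds$y))[1:5]
    if (all(1:3 %in% top5)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("prescreen index survives a JSON round trip", {
  ds <- small_signal_dataset(n = 40, p = 8, seed = 2)
  idx <- build_prescreen_index(ds, k_max = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_prescreen_index(idx, path)
  idx2 <- read_prescreen_index(path, ds)
  expect_identical(idx2$rankings, idx$rankings)
  expect_identical(idx2$k_max, idx$k_max)

  # the cache is keyed to the dataset it was built on
  other <- small_signal_dataset(n = 40, p = 8, seed = 3)
  expect_error(read_prescreen_index(path, other), "different data")
})
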