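test_that("a constant response yields a flagged root-only tree", {
  d <- tibble::tibble(x1 = rnorm(8), y = rep(2.5, 8))
  m <- fit_cart(d, "y")
  expect_true(m$tree$is_leaf)
  expect_true(m$constant_response)
  expect_equal(predict(m, d), rep(2.5, 8))
})

test_that("a noise-free two-class problem is solved by a single split", {
  d <- tibble::tibble(x1 = c(-4, -3, -2, -1, 1, 2, 3, 4),
                      x2 = c(5, 1, 4, 2, 3, 0, 6, 7),
                      y = c(1, 1, 1, 1, 2, 2, 2, 2))
  m <- fit_cart(d, "y")
  expect_false(m$tree$is_leaf)
  expect_identical(m$tree$feature, "x1")
  expect_equal(m$tree$threshold, 0)        # midpoint of -1 and 1
  expect_true(m$tree$left$is_leaf && m$tree$right$is_leaf)
  expect_equal(c(m$tree$left$prediction, m$tree$right$prediction), c(1, 2))
})

test_that("fitted trees match the exhaustive greedy oracle node-for-node", {
  for (case in 1:20) {
    set.seed(500 + case)
    X <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rnorm(12)
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- y
    m <- fit_cart(d, "y")
    o <- naive_cart(X, y)
    expect_same_tree(m$tree, o)
  }
})

test_that("the pruning sequence matches independent weakest-link enumeration", {
  for (case in 1:10) {
    set.seed(900 + case)
    X <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rnorm(12)
    d <- tibble::as_tibble(as.data.frame(X)); d$y <- y
    m <- fit_cart(d, "y")
    o <- naive_prune_sequence(naive_cart(X, y), sum((y - mean(y))^2))
    expect_equal(m$cp_table$cp, o$cp, tolerance = 1e-10)
    expect_equal(m$cp_table$n_leaves, o$n_leaves)
    expect_equal(m$cp_table$rel_error, o$rel_error, tolerance = 1e-10)
  }
})

test_that("tree size is non-increasing in cp and pruning is nested", {
  set.seed(77)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(12 * 5), 12, 5)))
  names(d) <- paste0("f", 1:5); d$y <- rnorm(12)
  m <- fit_cart(d, "y")
  expect_true(all(diff(m$cp_table$n_leaves) <= 0))
  sizes <- vapply(m$cp_table$cp, function(cp) {
    glance(prune_cart(m, cp))$n_leaves
  }, numeric(1))
  expect_equal(sizes, m$cp_table$n_leaves)
})

test_that("in-sample fitted values agree with rpart under matched controls", {
  skip_if_not_installed("rpart")
  for (case in 1:5) {
    set.seed(7000 + case)
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(12 * 4), 12, 4)))
    names(d) <- paste0("f", 1:4); d$y <- rnorm(12)
    m <- fit_cart(d, "y")
    r <- rpart::rpart(y ~ ., d, minsplit = 4, minbucket = 1, cp = 0, xval = 0,
                      maxsurrogate = 0, maxcompete = 0)
    expect_equal(unname(predict(m, d)), unname(predict(r, d)), tolerance = 1e-10)
  }
})

test_that("the 1-SE rule selects as hand-evaluated on constructed CV tables", {
  tab <- tibble::tibble(cp = c(0.01, 0.1, 1.0),
                        xerror = c(0.48, 0.5, 1.0),
                        xstd = c(0.1, 0.1, 0.1))
  expect_equal(select_cp_1se(tab), 0.1)     # 0.5 <= 0.48 + 0.1, 1.0 is not
  expect_equal(select_cp_1se(tab[2, ]), 0.1)
  ties <- tibble::tibble(cp = c(0.01, 0.2, 0.9), xerror = rep(0.7, 3),
                         xstd = rep(0.05, 3))
  expect_equal(select_cp_1se(ties), 0.9)    # ties favour parsimony
})

test_that("cross-validation is seeded, deterministic and 1-SE-consistent", {
  set.seed(31)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(12 * 4), 12, 4)))
  names(d) <- paste0("f", 1:4)
  d$y <- d$f1 * 2 + rnorm(12, sd = 0.3)
  m <- fit_cart(d, "y")
  m1 <- cv_select_cp(d, "y", m, k = 10, seed = 99)
  m2 <- cv_select_cp(d, "y", m, k = 10, seed = 99)
  expect_identical(m1$cv_table, m2$cv_table)
  expect_identical(m1$selected_cp, m2$selected_cp)
  # 1-SE never selects a larger tree than the min-error rule
  n_1se <- m1$cv_table$n_leaves[m1$cv_table$cp == m1$selected_cp]
  n_min <- m1$cv_table$n_leaves[which.min(m1$cv_table$xerror)]
  expect_lte(n_1se, n_min)
  expect_warning(cv_select_cp(d, "y", m, k = 20, seed = 1), "leave-one-out")
})

test_that("prediction routes thresholds right and errors on missing features", {
  d <- tibble::tibble(x1 = c(-4, -3, -2, -1, 1, 2, 3, 4),
                      y = c(1, 1, 1, 1, 2, 2, 2, 2))
  m <- fit_cart(d, "y")
  # a row exactly at the threshold goes right (>=)
  expect_equal(predict(m, tibble::tibble(x1 = m$tree$threshold)), 2)
  expect_equal(predict(m, tibble::tibble(x1 = m$tree$threshold - 1e-9)), 1)
  expect_error(predict(m, tibble::tibble(x2 = 1)), "lacks feature")
  # training rows return their leaf means (here y is fully separated)
  expect_equal(predict(m, d), d$y)
})

test_that("pearson_with_t reproduces the printed worked examples within r rounding", {
  cases <- data.frame(r = c(0.68, 0.6, 0.57, -0.72, 0.64),
                      t_printed = c(2.94, 2.37, 2.2, -3.28, 2.63))
  for (i in seq_len(nrow(cases))) {
    r <- cases$r[i]
    t_lo <- t_from_r(r - 0.005, 12); t_hi <- t_from_r(r + 0.005, 12)
    expect_gte(cases$t_printed[i], min(t_lo, t_hi) - 0.005)
    expect_lte(cases$t_printed[i], max(t_lo, t_hi) + 0.005)
    expect_lt(abs(t_from_r(r, 12) - cases$t_printed[i]), 0.015)
  }
})

test_that("pearson_with_t matches cor.test and handles degenerate inputs", {
  set.seed(61)
  a <- rnorm(12); b <- a + rnorm(12)
  res <- pearson_with_t(a, b)
  ct <- stats::cor.test(a, b)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$t, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$df, 10L)
  # perfect correlation: infinite t, zero p
  perfect <- pearson_with_t(1:10, (1:10) * 2 + 1)
  expect_true(is.infinite(perfect$t) && perfect$t > 0)
  expect_equal(perfect$p, 0)
  expect_warning(deg <- pearson_with_t(rep(1, 10), rnorm(10)), "constant")
  expect_true(deg$degenerate && is.na(deg$r))
})
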