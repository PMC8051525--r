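# Independent brute-force oracles, deliberately coded as plain loops so
# they share no code path with the package implementations.

# -- information transfer ---------------------------------------------------

naive_mean_kappa <- function(signal, delay, fs) {
  dt_ms <- 1000 * delay / fs
  vals <- c()
  for (t in 1:(length(signal) - delay)) {
    dv <- abs(signal[t + delay] - signal[t])
    if (dv != 0) vals <- c(vals, log(dv) / log(dt_ms))
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, n_valid = length(vals))
}

naive_mean_itcr <- function(src, dst, delay, eps = 1e-8) {
  vals <- c()
  excluded <- 0L
  for (t in 1:(length(src) - delay)) {
    d1 <- abs(src[t + delay] - src[t])
    d2 <- abs(dst[t + delay] - dst[t])
    if (d1 == 0 || d2 == 0 || abs(log(d2)) < eps) {
      excluded <- excluded + 1L
    } else {
      vals <- c(vals, log(d1) / log(d2))
    }
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       n_valid = length(vals), excluded = excluded)
}

# -- DFA --------------------------------------------------------------------

# classic DFA fluctuation at one scale, q = 2, polynomial detrend via lm()
naive_dfa_f2 <- function(signal, s, m = 1) {
  Y <- cumsum(signal - mean(signal))
  N <- length(Y)
  Ns <- floor(N / s)
  f2 <- c()
  for (v in 1:Ns) {
    seg <- Y[((v - 1) * s + 1):(v * s)]
    tt <- 1:s
    f2 <- c(f2, mean(stats::lm(seg ~ stats::poly(tt, m, raw = TRUE))$residuals^2))
  }
  for (v in 1:Ns) {
    seg <- Y[(N - v * s + 1):(N - (v - 1) * s)]
    tt <- 1:s
    f2 <- c(f2, mean(stats::lm(seg ~ stats::poly(tt, m, raw = TRUE))$residuals^2))
  }
  sqrt(mean(f2))
}

# -- CART -------------------------------------------------------------------

# exhaustive greedy split search: every feature, every midpoint, explicit sums
naive_cart <- function(X, y, minsplit = 4, minbucket = 1) {
  grow <- function(rows) {
    yy <- y[rows]
    rss <- sum((yy - mean(yy))^2)
    leaf <- list(is_leaf = TRUE, prediction = mean(yy), n = length(rows), rss = rss)
    if (length(rows) < minsplit || rss == 0) return(leaf)
    best_gain <- 0; best <- NULL
    for (j in seq_len(ncol(X))) {
      vals <- sort(unique(X[rows, j]))
      if (length(vals) < 2) next
      for (v in seq_len(length(vals) - 1)) {
        thr <- (vals[v] + vals[v + 1]) / 2
        left <- rows[X[rows, j] < thr]
        right <- rows[X[rows, j] >= thr]
        if (length(left) < minbucket || length(right) < minbucket) next
        ssl <- sum((y[left] - mean(y[left]))^2)
        ssr <- sum((y[right] - mean(y[right]))^2)
        gain <- rss - ssl - ssr
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best <- list(j = j, thr = thr, left = left, right = right)
        }
      }
    }
    if (is.null(best)) return(leaf)
    list(is_leaf = FALSE, feature = colnames(X)[best$j], threshold = best$thr,
         n = length(rows), prediction = mean(yy), rss = rss,
         left = grow(best$left), right = grow(best$right))
  }
  grow(seq_along(y))
}

naive_leaves <- function(node) if (node$is_leaf) 1 else naive_leaves(node$left) + naive_leaves(node$right)
naive_leaf_rss <- function(node) if (node$is_leaf) node$rss else naive_leaf_rss(node$left) + naive_leaf_rss(node$right)

# weakest-link pruning sequence by explicit enumeration of internal nodes
naive_prune_sequence <- function(tree, ss0) {
  links <- function(node, path = integer(0)) {
    if (node$is_leaf) return(list())
    g <- (node$rss - naive_leaf_rss(node)) / (naive_leaves(node) - 1)
    c(list(list(g = g, path = path)),
      links(node$left, c(path, 1L)), links(node$right, c(path, 2L)))
  }
  cut_at <- function(node, path) {
    if (!length(path)) {
      return(list(is_leaf = TRUE, prediction = node$prediction, n = node$n, rss = node$rss))
    }
    if (path[1] == 1L) node$left <- cut_at(node$left, path[-1])
    else node$right <- cut_at(node$right, path[-1])
    node
  }
  seqs <- data.frame(cp = 0, n_leaves = naive_leaves(tree),
                     rel_error = if (ss0 > 0) naive_leaf_rss(tree) / ss0 else 0)
  while (!tree$is_leaf) {
    ls <- links(tree)
    gs <- vapply(ls, function(l) l$g, numeric(1))
    alpha <- min(gs)
    repeat {
      ls <- links(tree)
      if (!length(ls)) break
      gs <- vapply(ls, function(l) l$g, numeric(1))
      i <- which.min(gs)
      if (gs[i] > alpha + 1e-9 * max(1, alpha)) break
      tree <- cut_at(tree, ls[[i]]$path)
    }
    seqs <- rbind(seqs, data.frame(cp = if (ss0 > 0) alpha / ss0 else 0,
                                   n_leaves = naive_leaves(tree),
                                   rel_error = if (ss0 > 0) naive_leaf_rss(tree) / ss0 else 0))
  }
  seqs[order(seqs$cp, -seqs$n_leaves), ]
}

# node-for-node structural comparison of a cart_model tree vs a naive tree
expect_same_tree <- function(fitted, oracle, tol = 1e-8) {
  walk <- function(a, b, where) {
    expect_identical(a$is_leaf, b$is_leaf,
                     info = paste("leaf/split mismatch at", where))
    expect_equal(a$prediction, b$prediction, tolerance = tol,
                 info = paste("prediction at", where))
    expect_identical(a$n, as.integer(b$n), info = paste("n at", where))
    if (!a$is_leaf && !b$is_leaf) {
      expect_identical(a$feature, b$feature, info = paste("feature at", where))
      expect_equal(a$threshold, b$threshold, tolerance = tol,
                   info = paste("threshold at", where))
      walk(a$left, b$left, paste0(where, "L"))
      walk(a$right, b$right, paste0(where, "R"))
    }
  }
  walk(fitted, oracle, "root")
}

# -- shared fixtures --------------------------------------------------------

make_test_cohort <- function(seed = 11, n_subjects = 12, duration = 240) {
  drv <- tibble::tibble(subscore = "TPM", lead = "5", band = "alpha", effect = 3)
  spec <- cohort_spec(n_subjects = n_subjects, n_leads = 10, fs = 250,
                      duration = duration, drivers = drv,
                      score_noise_sd = 0.1, seed = seed)
  gen_cohort(spec)
}
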