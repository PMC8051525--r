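#' Fit a CART regression tree
#'
#' Greedy binary recursive partitioning by variance reduction: each node
#' is split on the (feature, threshold) pair that maximally reduces the
#' total within-node sum of squares, provided the node holds at least
#' `minsplit` rows, both children hold at least `minbucket`, and the best
#' split strictly reduces the sum of squares.  Candidate thresholds are
#' midpoints of adjacent distinct feature values; rows with
#' `x < threshold` go left, `x >= threshold` go right; ties between splits
#' are broken by lower feature index, then lower threshold.  Leaf
#' predictions are training-subset means.
#'
#' The full weakest-link cost-complexity pruning sequence is computed at
#' fit time: repeatedly collapsing the internal node with the smallest
#' per-leaf error increase `g(t) = (R(t) - R(T_t)) / (|T_t| - 1)` yields a
#' nested subtree family indexed by the complexity parameter
#' `cp = alpha / SS0` (error increase relative to the root sum of
#' squares), recorded in `cp_table`.
#'
#' The study default `minsplit = 4` with `minbucket = 1` reflects the
#' small-cohort regime (n = 12 subjects): any stricter leaf floor would
#' forbid splitting entirely.
#'
#' @param data data frame of numeric feature columns plus the response.
#' @param response name of the response column in `data`.
#' @param features feature column names; defaults to every other numeric
#'   column.
#' @param minsplit minimum rows a node must hold to be considered for
#'   splitting.
#' @param minbucket minimum rows per child.
#' @return An object of class `cart_model`.
#' @examples
#' d <- tibble::tibble(x1 = c(-4, -3, -2, -1, 1, 2, 3, 4),
#'                     y  = c(1, 1, 1, 1, 2, 2, 2, 2))
#' fit_cart(d, "y")
#' @export
fit_cart <- function(data, response, features = NULL,
                     minsplit = 4L, minbucket = 1L) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("response column not found: ", response, call. = FALSE)
  if (is.null(features)) {
    features <- setdiff(names(data), c(response, "subject_id"))
    features <- features[vapply(data[features], is.numeric, logical(1))]
  }
  if (!length(features)) stop("no feature columns", call. = FALSE)
  X <- as.matrix(data[features])
  y <- data[[response]]
  if (anyNA(X) || anyNA(y)) stop("missing values: impute before fitting", call. = FALSE)
  if (nrow(X) < 1L) stop("empty training table", call. = FALSE)

  node_rss <- function(yy) sum((yy - mean(yy))^2)

  grow <- function(idx) {
    yy <- y[idx]
    node <- list(n = length(idx), prediction = mean(yy), rss = node_rss(yy),
                 is_leaf = TRUE)
    if (length(idx) < minsplit || node$rss <= 0) return(node)
    best <- list(gain = 0, j = NA_integer_, thr = NA_real_)
    for (j in seq_along(features)) {
      xo <- X[idx, j]
      o <- order(xo)
      xs <- xo[o]; ys <- yy[o]
      n <- length(ys)
      cy <- cumsum(ys); cy2 <- cumsum(ys^2)
      Ty <- cy[n]; Ty2 <- cy2[n]
      for (i in seq_len(n - 1L)) {
        if (xs[i + 1L] <= xs[i]) next                  # no boundary between ties
        if (i < minbucket || n - i < minbucket) next
        ssl <- cy2[i] - cy[i]^2 / i
        ssr <- (Ty2 - cy2[i]) - (Ty - cy[i])^2 / (n - i)
        gain <- node$rss - ssl - ssr
        if (gain > best$gain + 1e-12) {
          best <- list(gain = gain, j = j, thr = (xs[i] + xs[i + 1L]) / 2)
        }
      }
    }
    if (is.na(best$j)) return(node)
    go_left <- X[idx, best$j] < best$thr
    node$is_leaf <- FALSE
    node$feature <- features[best$j]
    node$threshold <- best$thr
    node$left <- grow(idx[go_left])
    node$right <- grow(idx[!go_left])
    node
  }

  tree <- grow(seq_along(y))
  ss0 <- node_rss(y)
  structure(
    list(tree = tree, features = features, response = response,
         minsplit = as.integer(minsplit), minbucket = as.integer(minbucket),
         n = length(y), ss0 = ss0,
         cp_table = prune_sequence(tree, ss0),
         constant_response = ss0 <= 0),
    class = "cart_model"
  )
}

n_tree_leaves <- function(node) {
  if (node$is_leaf) 1L else n_tree_leaves(node$left) + n_tree_leaves(node$right)
}

tree_leaf_rss <- function(node) {
  if (node$is_leaf) node$rss else tree_leaf_rss(node$left) + tree_leaf_rss(node$right)
}

# weakest internal link: smallest g(t) = (R(t) - R(T_t)) / (leaves - 1)
weakest_link <- function(node) {
  if (node$is_leaf) return(list(g = Inf))
  here <- list(g = (node$rss - tree_leaf_rss(node)) / (n_tree_leaves(node) - 1L),
               path = integer(0))
  for (side in c(1L, 2L)) {
    child <- if (side == 1L) node$left else node$right
    wl <- weakest_link(child)
    if (wl$g < here$g - 1e-12) here <- list(g = wl$g, path = c(side, wl$path))
  }
  here
}

collapse_at <- function(node, path) {
  if (length(path) == 0L) {
    return(list(n = node$n, prediction = node$prediction, rss = node$rss,
                is_leaf = TRUE))
  }
  if (path[1] == 1L) node$left <- collapse_at(node$left, path[-1])
  else node$right <- collapse_at(node$right, path[-1])
  node
}

# nested subtree sequence by weakest-link pruning; cp = alpha / ss0
prune_sequence <- function(tree, ss0) {
  rows <- list(tibble::tibble(cp = 0, n_leaves = n_tree_leaves(tree),
                              rel_error = if (ss0 > 0) tree_leaf_rss(tree) / ss0 else 0))
  while (!tree$is_leaf) {
    wl <- weakest_link(tree)
    alpha <- wl$g
    # collapse every current weakest link at this alpha
    while (!tree$is_leaf) {
      wl2 <- weakest_link(tree)
      if (wl2$g > alpha + 1e-9 * max(1, alpha)) break
      tree <- collapse_at(tree, wl2$path)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cp = if (ss0 > 0) alpha / ss0 else 0,
      n_leaves = n_tree_leaves(tree),
      rel_error = if (ss0 > 0) tree_leaf_rss(tree) / ss0 else 0
    )
  }
  tab <- dplyr::bind_rows(rows)
  tab[order(tab$cp, -tab$n_leaves), , drop = FALSE]
}

#' Prune a fitted tree at a complexity parameter
#'
#' Collapses internal nodes by weakest-link order until every remaining
#' internal node's per-leaf error increase exceeds `cp * SS0`, yielding
#' the cost-complexity-optimal subtree at that `cp`.
#'
#' @param model a [fit_cart()] model.
#' @param cp complexity parameter (error increase relative to the root sum
#'   of squares).
#' @return A `cart_model` with the pruned tree (cp stored in
#'   `$pruned_at`).
#' @export
prune_cart <- function(model, cp) {
  stopifnot(inherits(model, "cart_model"))
  alpha <- cp * model$ss0
  tree <- model$tree
  while (!tree$is_leaf) {
    wl <- weakest_link(tree)
    if (wl$g > alpha + 1e-12) break
    tree <- collapse_at(tree, wl$path)
  }
  model$tree <- tree
  model$pruned_at <- cp
  model
}

#' Cross-validated complexity selection (1-SE rule)
#'
#' Seeded k-fold cross-validation over the master model's pruning
#' sequence: folds are a uniform random partition into `k` near-equal
#' groups; each fold's model is grown on the remaining rows, pruned at the
#' geometric mean of adjacent master-sequence cp values, and scored on the
#' held-out rows.  Cross-validated error is reported relative to the root
#' sum of squares, with a standard error from the per-observation squared
#' prediction errors.  The selected cp is the largest (smallest tree)
#' whose CV error is within one standard error of the minimum — the
#' classical 1-SE parsimony rule.
#'
#' @inheritParams fit_cart
#' @param model the master [fit_cart()] model fitted to `data`.
#' @param k number of folds (default 10); if `n < k`, reduced to
#'   leave-one-out with a warning.
#' @param seed integer seed for the fold assignment (required: the fold
#'   split is the only source of randomness in the pipeline).
#' @return The model with `cv_table` (cp, n_leaves, rel_error, xerror,
#'   xstd) and `selected_cp` filled in.
#' @export
cv_select_cp <- function(data, response, model, k = 10L, seed,
                         features = NULL) {
  stopifnot(inherits(model, "cart_model"))
  if (missing(seed)) stop("`seed` is required for reproducible folds", call. = FALSE)
  data <- as.data.frame(data)
  n <- nrow(data)
  y <- data[[response]]
  if (n < k) {
    warning(sprintf("n = %d < k = %d folds; using leave-one-out", n, k))
    k <- n
  }
  cps <- model$cp_table$cp
  # evaluation points: geometric means of adjacent cp values (rpart style)
  eval_cp <- if (length(cps) > 1L) {
    c(sqrt(cps[-length(cps)] * cps[-1]), cps[length(cps)])
  } else cps
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  pred <- matrix(NA_real_, nrow = n, ncol = length(eval_cp))
  for (f in seq_len(k)) {
    hold <- fold == f
    fit_f <- fit_cart(data[!hold, , drop = FALSE], response,
                      features = model$features,
                      minsplit = model$minsplit, minbucket = model$minbucket)
    for (j in seq_along(eval_cp)) {
      pf <- prune_cart(fit_f, eval_cp[j])
      pred[hold, j] <- predict(pf, data[hold, , drop = FALSE])
    }
  }
  ss0 <- model$ss0
  if (ss0 <= 0) {
    model$cv_table <- dplyr::mutate(model$cp_table, xerror = 0, xstd = 0)
    model$selected_cp <- max(cps)
    return(model)
  }
  xerror <- colSums((pred - y)^2) / ss0
  xstd <- apply((pred - y)^2, 2, function(e) stats::sd(e) * sqrt(n)) / ss0
  model$cv_table <- dplyr::mutate(model$cp_table, xerror = xerror, xstd = xstd)
  model$selected_cp <- select_cp_1se(model$cv_table)
  model
}

#' @rdname cv_select_cp
#' @param cv_table a table with columns `cp`, `xerror`, `xstd`.
#' @return `select_cp_1se()`: the largest cp whose `xerror` does not
#'   exceed `min(xerror) + xstd[argmin]`.
#' @export
select_cp_1se <- function(cv_table) {
  stopifnot(all(c("cp", "xerror", "xstd") %in% names(cv_table)))
  i_min <- which.min(cv_table$xerror)
  thr <- cv_table$xerror[i_min] + cv_table$xstd[i_min]
  max(cv_table$cp[cv_table$xerror <= thr + 1e-12])
}

#' @export
predict.cart_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  used <- tree_features(object$tree)
  missing_f <- setdiff(used, names(newdata))
  if (length(missing_f)) {
    stop("test table lacks feature(s) used by the tree: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  route <- function(node, row) {
    while (!node$is_leaf) {
      node <- if (row[[node$feature]] < node$threshold) node$left else node$right
    }
    node$prediction
  }
  vapply(seq_len(nrow(newdata)), function(i) route(object$tree, newdata[i, , drop = FALSE]),
         numeric(1))
}

tree_features <- function(node) {
  if (node$is_leaf) return(character(0))
  unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

#' @export
print.cart_model <- function(x, ...) {
  cat(sprintf("<cart_model> n = %d, %d leaves (minsplit %d, minbucket %d)%s\n",
              x$n, n_tree_leaves(x$tree), x$minsplit, x$minbucket,
              if (!is.null(x$pruned_at)) sprintf(", pruned at cp = %.4g", x$pruned_at) else ""))
  dump_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%s* leaf: mean = %.4g (n = %d)\n", pad, node$prediction, node$n))
    } else {
      cat(sprintf("%s%s < %.6g ? (n = %d)\n", pad, node$feature, node$threshold, node$n))
      dump_node(node$left, indent + 1L)
      dump_node(node$right, indent + 1L)
    }
  }
  dump_node(x$tree, 1L)
  invisible(x)
}

#' @describeIn fit_cart one row per node: depth, type, feature, threshold,
#'   n, prediction, rss.
#' @param x a `cart_model`.
#' @param ... unused.
#' @export
tidy.cart_model <- function(x, ...) {
  rows <- list()
  walk <- function(node, depth, id) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      node = id, depth = depth,
      type = if (node$is_leaf) "leaf" else "split",
      feature = if (node$is_leaf) NA_character_ else node$feature,
      threshold = if (node$is_leaf) NA_real_ else node$threshold,
      n = node$n, prediction = node$prediction, rss = node$rss
    )
    if (!node$is_leaf) {
      walk(node$left, depth + 1L, paste0(id, "L"))
      walk(node$right, depth + 1L, paste0(id, "R"))
    }
  }
  walk(x$tree, 0L, "0")
  dplyr::bind_rows(rows)
}

#' @describeIn fit_cart one-row model summary (n, leaves, relative error,
#'   selected cp when CV has run).
#' @export
glance.cart_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_leaves = n_tree_leaves(x$tree),
    rel_error = if (x$ss0 > 0) tree_leaf_rss(x$tree) / x$ss0 else 0,
    selected_cp = if (is.null(x$selected_cp)) NA_real_ else x$selected_cp,
    constant_response = x$constant_response
  )
}
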