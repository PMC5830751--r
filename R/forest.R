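#' Hyperparameters of the randomized-split forest
#'
#' Defaults follow the embedded classifier under study: a resampling bagging
#' ensemble of eight trees, 128 random split candidates per node and a
#' minimum of one sample per leaf.
#'
#' @param n_trees Number of trees (>= 1).
#' @param n_random_splits Random (feature, threshold) candidates scored at
#'   every internal node (>= 1).
#' @param min_samples_per_leaf Minimum training samples a child may hold.
#' @param bagging Draw a bootstrap sample (size n, with replacement) per
#'   tree? With `FALSE` every tree sees the full training set.
#' @param seed Integer seed driving bootstrap draws and candidate sampling.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 8L, n_random_splits = 128L,
                          min_samples_per_leaf = 1L, bagging = TRUE,
                          seed = 1L) {
  stopifnot(n_trees >= 1, n_random_splits >= 1, min_samples_per_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 n_random_splits = as.integer(n_random_splits),
                 min_samples_per_leaf = as.integer(min_samples_per_leaf),
                 bagging = isTRUE(bagging), seed = as.integer(seed)),
            class = "forest_config")
}

#' Stratified train/test split of a feature table
#'
#' Rows are partitioned class-by-class so the behaviour proportions of the
#' full table are preserved (within one window) in both parts; the split is
#' disjoint, exhaustive and reproducible by seed.
#'
#' @param features Feature table from [feature_table()] (needs a `label`
#'   column).
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @param classes Class labels that must each have at least one row.
#' @return List with data frames `train` and `test`.
#' @export
split_train_test <- function(features, train_fraction = 0.7, seed = 1L,
                             classes = SHEEP_BEHAVIOURS) {
  stopifnot(is.data.frame(features), "label" %in% names(features),
            train_fraction > 0, train_fraction < 1)
  missing <- setdiff(classes, unique(features$label))
  if (length(missing) > 0)
    stop("cannot stratify: no windows for class(es) ",
         paste(missing, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in classes) {
    rows <- which(features$label == cl)
    n_tr <- round(train_fraction * length(rows))
    n_tr <- max(1L, min(length(rows) - 1L, n_tr))
    train_idx <- c(train_idx, sample(rows, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = features[train_idx, , drop = FALSE],
       test = features[setdiff(seq_len(nrow(features)), train_idx), , drop = FALSE])
}

gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Grow one tree on x[idx, ]. Nodes are appended to parallel vectors inside
# `env`: feature/threshold/left/right (0 = leaf) and a class-probability row.
grow_node <- function(x, y, idx, env, cfg, k) {
  node <- env$n_nodes + 1L
  env$n_nodes <- node
  counts <- tabulate(y[idx], nbins = k)
  env$probs[node, ] <- counts / length(idx)
  env$feature[node] <- 0L
  env$threshold[node] <- NA_real_
  env$left[node] <- 0L
  env$right[node] <- 0L
  if (sum(counts > 0) <= 1L) return(node)          # pure node
  xs <- x[idx, , drop = FALSE]
  feats <- sample.int(ncol(x), cfg$n_random_splits, replace = TRUE)
  lo <- apply(xs, 2, min)[feats]
  hi <- apply(xs, 2, max)[feats]
  ok <- hi > lo
  if (!any(ok)) return(node)                       # range-degenerate node
  thr <- lo + stats::runif(cfg$n_random_splits) * (hi - lo)
  # score all candidates at once: class counts left of each threshold
  cmp <- xs[, feats, drop = FALSE] < rep(thr, each = nrow(xs))
  n_left <- colSums(cmp)
  ok <- ok & n_left >= cfg$min_samples_per_leaf &
    (length(idx) - n_left) >= cfg$min_samples_per_leaf
  if (!any(ok)) return(node)
  left_counts <- matrix(0, k, cfg$n_random_splits)
  for (c in seq_len(k))
    left_counts[c, ] <- colSums(cmp[y[idx] == c, , drop = FALSE])
  n <- length(idx)
  g_parent <- gini(counts)
  g_left <- 1 - colSums((left_counts / rep(pmax(n_left, 1L), each = k))^2)
  right_counts <- counts - left_counts
  n_right <- n - n_left
  g_right <- 1 - colSums((right_counts / rep(pmax(n_right, 1L), each = k))^2)
  decrease <- g_parent - (n_left / n) * g_left - (n_right / n) * g_right
  decrease[!ok] <- -Inf
  best <- which.max(decrease)                      # ties: first candidate wins
  if (!is.finite(decrease[best])) return(node)
  go_left <- cmp[, best]
  env$feature[node] <- feats[best]
  env$threshold[node] <- thr[best]
  env$split_decrease[node] <- decrease[best]
  env$left[node] <- grow_node(x, y, idx[go_left], env, cfg, k)
  env$right[node] <- grow_node(x, y, idx[!go_left], env, cfg, k)
  node
}

grow_tree <- function(x, y, idx, cfg, k) {
  env <- new.env()
  n_cap <- 2L * length(idx) + 1L
  env$n_nodes <- 0L
  env$feature <- integer(n_cap)
  env$threshold <- rep(NA_real_, n_cap)
  env$left <- integer(n_cap)
  env$right <- integer(n_cap)
  env$split_decrease <- rep(NA_real_, n_cap)
  env$probs <- matrix(NA_real_, n_cap, k)
  grow_node(x, y, idx, env, cfg, k)
  nn <- env$n_nodes
  list(feature = env$feature[seq_len(nn)], threshold = env$threshold[seq_len(nn)],
       left = env$left[seq_len(nn)], right = env$right[seq_len(nn)],
       split_decrease = env$split_decrease[seq_len(nn)],
       probs = env$probs[seq_len(nn), , drop = FALSE])
}

#' Train a bagged ensemble of randomized decision trees
#'
#' Each tree is grown on a bootstrap sample of the training windows (when
#' bagging is enabled). At every node, `n_random_splits` candidate splits
#' are drawn — a feature uniformly among the 44 and a threshold uniformly
#' over that feature's range at the node — and the candidate with the
#' largest Gini impurity decrease is kept. Growth stops when a node is pure,
#' when every candidate feature is range-degenerate, or when no candidate
#' leaves both children with at least `min_samples_per_leaf` samples.
#' Leaves store training class frequencies.
#'
#' @param train Feature table with a `label` column (from
#'   [split_train_test()]).
#' @param config A [forest_config()].
#' @param classes Fixed class order used for probabilities and tie-breaks.
#' @return A `forest_model`.
#' @export
train_forest <- function(train, config = forest_config(),
                         classes = SHEEP_BEHAVIOURS) {
  stopifnot(is.data.frame(train), nrow(train) > 0, "label" %in% names(train))
  feat_cols <- intersect(feature_names(), names(train))
  if (length(feat_cols) == 0)
    feat_cols <- names(train)[vapply(train, is.numeric, logical(1)) &
                              !names(train) %in% c("fs", "window_s", "start_sample")]
  x <- as.matrix(train[, feat_cols, drop = FALSE])
  y <- as.integer(factor(train$label, levels = classes))
  if (anyNA(y)) stop("training labels outside the class set")
  if (length(unique(y)) < 2)
    warning("single-class training set: model will be a constant predictor")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  k <- length(classes)
  trees <- vector("list", config$n_trees)
  bag <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    idx <- if (config$bagging)
      sample.int(nrow(x), nrow(x), replace = TRUE) else seq_len(nrow(x))
    bag[[i]] <- idx
    trees[[i]] <- grow_tree(x, y, idx, config, k)
  }
  structure(list(trees = trees, classes = classes, features = feat_cols,
                 config = config, bag_indices = bag),
            class = "forest_model")
}

route_tree <- function(tree, x) {
  node <- rep(1L, nrow(x))
  repeat {
    f <- tree$feature[node]
    active <- f > 0L
    if (!any(active)) break
    ai <- which(active)
    goes_left <- x[cbind(ai, f[ai])] < tree$threshold[node[ai]]
    node[ai] <- ifelse(goes_left, tree$left[node[ai]], tree$right[node[ai]])
  }
  node
}

#' Predict behaviours with a trained forest
#'
#' The class-probability vector of a window is the mean of the leaf class
#' frequencies over all trees; the label is its argmax, with ties broken by
#' the fixed class order.
#'
#' @param object A `forest_model`.
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return List with `label` (character) and `prob` (matrix, one row per
#'   window, columns in class order).
#' @export
predict.forest_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0)
    stop("newdata is missing feature(s): ", paste(missing[1:min(3, length(missing))],
                                                  collapse = ", "))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  k <- length(object$classes)
  prob <- matrix(0, nrow(x), k)
  for (tree in object$trees)
    prob <- prob + tree$probs[route_tree(tree, x), , drop = FALSE]
  prob <- prob / length(object$trees)
  colnames(prob) <- object$classes
  label <- object$classes[max.col(prob, ties.method = "first")]
  list(label = label, prob = prob)
}

#' Serialize a forest model to JSON
#'
#' Versioned plain-text serialization (trees, thresholds, class order,
#' config) for inspection and exact reload with [load_forest()].
#'
#' @param model A `forest_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_forest <- function(model, path) {
  payload <- list(
    format = "oviclass-forest", version = 1L,
    classes = model$classes, features = model$features,
    config = unclass(model$config),
    trees = lapply(model$trees, function(tr)
      list(feature = tr$feature, threshold = tr$threshold, left = tr$left,
           right = tr$right, split_decrease = tr$split_decrease,
           probs = tr$probs)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a forest model saved by [save_forest()]
#' @param path JSON file path.
#' @return A `forest_model` (without bootstrap indices).
#' @export
load_forest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "oviclass-forest"))
    stop("not an oviclass forest model file")
  trees <- lapply(seq_len(nrow_or_len(payload$trees)), function(i) {
    tr <- if (is.data.frame(payload$trees)) lapply(payload$trees, `[[`, i)
          else payload$trees[[i]]
    tr$feature <- as.integer(tr$feature)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    tr$probs <- if (is.matrix(tr$probs)) tr$probs
                else do.call(rbind, lapply(tr$probs, as.numeric))
    tr
  })
  cfg <- do.call(forest_config, payload$config[c("n_trees", "n_random_splits",
                                                 "min_samples_per_leaf",
                                                 "bagging", "seed")])
  structure(list(trees = trees, classes = payload$classes,
                 features = payload$features, config = cfg),
            class = "forest_model")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
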