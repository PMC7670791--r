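#' Stratified 60/20/20 data split
#'
#' Randomly partitions a labeled table into training (60%), validation (20%)
#' and test (20%) subsets, stratified by class (per-class proportions are
#' preserved within rounding). Deterministic given `seed`.
#'
#' @param data Data frame with a class column.
#' @param seed Integer seed.
#' @param class Name of the class column.
#' @param prop Length-3 vector of proportions summing to 1.
#' @return Object of class `split3`: list with `train`, `validation`, `test`
#'   data frames and `seed`.
#' @export
#' @examples
#' d <- data.frame(class = factor(rep(c("a", "b"), each = 10)), x = 1:20)
#' s <- split_data(d, seed = 1)
#' nrow(s$train)
split_data <- function(data, seed = 1, class = "class",
                       prop = c(0.6, 0.2, 0.2)) {
  stopifnot(length(prop) == 3, abs(sum(prop) - 1) < 1e-9)
  y <- data[[class]]
  if (is.null(y)) stop(sprintf("no '%s' column in table", class))
  counts <- table(y)
  small <- names(counts)[counts < 5]
  if (length(small))
    stop(sprintf("class(es) too small to stratify (need >= 5 samples): %s",
                 paste(small, collapse = ", ")))
  with_seed(seed, function() {
    tr <- va <- te <- integer(0)
    for (l in unique(as.character(y))) {
      idx <- sample(which(y == l))
      n <- length(idx)
      n_tr <- round(prop[1] * n)
      n_va <- round(prop[2] * n)
      tr <- c(tr, idx[seq_len(n_tr)])
      va <- c(va, idx[n_tr + seq_len(n_va)])
      te <- c(te, idx[n_tr + n_va + seq_len(n - n_tr - n_va)])
    }
    structure(list(train = data[sort(tr), , drop = FALSE],
                   validation = data[sort(va), , drop = FALSE],
                   test = data[sort(te), , drop = FALSE],
                   seed = as.integer(seed)),
              class = "split3")
  })
}

#' @export
print.split3 <- function(x, ...) {
  cat(sprintf("<split3> train %d / validation %d / test %d (seed %d)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test), x$seed))
  invisible(x)
}

#' Information gain and gain ratio of a binary threshold split
#'
#' Entropies are in bits. `gain_ratio = info_gain / split_info`, defined as
#' 0 when the split information is 0.
#'
#' @param x Numeric attribute values.
#' @param y Class labels.
#' @param threshold Split point; left branch is `x <= threshold`.
#' @return List with `info_gain`, `split_info`, `gain_ratio`.
#' @export
#' @examples
#' gain_ratio(1:4, c("A", "A", "B", "B"), 2.5)
gain_ratio <- function(x, y, threshold) {
  y <- factor(y)
  left <- x <= threshold
  n <- length(y); nl <- sum(left); nr <- n - nl
  h <- entropy_bits(table(y))
  hl <- if (nl) entropy_bits(table(y[left])) else 0
  hr <- if (nr) entropy_bits(table(y[!left])) else 0
  ig <- h - (nl / n) * hl - (nr / n) * hr
  si <- entropy_bits(c(nl, nr))
  list(info_gain = ig, split_info = si,
       gain_ratio = if (si > 0) ig / si else 0)
}

#' Tree-growing control parameters
#'
#' @param min_leaf Minimum samples in each child of a split.
#' @param cf Confidence factor for C4.5 pessimistic pruning (`j48` only).
#'   `NA` selects the best of `cf_grid` by validation-set accuracy when a
#'   validation set is supplied.
#' @param cf_grid Candidate confidence factors tried when `cf = NA`.
#' @param stall Unused placeholder kept for config serialization.
#' @return A list of class `tree_control`.
#' @export
tree_control <- function(min_leaf = 2, cf = 0.25,
                         cf_grid = c(0.1, 0.25, 0.5), stall = NULL) {
  structure(list(min_leaf = min_leaf, cf = cf, cf_grid = cf_grid),
            class = "tree_control")
}

# --- internal growing machinery ------------------------------------------

# best (threshold, info_gain, gain_ratio) for one feature; candidates are
# midpoints between consecutive distinct sorted values with both children
# >= min_leaf; returns NULL if no candidate has positive info gain
#' @noRd
best_split_feature <- function(x, yi, C, min_leaf, criterion) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]; ys <- yi[o]
  cum <- matrix(0, n, C)
  cum[cbind(seq_len(n), ys)] <- 1
  cum <- apply(cum, 2, cumsum)
  cut_at <- which(xs[-n] < xs[-1])           # split after position i
  cut_at <- cut_at[cut_at >= min_leaf & (n - cut_at) >= min_leaf]
  if (!length(cut_at)) return(NULL)
  nl <- cut_at; nr <- n - cut_at
  lc <- cum[cut_at, , drop = FALSE]
  rc <- matrix(cum[n, ], length(cut_at), C, byrow = TRUE) - lc
  ent <- function(m, tot) {
    p <- m / tot
    rowSums(ifelse(p > 0, -p * log2(p), 0))
  }
  h <- entropy_bits(cum[n, ])
  ig <- h - (nl / n) * ent(lc, nl) - (nr / n) * ent(rc, nr)
  pos <- ig > 1e-12
  if (!any(pos)) return(NULL)
  pl <- nl / n
  si <- ifelse(pl > 0 & pl < 1, -pl * log2(pl) - (1 - pl) * log2(1 - pl), 0)
  gr <- ifelse(si > 0, ig / si, 0)
  score <- if (criterion == "gainratio") {
    # C4.5 guard: compare gain ratios only among splits with at least
    # average information gain, else tiny splits win on a small split_info
    avg <- mean(ig[pos])
    ifelse(pos & ig >= avg - 1e-12, gr, -Inf)
  } else ifelse(pos, ig, -Inf)
  k <- which.max(score)  # ties: lower threshold (sorted order) wins
  list(threshold = unname((xs[cut_at[k]] + xs[cut_at[k] + 1]) / 2),
       info_gain = ig[k], score = score[k])
}

#' @noRd
make_leaf <- function(counts) {
  cls <- names(counts)[which.max(counts)]   # ties: canonical class order
  list(type = "leaf", class = cls, counts = counts)
}

#' @noRd
grow_tree <- function(X, yi, classes, min_leaf, criterion, k_features = NULL) {
  C <- length(classes)
  counts <- stats::setNames(tabulate(yi, C), classes)
  if (sum(counts > 0) <= 1 || sum(counts) < 2 * min_leaf)
    return(make_leaf(counts))
  feats <- seq_len(ncol(X))
  if (!is.null(k_features) && k_features < length(feats))
    feats <- sort(sample(feats, k_features))
  best <- NULL; best_f <- NA_integer_
  for (f in feats) {
    cand <- best_split_feature(X[, f], yi, C, min_leaf, criterion)
    if (is.null(cand)) next
    # strict improvement required: iterating in canonical feature order
    # makes the earlier feature win ties
    if (is.null(best) || cand$score > best$score + 1e-12) {
      best <- cand; best_f <- f
    }
  }
  if (is.null(best)) return(make_leaf(counts))
  left <- X[, best_f] <= best$threshold
  list(type = "node", feature = colnames(X)[best_f],
       threshold = best$threshold, counts = counts,
       left = grow_tree(X[left, , drop = FALSE], yi[left], classes,
                        min_leaf, criterion, k_features),
       right = grow_tree(X[!left, , drop = FALSE], yi[!left], classes,
                         min_leaf, criterion, k_features))
}

# C4.5 pessimistic error: upper confidence bound on the error rate of a
# leaf observing E errors in N cases (normal approximation, z = qnorm(1-cf))
#' @noRd
pessimistic_errors <- function(E, N, cf) {
  if (N == 0) return(0)
  f <- E / N
  z <- stats::qnorm(1 - cf)
  N * (f + z^2 / (2 * N) + z * sqrt(f / N - f^2 / N + z^2 / (4 * N^2))) /
    (1 + z^2 / N)
}

#' @noRd
subtree_pessimistic <- function(node, cf) {
  if (node$type == "leaf") {
    N <- sum(node$counts)
    return(pessimistic_errors(N - max(node$counts), N, cf))
  }
  subtree_pessimistic(node$left, cf) + subtree_pessimistic(node$right, cf)
}

# bottom-up subtree replacement by the C4.5 pessimistic-error criterion
#' @noRd
prune_pessimistic <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_pessimistic(node$left, cf)
  node$right <- prune_pessimistic(node$right, cf)
  N <- sum(node$counts)
  e_leaf <- pessimistic_errors(N - max(node$counts), N, cf)
  e_tree <- subtree_pessimistic(node, cf)
  if (e_leaf <= e_tree + 0.1) make_leaf(node$counts) else node
}

#' @noRd
predict_node <- function(node, X) {
  n <- nrow(X)
  out <- character(n)
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$type == "leaf") {
      out[idx] <<- node$class
      return()
    }
    v <- X[idx, node$feature]
    rec(node$left, idx[v <= node$threshold])
    rec(node$right, idx[v > node$threshold])
  }
  rec(node, seq_len(n))
  out
}

# reduced-error pruning: replace a subtree by its majority leaf whenever the
# replacement does not increase error on the pruning set (ties prune)
#' @noRd
prune_rep <- function(node, X, y) {
  if (node$type == "leaf") return(node)
  v <- X[, node$feature]
  left <- v <= node$threshold
  node$left <- prune_rep(node$left, X[left, , drop = FALSE], y[left])
  node$right <- prune_rep(node$right, X[!left, , drop = FALSE], y[!left])
  if (nrow(X) == 0) return(make_leaf(node$counts))
  err_tree <- sum(predict_node(node, X) != y)
  maj <- names(node$counts)[which.max(node$counts)]
  err_leaf <- sum(y != maj)
  if (err_leaf <= err_tree) make_leaf(node$counts) else node
}

# --- fitting interface ----------------------------------------------------

#' Fit a decision-tree classifier
#'
#' Induces an axis-aligned binary classification tree on numeric features.
#' Three algorithms are available:
#'
#' * `"j48"` - C4.5-style: candidate thresholds are midpoints between
#'   consecutive distinct sorted values; the split maximizing the gain ratio
#'   among candidates with positive information gain is chosen; growing stops
#'   at purity or `min_leaf`; the grown tree is pruned bottom-up by the C4.5
#'   pessimistic-error criterion with confidence factor `cf`.
#' * `"rep"` - grown with the plain information-gain criterion, then pruned
#'   by reduced-error pruning against the `validation` set (required).
#' * `"rt"` - random tree: at each node, `ceiling(log2(M) + 1)` of the `M`
#'   features are sampled without replacement and the best information-gain
#'   split among them is taken; no pruning. Deterministic given `seed`.
#'
#' Ties between equally scoring splits are broken by canonical feature order
#' and then by the lower threshold, so fitting is fully deterministic.
#'
#' @param formula Model formula, e.g. `class ~ .` (the response must be the
#'   class column; only `.` or explicit feature sums are supported on the
#'   right-hand side).
#' @param data Training data frame.
#' @param algorithm `"j48"`, `"rep"` or `"rt"`.
#' @param validation Held-out data frame: the pruning set for `"rep"`, and
#'   optionally the selection set for `cf = NA` under `"j48"`.
#' @param seed Integer seed (used by `"rt"` only).
#' @param control A [tree_control()] list.
#' @return An object of class `weed_tree` with components `root` (nested
#'   node list), `algorithm`, `classes`, `feature_ranges` (per-feature
#'   training `[min, max]`), `control`, `call`.
#' @seealso [predict.weed_tree()], [evaluate()], [as_fis()]
#' @export
#' @examples
#' d <- data.frame(class = factor(rep(c("A", "B"), each = 10)),
#'                 x = c(rnorm(10, 0), rnorm(10, 4)))
#' fit <- weed_tree(class ~ ., d, algorithm = "j48")
#' print(fit)
weed_tree <- function(formula, data, algorithm = c("j48", "rep", "rt"),
                      validation = NULL, seed = 1,
                      control = tree_control()) {
  algorithm <- match.arg(algorithm)
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- droplevels(factor(stats::model.response(mf)))
  X <- as.matrix(mf[-1])
  storage.mode(X) <- "double"
  if (nrow(X) == 0) stop("empty training table")
  classes <- levels(y)
  yi <- as.integer(y)
  ranges <- apply(X, 2, range)

  fit_one <- function(cf) {
    root <- switch(algorithm,
      j48 = prune_pessimistic(
        grow_tree(X, yi, classes, control$min_leaf, "gainratio"), cf),
      rep = {
        if (is.null(validation))
          stop("algorithm 'rep' requires a validation (pruning) set")
        g <- grow_tree(X, yi, classes, control$min_leaf, "infogain")
        vmf <- stats::model.frame(formula, validation)
        vy <- as.character(stats::model.response(vmf))
        vX <- as.matrix(vmf[-1]); storage.mode(vX) <- "double"
        prune_rep(g, vX, vy)
      },
      rt = {
        M <- ncol(X)
        k <- ceiling(log2(M) + 1)
        with_seed(seed, function()
          grow_tree(X, yi, classes, control$min_leaf, "infogain",
                    k_features = k))
      })
    root
  }

  cf <- control$cf
  if (algorithm == "j48" && is.na(cf)) {
    if (is.null(validation))
      stop("cf = NA (select by validation accuracy) requires a validation set")
    vmf <- stats::model.frame(formula, validation)
    vy <- as.character(stats::model.response(vmf))
    vX <- as.data.frame(vmf[-1])
    accs <- vapply(control$cf_grid, function(cfi)
      mean(predict_node(fit_one(cfi), vX) == vy), numeric(1))
    cf <- control$cf_grid[which.max(accs)]
    control$cf <- cf
  }
  root <- fit_one(cf)

  structure(list(root = root, algorithm = algorithm, classes = classes,
                 feature_ranges = ranges, control = control, seed = seed,
                 n = nrow(X), call = cl),
            class = "weed_tree")
}

#' Number of leaves / internal nodes of a tree
#' @param tree A `weed_tree` or node list.
#' @return Integer count.
#' @export
n_leaves <- function(tree) {
  node <- if (inherits(tree, "weed_tree")) tree$root else tree
  if (node$type == "leaf") 1L else n_leaves(node$left) + n_leaves(node$right)
}

#' @rdname n_leaves
#' @export
n_nodes <- function(tree) {
  node <- if (inherits(tree, "weed_tree")) tree$root else tree
  if (node$type == "leaf") 0L else
    1L + n_nodes(node$left) + n_nodes(node$right)
}

#' @export
print.weed_tree <- function(x, ...) {
  cat(sprintf("Decision tree (%s): %d internal node(s), %d leaf(s), classes: %s\n",
              toupper(x$algorithm), n_nodes(x), n_leaves(x),
              paste(x$classes, collapse = ", ")))
  print_node <- function(node, indent, prefix) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s%s-> %s (%s)\n", pad, prefix, node$class,
                  paste(node$counts, collapse = "/")))
    } else {
      cat(sprintf("%s%s%s <= %.4g ?\n", pad, prefix, node$feature,
                  node$threshold))
      print_node(node$left, indent + 1, "yes: ")
      print_node(node$right, indent + 1, "no:  ")
    }
  }
  print_node(x$root, 0, "")
  invisible(x)
}

#' @export
summary.weed_tree <- function(object, ...) {
  feats <- unique(unlist(tree_features(object$root)))
  cat(sprintf("Decision tree fitted by %s on %d samples\n",
              toupper(object$algorithm), object$n))
  cat(sprintf("  internal nodes: %d, leaves: %d\n",
              n_nodes(object), n_leaves(object)))
  cat(sprintf("  features used: %s\n", paste(feats, collapse = ", ")))
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  invisible(object)
}

#' @noRd
tree_features <- function(node) {
  if (node$type == "leaf") return(character(0))
  c(node$feature, tree_features(node$left), tree_features(node$right))
}

#' Predict classes or class probabilities from a fitted tree
#'
#' Instances descend left when `value <= threshold` (values exactly at a
#' threshold go left). `type = "prob"` returns each leaf's training
#' class-frequency estimates.
#'
#' @param object A `weed_tree`.
#' @param newdata Data frame containing every feature the tree references.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric matrix of class
#'   probabilities (one column per class).
#' @export
predict.weed_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  need <- unique(tree_features(object$root))
  missing <- setdiff(need, names(newdata))
  if (length(missing))
    stop(sprintf("newdata is missing feature(s): %s",
                 paste(missing, collapse = ", ")))
  n <- nrow(newdata)
  if (type == "class") {
    return(factor(predict_node(object$root, newdata),
                  levels = object$classes))
  }
  P <- matrix(0, n, length(object$classes),
              dimnames = list(NULL, object$classes))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$type == "leaf") {
      tot <- sum(node$counts)
      p <- if (tot > 0) node$counts / tot else
        rep(1 / length(node$counts), length(node$counts))
      P[idx, ] <<- matrix(p, length(idx), length(p), byrow = TRUE)
      return()
    }
    v <- newdata[idx, node$feature]
    rec(node$left, idx[v <= node$threshold])
    rec(node$right, idx[v > node$threshold])
  }
  rec(object$root, seq_len(n))
  P
}

# --- evaluation -----------------------------------------------------------

#' Classification metrics from observed and predicted labels
#'
#' Computes the confusion matrix, overall accuracy (trace over total, the
#' two-class `(TP + TN) / (TP + TN + FP + FN)` generalized), Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products, and, when a probability matrix is supplied, the RMSE between
#' per-class predicted probabilities and the one-hot observed encoding,
#' averaged over instances and classes.
#'
#' @param obs Observed class labels.
#' @param pred Predicted class labels.
#' @param prob Optional numeric matrix of class probabilities (columns named
#'   by class) for the RMSE.
#' @param classes Class set; defaults to the union of observed and predicted.
#' @return List with `confusion`, `accuracy`, `kappa`, `rmse` (NA without
#'   `prob`).
#' @export
#' @examples
#' classification_metrics(c("a", "a", "b"), c("a", "b", "b"))$accuracy
classification_metrics <- function(obs, pred, prob = NULL, classes = NULL) {
  if (is.null(classes))
    classes <- sort(unique(c(as.character(obs), as.character(pred))))
  obs <- factor(obs, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(observed = obs, predicted = pred)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  rmse <- NA_real_
  if (!is.null(prob)) {
    onehot <- outer(as.character(obs), classes, `==`) * 1
    rmse <- sqrt(mean((prob[, classes, drop = FALSE] - onehot)^2))
  }
  list(confusion = cm, accuracy = po, kappa = kappa, rmse = rmse)
}

#' Evaluate a fitted tree on a labeled table
#'
#' @param tree A `weed_tree`.
#' @param data Labeled data frame.
#' @param positive_class Optional positive class for the TP/TN/FP/FN
#'   breakdown; must be one of the tree's classes.
#' @param class Name of the class column.
#' @return Object of class `tree_eval`: `confusion`, `accuracy`, `kappa`,
#'   `rmse`, and (with `positive_class`) `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate <- function(tree, data, positive_class = NULL, class = "class") {
  stopifnot(inherits(tree, "weed_tree"))
  if (nrow(data) == 0) stop("empty evaluation table")
  obs <- as.character(data[[class]])
  pred <- as.character(predict(tree, data))
  prob <- predict(tree, data, type = "prob")
  m <- classification_metrics(obs, pred, prob, classes = tree$classes)
  out <- c(m, list(n = nrow(data)))
  if (!is.null(positive_class)) {
    if (!positive_class %in% tree$classes)
      stop(sprintf("positive_class '%s' is not one of the tree's classes",
                   positive_class))
    is_pos_obs <- obs == positive_class
    is_pos_pred <- pred == positive_class
    out$tp <- sum(is_pos_obs & is_pos_pred)
    out$tn <- sum(!is_pos_obs & !is_pos_pred)
    out$fp <- sum(!is_pos_obs & is_pos_pred)
    out$fn <- sum(is_pos_obs & !is_pos_pred)
  }
  structure(out, class = "tree_eval")
}

#' @export
print.tree_eval <- function(x, ...) {
  cat(sprintf("accuracy %.4f | kappa %.4f | RMSE %.4f (n = %d)\n",
              x$accuracy, x$kappa, x$rmse, x$n))
  print(x$confusion)
  invisible(x)
}

# --- serialization --------------------------------------------------------

#' Serialize / deserialize a fitted tree as JSON
#'
#' The format is a nested node object (`feature`, `threshold`, `left`,
#' `right` for internal nodes; `class`, `counts` for leaves) plus the
#' algorithm, classes, control parameters and training feature ranges.
#' Numbers are written at full precision, so a round trip is exact.
#'
#' @param tree A `weed_tree`.
#' @param path Output/input file path.
#' @return `read_tree` returns a `weed_tree`; `write_tree` returns `path`
#'   invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "weed_tree"))
  prep <- function(node) {
    node$counts <- as.list(node$counts)   # keep class names in JSON
    if (node$type == "node") {
      node$left <- prep(node$left)
      node$right <- prep(node$right)
    }
    node
  }
  obj <- list(algorithm = tree$algorithm, classes = tree$classes,
              control = unclass(tree$control), seed = tree$seed, n = tree$n,
              feature_ranges = as.list(as.data.frame(tree$feature_ranges)),
              root = prep(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  fix_node <- function(node) {
    node$counts <- unlist(node$counts)
    if (node$type == "node") {
      node$left <- fix_node(node$left)
      node$right <- fix_node(node$right)
    }
    node
  }
  ranges <- do.call(cbind, lapply(obj$feature_ranges, unlist))
  structure(list(root = fix_node(obj$root), algorithm = obj$algorithm,
                 classes = unlist(obj$classes),
                 feature_ranges = ranges,
                 control = structure(obj$control, class = "tree_control"),
                 seed = obj$seed, n = obj$n, call = NULL),
            class = "weed_tree")
}
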