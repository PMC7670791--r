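# Correlation structures for CFS: mean |one-vs-rest point-biserial| per
# feature (feature-class) and |Pearson| between features, computed once.
#' @noRd
cfs_correlations <- function(data, class = "class") {
  y <- data[[class]]
  if (is.null(y)) stop(sprintf("no '%s' column in table", class))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("supervised selection requires >= 2 classes")
  X <- as.matrix(data[setdiff(names(data), class)])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("zero-variance feature(s) %s: correlations defined as 0",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
  ok <- sds > 0
  rcf <- numeric(ncol(X))
  ind <- sapply(levels(y), function(l) as.numeric(y == l))
  if (nlevels(y) == 2) ind <- ind[, 1, drop = FALSE]
  for (k in which(ok)) {
    rcf[k] <- mean(abs(suppressWarnings(stats::cor(X[, k], ind))))
  }
  rff <- matrix(0, ncol(X), ncol(X))
  if (sum(ok) >= 2) {
    rff[ok, ok] <- abs(suppressWarnings(stats::cor(X[, ok, drop = FALSE])))
    rff[is.na(rff)] <- 0
  }
  diag(rff) <- 1
  rownames(rff) <- colnames(rff) <- colnames(X)
  list(features = colnames(X), rcf = stats::setNames(rcf, colnames(X)),
       rff = rff)
}

#' @noRd
merit_from_correlations <- function(subset_idx, corrs) {
  k <- length(subset_idx)
  if (k == 0) return(0)
  rcf_bar <- mean(corrs$rcf[subset_idx])
  rff_bar <- if (k == 1) 0 else {
    m <- corrs$rff[subset_idx, subset_idx]
    (sum(m) - k) / (k * (k - 1))
  }
  denom <- sqrt(k + k * (k - 1) * rff_bar)
  if (denom == 0) return(0)
  k * rcf_bar / denom
}

#' CFS merit of a feature subset
#'
#' The correlation-based feature selection merit
#' `k * rcf / sqrt(k + k (k - 1) * rff)`, where `k` is the subset size,
#' `rcf` the mean absolute feature-class correlation and `rff` the mean
#' absolute pairwise feature-feature correlation. Feature-class correlation
#' is the absolute point-biserial correlation against the class indicator
#' (for more than two classes, the mean over one-vs-rest indicators).
#' Zero-variance features contribute correlation 0, with a warning.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param data Data frame with a class column and numeric feature columns.
#' @param class Name of the class column.
#' @return Merit score (single number).
#' @export
#' @examples
#' d <- data.frame(class = factor(rep(c("a", "b"), each = 10)),
#'                 x = rep(c(0, 1), each = 10) + rnorm(20, sd = 0.1),
#'                 z = rnorm(20))
#' cfs_merit("x", d) > cfs_merit("z", d)
cfs_merit <- function(subset, data, class = "class") {
  if (length(subset) == 0) stop("subset must be non-empty")
  corrs <- cfs_correlations(data, class)
  missing <- setdiff(subset, corrs$features)
  if (length(missing))
    stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
  merit_from_correlations(match(subset, corrs$features), corrs)
}

#' Correlation-based feature selection
#'
#' Best-first forward search over feature subsets, maximizing the CFS merit
#' ([cfs_merit()]). The search expands the best open subset, adding one
#' feature at a time, and stops after `stall` consecutive expansions that do
#' not improve the best merit found. Ties are broken by canonical (column)
#' feature order, making the result deterministic.
#'
#' @param data Data frame with a class column and `>= 2` numeric features.
#' @param class Name of the class column.
#' @param stall Consecutive non-improving expansions before stopping.
#' @return Object of class `cfs_selection`: list with `method`, `selected`
#'   (ordered feature names) and `merit`.
#' @export
cfs_select <- function(data, class = "class", stall = 5) {
  corrs <- cfs_correlations(data, class)
  p <- length(corrs$features)
  if (p < 2) stop("need at least 2 features")

  key <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  open_sets <- list(integer(0))
  open_merit <- 0
  closed <- new.env(parent = emptyenv())
  best_set <- integer(0); best_merit <- -Inf
  stalls <- 0L

  while (length(open_sets) > 0 && stalls < stall) {
    at <- which.max(open_merit)  # first max: earlier insertion wins ties
    cur <- open_sets[[at]]; cur_merit <- open_merit[at]
    open_sets <- open_sets[-at]; open_merit <- open_merit[-at]
    k <- key(cur)
    if (!is.null(closed[[k]])) next
    closed[[k]] <- TRUE
    if (cur_merit > best_merit + 1e-10) {
      best_merit <- cur_merit; best_set <- cur; stalls <- 0L
    } else stalls <- stalls + 1L
    for (f in setdiff(seq_len(p), cur)) {
      child <- c(cur, f)
      if (is.null(closed[[key(child)]])) {
        open_sets[[length(open_sets) + 1L]] <- child
        open_merit <- c(open_merit, merit_from_correlations(child, corrs))
      }
    }
  }
  if (length(best_set) == 0) best_set <- which.max(corrs$rcf)
  best_set <- sort(best_set)
  structure(list(method = "CFS",
                 selected = corrs$features[best_set],
                 merit = merit_from_correlations(best_set, corrs)),
            class = "cfs_selection")
}

#' @export
print.cfs_selection <- function(x, ...) {
  cat(sprintf("CFS selection: %d feature(s), merit %.4f\n",
              length(x$selected), x$merit))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Principal component reduction of a feature table
#'
#' Standardizes the features to z-scores, eigendecomposes the correlation
#' matrix and keeps the smallest number of leading components whose
#' cumulative variance fraction reaches `variance_kept`. Constant columns
#' are dropped with a warning before standardization. The class column, if
#' present, is ignored (the reduction is unsupervised) and carried through
#' to the score table.
#'
#' @param data Data frame of numeric features, optionally with a class column.
#' @param variance_kept Fraction of variance to retain, in `(0, 1]`.
#' @param class Name of the class column to ignore (if present).
#' @return Object of class `pca_reduction`: list with `method`, `loadings`
#'   (orthonormal columns), `n_components`, `cum_variance`, `eigenvalues`,
#'   `center`, `scale`, and `scores` (data frame of retained components,
#'   with the class column re-attached when present).
#' @export
pca_reduce <- function(data, variance_kept = 0.95, class = "class") {
  if (variance_kept <= 0 || variance_kept > 1)
    stop("variance_kept must lie in (0, 1]")
  y <- data[[class]]
  X <- as.matrix(data[setdiff(names(data), class)])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) < 1) stop("no non-constant features left")
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  # deterministic sign: largest-magnitude loading of each component positive
  for (k in seq_len(ncol(ev$vectors))) {
    v <- ev$vectors[, k]
    if (v[which.max(abs(v))] < 0) ev$vectors[, k] <- -v
  }
  cumvar <- cumsum(ev$values) / sum(ev$values)
  ncomp <- which(cumvar >= variance_kept - 1e-12)[1]
  load <- ev$vectors[, seq_len(ncomp), drop = FALSE]
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(ncomp))
  scores <- as.data.frame(Z %*% load)
  if (!is.null(y)) scores[[class]] <- y
  structure(list(method = "PCA", loadings = load, n_components = ncomp,
                 cum_variance = cumvar[ncomp], eigenvalues = ev$values,
                 center = ctr, scale = sds, scores = scores),
            class = "pca_reduction")
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("PCA reduction: %d component(s), %.1f%% of variance\n",
              x$n_components, 100 * x$cum_variance))
  invisible(x)
}
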