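# small in-code fixtures shared across test files

# a block with a single constant color
constant_block <- function(r, g, b, size = 8) {
  px <- array(0L, dim = c(size, size, 3L))
  px[, , 1] <- as.integer(r); px[, , 2] <- as.integer(g)
  px[, , 3] <- as.integer(b)
  rgb_block(px)
}

# 0/255 checkerboard matrix
checkerboard <- function(n = 4) {
  255 * outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
}

# brute-force direction-averaged GLCM by explicit pair enumeration
brute_glcm_mean <- function(labels, distance = 1, symmetric = TRUE,
                            levels = max(labels) + 1L) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  mats <- lapply(offs, function(off) {
    off <- off * distance
    counts <- matrix(0, levels, levels)
    for (r in seq_len(nrow(labels))) {
      for (cc in seq_len(ncol(labels))) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 >= 1 && r2 <= nrow(labels) && c2 >= 1 && c2 <= ncol(labels)) {
          i <- labels[r, cc] + 1; j <- labels[r2, c2] + 1
          counts[i, j] <- counts[i, j] + 1
          if (symmetric) counts[j, i] <- counts[j, i] + 1
        }
      }
    }
    counts / sum(counts)
  })
  Reduce(`+`, mats) / 4
}

# a well-separated 2-feature, 2-class table
two_class_table <- function(n_per_class = 20, gap = 4, seed = 1,
                            noise_features = 0) {
  set.seed(seed)
  d <- data.frame(
    class = factor(rep(c("A", "B"), each = n_per_class)),
    x1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap)),
    x2 = rnorm(2 * n_per_class))
  if (noise_features > 0)
    for (k in seq_len(noise_features))
      d[[paste0("noise", k)]] <- rnorm(2 * n_per_class)
  d
}

# exhaustive CFS oracle: best merit over all non-empty subsets
exhaustive_cfs <- function(data, class = "class") {
  feats <- setdiff(names(data), class)
  best <- NULL; best_merit <- -Inf
  for (k in seq_along(feats)) {
    for (idx in utils::combn(length(feats), k, simplify = FALSE)) {
      m <- suppressWarnings(cfs_merit(feats[idx], data, class))
      if (m > best_merit + 1e-10) {
        best_merit <- m; best <- feats[idx]
      }
    }
  }
  list(selected = best, merit = best_merit)
}
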