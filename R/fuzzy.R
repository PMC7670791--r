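# --- membership functions -------------------------------------------------

#' Trapezoidal membership function from a tree threshold
#'
#' Builds the trapezoid associated with a decision-tree node: membership
#' crosses 0.5 exactly at the threshold, with a linear transition of
#' half-width `band * (hi - lo)` around it. `side = "below"` gives full
#' membership below the threshold (corners `(lo, lo, t - d, t + d)`),
#' `side = "above"` above it (corners `(t - d, t + d, hi, hi)`).
#'
#' @param feature Input variable name.
#' @param threshold Crossing point; must lie strictly inside the universe.
#' @param universe `c(lo, hi)` of the variable.
#' @param side `"below"` or `"above"`.
#' @param band Transition half-width as a fraction of the universe width,
#'   in `(0, 0.25]`.
#' @param name Membership-function label (e.g. `"B1"`).
#' @return Object of class `trapezoid_mf` with fields `name`, `feature`,
#'   `corners` (a, b, c, d), `side`, `threshold`.
#' @export
#' @examples
#' mf <- make_mf("ave_S", 0.36, c(0, 1), side = "below", band = 0.05)
#' mf_value(mf, c(0, 0.36, 0.5))
make_mf <- function(feature, threshold, universe, side = c("below", "above"),
                    band = 0.05, name = NULL) {
  side <- match.arg(side)
  lo <- universe[1]; hi <- universe[2]
  if (!(lo < threshold && threshold < hi))
    stop(sprintf("threshold %.4g outside the universe [%.4g, %.4g] of '%s'",
                 threshold, lo, hi, feature))
  if (band <= 0 || band > 0.25) stop("band must lie in (0, 0.25]")
  d <- band * (hi - lo)
  corners <- if (side == "below") c(lo, lo, threshold - d, threshold + d)
             else c(threshold - d, threshold + d, hi, hi)
  structure(list(name = name %||% feature, feature = feature,
                 corners = corners, side = side, threshold = threshold),
            class = "trapezoid_mf")
}

#' Evaluate a trapezoidal membership function
#'
#' @param mf A `trapezoid_mf`, or a length-4 corner vector `(a, b, c, d)`.
#' @param x Numeric values.
#' @return Membership degrees in `[0, 1]` (vectorized).
#' @export
mf_value <- function(mf, x) {
  cr <- if (inherits(mf, "trapezoid_mf")) mf$corners else mf
  a <- cr[1]; b <- cr[2]; cc <- cr[3]; d <- cr[4]
  mu <- numeric(length(x))
  mu[x >= b & x <= cc] <- 1
  if (b > a) {
    up <- x > a & x < b
    mu[up] <- (x[up] - a) / (b - a)
  }
  if (d > cc) {
    dn <- x > cc & x < d
    mu[dn] <- (d - x[dn]) / (d - cc)
  }
  mu
}

# output variable: universe [0, n_classes], one trapezoid per class.
# two classes keep asymmetric shapes whose single-rule centroids fall
# strictly inside (0, 1) and (1, 2); k classes center class k at k - 0.5
#' @noRd
make_output_variable <- function(classes) {
  n <- length(classes)
  mfs <- if (n == 2) {
    list(structure(list(name = classes[1], feature = "Plant",
                        corners = c(0, 0, 0.4, 1.0), side = "below",
                        threshold = NA_real_), class = "trapezoid_mf"),
         structure(list(name = classes[2], feature = "Plant",
                        corners = c(1.0, 1.6, 2, 2), side = "above",
                        threshold = NA_real_), class = "trapezoid_mf"))
  } else {
    lapply(seq_len(n), function(k)
      structure(list(name = classes[k], feature = "Plant",
                     corners = c(k - 1, k - 0.7, k - 0.3, k), side = "above",
                     threshold = NA_real_), class = "trapezoid_mf"))
  }
  names(mfs) <- classes
  list(name = "Plant", universe = c(0, n), mfs = mfs)
}

# --- the fuzzy system object ---------------------------------------------

#' @noRd
new_mamdani_fis <- function(inputs, classes, rules, band) {
  structure(list(inputs = inputs, output = make_output_variable(classes),
                 classes = classes, rules = rules, band = band,
                 config = list(and = "min", implication = "min",
                               aggregation = "max",
                               defuzzification = "centroid", grid = 1001L)),
            class = "mamdani_fis")
}

#' @export
print.mamdani_fis <- function(x, ...) {
  cat(sprintf("Mamdani fuzzy system: %d input(s), %d rule(s), classes: %s\n",
              length(x$inputs), length(x$rules),
              paste(x$classes, collapse = ", ")))
  for (v in x$inputs) {
    cat(sprintf("  %s on [%.4g, %.4g]: %s\n", v$name, v$universe[1],
                v$universe[2],
                paste(vapply(v$mfs, function(m)
                  sprintf("%s@%.4g(%s)", m$name, m$threshold, m$side),
                  character(1)), collapse = ", ")))
  }
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    ante <- paste(vapply(r$antecedent, function(tm)
      sprintf("(%s is %s%s)", tm$variable, if (tm$negated) "not " else "",
              tm$mf), character(1)), collapse = " and ")
    cat(sprintf("  %d. If %s then (Plant is %s)\n", i, ante, r$consequent))
  }
  invisible(x)
}

#' @export
summary.mamdani_fis <- function(object, ...) {
  print(object)
}

# default MF label: initials of the feature name plus a per-feature counter
#' @noRd
auto_mf_name <- function(feature, k) {
  parts <- strsplit(feature, "_", fixed = TRUE)[[1]]
  paste0(paste(toupper(substr(parts, 1, 1)), collapse = ""), k)
}

#' Compile a decision tree into a Mamdani fuzzy inference system
#'
#' Each distinct feature in the tree becomes one input variable whose
#' universe is the feature's training range padded by `band`; each internal
#' node contributes one trapezoidal membership function crossing 0.5 at the
#' node's threshold (a feature appearing in several nodes gets several MFs);
#' and each leaf becomes one if-then rule: the conjunction of the membership
#' conditions along its root-to-leaf path, negated on the branch the MF does
#' not cover, with the leaf's class as consequent. With `side = "below"`
#' (default) the named MF covers the left (`<=`) branch; `side = "above"`
#' names the right branch instead, matching the published reference models.
#'
#' Inference uses min for AND and implication, max aggregation and centroid
#' defuzzification on a fixed 1001-point discretization of the output
#' universe.
#'
#' @param tree A fitted [weed_tree()] with at least one internal node.
#' @param band Transition half-width fraction (see [make_mf()]).
#' @param side Which branch the named MF covers.
#' @param mf_names Optional list of MF labels keyed by feature, each a
#'   character vector assigned to that feature's nodes in pre-order
#'   (root, left, right) of appearance.
#' @param ... Unused.
#' @return A `mamdani_fis` object (`n_rules` equals the tree's leaf count).
#' @export
as_fis <- function(tree, ...) UseMethod("as_fis")

#' @rdname as_fis
#' @export
as_fis.weed_tree <- function(tree, band = 0.05, side = c("below", "above"),
                             mf_names = NULL, ...) {
  side <- match.arg(side)
  if (tree$root$type == "leaf")
    stop("cannot fuzzify a leaf-only tree: it has no thresholds")

  # collect internal nodes in pre-order, tagging each with an id
  nodes <- list()
  walk <- function(node) {
    if (node$type == "leaf") return()
    nodes[[length(nodes) + 1L]] <<- list(feature = node$feature,
                                         threshold = node$threshold)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)

  feats <- unique(vapply(nodes, `[[`, character(1), "feature"))
  inputs <- list()
  mf_of_node <- character(length(nodes))
  for (f in feats) {
    rng <- tree$feature_ranges[, f]
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    pad <- band * diff(rng)
    uni <- c(rng[1] - pad, rng[2] + pad)
    idx <- which(vapply(nodes, `[[`, character(1), "feature") == f)
    labs <- if (!is.null(mf_names) && !is.null(mf_names[[f]])) {
      if (length(mf_names[[f]]) != length(idx))
        stop(sprintf("mf_names for '%s' must have %d label(s)", f, length(idx)))
      mf_names[[f]]
    } else vapply(seq_along(idx), function(k) auto_mf_name(f, k), character(1))
    mfs <- list()
    for (k in seq_along(idx)) {
      mfs[[labs[k]]] <- make_mf(f, nodes[[idx[k]]]$threshold, uni,
                                side = side, band = band, name = labs[k])
      mf_of_node[idx[k]] <- labs[k]
    }
    inputs[[f]] <- list(name = f, universe = uni, mfs = mfs)
  }

  # one rule per leaf: conditions along the root-to-leaf path
  rules <- list()
  nid <- 0L
  descend <- function(node, path) {
    if (node$type == "leaf") {
      rules[[length(rules) + 1L]] <<- list(antecedent = path,
                                           consequent = node$class)
      return()
    }
    nid <<- nid + 1L
    my <- nid
    term <- function(negated)
      list(variable = node$feature, mf = mf_of_node[my], negated = negated)
    # side = "below": named MF covers the left (<=) branch
    descend(node$left, c(path, list(term(negated = (side == "above")))))
    descend(node$right, c(path, list(term(negated = (side == "below")))))
  }
  descend(tree$root, list())

  new_mamdani_fis(inputs, tree$classes, rules, band)
}

# --- inference ------------------------------------------------------------

#' @noRd
rule_strengths <- function(fis, X) {
  n <- nrow(X)
  S <- matrix(1, n, length(fis$rules))
  for (r in seq_along(fis$rules)) {
    for (tm in fis$rules[[r]]$antecedent) {
      mf <- fis$inputs[[tm$variable]]$mfs[[tm$mf]]
      mu <- mf_value(mf, X[[tm$variable]])
      if (tm$negated) mu <- 1 - mu
      S[, r] <- pmin(S[, r], mu)
    }
  }
  S
}

#' Run fuzzy inference
#'
#' Evaluates the system on each row: rule strengths by min over antecedent
#' memberships (negated terms use `1 - mu`), min implication, max
#' aggregation, and centroid defuzzification over a fixed 1001-point grid of
#' the output universe. Inputs outside a variable's universe are clipped
#' with a warning. If no rule fires at all for some row, the output is the
#' universe midpoint and a warning is raised. The class label is the
#' half-open unit interval the crisp output falls into (`< 1` is the first
#' class, `>= 1` the second, and so on).
#'
#' @param object A `mamdani_fis`.
#' @param newdata Data frame containing every input variable.
#' @param ... Unused.
#' @return Data frame with columns `crisp` and `class`.
#' @export
#' @examples
#' fis <- reference_rep_cfs()
#' predict(fis, data.frame(ave_Bs = 5, cluster_shade_LL = 300))
predict.mamdani_fis <- function(object, newdata, ...) {
  need <- names(object$inputs)
  missing <- setdiff(need, names(newdata))
  if (length(missing))
    stop(sprintf("newdata is missing input variable(s): %s",
                 paste(missing, collapse = ", ")))
  X <- newdata[need]
  clipped <- FALSE
  for (v in need) {
    uni <- object$inputs[[v]]$universe
    x <- X[[v]]
    if (any(x < uni[1] | x > uni[2])) clipped <- TRUE
    X[[v]] <- pmin(pmax(x, uni[1]), uni[2])
  }
  if (clipped)
    warning("input value(s) outside a variable's universe were clipped")

  S <- rule_strengths(object, X)
  grid <- seq(object$output$universe[1], object$output$universe[2],
              length.out = object$config$grid)
  cons <- t(vapply(object$rules, function(r)
    mf_value(object$output$mfs[[r$consequent]], grid),
    numeric(length(grid))))

  n <- nrow(X)
  crisp <- numeric(n)
  chunk <- 512L
  for (s0 in seq(1, n, by = chunk)) {
    rows <- s0:min(n, s0 + chunk - 1L)
    agg <- matrix(0, length(rows), length(grid))
    for (r in seq_along(object$rules)) {
      clip <- pmin(matrix(S[rows, r], length(rows), length(grid)),
                   matrix(cons[r, ], length(rows), length(grid), byrow = TRUE))
      agg <- pmax(agg, clip)
    }
    area <- rowSums(agg)
    cr <- ifelse(area > 0, rowSums(agg * matrix(grid, length(rows),
                                                length(grid), byrow = TRUE)) /
                   area, mean(object$output$universe))
    crisp[rows] <- cr
  }
  if (any(rowSums(S) == 0))
    warning("uncovered input(s): no rule fired; output set to the universe midpoint")
  cls_idx <- pmin(pmax(floor(crisp) + 1, 1), length(object$classes))
  data.frame(crisp = crisp,
             class = factor(object$classes[cls_idx],
                            levels = object$classes))
}

# --- published reference models ------------------------------------------

# reconstruction of the two-node crop/weed tree behind the published
# three-rule fuzzy classifier: ave_Bs at 19.31, cluster_shade_LL at 822.1.
# Leaf counts are synthetic placeholders (the training data is not public);
# they never influence crisp inference.
#' @noRd
reference_tree <- function(root, features, ranges, classes = c("Peanut", "Weed")) {
  structure(list(root = root, algorithm = "reference", classes = classes,
                 feature_ranges = matrix(unlist(ranges), nrow = 2,
                                         dimnames = list(c("min", "max"),
                                                         features)),
                 control = tree_control(), seed = NA_integer_,
                 n = NA_integer_, call = NULL),
            class = "weed_tree")
}

#' @noRd
ref_leaf <- function(class, classes = c("Peanut", "Weed")) {
  counts <- stats::setNames(rep(0, length(classes)), classes)
  counts[class] <- 1
  list(type = "leaf", class = class, counts = counts)
}

#' Reconstructed two-node peanut/weed tree (REP variant)
#'
#' The published reduced-error-pruning crop/weed tree, rebuilt from its
#' printed rule antecedents and thresholds: `ave_Bs` at 19.31 with a
#' `cluster_shade_LL` node at 822.1 on the low-`ave_Bs` branch. High
#' `ave_Bs` or high `cluster_shade_LL` indicates peanut; both low indicates
#' weed. Feature ranges (`ave_Bs` 0-40, `cluster_shade_LL` 0-2500) are
#' reconstruction choices spanning the printed thresholds; leaf counts are
#' synthetic placeholders.
#'
#' @return A `weed_tree` with 2 internal nodes and 3 leaves.
#' @seealso [reference_rep_cfs()]
#' @export
reference_rep_tree <- function() {
  root <- list(type = "node", feature = "ave_Bs", threshold = 19.31,
               counts = c(Peanut = 2, Weed = 1),
               left = list(type = "node", feature = "cluster_shade_LL",
                           threshold = 822.1,
                           counts = c(Peanut = 1, Weed = 1),
                           left = ref_leaf("Weed"),
                           right = ref_leaf("Peanut")),
               right = ref_leaf("Peanut"))
  reference_tree(root, c("ave_Bs", "cluster_shade_LL"),
                 list(c(0, 40), c(0, 2500)))
}

#' Reconstructed six-node peanut/weed tree (C4.5 variant)
#'
#' The published gain-ratio crop/weed tree, rebuilt from the seven printed
#' rule antecedents over `ave_Bs`, `sum_entropy_HH`, `ave_S` (two nodes),
#' `correlation_LL` and `cluster_shade_LL`. Only two of its thresholds are
#' printed in the source tables (`sum_entropy_HH` 2.39 and `ave_S` 0.36 for
#' the S2 node); the remaining thresholds are UNKNOWN-IN-PAPER and default
#' to the stated arguments, which are package choices on each feature's
#' natural scale.
#'
#' @param ave_Bs_threshold Threshold of the root `ave_Bs` node
#'   (UNKNOWN-IN-PAPER; default borrows the 19.31 printed for the two-node
#'   model of the same feature).
#' @param sum_entropy_HH_threshold Printed as 2.39 (a neighbouring sentence
#'   says 2.36; 2.39 is the default).
#' @param ave_S2_threshold Printed as 0.36.
#' @param ave_S1_threshold Threshold of the second `ave_S` node
#'   (UNKNOWN-IN-PAPER).
#' @param correlation_LL_threshold UNKNOWN-IN-PAPER, on `[-1, 1]`.
#' @param cluster_shade_LL_threshold UNKNOWN-IN-PAPER; default borrows the
#'   822.1 printed for the two-node model.
#' @return A `weed_tree` with 6 internal nodes and 7 leaves.
#' @seealso [reference_j48_cfs()]
#' @export
reference_j48_tree <- function(ave_Bs_threshold = 19.31,
                               sum_entropy_HH_threshold = 2.39,
                               ave_S2_threshold = 0.36,
                               ave_S1_threshold = 0.20,
                               correlation_LL_threshold = 0.5,
                               cluster_shade_LL_threshold = 822.1) {
  # right of each node is the "is <MF>" branch (above-threshold side)
  high_bs <- list(
    type = "node", feature = "sum_entropy_HH",
    threshold = sum_entropy_HH_threshold, counts = c(Peanut = 2, Weed = 2),
    right = ref_leaf("Weed"),
    left = list(
      type = "node", feature = "ave_S", threshold = ave_S2_threshold,
      counts = c(Peanut = 2, Weed = 1),
      right = ref_leaf("Peanut"),
      left = list(
        type = "node", feature = "correlation_LL",
        threshold = correlation_LL_threshold,
        counts = c(Peanut = 1, Weed = 1),
        right = ref_leaf("Peanut"),
        left = ref_leaf("Weed"))))
  low_bs <- list(
    type = "node", feature = "cluster_shade_LL",
    threshold = cluster_shade_LL_threshold, counts = c(Peanut = 1, Weed = 2),
    right = list(
      type = "node", feature = "ave_S", threshold = ave_S1_threshold,
      counts = c(Peanut = 1, Weed = 1),
      right = ref_leaf("Peanut"),
      left = ref_leaf("Weed")),
    left = ref_leaf("Weed"))
  root <- list(type = "node", feature = "ave_Bs",
               threshold = ave_Bs_threshold, counts = c(Peanut = 3, Weed = 4),
               left = low_bs, right = high_bs)
  reference_tree(root,
                 c("ave_Bs", "sum_entropy_HH", "ave_S", "correlation_LL",
                   "cluster_shade_LL"),
                 list(c(0, 40), c(0, 4), c(0, 1), c(-1, 1), c(0, 2500)))
}

#' Published three-rule peanut/weed fuzzy classifier
#'
#' Reconstruction of the fuzzy system compiled from the two-node
#' reduced-error-pruning crop/weed tree: input variables `ave_Bs`
#' (membership `B1`, full above 19.31) and `cluster_shade_LL` (`CS1`, full
#' above 822.1), and three rules: `B1 -> Peanut`;
#' `not B1 and CS1 -> Peanut`; `not B1 and not CS1 -> Weed`. Crisp outputs
#' below 1 mean peanut, above 1 weed.
#'
#' @param band Transition half-width fraction of each universe.
#' @return A `mamdani_fis` with 3 rules.
#' @export
#' @examples
#' fis <- reference_rep_cfs()
#' predict(fis, data.frame(ave_Bs = c(5, 5, 30),
#'                         cluster_shade_LL = c(300, 2000, 300)))
reference_rep_cfs <- function(band = 0.05) {
  as_fis(reference_rep_tree(), band = band, side = "above",
         mf_names = list(ave_Bs = "B1", cluster_shade_LL = "CS1"))
}

#' Published seven-rule peanut/weed fuzzy classifier
#'
#' Reconstruction of the fuzzy system compiled from the six-node gain-ratio
#' crop/weed tree, with membership functions `B1` (`ave_Bs`), `SE1`
#' (`sum_entropy_HH`), `S1`/`S2` (`ave_S`), `CM1` (`correlation_LL`) and
#' `CS1` (`cluster_shade_LL`), each full above its threshold. Thresholds not
#' printed in the source are taken from [reference_j48_tree()]'s defaults
#' and are documented there as UNKNOWN-IN-PAPER.
#'
#' @param band Transition half-width fraction of each universe.
#' @param ... Threshold overrides passed to [reference_j48_tree()].
#' @return A `mamdani_fis` with 7 rules.
#' @export
reference_j48_cfs <- function(band = 0.05, ...) {
  as_fis(reference_j48_tree(...), band = band, side = "above",
         mf_names = list(ave_Bs = "B1", sum_entropy_HH = "SE1",
                         ave_S = c("S1", "S2"), correlation_LL = "CM1",
                         cluster_shade_LL = "CS1"))
}

# --- tree/FIS agreement ---------------------------------------------------

#' Agreement between a compiled fuzzy system and its source tree
#'
#' Samples points uniformly within the system's input universes, classifies
#' them with both the crisp tree and the fuzzy system, and returns the
#' agreement fraction. With `off_band = TRUE` every coordinate is resampled
#' until it lies outside all membership transition bands of its variable,
#' where the fuzzy decision provably matches the tree.
#'
#' @param fis A `mamdani_fis` compiled from `tree`.
#' @param tree The source `weed_tree`.
#' @param n Number of sample points.
#' @param seed Integer seed.
#' @param off_band Restrict samples to off-transition-band regions?
#' @return Agreement fraction in `[0, 1]`.
#' @export
fis_tree_agreement <- function(fis, tree, n = 1000, seed = 1,
                               off_band = FALSE) {
  with_seed(seed, function() {
    X <- as.data.frame(lapply(fis$inputs, function(v) {
      x <- stats::runif(n, v$universe[1], v$universe[2])
      if (off_band) {
        bands <- lapply(v$mfs, function(m)
          c(m$corners[if (m$side == "below") 3 else 1],
            m$corners[if (m$side == "below") 4 else 2]))
        in_band <- function(z) Reduce(`|`, lapply(bands, function(b)
          z > b[1] & z < b[2]), rep(FALSE, length(z)))
        for (it in 1:100) {
          bad <- in_band(x)
          if (!any(bad)) break
          x[bad] <- stats::runif(sum(bad), v$universe[1], v$universe[2])
        }
      }
      x
    }))
    names(X) <- names(fis$inputs)
    mean(as.character(predict(fis, X)$class) ==
           as.character(predict(tree, X)))
  })
}

# --- serialization --------------------------------------------------------

#' Serialize / deserialize a fuzzy system as JSON
#'
#' Writes the input variables (universes and MF corners), output variable,
#' rules (with negation markers) and inference configuration at full
#' numeric precision; reading the file back reproduces the system exactly.
#'
#' @param fis A `mamdani_fis`.
#' @param path File path.
#' @return `read_fis` returns a `mamdani_fis`; `write_fis` returns `path`
#'   invisibly.
#' @export
write_fis <- function(fis, path) {
  stopifnot(inherits(fis, "mamdani_fis"))
  strip <- function(v) list(name = v$name, universe = v$universe,
                            mfs = lapply(v$mfs, unclass))
  obj <- list(inputs = lapply(fis$inputs, strip),
              output = strip(fis$output),
              classes = fis$classes, rules = fis$rules, band = fis$band,
              config = fis$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fis
#' @export
read_fis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  revive <- function(v) {
    v$universe <- unlist(v$universe)
    v$mfs <- lapply(v$mfs, function(m) {
      m$corners <- unlist(m$corners)
      m$threshold <- if (is.null(m$threshold)) NA_real_ else m$threshold
      structure(m, class = "trapezoid_mf")
    })
    v
  }
  fis <- structure(list(inputs = lapply(obj$inputs, revive),
                        output = revive(obj$output),
                        classes = unlist(obj$classes),
                        rules = obj$rules, band = obj$band,
                        config = obj$config),
                   class = "mamdani_fis")
  fis$config$grid <- as.integer(fis$config$grid)
  fis
}
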