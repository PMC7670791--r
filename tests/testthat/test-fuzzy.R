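test_that("trapezoids cross one half exactly at the tree threshold", {
  mf <- make_mf("ave_S", 0.36, c(0, 1), side = "below", band = 0.05)
  expect_equal(mf_value(mf, 0), 1)
  expect_equal(mf_value(mf, 0.36), 0.5)
  expect_equal(mf_value(mf, 0.5), 0)
  expect_equal(mf$corners, c(0, 0, 0.31, 0.41))

  above <- make_mf("ave_S", 0.36, c(0, 1), side = "above", band = 0.05)
  expect_equal(mf_value(above, 0.36), 0.5)
  expect_equal(mf_value(above, 1), 1)
  expect_equal(mf_value(above, 0), 0)

  # plateau at 1, zero beyond the outer corners, complement symmetry
  xs <- seq(0, 1, by = 0.01)
  expect_true(all(mf_value(mf, xs) >= 0 & mf_value(mf, xs) <= 1))
  expect_equal(1 - mf_value(mf, 0.36), 0.5)

  expect_error(make_mf("f", 2, c(0, 1), side = "below"), "outside")
  expect_error(make_mf("f", 0.5, c(0, 1), band = 0.4), "band")
})

test_that("compiling a tree yields one rule per leaf over its features", {
  d <- two_class_table(n_per_class = 20, gap = 4, seed = 5,
                       noise_features = 2)
  fit <- weed_tree(class ~ ., d, algorithm = "j48",
                   control = tree_control(min_leaf = 1))
  fis <- as_fis(fit, band = 0.05)
  expect_s3_class(fis, "mamdani_fis")
  expect_equal(length(fis$rules), n_leaves(fit))
  feats <- unique(unlist(lapply(fis$rules, function(r)
    vapply(r$antecedent, `[[`, character(1), "variable"))))
  expect_setequal(feats, names(fis$inputs))

  leafy <- fit
  leafy$root <- list(type = "leaf", class = "A", counts = c(A = 1, B = 0))
  expect_error(as_fis(leafy), "leaf-only")

  set.seed(13)
  for (rep in 1:4) {
    dr <- data.frame(class = factor(sample(c("A", "B"), 40, replace = TRUE)),
                     x1 = rnorm(40), x2 = rnorm(40))
    ft <- weed_tree(class ~ ., dr, algorithm = "rep", validation = dr)
    if (ft$root$type == "leaf") next
    expect_equal(length(as_fis(ft)$rules), n_leaves(ft))
  }
})

test_that("negated memberships complement the plain ones everywhere", {
  fis <- reference_j48_cfs()
  for (v in fis$inputs) {
    xs <- seq(v$universe[1], v$universe[2], length.out = 101)
    for (m in v$mfs)
      expect_equal(mf_value(m, xs) + (1 - mf_value(m, xs)), rep(1, 101))
  }
})

test_that("the three-rule reference classifier matches its published form", {
  fis <- reference_rep_cfs()
  expect_equal(length(fis$rules), 3)
  expect_setequal(names(fis$inputs), c("ave_Bs", "cluster_shade_LL"))
  expect_equal(fis$inputs$ave_Bs$mfs$B1$threshold, 19.31)
  expect_equal(fis$inputs$cluster_shade_LL$mfs$CS1$threshold, 822.1)

  pat <- function(r) paste(sort(vapply(r$antecedent, function(tm)
    sprintf("%s:%s%s", tm$variable, if (tm$negated) "not_" else "", tm$mf),
    character(1))), collapse = "&")
  got <- vapply(fis$rules, function(r) paste0(pat(r), "=>", r$consequent),
                character(1))
  expect_setequal(got, c(
    "ave_Bs:B1=>Peanut",
    "ave_Bs:not_B1&cluster_shade_LL:CS1=>Peanut",
    "ave_Bs:not_B1&cluster_shade_LL:not_CS1=>Weed"))
})

test_that("the seven-rule reference classifier matches its published form", {
  fis <- reference_j48_cfs()
  expect_equal(length(fis$rules), 7)
  expect_equal(fis$inputs$sum_entropy_HH$mfs$SE1$threshold, 2.39)
  expect_equal(fis$inputs$ave_S$mfs$S2$threshold, 0.36)
  expect_true(all(vapply(fis$rules, function(r) length(r$antecedent),
                         integer(1)) <= 4))

  pat <- function(r) paste(sort(vapply(r$antecedent, function(tm)
    sprintf("%s:%s%s", tm$variable, if (tm$negated) "not_" else "", tm$mf),
    character(1))), collapse = "&")
  got <- vapply(fis$rules, function(r) paste0(pat(r), "=>", r$consequent),
                character(1))
  want <- c(
    "ave_Bs:B1&sum_entropy_HH:SE1=>Weed",
    "ave_Bs:B1&ave_S:S2&sum_entropy_HH:not_SE1=>Peanut",
    "ave_Bs:B1&ave_S:not_S2&correlation_LL:CM1&sum_entropy_HH:not_SE1=>Peanut",
    "ave_Bs:B1&ave_S:not_S2&correlation_LL:not_CM1&sum_entropy_HH:not_SE1=>Weed",
    "ave_Bs:not_B1&ave_S:S1&cluster_shade_LL:CS1=>Peanut",
    "ave_Bs:not_B1&ave_S:not_S1&cluster_shade_LL:CS1=>Weed",
    "ave_Bs:not_B1&cluster_shade_LL:not_CS1=>Weed")
  want <- vapply(strsplit(want, "=>"), function(p) {
    paste0(paste(sort(strsplit(p[1], "&")[[1]]), collapse = "&"), "=>", p[2])
  }, character(1))
  expect_setequal(got, want)
})

test_that("crisp outputs land on the published sides of the class boundary", {
  fis <- reference_rep_cfs()
  out <- predict(fis, data.frame(ave_Bs = c(5, 5, 30),
                                 cluster_shade_LL = c(300, 2000, 300)))
  # low ave_Bs and low cluster shade: weed (output above 1)
  expect_gt(out$crisp[1], 1)
  expect_equal(as.character(out$class[1]), "Weed")
  # high cluster shade or high ave_Bs: peanut (output below 1)
  expect_lt(out$crisp[2], 1)
  expect_equal(as.character(out$class[2]), "Peanut")
  expect_lt(out$crisp[3], 1)
  expect_equal(as.character(out$class[3]), "Peanut")
  expect_true(all(out$crisp >= 0 & out$crisp <= 2))
})

test_that("a single fully fired rule defuzzifies to its consequent centroid", {
  fis <- reference_rep_cfs()
  # deep weed region: only the not-B1/not-CS1 rule fires, at strength 1
  out <- predict(fis, data.frame(ave_Bs = 2, cluster_shade_LL = 100))
  grid <- seq(0, 2, length.out = 1001)
  mu <- mf_value(fis$output$mfs$Weed, grid)
  expect_equal(out$crisp, sum(grid * mu) / sum(mu))
})

test_that("inference clips out-of-universe inputs and flags uncovered ones", {
  fis <- reference_rep_cfs()
  expect_warning(out <- predict(fis, data.frame(ave_Bs = 500,
                                                cluster_shade_LL = 300)),
                 "clipped")
  expect_equal(as.character(out$class), "Peanut")

  # a gap system: single rule over a narrow membership leaves most of the
  # universe uncovered
  fisg <- as_fis(reference_rep_tree(), band = 0.05, side = "above")
  fisg$rules <- list(list(antecedent = list(list(variable = "ave_Bs",
                                                 mf = "AB1",
                                                 negated = FALSE)),
                          consequent = "Peanut"))
  expect_warning(out2 <- predict(fisg, data.frame(ave_Bs = 0,
                                                  cluster_shade_LL = 0)),
                 "uncovered")
  expect_equal(out2$crisp, 1)  # universe midpoint
})

test_that("fuzzy decisions agree with the source tree away from transitions", {
  d <- two_class_table(n_per_class = 25, gap = 4, seed = 12,
                       noise_features = 2)
  fit <- weed_tree(class ~ ., d, algorithm = "j48",
                   control = tree_control(min_leaf = 1))
  fis <- as_fis(fit, band = 0.05)
  expect_equal(fis_tree_agreement(fis, fit, n = 2000, seed = 3,
                                  off_band = TRUE), 1)
  expect_gte(fis_tree_agreement(fis, fit, n = 2000, seed = 3), 0.95)

  # shrinking the band makes the fuzzy boundary converge to the tree's
  ag <- vapply(c(0.10, 0.02, 0.005), function(b)
    fis_tree_agreement(as_fis(fit, band = b), fit, n = 2000, seed = 4),
    numeric(1))
  expect_true(all(diff(ag) >= -1e-9))
  expect_gte(ag[3], 0.99)
})

test_that("multi-class trees compile and infer with one output MF per class", {
  set.seed(17)
  d <- data.frame(class = factor(rep(c("A", "B", "C", "D"), each = 15)),
                  x1 = rep(c(0, 4, 8, 12), each = 15) + rnorm(60, sd = 0.4),
                  x2 = rnorm(60))
  fit <- weed_tree(class ~ ., d, algorithm = "j48")
  fis <- as_fis(fit, band = 0.05)
  expect_length(fis$output$mfs, 4)
  expect_equal(fis$output$universe, c(0, 4))
  out <- predict(fis, d)
  expect_true(all(out$crisp >= 0 & out$crisp <= 4))
  expect_gte(mean(as.character(out$class) == as.character(predict(fit, d))),
             0.9)
})

test_that("fuzzy systems round-trip through their JSON serialization", {
  fis <- reference_j48_cfs()
  path <- withr::local_tempfile(fileext = ".json")
  write_fis(fis, path)
  back <- read_fis(path)
  X <- data.frame(ave_Bs = c(5, 25, 40), sum_entropy_HH = c(1, 3, 2),
                  ave_S = c(0.1, 0.5, 0.3), correlation_LL = c(-0.5, 0.7, 0),
                  cluster_shade_LL = c(100, 1500, 900))
  expect_identical(predict(back, X), predict(fis, X))
  expect_equal(length(back$rules), length(fis$rules))
})
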