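# Reference-model training, scoring, mapping, PCA.

test_that("all three learners separate an easy two-class problem", {
  tab <- two_class_table(n_per_class = 30, p = 6, informative = 1:3,
                         effect = 1.6, well_cv = 0.05, seed = 2)
  for (algo in c("SVM", "LDA", "GBM")) {
    grid <- switch(algo, GBM = list(list(n_trees = 30, depth = 2,
                                         lr = 0.2)),
                   fast_grid)
    m <- train_reference(tab, "control", "mutant", algo,
                         fast_cv(seed = 2, n_repeats = 3), grid)
    expect_gte(m$accuracy, 0.95)
  }
})

test_that("no signal means chance accuracy; strong signal means 1.0", {
  null_tab <- two_class_table(n_per_class = 40, p = 8, informative = 1,
                              effect = 1, seed = 4)  # classes identical
  m0 <- train_reference(null_tab, "control", "mutant", "SVM",
                        fast_cv(seed = 4), fast_grid)
  expect_lt(abs(m0$accuracy - 0.5), 0.15)
  sep <- two_class_table(n_per_class = 30, p = 5, informative = 1,
                         effect = 3, well_cv = 0.02, seed = 5)
  m1 <- train_reference(sep, "control", "mutant", "SVM",
                        fast_cv(seed = 5), fast_grid)
  expect_equal(m1$accuracy, 1.0)
})

test_that("training is deterministic given the seed and reports SEM", {
  tab <- two_class_table(seed = 6)
  m1 <- train_reference(tab, "control", "mutant", "SVM",
                        fast_cv(seed = 9), fast_grid)
  m2 <- train_reference(tab, "control", "mutant", "SVM",
                        fast_cv(seed = 9), fast_grid)
  expect_identical(m1$accuracies, m2$accuracies)
  expect_identical(score_wells(m1, tab)$raw, score_wells(m2, tab)$raw)
  expect_equal(m1$accuracy_sem,
               sd(m1$accuracies) / sqrt(length(m1$accuracies)))
})

test_that("score anchors map training class medians to exactly 0 and 1", {
  tab <- two_class_table(n_per_class = 31, p = 8, informative = 1:2,
                         effect = 1.5, seed = 7)
  m <- train_reference(tab, "control", "mutant", "SVM", fast_cv(seed = 7),
                       fast_grid)
  sc <- score_wells(m, tab)
  expect_equal(median(sc$normalized[sc$condition == "control"]), 0,
               tolerance = 1e-10)
  expect_equal(median(sc$normalized[sc$condition == "mutant"]), 1,
               tolerance = 1e-10)
})

test_that("a half-shifted condition maps near the middle of the axis", {
  cat_ <- tiny_catalogue(8)
  rules <- setNames(rep(1.5, 3), paste0("^", cat_$name[1:3], "$"))
  ctrl <- effect_profile(cat_)
  mut <- effect_profile(cat_, rules)
  half <- effect_profile(cat_, rules, shift_toward = ctrl, lambda = 0.5)
  lay <- flat_layout(list(control = 40, mutant = 40, treated = 30))
  st <- sample_feature_table(lay, cat_,
                             list(control = ctrl, mutant = mut,
                                  treated = half),
                             noise_model(0.03, 0, 0, 0),
                             fields_per_well = 1, seed = 8)
  m <- train_reference(st$table, "control", "mutant", "SVM",
                       fast_cv(seed = 8), fast_grid)
  sc <- score_wells(m, st$table)
  med <- median(sc$normalized[sc$condition == "treated"])
  expect_gte(med, 0.3)
  expect_lte(med, 0.7)
})

test_that("conditions generated as the negative class score near 0", {
  cat_ <- tiny_catalogue(6)
  rules <- setNames(1.4, paste0("^", cat_$name[1], "$"))
  lay <- flat_layout(list(control = 40, mutant = 40, lookalike = 30))
  st <- sample_feature_table(
    lay, cat_, list(control = effect_profile(cat_),
                    mutant = effect_profile(cat_, rules),
                    lookalike = effect_profile(cat_)),
    noise_model(0.05, 0, 0, 0), fields_per_well = 1, seed = 9)
  m <- train_reference(st$table, "control", "mutant", "SVM",
                       fast_cv(seed = 9), fast_grid)
  sc <- score_wells(m, st$table)
  like <- sc$normalized[sc$condition == "lookalike"]
  se <- sd(like) / sqrt(length(like))
  expect_lte(abs(median(like)), 3 * se + 0.05)
})

test_that("scores are invariant to a global positive feature rescaling", {
  tab <- two_class_table(n_per_class = 25, p = 6, informative = 1,
                         effect = 1.5, seed = 10)
  m <- train_reference(tab, "control", "mutant", "SVM", fast_cv(seed = 10),
                       fast_grid)
  tab2 <- tab
  for (f in feature_cols(tab2)) tab2[[f]] <- tab2[[f]] * 3.7
  # standardization inside each fit removes the scale only for the
  # features the fit centered; rescaling all raw features uniformly
  # multiplies centered values by c, which cancels in the anchor map
  sc1 <- score_wells(m, tab)$normalized
  sc2 <- score_wells(m, tab2)$normalized
  expect_equal(order(sc1), order(sc2))
})

test_that("missing model features raise a mapping error", {
  tab <- two_class_table(seed = 11)
  m <- train_reference(tab, "control", "mutant", "SVM", fast_cv(seed = 11),
                       fast_grid)
  expect_error(score_wells(m, tab[setdiff(names(tab), "f01")]),
               "mapping error.*f01")
  expect_error(train_reference(tab, "control", "absent", "SVM"),
               "class error")
})

test_that("cross-plate validation generalizes without batch effects", {
  cat_ <- tiny_catalogue(8)
  rules <- setNames(rep(1.5, 2), paste0("^", cat_$name[1:2], "$"))
  eff <- list(control = effect_profile(cat_),
              mutant = effect_profile(cat_, rules))
  tabs <- lapply(1:3, function(i) {
    lay <- flat_layout(list(control = 30, mutant = 30),
                       plate_id = paste0("P", i))
    sample_feature_table(lay, cat_, eff, noise_model(0.05, 0, 0, 0),
                         fields_per_well = 1, seed = 20 + i)$table
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("feature_table", "data.frame")
  cpv <- cross_plate_validate(tab, "control", "mutant", "SVM",
                              fast_cv(seed = 12), fast_grid)
  within <- train_reference(tabs[[1]], "control", "mutant", "SVM",
                            fast_cv(seed = 12), fast_grid)$accuracy
  expect_true(all(abs(cpv$accuracy - within) <= 0.05 + 1e-9))
  # label shuffling destroys generalization
  shuf <- tab
  set.seed(1)
  shuf$condition[shuf$plate_id == "P1"] <-
    sample(shuf$condition[shuf$plate_id == "P1"])
  cpv0 <- cross_plate_validate(shuf, "control", "mutant", "SVM",
                               fast_cv(seed = 12), fast_grid)
  expect_lt(mean(cpv0$accuracy[cpv0$train_plate == "P1"]), 0.65)
  expect_error(cross_plate_validate(tabs[[1]], "control", "mutant"),
               ">= 2 plates")
})

test_that("PCA embedding: variance accounting and class separation", {
  lay <- flat_layout(list(control = 30))
  tab <- data.frame(lay, f1 = rnorm(30), stringsAsFactors = FALSE)
  tab$f2 <- 2 * tab$f1
  class(tab) <- c("feature_table", "data.frame")
  expect_warning(em <- pca_embed(tab, 2), "rank")
  expect_equal(em$explained[1], 1.0, tolerance = 1e-9)
  # isotropic noise spreads variance evenly
  set.seed(3)
  iso <- data.frame(flat_layout(list(control = 400)),
                    matrix(rnorm(400 * 5), 400, 5))
  names(iso)[8:12] <- paste0("f", 1:5)
  class(iso) <- c("feature_table", "data.frame")
  emi <- pca_embed(iso, 5)
  expect_true(all(abs(emi$explained - 0.2) < 0.05))
  expect_true(all(diff(emi$explained) <= 1e-12))
  # separated classes split along PC1
  sep <- two_class_table(n_per_class = 50, p = 5, informative = 1:2,
                         effect = 1.8, well_cv = 0.05, seed = 14)
  ems <- pca_embed(sep, 2)
  pc1 <- ems$coords[, 1]
  cl <- ems$meta$condition
  gap <- abs(median(pc1[cl == "control"]) - median(pc1[cl == "mutant"]))
  spread <- max(sd(pc1[cl == "control"]), sd(pc1[cl == "mutant"]))
  expect_gt(gap, 3 * spread)
})

test_that("models survive a save/load round trip", {
  tab <- two_class_table(n_per_class = 20, p = 5, informative = 1,
                         effect = 1.6, seed = 15)
  for (algo in c("SVM", "GBM")) {
    grid <- switch(algo, GBM = list(list(n_trees = 10, depth = 2,
                                         lr = 0.3)),
                   fast_grid)
    m <- train_reference(tab, "control", "mutant", algo,
                         fast_cv(seed = 15, n_repeats = 3), grid)
    dir <- tempfile("model")
    save_model(m, dir)
    m2 <- load_model(dir)
    expect_equal(score_wells(m2, tab)$normalized,
                 score_wells(m, tab)$normalized, tolerance = 1e-12)
    unlink(dir, recursive = TRUE)
  }
})
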