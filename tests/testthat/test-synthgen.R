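cat_A <- feature_catalogue("panelA")

test_that("plate layout: capacity, balance, spiking", {
  spec <- plate_spec(seed = 1)
  expect_equal(nrow(usable_wells(spec)), 308)  # 14 x 22 without edges
  lay <- make_layout(spec, list(control = "fill", mutant = "fill"),
                     seed = 3)
  expect_lte(abs(sum(lay$condition == "control") -
                 sum(lay$condition == "mutant")), 1)
  expect_equal(nrow(lay), 308)
  # six spiked wells per compound, drawn from mutant wells, none on edge
  lay2 <- make_layout(spec, list(control = 100, mutant = "fill"),
                      n_spiked_per_compound = 6,
                      compounds = c("PEP005", "prostratin"),
                      spike_from = "mutant", seed = 3)
  spk <- lay2[lay2$spiked == 1, ]
  expect_equal(nrow(spk), 12)
  expect_equal(length(unique(spk$well)), 12)
  expect_true(all(spk$condition == "mutant"))
  expect_true(all(spk$row > 1 & spk$row < 16 & spk$col > 1 & spk$col < 24))
  expect_equal(sort(unique(spk$compound)), c("PEP005", "prostratin"))
  # over-allocation
  expect_error(make_layout(spec, list(a = 300, b = 100)), "capacity")
  # determinism
  expect_identical(lay2, make_layout(spec, list(control = 100,
                                                mutant = "fill"),
                                     n_spiked_per_compound = 6,
                                     compounds = c("PEP005", "prostratin"),
                                     spike_from = "mutant", seed = 3))
})

test_that("noise-free tables reproduce baselines and effect sizes", {
  spec <- plate_spec(seed = 1)
  lay <- make_layout(spec, list(control = "fill", mutant = "fill"),
                     seed = 1)
  eff <- default_effects(cat_A)
  st <- sample_feature_table(lay, cat_A, eff, noise_model(0, 0, 0, 0),
                             fields_per_well = 9, seed = 1)
  tab <- st$table
  ctrl <- tab[tab$condition == "control", ]
  # control wells identical to baseline
  for (f in c("nuclei_count", "TH_pos_aSyn_int_mean"))
    expect_equal(unique(ctrl[[f]]),
                 cat_A$baseline[cat_A$name == f], tolerance = 1e-12)
  # mutant aSyn intensity is baseline x 1.15 exactly, TMRM-free panel
  mut <- tab[tab$condition == "mutant", ]
  expect_equal(mean(mut$TH_pos_aSyn_int_mean) /
                 mean(ctrl$TH_pos_aSyn_int_mean), 1.15,
               tolerance = 1e-12)
  # branch features down, aggregate area up
  expect_equal(mean(mut$neurites_branch_points) /
                 mean(ctrl$neurites_branch_points), 0.70,
               tolerance = 1e-12)
  expect_equal(mean(mut$TH_pos_agg_area_total_per_cell) /
                 mean(ctrl$TH_pos_agg_area_total_per_cell), 1.50,
               tolerance = 1e-12)
})

test_that("mitochondrial panel effects: TMRM x0.67, compactness x1.2", {
  cat_m <- feature_catalogue("panelMito")
  eff <- default_effects(cat_m)
  f <- eff$mutant$factors
  expect_equal(unname(f["mito_TMRM_int_mean"]), 0.67)
  expect_equal(unname(f["mito_compactness_mean"]), 1.2)
  expect_equal(unname(f["nuclei_count"]), 1)
})

test_that("well CV matches the noise model", {
  # ~900 wells across 3 plates, field and plate noise off so the
  # well-level CV is isolated
  eff <- list(control = effect_profile(cat_A))
  tabs <- lapply(1:3, function(i) {
    lay <- flat_layout(list(control = 308), plate_id = paste0("P", i))
    sample_feature_table(lay, cat_A, eff,
                         noise_model(well_cv = 0.10, plate_batch_sd = 0,
                                     field_cv = 0, outlier_rate = 0),
                         fields_per_well = 1, seed = i)$table
  })
  tab <- do.call(rbind, tabs)
  cvs <- vapply(feature_cols(tab)[1:20], function(f)
    sd(tab[[f]]) / mean(tab[[f]]), numeric(1))
  expect_true(all(abs(cvs - 0.10) < 0.01))
})

test_that("compound shift composes log-linearly between mutant and control", {
  rules <- c("_aSyn_int_" = 1.15, "branch" = 0.7)
  ctrl <- effect_profile(cat_A)
  mut <- effect_profile(cat_A, rules)
  full <- effect_profile(cat_A, rules, shift_toward = ctrl, lambda = 1)
  none <- effect_profile(cat_A, rules, shift_toward = ctrl, lambda = 0)
  half <- effect_profile(cat_A, rules, shift_toward = ctrl, lambda = 0.5)
  expect_equal(full$factors, ctrl$factors, tolerance = 1e-12)
  expect_equal(none$factors, mut$factors, tolerance = 1e-12)
  expect_equal(unname(half$factors["TH_pos_aSyn_int_mean"]),
               sqrt(1.15), tolerance = 1e-12)
})

test_that("monotonicity: larger effect factor raises the condition mean", {
  lay <- flat_layout(list(mutant = 20))
  vals <- vapply(c(1.0, 1.2, 1.5), function(fct) {
    eff <- list(mutant = effect_profile(cat_A,
                                        c("^nuclei_count$" = fct)))
    st <- sample_feature_table(lay, cat_A, eff, noise_model(0, 0, 0, 0),
                               fields_per_well = 1, seed = 1)
    mean(st$table$nuclei_count)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("generation is deterministic and truth is separate", {
  lay <- flat_layout(list(control = 10, mutant = 10))
  eff <- default_effects(cat_A)
  a <- sample_feature_table(lay, cat_A, eff, seed = 7)
  b <- sample_feature_table(lay, cat_A, eff, seed = 7)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$condition_factors, b$truth$condition_factors)
  expect_s3_class(a$truth, "ground_truth")
  # the table carries layout metadata but no truth factors
  expect_false(any(c("condition_factors", "outlier") %in% names(a$table)))
  # unknown condition errors
  expect_error(sample_feature_table(lay, cat_A,
                                    eff["control"], seed = 1),
               "no effect profile")
})

test_that("plate map round-trips through CSV", {
  lay <- make_layout(plate_spec(seed = 2), list(control = "fill",
                                                mutant = "fill"))
  path <- tempfile(fileext = ".csv")
  write_plate_map(lay, path)
  lay2 <- read_plate_map(path)
  expect_equal(as.data.frame(lay), as.data.frame(lay2))
  unlink(path)
})
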