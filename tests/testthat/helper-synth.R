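# Shared fixtures, all generated in code.

# minimal catalogue of p iid features (baseline 100)
tiny_catalogue <- function(p, baseline = 100) {
  data.frame(name = sprintf("f%02d", seq_len(p)), panel = "panelA",
             channel = "aSyn", population = "field", family = "intensity",
             baseline = baseline, stringsAsFactors = FALSE)
}

# flat layout without plate geometry: counts per condition, one plate
flat_layout <- function(counts, plate_id = "P1", compound = "DMSO") {
  n <- sum(unlist(counts))
  data.frame(plate_id = plate_id, well = sprintf("W%04d", seq_len(n)),
             row = 1L, col = seq_len(n),
             condition = rep(names(counts), unlist(counts)),
             compound = compound, spiked = 0L, stringsAsFactors = FALSE)
}

# two-class table over a tiny catalogue; `informative` features get
# `effect` as the mutant multiplicative factor
two_class_table <- function(n_per_class = 50, p = 10, informative = 1,
                            effect = 1.3, well_cv = 0.10, seed = 1,
                            plate_id = "P1") {
  cat_ <- tiny_catalogue(p)
  lay <- flat_layout(list(control = n_per_class, mutant = n_per_class),
                     plate_id = plate_id)
  rules <- setNames(rep(effect, length(informative)),
                    paste0("^", cat_$name[informative], "$"))
  eff <- list(control = effect_profile(cat_),
              mutant = effect_profile(cat_, rules))
  sample_feature_table(lay, cat_, eff,
                       noise_model(well_cv = well_cv, plate_batch_sd = 0,
                                   field_cv = 0, outlier_rate = 0),
                       fields_per_well = 1, seed = seed)$table
}

# quick CV spec for unit tests (full 25-repeat spec used in acceptance)
fast_cv <- function(seed = 1, n_repeats = 5L) cv_spec(n_repeats = n_repeats,
                                                      seed = seed)
fast_grid <- list(list(C = 1))

expect_feature_table <- function(tab) {
  expect_s3_class(tab, "feature_table")
  expect_true(all(c("plate_id", "well", "condition", "compound",
                    "spiked") %in% names(tab)))
}
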