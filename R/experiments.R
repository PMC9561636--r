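# Canned end-to-end experiments used by the acceptance machinery. These
# run the public pipeline; they exist so the test suite and the
# acceptance report execute the identical recipe.

#' Null beyond-3-SD hit-rate experiment
#'
#' Trains an SVM reference model on two synthetic plates (control vs
#' mutant, default effect profile and noise model), then generates fresh
#' mutant-DMSO wells from the identical null, preprocesses them the same
#' way (per-plate median normalization to control, robust outlier-well
#' removal), scores them through the trained model, and calls hits at
#' `k = 3` against the scored null wells' own median and SD. Under a
#' well-behaved score distribution the beyond-3-SD fraction approaches
#' the two-sided normal tail `2 * pnorm(-3)` (about 0.27%) and stays
#' below 1%.
#'
#' @param seed integer seed for the whole experiment.
#' @param n_null_plates pseudo-plates of fresh null wells.
#' @param wells_per_null_plate mutant wells per pseudo-plate (plus 20
#'   control wells for normalization).
#' @param k hit threshold in reference SDs.
#' @return list: `hit_fraction`, `n_scored`, `model_accuracy`, `k`.
#' @export
null_hit_rate_experiment <- function(seed = 1L, n_null_plates = 11L,
                                     wells_per_null_plate = 1000L,
                                     k = 3) {
  cat_A <- feature_catalogue("panelA")
  effects <- default_effects(cat_A)[c("control", "mutant")]
  noise <- noise_model()
  spec <- plate_spec(seed = seed)

  train_tabs <- lapply(1:2, function(i) {
    lay <- make_layout(spec, list(control = "fill", mutant = "fill"),
                       plate_id = sprintf("T%02d", i),
                       seed = child_seed(seed, paste0("train", i)))
    sample_feature_table(lay, cat_A, effects, noise,
                         fields_per_well = spec$fields_per_well,
                         seed = child_seed(seed, paste0("ttab", i)))$table
  })
  train_raw <- do.call(rbind, train_tabs)
  class(train_raw) <- c("feature_table", "data.frame")
  pp <- preprocess(train_raw, "control")
  model <- train_reference(pp$table, "control", "mutant", "SVM",
                           cv_spec(seed = child_seed(seed, "cv")))

  null_tabs <- lapply(seq_len(n_null_plates), function(i) {
    lay <- data.frame(
      plate_id = sprintf("N%02d", i),
      well = sprintf("W%04d", seq_len(wells_per_null_plate + 20)),
      row = 1L, col = seq_len(wells_per_null_plate + 20),
      condition = rep(c("control", "mutant"),
                      c(20, wells_per_null_plate)),
      compound = "DMSO", spiked = 0L, stringsAsFactors = FALSE)
    sample_feature_table(lay, cat_A, effects, noise,
                         fields_per_well = spec$fields_per_well,
                         seed = child_seed(seed, paste0("null", i)))$table
  })
  null_raw <- do.call(rbind, null_tabs)
  class(null_raw) <- c("feature_table", "data.frame")
  norm <- normalize_to_reference(null_raw, "control")
  filt <- remove_outlier_wells(norm$table)
  null_tab <- filt$table[filt$table$condition == "mutant", ]
  class(null_tab) <- c("feature_table", "data.frame")

  sc <- score_wells(model, null_tab)
  hc <- call_hits(sc, sc$normalized, k = k)
  list(hit_fraction = mean(hc$calls$hit), n_scored = nrow(sc),
       model_accuracy = model$accuracy, k = k)
}
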