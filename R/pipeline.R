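# End-to-end orchestration: simulate/extract -> preprocess -> train ->
# score -> screening statistics, with a machine-readable manifest and
# full seed propagation.

#' Build a run configuration
#'
#' @param panel staining panel.
#' @param out_dir run output directory.
#' @param n_plates number of synthetic plates.
#' @param wells_per_class reference wells per class per plate.
#' @param compounds named numeric vector of compound rescue fractions
#'   (lambda toward control).
#' @param n_spiked_per_compound spiked wells per compound per plate.
#' @param reference_condition normalization reference label.
#' @param class_neg,class_pos reference classes for training.
#' @param algorithm classifier.
#' @param cv a [cv_spec()]; its seed is overridden by `seed`.
#' @param noise a [noise_model()].
#' @param k hit-calling SD multiple.
#' @param r_threshold correlation-pruning threshold.
#' @param seed global seed propagated to every stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(panel = "panelA", out_dir = tempfile("psrun"),
                       n_plates = 2L, wells_per_class = 60L,
                       compounds = c(PEP005 = 0.3, prostratin = 0.6),
                       n_spiked_per_compound = 6L,
                       reference_condition = "control",
                       class_neg = "control", class_pos = "mutant",
                       algorithm = "SVM", cv = cv_spec(),
                       noise = noise_model(), k = 3, r_threshold = 0.9,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$cv$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Scalar fields override [run_config()] defaults; `compounds` is a named
#' mapping of rescue fractions, `cv` and `noise` nested mappings.
#'
#' @param path YAML file.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cv", "noise", "compounds"))]
  if (!is.null(y$compounds)) args$compounds <- unlist(y$compounds)
  if (!is.null(y$cv)) args$cv <- do.call(cv_spec, y$cv)
  if (!is.null(y$noise)) args$noise <- do.call(noise_model, y$noise)
  do.call(run_config, args)
}

#' Run the full synthetic screening pipeline
#'
#' Simulates plates, preprocesses, trains the reference model, scores all
#' wells, and computes Z-factor and hit calls. Outputs (tables, scores,
#' statistics, manifest) are written under `config$out_dir`; rerunning
#' with the same config reproduces identical numbers.
#'
#' @param config a [run_config()].
#' @return invisible list with the in-memory results (`table_raw`,
#'   `table`, `prep_report`, `model`, `scores`, `zfactor`, `hits`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  catalogue <- feature_catalogue(config$panel)
  effects <- default_effects(catalogue, lambda = config$compounds)
  if (!config$reference_condition %in% c("control", "mutant"))
    stop("stage simulate: reference condition '",
         config$reference_condition, "' is not generated")

  spec <- plate_spec(panel = config$panel, seed = config$seed)
  tabs <- list(); truths <- list()
  for (i in seq_len(config$n_plates)) {
    lay <- make_layout(
      spec,
      conditions = list(control = config$wells_per_class,
                        mutant = "fill"),
      n_spiked_per_compound = config$n_spiked_per_compound,
      compounds = names(config$compounds),
      spike_from = "mutant", plate_id = sprintf("P%02d", i),
      seed = child_seed(config$seed, paste0("plate", i)))
    st <- sample_feature_table(lay, catalogue, effects, config$noise,
                               fields_per_well = spec$fields_per_well,
                               seed = child_seed(config$seed,
                                                 paste0("table", i)))
    tabs[[i]] <- st$table; truths[[i]] <- st$truth
  }
  raw <- do.call(rbind, tabs)
  class(raw) <- c("feature_table", "data.frame")
  write.csv(raw, file.path(config$out_dir, "features_raw.csv"),
            row.names = FALSE)

  pp <- preprocess(raw, config$reference_condition,
                   r_threshold = config$r_threshold)
  write.csv(pp$table, file.path(config$out_dir, "features_processed.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    pp$report, file.path(config$out_dir, "prep_report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  ref <- pp$table[pp$table$compound == "DMSO", , drop = FALSE]
  class(ref) <- c("feature_table", "data.frame")
  model <- train_reference(ref, config$class_neg, config$class_pos,
                           config$algorithm, config$cv)
  scores <- score_wells(model, pp$table)
  write.csv(scores, file.path(config$out_dir, "scores.csv"),
            row.names = FALSE)

  is_ref_dmso <- function(cl) scores$condition == cl &
    scores$compound == "DMSO"
  zf <- z_factor(scores$normalized[is_ref_dmso(config$class_pos)],
                 scores$normalized[is_ref_dmso(config$class_neg)])
  hits <- call_hits(scores[!is_ref_dmso(config$class_neg), , drop = FALSE],
                    scores$normalized[is_ref_dmso(config$class_pos)],
                    k = config$k)
  write.csv(hits$calls, file.path(config$out_dir, "hit_calls.csv"),
            row.names = FALSE)

  cfg_plain <- config
  cfg_plain$cv <- unclass(cfg_plain$cv)
  cfg_plain$noise <- unclass(cfg_plain$noise)
  manifest <- list(
    package = "phenoscreen",
    version = as.character(utils::packageVersion("phenoscreen")),
    seed = config$seed,
    config_hash = digest::digest(unclass(cfg_plain)),
    config = unclass(cfg_plain),
    model = list(algorithm = model$algorithm,
                 accuracy = model$accuracy,
                 accuracy_sem = model$accuracy_sem,
                 n_features = length(model$features)),
    z_factor = zf$z,
    hit_summary = hits$summary)
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(
    sprintf("phenoscreen run (seed %d, config %s)", config$seed,
            substr(manifest$config_hash, 1, 8)),
    sprintf("model: %s, accuracy %.3f +/- %.3f SEM", model$algorithm,
            model$accuracy, model$accuracy_sem),
    sprintf("Z-factor (%s vs %s): %.3f", config$class_pos,
            config$class_neg, zf$z),
    "hit fractions:",
    sprintf("  %-10s %-12s %.3f", hits$summary$condition,
            hits$summary$compound, hits$summary$hit_fraction)),
    file.path(config$out_dir, "report.txt"))

  invisible(list(table_raw = raw, table = pp$table,
                 prep_report = pp$report, model = model, scores = scores,
                 zfactor = zf, hits = hits, manifest = manifest,
                 truths = truths))
}
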