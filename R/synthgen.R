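# Synthetic plate generator.
#
# Emulates the study design: 384-well plates (edge wells excluded from
# seeding), 9 fields per well averaged to one row per well, two genotype
# classes separated along a multi-feature axis (aSyn intensity +15%, TMRM
# intensity -33%, fewer branches, more compact mitochondria, more
# pS129-like aggregate area), compound treatments that shift mutant wells
# partway toward control, per-plate batch factors, and a handful of
# randomly spiked compound wells per plate. All noise is multiplicative
# log-normal so intensity-like features stay positive.

#' Plate geometry and acquisition specification
#'
#' @param rows,cols plate dimensions (default 16 x 24 = 384 wells).
#' @param exclude_edge drop the outer ring of wells (default TRUE; usable
#'   wells are then 14 x 22 = 308).
#' @param fields_per_well imaging fields averaged per well (default 9,
#'   a 3 x 3 montage).
#' @param panel staining panel, see [feature_catalogue()].
#' @param seed integer seed for layout draws.
#' @return object of class `plate_spec`.
#' @export
plate_spec <- function(rows = 16L, cols = 24L, exclude_edge = TRUE,
                       fields_per_well = 9L, panel = "panelA", seed = 1L) {
  stopifnot(is_count(rows), is_count(cols), is_count(fields_per_well),
            fields_per_well >= 1, rows * cols == 384)
  panel <- match.arg(panel, PANELS)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 exclude_edge = isTRUE(exclude_edge),
                 fields_per_well = as.integer(fields_per_well),
                 panel = panel, seed = as.integer(seed)),
            class = "plate_spec")
}

#' Usable wells of a plate
#'
#' @param spec a [plate_spec()].
#' @return data.frame with `well`, `row`, `col` for every assignable well.
#' @export
usable_wells <- function(spec) {
  g <- expand.grid(row = seq_len(spec$rows), col = seq_len(spec$cols))
  if (spec$exclude_edge)
    g <- g[g$row > 1 & g$row < spec$rows & g$col > 1 & g$col < spec$cols, ]
  g <- g[order(g$row, g$col), ]
  data.frame(well = well_name(g$row, g$col), row = g$row, col = g$col,
             stringsAsFactors = FALSE)
}

#' Well-to-well variability model
#'
#' All components are multiplicative log-normal: `well_cv` is the target
#' coefficient of variation of a feature across wells, `plate_batch_sd` the
#' log-scale SD of a per-plate-per-feature batch factor, `field_cv` the CV
#' of a single field around its well mean (averaged over
#' `fields_per_well`). With probability `outlier_rate` a well is corrupted
#' by multiplying every feature by `outlier_scale` or its inverse.
#'
#' @param well_cv,plate_batch_sd,field_cv,outlier_rate,outlier_scale see
#'   description.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(well_cv = 0.10, plate_batch_sd = 0.05,
                        field_cv = 0.15, outlier_rate = 0.01,
                        outlier_scale = 5) {
  stopifnot(well_cv >= 0, plate_batch_sd >= 0, field_cv >= 0,
            outlier_rate >= 0, outlier_rate < 0.1, outlier_scale > 0)
  structure(list(well_cv = well_cv, plate_batch_sd = plate_batch_sd,
                 field_cv = field_cv, outlier_rate = outlier_rate,
                 outlier_scale = outlier_scale), class = "noise_model")
}

#' Per-feature multiplicative effect profile for a condition
#'
#' A profile maps catalogue feature names to positive multiplicative
#' factors (unlisted features have factor 1). Profiles are built from
#' regex rules applied to the catalogue, e.g. the default mutant profile
#' scales all aSyn intensity features by 1.15.
#'
#' @param catalogue a [feature_catalogue()] data.frame.
#' @param rules named numeric vector: names are regular expressions matched
#'   against feature names, values the multiplicative factors. Later rules
#'   multiply onto earlier ones.
#' @param shift_toward optional reference `effect_profile`; the factors are
#'   interpolated in log space toward it by `lambda` (0 = unchanged,
#'   1 = equal to `shift_toward`), emulating a compound rescue.
#' @param lambda shift fraction in \[0, 1\].
#' @return object of class `effect_profile`: named factor vector over the
#'   full catalogue.
#' @export
effect_profile <- function(catalogue, rules = numeric(),
                           shift_toward = NULL, lambda = 0) {
  stopifnot(lambda >= 0, lambda <= 1, all(rules > 0))
  f <- setNames(rep(1, nrow(catalogue)), catalogue$name)
  for (i in seq_along(rules)) {
    hit <- grepl(names(rules)[i], names(f))
    f[hit] <- f[hit] * rules[[i]]
  }
  if (!is.null(shift_toward)) {
    stopifnot(inherits(shift_toward, "effect_profile"),
              identical(names(shift_toward$factors), names(f)))
    f <- exp((1 - lambda) * log(f) + lambda * log(shift_toward$factors))
  }
  structure(list(factors = f, rules = rules, lambda = lambda),
            class = "effect_profile")
}

#' Default genotype and compound effect profiles
#'
#' The mutant profile carries the observed phenotype effect sizes: aSyn
#' intensity x1.15, TMRM intensity x0.67, branch-related features x0.7,
#' mitochondrial compactness x1.2, aggregate (pS129-like) area x1.5.
#' Compound profiles shift the mutant profile a fraction `lambda` toward
#' control and may add compound-specific aSyn lowering (PEP005 x0.85,
#' prostratin x0.75).
#'
#' @param catalogue a [feature_catalogue()] data.frame.
#' @param lambda named numeric vector of rescue fractions per compound.
#' @return named list of `effect_profile`s: control, mutant, and one per
#'   compound in `lambda`.
#' @export
default_effects <- function(catalogue,
                            lambda = c(PEP005 = 0.3, prostratin = 0.6)) {
  mutant_rules <- c(
    "_aSyn_int_"          = 1.15,
    "_TMRM_int_(mean|median|sd|p90|total)" = 0.67,
    "branch"              = 0.70,
    "mito_compactness"    = 1.20,
    "agg_(area|count)"    = 1.50
  )
  control <- effect_profile(catalogue)
  mutant <- effect_profile(catalogue, mutant_rules)
  out <- list(control = control, mutant = mutant)
  extra <- c(PEP005 = 0.85, prostratin = 0.75)
  for (cmp in names(lambda)) {
    prof <- effect_profile(catalogue, mutant_rules, shift_toward = control,
                           lambda = lambda[[cmp]])
    if (cmp %in% names(extra)) {
      hit <- grepl("_aSyn_int_", names(prof$factors))
      prof$factors[hit] <- prof$factors[hit] * extra[[cmp]]
    }
    out[[cmp]] <- prof
  }
  out
}

#' Assign conditions and spiked compound wells to a plate
#'
#' Every usable well receives exactly one condition; spiked compound wells
#' are drawn uniformly at random without replacement from the mutant
#' reference wells (emulating randomly placed single compound wells in an
#' otherwise untreated plate).
#'
#' @param spec a [plate_spec()].
#' @param conditions named vector/list: condition label -> number of wells,
#'   or `"fill"` to split the remaining wells evenly among all `"fill"`
#'   conditions (difference at most 1).
#' @param n_spiked_per_compound wells per compound to spike (default 0).
#' @param compounds character vector of compound labels to spike.
#' @param spike_from condition label whose wells are eligible for spiking.
#' @param plate_id plate identifier string.
#' @param seed integer; the draw is deterministic given the seed.
#' @return `plate_layout`: data.frame with `plate_id`, `well`, `row`,
#'   `col`, `condition`, `compound`, `spiked`.
#' @export
make_layout <- function(spec, conditions, n_spiked_per_compound = 0L,
                        compounds = character(), spike_from = NULL,
                        plate_id = "P1", seed = spec$seed) {
  uw <- usable_wells(spec)
  n <- nrow(uw)
  counts <- vapply(conditions, function(x)
    if (identical(x, "fill")) NA_real_ else as.numeric(x), numeric(1))
  labs <- names(conditions)
  stopifnot(!is.null(labs), !anyDuplicated(labs))
  fixed <- sum(counts, na.rm = TRUE)
  n_fill <- sum(is.na(counts))
  if (fixed > n || (n_fill == 0 && fixed > n))
    stop("plate capacity exceeded: ", fixed, " wells requested, ",
         n, " usable")
  if (n_fill > 0) {
    rem <- n - fixed
    if (rem < n_fill) stop("plate capacity exceeded: nothing left to fill")
    base <- rem %/% n_fill
    extra <- rem %% n_fill
    counts[is.na(counts)] <- base + c(rep(1, extra), rep(0, n_fill - extra))
  } else if (fixed != n) {
    stop("conditions cover ", fixed, " of ", n,
         " usable wells; add a \"fill\" condition or match the count")
  }
  assign <- rep(labs, counts)
  lay <- with_seed(seed, "layout", {
    uw$condition <- sample(assign)[seq_len(n)]
    uw$compound <- "DMSO"
    uw$spiked <- 0L
    if (n_spiked_per_compound > 0) {
      stopifnot(length(compounds) > 0, !is.null(spike_from))
      pool <- which(uw$condition == spike_from)
      need <- n_spiked_per_compound * length(compounds)
      if (length(pool) < need)
        stop("not enough ", spike_from, " wells to spike: need ", need)
      pick <- sample(pool, need)
      uw$compound[pick] <- rep(compounds, each = n_spiked_per_compound)
      uw$spiked[pick] <- 1L
    }
    uw
  })
  lay <- cbind(plate_id = plate_id, lay, stringsAsFactors = FALSE)
  class(lay) <- c("plate_layout", "data.frame")
  lay
}

# condition key used to pick the effect profile for a well
.effect_key <- function(layout) {
  ifelse(layout$spiked == 1L, layout$compound, layout$condition)
}

#' Sample a well-level feature table with ground truth
#'
#' One row per usable well. A feature value is
#' `baseline * condition factor * plate factor * well factor`, where the
#' well factor is the mean over `fields_per_well` simulated field factors.
#' All factors are recorded in the returned ground truth; the feature
#' table itself carries no truth columns beyond the layout metadata
#' (spiked wells are only revealed by their `spiked`/`compound` metadata,
#' which downstream screening code must not use for calling).
#'
#' @param layout a [make_layout()] result (or several rbind-ed plates).
#' @param catalogue a [feature_catalogue()] data.frame.
#' @param effects named list of [effect_profile()]s covering every value of
#'   condition (and compound label for spiked wells) in the layout.
#' @param noise a [noise_model()].
#' @param fields_per_well fields averaged per well.
#' @param seed integer seed; generation is deterministic given it.
#' @return list with `table` (feature_table data.frame) and `truth`
#'   (ground_truth: per-well applied factors, outlier and spike flags).
#' @export
sample_feature_table <- function(layout, catalogue, effects,
                                 noise = noise_model(),
                                 fields_per_well = 9L, seed = 1L) {
  stopifnot(nrow(catalogue) > 0)
  keys <- .effect_key(layout)
  missing <- setdiff(unique(keys), names(effects))
  if (length(missing))
    stop("no effect profile for condition(s): ",
         paste(missing, collapse = ", "))
  p <- nrow(catalogue)
  nw <- nrow(layout)
  base <- catalogue$baseline
  sd_w <- sqrt(log(1 + noise$well_cv^2))
  sd_f <- sqrt(log(1 + noise$field_cv^2))
  with_seed(seed, "table", {
    plates <- unique(layout$plate_id)
    plate_fac <- matrix(1, length(plates), p,
                        dimnames = list(plates, catalogue$name))
    if (noise$plate_batch_sd > 0)
      plate_fac[] <- exp(matrix(rnorm(length(plates) * p, 0,
                                      noise$plate_batch_sd),
                                length(plates), p))
    cond_fac <- t(vapply(keys, function(k) effects[[k]]$factors,
                         numeric(p)))
    well_fac <- exp(matrix(rnorm(nw * p, -sd_w^2 / 2, sd_w), nw, p))
    if (noise$field_cv > 0 && fields_per_well >= 1) {
      ff <- matrix(0, nw, p)
      for (f in seq_len(fields_per_well))
        ff <- ff + exp(matrix(rnorm(nw * p, -sd_f^2 / 2, sd_f), nw, p))
      well_fac <- well_fac * ff / fields_per_well
    }
    out_flag <- rbinom(nw, 1, noise$outlier_rate) == 1
    out_dir <- sample(c(-1, 1), nw, replace = TRUE)
    out_fac <- ifelse(out_flag, noise$outlier_scale^out_dir, 1)
    vals <- cond_fac * plate_fac[layout$plate_id, , drop = FALSE] *
      well_fac * out_fac
    vals <- sweep(vals, 2, base, "*")
    colnames(vals) <- catalogue$name
    tab <- cbind(layout[c("plate_id", "well", "row", "col", "condition",
                          "compound", "spiked")],
                 as.data.frame(vals), stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    attr(tab, "provenance") <- "raw"
    class(tab) <- c("feature_table", "data.frame")
    truth <- list(layout = layout, effect_key = keys,
                  condition_factors = cond_fac, plate_factors = plate_fac,
                  outlier = out_flag, spiked = layout$spiked == 1L,
                  catalogue = catalogue$name)
    class(truth) <- "ground_truth"
    list(table = tab, truth = truth)
  })
}

#' Metadata and feature columns of a feature table
#'
#' @param table a feature_table data.frame.
#' @return character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), c("plate_id", "well", "row", "col", "condition",
                          "compound", "spiked"))
}

#' Write / read a plate map CSV
#'
#' @param layout a plate_layout.
#' @param path CSV path.
#' @return `path` (write) or plate_layout (read).
#' @export
write_plate_map <- function(layout, path) {
  write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  lay <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "row", "col", "condition", "compound",
            "spiked")
  if (!all(need %in% names(lay)))
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  class(lay) <- c("plate_layout", "data.frame")
  lay
}
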