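# Staining-panel feature catalogues.
#
# Each panel ships a fixed manifest of feature descriptors. Panel A
# (Hoechst/aSyn/TH/MAP2) has exactly 126 features of which exactly 54 are
# computed on the TH+ subpopulation; the mitochondrial panel
# (Hoechst/calcein/TMRM) has exactly 96. The LAMP1 panel is an analogous
# package-defined catalogue (82 features). Only the counts and a small set
# of named features (aSyn intensity, aggregate area, TH+ count, MAP2+ ratio,
# branch features, TMRM intensity, mitochondrial compactness/form factor,
# LAMP1 surface area) are fixed requirements; the remaining composition is
# a package-defined reconstruction, shipped as a manifest so it cannot
# drift silently.

PANELS <- c("panelA", "panelMito", "panelLAMP1")

panel_channels <- function(panel) {
  switch(panel,
    panelA     = c("Hoechst", "aSyn", "TH", "MAP2"),
    panelMito  = c("Hoechst", "calcein", "TMRM"),
    panelLAMP1 = c("Hoechst", "aSyn", "LAMP1", "MAP2"),
    stop("unknown panel: ", panel)
  )
}

INT_STATS <- c("mean", "median", "sd", "p90")
MORPHS <- c("area", "perimeter", "form_factor", "compactness", "eccentricity")

# baseline scales used by the synthetic generator (positive, arbitrary units)
.channel_scale <- c(Hoechst = 1500, aSyn = 800, TH = 1000, MAP2 = 1200,
                    calcein = 1100, TMRM = 900, LAMP1 = 700)
.morph_scale <- list(
  nuclei = c(area = 80, perimeter = 34, form_factor = 0.85,
             compactness = 0.80, eccentricity = 0.55),
  cells  = c(area = 300, perimeter = 75, form_factor = 0.60,
             compactness = 0.55, eccentricity = 0.65),
  mito   = c(area = 12, perimeter = 13, form_factor = 0.70,
             compactness = 0.60, eccentricity = 0.60),
  lyso   = c(area = 8, perimeter = 10, form_factor = 0.75,
             compactness = 0.65, eccentricity = 0.55)
)

.int_baseline <- function(ch, stat) {
  m <- .channel_scale[[ch]]
  switch(stat, mean = m, median = 0.95 * m, sd = 0.30 * m, p90 = 1.5 * m,
         total = 300 * m, cv = 0.30, stop("unknown stat: ", stat))
}

.morph_baseline <- function(group, morph, stat) {
  v <- .morph_scale[[group]][[morph]]
  switch(stat, mean = v, median = 0.97 * v, sd = 0.25 * v, p90 = 1.4 * v,
         p10 = 0.6 * v, stop("unknown stat: ", stat))
}

.cat_env <- new.env(parent = emptyenv())

#' Feature catalogue for a staining panel
#'
#' Returns the fixed descriptor table for a panel: one row per feature with
#' columns `name`, `panel`, `channel`, `population`, `family`, `baseline`.
#' The manifest is shipped with the package (`inst/extdata`) and is also
#' reproducible from [build_catalogue()].
#'
#' @param panel one of `"panelA"`, `"panelMito"`, `"panelLAMP1"`.
#' @return data.frame of feature descriptors, in canonical catalogue order.
#' @export
#' @examples
#' nrow(feature_catalogue("panelA"))  # 126
feature_catalogue <- function(panel = PANELS) {
  panel <- match.arg(panel)
  if (!is.null(.cat_env[[panel]])) return(.cat_env[[panel]])
  path <- system.file("extdata", paste0("catalogue_", panel, ".csv"),
                      package = "phenoscreen")
  cat <- if (nzchar(path)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    build_catalogue(panel)  # fallback when running from a source tree
  }
  validate_catalogue(cat, panel)
  .cat_env[[panel]] <- cat
  cat
}

#' Construct a panel catalogue from its compositional rules
#'
#' The generator behind the shipped manifests. Kept exported so the
#' manifests can be regenerated and tested for identity.
#'
#' @inheritParams feature_catalogue
#' @return data.frame as in [feature_catalogue()].
#' @export
build_catalogue <- function(panel = PANELS) {
  panel <- match.arg(panel)
  rows <- list()
  add <- function(name, channel, population, family, baseline) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, panel = panel, channel = channel,
      population = population, family = family, baseline = baseline,
      stringsAsFactors = FALSE)
  }
  chans <- panel_channels(panel)

  # -- field-level pixel statistics and granularity --------------------------
  for (ch in chans)
    for (st in c("mean", "sd", "p90"))
      add(sprintf("field_%s_int_%s", ch, st), ch, "field", "intensity",
          .int_baseline(ch, st))
  gran_ch <- switch(panel, panelA = c("aSyn", "MAP2", "Hoechst"),
                    panelMito = c("TMRM", "calcein"),
                    panelLAMP1 = c("aSyn", "LAMP1"))
  for (ch in gran_ch)
    for (r in c(2, 4))
      add(sprintf("field_%s_gran_r%d", ch, r), ch, "field", "texture",
          if (r == 2) 0.20 else 0.35)

  # -- nuclei ----------------------------------------------------------------
  add("nuclei_count", "Hoechst", "nuclei", "count", 120)
  add("nuclei_density", "Hoechst", "nuclei", "count", 120 / 192^2)
  for (st in INT_STATS)
    add(sprintf("nuclei_Hoechst_int_%s", st), "Hoechst", "nuclei",
        "intensity", .int_baseline("Hoechst", st))
  for (m in MORPHS)
    for (st in c("mean", "sd"))
      add(sprintf("nuclei_%s_%s", m, st), "Hoechst", "nuclei", "morphology",
          .morph_baseline("nuclei", m, st))

  # -- all segmented cells ---------------------------------------------------
  cell_ch <- if (panel == "panelMito") "calcein" else "MAP2"
  add("all_cells_count", cell_ch, "all_cells", "count", 90)
  for (ch in chans)
    for (st in INT_STATS)
      add(sprintf("all_cells_%s_int_%s", ch, st), ch, "all_cells",
          "intensity", .int_baseline(ch, st))
  for (m in MORPHS)
    for (st in c("mean", "sd"))
      add(sprintf("all_cells_%s_%s", m, st), cell_ch, "all_cells",
          "morphology", .morph_baseline("cells", m, st))
  ratios <- switch(panel,
    panelA = list(c("aSyn", "TH"), c("aSyn", "MAP2")),
    panelMito = list(c("TMRM", "calcein")),
    panelLAMP1 = list(c("aSyn", "MAP2"), c("LAMP1", "MAP2")))
  for (rt in ratios)
    add(sprintf("all_cells_ratio_%s_%s", rt[1], rt[2]), rt[1], "all_cells",
        "ratio", .channel_scale[[rt[1]]] / .channel_scale[[rt[2]]])

  if (panel != "panelMito") {
    # -- MAP2+ neurons -------------------------------------------------------
    add("MAP2_pos_count", "MAP2", "MAP2_pos", "count", 60)
    add("MAP2_pos_fraction", "MAP2", "MAP2_pos", "ratio", 0.65)
    add("MAP2_pos_MAP2_int_mean", "MAP2", "MAP2_pos", "intensity",
        .int_baseline("MAP2", "mean"))
    add("MAP2_pos_MAP2_int_sd", "MAP2", "MAP2_pos", "intensity",
        .int_baseline("MAP2", "sd"))
    add("MAP2_pos_aSyn_int_mean", "aSyn", "MAP2_pos", "intensity",
        .int_baseline("aSyn", "mean"))

    # -- neurite skeleton (MAP2 mask) ----------------------------------------
    add("neurites_total_length", "MAP2", "neurites", "morphology", 4000)
    add("neurites_branch_points", "MAP2", "neurites", "count", 150)
    add("neurites_end_points", "MAP2", "neurites", "count", 180)
    add("neurites_branch_density", "MAP2", "neurites", "ratio", 150 / 4000)
  }

  if (panel == "panelA") {
    # -- TH+ dopaminergic subpopulation (exactly 54 descriptors) -------------
    add("TH_pos_count", "TH", "TH_pos", "count", 35)
    add("TH_pos_fraction", "TH", "TH_pos", "ratio", 0.40)
    add("TH_pos_density", "TH", "TH_pos", "count", 35 / 192^2)
    for (ch in chans)
      for (st in c(INT_STATS, "total"))
        add(sprintf("TH_pos_%s_int_%s", ch, st), ch, "TH_pos", "intensity",
            .int_baseline(ch, st))
    for (m in MORPHS)
      for (st in c("mean", "median", "sd"))
        add(sprintf("TH_pos_%s_%s", m, st), "TH", "TH_pos", "morphology",
            .morph_baseline("cells", m, st))
    add("TH_pos_neurite_length_per_cell", "TH", "TH_pos", "morphology", 120)
    add("TH_pos_neurite_branch_points_per_cell", "TH", "TH_pos", "count", 4)
    add("TH_pos_neurite_end_points_per_cell", "TH", "TH_pos", "count", 5)
    add("TH_pos_neurite_branch_density", "TH", "TH_pos", "ratio", 4 / 120)
    # pS129-like aSyn aggregate (punctate) features inside TH+ somata
    add("TH_pos_agg_count_per_cell", "aSyn", "TH_pos", "count", 3)
    add("TH_pos_agg_area_mean", "aSyn", "TH_pos", "morphology", 6)
    add("TH_pos_agg_area_total_per_cell", "aSyn", "TH_pos", "morphology", 18)
    add("TH_pos_agg_int_mean", "aSyn", "TH_pos", "intensity", 1400)
    for (rt in list(c("aSyn", "TH"), c("aSyn", "MAP2"), c("TH", "MAP2"),
                    c("aSyn", "Hoechst")))
      add(sprintf("TH_pos_ratio_%s_%s", rt[1], rt[2]), rt[1], "TH_pos",
          "ratio", .channel_scale[[rt[1]]] / .channel_scale[[rt[2]]])
    for (ch in c("aSyn", "TH"))
      for (r in c(2, 4))
        add(sprintf("TH_pos_%s_gran_r%d", ch, r), ch, "TH_pos", "texture",
            if (r == 2) 0.20 else 0.35)
  }

  if (panel == "panelMito") {
    # -- mitochondria (puncta) -----------------------------------------------
    add("mito_count", "TMRM", "mitochondria", "count", 400)
    add("mito_count_per_cell", "TMRM", "mitochondria", "count", 4.5)
    add("mito_per_nucleus", "TMRM", "mitochondria", "ratio", 3.3)
    add("mito_area_total", "TMRM", "mitochondria", "morphology", 4800)
    add("mito_area_frac", "TMRM", "mitochondria", "ratio", 0.15)
    add("mito_area_per_cell", "TMRM", "mitochondria", "morphology", 55)
    for (st in c(INT_STATS, "total", "cv"))
      add(sprintf("mito_TMRM_int_%s", st), "TMRM", "mitochondria",
          "intensity", .int_baseline("TMRM", st))
    add("mito_TMRM_int_total_per_cell", "TMRM", "mitochondria", "intensity",
        55 * .channel_scale[["TMRM"]])
    add("mito_TMRM_bg_ratio", "TMRM", "mitochondria", "ratio", 3.0)
    add("mito_calcein_int_mean", "calcein", "mitochondria", "intensity",
        .int_baseline("calcein", "mean"))
    for (st in c("median", "sd", "p90"))
      add(sprintf("mito_calcein_int_%s", st), "calcein", "mitochondria",
          "intensity", .int_baseline("calcein", st))
    for (m in MORPHS)
      for (st in c("mean", "median", "sd"))
        add(sprintf("mito_%s_%s", m, st), "TMRM", "mitochondria",
            "morphology", .morph_baseline("mito", m, st))
    add("mito_area_p90", "TMRM", "mitochondria", "morphology",
        .morph_baseline("mito", "area", "p90"))
    add("mito_form_factor_p10", "TMRM", "mitochondria", "morphology",
        .morph_baseline("mito", "form_factor", "p10"))
    add("mito_compactness_p90", "TMRM", "mitochondria", "morphology",
        .morph_baseline("mito", "compactness", "p90"))
    add("mito_eccentricity_p90", "TMRM", "mitochondria", "morphology",
        .morph_baseline("mito", "eccentricity", "p90"))
    for (st in c("mean", "sd")) {
      add(sprintf("mito_extent_%s", st), "TMRM", "mitochondria",
          "morphology", .morph_baseline("mito", "form_factor", st) * 0.9)
      add(sprintf("mito_aspect_ratio_%s", st), "TMRM", "mitochondria",
          "morphology", if (st == "mean") 1.6 else 0.4)
      add(sprintf("mito_nn_dist_%s", st), "TMRM", "mitochondria",
          "morphology", if (st == "mean") 9 else 3)
    }
  }

  if (panel == "panelLAMP1") {
    # -- lysosomes (LAMP1 puncta); area_total is the "LAMP1 surface area" ----
    add("lyso_count", "LAMP1", "lysosomes", "count", 250)
    add("lyso_count_per_cell", "LAMP1", "lysosomes", "count", 2.8)
    add("lyso_area_total", "LAMP1", "lysosomes", "morphology", 2000)
    add("lyso_area_per_cell", "LAMP1", "lysosomes", "morphology", 22)
    add("lyso_area_mean", "LAMP1", "lysosomes", "morphology", 8)
    for (st in INT_STATS)
      add(sprintf("lyso_LAMP1_int_%s", st), "LAMP1", "lysosomes",
          "intensity", .int_baseline("LAMP1", st))
    for (m in c("form_factor", "compactness", "eccentricity"))
      add(sprintf("lyso_%s_mean", m), "LAMP1", "lysosomes", "morphology",
          .morph_baseline("lyso", m, "mean"))
  }

  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  validate_catalogue(cat, panel)
  cat
}

#' Validate a catalogue against its panel invariants
#'
#' Checks unique names, positive baselines, and the fixed panel counts
#' (panel A: 126 with 54 TH+-specific; mitochondrial panel: 96).
#'
#' @param cat catalogue data.frame.
#' @param panel panel name.
#' @return `cat` invisibly; stops on violation.
#' @export
validate_catalogue <- function(cat, panel) {
  stopifnot(all(c("name", "panel", "channel", "population", "family",
                  "baseline") %in% names(cat)))
  if (anyDuplicated(cat$name)) stop("duplicate feature names in catalogue")
  if (any(cat$baseline <= 0)) stop("baselines must be positive")
  if (!all(cat$panel == panel)) stop("panel column mismatch")
  n <- nrow(cat)
  if (panel == "panelA") {
    if (n != 126) stop("panelA must have 126 features, found ", n)
    n_th <- sum(cat$population == "TH_pos")
    if (n_th != 54) stop("panelA must have 54 TH_pos features, found ", n_th)
  }
  if (panel == "panelMito" && n != 96)
    stop("panelMito must have 96 features, found ", n)
  invisible(cat)
}

#' Write a catalogue manifest CSV
#'
#' @param cat catalogue data.frame.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_catalogue <- function(cat, path) {
  write.csv(cat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
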