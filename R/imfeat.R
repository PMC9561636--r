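# Field segmentation and per-well feature extraction over a panel
# catalogue.

#' Segmentation parameters
#'
#' @param nucleus_min_size minimum nucleus area (px).
#' @param soma_radius soma reconstruction radius around each nucleus (px).
#' @param ball_radius,tophat_radius,mito_min_area mitochondrial puncta
#'   segmentation, see [segment_mitochondria()].
#' @param agg_tophat_radius,agg_min_area aSyn aggregate (pS129-like)
#'   puncta detection inside somata.
#' @param illum_sigma illumination-correction sigma; NULL for default.
#' @param neurite_exclusion_factor the neurite mask excludes a disc of
#'   `soma_radius * neurite_exclusion_factor` around each nucleus, so the
#'   blurred rim of the soma cannot masquerade as a neurite loop.
#' @return object of class `seg_params`.
#' @export
seg_params <- function(nucleus_min_size = 10L, soma_radius = 8L,
                       ball_radius = 15L, tophat_radius = 5L,
                       mito_min_area = 4L, agg_tophat_radius = 3L,
                       agg_min_area = 2L, illum_sigma = NULL,
                       neurite_exclusion_factor = 1.35) {
  structure(as.list(environment()), class = "seg_params")
}

# assign every pixel within soma_radius of a nucleus centroid to the
# nearest nucleus: deterministic fixed-radius soma reconstruction
.soma_labels <- function(nuc_props, dim_img, soma_radius) {
  lab <- matrix(0L, dim_img[1], dim_img[2])
  if (nrow(nuc_props) == 0) return(lab)
  best_d2 <- matrix(Inf, dim_img[1], dim_img[2])
  r <- ceiling(soma_radius)
  for (i in seq_len(nrow(nuc_props))) {
    cy <- nuc_props$cy[i]; cx <- nuc_props$cx[i]
    ys <- max(1, floor(cy - r)):min(dim_img[1], ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(dim_img[2], ceiling(cx + r))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    upd <- d2 <= soma_radius^2 & d2 < best_d2[ys, xs]
    sub <- lab[ys, xs]; sub[upd] <- i
    lab[ys, xs] <- sub
    subd <- best_d2[ys, xs]; subd[upd] <- d2[upd]
    best_d2[ys, xs] <- subd
  }
  lab
}

#' Segment one multi-channel field
#'
#' Produces the full segmentation needed by the feature catalogues:
#' illumination-corrected channels, nuclei (Hoechst), nucleus-seeded soma
#' labels, TH/MAP2 positivity calls, neurite skeleton (cell-marker mask
#' minus somata), mitochondrial or lysosomal puncta depending on panel.
#'
#' @param images named list of channel matrices (raw).
#' @param panel staining panel.
#' @param thresholds optional named per-channel intensity thresholds
#'   (e.g. from [plate_threshold()] per plate); missing entries fall back
#'   to per-image Otsu.
#' @param params a [seg_params()].
#' @return object of class `segmentation_result`.
#' @export
segment_field <- function(images, panel, thresholds = list(),
                          params = seg_params()) {
  chans <- panel_channels(panel)
  if (!all(chans %in% names(images)))
    stop("catalogue error: panel ", panel, " needs channels ",
         paste(chans, collapse = ", "))
  corr <- lapply(images[chans], function(im) {
    correct_illumination(im, params$illum_sigma %||% (min(dim(im)) / 8))
  })
  th_of <- function(ch) thresholds[[ch]] %||% otsu_threshold(corr[[ch]])

  nuclei <- segment_channel(corr$Hoechst, th_of("Hoechst"),
                            params$nucleus_min_size)
  nuc_props <- region_props(nuclei)
  soma <- .soma_labels(nuc_props, dim(corr$Hoechst), params$soma_radius)
  soma_props <- region_props(soma, corr)

  res <- list(panel = panel, images = corr, nuclei = nuclei,
              nuclei_props = nuc_props, soma = soma,
              soma_props = soma_props, thresholds = lapply(
                setNames(chans, chans), th_of))

  marker_ch <- if (panel == "panelMito") "calcein" else "MAP2"
  if ("TH" %in% chans)
    res$th_pos <- classify_cells(soma_props[["TH_mean"]])
  if (marker_ch %in% names(soma_props) ||
      paste0(marker_ch, "_mean") %in% names(soma_props))
    res$marker_pos <- classify_cells(soma_props[[paste0(marker_ch,
                                                        "_mean")]])

  if (marker_ch == "MAP2" && "MAP2" %in% chans) {
    map2_mask <- corr$MAP2 > th_of("MAP2")
    excl <- .soma_labels(nuc_props, dim(corr$Hoechst),
                         params$soma_radius *
                           params$neurite_exclusion_factor)
    res$neurites <- skeletonize_neurites(map2_mask & excl == 0)
  }
  if (panel == "panelMito") {
    res$mito <- segment_mitochondria(images$TMRM, params$ball_radius,
                                     params$tophat_radius,
                                     params$mito_min_area)
    res$mito_props <- region_props(res$mito, corr)
  }
  if (panel == "panelLAMP1") {
    res$lyso <- segment_mitochondria(images$LAMP1, params$ball_radius,
                                     params$tophat_radius,
                                     params$agg_min_area)
    res$lyso_props <- region_props(res$lyso, corr)
  }
  if (panel %in% c("panelA", "panelLAMP1")) {
    agg <- segment_mitochondria(images$aSyn, params$ball_radius,
                                params$agg_tophat_radius,
                                params$agg_min_area)
    res$agg <- agg
    res$agg_props <- region_props(agg, corr)
  }
  class(res) <- "segmentation_result"
  res
}

.stat_fun <- function(stat) {
  switch(stat,
    mean = function(v) mean(v, na.rm = TRUE),
    median = function(v) median(v, na.rm = TRUE),
    sd = function(v) sd(v),
    p90 = function(v) unname(quantile(v, 0.9, na.rm = TRUE)),
    p10 = function(v) unname(quantile(v, 0.1, na.rm = TRUE)),
    total = function(v) sum(v, na.rm = TRUE),
    cv = function(v) sd(v) / mean(v, na.rm = TRUE),
    stop("unknown stat: ", stat))
}

# object-set statistics used by the name grammar:
# <pop>_<ch>_int_<stat>, <pop>_<morph>_<stat>, counts, ratios, texture.
.pop_stat <- function(props, col, stat) {
  if (is.null(props) || nrow(props) == 0) return(NA_real_)
  v <- props[[col]]
  if (is.null(v)) return(NA_real_)
  if (length(v) < 2 && stat %in% c("sd", "cv")) return(NA_real_)
  .stat_fun(stat)(v)
}

#' Compute all catalogue features for one segmented field
#'
#' @param seg a [segment_field()] result.
#' @param catalogue the matching panel catalogue.
#' @return named numeric vector, length `nrow(catalogue)`, in catalogue
#'   order. Features of an absent population are `NA`.
#' @export
field_features <- function(seg, catalogue) {
  if (!all(catalogue$panel == seg$panel))
    stop("catalogue error: catalogue panel does not match segmentation")
  imgs <- seg$images
  area_px <- prod(dim(imgs[[1]]))
  sp <- seg$soma_props
  n_cells <- nrow(sp)
  th_props <- if (!is.null(seg$th_pos) && n_cells > 0)
    sp[seg$th_pos, , drop = FALSE] else NULL
  map2_props <- if (!is.null(seg$marker_pos) && n_cells > 0 &&
                    seg$panel != "panelMito")
    sp[seg$marker_pos, , drop = FALSE] else NULL
  th_mask <- if (!is.null(seg$th_pos))
    matrix(seg$soma %in% sp$label[seg$th_pos], nrow(seg$soma)) else NULL
  agg_in_th <- NULL
  if (!is.null(seg$agg_props) && !is.null(th_mask) &&
      nrow(seg$agg_props) > 0) {
    inside <- th_mask[cbind(round(seg$agg_props$cy),
                            round(seg$agg_props$cx))]
    agg_in_th <- seg$agg_props[inside, , drop = FALSE]
  }

  nn_dists <- function(props) {
    if (is.null(props) || nrow(props) < 2) return(NULL)
    d <- as.matrix(dist(cbind(props$cy, props$cx)))
    diag(d) <- Inf
    apply(d, 1, min)
  }
  npi <- if (any(grepl("^nuclei_Hoechst_int_", catalogue$name)))
    region_props(seg$nuclei, imgs["Hoechst"]) else NULL

  val <- vapply(seq_len(nrow(catalogue)), function(i) {
    nm <- catalogue$name[i]
    # ---- field-level --------------------------------------------------------
    if (grepl("^field_", nm)) {
      p <- strsplit(nm, "_")[[1]]
      ch <- p[2]
      if (p[3] == "int") return(.stat_fun(p[4])(as.numeric(imgs[[ch]])))
      if (p[3] == "gran")
        return(granularity(imgs[[ch]],
                           as.integer(sub("r", "", p[4]))))
    }
    # ---- nuclei -------------------------------------------------------------
    if (nm == "nuclei_count") return(nrow(seg$nuclei_props))
    if (nm == "nuclei_density") return(nrow(seg$nuclei_props) / area_px)
    if (grepl("^nuclei_Hoechst_int_", nm)) {
      st <- sub("^nuclei_Hoechst_int_", "", nm)
      return(.pop_stat(npi, "Hoechst_mean", st))
    }
    if (grepl("^nuclei_", nm)) {
      p <- sub("^nuclei_", "", nm)
      st <- sub(".*_", "", p); m <- sub("_[a-z0-9]+$", "", p)
      return(.pop_stat(seg$nuclei_props, m, st))
    }
    # ---- all cells ----------------------------------------------------------
    if (nm == "all_cells_count") return(n_cells)
    if (grepl("^all_cells_ratio_", nm)) {
      p <- strsplit(sub("^all_cells_ratio_", "", nm), "_")[[1]]
      a <- .pop_stat(sp, paste0(p[1], "_mean"), "mean")
      b <- .pop_stat(sp, paste0(p[2], "_mean"), "mean")
      return(a / b)
    }
    if (grepl("^all_cells_([A-Za-z0-9]+)_int_", nm)) {
      p <- strsplit(sub("^all_cells_", "", nm), "_int_")[[1]]
      return(.pop_stat(sp, paste0(p[1], "_mean"), p[2]))
    }
    if (grepl("^all_cells_", nm)) {
      p <- sub("^all_cells_", "", nm)
      st <- sub(".*_", "", p); m <- sub("_[a-z0-9]+$", "", p)
      return(.pop_stat(sp, m, st))
    }
    # ---- MAP2+ --------------------------------------------------------------
    if (nm == "MAP2_pos_count")
      return(if (is.null(map2_props)) NA_real_ else nrow(map2_props))
    if (nm == "MAP2_pos_fraction")
      return(if (n_cells == 0) NA_real_ else
             sum(seg$marker_pos) / n_cells)
    if (grepl("^MAP2_pos_([A-Za-z0-9]+)_int_", nm)) {
      p <- strsplit(sub("^MAP2_pos_", "", nm), "_int_")[[1]]
      return(.pop_stat(map2_props, paste0(p[1], "_mean"), p[2]))
    }
    # ---- neurites -----------------------------------------------------------
    if (grepl("^neurites_", nm)) {
      ne <- seg$neurites
      if (is.null(ne)) return(NA_real_)
      return(switch(sub("^neurites_", "", nm),
        total_length = ne$total_length,
        branch_points = ne$n_branch_points,
        end_points = ne$n_end_points,
        branch_density = if (ne$total_length > 0)
          ne$n_branch_points / ne$total_length else 0))
    }
    # ---- TH+ ----------------------------------------------------------------
    if (grepl("^TH_pos_", nm)) {
      if (is.null(th_props)) return(NA_real_)
      n_th <- nrow(th_props)
      if (nm == "TH_pos_count") return(n_th)
      if (nm == "TH_pos_fraction")
        return(if (n_cells == 0) NA_real_ else n_th / n_cells)
      if (nm == "TH_pos_density") return(n_th / area_px)
      if (n_th == 0) return(NA_real_)
      if (grepl("^TH_pos_ratio_", nm)) {
        p <- strsplit(sub("^TH_pos_ratio_", "", nm), "_")[[1]]
        return(.pop_stat(th_props, paste0(p[1], "_mean"), "mean") /
               .pop_stat(th_props, paste0(p[2], "_mean"), "mean"))
      }
      if (grepl("_gran_r[0-9]$", nm)) {
        ch <- sub("^TH_pos_([A-Za-z0-9]+)_gran_r[0-9]$", "\\1", nm)
        r <- as.integer(sub(".*_gran_r", "", nm))
        return(granularity(imgs[[ch]] * th_mask, r))
      }
      if (grepl("^TH_pos_neurite_", nm)) {
        ne <- seg$neurites
        if (is.null(ne)) return(NA_real_)
        return(switch(sub("^TH_pos_neurite_", "", nm),
          length_per_cell = ne$total_length / n_cells,
          branch_points_per_cell = ne$n_branch_points / n_cells,
          end_points_per_cell = ne$n_end_points / n_cells,
          branch_density = if (ne$total_length > 0)
            ne$n_branch_points / ne$total_length else 0))
      }
      if (grepl("^TH_pos_agg_", nm)) {
        a <- agg_in_th
        return(switch(sub("^TH_pos_agg_", "", nm),
          count_per_cell = if (is.null(a)) 0 else nrow(a) / n_th,
          area_mean = if (is.null(a) || nrow(a) == 0) NA_real_
                      else mean(a$area),
          area_total_per_cell = if (is.null(a)) 0
                                else sum(a$area) / n_th,
          int_mean = if (is.null(a) || nrow(a) == 0) NA_real_
                     else mean(a$aSyn_mean)))
      }
      if (grepl("_int_", nm)) {
        p <- strsplit(sub("^TH_pos_", "", nm), "_int_")[[1]]
        col <- paste0(p[1], if (p[2] == "total") "_total" else "_mean")
        st <- if (p[2] == "total") "mean" else p[2]
        return(.pop_stat(th_props, col, st))
      }
      p <- sub("^TH_pos_", "", nm)
      st <- sub(".*_", "", p); m <- sub("_[a-z0-9]+$", "", p)
      return(.pop_stat(th_props, m, st))
    }
    # ---- mitochondria -------------------------------------------------------
    if (grepl("^mito_", nm)) {
      mp <- seg$mito_props
      if (is.null(mp)) return(NA_real_)
      n_mito <- nrow(mp)
      if (nm == "mito_count") return(n_mito)
      if (nm == "mito_count_per_cell")
        return(if (n_cells > 0) n_mito / n_cells else NA_real_)
      if (nm == "mito_per_nucleus") {
        nn <- nrow(seg$nuclei_props)
        return(if (nn > 0) n_mito / nn else NA_real_)
      }
      if (nm == "mito_area_total") return(sum(mp$area))
      if (nm == "mito_area_per_cell")
        return(if (n_cells > 0) sum(mp$area) / n_cells else NA_real_)
      if (nm == "mito_area_frac") {
        ca <- sum(sp$area)
        return(if (ca > 0) sum(mp$area) / ca else NA_real_)
      }
      if (nm == "mito_TMRM_bg_ratio") {
        inmask <- seg$mito > 0
        inside <- mean(imgs$TMRM[inmask])
        outside <- mean(imgs$TMRM[!inmask])
        return(inside / outside)
      }
      if (nm == "mito_TMRM_int_total_per_cell")
        return(if (n_cells > 0 && n_mito > 0)
               sum(mp$TMRM_total) / n_cells else NA_real_)
      if (grepl("^mito_nn_dist_", nm)) {
        d <- nn_dists(mp)
        return(.stat_fun(sub("^mito_nn_dist_", "", nm))(d %||% NA_real_))
      }
      if (grepl("_int_", nm)) {
        p <- strsplit(sub("^mito_", "", nm), "_int_")[[1]]
        if (p[2] == "total")
          return(if (n_mito > 0) sum(mp[[paste0(p[1], "_total")]])
                 else NA_real_)
        return(.pop_stat(mp, paste0(p[1], "_mean"), p[2]))
      }
      p <- sub("^mito_", "", nm)
      st <- sub(".*_", "", p); m <- sub("_[a-z0-9]+$", "", p)
      return(.pop_stat(mp, m, st))
    }
    # ---- lysosomes ----------------------------------------------------------
    if (grepl("^lyso_", nm)) {
      lp <- seg$lyso_props
      if (is.null(lp)) return(NA_real_)
      n_lyso <- nrow(lp)
      if (nm == "lyso_count") return(n_lyso)
      if (nm == "lyso_count_per_cell")
        return(if (n_cells > 0) n_lyso / n_cells else NA_real_)
      if (nm == "lyso_area_total") return(sum(lp$area))
      if (nm == "lyso_area_per_cell")
        return(if (n_cells > 0) sum(lp$area) / n_cells else NA_real_)
      if (grepl("_int_", nm)) {
        p <- strsplit(sub("^lyso_", "", nm), "_int_")[[1]]
        return(.pop_stat(lp, paste0(p[1], "_mean"), p[2]))
      }
      p <- sub("^lyso_", "", nm)
      st <- sub(".*_", "", p); m <- sub("_[a-z0-9]+$", "", p)
      return(.pop_stat(lp, m, st))
    }
    NA_real_
  }, numeric(1))
  setNames(val, catalogue$name)
}

#' Per-well feature vector from one or more fields
#'
#' Field feature vectors are averaged with the arithmetic mean (a well is
#' the mean of its fields); features missing in some fields are averaged
#' over the fields where they exist, and `NA` only if absent everywhere.
#'
#' @param fields list of `segmentation_result`s (or a single one).
#' @param catalogue the panel catalogue.
#' @return named numeric vector of length `nrow(catalogue)`.
#' @export
compute_well_features <- function(fields, catalogue) {
  if (inherits(fields, "segmentation_result")) fields <- list(fields)
  stopifnot(length(fields) >= 1)
  mat <- vapply(fields, field_features, numeric(nrow(catalogue)),
                catalogue = catalogue)
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  out <- rowMeans(mat, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  setNames(out, catalogue$name)
}

#' Extract a feature table from a directory of TIFF fields
#'
#' Expects the `{plate}_{well}_F{field}_C{channel}.tiff` layout written by
#' [render_well()] and a plate map CSV.
#'
#' @param plate_dir directory of TIFF files.
#' @param plate_map a plate_layout (or path to its CSV).
#' @param panel staining panel.
#' @param params a [seg_params()].
#' @param per_plate_thresholds estimate per-channel thresholds from the
#'   pooled plate histogram (default TRUE).
#' @return feature_table data.frame (one row per well present on disk).
#' @export
extract_plate_features <- function(plate_dir, plate_map, panel,
                                   params = seg_params(),
                                   per_plate_thresholds = TRUE) {
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  catalogue <- feature_catalogue(panel)
  chans <- panel_channels(panel)
  files <- list.files(plate_dir, pattern = "\\.tiff$")
  if (!length(files)) stop("no TIFF fields under ", plate_dir)
  meta <- do.call(rbind, lapply(files, function(f) {
    m <- regmatches(f, regexec(
      "^(.+)_([A-P][0-9]{2})_F([0-9]+)_C([0-9]+)\\.tiff$", f))[[1]]
    if (!length(m)) return(NULL)
    data.frame(file = f, plate_id = m[2], well = m[3],
               field = as.integer(m[4]), channel = chans[as.integer(m[5])],
               stringsAsFactors = FALSE)
  }))
  thresholds <- list()
  if (per_plate_thresholds) {
    for (ch in chans) {
      fs <- meta$file[meta$channel == ch]
      imgs <- lapply(file.path(plate_dir, fs), read_tiff)
      imgs <- lapply(imgs, correct_illumination)
      thresholds[[ch]] <- plate_threshold(imgs)
    }
  }
  rows <- list()
  for (w in unique(meta$well)) {
    mw <- meta[meta$well == w, ]
    segs <- lapply(sort(unique(mw$field)), function(f) {
      mf <- mw[mw$field == f, ]
      imgs <- setNames(lapply(file.path(plate_dir, mf$file), read_tiff),
                       mf$channel)
      segment_field(imgs, panel, thresholds, params)
    })
    vec <- compute_well_features(segs, catalogue)
    lay <- plate_map[plate_map$well == w, , drop = FALSE]
    if (nrow(lay) != 1)
      stop("well ", w, " not uniquely present in the plate map")
    rows[[w]] <- cbind(lay[c("plate_id", "well", "row", "col", "condition",
                             "compound", "spiked")],
                       as.data.frame(as.list(vec)),
                       stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  names(tab)[-(1:7)] <- catalogue$name
  attr(tab, "provenance") <- "raw"
  class(tab) <- c("feature_table", "data.frame")
  tab
}
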