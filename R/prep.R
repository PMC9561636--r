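# Preprocessing: per-plate median normalization to a reference condition,
# robust outlier-well removal, correlated-feature pruning. Fixed order:
# normalize -> outliers -> decorrelate. Every step emits a replayable
# report.

#' Per-plate median normalization to a reference condition
#'
#' Every feature value is divided by its plate's median over the
#' reference-condition wells, so the reference per-plate median of every
#' kept feature becomes exactly 1. Features whose reference median is not
#' positive (or below 1e-12) on some plate are dropped and logged.
#'
#' @param table a feature_table.
#' @param reference_condition condition label of the reference wells
#'   (must have >= 3 wells on every plate).
#' @return list: `table` (normalized), `report` (prep_report with the
#'   per-plate reference medians and any dropped features).
#' @export
normalize_to_reference <- function(table, reference_condition) {
  fc <- feature_cols(table)
  plates <- unique(table$plate_id)
  medians <- list()
  dropped <- character()
  for (pl in plates) {
    ref <- table$plate_id == pl & table$condition == reference_condition
    if (sum(ref) < 3)
      stop("plate ", pl, " has ", sum(ref), " '", reference_condition,
           "' reference wells; need >= 3")
    med <- vapply(fc, function(f) median(table[[f]][ref]), numeric(1))
    medians[[pl]] <- med
    dropped <- union(dropped, fc[!is.finite(med) | med < 1e-12])
  }
  keep <- setdiff(fc, dropped)
  for (pl in plates) {
    sel <- table$plate_id == pl
    for (f in keep) table[[f]][sel] <- table[[f]][sel] / medians[[pl]][f]
  }
  table <- table[c(setdiff(names(table), fc), keep)]
  attr(table, "provenance") <- "normalized"
  class(table) <- c("feature_table", "data.frame")
  report <- list(step = "normalize", reference = reference_condition,
                 medians = medians, dropped_features = dropped)
  list(table = table, report = report)
}

#' Remove outlier wells by a robust z-score vote
#'
#' Within each plate x condition group, a robust z-score
#' `(x - median) / (1.4826 * MAD)` is computed per feature; a well is
#' removed when the fraction of its features with `|z| > z_cut` exceeds
#' `frac_cut`. Features with zero MAD in a group abstain from the vote.
#'
#' @param table a feature_table.
#' @param z_cut robust z threshold per feature (default 3.5).
#' @param frac_cut fraction of flagged features that removes a well
#'   (default 0.2).
#' @return list: `table` (filtered), `report` (removed wells with their
#'   flag fractions).
#' @export
remove_outlier_wells <- function(table, z_cut = 3.5, frac_cut = 0.2) {
  fc <- feature_cols(table)
  grp <- interaction(table$plate_id, table$condition, drop = TRUE)
  frac <- rep(0, nrow(table))
  for (g in levels(grp)) {
    sel <- which(grp == g)
    x <- as.matrix(table[sel, fc, drop = FALSE])
    med <- apply(x, 2, median)
    madv <- apply(x, 2, mad)  # scaled by 1.4826
    use <- madv > 0
    if (!any(use)) next
    z <- abs(sweep(sweep(x[, use, drop = FALSE], 2, med[use]), 2,
                   madv[use], "/"))
    frac[sel] <- rowMeans(z > z_cut)
  }
  bad <- frac > frac_cut
  report <- list(step = "outliers", z_cut = z_cut, frac_cut = frac_cut,
                 removed = data.frame(
                   plate_id = table$plate_id[bad], well = table$well[bad],
                   flag_fraction = frac[bad], stringsAsFactors = FALSE))
  out <- table[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("feature_table", "data.frame")
  list(table = out, report = report)
}

#' Prune strongly correlated features
#'
#' Greedy scan in catalogue (column) order: a feature is dropped iff its
#' absolute Pearson correlation with any earlier kept feature reaches
#' `r_threshold`. Zero-variance features are dropped first.
#'
#' @param table a feature_table.
#' @param r_threshold absolute correlation threshold (default 0.9).
#' @return list: `table` (pruned), `report` (each dropped feature with its
#'   partner and correlation).
#' @export
drop_correlated_features <- function(table, r_threshold = 0.9) {
  fc <- feature_cols(table)
  x <- as.matrix(table[fc])
  sds <- apply(x, 2, sd)
  const <- fc[sds == 0 | !is.finite(sds)]
  drops <- data.frame(feature = const,
                      partner = rep(NA_character_, length(const)),
                      r = rep(NA_real_, length(const)),
                      reason = rep("zero_variance", length(const)),
                      stringsAsFactors = FALSE)
  cand <- setdiff(fc, const)
  kept <- character()
  if (length(cand)) {
    cm <- abs(cor(x[, cand, drop = FALSE]))
    for (f in cand) {
      if (length(kept)) {
        r <- cm[f, kept]
        j <- which(r >= r_threshold - 1e-12)
        if (length(j)) {
          drops <- rbind(drops, data.frame(
            feature = f, partner = kept[j[1]], r = unname(r[j[1]]),
            reason = "correlated", stringsAsFactors = FALSE))
          next
        }
      }
      kept <- c(kept, f)
    }
  }
  out <- table[c(setdiff(names(table), fc), kept)]
  attr(out, "provenance") <- "pruned"
  class(out) <- c("feature_table", "data.frame")
  list(table = out,
       report = list(step = "decorrelate", r_threshold = r_threshold,
                     dropped = drops, kept = kept))
}

#' Run the full preprocessing chain
#'
#' normalize -> outlier removal -> decorrelation, collecting one
#' replayable report.
#'
#' @param table raw feature_table.
#' @param reference_condition reference condition label.
#' @param z_cut,frac_cut see [remove_outlier_wells()].
#' @param r_threshold see [drop_correlated_features()].
#' @return list: `table`, `report` (class `prep_report`, a list of the
#'   three step reports).
#' @export
preprocess <- function(table, reference_condition, z_cut = 3.5,
                       frac_cut = 0.2, r_threshold = 0.9) {
  s1 <- normalize_to_reference(table, reference_condition)
  s2 <- remove_outlier_wells(s1$table, z_cut, frac_cut)
  s3 <- drop_correlated_features(s2$table, r_threshold)
  report <- structure(list(normalize = s1$report, outliers = s2$report,
                           decorrelate = s3$report), class = "prep_report")
  list(table = s3$table, report = report)
}

#' Replay a preprocessing report on a raw table
#'
#' Applies the recorded medians, removed wells and kept features verbatim,
#' reproducing the processed table bit-exactly.
#'
#' @param table the raw feature_table the report was derived from.
#' @param report a `prep_report`.
#' @return processed feature_table.
#' @export
replay_prep <- function(table, report) {
  fc <- feature_cols(table)
  keep <- setdiff(fc, report$normalize$dropped_features)
  for (pl in names(report$normalize$medians)) {
    sel <- table$plate_id == pl
    med <- report$normalize$medians[[pl]]
    for (f in keep) table[[f]][sel] <- table[[f]][sel] / med[f]
  }
  rem <- report$outliers$removed
  bad <- paste(table$plate_id, table$well) %in% paste(rem$plate_id, rem$well)
  out <- table[!bad, c(setdiff(names(table), fc),
                       report$decorrelate$kept)]
  rownames(out) <- NULL
  attr(out, "provenance") <- "pruned"
  class(out) <- c("feature_table", "data.frame")
  out
}
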