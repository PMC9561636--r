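# Screening statistics on classification scores: Z-factor, leave-one-
# feature-out attribution, 3-SD hit calling, replicate-power analysis,
# group tests, bootstrap intervals.

#' Z-factor between two score distributions
#'
#' `Z = 1 - 3 (sd_p + sd_n) / |mean_p - mean_n|` with sample (n-1) SDs.
#' 1 is perfect separation; equal means yield the -Inf sentinel with
#' `undefined = TRUE`.
#'
#' @param scores_pos,scores_neg numeric vectors (>= 2 values each).
#' @return list of class `z_factor_result`: mu_p, mu_n, sd_p, sd_n, z,
#'   undefined.
#' @export
z_factor <- function(scores_pos, scores_neg) {
  stopifnot(length(scores_pos) >= 2, length(scores_neg) >= 2)
  mu_p <- mean(scores_pos); mu_n <- mean(scores_neg)
  sd_p <- sd(scores_pos); sd_n <- sd(scores_neg)
  undefined <- abs(mu_p - mu_n) < 1e-300
  z <- if (undefined) -Inf else 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
  structure(list(mu_p = mu_p, mu_n = mu_n, sd_p = sd_p, sd_n = sd_n,
                 z = z, undefined = undefined),
            class = "z_factor_result")
}

#' Leave-one-feature-out attribution of the class Z-factor
#'
#' For each kept feature the model is retrained on the remaining features
#' with the same CV specification and seed (so the delta reflects feature
#' removal, not resampling noise), all reference wells are scored, and the
#' class Z-factor recomputed. `dz = z_full - z_without` attributes
#' separation to the feature; large positive dz marks an important one.
#'
#' @param table preprocessed feature_table.
#' @param class_neg,class_pos reference class labels.
#' @param algorithm,cv,grid as in [train_reference()].
#' @return list of class `attribution_result`: `z_full`, and `table`
#'   (feature, z_without, dz, ordered by decreasing dz).
#' @export
loocv_attribution <- function(table, class_neg, class_pos,
                              algorithm = "SVM", cv = cv_spec(),
                              grid = NULL) {
  feats <- feature_cols(table)
  if (length(feats) < 2)
    stop("need >= 2 features to leave one out")
  meta <- setdiff(names(table), feats)
  ref <- table$condition %in% c(class_neg, class_pos)
  zf_of <- function(tab) {
    model <- train_reference(tab, class_neg, class_pos, algorithm, cv,
                             grid)
    sc <- score_wells(model, tab[ref, , drop = FALSE])
    z_factor(sc$normalized[sc$condition == class_pos],
             sc$normalized[sc$condition == class_neg])$z
  }
  z_full <- zf_of(table)
  z_wo <- vapply(feats, function(f) {
    sub <- table[c(meta, setdiff(feats, f))]
    class(sub) <- c("feature_table", "data.frame")
    zf_of(sub)
  }, numeric(1))
  res <- data.frame(feature = feats, z_without = z_wo,
                    dz = z_full - z_wo, stringsAsFactors = FALSE)
  res <- res[order(-res$dz), ]
  rownames(res) <- NULL
  structure(list(z_full = z_full, table = res),
            class = "attribution_result")
}

#' 3-SD hit calling against a reference score distribution
#'
#' The reference median `m` and sample SD `s` define the corridor; a well
#' is a hit iff `|score - m| > k * s`. Hit fractions are summarized per
#' condition label.
#'
#' @param scores data.frame from [score_wells()] (or a numeric vector).
#' @param reference_scores numeric vector of reference-class scores
#'   (>= 8 wells).
#' @param k SD multiple (default 3).
#' @return list of class `hit_call`: `center`, `sd`, `k`, `calls` (per
#'   well: score, distance in reference SDs, hit, direction), `summary`
#'   (hit fraction per condition), `degenerate`.
#' @export
call_hits <- function(scores, reference_scores, k = 3) {
  stopifnot(k > 0, length(reference_scores) >= 8)
  if (is.numeric(scores))
    scores <- data.frame(well = seq_along(scores), condition = "x",
                         normalized = scores)
  m <- median(reference_scores)
  s <- sd(reference_scores)
  if (s < 1e-300) {
    warning("degenerate reference distribution (zero SD): no calls")
    return(structure(list(center = m, sd = s, k = k, calls = NULL,
                          summary = NULL, degenerate = TRUE),
                     class = "hit_call"))
  }
  d <- (scores$normalized - m) / s
  calls <- cbind(scores,
                 data.frame(distance_sd = d, hit = abs(d) > k,
                            direction = ifelse(d > 0, "up", "down")))
  if (!is.null(calls$compound)) {
    smry <- aggregate(hit ~ condition + compound, calls, mean)
    names(smry)[3] <- "hit_fraction"
  } else {
    smry <- aggregate(hit ~ condition, calls, mean)
    names(smry)[2] <- "hit_fraction"
  }
  structure(list(center = m, sd = s, k = k, calls = calls,
                 summary = smry, degenerate = FALSE),
            class = "hit_call")
}

#' Replicate-power analysis for single-well hit detection
#'
#' For n = 1..n_max replicate wells drawn from the null distribution
#' shifted by `d` reference SDs, a screen succeeds when at least one well
#' lies beyond `k` reference SDs from the null median (directional by
#' default: only deviations in the shift direction count; set
#' `directional = FALSE` for the two-sided variant). Power is the success
#' fraction over `n_sim` simulations; the minimal n reaching
#' `power_target` is reported (NA when not reached at n_max).
#'
#' @param null_model `"normal"` or a numeric vector of empirical null
#'   scores (resampled with replacement).
#' @param d effect size in reference-SD units (>= 0).
#' @param k hit threshold in reference SDs (default 3).
#' @param power_target desired power in (0, 1).
#' @param n_max largest replicate count examined.
#' @param n_sim simulations per n.
#' @param seed integer seed.
#' @param directional count only shifts in the effect direction.
#' @param method `"simulate"` (Monte Carlo, works for any null) or
#'   `"analytic"` (normal null only: per-well hit probability
#'   `p = pnorm(d - k)` directional, `pnorm(d - k) + pnorm(-d - k)`
#'   two-sided; power `1 - (1 - p)^n` exactly). Monte-Carlo `n_min` is
#'   jittery when the target falls within Monte-Carlo error of a power
#'   value; the analytic mode resolves such boundaries exactly.
#' @return list of class `power_result`: `power` (per-n estimates),
#'   `n_min`, plus the call parameters.
#' @export
replicate_power <- function(null_model = "normal", d, k = 3,
                            power_target = 0.85, n_max = 30L,
                            n_sim = 2000L, seed = 1L, directional = TRUE,
                            method = c("simulate", "analytic")) {
  stopifnot(d >= 0, power_target > 0, power_target < 1, n_max >= 1)
  method <- match.arg(method)
  empirical <- is.numeric(null_model)
  if (empirical) {
    m <- median(null_model); s <- sd(null_model)
    stopifnot(length(null_model) >= 8, s > 0)
    if (method == "analytic")
      stop("analytic power requires the normal null model")
  } else {
    stopifnot(identical(null_model, "normal"))
    m <- 0; s <- 1
  }
  if (method == "analytic") {
    p1 <- pnorm(d - k) + if (directional) 0 else pnorm(-d - k)
    pow <- 1 - (1 - p1)^seq_len(n_max)
    n_min <- which(pow >= power_target)[1]
    return(structure(list(power = pow, power_monotone = pow,
                          n_min = if (is.na(n_min)) NA_integer_ else n_min,
                          d = d, k = k, power_target = power_target,
                          n_max = n_max, n_sim = 0L,
                          directional = directional, method = "analytic",
                          reached = !is.na(n_min)),
                     class = "power_result"))
  }
  pow <- with_seed(seed, "power", {
    draw <- if (empirical)
      function(n) sample(null_model, n, replace = TRUE) + d * s
    else
      function(n) rnorm(n, m + d * s, s)
    vapply(seq_len(n_max), function(n) {
      hits <- vapply(seq_len(n_sim), function(i) {
        x <- draw(n)
        dev <- (x - m) / s
        if (directional) any(dev > k) else any(abs(dev) > k)
      }, logical(1))
      mean(hits)
    }, numeric(1))
  })
  # enforce the (theoretically guaranteed) monotonicity against MC jitter
  pow_mono <- cummax(pow)
  n_min <- which(pow_mono >= power_target)[1]
  structure(list(power = pow, power_monotone = pow_mono,
                 n_min = if (is.na(n_min)) NA_integer_ else n_min,
                 d = d, k = k, power_target = power_target,
                 n_max = n_max, n_sim = n_sim,
                 directional = directional, method = "simulate",
                 reached = !is.na(n_min)), class = "power_result")
}

#' Two-group comparison
#'
#' Two-sided Mann-Whitney U (exact where possible), Welch's t, or an
#' automatic choice: Welch when both groups pass a Shapiro-Wilk normality
#' check (p > 0.05), Mann-Whitney otherwise.
#'
#' @param x,y numeric vectors (>= 3 values each).
#' @param test `"mannwhitney"`, `"welch"` or `"auto"`.
#' @return list: `p`, `statistic`, `test`.
#' @export
compare_groups <- function(x, y, test = c("auto", "mannwhitney", "welch")) {
  test <- match.arg(test)
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied across both groups")
    return(list(p = 1, statistic = NA_real_, test = test))
  }
  if (test == "auto") {
    normal <- function(v) length(unique(v)) > 2 &&
      shapiro.test(v)$p.value > 0.05
    test <- if (normal(x) && normal(y)) "welch" else "mannwhitney"
  }
  if (test == "mannwhitney") {
    ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    list(p = ht$p.value, statistic = unname(ht$statistic),
         test = "mannwhitney")
  } else {
    ht <- t.test(x, y, var.equal = FALSE)
    list(p = ht$p.value, statistic = unname(ht$statistic), test = "welch")
  }
}

#' Percentile bootstrap confidence interval of the median
#'
#' @param x numeric vector (>= 5 values).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric vector `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(x, n_boot = 1000L, level = 0.95,
                                seed = 1L) {
  stopifnot(length(x) >= 5, n_boot >= 1)
  meds <- with_seed(seed, "boot", {
    vapply(seq_len(n_boot), function(i)
      median(sample(x, length(x), replace = TRUE)), numeric(1))
  })
  a <- (1 - level) / 2
  unname(quantile(meds, c(a, 1 - a), type = 7))
}
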