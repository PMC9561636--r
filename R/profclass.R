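# Two-class reference profiling: repeated shuffled-split training,
# decision-space mapping of additional conditions, cross-plate validation,
# PCA embedding.

#' Cross-validation specification
#'
#' Repeated stratified shuffle splits: train on 80%, test on 20%,
#' repeated 25 times by default.
#'
#' @param train_fraction fraction of wells used for training per repeat.
#' @param n_repeats number of shuffled splits.
#' @param stratified preserve class proportions in the split.
#' @param seed integer seed driving all splits.
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(train_fraction = 0.8, n_repeats = 25L,
                    stratified = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 2)
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Train a two-class reference profile model
#'
#' Per repeat: stratified shuffle split, hyperparameter grid search on the
#' training portion (k-fold CV accuracy), fit, test accuracy recorded.
#' The model keeps all per-repeat fits; a well's raw score is the ensemble
#' mean of the fits' signed decision values (log-odds for GBM). Score
#' anchors are the raw-score class medians over the training table, so
#' that on training data the negative class median maps to 0 and the
#' positive class median to 1.
#'
#' @param table preprocessed feature_table.
#' @param class_neg,class_pos condition labels of the two reference
#'   classes (negative maps to score 0, positive to 1).
#' @param algorithm `"LDA"`, `"SVM"` or `"GBM"`.
#' @param cv a [cv_spec()].
#' @param grid list of hyperparameter lists; default per algorithm
#'   (SVM: C in 0.01/0.1/1/10; GBM: trees 100/300 x depth 3/5 x lr
#'   0.05/0.1).
#' @return object of class `profile_model`.
#' @export
train_reference <- function(table, class_neg, class_pos,
                            algorithm = c("SVM", "LDA", "GBM"),
                            cv = cv_spec(), grid = NULL) {
  algorithm <- match.arg(algorithm)
  for (cl in c(class_neg, class_pos))
    if (sum(table$condition == cl) < 10)
      stop("class error: condition '", cl, "' has fewer than 10 wells")
  stopifnot(class_neg != class_pos)
  sub <- table[table$condition %in% c(class_neg, class_pos), , drop = FALSE]
  feats <- feature_cols(sub)
  X <- as.matrix(sub[feats])
  if (any(!is.finite(X))) stop("features must be finite; preprocess first")
  y <- ifelse(sub$condition == class_pos, 1, -1)
  grid <- grid %||% .default_grid(algorithm)

  n <- nrow(X)
  fits <- vector("list", cv$n_repeats)
  accs <- numeric(cv$n_repeats)
  for (r in seq_len(cv$n_repeats)) {
    idx_tr <- with_seed(cv$seed, paste0("split", r), {
      if (cv$stratified) {
        unlist(lapply(c(-1, 1), function(cl) {
          i <- which(y == cl)
          sample(i, round(cv$train_fraction * length(i)))
        }))
      } else sample(n, round(cv$train_fraction * n))
    })
    idx_te <- setdiff(seq_len(n), idx_tr)
    Xtr <- X[idx_tr, , drop = FALSE]
    ytr <- y[idx_tr]
    hp <- .grid_search(algorithm, Xtr, ytr, grid,
                       seed = child_seed(cv$seed, paste0("grid", r)))
    std <- .standardizer(Xtr)
    fit <- .fit_algo(algorithm, .apply_std(std, Xtr), ytr, hp)
    sc <- .decision(fit, .apply_std(std, X[idx_te, , drop = FALSE]))
    accs[r] <- mean((sc > 0) == (y[idx_te] > 0))
    fits[[r]] <- list(fit = fit, std = std, hyper = hp)
  }

  model <- structure(list(
    algorithm = algorithm, features = feats, fits = fits,
    class_neg = class_neg, class_pos = class_pos,
    accuracy = mean(accs), accuracy_sem = sd(accs) / sqrt(cv$n_repeats),
    accuracies = accs, cv = cv), class = "profile_model")

  raw <- .raw_scores(model, X)
  model$anchor_neg <- median(raw[y < 0])
  model$anchor_pos <- median(raw[y > 0])
  if (model$accuracy > 0.5 &&
      abs(model$anchor_pos - model$anchor_neg) < 1e-12)
    warning("score anchors coincide despite accuracy > 0.5")
  model
}

.raw_scores <- function(model, X) {
  sc <- vapply(model$fits, function(f)
    .decision(f$fit, .apply_std(f$std, X)), numeric(nrow(X)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(X))
  rowMeans(sc)
}

#' Score wells on a trained reference decision axis
#'
#' Raw score = ensemble mean decision value over the stored fits;
#' normalized score is the affine map sending the negative-class anchor to
#' 0 and the positive-class anchor to 1 ("classification proximity").
#' Wells never seen in training are scorable.
#'
#' @param model a [train_reference()] model.
#' @param table feature_table containing all model features.
#' @return data.frame: plate_id, well, condition, compound, spiked, raw,
#'   normalized.
#' @export
score_wells <- function(model, table) {
  miss <- setdiff(model$features, names(table))
  if (length(miss))
    stop("mapping error: table lacks model feature(s): ",
         paste(head(miss, 5), collapse = ", "))
  X <- as.matrix(table[model$features])
  raw <- .raw_scores(model, X)
  den <- model$anchor_pos - model$anchor_neg
  if (abs(den) < 1e-12) stop("degenerate score anchors")
  data.frame(plate_id = table$plate_id, well = table$well,
             condition = table$condition, compound = table$compound,
             spiked = table$spiked, raw = raw,
             normalized = (raw - model$anchor_neg) / den,
             stringsAsFactors = FALSE)
}

#' Leave-one-plate-in cross-validation
#'
#' Fits the model on each plate in turn and reports accuracy on every
#' other plate (train one plate, test on unseen plates).
#'
#' @param table preprocessed feature_table with >= 2 plates.
#' @param class_neg,class_pos reference class labels.
#' @param algorithm,cv,grid as in [train_reference()].
#' @return data.frame: train_plate, test_plate, accuracy.
#' @export
cross_plate_validate <- function(table, class_neg, class_pos,
                                 algorithm = "SVM", cv = cv_spec(),
                                 grid = NULL) {
  plates <- unique(table$plate_id)
  if (length(plates) < 2) stop("need >= 2 plates")
  out <- list()
  for (tp in plates) {
    tr <- table[table$plate_id == tp, , drop = FALSE]
    has <- all(c(class_neg, class_pos) %in% tr$condition) &&
      sum(tr$condition == class_neg) >= 10 &&
      sum(tr$condition == class_pos) >= 10
    if (!has) {
      warning("plate ", tp, " lacks a full reference class; skipped")
      next
    }
    model <- train_reference(tr, class_neg, class_pos, algorithm, cv, grid)
    for (hp in setdiff(plates, tp)) {
      te <- table[table$plate_id == hp &
                    table$condition %in% c(class_neg, class_pos), ,
                  drop = FALSE]
      if (!nrow(te)) next
      sc <- score_wells(model, te)
      pred_pos <- sc$normalized > 0.5
      out[[length(out) + 1]] <- data.frame(
        train_plate = tp, test_plate = hp,
        accuracy = mean(pred_pos == (te$condition == class_pos)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' PCA embedding of well profiles
#'
#' Features are standardized, then projected; explained-variance
#' fractions are non-increasing and sum to at most 1.
#'
#' @param table feature_table.
#' @param n_components number of components (truncated to the matrix rank
#'   with a warning if larger).
#' @return list: `coords` (wells x components), `explained` (variance
#'   fractions), `meta` (well metadata).
#' @export
pca_embed <- function(table, n_components = 2L) {
  feats <- feature_cols(table)
  X <- as.matrix(table[feats])
  sds <- apply(X, 2, sd)
  X <- X[, sds > 1e-12, drop = FALSE]
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(n_wells, n_features)")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_components > rank) {
    warning("n_components exceeds rank ", rank, "; truncated")
    n_components <- rank
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       meta = table[c("plate_id", "well", "condition", "compound")])
}

#' Save / load a profile model as a directory of JSON files
#'
#' Plain-text persistence: `meta.json` carries the model metadata and
#' anchors, `fits.json` the per-repeat fit states (weights and
#' standardizers; trees for GBM).
#'
#' @param model a `profile_model`.
#' @param dir target directory (created).
#' @return `dir` / the restored `profile_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- model[c("algorithm", "features", "class_neg", "class_pos",
                  "accuracy", "accuracy_sem", "accuracies",
                  "anchor_neg", "anchor_pos")]
  meta$cv <- unclass(model$cv)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model$fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  fits_raw <- jsonlite::read_json(file.path(dir, "fits.json"))
  num <- function(x) as.numeric(unlist(x))
  restore_tree <- function(nd) {
    if (isTRUE(nd$leaf)) return(list(leaf = TRUE, value = nd$value))
    list(leaf = FALSE, j = nd$j, cut = nd$cut,
         left = restore_tree(nd$left), right = restore_tree(nd$right))
  }
  fits <- lapply(fits_raw, function(f) {
    fit <- f$fit
    out <- if (fit$type == "gbm") {
      list(type = "gbm", f0 = fit$f0, lr = fit$lr,
           trees = lapply(fit$trees, restore_tree))
    } else {
      list(type = fit$type, w = num(fit$w), b = fit$b)
    }
    list(fit = out,
         std = list(mu = num(f$std$mu),
                    sd = num(lapply(f$std$sd, function(v)
                      if (identical(v, "Inf")) Inf else v))),
         hyper = f$hyper)
  })
  model <- list(algorithm = meta$algorithm, features = meta$features,
                fits = fits, class_neg = meta$class_neg,
                class_pos = meta$class_pos, accuracy = meta$accuracy,
                accuracy_sem = meta$accuracy_sem,
                accuracies = meta$accuracies,
                cv = structure(meta$cv, class = "cv_spec"),
                anchor_neg = meta$anchor_neg,
                anchor_pos = meta$anchor_pos)
  class(model) <- "profile_model"
  model
}
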