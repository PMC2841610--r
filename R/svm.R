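# RBF-SVM training, class balancing, leave-one-protein-out cross-validation
# with homology exclusion, MCC-driven grid search, and the metric suite.

#' SVM hyperparameters
#'
#' Defaults are the reference optima of the lipid-exposure classifier
#' (`gamma = 0.6`, trade-off `C = 1.5`); the contact classifier's optima are
#' `gamma = 24`, `C = 1` (see [contact_svm_params()]).
#'
#' @param gamma RBF kernel width parameter, `> 0`.
#' @param C Error/margin trade-off, `> 0`.
#' @param cost_factor Weight on positive-class errors (SVM cost factor j),
#'   used to restore an effective 1:1 balance after undersampling.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(gamma = 0.6, C = 1.5, cost_factor = 1) {
  stopifnot(gamma > 0, C > 0, cost_factor > 0)
  structure(list(gamma = gamma, C = C, cost_factor = cost_factor),
            class = "svm_params")
}

#' Reference optima for the residue-contact classifier
#' @return An `svm_params` with `gamma = 24`, `C = 1`.
#' @export
contact_svm_params <- function() svm_params(gamma = 24, C = 1)

# run expr with a temporarily-seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Balance a training set by random undersampling
#'
#' All positives are kept; negatives are subsampled without replacement down
#' to the positive count (the standard remedy for the roughly 1:50
#' contact/non-contact imbalance). Any residual imbalance is compensated by
#' the returned cost factor `j = n_neg_kept / n_pos`.
#'
#' @param features Feature matrix.
#' @param labels Logical (or 0/1) vector.
#' @param seed Integer seed; the subsample is deterministic given the seed.
#' @return List with `features`, `labels`, `cost_factor`, `index` (rows kept,
#'   in original order).
#' @export
balance_training <- function(features, labels, seed = 1L) {
  labels <- as.logical(labels)
  pos <- which(labels); neg <- which(!labels)
  if (length(pos) == 0L) stop("no positive examples to balance against")
  if (length(neg) > length(pos)) {
    keep_neg <- with_seed(seed, sort(sample(neg, length(pos))))
  } else keep_neg <- neg
  idx <- sort(c(pos, keep_neg))
  list(features = features[idx, , drop = FALSE],
       labels = labels[idx],
       cost_factor = length(keep_neg) / length(pos),
       index = idx)
}

#' Train an RBF-SVM classifier
#'
#' Wraps [e1071::svm()] with a radial kernel. The returned model's raw
#' decision score is positive for predicted positives (the sign convention
#' is normalised internally, independent of class ordering in the input).
#'
#' @param features Normalized feature matrix.
#' @param labels Logical (or 0/1) vector; both classes must be present.
#' @param params An [svm_params()].
#' @param norm_stats Optional Z-score statistics stored for later use.
#' @param config Optional [feature_config()] stored for provenance.
#' @return An object of class `trained_svm`.
#' @export
train_svm <- function(features, labels, params = svm_params(),
                      norm_stats = NULL, config = NULL) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("training labels are single-class")
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  wts <- c(neg = 1, pos = params$cost_factor)
  fit <- e1071::svm(x = as.matrix(features), y = y, type = "C-classification",
                    kernel = "radial", gamma = params$gamma, cost = params$C,
                    class.weights = wts, scale = FALSE)
  pr <- predict(fit, as.matrix(features), decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # e1071 reports values for "<first>/<second>"; flip so positive => "pos"
  sign_flip <- if (mean(dv[pr == "pos"]) < mean(dv[pr == "neg"])) -1 else 1
  structure(list(fit = fit, sign = sign_flip, params = params,
                 n_features = ncol(features), norm_stats = norm_stats,
                 config = config),
            class = "trained_svm")
}

#' Raw SVM decision scores
#'
#' @param model A `trained_svm` from [train_svm()].
#' @param features Feature matrix with the model's training dimensionality;
#'   assumed already normalized the same way as the training data.
#' @return Numeric vector of raw decision values; `score > 0` predicts the
#'   positive class.
#' @export
predict_scores <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop("feature width ", ncol(features), " does not match model width ",
         model$n_features)
  }
  pr <- predict(model$fit, features, decision.values = TRUE)
  model$sign * drop(attr(pr, "decision.values"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)`; MCC follows its standard
#' formula with 0 substituted when any denominator factor is zero (the
#' `degenerate` flag records this). Degenerate precision/recall/FPR/FNR
#' denominators also yield 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion-matrix counts (total `> 0`).
#' @return An object of class `metric_report`: list with the counts,
#'   `precision`, `recall`, `fpr`, `fnr`, `mcc`, `accuracy`, `degenerate`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  frac <- function(num, den) if (den > 0) num / den else 0
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / denom
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 precision = frac(tp, tp + fp),
                 recall = frac(tp, tp + fn),
                 fpr = frac(fp, fp + tn),
                 fnr = frac(fn, fn + tp),
                 mcc = mcc,
                 accuracy = (tp + tn) / total,
                 degenerate = degenerate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  precision %.3f  recall %.3f  FPR %.3f  FNR %.3f  MCC %.3f  accuracy %.1f%%\n",
              x$precision, x$recall, x$fpr, x$fnr, x$mcc, 100 * x$accuracy))
  invisible(x)
}

#' Metrics from predicted and true labels
#' @param predicted,truth Logical vectors.
#' @return A `metric_report`.
#' @export
metrics_from_labels <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  compute_metrics(sum(predicted & truth), sum(!predicted & !truth),
                  sum(predicted & !truth), sum(!predicted & truth))
}

#' Homology table
#'
#' Pairwise E-values between dataset sequences, used to exclude homologs of
#' the held-out protein from training folds (exclusion threshold `1e-4`).
#' Treated symmetrically; self E-values are 0.
#'
#' @param ids Character vector of protein ids.
#' @param evalues Optional data frame with columns `id1`, `id2`, `evalue`;
#'   pairs not listed default to `default_evalue`.
#' @param default_evalue E-value assumed for unlisted pairs (default 10,
#'   i.e. unrelated).
#' @return An object of class `homology_table` (symmetric matrix).
#' @export
homology_table <- function(ids, evalues = NULL, default_evalue = 10) {
  m <- matrix(default_evalue, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(m) <- 0
  if (!is.null(evalues)) {
    for (k in seq_len(nrow(evalues))) {
      a <- as.character(evalues$id1[k]); b <- as.character(evalues$id2[k])
      m[a, b] <- m[b, a] <- min(m[a, b], evalues$evalue[k])
    }
  }
  structure(m, class = c("homology_table", "matrix"))
}

#' Proteins excluded from a training fold
#' @param homology A [homology_table()] (or `NULL` for no homologs).
#' @param target_id Held-out protein id.
#' @param ids Candidate training ids.
#' @param threshold Exclusion E-value threshold, default `1e-4`.
#' @return Character vector of excluded ids (always includes `target_id`).
#' @export
fold_exclusions <- function(homology, target_id, ids, threshold = 1e-4) {
  if (is.null(homology)) return(target_id)
  ev <- unclass(homology)[target_id, ids]
  unique(c(target_id, ids[ev < threshold]))
}

#' Leave-one-protein-out cross-validation of an RBF-SVM
#'
#' For each protein, every sequence with an E-value below `1e-4` to it
#' (including itself) is excluded from the training pool; negatives may be
#' undersampled to balance; Z-score normalization is fitted on the fold's
#' training matrix only; predictions on the held-out protein are pooled
#' into one confusion matrix.
#'
#' @param dataset List of per-protein lists, each with `id`, `features`
#'   (raw, unnormalized) and `labels` (logical).
#' @param params An [svm_params()].
#' @param homology Optional [homology_table()].
#' @param balance Undersample negatives per fold (default `FALSE`).
#' @param balance_test Also evaluate each held-out protein on a
#'   class-balanced subset (all positives plus an equal-size seeded random
#'   subsample of negatives); makes the pooled MCC independent of the
#'   synthetic class ratio. Default `FALSE` (evaluate on all pairs).
#' @param seed Integer seed for balancing.
#' @return List with pooled `metrics`, per-fold `folds` (data frame), and
#'   `excluded` (list of training exclusions per fold).
#' @export
loo_cv <- function(dataset, params = svm_params(), homology = NULL,
                   balance = FALSE, balance_test = FALSE, seed = 1L) {
  if (length(dataset) < 2L) stop("leave-one-out CV needs at least 2 proteins")
  ids <- vapply(dataset, `[[`, "", "id")
  tp <- tn <- fp <- fn <- 0
  folds <- data.frame(id = ids, mcc = NA_real_, accuracy = NA_real_)
  excluded <- vector("list", length(dataset))
  names(excluded) <- ids
  for (k in seq_along(dataset)) {
    excl <- fold_exclusions(homology, ids[k], ids)
    excluded[[k]] <- excl
    train_idx <- which(!ids %in% excl)
    if (length(train_idx) == 0L) stop("no training proteins left for fold ", ids[k])
    tr_x <- do.call(rbind, lapply(dataset[train_idx], `[[`, "features"))
    tr_y <- unlist(lapply(dataset[train_idx], `[[`, "labels"))
    pars <- params
    if (balance) {
      bal <- balance_training(tr_x, tr_y, seed = seed + k)
      tr_x <- bal$features; tr_y <- bal$labels
      pars$cost_factor <- bal$cost_factor
    }
    norm <- fit_apply_zscore(tr_x, test = dataset[[k]]$features)
    model <- train_svm(norm$train, tr_y, pars)
    scores <- predict_scores(model, norm$test)
    pred <- scores > 0
    truth <- as.logical(dataset[[k]]$labels)
    if (balance_test) {
      pos <- which(truth); neg <- which(!truth)
      if (length(pos) > 0L && length(neg) > length(pos)) {
        keep <- c(pos, with_seed(seed + 7000L + k, sample(neg, length(pos))))
        pred <- pred[keep]; truth <- truth[keep]
      }
    }
    tp <- tp + sum(pred & truth); tn <- tn + sum(!pred & !truth)
    fp <- fp + sum(pred & !truth); fn <- fn + sum(!pred & truth)
    fm <- try(metrics_from_labels(pred, truth), silent = TRUE)
    if (!inherits(fm, "try-error")) {
      folds$mcc[k] <- fm$mcc; folds$accuracy[k] <- fm$accuracy
    }
  }
  list(metrics = compute_metrics(tp, tn, fp, fn), folds = folds,
       excluded = excluded)
}

#' MCC-driven grid search over SVM parameters
#'
#' Evaluates every grid point with leave-one-protein-out cross-validation
#' ([loo_cv()]) and returns the parameters maximizing the pooled MCC. Ties
#' are broken by smaller `C`, then smaller `gamma`.
#'
#' @param dataset As for [loo_cv()].
#' @param grid Data frame with columns `gamma` and `C` (non-empty).
#' @param homology Optional [homology_table()].
#' @param balance Undersample negatives per fold.
#' @param seed Integer seed.
#' @return List with `best` ([svm_params()]), `best_mcc`, and `results`
#'   (the grid with an `mcc` column).
#' @export
grid_search_cv <- function(dataset, grid, homology = NULL, balance = FALSE,
                           seed = 1L) {
  if (nrow(grid) == 0L) stop("empty parameter grid")
  if (length(dataset) < 2L) stop("grid search needs at least 2 proteins")
  grid$mcc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cv <- loo_cv(dataset, svm_params(gamma = grid$gamma[g], C = grid$C[g]),
                 homology = homology, balance = balance, seed = seed)
    grid$mcc[g] <- cv$metrics$mcc
  }
  ord <- order(-grid$mcc, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  list(best = svm_params(gamma = best$gamma, C = best$C),
       best_mcc = best$mcc, results = grid)
}
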