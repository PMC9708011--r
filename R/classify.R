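# Feature ranking, stepwise selection and SVM classification.
#
# MPCA features are ranked by Fisher's discriminant ratio, a top-k set is
# chosen by stepwise inclusion against a held-out tuning set, and a linear
# SVM (libsvm via e1071) is trained on the selected features. Mortality
# probabilities come from a seeded, cross-validated Platt-style logistic
# mapping of the SVM decision values. A linear kernel is used throughout:
# the single weight vector is what the saliency module back-projects.

#' Fisher's discriminant ratio of one feature
#'
#' `(mu1 - mu0)^2 / (var1 + var0 + eps)` with population (1/n) variances;
#' scale-invariant and nonnegative.
#'
#' @param x numeric feature values.
#' @param labels logical class labels (both classes must be present).
#' @param eps variance guard.
#' @return the Fisher score.
#' @export
fisher_score <- function(x, labels, eps = 1e-12) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  x1 <- x[labels]
  x0 <- x[!labels]
  pvar <- function(v) mean((v - mean(v))^2)
  (mean(x1) - mean(x0))^2 / (pvar(x1) + pvar(x0) + eps)
}

# vectorised Fisher scores over the columns of a feature matrix
fisher_scores <- function(features, labels, eps = 1e-12) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  m1 <- colMeans(features[labels, , drop = FALSE])
  m0 <- colMeans(features[!labels, , drop = FALSE])
  pv <- function(m) colMeans(sweep(m, 2, colMeans(m))^2)
  v1 <- pv(features[labels, , drop = FALSE])
  v0 <- pv(features[!labels, , drop = FALSE])
  (m1 - m0)^2 / (v1 + v0 + eps)
}

# raw linear SVM fit: weight vector oriented so that the positive class
# (labels TRUE) has the larger mean decision value
svm_weights <- function(features, labels, cost = 1) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2) stop("need >= 2 cases per class")
  if (all(duplicated(features)[-1])) {
    stop("degenerate training set: all feature rows identical")
  }
  fit <- e1071::svm(
    x = features, y = factor(labels, levels = c(FALSE, TRUE)),
    kernel = "linear", cost = cost, scale = FALSE
  )
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dv <- drop(features %*% w) + b
  if (mean(dv[labels]) < mean(dv[!labels])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Rank features by Fisher score and select a top-k set on a tuning set
#'
#' A stratified tuning set (default around 50 cases) is held out; features
#' are ranked by Fisher score computed on the remaining cases only; for
#' k = 1..`max_k` a linear SVM trained on the remaining cases with the
#' top-k features is scored by AUC on the tuning set, and the best k wins
#' (ties go to the smallest k).
#'
#' @param features n x p numeric matrix.
#' @param labels logical outcome labels.
#' @param tuning_size target tuning-set size (capped at half the cohort).
#' @param max_k largest candidate set size.
#' @param cost SVM regularisation parameter.
#' @param seed seed for the tuning draw.
#' @return object of class `selected_features`: `indices` (original column
#'   indices in rank order), `fisher_scores` (non-increasing), `k`,
#'   `tuning_metric` (AUC) and the per-k tuning curve.
#' @export
stepwise_select <- function(features, labels, tuning_size = 50, max_k = 30,
                            cost = 1, seed = 1) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels))
  set.seed(seed)
  tuning_size <- min(tuning_size, floor(nrow(features) / 2))
  tune_idx <- stratified_sample(labels, tuning_size)
  if (length(unique(labels[tune_idx])) < 2) {
    tune_idx <- stratified_sample(labels, tuning_size)
    if (length(unique(labels[tune_idx])) < 2) {
      stop("tuning set is missing a class")
    }
  }
  train_idx <- setdiff(seq_len(nrow(features)), tune_idx)
  if (length(unique(labels[train_idx])) < 2) stop("training part is missing a class")

  fs <- fisher_scores(features[train_idx, , drop = FALSE], labels[train_idx])
  rank_order <- order(fs, decreasing = TRUE)
  max_k <- min(max_k, ncol(features))
  tuning_auc <- numeric(max_k)
  for (k in seq_len(max_k)) {
    cols <- rank_order[seq_len(k)]
    fit <- svm_weights(features[train_idx, cols, drop = FALSE], labels[train_idx], cost)
    dv <- drop(features[tune_idx, cols, drop = FALSE] %*% fit$w) + fit$b
    tuning_auc[k] <- auc_mann_whitney(dv, labels[tune_idx])
  }
  best_k <- which.max(tuning_auc)
  structure(
    list(
      indices = rank_order[seq_len(best_k)],
      fisher_scores = fs[rank_order[seq_len(best_k)]],
      k = best_k,
      tuning_metric = tuning_auc[best_k],
      tuning_curve = tuning_auc,
      tuning_size = length(tune_idx),
      seed = seed
    ),
    class = "selected_features"
  )
}

# seeded stratified-CV Platt calibration: logistic map decision -> probability,
# fitted against Platt's regularised soft targets so the map stays finite
# even when the out-of-fold decision values separate the classes perfectly
platt_calibrate <- function(features, labels, cost, folds = 5, seed = 1) {
  labels <- as.logical(labels)
  set.seed(seed)
  folds <- max(2L, min(folds, sum(labels), sum(!labels)))
  fold_id <- stratified_folds(labels, folds)
  dv <- numeric(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- svm_weights(features[tr, , drop = FALSE], labels[tr], cost)
    dv[!tr] <- drop(features[!tr, , drop = FALSE] %*% fit$w) + fit$b
  }
  np <- sum(labels)
  nn <- sum(!labels)
  tgt <- ifelse(labels, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- stats::plogis(par[1] + par[2] * dv)
    -sum(tgt * log(p + 1e-12) + (1 - tgt) * log(1 - p + 1e-12))
  }
  o <- tryCatch(
    stats::optim(c(0, 1), nll, method = "BFGS", control = list(maxit = 500)),
    error = function(e) list(par = c(0, 1))
  )
  par <- o$par
  if (any(!is.finite(par))) par <- c(0, 1)
  c(intercept = par[1], slope = par[2])
}

#' Train a calibrated linear SVM on selected features
#'
#' Maximum-margin linear classifier (regularisation `cost`) with a
#' probability map fitted by seeded cross-validated logistic (Platt-style)
#' regression on out-of-fold decision values.
#'
#' @param features n x p matrix of the selected feature columns.
#' @param labels logical outcome labels (>= 2 cases per class).
#' @param selected optional `selected_features` describing which model
#'   features the columns are (stored for saliency back-projection).
#' @param view label stored with the model (`"SA"`, `"4Ch"`, `"combined"`).
#' @param cost SVM regularisation parameter.
#' @param seed seed for the calibration folds.
#' @return object of class `prognostic_model` with fields `w`, `b`,
#'   `platt`, `selected`, `view`.
#' @export
train_svm <- function(features, labels, selected = NULL, view = "SA",
                      cost = 1, seed = 1) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  fit <- svm_weights(features, labels, cost)
  platt <- platt_calibrate(features, labels, cost, seed = seed)
  structure(
    list(
      view = view,
      w = fit$w,
      b = fit$b,
      platt = platt,
      selected = selected,
      n_features = ncol(features),
      cost = cost,
      seed = seed
    ),
    class = "prognostic_model"
  )
}

#' Predicted mortality probability of a trained model
#'
#' @param model a `prognostic_model`.
#' @param features matrix (or vector) of the model's feature columns.
#' @param type `"probability"` (Platt-calibrated, in \[0,1\]) or
#'   `"decision"` (raw SVM decision value).
#' @return numeric vector.
#' @export
predict_probability <- function(model, features, type = "probability") {
  stopifnot(inherits(model, "prognostic_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$n_features) {
    stop(
      "feature count ", ncol(features), " does not match the model (",
      model$n_features, ")"
    )
  }
  dv <- drop(features %*% model$w) + model$b
  if (type == "decision") {
    return(dv)
  }
  stats::plogis(model$platt[["intercept"]] + model$platt[["slope"]] * dv)
}

#' @export
predict.prognostic_model <- function(object, newdata, type = "probability", ...) {
  predict_probability(object, newdata, type = type)
}

#' Repeated stratified cross-validation of the selection + SVM pipeline
#'
#' Runs `rounds` rounds of stratified `folds`-fold cross-validation. In
#' every fold, all fitted statistics come from the fold's training portion
#' only: with tensor input, MPCA is refit on the training tensors and all
#' subjects are projected through it; Fisher ranking and stepwise selection
#' use the training portion; the fold SVM is scored by AUC on the left-out
#' fold. The feature set of the best-performing fold (ties: first) is then
#' refit on the full data to give the final model.
#'
#' @param x n x p feature matrix, or a list of preprocessed tensors (MPCA
#'   is then refit per fold).
#' @param labels logical outcome labels.
#' @param rounds,folds cross-validation geometry (default 10 x 10).
#' @param seed master seed; all fold, tuning and calibration draws derive
#'   from it.
#' @param variance_kept MPCA retention (tensor input only).
#' @param tuning_size,max_k,cost passed to [stepwise_select()] /
#'   [train_svm()].
#' @param choose `"best"` (best single fold, default) or `"mean"` (the
#'   fold whose selected-set size equals the k with best mean AUC).
#' @return object of class `cv_prognostic`: `report` (one row per
#'   round x fold: auc, k, tuning metric), `chosen` (winning feature set),
#'   `final_model`, `mpca` (when refit on the full data) and settings.
#' @export
cross_validate <- function(x, labels, rounds = 10, folds = 10, seed = 1,
                           variance_kept = 0.97, tuning_size = 50, max_k = 30,
                           cost = 1, choose = c("best", "mean")) {
  choose <- match.arg(choose)
  labels <- as.logical(labels)
  tensor_input <- is.list(x) && !is.data.frame(x)
  n <- if (tensor_input) length(x) else nrow(x)
  stopifnot(n == length(labels), n >= folds)
  n_min <- min(sum(labels), sum(!labels))
  if (n_min < folds) {
    warning("reducing folds from ", folds, " to ", n_min, " (smallest class)")
    folds <- n_min
  }

  rows <- vector("list", rounds * folds)
  selections <- vector("list", rounds * folds)
  r <- 0L
  for (round in seq_len(rounds)) {
    set.seed(derive_seed(seed, round))
    fold_id <- stratified_folds(labels, folds)
    for (fold in seq_len(folds)) {
      r <- r + 1L
      test <- fold_id == fold
      if (tensor_input) {
        mpca <- fit_mpca(x[!test], variance_kept = variance_kept)
        feats <- t(vapply(x, function(tt) mpca_project(mpca, tt),
          numeric(prod(mpca$core_dims))
        ))
      } else {
        feats <- as.matrix(x)
      }
      sel <- stepwise_select(
        feats[!test, , drop = FALSE], labels[!test],
        tuning_size = tuning_size, max_k = max_k, cost = cost,
        seed = derive_seed(seed, round * 1000 + fold)
      )
      fit <- svm_weights(feats[!test, sel$indices, drop = FALSE], labels[!test], cost)
      dv <- drop(feats[test, sel$indices, drop = FALSE] %*% fit$w) + fit$b
      auc <- auc_mann_whitney(dv, labels[test])
      rows[[r]] <- data.frame(
        round = round, fold = fold, auc = auc,
        k = sel$k, tuning_auc = sel$tuning_metric
      )
      selections[[r]] <- sel
    }
  }
  report <- do.call(rbind, rows)

  best <- if (choose == "best") {
    which.max(report$auc)
  } else {
    # fold whose k matches the best mean-AUC k
    kbest <- as.integer(names(which.max(tapply(report$auc, report$k, mean))))
    which(report$k == kbest)[1]
  }
  chosen <- selections[[best]]

  if (tensor_input) {
    mpca_full <- fit_mpca(x, variance_kept = variance_kept)
    feats_full <- t(vapply(x, function(tt) mpca_project(mpca_full, tt),
      numeric(prod(mpca_full$core_dims))
    ))
  } else {
    mpca_full <- NULL
    feats_full <- as.matrix(x)
  }
  chosen$indices <- chosen$indices[chosen$indices <= ncol(feats_full)]
  final <- train_svm(
    feats_full[, chosen$indices, drop = FALSE], labels,
    selected = chosen, cost = cost, seed = derive_seed(seed, 999)
  )
  structure(
    list(
      report = report,
      chosen = chosen,
      final_model = final,
      mpca = mpca_full,
      rounds = rounds, folds = folds, seed = seed,
      settings = list(
        variance_kept = variance_kept, tuning_size = tuning_size,
        max_k = max_k, cost = cost, choose = choose
      )
    ),
    class = "cv_prognostic"
  )
}

#' Train the dual-scan (combined) SVM from two per-view feature blocks
#'
#' Concatenates the selected-feature blocks of the SA and 4Ch models for
#' the subjects present in both views and trains one calibrated SVM on the
#' concatenation.
#'
#' @param sa_features,fourch_features matrices of the per-view selected
#'   features with subject ids as rownames.
#' @param labels logical outcome labels named by subject id (or aligned
#'   with `sa_features` rows).
#' @param cost,seed passed to [train_svm()].
#' @return a `prognostic_model` with `view = "combined"` and a
#'   `block_sizes` field recording the two block widths.
#' @export
combine_dual_scan <- function(sa_features, fourch_features, labels,
                              cost = 1, seed = 1) {
  sa_features <- as.matrix(sa_features)
  fourch_features <- as.matrix(fourch_features)
  ids_sa <- rownames(sa_features)
  ids_4c <- rownames(fourch_features)
  if (is.null(ids_sa) || is.null(ids_4c)) {
    stopifnot(nrow(sa_features) == nrow(fourch_features))
    common <- seq_len(nrow(sa_features))
    lab <- as.logical(labels)
  } else {
    common <- intersect(ids_sa, ids_4c)
    dropped <- setdiff(union(ids_sa, ids_4c), common)
    if (length(dropped)) {
      message(
        length(dropped), " subject(s) present in only one view excluded: ",
        paste(utils::head(dropped, 5), collapse = ", ")
      )
    }
    lab <- if (!is.null(names(labels))) as.logical(labels[common]) else as.logical(labels)
    sa_features <- sa_features[common, , drop = FALSE]
    fourch_features <- fourch_features[common, , drop = FALSE]
  }
  model <- train_svm(
    cbind(sa_features, fourch_features), lab,
    view = "combined", cost = cost, seed = seed
  )
  model$block_sizes <- c(SA = ncol(sa_features), `4Ch` = ncol(fourch_features))
  model
}
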