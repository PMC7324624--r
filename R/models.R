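# Base learners and model selection: random forests and RBF-SVMs for vector
# features, the CNN for matrix features, stratified cross-validation with
# pooled out-of-fold scoring, and AUC-driven window-size selection.

#' Train a random forest base learner
#'
#' @param vectors Samples-by-dimension numeric matrix.
#' @param labels Binary 0/1 labels, both classes present.
#' @param n_trees Number of trees; default 500.
#' @param seed RNG seed for reproducible forests.
#' @return Fitted `randomForest` object.
#' @export
train_rf <- function(vectors, labels, n_trees = 500L, seed = 1L) {
  check_xy(vectors, labels)
  with_seed(seed, {
    randomForest::randomForest(x = vectors, y = factor(labels, levels = 0:1),
                               ntree = n_trees)
  })
}

#' Train an RBF support vector machine
#'
#' Radial-basis-function kernel with probability outputs (internal
#' cross-validated calibration). `gamma` defaults to `1 / (d * var(x))` and
#' `cost` to 1.
#'
#' @inheritParams train_rf
#' @param gamma RBF kernel width; `NULL` for the variance-scaled default.
#' @param cost Soft-margin cost parameter.
#' @return Fitted `svm` object from e1071.
#' @export
train_svm <- function(vectors, labels, gamma = NULL, cost = 1, seed = 1L) {
  check_xy(vectors, labels)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(vectors))
    gamma <- if (v > 0) 1 / (ncol(vectors) * v) else 1 / ncol(vectors)
  }
  with_seed(seed, {
    e1071::svm(x = vectors, y = factor(labels, levels = 0:1),
               kernel = "radial", gamma = gamma, cost = cost,
               probability = TRUE)
  })
}

check_xy <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  invisible(TRUE)
}

predict_prob <- function(fit, x) {
  if (inherits(fit, "malopred_cnn")) return(predict(fit, x))
  if (inherits(fit, "randomForest"))
    return(unname(predict(fit, x, type = "prob")[, "1"]))
  if (inherits(fit, "svm")) {
    p <- attr(predict(fit, x, probability = TRUE), "probabilities")
    return(unname(p[, "1"]))
  }
  stop("unsupported model class: ", paste(class(fit), collapse = "/"))
}

subset_x <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE]
  else if (is.array(x)) x[idx, , , drop = FALSE]
  else x[idx]
}

n_samples <- function(x) {
  if (is.matrix(x) || is.array(x)) dim(x)[1] else length(x)
}

#' Stratified fold assignment
#'
#' @param labels Binary labels.
#' @param folds Number of folds (each class must have at least `folds`
#'   members).
#' @param seed RNG seed.
#' @return Integer fold id per sample, each class spread evenly so fold sizes
#'   differ by at most one per class.
#' @export
stratified_folds <- function(labels, folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (folds < 2L) stop("folds must be >= 2")
  tab <- table(labels)
  if (any(tab < folds))
    stop("each class needs >= ", folds, " members for ", folds, "-fold CV")
  assign <- integer(length(labels))
  with_seed(seed, {
    for (lv in names(tab)) {
      idx <- sample(which(labels == as.integer(lv)))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

fit_one <- function(model_kind, x, y, seed, n_trees = 500L,
                    config = cnn_config()) {
  switch(model_kind,
    RF = train_rf(x, y, n_trees = n_trees, seed = seed),
    SVM = train_svm(x, y, seed = seed),
    CNN = {
      cfg <- config; cfg$seed <- as.integer(seed)
      train_cnn(x, y, cfg)
    },
    stop("unknown model kind: ", model_kind))
}

#' Stratified cross-validation with pooled out-of-fold scoring
#'
#' Assigns samples to stratified folds, fits the requested model kind on each
#' training complement and scores the held-out fold, so every sample receives
#' exactly one out-of-fold probability. The headline AUC is computed on the
#' pooled out-of-fold scores. For CNNs the penultimate-layer representation of
#' each held-out sample is also collected (for stacking).
#'
#' @param x Feature container: samples-by-dim matrix (RF/SVM) or list/array of
#'   fragment matrices (CNN).
#' @param labels Binary 0/1 labels.
#' @param model_kind `"RF"`, `"SVM"` or `"CNN"`.
#' @param folds Number of folds; default 10.
#' @param seed RNG seed (folds and fits).
#' @param n_trees Trees per forest (RF).
#' @param config [cnn_config()] for CNN fits.
#' @return Object of class `cv_result`: `oof_prob`, `oof_repr` (CNN, else
#'   NULL), `fold`, `fold_auc`, `auc` (pooled), `fold_metrics`.
#' @export
crossvalidate <- function(x, labels, model_kind = c("RF", "SVM", "CNN"),
                          folds = 10L, seed = 1L, n_trees = 500L,
                          config = cnn_config()) {
  model_kind <- match.arg(model_kind)
  y <- as.integer(labels)
  stopifnot(n_samples(x) == length(y))
  fold <- stratified_folds(y, folds, seed)
  oof <- numeric(length(y))
  oof_repr <- NULL
  fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    fit <- fit_one(model_kind, subset_x(x, which(tr)), y[tr],
                   seed = seed + f, n_trees = n_trees, config = config)
    pv <- predict_prob(fit, subset_x(x, which(te)))
    oof[te] <- pv
    fold_auc[f] <- if (length(unique(y[te])) == 2L) roc_auc(y[te], pv) else NA_real_
    if (model_kind == "CNN") {
      rp <- cnn_representation(fit, subset_x(x, which(te)))
      if (is.null(oof_repr)) oof_repr <- matrix(0, length(y), ncol(rp))
      oof_repr[te, ] <- rp
    }
  }
  structure(list(oof_prob = oof, oof_repr = oof_repr, fold = fold,
                 fold_auc = fold_auc, auc = roc_auc(y, oof),
                 model_kind = model_kind, folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s, %d folds, pooled OOF AUC %.3f\n",
              x$model_kind, x$folds, x$auc))
  invisible(x)
}

#' Fit one (feature, window, model) base component
#'
#' Encodes the fragments with one feature, generates out-of-fold probabilities
#' (and CNN representations) for leak-free stacking, then refits the model on
#' the full training data for deployment. For the `AAINDEX` feature a property
#' selection is derived from the training data when not supplied.
#'
#' @param fragments Equal-length training fragments.
#' @param labels Binary labels.
#' @param feature Feature name (see [encode_fragments()]).
#' @param model_kind `"CNN"`, `"RF"` or `"SVM"`.
#' @param stack_folds Folds used to generate out-of-fold outputs; default 5.
#' @param seed RNG seed.
#' @param selection Optional `property_selection` for `AAINDEX`.
#' @param k_properties Properties to select when `selection` is NULL;
#'   default 46.
#' @param pssm_fun Profile function for `PSSM`; default [pseudo_pssm()].
#' @param n_trees,config Passed to the underlying trainer.
#' @return Object of class `trained_component` with the fitted model, its
#'   encoder state, out-of-fold outputs and pooled CV AUC.
#' @export
fit_component <- function(fragments, labels, feature, model_kind,
                          stack_folds = 5L, seed = 1L, selection = NULL,
                          k_properties = 46L, pssm_fun = pseudo_pssm,
                          n_trees = 500L, config = cnn_config()) {
  y <- as.integer(labels)
  window <- nchar(fragments[[1]])
  if (feature == "AAINDEX" && is.null(selection))
    selection <- select_properties_by_ig(fragments, y, k = k_properties)
  x <- encode_fragments(fragments, feature, selection = selection,
                        pssm_fun = pssm_fun)
  if (model_kind == "CNN") x <- stack_input(x)
  cv <- crossvalidate(x, y, model_kind, folds = stack_folds, seed = seed,
                      n_trees = n_trees, config = config)
  fit <- fit_one(model_kind, x, y, seed = seed, n_trees = n_trees,
                 config = config)
  # Representations for meta-training come from the deployed network: unlike
  # probabilities, penultimate-layer coordinates are not comparable across
  # independently initialised fold models, so out-of-fold representations
  # cannot feed a meta-learner that will consume the final network's output.
  train_repr <- if (model_kind == "CNN") cnn_representation(fit, x) else NULL
  structure(list(feature = feature, window = window, kind = model_kind,
                 fit = fit, selection = selection, pssm_fun = pssm_fun,
                 oof_prob = cv$oof_prob, oof_repr = cv$oof_repr,
                 train_repr = train_repr, cv_auc = cv$auc, seed = seed),
            class = "trained_component")
}

component_encode <- function(component, fragments) {
  x <- encode_fragments(fragments, component$feature,
                        selection = component$selection,
                        pssm_fun = component$pssm_fun)
  if (component$kind == "CNN") x <- stack_input(x)
  x
}

#' Predict with a trained base component
#'
#' @param object A `trained_component`.
#' @param newdata Character vector of fragments at the component's window.
#' @param ... Ignored.
#' @return Positive-class probabilities.
#' @export
predict.trained_component <- function(object, newdata, ...) {
  if (nchar(newdata[[1]]) != object$window)
    stop("fragments have window ", nchar(newdata[[1]]),
         ", component expects ", object$window)
  predict_prob(object$fit, component_encode(object, newdata))
}

component_representation <- function(component, fragments) {
  if (component$kind != "CNN")
    stop("representation extraction is defined only for CNN components")
  cnn_representation(component$fit, component_encode(component, fragments))
}

#' @export
print.trained_component <- function(x, ...) {
  cat(sprintf("trained_component: %s/%s, window %d, OOF AUC %.3f\n",
              x$feature, x$kind, x$window, x$cv_auc))
  invisible(x)
}

#' Select a window size by cross-validated AUC
#'
#' Re-extracts fragments at every window in the grid, cross-validates the
#' (feature, model) pair and returns the window with the highest pooled
#' out-of-fold AUC; ties go to the smaller window. Windows that are invalid
#' for the feature (e.g. too few usable residues for PAAC, or too short for
#' the CNN topology) are skipped with a warning.
#'
#' @param sequences Named protein sequences.
#' @param sites Site table (`protein_id`, `position`, `label`).
#' @param feature Feature name.
#' @param model_kind Model kind.
#' @param window_grid Odd window sizes, e.g. `seq(15, 35, 2)` (mammal) or
#'   `seq(11, 39, 2)` (plant).
#' @param folds,seed,... Passed to [crossvalidate()] / encoders.
#' @return List with `best_window`, `best_auc` and the full `table`
#'   (data.frame of window vs AUC).
#' @export
window_grid_search <- function(sequences, sites, feature, model_kind,
                               window_grid, folds = 5L, seed = 1L, ...) {
  stopifnot(length(window_grid) > 0)
  if (any(window_grid %% 2L == 0L))
    stop("window sizes must be odd (2n + 1, lysine-centered)")
  rows <- lapply(sort(window_grid), function(wdw) {
    auc <- tryCatch({
      fr <- build_fragments(sequences, sites, n = (wdw - 1L) %/% 2L)
      sel <- if (feature == "AAINDEX")
        select_properties_by_ig(fr$fragment, fr$label, k = list(...)$k_properties %||% 46L)
      else NULL
      x <- encode_fragments(fr$fragment, feature, selection = sel)
      if (model_kind == "CNN") x <- stack_input(x)
      crossvalidate(x, fr$label, model_kind, folds = folds, seed = seed)$auc
    }, error = function(e) {
      warning("window ", wdw, " skipped: ", conditionMessage(e))
      NA_real_
    })
    data.frame(window = wdw, auc = auc)
  })
  tab <- do.call(rbind, rows)
  ok <- tab[!is.na(tab$auc), , drop = FALSE]
  if (!nrow(ok)) stop("no valid window in the grid for feature ", feature)
  best <- ok[order(-ok$auc, ok$window), ][1L, ]
  list(best_window = best$window, best_auc = best$auc, table = tab)
}
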