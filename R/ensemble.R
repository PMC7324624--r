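# Stacked ensembles: the mammalian NN meta-learner over CNN representations
# plus raw AAC/PAAC, the plant RBF-SVM meta-learner over the five component
# probabilities, and a majority-vote baseline. Meta-learners are trained on
# out-of-fold base-model outputs (generated by fit_component) so the stack
# never sees in-fold leakage; base models are refit on the full training data
# for deployment.

frag_provider <- function(fragments) {
  if (is.function(fragments)) return(fragments)
  function(window) {
    if (nchar(fragments[[1]]) != window)
      stop("fragments have window ", nchar(fragments[[1]]), " but window ",
           window, " is required; pass a function(window) provider instead")
    fragments
  }
}

#' Build the mammalian stacked ensemble (NN meta-learner)
#'
#' Meta-input is the concatenation of the three CNN components'
#' penultimate-layer representations with the raw 21-dim AAC and 34-dim PAAC
#' vectors; the meta-model is a small feed-forward network (one hidden layer
#' of 32 units). Representations are taken from the deployed networks (the
#' coordinates of independently initialised fold models are not mutually
#' comparable, so out-of-fold representation stacking is ill-posed); the
#' shuffled-label sanity check in the test suite guards the resulting
#' leakage surface. RF base models are deliberately excluded from this
#' preset. The default decision cutoff is 0.046.
#'
#' @param cnn_onehot,cnn_aaindex,cnn_pssm CNN `trained_component`s (from
#'   [fit_component()]) carrying out-of-fold representations.
#' @param aac_vectors `N x 21` AAC matrix of the training fragments.
#' @param paac_vectors `N x 34` PAAC matrix of the training fragments.
#' @param labels Binary training labels.
#' @param aac_window,paac_window Window sizes the raw vectors were computed
#'   at (needed to rebuild them at prediction time).
#' @param cutoff Decision threshold; default 0.046.
#' @param hidden Meta-network hidden width; default 32.
#' @param seed RNG seed for the meta fit.
#' @return Object of class `ensemble_model` with `aggregator = "NN_STACK"`.
#' @export
build_mammal_ensemble <- function(cnn_onehot, cnn_aaindex, cnn_pssm,
                                  aac_vectors, paac_vectors, labels,
                                  aac_window, paac_window,
                                  cutoff = 0.046, hidden = 32L, seed = 1L) {
  comps <- list(onehot = cnn_onehot, aaindex = cnn_aaindex, pssm = cnn_pssm)
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    if (!inherits(cmp, "trained_component") || cmp$kind != "CNN" ||
        is.null(cmp$train_repr))
      stop("component '", nm, "' must be a CNN trained_component with ",
           "training-set representations")
  }
  y <- as.integer(labels)
  meta_x <- cbind(do.call(cbind, lapply(comps, `[[`, "train_repr")),
                  aac_vectors, paac_vectors)
  w <- (length(y) / (2 * tabulate(y + 1L, 2L)))[y + 1L]
  meta <- with_seed(seed, {
    nnet::nnet(x = meta_x, y = nnet::class.ind(factor(y, levels = 0:1)),
               size = hidden, softmax = TRUE, weights = w, decay = 1e-4,
               maxit = 300L, trace = FALSE,
               MaxNWts = (ncol(meta_x) + 2L) * hidden + 100L)
  })
  structure(list(components = comps, aggregator = "NN_STACK", meta = meta,
                 cutoff = cutoff, aac_window = aac_window,
                 paac_window = paac_window, seed = seed),
            class = "ensemble_model")
}

#' Build the plant stacked ensemble (SVM meta-learner)
#'
#' Meta-input is the 5-dimensional vector of the five base components'
#' positive-class probabilities (out-of-fold during meta-training); the
#' meta-model is an RBF-SVM with probability outputs. The default decision
#' cutoff is 0.195.
#'
#' @param components List of exactly five `trained_component`s (conventionally
#'   CNNs on one-hot/AAindex/PSSM and RFs on AAC/PAAC).
#' @param labels Binary training labels.
#' @param cutoff Decision threshold; default 0.195.
#' @param seed RNG seed for the meta fit.
#' @return Object of class `ensemble_model` with `aggregator = "SVM_STACK"`.
#' @export
build_plant_ensemble <- function(components, labels, cutoff = 0.195,
                                 seed = 1L) {
  if (length(components) != 5L)
    stop("the plant ensemble stacks exactly 5 components, got ",
         length(components))
  if (!all(vapply(components, inherits, logical(1), "trained_component")))
    stop("all components must be trained_component objects")
  if (is.null(names(components)))
    names(components) <- vapply(components, `[[`, character(1), "feature")
  y <- as.integer(labels)
  meta_x <- do.call(cbind, lapply(components, `[[`, "oof_prob"))
  colnames(meta_x) <- names(components)
  meta <- train_svm(meta_x, y, seed = seed)
  structure(list(components = components, aggregator = "SVM_STACK",
                 meta = meta, cutoff = cutoff, seed = seed),
            class = "ensemble_model")
}

#' Majority-vote aggregation
#'
#' Positive iff strictly more than half of the component calls are positive;
#' an even split is a negative call (conservative tie rule).
#'
#' @param calls Binary vector of component calls, or a samples-by-components
#'   binary matrix.
#' @return Binary call(s).
#' @export
majority_vote <- function(calls) {
  if (is.matrix(calls))
    return(as.integer(rowSums(calls) > ncol(calls) / 2))
  as.integer(sum(calls) > length(calls) / 2)
}

#' Build a majority-vote ensemble
#'
#' Baseline aggregator: each component votes at `component_cutoff` and the
#' ensemble score is the positive-vote fraction; the ensemble call follows
#' [majority_vote()].
#'
#' @param components List of `trained_component`s.
#' @param component_cutoff Per-component voting threshold; default 0.5.
#' @return Object of class `ensemble_model` with `aggregator = "MAJORITY"`.
#' @export
build_majority_ensemble <- function(components, component_cutoff = 0.5) {
  if (is.null(names(components)))
    names(components) <- vapply(components, `[[`, character(1), "feature")
  structure(list(components = components, aggregator = "MAJORITY",
                 meta = NULL, cutoff = 0.5,
                 component_cutoff = component_cutoff),
            class = "ensemble_model")
}

meta_input <- function(ens, get_frags) {
  if (ens$aggregator == "NN_STACK") {
    reprs <- lapply(ens$components, function(cmp)
      component_representation(cmp, get_frags(cmp$window)))
    aac <- t(vapply(get_frags(ens$aac_window), encode_aac, numeric(21L)))
    paac <- encode_fragments(get_frags(ens$paac_window), "PAAC")
    cbind(do.call(cbind, reprs), aac, paac)
  } else {
    probs <- vapply(ens$components, function(cmp)
      predict(cmp, get_frags(cmp$window)), numeric(length(get_frags(
        ens$components[[1]]$window))))
    probs <- matrix(probs, ncol = length(ens$components))
    colnames(probs) <- names(ens$components)
    probs
  }
}

#' Score fragments with a stacked ensemble
#'
#' @param object An `ensemble_model`.
#' @param newdata Character vector of fragments (all components must then
#'   share one window), or a `function(window)` returning the fragments for
#'   any requested window.
#' @param ... Ignored.
#' @return List with `score` (ensemble positive probability, or vote fraction
#'   for the majority aggregator), `call` (binary at the ensemble cutoff) and
#'   `component_scores` (matrix of per-component probabilities).
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  get_frags <- frag_provider(newdata)
  comp_scores <- vapply(object$components, function(cmp)
    predict(cmp, get_frags(cmp$window)),
    numeric(length(get_frags(object$components[[1]]$window))))
  comp_scores <- matrix(comp_scores, ncol = length(object$components),
                        dimnames = list(NULL, names(object$components)))
  score <- switch(object$aggregator,
    NN_STACK = {
      mx <- meta_input(object, get_frags)
      unname(predict(object$meta, mx, type = "raw")[, 2L])
    },
    SVM_STACK = {
      mx <- meta_input(object, get_frags)
      predict_prob(object$meta, mx)
    },
    MAJORITY = {
      votes <- comp_scores >= object$component_cutoff
      rowMeans(votes)
    })
  list(score = score, call = as.integer(score >= object$cutoff),
       component_scores = comp_scores)
}

#' Predict malonylation sites across a whole protein
#'
#' Enumerates every lysine in the sequence, rebuilds each component's fragment
#' at its own window size, and scores each site with the ensemble at its
#' decision cutoff.
#'
#' @param ensemble A fitted `ensemble_model`.
#' @param sequence Protein sequence string.
#' @param protein_id Identifier carried into the output.
#' @return `data.frame` with one row per lysine: `protein_id`, `position`,
#'   `score`, `call`, and one `score_<component>` column per component. Zero
#'   rows (with a warning) if the protein has no lysine.
#' @export
predict_protein <- function(ensemble, sequence, protein_id = "protein") {
  pos <- enumerate_lysines(sequence)
  if (!length(pos)) {
    warning("no lysine in '", protein_id, "'; nothing to predict")
    return(data.frame(protein_id = character(0), position = integer(0),
                      score = numeric(0), call = integer(0)))
  }
  get_frags <- function(window) {
    n <- (window - 1L) %/% 2L
    vapply(pos, function(p) extract_fragment(sequence, p, n), character(1))
  }
  pr <- predict(ensemble, get_frags)
  out <- data.frame(protein_id = protein_id, position = pos,
                    score = pr$score, call = pr$call,
                    stringsAsFactors = FALSE)
  cs <- as.data.frame(pr$component_scores)
  names(cs) <- paste0("score_", names(cs))
  cbind(out, cs)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %s over %d components, cutoff %.3f\n",
              x$aggregator, length(x$components), x$cutoff))
  for (nm in names(x$components)) {
    cmp <- x$components[[nm]]
    cat(sprintf("  %-8s %s/%s window %d (OOF AUC %.3f)\n", nm, cmp$feature,
                cmp$kind, cmp$window, cmp$cv_auc))
  }
  invisible(x)
}

#' Persist / restore an ensemble bundle
#'
#' Writes a versioned directory bundle: `manifest.json` (package version,
#' aggregator, cutoff, per-component feature/window/kind, training-data hash)
#' plus the serialized model state.
#'
#' @param ensemble An `ensemble_model`.
#' @param dir Bundle directory (created if needed).
#' @param data_hash Optional hash string recording the training data.
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir, data_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("malopred")),
    aggregator = ensemble$aggregator,
    cutoff = ensemble$cutoff,
    data_hash = data_hash,
    components = lapply(ensemble$components, function(cmp)
      list(feature = cmp$feature, window = cmp$window, kind = cmp$kind,
           cv_auc = cmp$cv_auc)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(ensemble, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @param check_version Error when the bundle was written by a different
#'   bundle format version.
#' @export
load_ensemble <- function(dir, check_version = TRUE) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("not an ensemble bundle: ", dir)
  mf <- jsonlite::read_json(mf_path)
  if (check_version && !identical(as.integer(mf$format_version), 1L))
    stop("unsupported bundle format version: ", mf$format_version)
  readRDS(file.path(dir, "model.rds"))
}
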