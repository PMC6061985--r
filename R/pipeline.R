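#' Joint pipeline configuration
#'
#' Bundles every stage's configuration for the end-to-end classifier: window
#' layout, embedding hyper-parameters, SVM settings, ensemble size and
#' bootstrap fraction, joint mode, lexicons, and the negation window.
#'
#' @param window A [window_config()].
#' @param skipgram A [skipgram_config()].
#' @param svm An [svm_config()].
#' @param m Number of base SVMs in the ensemble.
#' @param frac Per-class bootstrap fraction.
#' @param joint_mode `"CONCAT"` or `"MULTIVIEW"`.
#' @param lexicons A [load_lexicons()] object.
#' @param negation_window Tokens a negation cue may precede a trigger by.
#' @param pool_scope Token scope for [pool_embedding()].
#' @param weights Instance weights applied to every base SVM (scalar or
#'   per-instance; exposed for up-weighting negation/trigger-bearing
#'   instances).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = window_config(),
                            skipgram = skipgram_config(),
                            svm = svm_config(), m = 10L, frac = 0.5,
                            joint_mode = c("CONCAT", "MULTIVIEW"),
                            lexicons = load_lexicons(),
                            negation_window = 4L,
                            pool_scope = c("window", "sentence"),
                            weights = 1) {
  structure(list(window = window, skipgram = skipgram, svm = svm,
                 m = as.integer(m), frac = frac,
                 joint_mode = match.arg(joint_mode), lexicons = lexicons,
                 negation_window = as.integer(negation_window),
                 pool_scope = match.arg(pool_scope), weights = weights),
            class = "pipeline_config")
}

# Shared per-pair preparation: linguistic layer (cached per sentence),
# blinded tokens, and the index-independent part of the feature bundle.
prepare_pairs <- function(pairs, config) {
  layer_cache <- new.env(parent = emptyenv())
  lapply(pairs, function(p) {
    sid <- p$sentence$sentence_id
    key <- paste0(sid, "#", nrow(p$sentence$tokens))
    layer <- if (!is.null(layer_cache[[key]])) layer_cache[[key]]
             else layer_cache[[key]] <- annotate(p$sentence$tokens)
    blinded <- blind_entities(p, layer)
    bundle <- extract_all(p, layer, config$window, config$lexicons,
                          corpus_index = NULL, blinded = blinded,
                          negation_window = config$negation_window)
    list(pair = p, layer = layer, blinded = blinded, bundle = bundle)
  })
}

# corpus-index-dependent features, added per training fold
index_features <- function(pair, corpus_index) {
  cnt <- unname(corpus_index[pair_key(pair)]) %|na|% 0
  list("CONCEPT:pair_occurrence" = as.numeric(cnt),
       "CONTEXT_GLOBAL:pair_freq_bucket" =
         if (cnt <= 1) "<=1" else if (cnt <= 5) "2-5" else ">5")
}

#' Train the full joint model on labeled pairs
#'
#' Runs the complete training workflow: embedding training on the training
#' sentences, feature extraction, feature-space fitting, joint
#' vectorization, and ensemble training.
#'
#' @param pairs Labeled [candidate_pair()] list.
#' @param config A [pipeline_config()].
#' @param seed Integer seed driving the bootstrap (the embedding uses
#'   `config$skipgram$seed`).
#' @return List of class `gdrex_model` with `ensemble`, `space`,
#'   `embedding`, `corpus_index`, `config`.
#' @export
train_pipeline <- function(pairs, config = pipeline_config(), seed = 1L) {
  labels <- vapply(pairs, `[[`, integer(1), "label")
  if (anyNA(labels)) stopf("training pairs must all be labeled")
  prep <- prepare_pairs(pairs, config)
  corpus <- lapply(pairs, function(p) p$sentence$tokens$token)
  embedding <- train_skipgram(corpus, config$skipgram)
  corpus_index <- build_pair_index(pairs)
  bundles <- lapply(prep, function(pr)
    c(pr$bundle, index_features(pr$pair, corpus_index)))
  pooled <- lapply(prep, function(pr)
    pool_embedding(pr$pair, pr$blinded, embedding, config$window,
                   config$pool_scope))
  space <- fit_space(bundles, config$skipgram$dim, config$joint_mode)
  X <- vectorize_matrix(bundles, pooled, space)
  ensemble <- train_ensemble(X, labels, m = config$m, frac = config$frac,
                             cfg = config$svm, seed = seed,
                             weights = config$weights)
  structure(list(ensemble = ensemble, space = space, embedding = embedding,
                 corpus_index = corpus_index, config = config),
            class = "gdrex_model")
}

#' Predict labels and scores for new candidate pairs
#'
#' @param object A [train_pipeline()] model.
#' @param pairs List of [candidate_pair()] (labels, if any, are ignored).
#' @param ... Unused.
#' @return Data frame `label`, `score`, one row per pair.
#' @export
predict.gdrex_model <- function(object, pairs, ...) {
  config <- object$config
  prep <- prepare_pairs(pairs, config)
  bundles <- lapply(prep, function(pr)
    c(pr$bundle, index_features(pr$pair, object$corpus_index)))
  pooled <- lapply(prep, function(pr)
    pool_embedding(pr$pair, pr$blinded, object$embedding, config$window,
                   config$pool_scope))
  X <- vectorize_matrix(bundles, pooled, object$space)
  predict(object$ensemble, X)
}

#' Stratified k-fold cross-validated evaluation
#'
#' For each fold, the embedding model, the corpus pair index, the feature
#' space and the SVM ensemble are all fitted on the k-1 training folds only,
#' then applied to the held-out fold, so no information leaks from test to
#' training. Reports per-fold precision/recall/F, the pooled (micro) scores
#' from summed confusion counts (the headline numbers), the macro averages
#' over folds, and the ROC over pooled vote-fraction scores.
#'
#' @param pairs Labeled [candidate_pair()] list.
#' @param config A [pipeline_config()].
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment, per-fold embedding and
#'   bootstrap seeds are all derived from it).
#' @return An object of class `prf_report`.
#' @export
cross_validate <- function(pairs, config = pipeline_config(), k = 10L,
                           seed = 1L) {
  labels <- vapply(pairs, `[[`, integer(1), "label")
  if (anyNA(labels)) stopf("cross-validation requires fully labeled pairs")
  folds <- kfold_split(length(pairs), k, labels, seed)
  prep <- prepare_pairs(pairs, config)
  corpus <- lapply(pairs, function(p) p$sentence$tokens$token)

  fold_rows <- vector("list", k)
  scores <- numeric(length(pairs)); preds <- integer(length(pairs))
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(pairs), test)
    sg_cfg <- config$skipgram
    sg_cfg$seed <- sg_cfg$seed + f                    # per-fold embedding seed
    embedding <- train_skipgram(corpus[train], sg_cfg)
    corpus_index <- build_pair_index(pairs[train])
    mk_xy <- function(idx) {
      bundles <- lapply(prep[idx], function(pr)
        c(pr$bundle, index_features(pr$pair, corpus_index)))
      pooled <- lapply(prep[idx], function(pr)
        pool_embedding(pr$pair, pr$blinded, embedding, config$window,
                       config$pool_scope))
      list(bundles = bundles, pooled = pooled)
    }
    tr <- mk_xy(train)
    space <- fit_space(tr$bundles, config$skipgram$dim, config$joint_mode)
    Xtr <- vectorize_matrix(tr$bundles, tr$pooled, space)
    w_all <- rep_len(config$weights, length(pairs))
    ensemble <- train_ensemble(Xtr, labels[train], m = config$m,
                               frac = config$frac, cfg = config$svm,
                               seed = (seed %% 1000003L) * 1000L + f,
                               weights = w_all[train])
    te <- mk_xy(test)
    Xte <- vectorize_matrix(te$bundles, te$pooled, space)
    out <- predict(ensemble, Xte)
    scores[test] <- out$score
    preds[test] <- out$label
    cc <- confusion_counts(labels[test], out$label)
    pf <- prf(cc)
    fold_rows[[f]] <- data.frame(fold = f, TP = cc$TP, FP = cc$FP,
                                 FN = cc$FN, TN = cc$TN,
                                 precision = pf$precision, recall = pf$recall,
                                 f = pf$f)
  }
  fold_df <- do.call(rbind, fold_rows)
  pooled_counts <- list(TP = sum(fold_df$TP), FP = sum(fold_df$FP),
                        FN = sum(fold_df$FN), TN = sum(fold_df$TN))
  micro <- prf(pooled_counts)
  macro <- list(precision = mean(fold_df$precision),
                recall = mean(fold_df$recall), f = mean(fold_df$f))
  roc <- roc_points(scores, labels)
  structure(list(folds = fold_df, pooled_counts = pooled_counts,
                 micro = micro, macro = macro, roc = roc,
                 auc = roc_auc(roc), scores = scores, predictions = preds,
                 labels = labels, k = k, seed = seed),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d pairs\n", x$k,
              length(x$labels)))
  cat(sprintf("  micro: P = %.2f  R = %.2f  F = %.2f\n",
              x$micro$precision, x$micro$recall, x$micro$f))
  cat(sprintf("  macro: P = %.2f  R = %.2f  F = %.2f\n",
              x$macro$precision, x$macro$recall, x$macro$f))
  cat(sprintf("  AUC (pooled scores): %.3f\n", x$auc))
  invisible(x)
}

#' Export an evaluation report as JSON and CSV
#'
#' Writes `report.json` (full report), `folds.csv` (per-fold scores) and
#' `roc.csv` (ROC points) into `dir`.
#'
#' @param report A [cross_validate()] report.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("report.json", "folds.csv", "roc.csv"))
  jsonlite::write_json(
    list(k = report$k, seed = report$seed,
         micro = report$micro[c("precision", "recall", "f")],
         macro = report$macro, pooled_counts = report$pooled_counts,
         auc = report$auc, folds = report$folds),
    paths[1], auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$folds, paths[2], row.names = FALSE)
  utils::write.csv(report$roc, paths[3], row.names = FALSE)
  invisible(paths)
}
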