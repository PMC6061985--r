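#' Base SVM configuration
#'
#' Soft-margin RBF-kernel SVM hyper-parameters: `cost` is the classification
#' penalty C of the primal problem, `gamma` the RBF width (default
#' `1 / dimensionality`, resolved at training time when `NULL`).
#'
#' @param cost Classification penalty C > 0.
#' @param gamma RBF kernel width > 0, or `NULL` for `1 / ncol(X)`.
#' @param tolerance Optimiser stopping tolerance.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = NULL, tolerance = 1e-3) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma, tolerance = tolerance),
            class = "svm_config")
}

#' Stratified bootstrap subsamples
#'
#' Draws `m` index subsets with replacement, each containing
#' `round(frac * n_class)` indices per class, so the class ratio of every
#' subset matches the full data. Deterministic under `seed`.
#'
#' @param labels Vector of +1/-1 labels.
#' @param m Number of subsets.
#' @param frac Per-class sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return List of `m` integer index vectors.
#' @export
stratified_bootstrap <- function(labels, m, frac, seed = 1L) {
  if (frac <= 0 || frac > 1) stopf("frac must be in (0, 1]")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stopf("stratified bootstrap requires both classes, found only {%s}",
          paste(classes, collapse = ","))
  with_seed(seed, {
    lapply(seq_len(m), function(i) {
      unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        sample(idx, size = round(frac * length(idx)), replace = TRUE)
      }), use.names = FALSE)
    })
  })
}

#' Train one instance-weighted RBF-kernel base SVM
#'
#' Solves the soft-margin SVM (penalty `C * weight_i` per instance) with the
#' RBF kernel. With uniform weights the problem is delegated to libsvm
#' (\pkg{e1071}); with non-uniform weights the dual quadratic program with
#' per-instance box constraints `0 <= alpha_i <= C * w_i` is solved directly
#' with \pkg{kernlab}'s interior-point optimiser. If all training vectors are
#' identical while both labels are present, the problem is degenerate and a
#' documented fallback constant model predicting the majority class (ties to
#' -1) is returned.
#'
#' @param X Numeric matrix, rows = instances.
#' @param y Labels +1/-1 (both must be present).
#' @param weights Non-negative instance weights (recycled scalar allowed).
#' @param cfg An [svm_config()].
#' @return An object of class `base_model` supporting [decision_values()]
#'   and [predict_base()].
#' @export
train_base <- function(X, y, weights = 1, cfg = svm_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  weights <- rep_len(weights, nrow(X))
  if (any(weights < 0)) stopf("instance weights must be non-negative")
  gamma <- cfg$gamma %||% (1 / ncol(X))

  if (all(duplicated(X)[-1])) {     # identical vectors, both labels present
    maj <- if (sum(y == 1) > sum(y == -1)) 1L else -1L
    return(structure(list(type = "constant", label = maj, gamma = gamma),
                     class = "base_model"))
  }

  uniform <- length(unique(weights)) == 1L
  if (uniform) {
    fit <- e1071::svm(X, factor(y, levels = c(-1, 1)), scale = FALSE,
                      type = "C-classification", kernel = "radial",
                      gamma = gamma, cost = cfg$cost * weights[1],
                      tolerance = cfg$tolerance)
    # normalise libsvm's decision sign so that positive means class +1
    sgn <- if (fit$levels[fit$labels[1]] == "1") 1 else -1
    model <- list(type = "libsvm", sv = fit$SV,
                  coef = sgn * as.numeric(fit$coefs),
                  b = -sgn * fit$rho, gamma = gamma)
  } else {
    model <- svm_dual_qp(X, y, cfg$cost * weights, gamma, cfg$tolerance)
  }
  structure(model, class = "base_model")
}

# Dual soft-margin SVM with per-instance upper bounds, via kernlab::ipop:
#   min  1/2 a' (yy' * K) a - 1'a   s.t.  y'a = 0,  0 <= a_i <= C_i
svm_dual_qp <- function(X, y, upper, gamma, tol) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  # small ridge keeps the dual strictly convex when bootstrap duplicates
  # make the kernel matrix rank-deficient
  H <- (y %o% y) * K + diag(1e-6, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(as.numeric(y), 1), b = 0,
                       l = rep(0, n), u = pmax(upper, 1e-12), r = 0,
                       sigf = 9)
  alpha <- pmin(pmax(kernlab::primal(sol), 0), upper)
  sv <- which(alpha > 1e-8)
  coef <- alpha[sv] * y[sv]
  f_no_b <- as.numeric(K[, sv, drop = FALSE] %*% coef)
  free <- sv[alpha[sv] < upper[sv] - 1e-6]
  b <- if (length(free)) mean(y[free] - f_no_b[free])
       else mean(y[sv] - f_no_b[sv])
  list(type = "qp", sv = X[sv, , drop = FALSE], coef = coef, b = b,
       gamma = gamma, alpha = alpha)
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Decision values of a base SVM
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; positive means class +1.
#'
#' @param model A [train_base()] model.
#' @param X Probe matrix.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  X <- as.matrix(X)
  if (model$type == "constant") return(rep(model$label * 1e-6, nrow(X)))
  as.numeric(rbf_kernel(X, model$sv, model$gamma) %*% model$coef) + model$b
}

#' @rdname decision_values
#' @return `predict_base` returns +1/-1 labels (0 decision value maps to -1).
#' @export
predict_base <- function(model, X) {
  ifelse(decision_values(model, X) > 0, 1L, -1L)
}

#' Majority vote over +-1 votes
#'
#' Sign of the vote sum; an exact tie resolves to -1 (the documented rule:
#' in doubt, no asserted association).
#'
#' @param votes Vector of +1/-1 votes (at least one).
#' @return +1 or -1.
#' @export
majority_vote <- function(votes) {
  if (!length(votes)) stopf("majority_vote needs at least one vote")
  if (!all(votes %in% c(-1, 1))) stopf("votes must be +1/-1")
  if (sum(votes) > 0) 1L else -1L
}

#' Train the bagged SVM ensemble
#'
#' Draws `m` stratified bootstrap subsamples and trains one base SVM per
#' subsample (in MULTIVIEW mode, one per subsample per view, with all votes
#' pooled at prediction time). With `resample = FALSE`, `m = 1` and
#' `frac = 1` the ensemble degenerates exactly to a single SVM on the full
#' data.
#'
#' @param X CONCAT: numeric matrix. MULTIVIEW: list of matrices (views).
#' @param y Labels +1/-1.
#' @param m Number of base models (per view).
#' @param frac Per-class bootstrap fraction.
#' @param cfg An [svm_config()].
#' @param seed Integer seed for the bootstrap.
#' @param weights Instance weights passed to every base model.
#' @param resample Set `FALSE` to train every base model on the full data.
#' @return An object of class `gdrex_ensemble`.
#' @export
train_ensemble <- function(X, y, m = 10L, frac = 0.5, cfg = svm_config(),
                           seed = 1L, weights = 1, resample = TRUE) {
  stopifnot(m >= 1)
  views <- if (is.list(X) && !is.data.frame(X)) X else list(X)
  n <- nrow(views[[1]])
  weights <- rep_len(weights, n)
  subsets <- if (resample) stratified_bootstrap(y, m, frac, seed)
             else replicate(m, seq_len(n), simplify = FALSE)
  base <- list()
  for (v in seq_along(views)) {
    for (i in seq_len(m)) {
      idx <- subsets[[i]]
      base[[length(base) + 1L]] <-
        train_base(views[[v]][idx, , drop = FALSE], y[idx], weights[idx], cfg)
    }
  }
  structure(list(base = base, m = as.integer(m), n_views = length(views),
                 frac = frac, cfg = cfg, seed = as.integer(seed),
                 mode = if (length(views) > 1) "MULTIVIEW" else "CONCAT",
                 subsets = subsets),
            class = "gdrex_ensemble")
}

#' Predict labels and vote-fraction scores from the ensemble
#'
#' Every base model casts a +-1 vote; the score is the fraction of +1 votes
#' and the label is +1 iff the score exceeds 0.5 (an exact tie resolves
#' to -1, consistently with [majority_vote()]).
#'
#' @param object A [train_ensemble()] model.
#' @param newdata Matrix (CONCAT) or list of matrices (MULTIVIEW), matching
#'   the training representation.
#' @param ... Unused.
#' @return Data frame with columns `label` (+1/-1) and `score` in \[0, 1\].
#' @export
predict.gdrex_ensemble <- function(object, newdata, ...) {
  views <- if (is.list(newdata) && !is.data.frame(newdata)) newdata
           else list(newdata)
  if (length(views) != object$n_views)
    stopf("model was trained with %d view(s), got %d", object$n_views,
          length(views))
  votes <- matrix(0L, nrow(views[[1]]), length(object$base))
  k <- 0L
  for (v in seq_along(views)) {
    for (i in seq_len(object$m)) {
      k <- k + 1L
      votes[, k] <- predict_base(object$base[[k]], views[[v]])
    }
  }
  score <- rowMeans(votes == 1L)
  data.frame(label = ifelse(score > 0.5, 1L, -1L), score = score)
}

#' @export
print.gdrex_ensemble <- function(x, ...) {
  cat(sprintf("<gdrex_ensemble> %d base SVM(s) x %d view(s), frac = %g\n",
              x$m, x$n_views, x$frac))
  invisible(x)
}

#' Save / load a trained model archive
#'
#' Self-describing archive (RDS) holding the ensemble, the fitted feature
#' space and the embedding model; predictions after a load are bit-identical
#' to predictions before the save.
#'
#' @param ensemble A [train_ensemble()] model.
#' @param space The fitted [fit_space()].
#' @param embedding The [train_skipgram()] model.
#' @param path Archive path.
#' @param extra Optional named list stored alongside (e.g. the run config).
#' @return `load_model` returns the named list back.
#' @export
save_model <- function(ensemble, space, embedding, path, extra = list()) {
  saveRDS(c(list(ensemble = ensemble, space = space, embedding = embedding),
            extra), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
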