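#' Fit the joint feature space
#'
#' Assigns one column to every feature observed in the training bundles.
#' Categorical (string-valued) features expand to `name=value` indicator
#' columns; logical and numeric features keep their name and value. Columns
#' are ordered by sorted name, so the space is invariant to bundle order and
#' to feature insertion order. The space is frozen after fitting: feature
#' names unseen at fit time are silently dropped at transform time (with a
#' dropped-count attribute), never grown.
#'
#' @param bundles List of [extract_all()] bundles (at least one).
#' @param D Dense embedding block width.
#' @param mode `"CONCAT"` (one joint vector: sparse block then dense block,
#'   the default) or `"MULTIVIEW"` (two parallel views, one per
#'   representation, combined at the ensemble level).
#' @return An object of class `feature_space` with `columns` (named index
#'   map), `D`, `mode`.
#' @export
fit_space <- function(bundles, D, mode = c("CONCAT", "MULTIVIEW")) {
  mode <- match.arg(mode)
  if (!length(bundles)) stopf("cannot fit a feature space on zero bundles")
  stopifnot(is_scalar_count(D))
  names_all <- unlist(lapply(bundles, function(b)
    mapply(column_key, names(b), b, USE.NAMES = FALSE)))
  cols <- sort(unique(names_all), method = "radix")
  structure(list(columns = stats::setNames(seq_along(cols), cols),
                 D = as.integer(D), mode = mode),
            class = "feature_space")
}

column_key <- function(name, value) {
  if (is.character(value)) paste0(name, "=", value) else name
}

column_value <- function(value) {
  if (is.character(value)) 1 else as.numeric(value)
}

#' Pooled embedding block for a candidate pair
#'
#' Mean of the embedding input vectors of the between-entity tokens plus the
#' window tokens around each entity (sizes from the [window_config()]),
#' L2-normalised; out-of-vocabulary tokens contribute nothing, and a pair
#' with no in-vocabulary token yields the zero vector. With
#' `scope = "sentence"` all sentence tokens are pooled instead.
#'
#' @param pair A [candidate_pair()].
#' @param blinded [blind_entities()] output.
#' @param model An [train_skipgram()] `embedding_model`.
#' @param cfg A [window_config()] (pooling token selection).
#' @param scope `"window"` (default) or `"sentence"`.
#' @return Numeric vector of length D.
#' @export
pool_embedding <- function(pair, blinded, model, cfg = window_config(),
                           scope = c("window", "sentence")) {
  scope <- match.arg(scope)
  toks <- blinded$tokens
  if (scope == "sentence") {
    sel <- seq_along(toks)
  } else {
    gp <- blinded$gene_pos; dp <- blinded$disease_pos
    safe_seq <- function(a, b) if (a > b) integer(0) else seq.int(a, b)
    sel <- c(between_indices(gp, dp),
             safe_seq(max(1L, gp - cfg$gene_left), gp - 1L),
             safe_seq(gp + 1L, min(length(toks), gp + cfg$gene_right)),
             safe_seq(max(1L, dp - cfg$disease_left), dp - 1L),
             safe_seq(dp + 1L, min(length(toks), dp + cfg$disease_right)))
    sel <- sort(unique(sel))
  }
  sel <- setdiff(sel, c(blinded$gene_pos, blinded$disease_pos))
  words <- normalize_token(toks[sel])
  words <- words[nzchar(words)]
  ids <- match(words, rownames(model$input))
  ids <- ids[!is.na(ids)]
  D <- ncol(model$input)
  if (!length(ids)) return(numeric(D))
  v <- colMeans(model$input[ids, , drop = FALSE])
  n <- sqrt(sum(v^2))
  if (n == 0) numeric(D) else v / n
}

#' Turn a bundle plus pooled embedding into the classifier input vector
#'
#' In CONCAT mode the result is a single numeric vector: the sparse
#' handcrafted block (in feature-space column order) followed by the dense
#' embedding block. In MULTIVIEW mode the two blocks are returned as two
#' tagged views. Unseen feature names are dropped; the number dropped is
#' recorded in the `dropped` attribute.
#'
#' @param bundle An [extract_all()] bundle.
#' @param pooled Dense vector of length `space$D` from [pool_embedding()].
#' @param space A fitted [fit_space()].
#' @return An object of class `joint_vector`.
#' @export
vectorize <- function(bundle, pooled, space) {
  stopifnot(inherits(space, "feature_space"))
  if (length(pooled) != space$D)
    stopf("pooled embedding has length %d, feature space expects D = %d",
          length(pooled), space$D)
  if (length(bundle)) {
    keys <- mapply(column_key, names(bundle), bundle, USE.NAMES = FALSE)
    vals <- vapply(bundle, column_value, numeric(1), USE.NAMES = FALSE)
    idx <- unname(space$columns[keys])
  } else {
    vals <- numeric(0); idx <- integer(0)
  }
  keep <- !is.na(idx)
  sparse <- numeric(length(space$columns))
  sparse[idx[keep]] <- vals[keep]
  out <- if (space$mode == "CONCAT") {
    list(vector = c(sparse, pooled))
  } else {
    list(views = list(sparse = sparse, dense = pooled))
  }
  structure(c(out, list(mode = space$mode)),
            class = "joint_vector", dropped = sum(!keep))
}

#' Vectorize many pairs into the design matrix (or matrices)
#'
#' @param bundles List of feature bundles.
#' @param pooled_list List of pooled embedding vectors (same length).
#' @param space A fitted [fit_space()].
#' @return CONCAT: a numeric matrix, rows = instances. MULTIVIEW: a list of
#'   two matrices named `sparse` and `dense`.
#' @export
vectorize_matrix <- function(bundles, pooled_list, space) {
  jvs <- Map(function(b, p) vectorize(b, p, space), bundles, pooled_list)
  if (space$mode == "CONCAT") {
    do.call(rbind, lapply(jvs, `[[`, "vector"))
  } else {
    list(sparse = do.call(rbind, lapply(jvs, function(j) j$views$sparse)),
         dense = do.call(rbind, lapply(jvs, function(j) j$views$dense)))
  }
}

#' Serialize / restore a fitted feature space as JSON
#'
#' @param space A [fit_space()] object.
#' @param path JSON file path.
#' @return `read_space` returns the restored `feature_space`.
#' @export
write_space <- function(space, path) {
  jsonlite::write_json(list(columns = as.list(space$columns), D = space$D,
                            mode = space$mode),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(columns = stats::setNames(as.integer(unlist(obj$columns)),
                                           names(obj$columns)),
                 D = as.integer(obj$D), mode = obj$mode),
            class = "feature_space")
}
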