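#' Skip-gram training configuration
#'
#' Hyper-parameters of the skip-gram negative-sampling embedding model. The
#' defaults follow the regime the method was built for: a context window of
#' 8, 25 negative samples per positive, and a frequent-word subsampling
#' threshold of 1e-5. The vector dimensionality is a free choice (default
#' 100). Training is single-threaded for bit-reproducibility; the `threads`
#' field is accepted and recorded but one thread is always used.
#'
#' @param dim Embedding dimensionality D (hidden-layer size).
#' @param window Maximum context offset c; per position the effective radius
#'   is sampled uniformly from `[1, window]`.
#' @param negative Noise samples K per positive example.
#' @param subsample Frequent-word subsampling threshold t.
#' @param min_count Vocabulary frequency floor.
#' @param epochs Training passes over the corpus.
#' @param alpha Initial learning rate (decays linearly to `alpha * 1e-4`).
#' @param seed Integer RNG seed for initialisation, subsampling, window
#'   radii and noise draws.
#' @param threads Recorded only; see Details.
#' @return An object of class `skipgram_config`.
#' @export
skipgram_config <- function(dim = 100L, window = 8L, negative = 25L,
                            subsample = 1e-5, min_count = 1L, epochs = 5L,
                            alpha = 0.025, seed = 1L, threads = 1L) {
  stopifnot(dim >= 1, window >= 1, negative >= 0, subsample > 0,
            subsample <= 1, epochs >= 0, min_count >= 1, alpha > 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negative = as.integer(negative), subsample = subsample,
                 min_count = as.integer(min_count),
                 epochs = as.integer(epochs), alpha = alpha,
                 seed = as.integer(seed), threads = as.integer(threads)),
            class = "skipgram_config")
}

# lowercase and strip edge punctuation, the normalisation applied before
# vocabulary construction ("cancer," must not become a separate word)
normalize_token <- function(tokens) {
  out <- tolower(tokens)
  out <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", out)
  out
}

normalize_corpus <- function(corpus) {
  lapply(corpus, function(sen) {
    s <- normalize_token(sen)
    s[nzchar(s)]
  })
}

#' Build the embedding vocabulary
#'
#' Counts token frequencies over a training corpus (a list of token
#' vectors), drops words below `min_count`, and assigns indices by
#' descending frequency with lexicographic tie-break.
#'
#' @param corpus List of character token vectors.
#' @param min_count Frequency floor.
#' @param normalize Apply the embedding token normalisation (lowercase,
#'   strip edge punctuation) before counting.
#' @return Data frame with columns `word`, `count`, ordered by index.
#' @export
build_vocab <- function(corpus, min_count = 1L, normalize = TRUE) {
  if (!length(corpus)) stopf("empty training corpus")
  if (normalize) corpus <- normalize_corpus(corpus)
  words <- unlist(corpus, use.names = FALSE)
  if (!length(words)) stopf("training corpus has no tokens")
  tab <- table(words)
  tab <- tab[tab >= min_count]
  if (!length(tab)) stopf("all words filtered out at min_count = %d", min_count)
  df <- data.frame(word = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, rank_lex(df$word)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

rank_lex <- function(x) match(x, sort(x, method = "radix"))

#' Probability of discarding a frequent word during subsampling
#'
#' `max(0, 1 - sqrt(t / f))` for a word with corpus frequency fraction `f`
#' and threshold `t` (the standard subsampling rule of the skip-gram
#' formulation; clamped to 0 for words rarer than the threshold).
#'
#' @param f Frequency fraction in (0, 1].
#' @param t Subsampling threshold > 0.
#' @return Discard probability in \[0, 1\].
#' @export
subsample_discard_prob <- function(f, t) {
  if (any(f <= 0) || any(f > 1)) stopf("frequency fraction must be in (0, 1]")
  if (any(t <= 0)) stopf("threshold must be positive")
  pmax(0, 1 - sqrt(t / f))
}

#' Train skip-gram word embeddings with negative sampling
#'
#' Stochastic-gradient training of the skip-gram objective with negative
#' sampling and frequent-word subsampling. The noise distribution is the
#' unigram distribution raised to 0.75; the per-position window radius is
#' sampled uniformly from `[1, window]`; the learning rate decays linearly.
#' Training is single-threaded with its own deterministic generator, so a
#' fixed seed gives bit-identical models.
#'
#' @param corpus List of character token vectors (normalised internally).
#' @param cfg A [skipgram_config()].
#' @return An object of class `embedding_model`: list with `vocab` (word /
#'   count data frame), `input` and `output` V x D matrices (rownames are
#'   words), and `cfg`.
#' @export
train_skipgram <- function(corpus, cfg = skipgram_config()) {
  norm <- normalize_corpus(corpus)
  vocab <- build_vocab(norm, cfg$min_count, normalize = FALSE)
  idx <- stats::setNames(seq_len(nrow(vocab)), vocab$word)
  sentences <- lapply(norm, function(s) {
    v <- unname(idx[s])
    as.integer(v[!is.na(v)])           # words under min_count are dropped
  })
  sentences <- sentences[lengths(sentences) > 0]
  fit <- sg_train_cpp(sentences, as.numeric(vocab$count), cfg$dim,
                      cfg$window, cfg$negative, cfg$subsample, cfg$epochs,
                      cfg$alpha, cfg$seed)
  rownames(fit$input) <- vocab$word
  rownames(fit$output) <- vocab$word
  structure(list(vocab = vocab, input = fit$input, output = fit$output,
                 cfg = cfg),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> V = %d words, D = %d\n",
              nrow(x$input), ncol(x$input)))
  invisible(x)
}

vocab_row <- function(model, word) {
  i <- match(word, rownames(model$input))
  if (is.na(i)) stopf("word '%s' is not in the vocabulary", word)
  i
}

#' Average log probability of a corpus under the full-softmax skip-gram model
#'
#' Computes `(1/N) * sum_t sum_{-c <= j <= c, j != 0} log p(w_{t+j} | w_t)`
#' where `p` is the softmax over output vectors of the input vector of the
#' centre word, with the window truncated at sentence boundaries. Used as an
#' exact (if expensive) training diagnostic; negative sampling optimises a
#' surrogate of this quantity.
#'
#' @param model An [train_skipgram()] model.
#' @param corpus List of token vectors; every token must be in vocabulary.
#' @param window Fixed context radius c.
#' @return The average log probability (a non-positive number).
#' @export
skipgram_objective <- function(model, corpus, window = model$cfg$window) {
  norm <- normalize_corpus(corpus)
  scores <- model$input %*% t(model$output)      # V x V of dot products
  logz <- apply(scores, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  logp <- scores - logz
  total <- 0; n_tokens <- 0
  for (sen in norm) {
    ids <- match(sen, rownames(model$input))
    if (anyNA(ids))
      stopf("out-of-vocabulary token '%s'", sen[which(is.na(ids))[1]])
    n <- length(ids); n_tokens <- n_tokens + n
    for (t in seq_len(n)) {
      ctx <- setdiff(seq(max(1, t - window), min(n, t + window)), t)
      if (length(ctx)) total <- total + sum(logp[ids[t], ids[ctx]])
    }
  }
  if (n_tokens == 0) return(0)
  total / n_tokens
}

#' Cosine similarity between two vocabulary words
#'
#' Normalised dot product of the input vectors.
#'
#' @param model An `embedding_model`.
#' @param w1,w2 Words; out-of-vocabulary words raise an error naming the word.
#' @return Value in \[-1, 1\].
#' @export
cosine <- function(model, w1, w2) {
  u <- model$input[vocab_row(model, w1), ]
  v <- model$input[vocab_row(model, w2), ]
  cosine_vec(u, v)
}

cosine_vec <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Nearest neighbours of a word by cosine similarity
#'
#' @param model An `embedding_model`.
#' @param word Query word (excluded from the result).
#' @param k Number of neighbours.
#' @return Data frame `word`, `cosine`, sorted by descending cosine with
#'   lexicographic tie-break.
#' @export
nearest_neighbors <- function(model, word, k = 10L) {
  stopifnot(k >= 1)
  i <- vocab_row(model, word)
  M <- model$input
  norms <- sqrt(rowSums(M^2))
  q <- M[i, ]; qn <- sqrt(sum(q^2))
  sims <- as.numeric(M %*% q) / ifelse(norms * qn == 0, Inf, norms * qn)
  df <- data.frame(word = rownames(M), cosine = sims,
                   stringsAsFactors = FALSE)[-i, , drop = FALSE]
  df <- df[order(-df$cosine, rank_lex(df$word)), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Write / read word vectors in the common text format
#'
#' Header line `V D`, then one line per word: the word followed by D floats.
#' Full double precision is written so that a read inverts a write exactly.
#'
#' @param model An `embedding_model` (input vectors are written).
#' @param path File path.
#' @return `write_word_vectors` invisibly returns the vocabulary size;
#'   `read_word_vectors` returns an `embedding_model` (with unknown counts
#'   and no output vectors).
#' @export
write_word_vectors <- function(model, path) {
  M <- model$input
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(M), ncol(M)), con)
  for (i in seq_len(nrow(M)))
    writeLines(paste(rownames(M)[i],
                     paste(formatC(M[i, ], format = "g", digits = 17),
                           collapse = " ")), con)
  invisible(nrow(M))
}

#' @rdname write_word_vectors
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stopf("invalid word-vector header: '%s'", lines[1])
  V <- hdr[1]; D <- hdr[2]
  if (length(lines) - 1L != V)
    stopf("header declares %d words but file has %d vector lines",
          V, length(lines) - 1L)
  M <- matrix(0, V, D)
  words <- character(V)
  for (i in seq_len(V)) {
    f <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]]
    if (length(f) != D + 1L)
      stopf("line %d: expected %d values, found %d", i + 1L, D + 1L, length(f))
    words[i] <- f[1]
    M[i, ] <- as.numeric(f[-1])
  }
  rownames(M) <- words
  structure(list(vocab = data.frame(word = words, count = NA_integer_,
                                    stringsAsFactors = FALSE),
                 input = M, output = NULL, cfg = NULL),
            class = "embedding_model")
}
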