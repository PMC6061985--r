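#' Deterministic biomedical tokenizer
#'
#' Splits `text` on whitespace and peels leading/trailing punctuation
#' (`.,;:!?()[]<>/"`) into tokens of their own. Hyphenated biomedical terms
#' (`HIF-1alpha`, `g.-247C/T` style tokens keep internal hyphens) are kept
#' whole. Every token is mapped to a 0-based half-open character span of the
#' input, so the input can be reconstructed exactly from the spans.
#'
#' @param text A single string. The empty string yields zero tokens.
#' @param breaks Optional sorted 0-based character positions at which tokens
#'   must additionally be split (used to keep entity mentions aligned to token
#'   boundaries when a corpus annotates mid-token offsets).
#' @return A data frame with columns `token`, `start`, `end` (0-based,
#'   half-open).
#' @examples
#' tokenize("restenosis after PTCA.")$token
#' @export
tokenize <- function(text, breaks = integer()) {
  assert_scalar_string(text, "text")
  empty <- data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)

  m <- gregexpr("[^[:space:]]+", text)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m) - 1L            # to 0-based
  lens <- attr(m, "match.length")
  punct <- c(".", ",", ";", ":", "!", "?", "(", ")", "[", "]", "<", ">",
             "/", "\"")

  tok <- character(); st <- integer(); en <- integer()
  emit <- function(s, e) { # s,e 0-based half-open
    tok[[length(tok) + 1L]] <<- substr(text, s + 1L, e)
    st[[length(st) + 1L]] <<- s
    en[[length(en) + 1L]] <<- e
  }
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- starts[i] + lens[i]
    # peel leading punctuation
    while (e - s > 1L && substr(text, s + 1L, s + 1L) %in% punct) {
      emit(s, s + 1L); s <- s + 1L
    }
    # collect trailing punctuation (emitted after the core token)
    trail <- integer()
    while (e - s > 1L && substr(text, e, e) %in% punct) {
      trail <- c(e - 1L, trail); e <- e - 1L
    }
    emit(s, e)
    for (p in trail) emit(p, p + 1L)
  }
  out <- data.frame(token = tok, start = st, end = en, stringsAsFactors = FALSE)

  if (length(breaks)) {
    breaks <- sort(unique(as.integer(breaks)))
    for (b in breaks) {
      hit <- which(out$start < b & out$end > b)
      if (length(hit) == 1L) {
        row <- out[hit, ]
        left <- data.frame(token = substr(text, row$start + 1L, b),
                           start = row$start, end = b, stringsAsFactors = FALSE)
        right <- data.frame(token = substr(text, b + 1L, row$end),
                            start = b, end = row$end, stringsAsFactors = FALSE)
        out <- rbind(out[seq_len(hit - 1L), ], left, right,
                     out[seq_len(nrow(out) - hit) + hit, ])
        rownames(out) <- NULL
      }
    }
  }
  out
}

#' Rule-based linguistic annotation (POS, lemma, chunk)
#'
#' Fills part-of-speech, lemma and BIO chunk layers for a token sequence.
#' By default a deterministic rule-based annotator is used so results never
#' depend on an external statistical model: closed-class words are tagged from
#' small lexicons, inflected verbs are recognised from a base-form lexicon,
#' numbers / adverbs / adjectives / plural nouns by suffix, everything else is
#' a noun. The lemma is the lowercased token with a final plural "s" removed
#' (length > 3, not "ss"). Chunks are noun-phrase runs of
#' determiners/adjectives/nouns/numbers (`B-NP`/`I-NP`), verb runs (`B-VP`/
#' `I-VP`), otherwise `O`.
#'
#' Any external tagger can be plugged in through `annotator`, a function
#' `function(tokens)` returning a list with equal-length character vectors
#' `pos`, `lemma` and `chunk`.
#'
#' @param tokens Character vector of tokens (or the data frame returned by
#'   [tokenize()]).
#' @param annotator Optional adapter function; see Details.
#' @return An object of class `linguistic_layer`: a list with `tokens`,
#'   `pos`, `lemma`, `chunk`, all the same length.
#' @export
annotate <- function(tokens, annotator = NULL) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  stopifnot(is.character(tokens))
  if (is.null(annotator)) {
    layer <- rule_annotate(tokens)
  } else {
    layer <- annotator(tokens)
    lens <- vapply(layer[c("pos", "lemma", "chunk")], length, integer(1))
    if (any(lens != length(tokens)))
      stopf("annotator returned layers of length %s for %d tokens",
            paste(lens, collapse = "/"), length(tokens))
  }
  structure(list(tokens = tokens, pos = layer$pos, lemma = layer$lemma,
                 chunk = layer$chunk),
            class = "linguistic_layer")
}

verb_bases <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "lexicons", "verb_bases.txt",
                          package = "gdrex")
      cache <<- read_lexicon_file(path)
    }
    cache
  }
})

rule_annotate <- function(tokens) {
  n <- length(tokens)
  pos <- character(n)
  determiners <- c("the", "a", "an", "this", "that", "these", "those")
  prepositions <- c("of", "in", "on", "at", "by", "with", "for", "to", "from",
                    "after", "before", "between", "among", "during", "upon",
                    "into", "through", "within")
  conjunctions <- c("and", "or", "but", "nor")
  pronouns <- c("we", "they", "it", "he", "she", "i", "you", "our", "their",
                "its")
  modals <- c("may", "might", "can", "could", "would", "should", "must",
              "will", "shall")
  aux <- c(is = "VBZ", has = "VBZ", does = "VBZ", are = "VBP", have = "VBP",
           do = "VBP", was = "VBD", were = "VBD", had = "VBD", did = "VBD",
           be = "VB", been = "VBN", being = "VBG")
  verbs <- verb_bases()
  for (i in seq_len(n)) {
    t <- tokens[i]; lo <- tolower(t)
    pos[i] <- if (is_punct_token(t)) {
      if (t %in% c(".", ",", ":")) t else "SYM"
    } else if (lo %in% determiners) "DT"
    else if (lo %in% prepositions) "IN"
    else if (lo %in% conjunctions) "CC"
    else if (lo %in% pronouns) "PRP"
    else if (lo %in% modals) "MD"
    else if (lo %in% names(aux)) unname(aux[lo])
    else if (grepl("^[0-9][0-9.,/-]*$", t)) "CD"
    else if (lo %in% verbs) "VB"
    else if (sub("s$", "", lo) %in% verbs || sub("es$", "e", lo) %in% verbs)
      "VBZ"
    else if (sub("ed$", "", lo) %in% verbs || sub("d$", "", lo) %in% verbs)
      "VBD"
    else if (sub("ing$", "", lo) %in% verbs || sub("ing$", "e", lo) %in% verbs)
      "VBG"
    else if (nchar(lo) > 3 && endsWith(lo, "ly")) "RB"
    else if (nchar(lo) > 4 && endsWith(lo, "ed")) "VBD"
    else if (nchar(lo) > 5 && endsWith(lo, "ing")) "VBG"
    else if (nchar(lo) > 4 &&
             (endsWith(lo, "al") || endsWith(lo, "ous") ||
              endsWith(lo, "ive") || endsWith(lo, "ic"))) "JJ"
    else if (nchar(lo) > 3 && endsWith(lo, "s") && !endsWith(lo, "ss") &&
             !endsWith(lo, "us") && !endsWith(lo, "is")) "NNS"
    else "NN"
  }
  lemma <- tolower(tokens)
  strip <- nchar(lemma) > 3 & endsWith(lemma, "s") & !endsWith(lemma, "ss") &
    !endsWith(lemma, "us") & !endsWith(lemma, "is")
  lemma[strip] <- sub("s$", "", lemma[strip])

  np_tags <- c("DT", "JJ", "NN", "NNS", "CD")
  vp_tags <- c("VB", "VBZ", "VBP", "VBD", "VBN", "VBG", "MD")
  chunk <- character(n)
  for (i in seq_len(n)) {
    chunk[i] <- if (pos[i] %in% np_tags) {
      if (i > 1L && chunk[i - 1L] %in% c("B-NP", "I-NP")) "I-NP" else "B-NP"
    } else if (pos[i] %in% vp_tags) {
      if (i > 1L && chunk[i - 1L] %in% c("B-VP", "I-VP")) "I-VP" else "B-VP"
    } else "O"
  }
  list(pos = pos, lemma = lemma, chunk = chunk)
}

#' Replace entity mentions with placeholder tokens
#'
#' Collapses the gene mention of a candidate pair into the single token
#' `GENE_ENTITY` and the disease mention into `DISEASE_ENTITY`, so that
#' window and pattern features generalise across entity names. Multi-token
#' mentions shrink to one placeholder; the index map records, for every
#' blinded token, which original token indices it covers.
#'
#' @param pair A [candidate_pair()].
#' @param layer Optional [annotate()] output for the sentence (kept for
#'   interface symmetry; tokens are taken from the pair's sentence).
#' @return An object of class `blinded_sentence`: list with `tokens`,
#'   `index_map` (list of 1-based original token indices per blinded token),
#'   `gene_pos`, `disease_pos` (1-based placeholder positions).
#' @export
blind_entities <- function(pair, layer = NULL) {
  stopifnot(inherits(pair, "candidate_pair"))
  toks <- pair$sentence$tokens$token
  g <- mention_token_idx(pair$gene)
  d <- mention_token_idx(pair$disease)
  if (length(intersect(g, d)))
    stopf("gene and disease mentions overlap (tokens %s vs %s): corrupt annotation",
          paste(range(g), collapse = "-"), paste(range(d), collapse = "-"))
  spans <- list(list(idx = g, tag = "GENE_ENTITY"),
                list(idx = d, tag = "DISEASE_ENTITY"))
  spans <- spans[order(vapply(spans, function(s) s$idx[1], integer(1)))]

  out <- character(); map <- list(); gene_pos <- NA_integer_; dis_pos <- NA_integer_
  i <- 1L
  while (i <= length(toks)) {
    hit <- Find(function(s) i == s$idx[1], spans)
    if (!is.null(hit)) {
      out <- c(out, hit$tag)
      map[[length(out)]] <- hit$idx
      if (hit$tag == "GENE_ENTITY") gene_pos <- length(out) else dis_pos <- length(out)
      i <- hit$idx[length(hit$idx)] + 1L
    } else {
      out <- c(out, toks[i])
      map[[length(out)]] <- i
      i <- i + 1L
    }
  }
  structure(list(tokens = out, index_map = map, gene_pos = gene_pos,
                 disease_pos = dis_pos),
            class = "blinded_sentence")
}

# 1-based R indices of the tokens covered by a mention (stored 0-based)
mention_token_idx <- function(mention) {
  if (is.na(mention$token_start) || is.na(mention$token_end))
    stopf("mention '%s' has no token span", mention$surface)
  seq.int(mention$token_start + 1L, mention$token_end)
}
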