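#' Window configuration for positional features
#'
#' Controls how many tokens are read to each side of the gene and disease
#' placeholders when building the word-window features (GW/GWR and DW/DWR),
#' and how far the between-entity scan for the relational keyword (RELW)
#' may run.
#'
#' The defaults (3, 1, 4, 3) reproduce the reference window layout of the
#' worked angiotensinogen/restenosis sentence; an alternative compact layout
#' (2, 2, 3, 3) is sometimes quoted for the same feature family and can be
#' configured here. `boundary_slot` models a quirk of windows computed over
#' entity-tagged text: the first right-hand slot of the rightmost entity is
#' consumed by the mention boundary and is emitted as the empty marker, with
#' real tokens starting at slot 2.
#'
#' @param gene_left,gene_right,disease_left,disease_right Non-negative token
#'   counts per window.
#' @param between_max Maximum number of between-entity tokens scanned for the
#'   relational keyword.
#' @param boundary_slot Logical; see Details.
#' @return An object of class `window_config`.
#' @export
window_config <- function(gene_left = 3L, gene_right = 1L, disease_left = 4L,
                          disease_right = 3L, between_max = Inf,
                          boundary_slot = TRUE) {
  vals <- c(gene_left, gene_right, disease_left, disease_right)
  if (any(vals < 0)) stopf("window sizes must be non-negative")
  structure(list(gene_left = as.integer(gene_left),
                 gene_right = as.integer(gene_right),
                 disease_left = as.integer(disease_left),
                 disease_right = as.integer(disease_right),
                 between_max = between_max,
                 boundary_slot = isTRUE(boundary_slot)),
            class = "window_config")
}

#' Word-window and relational-keyword features
#'
#' Emits the positional lexical features around the blinded entity
#' placeholders: `GW-i` / `GWR-i` are the i-th tokens left / right of
#' `GENE_ENTITY` (1-based, counting outward), `DW-i` / `DWR-i` likewise for
#' `DISEASE_ENTITY`, and `RELW` is the leftmost between-entity token found in
#' the relational-keyword lexicon. Stop words are retained in windows;
#' punctuation-only tokens are never emitted (they do not consume a slot);
#' positions beyond the sentence emit the explicit empty marker `""`.
#'
#' @param pair A [candidate_pair()].
#' @param blinded Output of [blind_entities()] for the pair.
#' @param cfg A [window_config()].
#' @param lex A [load_lexicons()] object.
#' @return Named list of `WINDOW:`-prefixed features.
#' @export
extract_windows <- function(pair, blinded, cfg = window_config(),
                            lex = load_lexicons()) {
  stopifnot(inherits(blinded, "blinded_sentence"))
  toks <- blinded$tokens
  gp <- blinded$gene_pos; dp <- blinded$disease_pos
  if (is.na(gp) || is.na(dp))
    stopf("blinded sentence lacks a %s placeholder",
          if (is.na(gp)) "GENE_ENTITY" else "DISEASE_ENTITY")
  rightmost <- max(gp, dp)

  fill <- function(pos, k, dir, reserve_first = FALSE) {
    vals <- character(0)
    if (k == 0L) return(vals)
    slot <- 1L
    if (reserve_first) { vals <- c(vals, ""); slot <- 2L }
    i <- pos + dir
    while (slot <= k) {
      if (i < 1L || i > length(toks)) { vals <- c(vals, ""); slot <- slot + 1L; next }
      if (!is_punct_token(toks[i])) { vals <- c(vals, toks[i]); slot <- slot + 1L }
      i <- i + dir
    }
    vals
  }
  feats <- list()
  add <- function(prefix, vals) {
    for (i in seq_along(vals))
      feats[[sprintf("WINDOW:%s-%d", prefix, i)]] <<- vals[i]
  }
  add("GW", fill(gp, cfg$gene_left, -1L))
  add("GWR", fill(gp, cfg$gene_right, +1L,
                  reserve_first = cfg$boundary_slot && gp == rightmost))
  add("DW", fill(dp, cfg$disease_left, -1L))
  add("DWR", fill(dp, cfg$disease_right, +1L,
                  reserve_first = cfg$boundary_slot && dp == rightmost))

  between <- between_indices(gp, dp)
  if (length(between) > cfg$between_max)
    between <- between[seq_len(cfg$between_max)]
  for (i in between) {
    if (tolower(toks[i]) %in% lex$relational_keywords) {
      feats[["WINDOW:RELW"]] <- toks[i]
      break
    }
  }
  feats
}

between_indices <- function(a, b) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi - lo <= 1L) integer(0) else seq.int(lo + 1L, hi - 1L)
}

#' Lexical features of the two mentions
#'
#' Lowercased unigram bag-of-words of each mention surface plus the POS tag
#' sequence of the mention tokens as a categorical feature.
#'
#' @inheritParams extract_windows
#' @param layer [annotate()] output aligned to the pair's sentence tokens.
#' @return Named list of `LEXICAL:`-prefixed features.
#' @export
extract_lexical <- function(pair, layer) {
  feats <- list()
  for (role in c("gene", "disease")) {
    m <- pair[[role]]
    idx <- mention_token_idx(m)
    words <- tolower(layer$tokens[idx])
    words <- words[!is_punct_token(words)]
    for (w in unique(words))
      feats[[sprintf("LEXICAL:bow_%s:%s", role, w)]] <- TRUE
    feats[[sprintf("LEXICAL:pos_%s", role)]] <-
      paste(layer$pos[idx], collapse = "_")
  }
  feats
}

#' Conceptual features: order, distance bucket, corpus pair occurrence
#'
#' Sequential order of the two mentions by token position, the bucketed
#' between-entity token gap (0 = adjacent, 1 = near, 2 = far; the near
#' threshold defaults to 5 tokens and is configurable), and the corpus-wide
#' occurrence count of the normalized (gene, disease) pair.
#'
#' @inheritParams extract_windows
#' @param corpus_index Named count vector from [build_pair_index()], or
#'   `NULL` to omit the occurrence feature.
#' @param near_threshold Largest gap still bucketed as "near".
#' @return Named list of `CONCEPT:`-prefixed features.
#' @export
extract_concept <- function(pair, corpus_index = NULL, near_threshold = 5L) {
  g <- pair$gene; d <- pair$disease
  order_feat <- if (g$token_start <= d$token_start) "GENE_DISEASE"
                else "DISEASE_GENE"
  first <- if (order_feat == "GENE_DISEASE") g else d
  second <- if (order_feat == "GENE_DISEASE") d else g
  gap <- max(0L, second$token_start - first$token_end)
  bucket <- if (gap == 0L) "0" else if (gap <= near_threshold) "1" else "2"
  feats <- list("CONCEPT:order" = order_feat,
                "CONCEPT:distance_bucket" = bucket)
  if (!is.null(corpus_index))
    feats[["CONCEPT:pair_occurrence"]] <-
      unname(corpus_index[pair_key(pair)]) %|na|% 0
  feats
}

#' Corpus-wide (gene, disease) pair occurrence index
#'
#' @param pairs List of [candidate_pair()].
#' @return Named integer vector of counts keyed by normalized pair.
#' @export
build_pair_index <- function(pairs) {
  keys <- vapply(pairs, pair_key, character(1))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

pair_key <- function(pair) {
  key <- function(m) m$normalized %||% tolower(m$surface)
  paste(key(pair$gene), key(pair$disease), sep = "||")
}

#' Local and global context features
#'
#' Local: for `k` tokens on each side of each entity, the POS|lemma|chunk
#' triple at that offset (no padding is emitted at sentence edges). Global:
#' token trigrams between the entities (lowercased, stop words and
#' punctuation removed before n-gram formation), a topic-sentence flag
#' (sentence_index 0), the bucketed corpus frequency of the pair, and the
#' corpus-supplied relationship-mention code when present (EU-ADR-style
#' `I`/`FI`/`IA`; passed through, never computed).
#'
#' @inheritParams extract_concept
#' @param layer [annotate()] output for the sentence.
#' @param lex A [load_lexicons()] object (stop word list).
#' @param k Local window size per side.
#' @param n n-gram order for the between-entity n-grams.
#' @return Named list of `CONTEXT_LOCAL:` / `CONTEXT_GLOBAL:` features.
#' @export
extract_context <- function(pair, layer, corpus_index = NULL,
                            lex = load_lexicons(), k = 2L, n = 3L) {
  feats <- list()
  ntok <- length(layer$tokens)
  triple <- function(i) paste(layer$pos[i], layer$lemma[i], layer$chunk[i],
                              sep = "|")
  for (role in c("gene", "disease")) {
    m <- pair[[role]]
    idx <- mention_token_idx(m)
    for (off in seq_len(k)) {
      li <- idx[1] - off
      if (li >= 1L)
        feats[[sprintf("CONTEXT_LOCAL:%s:L%d", role, off)]] <- triple(li)
      ri <- idx[length(idx)] + off
      if (ri <= ntok)
        feats[[sprintf("CONTEXT_LOCAL:%s:R%d", role, off)]] <- triple(ri)
    }
  }
  between <- between_token_indices(pair)
  words <- tolower(layer$tokens[between])
  words <- words[!is_punct_token(words) & !(words %in% lex$stop_words)]
  if (length(words) >= n) {
    for (i in seq_len(length(words) - n + 1L)) {
      key <- sprintf("CONTEXT_GLOBAL:trigram:%s",
                     paste(words[i:(i + n - 1L)], collapse = "_"))
      feats[[key]] <- (feats[[key]] %||% 0) + 1
    }
  }
  feats[["CONTEXT_GLOBAL:topic_sentence"]] <- pair$sentence$sentence_index == 0L
  if (!is.null(corpus_index)) {
    cnt <- unname(corpus_index[pair_key(pair)]) %|na|% 0
    feats[["CONTEXT_GLOBAL:pair_freq_bucket"]] <-
      if (cnt <= 1) "<=1" else if (cnt <= 5) "2-5" else ">5"
  }
  if (!is.null(pair$sentence$relation_code))
    feats[["CONTEXT_GLOBAL:relation_code"]] <- pair$sentence$relation_code
  feats
}

# original-token indices strictly between the two mentions
between_token_indices <- function(pair) {
  g <- pair$gene; d <- pair$disease
  first <- if (g$token_start <= d$token_start) g else d
  second <- if (g$token_start <= d$token_start) d else g
  if (second$token_start <= first$token_end) integer(0)
  else seq.int(first$token_end + 1L, second$token_start)  # 0-based half-open -> 1-based R
}

#' Pattern-template flags
#'
#' One boolean per lexicon family (trigger words, action-verb phrases,
#' genetic phenomena, context-specific phrases), scanning the between-entity
#' span plus two tokens on each side of it. Phrase matching is
#' case-insensitive and longest-first; the leftmost matched phrase of each
#' family is additionally emitted as a categorical feature.
#'
#' @inheritParams extract_windows
#' @return Named list of `PATTERN:`-prefixed features.
#' @export
extract_patterns <- function(pair, blinded, lex = load_lexicons()) {
  span <- pattern_span(blinded, margin = 2L)
  toks <- tolower(blinded$tokens[span])
  fams <- c(trigger = "trigger_words", action_verb = "action_verbs",
            genetic_phenomenon = "genetic_phenomena",
            context_specific = "context_specific")
  feats <- list()
  for (f in names(fams)) {
    hits <- match_phrases(toks, lex[[fams[[f]]]])
    feats[[sprintf("PATTERN:%s", f)]] <- nrow(hits) > 0L
    if (nrow(hits))
      feats[[sprintf("PATTERN:%s_phrase", f)]] <- hits$phrase[1]
  }
  feats
}

pattern_span <- function(blinded, margin = 2L) {
  lo <- min(blinded$gene_pos, blinded$disease_pos)
  hi <- max(blinded$gene_pos, blinded$disease_pos)
  seq.int(max(1L, lo - margin), min(length(blinded$tokens), hi + margin))
}

# leftmost-first, longest-first phrase matches of a lexicon over tokens
match_phrases <- function(tokens_low, phrases) {
  split <- strsplit(phrases, "[[:space:]]+")
  split <- split[lengths(split) > 0]
  ord <- order(-lengths(split))
  split <- split[ord]
  phrases <- vapply(split, paste, character(1), collapse = " ")
  starts <- integer(); lens <- integer(); hit <- character()
  n <- length(tokens_low)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (p in seq_along(split)) {
      pv <- split[[p]]; L <- length(pv)
      if (i + L - 1L <= n && all(tokens_low[i:(i + L - 1L)] == pv)) {
        starts <- c(starts, i); lens <- c(lens, L); hit <- c(hit, phrases[p])
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  data.frame(start = starts, len = lens, phrase = hit,
             stringsAsFactors = FALSE)
}

#' Negation feature
#'
#' Flags a candidate pair as negated when a negation cue occurs within
#' `window` tokens immediately before a trigger-word or action-verb match in
#' the between-entity span ("not involved in", "unlikely to be associated
#' with"). The matched cue is emitted as a categorical feature.
#'
#' @inheritParams extract_windows
#' @param window Token distance the cue may precede the trigger by.
#' @return Named list: `NEGATION:flag` (logical) and, when flagged,
#'   `NEGATION:cue`.
#' @export
extract_negation <- function(pair, blinded, lex = load_lexicons(),
                             window = 4L) {
  toks <- tolower(blinded$tokens)
  between <- between_indices(blinded$gene_pos, blinded$disease_pos)
  feats <- list("NEGATION:flag" = FALSE)
  if (!length(between)) return(feats)
  seg <- toks[between]
  trig <- rbind(match_phrases(seg, lex$trigger_words),
                match_phrases(seg, lex$action_verbs))
  if (!nrow(trig)) return(feats)
  cues <- match_phrases(toks, lex$negation_cues)
  if (!nrow(cues)) return(feats)
  trig_abs <- between[trig$start]              # absolute token positions
  for (p in sort(trig_abs)) {
    ok <- cues$start >= p - window & cues$start < p
    if (any(ok)) {
      feats[["NEGATION:flag"]] <- TRUE
      feats[["NEGATION:cue"]] <- cues$phrase[which(ok)[1]]
      break
    }
  }
  feats
}

#' Full feature bundle for a candidate pair
#'
#' Union of all feature families (window, lexical, concept, context, pattern,
#' negation), namespaced by family prefix. A pure function of its inputs:
#' identical sentence, configuration, lexicons and corpus index always give
#' the identical bundle.
#'
#' @inheritParams extract_windows
#' @inheritParams extract_context
#' @param layer [annotate()] output for the sentence; computed when `NULL`.
#' @param blinded [blind_entities()] output; computed when `NULL`.
#' @param negation_window Token window for [extract_negation()].
#' @return Named list of features (class `feature_bundle`).
#' @export
extract_all <- function(pair, layer = NULL, cfg = window_config(),
                        lex = load_lexicons(), corpus_index = NULL,
                        blinded = NULL, negation_window = 4L) {
  if (is.null(layer)) layer <- annotate(pair$sentence$tokens)
  if (is.null(blinded)) blinded <- blind_entities(pair, layer)
  feats <- c(extract_windows(pair, blinded, cfg, lex),
             extract_lexical(pair, layer),
             extract_concept(pair, corpus_index),
             extract_context(pair, layer, corpus_index, lex),
             extract_patterns(pair, blinded, lex),
             extract_negation(pair, blinded, lex, negation_window))
  structure(feats, class = "feature_bundle")
}
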