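#' Entity mention
#'
#' A gene or disease mention inside a sentence, with 0-based half-open
#' character offsets (and token offsets once the sentence is tokenized).
#'
#' @param entity_type `"GENE"` or `"DISEASE"`.
#' @param char_start,char_end 0-based half-open character offsets into the
#'   sentence text.
#' @param surface The mention text; must equal the substring at the offsets.
#' @param normalized Optional dictionary identifier.
#' @param token_start,token_end 0-based half-open token offsets; filled in by
#'   [annotated_sentence()].
#' @return An object of class `entity_mention`.
#' @export
entity_mention <- function(entity_type, char_start, char_end, surface,
                           normalized = NULL, token_start = NA_integer_,
                           token_end = NA_integer_) {
  entity_type <- match.arg(entity_type, c("GENE", "DISEASE"))
  char_start <- as.integer(char_start); char_end <- as.integer(char_end)
  if (!(char_start < char_end))
    stopf("mention '%s': char_start (%d) must be < char_end (%d)",
          surface, char_start, char_end)
  if (char_start < 0) stopf("mention '%s': negative char_start", surface)
  structure(list(entity_type = entity_type, char_start = char_start,
                 char_end = char_end,
                 token_start = as.integer(token_start),
                 token_end = as.integer(token_end),
                 surface = surface,
                 normalized = normalized),
            class = "entity_mention")
}

#' Annotated sentence
#'
#' The universal interchange record: a sentence with its tokens and its gene /
#' disease mentions. The text is tokenized on construction; token boundaries
#' are forced at mention boundaries so mentions never cross tokens, and each
#' mention receives 0-based half-open token offsets.
#'
#' @param text Raw sentence string.
#' @param mentions List of [entity_mention()] objects.
#' @param sentence_id Opaque identifier (generated when empty).
#' @param doc_id Document identifier (e.g. a PMID), or `""`.
#' @param sentence_index 0-based position of the sentence in its abstract.
#' @param source_corpus One of `EUADR`, `GAD`, `COMAGC`, `POLYSEARCH`,
#'   `SYNTHETIC`, `OTHER`.
#' @param relation_code Optional corpus-supplied relationship-mention code
#'   (e.g. `I`, `FI`, `IA` in EU-ADR-style annotation); never computed.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(text, mentions = list(), sentence_id = "",
                               doc_id = "", sentence_index = 0L,
                               source_corpus = "OTHER",
                               relation_code = NULL) {
  assert_scalar_string(text, "text")
  source_corpus <- match.arg(source_corpus,
                             c("EUADR", "GAD", "COMAGC", "POLYSEARCH",
                               "SYNTHETIC", "OTHER"))
  sentence_index <- as.integer(sentence_index)
  if (is.na(sentence_index) || sentence_index < 0)
    stopf("sentence_index must be >= 0")
  if (!nzchar(sentence_id))  # deterministic content-derived fallback id
    sentence_id <- paste0("s", abs(sum(utf8ToInt(text)) %% 1000003L), "_",
                          nchar(text))
  n <- nchar(text)
  for (m in mentions) {
    if (m$char_end > n)
      stopf("mention '%s' [%d,%d) exceeds sentence length %d",
            m$surface, m$char_start, m$char_end, n)
    actual <- substr(text, m$char_start + 1L, m$char_end)
    if (!identical(actual, m$surface))
      stopf("mention surface '%s' does not match text span '%s' at [%d,%d)",
            m$surface, actual, m$char_start, m$char_end)
  }
  breaks <- unlist(lapply(mentions, function(m) c(m$char_start, m$char_end)))
  tokens <- tokenize(text, breaks = breaks %||% integer())
  mentions <- lapply(mentions, function(m) {
    covered <- which(tokens$end > m$char_start & tokens$start < m$char_end)
    if (!length(covered))
      stopf("mention '%s' covers no tokens", m$surface)
    m$token_start <- covered[1] - 1L           # back to 0-based half-open
    m$token_end <- covered[length(covered)]
    m
  })
  structure(list(sentence_id = sentence_id, doc_id = doc_id,
                 sentence_index = sentence_index, text = text,
                 tokens = tokens, mentions = mentions,
                 source_corpus = source_corpus,
                 relation_code = relation_code),
            class = "annotated_sentence")
}

#' Candidate gene-disease pair
#'
#' One (gene mention, disease mention, sentence) instance with a binary
#' association label: the unit the classifier decides on.
#'
#' @param sentence An [annotated_sentence()] containing both mentions.
#' @param gene,disease [entity_mention()] objects of type GENE / DISEASE,
#'   taken from `sentence$mentions` (matched by offsets).
#' @param label `+1` (asserted association), `-1` (false association), or
#'   `NA` (unlabeled).
#' @return An object of class `candidate_pair`.
#' @export
candidate_pair <- function(sentence, gene, disease, label = NA_integer_) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  if (gene$entity_type != "GENE") stopf("gene mention has type %s", gene$entity_type)
  if (disease$entity_type != "DISEASE")
    stopf("disease mention has type %s", disease$entity_type)
  gene <- resolve_mention(sentence, gene)
  disease <- resolve_mention(sentence, disease)
  if (!is.na(label) && !label %in% c(1L, -1L))
    stopf("label must be +1, -1 or NA, got %s", label)
  structure(list(sentence = sentence, gene = gene, disease = disease,
                 label = if (is.na(label)) NA_integer_ else as.integer(label)),
            class = "candidate_pair")
}

# match a mention to the sentence copy (which carries token offsets)
resolve_mention <- function(sentence, mention) {
  for (m in sentence$mentions) {
    if (m$entity_type == mention$entity_type &&
        m$char_start == mention$char_start && m$char_end == mention$char_end)
      return(m)
  }
  stopf("mention '%s' [%d,%d) not found in sentence '%s'",
        mention$surface, mention$char_start, mention$char_end,
        sentence$sentence_id)
}

#' @export
print.candidate_pair <- function(x, ...) {
  lab <- if (is.na(x$label)) "UNLABELED" else sprintf("%+d", x$label)
  cat(sprintf("<candidate_pair %s> %s | %s\n  %s\n",
              lab, x$gene$surface, x$disease$surface, x$sentence$text))
  invisible(x)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<annotated_sentence %s> %d tokens, %d mentions\n  %s\n",
              x$sentence_id, nrow(x$tokens), length(x$mentions), x$text))
  invisible(x)
}
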