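#' Read a gold corpus into candidate pairs
#'
#' Normalises the four supported corpus dialects (plus the package's own
#' JSON-lines interchange format) into a list of [candidate_pair()] objects.
#' All offsets are converted to 0-based half-open; labels are mapped onto
#' `+1` / `-1` / `NA` (unlabeled); input order is preserved. An empty file
#' yields an empty list.
#'
#' Dialects:
#' \describe{
#'   \item{`GAD`}{Tab-separated sentence/label records. Because GAD-style
#'     files label the sentence rather than annotated offsets, the gene and
#'     disease columns are located in the sentence by [dictionary_tag()]; the
#'     first gene and first disease mention form the pair. The column layout
#'     varies between redistributions, so it is configurable via `col_map`
#'     (named positions for `label`, `gene`, `disease`, `sentence`, and
#'     optionally `doc_id`).}
#'   \item{`EUADR`}{Offset-annotated TSV with columns `sentence_id`, `doc_id`,
#'     `sentence_index`, `text`, `gene_start`, `gene_end`, `gene`,
#'     `disease_start`, `disease_end`, `disease`, `label` and optional
#'     `relation_code` (`I`/`FI`/`IA`). Native offsets are 1-based inclusive
#'     and are converted on read. Labels `PA`/`NA`/`SA` map to +1/-1/NA.}
#'   \item{`COMAGC`}{XML annotation units (see [read_comagc()]); the
#'     expression-change/causality class of each unit is mapped to +1 when it
#'     is in `comagc_positive`, otherwise -1.}
#'   \item{`POLYSEARCH`}{Relevance-coded TSV (`doc_id`, `relevance`, `gene`,
#'     `disease`, `sentence`); relevant codes map to +1, irrelevant to -1;
#'     mentions are completed by [dictionary_tag()] as for GAD.}
#'   \item{`INTERCHANGE`}{The JSON-lines format written by
#'     [write_interchange()]; reading inverts writing exactly.}
#' }
#'
#' @param path Path to the corpus file.
#' @param dialect One of `"GAD"`, `"EUADR"`, `"COMAGC"`, `"POLYSEARCH"`,
#'   `"INTERCHANGE"`.
#' @param col_map Named integer vector of 1-based column positions for the
#'   GAD dialect; default `c(label = 1, gene = 2, disease = 3, sentence = 4)`.
#' @param label_map Named list mapping dialect label strings to classes, with
#'   elements `positive`, `negative`, `unlabeled` (character vectors).
#' @param comagc_positive Character vector of CoMAGC annotation classes mapped
#'   to the positive label.
#' @param relevance_map As `label_map`, for the PolySearch dialect.
#' @return List of [candidate_pair()] objects, one or more per record.
#' @export
read_corpus <- function(path, dialect,
                        col_map = c(label = 1L, gene = 2L, disease = 3L,
                                    sentence = 4L),
                        label_map = list(positive = c("Y", "1", "+1"),
                                         negative = c("N", "0", "-1"),
                                         unlabeled = c("U", "?", "F")),
                        comagc_positive = c("Gene_up-regulated",
                                            "Gene_down-regulated",
                                            "causality"),
                        relevance_map = list(positive = c("R1", "R2"),
                                             negative = c("R0", "N"),
                                             unlabeled = "U")) {
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  dialect <- toupper(dialect)
  switch(dialect,
         GAD = read_tagged_tsv(path, col_map, label_map, "GAD"),
         POLYSEARCH = read_tagged_tsv(
           path,
           c(doc_id = 1L, label = 2L, gene = 3L, disease = 4L, sentence = 5L),
           relevance_map, "POLYSEARCH"),
         EUADR = read_euadr(path, label_map = list(positive = "PA",
                                                   negative = "NA",
                                                   unlabeled = "SA")),
         COMAGC = read_comagc(path, comagc_positive),
         INTERCHANGE = read_interchange(path),
         stopf("unknown dialect '%s'", dialect))
}

map_label <- function(value, label_map, where) {
  if (value %in% label_map$positive) return(1L)
  if (value %in% label_map$negative) return(-1L)
  if (value %in% label_map$unlabeled) return(NA_integer_)
  stopf("%s: unmapped label value '%s'", where, value)
}

read_tsv_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
}

# GAD / PolySearch style: sentence-level label, offsets completed by
# dictionary tagging of the gene and disease strings
read_tagged_tsv <- function(path, col_map, label_map, source) {
  rows <- read_tsv_raw(path)
  out <- vector("list", length(rows))
  need <- max(col_map)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < need)
      stopf("%s line %d: expected >= %d tab-separated fields, found %d",
            source, i, need, length(f))
    text <- f[col_map[["sentence"]]]
    gene_str <- f[col_map[["gene"]]]
    dis_str <- f[col_map[["disease"]]]
    if (!nzchar(gene_str)) stopf("%s line %d: empty gene field", source, i)
    if (!nzchar(dis_str)) stopf("%s line %d: empty disease field", source, i)
    gm <- dictionary_tag(text, gene_str, "GENE")
    if (!length(gm))
      stopf("%s line %d: gene '%s' not found in sentence", source, i, gene_str)
    dm <- dictionary_tag(text, dis_str, "DISEASE")
    dm <- Filter(function(m) m$char_start >= gm[[1]]$char_end ||
                   m$char_end <= gm[[1]]$char_start, dm)
    if (!length(dm))
      stopf("%s line %d: disease '%s' not found in sentence", source, i, dis_str)
    sen <- annotated_sentence(
      text, mentions = list(gm[[1]], dm[[1]]),
      sentence_id = paste0(tolower(source), "_", i),
      doc_id = if ("doc_id" %in% names(col_map)) f[col_map[["doc_id"]]] else "",
      source_corpus = source)
    out[[i]] <- candidate_pair(sen, gm[[1]], dm[[1]],
                               map_label(f[col_map[["label"]]], label_map,
                                         sprintf("%s line %d", source, i)))
  }
  out
}

read_euadr <- function(path, label_map) {
  rows <- read_tsv_raw(path)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 11)
      stopf("EUADR line %d: expected >= 11 fields, found %d", i, length(f))
    text <- f[4]
    conv <- function(s, e, field) {
      s <- suppressWarnings(as.integer(s)); e <- suppressWarnings(as.integer(e))
      if (is.na(s) || is.na(e))
        stopf("EUADR line %d: non-numeric %s offsets", i, field)
      c(s - 1L, e)  # 1-based inclusive -> 0-based half-open
    }
    g <- conv(f[5], f[6], "gene"); d <- conv(f[8], f[9], "disease")
    gm <- entity_mention("GENE", g[1], g[2], f[7])
    dm <- entity_mention("DISEASE", d[1], d[2], f[10])
    sen <- annotated_sentence(
      text, mentions = list(gm, dm), sentence_id = f[1], doc_id = f[2],
      sentence_index = as.integer(f[3]), source_corpus = "EUADR",
      relation_code = if (length(f) >= 12 && nzchar(f[12])) f[12] else NULL)
    out[[i]] <- candidate_pair(sen, gm, dm,
                               map_label(f[11], label_map,
                                         sprintf("EUADR line %d", i)))
  }
  out
}

#' Read a CoMAGC-style XML corpus
#'
#' Each `<annotation_unit>` holds a `<pmid>`, a `<sentence idx="...">`, a
#' `<gene start end>` and a `<cancer_term start end>` (offsets 1-based
#' inclusive in the native dialect), plus a `<change>` element giving the
#' expression-change/causality annotation class. CoMAGC has no explicit
#' positive/negative split, so classes listed in `positive_classes` map to
#' +1 and every other annotated pair to -1; the mapping is a configuration,
#' not a fact of the corpus.
#'
#' @param path XML file path.
#' @param positive_classes Annotation classes treated as positive.
#' @return List of [candidate_pair()].
#' @export
read_comagc <- function(path, positive_classes = c("Gene_up-regulated",
                                                   "Gene_down-regulated",
                                                   "causality")) {
  if (file.size(path) == 0) return(list())
  doc <- xml2::read_xml(path)
  units <- xml2::xml_find_all(doc, ".//annotation_unit")
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    sen_node <- xml2::xml_find_first(u, "./sentence")
    if (is.na(sen_node)) stopf("COMAGC unit %d: missing <sentence>", i)
    text <- xml2::xml_text(sen_node)
    grab <- function(tag, type) {
      node <- xml2::xml_find_first(u, paste0("./", tag))
      if (is.na(node)) stopf("COMAGC unit %d: missing <%s>", i, tag)
      s <- as.integer(xml2::xml_attr(node, "start"))
      e <- as.integer(xml2::xml_attr(node, "end"))
      if (is.na(s) || is.na(e))
        stopf("COMAGC unit %d: <%s> lacks numeric start/end", i, tag)
      entity_mention(type, s - 1L, e, xml2::xml_text(node))
    }
    gm <- grab("gene", "GENE"); dm <- grab("cancer_term", "DISEASE")
    cls <- xml2::xml_text(xml2::xml_find_first(u, "./change"))
    sen <- annotated_sentence(
      text, mentions = list(gm, dm),
      sentence_id = xml2::xml_attr(u, "id") %|na|% paste0("comagc_", i),
      doc_id = xml2::xml_text(xml2::xml_find_first(u, "./pmid")) %|na|% "",
      sentence_index = as.integer(xml2::xml_attr(sen_node, "idx") %|na|% "0"),
      source_corpus = "COMAGC")
    out[[i]] <- candidate_pair(sen, gm, dm,
                               if (!is.na(cls) && cls %in% positive_classes)
                                 1L else -1L)
  }
  out
}

`%|na|%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

read_interchange <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stopf("INTERCHANGE line %d: invalid JSON (%s)", i,
                            conditionMessage(e)))
    for (field in c("sentence", "gene", "disease"))
      if (is.null(rec[[field]]))
        stopf("INTERCHANGE line %d: missing field '%s'", i, field)
    s <- rec$sentence
    mk_mention <- function(m) entity_mention(m$entity_type, m$char_start,
                                             m$char_end, m$surface,
                                             normalized = m$normalized)
    gm <- mk_mention(rec$gene); dm <- mk_mention(rec$disease)
    sen <- annotated_sentence(s$text, mentions = list(gm, dm),
                              sentence_id = s$sentence_id %||% "",
                              doc_id = s$doc_id %||% "",
                              sentence_index = s$sentence_index %||% 0L,
                              source_corpus = s$source_corpus %||% "OTHER",
                              relation_code = s$relation_code)
    candidate_pair(sen, gm, dm, if (is.null(rec$label)) NA_integer_
                                else as.integer(rec$label))
  })
}

#' Write candidate pairs to the JSON-lines interchange format
#'
#' One JSON object per line per pair, with embedded sentence and mention
#' objects. `read_corpus(path, "INTERCHANGE")` inverts this exactly; an
#' unlabeled pair is serialised with a `null` label and restored as `NA`.
#'
#' @param pairs List of [candidate_pair()].
#' @param path Output file path.
#' @return Invisibly, the number of records written.
#' @export
write_interchange <- function(pairs, path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stopf("cannot write '%s': %s", path,
                                            conditionMessage(e)))
  on.exit(close(con))
  for (p in pairs) {
    stopifnot(inherits(p, "candidate_pair"))
    mention_rec <- function(m)
      list(entity_type = m$entity_type, char_start = m$char_start,
           char_end = m$char_end, token_start = m$token_start,
           token_end = m$token_end, surface = m$surface,
           normalized = m$normalized)
    rec <- list(
      sentence = list(sentence_id = p$sentence$sentence_id,
                      doc_id = p$sentence$doc_id,
                      sentence_index = p$sentence$sentence_index,
                      text = p$sentence$text,
                      source_corpus = p$sentence$source_corpus,
                      relation_code = p$sentence$relation_code),
      gene = mention_rec(p$gene),
      disease = mention_rec(p$disease),
      label = if (is.na(p$label)) NULL else p$label)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(length(pairs))
}

#' Corpus summary statistics
#'
#' Counts sentences, pairs, labels and unique entities over a pair list.
#' Entity uniqueness uses the normalized identifier when present, otherwise
#' the lowercased surface form. Totals are permutation-invariant.
#'
#' @param pairs List of [candidate_pair()].
#' @return A list of class `corpus_stats` with fields `n_sentences`,
#'   `n_pairs`, `n_positive`, `n_negative`, `n_unique_genes`,
#'   `n_unique_diseases`.
#' @export
corpus_stats <- function(pairs) {
  labels <- vapply(pairs, function(p) p$label %|na|% 0L, integer(1))
  key <- function(m) m$normalized %||% tolower(m$surface)
  structure(list(
    n_sentences = length(unique(vapply(pairs, function(p)
      p$sentence$sentence_id, character(1)))),
    n_pairs = length(pairs),
    n_positive = sum(labels == 1L),
    n_negative = sum(labels == -1L),
    n_unique_genes = length(unique(vapply(pairs, function(p) key(p$gene),
                                          character(1)))),
    n_unique_diseases = length(unique(vapply(pairs, function(p) key(p$disease),
                                             character(1))))),
    class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(paste0("corpus: %d sentences, %d pairs ",
                     "(%d positive / %d negative), ",
                     "%d unique genes, %d unique diseases\n"),
              x$n_sentences, x$n_pairs, x$n_positive, x$n_negative,
              x$n_unique_genes, x$n_unique_diseases))
  invisible(x)
}

#' Dictionary-matching entity tagger
#'
#' Case-insensitive longest-match-first scan of `text` against a lexicon of
#' literal entity names, at token boundaries, left to right, non-overlapping.
#' Serves as the pluggable tagger completing GAD/PolySearch-style records
#' that label the sentence without in-sentence offsets.
#'
#' @param text Sentence string.
#' @param lexicon Character vector of entity names (possibly multi-word).
#' @param entity_type `"GENE"` or `"DISEASE"`.
#' @return List of [entity_mention()] (possibly empty).
#' @export
dictionary_tag <- function(text, lexicon, entity_type) {
  if (!length(lexicon) || all(!nzchar(lexicon))) stopf("empty lexicon")
  toks <- tokenize(text)
  if (!nrow(toks)) return(list())
  entry_tokens <- lapply(lexicon, function(e) tolower(tokenize(e)$token))
  entry_tokens <- entry_tokens[lengths(entry_tokens) > 0]
  max_len <- max(lengths(entry_tokens))
  low <- tolower(toks$token)
  keys <- vapply(entry_tokens, paste, character(1), collapse = " ")

  out <- list()
  i <- 1L
  while (i <= nrow(toks)) {
    matched <- 0L
    for (len in seq(min(max_len, nrow(toks) - i + 1L), 1L)) {
      cand <- paste(low[i:(i + len - 1L)], collapse = " ")
      if (cand %in% keys) { matched <- len; break }
    }
    if (matched > 0L) {
      s <- toks$start[i]; e <- toks$end[i + matched - 1L]
      out[[length(out) + 1L]] <-
        entity_mention(entity_type, s, e, substr(text, s + 1L, e))
      i <- i + matched
    } else i <- i + 1L
  }
  out
}

read_lexicon_file <- function(path) {
  if (!file.exists(path)) stopf("lexicon file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  tolower(lines[nzchar(lines)])
}
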