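#' Synthetic corpus generator configuration
#'
#' Controls the labeled gene-disease corpus generator used for fully
#' reproducible end-to-end testing. Every generated sentence carries exactly
#' one fake gene and one fake disease mention with correct character
#' offsets. Positive sentences place a relational trigger/action phrase
#' between the entities; negative sentences either insert a negation cue
#' immediately before such a phrase (half of them) or co-mention the
#' entities with a neutral, non-relational template. Gene names follow gene
#' morphology (uppercase letters + digits), disease names are multiword
#' lowercase, so dictionary tagging is exercised realistically.
#'
#' @param n_pos,n_neg Numbers of positive / negative sentences.
#' @param n_genes,n_diseases Sizes of the fake entity vocabularies.
#' @param label_noise Probability in \[0, 0.5) of independently flipping each
#'   label.
#' @param distractor_rate Expected number of random filler tokens inserted
#'   per filler slot (0 disables distractors).
#' @param triggers Positive trigger phrases (verb-phrase form); defaults to
#'   a subset of the shipped action-verb lexicon.
#' @param negations Negation cues used in negated templates.
#' @param seed Integer seed; generation is fully deterministic under it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_pos = 500L, n_neg = 500L, n_genes = 40L,
                             n_diseases = 40L, label_noise = 0,
                             distractor_rate = 0.3,
                             triggers = NULL, negations = NULL, seed = 1L) {
  if (n_pos < 0 || n_neg < 0) stopf("sentence counts must be non-negative")
  if (label_noise < 0 || label_noise >= 0.5)
    stopf("label_noise must be in [0, 0.5)")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases),
                 label_noise = label_noise,
                 distractor_rate = distractor_rate,
                 triggers = triggers %||% default_triggers(),
                 negations = negations %||% c("not", "unlikely to be",
                                              "hardly", "rarely"),
                 seed = as.integer(seed)),
            class = "generator_config")
}

default_triggers <- function() {
  c("is associated with", "is involved in", "is implicated in",
    "is linked to", "contributes to", "predisposes to", "leads to",
    "interacts with", "binds")
}

synth_gene_names <- function(n) {
  stems <- c("ABC", "TNF", "LOX", "CHI", "HIF", "INS", "BRC", "EGF", "KRT",
             "MYC", "NOS", "APO", "CDK", "FGF", "GST", "ILR", "MMP", "PON",
             "SOD", "VDR")
  out <- character(n)
  for (i in seq_len(n))
    out[i] <- paste0(stems[((i - 1) %% length(stems)) + 1],
                     ((i - 1) %/% length(stems)) + 1,
                     if (i %% 3 == 0) "L" else "")
  out
}

synth_disease_names <- function(n) {
  first <- c("gastric", "renal", "hepatic", "cardiac", "pulmonary",
             "cervical", "colorectal", "ovarian", "prostate", "thyroid",
             "pancreatic", "cutaneous", "neural", "vascular", "bronchial")
  second <- c("carcinoma", "neuropathy", "fibrosis", "stenosis", "atrophy",
              "dystrophy", "sclerosis", "adenoma", "myopathy", "dysplasia")
  out <- character(n)
  for (i in seq_len(n))
    out[i] <- paste(first[((i - 1) %% length(first)) + 1],
                    second[((i - 1) %/% length(first)) %% length(second) + 1])
  out
}

filler_words <- function() {
  c("patients", "cohort", "population", "subjects", "samples", "tissue",
    "analysis", "levels", "cells", "japanese", "adult", "elderly",
    "clinical", "genomic", "plasma", "serum")
}

# build one sentence as a token list; returns text plus mention offsets
synth_sentence <- function(gene, disease, kind, cfg) {
  intro <- sample(list(c("These", "results", "suggest", "that"),
                       c("We", "conclude", "that", "the"),
                       c("Our", "findings", "indicate", "that")), 1)[[1]]
  distract <- function() {
    if (cfg$distractor_rate > 0 && stats::runif(1) < cfg$distractor_rate)
      sample(filler_words(), 1) else character(0)
  }
  tailing <- sample(list(c("in", "this", "cohort", "."),
                         c("in", "a", "large", "population", "."),
                         c("among", "adult", "patients", ".")), 1)[[1]]
  gene_toks <- strsplit(gene, " ", fixed = TRUE)[[1]]
  dis_toks <- strsplit(disease, " ", fixed = TRUE)[[1]]
  mid <- switch(kind,
    positive = strsplit(sample(cfg$triggers, 1), " ", fixed = TRUE)[[1]],
    negated = {
      trig <- strsplit(sample(cfg$triggers, 1), " ", fixed = TRUE)[[1]]
      cue <- strsplit(sample(cfg$negations, 1), " ", fixed = TRUE)[[1]]
      # cue goes right after the copula, before the trigger content
      if (trig[1] == "is") c("is", cue, trig[-1]) else c("is", cue, trig)
    },
    neutral = sample(list(c("and"), c("as", "well", "as"),
                          c("together", "with")), 1)[[1]])
  toks <- c(intro, distract(), gene_toks, mid, dis_toks, tailing)
  list(tokens = toks, gene_toks = gene_toks, dis_toks = dis_toks)
}

#' Generate a labeled synthetic gene-disease corpus
#'
#' See [generator_config()] for the generative structure. Each label is
#' flipped independently with probability `label_noise` after the sentence
#' is built, emulating annotation noise. Byte-identical output under a
#' fixed seed.
#'
#' @param cfg A [generator_config()].
#' @return List of [candidate_pair()] with `source_corpus = "SYNTHETIC"`.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_pos > 0 && !length(cfg$triggers))
    stopf("positive sentences requested but the trigger list is empty")
  genes <- synth_gene_names(cfg$n_genes)
  diseases <- synth_disease_names(cfg$n_diseases)
  kinds <- c(rep("positive", cfg$n_pos),
             rep(c("negated", "neutral"), length.out = cfg$n_neg))
  true_label <- c(rep(1L, cfg$n_pos), rep(-1L, cfg$n_neg))
  with_seed(cfg$seed, {
    out <- vector("list", length(kinds))
    for (i in seq_along(kinds)) {
      gene <- sample(genes, 1)
      disease <- sample(diseases, 1)
      parts <- synth_sentence(gene, disease, kinds[i], cfg)
      toks <- parts$tokens
      # char offsets from the token layout (single spaces, final "." attached
      # to the preceding space-joined layout is avoided: tokens joined by " ")
      text <- paste(toks, collapse = " ")
      starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_along(toks)]
      find_span <- function(sub_toks) {
        n <- length(sub_toks)
        for (j in seq_len(length(toks) - n + 1L)) {
          if (all(toks[j:(j + n - 1L)] == sub_toks)) {
            return(c(starts[j], starts[j + n - 1L] + nchar(toks[j + n - 1L])))
          }
        }
        stopf("internal: mention tokens not found")
      }
      gs <- find_span(parts$gene_toks)
      ds <- find_span(parts$dis_toks)
      gm <- entity_mention("GENE", gs[1], gs[2], gene)
      dm <- entity_mention("DISEASE", ds[1], ds[2], disease)
      lab <- true_label[i]
      if (cfg$label_noise > 0 && stats::runif(1) < cfg$label_noise)
        lab <- -lab
      sen <- annotated_sentence(
        text, mentions = list(gm, dm),
        sentence_id = sprintf("synth_%05d", i),
        doc_id = sprintf("doc%04d", ((i - 1L) %/% 4L) + 1L),
        sentence_index = (i - 1L) %% 4L,
        source_corpus = "SYNTHETIC")
      out[[i]] <- candidate_pair(sen, gm, dm, lab)
    }
    out
  })
}

#' Generate an unlabeled corpus for embedding training
#'
#' Draws sentences from the same relational templates (positives, negated
#' and neutral negatives in balanced proportion) plus pure filler sentences,
#' so that trigger words co-occur with entity tokens far more often than
#' with random filler. Returns token sequences ready for
#' [train_skipgram()].
#'
#' @param cfg A [generator_config()] (entity vocabularies, trigger and
#'   negation lists, seed).
#' @param n_sentences Number of sentences.
#' @return List of character token vectors.
#' @export
generate_embedding_corpus <- function(cfg = generator_config(),
                                      n_sentences = 1000L) {
  if (n_sentences == 0) return(list())
  genes <- synth_gene_names(cfg$n_genes)
  diseases <- synth_disease_names(cfg$n_diseases)
  with_seed(cfg$seed + 7919L, {
    lapply(seq_len(n_sentences), function(i) {
      if (i %% 5 == 0) {  # pure filler sentence, no entities or triggers
        sample(filler_words(), 6, replace = TRUE)
      } else {
        kind <- c("positive", "negated", "neutral")[1 + (i %% 3)]
        parts <- synth_sentence(sample(genes, 1), sample(diseases, 1),
                                kind, cfg)
        parts$tokens
      }
    })
  })
}

#' Two-cluster corpus for embedding sanity checks
#'
#' Sentences drawn entirely from one of two disjoint token clusters
#' (`g1,g2,g3` vs `d1,d2,d3`), so words within a cluster co-occur and words
#' across clusters never do. A trained embedding should place within-cluster
#' pairs closer (higher cosine) than between-cluster pairs.
#'
#' @param n_sentences Number of sentences.
#' @param sentence_length Tokens per sentence.
#' @param seed Integer seed.
#' @return List of character token vectors.
#' @export
two_cluster_corpus <- function(n_sentences = 200L, sentence_length = 6L,
                               seed = 7L) {
  clusters <- list(c("g1", "g2", "g3"), c("d1", "d2", "d3"))
  with_seed(seed, {
    lapply(seq_len(n_sentences), function(i)
      sample(clusters[[1 + i %% 2]], sentence_length, replace = TRUE))
  })
}
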