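#' Published characteristics of the four gene-disease gold corpora
#'
#' Reference summary of the four public gold-standard corpora the extraction
#' task is evaluated on in the literature (EU-ADR, GAD, CoMAGC, PolySearch):
#' abstract, mention, unique-entity and relation counts, and the
#' positive/negative annotation split where the corpus provides one (CoMAGC
#' has no native split). Useful for sanity-checking a downloaded corpus
#' against its documented size.
#'
#' @return Data frame with one row per corpus: `corpus`, `n_abstracts`,
#'   `n_disease_mentions`, `n_target_mentions`, `n_unique_diseases`,
#'   `n_unique_targets`, `n_relations`, `n_positive`, `n_negative`.
#' @export
corpus_characteristics <- function() {
  data.frame(
    corpus = c("EU-ADR", "GAD", "CoMAGC", "PolySearch"),
    n_abstracts = c(100L, 5330L, 408L, 374L),
    n_disease_mentions = c(964L, 5330L, 821L, 522L),
    n_target_mentions = c(1664L, 5330L, 821L, 522L),
    n_unique_diseases = c(126L, 923L, 3L, 10L),
    n_unique_targets = c(213L, 1652L, 538L, 243L),
    n_relations = c(941L, 5330L, 821L, 522L),
    n_positive = c(262L, 2801L, NA_integer_, 341L),
    n_negative = c(93L, 2529L, NA_integer_, 181L),
    stringsAsFactors = FALSE
  )
}

#' Published cross-validated scores of gene-disease extraction systems
#'
#' Reference precision/recall/F-score (percent) reported in the literature
#' for supervised gene-disease relation extraction on the four gold corpora,
#' for the joint ensemble method this package implements and for the
#' comparison systems BeFree, PKDE4J and PolySearch2.
#'
#' @return Data frame `corpus`, `system`, `precision`, `recall`, `f`.
#' @export
benchmark_scores <- function() {
  data.frame(
    corpus = c("EU-ADR", "EU-ADR", "GAD", "GAD", "GAD", "CoMAGC", "CoMAGC",
               "PolySearch", "PolySearch"),
    system = c("joint ensemble", "BeFree", "joint ensemble", "BeFree",
               "PKDE4J", "joint ensemble", "PKDE4J", "joint ensemble",
               "PolySearch2"),
    precision = c(76.43, 75.10, 79.21, 77.80, NA, 81.89, 71.5, 83.45, 87.08),
    recall = c(98.01, 97.70, 89.25, 87.20, NA, 93.70, 88.00, 87.82, 90.91),
    f = c(85.34, 84.6, 83.93, 82.20, 83.80, 87.39, 78.80, 85.57, 88.95),
    stringsAsFactors = FALSE
  )
}
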