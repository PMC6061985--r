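# Build a candidate pair from a plain sentence by locating the first
# occurrence of the gene and disease surfaces.
make_pair <- function(text, gene, disease, label = 1L, sentence_index = 0L,
                      relation_code = NULL) {
  span <- function(surface) {
    m <- regexpr(surface, text, fixed = TRUE)
    stopifnot(m > 0)
    c(m - 1L, m - 1L + attr(m, "match.length"))
  }
  gs <- span(gene); ds <- span(disease)
  gm <- entity_mention("GENE", gs[1], gs[2], gene)
  dm <- entity_mention("DISEASE", ds[1], ds[2], disease)
  sen <- annotated_sentence(text, mentions = list(gm, dm),
                            sentence_index = sentence_index,
                            relation_code = relation_code)
  candidate_pair(sen, gm, dm, label)
}

# error-analysis style corpus sentences used across feature tests
sentence_assoc <- paste("These results strongly suggest that the g.-247C/T",
                        "polymorphism in the CHI3L1 promoter region is",
                        "associated with the risk of atopy")
sentence_negated <- paste("These results suggest that the C1772T polymorphism",
                          "in HIF-1alpha is not involved in progression or",
                          "metastasis of colorectal carcinoma")
sentence_unlikely <- paste("Our findings suggest that the p53 codon 72",
                           "polymorphism is unlikely to be associated with",
                           "endometriosis in Japanese women")
example1_text <- paste("We conclude that the angiotensinogen M235T gene",
                       "polymorphism may be an independent predictor of",
                       "restenosis after PTCA.")

example1_pair <- function() {
  make_pair(example1_text, "angiotensinogen M235T", "restenosis")
}

tiny_sg_config <- function(...) {
  args <- list(dim = 8L, window = 3L, negative = 5L, subsample = 1,
               epochs = 3L, seed = 5L)
  override <- list(...)
  args[names(override)] <- override
  do.call(skipgram_config, args)
}

fast_pipeline_config <- function(...) {
  pipeline_config(skipgram = skipgram_config(dim = 16L, window = 4L,
                                             negative = 5L, subsample = 1,
                                             epochs = 2L, seed = 2L),
                  m = 5L, svm = svm_config(cost = 10), ...)
}

fixture_path <- function(name) testthat::test_path("fixtures", name)
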