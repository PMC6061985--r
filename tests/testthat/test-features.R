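lex <- load_lexicons()

test_that("window features reproduce the reference layout verbatim", {
  p <- example1_pair()
  w <- extract_windows(p, blind_entities(p), window_config(), lex)
  expect_equal(w[["WINDOW:GW-1"]], "the")
  expect_equal(w[["WINDOW:GW-2"]], "that")
  expect_equal(w[["WINDOW:GW-3"]], "conclude")
  expect_equal(w[["WINDOW:GWR-1"]], "gene")
  expect_equal(w[["WINDOW:RELW"]], "polymorphism")
  expect_equal(w[["WINDOW:DW-1"]], "of")
  expect_equal(w[["WINDOW:DW-2"]], "predictor")
  expect_equal(w[["WINDOW:DW-3"]], "independent")
  expect_equal(w[["WINDOW:DW-4"]], "an")
  expect_equal(w[["WINDOW:DWR-1"]], "")    # boundary slot of the last entity
  expect_equal(w[["WINDOW:DWR-2"]], "after")
  expect_equal(w[["WINDOW:DWR-3"]], "PTCA")
})

test_that("window slots beyond the sentence emit explicit empty markers", {
  p <- make_pair("TNF causes asthma", "TNF", "asthma")
  w <- extract_windows(p, blind_entities(p), window_config(), lex)
  expect_equal(w[["WINDOW:GW-1"]], "")
  expect_equal(w[["WINDOW:GW-3"]], "")
  expect_equal(w[["WINDOW:GWR-1"]], "causes")
})

test_that("adjacent entities yield no RELW and windows cross the other entity", {
  # hand-enumerated 6-token sentence with the entities adjacent
  p <- make_pair("aa bb GENEX dcancer yy zz", "GENEX", "dcancer")
  bl <- blind_entities(p)
  w <- extract_windows(p, bl, window_config(), lex)
  expect_null(w[["WINDOW:RELW"]])
  expect_equal(w[["WINDOW:DW-1"]], "GENE_ENTITY")
  expect_equal(w[["WINDOW:DW-2"]], "bb")
  expect_equal(w[["WINDOW:DW-3"]], "aa")
  expect_equal(w[["WINDOW:DW-4"]], "")
  # disease is the rightmost entity: boundary slot then the real neighbours
  expect_equal(w[["WINDOW:DWR-1"]], "")
  expect_equal(w[["WINDOW:DWR-2"]], "yy")
  expect_equal(w[["WINDOW:DWR-3"]], "zz")
})

test_that("missing placeholders are an error", {
  p <- make_pair("TNF causes asthma", "TNF", "asthma")
  bl <- blind_entities(p)
  broken <- bl; broken$gene_pos <- NA_integer_
  expect_error(extract_windows(p, broken, window_config(), lex),
               "GENE_ENTITY")
})

test_that("lexical features carry mention unigrams and POS sequences", {
  p <- example1_pair()
  f <- extract_lexical(p, annotate(p$sentence$tokens))
  expect_true(isTRUE(f[["LEXICAL:bow_gene:angiotensinogen"]]))
  expect_true(isTRUE(f[["LEXICAL:bow_gene:m235t"]]))
  expect_true(isTRUE(f[["LEXICAL:bow_disease:restenosis"]]))
  expect_match(f[["LEXICAL:pos_gene"]], "_")   # two tags joined

  hy <- make_pair("HIF-1alpha causes gastric carcinoma", "HIF-1alpha",
                  "gastric carcinoma")
  fh <- extract_lexical(hy, annotate(hy$sentence$tokens))
  expect_true(isTRUE(fh[["LEXICAL:bow_gene:hif-1alpha"]]))  # hyphen kept whole
  expect_length(grep("^LEXICAL:bow_gene:", names(fh)), 1)
})

test_that("concept features follow the distance-bucket rule", {
  # gap of 6 tokens -> far bucket, gene first
  p <- make_pair("GENEX w1 w2 w3 w4 w5 w6 dcancer end", "GENEX", "dcancer")
  f <- extract_concept(p)
  expect_equal(f[["CONCEPT:order"]], "GENE_DISEASE")
  expect_equal(f[["CONCEPT:distance_bucket"]], "2")
  # adjacent -> bucket 0
  f0 <- extract_concept(make_pair("GENEX dcancer tail", "GENEX", "dcancer"))
  expect_equal(f0[["CONCEPT:distance_bucket"]], "0")
  # gap in 1..5 -> bucket 1; disease-first order
  f1 <- extract_concept(make_pair("dcancer near GENEX", "GENEX", "dcancer"))
  expect_equal(f1[["CONCEPT:order"]], "DISEASE_GENE")
  expect_equal(f1[["CONCEPT:distance_bucket"]], "1")
})

test_that("pair occurrence counts are corpus-wide", {
  pairs <- list(make_pair("TNF causes asthma", "TNF", "asthma"),
                make_pair("tnf worsens Asthma badly", "tnf", "Asthma"),
                make_pair("TNF and asthma again", "TNF", "asthma"),
                make_pair("EGFR causes glioma", "EGFR", "glioma"))
  idx <- build_pair_index(pairs)
  f <- extract_concept(pairs[[1]], idx)
  expect_equal(f[["CONCEPT:pair_occurrence"]], 3)  # case-insensitive key
  expect_equal(extract_concept(pairs[[4]], idx)[["CONCEPT:pair_occurrence"]], 1)
})

test_that("context features: local triples, trigrams, topic flag, code", {
  p <- make_pair("GENEX alpha beta gamma delta dcancer", "GENEX", "dcancer",
                 sentence_index = 0L, relation_code = "FI")
  lay <- annotate(p$sentence$tokens)
  f <- extract_context(p, lay, lex = lex)
  # 4 non-stop between tokens -> exactly 2 trigrams
  expect_length(grep("^CONTEXT_GLOBAL:trigram:", names(f)), 2)
  expect_true(isTRUE(f[["CONTEXT_GLOBAL:topic_sentence"]]))
  expect_equal(f[["CONTEXT_GLOBAL:relation_code"]], "FI")
  # entity at sentence start: no left-local features for the gene, no padding
  expect_length(grep("^CONTEXT_LOCAL:gene:L", names(f)), 0)
  expect_length(grep("^CONTEXT_LOCAL:gene:R", names(f)), 2)
  expect_match(f[["CONTEXT_LOCAL:gene:R1"]], "\\|")  # pos|lemma|chunk triple

  p2 <- make_pair("GENEX alpha beta gamma delta dcancer", "GENEX", "dcancer",
                  sentence_index = 3L)
  f2 <- extract_context(p2, lay, lex = lex)
  expect_false(isTRUE(f2[["CONTEXT_GLOBAL:topic_sentence"]]))
  expect_null(f2[["CONTEXT_GLOBAL:relation_code"]])
})

test_that("pattern flags fire on lexicon families in and around the span", {
  p <- make_pair(sentence_assoc, "CHI3L1", "atopy")
  f <- extract_patterns(p, blind_entities(p), lex)
  expect_true(f[["PATTERN:action_verb"]])
  expect_equal(f[["PATTERN:action_verb_phrase"]], "associated with")

  # no lexicon hit -> all flags false
  q <- make_pair("GENEX alpha beta dcancer", "GENEX", "dcancer")
  fq <- extract_patterns(q, blind_entities(q), lex)
  expect_false(any(unlist(fq[c("PATTERN:trigger", "PATTERN:action_verb",
                               "PATTERN:genetic_phenomenon",
                               "PATTERN:context_specific")])))

  # multi-token phrase split across tokens still matches
  r <- make_pair("GENEX showed altered expression near dcancer",
                 "GENEX", "dcancer")
  fr <- extract_patterns(r, blind_entities(r), lex)
  expect_true(fr[["PATTERN:genetic_phenomenon"]])
})

test_that("negation flags cued triggers and leaves plain assertions alone", {
  neg <- make_pair(sentence_negated, "HIF-1alpha", "colorectal carcinoma")
  f <- extract_negation(neg, blind_entities(neg), lex)
  expect_true(f[["NEGATION:flag"]])
  expect_equal(f[["NEGATION:cue"]], "not")

  unl <- make_pair(sentence_unlikely, "p53", "endometriosis")
  fu <- extract_negation(unl, blind_entities(unl), lex)
  expect_true(fu[["NEGATION:flag"]])
  expect_equal(fu[["NEGATION:cue"]], "unlikely")

  pos <- make_pair(sentence_assoc, "CHI3L1", "atopy")
  fp <- extract_negation(pos, blind_entities(pos), lex)
  expect_false(fp[["NEGATION:flag"]])
})

test_that("inserting a negation cue before a matched trigger flips the flag", {
  base <- "GENEX is %sassociated with dcancer here"
  plain <- make_pair(sprintf(base, ""), "GENEX", "dcancer")
  cued <- make_pair(sprintf(base, "not "), "GENEX", "dcancer")
  expect_false(extract_negation(plain, blind_entities(plain),
                                lex)[["NEGATION:flag"]])
  expect_true(extract_negation(cued, blind_entities(cued),
                               lex)[["NEGATION:flag"]])
})

test_that("the full bundle is deterministic and lexicon-order invariant", {
  p <- make_pair(sentence_assoc, "CHI3L1", "atopy")
  idx <- build_pair_index(list(p))
  b1 <- extract_all(p, corpus_index = idx)
  b2 <- extract_all(p, corpus_index = idx)
  expect_identical(b1, b2)
  expect_equal(b1[["WINDOW:RELW"]], "risk")  # leftmost relational keyword between entities
  expect_equal(b1[["CONCEPT:order"]], "GENE_DISEASE")

  shuffled <- lex
  withr::with_seed(2, for (f in names(shuffled))
    shuffled[[f]] <- sample(shuffled[[f]]))
  b3 <- extract_all(p, lex = shuffled, corpus_index = idx)
  expect_identical(b1[sort(names(b1))], b3[sort(names(b3))])
})

test_that("tokens outside all windows never change the bundle", {
  t1 <- paste("filler one two three four five GENEX is associated with",
              "dcancer six seven eight nine ten alpha")
  t2 <- sub("^filler", "other", sub("alpha$", "omega", t1))
  p1 <- make_pair(t1, "GENEX", "dcancer")
  p2 <- make_pair(t2, "GENEX", "dcancer")
  b1 <- extract_all(p1); b2 <- extract_all(p2)
  expect_identical(b1, b2)
})
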