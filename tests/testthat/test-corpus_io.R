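test_that("GAD-style reader maps labels and completes offsets by dictionary", {
  pairs <- read_corpus(fixture_path("gad_mini.tsv"), "GAD")
  expect_length(pairs, 4)
  expect_equal(vapply(pairs, `[[`, integer(1), "label"),
               c(1L, -1L, 1L, NA_integer_))
  # offsets are located in the sentence text and are 0-based half-open
  p <- pairs[[1]]
  expect_identical(p$gene$surface, "TNF")
  expect_identical(substr(p$sentence$text, p$gene$char_start + 1,
                          p$gene$char_end), "TNF")
  # multiword disease located case-insensitively at token boundaries
  expect_identical(pairs[[3]]$disease$surface, "exfoliation glaucoma")
  expect_identical(pairs[[3]]$sentence$source_corpus, "GAD")
})

test_that("GAD reader accepts a configurable column map", {
  # same records with sentence first
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rows <- readLines(fixture_path("gad_mini.tsv"))
  writeLines(vapply(rows, function(r) {
    f <- strsplit(r, "\t")[[1]]
    paste(c(f[4], f[1:3]), collapse = "\t")
  }, character(1), USE.NAMES = FALSE), tmp)
  pairs <- read_corpus(tmp, "GAD",
                       col_map = c(sentence = 1L, label = 2L, gene = 3L,
                                   disease = 4L))
  expect_length(pairs, 4)
  expect_identical(pairs[[1]]$gene$surface, "TNF")
})

test_that("EU-ADR-style reader converts 1-based inclusive offsets", {
  pairs <- read_corpus(fixture_path("euadr_mini.tsv"), "EUADR")
  expect_length(pairs, 3)
  p <- pairs[[1]]
  expect_equal(p$gene$char_start, 0L)
  expect_equal(p$gene$char_end, 5L)
  expect_identical(p$gene$surface, "LOXL1")
  expect_identical(p$sentence$relation_code, "I")
  expect_equal(vapply(pairs, `[[`, integer(1), "label"),
               c(1L, -1L, NA_integer_))    # PA / NA / SA (speculative)
  expect_identical(pairs[[2]]$disease$surface, "ovarian cancer")
  expect_equal(pairs[[2]]$sentence$sentence_index, 1L)
})

test_that("CoMAGC-style reader maps annotation classes to labels", {
  pairs <- read_corpus(fixture_path("comagc_mini.xml"), "COMAGC")
  expect_length(pairs, 3)
  expect_equal(vapply(pairs, `[[`, integer(1), "label"), c(1L, -1L, 1L))
  expect_identical(pairs[[3]]$gene$surface, "RB1")
  # the class -> label mapping is overridable configuration
  flipped <- read_corpus(fixture_path("comagc_mini.xml"), "COMAGC",
                         comagc_positive = "none")
  expect_equal(vapply(flipped, `[[`, integer(1), "label"), c(-1L, 1L, -1L))
})

test_that("PolySearch-style reader maps relevance codes", {
  pairs <- read_corpus(fixture_path("polysearch_mini.tsv"), "POLYSEARCH")
  expect_equal(vapply(pairs, `[[`, integer(1), "label"), c(1L, -1L, 1L))
  expect_identical(pairs[[1]]$disease$surface,
                   "amyotrophic lateral sclerosis")
})

test_that("empty files yield empty corpora for every dialect", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  file.create(tmp)
  for (d in c("GAD", "EUADR", "COMAGC", "POLYSEARCH", "INTERCHANGE"))
    expect_length(read_corpus(tmp, d), 0)
})

test_that("malformed records and unknown dialects raise informative errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Y\tTNF\tasthma", tmp)       # missing the sentence column
  expect_error(read_corpus(tmp, "GAD"), "line 1")
  writeLines("Y\tTNF\tasthma\tno such entities here", tmp)
  expect_error(read_corpus(tmp, "GAD"), "gene")
  expect_error(read_corpus(tmp, "KLINGON"), "dialect")
  expect_error(read_corpus("/nonexistent/file.tsv", "GAD"), "not found")
})

test_that("interchange writing inverts reading field by field", {
  pairs <- c(
    list(make_pair("ABC1 is associated with gastric carcinoma", "ABC1",
                   "gastric carcinoma", 1L, relation_code = "IA"),
         make_pair("XYZ9 and renal fibrosis were studied", "XYZ9",
                   "renal fibrosis", -1L, sentence_index = 2L),
         make_pair("QRS2 may relate to cardiac atrophy", "QRS2",
                   "cardiac atrophy", NA_integer_)))
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  expect_equal(write_interchange(pairs, tmp), 3)
  back <- read_corpus(tmp, "INTERCHANGE")
  expect_length(back, 3)
  for (i in seq_along(pairs)) {
    expect_identical(back[[i]]$sentence$text, pairs[[i]]$sentence$text)
    expect_identical(back[[i]]$sentence$sentence_index,
                     pairs[[i]]$sentence$sentence_index)
    expect_identical(back[[i]]$sentence$relation_code,
                     pairs[[i]]$sentence$relation_code)
    expect_identical(back[[i]]$gene[c("char_start", "char_end", "surface")],
                     pairs[[i]]$gene[c("char_start", "char_end", "surface")])
    expect_identical(back[[i]]$disease$token_start,
                     pairs[[i]]$disease$token_start)
    expect_identical(back[[i]]$label, pairs[[i]]$label)  # NA survives as null
  }
  # writing zero pairs produces a valid empty file
  expect_equal(write_interchange(list(), tmp), 0)
  expect_length(read_corpus(tmp, "INTERCHANGE"), 0)
})

test_that("corpus statistics count entities case-insensitively", {
  expect_equal(corpus_stats(list())$n_pairs, 0)
  expect_equal(corpus_stats(list())$n_unique_genes, 0)
  texts <- c("TNF is associated with asthma",
             "Tnf is associated with sepsis",
             "tnf is associated with glioma",
             "TNF is associated with atopy")
  pairs <- Map(function(t, d) make_pair(t, strsplit(t, " ")[[1]][1], d, 1L),
               texts, c("asthma", "sepsis", "glioma", "atopy"))
  st <- corpus_stats(pairs)
  expect_equal(st$n_unique_genes, 1)
  expect_equal(st$n_unique_diseases, 4)
  expect_equal(st$n_positive + st$n_negative, st$n_pairs)
  # permutation invariance
  st2 <- corpus_stats(rev(pairs))
  expect_equal(st2[c("n_pairs", "n_positive", "n_unique_genes")],
               st[c("n_pairs", "n_positive", "n_unique_genes")])
})

# independent oracle: enumerate every token span, test substring equality,
# then greedily keep leftmost-longest non-overlapping matches
brute_force_tag <- function(text, lexicon) {
  toks <- tokenize(text)
  hits <- list()
  for (i in seq_len(nrow(toks))) for (j in i:nrow(toks)) {
    sub <- substr(text, toks$start[i] + 1, toks$end[j])
    if (tolower(sub) %in% tolower(lexicon))
      hits[[length(hits) + 1]] <- c(i, j)
  }
  sel <- list(); used_until <- 0
  for (i in seq_len(nrow(toks))) {
    if (i <= used_until) next
    cand <- Filter(function(h) h[1] == i, hits)
    if (!length(cand)) next
    best <- cand[[which.max(vapply(cand, function(h) h[2], numeric(1)))]]
    sel[[length(sel) + 1]] <- c(toks$start[best[1]], toks$end[best[2]])
    used_until <- best[2]
  }
  sel
}

test_that("dictionary tagging is longest-match-first at token boundaries", {
  m <- dictionary_tag("LOXL1 causes glaucoma", "LOXL1", "GENE")
  expect_length(m, 1)
  expect_equal(c(m[[1]]$char_start, m[[1]]$char_end), c(0, 5))
  # longest entry wins over its substring
  m <- dictionary_tag("breast cancer risk", c("breast cancer", "cancer"),
                      "DISEASE")
  expect_length(m, 1)
  expect_identical(m[[1]]$surface, "breast cancer")
  # no match inside a longer token
  expect_length(dictionary_tag("TNFA is here", "TNF", "GENE"), 0)
  expect_error(dictionary_tag("text", character(0), "GENE"), "empty lexicon")
})

test_that("dictionary tagging matches an exhaustive substring oracle", {
  lexicon <- c("gastric carcinoma", "carcinoma", "tnf receptor")
  words <- c("tnf", "receptor", "gastric", "carcinoma", "binds", "the",
             "levels", "of", "protein")
  withr::with_seed(42, {
    for (rep in 1:10) {
      text <- paste(sample(words, 50, replace = TRUE), collapse = " ")
      got <- dictionary_tag(text, lexicon, "DISEASE")
      want <- brute_force_tag(text, lexicon)
      expect_equal(lapply(got, function(m) c(m$char_start, m$char_end)), want)
    }
  })
})
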