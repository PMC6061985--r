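hand_model <- function(words, vectors) {
  M <- do.call(rbind, vectors)
  rownames(M) <- words
  structure(list(vocab = data.frame(word = words, count = 1L),
                 input = M, output = M * 0,
                 cfg = skipgram_config(dim = ncol(M))),
            class = "embedding_model")
}

test_that("vocabulary counts match a brute-force counter", {
  withr::with_seed(13, {
    corpus <- lapply(1:100, function(i)
      sample(letters[1:12], sample(3:9, 1), replace = TRUE))
  })
  v <- build_vocab(corpus, min_count = 1)
  counts <- table(unlist(corpus))
  expect_equal(nrow(v), length(counts))
  for (i in seq_len(nrow(v)))
    expect_equal(v$count[i], unname(as.integer(counts[v$word[i]])))
  # descending frequency, lexicographic ties
  expect_true(all(diff(v$count) <= 0))
  ties <- split(v$word, v$count)
  for (grp in ties) expect_equal(grp, sort(grp, method = "radix"))
})

test_that("vocabulary filtering and normalisation behave", {
  expect_equal(build_vocab(list(c("a", "a", "b")), min_count = 2)$word, "a")
  expect_equal(nrow(build_vocab(list(c("x", "y", "x")), min_count = 1)), 2)
  expect_error(build_vocab(list(c("a", "b")), min_count = 5), "filtered")
  # edge punctuation is stripped so "cancer," does not become a new word
  v <- build_vocab(list(c("cancer,", "Cancer", "cancer;")))
  expect_equal(v$word, "cancer")
  expect_equal(v$count, 3L)
})

test_that("subsampling discard probability follows max(0, 1 - sqrt(t/f))", {
  expect_equal(subsample_discard_prob(1e-5, 1e-5), 0)
  expect_equal(subsample_discard_prob(0.5, 1e-5), 1 - sqrt(2e-5),
               tolerance = 1e-12)
  expect_equal(round(subsample_discard_prob(0.5, 1e-5), 5), 0.99553)
  expect_equal(subsample_discard_prob(1e-7, 1e-5), 0)   # rarer than t: clamped
  expect_error(subsample_discard_prob(0, 1e-5), "fraction")
  expect_error(subsample_discard_prob(0.5, -1), "positive")
})

test_that("the full-softmax objective matches hand arithmetic", {
  # single-word vocabulary: p = 1 everywhere, objective 0
  m1 <- hand_model("a", list(c(1, 0)))
  m1$output <- matrix(c(2, 1), 1, 2, dimnames = list("a", NULL))
  expect_equal(skipgram_objective(m1, list(c("a", "a", "a")), window = 1), 0)

  # two 1-dim words with hand-set vectors; corpus "a b"
  m2 <- structure(list(vocab = data.frame(word = c("a", "b"), count = 1L),
                       input = matrix(c(1, -1), 2, 1,
                                      dimnames = list(c("a", "b"), NULL)),
                       output = matrix(c(0.5, -0.5), 2, 1,
                                       dimnames = list(c("a", "b"), NULL)),
                       cfg = skipgram_config(dim = 1)),
                  class = "embedding_model")
  # log p(b|a) = log p(a|b) = log( e^-0.5 / (e^0.5 + e^-0.5) )
  hand <- log(exp(-0.5) / (exp(0.5) + exp(-0.5)))
  expect_equal(skipgram_objective(m2, list(c("a", "b")), window = 1), hand,
               tolerance = 1e-12)
  # doubling the corpus by repetition leaves the average unchanged
  expect_equal(skipgram_objective(m2, list(c("a", "b"), c("a", "b")),
                                  window = 1), hand, tolerance = 1e-12)
  expect_error(skipgram_objective(m2, list(c("a", "zzz"))), "zzz")
})

test_that("training is bit-reproducible and epochs=0 returns initialisation", {
  corpus <- two_cluster_corpus(40, 5, seed = 3)
  cfg <- tiny_sg_config()
  m1 <- train_skipgram(corpus, cfg)
  m2 <- train_skipgram(corpus, cfg)
  expect_identical(m1$input, m2$input)
  expect_identical(m1$output, m2$output)

  cfg0 <- tiny_sg_config(epochs = 0L, negative = 0L)
  init <- train_skipgram(corpus, cfg0)
  expect_true(all(init$output == 0))                  # untouched output layer
  expect_true(all(abs(init$input) <= 0.5 / cfg0$dim)) # uniform init range
  expect_identical(init$input, train_skipgram(corpus, cfg0)$input)
})

test_that("skip-gram separates the two-cluster corpus", {
  corpus <- two_cluster_corpus(seed = 7)
  cfg <- skipgram_config(dim = 16, window = 3, epochs = 15, subsample = 1,
                         seed = 7, threads = 1)
  model <- train_skipgram(corpus, cfg)
  g <- c("g1", "g2", "g3"); d <- c("d1", "d2", "d3")
  within <- mean(c(cosine(model, "g1", "g2"), cosine(model, "g1", "g3"),
                   cosine(model, "g2", "g3"), cosine(model, "d1", "d2"),
                   cosine(model, "d1", "d3"), cosine(model, "d2", "d3")))
  between <- mean(outer(g, d, Vectorize(function(a, b) cosine(model, a, b))))
  expect_gt(within, between)
  # the surrogate-optimised objective improves over the initialisation
  init <- train_skipgram(corpus, skipgram_config(dim = 16, window = 3,
                                                 epochs = 0, subsample = 1,
                                                 seed = 7))
  expect_gt(skipgram_objective(model, corpus, window = 3),
            skipgram_objective(init, corpus, window = 3))
})

test_that("cosine similarity is exact on hand-set vectors", {
  m <- hand_model(c("u", "v", "w"),
                  list(c(1, 0), c(1, 1), c(-2, 0)))
  expect_equal(cosine(m, "u", "u"), 1)
  expect_equal(cosine(m, "u", "v"), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(cosine(m, "u", "v"), 5), 0.70711)
  expect_equal(cosine(m, "u", "w"), -1)
  expect_equal(cosine(m, "u", "v"), cosine(m, "v", "u"))     # symmetry
  m2 <- m; m2$input <- m$input * 37                          # scale invariance
  expect_equal(cosine(m2, "u", "v"), cosine(m, "u", "v"))
  expect_error(cosine(m, "u", "nope"), "nope")
})

test_that("nearest neighbours equal a brute-force scan", {
  withr::with_seed(11, {
    V <- 30
    M <- matrix(rnorm(V * 5), V, 5)
  })
  words <- sprintf("w%02d", seq_len(30))
  m <- hand_model(words, lapply(seq_len(30), function(i) M[i, ]))
  nn <- nearest_neighbors(m, "w01", k = 10)
  # oracle: compute every cosine directly and sort
  sims <- vapply(words[-1], function(w) cosine(m, "w01", w), numeric(1))
  ord <- order(-sims, names(sims))
  expect_equal(nn$word, names(sims)[ord][1:10])
  expect_equal(nn$cosine, unname(sims[ord][1:10]), tolerance = 1e-12)
  expect_true(all(diff(nn$cosine) <= 0))
  # k >= V - 1 returns everything except the query
  expect_equal(nrow(nearest_neighbors(m, "w01", k = 100)), 29)
  expect_error(nearest_neighbors(m, "absent", 3), "absent")
})

test_that("word-vector text format round-trips losslessly", {
  model <- train_skipgram(two_cluster_corpus(30, 4, seed = 2),
                          tiny_sg_config())
  tmp <- withr::local_tempfile(fileext = ".vec")
  write_word_vectors(model, tmp)
  hdr <- strsplit(readLines(tmp, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(nrow(model$input), ncol(model$input)))
  back <- read_word_vectors(tmp)
  expect_identical(rownames(back$input), rownames(model$input))
  expect_equal(unname(back$input), unname(model$input), tolerance = 0)
})
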