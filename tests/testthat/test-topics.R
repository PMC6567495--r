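test_that("corpus construction assigns ids in first-appearance order", {
  corpus <- build_corpus(list(c("a", "b", "a")))
  expect_equal(corpus$vocabulary, c("a", "b"))
  expect_equal(corpus$docs[[1]]$ids, c(1L, 2L))
  expect_equal(corpus$docs[[1]]$counts, c(2L, 1L))
  expect_equal(corpus$n_tokens, 3L)

  disjoint <- build_corpus(list(c("a", "b"), c("c", "d", "c")))
  expect_length(disjoint$vocabulary, 4L)

  expect_warning(two <- build_corpus(list(d1 = c("a"), d2 = character(0))),
                 "empty")
  expect_equal(two$doc_ids, "d1")
  expect_error(suppressWarnings(build_corpus(list(character(0)))), "empty")
})

test_that("a study-sized synthetic corpus builds quickly", {
  gen <- generate_corpus(corpus_config(n_topics = 15L, vocab_size = 1200L,
                                       n_docs = 28L,
                                       mean_doc_length = 1900,
                                       seed = 4L))
  dir <- withr::local_tempdir()
  write_transcripts(gen$corpus, dir)
  elapsed <- system.time({
    corpus <- build_corpus(read_transcripts(dir,
                                            preprocess_config(stem = FALSE)))
  })[["elapsed"]]
  expect_lt(elapsed, 5)
  expect_equal(length(corpus$docs), 28L)
})

test_that("single-topic LDA recovers smoothed corpus frequencies", {
  corpus <- build_corpus(list(c("a", "a", "b"), c("b", "c")))
  cfg <- lda_config(1L, alpha = 1, beta = 0.5, n_iter = 10L,
                    burn_in = 5L, seed = 1L)
  model <- fit_lda(corpus, cfg)
  counts <- c(a = 2, b = 2, c = 1)
  expect_equal(model$phi[1L, ], (counts + 0.5) / (5 + 3 * 0.5))
  expect_equal(unname(model$theta[, 1L]), c(1, 1))
})

test_that("fitted probability matrices are normalised and reproducible", {
  gen <- generate_corpus(corpus_config(n_topics = 3L, vocab_size = 60L,
                                       n_docs = 30L, mean_doc_length = 40,
                                       seed = 6L))
  cfg <- lda_config(3L, alpha = 0.1, beta = 0.01, n_iter = 60L,
                    burn_in = 30L, seed = 2L)
  m1 <- fit_lda(gen$corpus, cfg)
  m2 <- fit_lda(gen$corpus, cfg)
  expect_identical(m1$phi, m2$phi)
  expect_equal(unname(rowSums(m1$phi)), rep(1, 3L), tolerance = 1e-9)
  expect_equal(unname(rowSums(m1$theta)), rep(1, 30L), tolerance = 1e-9)
  expect_true(all(m1$phi >= 0) && all(m1$theta >= 0))
  expect_error(fit_lda(gen$corpus, lda_config(10000L)), "more topics")
})

test_that("training likelihood improves over the Gibbs run", {
  improved <- vapply(1:3, function(s) {
    gen <- generate_corpus(corpus_config(n_topics = 4L, vocab_size = 80L,
                                         n_docs = 40L,
                                         mean_doc_length = 60,
                                         seed = 30L + s))
    model <- fit_lda(gen$corpus,
                     lda_config(4L, alpha = 0.1, beta = 0.01,
                                n_iter = 80L, burn_in = 40L, seed = s))
    model$loglik[80L] > model$loglik[1L]
  }, TRUE)
  expect_gte(sum(improved), 2L)
})

test_that("perplexity of a uniform model equals the vocabulary size", {
  V <- 50L
  vocab <- sprintf("w%02d", seq_len(V))
  uniform <- structure(
    list(phi = matrix(1 / V, 1L, V, dimnames = list(NULL, vocab)),
         vocabulary = vocab, doc_ids = "m",
         config = list(alpha = 1)),
    class = "topic_model")
  heldout <- build_corpus(list(c("w01", "w02", "w03", "w01")))
  expect_equal(perplexity(uniform, heldout), V)
  expect_equal(perplexity(uniform, heldout, method = "fold-in"), V)
})

test_that("perplexity is invariant to duplicating a held-out document", {
  gen <- generate_corpus(corpus_config(n_topics = 3L, vocab_size = 50L,
                                       n_docs = 20L, mean_doc_length = 40,
                                       seed = 12L))
  model <- fit_lda(gen$corpus,
                   lda_config(3L, alpha = 0.1, beta = 0.01, n_iter = 60L,
                              burn_in = 30L, seed = 1L))
  doc_tokens <- rep(gen$corpus$vocabulary[gen$corpus$docs[[1]]$ids],
                    gen$corpus$docs[[1]]$counts)
  once <- build_corpus(list(d = doc_tokens))
  twice <- build_corpus(list(d1 = doc_tokens, d2 = doc_tokens))
  expect_equal(perplexity(model, twice, seed = 4L),
               perplexity(model, once, seed = 4L), tolerance = 0.05)

  # out-of-vocabulary tokens are dropped with a message
  oov <- build_corpus(list(c(doc_tokens[1:5], "zzzqqq")))
  expect_message(perplexity(model, oov, seed = 1L), "out-of-vocabulary")
})

test_that("topic-number selection is deterministic with sane edges", {
  gen <- generate_corpus(corpus_config(n_topics = 2L, vocab_size = 40L,
                                       n_docs = 30L, mean_doc_length = 30,
                                       seed = 3L))
  one <- select_num_topics(gen$corpus, candidates = 1L, seed = 1L,
                           n_iter = 30L, burn_in = 10L)
  expect_equal(one$best_T, 1L)

  grid <- c(2L, 4L)
  a <- select_num_topics(gen$corpus, candidates = grid, seed = 9L,
                         alpha = 0.1, n_iter = 40L, burn_in = 20L)
  b <- select_num_topics(gen$corpus, candidates = grid, seed = 9L,
                         alpha = 0.1, n_iter = 40L, burn_in = 20L)
  expect_identical(a$curve, b$curve)
  expect_true(a$best_T %in% grid)
  expect_error(select_num_topics(gen$corpus, candidates = grid,
                                 holdout_fraction = 0.999), "no documents")
})

test_that("top words are ranked with alphabetical tie-break", {
  vocab <- c("beta", "alpha", "gamma")
  model <- structure(
    list(phi = matrix(c(0.25, 0.25, 0.5), 1L, 3L,
                      dimnames = list(NULL, vocab)),
         vocabulary = vocab, doc_ids = "d",
         config = list(alpha = 1)),
    class = "topic_model")
  tw <- top_words(model, 1L, 3L)
  expect_equal(tw$word, c("gamma", "alpha", "beta"))
  expect_true(all(diff(tw$probability) <= 0))
  expect_error(top_words(model, 2L), "topic")
  expect_error(top_words(model, 1L, 0L), "k")
})

test_that("topic outputs are written as JSON and CSV", {
  gen <- generate_corpus(corpus_config(n_topics = 2L, vocab_size = 30L,
                                       n_docs = 10L, mean_doc_length = 30,
                                       seed = 5L))
  model <- fit_lda(gen$corpus,
                   lda_config(2L, alpha = 0.1, beta = 0.01, n_iter = 30L,
                              burn_in = 10L, seed = 1L))
  curve <- select_num_topics(gen$corpus, candidates = c(2L, 3L), seed = 1L,
                             n_iter = 30L, burn_in = 10L)
  dir <- withr::local_tempdir()
  write_topic_outputs(model, dir, curve = curve, corpus = gen$corpus)
  expect_true(all(file.exists(file.path(
    dir, c("topics.json", "perplexity.csv", "word_frequencies.csv")))))
  parsed <- jsonlite::read_json(file.path(dir, "topics.json"))
  expect_equal(parsed$n_topics, 2L)
  expect_length(parsed$top_words, 2L)
  freq <- read.csv(file.path(dir, "word_frequencies.csv"))
  expect_equal(sum(freq$count), gen$corpus$n_tokens)
})
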