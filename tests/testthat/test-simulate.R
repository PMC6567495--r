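test_that("degenerate mixture weights give the expected chains", {
  all_stay <- generate_interaction_sequence(
    interaction_config(length = 20L, stability = 1,
                       determinism_strength = 0, seed = 3L),
    alphabet = c("A", "B", "C"))
  expect_equal(all_stay$symbols, rep(all_stay$symbols[1], 20L))

  cyclic <- generate_interaction_sequence(
    interaction_config(length = 9L, stability = 0,
                       determinism_strength = 1, seed = 3L),
    alphabet = c("A", "B", "C"))
  # pure successor map: period-3 cycle from the first symbol
  expect_equal(cyclic$symbols[4:9], cyclic$symbols[1:6])
  expect_equal(length(unique(cyclic$symbols)), 3L)
})

test_that("sequence generation is seed-deterministic and alphabet-closed", {
  cfg <- interaction_config(n_members = 4L, length = 80L, seed = 17L)
  a <- generate_interaction_sequence(cfg)
  b <- generate_interaction_sequence(cfg)
  expect_identical(a, b)
  expect_true(all(a$symbols %in% dyad_alphabet(4L)))
  expect_length(a$symbols, 80L)

  expect_error(generate_interaction_sequence(cfg, alphabet = character(0)),
               "non-empty")
  expect_error(interaction_config(stability = 0.7,
                                  determinism_strength = 0.5), "<= 1")
  expect_error(interaction_config(stability = -0.1), "\\[0, 1\\]")
  expect_error(interaction_config(length = 0), "length")
})

test_that("recurrence rate increases with the stability weight", {
  mean_rr <- function(stab) {
    mean(vapply(1:10, function(s) {
      seq <- generate_interaction_sequence(
        interaction_config(n_members = 4L, length = 500L,
                           stability = stab,
                           determinism_strength = 0.1, seed = s),
        group_id = "g")
      recurrence_rate(recurrence_matrix(seq))
    }, 0))
  }
  expect_gt(mean_rr(0.6), mean_rr(0.1))
})

test_that("study generation is deterministic with valid Likert output", {
  cfg <- study_config(n_groups = 6L, seed = 5L)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)

  expect_true(all(a$responses$value %in% 1:7))
  expect_true(all(vapply(a$sequences, function(s) {
    all(s$symbols %in% s$alphabet)
  }, TRUE)))
  expect_equal(nrow(a$groups), 6L)
  expect_true(all(a$groups$n_events >= 10L))
  # every participant answers both scales completely
  per_part <- table(a$responses$participant)
  expect_true(all(per_part == 2L * cfg$items_per_scale))
})

test_that("noise-free items are identical and give Cronbach's alpha 1", {
  # a large recurrence effect keeps cross-participant variance after
  # rounding, so alpha is defined (its precondition)
  st <- generate_study(study_config(
    n_groups = 6L, noise_sd_group = 0, noise_sd_individual = 0,
    noise_sd_item = 0, beta_support_rr = 0.1, seed = 8L))
  m <- item_matrix(st$responses, "social_support")
  expect_true(all(m == m[, 1L]))
  expect_equal(cronbach_alpha(m), 1)
})

test_that("study writer round-trips through the ingestion formats", {
  st <- generate_study(study_config(n_groups = 3L, seed = 21L))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  files <- list.files(file.path(dir, "events"), full.names = TRUE)
  expect_length(files, 3L)
  ev <- read_event_log(files[1])
  enc <- encode_sequence(ev, st$groups$n_members[1])
  expect_equal(enc$symbols, st$sequences[[1]]$symbols)
  q <- read.csv(file.path(dir, "questionnaire.csv"))
  expect_equal(nrow(q), nrow(st$responses))
})

test_that("synthetic corpora have normalised truth and valid tokens", {
  cfg <- corpus_config(n_topics = 3L, vocab_size = 40L, n_docs = 15L,
                       mean_doc_length = 30, seed = 2L)
  gen <- generate_corpus(cfg)
  expect_equal(rowSums(gen$phi), rep(1, 3L), tolerance = 1e-12)
  expect_equal(rowSums(gen$theta), rep(1, 15L), tolerance = 1e-12)
  expect_length(gen$corpus$vocabulary, 40L)
  expect_identical(generate_corpus(cfg), gen)

  single <- generate_corpus(corpus_config(n_topics = 1L, vocab_size = 10L,
                                          n_docs = 4L,
                                          mean_doc_length = 20, seed = 1L))
  expect_equal(single$theta, matrix(1, 4L, 1L))

  expect_error(corpus_config(n_topics = 5L, vocab_size = 5L), "exceed")
  expect_error(corpus_config(alpha = 0), "positive")
})

test_that("transcript writer emits readable alphabetic pseudo-words", {
  gen <- generate_corpus(corpus_config(n_topics = 2L, vocab_size = 30L,
                                       n_docs = 4L, mean_doc_length = 50,
                                       seed = 9L))
  dir <- withr::local_tempdir()
  write_transcripts(gen$corpus, dir)
  expect_length(list.files(dir, pattern = "\\.txt$"), 4L)
  tokens <- read_transcripts(dir, preprocess_config(stem = FALSE))
  expect_true(all(grepl("^[a-z]+$", unlist(tokens))))
  # pseudo-words are 4+ characters, so none are lost to length filters
  expect_equal(sum(lengths(tokens)), gen$corpus$n_tokens)
})
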