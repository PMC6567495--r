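#!/usr/bin/env Rscript

# Stage 3: topic modelling of the transcripts.
#
# Preprocesses the group transcripts (lowercase, punctuation and digit
# stripping, stop-word removal, 3-14 character length filter, Porter
# stemming), fits LDA by collapsed Gibbs sampling over a grid of topic
# counts, selects the number of topics by held-out perplexity on a 10%
# document partition, and reports the top stems of the chosen model.
#
# Problem sizes: 28 documents, ~50k tokens; grid 5-30 topics; 400
# Gibbs sweeps per candidate with hyperparameters matched to the
# generator (alpha 0.1, beta 0.01).

suppressPackageStartupMessages(library(teamdyn))

data_dir <- file.path("scratch", "study")
if (!dir.exists(file.path(data_dir, "transcripts"))) {
  stop("run analysis/01_simulate.R first")
}

seed <- 20260903L
tokens <- read_transcripts(file.path(data_dir, "transcripts"))
corpus <- build_corpus(tokens)
print(corpus)

curve <- select_num_topics(
  corpus, candidates = c(5L, 10L, 15L, 20L, 25L, 30L),
  holdout_fraction = 0.1, seed = seed, alpha = 0.1, beta = 0.01,
  n_iter = 400L, burn_in = 200L)
print(curve)

model <- fit_lda(corpus, lda_config(curve$best_T, alpha = 0.1,
                                    beta = 0.01, n_iter = 400L,
                                    burn_in = 200L, seed = seed))
write_topic_outputs(model, "results", curve = curve, corpus = corpus)
file.rename("results/topics.json", "results/03_topics.json")
file.rename("results/perplexity.csv", "results/03_perplexity.csv")
file.rename("results/word_frequencies.csv",
            "results/03_word_frequencies.csv")

cat("\nTop stems of the first four topics:\n")
for (t in seq_len(min(4L, curve$best_T))) {
  tw <- top_words(model, t, 5L)
  cat(sprintf("  topic %d: %s\n", t,
              paste(sprintf("%s (%.3f)", tw$word, tw$probability),
                    collapse = ", ")))
}
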