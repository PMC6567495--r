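#!/usr/bin/env Rscript

# Stage 1: simulate the study.
#
# Generates the synthetic analogue of the study design -- 28 teams of
# 3-5 members, ~157 (SD 67) coded dyadic interactions per 30-minute
# session, two 7-point Likert subscales, and one transcript per team
# totalling ~53k words -- and writes it through the same CSV/text
# formats real coded data would arrive in. Raw data land in scratch/
# (regenerable); the summary table in results/.

suppressPackageStartupMessages(library(teamdyn))

seed <- 20260901L
data_dir <- file.path("scratch", "study")
dir.create("results", showWarnings = FALSE)

study <- generate_study(study_config(seed = seed))
write_study(study, data_dir)

corpus_truth <- generate_corpus(corpus_config(
  n_topics = 15L, vocab_size = 1200L, n_docs = nrow(study$groups),
  mean_doc_length = 1900, alpha = 0.1, beta = 0.01, seed = seed + 1L))
write_transcripts(corpus_truth$corpus, file.path(data_dir, "transcripts"))
saveRDS(corpus_truth[c("phi", "theta")],
        file.path(data_dir, "corpus_truth.rds"))

summary_tab <- data.frame(
  quantity = c("groups", "participants", "events_mean", "events_sd",
               "rr_mean", "rr_sd", "det_mean", "det_sd", "ent_mean",
               "transcript_words"),
  value = round(c(
    nrow(study$groups),
    length(unique(study$responses$participant)),
    mean(study$groups$n_events), sd(study$groups$n_events),
    mean(study$groups$rr), sd(study$groups$rr),
    mean(study$groups$det), sd(study$groups$det),
    mean(study$groups$ent),
    corpus_truth$corpus$n_tokens), 2))
write.csv(summary_tab, "results/01_simulation_summary.csv",
          row.names = FALSE)

cat("Simulated study written to", data_dir, "\n")
print(summary_tab, row.names = FALSE)
cat("\nGround-truth support-model coefficients:\n")
print(study$truth$beta_support)
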