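#' Configuration for one synthetic interaction sequence
#'
#' The generator is a first-order Markov mixture over the symbol
#' alphabet with three components: with probability `stability` the
#' previous symbol is repeated, with probability `determinism_strength`
#' the fixed cyclic successor of the previous symbol (alphabet order) is
#' emitted, and otherwise a symbol is drawn uniformly from the alphabet.
#' The two mixture weights map directly onto the recurrence-rate
#' ("stability") and determinism constructs of recurrence
#' quantification, which keeps recovery tests interpretable.
#'
#' @param n_members Group size the alphabet describes (typically 3--5).
#' @param length Number of events to generate (>= 1).
#' @param stability Probability in \[0, 1\] of repeating the previous
#'   symbol.
#' @param determinism_strength Probability in \[0, 1\] of following the
#'   cyclic successor map. `stability + determinism_strength` must not
#'   exceed 1.
#' @param seed RNG seed.
#' @return An object of class `interaction_config`.
#' @export
interaction_config <- function(n_members = 4L, length = 157L,
                               stability = 0.2,
                               determinism_strength = 0.2,
                               seed = 1L) {
  n_members <- as.integer(n_members)
  length <- as.integer(length)
  if (is.na(n_members) || n_members < 2L) {
    stop("`n_members` must be >= 2", call. = FALSE)
  }
  if (is.na(length) || length < 1L) stop("`length` must be >= 1", call. = FALSE)
  for (p in c(stability, determinism_strength)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      stop("mixture probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (stability + determinism_strength > 1 + 1e-12) {
    stop("`stability` + `determinism_strength` must be <= 1", call. = FALSE)
  }
  structure(
    list(n_members = n_members, length = length, stability = stability,
         determinism_strength = determinism_strength,
         seed = as.integer(seed)),
    class = "interaction_config"
  )
}

#' Generate a synthetic interaction sequence
#'
#' Simulates `config$length` who-interacts-with-whom symbols by the
#' repeat / cycle / uniform Markov mixture described in
#' [interaction_config()]. The first symbol is uniform on the alphabet;
#' identical config and seed give an identical sequence.
#'
#' @param config An [interaction_config()].
#' @param alphabet Non-empty symbol alphabet; defaults to the full dyad
#'   alphabet for `config$n_members`.
#' @param group_id Optional group label.
#' @return A [symbol_sequence()].
#' @export
#' @examples
#' s <- generate_interaction_sequence(interaction_config(length = 50))
#' rqa_measures(s)
generate_interaction_sequence <- function(config,
                                          alphabet = dyad_alphabet(config$n_members),
                                          group_id = NA_character_) {
  stopifnot(inherits(config, "interaction_config"))
  if (length(alphabet) == 0L) stop("alphabet must be non-empty", call. = FALSE)
  alphabet <- as.character(alphabet)
  a <- length(alphabet)
  set.seed(config$seed)
  idx <- integer(config$length)
  idx[1L] <- sample.int(a, 1L)
  if (config$length > 1L) {
    u <- stats::runif(config$length - 1L)
    unif_draw <- sample.int(a, config$length - 1L, replace = TRUE)
    for (t in 2L:config$length) {
      ut <- u[t - 1L]
      idx[t] <- if (ut < config$stability) {
        idx[t - 1L]
      } else if (ut < config$stability + config$determinism_strength) {
        idx[t - 1L] %% a + 1L  # cyclic successor in alphabet order
      } else {
        unif_draw[t - 1L]
      }
    }
  }
  symbol_sequence(alphabet[idx], alphabet, group_id)
}

#' Configuration for a full synthetic study
#'
#' Defines the conditions of a simulated multi-group study: group
#' count and sizes, per-group sequence lengths, the Markov-mixture
#' weights that drive each group's recurrence structure, and the linear
#' model that ties the group-level recurrence measures to the latent
#' "social support" questionnaire outcome. Defaults emulate the target
#' study design: 28 teams of 3--5 members, sequences of on average 157
#' (SD 67) dyadic interactions per 30-minute session, two 7-point Likert
#' subscales with group-level means near 5.68 (participation) and 4.78
#' (support), and support-model coefficients at the published point
#' estimates (0.022 per recurrence-rate point, -0.008 per determinism
#' point).
#'
#' @param n_groups Number of groups (>= 2).
#' @param members_range Inclusive range of group sizes.
#' @param events_mean,events_sd Normal distribution of per-group
#'   sequence lengths, floored at 10 so recurrence measures stay
#'   defined.
#' @param stability_range,determinism_range Uniform ranges from which
#'   each group's Markov-mixture weights are drawn; the variation makes
#'   the recurrence measures informative predictors.
#' @param beta0 Intercept of the latent support model.
#' @param beta_support_rr,beta_support_det Effects of the group's
#'   recurrence rate and determinism (percent scale) on latent support.
#' @param partic_mean Latent mean of the participation subscale (no
#'   recurrence effect is simulated for it).
#' @param noise_sd_group,noise_sd_individual,noise_sd_item Gaussian
#'   noise scales for group, participant and item levels (all >= 0).
#' @param items_per_scale Items per subscale (>= 2).
#' @param seed RNG seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_groups = 28L, members_range = c(3L, 5L),
                         events_mean = 157, events_sd = 67,
                         stability_range = c(0.05, 0.30),
                         determinism_range = c(0.10, 0.40),
                         beta0 = 4.8,
                         beta_support_rr = 0.022,
                         beta_support_det = -0.008,
                         partic_mean = 5.68,
                         noise_sd_group = 0.4,
                         noise_sd_individual = 0.5,
                         noise_sd_item = 0.6,
                         items_per_scale = 5L,
                         seed = 1L) {
  n_groups <- as.integer(n_groups)
  items_per_scale <- as.integer(items_per_scale)
  if (is.na(n_groups) || n_groups < 2L) stop("`n_groups` must be >= 2",
                                             call. = FALSE)
  if (is.na(items_per_scale) || items_per_scale < 2L) {
    stop("`items_per_scale` must be >= 2", call. = FALSE)
  }
  sds <- c(events_sd, noise_sd_group, noise_sd_individual, noise_sd_item)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all standard deviations must be >= 0", call. = FALSE)
  }
  if (members_range[1L] < 2L || members_range[2L] < members_range[1L]) {
    stop("`members_range` must be an increasing range with minimum >= 2",
         call. = FALSE)
  }
  for (r in list(stability_range, determinism_range)) {
    if (r[1L] < 0 || r[2L] > 1 || r[2L] < r[1L]) {
      stop("mixture weight ranges must lie within [0, 1]", call. = FALSE)
    }
  }
  if (stability_range[2L] + determinism_range[2L] > 1) {
    stop("upper ends of stability and determinism ranges must sum to <= 1",
         call. = FALSE)
  }
  structure(
    list(n_groups = n_groups, members_range = as.integer(members_range),
         events_mean = events_mean, events_sd = events_sd,
         stability_range = stability_range,
         determinism_range = determinism_range,
         beta0 = beta0, beta_support_rr = beta_support_rr,
         beta_support_det = beta_support_det, partic_mean = partic_mean,
         noise_sd_group = noise_sd_group,
         noise_sd_individual = noise_sd_individual,
         noise_sd_item = noise_sd_item,
         items_per_scale = items_per_scale, seed = as.integer(seed)),
    class = "study_config"
  )
}

likert_item <- function(latent, sd_item, n) {
  pmin(7L, pmax(1L, as.integer(round(latent + stats::rnorm(n, 0, sd_item)))))
}

#' Generate a synthetic multi-group study with known ground truth
#'
#' Simulates, per group: a member count, a Markov-mixture interaction
#' sequence (length ~ Normal(`events_mean`, `events_sd`) floored at 10),
#' and its recurrence measures; then, per participant, Likert item
#' responses on two subscales. The latent social-support score is
#' `beta0 + beta_support_rr * RR + beta_support_det * DET + group noise
#' + individual noise`; each item adds its own noise before rounding and
#' clamping to the integers 1--7. The participation subscale has latent
#' mean `partic_mean` with the same noise structure and no recurrence
#' effect. All generating parameters and the per-group recurrence
#' measures are returned as ground truth.
#'
#' @param config A [study_config()].
#' @param rqa_config An [rqa_config()] used for the ground-truth
#'   recurrence measures.
#' @return An object of class `study_dataset`: list with `groups` (data
#'   frame: group, n_members, stability, determinism, n_events, rr, det,
#'   ent), `sequences` (named list of [symbol_sequence()]), `responses`
#'   (data frame: participant, group, scale, item, value), and `truth`
#'   (the generating parameters).
#' @export
generate_study <- function(config = study_config(),
                           rqa_config = teamdyn::rqa_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  g <- config$n_groups
  n_members <- sample(seq(config$members_range[1L], config$members_range[2L]),
                      g, replace = TRUE)
  lens <- pmax(10L, as.integer(round(
    stats::rnorm(g, config$events_mean, config$events_sd))))
  stab <- stats::runif(g, config$stability_range[1L],
                       config$stability_range[2L])
  det_w <- stats::runif(g, config$determinism_range[1L],
                        config$determinism_range[2L])
  seq_seeds <- sample.int(.Machine$integer.max, g)

  sequences <- vector("list", g)
  rr <- det <- ent <- numeric(g)
  group_ids <- sprintf("g%02d", seq_len(g))
  for (i in seq_len(g)) {
    # condition on defined recurrence measures: a very short sequence
    # can lack any diagonal line >= lmin, so redraw its seed until all
    # three measures exist (deterministic given the study seed)
    for (attempt in 0:100) {
      cfg <- interaction_config(
        n_members = n_members[i], length = lens[i], stability = stab[i],
        determinism_strength = det_w[i],
        seed = (seq_seeds[i] + attempt) %% .Machine$integer.max)
      s <- generate_interaction_sequence(cfg, group_id = group_ids[i])
      m <- tryCatch(rqa_measures(s, rqa_config), error = function(e) NULL)
      if (!is.null(m)) break
    }
    if (is.null(m)) {
      stop("could not generate a sequence with defined recurrence ",
           "measures for group ", group_ids[i], call. = FALSE)
    }
    sequences[[i]] <- s
    rr[i] <- m$rr; det[i] <- m$det; ent[i] <- m$ent
  }
  names(sequences) <- group_ids

  # questionnaire responses (RNG state continues after the sequences;
  # reseed for a stream independent of sequence internals)
  set.seed(config$seed + 1L)
  group_noise_sup <- stats::rnorm(g, 0, config$noise_sd_group)
  group_noise_par <- stats::rnorm(g, 0, config$noise_sd_group)
  resp <- vector("list", g)
  pid <- 0L
  for (i in seq_len(g)) {
    np <- n_members[i]
    latent_sup <- config$beta0 + config$beta_support_rr * rr[i] +
      config$beta_support_det * det[i] + group_noise_sup[i] +
      stats::rnorm(np, 0, config$noise_sd_individual)
    latent_par <- config$partic_mean + group_noise_par[i] +
      stats::rnorm(np, 0, config$noise_sd_individual)
    k <- config$items_per_scale
    resp[[i]] <- data.frame(
      participant = rep(sprintf("p%03d", pid + seq_len(np)), each = 2L * k),
      group = group_ids[i],
      scale = rep(rep(c("social_support", "quality_of_participation"),
                      each = k), np),
      item = rep(seq_len(k), 2L * np),
      value = as.vector(vapply(seq_len(np), function(p) {
        c(likert_item(latent_sup[p], config$noise_sd_item, k),
          likert_item(latent_par[p], config$noise_sd_item, k))
      }, integer(2L * k))),
      stringsAsFactors = FALSE
    )
    pid <- pid + np
  }
  responses <- do.call(rbind, resp)
  rownames(responses) <- NULL

  structure(
    list(
      groups = data.frame(group = group_ids, n_members = n_members,
                          stability = stab, determinism = det_w,
                          n_events = lens, rr = rr, det = det, ent = ent,
                          stringsAsFactors = FALSE),
      sequences = sequences,
      responses = responses,
      truth = list(config = config,
                   beta_support = c(intercept = config$beta0,
                                    rr = config$beta_support_rr,
                                    det = config$beta_support_det))
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d groups, %d participants, %d coded events\n",
    nrow(x$groups), length(unique(x$responses$participant)),
    sum(x$groups$n_events)))
  cat(sprintf("  group-mean RR %.2f%%, DET %.2f%%, ENT %.2f bits\n",
              mean(x$groups$rr), mean(x$groups$det), mean(x$groups$ent)))
  invisible(x)
}

#' Decode a symbol sequence back into an event log
#'
#' Expands each dyad symbol `"a-b"` into a member-member event and each
#' `"a-T"` symbol into a member-team event, with evenly spaced
#' timestamps over a session of `session_s` seconds. Used by the study
#' writer so synthetic data flow through the same CSV path as real
#' coded data; `encode_sequence()` of the result reproduces the
#' sequence.
#'
#' @param seq A [symbol_sequence()] over a dyad alphabet.
#' @param session_s Session duration in seconds (default 30 minutes).
#' @param coder Coder label recorded in the log.
#' @return An event data frame (see [read_event_log()]).
#' @export
sequence_to_events <- function(seq, session_s = 1800, coder = "sim") {
  stopifnot(inherits(seq, "symbol_sequence"))
  s <- seq$symbols
  n <- length(s)
  parts <- strsplit(s, "-", fixed = TRUE)
  src <- as.integer(vapply(parts, `[`, "", 1L))
  tgt <- vapply(parts, `[`, "", 2L)
  tgt[tgt == "T"] <- TEAM_SENTINEL
  data.frame(
    time_s = round(seq_len(n) * session_s / (n + 1), 1),
    source = src,
    target = tgt,
    ipa_category = rep(1L, n),
    coder = coder,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic study to disk in the ingestion formats
#'
#' Emits one event-log CSV per group under `events/`, the questionnaire
#' as `questionnaire.csv`, and a `groups.csv` with the member counts, so
#' downstream stages can re-read the study through the real I/O path.
#'
#' @param study A `study_dataset` from [generate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(file.path(dir, "events"), recursive = TRUE, showWarnings = FALSE)
  for (gid in names(study$sequences)) {
    ev <- sequence_to_events(study$sequences[[gid]])
    write_event_log(ev, file.path(dir, "events", paste0(gid, ".csv")))
  }
  utils::write.csv(study$responses, file.path(dir, "questionnaire.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$groups[c("group", "n_members", "n_events")],
                   file.path(dir, "groups.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Configuration for a synthetic Dirichlet-multinomial corpus
#'
#' Parameters of the standard latent-Dirichlet-allocation generative
#' process used to produce test corpora with known topic structure.
#'
#' @param n_topics Number of topics T (>= 1).
#' @param vocab_size Vocabulary size V (> T).
#' @param n_docs Number of documents D.
#' @param mean_doc_length Expected tokens per document (Poisson,
#'   floored at 1 so no document is empty).
#' @param alpha Symmetric Dirichlet concentration of document-topic
#'   mixtures.
#' @param beta Symmetric Dirichlet concentration of topic-word rows.
#' @param seed RNG seed.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_topics = 5L, vocab_size = 200L, n_docs = 200L,
                          mean_doc_length = 100, alpha = 0.1, beta = 0.01,
                          seed = 1L) {
  n_topics <- as.integer(n_topics)
  vocab_size <- as.integer(vocab_size)
  n_docs <- as.integer(n_docs)
  if (is.na(n_topics) || n_topics < 1L) stop("`n_topics` must be >= 1",
                                             call. = FALSE)
  if (is.na(vocab_size) || vocab_size <= n_topics) {
    stop("`vocab_size` must exceed `n_topics`", call. = FALSE)
  }
  if (is.na(n_docs) || n_docs < 1L) stop("`n_docs` must be >= 1",
                                         call. = FALSE)
  if (mean_doc_length <= 0 || alpha <= 0 || beta <= 0) {
    stop("`mean_doc_length`, `alpha` and `beta` must be positive",
         call. = FALSE)
  }
  structure(
    list(n_topics = n_topics, vocab_size = vocab_size, n_docs = n_docs,
         mean_doc_length = mean_doc_length, alpha = alpha, beta = beta,
         seed = as.integer(seed)),
    class = "corpus_config"
  )
}

rdirichlet <- function(n, alpha) {
  # rows ~ Dirichlet(alpha); alpha is a concentration vector
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

make_pseudo_words <- function(v) {
  # pronounceable, all-alphabetic, length 4-9: survives the
  # punctuation/length filters of transcript preprocessing
  consonants <- strsplit("bcdfghjklmnprstvwz", "")[[1L]]
  vowels <- strsplit("aeiou", "")[[1L]]
  words <- character(0)
  while (length(words) < v) {
    need <- v - length(words)
    n_syl <- sample(2:4, need, replace = TRUE)
    w <- vapply(n_syl, function(k) {
      paste0(sample(consonants, k, replace = TRUE),
             sample(vowels, k, replace = TRUE), collapse = "")
    }, "")
    words <- unique(c(words, w))
  }
  words[seq_len(v)]
}

#' Generate a synthetic corpus with known topic structure
#'
#' Draws T topic-word distributions from Dirichlet(beta), one
#' document-topic mixture per document from Dirichlet(alpha), document
#' lengths from Poisson(`mean_doc_length`), and tokens topic-then-word.
#' Returns both the corpus and the true Phi (T x V) and Theta (D x T)
#' so topic-recovery tests have an exact target.
#'
#' @param config A [corpus_config()].
#' @return A list with `corpus` (a `teamdyn_corpus`, see
#'   [build_corpus()]), `phi`, `theta`, and `config`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  T_ <- config$n_topics; V <- config$vocab_size; D <- config$n_docs
  vocabulary <- make_pseudo_words(V)
  phi <- rdirichlet(T_, rep(config$beta, V))
  theta <- rdirichlet(D, rep(config$alpha, T_))
  lens <- pmax(1L, stats::rpois(D, config$mean_doc_length))
  docs <- vector("list", D)
  for (d in seq_len(D)) {
    z <- sample.int(T_, lens[d], replace = TRUE, prob = theta[d, ])
    w <- integer(lens[d])
    for (t in unique(z)) {
      sel <- z == t
      w[sel] <- sample.int(V, sum(sel), replace = TRUE, prob = phi[t, ])
    }
    docs[[d]] <- w
  }
  corpus <- corpus_from_ids(docs, vocabulary,
                            doc_ids = sprintf("doc%03d", seq_len(D)))
  list(corpus = corpus, phi = phi, theta = theta, config = config)
}

#' Write corpus documents as plain-text transcripts
#'
#' One UTF-8 `.txt` file per document, tokens space-separated and
#' wrapped, named after the document ids. Lets synthetic corpora
#' exercise the transcript ingestion path.
#'
#' @param corpus A `teamdyn_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_transcripts <- function(corpus, dir) {
  stopifnot(inherits(corpus, "teamdyn_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in seq_along(corpus$docs)) {
    tokens <- rep(corpus$vocabulary[corpus$docs[[d]]$ids],
                  corpus$docs[[d]]$counts)
    path <- file.path(dir, paste0(corpus$doc_ids[d], ".txt"))
    writeLines(strwrap(paste(tokens, collapse = " "), width = 78), path)
  }
  invisible(dir)
}
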