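#' Transcript preprocessing settings
#'
#' @param stopwords Character vector of stop words removed before
#'   length filtering; defaults to the English list shipped with the
#'   package (see [default_stopwords()]).
#' @param min_len Shortest token length kept (default 3: words of two
#'   or fewer characters are dropped).
#' @param max_len Longest token length kept (default 14: words of 15 or
#'   more characters are dropped).
#' @param stem Apply [porter_stem()] to the surviving tokens?
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(stopwords = default_stopwords(),
                              min_len = 3L, max_len = 14L, stem = TRUE) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(min_len) || min_len < 1L) stop("`min_len` must be >= 1",
                                           call. = FALSE)
  if (is.na(max_len) || max_len <= min_len) {
    stop("`max_len` must exceed `min_len`", call. = FALSE)
  }
  structure(
    list(stopwords = as.character(stopwords), min_len = min_len,
         max_len = max_len, stem = isTRUE(stem)),
    class = "preprocess_config"
  )
}

#' Default English stop-word list
#'
#' The list shipped at `inst/extdata/stopwords_en.txt` (one word per
#' line, `#` comments allowed). Shipping the exact list keeps
#' preprocessing reproducible; pass your own file to replace it.
#'
#' @param path Optional path to an alternative stop-word file.
#' @return Character vector of stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "teamdyn")
  }
  words <- readLines(path, encoding = "UTF-8")
  words <- trimws(words[!grepl("^\\s*#", words)])
  words[nzchar(words)]
}

#' Preprocess raw transcript text into tokens
#'
#' Lowercases, strips punctuation and digits (tokens are maximal runs
#' of alphabetic characters), removes stop words, drops tokens shorter
#' than `min_len` or longer than `max_len` characters, and Porter-stems
#' the remainder. Token order is preserved; empty text gives an empty
#' token vector.
#'
#' @param text Character scalar or vector of UTF-8 text (concatenated
#'   in order).
#' @param config A [preprocess_config()].
#' @return Character vector of processed tokens.
#' @export
#' @examples
#' preprocess_text("Talks, talking, TALKED!", preprocess_config())
preprocess_text <- function(text, config = preprocess_config()) {
  text <- tolower(paste(text, collapse = " "))
  text <- gsub("[^a-z]+", " ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tokens %in% config$stopwords]
  len <- nchar(tokens)
  tokens <- tokens[len >= config$min_len & len <= config$max_len]
  if (config$stem && length(tokens) > 0L) tokens <- porter_stem(tokens)
  tokens
}

#' Read a directory of transcripts as token lists
#'
#' One UTF-8 `.txt` file per group; files are read in alphabetical
#' order and preprocessed with [preprocess_text()].
#'
#' @param dir Directory containing `.txt` transcripts.
#' @param config A [preprocess_config()].
#' @return Named list of token vectors (names are file stems).
#' @export
read_transcripts <- function(dir, config = preprocess_config()) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) stop("no .txt transcripts in ", dir,
                                call. = FALSE)
  out <- lapply(files, function(f) {
    preprocess_text(readLines(f, encoding = "UTF-8", warn = FALSE), config)
  })
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}

corpus_from_ids <- function(id_docs, vocabulary, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- sprintf("doc%03d", seq_along(id_docs))
  docs <- lapply(id_docs, function(w) {
    tab <- table(w)
    list(ids = as.integer(names(tab)), counts = as.integer(tab))
  })
  structure(
    list(vocabulary = vocabulary, docs = docs, doc_ids = doc_ids,
         n_tokens = sum(vapply(id_docs, length, 0L))),
    class = "teamdyn_corpus"
  )
}

#' Build a bag-of-words corpus from token lists
#'
#' Assigns vocabulary ids in first-appearance order and stores sparse
#' per-document counts. Documents that are empty after preprocessing
#' are dropped with a warning; an error is raised if nothing survives.
#'
#' @param token_lists List (optionally named) of character token
#'   vectors, one per document.
#' @return An object of class `teamdyn_corpus`: `vocabulary` (id-to-word
#'   vector), `docs` (per-document `ids`/`counts`), `doc_ids`,
#'   `n_tokens`.
#' @export
build_corpus <- function(token_lists) {
  if (is.null(names(token_lists))) {
    names(token_lists) <- sprintf("doc%03d", seq_along(token_lists))
  }
  keep <- vapply(token_lists, length, 0L) > 0L
  if (!any(keep)) stop("all documents are empty after preprocessing",
                       call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " empty document(s) dropped: ",
            paste(names(token_lists)[!keep], collapse = ", "),
            call. = FALSE)
    token_lists <- token_lists[keep]
  }
  vocabulary <- unique(unlist(token_lists, use.names = FALSE))
  id_docs <- lapply(token_lists, function(tok) match(tok, vocabulary))
  corpus_from_ids(id_docs, vocabulary, doc_ids = names(token_lists))
}

#' @export
print.teamdyn_corpus <- function(x, ...) {
  cat(sprintf("Corpus: %d documents, vocabulary %d, %d tokens\n",
              length(x$docs), length(x$vocabulary), x$n_tokens))
  invisible(x)
}

# expand a corpus into parallel 0-based per-token doc/word index vectors
corpus_token_stream <- function(corpus) {
  doc <- integer(0); word <- integer(0)
  for (d in seq_along(corpus$docs)) {
    ids <- rep(corpus$docs[[d]]$ids, corpus$docs[[d]]$counts)
    word <- c(word, ids)
    doc <- c(doc, rep.int(d, length(ids)))
  }
  list(doc = doc - 1L, word = word - 1L)
}

#' Gibbs-sampler settings for LDA
#'
#' @param n_topics Number of topics T (>= 1).
#' @param alpha Symmetric document-topic concentration; `NULL` uses the
#'   common default 50/T.
#' @param beta Symmetric topic-word concentration (default 0.01).
#' @param n_iter Total Gibbs sweeps (default 1000).
#' @param burn_in Warm-up sweeps excluded from convergence summaries
#'   (default 500; must be < `n_iter`).
#' @param seed RNG seed of the sampler.
#' @return An object of class `lda_config`.
#' @export
lda_config <- function(n_topics, alpha = NULL, beta = 0.01,
                       n_iter = 1000L, burn_in = 500L, seed = 1L) {
  n_topics <- as.integer(n_topics)
  if (is.na(n_topics) || n_topics < 1L) stop("`n_topics` must be >= 1",
                                             call. = FALSE)
  if (is.null(alpha)) alpha <- 50 / n_topics
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be > 0",
                                    call. = FALSE)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (n_iter <= burn_in || burn_in < 0L) {
    stop("need `n_iter` > `burn_in` >= 0", call. = FALSE)
  }
  structure(
    list(n_topics = n_topics, alpha = alpha, beta = beta,
         n_iter = n_iter, burn_in = burn_in, seed = as.integer(seed)),
    class = "lda_config"
  )
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Samples token-topic assignments with the collapsed conditional
#' proportional to `(n_wt + beta) / (n_t + V beta) * (n_dt + alpha)`,
#' then estimates the topic-word matrix Phi and document-topic matrix
#' Theta from the final counts with the same smoothing. Seeded, hence
#' reproducible; a per-sweep training log-likelihood trace is kept for
#' convergence inspection.
#'
#' @param corpus A `teamdyn_corpus`.
#' @param config An [lda_config()].
#' @return An object of class `topic_model`: `phi` (T x V, rows sum to
#'   1), `theta` (D x T, rows sum to 1), `vocabulary`, `doc_ids`,
#'   `loglik` (length `n_iter`), `config`.
#' @export
fit_lda <- function(corpus, config) {
  stopifnot(inherits(corpus, "teamdyn_corpus"),
            inherits(config, "lda_config"))
  if (config$n_topics > corpus$n_tokens) {
    stop("more topics than tokens in the corpus", call. = FALSE)
  }
  stream <- corpus_token_stream(corpus)
  fit <- lda_gibbs_fit(stream$doc, stream$word,
                       n_docs = length(corpus$docs),
                       n_vocab = length(corpus$vocabulary),
                       n_topics = config$n_topics,
                       alpha = config$alpha, beta = config$beta,
                       n_iter = config$n_iter, burn_in = config$burn_in,
                       seed = config$seed)
  colnames(fit$phi) <- corpus$vocabulary
  rownames(fit$theta) <- corpus$doc_ids
  structure(
    list(phi = fit$phi, theta = fit$theta, vocabulary = corpus$vocabulary,
         doc_ids = corpus$doc_ids, loglik = as.numeric(fit$loglik),
         config = config),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("LDA topic model: %d topics, vocabulary %d, %d documents\n",
              nrow(x$phi), ncol(x$phi), nrow(x$theta)))
  invisible(x)
}

#' Held-out perplexity of a topic model
#'
#' `exp(-sum_d sum_w log p(w | d) / N)` over the scored held-out
#' tokens, with `p(w | d) = sum_t theta_dt phi_tw` and the document-
#' topic weights of the held-out documents estimated by fold-in Gibbs
#' sampling with Phi frozen, averaged over `n_chains` chains.
#'
#' With `method = "completion"` (the default) each held-out document is
#' split deterministically into alternating halves: theta-hat is
#' estimated on one half and the perplexity computed on the other.
#' Plain `method = "fold-in"` estimates theta-hat on the same tokens it
#' scores; that makes perplexity improve essentially monotonically with
#' the number of topics (more per-document parameters always fit the
#' scored tokens better), which defeats perplexity-based selection of a
#' finite topic count -- hence the completion default. Held-out words
#' absent from the model vocabulary are dropped and counted in a
#' message.
#'
#' @param model A `topic_model`.
#' @param heldout A `teamdyn_corpus` of held-out documents.
#' @param n_foldin Fold-in Gibbs sweeps (default 50).
#' @param seed Seed of the fold-in sampler.
#' @param method `"completion"` (estimate on half of each document,
#'   score the other half) or `"fold-in"` (estimate and score on all
#'   tokens).
#' @param n_chains Independent fold-in chains averaged on the
#'   probability scale (default 3).
#' @return Perplexity (positive scalar; lower is better).
#' @export
perplexity <- function(model, heldout, n_foldin = 50L, seed = 1L,
                       method = c("completion", "fold-in"),
                       n_chains = 3L) {
  stopifnot(inherits(model, "topic_model"),
            inherits(heldout, "teamdyn_corpus"))
  method <- match.arg(method)
  map <- match(heldout$vocabulary, model$vocabulary)
  doc <- integer(0); word <- integer(0)
  n_oov <- 0L
  for (d in seq_along(heldout$docs)) {
    ids <- rep(heldout$docs[[d]]$ids, heldout$docs[[d]]$counts)
    mapped <- map[ids]
    n_oov <- n_oov + sum(is.na(mapped))
    mapped <- mapped[!is.na(mapped)]
    word <- c(word, mapped)
    doc <- c(doc, rep.int(d, length(mapped)))
  }
  if (length(word) == 0L) {
    stop("held-out set has no in-vocabulary tokens", call. = FALSE)
  }
  if (n_oov > 0L) {
    message(n_oov, " out-of-vocabulary held-out token(s) dropped")
  }
  if (method == "completion") {
    pos <- unlist(lapply(split(seq_along(doc), doc), function(ii) {
      ii[seq_along(ii) %% 2L == 1L]
    }), use.names = FALSE)
    est <- sort(pos)
    sco <- setdiff(seq_along(doc), est)
    if (length(sco) == 0L) {
      stop("held-out documents are too short for completion scoring",
           call. = FALSE)
    }
  } else {
    est <- seq_along(doc)
    sco <- est
  }
  pw <- 0
  for (ch in seq_len(n_chains)) {
    theta <- lda_fold_in(doc[est] - 1L, word[est] - 1L,
                         n_docs = length(heldout$docs), phi = model$phi,
                         alpha = model$config$alpha,
                         n_iter = as.integer(n_foldin),
                         seed = as.integer(seed + 131L * (ch - 1L)))
    pw <- pw + rowSums(theta[doc[sco], , drop = FALSE] *
                         t(model$phi)[word[sco], , drop = FALSE])
  }
  exp(-sum(log(pw / n_chains)) / length(sco))
}

#' Select the number of topics by held-out perplexity
#'
#' Splits the corpus once at document level (a seeded random 10%
#' held-out partition by default), fits one LDA per candidate T on the
#' remaining documents, scores each on the held-out set, and picks the
#' T with the lowest perplexity (ties go to the smallest T).
#'
#' @param corpus A `teamdyn_corpus`.
#' @param candidates Integer vector of candidate topic counts (>= 1 of
#'   them; the default grid spans 5--30).
#' @param holdout_fraction Fraction of documents held out (default
#'   0.1); the held-out and fit partitions must both be non-empty.
#' @param seed Seed controlling the split and all fits.
#' @param alpha,beta,n_iter,burn_in,n_foldin Sampler settings passed to
#'   [lda_config()] and [perplexity()]; `alpha = NULL` uses 50/T per
#'   candidate.
#' @return An object of class `perplexity_curve`: data frame `curve`
#'   (`candidate_T`, `perplexity`) and `best_T`.
#' @export
select_num_topics <- function(corpus,
                              candidates = c(5L, 10L, 15L, 20L, 25L, 30L),
                              holdout_fraction = 0.1, seed = 1L,
                              alpha = NULL, beta = 0.01,
                              n_iter = 1000L, burn_in = 500L,
                              n_foldin = 50L) {
  stopifnot(inherits(corpus, "teamdyn_corpus"))
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 1L || any(candidates < 1L)) {
    stop("`candidates` must be positive topic counts", call. = FALSE)
  }
  n_docs <- length(corpus$docs)
  n_hold <- max(1L, round(holdout_fraction * n_docs))
  if (n_hold >= n_docs) {
    stop("held-out partition would leave no documents to fit on",
         call. = FALSE)
  }
  set.seed(seed)
  hold_idx <- sort(sample.int(n_docs, n_hold))
  subset_corpus <- function(idx) {
    structure(
      list(vocabulary = corpus$vocabulary, docs = corpus$docs[idx],
           doc_ids = corpus$doc_ids[idx],
           n_tokens = sum(vapply(idx, function(d) {
             sum(corpus$docs[[d]]$counts)
           }, 0))),
      class = "teamdyn_corpus")
  }
  fit_part <- subset_corpus(setdiff(seq_len(n_docs), hold_idx))
  hold_part <- subset_corpus(hold_idx)

  perp <- vapply(candidates, function(T_) {
    cfg <- lda_config(T_, alpha = alpha, beta = beta, n_iter = n_iter,
                      burn_in = burn_in, seed = seed)
    model <- fit_lda(fit_part, cfg)
    perplexity(model, hold_part, n_foldin = n_foldin, seed = seed)
  }, 0)

  best <- candidates[which.min(perp)]  # which.min takes the first = smallest T
  structure(
    list(curve = data.frame(candidate_T = candidates, perplexity = perp),
         best_T = best, holdout_docs = corpus$doc_ids[hold_idx]),
    class = "perplexity_curve"
  )
}

#' @export
print.perplexity_curve <- function(x, ...) {
  cat("Held-out perplexity by number of topics:\n")
  print(x$curve, row.names = FALSE)
  cat("best T:", x$best_T, "\n")
  invisible(x)
}

#' Highest-probability words of a topic
#'
#' @param model A `topic_model`.
#' @param topic Topic index in 1..T.
#' @param k Number of words (>= 1).
#' @return Data frame `word`, `probability`, sorted by decreasing
#'   probability with alphabetical tie-break.
#' @export
top_words <- function(model, topic, k = 10L) {
  stopifnot(inherits(model, "topic_model"))
  topic <- as.integer(topic); k <- as.integer(k)
  if (is.na(topic) || topic < 1L || topic > nrow(model$phi)) {
    stop("`topic` must be in 1..", nrow(model$phi), call. = FALSE)
  }
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  p <- model$phi[topic, ]
  ord <- order(-p, model$vocabulary)
  idx <- ord[seq_len(min(k, length(p)))]
  data.frame(word = model$vocabulary[idx], probability = unname(p[idx]),
             stringsAsFactors = FALSE)
}

#' Write topic-model outputs
#'
#' Emits a topics JSON (top-k stems with probabilities per topic and
#' the document-topic matrix), a perplexity-curve CSV when a curve is
#' supplied, and a corpus word-frequency CSV usable by external
#' word-cloud tools.
#'
#' @param model A `topic_model`.
#' @param dir Output directory (created if missing).
#' @param curve Optional `perplexity_curve`.
#' @param corpus Optional `teamdyn_corpus` for the word-frequency CSV.
#' @param k Top words per topic in the JSON.
#' @return `dir`, invisibly.
#' @export
write_topic_outputs <- function(model, dir, curve = NULL, corpus = NULL,
                                k = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tops <- lapply(seq_len(nrow(model$phi)), function(t) {
    tw <- top_words(model, t, k)
    list(topic = t, words = tw$word, probabilities = tw$probability)
  })
  theta <- as.data.frame(model$theta)
  names(theta) <- paste0("topic", seq_len(ncol(theta)))
  jsonlite::write_json(
    list(n_topics = nrow(model$phi),
         alpha = model$config$alpha, beta = model$config$beta,
         top_words = tops,
         theta = cbind(doc = model$doc_ids, theta)),
    file.path(dir, "topics.json"),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(curve)) {
    utils::write.csv(curve$curve, file.path(dir, "perplexity.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(corpus)) {
    counts <- numeric(length(corpus$vocabulary))
    for (d in corpus$docs) {
      counts[d$ids] <- counts[d$ids] + d$counts
    }
    freq <- data.frame(word = corpus$vocabulary, count = counts)
    freq <- freq[order(-freq$count, freq$word), ]
    utils::write.csv(freq, file.path(dir, "word_frequencies.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
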