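#' Derive a per-stage RNG seed from the global run seed
#'
#' One global seed fans out deterministically to the pipeline stages
#' (hashing the stage name) so any stage can be rerun in isolation and
#' still reproduce its part of a full run.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1009 * h) %% .Machine$integer.max)
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "teamdyn_run",
    simulate = list(study = list(), corpus = list()),
    inputs = NULL,
    rqa = list(lmin = 2L, theiler = 1L),
    lda = list(candidates = c(5L, 10L, 15L, 20L, 25L, 30L),
               holdout_fraction = 0.1, beta = 0.01,
               n_iter = 1000L, burn_in = 500L, top_k = 10L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Validate a pipeline run configuration
#'
#' Checks the constraints of every nested stage configuration and
#' returns all problems at once as a character vector (empty when the
#' configuration is valid). Exactly one of a `simulate` block or an
#' `inputs` block (paths to event logs, transcripts and questionnaire)
#' must be present.
#'
#' @param config A configuration list, or the path of a YAML file
#'   holding one.
#' @return Character vector of human-readable problems; empty if valid.
#'   The normalised configuration is attached as attribute `"config"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(default_run_config(), config)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    note("exactly one of `simulate` or `inputs` must be given")
  }
  if (has_inputs) {
    for (f in c("events_dir", "transcripts_dir", "questionnaire")) {
      if (is.null(config$inputs[[f]])) {
        note(paste0("`inputs$", f, "` is required"))
      } else if (!file.exists(config$inputs[[f]])) {
        note(paste0("`inputs$", f, "` does not exist: ",
                    config$inputs[[f]]))
      }
    }
  }
  if (config$rqa$lmin < 2) note("`rqa$lmin` must be >= 2")
  if (config$rqa$theiler < 1) note("`rqa$theiler` must be >= 1")
  lda <- config$lda
  if (length(lda$candidates) < 1 || any(lda$candidates < 1)) {
    note("`lda$candidates` must be positive topic counts")
  }
  if (lda$holdout_fraction <= 0 || lda$holdout_fraction >= 1) {
    note("`lda$holdout_fraction` must lie in (0, 1)")
  }
  if (!is.null(lda$alpha) && lda$alpha <= 0) note("`lda$alpha` must be > 0")
  if (lda$beta <= 0) note("`lda$beta` must be > 0")
  if (lda$n_iter <= lda$burn_in) note("`lda$n_iter` must exceed `lda$burn_in`")
  if (has_sim) {
    sim_ok <- tryCatch({
      do.call(study_config, config$simulate$study %||% list())
      do.call(corpus_config, config$simulate$corpus %||% list())
      TRUE
    }, error = function(e) { note(conditionMessage(e)); FALSE })
    invisible(sim_ok)
  }
  structure(problems, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate-or-ingest, sequence encoding, recurrence
#' quantification, topic modelling with perplexity-based selection, and
#' the two association models, writing all artifacts plus a manifest
#' into the output directory:
#' `measures.json`, `topics.json`, `perplexity.csv`,
#' `word_frequencies.csv`, `table1.csv`, `manifest.json`. Identical
#' configuration and seed give byte-identical outputs. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config Configuration list or YAML path (see
#'   [validate_config()]).
#' @param quiet Suppress stage progress messages?
#' @return The output directory, invisibly; results are also returned
#'   as attribute `"results"`.
#' @export
run_all <- function(config, quiet = FALSE) {
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  config <- attr(problems, "config")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[teamdyn] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  rqa_cfg <- rqa_config(lmin = config$rqa$lmin, theiler = config$rqa$theiler)

  # --- data: simulate or ingest -------------------------------------
  if (!is.null(config$simulate)) {
    say("simulating study data")
    study <- stage("simulate", {
      args <- config$simulate$study %||% list()
      args$seed <- args$seed %||% stage_seed(seed, "simulate")
      generate_study(do.call(study_config, args), rqa_config = rqa_cfg)
    })
    corpus_truth <- stage("simulate", {
      args <- config$simulate$corpus %||% list()
      args$seed <- args$seed %||% stage_seed(seed, "corpus")
      args$n_docs <- args$n_docs %||% nrow(study$groups)
      generate_corpus(do.call(corpus_config, args))
    })
    data_dir <- file.path(out_dir, "data")
    write_study(study, data_dir)
    write_transcripts(corpus_truth$corpus,
                      file.path(data_dir, "transcripts"))
    events_dir <- file.path(data_dir, "events")
    transcripts_dir <- file.path(data_dir, "transcripts")
    questionnaire <- file.path(data_dir, "questionnaire.csv")
  } else {
    events_dir <- config$inputs$events_dir
    transcripts_dir <- config$inputs$transcripts_dir
    questionnaire <- config$inputs$questionnaire
  }

  # --- encode + rqa -------------------------------------------------
  say("encoding sequences and computing recurrence measures")
  measures <- stage("rqa", {
    files <- sort(list.files(events_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no event logs in ", events_dir)
    rows <- lapply(files, function(f) {
      events <- read_event_log(f)
      ids <- suppressWarnings(
        as.integer(events$target[events$target != TEAM_SENTINEL]))
      n_members <- max(events$source, ids, na.rm = TRUE)
      gid <- sub("\\.csv$", "", basename(f))
      m <- rqa_measures(encode_sequence(events, n_members, group_id = gid),
                        rqa_cfg)
      data.frame(group = gid, n = m$n, rr = m$rr, det = m$det,
                 ent = m$ent, n_recurrent = m$n_recurrent,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  jsonlite::write_json(measures, file.path(out_dir, "measures.json"),
                       digits = NA)

  # --- topics -------------------------------------------------------
  say("topic modelling (candidate grid: ",
      paste(config$lda$candidates, collapse = ", "), ")")
  topic_out <- stage("topics", {
    tokens <- read_transcripts(transcripts_dir)
    corpus <- build_corpus(tokens)
    curve <- select_num_topics(
      corpus, candidates = config$lda$candidates,
      holdout_fraction = config$lda$holdout_fraction,
      seed = stage_seed(seed, "topics"),
      alpha = config$lda$alpha, beta = config$lda$beta,
      n_iter = config$lda$n_iter, burn_in = config$lda$burn_in)
    cfg <- lda_config(curve$best_T, alpha = config$lda$alpha,
                      beta = config$lda$beta,
                      n_iter = config$lda$n_iter,
                      burn_in = config$lda$burn_in,
                      seed = stage_seed(seed, "topics-final"))
    model <- fit_lda(corpus, cfg)
    write_topic_outputs(model, out_dir, curve = curve, corpus = corpus,
                        k = config$lda$top_k)
    list(model = model, curve = curve)
  })

  # --- association --------------------------------------------------
  say("fitting association models")
  association <- stage("associate", {
    responses <- utils::read.csv(questionnaire, stringsAsFactors = FALSE)
    run_association(measures, responses)
  })
  write_association_table(association, file.path(out_dir, "table1.csv"))

  # --- manifest -----------------------------------------------------
  artifacts <- c("measures.json", "topics.json", "perplexity.csv",
                 "word_frequencies.csv", "table1.csv")
  manifest <- list(
    seed = seed,
    # the hash identifies the analysis, not where it was written
    config_hash = digest::digest(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("teamdyn")),
    artifact_hashes = vapply(artifacts, function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }, "")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("run complete: ", out_dir)
  structure(invisible(out_dir),
            results = list(measures = measures, topics = topic_out,
                           association = association,
                           manifest = manifest))
}
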