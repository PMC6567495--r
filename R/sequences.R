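#' Symbolic interaction sequence
#'
#' An ordered categorical sequence of who-interacts-with-whom symbols
#' for one group session, together with the full symbol alphabet.
#'
#' @param symbols Character vector of symbols, length >= 1.
#' @param alphabet Character vector of admissible symbols; defaults to
#'   the distinct symbols observed.
#' @param group_id Optional group label.
#' @return An object of class `symbol_sequence`.
#' @export
symbol_sequence <- function(symbols, alphabet = unique(symbols),
                            group_id = NA_character_) {
  symbols <- as.character(symbols)
  alphabet <- as.character(alphabet)
  if (length(symbols) < 1L) {
    stop("a symbol sequence must contain at least one symbol", call. = FALSE)
  }
  bad <- setdiff(unique(symbols), alphabet)
  if (length(bad) > 0L) {
    stop("symbols outside the declared alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(symbols = symbols, alphabet = alphabet,
         group_id = as.character(group_id)),
    class = "symbol_sequence"
  )
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("symbol_sequence: %d events, alphabet size %d%s\n",
              length(x$symbols), length(x$alphabet),
              if (!is.na(x$group_id)) paste0(", group ", x$group_id) else ""))
  invisible(x)
}

#' @export
length.symbol_sequence <- function(x) length(x$symbols)

TEAM_SENTINEL <- "TEAM"

event_log_columns <- c("time_s", "source", "target", "ipa_category", "coder")

#' Read a coded interaction event log
#'
#' Parses a CSV of coded behaviours, one row per observed interaction
#' event, with header `time_s,source,target,ipa_category,coder`.
#' `target` is either a member id or the sentinel `TEAM` for a member
#' addressing the whole group. Rows are kept in file order (simultaneous
#' events are not reordered). All malformed rows are reported together,
#' with their line numbers.
#'
#' Validation: `time_s` must be a non-negative number, `source` a
#' positive integer, `target` a positive integer distinct from `source`
#' or `TEAM`, and `ipa_category` an integer in 1--12 (Bales' Interaction
#' Process Analysis scheme).
#'
#' @param path Path to the CSV file.
#' @return A data frame of events with columns `time_s` (numeric),
#'   `source` (integer), `target` (character: member id or `"TEAM"`),
#'   `ipa_category` (integer), `coder` (character).
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(event_log_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("event log is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[event_log_columns]
  n <- nrow(raw)
  problems <- character(0)
  add_problem <- function(rows, msg) {
    if (any(rows)) {
      # +1 for the header line
      problems <<- c(problems, paste0(
        "line ", paste(which(rows) + 1L, collapse = ", "), ": ", msg))
    }
  }

  time_s <- suppressWarnings(as.numeric(raw$time_s))
  add_problem(is.na(time_s) | time_s < 0,
              "time_s must be a non-negative number")
  source_id <- suppressWarnings(as.integer(raw$source))
  add_problem(is.na(source_id) | source_id < 1L |
                raw$source != as.character(source_id),
              "source must be a positive integer member id")
  is_team <- raw$target == TEAM_SENTINEL
  target_id <- suppressWarnings(as.integer(raw$target))
  bad_target <- !is_team & (is.na(target_id) | target_id < 1L |
                              raw$target != as.character(target_id))
  add_problem(bad_target, "target must be a positive integer or TEAM")
  self_loop <- !is_team & !bad_target & !is.na(source_id) &
    target_id == source_id
  add_problem(self_loop, "source and target must differ")
  ipa <- suppressWarnings(as.integer(raw$ipa_category))
  add_problem(is.na(ipa) | ipa < 1L | ipa > 12L,
              "ipa_category must be an integer in 1-12")

  if (length(problems) > 0L) {
    stop("malformed event log rows:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  data.frame(
    time_s = time_s,
    source = source_id,
    target = raw$target,
    ipa_category = ipa,
    coder = raw$coder,
    stringsAsFactors = FALSE
  )
}

#' Write an interaction event log as CSV
#'
#' Inverse of [read_event_log()]; the synthetic generator uses it so
#' simulated studies exercise the same I/O path as real coded data.
#'
#' @param events Event data frame as returned by [read_event_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(event_log_columns %in% names(events)))
  utils::write.csv(events[event_log_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dyad alphabet for a group of a given size
#'
#' All C(m, 2) unordered member-pair symbols `"a-b"` (a < b) plus the m
#' member-to-team symbols `"a-T"`.
#'
#' @param n_members Number of group members (>= 2).
#' @return Character vector of symbols.
#' @export
dyad_alphabet <- function(n_members) {
  n_members <- as.integer(n_members)
  if (is.na(n_members) || n_members < 2L) {
    stop("`n_members` must be an integer >= 2", call. = FALSE)
  }
  pairs <- utils::combn(n_members, 2L)
  c(paste0(pairs[1L, ], "-", pairs[2L, ]),
    paste0(seq_len(n_members), "-T"))
}

#' Encode an event log as a symbolic sequence
#'
#' Maps each interaction event to one categorical symbol: an unordered
#' member pair \{a, b\} becomes `"a-b"` with a < b (dyads carry no
#' direction by default, so (1 to 2) and (2 to 1) encode identically),
#' and a member a addressing the whole team becomes `"a-T"`. The
#' alphabet is the full set from [dyad_alphabet()], so groups of equal
#' size share an alphabet regardless of which dyads were observed.
#' Events are sorted by `time_s` (stably, so simultaneous events keep
#' file order); output length equals event count.
#'
#' @param events Event data frame (see [read_event_log()]).
#' @param n_members Number of members in the group.
#' @param group_id Optional group label attached to the sequence.
#' @param directed If `TRUE`, member-member dyads keep their direction
#'   and the alphabet contains all ordered pairs `"a>b"`.
#' @return A [symbol_sequence()].
#' @export
encode_sequence <- function(events, n_members, group_id = NA_character_,
                            directed = FALSE) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("cannot encode an empty event list", call. = FALSE)
  }
  n_members <- as.integer(n_members)
  is_team <- events$target == TEAM_SENTINEL
  src <- as.integer(events$source)
  tgt <- suppressWarnings(as.integer(events$target))
  used <- c(src, tgt[!is_team])
  if (any(used > n_members)) {
    stop("member id exceeds n_members = ", n_members, call. = FALSE)
  }
  ord <- order(events$time_s)  # stable: ties keep file order
  src <- src[ord]; tgt <- tgt[ord]; is_team <- is_team[ord]
  if (directed) {
    symbols <- ifelse(is_team, paste0(src, "-T"), paste0(src, ">", tgt))
    pairs <- expand.grid(a = seq_len(n_members), b = seq_len(n_members))
    pairs <- pairs[pairs$a != pairs$b, ]
    alphabet <- c(paste0(pairs$a, ">", pairs$b),
                  paste0(seq_len(n_members), "-T"))
  } else {
    lo <- pmin(src, tgt); hi <- pmax(src, tgt)
    symbols <- ifelse(is_team, paste0(src, "-T"), paste0(lo, "-", hi))
    alphabet <- dyad_alphabet(n_members)
  }
  symbol_sequence(symbols, alphabet, group_id)
}

#' Write a symbol sequence as plain text
#'
#' One symbol per line, preceded by a `# alphabet:` header comment and a
#' `# group:` line when a group id is set.
#'
#' @param seq A [symbol_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "symbol_sequence"))
  header <- paste0("# alphabet: ", paste(seq$alphabet, collapse = " "))
  if (!is.na(seq$group_id)) {
    header <- c(header, paste0("# group: ", seq$group_id))
  }
  writeLines(c(header, seq$symbols), path)
  invisible(path)
}

#' Read a symbol sequence written by [write_sequence()]
#'
#' @param path Text file path.
#' @return A [symbol_sequence()].
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  headers <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  alpha_line <- grep("^# alphabet:", headers, value = TRUE)
  alphabet <- if (length(alpha_line) == 1L) {
    strsplit(sub("^# alphabet:\\s*", "", alpha_line), "\\s+")[[1L]]
  } else unique(body)
  group_line <- grep("^# group:", headers, value = TRUE)
  group_id <- if (length(group_line) == 1L) {
    sub("^# group:\\s*", "", group_line)
  } else NA_character_
  symbol_sequence(body, alphabet, group_id)
}

#' Inter-rater reliability: ICC(2,1)
#'
#' Intraclass correlation from the two-way random-effects model, single
#' measures, absolute agreement -- the conservative form for rating
#' consistency between coders who each rated every subject. From the
#' two-way ANOVA decomposition:
#' \deqn{ICC(2,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS + k\,(JMS - EMS)/n}}
#' with BMS the between-subjects mean square, JMS the between-raters
#' mean square, EMS the residual mean square, k raters and n subjects.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns;
#'   at least 2 of each, no missing cells.
#' @return An object of class `icc_result` with fields `icc`,
#'   `n_subjects`, `n_raters`, `model_label`.
#' @export
#' @examples
#' icc_two_way_random(cbind(c(9, 6, 8, 7), c(10, 7, 8, 6)))
icc_two_way_random <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings contain missing cells", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  if (stats::var(as.vector(ratings)) == 0) {
    stop("ratings are constant: ICC is undefined", call. = FALSE)
  }
  grand <- mean(ratings)
  subj_means <- rowMeans(ratings)
  rater_means <- colMeans(ratings)
  bms <- k * sum((subj_means - grand)^2) / (n - 1)
  jms <- n * sum((rater_means - grand)^2) / (k - 1)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - k * sum((subj_means - grand)^2) -
    n * sum((rater_means - grand)^2)
  ems <- ss_err / ((n - 1) * (k - 1))
  icc <- (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  structure(
    list(icc = icc, n_subjects = n, n_raters = k,
         model_label = "two-way random, single measures, absolute agreement"),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  (%s; %d subjects, %d raters)\n",
              x$icc, x$model_label, x$n_subjects, x$n_raters))
  invisible(x)
}
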