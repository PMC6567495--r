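#' Recurrence quantification settings
#'
#' Bundles the tunable parameters of categorical recurrence
#' quantification: the minimum diagonal line length that counts as
#' "deterministic", the Theiler exclusion half-width around the line of
#' identity, and the logarithm base used for diagonal-line entropy.
#'
#' @param lmin Minimum diagonal line length entering the determinism
#'   numerator and the entropy distribution. Must be at least 2; a
#'   length-1 "line" is an isolated recurrence and carries no
#'   predictability information.
#' @param theiler Half-width of the excluded band around the main
#'   diagonal. The default 1 excludes only the line of identity itself,
#'   which is required for the recurrence rate to attain its full
#'   0--100 range (every state trivially recurs with itself).
#' @param entropy_log_base Base of the logarithm in the line-length
#'   entropy; 2 gives bits.
#'
#' @return An object of class `rqa_config`.
#' @export
#' @examples
#' rqa_config()
#' rqa_config(lmin = 3)
rqa_config <- function(lmin = 2L, theiler = 1L, entropy_log_base = 2) {
  lmin <- as.integer(lmin)
  theiler <- as.integer(theiler)
  if (is.na(lmin) || lmin < 2L) {
    stop("`lmin` must be an integer >= 2", call. = FALSE)
  }
  if (is.na(theiler) || theiler < 1L) {
    stop("`theiler` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(entropy_log_base) || entropy_log_base <= 1) {
    stop("`entropy_log_base` must be > 1", call. = FALSE)
  }
  structure(
    list(lmin = lmin, theiler = theiler,
         entropy_log_base = entropy_log_base),
    class = "rqa_config"
  )
}

as_symbol_vector <- function(seq) {
  if (inherits(seq, "symbol_sequence")) seq$symbols else as.character(seq)
}

#' Categorical recurrence plot
#'
#' Builds the binary N x N self-similarity matrix of a categorical
#' symbol sequence: cell (i, j) is 1 exactly when the symbols at times i
#' and j are identical. For categorical data the similarity threshold of
#' continuous-signal recurrence analysis degenerates to exact equality.
#' The matrix is symmetric and its main diagonal (the line of identity)
#' is all ones.
#'
#' @param seq A `symbol_sequence` or a plain vector of symbols, length
#'   at least 2.
#' @return An object of class `recurrence_plot`: a list with `matrix`
#'   (integer 0/1) and `n`.
#' @export
#' @examples
#' recurrence_matrix(c("A", "B", "A"))
recurrence_matrix <- function(seq) {
  s <- as_symbol_vector(seq)
  n <- length(s)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  if (anyNA(s)) stop("sequence contains missing symbols", call. = FALSE)
  m <- outer(s, s, "==")
  storage.mode(m) <- "integer"
  structure(list(matrix = m, n = n), class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat("Categorical recurrence plot, n =", x$n, "\n")
  dens <- (sum(x$matrix) - x$n) / (x$n^2 - x$n)
  cat(sprintf("off-diagonal recurrence density: %.3f\n", dens))
  invisible(x)
}

stopifnot_plot <- function(plot) {
  if (!inherits(plot, "recurrence_plot")) {
    stop("expected a `recurrence_plot` (see recurrence_matrix())",
         call. = FALSE)
  }
}

#' Histogram of maximal diagonal line lengths
#'
#' Enumerates every maximal run of consecutive recurrent cells along the
#' upper-triangle diagonals of a recurrence plot, at offsets of at least
#' the Theiler width. A run is maximal when it is bounded by
#' non-recurrent cells or the matrix edge; a length-l run contributes a
#' single count at l (no nested sub-runs). By symmetry the lower
#' triangle duplicates every line, so the upper triangle suffices for
#' determinism and entropy.
#'
#' @param plot A `recurrence_plot`.
#' @param config An `rqa_config`.
#' @return A named integer vector mapping line length to count, sorted
#'   by increasing length; empty when no off-diagonal recurrences exist.
#' @export
diagonal_line_histogram <- function(plot, config = rqa_config()) {
  stopifnot_plot(plot)
  m <- plot$matrix
  n <- plot$n
  lengths <- integer(0)
  for (d in seq(config$theiler, n - 1L)) {
    idx <- seq_len(n - d)
    v <- m[cbind(idx, idx + d)] == 1L
    r <- rle(v)
    lengths <- c(lengths, r$lengths[r$values])
  }
  if (length(lengths) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  tab <- table(lengths)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

off_diagonal_cells <- function(n, theiler) {
  # cells with |i - j| >= theiler
  as.numeric(n)^2 - n - 2 * sum(pmax(n - seq_len(theiler - 1L), 0))
}

#' Recurrence rate
#'
#' Percentage of off-line-of-identity cells that are recurrent:
#' `100 * recurrent cells / (N^2 - N)` for the default Theiler width of
#' 1. Symmetric cells count on both sides, in numerator and denominator
#' alike. Interpreted as the stability of the interaction pattern: 0
#' means no state is ever revisited, 100 a continuous repetition of a
#' single state.
#'
#' @inheritParams diagonal_line_histogram
#' @return Recurrence rate in percent, in \[0, 100\].
#' @export
#' @examples
#' recurrence_rate(recurrence_matrix(rep("A", 20)))  # 100
recurrence_rate <- function(plot, config = rqa_config()) {
  stopifnot_plot(plot)
  n <- plot$n
  m <- plot$matrix
  excl <- abs(row(m) - col(m)) < config$theiler
  num <- sum(m[!excl])
  den <- off_diagonal_cells(n, config$theiler)
  if (den <= 0) stop("sequence too short for this Theiler width",
                     call. = FALSE)
  100 * num / den
}

#' Percent determinism
#'
#' Percentage of recurrent points that lie on diagonal lines of length
#' at least `lmin` (default 2): the predictability of the sequence. Both
#' sums run over the upper-triangle line histogram; the denominator
#' includes all recurrent points (lengths >= 1), the numerator only
#' qualifying lines. Undefined -- an error -- when the plot has no
#' off-diagonal recurrence at all.
#'
#' @inheritParams diagonal_line_histogram
#' @return Determinism in percent, in \[0, 100\].
#' @export
#' @examples
#' determinism(recurrence_matrix(rep(1:3, 3)))  # 100
determinism <- function(plot, config = rqa_config()) {
  hist <- diagonal_line_histogram(plot, config)
  lens <- as.integer(names(hist))
  total <- sum(lens * hist)
  if (total == 0) {
    stop("no off-diagonal recurrent points: determinism is undefined",
         call. = FALSE)
  }
  keep <- lens >= config$lmin
  100 * sum(lens[keep] * hist[keep]) / total
}

#' Diagonal-line entropy
#'
#' Shannon entropy of the distribution of maximal diagonal line lengths
#' of at least `lmin`, in bits by default. Zero when every qualifying
#' line has the same length; larger when many different line lengths
#' occur, i.e. when the recurrence structure -- the interaction pattern
#' -- is more complex. An error when no line reaches `lmin`.
#'
#' @inheritParams diagonal_line_histogram
#' @return Entropy (non-negative), in units of `log(entropy_log_base)`.
#' @export
#' @examples
#' rqa_entropy(recurrence_matrix(rep(1:3, 2)))  # single line: 0 bits
rqa_entropy <- function(plot, config = rqa_config()) {
  hist <- diagonal_line_histogram(plot, config)
  lens <- as.integer(names(hist))
  hist <- hist[lens >= config$lmin]
  if (length(hist) == 0L || sum(hist) == 0) {
    stop(sprintf("no diagonal line reaches lmin = %d: entropy is undefined",
                 config$lmin), call. = FALSE)
  }
  p <- hist / sum(hist)
  -sum(p * log(p)) / log(config$entropy_log_base)
}

#' All recurrence quantification measures of a sequence
#'
#' Convenience bundle: builds the recurrence plot once and returns
#' recurrence rate, percent determinism, diagonal-line entropy, the
#' off-diagonal recurrent-cell count and the line histogram. A
#' deterministic function of its input. Errors from the component
#' measures (no recurrence; no qualifying line) propagate.
#'
#' @param seq A `symbol_sequence` or plain symbol vector, length >= 2.
#' @param config An `rqa_config`.
#' @return An object of class `rqa_measures` with fields `rr`, `det`,
#'   `ent`, `n_recurrent`, `line_histogram`, `n`, `group_id`.
#' @export
#' @examples
#' m <- rqa_measures(rep(1:3, 3))
#' m$rr   # 25
#' m$det  # 100
rqa_measures <- function(seq, config = rqa_config()) {
  plot <- recurrence_matrix(seq)
  hist <- diagonal_line_histogram(plot, config)
  excl <- abs(row(plot$matrix) - col(plot$matrix)) < config$theiler
  structure(
    list(
      rr = recurrence_rate(plot, config),
      det = determinism(plot, config),
      ent = rqa_entropy(plot, config),
      n_recurrent = sum(plot$matrix[!excl]),
      line_histogram = hist,
      n = plot$n,
      group_id = if (inherits(seq, "symbol_sequence")) seq$group_id else NA_character_
    ),
    class = "rqa_measures"
  )
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf(
    "RQA measures (n = %d%s)\n  recurrence rate: %6.2f %%\n  determinism:     %6.2f %%\n  entropy:         %6.3f bits\n",
    x$n,
    if (!is.na(x$group_id)) paste0(", group ", x$group_id) else "",
    x$rr, x$det, x$ent
  ))
  invisible(x)
}

#' Write a recurrence plot as CSV
#'
#' Writes the binary matrix as comma-separated 0/1 values, one row per
#' time point, with 1-based time labels `t1..tN` in the header.
#'
#' @param plot A `recurrence_plot`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recurrence_plot <- function(plot, path) {
  stopifnot_plot(plot)
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("`path` must be a non-empty file path", call. = FALSE)
  }
  m <- plot$matrix
  colnames(m) <- paste0("t", seq_len(plot$n))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recurrence plot written by [write_recurrence_plot()]
#'
#' @param path CSV file path.
#' @return A `recurrence_plot`.
#' @export
read_recurrence_plot <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (nrow(m) != ncol(m) || !all(m %in% c(0L, 1L))) {
    stop("file does not contain a square 0/1 matrix", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  structure(list(matrix = m, n = nrow(m)), class = "recurrence_plot")
}
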