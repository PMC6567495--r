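# Independent oracles used across the suite. The naive recurrence
# enumerator deliberately walks every diagonal cell by cell and shares
# no code with the package implementation.

naive_rqa <- function(symbols, lmin = 2L) {
  symbols <- as.character(symbols)
  n <- length(symbols)
  R <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) R[i, j] <- symbols[i] == symbols[j]
  }
  rec <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (i != j && R[i, j]) rec <- rec + 1L
  }
  rr <- 100 * rec / (n^2 - n)
  lens <- integer(0)
  for (d in seq_len(n - 1L)) {
    run <- 0L
    for (i in seq_len(n - d)) {
      if (R[i, i + d]) {
        run <- run + 1L
      } else {
        if (run > 0L) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  total <- sum(lens)
  det <- if (total > 0) 100 * sum(lens[lens >= lmin]) / total else NA_real_
  q <- lens[lens >= lmin]
  ent <- if (length(q) > 0) {
    tb <- table(q)
    p <- as.numeric(tb) / sum(tb)
    -sum(p * log2(p))
  } else NA_real_
  hist <- table(lens)
  list(rr = rr, det = det, ent = ent,
       hist = structure(as.integer(hist),
                        names = as.character(names(hist))),
       n_recurrent = rec)
}

# greedy one-to-one matching of fitted to true topics by total
# variation distance; returns the mean distance over matched pairs
greedy_mean_tv <- function(true_phi, fit_phi) {
  T_ <- nrow(true_phi)
  used <- integer(0)
  tot <- 0
  for (i in seq_len(T_)) {
    d <- apply(fit_phi, 1L, function(q) 0.5 * sum(abs(true_phi[i, ] - q)))
    d[used] <- Inf
    j <- which.min(d)
    used <- c(used, j)
    tot <- tot + d[j]
  }
  tot / T_
}

# participant-level support-scale data joined to group measures,
# shared by the GEE tests
support_gee_data <- function(study) {
  sc <- score_scale(study$responses)
  part <- sc$participant[sc$participant$scale == "social_support", ]
  merge(part, study$groups[c("group", "rr", "det", "ent")], by = "group")
}
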