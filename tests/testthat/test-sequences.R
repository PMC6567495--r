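write_log_lines <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("time_s,source,target,ipa_category,coder", rows), path)
  path
}

test_that("well-formed event logs parse in file order", {
  path <- write_log_lines(c("0.5,1,2,4,r1", "1.0,3,TEAM,6,r1", "1.0,2,1,4,r1"))
  ev <- read_event_log(path)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$source, c(1L, 3L, 2L))
  expect_equal(ev$target, c("2", "TEAM", "1"))
  expect_type(ev$time_s, "double")
})

test_that("malformed rows are rejected with their line numbers", {
  path <- write_log_lines(c("0.5,1,2,13,r1", "1.0,2,2,4,r1"))
  err <- expect_error(read_event_log(path), "ipa_category")
  expect_match(conditionMessage(err), "line 2")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "must differ")

  bad_cols <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,source", "1,2"), bad_cols)
  expect_error(read_event_log(bad_cols), "missing required columns")
  expect_error(read_event_log("no/such/file.csv"), "not found")
})

test_that("a simulated 157-event log survives the write/read round trip", {
  seq <- generate_interaction_sequence(
    interaction_config(n_members = 5L, length = 157L, seed = 99L))
  ev <- sequence_to_events(seq)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(ev, path)
  back <- read_event_log(path)
  expect_equal(back, ev)
  expect_equal(encode_sequence(back, 5L)$symbols, seq$symbols)
})

test_that("encoding maps events to unordered dyad and team symbols", {
  ev <- data.frame(time_s = c(1, 2, 3), source = c(1L, 2L, 3L),
                   target = c("2", "1", "TEAM"),
                   ipa_category = 1L, coder = "r1")
  s <- encode_sequence(ev, 3L)
  expect_equal(s$symbols, c("1-2", "1-2", "3-T"))
  expect_equal(length(s), 3L)
  expect_setequal(s$alphabet, c("1-2", "1-3", "2-3", "1-T", "2-T", "3-T"))

  # swapping source and target of member-member events changes nothing
  swapped <- ev
  swapped$source <- c(2L, 1L, 3L)
  swapped$target <- c("1", "2", "TEAM")
  expect_equal(encode_sequence(swapped, 3L)$symbols, s$symbols)

  expect_error(encode_sequence(ev[0, ], 3L), "empty")
  expect_error(encode_sequence(ev, 2L), "exceeds")
})

test_that("directed encoding keeps event direction", {
  ev <- data.frame(time_s = c(1, 2), source = c(1L, 2L),
                   target = c("2", "1"), ipa_category = 1L, coder = "r1")
  s <- encode_sequence(ev, 3L, directed = TRUE)
  expect_equal(s$symbols, c("1>2", "2>1"))
  expect_equal(length(s$alphabet), 3L * 2L + 3L)
})

test_that("encoding sorts by time but keeps file order within ties", {
  ev <- data.frame(time_s = c(2, 1, 1), source = c(1L, 2L, 1L),
                   target = c("2", "3", "3"), ipa_category = 1L,
                   coder = "r1")
  expect_equal(encode_sequence(ev, 3L)$symbols, c("2-3", "1-3", "1-2"))
})

test_that("sequence text files round trip with alphabet header", {
  s <- symbol_sequence(c("1-2", "2-3"), dyad_alphabet(3L), group_id = "g1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_sequence(s, path)
  expect_match(readLines(path)[1], "^# alphabet:")
  back <- read_sequence(path)
  expect_equal(back$symbols, s$symbols)
  expect_equal(back$alphabet, s$alphabet)
  expect_equal(back$group_id, "g1")
})

test_that("ICC(2,1) matches the two-way ANOVA decomposition", {
  # frozen from a hand-computed ANOVA table: BMS 4.125, JMS 0.125,
  # EMS 11/24 for the 4 x 2 matrix below
  ratings <- cbind(c(9, 6, 8, 7), c(10, 7, 8, 6))
  res <- icc_two_way_random(ratings)
  expect_equal(res$icc, 0.830188679245283, tolerance = 1e-12)
  expect_equal(res$n_subjects, 4L)
  expect_equal(res$n_raters, 2L)

  # independent route: mean squares from aov()
  long <- data.frame(y = as.vector(ratings),
                     subject = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  ms <- summary(aov(y ~ subject + rater, long))[[1]][["Mean Sq"]]
  bms <- ms[1]; jms <- ms[2]; ems <- ms[3]
  icc_aov <- (bms - ems) / (bms + (2 - 1) * ems + 2 * (jms - ems) / 4)
  expect_equal(res$icc, icc_aov, tolerance = 1e-12)
})

test_that("ICC is 1 for duplicated raters and shift-invariant", {
  scores <- c(3, 9, 5, 7, 4)
  expect_equal(icc_two_way_random(cbind(scores, scores))$icc, 1)

  ratings <- cbind(c(9, 6, 8, 7), c(10, 7, 8, 6))
  base <- icc_two_way_random(ratings)$icc
  expect_equal(icc_two_way_random(ratings + 5)$icc, base,
               tolerance = 1e-12)

  expect_error(icc_two_way_random(matrix(3, 4, 2)), "constant")
  expect_error(icc_two_way_random(cbind(1:5)), "at least 2")
  expect_error(icc_two_way_random(cbind(c(1, NA), c(1, 2))), "missing")
})

test_that("independent raters give near-zero ICC", {
  set.seed(11)
  low <- vapply(1:10, function(i) {
    abs(icc_two_way_random(matrix(rnorm(100), 50, 2))$icc) < 0.4
  }, TRUE)
  expect_gte(sum(low), 9L)
})
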