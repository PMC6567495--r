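test_that("scale scoring averages items then participants", {
  resp <- data.frame(
    participant = rep(c("p1", "p2"), each = 3L),
    group = "g1", scale = "social_support", item = rep(1:3, 2L),
    value = c(7L, 7L, 7L, 4L, 5L, 6L))
  sc <- score_scale(resp)
  expect_equal(sc$participant$score, c(7, 5))
  expect_equal(sc$group$score, 6)

  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(score_scale(shuffled), sc)

  dup <- rbind(resp, resp[1L, ])
  expect_error(score_scale(dup), "more than once")
})

test_that("scored groups recover the latent means of a synthetic study", {
  st <- generate_study(study_config(n_groups = 20L, noise_sd_group = 0.3,
                                    seed = 14L))
  sc <- score_scale(st$responses)
  par <- sc$group[sc$group$scale == "quality_of_participation", ]
  expect_lt(abs(mean(par$score) - 5.68), 0.3)
})

test_that("Cronbach's alpha matches the direct variance formula", {
  m <- cbind(c(1, 3, 5, 7), c(2, 3, 5, 6), c(1, 4, 4, 7))
  # independent route: every variance computed directly
  k <- 3
  direct <- k / (k - 1) *
    (1 - (var(m[, 1]) + var(m[, 2]) + var(m[, 3])) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), direct, tolerance = 1e-12)

  scores <- c(2, 5, 3, 7)
  expect_equal(cronbach_alpha(cbind(scores, scores, scores)), 1)
  expect_error(cronbach_alpha(matrix(4, 3, 3)), "zero total variance")
  expect_error(cronbach_alpha(m[1L, , drop = FALSE]), "at least 2")
})

test_that("alpha of independent equal-variance items tends to zero", {
  set.seed(19)
  m <- matrix(rnorm(2000 * 4), 2000, 4)
  expect_lt(abs(cronbach_alpha(m)), 0.1)
})

test_that("GEE under independence reproduces OLS with HC0 sandwich", {
  st <- generate_study(study_config(n_groups = 12L, seed = 31L))
  dat <- support_gee_data(st)
  gee <- fit_gee(score ~ rr + det + ent, dat, id = "group",
                 corstr = "independence")
  ols <- lm(score ~ rr + det + ent, dat)
  expect_equal(gee$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)

  # singleton clusters: exchangeable GEE collapses to OLS + HC0
  dat$one <- seq_len(nrow(dat))
  solo <- fit_gee(score ~ rr + det + ent, dat, id = "one")
  expect_equal(solo$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  X <- model.matrix(ols)
  e <- resid(ols)
  hc0 <- solve(crossprod(X)) %*% crossprod(X * e, X * e) %*%
    solve(crossprod(X))
  expect_equal(solo$coefficients$se, unname(sqrt(diag(hc0))),
               tolerance = 1e-8)
  expect_equal(solo$rho, 0)
})

test_that("constant outcomes give an exact intercept-only fit", {
  dat <- data.frame(y = 5, x = rnorm(20), g = rep(1:5, each = 4L))
  fit <- fit_gee(y ~ x, dat, id = "g")
  expect_equal(fit$coefficients$estimate, c(5, 0), tolerance = 1e-10)
})

test_that("exchangeable correlation is recovered from clustered data", {
  set.seed(40)
  n_g <- 150L; m <- 4L
  g <- rep(seq_len(n_g), each = m)
  x <- rnorm(n_g * m)
  rho_true <- 0.5
  u <- rep(rnorm(n_g, 0, sqrt(rho_true)), each = m)
  y <- 1 + 0.5 * x + u + rnorm(n_g * m, 0, sqrt(1 - rho_true))
  fit <- fit_gee(y ~ x, data.frame(y, x, g), id = "g")
  expect_lt(abs(fit$rho - rho_true), 0.1)
  expect_lt(abs(fit$coefficients$estimate[2] - 0.5), 0.1)
  expect_true(fit$converged)
  expect_gt(fit$rho, -1 / (m - 1))
  expect_lt(fit$rho, 1)
})

test_that("QIC is finite for nested models with a near-p trace term", {
  set.seed(41)
  n_g <- 200L; m <- 4L
  g <- rep(seq_len(n_g), each = m)
  x1 <- rnorm(n_g * m); x2 <- rnorm(n_g * m)
  y <- 2 + 0.3 * x1 + rnorm(n_g * m)  # independence truth
  dat <- data.frame(y, x1, x2, g)
  full <- fit_gee(y ~ x1 + x2, dat, id = "g")
  nested <- fit_gee(y ~ x1, dat, id = "g")
  expect_true(is.finite(qic(full)) && is.finite(qic(nested)))

  trace_term <- qic(full) - (sum((full$y - full$fitted)^2) / full$sigma2)
  expect_lt(abs(trace_term / 2 - 3) / 3, 0.3)  # p = 3 within 30%
})

test_that("wald statistics, intervals and p-values are consistent", {
  st <- generate_study(study_config(n_groups = 15L, seed = 77L))
  fit <- fit_gee(score ~ rr + det + ent, support_gee_data(st), id = "group")
  tab <- fit$coefficients
  expect_equal(tab$wald, (tab$estimate / tab$se)^2)
  expect_equal(tab$p, pchisq(tab$wald, 1, lower.tail = FALSE))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})

test_that("variance inflation matches the regression definition", {
  set.seed(50)
  d <- data.frame(a = rnorm(200))
  d$b <- d$a * 0.8 + rnorm(200, 0, 0.6)
  d$c <- rnorm(200)
  vif <- variance_inflation(d)
  # independent route: VIF_j = 1 / (1 - R^2_j)
  r2 <- summary(lm(a ~ b + c, d))$r.squared
  expect_equal(unname(vif["a"]), 1 / (1 - r2), tolerance = 1e-10)
})

test_that("the association table has two models with four terms each", {
  st <- generate_study(study_config(n_groups = 10L, seed = 3L))
  res <- run_association(st$groups[c("group", "rr", "det", "ent")],
                         st$responses)
  expect_equal(nrow(res$table), 8L)
  expect_equal(unique(res$table$outcome),
               c("Quality of participation", "Social support"))
  expect_equal(unique(res$table$parameter),
               c("(Intercept)", "Stability", "Determinism", "Complexity"))
  expect_length(res$fits, 2L)
  expect_length(res$vif, 3L)
  expect_true(all(res$alphas > 0 & res$alphas <= 1))

  path <- withr::local_tempfile(fileext = ".csv")
  write_association_table(res, path)
  written <- read.csv(path)
  expect_equal(nrow(written), 8L)
  # QIC printed to three decimals as in the published table layout
  expect_match(readLines(path)[2], ",[0-9]+\\.[0-9]{3},")
})

test_that("null effects are rarely flagged significant", {
  flags <- matrix(FALSE, 30L, 3L)
  for (r in seq_len(30L)) {
    st <- generate_study(study_config(
      n_groups = 60L, beta_support_rr = 0, beta_support_det = 0,
      seed = 500L + r))
    fit <- fit_gee(score ~ rr + det + ent, support_gee_data(st),
                   id = "group")
    flags[r, ] <- fit$coefficients$p[2:4] < 0.05
  }
  expect_true(all(colMeans(flags) <= 0.1))
})
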