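#' Score questionnaire subscales
#'
#' Participant score = mean of that participant's items on a scale;
#' group score = mean of its participants' scores. Row order of the
#' input is irrelevant.
#'
#' @param responses Data frame with columns `participant`, `group`,
#'   `scale`, `item`, `value` (integers 1--7; duplicated
#'   participant-scale-item rows are an error).
#' @return List with data frames `participant` (`participant`, `group`,
#'   `scale`, `score`) and `group` (`group`, `scale`, `score`).
#' @export
score_scale <- function(responses) {
  needed <- c("participant", "group", "scale", "item", "value")
  stopifnot(all(needed %in% names(responses)))
  if (nrow(responses) == 0L) stop("no responses to score", call. = FALSE)
  if (anyNA(responses$value)) stop("missing item values", call. = FALSE)
  key <- paste(responses$participant, responses$scale, responses$item)
  if (anyDuplicated(key)) {
    stop("a participant answered the same item more than once",
         call. = FALSE)
  }
  part <- stats::aggregate(value ~ participant + group + scale,
                           data = responses, FUN = mean)
  names(part)[names(part) == "value"] <- "score"
  part <- part[order(part$participant, part$scale), ]
  grp <- stats::aggregate(score ~ group + scale, data = part, FUN = mean)
  grp <- grp[order(grp$group, grp$scale), ]
  rownames(part) <- rownames(grp) <- NULL
  list(participant = part, group = grp)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_j s_j^2}{s_{total}^2}\Big)}
#' with k items, sample variances (denominator n - 1) of each item and
#' of the per-participant item sums.
#'
#' @param items Numeric matrix, participants in rows, items in columns
#'   (>= 2 of each, no missing values).
#' @return Alpha (<= 1; 1 when items are duplicates).
#' @export
#' @examples
#' m <- cbind(c(1, 3, 5, 7), c(2, 3, 5, 6), c(1, 4, 4, 7))
#' cronbach_alpha(m)
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (anyNA(items)) stop("item matrix has missing values", call. = FALSE)
  n <- nrow(items); k <- ncol(items)
  if (n < 2L || k < 2L) {
    stop("need at least 2 participants and 2 items", call. = FALSE)
  }
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total variance: alpha is undefined",
                           call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / total_var)
}

#' Responses in wide item-matrix form for one scale
#'
#' Helper for [cronbach_alpha()]: pivots the long response format into
#' a participants x items matrix for the given scale.
#'
#' @param responses Long response data frame (see [score_scale()]).
#' @param scale Scale label to extract.
#' @return Numeric matrix, participants in rows.
#' @export
item_matrix <- function(responses, scale) {
  sub <- responses[responses$scale == scale, ]
  if (nrow(sub) == 0L) stop("no responses for scale ", scale, call. = FALSE)
  wide <- stats::reshape(sub[c("participant", "item", "value")],
                         idvar = "participant", timevar = "item",
                         direction = "wide")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$participant
  m[, order(colnames(m)), drop = FALSE]
}

exchangeable_weight <- function(n_i, sigma2, rho) {
  # closed-form inverse of sigma2 * ((1 - rho) I + rho J)
  a <- 1 / (1 - rho)
  b <- -rho / ((1 - rho) * (1 - rho + n_i * rho))
  (diag(a, n_i) + matrix(b, n_i, n_i)) / sigma2
}

#' Generalized estimating equations for clustered Gaussian outcomes
#'
#' Marginal linear model with identity link and an exchangeable (or
#' independence) working correlation, for outcomes measured on
#' individuals nested in groups. Alternates generalized least squares
#' for the coefficients with a moment update of the common
#' within-cluster correlation from Pearson residuals, to convergence
#' (`max |delta beta| < tol`). Standard errors come from the robust
#' sandwich covariance, so inference is valid even when the working
#' correlation is wrong; per-term Wald chi-squares use 1 df and 95%
#' confidence intervals the normal quantile 1.96. With singleton
#' clusters (or `corstr = "independence"`) the coefficients equal
#' ordinary least squares.
#'
#' @param formula Model formula, e.g. `score ~ rr + det + ent`.
#' @param data Data frame holding outcome, predictors and the cluster
#'   id.
#' @param id Name of the cluster-id column.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param tol Convergence tolerance on the coefficient update.
#' @param maxit Maximum iterations.
#' @return An object of class `gee_fit`: `coefficients` table (`term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `wald`, `p`), `vcov`
#'   (robust), `rho`, `sigma2`, `n_clusters`, `converged`, plus the
#'   design kept for [qic()].
#' @export
fit_gee <- function(formula, data, id, corstr = c("exchangeable",
                                                  "independence"),
                    tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  stopifnot(id %in% names(data))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  cluster <- as.character(data[[id]][as.integer(rownames(mf))])
  idx <- split(seq_len(n), cluster)
  n_clusters <- length(idx)
  if (n_clusters < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (n_clusters <= p) {
    warning("fewer clusters than parameters: sandwich variance unreliable",
            call. = FALSE)
  }
  sizes <- lengths(idx)
  n_pairs <- sum(sizes * (sizes - 1) / 2)

  beta <- stats::lm.fit(X, y)$coefficients
  if (sum((y - drop(X %*% beta))^2) == 0) {
    # perfect fit (e.g. constant outcome): GLS cannot improve and the
    # sandwich collapses to zero
    coef_table <- data.frame(
      term = colnames(X), estimate = unname(beta), se = 0,
      ci_low = unname(beta), ci_high = unname(beta),
      wald = NA_real_, p = NA_real_,
      row.names = NULL, stringsAsFactors = FALSE)
    return(structure(
      list(coefficients = coef_table, vcov = matrix(0, p, p), rho = 0,
           sigma2 = 0, n_clusters = n_clusters, n = n, corstr = corstr,
           converged = TRUE, X = X, y = y, fitted = drop(X %*% beta),
           formula = formula),
      class = "gee_fit"))
  }
  rho <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    e <- y - drop(X %*% beta)
    sigma2 <- sum(e^2) / (n - p)
    if (corstr == "exchangeable" && n_pairs > 0) {
      cross <- sum(vapply(idx, function(i) {
        s <- sum(e[i]); (s^2 - sum(e[i]^2)) / 2
      }, 0))
      denom <- max(n_pairs - p, 1)
      rho <- cross / (denom * sigma2)
      rho_min <- -1 / (max(sizes) - 1) + 1e-6
      if (rho <= rho_min || rho >= 1 - 1e-6) {
        warning(sprintf("estimated rho = %.3f clamped into its valid range",
                        rho), call. = FALSE)
        rho <- min(max(rho, rho_min), 1 - 1e-6)
      }
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (i in idx) {
      W <- exchangeable_weight(length(i), sigma2, rho)
      Xi <- X[i, , drop = FALSE]
      A <- A + crossprod(Xi, W %*% Xi)
      b <- b + crossprod(Xi, W %*% y[i])
    }
    beta_new <- drop(solve(A, b))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("GEE did not converge in ", maxit, " iterations",
                          call. = FALSE)

  e <- y - drop(X %*% beta)
  sigma2 <- sum(e^2) / (n - p)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (i in idx) {
    W <- exchangeable_weight(length(i), sigma2, rho)
    Xi <- X[i, , drop = FALSE]
    B <- B + crossprod(Xi, W %*% Xi)
    u <- crossprod(Xi, W %*% e[i])
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  se <- sqrt(diag(vcov))
  wald <- (beta / se)^2
  coef_table <- data.frame(
    term = colnames(X), estimate = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    wald = wald, p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coef_table, vcov = vcov, rho = rho,
         sigma2 = sigma2, n_clusters = n_clusters, n = n,
         corstr = corstr, converged = converged,
         X = X, y = y, fitted = drop(X %*% beta), formula = formula),
    class = "gee_fit"
  )
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE (%s working correlation, %d clusters, n = %d)\n",
              x$corstr, x$n_clusters, x$n))
  cat(sprintf("rho = %.3f, sigma2 = %.3f, QIC = %.3f\n",
              x$rho, x$sigma2, qic(x)))
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], function(v) sprintf("%.4f", v))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' QIC model-selection criterion for a GEE fit
#'
#' Pan's quasi-likelihood under the independence model information
#' criterion: `-2 QL + 2 trace(Omega_I V_R)`, where QL is the Gaussian
#' quasi-likelihood of the fitted means under working independence,
#' `Omega_I = X'X / sigma2` the independence-model information, and
#' `V_R` the robust covariance. The trace term is close to the
#' parameter count when the working independence model is adequate.
#'
#' @param fit A `gee_fit`.
#' @return QIC (finite scalar).
#' @export
qic <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  if (fit$sigma2 == 0) return(NA_real_)  # degenerate perfect fit
  e <- fit$y - fit$fitted
  ql <- -sum(e^2) / (2 * fit$sigma2)
  omega <- crossprod(fit$X) / fit$sigma2
  -2 * ql + 2 * sum(diag(omega %*% fit$vcov))
}

#' Variance inflation factors of the GEE predictors
#'
#' Standard VIFs from the inverse correlation matrix of the non-
#' intercept columns of the design; values above 10 indicate
#' problematic linear dependence between predictors.
#'
#' @param data Data frame of predictor columns (numeric).
#' @return Named numeric vector of VIFs.
#' @export
variance_inflation <- function(data) {
  X <- as.matrix(data)
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  r <- stats::cor(X)
  stats::setNames(diag(solve(r)), colnames(X))
}

#' Fit the two marginal models linking recurrence measures to outcomes
#'
#' Scores both questionnaire subscales, joins each participant to the
#' recurrence measures of their group, and fits two GEEs with
#' exchangeable working correlation -- one per outcome (quality of
#' participation; social support) -- each with intercept plus the three
#' group-level predictors stability (recurrence rate), determinism and
#' complexity (entropy). Also reports predictor variance inflation
#' factors, flagged above 10.
#'
#' @param measures Data frame with columns `group`, `rr`, `det`, `ent`
#'   (one row per group).
#' @param responses Long questionnaire data frame (see
#'   [score_scale()]); `scale` must contain
#'   `"quality_of_participation"` and `"social_support"`.
#' @param corstr Working correlation passed to [fit_gee()].
#' @return An object of class `association_results`: `table` (rows
#'   Outcome, QIC, Parameter, B, SE, ci_low, ci_high, Wald, p), `fits`
#'   (named list of `gee_fit`), `vif`, `alphas` (Cronbach's alpha per
#'   scale), `scores` (the [score_scale()] output).
#' @export
run_association <- function(measures, responses,
                            corstr = "exchangeable") {
  stopifnot(all(c("group", "rr", "det", "ent") %in% names(measures)))
  scores <- score_scale(responses)
  scales <- c(`Quality of participation` = "quality_of_participation",
              `Social support` = "social_support")
  missing_scales <- setdiff(scales, unique(responses$scale))
  if (length(missing_scales) > 0L) {
    stop("responses lack scale(s): ",
         paste(missing_scales, collapse = ", "), call. = FALSE)
  }
  vif <- variance_inflation(measures[c("rr", "det", "ent")])
  if (any(vif > 10)) {
    warning("variance inflation above 10 for: ",
            paste(names(vif)[vif > 10], collapse = ", "), call. = FALSE)
  }
  param_labels <- c(`(Intercept)` = "(Intercept)", rr = "Stability",
                    det = "Determinism", ent = "Complexity")
  fits <- list(); rows <- list()
  for (nm in names(scales)) {
    part <- scores$participant[scores$participant$scale == scales[[nm]], ]
    dat <- merge(part, measures[c("group", "rr", "det", "ent")],
                 by = "group")
    fit <- fit_gee(score ~ rr + det + ent, dat, id = "group",
                   corstr = corstr)
    fits[[scales[[nm]]]] <- fit
    tab <- fit$coefficients
    rows[[nm]] <- data.frame(
      outcome = nm, qic = qic(fit),
      parameter = unname(param_labels[tab$term]),
      B = tab$estimate, SE = tab$se,
      ci_low = tab$ci_low, ci_high = tab$ci_high,
      wald = tab$wald, p = tab$p,
      stringsAsFactors = FALSE
    )
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  alphas <- vapply(scales, function(s) {
    cronbach_alpha(item_matrix(responses, s))
  }, 0)
  structure(
    list(table = table, fits = fits, vif = vif, alphas = alphas,
         scores = scores),
    class = "association_results"
  )
}

#' @export
print.association_results <- function(x, ...) {
  cat("GEE associations between recurrence measures and subscales\n")
  tab <- x$table
  tab[vapply(tab, is.numeric, TRUE)] <-
    lapply(tab[vapply(tab, is.numeric, TRUE)], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Cronbach's alpha: participation %.2f, support %.2f\n",
              x$alphas[["Quality of participation"]],
              x$alphas[["Social support"]]))
  cat("VIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Write the association results table as CSV
#'
#' One row per model term, mirroring the published layout: outcome,
#' QIC, parameter, B, SE, 95% CI bounds, Wald chi-square, p.
#'
#' @param results An `association_results` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path) {
  stopifnot(inherits(results, "association_results"))
  tab <- results$table
  tab$qic <- sprintf("%.3f", tab$qic)
  num <- c("B", "SE", "ci_low", "ci_high", "wald", "p")
  tab[num] <- lapply(tab[num], function(v) sprintf("%.4f", v))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
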