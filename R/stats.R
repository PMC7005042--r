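# Inference stage: nonparametric group comparisons, correlation screen,
# univariate -> multivariate logistic regression, ROC with Youden cut-offs.

#' Mann-Whitney U test for two independent samples
#'
#' The U statistic counts pairs with `x_i > y_j`, ties counted half (computed
#' directly from midranks). The p-value is the exact enumeration when the
#' pooled size is at most `exact_limit` and there are no cross-sample ties,
#' and the tie-corrected normal approximation with continuity correction
#' otherwise (both via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @param exact_limit Largest pooled size for the exact path under `"auto"`.
#' @return List with `U`, `p_value` and `method_used`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           exact_limit = 12) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
                  auto = (n1 + n2 <= exact_limit) && !ties,
                  exact = TRUE, normal = FALSE)
  if (all(duplicated(c(x, y))[-1])) {          # all values identical
    return(list(U = U, p_value = 1, method_used = "degenerate"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = U, p_value = min(1, wt$p.value),
       method_used = if (exact && !ties) "exact" else "normal")
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped; the statistic is the sum of positive-signed
#' midranks of `|d|`. Exact null enumeration for at most `exact_limit`
#' nonzero differences without magnitude ties, normal approximation with
#' continuity correction otherwise.
#'
#' @param diffs Paired differences.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit Largest n for the exact path under `"auto"`.
#' @return List with `W`, `p_value`, `n_used`, `method_used`.
#' @export
wilcoxon_signed_rank <- function(diffs, method = c("auto", "exact", "normal"),
                                 exact_limit = 12) {
  method <- match.arg(method)
  d <- diffs[is.finite(diffs)]
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero", call. = FALSE)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- switch(method,
                  auto = length(d) <= exact_limit && !ties,
                  exact = TRUE, normal = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p_value = min(1, wt$p.value),
       n_used = length(d),
       method_used = if (exact && !ties) "exact" else "normal")
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Product-moment correlations over pairwise-complete cases, with the usual
#' t-test p-value per cell. Cells involving a zero-variance column, or with
#' fewer than 3 complete pairs, are NA.
#'
#' @param df Data frame of numeric columns.
#' @return List of matrices `r` and `p`.
#' @export
pearson_correlation_matrix <- function(df) {
  df <- as.data.frame(df)
  k <- ncol(df)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(df), names(df)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- df[[i]]; xj <- df[[j]]
      ok <- is.finite(xi) & is.finite(xj)
      if (sum(ok) < 3) next
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Logistic regression with Wald odds-ratio summaries
#'
#' Maximum-likelihood binomial fit (IRLS via [stats::glm()]) of a binary
#' outcome on predictors kept in their raw units, so odds ratios read per
#' degree, per cm^3/s, per exponent unit and so on. Wald standard errors;
#' `OR = exp(coef)`, 95% CI `exp(coef +/- 1.96 SE)`. Non-convergence and
#' (quasi-)separation are flagged rather than silently reported.
#'
#' @param y Binary outcome (0/1 or logical).
#' @param X Data frame or matrix of predictors (rows match `y`).
#' @return List with `coefficients` (data frame: term, estimate, se, or,
#'   ci_lower, ci_upper, p_value), `converged`, `separation`.
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (length(unique(y[is.finite(y)])) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  X <- as.data.frame(X)
  if (any(vapply(X, function(c) stats::sd(c, na.rm = TRUE), 0) == 0)) {
    stop("constant predictor column", call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)$coefficients
  est <- s[-1, 1, drop = TRUE]
  se <- s[-1, 2, drop = TRUE]
  # huge Wald SEs are the signature of separation even without the warning
  if (any(se > 100 * pmax(1, abs(est)))) sep <- TRUE
  co <- data.frame(term = rownames(s)[-1],
                   estimate = est, se = se,
                   or = exp(est),
                   ci_lower = exp(est - 1.96 * se),
                   ci_upper = exp(est + 1.96 * se),
                   p_value = s[-1, 4, drop = TRUE],
                   row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = co, converged = fit$converged, separation = sep,
       intercept = unname(s[1, 1]), loglik = as.numeric(stats::logLik(fit)))
}

#' Univariate logistic screen over candidate predictors
#'
#' One single-predictor fit per candidate, in the order given.
#'
#' @param data Data frame holding the candidate columns.
#' @param vars Character vector of candidate column names.
#' @param y Binary outcome vector aligned with `data` rows.
#' @return Data frame with one row per candidate: term, estimate, se, or,
#'   ci_lower, ci_upper, p_value, converged, separation.
#' @export
univariate_screen <- function(data, vars, y) {
  rows <- lapply(vars, function(v) {
    f <- fit_logistic(y, data[, v, drop = FALSE])
    cbind(f$coefficients,
          converged = f$converged, separation = f$separation,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$term <- vars
  out
}

#' Entry rule and correlation-based pruning for the multivariate model
#'
#' Keeps candidates with univariate `p < p_enter`; then, for every retained
#' pair correlated beyond `|r| > r_max`, drops the member with the larger
#' univariate p-value (on a tie, the later one in input order). Every drop is
#' recorded in an audit log.
#'
#' @param screen Data frame from [univariate_screen()] (`term`, `p_value`).
#' @param corr Correlation matrix (`$r` of [pearson_correlation_matrix()])
#'   covering the screened terms.
#' @param p_enter Univariate entry threshold. Default 0.1.
#' @param r_max Absolute-correlation threshold. Default 0.5.
#' @return List with `selected` (character) and `audit` (data frame of drops
#'   with reasons).
#' @export
select_model_variables <- function(screen, corr, p_enter = 0.1, r_max = 0.5) {
  audit <- data.frame(variable = character(), reason = character(),
                      stringsAsFactors = FALSE)
  pv <- stats::setNames(screen$p_value, screen$term)
  keep <- screen$term[screen$p_value < p_enter]
  for (v in setdiff(screen$term, keep)) {
    audit <- rbind(audit, data.frame(
      variable = v,
      reason = sprintf("univariate p = %.4g >= %.3g", pv[[v]], p_enter)))
  }
  dropped <- character()
  ord <- stats::setNames(seq_along(screen$term), screen$term)
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (j <= i) next
      a <- keep[i]; b <- keep[j]
      if (a %in% dropped || b %in% dropped) next
      rij <- corr[a, b]
      if (!is.na(rij) && abs(rij) > r_max) {
        # drop the weaker (larger p); on tie, the later in input order
        worse <- if (pv[[a]] > pv[[b]]) a
                 else if (pv[[b]] > pv[[a]]) b
                 else if (ord[[a]] > ord[[b]]) a else b
        other <- setdiff(c(a, b), worse)
        dropped <- c(dropped, worse)
        audit <- rbind(audit, data.frame(
          variable = worse,
          reason = sprintf("|r| = %.3f with %s exceeds %.3g (univariate p %.4g vs %.4g)",
                           abs(rij), other, r_max, pv[[worse]], pv[[other]])))
      }
    }
  }
  list(selected = setdiff(keep, dropped), audit = audit)
}

#' Empirical ROC analysis with Youden-optimal cut-off
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' pooled scores (plus open ends); at each threshold a score above the
#' threshold calls a case. AUC is the trapezoid area, which equals the
#' Mann-Whitney U of the two score samples divided by `n1 * n2` with ties
#' counted half. The optimal cut-off maximises Youden's
#' `J = sensitivity + specificity - 1`, ties broken toward the smallest
#' threshold. Orientation is "higher score = case": callers flip the sign of
#' protective markers first.
#'
#' @param scores_cases,scores_controls Numeric score samples (non-empty).
#' @return List with `auc`, `coords` (data frame threshold / sensitivity /
#'   specificity), `cutoff`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' roc_analysis(c(5, 6, 7), c(1, 2, 3))
roc_analysis <- function(scores_cases, scores_controls) {
  ca <- scores_cases[is.finite(scores_cases)]
  co <- scores_controls[is.finite(scores_controls)]
  if (length(ca) == 0 || length(co) == 0) stop("empty sample", call. = FALSE)
  u <- sort(unique(c(ca, co)))
  thr <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  thr <- c(u[1] - 1, thr, u[length(u)] + 1)
  sca <- sort(ca); sco <- sort(co)
  sens <- 1 - findInterval(thr, sca) / length(ca)
  spec <- findInterval(thr, sco) / length(co)
  coords <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid over the ROC polygon; identical to U/(n1 n2) with half-ties
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  list(auc = auc, coords = coords, cutoff = thr[best],
       sensitivity = sens[best], specificity = spec[best])
}
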