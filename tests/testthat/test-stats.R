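test_that("Mann-Whitney U counts pairs and matches exact enumeration on tiny samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method_used, "exact")

  # U is the pair count with half ties, via midranks
  x <- c(1, 2, 2, 5); y <- c(2, 3, 4)
  u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(mann_whitney_u(x, y)$U, u_brute)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p_value, 1)

  big <- mann_whitney_u(rnorm(200, 10), rnorm(200, 0))
  expect_lt(big$p_value, 1e-10)
  expect_equal(big$U, 200 * 200, tolerance = 0.01)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Wilcoxon signed-rank takes the exact path on small samples and drops zeros", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$W, 15)
  expect_equal(r$p_value, 2 / 32, tolerance = 1e-12)
  anti <- wilcoxon_signed_rank(c(-2, 2, -5, 5))
  expect_equal(anti$p_value, 1)
  withz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(withz$n_used, 3)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("Pearson matrix gives unit diagonal, detects derived-flow correlation, flags degeneracy", {
  set.seed(51)
  n <- 2000
  vm <- runif(n, 60, 80)                 # bounded velocity variation
  p0 <- rnorm(n, 6, 1.5)
  df <- data.frame(vm = vm, p0 = p0, vfr = vm * p0 / 100,
                   noise = rnorm(n), flat = rep(1, n))
  cm <- pearson_correlation_matrix(df)
  expect_equal(unname(diag(cm$r)[1:4]), rep(1, 4))
  expect_gt(cm$r["vfr", "p0"], 0.9)
  expect_lt(abs(cm$r["noise", "vm"]), 0.08)
  expect_true(all(is.na(cm$r["flat", ])))   # zero variance column
  # independent columns at large n have near-zero correlation
  big <- pearson_correlation_matrix(data.frame(a = rnorm(1e4), b = rnorm(1e4)))
  expect_lt(abs(big$r["a", "b"]), 0.05)
})

test_that("logistic fit matches the grid-likelihood oracle and flags pathologies", {
  sym <- fit_logistic(c(0, 1, 0, 1), data.frame(x = c(0, 0, 1, 1)))
  expect_equal(sym$coefficients$estimate, 0, tolerance = 1e-8)
  expect_equal(sym$coefficients$or, 1, tolerance = 1e-8)

  set.seed(52)
  x <- rnorm(20)
  y <- rbinom(20, 1, plogis(0.3 + 0.8 * x))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_logistic(y, data.frame(x = x))
  oracle <- grid_logistic(y, x, step = 1e-3)
  expect_lt(abs(fit$coefficients$estimate - oracle$b1), 2e-3)
  expect_lt(abs(fit$intercept - oracle$b0), 2e-3)
  # the MLE log-likelihood dominates every grid point
  expect_gte(fit$loglik, oracle$loglik - 1e-9)

  sep <- fit_logistic(c(0, 0, 0, 1, 1, 1), data.frame(x = c(1, 2, 3, 7, 8, 9)))
  expect_true(sep$separation)
  expect_error(fit_logistic(rep(1, 5), data.frame(x = rnorm(5))), "classes")
  expect_error(fit_logistic(c(0, 1, 0, 1), data.frame(x = rep(2, 4))), "constant")
})

test_that("univariate screen fits one model per candidate with null coverage", {
  set.seed(53)
  n <- 300
  dat <- data.frame(strong = c(rnorm(n / 2, 1), rnorm(n / 2)),
                    noise = rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  sc <- univariate_screen(dat, c("strong", "noise"), y)
  expect_equal(sc$term, c("strong", "noise"))
  expect_lt(sc$p_value[1], 0.001)
  # pure-noise CI spans 1 for most seeds
  cover <- replicate(40, {
    yy <- rbinom(100, 1, 0.5)
    if (length(unique(yy)) < 2) return(TRUE)
    f <- univariate_screen(data.frame(z = rnorm(100)), "z", yy)
    f$ci_lower[1] < 1 && f$ci_upper[1] > 1
  })
  expect_gte(mean(cover), 0.85)
})

test_that("variable selection applies the entry threshold and correlation tie-breaks", {
  corr0 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sc <- data.frame(term = c("a", "b"), p_value = c(0.02, 0.5))
  s1 <- select_model_variables(sc, corr0)
  expect_equal(s1$selected, "a")
  expect_equal(s1$audit$variable, "b")

  corr1 <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sc2 <- data.frame(term = c("a", "b"), p_value = c(0.01, 0.02))
  s2 <- select_model_variables(sc2, corr1)
  expect_equal(s2$selected, "a")
  expect_match(s2$audit$reason[s2$audit$variable == "b"], "exceeds")

  # tie on p drops the later variable in input order
  sc3 <- data.frame(term = c("a", "b"), p_value = c(0.02, 0.02))
  expect_equal(select_model_variables(sc3, corr1)$selected, "a")
})

test_that("ROC analysis: separated samples, null behaviour, binormal limit", {
  r <- roc_analysis(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 4)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  set.seed(54)
  null <- roc_analysis(rnorm(2000), rnorm(2000))
  expect_equal(null$auc, 0.5, tolerance = 0.05)

  binorm <- roc_analysis(rnorm(1e5, 1), rnorm(1e5, 0))
  expect_equal(binorm$auc, pnorm(1 / sqrt(2)), tolerance = 0.01)
  expect_error(roc_analysis(numeric(0), 1), "empty")
})

test_that("AUC equals U/(n1 n2) exactly, including heavy ties", {
  set.seed(55)
  for (i in 1:30) {
    ca <- sample(0:5, 40, replace = TRUE) + ifelse(runif(40) < 0.5, 0.5, 0)
    co <- sample(0:5, 25, replace = TRUE)
    r <- roc_analysis(ca, co)
    u <- mann_whitney_u(ca, co)$U
    expect_equal(r$auc, u / (40 * 25), tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly increasing score transforms", {
  set.seed(56)
  ca <- rnorm(60, 1); co <- rnorm(80)
  r1 <- roc_analysis(ca, co)
  mono <- function(z) exp(z) + z^3
  r2 <- roc_analysis(mono(ca), mono(co))
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$sensitivity, r2$sensitivity)
  expect_equal(r1$specificity, r2$specificity)
  # the mapped cut-off classifies identically
  expect_equal(sum(mono(ca) > r2$cutoff), sum(ca > r1$cutoff))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(57)
  ca <- rnorm(70, 0.8); co <- rnorm(90)
  ours <- roc_analysis(ca, co)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 70), rep(0, 90)), predictor = c(ca, co),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
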