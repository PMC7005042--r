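# Shared fixtures and independent oracles used across test files.

# Brute-force grid scan for the junction exponent: locate the sign change of
# f(n) = (r1/r0)^n + (r2/r0)^n - 1 on a coarse grid, then refine on a 1e-6
# grid inside the bracketing cell. Independent of the package's bisection.
grid_junction_exponent <- function(r0, r1, r2, coarse = 0.01, fine = 1e-6,
                                   lo = 0.1, hi = 20) {
  f <- function(n) (r1 / r0)^n + (r2 / r0)^n - 1
  n <- seq(lo, hi, by = coarse)
  fv <- f(n)
  i <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  n2 <- seq(n[i] - fine, n[i + 1] + 2 * fine, by = fine)
  fv2 <- f(n2)
  j <- which(fv2[-length(fv2)] > 0 & fv2[-1] <= 0)[1]
  (n2[j] + n2[j + 1]) / 2
}

# Radii triples valid for both rule families: r0 strictly between r1 and
# sqrt(r1^2 + r2^2) keeps a positive root and both triangle inequalities.
random_valid_triple <- function() {
  repeat {
    r1 <- runif(1, 0.6, 1.6)
    r2 <- runif(1, 0.4, 1) * r1
    lo <- r1
    hi <- sqrt(r1^2 + r2^2)
    r0 <- runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    if (r0 > r1 && r0^2 < r1^2 + r2^2) return(c(r0 = r0, r1 = r1, r2 = r2))
  }
}

# Minimal two-group cohort (3 rows per group) with clean geometry; small
# enough that every nonparametric p-value takes the exact path.
tiny_cohort <- function() {
  data.frame(
    subject_id = sprintf("S%02d", 1:6),
    group = rep(c("An", "R"), each = 3),
    r0 = c(1.40, 1.35, 1.45, 1.30, 1.28, 1.33),
    r1 = c(1.15, 1.10, 1.20, 1.12, 1.08, 1.14),
    r2 = c(0.85, 0.80, 0.90, 0.83, 0.86, 0.80),
    p0 = c(6.2, 5.7, 6.6, 5.3, 5.1, 5.6),
    p1 = c(4.2, 3.8, 4.5, 3.9, 3.7, 4.1),
    p2 = c(2.3, 2.0, 2.5, 2.2, 2.3, 2.0),
    alpha_deg = c(131, 122, 140, 96, 101, 91),
    beta_deg = c(120, 125, 118, 133, 130, 136),
    gamma_deg = c(99, 104, 95, 118, 112, 120),
    vps = c(101, 96, 108, 95, 93, 99),
    ved = c(44, 41, 47, 43, 42, 45),
    vm = c(63, 60, 67, 62, 60, 64),
    tortuosity = c(0.05, 0.06, 0.07, 0.08, 0.06, 0.07),
    stringsAsFactors = FALSE)
}

# Grid-search maximiser of the Bernoulli log-likelihood for a one-predictor
# logistic model; coarse-to-fine refinement ending at `step`. Independent of
# glm's IRLS path.
grid_logistic <- function(y, x, step = 1e-3) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b <- c(0, 0)
  width <- c(8, 8)
  repeat {
    b0s <- seq(b[1] - width[1], b[1] + width[1], length.out = 41)
    b1s <- seq(b[2] - width[2], b[2] + width[2], length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    ij <- arrayInd(which.max(vals), dim(vals))
    b <- c(b0s[ij[1]], b1s[ij[2]])
    if (max(width) / 20 <= step / 2) break
    width <- width / 10
  }
  list(b0 = b[1], b1 = b[2], loglik = ll(b[1], b[2]))
}
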