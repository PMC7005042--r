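# Predicted optimal branching angles under the principle of minimum work.
#
# Both rule families reduce to the angles of a triangle: with side lengths
# (r0, r1, r2) for the minimum-surface / minimum-endothelial-drag rules, and
# (r0^2, r1^2, r2^2) for the minimum-volume / minimum-pumping-power rules.
# Validity is exactly the triangle inequality on those side lengths.

acos_deg <- function(x) acos(x) * 180 / pi

# Cosine arguments within `eps` of +/-1 are boundary geometry, not error;
# anything further out means no interior optimum exists for that rule.
.optimal_angles <- function(w0, w1, w2, eps = 1e-12) {
  c1 <- (w0^2 + w1^2 - w2^2) / (2 * w0 * w1)
  c2 <- (w0^2 + w2^2 - w1^2) / (2 * w0 * w2)
  ct <- (w0^2 - w1^2 - w2^2) / (2 * w1 * w2)
  valid <- abs(c1) <= 1 + eps & abs(c2) <= 1 + eps & abs(ct) <= 1 + eps
  clamp <- function(x) pmin(1, pmax(-1, x))
  phi1 <- ifelse(valid, acos_deg(clamp(c1)), NA_real_)
  phi2 <- ifelse(valid, acos_deg(clamp(c2)), NA_real_)
  total <- ifelse(valid, acos_deg(clamp(ct)), NA_real_)
  list(phi1 = phi1, phi2 = phi2, total = total, valid = valid)
}

#' Optimal angles under the minimum-surface and minimum-endothelial-drag rules
#'
#' Predicted optimal angles between the trunk-axis prolongation and the
#' larger (`phi1`) and smaller (`phi2`) branches:
#' `cos(phi1) = (r0^2 + r1^2 - r2^2) / (2 r0 r1)`,
#' `cos(phi2) = (r0^2 + r2^2 - r1^2) / (2 r0 r2)`,
#' `cos(phi1 + phi2) = (r0^2 - r1^2 - r2^2) / (2 r1 r2)`.
#' When any cosine argument leaves `[-1, 1]` the radii admit no interior
#' optimum under this rule; angles are NA and `valid_s` is FALSE (no
#' clamping, which would fabricate a 0 or 180 degree optimum).
#'
#' @param r0,r1,r2 Radii, mm, canonical order (vectorised).
#' @return List with `phi1_s_deg`, `phi2_s_deg`, `total_s_deg`, `valid_s`.
#' @export
#' @examples
#' optimal_angles_surface(1.39, 1.16, 0.84)
optimal_angles_surface <- function(r0, r1, r2) {
  if (any(!is.finite(c(r0, r1, r2))) || any(c(r0, r1, r2) <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  a <- .optimal_angles(r0, r1, r2)
  list(phi1_s_deg = a$phi1, phi2_s_deg = a$phi2,
       total_s_deg = a$total, valid_s = a$valid)
}

#' Optimal angles under the minimum-volume and minimum-pumping-power rules
#'
#' Same construction as [optimal_angles_surface()] but with squared radii:
#' `cos(phi1') = (r0^4 + r1^4 - r2^4) / (2 r0^2 r1^2)`, etc. For a
#' symmetric cube-law bifurcation this yields the classic Murray optimum
#' `phi' = acos(2^(-1/3)) ~ 37.47` degrees per branch.
#'
#' @inheritParams optimal_angles_surface
#' @return List with `phi1_v_deg`, `phi2_v_deg`, `total_v_deg`, `valid_v`.
#' @export
optimal_angles_volume <- function(r0, r1, r2) {
  if (any(!is.finite(c(r0, r1, r2))) || any(c(r0, r1, r2) <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  a <- .optimal_angles(r0^2, r1^2, r2^2)
  list(phi1_v_deg = a$phi1, phi2_v_deg = a$phi2,
       total_v_deg = a$total, valid_v = a$valid)
}

#' Predicted-minus-observed angle deviations
#'
#' The six deviations contrast each predicted optimal angle with the
#' corresponding observed angle: the per-branch optima against the observed
#' trunk-axis angles `Phi1`, `Phi2`, and the optimal total against the
#' observed inter-branch angle `alpha`. Negative values mean the observed
#' bifurcation opens wider than its energetic optimum. An invalid rule
#' propagates as NA.
#'
#' @param opt A list as returned by combining [optimal_angles_surface()] and
#'   [optimal_angles_volume()] (fields `phi1_s_deg`, ..., `total_v_deg`).
#' @param phi1_obs_deg,phi2_obs_deg Observed trunk-axis branch angles, degrees.
#' @param alpha_deg Observed angle between the branches, degrees.
#' @return List with `d1_s`, `d2_s`, `dt_s`, `d1_v`, `d2_v`, `dt_v` (degrees).
#' @export
#' @examples
#' opt <- c(optimal_angles_surface(1.39, 1.16, 0.84),
#'          optimal_angles_volume(1.39, 1.16, 0.84))
#' angle_deviations(opt, 58.5, 82.4, 128.6)
angle_deviations <- function(opt, phi1_obs_deg, phi2_obs_deg, alpha_deg) {
  list(d1_s = opt$phi1_s_deg - phi1_obs_deg,
       d2_s = opt$phi2_s_deg - phi2_obs_deg,
       dt_s = opt$total_s_deg - alpha_deg,
       d1_v = opt$phi1_v_deg - phi1_obs_deg,
       d2_v = opt$phi2_v_deg - phi2_obs_deg,
       dt_v = opt$total_v_deg - alpha_deg)
}

#' Weighted-Fermat-point oracle for the optimal branching angles
#'
#' Independent numerical check of the closed-form optima. Three fixed
#' endpoints (parent source and two branch targets) are placed in the plane,
#' far from collinear, and the junction position `J` minimising the weighted
#' total cable length `sum_i w_i |J - X_i|` with weights `w_i = r_i^k` is
#' found by Weiszfeld fixed-point iteration from the endpoint centroid
#' (derivative-free; stops when `J` moves less than 1e-10 between
#' iterations). `k = 1` reproduces the minimum-surface optimum, `k = 2` the
#' minimum-volume optimum; the returned angles are measured at `J` between
#' the parent-flow direction and each branch segment and are independent of
#' the (seeded) endpoint placement.
#'
#' @param r0,r1,r2 Radii (scalars), canonical order.
#' @param k Weight exponent, 1 or 2.
#' @param seed Integer seed controlling endpoint placement.
#' @return List with `phi1_deg`, `phi2_deg`.
#' @export
weighted_fermat_oracle <- function(r0, r1, r2, k = 1, seed = 1L) {
  stopifnot(k %in% c(1, 2))
  if (any(c(r0, r1, r2) <= 0)) stop("radii must be positive", call. = FALSE)
  w <- c(r0, r1, r2)^k
  if (any(w >= sum(w) - w)) {
    stop("oracle infeasible: one weight dominates, optimum sits at an endpoint",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # The junction stays interior only when the branch endpoints subtend a
  # narrow enough angle at the parent endpoint (a wide placement parks the
  # optimum on an endpoint). Try a shrinking schedule of subtended angles
  # and accept the first interior stationary point, certified by the
  # weighted force-balance residual -- a check independent of any closed form.
  weiszfeld <- function(X) {
    J <- colMeans(X)
    for (iter in 1:100000) {
      d <- sqrt(rowSums((X - matrix(J, 3, 2, byrow = TRUE))^2))
      if (any(d < 1e-12)) return(list(J = J, d = d, ok = FALSE))
      Jn <- colSums(X * (w / d)) / sum(w / d)
      moved <- sqrt(sum((Jn - J)^2))
      J <- Jn
      if (moved < 1e-10) break
    }
    d <- sqrt(rowSums((X - matrix(J, 3, 2, byrow = TRUE))^2))
    E <- (X - matrix(J, 3, 2, byrow = TRUE)) / d      # unit vectors J -> X_i
    resid <- sqrt(sum(colSums(w * E)^2)) / sum(w)
    list(J = J, d = d, ok = all(d > 1e-6 * max(d)) && resid < 1e-7)
  }
  L <- stats::runif(3, 5, 10)
  jit <- stats::runif(2, -0.05, 0.05)
  for (theta_deg in c(150, 120, 90, 60, 40, 25, 15, 8, 4, 2)) {
    half <- theta_deg * pi / 360
    X <- rbind(c(-L[1], 0),
               L[2] * c(cos(half + jit[1]), sin(half + jit[1])),
               L[3] * c(cos(-half + jit[2]), sin(-half + jit[2])))
    fit <- weiszfeld(X)
    if (fit$ok) {
      J <- fit$J
      u0 <- (J - X[1, ]); u0 <- u0 / sqrt(sum(u0^2))  # parent flow direction
      b1 <- (X[2, ] - J); b1 <- b1 / sqrt(sum(b1^2))
      b2 <- (X[3, ] - J); b2 <- b2 / sqrt(sum(b2^2))
      ang <- function(u, v) acos_deg(pmin(1, pmax(-1, sum(u * v))))
      return(list(phi1_deg = ang(u0, b1), phi2_deg = ang(u0, b2)))
    }
  }
  stop("oracle infeasible: no interior optimum found for any endpoint placement",
       call. = FALSE)
}
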