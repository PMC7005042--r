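#' Vessel radius from a best-fit diameter
#'
#' Radii of the parent trunk and both branches enter every downstream index;
#' segmentation software typically reports best-fit diameters, so the
#' conversion is simply `d / 2`.
#'
#' @param d Best-fit diameter in mm (vectorised). Must be strictly positive.
#' @return Radius in mm.
#' @export
#' @examples
#' radius_from_diameter(2.78)
radius_from_diameter <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("diameter must be a positive finite number", call. = FALSE)
  }
  d / 2
}

#' Canonical branch ordering for a bifurcation
#'
#' Downstream formulas assume branch 1 is the larger branch (`r1 >= r2`) and
#' that the beta angle (trunk vs larger branch) stays paired with it. Given
#' two branches in arbitrary order, this swaps radii, angles and
#' cross-sectional areas together so the convention holds. On an exact radius
#' tie the input order is preserved.
#'
#' @param r_a,r_b Branch radii, mm.
#' @param beta_raw Angle between trunk and branch a, degrees.
#' @param gamma_raw Angle between trunk and branch b, degrees.
#' @param p_a,p_b Optional branch cross-sectional areas, mm^2.
#' @return A list with `r1`, `r2`, `beta_deg`, `gamma_deg`, `p1`, `p2` and a
#'   logical `swapped`.
#' @export
canonicalize <- function(r_a, r_b, beta_raw = NA_real_, gamma_raw = NA_real_,
                         p_a = NA_real_, p_b = NA_real_) {
  if (!is.finite(r_a) || !is.finite(r_b) || r_a <= 0 || r_b <= 0) {
    stop("branch radii must be positive", call. = FALSE)
  }
  swap <- r_b > r_a   # strict: tie keeps input order
  if (swap) {
    list(r1 = r_b, r2 = r_a, beta_deg = gamma_raw, gamma_deg = beta_raw,
         p1 = p_b, p2 = p_a, swapped = TRUE)
  } else {
    list(r1 = r_a, r2 = r_b, beta_deg = beta_raw, gamma_deg = gamma_raw,
         p1 = p_a, p2 = p_b, swapped = FALSE)
  }
}

#' Construct a validated bifurcation geometry record
#'
#' @param r0 Parent-trunk radius, mm.
#' @param r1,r2 Larger/smaller branch radii, mm (`r1 >= r2`).
#' @param p0,p1,p2 Optional cross-sectional areas, mm^2.
#' @param alpha_deg Angle between the two post-bifurcation branches, degrees.
#' @param beta_deg,gamma_deg Angles between the trunk and the larger/smaller
#'   branch, degrees. All angles must lie in (0, 180].
#' @param tortuosity Optional dimensionless pass-through value.
#' @return An object of class `bifurcation_geometry` (a named list).
#' @export
bifurcation_geometry <- function(r0, r1, r2, p0 = NA_real_, p1 = NA_real_,
                                 p2 = NA_real_, alpha_deg = NA_real_,
                                 beta_deg = NA_real_, gamma_deg = NA_real_,
                                 tortuosity = NA_real_) {
  if (any(!is.finite(c(r0, r1, r2))) || any(c(r0, r1, r2) <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  if (r1 < r2) stop("geometry not canonical: r1 < r2 (use canonicalize())", call. = FALSE)
  for (p in c(p0, p1, p2)) {
    if (!is.na(p) && p <= 0) stop("cross-sectional areas must be positive when present", call. = FALSE)
  }
  for (a in c(alpha_deg, beta_deg, gamma_deg)) {
    if (!is.na(a) && (a <= 0 || a > 180)) {
      stop("angles must lie in (0, 180] degrees", call. = FALSE)
    }
  }
  structure(list(r0 = r0, r1 = r1, r2 = r2, p0 = p0, p1 = p1, p2 = p2,
                 alpha_deg = alpha_deg, beta_deg = beta_deg,
                 gamma_deg = gamma_deg, tortuosity = tortuosity),
            class = "bifurcation_geometry")
}

#' Bifurcation asymmetry and area ratios
#'
#' The asymmetry ratio `r2^2 / r1^2` compares branch calibres (1 for a
#' symmetric bifurcation); the area ratio `(r1^2 + r2^2) / r0^2` compares the
#' summed branch lumen to the trunk lumen. Both are invariant under uniform
#' scaling of the radii.
#'
#' @param r0,r1,r2 Radii in mm (vectorised), canonical order `r1 >= r2`; or
#'   pass a `bifurcation_geometry` as the single first argument.
#' @return A list with `asymmetry_ratio` and `area_ratio`.
#' @export
#' @examples
#' bifurcation_ratios(1.39, 1.16, 0.84)
bifurcation_ratios <- function(r0, r1, r2) {
  if (inherits(r0, "bifurcation_geometry")) {
    g <- r0; r0 <- g$r0; r1 <- g$r1; r2 <- g$r2
  }
  if (any(!is.finite(c(r0, r1, r2))) || any(c(r0, r1, r2) <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  list(asymmetry_ratio = r2^2 / r1^2,
       area_ratio = (r1^2 + r2^2) / r0^2)
}

#' Observed branch angles relative to the trunk axis
#'
#' The measured beta/gamma angles open between the trunk and each branch;
#' the angles of interest open between the *prolongation* of the trunk axis
#' and each branch, hence `Phi = 180 - angle`.
#'
#' @param beta_deg Trunk vs larger-branch angle, degrees in (0, 180].
#' @param gamma_deg Trunk vs smaller-branch angle, degrees in (0, 180].
#' @return A list with `phi1_obs_deg` and `phi2_obs_deg`.
#' @export
observed_branch_angles <- function(beta_deg, gamma_deg) {
  ang <- c(beta_deg, gamma_deg)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang > 180)) {
    stop("angles must lie in (0, 180] degrees", call. = FALSE)
  }
  list(phi1_obs_deg = 180 - beta_deg, phi2_obs_deg = 180 - gamma_deg)
}

#' Junction exponent of a bifurcation
#'
#' Solves `r0^n = r1^n + r2^n` for the exponent `n`, the index of how close a
#' bifurcation sits to the principle-of-minimum-work optimum (`n = 3`, the
#' cube law). Writing `f(n) = (r1/r0)^n + (r2/r0)^n - 1`, `f` is strictly
#' decreasing with `f(0+) = 1` whenever `r0 > r1`, so the positive root is
#' unique; it is found by bisection until `|f| < tol`.
#'
#' When `r0 <= r1` the equation has no positive root (`f >= (r1/r0)^n >= ...`
#' stays positive is violated -- `f` never crosses zero) and the status is
#' `"no_solution"`. Roots beyond `n_cap` (which occur as `r0` approaches `r1`
#' from above) are truncated to `n_cap` with status `"capped"` rather than
#' chasing a numerically meaningless near-singularity.
#'
#' @param r0,r1,r2 Radii, mm, canonical order `r1 >= r2 > 0` (vectorised).
#' @param tol Convergence tolerance on `|f(n)|`. Default `1e-10`.
#' @param n_cap Largest exponent reported. Default 20.
#' @return A list with numeric `n` (NA when no solution) and character
#'   `status` in `{"ok", "no_solution", "capped"}`.
#' @export
#' @examples
#' junction_exponent(2^(1/3), 1, 1)  # cube law: n = 3
junction_exponent <- function(r0, r1, r2, tol = 1e-10, n_cap = 20) {
  if (any(!is.finite(c(r0, r1, r2))) || any(c(r0, r1, r2) <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  k <- max(length(r0), length(r1), length(r2))
  r0 <- rep_len(r0, k); r1 <- rep_len(r1, k); r2 <- rep_len(r2, k)
  n_out <- rep(NA_real_, k)
  status <- rep("no_solution", k)
  for (i in seq_len(k)) {
    if (r0[i] <= r1[i]) next
    a <- r1[i] / r0[i]; b <- r2[i] / r0[i]
    f <- function(n) a^n + b^n - 1
    if (f(n_cap) > 0) {
      n_out[i] <- n_cap
      status[i] <- "capped"
      next
    }
    lo <- 1e-3; hi <- n_cap
    # f(lo) ~ 1 > 0, f(hi) <= 0; plain bisection on the monotone f
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < tol || (hi - lo) < .Machine$double.eps * max(1, mid)) break
      if (fm > 0) lo <- mid else hi <- mid
    }
    n_out[i] <- mid
    status[i] <- "ok"
  }
  list(n = n_out, status = status)
}
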