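# Seeded synthetic-cohort generator calibrated to published group summary
# statistics. Patient-level data for the study groups are unavailable, so a
# cohort with the printed per-group means/SDs and sample sizes stands in for
# them when exercising the pipeline end to end.

# Inverse-CDF draw from a normal truncated to [lo, hi].
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Build a group specification for the cohort generator
#'
#' @param label Group label, one of `"An"`, `"nonAn"`, `"R"`, `"L"`.
#' @param n Group size (number of bifurcations).
#' @param params Named list; each element is `c(mean, sd)` or
#'   `c(mean, sd, lower, upper)` giving the marginal location/scale and
#'   optional truncation bounds for one parameter.
#' @return A `group_spec` object.
#' @export
group_spec <- function(label, n, params) {
  stopifnot(label %in% c("An", "nonAn", "R", "L"), n >= 1)
  params <- lapply(params, function(p) {
    if (length(p) == 2) p <- c(p, -Inf, Inf)
    stopifnot(length(p) == 4, p[2] >= 0, p[3] < p[4])
    names(p) <- c("mean", "sd", "lower", "upper")
    p
  })
  # unsatisfiable truncation: a bound excluding mean +/- 6 SD is a config error
  for (nm in names(params)) {
    p <- params[[nm]]
    if (p["sd"] > 0 &&
        (p["lower"] > p["mean"] + 6 * p["sd"] || p["upper"] < p["mean"] - 6 * p["sd"])) {
      stop("unsatisfiable truncation for parameter ", nm, call. = FALSE)
    }
  }
  structure(list(label = label, n = as.integer(n), params = params),
            class = "group_spec")
}

#' Default group specifications calibrated to the published cohort
#'
#' Returns the four group specifications -- aneurysmal bifurcations (`An`,
#' n = 102), contralateral non-aneurysmal bifurcations (`nonAn`, n = 82) and
#' right/left control bifurcations (`R`, n = 88; `L`, n = 87) -- with the
#' published per-parameter means and SDs: trunk/branch radii and
#' cross-sections, trunk tortuosity, observed angles (`phi1`, `phi2`,
#' `alpha`), mean velocity, volume flow rate and pulsatility index.
#' Physiologic truncation bounds are applied by default: radii above 0.3 mm,
#' angles inside (5, 179) degrees (branch-axis angles inside (1, 175)),
#' velocities above 5 cm/s. Derived quantities (junction exponent, asymmetry
#' and area ratios) are never part of a spec: they are computed from the
#' drawn geometry.
#'
#' @return Named list of four [group_spec()] objects.
#' @export
default_table1_specs <- function() {
  tab <- list(
    #            An             nonAn          R              L
    r0    = list(c(1.39, 0.18), c(1.42, 0.20), c(1.35, 0.16), c(1.31, 0.19)),
    r1    = list(c(1.16, 0.17), c(1.17, 0.20), c(1.14, 0.17), c(1.11, 0.18)),
    r2    = list(c(0.84, 0.20), c(0.89, 0.17), c(0.85, 0.17), c(0.84, 0.18)),
    tortuosity = list(c(0.06, 0.04), c(0.07, 0.05), c(0.07, 0.06), c(0.08, 0.07)),
    p0    = list(c(6.1, 1.6),   c(6.3, 1.8),   c(5.7, 1.2),   c(5.4, 1.6)),
    p1    = list(c(4.3, 1.2),   c(4.3, 1.5),   c(4.2, 1.2),   c(3.9, 1.4)),
    p2    = list(c(2.3, 1.0),   c(2.51, 1.1),  c(2.3, 0.9),   c(2.3, 1.0)),
    phi1  = list(c(58.5, 24.8), c(48.3, 21.2), c(47.4, 22.9), c(42.8, 22.0)),
    phi2  = list(c(82.4, 20.9), c(68.1, 20.6), c(61.7, 17.1), c(65.1, 18.3)),
    alpha = list(c(128.6, 24.2), c(105.8, 19.7), c(98.6, 21.4), c(93.1, 18.5)),
    vm    = list(c(70.6, 14.1), c(67.1, 14.5), c(67.0, 11.9), c(66.8, 11.5)),
    vfr   = list(c(4.42, 1.46), c(4.30, 1.54), c(3.68, 0.92), c(3.46, 1.21)),
    pi    = list(c(0.81, 0.11), c(0.84, 0.11), c(0.86, 0.15), c(0.85, 0.14))
  )
  bounds <- list(
    r0 = c(0.3, Inf), r1 = c(0.3, Inf), r2 = c(0.3, Inf),
    tortuosity = c(-Inf, Inf),
    p0 = c(0.3, Inf), p1 = c(0.3, Inf), p2 = c(0.3, Inf),
    phi1 = c(1, 175), phi2 = c(1, 175), alpha = c(5, 179),
    vm = c(5, Inf), vfr = c(0.1, Inf), pi = c(0.05, Inf)
  )
  labels <- c("An", "nonAn", "R", "L")
  sizes <- c(An = 102L, nonAn = 82L, R = 88L, L = 87L)
  specs <- lapply(seq_along(labels), function(g) {
    params <- lapply(names(tab), function(nm) c(tab[[nm]][[g]], bounds[[nm]]))
    names(params) <- names(tab)
    group_spec(labels[g], sizes[g], params)
  })
  names(specs) <- labels
  specs
}

# stable content hash of an R object (polynomial rolling hash of its
# deparsed form; provenance fingerprint only, not cryptographic)
spec_hash <- function(specs) {
  bytes <- utf8ToInt(paste(deparse(specs), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate a synthetic bifurcation cohort
#'
#' Draws one row per bifurcation from per-group truncated-normal marginals.
#'
#' In `"marginal"` mode every parameter is drawn independently from its
#' specified marginal; branch radii (and their paired areas) are relabelled
#' so `r1 >= r2`; measured angles are reported as `beta = 180 - phi1`,
#' `gamma = 180 - phi2`; the drawn `vfr` and `pi` columns are carried in the
#' table and used directly by the discrimination analyses. In
#' `"mechanistic"` mode only the geometry and velocities are drawn
#' (optionally with correlation `rho_vm_r0` between `vm` and `r0`) and
#' `p0 = pi * r0^2`, `VFR = vm * p0 / 100` are derived, so hemodynamics and
#' geometry are internally consistent. Peak-systolic and end-diastolic
#' velocities are reconstructed from the drawn `vm` and `pi` with the
#' systolic excursion taking 55% of the pulse amplitude, so
#' `(vps - ved)/vm` reproduces the drawn index exactly.
#'
#' Identical `(specs, seed, mode)` yield byte-identical tables.
#'
#' @param specs List of [group_spec()] objects (see [default_table1_specs()]).
#' @param seed Integer seed.
#' @param mode `"marginal"` (default) or `"mechanistic"`.
#' @param rho_vm_r0 Correlation between `vm` and `r0` in mechanistic mode.
#' @return A `data.frame` with columns `subject_id`, `group`, geometry,
#'   Doppler and (marginal mode) `vfr`/`pi` columns, plus a `provenance`
#'   attribute (`seed`, `mode`, `spec_hash`).
#' @export
generate_cohort <- function(specs, seed = 1L, mode = c("marginal", "mechanistic"),
                            rho_vm_r0 = 0) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(specs, inherits, TRUE, "group_spec")))
  set.seed(seed)
  draw <- function(sp, nm) {
    p <- sp$params[[nm]]
    rnorm_trunc(sp$n, p["mean"], p["sd"], p["lower"], p["upper"])
  }
  blocks <- lapply(specs, function(sp) {
    n <- sp$n
    if (mode == "marginal") {
      r1 <- draw(sp, "r1"); r2 <- draw(sp, "r2")
      p1 <- draw(sp, "p1"); p2 <- draw(sp, "p2")
      swap <- r2 > r1
      tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
      tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      phi1 <- draw(sp, "phi1"); phi2 <- draw(sp, "phi2")
      vm <- draw(sp, "vm"); pix <- draw(sp, "pi")
      df <- data.frame(
        group = sp$label,
        r0 = draw(sp, "r0"), r1 = r1, r2 = r2,
        p0 = draw(sp, "p0"), p1 = p1, p2 = p2,
        alpha_deg = draw(sp, "alpha"),
        beta_deg = 180 - phi1, gamma_deg = 180 - phi2,
        vps = vm * (1 + 0.55 * pix), ved = vm * (1 - 0.45 * pix), vm = vm,
        tortuosity = draw(sp, "tortuosity"),
        vfr = draw(sp, "vfr"), pi = pix,
        stringsAsFactors = FALSE)
    } else {
      pr0 <- sp$params[["r0"]]; pvm <- sp$params[["vm"]]
      z0 <- stats::rnorm(n)
      zv <- rho_vm_r0 * z0 + sqrt(1 - rho_vm_r0^2) * stats::rnorm(n)
      r0 <- pmax(pr0["mean"] + pr0["sd"] * z0, pr0["lower"])
      vm <- pmax(pvm["mean"] + pvm["sd"] * zv, pvm["lower"])
      r1 <- draw(sp, "r1"); r2 <- draw(sp, "r2")
      swap <- r2 > r1
      tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
      p0 <- base::pi * r0^2
      phi1 <- draw(sp, "phi1"); phi2 <- draw(sp, "phi2")
      pix <- draw(sp, "pi")
      df <- data.frame(
        group = sp$label,
        r0 = r0, r1 = r1, r2 = r2,
        p0 = p0, p1 = base::pi * r1^2, p2 = base::pi * r2^2,
        alpha_deg = draw(sp, "alpha"),
        beta_deg = 180 - phi1, gamma_deg = 180 - phi2,
        vps = vm * (1 + 0.55 * pix), ved = vm * (1 - 0.45 * pix), vm = vm,
        tortuosity = draw(sp, "tortuosity"),
        stringsAsFactors = FALSE)
    }
    df
  })
  out <- do.call(rbind, c(blocks, make.row.names = FALSE))
  # subject linkage: contralateral nonAn rows reuse the ids of the first
  # aneurysm patients (mirror-aneurysm patients have no nonAn row)
  ids <- character(nrow(out))
  offset <- 0L; next_id <- 1L
  for (sp in specs) {
    idx <- offset + seq_len(sp$n)
    if (sp$label == "nonAn" && any(out$group == "An")) {
      an_ids <- unique(ids[out$group == "An"])
      ids[idx] <- an_ids[seq_len(min(sp$n, length(an_ids)))]
    } else {
      ids[idx] <- sprintf("S%04d", next_id + seq_len(sp$n) - 1L)
      next_id <- next_id + sp$n
    }
    offset <- offset + sp$n
  }
  out <- cbind(subject_id = ids, out, stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(seed = as.integer(seed), mode = mode,
                                  spec_hash = spec_hash(specs))
  out
}

#' Write a cohort table to CSV
#'
#' Plain UTF-8 comma-separated output with a '.' decimal mark; the
#' provenance attribute is written as a `#`-prefixed header comment.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  prov <- attr(cohort, "provenance")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(prov)) {
    writeLines(sprintf("# seed=%d mode=%s spec_hash=%s",
                       prov$seed, prov$mode, prov$spec_hash), con)
  }
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}
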