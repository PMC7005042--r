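# Cohort I/O, per-row metric derivation and the full analysis orchestration.

GROUPS <- c("An", "nonAn", "R", "L")
PAIRWISE <- list(c("An", "nonAn"), c("An", "R"), c("An", "L"),
                 c("nonAn", "R"), c("nonAn", "L"))

#' Default analysis configuration
#'
#' Every statistical threshold of the pipeline in one place: the univariate
#' entry rule `p_enter`, the correlation-pruning threshold `r_max`, the
#' largest pooled sample size for exact nonparametric p-values
#' `exact_limit`, the junction-exponent solver controls `n_cap` / `tol`, and
#' the case-control outcome definition (aneurysmal bifurcations vs the
#' pooled bilateral controls; the contralateral `nonAn` group sits in
#' neither arm by default).
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(
    p_enter = 0.1,
    r_max = 0.5,
    exact_limit = 12,
    n_cap = 20,
    tol = 1e-10,
    case_groups = "An",
    control_groups = c("R", "L"),
    candidate_vars = c("r0", "p0", "junction_exponent", "asymmetry_ratio",
                       "area_ratio", "phi1_obs_deg", "phi2_obs_deg",
                       "alpha_deg", "vm", "vfr", "pi")
  )
}

#' Read an analysis configuration from JSON
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path Path to a JSON config file.
#' @return Config list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg[names(user)] <- user
  cfg
}

#' Read a cohort CSV
#'
#' Expects columns `subject_id`, `group` (one of An / nonAn / R / L) and the
#' per-bifurcation measurements: radii `r0`, `r1`, `r2` (or best-fit
#' diameters `d0`, `d1`, `d2`, halved on load when the radius is absent),
#' optional areas `p0`, `p1`, `p2`, angles `alpha_deg`, `beta_deg`,
#' `gamma_deg`, Doppler velocities `vps`, `ved`, `vm`, and optional
#' `tortuosity`, `vfr`, `pi` columns. Branch order is canonicalised
#' (`r1 >= r2`, swapping areas and beta/gamma along) with a warning per
#' swapped row; rows violating basic invariants (non-positive radius,
#' out-of-range angle) are rejected with a line-numbered log and the rest of
#' the file proceeds. `#`-prefixed header lines are ignored.
#'
#' @param path CSV file path.
#' @return Cohort `data.frame`; rejected-row log in attribute `rejected`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_grp <- setdiff(unique(df$group), GROUPS)
  if (length(bad_grp)) {
    stop("unknown group labels: ", paste(bad_grp, collapse = ", "), call. = FALSE)
  }
  for (i in 0:2) {
    r <- paste0("r", i); d <- paste0("d", i)
    if (!r %in% names(df)) {
      if (!d %in% names(df)) {
        stop("missing mandatory columns: ", r, " (or ", d, ")", call. = FALSE)
      }
      df[[r]] <- df[[d]] / 2
    } else if (d %in% names(df)) {
      mism <- which(is.finite(df[[d]]) & abs(df[[d]] / 2 - df[[r]]) > 0.01 * df[[r]])
      if (length(mism)) {
        warning(sprintf("%d row(s) with %s/2 differing from %s by > 1%%; radii used",
                        length(mism), d, r), call. = FALSE)
      }
    }
  }
  for (cn in c("p0", "p1", "p2", "alpha_deg", "beta_deg", "gamma_deg",
               "vps", "ved", "vm", "tortuosity")) {
    if (!cn %in% names(df)) df[[cn]] <- NA_real_
  }
  swap <- which(is.finite(df$r1) & is.finite(df$r2) & df$r2 > df$r1)
  if (length(swap)) {
    warning(sprintf("%d row(s) had branches in non-canonical order; swapped on load",
                    length(swap)), call. = FALSE)
    for (cols in list(c("r1", "r2"), c("p1", "p2"), c("beta_deg", "gamma_deg"))) {
      tmp <- df[swap, cols[1]]
      df[swap, cols[1]] <- df[swap, cols[2]]
      df[swap, cols[2]] <- tmp
    }
  }
  ok_rad <- is.finite(df$r0) & is.finite(df$r1) & is.finite(df$r2) &
    df$r0 > 0 & df$r1 > 0 & df$r2 > 0
  ang_ok <- function(a) is.na(a) | (a > 0 & a <= 180)
  ok_ang <- ang_ok(df$alpha_deg) & ang_ok(df$beta_deg) & ang_ok(df$gamma_deg)
  pos_ok <- function(p) is.na(p) | p > 0
  ok_area <- pos_ok(df$p0) & pos_ok(df$p1) & pos_ok(df$p2)
  keep <- ok_rad & ok_ang & ok_area
  rejected <- data.frame(line = which(!keep) + 1L,
                         reason = ifelse(!ok_rad[!keep], "non-positive or missing radius",
                                  ifelse(!ok_ang[!keep], "angle outside (0, 180]",
                                         "non-positive area")))
  if (nrow(rejected)) {
    warning(sprintf("rejected %d invalid row(s); see attr(, 'rejected')",
                    nrow(rejected)), call. = FALSE)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Derive per-bifurcation metrics for a cohort
#'
#' Adds the observed trunk-axis angles, asymmetry/area ratios, junction
#' exponent (with status), pulsatility index and volume flow rate (drawn
#' columns are used when present, otherwise derived from velocities and
#' `vm * p0 / 100`), the predicted optimal angles under both rule families
#' and the six predicted-minus-observed deviations.
#'
#' @param cohort Cohort data frame ([read_cohort_csv()] / [generate_cohort()]).
#' @param config Config list, see [default_config()].
#' @return The cohort with derived columns appended.
#' @export
derive_metrics <- function(cohort, config = default_config()) {
  d <- cohort
  d$phi1_obs_deg <- 180 - d$beta_deg
  d$phi2_obs_deg <- 180 - d$gamma_deg
  ratios <- bifurcation_ratios(d$r0, d$r1, d$r2)
  d$asymmetry_ratio <- ratios$asymmetry_ratio
  d$area_ratio <- ratios$area_ratio
  je <- junction_exponent(d$r0, d$r1, d$r2, tol = config$tol, n_cap = config$n_cap)
  d$junction_exponent <- ifelse(je$status == "ok", je$n, NA_real_)
  d$junction_status <- je$status
  if (!"pi" %in% names(d)) {
    d$pi <- (d$vps - d$ved) / d$vm
  }
  if (!"vfr" %in% names(d)) {
    d$vfr <- d$vm * d$p0 / 100
  }
  s <- optimal_angles_surface(d$r0, d$r1, d$r2)
  v <- optimal_angles_volume(d$r0, d$r1, d$r2)
  d <- cbind(d, as.data.frame(s), as.data.frame(v))
  dev <- angle_deviations(c(s, v), d$phi1_obs_deg, d$phi2_obs_deg, d$alpha_deg)
  cbind(d, as.data.frame(dev))
}

group_summary <- function(x, g) {
  vapply(GROUPS, function(lab) {
    xi <- x[g == lab]
    xi <- xi[is.finite(xi)]
    c(mean = mean(xi), sd = stats::sd(xi), n = length(xi))
  }, c(mean = 0, sd = 0, n = 0))
}

pairwise_p <- function(x, g, exact_limit) {
  vapply(PAIRWISE, function(pr) {
    a <- x[g == pr[1]]; b <- x[g == pr[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    mann_whitney_u(a, b, exact_limit = exact_limit)$p_value
  }, 0)
}

#' Run the full case-control analysis
#'
#' Derives per-row metrics, then builds the four report tables and the ROC
#' stage: (1) per-parameter group means/SDs with the five pairwise
#' Mann-Whitney comparisons; (2) per-group predicted vs observed angle means
#' with paired Wilcoxon signed-rank p-values for both optimality rule
#' families; (3) predicted-minus-observed deviation means with between-group
#' Mann-Whitney comparisons; (4) univariate logistic screen over the
#' candidate predictors, the `p < p_enter` / correlation-pruning selection
#' rule, and the multivariate fit; plus an empirical ROC with Youden cut-off
#' for each final multivariate predictor (protective markers are sign-flipped
#' so higher score always calls a case; the reported cut-off is on the
#' original scale). Tables 2 and 3 are computed on the rows where both rule
#' families are geometrically valid, so the deviation means equal predicted
#' minus observed means exactly.
#'
#' Deterministic: the report payload is a function of the cohort and config
#' alone.
#'
#' @param cohort Cohort data frame.
#' @param config Config list, see [default_config()].
#' @return An `analysis_report` list with elements `table1`, `table2`,
#'   `table3`, `table4`, `roc`, `exclusions`, `provenance`.
#' @export
run_full_analysis <- function(cohort, config = default_config()) {
  grps <- unique(cohort$group)
  counts <- table(cohort$group)
  if (length(grps) < 2 || any(counts < 3)) {
    stop("need at least 2 groups with at least 3 rows each", call. = FALSE)
  }
  d <- derive_metrics(cohort, config)
  g <- d$group
  el <- config$exact_limit

  ## Table 1: group summaries + five pairwise comparisons
  params1 <- c("r0", "r1", "r2", "junction_exponent", "tortuosity",
               "p0", "p1", "p2", "asymmetry_ratio", "area_ratio",
               "phi1_obs_deg", "phi2_obs_deg", "alpha_deg", "vm", "vfr", "pi")
  params1 <- params1[params1 %in% names(d)]
  table1 <- do.call(rbind, lapply(params1, function(pn) {
    sm <- group_summary(d[[pn]], g)
    pp <- pairwise_p(d[[pn]], g, el)
    out <- data.frame(parameter = pn)
    for (lab in GROUPS) {
      out[[paste0(lab, "_mean")]] <- sm["mean", lab]
      out[[paste0(lab, "_sd")]] <- sm["sd", lab]
      out[[paste0(lab, "_n")]] <- sm["n", lab]
    }
    names(pp) <- vapply(PAIRWISE, function(pr) paste0("p_", pr[1], "_", pr[2]), "")
    cbind(out, as.data.frame(as.list(pp)))
  }))

  ## Tables 2-3 on complete-case rows (both rule families valid, angles present)
  cc <- d$valid_s & d$valid_v &
    is.finite(d$phi1_obs_deg) & is.finite(d$phi2_obs_deg) & is.finite(d$alpha_deg)
  dc <- d[cc, , drop = FALSE]
  gc <- dc$group
  slots <- list(
    list(angle = "phi1", s = "phi1_s_deg", v = "phi1_v_deg", obs = "phi1_obs_deg",
         ds = "d1_s", dv = "d1_v"),
    list(angle = "phi2", s = "phi2_s_deg", v = "phi2_v_deg", obs = "phi2_obs_deg",
         ds = "d2_s", dv = "d2_v"),
    list(angle = "total", s = "total_s_deg", v = "total_v_deg", obs = "alpha_deg",
         ds = "dt_s", dv = "dt_v"))
  table2 <- do.call(rbind, lapply(slots, function(sl) {
    do.call(rbind, lapply(GROUPS, function(lab) {
      if (!any(gc == lab)) return(NULL)
      sub <- dc[gc == lab, ]
      ps <- tryCatch(wilcoxon_signed_rank(sub[[sl$ds]], exact_limit = el)$p_value,
                     error = function(e) NA_real_)
      pv <- tryCatch(wilcoxon_signed_rank(sub[[sl$dv]], exact_limit = el)$p_value,
                     error = function(e) NA_real_)
      data.frame(angle = sl$angle, group = lab, n = nrow(sub),
                 pred_s_mean = mean(sub[[sl$s]]), pred_s_sd = stats::sd(sub[[sl$s]]),
                 pred_v_mean = mean(sub[[sl$v]]), pred_v_sd = stats::sd(sub[[sl$v]]),
                 obs_mean = mean(sub[[sl$obs]]), obs_sd = stats::sd(sub[[sl$obs]]),
                 p_surface = ps, p_volume = pv)
    }))
  }))
  devs <- c("d1_s", "d2_s", "dt_s", "d1_v", "d2_v", "dt_v")
  table3 <- do.call(rbind, lapply(devs, function(pn) {
    sm <- group_summary(dc[[pn]], gc)
    pp <- pairwise_p(dc[[pn]], gc, el)
    out <- data.frame(deviation = pn)
    for (lab in GROUPS) {
      out[[paste0(lab, "_mean")]] <- sm["mean", lab]
      out[[paste0(lab, "_sd")]] <- sm["sd", lab]
      out[[paste0(lab, "_n")]] <- sm["n", lab]
    }
    names(pp) <- vapply(PAIRWISE, function(pr) paste0("p_", pr[1], "_", pr[2]), "")
    cbind(out, as.data.frame(as.list(pp)))
  }))

  ## Table 4: univariate screen -> selection -> multivariate fit
  cc4 <- d$group %in% c(config$case_groups, config$control_groups)
  d4 <- d[cc4, , drop = FALSE]
  y <- as.integer(d4$group %in% config$case_groups)
  cand <- config$candidate_vars[config$candidate_vars %in% names(d4)]
  cand <- cand[vapply(cand, function(v) {
    xi <- d4[[v]][is.finite(d4[[v]])]
    length(xi) >= 10 && stats::sd(xi) > 0
  }, TRUE)]
  if (length(cand) == 0 || length(unique(y)) < 2) {
    screen <- NULL
    sel <- list(selected = character(0), audit = NULL)
    table4 <- list(univariate = NULL, selected = character(0),
                   selection_audit = NULL, multivariate = NULL,
                   note = "regression stage skipped: too few usable candidates or one-class outcome")
  } else {
    screen <- univariate_screen(d4, cand, y)
    corr <- pearson_correlation_matrix(d4[, cand, drop = FALSE])
    sel <- select_model_variables(screen, corr$r,
                                  p_enter = config$p_enter, r_max = config$r_max)
    multi <- NULL
    if (length(sel$selected) >= 1) {
      ccm <- stats::complete.cases(d4[, sel$selected, drop = FALSE])
      multi <- fit_logistic(y[ccm], d4[ccm, sel$selected, drop = FALSE])
    }
    table4 <- list(univariate = screen, selected = sel$selected,
                   selection_audit = sel$audit,
                   multivariate = if (is.null(multi)) NULL else multi$coefficients,
                   multivariate_converged = if (is.null(multi)) NA else multi$converged,
                   multivariate_separation = if (is.null(multi)) NA else multi$separation)
  }

  ## ROC per final multivariate predictor
  roc <- list()
  for (v in sel$selected) {
    sc <- d4[[v]]
    ok <- is.finite(sc)
    flip <- screen$estimate[screen$term == v] < 0
    s_ca <- sc[ok & y == 1]; s_co <- sc[ok & y == 0]
    r <- if (flip) roc_analysis(-s_ca, -s_co) else roc_analysis(s_ca, s_co)
    roc[[v]] <- list(auc = r$auc,
                     cutoff = if (flip) -r$cutoff else r$cutoff,
                     orientation = if (flip) "lower score = case" else "higher score = case",
                     sensitivity = r$sensitivity, specificity = r$specificity,
                     coords = r$coords)
  }

  prov_in <- attr(cohort, "provenance")
  report <- list(
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    roc = roc,
    exclusions = list(
      junction_excluded = sum(d$junction_status != "ok"),
      junction_capped = sum(d$junction_status == "capped"),
      invalid_geometry_rows = sum(!cc)),
    provenance = list(
      input_hash = spec_hash(cohort),
      seed = if (is.null(prov_in)) NA else prov_in$seed,
      cohort_mode = if (is.null(prov_in)) NA else prov_in$mode,
      config = config,
      package_version = as.character(utils::packageVersion("mcabif"))))
  class(report) <- "analysis_report"
  report
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full payload at full precision) and, when `"csv"` is
#' requested, `table1.csv` ... `table4.csv` and `roc_curves.csv`. The JSON
#' payload contains no timestamps, so a rerun on the same inputs is
#' byte-identical.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("json", "csv")`.
#' @return Character vector of file paths written, invisibly.
#' @export
write_report <- function(report, out_dir, formats = c("json", "csv")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  written <- character()
  if ("json" %in% formats) {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, p)
  }
  if ("csv" %in% formats) {
    for (nm in c("table1", "table2", "table3")) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      written <- c(written, p)
    }
    t4 <- report$table4$univariate
    if (is.null(t4)) t4 <- data.frame(term = character(), p_value = numeric())
    t4$in_final_model <- t4$term %in% report$table4$selected
    if (!is.null(report$table4$multivariate)) {
      mv <- report$table4$multivariate
      idx <- match(t4$term, mv$term)
      t4$multi_or <- mv$or[idx]
      t4$multi_ci_lower <- mv$ci_lower[idx]
      t4$multi_ci_upper <- mv$ci_upper[idx]
      t4$multi_p_value <- mv$p_value[idx]
    }
    p <- file.path(out_dir, "table4.csv")
    utils::write.csv(t4, p, row.names = FALSE)
    written <- c(written, p)
    rc <- do.call(rbind, lapply(names(report$roc), function(v) {
      cbind(predictor = v, report$roc[[v]]$coords)
    }))
    if (is.null(rc)) {
      rc <- data.frame(predictor = character(), threshold = numeric(),
                       sensitivity = numeric(), specificity = numeric())
    }
    p <- file.path(out_dir, "roc_curves.csv")
    utils::write.csv(rc, p, row.names = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Simulate the default calibrated cohort and analyse it
#'
#' Convenience wrapper: [default_table1_specs()] -> [generate_cohort()] ->
#' [run_full_analysis()].
#'
#' @param seed Integer seed for the cohort draw.
#' @param mode Cohort generation mode, see [generate_cohort()].
#' @param config Analysis configuration.
#' @return An `analysis_report`.
#' @export
reproduce_study <- function(seed = 1L, mode = "marginal",
                            config = default_config()) {
  cohort <- generate_cohort(default_table1_specs(), seed = seed, mode = mode)
  run_full_analysis(cohort, config)
}

#' Replicate the discrimination stage over many simulated cohorts
#'
#' For each replicate, draws a fresh calibrated cohort and computes the
#' empirical case-control AUC of the total bifurcation angle and of the
#' volume flow rate, and the univariate logistic odds ratio per degree of
#' the total angle (cases = aneurysmal bifurcations, controls = pooled
#' bilateral controls). Used to compare the simulated sampling distribution
#' of these discrimination metrics against their published point values.
#'
#' @param replicates Number of replicate cohorts.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param specs Group specifications (default [default_table1_specs()]).
#' @param config Analysis configuration (outcome definition).
#' @return Data frame with columns `replicate`, `auc_alpha`, `auc_vfr`,
#'   `or_alpha`, `n_cases`, `n_controls`.
#' @export
calibration_replicates <- function(replicates = 500, seed = 1L,
                                   specs = default_table1_specs(),
                                   config = default_config()) {
  out <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    co <- generate_cohort(specs, seed = seed + i, mode = "marginal")
    keep <- co$group %in% c(config$case_groups, config$control_groups)
    co <- co[keep, , drop = FALSE]
    y <- as.integer(co$group %in% config$case_groups)
    auc_a <- roc_analysis(co$alpha_deg[y == 1], co$alpha_deg[y == 0])$auc
    auc_v <- roc_analysis(co$vfr[y == 1], co$vfr[y == 0])$auc
    or_a <- fit_logistic(y, co[, "alpha_deg", drop = FALSE])$coefficients$or[1]
    out[[i]] <- data.frame(replicate = i, auc_alpha = auc_a, auc_vfr = auc_v,
                           or_alpha = or_a,
                           n_cases = sum(y == 1), n_controls = sum(y == 0))
  }
  do.call(rbind, out)
}
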