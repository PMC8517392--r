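# Study orchestration: generate (or load) a cohort, run the work engine,
# produce the comparison / correlation / regression / agreement tables, and
# write everything as reproducible CSV output with seed and config hash
# stamped into every file.

# variables routed to the Mann-Whitney test by default; everything else
# continuous uses the pooled-variance t, binary variables use chi-square
DEFAULT_MW_VARS <- c("hdl_c", "lvef", "gls_pct", "gww_mmhg_pct", "gwe_pct")
DEFAULT_CHI2_VARS <- c("male", "smoking")
REGRESSION_CANDIDATES <- c("age", "bsa", "heart_rate", "sbp_mmhg", "dbp_mmhg",
                           "pulse_pressure", "tc", "tg", "hdl_c", "ldl_c",
                           "hba1c", "fpg", "ppg_2h", "duration_yr")

#' Default run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"from-files"` (read the
#'   strain/events/cohort CSV trio).
#' @param seed master seed for every source of randomness in the run.
#' @param outdir output directory for the report bundle.
#' @param n_nc,n_t2dm group sizes in synthetic mode.
#' @param strain_csv,events_csv,cohort_csv input paths for from-files mode.
#' @param dt work-grid step in seconds (`NULL`: work window / 2000).
#' @param gls_weights GLS segment weights (`NULL`: equal).
#' @param mw_vars,chi2_vars statistical routing: variables sent to the
#'   Mann-Whitney and chi-square tests; all other compared variables use the
#'   pooled t.
#' @param p_enter,p_remove stepwise selection thresholds.
#' @param replicate_sd named re-measurement SDs (mmHg.% or %) used to
#'   simulate intra-observer replicates for the Bland-Altman table; the
#'   inter-observer simulation uses `inter_factor` times these SDs.
#' @param inter_factor multiplier for inter-observer re-measurement noise.
#' @param n_replicate number of subjects re-measured for agreement analysis.
#' @return a `run_config` list.
#' @export
default_run_config <- function(mode = c("synthetic", "from-files"), seed = 1,
                               outdir = tempfile("psl_run_"),
                               n_nc = 50, n_t2dm = 50,
                               strain_csv = NULL, events_csv = NULL,
                               cohort_csv = NULL, dt = NULL,
                               gls_weights = NULL,
                               mw_vars = DEFAULT_MW_VARS,
                               chi2_vars = DEFAULT_CHI2_VARS,
                               p_enter = 0.05, p_remove = 0.10,
                               replicate_sd = c(gwi_mmhg_pct = 26, gcw_mmhg_pct = 62,
                                                gww_mmhg_pct = 3, gwe_pct = 0.36),
                               inter_factor = 1.6,
                               n_replicate = 20) {
  structure(list(mode = match.arg(mode), seed = as.integer(seed), outdir = outdir,
                 n_nc = n_nc, n_t2dm = n_t2dm,
                 strain_csv = strain_csv, events_csv = events_csv,
                 cohort_csv = cohort_csv, dt = dt, gls_weights = gls_weights,
                 mw_vars = mw_vars, chi2_vars = chi2_vars,
                 p_enter = p_enter, p_remove = p_remove,
                 replicate_sd = replicate_sd, inter_factor = inter_factor,
                 n_replicate = n_replicate),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config[setdiff(names(config), "outdir")]), tf)
  unname(tools::md5sum(tf))
}

#' Compute per-subject global work from loaded inputs
#'
#' @param strains named list of per-subject trace lists ([read_strain_csv()]).
#' @param events named list of per-subject [valve_events()] ([read_events_csv()]).
#' @param cohort cohort covariate data.frame with `subject_id`, `sbp_mmhg`,
#'   `dbp_mmhg`.
#' @param dt,gls_weights work-engine parameters.
#' @return list with `work` (data.frame: subject_id, gls_pct, gwi_mmhg_pct,
#'   gcw_mmhg_pct, gww_mmhg_pct, gwe_pct) and `exclusions` (data.frame:
#'   subject_id, reason) for subjects that could not be processed.
#' @export
compute_cohort_work <- function(strains, events, cohort, dt = NULL,
                                gls_weights = NULL) {
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- as.character(cohort$subject_id[i])
    tr <- strains[[sid]]; ev <- events[[sid]]
    if (is.null(tr) || is.null(ev)) {
      excl[[sid]] <- "missing strain traces or valve events"
      next
    }
    if (length(tr) != 17L) {
      excl[[sid]] <- sprintf("incomplete segmentation: %d of 17 segments", length(tr))
      next
    }
    cuff <- cuff_pressure(cohort$sbp_mmhg[i], cohort$dbp_mmhg[i])
    gw <- subject_work(tr, ev, cuff, dt = dt, weights = gls_weights)
    rows[[sid]] <- data.frame(subject_id = sid, gls_pct = gw$gls,
                              gwi_mmhg_pct = gw$gwi, gcw_mmhg_pct = gw$gcw,
                              gww_mmhg_pct = gw$gww, gwe_pct = gw$gwe)
  }
  work <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), gls_pct = numeric(0),
               gwi_mmhg_pct = numeric(0), gcw_mmhg_pct = numeric(0),
               gww_mmhg_pct = numeric(0), gwe_pct = numeric(0))
  rownames(work) <- NULL
  exclusions <- data.frame(subject_id = names(excl),
                           reason = unlist(excl, use.names = FALSE))
  list(work = work, exclusions = exclusions)
}

summary_string <- function(x, type) {
  if (type == "mw") {
    sprintf("%.2f (%.2f)", stats::median(x), stats::IQR(x))
  } else {
    sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
  }
}

#' Two-group comparison table
#'
#' Compares every routed variable between the NC and T2DM rows of a cohort
#' table: pooled t for normally summarized variables, Mann-Whitney Z for
#' skewed ones, chi-square for binary ones. Variables absent in one group
#' (diabetes-only fields) are summarized for T2DM without a test.
#'
#' @param cohort cohort data.frame with a `group` column (`NC`/`T2DM`).
#' @param variables variables to compare (default: all routed columns found).
#' @param mw_vars,chi2_vars routing, see [default_run_config()].
#' @return data.frame: variable, test, NC and T2DM summaries, statistic, p.
#' @export
comparison_table <- function(cohort, variables = NULL,
                             mw_vars = DEFAULT_MW_VARS,
                             chi2_vars = DEFAULT_CHI2_VARS) {
  g1 <- cohort[cohort$group == "NC", ]
  g2 <- cohort[cohort$group == "T2DM", ]
  if (is.null(variables)) {
    variables <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                         character(0))
  }
  rows <- lapply(variables, function(v) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    if (v %in% chi2_vars) {
      res <- tryCatch(
        chi_square_2x2(sum(x1 == 1), sum(x1 == 0), sum(x2 == 1), sum(x2 == 0)),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_))
      data.frame(variable = v, test = "chi2",
                 nc = sprintf("%d (%.0f%%)", sum(x1 == 1), 100 * mean(x1)),
                 t2dm = sprintf("%d (%.0f%%)", sum(x2 == 1), 100 * mean(x2)),
                 statistic = res$statistic, p_value = res$p_value)
    } else if (length(x1) == 0 || length(x2) == 0) {
      data.frame(variable = v, test = "none",
                 nc = if (length(x1)) summary_string(x1, "t") else "-",
                 t2dm = if (length(x2)) summary_string(x2, "t") else "-",
                 statistic = NA_real_, p_value = NA_real_)
    } else if (v %in% mw_vars) {
      res <- mann_whitney(x1, x2)
      data.frame(variable = v, test = "Z",
                 nc = summary_string(x1, "mw"), t2dm = summary_string(x2, "mw"),
                 statistic = res$statistic, p_value = res$p_value)
    } else {
      res <- t_from_raw(x1, x2)
      data.frame(variable = v, test = "t",
                 nc = summary_string(x1, "t"), t2dm = summary_string(x2, "t"),
                 statistic = res$statistic, p_value = res$p_value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariable plus stepwise multivariable regression table
#'
#' Regresses the outcome on each candidate alone (univariable standardized
#' coefficients), then runs stepwise selection over the candidates with
#' univariable p below 0.05.
#'
#' @param data data.frame holding outcome and candidates.
#' @param outcome outcome column name.
#' @param candidates candidate predictor column names (those absent or
#'   all-`NA` are dropped).
#' @param p_enter,p_remove stepwise thresholds.
#' @return list with `univariable` (data.frame: predictor, beta_std, p),
#'   `model` (a `regression_result`) and `entered` (candidates passed to
#'   stepwise selection).
#' @export
regression_table <- function(data, outcome, candidates = REGRESSION_CANDIDATES,
                             p_enter = 0.05, p_remove = 0.10) {
  candidates <- candidates[candidates %in% names(data)]
  candidates <- candidates[vapply(candidates, function(v) {
    x <- data[[v]]
    sum(is.finite(x)) > 3 && stats::sd(x[is.finite(x)]) > 0
  }, logical(1))]
  y <- data[[outcome]]
  uni <- do.call(rbind, lapply(candidates, function(v) {
    fit <- ols_standardized(y, data[, v, drop = FALSE])
    data.frame(predictor = v, beta_std = fit$beta_std, p_value = fit$p_values)
  }))
  rownames(uni) <- NULL
  entered <- uni$predictor[uni$p_value < 0.05]
  model <- if (length(entered) > 0) {
    stepwise_select(y, data[, entered, drop = FALSE],
                    p_enter = p_enter, p_remove = p_remove)
  } else {
    structure(list(predictors = character(0), beta_raw = numeric(0),
                   beta_std = numeric(0), p_values = numeric(0),
                   r_squared = 0, adj_r_squared = 0,
                   n = sum(is.finite(y)), selected_none = TRUE),
              class = "regression_result")
  }
  list(univariable = uni, model = model, entered = entered)
}

#' Simulated repeatability (Bland-Altman) table
#'
#' Emulates the intra-/inter-observer design: a random subset of subjects is
#' "re-measured" by adding zero-mean Gaussian re-measurement noise to each
#' work parameter, and agreement between the original and re-measured values
#' is summarized as bias and 95% limits of agreement.
#'
#' @param work per-subject work table (columns as in [compute_cohort_work()]).
#' @param seed master seed (the replicate substream is derived from it).
#' @param replicate_sd,inter_factor,n_replicate see [default_run_config()].
#' @return data.frame: observer block, parameter, paired means, bias, LOA.
#' @export
agreement_table <- function(work, seed, replicate_sd, inter_factor = 1.6,
                            n_replicate = 20) {
  n_replicate <- min(n_replicate, nrow(work))
  with_seed(stable_seed(seed, "replicates"), {
    idx <- sample(nrow(work), n_replicate)
    rows <- list()
    for (block in c("intraobserver", "interobserver")) {
      fac <- if (block == "intraobserver") 1 else inter_factor
      for (v in names(replicate_sd)) {
        m1 <- work[[v]][idx]
        m2 <- m1 + stats::rnorm(n_replicate, 0, replicate_sd[[v]] * fac)
        if (v == "gwe_pct") m2 <- pmin(m2, 100)
        ba <- bland_altman(m1, m2)
        rows[[paste(block, v)]] <- data.frame(
          observer = block, parameter = v,
          mean1 = mean(m1), mean2 = mean(m2),
          bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Run the full study workflow
#'
#' Orchestrates generate (or load) -> myocardial work -> statistical analysis
#' -> report bundle. Deterministic given the configuration seed; every output
#' CSV carries the seed and configuration hash as comment-prefixed metadata
#' lines, and a run log records versions, seed, hash and subject accounting
#' (no subject is dropped silently).
#'
#' @param config a [default_run_config()] list.
#' @return (invisibly) a list with `cohort`, `work`, `comparison`,
#'   `correlation`, `regression_gwi`, `regression_gcw`, `agreement`,
#'   `exclusions` and `outdir`.
#' @export
run_full_study <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "from-files") {
    for (key in c("strain_csv", "events_csv", "cohort_csv")) {
      if (is.null(config[[key]]) || !file.exists(config[[key]])) {
        stop(sprintf("configuration error: '%s' is required and must exist in from-files mode", key),
             call. = FALSE)
      }
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- c(seed = config$seed, config_hash = hash,
            pslwork_version = as.character(utils::packageVersion("pslwork")))

  exclusions <- data.frame(subject_id = character(0), reason = character(0))
  if (config$mode == "synthetic") {
    cc <- generate_cohort(default_group_spec("NC", config$n_nc),
                          default_group_spec("T2DM", config$n_t2dm),
                          seed = config$seed, dt = config$dt)
    cohort <- cc$cohort
    n_input <- nrow(cohort)
    work <- cohort[, c("subject_id", "gls_pct", "gwi_mmhg_pct", "gcw_mmhg_pct",
                       "gww_mmhg_pct", "gwe_pct")]
  } else {
    strains <- read_strain_csv(config$strain_csv)
    events <- read_events_csv(config$events_csv)
    cohort <- read_psl_csv(config$cohort_csv)
    n_input <- nrow(cohort)
    cw <- compute_cohort_work(strains, events, cohort, dt = config$dt,
                              gls_weights = config$gls_weights)
    work <- cw$work
    exclusions <- cw$exclusions
    cohort <- merge(cohort[!cohort$subject_id %in% exclusions$subject_id, ],
                    work, by = "subject_id", sort = TRUE)
  }

  comparison <- comparison_table(cohort,
                                 mw_vars = config$mw_vars,
                                 chi2_vars = config$chi2_vars)
  corr <- do.call(rbind, lapply(c("gwi_mmhg_pct", "gcw_mmhg_pct",
                                  "gww_mmhg_pct", "gwe_pct"), function(v) {
    pr <- pearson_r(cohort$gls_pct, cohort[[v]])
    data.frame(pair = paste0("gls_pct~", v), r = pr$r, p_value = pr$p_value, n = pr$n)
  }))
  t2dm <- cohort[cohort$group == "T2DM", ]
  reg_gwi <- regression_table(t2dm, "gwi_mmhg_pct",
                              p_enter = config$p_enter, p_remove = config$p_remove)
  reg_gcw <- regression_table(t2dm, "gcw_mmhg_pct",
                              p_enter = config$p_enter, p_remove = config$p_remove)
  agreement <- agreement_table(work, config$seed, config$replicate_sd,
                               config$inter_factor, config$n_replicate)

  write_psl_csv(cohort, file.path(config$outdir, "cohort.csv"), meta)
  write_psl_csv(work, file.path(config$outdir, "work_table.csv"), meta)
  write_psl_csv(comparison, file.path(config$outdir, "comparison_table.csv"), meta)
  write_psl_csv(corr, file.path(config$outdir, "correlation_table.csv"), meta)
  write_psl_csv(agreement, file.path(config$outdir, "agreement_table.csv"), meta)
  write_psl_csv(exclusions, file.path(config$outdir, "exclusions.csv"), meta)
  for (nm in c("gwi", "gcw")) {
    rt <- if (nm == "gwi") reg_gwi else reg_gcw
    write_psl_csv(rt$univariable,
                  file.path(config$outdir, sprintf("regression_%s_univariable.csv", nm)), meta)
    mv <- data.frame(predictor = rt$model$predictors,
                     beta_std = rt$model$beta_std, p_value = rt$model$p_values)
    attr(mv, "r_squared") <- rt$model$r_squared
    mv_meta <- c(meta, r_squared = sprintf("%.6f", rt$model$r_squared),
                 adj_r_squared = sprintf("%.6f", rt$model$adj_r_squared))
    write_psl_csv(mv,
                  file.path(config$outdir, sprintf("regression_%s_multivariable.csv", nm)), mv_meta)
  }
  log_lines <- c(
    sprintf("pslwork version: %s", utils::packageVersion("pslwork")),
    sprintf("R version: %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("mode: %s", config$mode),
    sprintf("seed: %d", config$seed),
    sprintf("config hash: %s", hash),
    sprintf("subjects in: %d", n_input),
    sprintf("subjects analyzed: %d", nrow(cohort)),
    sprintf("subjects excluded: %d", nrow(exclusions)),
    if (nrow(exclusions) > 0) sprintf("  excluded %s: %s",
                                      exclusions$subject_id, exclusions$reason)
  )
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(list(cohort = cohort, work = work, comparison = comparison,
                 correlation = corr, regression_gwi = reg_gwi,
                 regression_gcw = reg_gcw, agreement = agreement,
                 exclusions = exclusions, outdir = config$outdir))
}

#' Write a small self-contained fixture dataset
#'
#' Generates a 4-subject (2 NC, 2 T2DM) synthetic bundle - strain traces,
#' valve events and cohort covariates - usable by from-files mode and by unit
#' tests.
#'
#' @param outdir writable output directory.
#' @param seed master seed.
#' @return (invisibly) named paths of the three CSVs.
#' @export
make_fixtures <- function(outdir, seed = 733339) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cc <- generate_cohort(default_group_spec("NC", 2),
                        default_group_spec("T2DM", 2), seed = seed)
  meta <- c(seed = seed, note = "synthetic fixture")
  cov_cols <- setdiff(names(cc$cohort),
                      c("gls_pct", "gwi_mmhg_pct", "gcw_mmhg_pct",
                        "gww_mmhg_pct", "gwe_pct"))
  paths <- c(strain = file.path(outdir, "fixture_strain.csv"),
             events = file.path(outdir, "fixture_events.csv"),
             cohort = file.path(outdir, "fixture_cohort.csv"))
  write_strain_csv(cc$bundles, paths[["strain"]], meta = meta)
  write_events_csv(cc$bundles, paths[["events"]], meta = meta)
  cohort <- cc$cohort[, cov_cols]
  cohort[vapply(cohort, is.numeric, logical(1))] <-
    lapply(cohort[vapply(cohort, is.numeric, logical(1))], round, 4)
  write_psl_csv(cohort, paths[["cohort"]], meta = meta)
  invisible(paths)
}
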