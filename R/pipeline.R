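# End-to-end orchestration: simulate -> build networks -> threshold sweeps ->
# longitudinal statistics, with a manifest for reproducibility.

pipeline_log <- function(con, stage, level, message, record = "") {
  line <- sprintf("%s\t%s\t%s\t%s", stage, level, record, message)
  if (!is.null(con)) writeLines(line, con)
  if (level %in% c("info", "warn", "error")) {
    message(sprintf("[%s] %s%s", stage, message,
                    if (nzchar(record)) paste0(" (", record, ")") else ""))
  }
  invisible(NULL)
}

stage_guard <- function(stage, record, expr, log_con = NULL) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed%s: %s", stage,
                   if (nzchar(record)) paste0(" at ", record) else "",
                   conditionMessage(e)), call. = FALSE)
    }),
    warning = function(w) {
      # warnings are expected (sparse graphs, boundary fits); log, not spam
      if (!is.null(log_con)) {
        pipeline_log(log_con, stage, "debug", conditionMessage(w), record)
      }
      invokeRestart("muffleWarning")
    })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation; baseline TIV adjustment and
#' group-level structural covariance; per-record functional and individual
#' structural covariance networks; proportional-threshold metric sweeps with
#' AUC summaries; outcome simulation driven by the measured global
#' efficiency; and the statistical layer (per-timepoint group comparisons,
#' within-group paired contrasts against baseline, moderation models at a
#' fixed sparsity of 0.1 and on AUCs, and per-group trajectory fits). All
#' tables are written under `out_dir` together with a JSON manifest (config
#' hash, seed, file checksums).
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory; must not exist unless `force = TRUE`.
#' @param grid sparsity grid for the sweeps.
#' @param n_null null networks per threshold (0 skips gamma/lambda/sigma).
#' @param fixed_sparsity sparsity at which metrics enter the moderation
#'   models (default 0.1).
#' @param force overwrite an existing `out_dir`.
#' @return The run manifest (list), invisibly; see [summarize_run()].
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         grid = threshold_grid(), n_null = 0L,
                         fixed_sparsity = 0.1, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !isTRUE(force)) {
    stop("output directory exists and is not empty; use force = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  lg <- function(stage, msg, record = "", level = "info") {
    pipeline_log(con, stage, level, msg, record)
  }

  # -- simulate ---------------------------------------------------------
  lg("simulate", sprintf("seed %d, %d ROIs, %d subjects", config$seed,
                         config$n_roi, 2L * config$n_per_group))
  cohort <- stage_guard("simulate", "", simulate_cohort(config))
  write_table_tsv(cohort$morphometry, file.path(out_dir, "morphometry.tsv"))
  ts_dir <- file.path(out_dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  for (rec in cohort$timeseries) {
    f <- file.path(ts_dir, sprintf("%s_m%02d.csv", rec$subject,
                                   as.integer(rec$timepoint)))
    utils::write.csv(rec$series, f, row.names = FALSE)
  }

  # -- netbuild ---------------------------------------------------------
  lg("netbuild", "baseline TIV adjustment + group covariance")
  adj <- stage_guard("netbuild", "baseline morphometry",
                     residualize_morphometry(cohort$morphometry))
  gc <- stage_guard("netbuild", "group covariance",
                    build_group_covariance(adj))
  write_matrix_tsv(gc$scn, file.path(out_dir, "group_scn.tsv"))

  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  networks <- list()
  rois <- roi_columns(cohort$morphometry)
  for (i in seq_len(nrow(cohort$morphometry))) {
    row <- cohort$morphometry[i, ]
    rec_id <- sprintf("%s m%g", row$subject, row$timepoint)
    m <- stage_guard("netbuild", rec_id, {
      esd <- compute_esd(unlist(row[rois]), gc$reference)
      build_individual_scn(weight_from_esd(esd), gc$reference)
    })
    networks[[length(networks) + 1L]] <- list(
      subject = row$subject, group = as.character(row$group),
      timepoint = row$timepoint, kind = "individual_scn", matrix = m)
  }
  for (rec in cohort$timeseries) {
    rec_id <- sprintf("%s m%g", rec$subject, rec$timepoint)
    m <- stage_guard("netbuild", rec_id, build_functional_network(rec))
    networks[[length(networks) + 1L]] <- list(
      subject = rec$subject, group = rec$group, timepoint = rec$timepoint,
      kind = "functional_z", matrix = m)
  }
  for (nw in networks) {
    f <- file.path(net_dir, sprintf("%s_m%02d_%s.tsv", nw$subject,
                                    as.integer(nw$timepoint), nw$kind))
    write_matrix_tsv(nw$matrix, f,
                     sidecar = list(kind = nw$kind, subject = nw$subject,
                                    timepoint = nw$timepoint))
  }

  # -- graphmetrics -----------------------------------------------------
  lg("graphmetrics", sprintf("sweeping %d networks over %d thresholds",
                             length(networks), length(grid)))
  metric_rows <- list()
  auc_rows <- list()
  for (k in seq_along(networks)) {
    nw <- networks[[k]]
    sw <- stage_guard("graphmetrics",
                      sprintf("%s m%g %s", nw$subject, nw$timepoint, nw$kind),
                      sweep_thresholds(nw$matrix, grid, n_null = n_null,
                                       seed = config$seed + 17L * k),
                      log_con = con)
    fails <- attr(sw, "failures")
    if (nrow(fails)) {
      for (j in seq_len(nrow(fails))) {
        lg("graphmetrics", fails$message[j],
           record = sprintf("%s m%g %s s=%.2f", nw$subject, nw$timepoint,
                            nw$kind, fails$sparsity[j]),
           level = "warn")
      }
    }
    long <- stats::reshape(
      as.data.frame(sw), direction = "long",
      varying = setdiff(names(sw), "sparsity"),
      v.names = "value", timevar = "metric",
      times = setdiff(names(sw), "sparsity"))
    metric_rows[[k]] <- data.frame(
      subject = nw$subject, group = nw$group, timepoint = nw$timepoint,
      kind = nw$kind, metric = long$metric, sparsity = long$sparsity,
      value = long$value, row.names = NULL)
    aucs <- sweep_auc(sw)
    auc_rows[[k]] <- data.frame(
      subject = nw$subject, group = nw$group, timepoint = nw$timepoint,
      kind = nw$kind, metric = names(aucs), auc = unname(aucs),
      row.names = NULL)
  }
  metrics_long <- do.call(rbind, metric_rows)
  auc_table <- do.call(rbind, auc_rows)
  write_table_tsv(metrics_long, file.path(out_dir, "metrics_long.tsv"))
  write_table_tsv(auc_table, file.path(out_dir, "metrics_auc.tsv"))

  # -- outcomes ---------------------------------------------------------
  near <- function(a, b) abs(a - b) < 1e-9
  eg_fixed <- metrics_long[metrics_long$kind == "functional_z" &
                             metrics_long$metric == "eg" &
                             near(metrics_long$sparsity, fixed_sparsity), ]
  if (!nrow(eg_fixed)) {
    stop(sprintf("pipeline stage 'outcomes' failed: sparsity %.2f not in grid",
                 fixed_sparsity), call. = FALSE)
  }
  metric_table <- data.frame(subject = eg_fixed$subject,
                             group = eg_fixed$group,
                             timepoint = eg_fixed$timepoint,
                             metric = eg_fixed$value)
  lg("outcomes", sprintf("locomotor + DTI outcomes from Eg at s=%.2f",
                         fixed_sparsity))
  outcomes <- stage_guard("outcomes", "",
                          simulate_outcomes(config, metric_table))
  write_table_tsv(outcomes, file.path(out_dir, "outcomes.tsv"))

  # -- longstats --------------------------------------------------------
  lg("longstats", "group comparisons, moderation models, trajectories")
  stats_out <- stage_guard("longstats", "", pipeline_stats(
    config, metrics_long, auc_table, outcomes, fixed_sparsity),
    log_con = con)
  write_table_tsv(stats_out$comparisons,
                  file.path(out_dir, "comparisons.tsv"))
  write_table_tsv(stats_out$moderation,
                  file.path(out_dir, "moderation.tsv"))
  write_table_tsv(stats_out$trajectories,
                  file.path(out_dir, "trajectories.tsv"))
  jsonlite::write_json(stats_out$moderation_detail,
                       file.path(out_dir, "moderation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  # -- manifest ---------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "pipeline.log"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sciconn")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(config),
    fixed_sparsity = fixed_sparsity,
    n_null = n_null,
    grid = as.numeric(grid),
    planted = list(metric_effect = config$metric_effect,
                   interaction_effects = as.list(config$interaction_effects)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    out_dir = normalizePath(out_dir),
    inventory = file_inventory(files, normalizePath(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  lg("manifest", sprintf("%d files, config %s", nrow(manifest$inventory),
                         manifest$config_hash))
  invisible(manifest)
}

pipeline_stats <- function(config, metrics_long, auc_table, outcomes,
                           fixed_sparsity) {
  # between-group comparison of every metric AUC at every timepoint, and
  # within-group paired contrasts of each follow-up against baseline
  comp_rows <- list()
  for (kind in unique(auc_table$kind)) {
    for (met in unique(auc_table$metric)) {
      sub <- auc_table[auc_table$kind == kind & auc_table$metric == met, ]
      sub <- sub[!is.na(sub$auc), , drop = FALSE]
      if (!nrow(sub)) next
      for (tp in sort(unique(sub$timepoint))) {
        at_tp <- sub[sub$timepoint == tp, ]
        a <- at_tp$auc[at_tp$group == "sci"]
        b <- at_tp$auc[at_tp$group == "treatment"]
        res <- tryCatch(select_and_compare(a, b), error = function(e) NULL)
        if (!is.null(res)) {
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            contrast = "between_group", kind = kind, metric = met,
            group = "both", timepoint = tp, test = res$test_name,
            statistic = res$statistic, p = res$p_value)
        }
      }
      for (grp in c("sci", "treatment")) {
        g_base <- sub[sub$group == grp & sub$timepoint == 0, ]
        for (tp in setdiff(sort(unique(sub$timepoint)), 0)) {
          g_tp <- sub[sub$group == grp & sub$timepoint == tp, ]
          g_tp <- g_tp[match(g_base$subject, g_tp$subject), ]
          res <- tryCatch(select_and_compare(g_tp$auc, g_base$auc,
                                             paired = TRUE),
                          error = function(e) NULL)
          if (!is.null(res)) {
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
              contrast = "vs_baseline", kind = kind, metric = met,
              group = grp, timepoint = tp, test = res$test_name,
              statistic = res$statistic, p = res$p_value)
          }
        }
      }
    }
  }
  comparisons <- do.call(rbind, comp_rows)

  # moderation: locomotor outcome ~ Eg (fixed sparsity and AUC) x group
  near <- function(a, b) abs(a - b) < 1e-9
  mod_rows <- list()
  mod_detail <- list()
  metric_sets <- list(
    eg_fixed = outcomes$metric,
    eg_auc = {
      eg_auc <- auc_table[auc_table$kind == "functional_z" &
                            auc_table$metric == "eg", ]
      eg_auc$auc[match(paste(outcomes$subject, outcomes$timepoint),
                       paste(eg_auc$subject, eg_auc$timepoint))]
    })
  for (mname in names(metric_sets)) {
    for (oname in c("path_length", "step_height", "stride_length")) {
      fit <- tryCatch(
        fit_moderation_model(outcomes[[oname]], metric_sets[[mname]],
                             outcomes$group, outcomes$timepoint,
                             outcomes$subject),
        error = function(e) NULL)
      if (is.null(fit)) next
      ix <- interaction_row(fit)
      cf <- fit$coefficients[ix, ]
      planted <- config$interaction_effects[[oname]]
      recovered <- (cf$lower > 0 || cf$upper < 0) &&
        sign(cf$estimate) == sign(planted) && planted != 0
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        metric = mname, outcome = oname,
        interaction_beta = cf$estimate, se = cf$se, df = cf$df, p = cf$p,
        lower = cf$lower, upper = cf$upper,
        planted_beta = planted, recovered = recovered,
        r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
        f2_interaction = fit$f2_interaction)
      mod_detail[[paste(mname, oname, sep = ".")]] <- list(
        coefficients = fit$coefficients,
        simple_slopes = as.data.frame(fit$simple_slopes),
        df_method = fit$df_method)
    }
  }
  moderation <- do.call(rbind, mod_rows)

  # trajectories: metric AUC over months, per group and network kind
  traj_rows <- list()
  for (kind in unique(auc_table$kind)) {
    for (met in c("eg", "cp")) {
      for (grp in c("sci", "treatment")) {
        sub <- auc_table[auc_table$kind == kind & auc_table$metric == met &
                           auc_table$group == grp, ]
        sub <- sub[!is.na(sub$auc), , drop = FALSE]
        if (!nrow(sub)) next
        tf <- tryCatch(fit_trajectory(sub$auc, sub$timepoint, sub$subject),
                       error = function(e) NULL)
        if (is.null(tf)) next
        traj_rows[[length(traj_rows) + 1L]] <- data.frame(
          kind = kind, metric = met, group = grp,
          k_selected = tf$k_selected, edf = tf$edf, p_smooth = tf$p_smooth,
          slope = tf$slope, slope_se = tf$slope_se)
      }
    }
  }
  trajectories <- do.call(rbind, traj_rows)
  list(comparisons = comparisons, moderation = moderation,
       trajectories = trajectories, moderation_detail = mod_detail)
}

#' Summarize a completed pipeline run
#'
#' Reads the tables a [run_pipeline()] manifest points to and assembles a
#' human-readable report: per-timepoint comparisons, AUC statistics,
#' moderation coefficients with simple slopes, trajectory summaries, and
#' which planted interaction effects were recovered (95% CI excludes zero
#' with matching sign). Regenerating the report from the same manifest gives
#' an identical document.
#'
#' @param manifest a [run_pipeline()] manifest (or path to `manifest.json`).
#' @return Character vector of report lines (class `pipeline_report`),
#'   printed with one line per element.
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  out_dir <- manifest$out_dir
  need <- c("comparisons.tsv", "moderation.tsv", "trajectories.tsv",
            "metrics_auc.tsv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("incomplete run: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  comp <- read_table_tsv(file.path(out_dir, "comparisons.tsv"))
  mod <- read_table_tsv(file.path(out_dir, "moderation.tsv"))
  traj <- read_table_tsv(file.path(out_dir, "trajectories.tsv"))
  if (!nrow(mod)) stop("incomplete run: statistics stage produced no models",
                       call. = FALSE)
  lines <- c(
    sprintf("pipeline run %s (seed %s, config %s)", manifest$created,
            manifest$seed, manifest$config_hash),
    sprintf("comparisons: %d tests, %d at p < 0.05", nrow(comp),
            sum(comp$p < 0.05)),
    "moderation models (metric x group interaction):")
  for (i in seq_len(nrow(mod))) {
    lines <- c(lines, sprintf(
      "  %s on %s: beta=%.3f [%.3f, %.3f], p=%.4f, planted=%.3f -> %s",
      mod$metric[i], mod$outcome[i], mod$interaction_beta[i], mod$lower[i],
      mod$upper[i], mod$p[i], mod$planted_beta[i],
      if (mod$recovered[i]) "recovered" else "not recovered"))
  }
  lines <- c(lines, "trajectories (AUC vs months):")
  for (i in seq_len(nrow(traj))) {
    lines <- c(lines, sprintf(
      "  %s %s [%s]: k=%d, edf=%.2f, p_smooth=%.4f, slope=%.4f/mo",
      traj$kind[i], traj$metric[i], traj$group[i], traj$k_selected[i],
      traj$edf[i], traj$p_smooth[i], traj$slope[i]))
  }
  structure(lines, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(unclass(x))
  invisible(x)
}
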