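#' Configuration for a synthetic spinal-cord-injury cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults emulate
#' the study design the package targets: eight adult subjects split equally
#' into an injury-only group and a treatment group, scanned at baseline and at
#' 1, 2, 3, 6 and 12 months post-injury, with regional time series of 110
#' retained samples (120 acquired volumes minus the 10 discarded at the start
#' of each run). The inter-regional covariance is modular: `n_modules`
#' communities with Pearson correlation `r_within` inside a community and
#' `r_between` across communities.
#'
#' Planted effect sizes default to the coefficient magnitudes this kind of
#' moderation analysis reports in the macaque literature (a metric main effect
#' of -6.137 gait units per unit network metric, a metric-by-group interaction
#' of +9.087 on path length and -4.553 on stride length, and a +0.549 main
#' effect of spinal-cord fractional anisotropy on a global-efficiency-like
#' latent), so parameter-recovery tests exercise realistic magnitudes.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param timepoints months since injury; strictly increasing, first must be 0
#'   (the healthy baseline).
#' @param n_roi number of brain regions (>= 3 * `n_modules`).
#' @param n_timepoints_ts samples per regional time series.
#' @param n_modules number of covariance communities.
#' @param r_within,r_between within/between-community Pearson correlation of
#'   the baseline reference covariance.
#' @param gmv_mean,gmv_rel_sd centre and relative spread of per-region
#'   gray-matter volume means (arbitrary volume units).
#' @param tiv_mean,tiv_sd,tiv_slope total-intracranial-volume distribution and
#'   the allometric GMV-per-TIV-unit slope used at generation time.
#' @param injury_effect named list with elements `sci` and `treatment`, each a
#'   per-timepoint mean GMV shift in units of the baseline SD (first entry 0).
#' @param metric_effect reference-group (injury-only) slope of the network
#'   metric on each locomotor outcome.
#' @param interaction_effects named vector of planted metric-by-group
#'   interaction coefficients for `path_length`, `step_height`,
#'   `stride_length`.
#' @param fa_effect planted main-effect coefficient of fractional anisotropy
#'   on the global-efficiency-like latent outcome.
#' @param noise_sd named list of residual scales: `outcome` (locomotor
#'   residual SD), `subject` (random-intercept SD), `eg_latent`, `fa`.
#' @param perturb_covariance if `TRUE`, post-injury draws also shrink
#'   between-community correlation (covariance perturbation); by default
#'   injury shifts region means only.
#' @param seed integer master seed; every generator operation derives its own
#'   substream from it, so outputs are byte-identical across runs.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 4L,
                          timepoints = c(0, 1, 2, 3, 6, 12),
                          n_roi = 60L,
                          n_timepoints_ts = 110L,
                          n_modules = 6L,
                          r_within = 0.6,
                          r_between = 0.1,
                          gmv_mean = 500,
                          gmv_rel_sd = 0.05,
                          tiv_mean = 90000,
                          tiv_sd = 4500,
                          tiv_slope = 0.002,
                          injury_effect = NULL,
                          metric_effect = -6.137,
                          interaction_effects = c(path_length = 9.087,
                                                  step_height = 0,
                                                  stride_length = -4.553),
                          fa_effect = 0.549,
                          noise_sd = list(outcome = 2, subject = 1,
                                          eg_latent = 0.05, fa = 0.03),
                          perturb_covariance = FALSE,
                          seed = 1L) {
  nt <- length(timepoints)
  if (is.null(injury_effect)) {
    # monotone GMV loss after injury, partially reversed under treatment
    injury_effect <- list(
      sci       = approx_profile(c(0, -0.8, -1.0, -1.1, -1.2, -1.2), nt),
      treatment = approx_profile(c(0, -0.8, -0.7, -0.5, -0.3, -0.2), nt)
    )
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    timepoints = as.numeric(timepoints),
    n_roi = as.integer(n_roi),
    n_timepoints_ts = as.integer(n_timepoints_ts),
    n_modules = as.integer(n_modules),
    r_within = r_within, r_between = r_between,
    gmv_mean = gmv_mean, gmv_rel_sd = gmv_rel_sd,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd, tiv_slope = tiv_slope,
    injury_effect = injury_effect,
    metric_effect = metric_effect,
    interaction_effects = interaction_effects,
    fa_effect = fa_effect,
    noise_sd = noise_sd,
    perturb_covariance = isTRUE(perturb_covariance),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

approx_profile <- function(values, n) {
  if (n == length(values)) return(values)
  stats::approx(seq_along(values), values, n = n)$y
}

validate_cohort_config <- function(cfg) {
  stopifnot_scalar_number(cfg$n_per_group, "n_per_group", lower = 2)
  stopifnot_scalar_number(cfg$n_roi, "n_roi", lower = 3)
  stopifnot_scalar_number(cfg$n_modules, "n_modules", lower = 1)
  if (cfg$n_roi < 3L * cfg$n_modules) {
    stop("`n_roi` must be at least 3 * `n_modules`", call. = FALSE)
  }
  tp <- cfg$timepoints
  if (length(tp) < 2L || any(diff(tp) <= 0) || tp[1L] != 0) {
    stop("`timepoints` must be strictly increasing and start at 0 (baseline)",
         call. = FALSE)
  }
  for (nm in c("sci", "treatment")) {
    eff <- cfg$injury_effect[[nm]]
    if (is.null(eff) || length(eff) != length(tp)) {
      stop(sprintf("injury_effect$%s must have one entry per timepoint", nm),
           call. = FALSE)
    }
    if (eff[1L] != 0) {
      stop("injury_effect must be 0 at baseline", call. = FALSE)
    }
  }
  sds <- c(cfg$gmv_rel_sd, cfg$tiv_sd, unlist(cfg$noise_sd))
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("all SD parameters must be strictly positive", call. = FALSE)
  }
  need <- c("path_length", "step_height", "stride_length")
  if (!all(need %in% names(cfg$interaction_effects))) {
    stop("interaction_effects must name path_length, step_height, stride_length",
         call. = FALSE)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic SCI cohort configuration\n")
  cat(sprintf("  %d subjects/group x 2 groups, timepoints (months): %s\n",
              x$n_per_group, paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  %d ROIs in %d covariance modules (r_within=%.2f, r_between=%.2f)\n",
              x$n_roi, x$n_modules, x$r_within, x$r_between))
  cat(sprintf("  time series: %d samples; seed %d\n",
              x$n_timepoints_ts, x$seed))
  invisible(x)
}

cohort_subjects <- function(cfg) {
  n <- 2L * cfg$n_per_group
  data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = factor(rep(c("sci", "treatment"), each = cfg$n_per_group),
                   levels = c("sci", "treatment")),
    stringsAsFactors = FALSE
  )
}

module_assignment <- function(n_roi, n_modules) {
  sort(rep_len(seq_len(n_modules), n_roi))
}

#' Baseline (healthy-period) reference for the synthetic cohort
#'
#' Draws per-region healthy-period mean and SD gray-matter volumes and builds
#' the modular inter-regional correlation matrix that both the morphometry and
#' the time-series simulators share: `r_within` inside each community,
#' `r_between` across communities, unit diagonal. The matrix is checked for
#' positive semi-definiteness; infeasible block parameters (for example a
#' strongly negative between-community correlation with several communities)
#' raise an error rather than silently producing an invalid covariance.
#'
#' @param config a [cohort_config()].
#' @return Object of class `cohort_reference` with elements `mean`, `sd`
#'   (per-ROI), `corr` (ROI x ROI correlation), `modules` (community index per
#'   ROI) and `roi_labels`.
#' @export
generate_baseline_reference <- function(config) {
  cfg <- validate_cohort_config(config)
  labels <- roi_labels_for(cfg$n_roi)
  modules <- module_assignment(cfg$n_roi, cfg$n_modules)
  corr <- matrix(cfg$r_between, cfg$n_roi, cfg$n_roi)
  for (m in seq_len(cfg$n_modules)) {
    idx <- which(modules == m)
    corr[idx, idx] <- cfg$r_within
  }
  diag(corr) <- 1
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf(paste0("infeasible block correlation parameters: matrix is ",
                        "not positive semi-definite (min eigenvalue %.3e)"),
                 min(ev)), call. = FALSE)
  }
  withr::with_seed(substream_seed(cfg$seed, "reference"), {
    mu <- cfg$gmv_mean * exp(rnorm(cfg$n_roi, 0, 0.15))
    sds <- cfg$gmv_rel_sd * mu
  })
  structure(
    list(mean = setNames(mu, labels), sd = setNames(sds, labels),
         corr = `dimnames<-`(corr, list(labels, labels)),
         modules = setNames(modules, labels), roi_labels = labels),
    class = "cohort_reference"
  )
}

reference_chol <- function(reference) {
  # transpose of the upper Cholesky factor, with a tiny ridge when the
  # correlation is only semi-definite
  R <- reference$corr
  ch <- tryCatch(chol(R), error = function(e) chol(R + 1e-8 * diag(nrow(R))))
  ch
}

#' Simulate regional morphometry for the cohort
#'
#' Baseline gray-matter volumes are multivariate normal draws around the
#' healthy-period reference (correlation `reference$corr`, per-region mean and
#' SD from the reference) plus an allometric total-intracranial-volume
#' component with slope `tiv_slope`. At post-injury timepoints every region's
#' mean is shifted by the group- and timepoint-specific `injury_effect`,
#' expressed in units of that region's baseline SD. Draws at different
#' timepoints are independent given the subject's TIV.
#'
#' @param config a [cohort_config()].
#' @param reference a [generate_baseline_reference()] result.
#' @return A data frame with one row per subject x timepoint: `subject`,
#'   `group`, `timepoint`, `tiv`, then one `roi_*` column per region.
#' @export
simulate_morphometry <- function(config, reference) {
  cfg <- validate_cohort_config(config)
  stopifnot(inherits(reference, "cohort_reference"))
  subjects <- cohort_subjects(cfg)
  n_sub <- nrow(subjects)
  nt <- length(cfg$timepoints)
  ch <- reference_chol(reference)
  D <- reference$sd
  withr::with_seed(substream_seed(cfg$seed, "morphometry"), {
    tiv <- rnorm(n_sub, cfg$tiv_mean, cfg$tiv_sd)
    rows <- vector("list", n_sub * nt)
    k <- 0L
    for (s in seq_len(n_sub)) {
      grp <- as.character(subjects$group[s])
      eff_key <- if (grp == "sci") "sci" else "treatment"
      for (t in seq_len(nt)) {
        z <- rnorm(cfg$n_roi)
        dev <- D * drop(crossprod(ch, z))
        shift <- cfg$injury_effect[[eff_key]][t] * D
        gmv <- reference$mean + dev + shift +
          cfg$tiv_slope * (tiv[s] - cfg$tiv_mean)
        k <- k + 1L
        rows[[k]] <- c(list(subject = subjects$subject[s], group = grp,
                            timepoint = cfg$timepoints[t], tiv = tiv[s]),
                       as.list(setNames(gmv, reference$roi_labels)))
      }
    }
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out$group <- factor(out$group, levels = c("sci", "treatment"))
  rownames(out) <- NULL
  out
}

#' Simulate regional time series for the cohort
#'
#' Each subject x timepoint record is an i.i.d. Gaussian noise matrix mixed by
#' the transpose-Cholesky square root of the reference correlation, so the
#' population zero-lag correlation of every series equals `reference$corr`.
#' No temporal autocorrelation is modelled: the downstream functional-network
#' construction consumes only zero-lag Pearson correlations.
#'
#' @inheritParams simulate_morphometry
#' @param n_samples optional override of `config$n_timepoints_ts`.
#' @return A list of records, each with `subject`, `group`, `timepoint` and
#'   `series` (samples x ROI matrix with ROI column labels).
#' @export
simulate_timeseries <- function(config, reference, n_samples = NULL) {
  cfg <- validate_cohort_config(config)
  stopifnot(inherits(reference, "cohort_reference"))
  n_ts <- if (is.null(n_samples)) cfg$n_timepoints_ts else as.integer(n_samples)
  if (n_ts < 2L) stop("need at least 2 time samples per series", call. = FALSE)
  subjects <- cohort_subjects(cfg)
  ch <- reference_chol(reference)
  withr::with_seed(substream_seed(cfg$seed, "timeseries"), {
    records <- list()
    for (s in seq_len(nrow(subjects))) {
      for (t in seq_along(cfg$timepoints)) {
        z <- matrix(rnorm(n_ts * cfg$n_roi), n_ts, cfg$n_roi)
        series <- z %*% ch
        colnames(series) <- reference$roi_labels
        records[[length(records) + 1L]] <- list(
          subject = subjects$subject[s],
          group = as.character(subjects$group[s]),
          timepoint = cfg$timepoints[t],
          series = series
        )
      }
    }
  })
  records
}

#' Simulate locomotor and spinal-cord outcomes
#'
#' Locomotor parameters (path length, step height, stride length; arbitrary
#' gait units) are generated from a linear mixed model with fixed effects
#' metric, group, metric-by-group interaction (the planted
#' `interaction_effects`) and timepoint, a Gaussian subject random intercept,
#' and Gaussian residual noise. Spinal-cord diffusion scalars follow
#' group-specific recovery profiles; fractional anisotropy is clipped to
#' [0, 1] and the diffusivities are kept strictly positive. A
#' global-efficiency-like latent outcome `eg_latent` is generated with the
#' planted `fa_effect` coefficient on FA, for main-effect recovery tests.
#'
#' @param config a [cohort_config()].
#' @param metric_table data frame with columns `subject`, `group`,
#'   `timepoint`, `metric`: one network metric value (measured or latent) per
#'   subject x timepoint. Missing combinations raise an error.
#' @return A data frame with one row per subject x timepoint: identifiers,
#'   `path_length`, `step_height`, `stride_length`, `fa`, `md`, `rd`, `ad`,
#'   `eg_latent` and the `metric` used.
#' @export
simulate_outcomes <- function(config, metric_table) {
  cfg <- validate_cohort_config(config)
  need_cols <- c("subject", "group", "timepoint", "metric")
  if (!all(need_cols %in% names(metric_table))) {
    stop("metric_table must have columns subject, group, timepoint, metric",
         call. = FALSE)
  }
  subjects <- cohort_subjects(cfg)
  grid <- expand.grid(subject = subjects$subject,
                      timepoint = cfg$timepoints,
                      stringsAsFactors = FALSE)
  key <- paste(metric_table$subject, metric_table$timepoint)
  missing <- setdiff(paste(grid$subject, grid$timepoint), key)
  if (length(missing)) {
    stop("metric_table is missing subject x timepoint combinations: ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  }
  mt <- metric_table[match(paste(grid$subject, grid$timepoint), key), ]
  grp <- subjects$group[match(grid$subject, subjects$subject)]
  is_trt <- as.numeric(grp == "treatment")
  t_idx <- match(grid$timepoint, cfg$timepoints)
  n <- nrow(grid)
  metric_c <- mt$metric - mean(mt$metric)

  base <- c(path_length = 30, step_height = 5, stride_length = 25)
  # locomotor performance degrades at injury then partially recovers
  time_prof <- list(
    path_length   = approx_profile(c(0, 2, 3, 4, 5, 6), length(cfg$timepoints)),
    step_height   = approx_profile(c(0, -2, -1.5, -1, -0.8, -0.5),
                                   length(cfg$timepoints)),
    stride_length = approx_profile(c(0, -6, -5, -4, -3, -2),
                                   length(cfg$timepoints))
  )
  group_main <- c(path_length = -2, step_height = 0.5, stride_length = 2)

  withr::with_seed(substream_seed(cfg$seed, "outcomes"), {
    u <- rnorm(nrow(subjects), 0, cfg$noise_sd$subject)
    names(u) <- subjects$subject
    out <- data.frame(subject = grid$subject, group = grp,
                      timepoint = grid$timepoint, metric = mt$metric,
                      stringsAsFactors = FALSE)
    for (nm in names(base)) {
      beta_int <- cfg$interaction_effects[[nm]]
      out[[nm]] <- base[[nm]] + time_prof[[nm]][t_idx] +
        group_main[[nm]] * is_trt +
        cfg$metric_effect * metric_c +
        beta_int * metric_c * is_trt +
        u[grid$subject] + rnorm(n, 0, cfg$noise_sd$outcome)
    }
    # spinal-cord DTI scalars: FA drops at injury, recovers under treatment
    fa_prof <- list(
      sci       = approx_profile(c(0.55, 0.32, 0.30, 0.30, 0.32, 0.33),
                                 length(cfg$timepoints)),
      treatment = approx_profile(c(0.55, 0.36, 0.40, 0.44, 0.48, 0.50),
                                 length(cfg$timepoints))
    )
    prof_key <- ifelse(is_trt == 1, "treatment", "sci")
    fa_mu <- vapply(seq_len(n),
                    function(i) fa_prof[[prof_key[i]]][t_idx[i]], numeric(1))
    out$fa <- pmin(1, pmax(0, fa_mu + rnorm(n, 0, cfg$noise_sd$fa)))
    out$md <- pmax(1e-6, 1.00 + 0.25 * (0.55 - fa_mu) + rnorm(n, 0, 0.03))
    out$rd <- pmax(1e-6, 0.70 + 0.40 * (0.55 - fa_mu) + rnorm(n, 0, 0.03))
    out$ad <- pmax(1e-6, 1.70 + rnorm(n, 0, 0.04))
    u2 <- 0.4 * u / cfg$noise_sd$subject * cfg$noise_sd$eg_latent
    out$eg_latent <- 0.30 + cfg$fa_effect * out$fa + u2[grid$subject] +
      rnorm(n, 0, cfg$noise_sd$eg_latent)
  })
  out$group <- factor(out$group, levels = c("sci", "treatment"))
  out
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: reference, morphometry and time series under one
#' configuration and seed.
#'
#' @param config a [cohort_config()].
#' @return List with `config`, `reference`, `morphometry`, `timeseries`.
#' @export
simulate_cohort <- function(config) {
  reference <- generate_baseline_reference(config)
  list(config = config,
       reference = reference,
       morphometry = simulate_morphometry(config, reference),
       timeseries = simulate_timeseries(config, reference))
}
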