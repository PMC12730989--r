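#' Connectivity matrix container
#'
#' Thin S3 wrapper around a symmetric, zero-diagonal ROI x ROI matrix with a
#' `kind` tag: `"functional_z"` (positive Pearson, Fisher-z), `"group_scn"`
#' (healthy-period structural covariance) or `"individual_scn"` (effect-size
#' weighted covariance for one subject at one timepoint).
#'
#' @param values square numeric matrix (symmetric, diagonal forced to zero).
#' @param kind one of `"functional_z"`, `"group_scn"`, `"individual_scn"`.
#' @param roi_labels optional ROI labels; defaults to existing dimnames.
#' @export
connectivity_matrix <- function(values,
                                kind = c("functional_z", "group_scn",
                                         "individual_scn"),
                                roi_labels = NULL) {
  kind <- match.arg(kind)
  check_square_symmetric(values, "values")
  if (is.null(roi_labels)) roi_labels <- rownames(values)
  if (is.null(roi_labels)) roi_labels <- roi_labels_for(nrow(values))
  values <- zero_diag(values)
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(values, kind = kind, class = c("connectivity_matrix", "matrix"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix kind=%s, %d ROIs>\n",
              attr(x, "kind"), nrow(x)))
  cat(sprintf("  edge weights: min %.4f, median %.4f, max %.4f\n",
              min(x[upper.tri(x)]), stats::median(x[upper.tri(x)]),
              max(x[upper.tri(x)])))
  invisible(x)
}

cm_values <- function(m) {
  v <- unclass(m)
  attr(v, "kind") <- NULL
  v
}

roi_columns <- function(df) grep("^roi_", names(df), value = TRUE)

#' Adjust regional gray-matter volumes for total intracranial volume
#'
#' Fits, for every region, an ordinary least-squares regression of baseline
#' GMV on an intercept and total intracranial volume (TIV) across the
#' baseline (healthy-period) subjects, and returns the residuals together
#' with the fitted coefficients. The baseline fit can be reapplied to later
#' timepoints (see [apply_adjustment()]) so that longitudinal deviations from
#' the healthy period are preserved rather than re-centred at every visit.
#'
#' @param morphometry data frame as produced by [simulate_morphometry()] (or
#'   read from a morphometry TSV): columns `subject`, `timepoint`, `tiv` and
#'   `roi_*` volume columns.
#' @param baseline_timepoint which timepoint is the healthy period (default 0).
#' @return Object of class `gmv_adjustment`: `residuals` (subject x ROI
#'   matrix, per-ROI mean exactly zero), `coefficients` (2 x ROI: intercept
#'   and TIV slope), `gmv` (raw baseline subject x ROI matrix), `tiv`,
#'   `subjects`.
#' @export
residualize_morphometry <- function(morphometry, baseline_timepoint = 0) {
  base <- morphometry[morphometry$timepoint == baseline_timepoint, , drop = FALSE]
  if (nrow(base) < 3L) {
    stop("need at least 3 baseline subjects to fit the TIV adjustment",
         call. = FALSE)
  }
  if (anyNA(base$tiv)) stop("TIV missing for some baseline subjects",
                            call. = FALSE)
  if (stats::sd(base$tiv) == 0) {
    stop("TIV is constant across baseline subjects: design matrix singular",
         call. = FALSE)
  }
  rois <- roi_columns(base)
  gmv <- as.matrix(base[, rois, drop = FALSE])
  X <- cbind(`(Intercept)` = 1, tiv = base$tiv)
  fit <- stats::lm.fit(X, gmv)
  res <- fit$residuals
  dimnames(res) <- list(base$subject, rois)
  coefs <- fit$coefficients
  structure(
    list(residuals = res, coefficients = coefs, gmv = gmv,
         tiv = setNames(base$tiv, base$subject), subjects = base$subject),
    class = "gmv_adjustment"
  )
}

#' Apply a baseline TIV adjustment to new morphometry records
#'
#' @param adjustment a [residualize_morphometry()] fit.
#' @param gmv subject x ROI matrix (or single named vector) of raw volumes.
#' @param tiv total intracranial volume per row of `gmv`.
#' @return Matrix of residuals under the baseline coefficients.
#' @export
apply_adjustment <- function(adjustment, gmv, tiv) {
  stopifnot(inherits(adjustment, "gmv_adjustment"))
  if (is.null(dim(gmv))) gmv <- matrix(gmv, 1L, dimnames = list(NULL, names(gmv)))
  rois <- colnames(adjustment$coefficients)
  gmv <- gmv[, rois, drop = FALSE]
  pred <- cbind(1, tiv) %*% adjustment$coefficients
  gmv - pred
}

#' Healthy-period baseline reference for individual-network weighting
#'
#' @param mean,sd per-ROI healthy-period mean and SD of raw GMV.
#' @param scn_hc ROI x ROI group-level structural covariance (correlation of
#'   TIV-adjusted residuals across healthy-period subjects).
#' @export
baseline_reference <- function(mean, sd, scn_hc) {
  if (any(sd <= 0)) {
    stop("baseline reference SDs must be strictly positive", call. = FALSE)
  }
  check_square_symmetric(scn_hc, "scn_hc")
  if (max(abs(diag(scn_hc) - 1)) > 1e-8 || max(abs(scn_hc)) > 1 + 1e-8) {
    stop("scn_hc must have unit diagonal and entries in [-1, 1]", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, scn_hc = scn_hc),
            class = "baseline_reference")
}

#' Group-level structural covariance of the healthy period
#'
#' Pearson correlation, across baseline subjects, of the TIV-adjusted GMV
#' residuals of every pair of regions; the correlations are kept signed. Also
#' computes the per-region mean and SD of the raw baseline volumes, which the
#' individual weighting uses as the healthy-period reference.
#'
#' @param adjustment a [residualize_morphometry()] fit.
#' @return List with `scn` (a `group_scn` [connectivity_matrix()]) and
#'   `reference` (a [baseline_reference()]).
#' @export
build_group_covariance <- function(adjustment) {
  stopifnot(inherits(adjustment, "gmv_adjustment"))
  res <- adjustment$residuals
  if (nrow(res) < 3L) stop("need residuals from at least 3 baseline subjects",
                           call. = FALSE)
  v <- apply(res, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance residuals for ROI(s): ",
         paste(colnames(res)[v == 0], collapse = ", "), call. = FALSE)
  }
  r <- cor(res)
  scn <- connectivity_matrix(r, kind = "group_scn")
  ref <- baseline_reference(
    mean = colMeans(adjustment$gmv),
    sd = apply(adjustment$gmv, 2L, stats::sd),
    scn_hc = r
  )
  list(scn = scn, reference = ref)
}

#' Inter-regional effect-size difference for one subject at one timepoint
#'
#' For regions i and j with observed volumes x_i, x_j, healthy-period means
#' M_i, M_j and SDs S_i, S_j:
#' \deqn{ESD(i,j) = \frac{|(x_i - M_i) - (x_j - M_j)|}{\sqrt{(S_i^2 + S_j^2)/2}}}
#' i.e. the absolute difference of the two regions' deviations from the
#' healthy mean, standardized by the pooled SD. Symmetric, nonnegative, zero
#' diagonal; zero whenever the two regions deviate identically.
#'
#' @param gmv named per-ROI volume vector for one subject x timepoint.
#' @param reference a [baseline_reference()] (any object with `mean` and `sd`).
#' @return ROI x ROI ESD matrix.
#' @export
compute_esd <- function(gmv, reference) {
  mu <- reference$mean
  s <- reference$sd
  if (length(gmv) != length(mu)) {
    stop("GMV length does not match the baseline reference", call. = FALSE)
  }
  if (any(s == 0)) stop("baseline reference SD is zero for ROI(s): ",
                        paste(names(s)[s == 0], collapse = ", "),
                        call. = FALSE)
  if (!is.null(names(gmv)) && !is.null(names(mu))) gmv <- gmv[names(mu)]
  dev <- as.numeric(gmv) - as.numeric(mu)
  pooled <- sqrt(outer(s^2, s^2, `+`) / 2)
  esd <- abs(outer(dev, dev, `-`)) / pooled
  dimnames(esd) <- list(names(mu), names(mu))
  zero_diag(esd)
}

#' Effect-size weighting of edges
#'
#' Maps the ESD matrix to a similarity weight in (0, 1]:
#' R = (exp(2 ESD) - 1) / (exp(2 ESD) + 1), algebraically tanh(ESD), and
#' W = 1 - R. Regions whose deviations from the healthy mean are similar
#' (small ESD) keep weight near 1; strongly discordant pairs are down-weighted
#' toward 0.
#'
#' @param esd nonnegative symmetric ESD matrix from [compute_esd()].
#' @return Object of class `weight_matrix` with elements `esd`, `r`, `w`.
#' @export
weight_from_esd <- function(esd) {
  check_square_symmetric(esd, "esd")
  if (any(esd < 0)) stop("ESD entries must be nonnegative", call. = FALSE)
  e2 <- exp(2 * esd)
  r <- (e2 - 1) / (e2 + 1)
  r[is.nan(r)] <- 1  # exp overflow at extreme ESD: tanh saturates at 1
  w <- 1 - r
  structure(list(esd = esd, r = r, w = w), class = "weight_matrix")
}

#' Individual structural covariance network
#'
#' Entrywise product of the subject's weighting matrix W with the group-level
#' healthy-period covariance: M[i,j] = W[i,j] * SCN_HC[i,j], diagonal zero. A
#' subject at the healthy mean (W = 1 everywhere) recovers the group network;
#' edges between regions that deviate discordantly are attenuated.
#'
#' @param w a [weight_from_esd()] result (or plain W matrix).
#' @param reference a [baseline_reference()] carrying `scn_hc`.
#' @return An `individual_scn` [connectivity_matrix()].
#' @export
build_individual_scn <- function(w, reference) {
  W <- if (inherits(w, "weight_matrix")) w$w else w
  scn_hc <- reference$scn_hc
  if (!all(dim(W) == dim(scn_hc))) {
    stop("weight matrix and group covariance shapes differ", call. = FALSE)
  }
  connectivity_matrix(zero_diag(W * scn_hc), kind = "individual_scn",
                      roi_labels = rownames(scn_hc))
}

#' Positive-correlation Fisher-z functional network
#'
#' Pairwise Pearson correlation of the regional time series; nonpositive
#' correlations are set to zero (negative edges have no agreed physiological
#' interpretation in this construction), and the remaining correlations are
#' Fisher-z transformed (atanh), with r clipped at 1 - 1e-7 so perfectly
#' collinear regions get a large finite weight instead of infinity.
#'
#' @param record a time-series record (list with `series`) from
#'   [simulate_timeseries()], or a samples x ROI matrix directly.
#' @param min_samples minimum number of time samples (default 30).
#' @return A `functional_z` [connectivity_matrix()].
#' @export
build_functional_network <- function(record, min_samples = 30L) {
  series <- if (is.list(record) && !is.null(record$series)) record$series
            else record
  if (!is.matrix(series)) stop("time series must be a samples x ROI matrix",
                               call. = FALSE)
  if (nrow(series) < min_samples) {
    stop(sprintf("time series too short: %d samples (< %d)",
                 nrow(series), min_samples), call. = FALSE)
  }
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance time series for ROI(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- cor(series)
  r[r <= 0] <- 0
  r <- pmin(r, 1 - 1e-7)
  z <- atanh(r)
  connectivity_matrix(zero_diag(z), kind = "functional_z",
                      roi_labels = colnames(series))
}
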