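#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm p.adjust pnorm predict qnorm qt quantile
#'   residuals rnorm runif sd setNames shapiro.test t.test var vcov wilcox.test
#'   BIC aggregate as.formula
#' @importFrom utils read.delim write.table modifyList
NULL

# Substream seeds: one user-facing seed feeds a fixed per-operation offset
# scheme so adding a stage never perturbs another stage's draws. Offsets are
# part of the package contract (see op_offsets below); result kept < 2^31.
substream_seed <- function(seed, op) {
  offsets <- c(
    reference   = 101L,
    morphometry = 211L,
    timeseries  = 307L,
    outcomes    = 401L,
    nulls       = 503L,
    stats_sim   = 601L
  )
  if (!op %in% names(offsets)) {
    stop("unknown substream operation: ", op, call. = FALSE)
  }
  as.integer((as.numeric(seed) + 77003 * offsets[[op]]) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

check_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` must be symmetric (max asymmetry > %g)", name, tol),
         call. = FALSE)
  }
  invisible(m)
}

zero_diag <- function(m) { diag(m) <- 0; m }

roi_labels_for <- function(n) sprintf("roi_%03d", seq_len(n))
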