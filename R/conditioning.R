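#' Conditioning configuration for ROI time series
#'
#' Band edges default to the standard resting-state window 0.01--0.08 Hz,
#' which removes slow scanner drift below and cardiorespiratory
#' physiological noise above the band. The band must sit strictly inside
#' (0, Nyquist) where Nyquist = 1/(2 TR).
#'
#' @param band_low_hz,band_high_hz pass-band edges in Hz.
#' @param tr_seconds repetition time in seconds.
#' @param detrend_order polynomial order removed before filtering: 0
#'   (mean) or 1 (linear).
#' @param nuisance optional volumes-by-regressors matrix of per-volume
#'   nuisance covariates (e.g. white-matter/CSF signals, motion).
#' @return an object of class `conditioning_config`.
#' @export
conditioning_config <- function(band_low_hz = 0.01, band_high_hz = 0.08,
                                tr_seconds = 2, detrend_order = 1,
                                nuisance = NULL) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz &&
        band_high_hz < nyquist))
    stop(sprintf(
      "band [%g, %g] Hz invalid: need 0 < low < high < Nyquist (%g Hz)",
      band_low_hz, band_high_hz, nyquist))
  if (!detrend_order %in% c(0, 1))
    stop("detrend_order must be 0 or 1")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 tr_seconds = tr_seconds, detrend_order = detrend_order,
                 nuisance = nuisance),
            class = "conditioning_config")
}

#' Remove a per-region polynomial trend
#'
#' Least-squares removal of the order-`order` polynomial (with intercept)
#' from each region's time series; the output mean per region is zero.
#'
#' @param series regions-by-volumes matrix.
#' @param order 0 (demean) or 1 (linear detrend).
#' @return matrix of the same shape.
#' @export
detrend_series <- function(series, order = 1) {
  stopifnot(is.matrix(series), order %in% c(0, 1))
  n_vol <- ncol(series)
  if (n_vol <= order + 1)
    stop("n_volumes must exceed detrend_order + 1")
  tt <- seq_len(n_vol)
  x <- matrix(1, n_vol, 1)
  if (order >= 1) x <- cbind(x, tt - mean(tt))
  # residual-maker applied on the time dimension
  qx <- qr(x)
  t(qr.resid(qx, t(series)))
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]) per region, so the net filter has zero phase,
#' monotone pass-band response and at least 20 dB stop-band attenuation
#' at frequencies well outside the band.
#'
#' @param series regions-by-volumes matrix.
#' @param config a [conditioning_config()].
#' @return filtered matrix of the same shape.
#' @export
bandpass_series <- function(series, config = conditioning_config()) {
  stopifnot(is.matrix(series), inherits(config, "conditioning_config"))
  nyquist <- 1 / (2 * config$tr_seconds)
  wc <- c(config$band_low_hz, config$band_high_hz) / nyquist
  bf <- signal::butter(4, wc, type = "pass")
  out <- t(apply(series, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(series)
  out
}

#' Regress nuisance covariates out of each region's series
#'
#' Residualizes every region's time series on an intercept plus the given
#' nuisance regressors; residuals are orthogonal to every nuisance
#' column. An empty/NULL nuisance matrix reduces to demeaning.
#'
#' @param series regions-by-volumes matrix.
#' @param nuisance volumes-by-regressors matrix, or NULL.
#' @return residual matrix of the same shape.
#' @export
regress_nuisance <- function(series, nuisance = NULL) {
  stopifnot(is.matrix(series))
  n_vol <- ncol(series)
  if (is.null(nuisance) || (is.matrix(nuisance) && ncol(nuisance) == 0)) {
    return(series - rowMeans(series))
  }
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != n_vol)
    stop("nuisance must have one row per volume")
  x <- cbind(intercept = 1, nuisance)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    cols <- colnames(x)
    if (is.null(cols)) cols <- paste0("col", seq_len(ncol(x)))
    dropped <- cols[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("nuisance matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  t(qr.resid(qx, t(series)))
}

#' Apply the full conditioning chain to one series or subject
#'
#' Order matters and is fixed: detrend, then band-pass, then nuisance
#' regression.
#'
#' @param x a regions-by-volumes matrix or a `subject_ts`.
#' @param config a [conditioning_config()].
#' @return the conditioned matrix or subject.
#' @export
condition_series <- function(x, config = conditioning_config()) {
  if (inherits(x, "subject_ts")) {
    x$series <- condition_series(x$series, config)
    return(x)
  }
  out <- detrend_series(x, config$detrend_order)
  out <- bandpass_series(out, config)
  regress_nuisance(out, config$nuisance)
}

#' Condition every subject of a cohort
#'
#' @param cohort a `cohort`.
#' @param config a [conditioning_config()].
#' @return the cohort with conditioned series.
#' @export
condition_cohort <- function(cohort, config = conditioning_config()) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$subjects <- lapply(cohort$subjects, condition_series,
                            config = config)
  cohort
}
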