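# Accepts a SessionSeries or a plain matrix; returns list(mat, tr, wrap()).
.unwrapSeries <- function(series, trSeconds = NULL) {
  if (is(series, "SessionSeries")) {
    list(mat = seriesData(series), tr = trSeconds(series),
         wrap = function(m) {
           s <- series; s@data <- m; validObject(s); s
         })
  } else {
    if (is.null(trSeconds))
      stop("'trSeconds' required when 'series' is a plain matrix")
    m <- as.matrix(series)
    list(mat = m, tr = trSeconds, wrap = identity)
  }
}

# Odd Savitzky-Golay window length (in volumes) for a second-length window.
.sgWindow <- function(windowSeconds, tr, polyorder) {
  n <- round(windowSeconds / tr)
  if (n %% 2 == 0) n <- n + 1L
  if (n < polyorder + 2) n <- polyorder + 2 + (polyorder %% 2)
  as.integer(n)
}

#' Savitzky-Golay detrending of ROI time series
#'
#' Removes slow scanner drift by subtracting a Savitzky-Golay-smoothed
#' baseline (default window 240 s) from each ROI, re-adding the per-ROI
#' mean. A constant series passes through unchanged, and polynomial
#' trends up to `polyorder` are captured exactly on interior samples.
#'
#' @param series [SessionSeries-class] or volumes x ROI matrix.
#' @param windowSeconds window length in seconds (default 240).
#' @param polyorder polynomial order of the local fit (default 3).
#' @param trSeconds repetition time; required for plain matrices.
#' @return object of the same kind as `series`, detrended.
#' @export
savgolDetrend <- function(series, windowSeconds = 240, polyorder = 3,
                          trSeconds = NULL) {
  u <- .unwrapSeries(series, trSeconds)
  n <- .sgWindow(windowSeconds, u$tr, polyorder)
  if (nrow(u$mat) < n)
    stop("series (", nrow(u$mat), " volumes) shorter than the ",
         "Savitzky-Golay window (", n, " volumes); use a smaller ",
         "'windowSeconds'")
  out <- apply(u$mat, 2, function(x) {
    baseline <- signal::sgolayfilt(x, p = polyorder, n = n)
    x - baseline + mean(x)
  })
  u$wrap(out)
}

#' Regress confound time series out of ROI signals
#'
#' Per ROI, replaces the signal by the ordinary-least-squares residual of
#' the signal on an intercept plus the confound columns, with the
#' original per-ROI mean added back. Confounds should be passed through
#' the same Savitzky-Golay filtering as the data beforehand (see
#' [cleanSession()], which does this). Linearly dependent confound
#' columns are dropped with a warning.
#'
#' @param series [SessionSeries-class] or volumes x ROI matrix.
#' @param confounds volumes x k numeric matrix (or NULL for identity).
#' @param trSeconds repetition time for plain-matrix input.
#' @return object of the same kind as `series`, residualized.
#' @export
regressConfounds <- function(series, confounds, trSeconds = NULL) {
  u <- .unwrapSeries(series, trSeconds)
  if (is.null(confounds) || NCOL(confounds) == 0L) return(series)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(u$mat))
    stop("confounds and series must have the same number of volumes")
  X <- cbind(1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("confound matrix is rank-deficient; ",
            ncol(X) - qrX$rank, " dependent column(s) dropped")
  mu <- colMeans(u$mat)
  res <- qr.resid(qrX, u$mat)
  out <- sweep(res, 2, mu, "+")
  dimnames(out) <- dimnames(u$mat)
  u$wrap(out)
}

#' High-pass filter via discrete-cosine basis projection
#'
#' Removes fluctuations slower than `cutoffHz` by regressing out the
#' discrete-cosine basis functions whose frequency `k / (2 N TR)` lies
#' below the cutoff, then re-adding the per-ROI mean. The projection has
#' zero phase distortion and exactly unit gain on retained components.
#'
#' @param series [SessionSeries-class] or volumes x ROI matrix.
#' @param cutoffHz cutoff frequency in Hz (default 0.01).
#' @param trSeconds repetition time for plain-matrix input.
#' @return object of the same kind as `series`, filtered.
#' @export
highpassFilter <- function(series, cutoffHz = 0.01, trSeconds = NULL) {
  u <- .unwrapSeries(series, trSeconds)
  n <- nrow(u$mat)
  nyquist <- 1 / (2 * u$tr)
  if (cutoffHz >= nyquist)
    stop("cutoff (", cutoffHz, " Hz) must be below Nyquist (",
         signif(nyquist, 4), " Hz)")
  kMax <- floor(2 * n * u$tr * cutoffHz)   # components with f_k < cutoff
  mu <- colMeans(u$mat)
  if (kMax < 1) return(series)
  t <- seq_len(n) - 0.5
  basis <- sapply(seq_len(kMax), function(k) cos(pi * k * t / n))
  qrX <- qr(cbind(1, basis))
  out <- sweep(qr.resid(qrX, u$mat), 2, mu, "+")
  dimnames(out) <- dimnames(u$mat)
  u$wrap(out)
}

#' Flag high-motion volumes
#'
#' A volume is flagged when its framewise displacement strictly exceeds
#' the threshold (`FD > threshold`; a volume exactly at the threshold is
#' kept).
#'
#' @param fd non-negative numeric FD vector (mm).
#' @param threshold censoring threshold in mm (default 0.2).
#' @return logical vector, TRUE = flagged.
#' @export
flagVolumes <- function(fd, threshold = 0.2) {
  if (any(fd < 0)) stop("FD values must be non-negative")
  fd > threshold
}

#' Union (ordinary) scrubbing mask across sessions
#'
#' A volume is censored in every session if it is flagged in any session,
#' yielding a shared mask so all sessions keep comparable time series.
#'
#' @param flagMatrix logical sessions x volumes matrix from
#'   [flagVolumes()].
#' @return list with `keep` (logical per volume), `rule = "ordinary"`.
#' @export
scrubUnion <- function(flagMatrix) {
  flagMatrix <- as.matrix(flagMatrix)
  list(keep = !apply(flagMatrix, 2, any), rule = "ordinary")
}

#' Percentage-based scrubbing mask across sessions
#'
#' A volume is censored in all sessions when it is flagged in at least
#' `ceiling(pct * nSessions)` sessions. With 30 sessions, `pct = 0.10`
#' censors volumes flagged in 3 or more sessions and `pct = 0.05` in 2
#' or more; a `pct` small enough that the count threshold is 1 reduces
#' to union scrubbing.
#'
#' @param flagMatrix logical sessions x volumes matrix.
#' @param pct fraction of sessions in (0, 1].
#' @return list with `keep` (logical per volume), `rule = "percentage"`,
#'   `pct`, and `countThreshold`.
#' @export
scrubPercentage <- function(flagMatrix, pct) {
  if (pct <= 0 || pct > 1) stop("'pct' must lie in (0, 1]")
  flagMatrix <- as.matrix(flagMatrix)
  thr <- ceiling(pct * nrow(flagMatrix))
  counts <- colSums(flagMatrix)
  list(keep = counts < thr, rule = "percentage", pct = pct,
       countThreshold = as.integer(thr))
}

#' Apply a censoring mask to a session
#'
#' Drops censored volumes (row deletion, no interpolation).
#'
#' @param series [SessionSeries-class] or volumes x ROI matrix.
#' @param keep logical keep-vector (or a mask list from the scrubbing
#'   functions).
#' @return object of the same kind as `series` with censored rows removed.
#' @export
applyCensor <- function(series, keep) {
  if (is.list(keep)) keep <- keep$keep
  if (is(series, "SessionSeries")) {
    if (length(keep) != nVolumes(series))
      stop("mask length does not match volume count")
    s <- series
    s@data <- seriesData(series)[keep, , drop = FALSE]
    validObject(s)
    s
  } else {
    series[keep, , drop = FALSE]
  }
}

#' Full signal-conditioning pipeline for one session
#'
#' Savitzky-Golay detrending, confound regression (confounds filtered
#' with the same Savitzky-Golay step first, so filtering artifacts are
#' not re-introduced), then discrete-cosine high-pass filtering. When no
#' confounds are supplied (e.g., a session whose physiological recording
#' failed) the regression step is skipped and noted.
#'
#' @param session a [SessionSeries-class].
#' @param confounds optional volumes x k confound matrix.
#' @param windowSeconds Savitzky-Golay window (default 240 s).
#' @param polyorder Savitzky-Golay polynomial order (default 3).
#' @param cutoffHz high-pass cutoff (default 0.01 Hz).
#' @return cleaned [SessionSeries-class].
#' @export
cleanSession <- function(session, confounds = NULL, windowSeconds = 240,
                         polyorder = 3, cutoffHz = 0.01) {
  stopifnot(is(session, "SessionSeries"))
  out <- savgolDetrend(session, windowSeconds, polyorder)
  if (!is.null(confounds) && NCOL(confounds) > 0L) {
    cf <- savgolDetrend(as.matrix(confounds), windowSeconds, polyorder,
                        trSeconds = trSeconds(session))
    cf <- sweep(cf, 2, colMeans(cf))   # drop means; intercept handles them
    out <- regressConfounds(out, cf)
  } else {
    message("no confounds supplied for day ", sessionDay(session),
            "; confound regression skipped")
  }
  highpassFilter(out, cutoffHz)
}
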