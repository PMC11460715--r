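#' Pair a session-day metric series with a lagged daily factor
#'
#' Returns the pairs `(metric(d), factor(d - lag))` over all session
#' days. The lag grid of the lagged analysis is 1 to 15 days; a lag
#' outside it is an invalid configuration.
#'
#' @param metricValues numeric metric value per session.
#' @param factorDaily data.frame with `day` and the factor column, or a
#'   numeric vector indexed by day.
#' @param sessionDays integer day per session.
#' @param lag integer lag in days, in 1..15.
#' @param factorName column name when `factorDaily` is a data.frame.
#' @return data.frame with columns `metric` and `factor`.
#' @export
alignLag <- function(metricValues, factorDaily, sessionDays, lag,
                     factorName = NULL) {
  if (lag < 1 || lag > 15 || lag != round(lag))
    stop("'lag' must be an integer in 1..15")
  if (is.data.frame(factorDaily)) {
    pos <- match(sessionDays - lag, factorDaily$day)
    if (anyNA(pos))
      stop("factor not available on day(s) ",
           paste((sessionDays - lag)[is.na(pos)], collapse = ", "))
    f <- factorDaily[[factorName]][pos]
  } else {
    f <- factorDaily[sessionDays - lag]
  }
  data.frame(metric = metricValues, factor = f)
}

#' Fourier phase-randomized surrogate series
#'
#' Generates surrogates sharing the exact amplitude spectrum of the
#' input (hence its autocovariance and mean) but with independently
#' randomized phases: the phases of all paired frequencies are drawn
#' uniformly with conjugate symmetry enforced, while the DC component
#' and (for even lengths) the Nyquist component keep their phase so the
#' output is real and the mean is preserved exactly.
#'
#' @param series real numeric vector, length >= 4.
#' @param nSurr number of surrogates (default 1).
#' @param seed integer seed.
#' @return numeric matrix, `length(series)` x `nSurr`.
#' @export
phaseSurrogate <- function(series, nSurr = 1L, seed = 1L) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4")
  set.seed(seed)
  Xf <- fft(series)
  amp <- Mod(Xf)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2  # paired freqs
  Z <- matrix(complex(real = 0), n, nSurr)
  Z[1, ] <- Xf[1]                                      # DC fixed
  if (n %% 2 == 0) Z[n / 2 + 1, ] <- Xf[n / 2 + 1]     # Nyquist fixed
  if (half >= 1) {
    phi <- matrix(runif(half * nSurr, 0, 2 * pi), half, nSurr)
    k <- seq_len(half) + 1L
    Z[k, ] <- amp[k] * exp(1i * phi)
    Z[n + 2L - k, ] <- Conj(Z[k, , drop = FALSE])
  }
  out <- Re(mvfft(Z, inverse = TRUE)) / n
  dimnames(out) <- NULL
  out
}

#' Surrogate-calibrated lagged cross-correlation for one series pair
#'
#' Computes the correlation between a metric series (on session days)
#' and a daily behavioral factor at each lag, and calibrates it against
#' correlations with phase-randomized surrogates of the factor
#' (generated on the full daily grid, then subsampled to the lagged
#' session days, preserving the irregular twice-weekly sampling).
#' Two-sided p-values use the add-one rule. A constant metric series
#' has no defined correlation and is reported as NA, not zero.
#'
#' @param metricValues numeric metric value per session.
#' @param factorDaily numeric vector of the factor on days
#'   `1..length(factorDaily)` (imputed, no NAs).
#' @param sessionDays integer day per session.
#' @param lags integer lags, subset of 1..15 (default all).
#' @param nSurr number of surrogates (default 10000).
#' @param seed integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns `lag`, `rho`, `p`.
#' @export
surrogateTest <- function(metricValues, factorDaily, sessionDays,
                          lags = 1:15, nSurr = 10000L, seed = 1L,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (any(lags < 1 | lags > 15)) stop("lags must lie in 1..15")
  if (nSurr < 100) warning("nSurr < 100 gives unstable p-values")
  if (min(sessionDays) - max(lags) < 1)
    stop("factor series does not cover the largest lag")
  if (sd(metricValues) == 0) {
    return(data.frame(lag = lags, rho = NA_real_, p = NA_real_))
  }
  S <- phaseSurrogate(factorDaily, nSurr = nSurr, seed = seed)
  m <- if (method == "spearman") rank(metricValues) else metricValues
  res <- lapply(lags, function(L) {
    f <- factorDaily[sessionDays - L]
    Fs <- S[sessionDays - L, , drop = FALSE]
    if (method == "spearman") {
      f <- rank(f)
      Fs <- apply(Fs, 2, rank)
    }
    rho <- cor(m, f)
    rhoStar <- as.numeric(cor(m, Fs))
    p <- (1 + sum(abs(rhoStar) >= abs(rho))) / (1 + nSurr)
    data.frame(lag = L, rho = rho, p = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Lagged cross-correlation table across networks, metrics and factors
#'
#' Runs [surrogateTest()] for every network x metric x factor
#' combination at one proportional threshold, then BH-adjusts across
#' networks separately for each (factor, lag, metric) tuple, treating
#' each variable-lag pair as independent.
#'
#' @param metricTable output of [metricSeries()].
#' @param behavior imputed behavioral data.frame with a `day` column.
#' @param factors factor names.
#' @param threshold which proportional threshold to use (default 0.10).
#' @param lags integer lags, subset of 1..15.
#' @param nSurr number of surrogates.
#' @param seed integer seed.
#' @param method correlation type for [surrogateTest()].
#' @return data.frame: `network`, `metric`, `factor`, `lag`, `rho`,
#'   `p`, `q`.
#' @export
lagCorrelation <- function(metricTable, behavior, factors,
                           threshold = 0.10, lags = 1:15,
                           nSurr = 10000L, seed = 1L,
                           method = "pearson") {
  if (!identical(as.integer(behavior$day), seq_len(nrow(behavior))))
    stop("behavior table must cover contiguous days 1..nDays")
  sub <- metricTable[metricTable$threshold == threshold, ]
  out <- list()
  sid <- 0L
  for (met in unique(sub$metric)) {
    for (net in unique(sub$network)) {
      block <- sub[sub$metric == met & sub$network == net, ]
      block <- block[order(block$sessionDay), ]
      for (fac in factors) {
        sid <- sid + 1L
        r <- surrogateTest(block$value, behavior[[fac]],
                           block$sessionDay, lags = lags,
                           nSurr = nSurr, seed = seed + sid,
                           method = method)
        r <- cbind(network = net, metric = met, factor = fac, r,
                   stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, out)
  out$q <- NA_real_
  for (met in unique(out$metric)) {
    for (fac in unique(out$factor)) {
      for (L in unique(out$lag)) {
        sel <- out$metric == met & out$factor == fac & out$lag == L &
          !is.na(out$p)
        if (any(sel)) out$q[sel] <- bhFDR(out$p[sel])
      }
    }
  }
  rownames(out) <- NULL
  out
}
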