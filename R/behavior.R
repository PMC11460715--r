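#' PANAS negative and positive affect scores
#'
#' Negative affect (NAF) is the sum of the afraid, nervous, upset,
#' hostile and ashamed items; positive affect (PAF) is the sum of the
#' active, determined, attentive, inspired and alert items. A score whose
#' items are not all present is marked missing, never zero-filled.
#'
#' @param responses data.frame with one row per questionnaire response
#'   and the ten item columns (missing items as NA or absent columns).
#' @return data.frame with columns `NAF` and `PAF`, one row per response.
#' @examples
#' r <- data.frame(afraid = 2, nervous = 3, upset = 1, hostile = 1,
#'                 ashamed = 1, active = 1, determined = 1, attentive = 1,
#'                 inspired = 1, alert = 1)
#' panasScores(r)  # NAF 8, PAF 5
#' @export
panasScores <- function(responses) {
  negItems <- c("afraid", "nervous", "upset", "hostile", "ashamed")
  posItems <- c("active", "determined", "attentive", "inspired", "alert")
  scoreOf <- function(items) {
    present <- intersect(items, names(responses))
    if (length(present) < length(items))
      return(rep(NA_real_, nrow(responses)))
    m <- as.matrix(responses[, items, drop = FALSE])
    s <- rowSums(m)            # NA propagates when any item is NA
    as.numeric(s)
  }
  data.frame(NAF = scoreOf(negItems), PAF = scoreOf(posItems))
}

#' Aggregate within-day samples into daily statistics
#'
#' Collapses a stream of (day, value) samples to one value per day per
#' requested statistic. Days in the covered range with no samples are
#' marked missing. The SD of a single sample is defined as 0 (keeping
#' sd columns aligned with mean columns for sparse sensors).
#'
#' @param samples data.frame with columns `day` (integer) and `value`.
#' @param statistics character subset of
#'   `c("mean", "median", "min", "max", "sd")`.
#' @param days optional integer vector of days to report; defaults to the
#'   contiguous range covered by `samples`.
#' @return data.frame with column `day` plus one column per statistic.
#' @export
dailyAggregate <- function(samples, statistics = "mean", days = NULL) {
  known <- c("mean", "median", "min", "max", "sd")
  bad <- setdiff(statistics, known)
  if (length(bad))
    stop("unknown statistic(s): ", paste(bad, collapse = ", "))
  samples <- samples[!is.na(samples$value), , drop = FALSE]
  if (is.null(days)) {
    if (!nrow(samples)) stop("no samples and no 'days' supplied")
    days <- seq(min(samples$day), max(samples$day))
  }
  fns <- list(mean = mean, median = median, min = min, max = max,
              sd = function(x) if (length(x) == 1L) 0 else sd(x))
  out <- data.frame(day = days)
  grouped <- split(samples$value, factor(samples$day, levels = days))
  for (st in statistics) {
    out[[st]] <- vapply(grouped, function(v) {
      if (!length(v)) NA_real_ else fns[[st]](v)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Mean imputation of a numeric series
#'
#' Replaces missing values by the mean of the observed values; observed
#' values are untouched (so the series mean is preserved exactly).
#'
#' @param series numeric vector with possible NAs.
#' @return numeric vector without NAs.
#' @export
imputeMean <- function(series) {
  obs <- !is.na(series)
  if (!any(obs)) stop("cannot impute an all-missing series")
  series[!obs] <- mean(series[obs])
  series
}

#' Mean-impute every factor column of a behavioral table
#'
#' @param table data.frame; every non-`day` numeric column is imputed
#'   with [imputeMean()].
#' @return data.frame without missing cells.
#' @export
imputeMeanTable <- function(table) {
  for (nm in setdiff(names(table), "day")) {
    if (is.numeric(table[[nm]])) table[[nm]] <- imputeMean(table[[nm]])
  }
  table
}

# VIF of each column of X regressed on the remaining columns: 1/(1 - R^2).
.vifAll <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(k) {
    y <- X[, k]
    others <- X[, -k, drop = FALSE]
    fit <- lm.fit(cbind(1, others), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Collinearity screen: VIF then pairwise rank correlation
#'
#' Screens an imputed factor table for multicollinearity in two passes.
#' First, zero-variance columns are dropped (VIF is undefined for them).
#' Second, the factor with the largest variance inflation factor is
#' dropped repeatedly until every VIF is at or below `vifThreshold`.
#' Third, for every remaining pair with absolute Spearman correlation
#' above `corrThreshold`, only the variable earlier in the priority
#' order is retained. Every drop is recorded with its trigger value.
#'
#' @param table data.frame of factors (a `day` column, if present, is
#'   carried along but not screened); must contain no missing values.
#' @param vifThreshold VIF cutoff (default 5).
#' @param corrThreshold absolute rank-correlation cutoff (default 0.7).
#' @param priority character vector ordering the factors by preference
#'   (earlier = kept); defaults to column order.
#' @return list with `retained` (character), `dropped` (data.frame:
#'   variable, reason, value) and `table` (the screened data.frame).
#' @export
collinearityScreen <- function(table, vifThreshold = 5,
                               corrThreshold = 0.7, priority = NULL) {
  dayCol <- table[["day"]]
  X <- table[, setdiff(names(table), "day"), drop = FALSE]
  if (anyNA(X)) stop("screen requires an imputed (complete) table")
  if (ncol(X) < 2) stop("need at least two factors to screen")
  if (is.null(priority)) priority <- names(X)
  rank <- match(names(X), priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  names(rank) <- names(X)
  dropped <- data.frame(variable = character(), reason = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  note <- function(v, reason, value) {
    dropped[nrow(dropped) + 1L, ] <<- list(v, reason, value)
  }
  # 1. zero variance
  for (nm in names(X)) {
    if (sd(X[[nm]]) == 0) {
      note(nm, "zero variance", 0)
      X[[nm]] <- NULL
    }
  }
  # 2. iterative VIF
  while (ncol(X) >= 2) {
    v <- .vifAll(as.matrix(X))
    if (max(v) <= vifThreshold) break
    worst <- which(v == max(v))
    # among tied maxima, drop the lowest-priority (latest) variable
    worst <- worst[which.max(rank[names(X)[worst]])]
    note(names(X)[worst], "VIF", max(v))
    X[[worst]] <- NULL
  }
  # 3. pairwise rank correlation, keep the higher-priority variable
  repeat {
    if (ncol(X) < 2) break
    rho <- cor(as.matrix(X), method = "spearman")
    diag(rho) <- 0
    if (max(abs(rho)) <= corrThreshold) break
    idx <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    pair <- names(X)[idx]
    loser <- pair[which.max(rank[pair])]
    note(loser, "rank correlation", max(abs(rho)))
    X[[loser]] <- NULL
  }
  out <- X
  if (!is.null(dayCol)) out <- cbind(day = dayCol, out)
  list(retained = names(X), dropped = dropped, table = out)
}
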