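#' Sliding-window segmentation of a run
#'
#' Divides a run of `T` volumes into overlapping segments of `window`
#' TRs advanced by `step` TRs: `floor((T - window) / step) + 1` segments,
#' segment k starting at volume `(k - 1) * step + 1`. A 970-volume movie
#' run with window 25 and step 1 yields 946 segments of 14.85 s at TR
#' 0.594 s. Segments containing censored volumes can be excluded via
#' `keep`.
#'
#' @param nVolumes run length in volumes (or a [SessionSeries-class]).
#' @param window segment length in TRs (default 25).
#' @param step slide in TRs (default 1).
#' @param keep optional logical keep-vector; segments overlapping a
#'   censored volume are dropped (count reported in a message).
#' @return list of class `segmentSet`: `starts`, `window`, `step`,
#'   `nSegments`.
#' @export
makeSegments <- function(nVolumes, window = 25L, step = 1L, keep = NULL) {
  if (is(nVolumes, "SessionSeries")) nVolumes <- nVolumes(nVolumes)
  if (nVolumes < window)
    stop("run (", nVolumes, " volumes) shorter than the window (",
         window, ")")
  if (step < 1) stop("'step' must be at least 1")
  starts <- seq(1L, nVolumes - window + 1L, by = step)
  if (!is.null(keep)) {
    ok <- vapply(starts, function(st) all(keep[st:(st + window - 1L)]),
                 logical(1))
    if (any(!ok))
      message(sum(!ok), " segment(s) dropped for overlapping censored ",
              "volumes")
    starts <- starts[ok]
  }
  structure(list(starts = starts, window = as.integer(window),
                 step = as.integer(step), nSegments = length(starts)),
            class = "segmentSet")
}

#' Chance level of segment identification
#'
#' Uniform guessing among `nSegments` candidates succeeds with
#' probability `1 / nSegments` (1/946 for the full movie run).
#'
#' @param nSegments number of candidate segments.
#' @return probability of a correct guess by chance.
#' @export
chanceLevel <- function(nSegments) {
  if (nSegments < 1) stop("'nSegments' must be at least 1")
  1 / nSegments
}

# Segments x window matrix of one ROI's time course.
.segmentMatrix <- function(x, segs) {
  t(vapply(segs$starts, function(st) x[st:(st + segs$window - 1L)],
           numeric(segs$window)))
}

# Row-wise standardization for fast correlation; zero-variance rows
# are flagged so their correlations can be forced to -Inf.
.rowStd <- function(M) {
  mu <- rowMeans(M)
  Mc <- M - mu
  ss <- sqrt(rowSums(Mc^2))
  bad <- ss == 0
  ss[bad] <- 1
  list(M = Mc / ss, bad = bad)
}

#' Leave-one-session-out time-segment identification
#'
#' For every spatial unit (ROI) and every left-out session, each of the
#' left-out session's segments is matched, by Pearson correlation of
#' the window-long pattern, against the average segment patterns of the
#' remaining sessions; the predicted position is the template with the
#' highest correlation (ties go to the smallest index, zero-variance
#' templates are never selected). Accuracy is the fraction of segments
#' assigned to their true position.
#'
#' @param sessions list of [SessionSeries-class] with identical volume
#'   counts (apply the same shared scrub mask first).
#' @param window,step segmentation parameters (default 25 and 1).
#' @param keep optional shared keep-vector passed to [makeSegments()].
#' @param rois ROI indices to classify (default all).
#' @return list with `accuracy` (sessions x ROI matrix), `nSegments`,
#'   and `chance`.
#' @export
looIdentify <- function(sessions, window = 25L, step = 1L, keep = NULL,
                        rois = seq_len(nRois(sessions[[1]]))) {
  nSess <- length(sessions)
  if (nSess < 2) stop("need at least 2 sessions")
  nv <- vapply(sessions, nVolumes, integer(1))
  if (length(unique(nv)) != 1L)
    stop("all sessions must have the same number of volumes ",
         "(use a shared scrub mask)")
  segs <- makeSegments(nv[1], window, step, keep)
  nSeg <- segs$nSegments
  acc <- matrix(NA_real_, nSess, length(rois))
  for (k in seq_along(rois)) {
    segMats <- lapply(sessions, function(s)
      .segmentMatrix(seriesData(s)[, rois[k]], segs))
    total <- Reduce(`+`, segMats)
    for (s in seq_len(nSess)) {
      template <- (total - segMats[[s]]) / (nSess - 1)
      A <- .rowStd(segMats[[s]])
      B <- .rowStd(template)
      C <- tcrossprod(A$M, B$M)          # segments x templates
      C[, B$bad] <- -Inf
      C[A$bad, ] <- -Inf
      pred <- max.col(C, ties.method = "first")
      acc[s, k] <- mean(pred == seq_len(nSeg))
    }
  }
  dimnames(acc) <- list(paste0("session", seq_len(nSess)),
                        paste0("roi", rois))
  list(accuracy = acc, nSegments = nSeg, chance = chanceLevel(nSeg))
}

#' Regress accuracy maps on lagged daily factors
#'
#' Unit-wise permutation regression of leave-one-out identification
#' accuracy on behavioral factors aligned at the requested lag, with
#' BH-FDR across units per predictor (the desk-scale stand-in for
#' voxelwise permutation correction).
#'
#' @param accuracy sessions x units accuracy matrix from
#'   [looIdentify()].
#' @param behavior imputed behavioral data.frame with a `day` column.
#' @param factors factor names entering the model.
#' @param sessionDays integer day per session (rows of `accuracy`).
#' @param lag alignment lag in days (default 1).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return data.frame: `unit`, `predictor`, `beta`, `t`, `p`, `q`.
#' @export
accuracyRegression <- function(accuracy, behavior, factors, sessionDays,
                               lag = 1L, nPerm = 10000L, seed = 1L) {
  X <- alignPreviousDay(behavior, sessionDays, factors, lag)
  ok <- apply(accuracy, 2, function(v) !anyNA(v) && sd(v) > 0)
  if (!any(ok)) stop("no unit has varying accuracy to model")
  Y <- accuracy[, ok, drop = FALSE]
  fit <- .permModel(Y, as.matrix(X), nPerm, seed)
  units <- colnames(accuracy)[ok]
  if (is.null(units)) units <- paste0("unit", which(ok))
  preds <- colnames(X)
  out <- do.call(rbind, lapply(seq_along(preds), function(jp) {
    data.frame(unit = units, predictor = preds[jp],
               beta = fit$beta[jp, ], t = fit$t[jp, ],
               p = fit$p[jp, ], q = fit$q[jp, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
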