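#' Day-by-day brain similarity for one ROI (single-subject ISC)
#'
#' Treats each day's session as one "subject" in the inter-subject
#' correlation framework: entry (i, j) is the Pearson correlation of the
#' ROI's time course on session i with the same ROI's time course on
#' session j, over the volumes retained by a mask shared by all sessions
#' (so every session contributes the same time points).
#'
#' @param sessions list of [SessionSeries-class], all with the same
#'   number of volumes.
#' @param roi ROI index (column) to compare.
#' @param keep shared logical keep-vector or scrubbing mask list.
#' @return symmetric session x session correlation matrix (diagonal 1).
#' @export
roiISC <- function(sessions, roi, keep = NULL) {
  if (is.list(keep) && !is.null(keep$keep)) keep <- keep$keep
  tc <- sapply(sessions, function(s) {
    x <- seriesData(s)[, roi]
    if (!is.null(keep)) x <- x[keep]
    x
  })
  if (nrow(tc) < 3)
    stop("fewer than 3 retained volumes; use a looser scrubbing ",
         "percentage")
  r <- cor(tc)
  dimnames(r) <- list(paste0("day", vapply(sessions, sessionDay,
                                           integer(1))),
                      paste0("day", vapply(sessions, sessionDay,
                                           integer(1))))
  r
}

#' Day-by-day behavioral similarity under NN or AK structure
#'
#' Rank-transforms the per-day behavioral values to `r_i` in `[0, 1]`
#' (average ranks on ties) and builds the similarity matrix of the
#' nearest-neighbors model, `sim(i, j) = -|r_i - r_j|` (days with close
#' values are alike), or the Anna-Karenina model,
#' `sim(i, j) = (r_i + r_j) / 2` (high-scoring days are alike,
#' low-scoring days are idiosyncratic).
#'
#' @param values numeric behavioral value per session day.
#' @param model `"NN"` or `"AK"`.
#' @return symmetric similarity matrix.
#' @export
behaviorSimilarity <- function(values, model = c("NN", "AK")) {
  model <- match.arg(model)
  n <- length(values)
  rk <- rank(values)               # average ranks on ties
  r01 <- if (n > 1) (rk - 1) / (n - 1) else rep(0.5, n)
  if (model == "NN") {
    sim <- -abs(outer(r01, r01, "-"))
  } else {
    sim <- outer(r01, r01, "+") / 2
  }
  diag(sim) <- if (model == "NN") 0 else r01
  sim
}

#' Mantel test between two similarity matrices
#'
#' Statistic: rank (Spearman) correlation of the vectorized upper
#' triangles (diagonal excluded). Null distribution: simultaneous
#' row-and-column permutations of the second matrix. The default
#' alternative is one-sided positive (more similar brains on more
#' similar days); p-values use the add-one rule.
#'
#' @param simA,simB symmetric matrices with identical dimensions and
#'   ordering.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param method correlation for the statistic, `"spearman"` (default)
#'   or `"pearson"`.
#' @return list with `rho`, `p`, `nPerm`.
#' @export
mantelTest <- function(simA, simB, nPerm = 10000L, seed = 1L,
                       alternative = c("greater", "two.sided"),
                       method = c("spearman", "pearson")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!all(dim(simA) == dim(simB)))
    stop("similarity matrices must have identical dimensions")
  n <- nrow(simA)
  ut <- upper.tri(simA)
  a <- simA[ut]
  b <- simB[ut]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant upper triangle; Mantel statistic undefined")
    return(list(rho = NA_real_, p = NA_real_, nPerm = nPerm))
  }
  B <- simB
  if (method == "spearman") {
    a <- rank(a)
    # ranks of a row/column-relabeled matrix are the relabeled ranks
    # (the upper-triangle multiset is permutation-invariant), so rank
    # once and permute the ranked matrix in the loop
    B[ut] <- rank(b)
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
  }
  rho <- cor(a, B[ut])
  set.seed(seed)
  count <- 0L
  for (k in seq_len(nPerm)) {
    perm <- sample.int(n)
    rhoStar <- cor(a, B[perm, perm][ut])
    hit <- if (alternative == "greater") rhoStar >= rho
    else abs(rhoStar) >= abs(rho)
    count <- count + hit
  }
  list(rho = rho, p = (1 + count) / (1 + nPerm), nPerm = nPerm)
}

#' Inter-day RSA across ROIs with FDR correction
#'
#' For each ROI, compares its day-by-day ISC matrix with the behavioral
#' similarity matrix of one factor (NN or AK model) via the Mantel
#' test, then BH-adjusts the p-values across ROIs.
#'
#' @param sessions list of [SessionSeries-class] (same shared mask
#'   applies to all).
#' @param keep shared keep-vector or mask list.
#' @param behaviorValues one behavioral value per session (previous-day
#'   aligned).
#' @param model `"NN"` or `"AK"`.
#' @param rois ROI indices to test (default all).
#' @param nPerm Mantel permutations per ROI.
#' @param seed integer seed.
#' @return data.frame: `roi`, `model`, `rho`, `p`, `q`.
#' @export
idrsaAcrossRois <- function(sessions, keep, behaviorValues,
                            model = "NN",
                            rois = seq_len(nRois(sessions[[1]])),
                            nPerm = 10000L, seed = 1L) {
  simB <- behaviorSimilarity(behaviorValues, model)
  res <- lapply(seq_along(rois), function(k) {
    simA <- roiISC(sessions, rois[k], keep)
    mt <- mantelTest(simA, simB, nPerm = nPerm, seed = seed + k)
    data.frame(roi = rois[k], model = model, rho = mt$rho, p = mt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  if (any(ok)) out$q[ok] <- bhFDR(out$p[ok])
  rownames(out) <- NULL
  out
}
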