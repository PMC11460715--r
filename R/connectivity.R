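# Correlation matrix with zero-variance columns reported as NA links.
.corAdjacency <- function(mat, what = "ROI") {
  sds <- apply(mat, 2, sd)
  bad <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(mat))
  if (any(bad)) {
    warning(sum(bad), " zero-variance ", what,
            " column(s); their links set to NA")
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Pearson adjacency matrix of one session
#'
#' Correlates every pair of ROI time courses over the retained volumes
#' (censored volumes are removed by row deletion, identically for all
#' ROIs, so the correlation support is pairwise-consistent).
#'
#' @param session a [SessionSeries-class].
#' @param keep optional logical keep-vector or scrubbing mask list.
#' @return an [Adjacency-class] in the `"r"` domain.
#' @export
pearsonAdjacency <- function(session, keep = NULL) {
  stopifnot(is(session, "SessionSeries"))
  if (!is.null(keep)) session <- applyCensor(session, keep)
  if (nVolumes(session) < 3)
    stop("need at least 3 retained volumes to correlate")
  r <- .corAdjacency(seriesData(session))
  Adjacency(r, domain = "r", sessionDay = sessionDay(session),
            task = taskLabel(session))
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of gammas (peak 6 s, undershoot 16 s, ratio 1/6),
#' scaled to unit peak. Zero for negative times.
#'
#' @param t time in seconds (vectorized).
#' @return HRF values.
#' @export
canonicalHRF <- function(t) {
  h <- ifelse(t < 0, 0,
              dgamma(t, shape = 6, rate = 1) -
                dgamma(t, shape = 16, rate = 1) / 6)
  peak <- max(dgamma(seq(0, 30, by = 0.01), shape = 6, rate = 1) -
                dgamma(seq(0, 30, by = 0.01), shape = 16, rate = 1) / 6)
  h / peak
}

# One HRF-convolved regressor per trial, sampled on the volume grid.
.trialDesign <- function(onsets, nVol, tr, hrf) {
  tGrid <- (seq_len(nVol) - 1) * tr
  sapply(onsets, function(o) hrf(tGrid - o))
}

#' Trial-wise beta series from a least-squares-all GLM
#'
#' Models every trial with its own HRF-convolved regressor and fits all
#' trials simultaneously (LSA) alongside an intercept and a linear drift
#' column, yielding one amplitude estimate per trial per ROI. With
#' `method = "lss"`, each trial is instead estimated from its own model
#' in which the remaining trials share a single regressor. A
#' near-singular design (heavily overlapping trials) triggers a warning
#' and a small ridge penalty on the trial block.
#'
#' @param session a [SessionSeries-class].
#' @param trials data.frame with an `onset` column (seconds).
#' @param hrf hemodynamic response function of time in seconds
#'   (default [canonicalHRF()]).
#' @param method `"lsa"` (default) or `"lss"`.
#' @param drift include a linear drift column (default TRUE).
#' @return list with `betas` (trials x ROI matrix) and `trials`.
#' @export
fitBetaSeries <- function(session, trials, hrf = canonicalHRF,
                          method = c("lsa", "lss"), drift = TRUE) {
  method <- match.arg(method)
  stopifnot(is(session, "SessionSeries"))
  Y <- seriesData(session)
  nVol <- nrow(Y)
  tr <- trSeconds(session)
  runDur <- nVol * tr
  if (any(trials$onset < 0 | trials$onset >= runDur))
    stop("trial onsets must lie within the run duration")
  D <- .trialDesign(trials$onset, nVol, tr, hrf)
  nuisance <- cbind(intercept = rep(1, nVol))
  if (drift) nuisance <- cbind(nuisance, drift = seq_len(nVol) / nVol)
  solveBlock <- function(X) {
    XtX <- crossprod(X)
    cn <- kappa(XtX, exact = FALSE)
    if (!is.finite(cn) || cn > 1e10) {
      warning("design near-singular (condition number ", signif(cn, 3),
              "); applying ridge fallback")
      XtX <- XtX + diag(1e-6 * mean(diag(XtX)), ncol(X))
    }
    solve(XtX, crossprod(X, Y))
  }
  if (method == "lsa") {
    B <- solveBlock(cbind(D, nuisance))
    betas <- B[seq_len(ncol(D)), , drop = FALSE]
  } else {
    betas <- matrix(NA_real_, nrow(trials), ncol(Y))
    for (j in seq_len(nrow(trials))) {
      others <- if (nrow(trials) > 1)
        rowSums(D[, -j, drop = FALSE]) else NULL
      X <- cbind(D[, j], others, nuisance)
      betas[j, ] <- solveBlock(X)[1, ]
    }
  }
  rownames(betas) <- paste0("trial", seq_len(nrow(trials)))
  colnames(betas) <- colnames(Y)
  list(betas = betas, trials = trials)
}

#' Beta-series adjacency matrix
#'
#' Correlates trial-wise amplitude estimates between ROIs, giving the
#' task-state connectivity matrix.
#'
#' @param betaSeries result of [fitBetaSeries()].
#' @param sessionDay,task metadata stored in the result.
#' @return an [Adjacency-class] in the `"r"` domain.
#' @export
betaAdjacency <- function(betaSeries, sessionDay = 1L, task = "pvt") {
  B <- betaSeries$betas
  if (nrow(B) < 3) stop("need at least 3 trials to correlate beta series")
  Adjacency(.corAdjacency(B, what = "beta"), domain = "r",
            sessionDay = sessionDay, task = task)
}

#' Fisher variance-stabilizing transform and its inverse
#'
#' `fisherZ` maps correlations to `atanh(r)`, clipping `|r| = 1` to
#' `1 - 1e-7`; `fisherInverse` maps back with `tanh`. The diagonal is
#' excluded (set to 0 in the z domain, 1 in the r domain).
#'
#' @param adjacency an [Adjacency-class].
#' @return an [Adjacency-class] in the other domain.
#' @export
fisherZ <- function(adjacency) {
  stopifnot(is(adjacency, "Adjacency"))
  if (adjacencyDomain(adjacency) != "r")
    stop("fisherZ expects an r-domain adjacency")
  r <- adjacencyWeights(adjacency)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  new("Adjacency", weights = z, domain = "fisher_z",
      sessionDay = adjacency@sessionDay, task = adjacency@task)
}

#' @rdname fisherZ
#' @export
fisherInverse <- function(adjacency) {
  stopifnot(is(adjacency, "Adjacency"))
  if (adjacencyDomain(adjacency) != "fisher_z")
    stop("fisherInverse expects a fisher_z-domain adjacency")
  r <- tanh(adjacencyWeights(adjacency))
  diag(r) <- 1
  new("Adjacency", weights = r, domain = "r",
      sessionDay = adjacency@sessionDay, task = adjacency@task)
}

# Upper-triangle link index of an n x n matrix, as a 2-column matrix.
.linkIndex <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Sessions x links matrix from an adjacency stack
#'
#' Flattens a list of same-sized [Adjacency-class] objects into a
#' sessions x links matrix of upper-triangle weights, with the (i, j)
#' index of each link attached as the `"linkIndex"` attribute.
#'
#' @param stack list of [Adjacency-class] objects.
#' @return numeric matrix, one row per session, one column per link.
#' @export
stackLinkMatrix <- function(stack) {
  n <- nrow(adjacencyWeights(stack[[1]]))
  idx <- .linkIndex(n)
  M <- t(vapply(stack, function(a) adjacencyWeights(a)[idx],
                numeric(nrow(idx))))
  colnames(M) <- paste0("L", idx[, 1], "_", idx[, 2])
  attr(M, "linkIndex") <- idx
  M
}

#' Residualize mean framewise displacement from an adjacency stack
#'
#' For every link, the Fisher-z weights across sessions are regressed on
#' the session-level mean FD; the output is the per-link across-session
#' mean plus the residual, so the mean of each link is preserved and the
#' residualized weights remain interpretable as connectivity. The stack
#' is then mapped back to the r domain. A constant mean-FD vector leaves
#' the stack unchanged (with a message).
#'
#' @param stack list of [Adjacency-class] objects in the `"fisher_z"`
#'   domain, one per session.
#' @param meanFD numeric vector of per-session mean FD values.
#' @return list of [Adjacency-class] objects in the `"r"` domain.
#' @export
residualizeMotion <- function(stack, meanFD) {
  if (length(meanFD) != length(stack))
    stop("need one mean-FD value per session")
  if (any(vapply(stack, adjacencyDomain, character(1)) != "fisher_z"))
    stop("stack must be in the fisher_z domain")
  n <- nrow(adjacencyWeights(stack[[1]]))
  Z <- stackLinkMatrix(stack)
  idx <- attr(Z, "linkIndex")
  if (sd(meanFD) == 0) {
    message("mean FD constant across sessions; motion residualization ",
            "is the identity")
    out <- Z
  } else {
    fdc <- meanFD - mean(meanFD)
    b <- crossprod(fdc, Z)[1, ] / sum(fdc^2)
    out <- Z - outer(fdc, b)
  }
  lapply(seq_along(stack), function(s) {
    W <- matrix(0, n, n)
    W[idx] <- out[s, ]
    W <- W + t(W)
    z <- new("Adjacency", weights = W, domain = "fisher_z",
             sessionDay = stack[[s]]@sessionDay, task = stack[[s]]@task)
    fisherInverse(z)
  })
}
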