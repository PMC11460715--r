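#' Z-score columns of a design matrix or response
#'
#' Centers to mean 0 and scales to SD 1 (denominator n - 1). A constant
#' column cannot be standardized and raises an error naming it.
#'
#' @param x numeric vector or matrix/data.frame of columns.
#' @return object of the same shape, standardized.
#' @export
standardize <- function(x) {
  if (is.null(dim(x))) {
    if (sd(x) == 0) stop("cannot standardize a constant vector")
    return((x - mean(x)) / sd(x))
  }
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x)[, , drop = FALSE]
}

# t statistics of the predictors of X1 = [1 | X] for every column of Y.
# Returns p x m matrix (predictors x responses). C and qrX are reusable.
.tStats <- function(X1, Y, C, df) {
  B <- C$M %*% Y                            # (p+1) x m coefficients
  fitted <- X1 %*% B
  rss <- colSums((Y - fitted)^2)
  se <- sqrt(outer(C$diagC[-1], rss / df))  # p x m
  (B[-1, , drop = FALSE] / se)
}

.olsPrep <- function(X1) {
  XtX <- crossprod(X1)
  Cinv <- solve(XtX)
  list(M = Cinv %*% t(X1), diagC = diag(Cinv))
}

#' Permutation inference for a standardized multiple regression
#'
#' Fits `y ~ X` on z-scored data and assesses each predictor's t
#' statistic against a null built by permuting the response rows
#' (`scheme = "response"`, the default) or by the Freedman-Lane scheme
#' (permuting reduced-model residuals per predictor). Two-sided
#' p-values use the add-one rule, `p = (1 + #{|t*| >= |t|}) / (1 +
#' nPerm)`, so the smallest attainable p is `1/(nPerm + 1)`.
#'
#' @param y numeric response (one value per observation).
#' @param X numeric matrix/data.frame of predictors.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param scheme `"response"` or `"freedman-lane"`.
#' @return data.frame with one row per predictor: `predictor`, `beta`
#'   (standardized coefficient), `t`, `p`, plus `nPerm` and `seed`.
#' @export
permLM <- function(y, X, nPerm = 10000L, seed = 1L,
                   scheme = c("response", "freedman-lane")) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need more observations than predictors + 1")
  if (nPerm < 100) warning("nPerm < 100 gives unstable p-values")
  ys <- standardize(y)
  Xs <- standardize(X)
  X1 <- cbind(1, Xs)
  df <- n - p - 1
  C <- .olsPrep(X1)
  tObs <- .tStats(X1, matrix(ys, ncol = 1), C, df)[, 1]
  beta <- (C$M %*% ys)[-1, 1]
  set.seed(seed)
  if (scheme == "response") {
    P <- replicate(nPerm, sample.int(n))
    Ystar <- matrix(ys[P], n, nPerm)
    tStar <- abs(.tStats(X1, Ystar, C, df))
    exceed <- rowSums(tStar >= abs(tObs))
  } else {
    exceed <- integer(p)
    for (j in seq_len(p)) {
      Xr <- cbind(1, Xs[, -j, drop = FALSE])
      qr_r <- qr(Xr)
      fr <- qr.fitted(qr_r, ys)
      er <- ys - fr
      P <- replicate(nPerm, sample.int(n))
      Ystar <- fr + matrix(er[P], n, nPerm)
      tStar <- abs(.tStats(X1, Ystar, C, df)[j, ])
      exceed[j] <- sum(tStar >= abs(tObs[j]))
    }
  }
  data.frame(predictor = colnames(X), beta = as.numeric(beta),
             t = as.numeric(tObs),
             p = (1 + exceed) / (1 + nPerm),
             nPerm = nPerm, seed = seed, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} m p_(j) / j`, mapped back to
#' the input order and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values.
#' @export
bhFDR <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Align daily behavioral factors to session days
#'
#' Session on day `d` is paired with the factor values of day `d - lag`
#' (the previous-day design at `lag = 1`).
#'
#' @param behavior imputed behavioral data.frame with a `day` column.
#' @param sessionDays integer day index per session.
#' @param factors character vector of factor column names.
#' @param lag non-negative integer lag in days (default 1).
#' @return data.frame, one row per session, columns = `factors`.
#' @export
alignPreviousDay <- function(behavior, sessionDays, factors, lag = 1L) {
  wanted <- sessionDays - lag
  pos <- match(wanted, behavior$day)
  if (anyNA(pos))
    stop("behavior table does not cover day(s) ",
         paste(wanted[is.na(pos)], collapse = ", "),
         " needed for sessions on day(s) ",
         paste(sessionDays[is.na(pos)], collapse = ", "))
  missingFac <- setdiff(factors, names(behavior))
  if (length(missingFac))
    stop("factor(s) not in behavior table: ",
         paste(missingFac, collapse = ", "))
  behavior[pos, factors, drop = FALSE]
}

# Shared engine: permutation regression of a sessions x units response
# matrix on a common design, FDR per predictor across units.
.permModel <- function(Y, X, nPerm, seed) {
  n <- nrow(Y)
  p <- ncol(X)
  if (n <= p + 1) stop("need more sessions than predictors + 1")
  Xs <- standardize(X)
  Ys <- apply(Y, 2, standardize)
  X1 <- cbind(1, Xs)
  df <- n - p - 1
  C <- .olsPrep(X1)
  tObs <- .tStats(X1, Ys, C, df)            # p x L
  betaObs <- (C$M %*% Ys)[-1, , drop = FALSE]
  set.seed(seed)
  exceed <- matrix(0L, p, ncol(Y))
  for (b in seq_len(nPerm)) {
    perm <- sample.int(n)
    tStar <- abs(.tStats(X1, Ys[perm, , drop = FALSE], C, df))
    exceed <- exceed + (tStar >= abs(tObs))
  }
  pMat <- (1 + exceed) / (1 + nPerm)
  qMat <- t(apply(pMat, 1, bhFDR))
  list(beta = betaObs, t = tObs, p = pMat, q = matrix(qMat, nrow = p))
}

#' Link-wise permutation regression of connectivity on daily factors
#'
#' For every link among the ROIs of the selected networks, regresses the
#' across-session link weights on the previous-day behavioral factors
#' (plus optional covariates), with permutation p-values and BH-FDR
#' across links separately for each predictor.
#'
#' @param stack list of [Adjacency-class] objects, one per session.
#' @param behavior imputed behavioral data.frame with a `day` column.
#' @param factors factor names entering the model.
#' @param atlas atlas data.frame with `network` labels.
#' @param networks networks whose ROIs define the candidate links (both
#'   endpoints must belong to the selected networks).
#' @param covariates optional additional predictor names (e.g., the
#'   prolonged-eye-closure percentage).
#' @param lag alignment lag in days (default 1 = previous day).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return data.frame: `i`, `j`, `predictor`, `beta`, `t`, `p`, `q`.
#' @export
modelLinks <- function(stack, behavior, factors, atlas,
                       networks = unique(atlas$network),
                       covariates = NULL, lag = 1L, nPerm = 10000L,
                       seed = 1L) {
  sessionDays <- vapply(stack, function(a) a@sessionDay, integer(1))
  X <- alignPreviousDay(behavior, sessionDays,
                        c(factors, covariates), lag)
  M <- stackLinkMatrix(stack)
  idx <- attr(M, "linkIndex")
  inNet <- atlas$network %in% networks
  keep <- inNet[idx[, 1]] & inNet[idx[, 2]]
  keep <- keep & apply(M, 2, function(v) !anyNA(v) && sd(v) > 0)
  M <- M[, keep, drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  fit <- .permModel(M, as.matrix(X), nPerm, seed)
  preds <- colnames(X)
  out <- do.call(rbind, lapply(seq_along(preds), function(jp) {
    data.frame(i = idx[, 1], j = idx[, 2], predictor = preds[jp],
               beta = fit$beta[jp, ], t = fit$t[jp, ],
               p = fit$p[jp, ], q = fit$q[jp, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Network-level permutation regression of graph metrics on daily factors
#'
#' Same engine as [modelLinks()], applied to the network-mean
#' participation coefficient and within-network efficiency series; the
#' FDR family per predictor is the set of networks (separately per
#' metric and threshold).
#'
#' @param metricTable output of [metricSeries()].
#' @param behavior imputed behavioral data.frame.
#' @param factors factor names entering the model.
#' @param covariates optional additional predictor names.
#' @param lag alignment lag in days (default 1).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return data.frame: `network`, `metric`, `threshold`, `predictor`,
#'   `beta`, `t`, `p`, `q`.
#' @export
modelMetrics <- function(metricTable, behavior, factors,
                         covariates = NULL, lag = 1L, nPerm = 10000L,
                         seed = 1L) {
  out <- list()
  for (met in unique(metricTable$metric)) {
    for (thr in unique(metricTable$threshold)) {
      sub <- metricTable[metricTable$metric == met &
                           metricTable$threshold == thr, ]
      nets <- unique(sub$network)
      days <- sort(unique(sub$sessionDay))
      Y <- sapply(nets, function(nw) {
        v <- sub$value[sub$network == nw]
        v[order(sub$sessionDay[sub$network == nw])]
      })
      ok <- apply(Y, 2, function(v) !anyNA(v) && sd(v) > 0)
      Y <- Y[, ok, drop = FALSE]
      nets <- nets[ok]
      if (!length(nets)) next
      X <- alignPreviousDay(behavior, days, c(factors, covariates), lag)
      fit <- .permModel(Y, as.matrix(X), nPerm, seed)
      preds <- colnames(X)
      for (jp in seq_along(preds)) {
        out[[length(out) + 1L]] <- data.frame(
          network = nets, metric = met, threshold = thr,
          predictor = preds[jp], beta = fit$beta[jp, ],
          t = fit$t[jp, ], p = fit$p[jp, ], q = fit$q[jp, ],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
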