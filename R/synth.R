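#' Specification of an injected brain-behavior coupling
#'
#' Describes a known ground-truth association for the synthetic generator:
#' a set of target links whose generating correlation follows a behavioral
#' factor at a fixed lag. The coupling is applied on the Fisher-z scale,
#'
#'   r(day d) = tanh( atanh(baseCorr) + slope * factor(d - lagDays) ),
#'
#' which keeps the generating correlation inside (-1, 1) for any factor
#' value while remaining monotone in the factor, so sign and lag of the
#' injected effect are recoverable downstream.
#'
#' @param links two-column integer matrix of ROI index pairs (one row per
#'   target link), or a list of length-2 vectors.
#' @param factorName name of the behavioral factor driving the links.
#' @param lagDays non-negative integer lag in days (the link on day `d`
#'   follows the factor on day `d - lagDays`).
#' @param slope effect on the Fisher-z scale per SD of the factor.
#' @param baseCorr baseline correlation of the target links, in (-1, 1).
#' @return An object of class `effectSpec` (a validated list).
#' @examples
#' effectSpec(rbind(c(1, 5), c(2, 6)), "total_sleep", lagDays = 1,
#'            slope = 0.4, baseCorr = 0.2)
#' @export
effectSpec <- function(links, factorName, lagDays = 1L, slope = 0.3,
                       baseCorr = 0.2) {
  if (is.list(links)) links <- do.call(rbind, links)
  links <- matrix(as.integer(links), ncol = 2)
  if (any(links[, 1] == links[, 2]))
    stop("target links must join two distinct ROIs")
  links <- t(apply(links, 1, sort))
  if (lagDays < 0 || lagDays != round(lagDays))
    stop("'lagDays' must be a non-negative integer")
  if (abs(baseCorr) >= 1) stop("'baseCorr' must lie strictly in (-1, 1)")
  structure(
    list(links = links, factorName = factorName,
         lagDays = as.integer(lagDays), slope = slope, baseCorr = baseCorr),
    class = "effectSpec"
  )
}

#' Configuration of the synthetic study
#'
#' Encodes the study design the generator emulates: roughly twice-weekly
#' scanning sessions (a Monday/Friday pattern: day offsets 0, 4, 7, 11,
#' 14, ...) embedded in a months-long daily behavioral record.
#'
#' @param nSessions number of scanning sessions (default 30).
#' @param nDays number of calendar days covered by the behavioral record
#'   (default 133, about 19 weeks).
#' @param sessionDays strictly increasing day indices of the sessions; the
#'   default lays `nSessions` sessions on the Monday/Friday grid starting
#'   at day `firstDay`.
#' @param firstDay first session day (default 16, leaving a 15-day
#'   behavioral run-in before the first scan).
#' @param nRois number of ROIs (default 300).
#' @param nNetworks number of network communities in the atlas (default 13).
#' @param nTime volumes per session (default 800).
#' @param trSeconds repetition time in seconds (default 0.594).
#' @param arCoefficient AR(1) coefficient of the behavioral factors, in
#'   `[0, 1)` (default 0.5).
#' @param withinCorr baseline within-community correlation (default 0.3).
#' @param betweenCorr baseline between-community correlation (default 0).
#' @param missingFraction fraction of behavioral entries replaced by NA
#'   (default 0.05).
#' @param seed integer seed recorded with the configuration.
#' @return An object of class `synthConfig`.
#' @export
synthConfig <- function(nSessions = 30L, nDays = 133L, sessionDays = NULL,
                        firstDay = 16L, nRois = 300L, nNetworks = 13L,
                        nTime = 800L, trSeconds = 0.594,
                        arCoefficient = 0.5, withinCorr = 0.3,
                        betweenCorr = 0, missingFraction = 0.05,
                        seed = 1L) {
  if (is.null(sessionDays)) {
    k <- seq_len(nSessions) - 1L
    sessionDays <- firstDay + 7L * (k %/% 2L) + 4L * (k %% 2L)
  }
  sessionDays <- as.integer(sessionDays)
  if (any(diff(sessionDays) <= 0))
    stop("'sessionDays' must be strictly increasing")
  if (max(sessionDays) > nDays)
    stop("'sessionDays' must all lie within 1..nDays")
  if (arCoefficient < 0 || arCoefficient >= 1)
    stop("'arCoefficient' must lie in [0, 1)")
  if (missingFraction < 0 || missingFraction >= 1)
    stop("'missingFraction' must lie in [0, 1)")
  structure(
    list(nSessions = as.integer(length(sessionDays)),
         nDays = as.integer(nDays), sessionDays = sessionDays,
         nRois = as.integer(nRois), nNetworks = as.integer(nNetworks),
         nTime = as.integer(nTime), trSeconds = trSeconds,
         arCoefficient = arCoefficient, withinCorr = withinCorr,
         betweenCorr = betweenCorr, missingFraction = missingFraction,
         seed = as.integer(seed)),
    class = "synthConfig"
  )
}

# Canonical network names for the first communities; extras are numbered.
.networkNames <- function(n) {
  base <- c("DMN", "FPN", "CON", "somatomotor", "visual", "auditory",
            "salience", "DAN", "VAN", "limbic", "subcortical",
            "cerebellar", "reward")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("net", seq_len(n - length(base))))
}

#' Generate a synthetic ROI atlas
#'
#' Assigns each ROI to exactly one network community (round-robin, so
#' every community is non-empty) and draws unique 3-D coordinates.
#'
#' @param nRois number of ROIs.
#' @param nNetworks number of communities; must not exceed `nRois`.
#' @param seed integer seed.
#' @return data.frame with columns `roi_id`, `x`, `y`, `z`, `network`.
#' @examples
#' atlas <- genAtlas(300, 13, seed = 1)
#' table(atlas$network)
#' @export
genAtlas <- function(nRois, nNetworks, seed = 1L) {
  if (nNetworks < 2) stop("'nNetworks' must be at least 2")
  if (nRois < nNetworks)
    stop("'nRois' must be at least 'nNetworks' (every community non-empty)")
  set.seed(seed)
  nets <- .networkNames(nNetworks)
  network <- nets[rep_len(seq_len(nNetworks), nRois)]
  coords <- matrix(round(runif(3L * nRois, -90, 90), 2), ncol = 3)
  while (anyDuplicated(coords)) {
    dup <- duplicated(coords)
    coords[dup, ] <- matrix(round(runif(3L * sum(dup), -90, 90), 2), ncol = 3)
  }
  data.frame(roi_id = seq_len(nRois), x = coords[, 1], y = coords[, 2],
             z = coords[, 3], network = network,
             stringsAsFactors = FALSE)
}

#' Generate daily behavioral factors
#'
#' Each factor is an AR(1) series over the study days, standardized to
#' mean 0 / SD 1, after which a fraction of entries is replaced by NA
#' completely at random. The complete (pre-missingness) values are
#' returned alongside so recovery tests can use the ground truth.
#'
#' @param config a [synthConfig()].
#' @param factors character vector of factor names.
#' @param seed integer seed.
#' @return list with elements `observed` (data.frame, day + factors, with
#'   NAs) and `truth` (same shape, complete).
#' @export
genBehavior <- function(config,
                        factors = c("total_sleep", "awake_time", "restless",
                                    "steps", "inactive_time", "hrv_mean",
                                    "hrv_max", "hrv_min", "resp_mean",
                                    "resp_max", "naf_mean", "paf_mean",
                                    "microsleep_pct"),
                        seed = 1L) {
  stopifnot(inherits(config, "synthConfig"))
  set.seed(seed)
  n <- config$nDays
  phi <- config$arCoefficient
  truth <- sapply(factors, function(f) {
    e <- rnorm(n)
    x <- numeric(n)
    x[1] <- e[1] / sqrt(max(1 - phi^2, .Machine$double.eps))
    for (t in seq_len(n - 1L)) x[t + 1L] <- phi * x[t] + e[t + 1L]
    (x - mean(x)) / sd(x)
  })
  truth <- as.data.frame(truth)
  observed <- truth
  if (config$missingFraction > 0) {
    for (f in factors) {
      miss <- runif(n) < config$missingFraction
      observed[[f]][miss] <- NA_real_
    }
  }
  truth <- cbind(day = seq_len(n), truth)
  observed <- cbind(day = seq_len(n), observed)
  list(observed = observed, truth = truth)
}

# Generating correlation of a target link on a given day.
.couplingCorr <- function(baseCorr, slope, factorValue) {
  tanh(atanh(baseCorr) + slope * factorValue)
}

# Block-structured baseline correlation matrix from atlas communities.
.baselineCorr <- function(atlas, withinCorr, betweenCorr) {
  same <- outer(atlas$network, atlas$network, "==")
  C <- ifelse(same, withinCorr, betweenCorr)
  diag(C) <- 1
  C
}

# Nearest-PSD repair: clip eigenvalues, rescale to unit diagonal.
.psdRepair <- function(C, eps = 1e-8) {
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) > eps) return(C)
  vals <- pmax(ev$values, eps)
  C2 <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(C2))
  C2 <- C2 / tcrossprod(d)
  diag(C2) <- 1
  (C2 + t(C2)) / 2
}

#' Generate synthetic scanning sessions with known link-level truth
#'
#' Per session, ROI signals are drawn from a multivariate normal whose
#' correlation matrix combines the community block baseline with the
#' session-specific correlations dictated by each [effectSpec()] (target
#' matrix eigenvalue-repaired to positive semidefinite, then Cholesky
#' sampled). The realized generating correlation of every target link is
#' recorded as ground truth.
#'
#' @param config a [synthConfig()].
#' @param atlas atlas data.frame from [genAtlas()]; must have
#'   `config$nRois` rows.
#' @param behavior complete behavioral table (the `truth` element of
#'   [genBehavior()]); factors are looked up by name at `day - lagDays`.
#' @param effectSpecs list of [effectSpec()] objects (possibly empty).
#' @param task task label stored in each session.
#' @param seed integer seed.
#' @return list with `sessions` (list of [SessionSeries-class]) and
#'   `truth` (data.frame: session, day, i, j, factor, lag, rGenerating).
#' @export
genSessions <- function(config, atlas, behavior, effectSpecs = list(),
                        task = "rest", seed = 1L) {
  stopifnot(inherits(config, "synthConfig"))
  if (nrow(atlas) != config$nRois)
    stop("atlas size does not match config$nRois")
  if (inherits(effectSpecs, "effectSpec")) effectSpecs <- list(effectSpecs)
  maxLag <- if (length(effectSpecs))
    max(vapply(effectSpecs, `[[`, integer(1), "lagDays")) else 0L
  if (min(config$sessionDays) - maxLag < 1L)
    stop("behavior does not cover sessionDays minus the maximum lag")
  for (sp in effectSpecs) {
    if (!sp$factorName %in% names(behavior))
      stop("factor '", sp$factorName, "' not found in behavior table")
    if (max(sp$links) > config$nRois)
      stop("target link index exceeds number of ROIs")
  }
  set.seed(seed)
  base <- .baselineCorr(atlas, config$withinCorr, config$betweenCorr)
  sessions <- vector("list", config$nSessions)
  truthRows <- list()
  for (s in seq_len(config$nSessions)) {
    d <- config$sessionDays[s]
    C <- base
    for (sp in effectSpecs) {
      f <- behavior[[sp$factorName]][d - sp$lagDays]
      r <- .couplingCorr(sp$baseCorr, sp$slope, f)
      for (k in seq_len(nrow(sp$links))) {
        i <- sp$links[k, 1]; j <- sp$links[k, 2]
        C[i, j] <- C[j, i] <- r
      }
    }
    C <- .psdRepair(C)
    L <- chol(C)
    X <- matrix(rnorm(config$nTime * config$nRois), config$nTime) %*% L
    colnames(X) <- paste0("roi", seq_len(config$nRois))
    sessions[[s]] <- SessionSeries(X, trSeconds = config$trSeconds,
                                   task = task, sessionDay = d)
    for (sp in effectSpecs) {
      for (k in seq_len(nrow(sp$links))) {
        i <- sp$links[k, 1]; j <- sp$links[k, 2]
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          session = s, day = d, i = i, j = j,
          factor = sp$factorName, lag = sp$lagDays,
          rGenerating = C[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truthRows)) do.call(rbind, truthRows)
  else data.frame(session = integer(), day = integer(), i = integer(),
                  j = integer(), factor = character(), lag = integer(),
                  rGenerating = numeric(), stringsAsFactors = FALSE)
  list(sessions = sessions, truth = truth)
}

#' Generate framewise-displacement traces with spike contamination
#'
#' Baseline FD stays strictly below the 0.2 mm censoring threshold; with
#' probability `spikeProb` per volume the value is replaced by a
#' motion spike exceeding the threshold.
#'
#' @param config a [synthConfig()].
#' @param spikeProb per-volume spike probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list of numeric FD vectors (one per session, length
#'   `config$nTime`), all non-negative.
#' @export
genFD <- function(config, spikeProb = 0.05, seed = 1L) {
  stopifnot(inherits(config, "synthConfig"))
  if (spikeProb < 0 || spikeProb > 1) stop("'spikeProb' must be in [0, 1]")
  set.seed(seed)
  lapply(seq_len(config$nSessions), function(s) {
    fd <- pmin(0.05 + abs(rnorm(config$nTime, sd = 0.03)), 0.19)
    spike <- runif(config$nTime) < spikeProb
    fd[spike] <- 0.25 + rexp(sum(spike), rate = 10)
    fd
  })
}

#' Generate task trial onsets
#'
#' Onsets accumulate random inter-trial intervals drawn uniformly from
#' the stated range (emulating a reaction-time task whose inter-stimulus
#' interval varies between 2 and 10 s).
#'
#' @param nTrials number of trials (0 gives an empty table).
#' @param itiRange length-2 numeric, inter-onset interval bounds in
#'   seconds (default `c(2, 10)`).
#' @param seed integer seed.
#' @return data.frame with columns `trial` and `onset` (seconds),
#'   strictly increasing.
#' @export
genTrials <- function(nTrials, itiRange = c(2, 10), seed = 1L) {
  if (length(itiRange) != 2L || any(itiRange <= 0) ||
      itiRange[2] < itiRange[1])
    stop("'itiRange' must be two positive increasing numbers")
  if (nTrials == 0L)
    return(data.frame(trial = integer(), onset = numeric()))
  set.seed(seed)
  gaps <- runif(nTrials, itiRange[1], itiRange[2])
  data.frame(trial = seq_len(nTrials), onset = cumsum(gaps))
}

#' Write a full synthetic dataset to disk
#'
#' Produces the on-disk layout downstream stages read: one TSV per
#' session (rows = volumes, columns = ROIs), `atlas.tsv`, `behavior.tsv`,
#' `fd/<session>.tsv` and `truth.json` with the ground-truth effect
#' specifications and realized generating correlations.
#'
#' @param dir output directory (created if needed).
#' @param config a [synthConfig()].
#' @param effectSpecs list of [effectSpec()] objects.
#' @param spikeProb FD spike probability.
#' @param seed integer master seed (per-component seeds derived from it).
#' @return invisibly, the list of generated objects.
#' @export
writeSynthDataset <- function(dir, config = synthConfig(),
                              effectSpecs = list(), spikeProb = 0.05,
                              seed = 1L) {
  dir.create(file.path(dir, "fd"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  atlas <- genAtlas(config$nRois, config$nNetworks, seed = seed)
  beh <- genBehavior(config, seed = seed + 1L)
  gen <- genSessions(config, atlas, beh$truth, effectSpecs, seed = seed + 2L)
  fd <- genFD(config, spikeProb = spikeProb, seed = seed + 3L)
  write.table(atlas, file.path(dir, "atlas.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(beh$observed, file.path(dir, "behavior.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (s in seq_along(gen$sessions)) {
    nm <- sprintf("session%02d", s)
    write.table(seriesData(gen$sessions[[s]]),
                file.path(dir, "sessions", paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(data.frame(fd = fd[[s]]),
                file.path(dir, "fd", paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  truth <- list(
    config = unclass(config),
    effects = lapply(effectSpecs, function(sp) {
      list(links = apply(sp$links, 1, as.list), factor = sp$factorName,
           lagDays = sp$lagDays, slope = sp$slope, baseCorr = sp$baseCorr)
    }),
    realized = gen$truth
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(atlas = atlas, behavior = beh, sessions = gen$sessions,
                 truth = gen$truth, fd = fd))
}
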