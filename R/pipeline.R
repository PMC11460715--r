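#' Analysis presets for the eight study hypotheses
#'
#' Returns the factor set, network set, task and analysis type of one of
#' the pre-registered hypothesis families: previous-day permutation
#' regression on links and graph metrics (H1 sustained attention, H2
#' working memory, H3 rest), inter-day RSA during movie watching (H4),
#' lagged cross-correlation up to 15 days (H5-H7), and accuracy-map
#' regression of between-days time-segment classification (H8).
#'
#' @param id one of `"H1"` ... `"H8"`.
#' @return list with `task`, `factors`, `networks`, `analysis`, and
#'   optionally `covariates`.
#' @examples
#' hypothesisPreset("H1")
#' @export
hypothesisPreset <- function(id) {
  sleep <- c("total_sleep", "awake_time", "restless")
  activity <- c("steps", "inactive_time")
  ansMood <- c("hrv_mean", "resp_mean", "naf_mean", "paf_mean")
  presets <- list(
    H1 = list(task = "pvt", factors = sleep,
              networks = c("FPN", "DMN", "somatomotor", "CON"),
              analysis = "regression"),
    H2 = list(task = "nback", factors = c(sleep, activity),
              networks = c("DMN", "FPN", "somatomotor"),
              analysis = "regression"),
    H3 = list(task = "rest", factors = c(sleep, ansMood),
              networks = c("DMN", "FPN", "CON"),
              analysis = "regression", covariates = "microsleep_pct"),
    H4 = list(task = "movie", factors = c(sleep, ansMood),
              networks = c("FPN", "DMN", "salience"),
              analysis = "idrsa"),
    H5 = list(task = "pvt", factors = sleep,
              networks = c("FPN", "DMN", "somatomotor", "CON"),
              analysis = "lagcorr"),
    H6 = list(task = "nback", factors = c(sleep, activity),
              networks = c("DMN", "FPN", "somatomotor"),
              analysis = "lagcorr"),
    H7 = list(task = "rest", factors = c(sleep, ansMood),
              networks = c("DMN", "FPN", "CON"),
              analysis = "lagcorr"),
    H8 = list(task = "movie",
              factors = c(sleep, "naf_mean", "resp_mean", "hrv_mean"),
              networks = character(0),
              analysis = "segclass"))
  if (!id %in% names(presets)) stop("unknown hypothesis id: ", id)
  presets[[id]]
}

#' Read a session time-series TSV written by [writeSynthDataset()]
#' @param path TSV path (rows = volumes, columns = ROIs).
#' @param trSeconds,task,sessionDay metadata for the session.
#' @return a [SessionSeries-class].
#' @export
readSessionTSV <- function(path, trSeconds = 0.594, task = "rest",
                           sessionDay = 1L) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t"))
  SessionSeries(m, trSeconds = trSeconds, task = task,
                sessionDay = sessionDay)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param outDir output directory.
#' @param synth a [synthConfig()] describing the simulated study.
#' @param effectSpecs list of [effectSpec()] ground-truth couplings.
#' @param hypotheses character subset of H1..H8 to run (analyses needing
#'   a task share the one simulated task set).
#' @param densities proportional thresholds (default 0.10/0.20/0.30).
#' @param nPerm permutations for regression and Mantel tests.
#' @param nSurr surrogates for the lagged analysis.
#' @param lags lag grid for the lagged analysis.
#' @param scrubPct percentage-scrubbing fraction for the shared mask.
#' @param window,step segment-classification parameters.
#' @param windowSeconds,polyorder,cutoffHz signal-conditioning
#'   parameters passed to [cleanSession()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(outDir, synth = synthConfig(),
                      effectSpecs = list(),
                      hypotheses = c("H3", "H7"),
                      densities = c(0.10, 0.20, 0.30),
                      nPerm = 1000L, nSurr = 1000L, lags = 1:15,
                      scrubPct = 0.05, window = 25L, step = 1L,
                      windowSeconds = 240, polyorder = 3,
                      cutoffHz = 0.01, seed = 1L) {
  bad <- setdiff(hypotheses, paste0("H", 1:8))
  if (length(bad)) stop("unknown hypothesis id(s): ",
                        paste(bad, collapse = ", "))
  structure(list(outDir = outDir, synth = synth,
                 effectSpecs = effectSpecs, hypotheses = hypotheses,
                 densities = densities, nPerm = as.integer(nPerm),
                 nSurr = as.integer(nSurr), lags = lags,
                 scrubPct = scrubPct, window = as.integer(window),
                 step = as.integer(step), windowSeconds = windowSeconds,
                 polyorder = polyorder, cutoffHz = cutoffHz,
                 seed = as.integer(seed)),
            class = "runConfig")
}

# Deterministic per-stage seeds fanned out from the master seed.
.stageSeeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(2^31 - 2, 8)
  names(s) <- c("synth", "fd", "adjacency", "regression", "lagcorr",
                "idrsa", "segclass", "misc")
  s
}

.writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates the study described by the configuration, conditions the
#' signals, builds the shared percentage-scrubbing mask, estimates
#' per-session adjacency (Fisher transform, motion residualization),
#' computes the graph-metric series, and executes the analyses of the
#' requested hypothesis presets, writing every result table as TSV plus
#' a `manifest.json`. Rerunning with the same configuration and seed
#' reproduces all numeric outputs exactly.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list of the in-memory results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(file.path(config$outDir, "adjacency"), recursive = TRUE,
             showWarnings = FALSE)
  seeds <- .stageSeeds(config$seed)
  sc <- config$synth

  atlas <- genAtlas(sc$nRois, sc$nNetworks, seed = seeds[["synth"]])
  beh <- genBehavior(sc, seed = seeds[["synth"]] %% 1e6 + 1L)
  gen <- genSessions(sc, atlas, beh$truth, config$effectSpecs,
                     seed = seeds[["adjacency"]])
  fd <- genFD(sc, seed = seeds[["fd"]])
  behImp <- imputeMeanTable(beh$observed)

  cleaned <- lapply(gen$sessions, cleanSession,
                    windowSeconds = config$windowSeconds,
                    polyorder = config$polyorder,
                    cutoffHz = config$cutoffHz)
  flags <- t(vapply(fd, flagVolumes, logical(sc$nTime)))
  mask <- scrubPercentage(flags, config$scrubPct)
  meanFD <- vapply(fd, mean, numeric(1))

  stackR <- lapply(cleaned, pearsonAdjacency, keep = mask)
  stackZ <- lapply(stackR, fisherZ)
  stack <- residualizeMotion(stackZ, meanFD)

  metrics <- metricSeries(stack, atlas, densities = config$densities)

  .writeTSV(atlas, file.path(config$outDir, "atlas.tsv"))
  .writeTSV(behImp, file.path(config$outDir, "behavior.tsv"))
  .writeTSV(metrics, file.path(config$outDir, "metrics.tsv"))
  for (s in seq_along(stack)) {
    .writeTSV(as.data.frame(adjacencyWeights(stack[[s]])),
              file.path(config$outDir, "adjacency",
                        sprintf("session%02d.tsv", s)))
  }

  results <- list(atlas = atlas, behavior = behImp, metrics = metrics,
                  truth = gen$truth, mask = mask)
  regRows <- list(); lagRows <- list(); idrsaRows <- list()
  segRows <- list()
  for (h in config$hypotheses) {
    ps <- hypothesisPreset(h)
    nets <- intersect(ps$networks, unique(atlas$network))
    facs <- intersect(ps$factors, names(behImp))
    covs <- intersect(ps$covariates, names(behImp))
    if (ps$analysis == "regression") {
      links <- modelLinks(stack, behImp, facs, atlas, nets,
                          covariates = if (length(covs)) covs,
                          nPerm = config$nPerm,
                          seed = seeds[["regression"]])
      netres <- modelMetrics(metrics[metrics$network %in% nets, ],
                             behImp, facs,
                             covariates = if (length(covs)) covs,
                             nPerm = config$nPerm,
                             seed = seeds[["regression"]] + 1L)
      regRows[[h]] <- cbind(hypothesis = h, level = "network", netres,
                            stringsAsFactors = FALSE)
      results[[paste0(h, "_links")]] <- links
    } else if (ps$analysis == "lagcorr") {
      lr <- lagCorrelation(metrics[metrics$network %in% nets, ],
                           behImp, facs,
                           threshold = config$densities[1],
                           lags = config$lags, nSurr = config$nSurr,
                           seed = seeds[["lagcorr"]])
      lagRows[[h]] <- cbind(hypothesis = h, lr,
                            stringsAsFactors = FALSE)
    } else if (ps$analysis == "idrsa") {
      sess <- lapply(cleaned, applyCensor, keep = mask)
      vals <- alignPreviousDay(
        behImp, vapply(gen$sessions, sessionDay, integer(1)),
        facs[1])[[1]]
      ir <- idrsaAcrossRois(sess, NULL, vals, model = "NN",
                            nPerm = config$nPerm,
                            seed = seeds[["idrsa"]])
      idrsaRows[[h]] <- cbind(hypothesis = h, factor = facs[1], ir,
                              stringsAsFactors = FALSE)
    } else if (ps$analysis == "segclass") {
      sess <- lapply(cleaned, applyCensor, keep = mask)
      loo <- looIdentify(sess, window = config$window,
                         step = config$step)
      ar <- accuracyRegression(
        loo$accuracy, behImp, facs,
        vapply(gen$sessions, sessionDay, integer(1)),
        nPerm = config$nPerm, seed = seeds[["segclass"]])
      segRows[[h]] <- cbind(hypothesis = h, chance = loo$chance, ar,
                            stringsAsFactors = FALSE)
      results[[paste0(h, "_accuracy")]] <- loo$accuracy
    }
  }
  if (length(regRows))
    .writeTSV(do.call(rbind, regRows),
              file.path(config$outDir, "regression.tsv"))
  if (length(lagRows))
    .writeTSV(do.call(rbind, lagRows),
              file.path(config$outDir, "lagcorr.tsv"))
  if (length(idrsaRows))
    .writeTSV(do.call(rbind, idrsaRows),
              file.path(config$outDir, "idrsa.tsv"))
  if (length(segRows))
    .writeTSV(do.call(rbind, segRows),
              file.path(config$outDir, "segclass.tsv"))

  manifest <- list(
    package = "denseFC",
    version = as.character(utils::packageVersion("denseFC")),
    seed = config$seed,
    stageSeeds = as.list(seeds),
    config = list(
      synth = unclass(sc), hypotheses = config$hypotheses,
      densities = config$densities, nPerm = config$nPerm,
      nSurr = config$nSurr, lags = config$lags,
      scrubPct = config$scrubPct, window = config$window,
      step = config$step))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
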