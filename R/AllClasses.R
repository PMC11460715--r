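#' SessionSeries: one scanning session's ROI time series
#'
#' Container for a single session's region-of-interest (ROI) time series:
#' a volumes x ROI numeric matrix plus the repetition time, the task label
#' and the study day the session was acquired on. It is the unit on which
#' signal conditioning and connectivity estimation operate.
#'
#' @slot data numeric matrix, volumes (rows) x ROIs (columns).
#' @slot trSeconds repetition time in seconds.
#' @slot task character, one of `"pvt"`, `"rest"`, `"movie"`, `"nback"`.
#' @slot sessionDay integer study-day index (1-based).
#'
#' @name SessionSeries-class
#' @aliases SessionSeries-class
#' @exportClass SessionSeries
setClass("SessionSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    task = "character",
    sessionDay = "integer"
  )
)

setValidity("SessionSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "'data' must be numeric")
  if (nrow(object@data) < 2L) msg <- c(msg, "need at least 2 volumes")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "'data' contains non-finite values")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msg <- c(msg, "'trSeconds' must be a single positive number")
  if (!object@task %in% c("pvt", "rest", "movie", "nback"))
    msg <- c(msg, "'task' must be one of pvt, rest, movie, nback")
  if (length(msg)) msg else TRUE
})

#' Construct a SessionSeries
#'
#' @param data volumes x ROI numeric matrix.
#' @param trSeconds repetition time in seconds.
#' @param task task label (`"pvt"`, `"rest"`, `"movie"` or `"nback"`).
#' @param sessionDay study-day index of the session.
#' @return A [SessionSeries-class] object.
#' @examples
#' s <- SessionSeries(matrix(rnorm(40), 20, 2), trSeconds = 0.594,
#'                    task = "rest", sessionDay = 1)
#' nVolumes(s)
#' @export
SessionSeries <- function(data, trSeconds = 0.594, task = "rest",
                          sessionDay = 1L) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("roi", seq_len(ncol(data)))
  new("SessionSeries", data = data, trSeconds = as.numeric(trSeconds),
      task = task, sessionDay = as.integer(sessionDay))
}

#' @describeIn SessionSeries-class number of volumes (time points).
#' @param object,x a `SessionSeries`.
#' @export
nVolumes <- function(object) nrow(seriesData(object))

#' @describeIn SessionSeries-class number of ROIs.
#' @export
nRois <- function(object) ncol(seriesData(object))

#' @describeIn SessionSeries-class the volumes x ROI data matrix.
#' @export
seriesData <- function(object) object@data

#' @describeIn SessionSeries-class repetition time in seconds.
#' @export
trSeconds <- function(object) object@trSeconds

#' @describeIn SessionSeries-class task label.
#' @export
taskLabel <- function(object) object@task

#' @describeIn SessionSeries-class study-day index.
#' @export
sessionDay <- function(object) object@sessionDay

setMethod("show", "SessionSeries", function(object) {
  cat(sprintf("SessionSeries: %d volumes x %d ROIs, TR %.3f s, task '%s', day %d\n",
              nVolumes(object), nRois(object), trSeconds(object),
              taskLabel(object), sessionDay(object)))
})

#' Adjacency: one session's weighted connectivity matrix
#'
#' Symmetric ROI x ROI matrix of connectivity weights for a single session,
#' flagged with the domain of the weights: `"r"` (Pearson correlations,
#' unit diagonal) or `"fisher_z"` (variance-stabilized atanh weights).
#'
#' @slot weights symmetric numeric matrix.
#' @slot domain `"r"` or `"fisher_z"`.
#' @slot sessionDay integer study-day index.
#' @slot task task label.
#'
#' @name Adjacency-class
#' @exportClass Adjacency
setClass("Adjacency",
  representation(
    weights = "matrix",
    domain = "character",
    sessionDay = "integer",
    task = "character"
  )
)

setValidity("Adjacency", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "'weights' must be square")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-8, check.attributes = FALSE)))
    msg <- c(msg, "'weights' must be symmetric")
  if (!object@domain %in% c("r", "fisher_z"))
    msg <- c(msg, "'domain' must be 'r' or 'fisher_z'")
  if (object@domain == "r") {
    off <- w[upper.tri(w)]
    if (any(abs(off) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "r-domain weights must satisfy |r| <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Adjacency
#'
#' @param weights symmetric ROI x ROI numeric matrix.
#' @param domain `"r"` or `"fisher_z"`.
#' @param sessionDay study-day index.
#' @param task task label.
#' @return An [Adjacency-class] object.
#' @export
Adjacency <- function(weights, domain = "r", sessionDay = 1L, task = "rest") {
  weights <- as.matrix(weights)
  weights <- (weights + t(weights)) / 2   # enforce exact symmetry
  if (domain == "r") diag(weights) <- 1
  new("Adjacency", weights = weights, domain = domain,
      sessionDay = as.integer(sessionDay), task = task)
}

#' @describeIn Adjacency-class the weight matrix.
#' @param object an `Adjacency`.
#' @export
adjacencyWeights <- function(object) object@weights

#' @describeIn Adjacency-class the weight domain (`"r"` or `"fisher_z"`).
#' @export
adjacencyDomain <- function(object) object@domain

setMethod("show", "Adjacency", function(object) {
  cat(sprintf("Adjacency: %d x %d, domain '%s', task '%s', day %d\n",
              nrow(object@weights), ncol(object@weights), object@domain,
              object@task, object@sessionDay))
})

#' BinaryGraph: thresholded, binarized connectivity network
#'
#' Result of MST-anchored proportional thresholding: an unweighted,
#' undirected, connected graph over the ROIs.
#'
#' @slot edges integer matrix with two columns (node index pairs, i < j).
#' @slot nNodes number of nodes.
#' @slot density realized edge density (fraction of possible edges).
#' @slot requestedDensity density that was asked for.
#'
#' @name BinaryGraph-class
#' @exportClass BinaryGraph
setClass("BinaryGraph",
  representation(
    edges = "matrix",
    nNodes = "integer",
    density = "numeric",
    requestedDensity = "numeric"
  )
)

setValidity("BinaryGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (ncol(e) != 2L) msg <- c(msg, "'edges' must have two columns")
  if (nrow(e) && any(e[, 1] >= e[, 2]))
    msg <- c(msg, "edges must be stored with i < j")
  if (nrow(e) && (min(e) < 1L || max(e) > object@nNodes))
    msg <- c(msg, "edge indices out of range")
  if (length(msg)) msg else TRUE
})

#' @describeIn BinaryGraph-class two-column matrix of edges (i < j).
#' @param object a `BinaryGraph`.
#' @export
graphEdges <- function(object) object@edges

#' @describeIn BinaryGraph-class number of nodes.
#' @export
graphNodes <- function(object) object@nNodes

#' @describeIn BinaryGraph-class realized edge density.
#' @export
graphDensity <- function(object) object@density

#' Dense logical adjacency matrix of a BinaryGraph
#' @param object a [BinaryGraph-class].
#' @return logical nNodes x nNodes matrix.
#' @export
graphMatrix <- function(object) {
  n <- object@nNodes
  a <- matrix(FALSE, n, n)
  e <- object@edges
  if (nrow(e)) {
    a[e] <- TRUE
    a[e[, 2:1, drop = FALSE]] <- TRUE
  }
  a
}

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges (density %.3f, requested %.3f)\n",
              object@nNodes, nrow(object@edges), object@density,
              object@requestedDensity))
})
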