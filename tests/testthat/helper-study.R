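# Small synthetic-study builders shared across test files.

tinyConfig <- function(nSessions = 10, nRois = 20, nNetworks = 4,
                       nTime = 200, nDays = 80, missingFraction = 0,
                       arCoefficient = 0.5) {
  synthConfig(nSessions = nSessions, nDays = nDays, nRois = nRois,
              nNetworks = nNetworks, nTime = nTime, firstDay = 16,
              missingFraction = missingFraction,
              arCoefficient = arCoefficient)
}

tinyStudy <- function(effectSpecs = list(), seed = 1L, ...) {
  sc <- tinyConfig(...)
  atlas <- genAtlas(sc$nRois, sc$nNetworks, seed = seed)
  beh <- genBehavior(sc, seed = seed + 1L)
  gen <- genSessions(sc, atlas, beh$truth, effectSpecs, seed = seed + 2L)
  list(config = sc, atlas = atlas, behavior = beh,
       sessions = gen$sessions, truth = gen$truth)
}

# Adjacency stack straight from generated (already drift-free) sessions.
rawStack <- function(sessions) lapply(sessions, pearsonAdjacency)
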