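# Maximum common connected induced subgraph between two element-labelled
# molecular graphs (McGregor-style backtracking).
#
# Definition used throughout the package: a common subgraph is a pair of
# vertex subsets plus a bijection that preserves element labels, adjacency
# AND non-adjacency (induced), and whose shared edge set is connected.
# Inducedness prevents mapping atoms across a bond that exists in only one
# of the molecules; connectedness keeps the correspondence geometrically
# meaningful for a rigid superposition.
#
# Enumeration is exhaustive and deterministic (ascending vertex indices);
# every maximum-size mapping is found, and up to `maxCandidates` of them
# are retained in enumeration order.  Each mapping is visited exactly once:
# the seed vertex is required to be the smallest mapped A-index, and the
# search extends by the smallest eligible unmapped neighbour with an
# explicit include/exclude branch.

#' Maximum common subgraph mappings
#'
#' Enumerates all maximum common connected induced element-matched subgraph
#' mappings between two molecular graphs.
#'
#' @param gA,gB [MolecularGraph-class] objects (or [LigandInstance-class]s).
#' @param maxCandidates cap on retained mappings (default 1000).
#' @return list of two-column integer matrices (A index, B index), possibly
#'   empty when the graphs share no element.
#' @examples
#' ringTail <- ligandTemplate("ring-tail")
#' benzene <- ligandTemplate("benzene")
#' length(mcsMappings(buildGraph(benzene), buildGraph(ringTail))[[1]][, 1])
#' @export
mcsMappings <- function(gA, gB, maxCandidates = 1000L) {
  if (is(gA, "LigandInstance")) gA <- buildGraph(gA)
  if (is(gB, "LigandInstance")) gB <- buildGraph(gB)
  adjA <- gA@adjacency; adjB <- gB@adjacency
  elA <- gA@elements; elB <- gB@elements
  nA <- length(elA); nB <- length(elB)
  if (!length(intersect(elA, elB))) return(list())

  state <- new.env(parent = emptyenv())
  state$best <- 0L
  state$store <- list()

  record <- function(mapA, mapB) {
    k <- length(mapA)
    if (k > state$best) {
      state$best <- k
      state$store <- list()
    }
    if (k == state$best && length(state$store) < maxCandidates)
      state$store[[length(state$store) + 1L]] <- cbind(mapA, mapB)
  }

  recurse <- function(mapA, mapB, forbidden, seed) {
    size <- length(mapA)
    inMapA <- logical(nA); inMapA[mapA] <- TRUE
    # eligible extensions: unmapped A vertices above the seed, not excluded,
    # adjacent to the mapped set
    elig <- which(!inMapA & !forbidden & seq_len(nA) > seed &
                    colSums(adjA[mapA, , drop = FALSE]) > 0L)
    if (!length(elig)) {
      record(mapA, mapB)
      return(invisible())
    }
    # bound: even mapping every remaining eligible-ever vertex cannot beat
    # the current best (equal-size mappings are still collected)
    remA <- sum(!inMapA & !forbidden & seq_len(nA) > seed)
    if (size + min(remA, nB - size) < state$best)
      return(invisible())
    aNext <- elig[1L]
    usedB <- logical(nB); usedB[mapB] <- TRUE
    # include branch: map aNext to every compatible B vertex
    for (b in which(!usedB & elB == elA[aNext])) {
      ok <- TRUE
      for (k in seq_len(size)) {
        if (adjA[aNext, mapA[k]] != adjB[b, mapB[k]]) { ok <- FALSE; break }
      }
      if (ok) recurse(c(mapA, aNext), c(mapB, b), forbidden, seed)
    }
    # exclude branch
    forbidden[aNext] <- TRUE
    recurse(mapA, mapB, forbidden, seed)
  }

  for (a in seq_len(nA)) {
    if (state$best > min(nA - a + 1L, nB)) next  # cannot reach best from here
    for (b in which(elB == elA[a])) {
      recurse(a, b, logical(nA), a)
    }
  }
  state$store
}
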