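# Element-labelled molecular graphs, atom-mapping (name match, graph
# isomorphism, maximum common subgraph) and simple descriptors.

#' @importFrom igraph graph_from_edgelist make_empty_graph vcount ecount
#'   bridges degree components V isomorphisms
NULL

#' Element-labelled molecular graph
#'
#' @slot graph an igraph object (undirected simple graph).
#' @slot elements element symbol per node.
#' @slot adjacency logical adjacency matrix.
#' @slot ringEdge per-edge logical, TRUE iff the edge lies on a cycle.
#' @slot edges two-column integer matrix of the edges (i < j).
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(graph = "ANY", elements = "character",
                 adjacency = "matrix", ringEdge = "logical",
                 edges = "matrix")
)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d nodes, %d edges (%d in rings)\n",
              length(object@elements), nrow(object@edges),
              sum(object@ringEdge)))
})

#' Build the molecular graph of a ligand
#'
#' Nodes are the heavy atoms (element-labelled); edges are the inferred
#' bonds.  An edge is marked as a ring edge iff it lies on at least one
#' cycle, i.e. iff it is not a bridge.  Disconnected graphs are allowed.
#'
#' @param ligand a [LigandInstance-class] with bonds inferred, or a list
#'   with `elements` and a two-column `bonds` matrix.
#' @return A [MolecularGraph-class].
#' @examples
#' lig <- ligandTemplate("benzamidine")
#' buildGraph(lig)
#' @export
buildGraph <- function(ligand) {
  if (is(ligand, "LigandInstance")) {
    el <- elements(ligand); ed <- ligand@bonds
  } else {
    el <- toupper(ligand$elements); ed <- matrix(as.integer(ligand$bonds),
                                                 ncol = 2)
  }
  n <- length(el)
  g <- if (nrow(ed)) graph_from_edgelist(ed, directed = FALSE)
       else make_empty_graph(n, directed = FALSE)
  if (vcount(g) < n) g <- igraph::add_vertices(g, n - vcount(g))
  adj <- matrix(FALSE, n, n)
  if (nrow(ed)) {
    adj[ed] <- TRUE
    adj[ed[, c(2, 1), drop = FALSE]] <- TRUE
  }
  ring <- logical(nrow(ed))
  if (nrow(ed)) {
    br <- as.integer(bridges(g))
    ring <- !(seq_len(nrow(ed)) %in% br)
  }
  new("MolecularGraph", graph = g, elements = el, adjacency = adj,
      ringEdge = ring, edges = ed)
}

#' Rotatable-bond count
#'
#' A bond is rotatable iff it is not in a ring and both endpoints have
#' heavy-atom degree at least 2 (terminal bonds cannot generate a new
#' conformer).  The relative count is rotatable / total bonds (0 when the
#' molecule has no bonds), the measure used to avoid bias towards large
#' molecules.
#'
#' @param g a [MolecularGraph-class] (or a [LigandInstance-class]).
#' @return list with `absolute` (integer) and `relative` (fraction).
#' @examples
#' rotatableBonds(buildGraph(ligandTemplate("butane")))  # 1 of 3
#' @export
rotatableBonds <- function(g) {
  if (is(g, "LigandInstance")) g <- buildGraph(g)
  ed <- g@edges
  if (!nrow(ed)) return(list(absolute = 0L, relative = 0))
  deg <- degree(g@graph)
  rot <- !g@ringEdge & deg[ed[, 1]] >= 2L & deg[ed[, 2]] >= 2L
  list(absolute = sum(rot), relative = sum(rot) / nrow(ed))
}

#' Molecular weight from atoms or a formula
#'
#' Sums standard atomic masses over the atoms present in the file, or over
#' an explicit element-count map when provided.  Note that a file-derived
#' weight omits hydrogens (PDB X-ray entries rarely contain them); supply
#' `formulaOverride` for the hydrogen-complete weight.
#'
#' @param ligand a [LigandInstance-class].
#' @param formulaOverride optional named numeric vector of element counts
#'   (e.g. `c(C = 7, H = 8, N = 2)`) or a formula string such as "C7H8N2".
#' @return weight in g/mol.
#' @examples
#' molecularWeight(ligandTemplate("benzamidine"), "C7H8N2")  # 120.155
#' @export
molecularWeight <- function(ligand, formulaOverride = NULL) {
  if (is.character(formulaOverride)) {
    formulaOverride <- if (length(formulaOverride) &&
                           nzchar(formulaOverride[1]))
      parseFormula(formulaOverride[1]) else NULL
  }
  if (!is.null(formulaOverride) && length(formulaOverride)) {
    return(sum(atomicMass(names(formulaOverride)) *
                 as.numeric(formulaOverride)))
  }
  sum(atomicMass(elements(ligand)))
}

#' Parse a molecular formula string
#'
#' @param formula e.g. "C7H8N2".
#' @return named numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1
  setNames(ct, el)
}

# ---- atom mapping ------------------------------------------------------

.elementCodes <- function(elA, elB) {
  lev <- sort(unique(c(elA, elB)))
  list(a = as.integer(factor(elA, levels = lev)),
       b = as.integer(factor(elB, levels = lev)))
}

# All element-preserving full graph isomorphisms A -> B, deterministic VF2
# enumeration order, capped.
.allIsomorphisms <- function(gA, gB, maxCandidates = 1000L) {
  if (length(gA@elements) != length(gB@elements)) return(list())
  if (!identical(sort(gA@elements), sort(gB@elements))) return(list())
  if (nrow(gA@edges) != nrow(gB@edges)) return(list())
  cols <- .elementCodes(gA@elements, gB@elements)
  maps <- isomorphisms(gA@graph, gB@graph, method = "vf2",
                       vertex.color1 = cols$a, vertex.color2 = cols$b)
  if (!length(maps)) return(list())
  maps <- head(maps, maxCandidates)
  lapply(maps, function(m) cbind(seq_along(gA@elements), as.integer(m)))
}

#' Atom mapping between two ligands
#'
#' Returns an injective element-preserving atom correspondence, searched in
#' priority order: (1) atom-name mapping when both ligands are the same
#' chemical component with matching atom-name sets; (2) a full element-
#' labelled graph isomorphism; (3) the maximum common connected induced
#' element-matched subgraph.  When several candidate mappings exist
#' (automorphisms of symmetric molecules, multiple MCS embeddings), up to
#' `maxCandidates` are enumerated in deterministic order and the one whose
#' optimal superposition RMSD (RMSD'') is smallest is returned.
#'
#' @param ligA,ligB [LigandInstance-class] objects with bonds inferred.
#' @param useNames consider the atom-name tier (default TRUE).  Set FALSE
#'   for symmetry-corrected RMSDs, where the minimum over all isomorphisms
#'   is wanted even for identically named ligands.
#' @param maxCandidates candidate enumeration cap (default 1000).
#' @return An [AtomMapping-class].  Errors with "unmappable" when the best
#'   mapping has fewer than 3 atoms or all mapped atoms are collinear.
#' @export
matchAtoms <- function(ligA, ligB, useNames = TRUE, maxCandidates = 1000L) {
  gA <- buildGraph(ligA); gB <- buildGraph(ligB)
  cA <- coords(ligA); cB <- coords(ligB)

  if (useNames && toupper(ligA@compId) == toupper(ligB@compId)) {
    na <- ligA@atoms$name; nb <- ligB@atoms$name
    if (!anyDuplicated(na) && !anyDuplicated(nb) && setequal(na, nb)) {
      idx <- match(na, nb)
      if (all(gA@elements == gB@elements[idx]))
        return(.selectMapping(list(cbind(seq_along(na), idx)), "name-match",
                              cA, cB, ligA@compId, ligB@compId))
    }
  }
  iso <- .allIsomorphisms(gA, gB, maxCandidates)
  if (length(iso))
    return(.selectMapping(iso, "isomorphism", cA, cB,
                          ligA@compId, ligB@compId))
  mcs <- mcsMappings(gA, gB, maxCandidates)
  .selectMapping(mcs, "mcs", cA, cB, ligA@compId, ligB@compId)
}

# choose, among candidate pair matrices, the one minimising the optimal
# superposition RMSD; candidates below 3 atoms or collinear are unusable
.selectMapping <- function(cands, source, cA, cB, compA, compB) {
  if (!length(cands))
    stop(sprintf("unmappable ligand pair %s / %s: no common subgraph",
                 compA, compB))
  best <- NULL; bestRmsd <- Inf
  for (p in cands) {
    if (nrow(p) < 3L) next
    a <- cA[p[, 1L], , drop = FALSE]; b <- cB[p[, 2L], , drop = FALSE]
    if (.isCollinear(a) || .isCollinear(b)) next
    if (length(cands) == 1L) { best <- p; break }
    r <- .kabschCore(a, b)
    if (r < bestRmsd - 1e-12) { bestRmsd <- r; best <- p }
  }
  if (is.null(best))
    stop(sprintf(
      "unmappable ligand pair %s / %s: best mapping below 3 atoms or collinear",
      compA, compB))
  AtomMapping(best, source)
}

# internal: enumerate all candidate mappings (used by conformerDistance)
.enumerateMappings <- function(ligA, ligB, maxCandidates = 1000L) {
  gA <- buildGraph(ligA); gB <- buildGraph(ligB)
  iso <- .allIsomorphisms(gA, gB, maxCandidates)
  if (length(iso)) return(list(cands = iso, source = "isomorphism"))
  list(cands = mcsMappings(gA, gB, maxCandidates), source = "mcs")
}
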