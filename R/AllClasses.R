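#' Rigid-body transform
#'
#' A proper rotation plus translation carrying coordinates from the frame of
#' structure B into the frame of structure A: `y = R x + t`.  Reflections are
#' rejected by the validity method, as a physical ligand cannot be mirrored.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 vector, Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0))
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
    return("rotation must be a numeric 3x3 matrix")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be a finite length-3 numeric vector")
  if (any(!is.finite(R)))
    return("rotation contains non-finite values")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal (R'R != I within 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation is not proper (det != +1): reflections are not allowed")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation, Angstrom.
#' @return A [RigidTransform-class] object.
#' @examples
#' RigidTransform()                     # identity
#' RigidTransform(diag(3), c(5, 0, 0))  # pure translation
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' One bound copy of a chemical component in one structure
#'
#' Heavy atoms only: PDB X-ray entries usually lack hydrogens and all
#' dataset rules of this package count non-hydrogen atoms, so hydrogens are
#' dropped at parse time and the validity method rejects them.
#'
#' @slot pdbId PDB identifier (or any structure label).
#' @slot compId 3-character PDB chemical component identifier.
#' @slot chainId chain identifier the ligand belongs to.
#' @slot resno author residue number of the ligand residue.
#' @slot atoms data.frame with columns serial, name, element, x, y, z,
#'   occupancy, altloc.
#' @slot bonds integer matrix with two columns of atom indices (may have
#'   zero rows when bonds were not inferred yet).
#' @exportClass LigandInstance
setClass("LigandInstance",
  representation(pdbId = "character", compId = "character",
                 chainId = "character", resno = "integer",
                 atoms = "data.frame", bonds = "matrix")
)

setValidity("LigandInstance", function(object) {
  at <- object@atoms
  need <- c("serial", "name", "element", "x", "y", "z", "occupancy", "altloc")
  if (!all(need %in% names(at)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(at) < 1L) return("a ligand must have at least one atom")
  if (any(.isHydrogen(at$element)))
    return("hydrogens are not allowed in a LigandInstance")
  if (any(!is.finite(c(at$x, at$y, at$z))))
    return("atom coordinates must be finite")
  b <- object@bonds
  if (ncol(b) != 2L) return("bonds must be a two-column matrix")
  if (nrow(b) > 0L) {
    if (any(b < 1L) || any(b > nrow(at))) return("bond indices out of range")
    if (any(b[, 1L] == b[, 2L])) return("self-bonds are not allowed")
  }
  TRUE
})

#' Construct a LigandInstance
#'
#' @param pdbId,compId,chainId,resno identity of the ligand copy.
#' @param atoms data.frame of heavy atoms (see [LigandInstance-class]).
#' @param bonds two-column integer matrix of atom-index pairs.
#' @return A [LigandInstance-class] object.
#' @export
LigandInstance <- function(pdbId, compId, chainId, resno, atoms,
                           bonds = matrix(integer(), ncol = 2)) {
  new("LigandInstance", pdbId = as.character(pdbId),
      compId = as.character(compId), chainId = as.character(chainId),
      resno = as.integer(resno), atoms = atoms,
      bonds = matrix(as.integer(bonds), ncol = 2))
}

#' Protein chain extracted from a PDB file
#'
#' @slot chainId chain identifier as read.
#' @slot atoms data.frame with columns serial, name, element, resname,
#'   resno, icode, x, y, z, occupancy, altloc.
#' @slot sequence one-letter amino-acid string over the chain's standard
#'   residues, in file order (author numbering preserved in `atoms`).
#' @exportClass ProteinChain
setClass("ProteinChain",
  representation(chainId = "character", atoms = "data.frame",
                 sequence = "character")
)

#' An injective atom correspondence between two ligands
#'
#' @slot pairs integer matrix, column 1 = atom index in A, column 2 = atom
#'   index in B; injective on both sides.
#' @slot source one of "name-match", "isomorphism", "mcs".
#' @exportClass AtomMapping
setClass("AtomMapping",
  representation(pairs = "matrix", source = "character")
)

setValidity("AtomMapping", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) < 1L) return("mapping must contain at least one pair")
  if (anyDuplicated(p[, 1L]) || anyDuplicated(p[, 2L]))
    return("mapping must be injective on both sides")
  if (!object@source %in% c("name-match", "isomorphism", "mcs"))
    return("source must be one of name-match, isomorphism, mcs")
  TRUE
})

AtomMapping <- function(pairs, source) {
  new("AtomMapping", pairs = matrix(as.integer(pairs), ncol = 2),
      source = source)
}

#' Result of an optimal rigid superposition
#'
#' @slot transform the [RigidTransform-class] carrying B onto A.
#' @slot rmsd root-mean-square deviation after superposition, Angstrom.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(transform = "RigidTransform", rmsd = "numeric")
)

setValidity("SuperpositionResult", function(object) {
  if (length(object@rmsd) != 1L || !is.finite(object@rmsd) || object@rmsd < 0)
    return("rmsd must be a single non-negative number")
  TRUE
})

#' Result of scoring one binding-site alignment
#'
#' `score = rmsdAligned - rmsdOptimal` (RMSD' - RMSD'').  Both RMSDs use the
#' same atom correspondence, so the score is never meaningfully negative.
#'
#' @slot rmsdAligned RMSD' under the aligner's transform, Angstrom.
#' @slot rmsdOptimal RMSD'' of the optimal superposition, Angstrom.
#' @slot score LigandRMSD = RMSD' - RMSD'', Angstrom.
#' @slot mappingSize number of mapped atom pairs.
#' @slot mappingSource how the atom mapping was obtained.
#' @slot similar TRUE iff score <= the similarity threshold (default 3).
#' @exportClass LigandRMSDResult
setClass("LigandRMSDResult",
  representation(rmsdAligned = "numeric", rmsdOptimal = "numeric",
                 score = "numeric", mappingSize = "integer",
                 mappingSource = "character", similar = "logical")
)

setValidity("LigandRMSDResult", function(object) {
  if (object@score < -1e-6)
    return("score is below -1e-6; RMSD'' must be optimal for the mapping")
  TRUE
})

#' Analysis cut-offs
#'
#' All thresholds of the promiscuity analysis in one place.  Comparisons are
#' inclusive: a pair at exactly the cut-off passes.
#'
#' @slot ligandRmsdMax similarity threshold on LigandRMSD, Angstrom
#'   (default 3).
#' @slot conformerCut dendrogram cut height for conformer clustering,
#'   Angstrom (default 1.4).
#' @slot identityCluster percent sequence identity for target clustering
#'   (default 95).
#' @slot tmSimilar TM-score at or above which two structures count as
#'   globally similar (default 0.5).
#' @slot promiscuityMinTargets minimum non-redundant target count for a drug
#'   to be called promiscuous (default 3).
#' @slot alignerPvalueCut aligner P-value threshold used only by
#'   [compareFilters()]; no shipped default, must be set by the caller.
#' @exportClass Thresholds
setClass("Thresholds",
  representation(ligandRmsdMax = "numeric", conformerCut = "numeric",
                 identityCluster = "numeric", tmSimilar = "numeric",
                 promiscuityMinTargets = "integer",
                 alignerPvalueCut = "numeric"),
  prototype(ligandRmsdMax = 3.0, conformerCut = 1.4, identityCluster = 95,
            tmSimilar = 0.5, promiscuityMinTargets = 3L,
            alignerPvalueCut = NA_real_)
)

setValidity("Thresholds", function(object) {
  vals <- c(object@ligandRmsdMax, object@conformerCut,
            object@identityCluster, object@tmSimilar,
            object@promiscuityMinTargets)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all thresholds must be positive")
  TRUE
})

#' Construct the default (or a modified) set of thresholds
#'
#' @param ... named slot overrides, e.g. `ligandRmsdMax = 2.5`.
#' @return A [Thresholds-class] object.
#' @examples
#' defaultThresholds()
#' defaultThresholds(conformerCut = 2.0)
#' @export
defaultThresholds <- function(...) {
  args <- list(...)
  if ("promiscuityMinTargets" %in% names(args))
    args$promiscuityMinTargets <- as.integer(args$promiscuityMinTargets)
  do.call(new, c(list("Thresholds"), args))
}

#' Ligand blacklist configuration
#'
#' A ligand is blacklisted when its heavy-atom count is at most
#' `maxHeavyAtoms` or its component identifier is in `excludedCompIds`.
#' The excluded-component list ("common cofactors, detergents or solutes")
#' is an editable configuration, not a hard-coded constant; a small default
#' list ships in `inst/extdata/blacklist.tsv`.
#'
#' @slot maxHeavyAtoms maximum heavy-atom count treated as "small compound"
#'   (default 5).
#' @slot excludedCompIds character vector of excluded component identifiers.
#' @exportClass BlacklistConfig
setClass("BlacklistConfig",
  representation(maxHeavyAtoms = "integer", excludedCompIds = "character"),
  prototype(maxHeavyAtoms = 5L, excludedCompIds = character())
)

setValidity("BlacklistConfig", function(object) {
  if (object@maxHeavyAtoms < 0L) return("maxHeavyAtoms must be >= 0")
  TRUE
})

#' Construct a BlacklistConfig
#'
#' @param maxHeavyAtoms heavy-atom cut-off (default 5).
#' @param excludedCompIds excluded chemical component identifiers.
#' @return A [BlacklistConfig-class] object.
#' @export
BlacklistConfig <- function(maxHeavyAtoms = 5L, excludedCompIds = character()) {
  new("BlacklistConfig", maxHeavyAtoms = as.integer(maxHeavyAtoms),
      excludedCompIds = toupper(as.character(excludedCompIds)))
}

#' Clustering of the bound conformers of one drug
#'
#' @slot drug chemical component identifier.
#' @slot instances list of [LigandInstance-class] objects.
#' @slot distanceMatrix symmetric matrix of pairwise superposition RMSDs.
#' @slot cutHeight dendrogram cut height, Angstrom.
#' @slot labels integer cluster label per instance (1-based, in order of
#'   first appearance).
#' @slot tree the average-linkage `hclust` object (NULL for n = 1).
#' @exportClass ConformerClustering
setClass("ConformerClustering",
  representation(drug = "character", instances = "list",
                 distanceMatrix = "matrix", cutHeight = "numeric",
                 labels = "integer", tree = "ANY")
)

setValidity("ConformerClustering", function(object) {
  n <- length(object@instances)
  D <- object@distanceMatrix
  if (!identical(dim(D), c(n, n))) return("distance matrix dimension mismatch")
  if (n && max(abs(D - t(D))) > 1e-9) return("distance matrix not symmetric")
  if (n && any(abs(diag(D)) > 1e-9)) return("distance matrix diagonal not zero")
  if (length(object@labels) != n) return("one label per instance required")
  k <- length(unique(object@labels))
  if (n && (k < 1L || k > n)) return("cluster count must be in [1, n]")
  TRUE
})

# ---- accessors & show methods -----------------------------------------

#' @describeIn LigandInstance-class number of heavy atoms.
#' @param x,object a `LigandInstance`.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname LigandInstance-class
#' @export
setMethod("nAtoms", "LigandInstance", function(x) nrow(x@atoms))

#' Coordinates of an object's atoms
#'
#' @param x a `LigandInstance` or `ProteinChain`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "LigandInstance", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' @rdname coords
#' @export
setMethod("coords", "ProteinChain", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' Element symbols of a ligand's atoms
#' @param x a `LigandInstance`.
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname elements
#' @export
setMethod("elements", "LigandInstance", function(x) toupper(x@atoms$element))

#' Bond list of a ligand
#' @param x a `LigandInstance`.
#' @return two-column integer matrix of atom-index pairs.
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname bonds
#' @export
setMethod("bonds", "LigandInstance", function(x) x@bonds)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (y = R x + t, B -> A)\n")
  cat("  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(sprintf("%.3f", object@translation),
                              collapse = " "), "\n")
})

setMethod("show", "LigandInstance", function(object) {
  cat(sprintf("LigandInstance %s %s chain %s resno %d: %d heavy atoms, %d bonds\n",
              object@pdbId, object@compId, object@chainId, object@resno,
              nrow(object@atoms), nrow(object@bonds)))
})

setMethod("show", "ProteinChain", function(object) {
  cat(sprintf("ProteinChain %s: %d atoms, %d standard residues\n",
              object@chainId, nrow(object@atoms), nchar(object@sequence)))
})

setMethod("show", "AtomMapping", function(object) {
  cat(sprintf("AtomMapping (%s): %d pairs\n", object@source,
              nrow(object@pairs)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", object@rmsd))
})

setMethod("show", "LigandRMSDResult", function(object) {
  cat(sprintf(
    "LigandRMSDResult: RMSD' = %.2f, RMSD'' = %.2f, LigandRMSD = %.2f A (%s, %d atoms) -> %s\n",
    object@rmsdAligned, object@rmsdOptimal, object@score,
    object@mappingSource, object@mappingSize,
    if (object@similar) "similar" else "not similar"))
})

setMethod("show", "ConformerClustering", function(object) {
  k <- length(unique(object@labels))
  cat(sprintf("ConformerClustering %s: %d conformers in %d clusters (cut %.2f A)\n",
              object@drug, length(object@instances), k, object@cutHeight))
})

setMethod("show", "Thresholds", function(object) {
  cat("Thresholds:\n")
  cat(sprintf("  LigandRMSD similarity     <= %.2f A\n", object@ligandRmsdMax))
  cat(sprintf("  conformer cluster cut     <= %.2f A\n", object@conformerCut))
  cat(sprintf("  target identity cluster   >= %.1f %%\n", object@identityCluster))
  cat(sprintf("  TM-score global similar   >= %.2f\n", object@tmSimilar))
  cat(sprintf("  promiscuous drug          >= %d targets\n",
              object@promiscuityMinTargets))
  cat(sprintf("  aligner P-value cut       %s\n",
              ifelse(is.na(object@alignerPvalueCut), "(unset)",
                     format(object@alignerPvalueCut))))
})
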