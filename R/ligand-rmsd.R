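# The core score: LigandRMSD of a binding-site alignment, the
# cluster-level similarity verdict, and the P-value filter comparison.

#' LigandRMSD of a binding-site alignment
#'
#' Scores a rigid transform produced by an external binding-site (or
#' global structure) aligner through the ligands it superposes.  One atom
#' mapping is chosen by [matchAtoms()] (minimising RMSD'' among candidate
#' mappings); RMSD' is the ligand-ligand RMSD induced by the given
#' transform, RMSD'' the Kabsch-optimal RMSD of the same pair under the
#' SAME mapping, and the score is their difference.  Because RMSD'' is the
#' optimum for the very mapping used in RMSD', the score is non-negative
#' (up to numerical noise) and independent of conformational differences
#' between the two bound copies: a perfectly aligned pair scores 0 even
#' when the conformers differ.  The verdict is inclusive:
#' `score <= thresholds@ligandRmsdMax` (default 3 Angstrom) means similar
#' binding sites.
#'
#' @param ligA,ligB [LigandInstance-class] objects, the same drug or a pair
#'   sharing a common subgraph of at least 3 non-collinear atoms.
#' @param transform the aligner's [RigidTransform-class] carrying B-frame
#'   coordinates into A's frame.
#' @param thresholds a [Thresholds-class].
#' @param mapping optional pre-computed [AtomMapping-class] (skips
#'   [matchAtoms()]).
#' @return A [LigandRMSDResult-class].
#' @examples
#' lig <- ligandTemplate("benzamidine")
#' ligandRMSD(lig, lig, RigidTransform())  # exact copy: score 0, similar
#' @export
ligandRMSD <- function(ligA, ligB, transform,
                       thresholds = defaultThresholds(), mapping = NULL) {
  if (is.null(mapping)) mapping <- matchAtoms(ligA, ligB)
  cA <- coords(ligA); cB <- coords(ligB)
  p <- mapping@pairs
  a <- cA[p[, 1L], , drop = FALSE]
  b <- cB[p[, 2L], , drop = FALSE]
  moved <- b %*% t(transform@rotation) +
    rep(transform@translation, each = nrow(b))
  rmsdAligned <- sqrt(mean(rowSums((a - moved)^2)))
  rmsdOptimal <- .kabschCore(a, b)
  score <- rmsdAligned - rmsdOptimal
  new("LigandRMSDResult",
      rmsdAligned = rmsdAligned, rmsdOptimal = rmsdOptimal, score = score,
      mappingSize = nrow(mapping@pairs), mappingSource = mapping@source,
      similar = score <= thresholds@ligandRmsdMax)
}

#' Similarity verdict for a pair of non-redundant targets
#'
#' A representative pair of targets is called similar when at least one of
#' its member-structure alignments scores as similar, mirroring the
#' member-level rule used to collapse redundant structures.
#'
#' @param scores numeric vector of LigandRMSD scores for all member-pair
#'   alignments of one non-redundant target pair (one drug).
#' @param thresholds a [Thresholds-class].
#' @return logical.
#' @examples
#' sitePairSimilarity(c(4.1, 2.2, 5.0))  # TRUE
#' sitePairSimilarity(3.0)               # TRUE, inclusive threshold
#' @export
sitePairSimilarity <- function(scores, thresholds = defaultThresholds()) {
  if (!length(scores)) stop("empty record list for target pair")
  any(scores <= thresholds@ligandRmsdMax)
}

#' Compare the LigandRMSD filter with an aligner P-value cut
#'
#' Classifies scored alignment records as similar/dissimilar by LigandRMSD
#' and by the aligner's P-value at `pvalueCut`, and reports the 2x2
#' contingency counts together with the percentage of LigandRMSD-similar
#' pairs the P-value cut misses.
#'
#' @param scored data.frame with columns `score` (LigandRMSD, Angstrom) and
#'   `aligner_pvalue`.
#' @param pvalueCut P-value threshold (required; no shipped default).
#' @param thresholds a [Thresholds-class].
#' @return list with `table` (2x2 matrix, rows = LigandRMSD verdict,
#'   columns = P-value verdict), `missedByPvaluePct` (percentage of
#'   LigandRMSD-similar pairs not passing the P-value cut, relative to the
#'   P-value-passing similar pairs) and the two thresholds.
#' @export
compareFilters <- function(scored, pvalueCut,
                           thresholds = defaultThresholds()) {
  if (!nrow(scored)) stop("empty record list")
  if (missing(pvalueCut) || is.null(pvalueCut) || is.na(pvalueCut))
    stop("pvalueCut is required (no default P-value threshold is shipped)")
  if (!"aligner_pvalue" %in% names(scored) ||
      any(is.na(scored$aligner_pvalue))) {
    bad <- if ("aligner_pvalue" %in% names(scored))
      which(is.na(scored$aligner_pvalue)) else seq_len(nrow(scored))
    stop("records without aligner P-value: rows ",
         paste(head(bad, 10), collapse = ", "))
  }
  byRmsd <- scored$score <= thresholds@ligandRmsdMax
  byP <- scored$aligner_pvalue <= pvalueCut
  tab <- matrix(c(sum(byRmsd & byP), sum(byRmsd & !byP),
                  sum(!byRmsd & byP), sum(!byRmsd & !byP)),
                nrow = 2, byrow = TRUE,
                dimnames = list(LigandRMSD = c("similar", "dissimilar"),
                                Pvalue = c("pass", "fail")))
  nPassBoth <- tab["similar", "pass"]
  missed <- if (nPassBoth + 0 == 0) NA_real_
            else 100 * tab["similar", "fail"] / nPassBoth
  list(table = tab, missedByPvaluePct = missed,
       pvalueCut = pvalueCut, ligandRmsdMax = thresholds@ligandRmsdMax)
}

# ---- alignment-record I/O ---------------------------------------------

#' Score a table of alignment records
#'
#' Applies [ligandRMSD()] to every record of an alignment table against a
#' pool of parsed ligand instances.
#'
#' @param records data.frame with columns drug, pdb_a, chain_a, resno_a,
#'   pdb_b, chain_b, resno_b, transform (JSON string, see
#'   [transformToJSON()]) and optionally aligner_pvalue, tm_score,
#'   aligner_name.
#' @param ligands list of [LigandInstance-class]; looked up by
#'   (pdbId, compId, chainId, resno).
#' @param thresholds a [Thresholds-class].
#' @return the records data.frame with columns rmsd_aligned, rmsd_optimal,
#'   score, mapping_size, mapping_source, similar appended.
#' @export
scoreAlignments <- function(records, ligands,
                            thresholds = defaultThresholds()) {
  key <- vapply(ligands, function(l)
    paste(l@pdbId, l@compId, l@chainId, l@resno, sep = "|"), character(1))
  lookup <- function(pdb, drug, chain, resno, i) {
    hit <- which(key == paste(pdb, drug, chain, resno, sep = "|"))
    if (!length(hit))
      stop(sprintf("record %d: ligand %s %s %s/%s not found", i, pdb, drug,
                   chain, resno))
    ligands[[hit[1]]]
  }
  n <- nrow(records)
  out <- cbind(records, rmsd_aligned = NA_real_, rmsd_optimal = NA_real_,
               score = NA_real_, mapping_size = NA_integer_,
               mapping_source = NA_character_, similar = NA)
  # the atom mapping depends only on the two ligands' topology (names,
  # elements, bonds), so it is cached across records of the same pair type
  mapCache <- new.env(parent = emptyenv())
  cachedMapping <- function(la, lb) {
    k <- paste(la@compId, lb@compId,
               paste(la@atoms$name, collapse = ","),
               paste(lb@atoms$name, collapse = ","),
               paste(elements(la), collapse = ","),
               paste(elements(lb), collapse = ","),
               paste(la@bonds, collapse = ","),
               paste(lb@bonds, collapse = ","), sep = "|")
    m <- mapCache[[k]]
    if (is.null(m)) {
      m <- matchAtoms(la, lb)
      # only the atom-name mapping is coordinate-independent; candidate
      # selection by RMSD'' must be redone per conformer pair otherwise
      if (m@source == "name-match") mapCache[[k]] <- m
    }
    m
  }
  for (i in seq_len(n)) {
    la <- lookup(records$pdb_a[i], records$drug[i], records$chain_a[i],
                 records$resno_a[i], i)
    lb <- lookup(records$pdb_b[i], records$drug[i], records$chain_b[i],
                 records$resno_b[i], i)
    tr <- transformFromJSON(records$transform[i])
    r <- ligandRMSD(la, lb, tr, thresholds, mapping = cachedMapping(la, lb))
    out$rmsd_aligned[i] <- r@rmsdAligned
    out$rmsd_optimal[i] <- r@rmsdOptimal
    out$score[i] <- r@score
    out$mapping_size[i] <- r@mappingSize
    out$mapping_source[i] <- r@mappingSource
    out$similar[i] <- r@similar
  }
  out
}

#' Read / write alignment-record tables
#'
#' Tab-separated records with the rigid transform embedded as a JSON
#' string per row (see [transformToJSON()] for the convention).
#'
#' @param path file path.
#' @return data.frame of records.
#' @export
readAlignmentRecords <- function(path) {
  # quote = "": the transform column is raw JSON containing double quotes
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             quote = "")
}

#' @rdname readAlignmentRecords
#' @param records data.frame of alignment records.
#' @export
writeAlignmentRecords <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
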