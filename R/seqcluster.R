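# Global sequence alignment (affine-gap Needleman-Wunsch), percent
# identity, and 95%-identity single-linkage clustering into non-redundant
# targets.

.pkgCache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to the 20 standard residues plus X; X scores 0
# against everything (unknown/nonstandard residues are neutral).
.substMatrix <- function() {
  if (is.null(.pkgCache$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    m <- e$BLOSUM62[c(letters20, "X"), c(letters20, "X")]
    m["X", ] <- 0; m[, "X"] <- 0
    storage.mode(m) <- "double"
    .pkgCache$blosum <- m
  }
  .pkgCache$blosum
}

.encodeSeq <- function(s) {
  m <- .substMatrix()
  ch <- strsplit(toupper(s), "")[[1]]
  ch[!ch %in% rownames(m)] <- "X"
  match(ch, rownames(m))
}

#' Global pairwise alignment
#'
#' @slot alignedA,alignedB equal-length gapped strings ("-" for gaps).
#' @slot score substitution-matrix units.
#' @slot identityPct identical columns / alignment length x 100.
#' @exportClass GlobalAlignment
setClass("GlobalAlignment",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", identityPct = "numeric")
)

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment: score %.1f, identity %.1f%%\n",
              object@score, object@identityPct))
  cat(" ", object@alignedA, "\n ", object@alignedB, "\n")
})

#' Affine-gap global sequence alignment
#'
#' Needleman-Wunsch (Gotoh) with BLOSUM62 and the gap convention of the
#' EMBOSS `needle` tool: a gap of length L costs
#' `gapOpen + (L - 1) * gapExt` (defaults 10 and 0.5); end gaps are
#' penalised like internal gaps.  Nonstandard residues are mapped to X,
#' which scores 0 against everything.  Percent identity uses the full
#' alignment length (gap columns included) as denominator.  Ties between
#' co-optimal alignments are broken deterministically: maximal identical
#' columns, then minimal alignment length.
#'
#' @param seqA,seqB non-empty amino-acid strings.
#' @param gapOpen,gapExt gap penalties (positive).
#' @return A [GlobalAlignment-class].
#' @examples
#' globalAlign("HEAGAWGHEE", "PAWHEAE")
#' @export
globalAlign <- function(seqA, seqB, gapOpen = 10, gapExt = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  m <- .substMatrix()
  a <- .encodeSeq(seqA); b <- .encodeSeq(seqB)
  res <- .gotohAlign(a, b, m, gapOpen, gapExt, TRUE)
  let <- rownames(m)
  chA <- ifelse(res$colA == 0L, "-", let[a[pmax(res$colA, 1L)]])
  chB <- ifelse(res$colB == 0L, "-", let[b[pmax(res$colB, 1L)]])
  new("GlobalAlignment",
      alignedA = paste(chA, collapse = ""),
      alignedB = paste(chB, collapse = ""),
      score = res$score,
      identityPct = 100 * res$identical / res$length)
}

#' Percent identity of two sequences
#'
#' Identity of the optimal global alignment, identical columns over full
#' alignment length.
#'
#' @inheritParams globalAlign
#' @return percent in `[0, 100]`.
#' @export
percentIdentity <- function(seqA, seqB, gapOpen = 10, gapExt = 0.5) {
  res <- .gotohAlign(.encodeSeq(seqA), .encodeSeq(seqB), .substMatrix(),
                     gapOpen, gapExt, FALSE)
  100 * res$identical / res$length
}

# Conservative pre-screen: can this pair possibly reach `cut` percent
# identity?  Uses the length-ratio bound (identical columns cannot exceed
# the shorter sequence, alignment length cannot be below the longer) and a
# shared 4-mer fraction with a wide safety margin (at >= 90% identity the
# vast majority of 4-mers must be shared; 0.3 is far below that).
.identityPossible <- function(seqA, seqB, cut, k = 4L) {
  la <- nchar(seqA); lb <- nchar(seqB)
  if (100 * min(la, lb) / max(la, lb) < cut) return(FALSE)
  if (min(la, lb) < 5 * k) return(TRUE)
  km <- function(s, n) {
    unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
  }
  ka <- km(seqA, la); kb <- km(seqB, lb)
  length(intersect(ka, kb)) / min(length(ka), length(kb)) >= 0.3
}

#' Cluster protein chains at a sequence-identity cut
#'
#' Single-linkage transitive closure over all chain pairs whose global
#' alignment identity reaches `identityCut` percent, yielding the
#' non-redundant target set.  The representative of a cluster is its
#' longest member sequence (ties: lexicographically smallest identifier).
#'
#' @param sequences named character vector of amino-acid sequences (names
#'   are chain identifiers), or a list of [ProteinChain-class] objects.
#' @param identityCut percent identity threshold (default 95; inclusive).
#' @param screen apply the conservative k-mer/length pre-screen before
#'   aligning a pair (default TRUE).  Screened-out pairs provably cannot
#'   reach the cut.
#' @return data.frame with columns cluster_id, representative, member,
#'   identity_to_representative.
#' @examples
#' seqs <- c(ch1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'           ch2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'           ch3 = "WWGGHHPPLLKKNNAAQQEERRTTYYIIVVMMC")
#' clusterTargets(seqs)
#' @export
clusterTargets <- function(sequences, identityCut = 95, screen = TRUE) {
  if (is.list(sequences) && length(sequences) &&
      is(sequences[[1]], "ProteinChain")) {
    nm <- vapply(sequences, function(ch) ch@chainId, character(1))
    sequences <- setNames(vapply(sequences, function(ch) ch@sequence,
                                 character(1)), nm)
  }
  n <- length(sequences)
  if (n < 1L) stop("at least one chain is required")
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must have unique names")

  comp <- seq_len(n)  # union-find
  findRoot <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (findRoot(i) == findRoot(j)) next
        if (screen && !.identityPossible(sequences[i], sequences[j],
                                         identityCut)) next
        if (percentIdentity(sequences[i], sequences[j]) >= identityCut) {
          comp[findRoot(j)] <- findRoot(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    members <- which(roots == r)
    lens <- nchar(sequences[members])
    rep <- ids[members][order(-lens, ids[members])][1L]
    data.frame(representative = rep, member = ids[members],
               identity_to_representative = vapply(members, function(i) {
                 if (ids[i] == rep) 100
                 else percentIdentity(sequences[i], sequences[ids == rep])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  reps <- unique(out$representative)
  out$cluster_id <- paste0("TC", sprintf("%04d", match(out$representative,
                                                       reps)))
  rownames(out) <- NULL
  out[, c("cluster_id", "representative", "member",
          "identity_to_representative")]
}

#' Promiscuity degree of a drug
#'
#' The number of distinct non-redundant targets (identity clusters)
#' containing at least one chain co-crystallised with the drug.  A drug is
#' promiscuous when its degree reaches the threshold (default 3).
#'
#' @param drug chemical component identifier.
#' @param clusters data.frame from [clusterTargets()].
#' @param drugLinks data.frame with columns `chain` and `drug` linking
#'   chain identifiers to bound drugs.
#' @return integer degree.
#' @export
promiscuityDegree <- function(drug, clusters, drugLinks) {
  hit <- drugLinks$drug == drug
  if (!any(hit)) stop("drug ", drug, " absent from the dataset")
  chains <- unique(drugLinks$chain[hit])
  length(unique(clusters$cluster_id[clusters$member %in% chains]))
}

#' Read/write FASTA sequences
#'
#' Thin wrappers around Biostrings FASTA I/O returning plain named
#' character vectors.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
readSequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname readSequences
#' @param sequences named character vector.
#' @export
writeSequences <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
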