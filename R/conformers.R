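# Bound-conformer comparison and clustering: symmetry-corrected minimum
# RMSD between two conformers, average-linkage clustering cut at 1.4 A.

#' Superposition distance between two conformers
#'
#' The minimum, over all enumerated candidate atom mappings (graph
#' automorphisms/isomorphisms, or maximum common subgraph embeddings when
#' the graphs differ), of the optimal rigid-superposition RMSD.  Taking the
#' minimum over mappings guards against a suboptimal atom correspondence in
#' symmetric molecules (symmetry-corrected RMSD).
#'
#' @param a,b [LigandInstance-class] objects with bonds inferred.
#' @param maxCandidates mapping enumeration cap (default 1000).
#' @param mappings optional pre-enumerated list of candidate mapping
#'   matrices, reused across the pairs of one clustering.
#' @return RMSD in Angstrom.
#' @examples
#' lig <- ligandTemplate("benzamidine")
#' conformerDistance(lig, lig)  # 0
#' @export
conformerDistance <- function(a, b, maxCandidates = 1000L,
                              mappings = NULL, checkCollinear = TRUE) {
  if (is.null(mappings)) mappings <- .enumerateMappings(a, b,
                                                        maxCandidates)$cands
  cA <- coords(a); cB <- coords(b)
  best <- Inf
  for (p in mappings) {
    if (nrow(p) < 3L) next
    pa <- cA[p[, 1L], , drop = FALSE]; pb <- cB[p[, 2L], , drop = FALSE]
    if (checkCollinear && (.isCollinear(pa) || .isCollinear(pb))) next
    best <- min(best, .kabschCore(pa, pb))
  }
  if (!is.finite(best))
    stop(sprintf("unmappable conformer pair %s / %s", a@compId, b@compId))
  best
}

#' Cluster the bound conformers of a drug
#'
#' Agglomerative average-linkage clustering of the pairwise superposition
#' RMSD matrix; the dendrogram is cut at `cut` Angstrom, with merges at
#' height exactly `cut` retained (inclusive, matching the convention that
#' conformers at RMSD equal to the cut are clustered together).  Cluster
#' labels are numbered by smallest member index.
#'
#' @param instances list of [LigandInstance-class] conformers of one drug.
#' @param cut dendrogram cut height in Angstrom (default 1.4).
#' @param distanceMatrix optional precomputed symmetric RMSD matrix.
#' @return A [ConformerClustering-class].
#' @export
clusterConformers <- function(instances, cut = 1.4, distanceMatrix = NULL) {
  n <- length(instances)
  if (n < 1L) stop("at least one conformer is required")
  drug <- if (n) instances[[1]]@compId else ""
  if (is.null(distanceMatrix)) {
    distanceMatrix <- matrix(0, n, n)
    if (n > 1L) {
      # all instances of one drug share atom order and bond list, so the
      # candidate mapping set (graph automorphisms) is the same for every
      # pair and is enumerated once
      shared <- NULL
      if (all(vapply(instances, function(l)
            identical(l@bonds, instances[[1]]@bonds) &&
              identical(elements(l), elements(instances[[1]])),
            logical(1))))
        shared <- .enumerateMappings(instances[[1]], instances[[1]])$cands
      # degenerate (collinear) instances are screened once, not per pair
      noCheck <- !is.null(shared) &&
        !any(vapply(instances, function(l) .isCollinear(coords(l)),
                    logical(1)))
      for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        d <- conformerDistance(instances[[i]], instances[[j]],
                               mappings = shared,
                               checkCollinear = !noCheck)
        distanceMatrix[i, j] <- distanceMatrix[j, i] <- d
      }
    }
  }
  if (n == 1L) {
    return(new("ConformerClustering", drug = drug, instances = instances,
               distanceMatrix = distanceMatrix, cutHeight = cut,
               labels = 1L, tree = NULL))
  }
  tree <- hclust(as.dist(distanceMatrix), method = "average")
  labels <- .cutInclusive(tree, cut, n)
  new("ConformerClustering", drug = drug, instances = instances,
      distanceMatrix = distanceMatrix, cutHeight = cut,
      labels = labels, tree = tree)
}

# Extract flat clusters by applying every merge whose height is <= cut
# (guaranteed-inclusive at equality), then renumbering clusters by their
# smallest member index.
.cutInclusive <- function(tree, cut, n) {
  comp <- seq_len(n)
  findRoot <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  nodeMembers <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[k, ]
    mem <- unlist(lapply(kids, function(x)
      if (x < 0) -x else nodeMembers[[x]]))
    nodeMembers[[k]] <- mem
    if (tree$height[k] <= cut) {
      r <- findRoot(mem[1])
      for (other in mem[-1]) comp[findRoot(other)] <- r
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  firstIdx <- vapply(unique(roots), function(r) min(which(roots == r)),
                     integer(1))
  ord <- unique(roots)[order(firstIdx)]
  as.integer(match(roots, ord))
}

#' Membership statistics of a conformer clustering
#'
#' @param x a [ConformerClustering-class].
#' @return list with count (clusters), minMembers, meanMembers, maxMembers.
#' @export
clusterStats <- function(x) {
  sizes <- as.integer(table(x@labels))
  list(count = length(sizes), minMembers = min(sizes),
       meanMembers = mean(sizes), maxMembers = max(sizes))
}

#' Flexibility table across drugs
#'
#' One row per drug: the number of conformer clusters (distinct bound
#' conformers over all structures) and the minimum / mean / maximum number
#' of cluster members, sorted by cluster count.
#'
#' @param clusterings list of [ConformerClustering-class] objects.
#' @return data.frame with columns drug, n_instances, conformer_clusters,
#'   min_members, mean_members, max_members.
#' @export
conformerStats <- function(clusterings) {
  out <- do.call(rbind, lapply(clusterings, function(cc) {
    s <- clusterStats(cc)
    data.frame(drug = cc@drug, n_instances = length(cc@instances),
               conformer_clusters = s$count, min_members = s$minMembers,
               mean_members = round(s$meanMembers, 2),
               max_members = s$maxMembers, stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$conformer_clusters, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a conformer dendrogram in Newick format
#'
#' @param x a [ConformerClustering-class] with at least two conformers.
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportDendrogram <- function(x, path) {
  if (is.null(x@tree)) stop("dendrogram export needs >= 2 conformers")
  phy <- ape::as.phylo(x@tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
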