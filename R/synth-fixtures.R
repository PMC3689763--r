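# Seeded generators for every input the analysis needs: protein-ligand
# complex pairs with known rigid motions, conformer sets with planted
# clusters, and whole drug-target cohorts with planted similarity
# structure and a planted correlation between promiscuity and similar-site
# count.  Identical seed => identical output.

.AA1TO3 <- setNames(names(.AA3TO1), .AA3TO1)

.helixTrace <- function(n, rise = 1.5, radius = 2.3, turn = 100) {
  t <- seq_len(n)
  ang <- t * turn * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * t)
}

.chainLines <- function(sequence, xyz, chainId = "A", firstSerial = 1L) {
  res3 <- .AA1TO3[strsplit(sequence, "")[[1]]]
  vapply(seq_along(res3), function(i) {
    .pdbAtomLine("ATOM", firstSerial + i - 1L, "CA", res3[i], chainId, i,
                 xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, "C")
  }, character(1))
}

# Full PDB text: one CA-trace chain plus one ligand with CONECT records;
# ligand serials continue after the chain's
.structureText <- function(sequence, chainXYZ, ligand) {
  ligand@atoms$serial <- nchar(sequence) + seq_len(nrow(ligand@atoms))
  c(.chainLines(sequence, chainXYZ, ligand@chainId),
    "TER",
    writeLigandPDB(ligand))
}

.applyMotion <- function(xyz, transform) applyTransform(transform, xyz)

#' Synthetic protein-ligand complex pair with a known rigid motion
#'
#' Builds one complex (CA-trace helix chain plus a template ligand with
#' CONECT records), produces a second copy moved by the stated rigid
#' motion with optional Gaussian coordinate noise, and returns the exact
#' inverse motion: scoring the pair with the returned transform and zero
#' noise gives LigandRMSD 0.
#'
#' @param seed integer seed; identical seeds give byte-identical files.
#' @param nResidues chain length (>= 5).
#' @param ligandSpec template name, see [ligandTemplate()] (>= 4
#'   non-collinear heavy atoms required).
#' @param rotationDeg,translationA magnitude of the rigid motion applied
#'   to copy B (random seeded axis/direction).
#' @param coordNoiseSd isotropic Gaussian noise, Angstrom (default 0).
#' @return list with `pdbA`, `pdbB` (PDB text strings), `transform` (the
#'   true B-to-A [RigidTransform-class]), `ligandRef` (compId, chainId,
#'   resno) and `seed`.
#' @export
makeComplexPair <- function(seed, nResidues = 30L, ligandSpec = "benzamidine",
                            rotationDeg = 25, translationA = 8,
                            coordNoiseSd = 0) {
  if (nResidues < 5L) stop("nResidues must be >= 5")
  set.seed(seed)
  lig <- ligandTemplate(ligandSpec, pdbId = "SYNA")
  if (nAtoms(lig) < 4L || .isCollinear(coords(lig)))
    stop("degenerate ligand spec: need >= 4 non-collinear heavy atoms")

  helix <- .helixTrace(nResidues)
  seqAA <- paste(sample(names(.AA1TO3), nResidues, replace = TRUE),
                 collapse = "")
  ligXYZ <- sweep(coords(lig), 2, colMeans(coords(lig)))
  ligXYZ <- sweep(ligXYZ, 2, c(6.5, 0, 1.5 * nResidues / 2), `+`)
  ligA <- .withCoords(lig, ligXYZ, resno = nResidues + 10L)

  R0 <- .rotationMatrix(.randomUnit(), rotationDeg * pi / 180)
  t0 <- translationA * .randomUnit()
  fwd <- RigidTransform(R0, t0)             # A frame -> B frame
  noise <- function(m) m + matrix(rnorm(length(m), sd = coordNoiseSd),
                                  nrow(m))
  helixB <- noise(.applyMotion(helix, fwd))
  ligB <- .withCoords(ligA, noise(.applyMotion(coords(ligA), fwd)),
                      pdbId = "SYNB")

  list(pdbA = paste(.structureText(seqAA, helix, ligA), collapse = "\n"),
       pdbB = paste(.structureText(seqAA, helixB, ligB), collapse = "\n"),
       transform = invertTransform(fwd),
       ligandRef = list(compId = ligA@compId, chainId = ligA@chainId,
                        resno = ligA@resno),
       seed = seed)
}

# one deformed conformer of `base`: torsion twists where possible plus a
# non-rigid Gaussian displacement field of scale `sd`
.deformConformer <- function(base, sd) {
  out <- base
  rb <- rotatableBonds(buildGraph(base))
  if (rb$absolute > 0) {
    g <- buildGraph(base)
    deg <- degree(g@graph)
    rot <- which(!g@ringEdge & deg[g@edges[, 1]] >= 2 &
                   deg[g@edges[, 2]] >= 2)
    for (e in rot[sample.int(length(rot), min(2L, length(rot)))]) {
      out <- try(twistBond(out, g@edges[e, ], runif(1, 60, 300)),
                 silent = TRUE)
      if (inherits(out, "try-error")) out <- base
    }
  }
  xyz <- coords(out) + matrix(rnorm(3 * nAtoms(out), sd = sd), ncol = 3)
  .withCoords(out, xyz)
}

#' Conformer set with planted clusters
#'
#' Generates `kClusters` well-separated conformer shapes of a template
#' ligand and populates each with rigid-motion copies perturbed by small
#' non-rigid noise, so that all intra-cluster superposition RMSDs stay at
#' or below `intraRmsdMax` and all inter-cluster RMSDs at or above
#' `interRmsdMin` (verified with [conformerDistance()]; regenerated on
#' violation within a bounded retry budget).
#'
#' @param seed integer seed.
#' @param ligandSpec template name.
#' @param kClusters number of planted conformer clusters.
#' @param intraRmsdMax,interRmsdMin RMSD bounds, Angstrom; must bracket the
#'   clustering cut.
#' @param membersPerCluster integer vector (recycled) of cluster sizes;
#'   default 1-3 members, seeded.
#' @param maxRetries retry budget per generated conformer (default 50).
#' @return list with `instances` (list of [LigandInstance-class]) and
#'   `labels` (planted cluster index per instance).
#' @export
makeConformerSet <- function(seed, ligandSpec = "ring-tail", kClusters = 3L,
                             intraRmsdMax = 0.5, interRmsdMin = 3.0,
                             membersPerCluster = NULL, maxRetries = 50L) {
  if (intraRmsdMax >= interRmsdMin)
    stop("intraRmsdMax must be below interRmsdMin")
  set.seed(seed)
  base <- ligandTemplate(ligandSpec)
  if (is.null(membersPerCluster))
    membersPerCluster <- sample(1:3, kClusters, replace = TRUE)
  sizes <- rep_len(membersPerCluster, kClusters)

  # cluster centres: deformations separated with margin for member noise
  margin <- interRmsdMin + 2 * intraRmsdMax
  centres <- list(base)
  tries <- 0L
  while (length(centres) < kClusters) {
    cand <- .deformConformer(base, sd = interRmsdMin * 0.9)
    dmin <- min(vapply(centres, function(ctr)
      conformerDistance(ctr, cand), numeric(1)))
    if (dmin >= margin) centres[[length(centres) + 1L]] <- cand
    tries <- tries + 1L
    if (tries > maxRetries * kClusters)
      stop("infeasible conformer bounds: could not separate cluster centres")
  }

  instances <- list(); labels <- integer()
  for (k in seq_len(kClusters)) {
    got <- 0L; tries <- 0L
    members <- list()
    while (got < sizes[k]) {
      xyz <- coords(centres[[k]]) +
        matrix(rnorm(3 * nAtoms(base), sd = intraRmsdMax / 4), ncol = 3)
      Rm <- .randomRotation()
      xyz <- sweep(xyz %*% t(Rm), 2, runif(3, -20, 20), `+`)
      cand <- .withCoords(centres[[k]], xyz,
                          pdbId = sprintf("SN%02d%d", k, got + 1L))
      okIntra <- all(vapply(members, function(mm)
        conformerDistance(mm, cand) <= intraRmsdMax, logical(1))) &&
        conformerDistance(centres[[k]], cand) <= intraRmsdMax
      okInter <- all(vapply(seq_len(kClusters)[-k], function(j)
        conformerDistance(centres[[j]], cand) >=
          interRmsdMin + intraRmsdMax, logical(1)))
      if (okIntra && okInter) {
        members[[got + 1L]] <- cand
        got <- got + 1L
      }
      tries <- tries + 1L
      if (tries > maxRetries)
        stop("infeasible conformer bounds: member generation exhausted retries")
    }
    instances <- c(instances, members)
    labels <- c(labels, rep(k, sizes[k]))
  }
  list(instances = instances, labels = labels, seed = seed)
}
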