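# Whole drug-target cohort generator: structures, sequences, alignment
# records with planted LigandRMSD outcomes, descriptor tables and ground
# truth.  The generation is staged so that all "bookkeeping" random draws
# (degrees, member counts, planted similar-pair counts, descriptors)
# happen before any geometry: `detail = "counts"` stops after stage one
# and yields the same planted cohort table as a full generation under the
# same seed.

.cohortCompIds <- function(n) {
  grid <- expand.grid(a = LETTERS, b = LETTERS, stringsAsFactors = FALSE)
  ids <- paste0("X", grid$a, grid$b)
  if (n > length(ids)) stop("too many drugs requested")
  ids[seq_len(n)]
}

.defaultDegreeSampler <- function(n) {
  # promiscuity distribution shaped like a PDB drug-target census: most
  # drugs have one or two targets, ~30% have three or more, heavy tail
  u <- runif(n)
  extra <- rnbinom(n, size = 1.2, mu = 1.6)
  d <- ifelse(u < 0.45, 1L, ifelse(u < 0.70, 2L, 3L + extra))
  pmin(as.integer(d), 37L)
}

.defaultMembersSampler <- function(n) {
  sample(1:6, n, replace = TRUE,
         prob = c(0.15, 0.20, 0.25, 0.20, 0.12, 0.08))
}

.defaultConformerSampler <- function(n) {
  # bound-conformer multiplicity: ~68% one conformer, 18% two, rest 3-5
  sample(1:5, n, replace = TRUE, prob = c(0.68, 0.18, 0.08, 0.04, 0.02))
}

# Solve for the latent Gaussian correlation rhoL such that, after
# discretising the latent through the copula marginal `marg` (levels
# 0..3 similar pairs), the expected Pearson correlation between the
# degree and sqrt(similar pairs) equals the requested rho.  Closed form
# given the standardised degrees xt: z | x ~ N(rhoL * xt, 1 - rhoL^2),
# all level probabilities are normal tail differences.
.calibrateLatentRho <- function(xt, marg, rho) {
  if (abs(rho) < 1e-12) return(0)
  vals <- sqrt(seq_along(marg) - 1)
  tk <- qnorm(cumsum(marg)[-length(marg)])
  realized <- function(rhoL) {
    sig <- sqrt(max(1e-12, 1 - rhoL^2))
    probs <- vapply(seq_along(xt), function(i) {
      cuts <- pnorm((tk - rhoL * xt[i]) / sig)
      diff(c(0, cuts, 1))
    }, numeric(length(marg)))
    Eg <- as.numeric(t(probs) %*% vals)
    Eg2 <- as.numeric(t(probs) %*% vals^2)
    vg <- mean(Eg2) - mean(Eg)^2
    if (vg <= 1e-12) return(0)
    (mean(xt * Eg) - mean(xt) * mean(Eg)) / (sd(xt) * sqrt(vg))
  }
  f <- function(rhoL) realized(sign(rho) * rhoL) - rho
  hi <- 0.999
  if (f(hi) < 0 && rho > 0) return(sign(rho) * hi)
  if (rho < 0 && f(hi) > 0) return(sign(rho) * hi)
  sign(rho) * uniroot(f, c(0, hi), tol = 1e-6)$root
}

.mutateSequence <- function(base, nMut) {
  if (nMut == 0L) return(base)
  ch <- strsplit(base, "")[[1]]
  pos <- sample.int(length(ch), nMut)
  for (p in pos) ch[p] <- sample(setdiff(names(.AA1TO3), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Synthetic drug-target cohort with planted ground truth
#'
#' Generates a full structural promiscuity dataset: drugs with a seeded
#' target-count (degree) distribution, redundant member structures per
#' non-redundant target, chain sequences with controlled identity (members
#' of a target stay above the 95% clustering cut, distinct targets are
#' unrelated), bound-ligand conformer variants, and one alignment record
#' per member-structure pair of each promiscuous drug whose rigid
#' transform is the optimal superposition composed with a controlled
#' displacement, so that the resulting LigandRMSD lands exactly on the
#' planted side of the similarity threshold.  A target correlation `rho`
#' between the degree and the square root of the similar-pair count is
#' planted via a latent Gaussian.
#'
#' @param seed integer seed; the bundle is a deterministic function of it.
#' @param nDrugs total number of drugs (default 543).
#' @param degreeDistribution function(n) returning n integer degrees;
#'   the default yields ~30% promiscuous drugs (degree >= 3) with mean
#'   promiscuous degree ~4.6.
#' @param rho planted correlation between degree and sqrt(similar pairs)
#'   across promiscuous drugs (default 0.6).  Planting uses a Gaussian
#'   copula with a fixed global marginal on 0..3 similar pairs, so the
#'   correlation is free of budget-clamping bias at any rho (the marginal
#'   leaves ~71% of promiscuous drugs with at least one similar pair).
#' @param similarPairRate optional target fraction of non-redundant pairs
#'   that are similar (e.g. 0.41 for a funnel where the score stage
#'   removes 59%).  When set, similar-pair counts are planted proportional
#'   to each drug's pair budget and `rho` only orders the spread; the
#'   realised correlation is then dominated by the budgets and reported in
#'   the truth record.
#' @param fractionWithSimilar,fractionAllSimilar optional exact fractions
#'   of promiscuous drugs with >= 1 similar pair / with all pairs similar;
#'   NA (default) leaves the counts where the correlation puts them.
#' @param seqLength chain length in residues (default 80).
#' @param detail "full" (default) generates structures, sequences and
#'   alignment records; "counts" stops after the planted per-drug table
#'   (same table as "full" under the same seed).
#' @param thresholds a [Thresholds-class]; its similarity threshold is the
#'   boundary the planted scores avoid (margin 0.5 A on either side).
#' @return list with elements `drugs` (per-drug table incl. planted
#'   similar-pair counts), `truth` (planted and realised quantities), and
#'   for full detail additionally `structures`, `pdbTexts`, `sequences`,
#'   `drugLinks`, `records`, `descriptors`, `pfam`, `tmScores`.
#' @export
makeCohort <- function(seed, nDrugs = 543L, degreeDistribution = NULL,
                       rho = 0.6, similarPairRate = NULL,
                       fractionWithSimilar = NA,
                       fractionAllSimilar = NA, seqLength = 80L,
                       detail = c("full", "counts"),
                       thresholds = defaultThresholds()) {
  detail <- match.arg(detail)
  set.seed(seed)
  if (is.null(degreeDistribution)) degreeDistribution <- .defaultDegreeSampler

  # ---- stage 1: bookkeeping draws -------------------------------------
  degrees <- degreeDistribution(nDrugs)
  if (any(degrees < 1L)) stop("degrees must be >= 1")
  drugIds <- .cohortCompIds(nDrugs)
  minT <- thresholds@promiscuityMinTargets
  prom <- degrees >= minT

  tplNames <- c("benzamidine", "ring-tail", "chain8", "biphenyl")
  tplOf <- rep_len(tplNames, nDrugs)
  tplInstances <- lapply(tplNames, ligandTemplate)
  names(tplInstances) <- tplNames
  mw <- vapply(tplOf, function(tn) molecularWeight(tplInstances[[tn]]),
               numeric(1))
  rot <- lapply(tplOf, function(tn) rotatableBonds(buildGraph(tplInstances[[tn]])))
  rotAbs <- vapply(rot, `[[`, numeric(1), "absolute")
  rotRel <- vapply(rot, `[[`, numeric(1), "relative")
  logp <- rnorm(nDrugs, 2.3, 2.0)
  kConf <- .defaultConformerSampler(nDrugs)
  kConf[!prom] <- 1L

  # members per target: redundancy only matters for promiscuous drugs
  membersOf <- lapply(seq_len(nDrugs), function(i) {
    if (prom[i]) .defaultMembersSampler(degrees[i]) else rep(1L, degrees[i])
  })
  kConf <- pmin(kConf, vapply(membersOf, sum, integer(1)))

  # planted similar-pair counts on the promiscuous drugs
  x <- degrees[prom]
  nProm <- length(x)
  s <- integer(nProm)
  if (nProm >= 2L) {
    P <- choose(x, 2)
    xt <- if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, nProm)
    z <- rho * xt + sqrt(max(0, 1 - rho^2)) * rnorm(nProm)
    if (!is.null(similarPairRate)) {
      # budget-proportional planting: the pair-weighted mean fraction is
      # normalised so the overall similar-pair rate equals the requested
      # value up to rounding; the latent z spreads drugs around it
      frac0 <- pmax(0, 1 + 0.35 * z)
      scale <- similarPairRate * sum(P) / sum(P * frac0)
      s <- as.integer(round(pmin(1, frac0 * scale) * P))
    } else {
      # Gaussian-copula planting with a fixed global marginal on 0..3:
      # every value is reachable for every promiscuous drug (P >= 3), so
      # the planted correlation carries no budget-clamping bias at any
      # rho; the latent correlation is calibrated in closed form so the
      # discretised counts realise the requested rho in expectation
      marg <- c(0.29, 0.35, 0.20, 0.16)
      rhoL <- .calibrateLatentRho(xt, marg, rho)
      z <- rhoL * xt + sqrt(max(0, 1 - rhoL^2)) * rnorm(nProm)
      s <- findInterval(pnorm(z), cumsum(marg)[-length(marg)])
    }
    s <- pmin(as.integer(s), as.integer(P))
    ord <- order(-z, x)
    if (!is.na(fractionWithSimilar)) {
      kWith <- round(fractionWithSimilar * nProm)
      s[ord[seq_len(nProm) > kWith]] <- 0L
      if (kWith > 0) s[ord[seq_len(kWith)]] <- pmax(s[ord[seq_len(kWith)]], 1L)
    }
    if (!is.na(fractionAllSimilar)) {
      kAll <- round(fractionAllSimilar * nProm)
      if (kAll > 0) s[ord[seq_len(kAll)]] <- as.integer(P[ord[seq_len(kAll)]])
    }
  }
  realizedR <- if (nProm >= 3L && sd(x) > 0 && sd(sqrt(s)) > 0)
    cor(x, sqrt(s)) else NA_real_

  rawPairsPerDrug <- vapply(seq_len(nDrugs), function(i) {
    m <- membersOf[[i]]
    if (!prom[i] || degrees[i] < 2L) return(0)
    sum(combn(length(m), 2, function(ij) m[ij[1]] * m[ij[2]]))
  }, numeric(1))
  nonRedPerDrug <- ifelse(prom, choose(degrees, 2), 0)

  similarPer <- integer(nDrugs)
  similarPer[prom] <- s
  drugs <- data.frame(
    drug = drugIds, degree = degrees, promiscuous = prom,
    similar_pairs = similarPer, possible_pairs = ifelse(prom, choose(degrees, 2), 0),
    conformer_clusters = kConf, mw = mw, logp = logp,
    rotatable_abs = rotAbs, rotatable_rel = rotRel,
    template = tplOf, stringsAsFactors = FALSE)

  truth <- list(
    seed = seed, plantedRho = rho, realizedR = realizedR,
    nDrugs = nDrugs, nPromiscuous = nProm,
    rawPairs = sum(rawPairsPerDrug), nonRedundantPairs = sum(nonRedPerDrug),
    similarPairs = sum(similarPer),
    clusterStageFraction = if (sum(rawPairsPerDrug) > 0)
      sum(nonRedPerDrug) / sum(rawPairsPerDrug) else NA_real_,
    removedByScoreFraction = if (sum(nonRedPerDrug) > 0)
      1 - sum(similarPer) / sum(nonRedPerDrug) else NA_real_,
    fractionWithSimilar = if (nProm) mean(similarPer[prom] >= 1) else NA_real_,
    fractionAllSimilar = if (nProm)
      mean(similarPer[prom] == nonRedPerDrug[prom] & nonRedPerDrug[prom] > 0)
      else NA_real_)

  if (detail == "counts")
    return(list(drugs = drugs, truth = truth, seed = seed))

  # ---- stage 2: geometry, sequences, records --------------------------
  cutMax <- thresholds@ligandRmsdMax
  ligCenter <- c(6.5, 0, 1.5 * seqLength / 2)
  helix <- .helixTrace(seqLength)

  structures <- list(); pdbTexts <- list(); sequences <- character()
  linkRows <- list()
  pfamRows <- list(); tmRows <- list(); recRows <- list()
  structCounter <- 0L

  for (i in seq_len(nDrugs)) {
    di <- drugIds[i]
    tpl <- ligandTemplate(tplOf[i], compId = di)
    lay0 <- sweep(coords(tpl), 2, colMeans(coords(tpl)))
    lay0 <- sweep(lay0, 2, ligCenter, `+`)

    # conformer variant layouts, separated well above the conformer cut
    variants <- list(lay0)
    vTries <- 0L
    while (length(variants) < kConf[i]) {
      cand <- .deformConformer(.withCoords(tpl, lay0),
                               sd = thresholds@conformerCut)
      dmin <- min(vapply(variants, function(v)
        conformerDistance(.withCoords(tpl, v), cand), numeric(1)))
      if (dmin >= thresholds@conformerCut + 0.6)
        variants[[length(variants) + 1L]] <- coords(cand)
      vTries <- vTries + 1L
      if (vTries > 60L) { kConf[i] <- length(variants); break }
    }

    members <- membersOf[[i]]
    nStruct <- sum(members)
    variantOf <- rep_len(seq_along(variants), nStruct)  # every variant used
    # structure placement motions and texts
    Fs <- vector("list", nStruct)
    pdbIds <- character(nStruct)
    targetOf <- rep(seq_along(members), members)
    baseSeqs <- vapply(seq_along(members), function(k)
      paste(sample(names(.AA1TO3), seqLength, replace = TRUE),
            collapse = ""), character(1))
    for (sdx in seq_len(nStruct)) {
      structCounter <- structCounter + 1L
      pid <- sprintf("P%04d", structCounter)
      pdbIds[sdx] <- pid
      Fs[[sdx]] <- RigidTransform(.randomRotation(), runif(3, -40, 40))
      # first member of a target carries the base sequence so that every
      # member stays within the identity cut of it (single-linkage closure)
      firstOfTarget <- sdx == match(targetOf[sdx], targetOf)
      sq <- .mutateSequence(baseSeqs[targetOf[sdx]],
                            if (firstOfTarget) 0L else sample(0:3, 1L))
      lig <- .withCoords(tpl, applyTransform(Fs[[sdx]],
                                             variants[[variantOf[sdx]]]),
                         pdbId = pid, resno = seqLength + 10L)
      chainXYZ <- applyTransform(Fs[[sdx]], helix)
      pdbTexts[[pid]] <- paste(.structureText(sq, chainXYZ, lig),
                               collapse = "\n")
      cid <- paste0(pid, "_A")
      sequences[cid] <- sq
      linkRows[[length(linkRows) + 1L]] <-
        data.frame(chain = cid, drug = di, stringsAsFactors = FALSE)
      structures[[pid]] <- data.frame(
        pdb_id = pid, drug = di, target = targetOf[sdx],
        member = sdx, variant = variantOf[sdx], chain = cid,
        stringsAsFactors = FALSE)
    }

    # Pfam families: drawn from a drug-specific pool whose size tracks the
    # degree, so family counts correlate with promiscuity
    poolSize <- max(1L, round(0.7 * degrees[i]))
    famPool <- sprintf("PF%05d", (i - 1L) * 40L + seq_len(poolSize))
    famOf <- sample(famPool, degrees[i], replace = TRUE)
    for (k in seq_along(members)) {
      mem <- which(targetOf == k)
      pfamRows[[length(pfamRows) + 1L]] <- data.frame(
        chain = paste0(pdbIds[mem], "_A"), family = famOf[k],
        stringsAsFactors = FALSE)
    }

    if (!prom[i] || degrees[i] < 2L) next

    # alignment records for every member pair of every target pair
    sPlanted <- similarPer[i]
    pairMat <- t(combn(degrees[i], 2))
    simPairs <- if (sPlanted > 0)
      sample.int(nrow(pairMat), sPlanted) else integer()
    # cache optimal transforms between variant layouts
    vKab <- list()
    idMap <- cbind(seq_len(nAtoms(tpl)), seq_len(nAtoms(tpl)))
    nRec <- as.integer(rawPairsPerDrug[i])
    rPdbA <- character(nRec); rPdbB <- character(nRec)
    rTrans <- character(nRec); rPv <- numeric(nRec); rTm <- numeric(nRec)
    ri <- 0L
    for (pr in seq_len(nrow(pairMat))) {
      ti <- pairMat[pr, 1]; tj <- pairMat[pr, 2]
      isSim <- pr %in% simPairs
      tm <- if (isSim) rbeta(1, 2.8, 2.5) else rbeta(1, 2.0, 3.2)
      memI <- which(targetOf == ti); memJ <- which(targetOf == tj)
      first <- TRUE
      for (a in memI) for (bb in memJ) {
        if (isSim && first) { u <- runif(1, 0.3, cutMax - 0.5); first <- FALSE }
        else if (isSim) {
          u <- if (runif(1) < 0.5) runif(1, 0.3, cutMax - 0.5)
               else runif(1, cutMax + 0.5, cutMax + 6)
        } else u <- runif(1, cutMax + 0.2, cutMax + 6)
        ka <- paste(variantOf[a], variantOf[bb])
        if (is.null(vKab[[ka]]))
          vKab[[ka]] <- kabsch(variants[[variantOf[a]]],
                               variants[[variantOf[bb]]], idMap)
        r2 <- vKab[[ka]]@rmsd
        Topt <- composeTransforms(composeTransforms(Fs[[a]],
                                                    vKab[[ka]]@transform),
                                  invertTransform(Fs[[bb]]))
        d <- sqrt((u + r2)^2 - r2^2)
        Trec <- RigidTransform(Topt@rotation,
                               Topt@translation + d * .randomUnit())
        ri <- ri + 1L
        rPdbA[ri] <- pdbIds[a]; rPdbB[ri] <- pdbIds[bb]
        rTrans[ri] <- transformToJSON(Trec)
        rPv[ri] <- if (u <= cutMax) 10^runif(1, -8, -1)
                   else 10^runif(1, -4, 0)
        rTm[ri] <- tm
      }
      # TM-score at representative level (smallest chain id = representative)
      tmRows[[length(tmRows) + 1L]] <- data.frame(
        drug = di, chain_a = paste0(min(pdbIds[memI]), "_A"),
        chain_b = paste0(min(pdbIds[memJ]), "_A"), tm_score = tm,
        stringsAsFactors = FALSE)
    }
    recRows[[length(recRows) + 1L]] <- data.frame(
      drug = di, pdb_a = rPdbA, chain_a = "A", resno_a = seqLength + 10L,
      pdb_b = rPdbB, chain_b = "A", resno_b = seqLength + 10L,
      transform = rTrans, aligner_pvalue = rPv, tm_score = rTm,
      aligner_name = "synthetic", stringsAsFactors = FALSE)
  }

  drugs$conformer_clusters <- kConf
  descriptors <- data.frame(drug = drugIds, mw = mw, logp = logp,
                            rotatable_abs = rotAbs, rotatable_rel = rotRel,
                            stringsAsFactors = FALSE)
  list(drugs = drugs, truth = truth, seed = seed,
       structures = do.call(rbind, structures),
       pdbTexts = pdbTexts, sequences = sequences,
       drugLinks = do.call(rbind, linkRows),
       records = do.call(rbind, recRows),
       descriptors = descriptors,
       pfam = do.call(rbind, pfamRows),
       tmScores = do.call(rbind, tmRows))
}

#' Write a cohort bundle to a fixture directory
#'
#' Produces a self-contained input set for [runPipeline()]: a structures/
#' directory of PDB files, a FASTA of chain sequences, the alignment
#' records TSV, descriptor/Pfam/TM-score tables, the ground-truth JSON and
#' a ready-to-use pipeline configuration.
#'
#' @param cohort result of [makeCohort()] (full detail).
#' @param dir output directory (created).
#' @return the path to the written config file, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (is.null(cohort$pdbTexts))
    stop("cohort was generated with detail='counts'; no files to write")
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  for (pid in names(cohort$pdbTexts))
    writeLines(cohort$pdbTexts[[pid]],
               file.path(dir, "structures", paste0(pid, ".pdb")))
  writeSequences(cohort$sequences, file.path(dir, "sequences.fasta"))
  writeAlignmentRecords(cohort$records, file.path(dir, "alignments.tsv"))
  write.table(cohort$descriptors, file.path(dir, "descriptors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$pfam, file.path(dir, "pfam.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$tmScores, file.path(dir, "tm_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$drugLinks, file.path(dir, "drug_links.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- list(
    paths = list(structures = "structures", alignments = "alignments.tsv",
                 sequences = "sequences.fasta",
                 descriptors = "descriptors.tsv", pfam = "pfam.tsv",
                 tm_scores = "tm_scores.tsv"),
    thresholds = list(ligand_rmsd_max = 3.0, conformer_cut = 1.4,
                      identity_cluster = 95, tm_similar = 0.5,
                      promiscuity_min_targets = 3),
    seed = cohort$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
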