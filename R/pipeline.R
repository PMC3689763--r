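# Three-stage analysis pipeline: score all binding-site alignments,
# collapse to non-redundant target pairs via sequence-identity clustering,
# filter by LigandRMSD; then assemble the promiscuity table and all
# statistics.  Chain identifiers follow the convention <pdbId>_<chainId>.

#' Load a pipeline configuration
#'
#' @param path YAML file with `paths` (structures, alignments, sequences,
#'   descriptors, optional pfam, tm_scores, drug_links), optional
#'   `thresholds` overrides and `seed`.
#' @return list with `paths`, `thresholds` ([Thresholds-class]), `seed`,
#'   `baseDir`.
#' @export
pipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- defaultThresholds()
  tc <- cfg$thresholds
  if (!is.null(tc)) {
    if (!is.null(tc$ligand_rmsd_max)) th@ligandRmsdMax <- tc$ligand_rmsd_max
    if (!is.null(tc$conformer_cut)) th@conformerCut <- tc$conformer_cut
    if (!is.null(tc$identity_cluster))
      th@identityCluster <- tc$identity_cluster
    if (!is.null(tc$tm_similar)) th@tmSimilar <- tc$tm_similar
    if (!is.null(tc$promiscuity_min_targets))
      th@promiscuityMinTargets <- as.integer(tc$promiscuity_min_targets)
    if (!is.null(tc$aligner_pvalue_cut))
      th@alignerPvalueCut <- tc$aligner_pvalue_cut
  }
  validObject(th)
  list(paths = cfg$paths, thresholds = th,
       seed = if (is.null(cfg$seed)) 0L else as.integer(cfg$seed),
       baseDir = dirname(normalizePath(path)))
}

.msg <- function(verbose, ...) if (verbose) message(...)

#' Run the full binding-site similarity pipeline
#'
#' Stages: (1) score every alignment record with [ligandRMSD()]; (2)
#' cluster each drug's target chains at 95% identity and collapse member
#' records to non-redundant target pairs (a pair is similar when at least
#' one member alignment is); (3) cluster bound conformers, assemble the
#' per-drug table and compute the correlation, distribution and
#' regression statistics.  Outputs are written as TSV/JSON to `outDir`
#' together with a machine-readable manifest; a rerun with the same
#' inputs and seed is byte-identical.
#'
#' @param config path to a YAML configuration, or the result of
#'   [pipelineConfig()], or an in-memory cohort bundle from
#'   [makeCohort()] (full detail).
#' @param outDir output directory; NULL computes without writing.
#' @param thresholds optional [Thresholds-class] override (used for
#'   in-memory bundles).
#' @param verbose log stage progress to standard error (default FALSE).
#' @return list with `scored`, `clusters`, `degrees`, `pairVerdicts`,
#'   `conformers`, `table`, `correlations`, `ksTests`, `regression`,
#'   `summary`, `stageCounts`, `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL,
                        thresholds = defaultThresholds(), verbose = FALSE) {
  if (is.character(config)) config <- pipelineConfig(config)
  if (!is.null(config$pdbTexts)) {
    # in-memory cohort bundle
    bundle <- list(
      ligands = .bundleLigands(config),
      records = config$records, sequences = config$sequences,
      drugLinks = config$drugLinks, descriptors = config$descriptors,
      pfam = config$pfam, tmScores = config$tmScores,
      seed = config$seed)
    th <- thresholds
  } else {
    bundle <- .loadPipelineInputs(config)
    th <- config$thresholds
  }
  .runPipelineCore(bundle, th, outDir, verbose)
}

.bundleLigands <- function(cohort) {
  ligs <- list()
  for (pid in names(cohort$pdbTexts)) {
    p <- parseStructure(cohort$pdbTexts[[pid]])
    for (l in p$ligands) { l@pdbId <- pid; ligs[[length(ligs) + 1L]] <- l }
  }
  ligs
}

.loadPipelineInputs <- function(config) {
  pth <- function(p) if (is.null(p)) NULL else
    file.path(config$baseDir, p)
  structDir <- pth(config$paths$structures)
  files <- sort(list.files(structDir, pattern = "\\.(pdb|ent)$",
                           full.names = TRUE))
  if (!length(files)) stop("stage input: no PDB files in ", structDir)
  ligs <- list()
  for (f in files) {
    p <- readStructure(f)
    ligs <- c(ligs, p$ligands)
  }
  records <- readAlignmentRecords(pth(config$paths$alignments))
  sequences <- readSequences(pth(config$paths$sequences))
  descriptors <- read.delim(pth(config$paths$descriptors),
                            stringsAsFactors = FALSE)
  pfam <- if (!is.null(config$paths$pfam) &&
              file.exists(pth(config$paths$pfam)))
    read.delim(pth(config$paths$pfam), stringsAsFactors = FALSE) else NULL
  tmScores <- if (!is.null(config$paths$tm_scores) &&
                  file.exists(pth(config$paths$tm_scores)))
    read.delim(pth(config$paths$tm_scores), stringsAsFactors = FALSE)
    else NULL
  drugLinks <- if (!is.null(config$paths$drug_links) &&
                   file.exists(pth(config$paths$drug_links)))
    read.delim(pth(config$paths$drug_links), stringsAsFactors = FALSE)
    else .linksFromLigands(ligs)
  list(ligands = ligs, records = records, sequences = sequences,
       drugLinks = drugLinks, descriptors = descriptors, pfam = pfam,
       tmScores = tmScores, seed = config$seed)
}

.linksFromLigands <- function(ligands) {
  do.call(rbind, lapply(ligands, function(l) data.frame(
    chain = paste0(l@pdbId, "_", l@chainId), drug = l@compId,
    stringsAsFactors = FALSE)))
}

.runPipelineCore <- function(bundle, thresholds, outDir, verbose) {
  t0 <- Sys.time()
  records <- bundle$records
  nRaw <- nrow(records)
  .msg(verbose, "stage 1: scoring ", nRaw, " alignment records")
  scored <- scoreAlignments(records, bundle$ligands, thresholds)

  .msg(verbose, "stage 2: clustering targets at ",
       thresholds@identityCluster, "% identity")
  drugsAll <- sort(unique(bundle$drugLinks$drug))
  clustersList <- lapply(drugsAll, function(d) {
    chains <- sort(unique(bundle$drugLinks$chain[bundle$drugLinks$drug == d]))
    cl <- clusterTargets(bundle$sequences[chains],
                         identityCut = thresholds@identityCluster)
    cl$drug <- d
    cl$cluster_id <- paste0(d, ".", cl$cluster_id)
    cl
  })
  clusters <- do.call(rbind, clustersList)
  degrees <- data.frame(
    drug = drugsAll,
    degree = vapply(clustersList, function(cl)
      length(unique(cl$cluster_id)), integer(1)),
    stringsAsFactors = FALSE)

  # collapse member records to non-redundant target pairs
  repOf <- setNames(clusters$representative, clusters$member)
  chA <- paste0(scored$pdb_a, "_", scored$chain_a)
  chB <- paste0(scored$pdb_b, "_", scored$chain_b)
  repA <- repOf[chA]; repB <- repOf[chB]
  lost <- which(is.na(repA) | is.na(repB))
  if (length(lost))
    stop("stage 2: records reference unclustered chains, e.g. row ",
         lost[1])
  pairKey <- paste(scored$drug, pmin(repA, repB), pmax(repA, repB))
  keyOrder <- !duplicated(pairKey)
  pairVerdicts <- data.frame(
    drug = scored$drug[keyOrder],
    rep_a = pmin(repA, repB)[keyOrder],
    rep_b = pmax(repA, repB)[keyOrder],
    n_member_records = as.integer(table(pairKey)[pairKey[keyOrder]]),
    similar = as.logical(tapply(scored$similar, pairKey,
                                any)[pairKey[keyOrder]]),
    min_score = as.numeric(tapply(scored$score, pairKey,
                                  min)[pairKey[keyOrder]]),
    stringsAsFactors = FALSE)
  if ("tm_score" %in% names(scored))
    pairVerdicts$tm_score <- as.numeric(
      tapply(scored$tm_score, pairKey, max)[pairKey[keyOrder]])
  pairVerdicts$identity_pct <- vapply(seq_len(nrow(pairVerdicts)),
    function(i) percentIdentity(bundle$sequences[pairVerdicts$rep_a[i]],
                                bundle$sequences[pairVerdicts$rep_b[i]]),
    numeric(1))
  nNonRed <- nrow(pairVerdicts)
  nSimilar <- sum(pairVerdicts$similar)

  .msg(verbose, "stage 3: clustering conformers (cut ",
       thresholds@conformerCut, " A)")
  promDrugs <- degrees$drug[degrees$degree >=
                              thresholds@promiscuityMinTargets]
  ligByDrug <- split(bundle$ligands,
                     vapply(bundle$ligands, function(l) l@compId,
                            character(1)))
  confList <- lapply(promDrugs, function(d) {
    inst <- ligByDrug[[d]]
    if (is.null(inst)) return(NULL)
    clusterConformers(inst, cut = thresholds@conformerCut)
  })
  names(confList) <- promDrugs
  confList <- confList[!vapply(confList, is.null, logical(1))]
  conformerTable <- conformerStats(confList)
  names(conformerTable)[names(conformerTable) == "conformer_clusters"] <-
    "conformer_clusters"

  pfamCounts <- NULL
  if (!is.null(bundle$pfam)) {
    famOf <- setNames(bundle$pfam$family, bundle$pfam$chain)
    pfamCounts <- data.frame(
      drug = drugsAll,
      families = vapply(drugsAll, function(d) {
        chains <- bundle$drugLinks$chain[bundle$drugLinks$drug == d]
        length(unique(na.omit(famOf[chains])))
      }, integer(1)), stringsAsFactors = FALSE)
  }

  table <- buildPromiscuityTable(degrees, pairVerdicts, conformerTable,
                                 bundle$descriptors, pfamCounts,
                                 thresholds)
  correlations <- analyzeCorrelations(table)
  # suppressed warnings: lm warns on essentially perfect fits, which
  # legitimately occur in planted cohorts
  regression <- tryCatch(suppressWarnings(regressCombined(table)),
                         error = function(e)
                           list(error = conditionMessage(e)))

  # distribution comparisons: promiscuous drugs vs the full drug set
  ks <- list()
  isProm <- bundle$descriptors$drug %in% table$drug
  if (sum(isProm) >= 3 && sum(!isProm) >= 3) {
    for (prop in c("mw", "logp", "rotatable_rel")) {
      ks[[prop]] <- ksCompare(bundle$descriptors[[prop]][isProm],
                              bundle$descriptors[[prop]])
    }
  }

  simIdent <- pairVerdicts[pairVerdicts$similar, c("drug", "identity_pct")]
  summary <- summarizeDrugs(table, pairIdentities = simIdent)

  stageCounts <- list(
    rawRecords = nRaw, nonRedundantPairs = nNonRed,
    similarPairs = nSimilar,
    clusterStageFraction = if (nRaw) nNonRed / nRaw else NA_real_,
    removedByScoreFraction = if (nNonRed) 1 - nSimilar / nNonRed
                             else NA_real_,
    nDrugs = length(drugsAll), nPromiscuous = nrow(table))

  manifest <- list(
    package = "LigandRMSD",
    version = as.character(packageVersion("LigandRMSD")),
    schema = "1",
    seed = bundle$seed,
    thresholds = list(
      ligand_rmsd_max = thresholds@ligandRmsdMax,
      conformer_cut = thresholds@conformerCut,
      identity_cluster = thresholds@identityCluster,
      tm_similar = thresholds@tmSimilar,
      promiscuity_min_targets = thresholds@promiscuityMinTargets),
    stageCounts = stageCounts)

  out <- list(scored = scored, clusters = clusters, degrees = degrees,
              pairVerdicts = pairVerdicts, conformers = conformerTable,
              table = table, correlations = correlations, ksTests = ks,
              regression = regression, summary = summary,
              stageCounts = stageCounts, manifest = manifest)
  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  .msg(verbose, sprintf("pipeline done in %.1f s",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

.writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    for (cn in names(df)[num]) df[[cn]] <- formatC(df[[cn]], digits = 10,
                                                   format = "g")
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  sc <- out$scored
  sc$transform <- NULL
  wt(sc, "scored_pairs.tsv")
  wt(out$clusters, "target_clusters.tsv")
  wt(out$pairVerdicts, "nonredundant_pairs.tsv")
  wt(out$conformers, "conformer_clusters.tsv")
  wt(out$table, "promiscuity_table.tsv")
  corDf <- do.call(rbind, lapply(names(out$correlations), function(nm) {
    cr <- out$correlations[[nm]]
    data.frame(panel = nm, r = cr@r, p_value = cr@pValue, n = cr@n,
               y_transform = cr@yTransform, stringsAsFactors = FALSE)
  }))
  if (!is.null(corDf)) wt(corDf, "correlations.tsv")
  ksDf <- do.call(rbind, lapply(names(out$ksTests), function(nm) {
    k <- out$ksTests[[nm]]
    data.frame(property = nm, D = k$D, p_value = k$pValue, n_a = k$nA,
               n_b = k$nB, stringsAsFactors = FALSE)
  }))
  if (!is.null(ksDf)) wt(ksDf, "ks_tests.tsv")
  jsonlite::write_json(
    list(summary = list(
           fractionWithSimilar = out$summary$fractionWithSimilar,
           fractionAllSimilar = out$summary$fractionAllSimilar,
           degreeHistogram = as.list(out$summary$degreeHistogram)),
         regression = out$regression,
         stageCounts = out$stageCounts),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Scatter panels of the promiscuity correlations (SVG)
#'
#' Presentation-only convenience plot: one panel per studied property
#' against the target count, with per-degree means overlaid.
#'
#' @param table promiscuity table from [buildPromiscuityTable()].
#' @param file output SVG path.
#' @return the file path, invisibly.
#' @export
plotCorrelationPanels <- function(table, file) {
  panels <- list(mw = "Molecular weight [g/mol]", logp = "logP",
                 conformer_cluster_count = "Conformer clusters",
                 pfam_family_count = "Pfam families",
                 structural_similar_pair_count =
                   "sqrt(structurally similar pairs)",
                 similar_pair_count = "sqrt(similar site pairs)")
  panels <- panels[names(panels) %in% names(table)]
  svg(file, width = 9, height = 6)
  on.exit(dev.off())
  par(mfrow = c(2, 3), mar = c(4, 4, 1, 1))
  for (nm in names(panels)) {
    y <- table[[nm]]
    if (grepl("pair_count", nm)) y <- sqrt(y)
    plot(table$target_count, y, xlab = "Targets", ylab = panels[[nm]],
         pch = 19, col = "#00000055")
    mx <- tapply(y, table$target_count, mean, na.rm = TRUE)
    points(as.numeric(names(mx)), mx, col = "darkgreen", pch = 19)
  }
  invisible(file)
}
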