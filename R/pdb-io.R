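# PDB-format reading and writing: protein chains, ligand instances,
# CONECT records, the altloc occupancy rule and the ligand blacklist.

.substrTrim <- function(x, a, b) trimws(substr(x, a, b))

.parseNum <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(v) & nzchar(trimws(s)))
  bad2 <- which(!nzchar(trimws(s)))
  if (length(bad) || length(bad2))
    stop(sprintf("malformed %s field at line %d", what,
                 lineno[c(bad, bad2)][1]))
  v
}

.elementFromName <- function(name) {
  # fallback when element columns 77-78 are blank
  alpha <- gsub("[^A-Za-z]", "", name)
  toupper(substr(alpha, 1, 1))
}

# Resolve alternate locations within one residue: per atom name keep the
# highest occupancy; ties prefer altloc 'A', then blank, then lexicographic.
.resolveAltlocs <- function(at) {
  if (all(!nzchar(at$altloc)) || !anyDuplicated(at$name)) return(at)
  keep <- unlist(lapply(split(seq_len(nrow(at)), at$name), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- at[idx, ]
    pri <- match(sub$altloc, c("A", ""), nomatch = 3L)
    idx[order(-sub$occupancy, pri, sub$altloc)[1L]]
  }))
  at[sort(keep), , drop = FALSE]
}

#' Parse PDB-format text
#'
#' Reads ATOM, HETATM, TER and CONECT records.  Every non-water HETATM
#' residue that is not a covalently linked modified residue of a polymer
#' chain yields one [LigandInstance-class] (multiple copies of the same
#' component are separate instances).  Hydrogens are dropped everywhere;
#' alternate locations are resolved to the highest-occupancy copy (ties:
#' altloc 'A', then blank).
#'
#' @param pdbText a single string or a character vector of lines.
#' @param inferLigandBonds infer each ligand's bonds (CONECT first, distance
#'   fallback); default TRUE.
#' @return A list with elements `chains` (list of [ProteinChain-class]),
#'   `ligands` (list of [LigandInstance-class]) and `conect` (named list
#'   mapping atom serial to bonded serials).
#' @examples
#' pair <- makeComplexPair(seed = 1)
#' str(parseStructure(pair$pdbA), max.level = 1)
#' @export
parseStructure <- function(pdbText, inferLigandBonds = TRUE) {
  lines <- if (length(pdbText) == 1L && grepl("\n", pdbText, fixed = TRUE))
    strsplit(pdbText, "\n", fixed = TRUE)[[1]] else pdbText
  rec <- substr(lines, 1, 6)
  isAtom <- rec == "ATOM  "
  isHet <- rec == "HETATM"
  if (!any(isAtom | isHet)) stop("no ATOM or HETATM records in input")

  idx <- which(isAtom | isHet)
  ln <- lines[idx]
  at <- data.frame(
    record = trimws(rec[idx]),
    serial = as.integer(.parseNum(substr(ln, 7, 11), idx, "serial")),
    name = .substrTrim(ln, 13, 16),
    altloc = .substrTrim(ln, 17, 17),
    resname = .substrTrim(ln, 18, 20),
    chain = .substrTrim(ln, 22, 22),
    resno = as.integer(.parseNum(substr(ln, 23, 26), idx, "residue number")),
    icode = .substrTrim(ln, 27, 27),
    x = .parseNum(substr(ln, 31, 38), idx, "coordinate"),
    y = .parseNum(substr(ln, 39, 46), idx, "coordinate"),
    z = .parseNum(substr(ln, 47, 54), idx, "coordinate"),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
      o[is.na(o)] <- 1.0
      o
    },
    element = .substrTrim(ln, 77, 78),
    stringsAsFactors = FALSE
  )
  noel <- !nzchar(at$element)
  at$element[noel] <- .elementFromName(at$name[noel])
  at$element <- toupper(at$element)
  at <- at[!.isHydrogen(at$element), , drop = FALSE]

  # CONECT map: serial -> bonded serials
  conect <- list()
  for (l in lines[rec == "CONECT"]) {
    flds <- suppressWarnings(as.integer(
      substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2L) {
      key <- as.character(flds[1L])
      conect[[key]] <- sort(unique(c(conect[[key]], flds[-1L])))
    }
  }

  # polymer chains from ATOM records
  poly <- at[at$record == "ATOM", , drop = FALSE]
  chains <- list()
  for (cid in unique(poly$chain)) {
    ca <- poly[poly$chain == cid, , drop = FALSE]
    if (any(nzchar(ca$altloc))) {   # slow path only when altlocs exist
      ca <- do.call(rbind, lapply(
        split(ca, paste(ca$resno, ca$icode, ca$resname)), .resolveAltlocs))
      ca <- ca[order(match(ca$serial, at$serial)), , drop = FALSE]
    }
    resOrder <- !duplicated(paste(ca$resno, ca$icode))
    resnames <- ca$resname[resOrder]
    seq1 <- paste(.AA3TO1[resnames[resnames %in% names(.AA3TO1)]],
                  collapse = "")
    chains[[cid]] <- new("ProteinChain", chainId = cid,
      atoms = ca[, c("serial", "name", "element", "resname", "resno",
                     "icode", "x", "y", "z", "occupancy", "altloc")],
      sequence = seq1)
  }

  # ligand instances from HETATM residues
  het <- at[at$record == "HETATM" & !(at$resname %in% .WATER_RESNAMES), ,
            drop = FALSE]
  ligands <- list()
  if (nrow(het)) {
    key <- paste(het$chain, het$resno, het$icode, het$resname, sep = "|")
    for (k in unique(key)) {
      la <- .resolveAltlocs(het[key == k, , drop = FALSE])
      cid <- la$chain[1L]
      # modified polymer residue: shares the chain's residue numbering range
      # and sits at covalent distance of the polymer -> not a ligand
      if (cid %in% names(chains)) {
        ch <- chains[[cid]]
        rng <- range(ch@atoms$resno)
        if (la$resno[1L] >= rng[1L] && la$resno[1L] <= rng[2L]) {
          d2 <- .minCrossDist2(as.matrix(la[, c("x", "y", "z")]),
                               coords(ch))
          if (sqrt(d2) <= 2.0) next
        }
      }
      lig <- LigandInstance(
        pdbId = "", compId = la$resname[1L], chainId = cid,
        resno = la$resno[1L],
        atoms = la[, c("serial", "name", "element", "x", "y", "z",
                       "occupancy", "altloc")])
      if (inferLigandBonds) lig@bonds <- inferBonds(lig, conect)
      ligands[[length(ligands) + 1L]] <- lig
    }
  }
  list(chains = chains, ligands = ligands, conect = conect)
}

.minCrossDist2 <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    best <- min(best, min(d2))
  }
  best
}

#' Read and parse a PDB file
#'
#' @param path path to a PDB-format file.
#' @param pdbId structure identifier stamped onto the extracted ligands;
#'   defaults to the file base name.
#' @inheritParams parseStructure
#' @return See [parseStructure()].
#' @export
readStructure <- function(path, pdbId = sub("\\.(pdb|ent)$", "",
                                            basename(path)),
                          inferLigandBonds = TRUE) {
  parsed <- parseStructure(readLines(path, warn = FALSE), inferLigandBonds)
  parsed$ligands <- lapply(parsed$ligands, function(l) { l@pdbId <- pdbId; l })
  parsed
}

#' Infer the bond list of a ligand
#'
#' CONECT records win when they provide at least one intra-ligand bond;
#' otherwise a bond is created between every atom pair whose distance is at
#' most the sum of covalent radii plus 0.45 Angstrom.  Self-bonds never
#' occur; isolated atoms are allowed.
#'
#' @param ligand a [LigandInstance-class].
#' @param conect named list mapping atom serial to bonded serials (as
#'   returned by [parseStructure()]); may be empty.
#' @return two-column integer matrix of atom-index pairs (i < j), sorted.
#' @export
inferBonds <- function(ligand, conect = list()) {
  at <- ligand@atoms
  n <- nrow(at)
  if (n < 1L) stop("ligand has no atoms")
  serials <- at$serial
  pairs <- matrix(integer(), ncol = 2)
  if (length(conect)) {
    hits <- intersect(as.character(serials), names(conect))
    if (length(hits)) {
      from <- match(as.integer(hits), serials)
      bl <- lapply(seq_along(hits), function(i) {
        to <- match(conect[[hits[i]]], serials)
        to <- to[!is.na(to)]
        if (length(to)) cbind(from[i], to) else NULL
      })
      pairs <- do.call(rbind, c(bl, list(matrix(integer(), ncol = 2))))
    }
  }
  if (nrow(pairs) == 0L && n > 1L) {
    xyz <- coords(ligand)
    r <- .covalentRadius(elements(ligand))
    cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                       xyz[cand[, 2], , drop = FALSE])^2))
    cut <- r[cand[, 1]] + r[cand[, 2]] + .BOND_TOLERANCE
    pairs <- cand[d <= cut, , drop = FALSE]
  }
  if (nrow(pairs)) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  matrix(as.integer(pairs), ncol = 2)
}

#' Is a ligand blacklisted?
#'
#' A ligand is excluded from analysis when it has at most
#' `config@maxHeavyAtoms` heavy atoms (small compound) or its component
#' identifier is on the excluded list (cofactors, detergents, solutes).
#'
#' @param ligand a [LigandInstance-class].
#' @param config a [BlacklistConfig-class].
#' @return logical.
#' @export
isBlacklisted <- function(ligand, config = defaultBlacklist()) {
  nAtoms(ligand) <= config@maxHeavyAtoms ||
    toupper(ligand@compId) %in% config@excludedCompIds
}

#' Default blacklist configuration
#'
#' Loads the excluded-component list shipped in
#' `inst/extdata/blacklist.tsv` (an editable approximation of the usual
#' crystallisation additives, buffers and cofactors) with the 5-heavy-atom
#' small-compound rule.
#'
#' @param path optional path to an alternative TSV with a `comp_id` column.
#' @param maxHeavyAtoms heavy-atom cut-off, default 5.
#' @return A [BlacklistConfig-class].
#' @export
defaultBlacklist <- function(path = system.file("extdata", "blacklist.tsv",
                                                package = "LigandRMSD"),
                             maxHeavyAtoms = 5L) {
  ids <- character()
  if (nzchar(path) && file.exists(path)) {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    ids <- tab$comp_id
  }
  BlacklistConfig(maxHeavyAtoms, ids)
}

#' Ligand inventory of parsed structures
#'
#' @param parsedList list of [parseStructure()]/[readStructure()] results.
#' @param config a [BlacklistConfig-class].
#' @return data.frame with columns pdb_id, chem_comp_id, chain_id,
#'   residue_number, n_heavy_atoms, blacklisted.
#' @export
ligandInventory <- function(parsedList, config = defaultBlacklist()) {
  rows <- lapply(parsedList, function(p) {
    do.call(rbind, lapply(p$ligands, function(l) data.frame(
      pdb_id = l@pdbId, chem_comp_id = l@compId, chain_id = l@chainId,
      residue_number = l@resno, n_heavy_atoms = nAtoms(l),
      blacklisted = isBlacklisted(l, config), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pdb_id = character(), chem_comp_id = character(),
                      chain_id = character(), residue_number = integer(),
                      n_heavy_atoms = integer(), blacklisted = logical())
  rownames(out) <- NULL
  out
}

#' The chain in contact with a ligand
#'
#' The target chain of a structure is defined as the chain with the most
#' heavy atoms within `radius` Angstrom of the ligand.
#'
#' @param chains list of [ProteinChain-class] objects.
#' @param ligand a [LigandInstance-class].
#' @param radius contact radius in Angstrom (default 5).
#' @return The chain identifier, or NA when no chain has a contact.
#' @export
targetChain <- function(chains, ligand, radius = 5.0) {
  lx <- coords(ligand)
  counts <- vapply(chains, function(ch) {
    cx <- coords(ch)
    n <- 0L
    for (i in seq_len(nrow(cx))) {
      d2 <- min((lx[, 1] - cx[i, 1])^2 + (lx[, 2] - cx[i, 2])^2 +
                  (lx[, 3] - cx[i, 3])^2)
      if (d2 <= radius^2) n <- n + 1L
    }
    n
  }, integer(1))
  if (!length(counts) || max(counts) == 0L) return(NA_character_)
  ids <- vapply(chains, function(ch) ch@chainId, character(1))
  ids[order(-counts, ids)][1L]
}

# ---- writing -----------------------------------------------------------

.pdbAtomLine <- function(record, serial, name, resname, chain, resno,
                         x, y, z, occupancy = 1.0, element = "") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, nm, resname, chain, resno %% 10000L,
          x, y, z, occupancy, 0, toupper(element))
}

#' Write a ligand back to PDB-format text
#'
#' Emits HETATM records (with element columns) and CONECT records for the
#' ligand's bonds.  Re-parsing the output yields identical atom names,
#' elements and coordinates to three decimals.
#'
#' @param ligand a [LigandInstance-class].
#' @param file optional path; when given the text is also written there.
#' @return character vector of PDB lines, invisibly when `file` is set.
#' @export
writeLigandPDB <- function(ligand, file = NULL) {
  at <- ligand@atoms
  lines <- vapply(seq_len(nrow(at)), function(i) {
    .pdbAtomLine("HETATM", at$serial[i], at$name[i], ligand@compId,
                 ligand@chainId, ligand@resno, at$x[i], at$y[i], at$z[i],
                 at$occupancy[i], at$element[i])
  }, character(1))
  if (nrow(ligand@bonds)) {
    adj <- split(c(at$serial[ligand@bonds[, 2]], at$serial[ligand@bonds[, 1]]),
                 c(at$serial[ligand@bonds[, 1]], at$serial[ligand@bonds[, 2]]))
    cl <- vapply(names(adj), function(s) {
      paste0("CONECT", sprintf("%5d", as.integer(s)),
             paste(sprintf("%5d", sort(unique(adj[[s]]))), collapse = ""))
    }, character(1))
    lines <- c(lines, cl[order(as.integer(names(adj)))])
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
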