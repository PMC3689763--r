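# PDB parsing, altloc resolution, bond inference and blacklist rules.

makeMiniPDB <- function() {
  lig <- ligandTemplate("benzamidine", pdbId = "MINI", resno = 20L)
  chain <- vapply(1:10, function(i) {
    LigandRMSD:::.pdbAtomLine("ATOM", i, "CA", "ALA", "A", i,
                              i * 3.8, 0, 0, 1.0, "C")
  }, character(1))
  c(chain, "TER", writeLigandPDB(lig))
}

test_that("a chain plus a het residue parse into one chain and one ligand", {
  p <- parseStructure(makeMiniPDB())
  expect_length(p$chains, 1)
  expect_length(p$ligands, 1)
  expect_equal(nAtoms(p$ligands[[1]]), 9)
  expect_equal(p$chains[["A"]]@sequence, strrep("A", 10))
  # CONECT records were honoured
  expect_equal(nrow(p$ligands[[1]]@bonds), 9)
})

test_that("water never yields a ligand and empty input errors", {
  water <- vapply(1:3, function(i) {
    LigandRMSD:::.pdbAtomLine("HETATM", i, "O", "HOH", "A", 100 + i,
                              i * 5, 0, 0, 1.0, "O")
  }, character(1))
  p <- parseStructure(water)
  expect_length(p$ligands, 0)
  expect_error(parseStructure("REMARK nothing here"), "no ATOM")
})

test_that("altloc resolution keeps the highest occupancy, ties prefer A", {
  l1 <- "HETATM    1  C1  LIG A 401      10.000  10.000  10.000  0.60      C"
  l2 <- "HETATM    2  C1  LIG A 401      20.000  20.000  20.000  0.40      C"
  l3 <- "HETATM    3  C2  LIG A 401      11.500  10.000  10.000  1.00      C"
  lines <- c(l1, l2, l3)
  substr(lines[1], 17, 17) <- "A"
  substr(lines[2], 17, 17) <- "B"
  lig <- parseStructure(lines)$ligands[[1]]
  expect_equal(nAtoms(lig), 2)
  expect_equal(lig@atoms$x[lig@atoms$name == "C1"], 10.0)
  # equal occupancy: altloc A wins
  substr(lines[2], 55, 60) <- "  0.60"
  lig2 <- parseStructure(lines)$ligands[[1]]
  expect_equal(lig2@atoms$x[lig2@atoms$name == "C1"], 10.0)
})

test_that("malformed coordinates raise an error naming the line", {
  bad <- makeMiniPDB()
  substr(bad[3], 31, 38) <- "   xx.xx"
  expect_error(parseStructure(bad), "line 3")
})

test_that("bond inference: covalent distances, CONECT dedup, no self bonds", {
  at <- data.frame(serial = 1:2, name = c("C1", "C2"),
                   element = "C", x = c(0, 1.52), y = 0, z = 0,
                   occupancy = 1, altloc = "")
  lig <- LigandInstance("T", "LIG", "A", 1L, at)
  expect_equal(nrow(inferBonds(lig)), 1)
  at$x[2] <- 3.0
  lig2 <- LigandInstance("T", "LIG", "A", 1L, at)
  expect_equal(nrow(inferBonds(lig2)), 0)
  # CONECT listing (1,2) twice and (2,1): exactly one bond
  conect <- list(`1` = c(2L, 2L), `2` = 1L)
  expect_equal(nrow(inferBonds(lig2, conect)), 1)
})

test_that("round trip preserves names, elements and coordinates to 3 dp", {
  set.seed(42)
  lig <- randomLigand(8)
  lig2 <- parseStructure(writeLigandPDB(lig))$ligands[[1]]
  expect_identical(lig2@atoms$name, lig@atoms$name)
  expect_identical(elements(lig2), elements(lig))
  expect_true(max(abs(coords(lig2) - coords(lig))) < 5e-4)
})

test_that("no hydrogen survives parsing", {
  lines <- c(
    "HETATM    1  C1  LIG A 401      10.000  10.000  10.000  1.00      C",
    "HETATM    2  H1  LIG A 401      11.000  10.000  10.000  1.00      H",
    "HETATM    3  O1  LIG A 401      12.400  10.000  10.000  1.00      O")
  lig <- parseStructure(lines)$ligands[[1]]
  expect_equal(nAtoms(lig), 2)
  expect_false(any(elements(lig) == "H"))
  expect_error(validObject(
    LigandInstance("T", "L", "A", 1L,
                   data.frame(serial = 1, name = "H1", element = "H",
                              x = 0, y = 0, z = 0, occupancy = 1,
                              altloc = ""))),
    "hydrogens")
})

test_that("blacklist: heavy-atom cut-off is inclusive, exclusions apply, monotone", {
  at5 <- data.frame(serial = 1:5, name = paste0("C", 1:5), element = "C",
                    x = seq(0, 6, length.out = 5), y = 0, z = 0,
                    occupancy = 1, altloc = "")
  small <- LigandInstance("T", "ABC", "A", 1L, at5)
  cfg0 <- BlacklistConfig(5L, character())
  expect_true(isBlacklisted(small, cfg0))
  at6 <- rbind(at5, data.frame(serial = 6, name = "C6", element = "C",
                               x = 9, y = 0, z = 0, occupancy = 1,
                               altloc = ""))
  six <- LigandInstance("T", "ABC", "A", 1L, at6)
  expect_false(isBlacklisted(six, cfg0))
  ben <- ligandTemplate("benzamidine")
  expect_false(isBlacklisted(ben, BlacklistConfig(5L, c("GOL", "EDO"))))
  expect_true(isBlacklisted(ben, BlacklistConfig(5L, c("GOL", "BEN"))))
  # monotone: enlarging the exclusion set never un-blacklists
  sets <- list(character(), "GOL", c("GOL", "EDO"), c("GOL", "EDO", "BEN"))
  surv <- vapply(sets, function(s)
    !isBlacklisted(ben, BlacklistConfig(5L, s)), logical(1))
  expect_true(all(diff(as.integer(surv)) <= 0))
})

test_that("a covalently linked het residue inside a chain is not a ligand", {
  chain <- vapply(1:10, function(i) {
    LigandRMSD:::.pdbAtomLine("ATOM", i, "CA", "ALA", "A", i,
                              i * 3.8, 0, 0, 1.0, "C")
  }, character(1))
  # modified residue at position 5, touching the chain (1.4 A away)
  mod <- LigandRMSD:::.pdbAtomLine("HETATM", 50, "C1", "MSE", "A", 5,
                                   5 * 3.8 + 1.4, 0, 0, 1.0, "C")
  # plus a genuine ligand far away with residue number outside the range
  far <- LigandRMSD:::.pdbAtomLine("HETATM", 60, "C1", "LIG", "A", 200,
                                   50, 50, 50, 1.0, "C")
  far2 <- LigandRMSD:::.pdbAtomLine("HETATM", 61, "C2", "LIG", "A", 200,
                                    51.5, 50, 50, 1.0, "C")
  p <- parseStructure(c(chain, "TER", mod, far, far2))
  expect_length(p$ligands, 1)
  expect_equal(p$ligands[[1]]@compId, "LIG")
})

test_that("ligand inventory lists every copy separately", {
  lig1 <- ligandTemplate("benzamidine", pdbId = "AB12", resno = 301L)
  lig2 <- ligandTemplate("benzamidine", pdbId = "AB12", chainId = "B",
                         resno = 302L)
  txt <- c(writeLigandPDB(lig1)[1:9], writeLigandPDB(lig2)[1:9])
  p <- parseStructure(txt)
  expect_length(p$ligands, 2)
  inv <- ligandInventory(list(p))
  expect_equal(nrow(inv), 2)
  expect_true(all(inv$n_heavy_atoms == 9))
  expect_true(all(!inv$blacklisted))
})

test_that("parsed coordinates agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  pair <- makeComplexPair(seed = 5)
  f <- tempfile(fileext = ".pdb")
  writeLines(pair$pdbA, f)
  mine <- parseStructure(pair$pdbA)
  ref <- bio3d::read.pdb(f, verbose = FALSE)
  refXyz <- matrix(ref$xyz, ncol = 3, byrow = TRUE)
  het <- ref$atom$type == "HETATM"
  expect_equal(unname(coords(mine$ligands[[1]])),
               unname(refXyz[het, , drop = FALSE]), tolerance = 1e-6)
})
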