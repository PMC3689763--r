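# Molecular graphs, descriptors and atom mapping.

test_that("graph construction: rings, chains, disconnected fragments", {
  benzene <- buildGraph(ligandTemplate("benzene"))
  expect_equal(length(benzene@elements), 6)
  expect_equal(nrow(benzene@edges), 6)
  expect_true(all(benzene@ringEdge))
  butane <- buildGraph(ligandTemplate("butane"))
  expect_equal(nrow(butane@edges), 3)
  expect_false(any(butane@ringEdge))
  # two disconnected fragments are allowed
  frag <- buildGraph(list(elements = c("C", "C", "O", "O"),
                          bonds = rbind(c(1, 2), c(3, 4))))
  expect_equal(igraph::components(frag@graph)$no, 2)
})

test_that("rotatable bonds: terminal and ring bonds never count", {
  but <- rotatableBonds(buildGraph(ligandTemplate("butane")))
  expect_equal(but$absolute, 1)           # only the central bond
  expect_equal(but$relative, 1 / 3)
  ben <- rotatableBonds(buildGraph(ligandTemplate("benzene")))
  expect_equal(ben$absolute, 0)           # ring bonds are not rotatable
  bip <- rotatableBonds(buildGraph(ligandTemplate("biphenyl")))
  expect_equal(bip$absolute, 1)           # the ring-joining bond
  # adding a ring edge never increases the absolute count
  set.seed(31)
  for (i in 1:20) {
    spec <- randomGraphSpec(7, extraEdges = 0)
    before <- rotatableBonds(specToGraph(spec))$absolute
    extra <- sort(sample.int(7, 2))
    spec2 <- spec
    spec2$edges <- unique(rbind(spec$edges, extra))
    after <- rotatableBonds(specToGraph(spec2))$absolute
    expect_lte(after, before)
    expect_true(rotatableBonds(specToGraph(spec2))$relative >= 0)
    expect_true(rotatableBonds(specToGraph(spec2))$relative <= 1)
  }
})

test_that("molecular weight: atoms, formula override, unknown elements", {
  carbon <- LigandInstance("T", "LIG", "A", 1L,
    data.frame(serial = 1, name = "C1", element = "C", x = 0, y = 0,
               z = 0, occupancy = 1, altloc = ""))
  expect_equal(molecularWeight(carbon), 12.011)
  expect_equal(molecularWeight(carbon, "C7H8N2"), 120.15, tolerance = 1e-4)
  expect_equal(molecularWeight(carbon, c(C = 7, H = 8, N = 2)), 120.155,
               tolerance = 1e-9)
  expect_equal(molecularWeight(carbon, character(0)), 12.011) # empty override
  expect_error(molecularWeight(carbon, "Qq3"), "unknown element")
})

test_that("identical ligands map by atom name at full size", {
  lig <- ligandTemplate("benzamidine")
  m <- matchAtoms(lig, lig)
  expect_equal(m@source, "name-match")
  expect_equal(nrow(m@pairs), nAtoms(lig))
  expect_equal(m@pairs[, 1], m@pairs[, 2])
})

test_that("ring relabeling is fixed by the RMSD-minimising isomorphism", {
  lig <- ligandTemplate("benzamidine")
  # rotate atom order of the ring: same graph, different labels
  perm <- c(2:6, 1, 7:9)
  at <- lig@atoms[perm, ]
  at$serial <- seq_len(nrow(at))
  bmap <- match(seq_len(9), perm)
  bonds <- cbind(bmap[lig@bonds[, 1]], bmap[lig@bonds[, 2]])
  lig2 <- LigandInstance("T2", "BEN", "A", 1L, at, bonds)
  lig2@atoms$name <- paste0("Q", 1:9)     # force the isomorphism tier
  m <- matchAtoms(lig, lig2)
  expect_equal(m@source, "isomorphism")
  expect_equal(nrow(m@pairs), 9)
  # the selected mapping must reach the true optimum over all isomorphisms
  best <- kabsch(coords(lig), coords(lig2), m@pairs)@rmsd
  expect_lt(best, 1e-9)
})

test_that("MCS of a ring vs ring-plus-tail covers the ring", {
  benzene <- buildGraph(ligandTemplate("benzene"))
  tailed <- buildGraph(ligandTemplate("ring-tail"))
  mm <- mcsMappings(benzene, tailed)
  expect_equal(nrow(mm[[1]]), 6)
  # oracle agreement on this instance
  expect_equal(nrow(mm[[1]]),
               bfMcsSize(benzene@adjacency, benzene@elements,
                         tailed@adjacency, tailed@elements))
})

test_that("MCS size equals exhaustive enumeration on random graph pairs", {
  set.seed(77)
  for (i in 1:60) {
    sA <- randomGraphSpec(sample(3:8, 1), extraEdges = sample(0:2, 1))
    sB <- randomGraphSpec(sample(3:8, 1), extraEdges = sample(0:2, 1))
    gA <- specToGraph(sA); gB <- specToGraph(sB)
    mm <- mcsMappings(gA, gB)
    got <- if (length(mm)) nrow(mm[[1]]) else 0L
    expect_equal(got, bfMcsSize(sA$adj, sA$elements, sB$adj, sB$elements),
                 info = paste("pair", i))
    # symmetry of the MCS size
    mm2 <- mcsMappings(gB, gA)
    got2 <- if (length(mm2)) nrow(mm2[[1]]) else 0L
    expect_equal(got, got2)
    expect_lte(got, min(length(sA$elements), length(sB$elements)))
  }
})

test_that("unmappable pairs are rejected", {
  # no common element
  o2 <- LigandInstance("T", "OXY", "A", 1L,
    data.frame(serial = 1:2, name = c("O1", "O2"), element = "O",
               x = c(0, 1.2), y = 0, z = 0, occupancy = 1, altloc = ""),
    rbind(c(1, 2)))
  lig <- ligandTemplate("butane")
  expect_error(matchAtoms(lig, o2), "unmappable")
  # common subgraph below 3 atoms
  co <- LigandInstance("T", "CO1", "A", 1L,
    data.frame(serial = 1:2, name = c("C1", "O1"),
               element = c("C", "O"), x = c(0, 1.2), y = 0, z = 0,
               occupancy = 1, altloc = ""), rbind(c(1, 2)))
  expect_error(matchAtoms(lig, co), "unmappable")
})
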