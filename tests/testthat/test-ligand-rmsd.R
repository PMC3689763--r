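# The LigandRMSD score and its defining properties.

test_that("an exact rigid copy with the true transform scores zero", {
  lig <- ligandTemplate("benzamidine")
  tr <- RigidTransform(LigandRMSD:::.rotationMatrix(c(0, 0, 1), 0.9),
                       c(4, -2, 7))
  ligB <- LigandRMSD:::.withCoords(lig, applyTransform(invertTransform(tr),
                                                       coords(lig)))
  r <- ligandRMSD(lig, ligB, tr)
  expect_lt(r@rmsdAligned, 1e-9)
  expect_lt(r@rmsdOptimal, 1e-9)
  expect_lt(abs(r@score), 1e-9)
  expect_true(r@similar)
})

test_that("composing the optimum with a translation adds exactly its length", {
  lig <- ligandTemplate("ring-tail")
  set.seed(21)
  ligB <- LigandRMSD:::.withCoords(
    lig, applyTransform(RigidTransform(LigandRMSD:::.randomRotation(),
                                       runif(3, -10, 10)), coords(lig)))
  opt <- kabsch(coords(lig), coords(ligB), matchAtoms(lig, ligB)@pairs)
  for (d in c(2.0, 3.5)) {
    tr <- RigidTransform(opt@transform@rotation,
                         opt@transform@translation + d * c(1, 0, 0))
    r <- ligandRMSD(lig, ligB, tr)
    expect_equal(r@score, d, tolerance = 1e-6)
    expect_equal(r@similar, d <= 3)
  }
})

test_that("the score ignores conformational differences", {
  set.seed(22)
  for (tpl in c("benzamidine", "ring-tail", "chain8")) {
    lig <- ligandTemplate(tpl)
    pert <- torsionPerturbed(lig, angle = runif(1, 40, 120))
    m <- matchAtoms(lig, pert)
    opt <- kabsch(coords(lig), coords(pert), m@pairs)
    r <- ligandRMSD(lig, pert, opt@transform)
    expect_gt(r@rmsdOptimal, 0.05)   # the conformers really differ
    expect_lt(abs(r@score), 1e-6)    # yet the score is zero
  }
})

test_that("score is never meaningfully negative over random draws", {
  set.seed(23)
  worst <- Inf
  for (i in 1:200) {
    lig <- randomLigand(sample(5:9, 1))
    ligB <- torsionPerturbed(lig, angle = runif(1, 0, 180))
    tr <- RigidTransform(LigandRMSD:::.randomRotation(), rnorm(3, sd = 6))
    r <- ligandRMSD(lig, ligB, tr)
    worst <- min(worst, r@score)
  }
  expect_gte(worst, -1e-6)
})

test_that("growing rigid perturbations never decrease the score", {
  lig <- ligandTemplate("benzamidine")
  set.seed(24)
  ligB <- LigandRMSD:::.withCoords(
    lig, applyTransform(RigidTransform(LigandRMSD:::.randomRotation(),
                                       runif(3, -8, 8)), coords(lig)))
  opt <- kabsch(coords(lig), coords(ligB), matchAtoms(lig, ligB)@pairs)
  dirs <- LigandRMSD:::.randomUnit()
  scores <- vapply(seq(0, 6, by = 0.5), function(d) {
    tr <- RigidTransform(opt@transform@rotation,
                         opt@transform@translation + d * dirs)
    ligandRMSD(lig, ligB, tr)@score
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("the score is invariant under a common rigid motion", {
  set.seed(25)
  lig <- ligandTemplate("ring-tail")
  ligB <- torsionPerturbed(lig)
  tr <- RigidTransform(LigandRMSD:::.randomRotation(), rnorm(3, sd = 4))
  base <- ligandRMSD(lig, ligB, tr)@score
  G <- RigidTransform(LigandRMSD:::.randomRotation(), rnorm(3, sd = 6))
  ligG <- LigandRMSD:::.withCoords(lig, applyTransform(G, coords(lig)))
  ligBG <- LigandRMSD:::.withCoords(ligB, applyTransform(G, coords(ligB)))
  conj <- composeTransforms(G, composeTransforms(tr, invertTransform(G)))
  expect_equal(ligandRMSD(ligG, ligBG, conj)@score, base,
               tolerance = 1e-9)
})

test_that("site pair verdict: at least one similar member, inclusive cut", {
  expect_true(sitePairSimilarity(c(4.1, 2.2, 5.0)))
  expect_false(sitePairSimilarity(c(3.4, 6.0)))
  expect_true(sitePairSimilarity(3.0))     # inclusive threshold
  expect_false(sitePairSimilarity(3.0 + 1e-9))
  expect_error(sitePairSimilarity(numeric(0)), "empty")
})

test_that("filter comparison bookkeeping and error handling", {
  scored <- data.frame(
    score = c(rep(1, 84), rep(2, 16), rep(5, 10)),
    aligner_pvalue = c(rep(1e-4, 84), rep(0.5, 16), rep(1e-4, 5),
                       rep(0.5, 5)))
  cmp <- compareFilters(scored, pvalueCut = 1e-3)
  expect_equal(cmp$table["similar", "pass"], 84)
  expect_equal(cmp$table["similar", "fail"], 16)
  expect_equal(cmp$missedByPvaluePct, 100 * 16 / 84, tolerance = 1e-9)
  # all similar by both: off-diagonals zero
  allsim <- data.frame(score = rep(1, 5), aligner_pvalue = rep(1e-5, 5))
  cmp2 <- compareFilters(allsim, pvalueCut = 1e-3)
  expect_equal(cmp2$table["similar", "fail"], 0)
  expect_equal(cmp2$table["dissimilar", "pass"], 0)
  expect_error(compareFilters(scored[0, ], 1e-3), "empty")
  expect_error(compareFilters(data.frame(score = 1), 1e-3), "P-value")
  expect_error(compareFilters(scored), "required")
})

test_that("scoring a record table resolves ligands and reports verdicts", {
  pair <- makeComplexPair(seed = 31, coordNoiseSd = 0)
  ligA <- parseStructure(pair$pdbA)$ligands[[1]]
  ligA@pdbId <- "SYNA"
  ligB <- parseStructure(pair$pdbB)$ligands[[1]]
  ligB@pdbId <- "SYNB"
  rec <- data.frame(
    drug = ligA@compId, pdb_a = "SYNA", chain_a = "A",
    resno_a = ligA@resno, pdb_b = "SYNB", chain_b = "A",
    resno_b = ligB@resno, transform = transformToJSON(pair$transform),
    stringsAsFactors = FALSE)
  out <- scoreAlignments(rec, list(ligA, ligB))
  expect_lt(out$score[1], 1e-3)
  expect_true(out$similar[1])
  bad <- rec; bad$pdb_a <- "NOPE"
  expect_error(scoreAlignments(bad, list(ligA, ligB)), "not found")
})
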