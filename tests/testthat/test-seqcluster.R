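# Global alignment with affine gaps, percent identity, target clustering.

test_that("self alignment: 100% identity, no gaps, symmetric score", {
  s <- "HEAGAWGHEE"
  al <- globalAlign(s, s)
  expect_equal(al@identityPct, 100)
  expect_false(grepl("-", al@alignedA, fixed = TRUE))
  al2 <- globalAlign(s, "PAWHEAE")
  al3 <- globalAlign("PAWHEAE", s)
  expect_equal(al2@score, al3@score)
  expect_equal(al2@identityPct, al3@identityPct)
})

test_that("a single substitution gives 75% identity on length 4", {
  expect_equal(globalAlign("AAAA", "AATA")@identityPct, 75)
  expect_error(globalAlign("", "AA"), "non-empty")
})

test_that("gap costs follow the 10 + (L-1)*0.5 convention", {
  # one internal gap of length 2 in an otherwise perfect alignment:
  # score must equal matches - (10 + 0.5)
  a <- "WWWWCCWWWW"
  b <- "WWWWWWWW"     # the two C are deleted
  al <- glob <- globalAlign(a, b)
  sub <- LigandRMSD:::.substMatrix()
  matches <- 8 * sub["W", "W"]
  expect_equal(al@score, matches - 10.5)
})

test_that("nonstandard residues map to X and score zero", {
  al <- globalAlign("WBWUW", "WWW")   # B and U -> X
  expect_true(grepl("X", al@alignedA))
  # X against anything contributes 0: exact score accounting
  al2 <- globalAlign("WXW", "WCW")
  sub <- LigandRMSD:::.substMatrix()
  expect_equal(al2@score, 2 * sub["W", "W"] + 0)
})

test_that("DP agrees with brute-force enumeration on short sequences", {
  set.seed(51)
  for (i in 1:120) {
    sa <- randomSeq(sample(1:6, 1))
    sb <- randomSeq(sample(1:6, 1))
    al <- globalAlign(sa, sb)
    bf <- bfAlign(sa, sb)
    expect_equal(al@score, bf$score, tolerance = 1e-9,
                 info = paste(sa, sb))
    expect_equal(al@identityPct, bf$identityPct, tolerance = 1e-9,
                 info = paste(sa, sb))
  }
})

test_that("DP score agrees with the reference aligner convention", {
  # Biostrings charges open + L*ext per gap; open 9.5 / ext 0.5 is the
  # same cost model as 10 + (L-1)*0.5
  set.seed(52)
  for (i in 1:15) {
    sa <- paste(sample(rownames(LigandRMSD:::.substMatrix())[1:20],
                       sample(5:30, 1), TRUE), collapse = "")
    sb <- paste(sample(rownames(LigandRMSD:::.substMatrix())[1:20],
                       sample(5:30, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      sa, sb, substitutionMatrix = "BLOSUM62", gapOpening = 9.5,
      gapExtension = 0.5, type = "global", scoreOnly = TRUE)
    expect_equal(globalAlign(sa, sb)@score, ref, tolerance = 1e-9)
  }
})

test_that("identity clustering: thresholds, transitivity, representatives", {
  set.seed(53)
  base <- paste(sample(names(LigandRMSD:::.AA1TO3), 60, TRUE),
                collapse = "")
  near <- LigandRMSD:::.mutateSequence(base, 2)    # ~96.7%
  near2 <- LigandRMSD:::.mutateSequence(base, 2)
  far <- paste(sample(names(LigandRMSD:::.AA1TO3), 60, TRUE),
               collapse = "")
  cl <- clusterTargets(c(c1 = base, c2 = near, c3 = near2, c4 = far))
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_true(all(cl$identity_to_representative[cl$member != "c4"] >= 90))
  # all pairs below the cut: all singletons
  faraway <- setNames(vapply(1:4, function(i)
    paste(sample(names(LigandRMSD:::.AA1TO3), 60, TRUE), collapse = ""),
    character(1)), paste0("s", 1:4))
  expect_equal(length(unique(clusterTargets(faraway)$cluster_id)), 4)
  # representative is the longest member, ties by identifier
  cl2 <- clusterTargets(c(bb = base, aa = base))
  expect_true(all(cl2$representative == "aa"))
  cl3 <- clusterTargets(c(sh = substr(base, 1, 58), lo = base))
  expect_true(all(cl3$representative == "lo"))
})

test_that("single-linkage closure joins chains through an intermediate", {
  # a ~ b and b ~ c at 96.7%, a ~ c at 93.3%: cut 95 -> one cluster
  b <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)                 # 60 residues
  mutAt <- function(s, pos, to) {
    ch <- strsplit(s, "")[[1]]; ch[pos] <- to
    paste(ch, collapse = "")
  }
  a <- mutAt(b, c(1, 21), c("W", "W"))
  cc <- mutAt(b, c(5, 25), c("K", "K"))
  expect_gte(percentIdentity(a, b), 95)
  expect_gte(percentIdentity(b, cc), 95)
  expect_lt(percentIdentity(a, cc), 95)
  cl <- clusterTargets(c(a = a, b = b, c = cc), identityCut = 95)
  expect_equal(length(unique(cl$cluster_id)), 1)
})

test_that("the k-mer screen never drops a pair above the cut", {
  set.seed(55)
  for (i in 1:30) {
    base <- paste(sample(names(LigandRMSD:::.AA1TO3), 70, TRUE),
                  collapse = "")
    other <- LigandRMSD:::.mutateSequence(base, sample(0:4, 1))
    if (percentIdentity(base, other) >= 95)
      expect_true(LigandRMSD:::.identityPossible(base, other, 95))
  }
  # screened and unscreened clustering agree on a mixed cohort
  seqs <- character()
  for (g in 1:4) {
    b <- paste(sample(names(LigandRMSD:::.AA1TO3), 60, TRUE),
               collapse = "")
    seqs[paste0("g", g, "m1")] <- b
    seqs[paste0("g", g, "m2")] <- LigandRMSD:::.mutateSequence(b, 2)
  }
  clS <- clusterTargets(seqs, screen = TRUE)
  clU <- clusterTargets(seqs, screen = FALSE)
  expect_equal(clS[order(clS$member), -1], clU[order(clU$member), -1])
})

test_that("raising the identity cut never decreases the cluster count", {
  set.seed(56)
  base <- paste(sample(names(LigandRMSD:::.AA1TO3), 60, TRUE),
                collapse = "")
  seqs <- setNames(c(base,
                     LigandRMSD:::.mutateSequence(base, 1),
                     LigandRMSD:::.mutateSequence(base, 3),
                     LigandRMSD:::.mutateSequence(base, 6),
                     LigandRMSD:::.mutateSequence(base, 12)),
                   paste0("m", 1:5))
  counts <- vapply(c(80, 90, 94, 96, 99, 100), function(cut)
    length(unique(clusterTargets(seqs, identityCut = cut)$cluster_id)),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("promiscuity degree counts distinct clusters, boundary at 3", {
  clusters <- data.frame(
    cluster_id = c("T1", "T1", "T2", "T3"),
    representative = c("a", "a", "c", "d"),
    member = c("a", "b", "c", "d"),
    identity_to_representative = c(100, 97, 100, 100))
  links <- data.frame(chain = c("a", "b", "c", "d", "d"),
                      drug = c("DG1", "DG1", "DG1", "DG2", "DG1"))
  expect_equal(promiscuityDegree("DG1", clusters, links), 3)
  expect_equal(promiscuityDegree("DG2", clusters, links), 1)
  expect_error(promiscuityDegree("DG9", clusters, links), "absent")
  th <- defaultThresholds()
  expect_true(promiscuityDegree("DG1", clusters, links) >=
                th@promiscuityMinTargets)
})

test_that("FASTA round trip", {
  seqs <- c(ch1 = "MKTAYIAK", ch2 = "WWGGHHPP")
  f <- tempfile(fileext = ".fasta")
  writeSequences(seqs, f)
  expect_equal(readSequences(f), seqs)
})
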