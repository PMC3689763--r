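# Independent oracles used to validate the package's core algorithms.
# Each is a deliberately naive construction: enumeration, grid search or
# direct re-implementation from the definition.

# ---- brute-force global alignment ------------------------------------
# Enumerates every global alignment as a column sequence; a gap run of
# length L costs open + (L-1)*ext.  Lexicographic objective: max score,
# then max identical columns, then min alignment length (the same
# tie-break the package documents).
bfAlign <- function(sa, sb, open = 10, ext = 0.5) {
  sub <- LigandRMSD:::.substMatrix()
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  la <- length(a); lb <- length(b)
  best <- c(score = -Inf, ident = 0, len = 0)
  lexBetter <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1] + 1e-9)
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] < y[3]
  }
  rec <- function(i, j, sc, id, ln, last) {
    if (i > la && j > lb) {
      cand <- c(sc, id, ln)
      if (lexBetter(cand, best)) best <<- cand
      return(invisible())
    }
    if (i <= la && j <= lb)
      rec(i + 1, j + 1, sc + sub[a[i], b[j]], id + (a[i] == b[j]), ln + 1,
          "M")
    if (i <= la)
      rec(i + 1, j, sc - (if (last == "X") ext else open), id, ln + 1, "X")
    if (j <= lb)
      rec(i, j + 1, sc - (if (last == "Y") ext else open), id, ln + 1, "Y")
  }
  rec(1, 1, 0, 0, 0, "start")
  list(score = unname(best[1]), identityPct = 100 * best[2] / best[3])
}

# ---- exhaustive maximum-common-subgraph size -------------------------
# Maximum size of a connected induced element-matched common subgraph,
# found by enumerating every vertex subset of A (bitmask), checking
# connectivity, and searching for any induced embedding into B.
bfMcsSize <- function(adjA, elA, adjB, elB) {
  nA <- length(elA)
  connected <- function(vs) {
    if (length(vs) <= 1) return(TRUE)
    seen <- vs[1]; frontier <- vs[1]
    while (length(frontier)) {
      nxt <- setdiff(vs[colSums(adjA[frontier, vs, drop = FALSE]) > 0],
                     seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(vs)
  }
  embeds <- function(vs) {
    k <- length(vs)
    assign <- integer(k)
    try1 <- function(pos) {
      if (pos > k) return(TRUE)
      va <- vs[pos]
      for (vb in seq_along(elB)) {
        if (vb %in% assign[seq_len(pos - 1)]) next
        if (elB[vb] != elA[va]) next
        ok <- TRUE
        for (q in seq_len(pos - 1)) {
          if (adjA[va, vs[q]] != adjB[vb, assign[q]]) { ok <- FALSE; break }
        }
        if (ok) {
          assign[pos] <<- vb
          if (try1(pos + 1)) return(TRUE)
          assign[pos] <<- 0L
        }
      }
      FALSE
    }
    try1(1)
  }
  best <- 0L
  for (mask in seq_len(2^nA - 1L)) {
    vs <- which(bitwAnd(mask, 2^(seq_len(nA) - 1L)) > 0)
    if (length(vs) <= best) next
    if (!connected(vs)) next
    if (embeds(vs)) best <- length(vs)
  }
  best
}

# random element-labelled connected graph for MCS property tests
randomGraphSpec <- function(n, extraEdges = 1L,
                            elements = c("C", "C", "N", "O")) {
  el <- sample(elements, n, replace = TRUE)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  for (k in seq_len(extraEdges)) {
    cand <- sort(sample.int(n, 2L))
    if (cand[1] != cand[2]) edges <- rbind(edges, cand)
  }
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE; adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  list(elements = el, edges = edges, adj = adj)
}

specToGraph <- function(spec) {
  buildGraph(list(elements = spec$elements, bonds = spec$edges))
}

# ---- quaternion-grid rigid superposition -----------------------------
# Dense random search over rotation space (unit quaternions) with the
# optimal (centroid) translation, refined by Nelder-Mead; independent of
# the SVD route.
quatToRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

bfSuperposeRmsd <- function(a, b, nGrid = 4000L) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  evalQ <- function(q) {
    R <- quatToRot(q)
    sqrt(mean(rowSums((ac - bc %*% t(R))^2)))
  }
  qs <- matrix(rnorm(4 * nGrid), ncol = 4)
  vals <- apply(qs, 1, evalQ)
  q0 <- qs[which.min(vals), ]
  opt <- optim(q0, evalQ, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  opt$value
}

# ---- naive average-linkage agglomeration -----------------------------
# Direct re-implementation by repeated matrix scan: merge the pair of
# clusters with the smallest average inter-cluster distance while that
# minimum is at or below the cut.
bfAverageLinkage <- function(D, cut) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    bestD <- Inf; bestIJ <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestD - 1e-12) { bestD <- d; bestIJ <- c(i, j) }
      }
    }
    if (bestD > cut) break
    clusters[[bestIJ[1]]] <- c(clusters[[bestIJ[1]]],
                               clusters[[bestIJ[2]]])
    clusters[[bestIJ[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels   # compare partitions with adjustedRand(), not label-exactly
}

# adjusted Rand index between two labelings
adjustedRand <- function(x, y) {
  n <- length(x)
  if (n < 2) return(1)
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- length(x)
  expd <- b * cc / choose(n, 2)
  mx <- (b + cc) / 2
  if (!is.finite(expd) || mx == expd) return(1)
  (a - expd) / (mx - expd)
}

# random amino-acid string
randomSeq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# torsion-perturbed copy of a template with a random rigid motion applied
torsionPerturbed <- function(lig, angle = 75) {
  g <- buildGraph(lig)
  deg <- igraph::degree(g@graph)
  rot <- which(!g@ringEdge & deg[g@edges[, 1]] >= 2 & deg[g@edges[, 2]] >= 2)
  out <- lig
  if (length(rot))
    out <- twistBond(lig, g@edges[rot[sample.int(length(rot), 1)], ], angle)
  R <- LigandRMSD:::.randomRotation()
  xyz <- sweep(coords(out) %*% t(R), 2, runif(3, -10, 10), `+`)
  LigandRMSD:::.withCoords(out, xyz)
}
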