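# Idealised ligand templates and geometry helpers for the synthetic-data
# generators and tests.

.ligAtoms <- function(names, el, xyz) {
  data.frame(serial = seq_along(names), name = names, element = el,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1.0, altloc = "", stringsAsFactors = FALSE)
}

.hexagon <- function(r = 1.39) {
  ang <- (0:5) * pi / 3
  cbind(r * cos(ang), r * sin(ang), 0)
}

#' Idealised ligand templates
#'
#' Small built-in molecules with idealised coordinates, element labels,
#' atom names and explicit bonds, used by the synthetic-data generators
#' and in examples.  Available templates:
#' \describe{
#'   \item{benzamidine}{9 heavy atoms: phenyl ring plus amidine group.}
#'   \item{benzene}{6-carbon ring.}
#'   \item{butane}{4-carbon chain.}
#'   \item{ring-tail}{benzene ring with a 3-carbon tail.}
#'   \item{biphenyl}{two rings joined by one rotatable bond.}
#'   \item{chain8}{8-atom acyclic chain with N and O substituents.}
#' }
#'
#' @param name template name.
#' @param compId chemical component identifier stamped on the instance
#'   (default: template-specific 3-letter code).
#' @param pdbId,chainId,resno instance identity fields.
#' @return A [LigandInstance-class] with bonds set.
#' @examples
#' nAtoms(ligandTemplate("benzamidine"))  # 9
#' @export
ligandTemplate <- function(name, compId = NULL, pdbId = "TMPL",
                           chainId = "A", resno = 900L) {
  hex <- .hexagon()
  spec <- switch(name,
    "benzamidine" = {
      c7 <- c(1.39 + 1.49, 0, 0)
      n1 <- c7 + 1.32 * c(cos(pi / 3), sin(pi / 3), 0)
      n2 <- c7 + 1.32 * c(cos(-pi / 3), sin(-pi / 3), 0)
      list(names = c(paste0("C", 1:7), "N1", "N2"),
           el = c(rep("C", 7), "N", "N"),
           xyz = rbind(hex, c7, n1, n2),
           bonds = rbind(cbind(1:6, c(2:6, 1)), c(1, 7), c(7, 8), c(7, 9)),
           comp = "BEN")
    },
    "benzene" = list(names = paste0("C", 1:6), el = rep("C", 6), xyz = hex,
                     bonds = cbind(1:6, c(2:6, 1)), comp = "BNZ"),
    "butane" = {
      xyz <- cbind((0:3) * 1.3, rep(c(0, 0.75), 2), 0)
      list(names = paste0("C", 1:4), el = rep("C", 4), xyz = xyz,
           bonds = cbind(1:3, 2:4), comp = "BUT")
    },
    "ring-tail" = {
      t1 <- c(1.39 + 1.50, 0, 0)
      t2 <- t1 + c(1.1, 1.0, 0.3)
      t3 <- t2 + c(1.4, -0.3, 0.6)
      list(names = c(paste0("C", 1:6), "C7", "C8", "O1"),
           el = c(rep("C", 8), "O"),
           xyz = rbind(hex, t1, t2, t3),
           bonds = rbind(cbind(1:6, c(2:6, 1)), c(1, 7), c(7, 8), c(8, 9)),
           comp = "RGT")
    },
    "biphenyl" = {
      hex2 <- sweep(.hexagon(), 2, c(1.39 + 1.48 + 1.39, 0, 0), `+`)
      hex2 <- hex2[, c(1, 3, 2)]  # second ring in the xz-plane (twisted)
      list(names = paste0("C", 1:12), el = rep("C", 12),
           xyz = rbind(hex, hex2),
           bonds = rbind(cbind(1:6, c(2:6, 1)), cbind(7:12, c(8:12, 7)),
                         c(1, 10)),
           comp = "BPH")
    },
    "chain8" = {
      xyz <- cbind((0:7) * 1.35, rep(c(0, 0.8), 4),
                   c(0, 0.2, 0, -0.2, 0, 0.3, 0, -0.1))
      list(names = c("C1", "C2", "N1", "C3", "C4", "O1", "C5", "N2"),
           el = c("C", "C", "N", "C", "C", "O", "C", "N"), xyz = xyz,
           bonds = cbind(1:7, 2:8), comp = "CH8")
    },
    stop("unknown ligand template: ", name)
  )
  LigandInstance(pdbId = pdbId,
                 compId = if (is.null(compId)) spec$comp else compId,
                 chainId = chainId, resno = resno,
                 atoms = .ligAtoms(spec$names, spec$el, spec$xyz),
                 bonds = spec$bonds)
}

#' Random tree-shaped ligand
#'
#' Grows a random acyclic molecule of `n` heavy atoms (bond length 1.5 A,
#' random directions, elements sampled from C/N/O) for property-style
#' tests.  Uses the current RNG state: call `set.seed()` first for
#' reproducibility.
#'
#' @param n number of heavy atoms (>= 3).
#' @param elements element pool to sample from.
#' @return A [LigandInstance-class].
#' @export
randomLigand <- function(n, elements = c("C", "C", "C", "N", "O")) {
  stopifnot(n >= 3)
  xyz <- matrix(0, n, 3)
  parent <- integer(n)
  for (i in 2:n) {
    parent[i] <- sample.int(i - 1L, 1L)
    repeat {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      cand <- xyz[parent[i], ] + 1.5 * dir
      d2 <- rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE], 2,
                          cand)^2)
      if (min(d2) > 1.2^2) break
    }
    xyz[i, ] <- cand
  }
  el <- sample(elements, n, replace = TRUE)
  LigandInstance(pdbId = "RND", compId = "RND", chainId = "A", resno = 900L,
                 atoms = .ligAtoms(paste0(el, seq_len(n)), el, xyz),
                 bonds = cbind(2:n, parent[2:n]))
}

# Rodrigues rotation matrix about `axis` by `angle` (radians)
.rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Random proper rotation from the current RNG state
.randomRotation <- function() {
  axis <- rnorm(3)
  .rotationMatrix(axis, runif(1, 0, 2 * pi))
}

# Random unit vector
.randomUnit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Rotate part of a ligand about one of its bonds
#'
#' Splits the molecule at the given acyclic bond and rotates the smaller
#' side about the bond axis by `angleDeg` degrees — a torsional
#' perturbation that changes the conformer without breaking bond lengths.
#'
#' @param ligand a [LigandInstance-class].
#' @param bond integer length-2: atom indices of an acyclic bond.
#' @param angleDeg torsion angle change in degrees.
#' @return A new [LigandInstance-class].
#' @export
twistBond <- function(ligand, bond, angleDeg) {
  g <- buildGraph(ligand)
  e1 <- pmin(g@edges[, 1], g@edges[, 2])
  e2 <- pmax(g@edges[, 1], g@edges[, 2])
  keep <- !(e1 == min(bond) & e2 == max(bond))
  gcut <- graph_from_edgelist(g@edges[keep, , drop = FALSE],
                              directed = FALSE)
  if (vcount(gcut) < nAtoms(ligand))
    gcut <- igraph::add_vertices(gcut, nAtoms(ligand) - vcount(gcut))
  mem <- components(gcut)$membership
  if (mem[bond[1]] == mem[bond[2]])
    stop("bond lies on a ring; torsion is undefined")
  # either side may rotate: both bond atoms lie on the rotation axis
  sideB <- which(mem == mem[bond[2]])
  side <- if (length(sideB) <= nAtoms(ligand) / 2) sideB
          else which(mem == mem[bond[1]])
  xyz <- coords(ligand)
  axis <- xyz[bond[2], ] - xyz[bond[1], ]
  R <- .rotationMatrix(axis, angleDeg * pi / 180)
  origin <- xyz[bond[1], ]
  rot <- sweep(sweep(xyz[side, , drop = FALSE], 2, origin) %*% t(R),
               2, origin, `+`)
  at <- ligand@atoms
  at[side, c("x", "y", "z")] <- rot
  out <- ligand
  out@atoms <- at
  out
}

# Replace a ligand's coordinates (keeping names/bonds)
.withCoords <- function(ligand, xyz, pdbId = ligand@pdbId,
                        chainId = ligand@chainId, resno = ligand@resno) {
  at <- ligand@atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  out <- ligand
  out@atoms <- at
  out@pdbId <- pdbId; out@chainId <- chainId; out@resno <- as.integer(resno)
  out
}
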