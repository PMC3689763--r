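---
title: "Scoring binding-site alignments through their ligands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring binding-site alignments through their ligands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The score

A binding-site alignment of two protein–ligand complexes of the same
drug is a rigid transform $T = (R, t)$ carrying structure B's frame onto
structure A's (`y = R x + t`, the convention used in all I/O). Given an
injective atom correspondence $m$ between the two bound ligand copies,
the package computes

* RMSD′ — the root-mean-square deviation over $m$ after applying $T$ to
  B's ligand, with no refitting; this measures how well the *site*
  alignment superposes the ligands;
* RMSD″ — the minimum RMSD over all proper rigid motions for the same
  $m$ (Kabsch superposition); this is the best the ligand pair could do;
* LigandRMSD = RMSD′ − RMSD″, with the verdict *similar* when the score
  is at most 3 Å (inclusive).

Using one and the same correspondence in both terms is what makes the
subtraction meaningful. It gives the score two properties that the tests
verify directly: it is non-negative up to floating-point noise (RMSD″ is
the optimum of the quantity RMSD′ evaluates), and it is independent of
conformational differences between the two bound copies — for any pair
of conformers, plugging in the mapping's own optimal transform gives a
score of zero even when RMSD″ itself is large. The score therefore
isolates the quality of the *alignment* from the flexibility of the
ligand, which is the point: a site aligner should not be penalised
because the drug bends, and should not be rewarded for a good ligand
overlay it did not produce.

Reflections are excluded throughout (the rotation's determinant must be
+1): a physical ligand cannot be mirrored, so a mirror-image overlay
must score poorly rather than perfectly.

# Atom correspondence

The correspondence is chosen in three tiers:

1. **Atom names**, when both copies are the same chemical component with
   identical, duplicate-free atom-name sets. This is the common case for
   one drug extracted from two PDB entries.
2. **Element-labelled graph isomorphism** (VF2), when the graphs match
   but the names do not.
3. **Maximum common connected induced subgraph** (MCS) otherwise, which
   also extends the score to chemically different ligands.

Symmetric molecules admit several equivalent mappings (ring flips,
amidine nitrogen swaps, and so on). Up to 1000 candidates are enumerated
in a deterministic order and the one minimising RMSD″ is used; the cap
bounds runtime on pathologically symmetric molecules while the
deterministic order keeps reruns identical. A mapping must cover at
least 3 non-collinear atoms, below which a rigid superposition is
under-determined; such pairs are rejected as unmappable.

Two design choices deserve a note. Bond orders are ignored — node labels
are elements only — because PDB files carry no reliable order
information and the analysis compares identical drugs, where
element-level matching suffices. And the MCS is *induced* (adjacency and
non-adjacency both preserved) and *connected*: inducedness stops the
search from mapping atoms across a bond that exists in only one
molecule, and connectedness keeps the matched substructure a single
rigid fragment, which is what a superposition needs. The name-match and
isomorphism tiers map whole ligands and are exempt from the
connectedness requirement so that genuinely disconnected ligands (two
fragments in one residue) remain scoreable. The MCS search is an
exhaustive McGregor-style backtracking; its size is validated against an
independent subset-enumeration oracle on random labelled graphs of up to
8 nodes.

# Conformer clustering

All bound copies of a drug are compared pairwise by their
symmetry-corrected minimum RMSD: the minimum over the enumerated
candidate mappings of the Kabsch-optimal RMSD. Taking the minimum over
mappings guards against a suboptimal correspondence in symmetric
molecules and realises "keep the lowest RMSD" with a single engine. The
matrix is clustered by average-linkage agglomeration and the dendrogram
is cut at 1.4 Å, merges at exactly the cut included — conformers at an
RMSD equal to the cut belong together. The cut stays well below the
2.5 Å customary in docking-pose comparison, so members of one cluster
are genuinely the same bound shape. Cluster extraction applies every
merge with height ≤ cut on top of `stats::hclust`, which guarantees the
inclusive boundary independent of `cutree`'s behaviour at exact
equality; a planted pair at 1.39 Å merges and at 1.41 Å splits, which
the tests pin down. Ties between merge candidates are resolved by
`hclust`'s deterministic ordering; with continuous RMSDs they have
probability zero. Average linkage on a min-over-mappings RMSD is not
backed by metric-space guarantees (the minimum can mildly violate the
triangle inequality); the planted-recovery tests cover the regime the
analysis relies on (intra ≤ 0.5 Å, inter ≥ 3 Å).

# Sequences and non-redundant targets

Chains are aligned globally with an affine-gap Needleman–Wunsch
(Gotoh) using BLOSUM62; a gap of length $L$ costs $10 + (L-1)\cdot 0.5$
and end gaps are penalised like internal ones. Nonstandard residues map
to X, which scores 0 against everything. Percent identity divides
identical columns by the full alignment length including gap columns;
the alternative denominators (shorter sequence, aligned columns) were
rejected to keep one reproducible convention. Co-optimal alignments can
differ in identity, so the dynamic program optimises lexicographically —
score, then identical columns, then shorter alignment — which makes the
reported identity a deterministic function of the inputs and lets a
brute-force enumeration oracle reproduce it exactly. The kernel is
implemented in C++ (Rcpp); its scores are additionally cross-checked
against `Biostrings::pairwiseAlignment`, whose `gapOpening = 9.5,
gapExtension = 0.5` is the same cost model.

Targets are clustered at 95 % identity by single-linkage transitive
closure; the representative is the longest member (ties: smallest
identifier). A drug's promiscuity degree is the number of clusters
containing at least one chain it binds; promiscuous means degree ≥ 3.
Clustering is computed per drug: the analysis only ever uses clusters
among the chains of one drug, and cross-drug chain comparisons would add
quadratic cost without entering any statistic. All-vs-all alignment is
preceded by a conservative screen (length ratio and shared 4-mer
fraction) that only skips pairs provably unable to reach the cut; tests
compare screened and unscreened clustering on mixed cohorts.

# Statistics

Pearson correlations between the degree and each drug property use
`stats::cor.test` (two-sided, t statistic with $n-2$ df). Pair counts
are square-root transformed before correlating, since a drug with $n$
targets has up to $n(n-1)/2$ similar pairs. Distribution comparisons use
the two-sample Kolmogorov–Smirnov test with the asymptotic P-value; the
combined model is an ordinary least-squares regression of the degree on
logP, molecular weight, conformer-cluster count and the relative and
absolute rotatable-bond counts. Missing optional descriptors are
excluded pairwise per analysis, maximising the sample behind each panel.
Calibration is checked empirically: the KS null rejection rate at
$\alpha = 0.05$ (measured on samples of 100 vs 150 — unequal sizes,
because equal sizes put the statistic on a coarse lattice where the
asymptotic approximation is visibly conservative) and the t-based
Pearson P against a 100 000-permutation oracle.

# Synthetic data

The generators produce every input the pipeline consumes, with ground
truth attached, and are deterministic functions of their seed.

*Complex pairs* place a template ligand (idealised coordinates, explicit
CONECT bonds) beside a CA-trace helix chain and move the copy by a known
rigid motion plus optional isotropic Gaussian coordinate noise; the
exact inverse motion is returned, so the true score of the pair is
analytically known (0, or exactly the magnitude of an extra
displacement).

*Conformer sets* plant $k$ clusters by deforming the template
(torsion twists plus a non-rigid displacement field) into well-separated
centres and populating each with small-noise copies; the planted bounds
(intra ≤ 0.5 Å, inter ≥ 3 Å around the 1.4 Å cut) are verified with the
package's own distance engine and regenerated on violation within a
bounded retry budget.

*Cohorts* emulate a structural promiscuity study. Defaults follow the
study conditions the analysis is meant for: 543 drugs of which ~30 %
are promiscuous with mean promiscuous degree ≈ 4.6 (capped at 37);
1–6 member structures per non-redundant target (mean ≈ 3.2, which makes
redundancy collapse keep roughly 10 % of raw alignment pairs);
conformer multiplicities of 68 % / 18 % / 14 % for 1 / 2 / ≥3 bound
conformers; member sequences within 3 mutations of an 80-residue target
base sequence (so every member stays above the 95 % cut via its base),
distinct targets drawn independently (identity far below the cut).
Alignment records are planted exactly: each record's transform is the
true optimal superposition of the two ligand instances composed with a
displacement of analytically chosen length, so the resulting LigandRMSD
lands exactly on the intended side of the 3 Å threshold (margin 0.5 Å on
the similar side, 0.2 Å on the dissimilar side). Scoring such records is
deterministic, which is why recovered per-drug similar-pair counts equal
the planted ones exactly — a property the pipeline tests assert
end-to-end; the many-seed correlation-recovery sweeps therefore measure
the planted tables directly rather than re-running the identical scoring
each time, and problem sizes are chosen accordingly (200 count-level
cohorts at the study scale of 164 promiscuous drugs, full pipelines on
cohorts of 12–60 drugs plus one 543-drug run in the acceptance script).

The correlation between the degree and the square root of the
similar-pair count is planted through a Gaussian copula with a fixed
global marginal on 0–3 similar pairs. Because every promiscuous drug can
realise any value of that marginal (its pair budget is at least 3), the
planting is free of budget-clamping bias at any $\rho$ — a property the
null case ($\rho = 0$) makes visible — and the latent correlation is
calibrated in closed form so the discretised counts realise the
requested $\rho$ in expectation. The marginal leaves 71 % of promiscuous
drugs with at least one similar pair. Funnel-shaped cohorts use an
alternative budget-proportional planting (`similarPairRate`), normalised
on the pair-weighted mean so the overall similar fraction matches the
requested rate (e.g. 0.41, a score stage removing 59 %); under that mode
the realised correlation is dominated by the budgets and is reported in
the truth record rather than controlled.

What the generators do *not* emulate: real protein geometry (chains are
CA helices), crystallographic noise models, chemistry beyond
element-labelled graphs, aligner-specific score distributions (record
P-values are synthetic and only ordered against the planted verdicts),
and real sequence evolution. Passing tests demonstrate the correctness
and calibration of the machinery on data with known truth; they do not
certify discoveries on real structures.

# Numerical choices and degenerate inputs

* Rotations are validated to be orthonormal with determinant +1 within
  1e-8; Kabsch corrects reflections via the sign of the smallest
  singular direction.
* Collinearity is detected by the ratio of the second singular value to
  the first (1e-8); collinear mapped sets are rejected.
* Score comparisons against thresholds are inclusive; scores are
  reported to two decimals in text output but compared at full
  precision.
* Bond inference uses CONECT records verbatim when they yield at least
  one intra-ligand bond, otherwise a distance rule (sum of covalent
  radii + 0.45 Å); alternate locations resolve to the highest occupancy,
  ties preferring altloc A, then blank.
* Atom masses omit hydrogens when computed from file atoms (PDB X-ray
  entries rarely carry them); a formula override yields the
  hydrogen-complete weight.
* The aligner P-value threshold used by the filter comparison has no
  shipped default — it is an external aligner's calibration, not this
  package's — and must be supplied by the caller.
* A HETATM residue is treated as a modified polymer residue (not a
  ligand) when its residue number falls inside the chain's range *and*
  it sits at covalent distance (≤ 2 Å) of a polymer atom.

# Known limitations

The MCS search is exponential in the worst case; the 1000-candidate cap
bounds the enumeration of equivalent mappings but not the search for the
maximum itself, so very large, very symmetric ligand pairs are
expensive. Identity clustering is exact single linkage within a drug but
does not reproduce a PDB-wide clustering across drugs. The blacklist's
excluded-component list is an editable approximation of the usual
additives and cofactors; no authoritative list ships with the package.
Statistics assume one row per drug and do not model shared targets
between drugs.
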