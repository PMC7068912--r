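---
title: "Reading-frame phase geometry of genome fragments: model, conventions and design choices"
author: "tripletPhase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading-frame phase geometry of genome fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletPhase)
```

## The model

A genome is treated as a string over {A,C,G,T} of length $N$ with an
annotation that marks coding regions on both strands.  "Coding" is read
widely: protein-coding genes, tRNA and rRNA genes and other annotated RNA
genes all count.  The genome is cut into overlapping windows of length $L$
(default 603) taken every $R$ positions (default 11), so there are
$\lfloor (N-L)/R \rfloor + 1$ fragments.  $L$ must be odd and divisible by
3 — the window then holds a whole number of triplets and has an integer
center position $\mathrm{start} + (L-1)/2$ — and $R$ must not be divisible
by 3, so consecutive windows visit all three frame offsets.

Each fragment is converted into its $W_{(3,3)}$ frequency dictionary: the
64 triplets are counted by tiling the fragment with non-overlapping
3-letter windows from its first position (windows containing an ambiguous
base are skipped), and counts are divided by the number $M$ of clean
windows,

$$ f_\omega = n_\omega / M, \qquad \sum_{\omega=\mathsf{AAA}}^{\mathsf{TTT}} f_\omega = 1 . $$

The sum constraint leaves 63 independent coordinates.  Rather than
dropping an arbitrary coordinate, the triplet whose frequency has the
*smallest standard deviation* across the fragment ensemble is excluded:
it is the least discriminating coordinate, so its removal costs the least
information.  Distances between dictionaries are Euclidean over the
triplet coordinates.

Fragments are labeled from the annotation:

* **JUNK** — at least half the window ($\lceil L/2 \rceil$ positions) lies
  outside every annotated region;
* **TAIL** — at least half the window is covered by tRNA/rRNA genes (the
  dense GC-rich RNA blocks);
* otherwise a **coding phase** F0–F2 (forward strand) or B0–B2 (backward
  strand) from the region containing the window center, as described next.

In the embedding, the fragments of one genome then gather into eight
clusters: six phase clusters, the junk cloud, and the tail.

## The frame-index convention

The phase index encodes the reading-frame offset of the fragment's triplet
tiling relative to the codon frame of the gene containing its center.  The
package counts the nucleotides from the region's first nucleotide (forward
strand) or last nucleotide (backward strand) through the central
nucleotide, *inclusively*, and takes the result mod 3:

$$ \mathrm{F}:\ (c - s + 1) \bmod 3, \qquad
   \mathrm{B}:\ (e - c + 1) \bmod 3, $$

with $c$ the center and $s,e$ the region's first/last coordinate.  Two
facts motivated this choice over the superficially simpler $(c-s) \bmod 3$:

1. Because the center offset $(L-1)/2$ is congruent to 1 mod 3 for every
   admissible $L$, the convention fixes which cluster corresponds to the
   *codon-aligned* tiling.  Under the inclusive count the aligned frames
   carry index 2 on both strands, so the F2 and B2 clusters are the two
   whose triplet composition equals the codon usage itself (read on
   opposite strands).  Whenever the usage respects intra-strand Chargaff
   parity — as real genomes approximately do — those two clusters
   coincide, which is exactly the merged F2–B2 cluster characteristic of
   chloroplast fragment distributions.
2. The same arithmetic makes the six expected phase centroids pair as
   F0–B1, F1–B0, F2–B2, the pairing observed in chloroplast genomes.  A
   shift of the label origin on either strand permutes the names and
   produces a different (wrong) nominal pairing while leaving the geometry
   untouched; the inclusive count is the unique choice consistent with
   both observations and with a symmetric treatment of the two strands.

Ties and gaps are resolved deterministically: when the center falls in two
overlapping regions, the region overlapping the fragment most wins (ties:
forward strand, then smaller start); when the center sits in a short
intergenic gap of a mostly-coding fragment, the phase of the
largest-overlap region is assigned so that no fragment is left unlabeled.

## Circuit directions, mirror versus rotational symmetry

The six coding-phase centroids form two triangles, (F0,F1,F2) and
(B0,B1,B2).  Traversing each triangle in label order defines a circuit
direction, measured as the sign of the triangle's signed area in a chosen
plane.  Opposite signs mean the circuits counter-rotate — **mirror**
symmetry, the chloroplast configuration; equal signs mean **rotational**
symmetry, the configuration reported for bacteria.

Which plane?  The fragment cloud is embedded by PCA (top three components
of the column-centered 63-column matrix, with each component's sign fixed
so its largest-magnitude loading is positive).  In data with a strong tail
and junk cloud, PC1 and PC2 are often dominated by the GC axis (tail) and
the coding/non-coding contrast, leaving the phase hexagon nearly edge-on
in the (PC1,PC2) projection: projected triangle areas can be orders of
magnitude below their true size and their *signs* become sampling noise.
The default is therefore `plane = "centroid"`: the best-fit plane of the
six phase centroids themselves inside the embedding — the plane the
hexagon actually spans.  This choice is invariant under rotations of the
embedding and classifies robustly; any explicit PC pair remains available
via `runConfig(plane = c(1, 2))` for comparison with projection figures.

The up/down (**U**/**D**) orientation is defined operationally: U when the
pooled F2/B2 fragments lie above the pooled remaining coding fragments
along PC3 of the sign-canonicalized embedding.  Published orientation
labels for real genome sets depend on an unknowable sign convention in the
original analysis, so only the two-class split is meaningful; a global
`orientationFlip` switch aligns the proxy with any chosen reference.

## The synthetic generator

`generateGenome()` builds an annotated genome with known ground truth:

| parameter | default | meaning |
|---|---|---|
| `N` | 120 000 | genome length (nt) |
| `nForwardGenes`, `nBackwardGenes` | 25 + 25 | protein-coding genes per strand |
| `geneLengthRange` | 900–2 400 | gene lengths (multiples of 3) |
| `codonUsage` | `defaultCodonUsage()` | strongly non-uniform, Chargaff-symmetrized, coding GC ≈ 0.40 |
| `intergenicGC` | 0.35 | GC of i.i.d. intergenic sequence |
| `tailGenes` | 30 | short RNA genes in one dense block |
| `tailGeneLengthRange` | 72–150 | RNA gene lengths (tRNA/rRNA-sized) |
| `tailGC` | 0.60 | GC of the RNA block (genes and 21 nt spacers) |

Forward genes emit i.i.d. codons from the usage; backward genes emit
i.i.d. codons that are reverse-complemented onto the forward strand and
annotated on the backward strand; the RNA block is a contiguous run of
short genes (alternating strands, annotated tRNA/rRNA) whose composition
is i.i.d. at the tail GC.  Intergenic stretches fill the remaining length
with exponential-like size variability, so both short spacers (whose
covering fragments stay phase-labeled) and junk-sized gaps occur.  The
gene census was sized so that roughly 72% of the genome is genic —
matching real plastid coding fractions — while leaving enough long
intergenic runs to populate the junk cluster; a denser packing of
900–2 400 nt genes would not fit a 120 kb genome at all.

Everything is driven by one seed; the same seed reproduces the genome,
annotation and per-position ground truth byte for byte.

**What the generator does not emulate:** codon correlations along genes,
stop codons and real gene grammar, inverted repeats, introns, and
strand-specific mutational asymmetries.  Passing tests on this generator
therefore demonstrate that the pipeline recovers the structure its own
assumptions encode — frame-specific triplet statistics, GC strata, and
annotation-driven labels — not that any particular real genome will show
the same configuration.

## The analytic oracle and the structure of the mirror

`expectedPhaseDistribution()` gives the exact expected triplet
distribution of each phase over an infinite i.i.d. codon stream: the
aligned frame is the usage itself, the two shifted frames are
marginalizations over adjacent codon pairs (enumerated over all 64 × 64
pairs), and backward phases reduce to the reverse-complement coordinate
permutation $\rho$ applied to the forward-type readings.  Under the
package's label convention the identity is particularly clean:
$\mathrm{B}_k = \rho(\mathrm{F}_k)$ computed from the backward usage.

A consequence worth stating explicitly: whenever the backward genes are
reverse-complemented draws from *any* single usage, the backward centroid
set is the $\rho$-image of the forward-type readings taken in reversed
frame order, and since $\rho$ is an isometry the two expected circuits are
exactly counter-directed.  **Mirror symmetry is structural for any
matched-strand i.i.d. codon model** — a satisfying account of why the
mirror configuration is so stubbornly universal in genomes whose two
strands share triplet statistics.  Conversely, a rotational
(bacteria-like) configuration cannot be produced by the mirrored
construction at all.  The control conditions (`controlSpec()`) therefore
use a frozen pair of genuinely independent per-strand usages
(`controlCodonUsages()`), selected with the analytic oracle and pilot
simulations so that the expected circuits run in the same direction with
a margin well above centroid sampling noise.  The control demonstrates
that the classifier distinguishes the two configurations; it is a
designed control, not a claim about what bacterial codon usage looks
like.

## Numerical choices

* **Standard deviation flavor** for the excluded triplet: population SD
  (divisor $n$); ties broken lexicographically (AAA first).  The exclusion
  is computed per genome over that genome's fragment ensemble.
* **Ambiguous bases** are kept in the sequence; any triplet window
  containing one is skipped and $M$ reduced, preserving normalization.
* **K-means** verification: Euclidean inertia, 10 restarts under a fixed
  seed, `iter.max` 100; clusters renumbered by ascending centroid norm so
  assignments are comparable across runs and seeds.
* **PCA** signs: each component flipped so its largest-magnitude loading
  is positive; embeddings of rank < 3 raise an error carrying the
  achievable rank.
* **Junk threshold** "half or longer" with odd $L$: $\lceil L/2 \rceil$
  (302 positions for $L = 603$); the junk rule precedes the tail rule,
  which precedes the frame rules.
* **Half-open questions resolved deterministically**: pseudogenes and
  partial features count per their parsed feature type; circular records
  are stored and fragmented linearly, with origin-spanning features split
  at the origin on input.

## Problem sizes

The test suite exercises the full default conditions (120 kb, ~10 855
fragments) for the end-to-end structure checks, a 30 kb reduced spec for
pipeline mechanics, and pools 24 generated genomes for the
centroid-convergence check — overlapping fragments re-read the same
codons, so each genome contributes only its distinct codon content
(~13 700 codons per phase) to those estimates, and a single genome cannot
beat an L1 error of about 0.03 regardless of fragment count.  The
acceptance script runs the default conditions once per quantity.

## Known limitations

* Real-record checks (whole-genome GC, phase-abundance statistics of
  specific accessions) require the corresponding EMBL records; the package
  ships only their published lengths, and the tests for those values
  report failure until the records are placed under
  `inst/extdata/real/` (see the README).
* The published orientation (U/D) tables cannot be re-derived without the
  original analysis' sign conventions; only internal consistency is
  testable.
* The generator's i.i.d. codon model understates within-gene
  heterogeneity; empirical phase clusters of real genomes are broader and
  can overlap in ways the synthetic conditions do not produce.
* Corpus-scale census quantities (cross-genome correlation tables,
  excluded-triplet tallies over hundreds of genomes) are out of scope at
  desk scale; the qualitative patterns are asserted on synthetic corpora
  instead.
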