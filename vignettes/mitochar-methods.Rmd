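---
title: "Methods: mitogenome characterization, cloverleaf folding and ML phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization, cloverleaf folding and ML phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

mitochar reproduces, as reusable and testable code, the analysis a vertebrate
mitogenome announcement runs: characterizing an annotated circular genome
(gene lengths, intergenic spacing, start/stop codons, base composition, skews,
codon usage), predicting tRNA cloverleaf secondary structures, and placing the
genome on a maximum-likelihood phylogeny. This vignette describes the models
and procedures, the parameters that matter, and the choices made where the
design was genuinely open.

## Coordinate conventions and the characterization table

Annotation tables print 1-based, fully closed intervals on the heavy (H)
strand; all internal arithmetic uses that convention. A feature's length is
`to - from + 1`. The intergenic column for row *i* (in table order) is
`from(i) - to(i-1) - 1`, computed over H-strand coordinates regardless of
strand, with negative values denoting overlap and the first row set to 0.
This is the only convention that reproduces the printed values of the
pangolin-style reference annotation shipped in `inst/extdata/` — including a
40 bp ATP8/ATP6 overlap and a 27 bp overlap of ND2 with its upstream tRNA.
The wrap-around gap from the last feature back to the first on the circle is
reported as an attribute, never as a row. Wrap-around *features* are rejected:
none occur in the reference table, and supporting them would complicate every
downstream consumer for no tested benefit (a documented limitation).

Protein-coding genes are checked under the vertebrate mitochondrial code
(NCBI table 2): any ATN triplet is accepted as a start (a non-ATN start
warns rather than errors, since other taxa violate the rule), and the stop is
classified from `length mod 3`: a remainder of 0 requires a complete stop
triplet from {TAA, TAG, AGA, AGG}; a remainder of 1 requires a trailing `T`
(reported `T--`); a remainder of 2 requires trailing `TA` (reported `TA-`).
Incomplete stops are completed to UAA by polyadenylation after transcription,
which is why annotation tables print them this way. The full code-table stop
set is used even though the reference genome only exhibits TAA and AGA:
code-table correctness beats an observed subset.

The shipped reference table has three internal inconsistencies worth knowing
about, all asserted in the test suite rather than papered over: the control
region's printed length (1049) disagrees with its own coordinates
(15521..16570 = 1050) — lengths here are always computed from coordinates;
the COX1 composition row's percentages sum to 99.00, not 100, although its
printed skews are consistent with its printed percentages; and the pooled
tRNA length (1,495) is 2 nt short of the sum of the printed tRNA lengths
(two single-base overlaps), so that number is not targeted.

## Composition and skew

AT skew is `(A - T) / (A + T)` and GC skew `(G - C) / (G + C)`; both are
scale-invariant (counts or percentages give the same value) and flip sign
under reverse complementation, which is why the one L-strand protein-coding
gene (ND6) shows inverted skews when composed — as all rows are — on its
coding strand. N bases are excluded from numerator and denominator.

Two provenances of a "recomputed" skew must be kept apart. Skews from raw
counts are the primary statistic (`composition_report()`); skews recomputed
from *printed, rounded* percentages (`skews_from_percentages()`) exist to
verify published tables and can differ in the fourth decimal — the reference
genome's whole-genome AT skew is 0.1515 from counts but 0.1519 from the
1-dp percentages 34.5/25.4. Display rounding is half-up, 2 decimals for
percentages and 4 for skews, matching how such tables print.

Pooled rows (all rRNA, all PCGs, all tRNA) concatenate coding-strand gene
sequences, so positions inside gene overlaps count once per gene; that plain
concatenation is what makes the pooled PCG length the simple sum 11,396.

Codon usage is tallied in frame from base 1 of each coding sequence;
incomplete trailing codons are ignored and internal in-frame stops warn with
gene and codon position. RSCU is a codon's count divided by the mean count of
its synonymous family (stop codons form their own family and get no RSCU), so
a uniformly used family has RSCU 1 throughout.

## tRNA cloverleaf folding

The folder is a constrained exhaustive search, not a thermodynamic one. The
claim a mitogenome paper makes about tRNA structure is topological — four
base-paired arms, or a missing DHU arm — so the score is simply the number of
base pairs, which keeps an exact brute-force oracle feasible and is how the
test suite validates the implementation. Stems must pair perfectly
(Watson-Crick or G·U wobble, T read as U); bulges and mismatches within stems
are not modeled (a documented limitation relative to covariance-model
annotators). All geometry bounds live in one config object
(`cloverleaf_geometry()`): acceptor stem 6-7 bp, DHU stem 3-4 bp with a
4-11 nt loop, anticodon stem 4-5 bp with a fixed 7 nt loop carrying the
anticodon at loop positions 3-5, variable region 3-23 nt, TψC stem 4-5 bp
with a 4-9 nt loop, up to 3 nt and 2 nt of inter-arm spacers, and up to 5 nt
of 3' tail. These are canonical tRNA dimensions; users can widen them.

Every placement consistent with the bounds (and with the annotated anticodon,
when given) is enumerated; the maximum-pairs placement wins, with ties broken
by more Watson-Crick pairs, then smaller total loop length, then the leftmost
DHU arm, then enumeration order — fully deterministic. If *no* full placement
exists (equivalently, no DHU stem of at least 3 bp fits between the acceptor
5' half and the anticodon arm), the search reruns without the DHU arm and
returns a degenerate cloverleaf, the well-known mitochondrial tRNA-Ser(GCU)
morphology. Internally the search is O(1) per placement after computing
run-length tables of maximal perfect stems, so the full enumeration stays
fast at tRNA scale.

## Alignment

The built-in aligner exists to make the phylogenetics stage self-contained at
the near-identical divergences mitogenome comparisons involve; it is not a
general-purpose aligner. Pairwise and profile-profile alignment use global
Needleman-Wunsch/Gotoh with affine gaps (defaults: match 2, mismatch -1, gap
open -5, gap extend -1; end gaps penalized) and deterministic tie-breaking
(substitution preferred over gaps, gap in the first profile preferred over
the second). Progressive alignment orders merges with a UPGMA guide tree on
k-mer distances. Column scores between profiles are expected sum-of-pairs
with gap/N residues scoring zero. The dynamic program keeps rolling score
rows and byte traceback matrices, so memory is one byte per cell per state.

## The GTR+F+I+G4 model and tree search

The substitution model is the general time-reversible rate matrix with six
exchangeabilities (GT fixed at 1 during optimization), empirical base
frequencies counted from the alignment ("+F"), a proportion `p_inv` of
invariant sites ("+I") and discrete-gamma rate heterogeneity with 4
equal-probability categories whose rates are the conditional means of their
quantile bands ("+G4"), rescaled so the +I+G mixture has mean rate 1 — branch
lengths are therefore expected substitutions per site. The rate matrix is
scaled to unit mean rate at stationarity and exponentiated through the
eigendecomposition of its symmetrized form.

Likelihoods come from Felsenstein pruning over compressed site patterns, with
gaps and N treated as fully missing. Per-edge rescaling of partial
likelihoods is engaged lazily: the unscaled pass is used unless a site
underflows, which cannot happen at the tree depths used here but is guarded
anyway. The test suite pins the implementation to three independent
references: a brute-force sum over internal-node state assignments on small
trees, the Jukes-Cantor closed form on two taxa, and `phangorn::pml` on
simulated data (phangorn is used only as a cross-check, never as the
implementation).

`fit_and_search()` starts from neighbor joining on JC69 distances, then
alternates bounded coordinate descent — branch lengths first, then
exchangeabilities (log scale), then the gamma shape, then `p_inv`, each by
golden-section line search, tolerance 1e-6 log-likelihood units — with
nearest-neighbor-interchange hill climbing, re-optimizing fully after each
accepted move, until no NNI improves the likelihood. Everything is
deterministic given the input; non-convergence at the round cap returns the
best-so-far fit with a warning flag. Bootstrap support is the standard
nonparametric column-resampling bootstrap with the whole search rerun per
replicate; supports are percentages of replicates containing each original
bipartition. An ultrafast approximation was deliberately not implemented: at
package scale the plain bootstrap is affordable and has the cleaner contract.

Monophyly classification requires an explicit outgroup (or an already-rooted
tree): published mitogenome phylogenies rarely state their rooting, so making
it an argument keeps the test honest. A group is monophyletic if it is
exactly a clade's tip set; otherwise paraphyletic if the non-group tips
inside its minimal spanning clade form a single clade; otherwise
polyphyletic.

## The synthetic-data generator

Real annotated pangolin-scale mitogenomes cannot ship with the package, so
`generate_mitogenome()` realizes the packaged 38-feature plan (13 PCGs, 22
tRNAs, 2 rRNAs, control region, with the reference annotation's exact
lengths, strands, spacings — including the -40 and -27 overlaps — start
codons and stop types) into a concrete sequence with known truth. Per-region
base-composition targets default to pangolin-like values: A-rich and G-poor
overall, with category-specific profiles for PCGs, structural RNAs and
non-coding sequence. PCGs are codon-sampled with in-frame stops rejected;
tRNAs are built from sampled valid arm geometries with perfectly paired stems
(10% G·U); spacers and RNAs are drawn at their composition targets. All
sampling is driven by a single seed: the same seed yields a byte-identical
genome.

Gene overlaps make one-pass generation impossible — ND2's forced ATG start
lies inside tRNA-Met, ATP8's TAA stop inside ATP6 — so features are written
in table order (later features win overlapped positions) and a final pass
force-writes every PCG's start and stop bases, then resamples any in-frame
stop codon that has at least one unforced base. Templates whose PCG start/stop
constraints demand two different bases at one position are rejected as
unrealizable before any sampling. Two documented consequences: a tRNA whose
span was partially overwritten by an overlapping gene's forced bases may no
longer fold (structure round-trip tests therefore use standalone
`generate_trna()` output, and the genome pipeline reports such tRNAs as
unfoldable rather than failing), and codon-level stop rejection biases PCG
composition slightly off target (the ±1.5 percentage-point composition
guarantee applies to spacer sequence, where sampling is unconstrained).

`generate_trna()` records arm-coordinate truth. By default it resamples
constructions whose loops accidentally admit an alternative placement that
would outrank the constructed arms under the folder's tie-breaks, so folding
recovers the construction; with `avoid_ambiguity = FALSE` (used inside genome
generation, where arm truth is not consumed) the first draw is kept.

`evolve_sequences()` simulates site-independent evolution along a tree under
the same GTR+I+G4 machinery used for inference: each site draws a rate (0
with probability `p_inv`, else a rescaled gamma-category rate) and each
branch applies eigendecomposition-based transition probabilities. Indels are
not simulated; alignment tests use engineered deletions instead, which keeps
alignment truth exact.

What passing tests on synthetic data do *not* show: real mitogenomes have
strand-asymmetric mutational processes, composition heterogeneity along the
molecule, and tRNA stems with bulges and mismatches; the generator emulates
none of these. The synthetic data validates the *arithmetic and algorithms*,
not the biology.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is meaningfully exercised: oracle
equivalence for the likelihood on 4-5 taxa and a handful of sites (the
enumeration oracle is exponential in internal nodes); GTR+G parameter
recovery on a 5-taxon, 100,000-site simulation (large enough that 10%
relative error on exchangeabilities and gamma shape is a fair bar); topology
recovery on 6 taxa and 1,000 sites; cloverleaf oracle equivalence on 60-75 nt
sequences. Optimizer bounds are branch lengths in [1e-8, 10], exchangeabilities
in [1e-4, 200], alpha in [0.02, 50], `p_inv` in [0, 0.9]; golden-section
tolerances are 1e-7 (branch lengths) and 1e-5 (model parameters). Degenerate
inputs are handled explicitly: alignments with no variable sites fit a
near-zero-length tree and flag bootstrap supports as undefined; all-N or
empty sequences error at validation.
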