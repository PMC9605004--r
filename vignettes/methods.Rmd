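---
title: "Methods: comparative analysis of secreted fungal enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of secreted fungal enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoenz)
```

Entomopathogenic fungi kill insects by secreting a battery of exoenzymes —
subtilisin-like proteases, lipases, chitinases — that degrade the cuticle
and, for pests that overwinter in cocoons, must remain active at low
temperature. `exoenz` packages the desk side of characterising such
enzymes: homologue mapping across reference proteomes, distance-based
phylogenetics, composition-based thermal-adaptation classification, and
motif scanning. This vignette explains each model, its assumptions, the
tunable parameters, and the design choices taken where more than one
reasonable implementation exists.

## Blast score ratio (BSR)

For a query protein $q$ and a reference proteome $R$, the BSR is

$$\mathrm{BSR}(q, R) = \frac{\max_{r \in R} S'(q, r)}{S'(q, q)},$$

where $S'$ is the bit score of the optimal local alignment. A BSR of 1
means the proteome contains (at least) an exact copy of the query; 0 means
no match; values over 0.4 are conventionally read as "a homologue is
present". Calls are strict (`value > threshold`): a cell exactly at the
cutoff is not a homologue.

Scores come from an exact affine-gap Smith–Waterman dynamic program
(`src/sw.cpp`), not a heuristic seeded search: at the scale of a handful of
query enzymes against proteome files, exactness is affordable and makes the
engine testable against an exhaustive enumeration oracle. Raw scores are
rescaled to bits with the Karlin–Altschul formula
$S' = (\lambda S - \ln K)/\ln 2$ using the published gapped BLOSUM62/11/1
constants $\lambda = 0.267$, $K = 0.041$ (configurable via
`alignment_params()`). Numerical conventions:

* a raw score of 0 (no positive-scoring local alignment) reports 0 bits,
  and the formula's value is floored at 0;
* hits under `bit_floor` (default 1 bit) count as "no match" and give
  BSR 0;
* the denominator is the query's **self**-alignment bit score, the standard
  BSR reference; ratios are clamped to $[0,1]$ and any pre-clamp value
  above 1 (a reference out-scoring the self-alignment, impossible for
  BLOSUM62's dominant diagonal but possible for exotic matrices) is
  surfaced as a warning;
* `X` scores 0 against every residue, so unknown positions neither help
  nor hurt;
* a length-1 gap costs `gap_open + gap_extend` (the BLAST convention).

## p-distance neighbor joining with bootstrap

Relatedness of enzyme families is summarised from a user-supplied protein
MSA (alignment construction itself is out of scope — any aligner works).
The evolutionary distance is the p-distance: the proportion of differing
amino acids per comparable site. Gaps and `X` are not comparable; the
default **pairwise deletion** uses each pair's own comparable sites, and
**complete deletion** (drop any column with a gap anywhere) is switchable —
published MEGA-style analyses do not always say which they used, so the
choice is explicit here.

Trees are built with Saitou–Nei neighbor joining. Two numerical choices
matter:

* **Tie-breaking.** When two pairs have exactly equal Q criteria (common in
  bootstrap resamples of short alignments), the pair whose clusters have
  the lexicographically smallest tip labels is joined. This is
  deterministic *and* independent of taxon input order, which keeps
  bootstrap supports invariant under row reordering — an index-based
  tie-break would be deterministic but order-sensitive.
* **Negative branch lengths** (a known NJ artefact on non-additive input)
  are clamped to 0; the count of clamped edges is kept in the tree's
  `"clamped"` attribute.

Bootstrap support for each internal edge is the percentage of
column-resampled replicates whose NJ tree contains the same bipartition
(1000 replicates is the conventional setting; tests use 10–50 to stay
fast). A replicate that leaves some pair with zero comparable sites is
redrawn, up to 100 times, so supports are always over the requested number
of valid replicates. Supports are written as integer internal-node labels
in Newick.

On any additive distance matrix NJ provably recovers the generating
topology; the test suite verifies this against an exhaustive
least-squares topology search for 5–6 taxa and against the generating
trees for up to 8 taxa, and cross-checks topologies against an independent
NJ implementation (`ape::nj`).

## Composition-based thermal classification

Cold-adapted (psychrophilic) enzymes tend to trade conformational rigidity
for flexibility; compositionally this shows up as more glycine and less
glutamic acid and tyrosine than in mesophilic and thermophilic
counterparts. The classifier formalises the standard literature-panel
comparison:

1. **Composition.** Each protein's 20 residue percentages
   (`aa_composition()`, `X` excluded from numerator and denominator; the
   vector always sums to 100).
2. **Testing.** For each residue and each unordered pair of the three
   groups, a Welch unequal-variance t test (`welch_t`). "A t test between
   the three groups" is read as all three pairwise tests — an omnibus
   ANOVA is deliberately not substituted, staying literal to the stated
   procedure; Welch rather than Student because panel variances differ.
   Degenerate constant samples follow fixed conventions (equal constants:
   p = 1; unequal constants: p = 0 with a `degenerate` flag).
3. **Multiplicity.** The two-stage Benjamini–Krieger–Yekutieli step-up
   procedure at Q = 1% (`bky_two_stage`), applied **jointly** across all
   60 residue-by-pair p-values, because the study-wide Q is stated once
   for the whole analysis, not per residue.
4. **Axes.** Residues with at least one rejected pair, ordered by smallest
   p-value and capped at 3 (`select_axes`) so the result is a plottable 3D
   coordinate system.
5. **Classification.** The published practice is to eyeball the 3D
   scatter; `classify_thermal()` formalises it as nearest group centroid
   in axis space (Euclidean, ties reported as all tied labels), and always
   returns the per-group distances so users can apply their own rule.
   Residues outside the axes never affect the result.

`fit_thermal_model()` also accepts pre-chosen axes, which skips testing —
useful for single-protein groups or for re-using published axes.

## Motif scanning

The motif grammar is exactly what the signatures are written in: literal
residues plus the `X` wildcard (`GXSXG`, `SXGG`, `DXXDXDXE`). No PROSITE
ranges, no HMMs — the claims stay literal. Coordinates are 1-based on the
full provided chain (no signal-peptide renumbering), matching
Ser<sup>226</sup>-style position statements; `catalytic_serine()` returns
the anchor (central serine) of the leftmost `GXSXG` hit. Overlapping
occurrences are all reported.

## Predicted masses

`molecular_mass()` sums **average** (isotope-weighted) residue masses plus
one water and reports kDa — the scale used for "~ kDa" gel annotations;
monoisotopic masses would be systematically low by ~0.06%. Masses are
computed on the full chain; whether a published "~ kDa" refers to the
precursor or the signal-cleaved mature chain is often unstated, so no
cleavage is attempted and users can pre-trim.

## What the synthetic generators emulate

The generators produce data with exactly the statistical structure each
stage assumes, and no more:

* `generate_thermal_panels()` draws residue-wise i.i.d. sequences from a
  baseline simplex (default uniform 5%) with per-group percentage-point
  shifts — default cold: Gly +4, Glu −2, Tyr −1.5; thermophilic mirrored;
  mesophilic at baseline — 20 proteins per group of 200–400 residues.
  The shift directions encode the cold-adaptation signal; the magnitudes
  are chosen once as a clearly detectable but not overwhelming effect at
  panel sizes of 15–20 (roughly 3–8 pooled standard errors between extreme
  groups).
* `evolve_family()` mutates a uniform-random root along a known tree:
  per site, a Poisson number of events per branch (mean = branch length in
  expected substitutions/site), each replacing the residue with a
  uniformly chosen *different* one. This is the simplest model with a
  tractable Monte-Carlo oracle; multiple hits saturate exactly as the
  oracle predicts.
* `generate_null_panel()` draws all three groups from one common uniform
  composition distribution, so every rejection of the comparison procedure
  is a false discovery by construction.

Real proteins are not residue-wise i.i.d. (they have domains, signal
peptides, biased local composition) and real families evolve with
rate heterogeneity, indels and empirical exchangeabilities (JTT/WAG).
Passing tests therefore demonstrate that the *procedures* are correct and
calibrated under their stated assumptions — FDR control, axis recovery,
topology recovery, score bounds — not that any particular biological panel
will separate cleanly.

## Problem sizes and seeds

All randomness flows through explicit integer seeds (`withr::with_seed`),
so every generator is a pure function of its arguments. The test suite
runs at desk scale by design: FDR control is checked over 500 null panels
(3 groups × 10 proteins × 150 residues), axis recovery over 50 seeds at 20
proteins/group, alignment against the enumeration oracle on all pairs up
to length 6, NJ consistency on 100 random trees of up to 8 taxa, and
bootstrap behaviour at 10–50 replicates. The same computations scale to
1000-replicate bootstraps and full proteome directories through the same
functions.

## Known limitations

* No E-values and no heuristic search: the aligner is exact but
  quadratic, so genome-scale all-vs-all scans are out of scope.
* No model-corrected distances (Poisson/JTT): p-distance is the stated
  method; saturated alignments will compress deep branches.
* The thermal classifier is a nearest-centroid rule on at most three
  composition axes — intentionally simple and auditable, not a tuned
  discriminant (no LDA/SVM).
* GenBank accession fetching is out of scope; users supply FASTA.
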