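# exoenz

Comparative sequence analysis of exoenzymes secreted by entomopathogenic
fungi — the proteases, lipases and chitinases these biocontrol agents use
to degrade insect cuticle, including at the low temperatures where pests
overwinter inside cocoons. The package is aimed at researchers
characterising such enzyme batteries from a sequenced strain: given the
enzyme sequences, it answers *which related fungi carry homologues*, *how
the enzyme families are related*, *whether the enzymes look cold-adapted*,
and *where their catalytic signatures sit*.

Four connected analyses:

* **Blast score ratio (BSR) homologue mapping.** For query $q$ against
  reference proteome $R$,
  $\mathrm{BSR}(q,R) = \max_{r \in R} S'(q,r) \,/\, S'(q,q)$,
  with $S'$ the Karlin–Altschul bit score
  $S' = (\lambda S - \ln K)/\ln 2$ of an exact affine-gap Smith–Waterman
  alignment (BLOSUM62, gap 11/1, $\lambda = 0.267$, $K = 0.041$ by
  default). BSR 1 = identical match present, 0 = no match, and values
  strictly over 0.4 are called homologues.
* **p-distance neighbor-joining phylogenetics** on a user-supplied protein
  MSA, with column-resampling bootstrap supports and Newick output.
* **Thermal-adaptation classification** from whole-protein amino-acid
  composition: pairwise Welch t tests per residue across
  cold/mesophilic/thermophilic panels, the two-stage
  Benjamini–Krieger–Yekutieli FDR step-up at Q = 1%, selection of the
  discriminant residues as 3D axes, and nearest-centroid classification of
  query enzymes (cold-adapted proteins characteristically show more Gly
  and less Glu/Tyr).
* **Motif scanning** for the lipase `GXSXG` nucleophile elbow and the
  family-18 chitinase `SXGG` / `DXXDXDXE` signatures, with 1-based
  catalytic-residue coordinates, plus average-mass prediction in kDa.

Seeded synthetic-data generators (`generate_thermal_panels`,
`evolve_family`, `generate_null_panel`) reproduce the statistical
structure each stage assumes, so the whole pipeline is testable offline.

## Worked example

```r
library(exoenz)

## homologue mapping: one query enzyme vs two reference "proteomes"
fam <- evolve_family(ape::read.tree(
  text = "(chi_query:0.08,chi_sib:0.08,chi_far:0.45);"),
  root_length = 250, seed = 42)
queries   <- fam$records[1, ]
proteomes <- list(close_species   = protein_set("hit1", fam$records$sequence[2]),
                  distant_species = protein_set("hit2", fam$records$sequence[3]))
build_bsr_matrix(queries, proteomes)
#> bsr_matrix: 1 queries x 2 proteomes; threshold > 0.4
#>           close_species distant_species
#> chi_query         0.831           0.526
```

Both ratios clear 0.4, so both reference species carry a homologue; the
closer relative scores 0.831 because fewer substitutions separate it from
the query (identity would give exactly 1, no detectable match 0).

```r
## thermal classification on labelled composition panels
panels <- generate_thermal_panels(seed = 1)   # cold / mesophilic / thermophilic
model  <- fit_thermal_model(lapply(panels, composition_matrix), q = 0.01)
model
#> thermal_model: axes E, G, Y | q = 0.01
#>                 E    G    Y
#> cold         3.06 9.19 3.75
#> mesophilic   4.75 5.03 5.23
#> thermophilic 7.19 0.98 6.47

classify_thermal(composition_matrix(panels$cold)["cold_02", ], model)
#> $label
#> [1] "cold"
#> $distances
#>         cold   mesophilic thermophilic
#>     2.636350     3.223035     7.848431
```

The FDR-controlled tests recover glutamic acid, glycine and tyrosine as
the discriminant axes; centroids are per-group mean percentages on those
residues, and the query protein sits nearest the cold centroid (Euclidean
distance 2.64 vs 3.22 and 7.85). Distances are always reported: proteins
near a centroid boundary classify with small margins.

```r
## motif scanning and predicted mass
find_motif("MKLAVGASAGKLDE", "GXSXG")
#>   protein_id pattern_name start end match anchor_position
#> 1       <NA>        GXSXG     6  10 GASAG               8
molecular_mass("MKLAVGASAGKLDE")
#> [1] 1.3896   # kDa
```

The `GXSXG` lipase motif occupies residues 6–10 and its catalytic serine
(the anchor) is residue 8 of the chain.

`run_study()` chains every stage from a `study_config()` (or a plain
`key = value` file) and writes TSV tables, a Newick tree and a JSON
manifest; `inst/scripts/exoenz` wraps the same functions as shell
subcommands (`compose`, `thermal`, `bsr`, `phylo`, `motifs`, `simulate`,
`run-study`).

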