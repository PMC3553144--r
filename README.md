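# ankevol

Evolutionary and structural analysis of ankyrin-repeat protein families.

The IκB proteins that inhibit the NF-κB transcription factors are a family
of ankyrin-repeat domain (ARD) proteins whose subfamilies differ in repeat
number, binding partners and turnover. Understanding how such a family
diversified requires answering, in one coherent workflow: how similar are
the subfamilies (and which homologs even belong)? what does their
phylogeny look like, and how robust is it? after duplication, which sites
changed *rate* (type I functional divergence) and which swapped to a
radically different residue class (type II)? is the repeat domain under
purifying selection? and do the domain's intrinsic motions — predicted by
an elastic network model and observed across crystal/NMR conformers —
agree on where the flexibility lives?

`ankevol` implements that workflow as composable R functions plus a
pipeline driver, testable end to end on synthetic data with known ground
truth.

## The models at the core

* **Similarity / filtering** — Needleman–Wunsch global alignment (affine
  gaps, BLOSUM62, open 10 / extend 0.5), inter/intra-group min–max range
  tables, strict length-window + identity homolog filtering, and
  PEST-motif detection (score `0.55·mass% − 0.5·hydrophobicity`,
  threshold +5).
* **Phylogeny** — Jukes–Cantor protein distances with pairwise deletion,
  `d = −(19/20)·ln(1 − (20/19)p)`; Saitou–Nei neighbor joining
  (Studier–Keppler Q); nonparametric bootstrap supports; outgroup rooting.
* **Type I divergence (Gu)** — per-site Fitch substitution counts in two
  clusters; mixture likelihood in which a site's gamma rate is shared with
  probability `1−θ` and decoupled with probability `θ`; boundary-mixture
  LRT, standard errors, per-site posteriors, candidate sites at
  posterior > 0.85.
* **Type II divergence** — sites frozen within clusters but fixed for
  different residues between them, scored by a rate-coupled posterior
  ratio (cutoff > 17) and classified by biochemical property change
  (`+`, `−`, hydrophobic, hydrophilic).
* **Ka/Ks** — Nei–Gojobori counting with pathway averaging and nucleotide
  JC correction; site classes purifying / neutral / positive.
* **ANM** — Cα Hessian at a 15 Å cutoff, `H_ij = −(γ/r²)·r rᵀ` blocks,
  3N−6 modes, mean-square fluctuations `Σ |U_k(i)|²/λ_k`, theoretical
  B-factors `(8π²/3)·msf` with least-squares scaling and Pearson r.
* **Ensemble PCA** — reference-anchored conformer matching, iterative
  Kabsch superposition, coordinate-covariance PCA, PC-space clustering,
  and PCA↔ANM mode overlap (absolute cosines and projection
  correlations).

Synthetic-data generators (ankyrin-like Cα chains, conformer ensembles
with planted deformation directions, families evolved on known trees with
planted rate shifts, codon alignments with per-site ω) provide the ground
truth every stage is validated against.

## Worked example

Build a 7-repeat ankyrin-like chain, compute its ANM modes, generate a
conformer ensemble displaced along the lowest mode, and confirm that
ensemble PCA finds that motion; then estimate type I divergence on a
simulated family with a planted rate shift:

```r
library(ankevol)

ank   <- make_ankyrin_calpha(7, seed = 1)          # 231 residues
modes <- anm_modes(build_hessian(ank, r_c = 15))
modes
#> <mode_set> anm: 687 modes over 231 atoms (leading fraction 0.08)

me  <- make_ensemble(ank, directions = matrix(modes$vectors[, 1], 1),
                     variances = 4, M = 150, seed = 2)
pca <- ensemble_pca(iterative_superposition(me$ensemble))
mode_overlap(pca, modes)
#> <overlap_report> |cosine| overlap:
#>     ANM1  ANM2  ANM3
#> PC1    1 0.000 0.000
#> PC2    0 0.051 0.030
#> PC3    0 0.001 0.031
```

PC1 of the superposed ensemble is (to 3 decimals) exactly the ANM mode the
conformers were displaced along, and the conformer projections on the two
axes correlate at r = 1.00 — the self-consistency behind comparing
observed conformational spread with network-model predictions.

```r
tree <- divergence_study_tree()                    # two 8-taxon clusters
fam  <- simulate_family(tree, 1000, alpha = 0.5,
                        clusterB = paste0("b", 1:8),
                        theta = 0.6, seed = 3)     # 60% rate-shifted sites
pair <- cluster_pair(fam$alignment, tree,
                     paste0("a", 1:8), paste0("b", 1:8))
estimate_type1(fitch_counts(pair), seed = 1)
#> <type1_result> theta = 0.544 +/- 0.052, LRT = 146.47 (p = 5.13e-34), alpha = (0.90, 0.67)

property_change_label("Q", "K")                    # type II property map
#> [1] "Hydrophilic/+"
```

The estimator recovers the planted coefficient (θ̂ = 0.54 against a
planted 0.6; parsimony counting attenuates mildly — see the methods
vignette) with a decisively significant likelihood-ratio test.

A fully synthetic end-to-end run of every stage, writing TSV reports and a
manifest, is one call (or `exec/ankpipe demo` from the shell):

```r
demo_pipeline("ankevol_demo", seed = 1)
```

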