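---
title: "Methods: evolutionary and structural analysis of ankyrin-repeat families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary and structural analysis of ankyrin-repeat families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ankevol is a multi-stage pipeline for studying how a family of
ankyrin-repeat proteins — the IκB inhibitors of NF-κB are the motivating
case — diverged in sequence, function and structural dynamics. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, what the synthetic-data generators emulate, and the
numerical and design choices a maintainer should know about. No empirical
claim is made here beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Sequence similarity and homolog filtering

Pairwise comparisons use optimal global (Needleman–Wunsch) alignment with
affine gaps, BLOSUM62, gap open 10 and gap extension 0.5 (a gap of length
$k$ costs $10 + 0.5k$). Identity and similarity percentages divide by the
full alignment length, gap columns included; a column is *similar* when it
is identical or its substitution scores positively. The ambiguity residue
`X` is scored 0 against everything and never counts as identical — it
neither rewards nor penalises a match. Family-level summaries
(`group_range_matrix()`) reduce all cross-group alignments to min–max
ranges, the usual inter/intra-subfamily similarity table.

Homolog filtering (`filter_homologs()`) keeps hits whose ungapped length
lies *strictly* inside a per-subfamily window and whose global identity to
the query exceeds a threshold (default 35%). Both bounds are exclusive,
matching the ">X <Y" convention such searches are usually reported with.

## PEST motifs

PEST regions — proline/glutamate/serine/threonine-rich stretches flanked by
positive residues, associated with rapid turnover — are detected with the
classical composition-and-score rule: a candidate is a maximal stretch
between K/R/H (or the termini) of length ≥ 12 containing at least one D/E,
one P and one S/T. The score is

$$ 0.55 \cdot \mathrm{PEST\ mass\%} - 0.5 \cdot \mathrm{hydrophobicity}, $$

where the mass percent of D/E/P/S/T is corrected by one equivalent of each
of (D or E), P and (S or T) — when both members of a category occur we
subtract the lighter one, the least punitive reading of the one-equivalent
rule — and the hydrophobicity index is the mean Kyte–Doolittle hydropathy
rescaled to $10\,\mathrm{KD} + 45$ (range 0–90). Scores ≥ +5 are flagged
valid. The reference EMBOSS implementation is not available in this
environment, so the tests pin independent hand arithmetic rather than a
binary-to-binary comparison.

## Distances, neighbor joining, bootstrap

Protein distances use the 20-state Jukes–Cantor correction
$d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ with **pairwise deletion**:
each pair is compared only at columns where both rows carry a residue
(gaps and `X` excluded). Mismatch proportions at or beyond the 19/20
saturation point receive a configurable ceiling (default 5
substitutions/site) and a flag.

`nj_tree()` implements Saitou–Nei neighbor joining with the
Studier–Keppler Q-criterion. Ties in Q are broken by the smallest (i, j)
index pair so results are deterministic; negative branch-length estimates
are clamped to zero with the deficit moved to the sibling edge, preserving
the joined path length, so additive matrices are still reproduced exactly
(verified to 1e-9 in the tests). Bootstrap supports
(`bootstrap_support()`) resample columns with replacement, one seeded RNG
stream, indices drawn replicate-major; the support of each bipartition of
the point-estimate tree is the percentage of replicates containing it.
Replicates that fail (e.g. a pair left with no comparable sites) are
skipped and counted. Outgroup rooting splits the subtending edge 50/50.

## Type I functional divergence

Type I divergence (rate decoupling after duplication) is estimated from
per-site substitution counts in two clusters. Counts come from Fitch
parsimony on each cluster's subtree (`fitch_counts()`), with gaps and `X`
treated as missing. The model (`estimate_type1()`):

* each site carries a rate $\lambda \sim \Gamma(\alpha)$ with mean 1;
* with probability $1-\theta$ the two clusters share one rate; with
  probability $\theta$ their rates are independent;
* counts are Poisson with mean $\lambda T_c$ per cluster, marginalised
  analytically (negative-binomial forms, a bivariate one for the shared
  component).

$\theta$, per-cluster shapes $\alpha_A, \alpha_B$ (the shared component
uses their mean) and scales $T_A, T_B$ are fitted by bounded L-BFGS-B with
moment-based starts plus jittered restarts. The LRT against $\theta = 0$
is referred to the boundary 50:50 mixture of a point mass at zero and
$\chi^2_1$ (p ≤ 0.05 means LRT > 2.71); the standard error comes from the
observed information, and per-site posteriors of rate decoupling from
Bayes' rule. Candidate sites use a strict posterior cutoff (default 0.85)
and can be mapped onto a reference row's residue numbering.

**Study design.** The recovery study simulates 8 sequences per cluster
(two representatives from each of four species classes, the grouping
density these comparisons typically use), with tip branches 0.15,
intra-cluster internals 0.08 and 0.2 on each side of the root
(`divergence_study_tree()`). This sits inside the operating regime of
parsimony counting: Fitch counts on an $n$-taxon subtree are capped at
$n-1$ changes per column, so with few taxa or long branches the gamma tail
is truncated, the shape estimate inflates and $\hat\theta$ attenuates.
With 4-taxon clusters at tip length 0.25 this attenuation is severe —
a genuine limitation of count-based divergence estimation, not of this
implementation — and we document rather than hide it: even in the 8-taxon
design, mean $\hat\theta$ runs ~0.1 below the planted value at
$\theta = 0.6$. Null calibration (LRT rejection rate, site false-positive
rate at cutoff 0.85) is run on the model's own count sampler
(`sample_type1_counts()`), which isolates the estimator from the
counting-stage misspecification.

## Type II functional divergence

Type II sites are conserved within each cluster but fixed for different
residues between clusters. `estimate_type2()` scores columns under a
two-class mixture. In the background class a *single* gamma rate per site
drives both the within-cluster counts and the probability that the cluster
ancestors differ (20-state uniform model along the inter-cluster path,
marginalised numerically over the rate). This coupling is the crux: a
site frozen within both clusters implies a low rate, hence a low chance of
an ancestral difference — which is exactly why a frozen fixed difference
is informative. The divergent class expects near-frozen counts (rate
factor `delta = 0.05`) and different consensuses (strict majority; ties
excluded and logged). The mixture weight $\theta_{II}$ is fitted by 1-D
maximum likelihood; each column's score is the posterior ratio
divergent/background, reported on the conventional "> 17" cutoff scale
(it is a ratio, not a probability). Radical sites additionally require a
property-class change under the map: positive {K,R,H}, negative {D,E},
hydrophobic {A,V,L,I,M,F,W}, hydrophilic {S,T,N,Q,C,G,P,Y}.

## Site-wise Ka/Ks

The selection stage uses Nei–Gojobori (1986) counting rather than a
random-effects codon ML model: synonymous/nonsynonymous sites by codon
degeneracy fractions (changes to stop codons excluded from the
denominator), differences averaged over all minimal mutational pathways
(pathways through stops excluded), and the nucleotide Jukes–Cantor
correction applied to both proportions. This deliberate substitution keeps
the stage transparent and desk-testable; it supports the qualitative
question (is a region under purifying selection?) but does not reproduce
ML site calls. Classes: purifying $\omega < 0.9$, neutral within ±0.1 of
1, positive $\omega > 1.1$. Calibration runs on `kaks_study_tree()` (8
taxa at within-subfamily codon divergence, pairwise 0.3–0.6
substitutions/codon) with the uniform-rate codon simulator
(`simulate_codons()`, default $\kappa = 1$, under which NG86 counting is
unbiased). Single-alignment estimates at L = 300 codons carry counting
noise of roughly ±0.12 around 1, so calibration statements are about seed
means; the bias check at L = 1000 holds $|\bar\omega - 1| < 0.1$.

## Anisotropic network model

`build_hessian()` connects every Cα pair at distance ≤ 15 Å (the
"less than or equal" reading of the cutoff) with a uniform spring
$\gamma = 1$; the off-diagonal 3×3 superblock for a connected pair is
$-(\gamma/r_{ij}^2)\, r_{ij} r_{ij}^\top$ and diagonal superblocks enforce
zero row sums, making $H$ symmetric positive semidefinite with the six
rigid-body motions in its null space. Since only relative fluctuations
and correlations are used, $\gamma$ and $kT$ are unit. `anm_modes()` takes
the full dense symmetric eigendecomposition (structures here are a few
hundred residues; no sparse path is warranted) and classifies eigenvalues
below $10^{-8} \lambda_{max}$ as rigid — exactly six must appear for a
connected network, and a disconnected one is flagged at Hessian-build
time. Per-residue mean-square fluctuations sum $|U_k(i)|^2/\lambda_k$ over
non-rigid modes and equal the diagonal block traces of the pseudo-inverse
when all modes are used (asserted against `MASS::ginv` to 1e-8).
Theoretical B-factors are $(8\pi^2/3)\,\mathrm{msf}$, least-squares scaled
onto the experimental column, with the Pearson correlation reported; a
constant experimental column yields `NA`.

## Ensemble PCA and mode overlap

`build_ensemble()` anchors heterogeneous structures on a reference:
residues are matched by global sequence alignment, members covering under
40% of the reference are excluded, and reference positions observed in
fewer than 90% of members are dropped ensemble-wide (remaining gaps are
masked). `iterative_superposition()` alternates Kabsch fits onto the
running mean with mean updates until the mean moves < 1e-5 Å; the first
fit is anchored on the reference frame because averaging members that
still carry arbitrary rigid transforms would produce a meaningless start.
PCA runs on the covariance (divisor $M-1$) of the flattened 3N deviations,
masked positions imputed from the mean so they contribute no variance; no
mass weighting is applied, matching the Cα-only representation. Overlap
between a PC and an ANM mode is the absolute cosine (eigenvector sign is
arbitrary); the projection correlation is the Pearson correlation across
conformers between their scores on the two axes. Both quantities are
reported separately and never conflated.

## Synthetic data: what it does and does not emulate

Every stage is exercised on generated inputs with known truth:

* `make_ankyrin_calpha()` builds an ideal-geometry repeat stack — two
  antiparallel helices (rise 1.5 Å/residue, 100°/residue, radius chosen so
  consecutive Cα sit 3.8 Å apart), a 3-residue hairpin turn, and a
  projecting loop arc to the next repeat (10 Å stacking translation),
  plus 0.03 Å seeded jitter. It reproduces the connectivity and
  tail-flexibility phenomenology of real ankyrin-repeat domains, not their
  side-chain packing or sequence composition.
* `make_ensemble()` plants orthonormal internal deformation directions
  (rigid-body components projected out) with chosen variances, adds a
  0.005 Å isotropic noise floor — kept far below any planted variance so
  the planted modes dominate, as the construction assumes — and optional
  random rigid transforms.
* `simulate_family()` evolves sites down a known tree under mean-1 gamma
  rates with Poisson substitution to uniform alternatives, planting a
  fraction θ of rate-decoupled sites in a chosen clade (stem edge
  included). It realises exactly the model the type I estimator assumes —
  passing recovery tests therefore validates the estimator, not the
  realism of protein evolution (no exchangeability structure, no indels;
  gap handling is tested with hand-made fixtures).
* `simulate_codons()` is GY94-like with uniform codon frequencies and
  per-site ω; stop codons are disallowed and rates are scaled so one unit
  of branch length is one expected substitution per codon site at ω = 1.

All generators are bit-reproducible from (parameters, seed).

## Numerical choices and degenerate inputs

Optimisation is bounded L-BFGS-B with moment starts and jittered restarts;
θ is constrained to $[0, 1-10^{-6}]$ and gamma shapes to $[0.05, 50]$.
NJ Q-ties break on the smallest index pair; saturated JC pairs receive a
ceiling; pairs with zero comparable sites raise an error naming the pair.
Consensus ties, all-missing columns, constant B-factor columns, singleton
groups and M < 3 ensembles are all explicit, tested degenerate cases
rather than silent paths. The type II background likelihood integrates
the gamma rate on a 96-point quantile grid — the integrand is smooth and
bounded, and scores are insensitive to the grid beyond ~48 points.

## Problem sizes

The test suite and acceptance script run deskside: alignments up to
L = 2000 columns and 16 taxa, 200-replicate bootstraps and null studies of
200 simulations, structures up to 231 residues and ensembles up to M = 500
conformers. These sizes were chosen as the smallest at which each
statistical statement stabilises.

## Known limitations

* Parsimony-count attenuation biases $\hat\theta_I$ downward (see above);
  cluster sizes below ~6 taxa or within-cluster divergence beyond ~0.5
  substitutions/site push the estimator out of its operating regime.
* NG86 counting is a stand-in for random-effects codon ML; it will not
  reproduce site-level positive-selection calls made by such models.
* The type II score is a posterior ratio whose absolute scale depends on
  the fitted background; cross-dataset comparisons of scores (as opposed
  to within-dataset rankings and the conventional cutoff) are not
  meaningful.
* Bayesian tree inference, MSA construction, homology modelling and
  molecular dynamics are out of scope; the pipeline consumes precomputed
  alignments and structures.
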