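---
title: "Dowker-complex spectral descriptors for binding-affinity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dowker-complex spectral descriptors for binding-affinity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcscore)
```

## The representation problem

Machine-learning scoring functions for protein–ligand binding stand or
fall with their molecular representation.  `dcscore` represents the
*interaction* between the two molecules — not either molecule alone — as a
family of weighted bipartite graphs, and summarises the multiscale
topology of those graphs with spectral invariants.  The pipeline is:

1. **Binding core.**  All protein atoms within 10 Å of any ligand atom
   are kept (`extract_binding_core()`, inclusive cutoff).  10 Å equals
   the upper end of the distance filtration, so no discarded atom could
   ever enter a thresholded graph.
2. **Element-specific bipartite graphs.**  Protein atoms are split by
   element into {C, N, O, S} and ligand atoms into {C, N, O, S, P, F,
   Cl, Br, I}, giving 36 = 4 × 9 element-pair groups; the electrostatic
   mode adds hydrogen on both sides, giving 50 = 5 × 10 groups.  For one
   group the biadjacency weight between protein atom $v_i$ and ligand
   atom $v_j$ is either the Euclidean distance
   $w_{ij} = d(v_i, v_j)$ (Å) or the logistic electrostatic weight
   $$w_{ij} = \frac{1}{1 + \exp(-c\, q_i q_j / d(v_i, v_j))},$$
   with partial charges $q_i, q_j$ (elementary charges) and coupling
   constant $c = 100$.  The weight lies strictly in $(0,1)$: strongly
   attractive pairs (opposite charges) sit near 0 and therefore enter
   the filtration first, like-charged pairs near 1, uncharged pairs at
   exactly $1/2$.  Note the weight is monotone *increasing* in
   $q_iq_j/d$ — the sublevel filtration sweeps from attractive to
   repulsive interactions.
3. **Dowker complexes.**  Thresholding the weights at $f$ gives a
   relation $E_f = \{(i,j) : w_{ij} \le f\}$.  The Dowker construction
   produces two disjoint simplicial complexes: protein atoms span a
   simplex iff some ligand atom ("witness") relates to all of them, and
   symmetrically for the ligand side.  Dowker's theorem guarantees the
   two sides have isomorphic homology in every positive degree, and in
   degree 0 whenever the thresholded bipartite graph is connected — the
   package's test suite uses this as a global correctness property.
4. **Hodge Laplacians and zeta descriptors.**  For each complex the
   signed boundary matrices $B_k$ give the combinatorial Laplacians
   $L_k = B_k^{\mathsf T}B_k + B_{k+1}B_{k+1}^{\mathsf T}$; $L_0$ is the
   graph Laplacian of the Dowker 1-skeleton.  Each spectrum
   $\{\lambda_i\}$ is summarised by eleven spectral zeta values
   $\zeta(s) = \sum_{\lambda_i > 0} \lambda_i^{-s}$ for
   $s = 5, 4, \ldots, -5$.  Production features use only the
   0-dimensional spectra; higher Laplacians exist for validation.
5. **Feature assembly and regression.**  Zeta rows along the filtration
   grid, over both sides of all groups, concatenate into vectors of
   fixed length 63,360 (distance: 36 × 2 × 80 × 11), 55,000
   (electrostatic: 50 × 2 × 50 × 11) or 118,360 (combined).  A
   gradient-boosted-tree regressor (`dc_gbt()`) maps features to
   pKd/pKi.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| core cutoff | 10 | Å | matches the filtration's upper endpoint |
| distance grid | 2.1, 2.2, …, 10.0 | Å | 80 values; 2.0 dropped (no heavy-atom pair sits below 2 Å, the scale is edgeless) |
| electrostatic grid | 0.02, 0.04, …, 1.00 | — | 50 values; 0 dropped (weights are strictly positive) |
| electrostatic coupling $c$ | 100 | — | keeps $c\,q_iq_j/d$ of order 1–100 for contact-range pairs |
| zeta exponents | 5 … −5 | — | eleven spectral moments, from kernel-dominated to trace-dominated |
| zero tolerance | $10^{-8}\times\max(1, \lambda_{\max})$ | relative | integer matrices; symmetric eigensolvers are accurate far beyond this |
| GBT | 40,000 trees, lr 0.001, depth 6, subsample 0.7, sqrt features, 10 repetitions | — | production profile |
| reduced GBT | 500 trees, lr 0.05 | — | desk-scale profile for tests and examples |

## Numerical and design choices

**Zero eigenvalues are excluded from every $\zeta(s)$.**  For $s > 0$,
$\lambda = 0$ diverges; applying the exclusion uniformly is the only
convention under which all eleven exponents are finite.  Consequently
$\zeta(0)$ equals the Laplacian rank (vertex count minus $\beta_0$ for
$k = 0$) and $\zeta(-1)$ the trace (twice the edge count).

**Vertex convention.**  Under the literal Dowker definition a vertex
exists at threshold $f$ only once it has a relation, so the $L_0$ size
grows along the filtration.  An alternative convention keeps every atom
present as a 0-simplex from the start, which keeps the matrix size
constant; it is available via `vertex_rule = "all"` in
`build_dowker_pair()`.  The two conventions differ only by zero
eigenvalues, so every zeta descriptor — and hence every feature — is
identical under both; only Betti numbers of disconnected thresholds
differ.  The literal rule is the production default.

**Grid endpoints.**  Each grid has exactly its documented count (80/50)
by dropping the edgeless lower endpoint and keeping the upper one; the
final distance value then coincides with the 10 Å core cutoff.

**Orientation and tie-breaks.**  Simplex orientation follows ascending
atom index within each group; spectra are orientation-invariant, so this
is purely internal.  Ranking ties in the screening metrics break by
ascending candidate index, and candidates tied with the last one inside
the top-$x\%$ cut are all included; in the 195-molecule, 1%
configuration an inflated tied top set reports the conventional
enrichment value 66.6.  Predicted screening energies are rounded to two
decimals before ranking, matching the precision of the affinity tables
they emulate.

**Feature layout.**  The index order — group-major (protein element,
then ligand element, in the fixed element orders), then side (protein
before ligand), then ascending filtration, then the exponent order
$5 \ldots -5$ — is frozen and encoded in `feature_names()`.  Any fixed
order serves a tree model equally well; reproducibility demands exactly
one.  Empty element groups contribute all-zero blocks rather than
missing values, so vectors have input-independent length.

**GBT engine.**  `dc_gbt()` drives xgboost configured to behave like a
classical least-squares gradient-boosted tree: row subsampling 0.7,
square-root feature subsampling per split, no L1/L2 regularisation,
depth 6.  Repetition $r$ of `scoring_power()` uses seed
$\text{base} + r - 1$; medians over the repetitions are reported (the
even-count median is the mean of the middle two).

## What the synthetic generator emulates — and what it does not

`random_complex()` draws a ligand uniformly inside the central third of
a 20 Å box with protein atoms around it, element frequencies close to
all-atom compositions (about half hydrogen on the protein side; C
dominating the heavy atoms; occasional S, P and halogens on the ligand),
and uniform partial charges in $[-1, 1]$.  `random_complex_set()`
additionally varies atom counts per complex (protein 30–60, ligand
8–20), because between-complex size variation is the dominant natural
source of contact-count — and hence affinity — variation in real
data sets; with all complexes the same size the planted signal would be
dominated by label noise no matter how good the featurization.

Planted labels are a stated monotone function of heavy-atom
protein–ligand contacts within 5 Å:
$y = 1 + 0.05\,\#\text{contacts} + \mathcal N(0, 0.3^2)$.  Contacts are
counted over heavy atoms because the distance-mode descriptor is built
on heavy atoms; hydrogen positions act as nuisance structure that a
correct implementation should ignore, not signal it should recover.

The generator does **not** emulate covalent geometry, excluded volume,
protonation states, realistic charge distributions, or pose physics.
Passing the recovery test therefore shows that the pipeline preserves
and ranks contact-density information through the full
featurize-train-predict path — it does not certify benchmark accuracy
on real protein–ligand data, which requires curated experimental
structures and affinities.

## Problem sizes in the shipped tests

The property suites run 200 random bipartite graphs (3–6 vertices per
side) through every distinct threshold of their filtrations, checking
Dowker duality ($\beta_1$ always; $\beta_0$ under connectivity;
$\beta_2$ on a subset with one extra enumerated dimension) and
Laplacian-kernel versus rank-oracle Betti numbers.  The end-to-end
recovery experiment uses 150 synthetic complexes (100 train / 50 test)
with the reduced GBT profile; these sizes keep the whole suite at a few
minutes on one CPU while leaving every assertion structural rather than
statistical.

## Known limitations

* Only 0-dimensional spectral information enters production features;
  the higher Laplacians are implemented and tested but not featurized.
* The electrostatic mode requires charges on every grouped atom and
  refuses coincident atoms (the logistic weight is undefined at
  $d = 0$).
* Docking- and screening-power harnesses consume externally produced
  pose tables (scores, RMSDs, binder flags); pose generation itself is
  out of scope.
* `dc_gbt()` exposes neither `coef()` nor `simulate()` — a boosted tree
  ensemble has no coefficient vector and no generative model.
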