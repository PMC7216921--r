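---
title: "Inferring nitrogenase metal dependence from active-site features"
author: "paleonif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nitrogenase metal dependence from active-site features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleonif)
```

## The problem

Nitrogenases fix atmospheric N~2~ using a homocitrate--metallocluster
cofactor at the active site of the catalytic D-subunit. The three enzyme
forms differ in the metal of that cluster — Mo (Nif), V (Vnf), or Fe-only
(Anf) — and the history of this metal dependence ties protein evolution to
the chemistry of ancient oceans. Because the forms are homologous and only
a handful of pocket residues track the cofactor, the question "which metal
did an ancestral or uncharacterized nitrogenase bind?" can be posed as a
sequence-classification problem over the ~30 D-subunit residues that lie
within 5 Å of the cofactor.

`paleonif` implements that inference end to end: a substitution-model layer
that turns observed residues into probability distributions, a structural
layer that defines which positions count as active site, a marginal
ancestral-reconstruction engine that produces per-site posteriors at
internal nodes of a fixed phylogeny, a weighted support-vector classifier
of metal dependence, a grid-based pocket-volume calculator, and a seeded
synthetic family generator that provides planted ground truth for all of
the above.

## Site probability features

For an observed residue the classifier does not see a one-hot vector but a
mixture of three components, each a distribution over the 20 amino acids:

1. the **observed** component — probability 1 on the observed residue;
2. the **mutational neighbourhood** — the row of the JTT transition matrix
   $P(t) = e^{Qt}$ at a short distance $t = 0.01$ substitutions/site,
   starting from the observed residue;
3. a **diffuse regularizer** that keeps every residue's probability
   strictly positive.

The mixture is an unweighted average by default (`component_weights =
c(1,1,1)/3`): plain averaging is the natural reading of combining three
sources of evidence, and the weights are exposed in
`distribution_config()` for sensitivity analyses. The regularizer defaults
to the JTT equilibrium frequencies, a single diffuse pseudocount
distribution satisfying the requirement of "low probability everywhere";
any 20-vector (e.g. a Dirichlet-mixture posterior mean) can be plugged in.
Gap and ambiguity symbols carry no information about the residue, so they
contribute the regularizer alone.

The JTT model itself is built from the published exchangeability integers
and frequencies, shipped as a plain-text table in the classic PAML dat
layout (`inst/extdata/jtt.dat`), normalized so that one time unit equals
one expected substitution per site at equilibrium. Reversibility gives a
symmetric similarity transform of $Q$, so $P(t)$ is computed by spectral
decomposition (cached in the model object); rows are clipped at zero and
renormalized to remove eigensolver roundoff.

## Active-site definition and numbering

On the real-data path, `residues_near_cofactor()` returns every protein
residue with a non-hydrogen atom within the cutoff (default 5 Å) of any
cofactor atom; the cofactor is selected by het-group name or
chain/residue-number, since het nomenclature varies between entries.
`active_site_union()` maps contact residues from several structures (e.g. a
MoFe and a VFe protein) into one reference numbering frame — classic
*A. vinelandii* NifD coordinates — by global pairwise alignment (BLOSUM62,
affine gaps), collapsing copies from homo-oligomer chains. Hydrogens are
ignored because crystal structures model them inconsistently. Alternate
locations are resolved to the highest-occupancy copy.

`extract_active_site()` then slices a labeled alignment down to the columns
realizing those reference positions, which is the input to both the feature
encoder and the unique-residue tabulation.

## Marginal ancestral reconstruction

`site_posteriors()` computes, for every internal node and site, the exact
marginal posterior over amino acids given all leaves, under the reversible
model with equilibrium root prior and independent sites. The implementation
is two-pass belief propagation: a postorder (pruning) pass accumulates
subtree-conditional likelihoods with per-site rescaling, and a preorder
pass distributes the complementary evidence, so all nodes are obtained in
one sweep. Exactness is checked in the test suite against brute-force
enumeration of every internal-state assignment on random small trees
(agreement to 1e-10), and the total likelihood is verified to be invariant
to root placement, as it must be for a reversible model.

Point ancestors are per-site argmax of the marginal posteriors
(`ml_ancestor()`), with exact ties broken toward the alphabetically first
residue and recorded. Gaps are not part of the substitution alphabet;
presence/absence is reconstructed separately by Fitch parsimony
(`infer_gaps()`), with ambiguity resolved toward presence so that
downstream feature extraction sees a residue rather than a hole wherever
parsimony permits one. `sample_ancestors()` draws each site independently
from its posterior, the standard way of propagating reconstruction
uncertainty into downstream structural or biochemical analyses; draws are
reproducible under a seed.

Two simplifications are deliberate. First, point ancestors are marginal
argmax rather than joint maximum likelihood: every consumer in this
pipeline (the classifier's posterior encoding, Bayesian sampling, support
summaries) is defined on site posteriors, and at the high per-site supports
seen here the two reconstructions rarely differ. Second, a single
substitution rate is used across sites; rate heterogeneity belongs to tree
inference, which this package treats as an input.

## The metal-dependence classifier

Labeled extant sequences are encoded as the concatenation of their 30
active-site distributions (600 features). Training follows a replicated
evaluation design: in each of 10 replicates the labeled data are split
uniformly at random 60/40, class weights
$w(c) = N/(3\,\mathrm{count}(c))$ and the radial-basis kernel coefficient
$\gamma = 1/(\text{n features} \times \mathrm{Var}(\text{features}))$
(population variance of the pooled training matrix) are computed on the
training split, the cost parameter is chosen from {0.1, 1, 10, 100} by
five-fold cross-validation, and out-of-sample accuracy is recorded. The
deployed model is refit on all labeled data afterwards — ancestors and
uncharacterized sequences deserve every labeled example — while the last
evaluation model is retained for inspection.

One-vs-rest multiclass is assembled explicitly from three binary machines,
and classification support is reported as the signed distance to each
class-defining hyperplane (greater distance, greater support). The
underlying binary solver accepts class-level but not per-sample weights, so
the pooled "rest" class receives the count-weighted mean of its
constituents' weights — identical to the average per-sample weight the
formula implies. Splits are unstratified by default (a stratified option
exists); cross-validation folds are stratified internally so small classes
never vanish from a fold.

`pca_separability()` documents how much structure the features carry before
any kernel: scores are projected onto principal components and each
contrast is tested for perfect separation — disjoint ranges at one
component, a hard linear boundary (linear SVM at cost 10^6^ with zero
training errors; the environment offers no exact LP separability test) at
two or more.

Ancestral inputs are classified two ways: re-encoding the point-ancestor
sequence like any extant sequence, and feeding the posterior rows directly
as feature blocks (`encode_ancestor()`), which carries reconstruction
uncertainty into the decision. Agreement between the two is itself a
robustness check.

## Pocket volumes

`pocket_volume()` reimplements the grid procedure: an axis-aligned lattice
at 0.5 Å spacing anchored at the inclusion region's bounding-box minimum
(a stated anchor makes grids reproducible), restricted to a user-specified
union of inclusion spheres; carving removes points closer to any receptor
atom than its van der Waals radius plus a 1.09 Å pad (Bondi-style radius
table shipped, per-element, fallback configurable; the structure's own
cofactor is excluded so its pocket can be measured); a convex-hull filter
over the pocket-lining atoms (those within 8 Å of the region — hulls are
region-local, not whole-protein) removes solvent-exposed volume; and a
26-neighbourhood contiguity filter keeps the seeded (default: largest)
lattice component, ties resolving to the lexicographically smallest
coordinate. Volume is retained points × spacing³.

Hull half-spaces are enumerated by brute force over atom triples in
compiled code — exact, with cost O(n⁴) acceptable for pocket-lining shells
of up to a few hundred atoms — because no 3-D hull library is available;
membership is verified in tests against a quadratic-programming oracle.
`compare_volume_groups()` summarizes volume sets per group and applies the
two-sided Wilcoxon rank-sum test to every pair, matching the
non-parametric median comparison used for such data.

Accuracy of the whole chain is anchored to closed forms: a 5 Å inclusion
sphere with no receptor must integrate to 523.6 ų (observed error ≈ 0.5%
at 0.5 Å spacing), and a hollow carbon shell of radius 8 Å must leave a
cavity of radius 8 − 1.70 − 1.09 Å (observed error ≈ 0.2%). A caveat the
tests respect: the closed form assumes a continuous wall, while a shell of
discrete atoms lets the carved surface bulge slightly between atoms, so the
carve-exercising test uses a fine (700-atom) shell.

## The synthetic family and what it does (not) show

`generate_family()` emulates the study conditions at desk scale: seven
clades on the fixed rooted topology
`((NifI,NifII)AncE,(Clfx,(FMc,(MbMc,(Vnf,Anf)AncA)AncB)AncC)AncD)` with 30
Nif-I, 20 Nif-II, 8 Mb-Mc, 14 Vnf, 14 Anf, 8 F-Mc, and 3 Clfx leaves
(sequence length 500). Mb-Mc, F-Mc, and Clfx are generated unlabeled so the
pipeline exercises the classify-the-uncharacterized path; their active
sites are Mo-like. The root sequence is drawn from JTT equilibrium and
overwritten at the planted active-site positions; background positions
evolve freely under JTT along every branch.

The 30 active-site positions carry three planted layers:

* **11 universally conserved residues** (the ten classic ones — Val-70,
  Gln-191, His-195, Cys-275, Arg-277, Ser-278, Gly-356, Phe-381, Gly-424,
  His-442 — plus Gly-357, which both real loop variants IGGLRP/TGGPRL
  share), held fixed everywhere;
* **14 signature positions** switched on designated stem branches and held
  fixed below: Mo-like states at the root; V/Fe-shared states plus Thr-355,
  Pro-358, Val-427 on the branch entering AncA; V-only states (Leu-69,
  Trp-300, Pro-425) on the Vnf stem; Fe states on the Anf stem; within-Mo
  variation on the Nif-II stem. The resulting leaf table is exactly 3
  Mo-unique, 6 V-unique, 5 Fe-unique, and 6 V/Fe-union residues, and
  `unique_residues()` must recover it exactly;
* **5 scaffold positions** evolving at rate multiplier 0.2 within clades
  and frozen between them — strong purifying selection on the pocket
  scaffold. This freezing is what makes the planted signature table exact
  for every seed: a slow stem-branch substitution would otherwise have a
  few-percent chance of minting an accidental clade-unique residue.

Branch lengths are fixed defaults chosen once: 0.12 within-clade depth,
0.06 backbone steps, and asymmetric daughter stems below AncA (Vnf 0.04,
Anf 0.35, entering branch 0.15). The asymmetry encodes the biology the
family is meant to emulate — the Fe form is the most derived — and it is
what makes the V-like states planted at AncA statistically recoverable:
every identifiable planted state reaches posterior > 0.9, and the
reconstructed AncA carries the TGGPRL loop. States that one daughter
lineage overwrites back toward the upstream residue are *structurally*
ambiguous for marginal reconstruction (a two-substitution history competes
with a one-substitution one); the generator therefore keeps such V-only
residues on the Vnf stem, and the `anca_identifiable` entry of
`active_site_plan()` records which planted ancestral states a correct
method is expected to resolve. Real reconstructions show the same
phenomenon as ambiguous alternative states at a handful of pocket
positions.

With these settings the family lands at ~72% active-site identity between
the V and Fe clades against ~59% between Mo and V/Fe — the same qualitative
contrast the real family shows (~71% vs ~50%) — while full-sequence
identities are lower and less contrasted, which is exactly the pattern that
motivates classifying on pockets rather than whole sequences.

What passing tests on this family do **not** show: robustness to alignment
error (the synthetic family is generated aligned and gap-free; gap handling
is exercised by hand-built fixtures), to indel evolution, to rate
heterogeneity across sites, to model misspecification (data are simulated
under the analysis model), or to homology-modeling noise in real pocket
volumes. The pocket fixtures validate the geometry pipeline, not the
biology of modeled structures.

## Numerical choices and degenerate inputs

* Transition matrices: spectral decomposition, negative roundoff clipped,
  rows renormalized; `t = 0` returns the identity exactly.
* Pruning: per-site rescaling by row maxima keeps 100-taxon × 500-site
  problems in double range; posteriors renormalize per site.
* Argmax ties (exact equality) go to the alphabetically first residue and
  are recorded in an attribute rather than silently dropped.
* Empty inclusion regions or sub-lattice spheres yield volume 0, not an
  error; an empty structure or unmatched cofactor selector is an error that
  lists the available het groups.
* Filter stages never increase point counts; the pipeline records per-stage
  counts for auditability.
* The master seed fans out additively to stage seeds (`seed + stage
  index`), so any stage can be reproduced in isolation.

## Problem sizes used in validation

The shipped tests validate on a reduced family (6/5/3/4/4/3/2 leaves,
length 450) for unit-level checks and on the full default family for the
end-to-end checks; exhaustive-enumeration comparisons use 100 random trees
of 3–5 leaves, where enumeration over all internal-state assignments is
exact and cheap. These sizes were chosen as the smallest at which every
planted phenomenon is expressed.

## Known limitations

* Joint-ML reconstruction is not implemented; for strongly supported sites
  marginal argmax coincides with it, but pathological cases exist.
* The brute-force hull is quartic in atom count; pocket-lining shells of a
  few hundred atoms are fine, whole proteins are not its use case.
* The classifier's rest-class weighting is the class-mean approximation
  described above; with strongly unbalanced and non-separable data it could
  differ from true per-sample weighting.
* `percent_identity()` treats an ambiguity code as an ordinary mismatching
  character rather than a wildcard.
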