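---
title: "Compartment-resolved proteomics and semi-tryptic proteolysis analysis: methods"
author: "proteocaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved proteomics and semi-tryptic proteolysis analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistics: the models and
procedures implemented, the parameters that matter, the choices made where
the design was genuinely open, and what the synthetic cohort does and does
not establish about real data.

## The analytical problem

Solid tumors growing expansively compress the adjacent parenchyma into a
fibrous pseudocapsule (PC). A patient-matched bottom-up proteomics design
with TUMOR, PC and NAT (normal-adjacent tissue) compartments asks two
linked questions. At the protein level: which proteins distinguish the PC
from both of its neighbours, how does PC composition change with tumor
size, and which processes rise or fall monotonically from NAT through PC
to tumor? At the peptide level: where has endogenous proteolysis — protease
activity in the tissue before any laboratory digestion — left its mark?
The second question is answered through *semi-tryptic* peptides: peptides
with exactly one terminus that the digestion enzyme cannot have produced.

## Peptide specificity classification

Every stripped peptide sequence is located exactly in its mapped protein
(all occurrences, overlaps allowed). Each terminus is classified against an
enzyme rule (default: cleavage C-terminal to K or R, matching a tandem
Lys-C + trypsin digestion):

* **N-side** — `protein_terminal` if the peptide starts at position
  ≤ `ntermWindow`; else `enzymatic` if the preceding residue is a cleavage
  residue; else `nonenzymatic`.
* **C-side** — `protein_terminal` at the protein C-terminus; else
  `enzymatic` if the last peptide residue is a cleavage residue; else
  `nonenzymatic`.

The class is `full` (both termini enzymatic), `semi_N` / `semi_C` (exactly
one nonenzymatic terminus) or `nonspecific` (both). Parameters:

* `ntermWindow = 2` — start positions 1 and 2 count as the protein
  N-terminus, absorbing initiator-methionine excision. Protein-terminal
  peptides are *flagged and excluded* from all proteolysis statistics
  because their unusual terminus reflects translation, not proteolysis.
  For flagged peptides the class label treats the terminal side as
  specific; the label is informational only since these peptides never
  enter downstream statistics.
* `prolineBlock = FALSE` — the Trypsin/P convention used by common DIA
  search engines; a flag enables the classical proline restriction.
* Multi-occurrence peptides take the **most specific** occurrence
  (full > semi > nonspecific, earliest position on ties), and multi-mapped
  peptides the most specific mapping. This is deliberately conservative:
  a peptide is only called a proteolysis product if *no* mapping explains
  it as fully tryptic.
* `nonspecific` peptides are reported but counted in neither the numerator
  nor the denominator of semi-tryptic fractions: with two nonenzymatic
  termini they are more likely identification artefacts than single
  cleavage events.

The implementation is a compiled batch classifier; its contract is pinned
by an exhaustive oracle test that classifies every 7–30-residue substring
of a random 200-residue protein with an independent brute-force checker
(100 % agreement required).

## Proteolysis read-outs

For each sample, among classified full + semi peptides with a measured
intensity: `fraction_count = n_semi / (n_semi + n_full)` and
`fraction_intensity = Σ I_semi / Σ I_full+semi` on the raw linear scale —
a proportion of measured signal, which is the robust quantity when
peptides differ wildly in response. The denominator includes full + semi
only, with terminal-excluded peptides removed from both sides — chosen for
symmetry with the count fraction.

Compartment comparison deliberately reports two families side by side: a
rank-based Kruskal–Wallis omnibus with Dunn's pairwise z tests
(tie-corrected, BH-adjusted across the three contrasts) and a parametric
one-way ANOVA with Tukey HSD. Dunn's test is implemented from its
definition (no installed package provides it); its size is verified by
simulation under the null (type-I error within [0.03, 0.07] at α = 0.05
over 2,000 simulations).

Cleavage events are located by the P1 residue index (the bond between P1
and P1′), with an 8-residue P4…P4′ window padded with `X` beyond protein
ends. The motif matrix uses Laplace-smoothed position frequencies
(pseudocount 1) against one of two backgrounds: overall proteome residue
frequencies (default — simplest and assumption-free) or position-matched
frequencies around all in-silico tryptic sites, which removes the trivial
K/R enrichment at P1 when events are compared against the digestion
landscape itself.

## Protein quantification

The roll-up implements the pairwise median-ratio formulation of label-free
quantification: using proteotypic peptides only, the protein-level
difference between samples i and j is estimated as the median of
peptide-wise log2 differences over shared peptides
(`minShared = 1` by default, because cohort-scale peptide data are
sparse); the per-sample protein values minimise the squared disagreement
with all pairwise estimates. The resulting Laplacian system is solved per
connected component of the sample-pair graph (RcppArmadillo); samples with
no peptide evidence stay missing. Each component is anchored so that the
mean of the protein values equals the mean of per-sample mean observed
peptide intensities — this particular anchor makes the roll-up exactly
shift-equivariant: adding a constant to one sample's peptides adds exactly
that constant to that sample's protein value, and nothing else.

In the full pipeline the roll-up consumes *fully tryptic, non-terminal*
peptides only: semi-tryptic peptides carry compartment-dependent
proteolysis signal that would otherwise leak into protein abundance.

Completeness filtering is two-tier: the **core** matrix keeps proteins
present in ≥ 70 % of samples of *every* compartment (stringent, suitable
for unimputed analysis); the **extended** matrix keeps proteins present in
≥ 50 % of *at least one* compartment, accommodating compartment-restricted
expression at the cost of more missingness. Core survivors provably nest
within extended survivors at the default thresholds.

Missing values in the extended matrix are imputed from a left-shifted
Gaussian per sample, Normal(μ_s − 1.8 σ_s, (0.3 σ_s)²) — the standard
MinProb-style encoding of the detection-limit (MNAR) mechanism, chosen
over ensemble imputation selection because it is deterministic under a
seed, has two transparent parameters, and its left-censoring behaviour is
directly testable. Present values are never altered.

## Differential abundance

The moderated two-sample test shrinks per-feature pooled variances s²
(residual df d) towards a prior: on z = log s², the excess of var(z) over
the χ² sampling contribution trigamma(d/2) identifies the prior df d₀
through the trigamma inverse, and the prior scale s₀² follows from the
mean of z. The posterior variance is s̃² = (d₀ s₀² + d s²)/(d₀ + d) and
t = Δmean / (s̃ √(1/n₁ + 1/n₂)) with d₀ + d degrees of freedom (normal
limit when the variances show no excess dispersion, in which case the
prior collapses to the mean variance). A Welch mode is provided as an
unmoderated cross-check. The installed reference implementation of
moderated statistics is used in the test suite as an independent oracle,
never as the implementation. BH adjustment is the step-up rule implemented
from its definition and pinned against brute-force enumeration.

Contrasts are unpaired group comparisons (the compartment design has
unequal, partially overlapping patient sets per compartment; a
patient-blocked model is out of scope). The sign convention is
first-named group minus second, stated in the output attributes. The
compartment-unique signature takes features significant with
|log2FC| ≥ log2(1.5), BH-adjusted p ≤ 0.05, in *both* contrasts against
the other compartments, in the same direction; up and down sets are
disjoint by construction. Differential abundance runs on the imputed
extended matrix by default, with the unimputed core matrix available for
complete-case analysis.

## Compartment structure

* **PCA** — column-centred SVD of samples × features (optional feature
  standardisation); component signs fixed so the largest-magnitude loading
  is positive; reconstruction from all components reproduces the centred
  matrix to 1e-9 in the tests.
* **Trend calls** — features are z-scored, compartment means computed, and
  a feature is `increasing` when mean(NAT) ≤ mean(PC) ≤ mean(TUMOR) with a
  NAT→TUMOR span ≥ `margin` (default 0.5 sd), `decreasing` symmetrically.
  This deterministic rule replaces co-expression clustering: when the
  expected structure is two opposite monotone clusters, a transparent
  monotone test is reproducible and has a tunable, interpretable margin.
  The margin is calibrated for cohort-scale groups (≈ 30–55 samples per
  compartment); in much smaller designs the z-scores of null features are
  noisy enough that a larger margin is advisable.
* **Size correlation** — per-feature Pearson correlation of PC log2
  abundance against the matched lesion's diameter in millimetres (raw
  scale; Spearman by flag), p-values from the t transform, BH across
  features. PC specimens inherit the diameter of their matched tumor
  lesion through the (patient, lesion) join.
* **Marker correlations** — Pearson r of an anchor gene (e.g. PCNA)
  against a panel (e.g. MCM2–7), within each compartment, with per-cell n.
* **Concordance** — Pearson r between peptide-level and parent-protein
  log2 fold changes; peptides significant at |FC| ≥ 1.5 whose parent is
  non-significant or oppositely signed are flagged as discordant —
  candidates for domain-level (proteolytic) regulation.

## Annotation and enrichment

Matrisome annotation is a case-insensitive gene lookup in a
division/category table; a small representative table (collagens, ECM
glycoproteins, proteoglycans, regulators, secreted factors,
ECM-affiliated) ships for examples and tests, and users supply complete
tables as TSV. Over-representation uses the upper-tail hypergeometric
probability P(X ≥ k) via the base distribution function, with fold
enrichment (k/n)/(K/N) and BH control across sets; ranked (GSEA-style)
enrichment is deliberately out of scope. Note the direction of the
query-size effect: at fixed overlap k, a larger query makes the overlap
*less* surprising, so the p-value is non-decreasing in query size — the
property suite asserts exactly this.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not mass spectra:

* **Design** — 34 patients; 54 tumor lesions (12 patients contribute
  metachronous lesions), 45 of them with a matched PC specimen, 31
  patients with a NAT specimen. Diameters are log-uniform on 10–90 mm;
  grades sampled at the 11 : 40 : 3 G1/G2/G3 cohort ratio.
* **Proteome** — 300 random sequences of 150–1,000 residues at 11 % K+R,
  digested in silico (7–30 residues, ≤ 1 missed cleavage). Panel genes
  carry conventional symbols (COL1A1, HK2, NDUFS1, PCNA, …) so that
  matrisome and gene-set fixtures work on simulated data; the sequences
  themselves are random, keeping the repository database-free.
* **Intensities** — log2 peptide intensity = protein base (N(20, 2²)) +
  planted compartment effect (± log2(1.5)·1.33 on the PC-matrisome,
  tumor-glycolysis and tumor-OXPHOS panels; the 1.33 factor compensates
  the attenuation introduced by left-censored imputation so the observed
  protein-level fold change lands near 1.5) + tumor-size slope (PC
  samples of the 25 + 25 size panels, calibrated to Pearson r ≈ 0.6) +
  a shared proliferation factor coupling PCNA to MCM2–7 within tumors
  (r ≈ 0.6) + patient random effect (sd 0.4) + per-peptide response
  offset (sd 1.0) + measurement noise (sd 0.3).
* **Proteolysis** — 800 endogenous cleavage events sampled over eligible
  in-fragment positions with an 8 : 1 P1′ preference for leucine, 75 % of
  them concentrated on two designated collagen genes (mirroring
  proteolysis focused on a few ECM scaffold proteins). Each event
  truncates a tryptic fragment into a valid semi-tryptic product, verified
  to classify as semi against its own protein. Semi-peptide intensities
  are scaled per compartment so their expected share of total (full +
  semi, terminal-excluded removed) linear intensity equals the configured
  shares — 0.10 (NAT), 0.15 (PC), 0.25 (TUMOR). Parameterising the *share
  of signal* rather than event counts matches the analysis' headline
  statistic.
* **Missingness** — each cell is lost with probability
  logistic((17 − log2 I) / 1) plus 2 % MCAR, giving ≈ 15–17 % missingness
  at the peptide level with the expected left-censoring direction.

What passing tests on this generator show: the pipeline recovers known
proteolysis shares, planted signatures, planted correlations and planted
trends from data with the right dependence structure (patient matching,
shared lesions, MNAR). What they cannot show: robustness to real-data
phenomena the generator does not emulate — interference and co-elution,
FDR structure of the search engine, retention-time-dependent intensity
bias, shared peptides between homologous proteins, post-translational
modifications, or protease specificity beyond a single P1′ preference.

## Numerical choices and degenerate inputs

* Zero-variance features: p = 1 when means are equal; under Welch with
  unequal means the feature is flagged `degenerate` with p → 0 rather
  than silently dropped.
* Constant features in correlation screens are reported `ns` with a
  `constant` flag.
* Sample pairs sharing fewer than `minShared` peptides contribute no
  ratio; disconnected sample blocks are solved and anchored separately.
* The imputation, generator and pipeline restore the caller's RNG state;
  every stochastic entry point takes an explicit seed.
* Ties in Dunn's test use the standard (t³ − t) correction; ties in the
  specificity rule break towards the earliest occurrence.
* Problem sizes in the test suite: the exhaustive specificity oracle runs
  on one 200-residue protein (~4,100 substrings); digestion is checked on
  50 random proteins; null calibration uses 2,000 simulations of 500
  features at n = 10 vs 10; generator-truth checks use 20 cohort seeds at
  the full 130-sample design; ORA is enumerated exhaustively for all
  universes up to N = 25.

## Known limitations

* Protein groups are quantified as given; no parsimony re-grouping or
  isoform collapsing.
* The unpaired moderated test ignores patient matching; with strong
  patient effects shared across compartments it is conservative for
  between-compartment contrasts.
* The motif matrix describes residue preferences; it does not attempt
  protease attribution.
* The trend rule is univariate and monotone-only; features with
  PC-specific peaks belong to the signature logic, not the trend calls.
* FDR filtering of identifications is assumed upstream (the peptide table
  is taken at face value).
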