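# proteocaps

Compartment-resolved bottom-up proteomics of solid tumors that form a
fibrous **pseudocapsule (PC)** at the boundary between malignant tissue and
normal-adjacent tissue (NAT). The package is aimed at proteomics analysts
working with DIA-style peptide quantification reports from patient-matched
three-compartment designs (TUMOR / PC / NAT) who want to go beyond protein
abundance and ask *where endogenous proteolysis is happening*: which
peptides are semi-tryptic (one terminus not produced by the digestion
enzyme — the fingerprint of in-vivo proteolytic processing), how their
intensity share differs between compartments, which residues flank the
cleavage sites, and how the protein-level landscape (differential
abundance, tumor-size correlation, compartment trends, matrisome
enrichment) changes alongside.

Because patient-level proteomic data from such cohorts is typically not
shareable, the package includes a first-class synthetic cohort generator
that reproduces the statistical structure of a 34-patient cohort (54 tumor,
45 PC, 31 NAT samples, metachronous lesions allowed) with
compartment-dependent proteolysis, planted abundance effects and
intensity-dependent missingness, so every stage of the pipeline is testable
end to end.

## What the package computes

**Peptide specificity.** Each stripped peptide is located in its protein
and both termini are classified against the enzyme rule (default
Lys-C/trypsin, cleavage after K/R). A peptide is *full* when both termini
are enzymatic, *semi_N* / *semi_C* when exactly one is not, *nonspecific*
when neither is. Peptides containing the protein N- or C-terminus are
flagged and excluded from all proteolysis statistics. For each semi-tryptic
peptide the cleavage event is extracted as the P4…P4′ residue window around
the scissile bond, and a 20 × 8 log2 enrichment matrix

&nbsp;&nbsp;&nbsp;&nbsp;E(a, p) = log2 [ (c(a, p) + λ) / (Σ_a c(a, p) + 20λ) ÷ bg(a, p) ]

is built against either proteome residue frequencies or position-matched
frequencies around in-silico tryptic sites.

**Proteolysis read-outs.** Per sample, the count fraction
n_semi / (n_semi + n_full) and the intensity fraction
Σ I_semi / Σ I_(full+semi) (raw linear scale), compared across compartments
with both a Kruskal–Wallis omnibus + Dunn pairwise z tests (BH-adjusted)
and one-way ANOVA + Tukey HSD.

**Protein quantification.** MaxLFQ-style roll-up from proteotypic peptides:
for every sample pair (i, j) the median pairwise peptide log-ratio
r_ij = med_p (x_pi − x_pj), then the per-sample protein values v minimise
Σ_(i,j) (v_i − v_j − r_ij)², solved per connected component in compiled
code and anchored to the mean observed peptide intensity. Followed by
median centering, two-tier completeness filtering (core: ≥ 70 % presence in
*each* compartment; extended: ≥ 50 % in *at least one*), and left-censored
MNAR imputation from Normal(μ_s − 1.8 σ_s, (0.3 σ_s)²).

**Differential abundance.** Empirical-Bayes moderated t-test with a
method-of-moments prior on log s² (posterior variance
s̃² = (d₀s₀² + d s²)/(d₀ + d), t with d₀ + d df), Benjamini–Hochberg
step-up control, and compartment-unique signature logic (significant with
|FC| ≥ 1.5 against *both* other compartments).

**Compartment structure.** Sample PCA, monotone NAT→PC→TUMOR trend calls,
Pearson screening of PC protein abundance against tumor diameter,
anchor-vs-panel marker correlations per compartment, and peptide/protein
fold-change concordance with discordant-peptide flagging.

**Annotation.** Matrisome division/category lookup and hypergeometric
over-representation analysis of gene sets (GMT).

## Worked example

```r
library(proteocaps)

cohort <- simulateCohort(simConfig(), seed = 1)
ann <- classifyPeptides(cohort$peptideTable$peptides, cohort$proteins)
table(ann$spec_class)
#>   full semi_C semi_N
#>  22434    420    380

fr <- semiFractionPerSample(ann, cohort$peptideTable)
head(fr, 3)
#>   sample_id n_full n_semi fraction_count fraction_intensity
#> 1  NAT_Pt01  17940    767     0.04100069         0.09959050
#> 2  NAT_Pt02  17900    763     0.04088303         0.10873584
#> 3  NAT_Pt03  17958    761     0.04065388         0.09164331

comp <- cohort$metadata$compartment[match(fr$sample_id,
                                          cohort$metadata$sample_id)]
round(tapply(fr$fraction_intensity, comp, mean), 3)
#>   NAT    PC TUMOR
#> 0.101 0.151 0.252

tests <- groupCompareFractions(fr, cohort$metadata)
subset(tests$pairwise, method == "dunn")
#>    contrast method  estimate  statistic            p        adj_p
#> 1    NAT-PC   dunn -37.61864  -4.278255 1.883641e-05 1.883641e-05
#> 3 NAT-TUMOR   dunn -87.27419 -10.281048 8.578919e-25 2.573676e-24
#> 5  PC-TUMOR   dunn -49.65556  -6.530353 6.561469e-11 9.842203e-11
```

The generator was configured with semi-tryptic intensity shares of 0.10
(NAT), 0.15 (PC) and 0.25 (TUMOR); the per-sample intensity fractions
recover those shares and the Dunn tests resolve every pairwise compartment
difference. `runPipeline(simConfig(), seed = 1)` chains the remaining
stages (roll-up, filtering, imputation, differential contrasts, PC-unique
signature, size-correlation screen, trend calls, motif matrix) and returns
a one-row-per-quantity summary.

## Vignette

`vignettes/proteocaps-methods.Rmd` documents the statistical model behind
each stage, every tunable parameter with its default and rationale, what
the synthetic cohort does and does not emulate, and known limitations.
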