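---
title: "Population-genomic analysis of inbred rice panels: models and methods"
author: "ricepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic analysis of inbred rice panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ricepop implements the computational core of a resequencing-based
population-genomics workflow for highly inbred, structured crop panels —
the setting typical of rice (*Oryza sativa*) landrace collections, where
predominant selfing pushes Wright's inbreeding coefficient F close to 0.9
and the panel splits into Indica- and Japonica-type subpopulations. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, the synthetic-data generator the tests run against, and the
numerical and design choices that were genuinely open.

## The genotype substrate

Every stage consumes a `genotype_matrix`: samples by biallelic SNPs, coded
as ALT-allele dosage 0/1/2 with `NA` for missing calls. Coordinates are
1-based inclusive throughout (the native convention of both VCF and GFF3),
positions are strictly increasing within a chromosome, and heterozygote
phase is deliberately not represented — the entire analysis is unphased.
Multi-allelic records are dropped (not split) on input, and tallied, so
that site counts downstream refer to strictly biallelic SNPs.

## Inbreeding-aware SNP filtering

In a panel inbred at level F, the expected fraction of heterozygous calls
at a site with allele frequency p is (1 − F) · 2p(1 − p), not the
Hardy-Weinberg 2p(1 − p). The filter module exploits this in two steps:

1. **Estimate F** as the median of 1 − Hobs/Hexp over sites with
   Hobs/Hexp < 1 and minor allele frequency above 5%. Hexp = 2p̂(1 − p̂)
   with no finite-sample correction; the correction choice would be
   absorbed into F anyway. The median is the standard midpoint-averaged
   definition for even counts.
2. **Remove heterozygosity excess**: a site whose Hobs/Hexp exceeds
   `factor × (1 − F)` (factor 5 by default) carries far more heterozygotes
   than the panel's inbreeding permits — the signature of collapsed
   paralogs or mismapping rather than real polymorphism. At F = 0.882 the
   cutoff is 5 × (1 − 0.882) = 0.590. Monomorphic sites have no defined
   ratio and pass this filter untouched.

One subtlety the package documents rather than hides: the estimator reads
the *total* heterozygote deficit of the panel. In a structured panel that
deficit includes the Wahlund effect, so the estimate is an F_IT, not the
IBD-only F of any one subpopulation. The simulation checks of estimator
accuracy therefore run on a homogeneous (K = 1) panel, where the estimand
coincides with the simulator's F parameter; on structured panels the
estimate is expected to sit above the within-population F.

Hard filters (site QUAL, minor-allele count, missingness, MAF) are applied
in one pass with per-criterion counts. LD pruning slides a window
(`window_snps`, default 50, stepping by 10) along each chromosome and,
while any retained pair inside the window has squared dosage correlation
above `r2_max` (default 0.8), removes the lower-MAF member of the worst
pair (ties: the larger coordinate). Missing dosages are mean-imputed
inside the correlation only, never written back. The removal rule is this
package's deterministic choice; the classical pruning tools leave their
internal tie-breaking unspecified, and determinism matters more here than
bit-for-bit tool mimicry. A final greedy left-to-right thinning can
enforce a minimum inter-SNP spacing in bp.

## Admixture inference

The structure module fits the standard admixture likelihood: individual i
carries ancestry proportions q_ik over K ancestral populations with
per-site ALT frequencies p_kl, the per-gamete ALT probability is
f_il = Σ_k q_ik p_kl, and called dosages are Binomial(2, f_il). Inference
is maximum likelihood by the classical alternating EM on expected
allele-origin counts, with P clamped to [1e-6, 1 − 1e-6] and missing
genotypes skipped in every sum. EM guarantees a non-decreasing likelihood,
which the tests assert at tolerance 1e-6 every iteration. The inner loop
is compiled (single fused pass over the genotype matrix, O(nLK) per
iteration) because replicate-by-K scans dominate the workflow's runtime.

The Bayesian MCMC machinery of the classical structure tools is out of
scope by design: the quantities this workflow consumes are the point
estimates Q and the per-run log-likelihoods, and a deterministic,
desk-scale ML fit with multiple random restarts provides both.

Label switching across replicate runs is resolved by exhaustive search
over column permutations (K ≤ 8; Frobenius distance to a reference run)
or greedy correlation matching above that. Replicates are then clustered
by aligned mean per-entry distance at 0.1, and up to 10 members of the
largest cluster are averaged — a concrete operationalisation of
"average the runs in the dominant mode", with both knobs exposed.

K is selected by the Evanno statistic: ΔK = |L″(K)| / sd(K) over replicate
final log-likelihoods, undefined at boundary K and wherever the replicate
sd is zero (flagged `NA`, never infinite).

Subpopulation assignment uses a threshold on the largest ancestry
component, with presets mirroring the three uses in practice: 0.75 for a
coarse Indica/Japonica split, 0.6 within a country-level panel, and 0.65
with a major-group fallback (a sample whose summed Indica-column ancestry
reaches the group threshold becomes `Ind-adm`, likewise `Jap-adm`, the
rest `admix`). Boundaries are inclusive (≥); argmax ties break to the
lowest column index so the assignment is total and deterministic.

PCA standardizes each site by 2p̂ and √(2p̂(1 − p̂)) (missing → 0 after
centring), skips monomorphic sites, and fixes each component's sign by
making its largest-magnitude loading positive. Principal coordinates
delegate classical double-centring scaling to `stats::cmdscale`, dropping
negative eigenvalues with a warning; on complete data with unscaled PCA
the two embeddings agree, which the tests exploit as an oracle.

## Nucleotide diversity

Windowed π follows the genotype-based estimator: at a site with c0 REF and
c1 ALT called allele copies (m = c0 + c1 ≥ 2) the site diversity is
c0·c1 / C(m, 2), the probability two copies drawn without replacement
differ. Window π sums site diversities in 100-kb windows advancing by
10 kb and divides by the full window span, so monomorphic and uncalled
positions count as zero diversity — the convention that puts per-bp π for
dense resequencing data on its familiar ~1e-3 scale. Terminal windows
keep their true span and are flagged partial (droppable on request).

## Mixed-model GWAS

Traits are screened by coefficient of variation (eligible when
0 < CV < 56%) and sample count. The association model is the
single-variance-component MLM
y = Wα + x_s β + g + e, g ~ N(0, σg² K), e ~ N(0, σe² I), with K the
VanRaden genomic relationship matrix (centred dosages, missing → 0 after
centring, normalised by 2Σp(1 − p); its mean diagonal lands near 1 + F on
an inbred panel) and W an intercept plus the ancestry proportions with
one column dropped (Q rows sum to 1, so the full matrix is collinear with
the intercept). Variance components are estimated once on the null model
by REML profiled over δ = σe²/σg² via the eigendecomposition of K
(Brent search on log δ in [−6·ln10, 6·ln10] natural-log units);
each SNP is then a generalized least-squares test on the rotated data
with a two-sided Wald t-test at n − p − 1 degrees of freedom. Samples
missing the trait are dropped listwise; per-SNP missing dosages are
mean-imputed. An indefinite kinship is ridged by shifting its spectrum to
1e-6.

Multi-locus "super" refinements of the kinship are deliberately not
reimplemented: the acceptance surface here is calibration (uniform null
p-values, genomic inflation λ near 1 on structured data once Q and K are
in the model) and power (a planted large-effect locus tops the scan),
both of which the plain MLM delivers and the tests measure.

## QTL construction

Association peaks become intervals by fixed rules: SNPs with
−log10(p) ≥ 8 (inclusive) are chained along a chromosome while the
inter-SNP gap is ≤ 250 kb; chains need ≥ 2 significant SNPs; segments
narrower than 100 kb are replaced by peak ± 50 kb (start floored at 1);
segments of the same trait class on the same chromosome merge when their
intervals overlap by ≥ 1 bp, with grain length, grain width and the
length/width ratio collapsing into a single grain-size class. Genes count
toward a region when their annotated interval overlaps it by ≥ 1 bp, both
ends inclusive. The 250-kb chaining gap is not dictated by any formula;
it is the value that keeps adjacent same-trait peaks ~260 kb apart
distinct while leaving megabase-scale peak clusters intact, and it is
exposed as a parameter. The fixed −log10(p) ≥ 8 threshold is used as
printed in the field; no FDR recomputation is layered on top.

The packaged QTL table (`inst/extdata/rice_qtl_table.tsv`, 21 rice QTLs
for plant-description traits across a full diversity panel and Indica and
Japonica subpanels) exercises the report aggregation: summed significant
associations (643), summed genes (1730), panel counts (17 full-panel,
4 Japonica-only), and distinct chromosomes (10). Its `min_p` column is
validated structurally (start < end, ≥ 2 SNPs per QTL) but the
−log10(min p) ≥ threshold check is opt-in, because published tables —
including this one — can carry rows whose printed minimum p sits slightly
below the headline threshold after rounding and peak-selection
conventions.

## The synthetic-data generator

Because the original accessions are not redistributable at desk scale,
every inferential claim is validated on simulated panels whose statistical
structure mimics the real data:

- **Divergence**: Balding-Nichols — ancestral frequency
  p0 ~ U(0.05, 0.95) per site, population frequencies Beta-distributed
  with mean p0 and variance Fst·p0(1 − p0), clamped into (0, 1).
- **Admixture**: rows of Q drawn symmetric-Dirichlet(α); α = 0.2 by
  default, giving mostly-pure individuals with a real admixed fraction.
- **Inbreeding**: modelled at the genotype level — with probability F the
  two gametes are identical by descent (genotype 2 with probability f_il,
  else 0), otherwise Binomial(2, f_il). This reproduces exactly the
  (1 − F)-scaled heterozygosity the filter module inverts, at a fraction
  of the cost of pedigree simulation.
- **Layout**: positions scatter uniformly over three 15-Mb chromosomes by
  default, so windowed π and QTL logic see realistic coordinates.
- **Traits**: additive genetic values over designated causal sites plus
  Gaussian noise scaled to a target h², with an optional baseline to put
  the phenotype on a realistic positive measurement scale.

The standing small fixture is K = 3, n = 120, L = 5,000, Fst = 0.15,
α = 0.2, F = 0.88, 2% missing, seed 1 — F at the level reported for
selfing rice landrace panels, and sized so the full pipeline runs in
seconds. What the generator does **not** emulate: linkage disequilibrium
decay (sites are exchangeable given ancestry; pruning tests plant
perfectly correlated site copies instead), selection, mutation-rate
heterogeneity, and sequencing-error structure. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, and calibration/power at the simulated sample sizes — not
robustness to every artefact of real resequencing data.

Simulation sizes used by the heavier checks: F-recovery runs at n = 500,
L = 20,000 for F ∈ {0.5, 0.7, 0.9} across three seeds (the estimator
lands within ±0.02); structure recovery and Evanno scans at n = 150,
L = 3,000 with replicate EM fits capped at 100–200 iterations (the
capped fits already put the mean per-entry Q error near 0.03, well under
the 0.08 the checks require, and the log-likelihood plateau that Evanno
consumes is established long before full convergence); GWAS calibration
at n = 300, L = 5,000.

## Degenerate inputs and numerical conventions

- Monomorphic sites: undefined Hobs/Hexp (excluded from F, retained by
  the heterozygosity filter), skipped by PCA and kinship, r² = 0 in
  pruning, zero site diversity in π.
- All-missing sites carry `NA` statistics; all-missing samples are
  rejected by the EM.
- Dosage missingness is imputed only where a method needs a complete
  vector (r², PCA/kinship centring, per-SNP GLS), never persisted.
- The EM trace may move by less than 1e-6 per iteration near a plateau;
  convergence is declared on likelihood gain < `tol`.
- `population_spec` validates every rate range up front, so downstream
  code never sees an out-of-range F, α or missing rate.

## Workflow scripts

The `analysis/` directory holds the numbered drivers that chain the
stages end to end on the synthetic panel: simulate (`01`), filter
(`02`), structure + embeddings (`03`), windowed π (`04`), mixed-model
GWAS (`05`), and QTL construction with the published-table cross-check
(`06`). Each writes plain TSV/VCF outputs under `results/` and prints the
headline numbers it found; the package functions they call are the tested
surface.
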