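---
title: "Models and methods behind islescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind islescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

islescan analyzes cohorts whose genomes are recent mosaics of a few
differentiated ancestries — the motivating system is a southwestern
European island population carrying European (EUR), North African (NAF)
and sub-Saharan African (SSA) ancestry from an admixture pulse roughly
half a millennium old, with island-scale isolation on top. This vignette
is the package's own account of the models it implements, the parameters
that matter, and the choices made where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic cohort: what it emulates

`simulateCohort()` is a first-class module, not a test fixture. It
generates diploid individuals whose haplotypes are **Markov ancestry
mosaics**: along each chromosome, the ancestry at the start is drawn
from the admixture proportions `p`; switch events arrive as a Poisson
process at rate `g` per Morgan (`g` = generations since the pulse), and
at each switch the ancestry is redrawn from `p`. Because a redraw may
return the same ancestry, the *observed* constant-ancestry tract of
ancestry `k` is exponential with mean `100 / (g (1 - p_k))` cM — the
standard single-pulse tract-length model, and the same exponential decay
the dating module fits. Defaults are `p = (0.75, 0.22, 0.03)` for
EUR/NAF/SSA and `g = 15`, the working figures for the motivating
population.

Allele frequencies are **Balding–Nichols**: an ancestral frequency
`p ~ U(0.05, 0.95)` per locus, and per ancestry
`f_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so `E[f_k] = p` and
`Var[f_k] = F_k p (1-p)`. The divergence defaults
`F = (0.02, 0.03, 0.12)` are a deliberate calibration, not an estimate:
no published F values exist for these exact panels, so they were chosen
once to satisfy the qualitative constraint that EUR–NAF differentiation
is small-to-moderate while both are far less diverged from each other
than from SSA. Haplotype alleles are Bernoulli draws from the local
ancestry's frequency; genotypes are haplotype sums; the truth dosage is
the integer ancestry count (always summing to 2).

Two kinds of signals can be injected with recorded truth:

- **Ancestry-deviant regions** (`injectSignals()`): inside the interval,
  every haplotype is redrawn as one whole-interval block, with *exactly*
  `round(target × 2n)` haplotypes assigned the focal ancestry and the
  rest drawn from the renormalized background. This hits the target mean
  within `1/(4n)` by construction and preserves block contiguity; the
  price is that the background mosaic structure inside the interval is
  replaced by whole-interval tracts, which is irrelevant to the scan
  (it averages over individuals per locus) but means tract-length
  statistics should not be read inside injected intervals.
- **Autozygous tracts**: the second haplotype of the chosen individual
  is overwritten by the first inside the interval, so every genotype
  there is homozygous — the idealized ROH.

What the generator does **not** emulate: array ascertainment bias,
genotyping error, phasing uncertainty, local-ancestry *inference* noise
(truth dosages are exact integers, whereas ELAI-style dosages are
smoothed posteriors), background LD within ancestries (alleles are
independent given the local ancestry), and non-uniform recombination
(the default map is 1 cM/Mb; any monotone map can be supplied). Passing
recovery tests on these cohorts therefore demonstrates the estimators'
correctness under the generating model, not robustness to those
real-data artifacts — the main reason the scan and dating windows on
real data are expected to be noisier than the tests suggest.

The default genome is 22 autosomes with human-proportional lengths
scaled to 3,000 Mb, SNPs on a regular 20-kb grid.

## Admixture dating by weighted LD decay

For locus pair `(i, j)` at genetic distance `d`, the statistic is
`cov(g_i, g_j) · w_i · w_j`, with the covariance taken across admixed
individuals and `w_i` the allele-frequency difference between two
reference panels. Under a single pulse `n` generations ago the ancestry
autocorrelation — and hence this weighted covariance — decays as
`exp(-n d)` with `d` in Morgans, so the fitted decay constant *is* the
age in generations. Pairs closer than `minCM = 0.5` cM are excluded
(ancestral short-range LD would otherwise contaminate the curve); bins
are 0.05 cM wide up to `maxCM = 50` cM — the defaults of the standard
weighted-LD dating tool.

Numerics: for fixed `n` the model `A e^{-nd} + c` is linear in `(A, c)`,
so `fitDecay()` profiles the residual sum of squares over `n` (60-point
log grid on [0.2, 500] followed by golden-section refinement) and solves
the linear part exactly. This is deterministic and cannot fail to
converge; a non-positive fitted amplitude is reported as "no admixture
signal". Standard errors come from a leave-one-chromosome-out jackknife
over the per-chromosome bin sums, and the amplitude z-score
(amplitude / jackknife SE, detection at z ≥ 2) replaces the reference
tool's multi-population pretest, whose machinery is out of scope here.
Calendar conversion is a fixed 33 years per generation;
`dateAdmixture()` reports `[floor(n−SE), ceiling(n+SE)] × 33` years BP.

Precision: the information bound for the three-parameter fit at the
test design (50 bins, noise 5% of amplitude) puts SD(n̂) near one
generation; the profiled fit attains it, and the test suite asserts
unbiasedness plus CRLB-efficiency rather than a tighter coverage no
estimator could meet. Short chromosomes limit accuracy for slow decays:
at `g = 5` the curve needs ~100+ cM of range before the offset and the
decay separate, which is why the recovery tests use fewer, longer
chromosomes for that setting.

Implementation note: the covariance band is computed with blocked BLAS
cross-products (2,048-column blocks, diagonals extracted by strided
indexing), so the full-scale curve (150,000 SNPs, 200 individuals) runs
in about a minute without ever materializing a SNP×SNP matrix; with
missing genotypes the code falls back to a streamed pairwise-complete
path.

## The local-ancestry deviation scan

Per ancestry `k` and locus `j`, the scanned quantity is the cohort mean
ancestry fraction `ā_jk` (mean dosage/2 over individuals — individuals,
not haplotypes, because ELAI-style dosages are unphased), standardized
by the genome-wide mean and the **empirical SD across loci**:
`Z = (ā − μ)/σ`. The empirical σ, rather than a binomial standard
error, absorbs local-ancestry inference noise and autocorrelation, and
makes the threshold |Z| > 3 correspond to the two-sided normal tail
P = 2.7×10⁻³. A per-individual-variance variant of the statistic exists
in the literature; the pooled form is the default here and the only one
tested. Regions are maximal runs of consecutive loci beyond the
threshold (`maxGapSnps = 0` by default; configurable for sparse arrays),
with the lead SNP the largest |Z| (ties broken to the lowest position).

On null cohorts the per-locus exceedance rate matches the binomial
benchmark at the normal tail, but exceedances cluster (the mosaic is
autocorrelated), so isolated one-SNP noise regions do occur; detection
claims in the tests are therefore about the seeded region being the top
region, and the false-positive control is asserted at locus level with
a factor-two band around the benchmark.

The diversity follow-up computes per-SNP observed heterozygosity and the
number of individuals whose ROH covers the SNP, compares region versus
genome-wide distributions by two-sided rank-sum, and applies Bonferroni
(0.05/6 ≈ 8×10⁻³ when six regions are tested).

## Runs of homozygosity

The caller reproduces the PLINK screen: a scanning window of
`windowSnp = 50` consecutive SNPs, truncated so it never spans more than
`windowKb = 5,000`; a window passes when it has at most 1 heterozygous
and 5 missing calls; a SNP is eligible when at least `hitFraction =
0.05` of the windows containing it pass; maximal eligible runs (split at
gaps > 1,000 kb, trimmed to start and end on homozygous calls) are kept
when ≥ 500 kb long and ≤ 50 kb/SNP. The SNP-count constraint matters: a
purely length-based 5,000-kb window tolerating one heterozygote can
never pass around a multi-Mb autozygous tract at array densities, so the
screen would detect nothing — the dual constraint is what the standard
tool actually implements. `hitFraction` and the gap are defaults the
printed parameter set leaves implicit; they are exposed prominently
because they affect reproduction on external data. Hit-rate eligibility
smears segment ends by a few SNPs beyond the true tract (the same
behavior as the reference implementation); the recovery tests allow a
few inter-SNP gaps of slack. Segments are summarized per individual and
group in the six length classes (0.5–1 … >16 Mb) and the ≤1.6/>1.6-Mb
split used to separate old background homozygosity from recent
inbreeding.

## Ancestry blocks

Dosages round at 0.6/1.4 to integer calls {0,1,2}; loci whose rounded
calls do not sum to 2 are flagged ambiguous and excluded. Blocks are
maximal runs of constant call level ≥ 1 per individual and ancestry,
split at chromosome ends and centromeres (hg19 centromere intervals are
bundled; arrays give no coverage there and bridging them would inflate
lengths). Since the dosages are unphased, a level-2 run is one
homozygous block; for the expected-count arithmetic lengths are put on
the **haploid scale** by counting level-2 blocks twice — one defensible
reading of how per-haploid-genome block counts are constructed from
unphased calls. Expected counts are `N_k = round(p_k L / ℓ̄_k)`; with
the canonical mean lengths (13.05/8.46/7.48 Mb), proportions
(0.75/0.22/0.03) and `L = 3150` Mb this gives 181/82/13 (276 total). The
lognormal fit on block lengths uses the closed-form MLE on log lengths.

## Selection statistics and the coalescent null

`windowStats()` tiles a region with non-overlapping 10-kb windows
anchored at the region start and computes S, π and Tajima's D; π uses
genotype allele frequencies under random union of gametes
(`Σ 2p̂(1−p̂)·2n/(2n−1)`), with an `nHap` override for phased input. FST
is Hudson's ratio-of-averages estimator — robust to rare variants and
the standard choice under PBS; the estimator identity of the original
analysis is unstated, and this choice is the main reproduction risk for
printed PBS values. `PBS_A = (T_AB + T_AC − T_BC)/2` with
`T = −log(1 − FST)`, FST clamped to `[0, 1−10⁻⁹]` before the log.

The null comes from the package's own **structured coalescent with
recombination**: ms conventions throughout (time in 4N₀ generations,
sizes in N₀ units, migration 4N₀m, ρ per locus), exponential growth
handled by closed-form inversion of the integrated hazard, events
`-es/-ej/-en/-eM` applied at their scheduled times, lineages carrying
ancestral-segment lists with per-segment descendant sets, segments
dropped once they reach their MRCA, and infinite-sites mutations laid
down between events at rate θ per unit of active ancestral length. The
verbatim four-population demographic command (African, European, Asian,
islander; 28 sampled islander haplotypes; an admixture split of fraction
0.1 and a contraction to 0.068·N₀ ≈ 500 individuals at the colonization
time) parses and simulates directly. Per-replicate (θ, ρ) follow the
stated randomization: normal with variance equal to the mean, truncated
positive by resampling. θ is a user input here (its estimation from
outgroup orthologs is out of scope); the demonstration values θ̂ = 7.3,
ρ̂ = 3.8 correspond to a 10-kb window at N₀ = 7310 with standard human
mutation and recombination rates. N₀ = 7310 itself is used only for
reporting conversions.

Empirical p-values are `count/N` with zero counts floored at `1/N` and
printed as `"< 1/N"` (at N = 5,000: "< 2.0×10⁻⁴"); the `(count+1)/(N+1)`
variant was rejected because the flooring convention matches the printed
significance statements. Tajima's D is tested in the lower tail, PBS in
the upper; Bonferroni families are counted per statistic (0.05/3 → 0.017
for D, 0.05/5 → 0.01 for PBS in the motivating analysis). For PBS nulls
the model samples additional haplotypes from the African and European
demes (the published output kept only the islander haplotypes; of the
two possible readings — simulate all three populations, or pair
simulated islanders with fixed real panels — the former is the default
because it needs no external data).

Because every p-value in a scan shares one finite ensemble, the
p-values are mutually correlated; the calibration tests therefore use
the two-sample Kolmogorov–Smirnov comparison of observed and null draws,
which is the exact form of the claim "observations are draws from the
null".

## Degenerate inputs and tie-breaks

- HWE exact test: monomorphic sites return p = 1; the conditional
  distribution is evaluated by the stable heterozygote-count recurrence,
  and a 1+10⁻¹² relative tolerance guards equal-probability ties.
- LD pruning drops the lower-MAF member of a violating pair (ties: the
  later variant), matching the common tool convention; exclusion of the
  four canonical long-range-LD regions happens before pruning.
- QC order is fixed: sample call rate, then variant call rate, MAF, HWE;
  thresholds are "remove below", so values exactly at a threshold stay.
- Z-scan with a constant ancestry (σ = 0) returns all-zero Z with a
  warning rather than NaN.
- `sampleStats`/`windowStats` report D as missing when S = 0; empty
  windows are kept in the tiling with S = 0.
- Rank-sum tests use midranks; with every value tied the p-value is 1 by
  convention; no continuity correction, so identical samples give
  exactly p = 1.
- Dosage rows violating the sum-to-2 tolerance (±0.05) are rejected and
  counted, never silently renormalized.

## Problem sizes in the test suite

The suite (about five minutes end to end) uses reduced but structurally
faithful cohorts, chosen as the smallest sizes at which each recovery
claim is statistically meaningful: dating on 100 diploids over 600 Mb
(10 chromosomes for `g = 15`; 5 longer chromosomes for the
`g ∈ {5, 15, 30}` bias checks, three seeds each); scan power and
false-positive rate on 200 diploids over 250 Mb at 1 SNP/20 kb (20
seeded and 10 null seeds); coalescent expectations at 2,500 replicates;
ROH oracle equality on 200-SNP instances. `scripts/acceptance.R` runs
the dating recovery at full scale — 200 diploids, 3,000 Mb, 22
autosomes, 1 cM/Mb, 1 SNP per 20 kb — in roughly a minute and a half.

## Known limitations

- Local-ancestry dosages are *inputs*; no LAI HMM is implemented, so
  real-data scans inherit whatever bias the upstream tool has.
- The dating module implements one-reference-pair weighted LD; multiple
  pulses, amplitude-based mixture fractions, and the full multi-panel
  pretest are out of scope.
- The coalescent engine covers the ms dialect subset above; hotspot
  recombination maps and selection are not simulated.
- Relatedness filtering (IBD/PIHAT) is not implemented; cohorts are
  assumed unrelated.
- The HWE filter is applied globally by default; a per-group option
  exists but mirrors an ambiguity in standard practice (reference panels
  are often filtered per population).
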