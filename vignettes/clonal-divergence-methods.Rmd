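---
title: "Methods: paired-tumour clonal divergence under divergent immune selection"
author: "ClonalDivergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-tumour clonal divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClonalDivergence)
```

# The analytical problem

Paired baseline/recurrence tumour exomes from formalin-fixed (FFPE)
archival material allow two questions to be asked at once: how much does
a tumour's mutational repertoire turn over between resection and
recurrence, and does the immune environment at recurrence (for example,
post-transplant immunosuppression versus immunocompetence) leave a
genomic footprint on that turnover? Answering either requires a chain of
steps — artefact-aware variant filtering, cancer cell fraction (CCF)
estimation, clone clustering, divergence statistics against a proper
null, neoantigen dynamics, and immune-evasion genotyping — each of which
this package implements and tests. Because cohorts of this kind are
typically under controlled access, the package treats its synthetic
cohort generator as a first-class module: the generator defines the
study conditions under which every guarantee is measured.

# FFPE-aware variant filtering

Formalin fixation deaminates cytosines, producing artefactual C>T (read
as G>A on the opposite strand) calls at characteristically low variant
allele frequencies (VAF). `applyArtifactFilters()` runs two stages in a
fixed order so the report attributes every removal unambiguously:

1. **Signature stage** — removes C>T/G>A substitutions that look like
   deamination artefacts. When the input carries caller filter flags
   (e.g. an orientation-bias module's flags), flagged C>T/G>A calls are
   removed; for flag-less inputs a declarative stand-in removes C>T/G>A
   calls with VAF below `signatureSubThreshold` (default 0.05). The
   stand-in replaces the caller's proprietary artefact model with a
   transparent, testable rule.
2. **VAF stage** — removes every variant with VAF strictly below
   `vafThreshold` (default 0.10). *Strictly below* is a deliberate
   boundary convention: a VAF of exactly 10% is retained. The threshold
   is applied to all variant types alike, including indels.

Two properties are asserted by the test suite: raising the threshold
never increases the retained count, and filtering an already-filtered
set removes nothing further.

# CCF estimation

For a mutation carried on $m$ mutant copies at cancer cell fraction
$\varphi$, in a sample of purity $\rho$ at a locus with tumour total copy
number $CN_t$ and normal copy number $CN_n$:

$$\mathrm{E}[v] \;=\; \frac{\varphi\,\rho\,m}{\rho\,CN_t + (1-\rho)\,CN_n}$$

`computeCcf()` inverts this: $m$ is chosen from $1..\mathrm{major}_{CN}$
to minimise the distance between the observed VAF and the expected
*clonal* ($\varphi = 1$) VAF, and then
$\varphi = v\,(\rho\,CN_t + (1-\rho)\,CN_n)/(\rho\,m)$. Numerical
conventions:

- **Tie-break:** when two multiplicities fit equally, the smaller $m$
  wins — the conservative choice, since it yields the larger CCF
  denominator only when justified.
- **Capping:** CCF estimates are capped at 1; the uncapped value is kept
  (`ccf_uncapped`) because values well above 1 flag purity or copy-number
  misfit.
- **Homozygous deletions** ($\mathrm{major}_{CN} = 0$) cannot carry a
  mutation in tumour cells; such calls are flagged `inconsistent` and
  excluded from clustering.
- **No covering segment:** the variant is assumed diploid
  ($CN_t = CN_n$, $m = 1$). Segment joins use 1-based inclusive
  containment via GenomicRanges.

# Clone clustering

Mutations with similar CCFs are taken to co-exist in the same cellular
population. `clusterCcfs()` fits, for each candidate clone count
$k = 1..15$, a $k$-component binomial mixture over alt read counts in
which component $j$ places mutation $i$'s count at
$\mathrm{Bin}(d_i,\; c_j s_i)$, where $s_i$ is the mutation's expected
VAF at CCF 1. The count cap of 15 mirrors the subclone ceiling used in
cohort practice for this tumour type. Model size is selected by BIC
($-2\log L + (2k-1)\log n$), and each mutation is assigned to its
maximum-responsibility component.

Numerical choices: components are initialised at CCF quantiles, which
makes the fit deterministic (no random restarts to reconcile); the EM
stops when the relative log-likelihood change falls below $10^{-7}$ or
after 200 iterations; centre estimates are clamped to
$[10^{-4}, 1]$; empty components are dropped before reporting; an input
whose CCFs are all identical collapses to a single cluster. The fit is a
transparent stand-in for variational Bayesian clone deconvolution
machinery: the downstream statistics need CCF clusters and their
mutation fractions, not posterior uncertainty, and the EM/BIC route is
exactly reproducible and fast enough to run inside the test suite. On
simulated data with three clones at CCF 0.2/0.5/1.0 (100 mutations each,
depth 500) the procedure recovers the count and centres to within 0.05
across seeds (asserted in the acceptance tests).

# Clonality score and its deltas

The clonality score of a sample is
$\sum_c f_c\,\mathrm{CCF}_c$ over clones, with $f_c$ the fraction of
mutations in clone $c$ — algebraically the mutation-level mean CCF, which
is how `clonalityScore()` computes it (the equivalence is asserted to
machine precision). It ranges from 0 (entirely subclonal) to 1 (entirely
clonal). A defensible alternative reading of "weighted by its frequency"
would weight each mutation by its VAF; we adopt the clone-fraction
reading because it is the one that yields a $[0,1]$ range whose
endpoints mean exactly "entirely subclonal" and "entirely clonal". `deltaClonality()` reports recurrence − baseline
per patient and compares groups with a two-sided tie-corrected rank-sum
test.

# Divergence and the unmatched null

Mutation identity is the exact chrom/pos/ref/alt tuple; gene annotation
is ignored. Two overlap statistics are reported, because they answer
different questions:

- **Percent public** $= 100\,|A \cap B|/|A \cup B|$ — symmetric; the
  display statistic for private/public breakdowns.
- **Overlap percent** $= 100\,|A \cap B|/|A|$ — asymmetric
  (first-profile denominator); the statistic enumerated over *ordered*
  pairs in the unmatched null.

The null (`buildUnmatchedNull()`) enumerates every ordered pair of
unrelated profiles; with self-pairs included, $N$ profiles give exactly
$N^2$ values (360 give 129,600). Only the total pair count pins down
the enumeration convention — the denominator and the self-pair question
remain open — so both choices are explicit flags rather than silent
guesses:
`includeSelfPairs = TRUE` reproduces the $N^2$ count, and `FALSE` gives
the more conservative $N(N-1)$ null without the guaranteed-100% diagonal.
Internally the enumeration is a sparse incidence cross-product, so
cohort-scale nulls complete in seconds. `compareMatchedVsNull()` then
applies the rank-sum test, reporting direction alongside the p-value and
degenerate all-tied inputs as p = 1 with a warning.

# Neoantigen dynamics

Affinity tiers use the conventional inclusive thresholds: IC50 ≤ 100 nM
strong, ≤ 500 nM weak, > 500 nM non-binder, missing → unknown (both
boundaries configurable). A stringent externally supplied consensus flag
is carried through separately; neoantigen calling itself (HLA typing,
peptide–MHC prediction) is out of scope — the module consumes labels.

`computeDeltaCcf()` takes the union of the two timepoints' mutations,
with a mutation absent from a timepoint contributing CCF 0 there — it is
genuinely carried by no cell, not merely unmeasured. Because private
mutations dominate these cohorts, union-with-zeros is the default; an
intersection mode is provided for sensitivity analysis.

`compareDynamics()` compares neoantigen vs control delta-CCF
distributions per patient and pooled. The pooled analysis must respect
patient structure (patients differ in purity, depth and turnover), so
the default centres each patient's deltas on their within-patient mean
before pooling into one rank-sum test; Fisher's combination of
per-patient p-values is the config-switchable alternative. Under the
no-selection null the centring is label-independent, so the test retains
its nominal level — the acceptance suite verifies a rejection rate of
5% ± 2% at $\alpha = 0.05$ over 500 simulated cohorts, and ≥ 80% power
to detect a selection coefficient of 0.5 over 200 cohorts of 15
patients.

# Immune evasion

Loss of function is the classification set {nonsense, frameshift
insertion/deletion, in-frame indel, nonstop}; "other indels" are mapped
to the in-frame indel class per MAF conventions, and missense calls are
excluded because their functional impact is hard to read. The gene
catalogue ships as an editable TSV (antigen presentation machinery plus
CRISPR-screen CD8-killing-resistance hits, each tagged with provenance);
it seeds the recurrently altered genes and deliberately does not claim
to freeze the version-dependent KEGG or screen lists. Flags can be
aggregated per sample or per patient (baseline and recurrence combined),
since published per-tumour counts can be read either way. Proportions
are compared with Fisher's exact test (sample odds ratio with the
Haldane 0.5 correction when a cell is zero; group order follows the
factor levels) and covariates (mutational burden, CD8 infiltration,
CD8/Treg ratio) with rank-sum tests.

# Promoter methylation

`summarisePromoters()` averages beta values (mean primary, median always
also emitted) over probes in the upstream regulatory classes TSS200,
TSS1500 and 1stExon; gene-body/"other" probes never contribute, and
probes mapping to several genes contribute to each. A gene is
"neoantigen-bearing" if any stringent-pass neoantigen mutation falls in
it — the natural default when a gene carries a mixture.
`compareShifts()` tests recurrence − baseline shifts between
neoantigen-bearing and other genes, stratified by immune group.

# The synthetic cohort: what it emulates, and what it does not

The generator (`simulateCohort()`) uses a **flat clone model**: clones
are CCF clusters with no phylogeny, matching the analysis decision not
to reconstruct trees from single-region data. Per patient: a truncal
clone at CCF 1 in both samples, a shared subclone with independent CCFs
at the two timepoints, and timepoint-private clones (private mutations
have CCF 0 at the other timepoint — truly absent, with an off-by-default
detection-limit censoring toggle). Key defaults, chosen once as
realistic study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 15 | realistic size for a paired-recurrence archival cohort |
| `tumour_depth_mean` / `normal_depth_mean` | 100 / 50 reads | the exome coverage design this setting uses |
| `mutations_per_sample_range` | 80–150 | exome somatic burden typical of HCC |
| `trunk_shared_fraction` | 0.2 | "vast majority private" without a published number; config-exposed |
| `shared_subclone_fraction` | 0.3 | truncal dominance among shared mutations; 0 gives a fully clonal tumour |
| `clones_per_sample_range` | 3–6 | small clonal populations over a subclonal majority |
| `purity_range` | 0.4–0.9 | resected/archival specimens |
| `ffpe_artifact_rate` | 10 per sample | visible but not dominant artefact load |
| `artifact_vaf_beta_params` | Beta(1.5, 30) | mean VAF ≈ 0.05, ~90% of mass below the 10% threshold |
| `neoantigen_fraction` | 0.15 | stringent-consensus call rates |
| `selection_coefficient_s` | 0 | the immune-escape null |

Read counts are drawn as
$\mathrm{Bin}(d,\ \mathrm{E}[v])$ with $d \sim \mathrm{Poisson}$ around
the configured mean, floored at 10 reads; draws with zero alt reads are
not emitted (the variant was not called). Copy-number profiles are drawn
per patient and shared between timepoints so a mutation keeps one
multiplicity. Artefacts are C>T/G>A calls with Beta-distributed VAFs,
Poisson counts per sample, and at least one alt read (an artefact is by
definition a call); their truth labels live in the truth table, never in
the variant table, so filters cannot see them. Immunoediting multiplies
recurrence CCFs of neoantigen mutations by $1-s$ before read sampling.
Simulated MAFs carry no caller filter flags, so the signature filter
exercises its flag-less sub-threshold path.

**Not emulated:** read-level errors (no FASTQ/BAM), trinucleotide
signature spectra, germline variation, copy-number change between
timepoints, inter-patient hotspot sharing, and spatial heterogeneity.
Passing tests therefore demonstrate correctness of the statistical
machinery under a faithful read-sampling model — not robustness to
alignment artefacts, subclonal copy number, or multi-region sampling
effects in real data.

# Problem sizes used by the test suite

The suite runs the generator at the defaults above: 500 null cohorts and
200 selection cohorts of 15 patients for detector calibration and power,
100 cohorts for the divergence-direction check, 360 profiles for the
null-size law, 1,000 random instances for the CCF oracle, and 20 seeds
for clone recovery. These sizes give binomial standard errors comfortably
inside the asserted bands while keeping a full run in the minutes range
on one core.

# Known limitations

- The clone clustering stand-in reports point centres, not posterior
  clone assignments; mutations near cluster boundaries are hard-assigned.
- CCF estimation trusts the purity and segment calls it is given;
  uncapped CCF diagnostics surface, but do not correct, misfit.
- The unmatched null treats profiles as exchangeable bags of keys;
  shared hotspot biology in real cohorts would lift the null slightly,
  making the matched-vs-null comparison anti-conservative by a margin
  the package does not model.
- The methylation module summarises and tests; it does not normalise raw
  arrays or deconvolve cell types.
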