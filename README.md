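# ClonalDivergence

Tools for analysing the clonal evolution of paired baseline/recurrent
tumours profiled by whole-exome sequencing from formalin-fixed (FFPE)
material — the setting of hepatocellular carcinoma (HCC) cohorts in which
some patients recur under post-transplant immunosuppression and others
while immunocompetent, so that the two groups experience divergent immune
selection pressures.

The package is aimed at cancer-genomics analysts who have per-sample
somatic variant tables (MAF-style TSV or VCF), Sequenza-style
allele-specific copy-number segments with purity estimates, and optional
neoantigen/methylation/immune annotations — and who want the complete,
tested chain of analyses from FFPE artefact filtering to immunoediting
statistics. Because patient-level data of this kind are typically under
controlled access, a synthetic-cohort generator with known clonal truth is
a first-class component: every downstream stage can be exercised, and its
error rates measured, without any protected data.

## What it computes

**CCF estimation.** For a mutation with observed variant allele frequency
*v* in a sample of purity *ρ*, at a locus of tumour total copy number
*CN<sub>t</sub>* (normal *CN<sub>n</sub>*), carried on *m* mutant copies,
the expected VAF is

    E[v] = φ ρ m / (ρ CNt + (1 − ρ) CNn)

where *φ* is the cancer cell fraction (CCF). The multiplicity *m* is
chosen from 1..major<sub>CN</sub> to bring the expected clonal VAF closest
to the observed one (ties towards the smaller, conservative *m*), and the
CCF estimate is capped at 1 with the uncapped value retained as a
purity/copy-number diagnostic.

**Clone clustering.** A seeded EM binomial mixture over alt read counts,
with component success probabilities induced by candidate clone CCFs and
the clone count selected by BIC, capped at 15 subclones.

**Clonality score.** The frequency-weighted sum of clone CCFs,
Σ<sub>c</sub> f<sub>c</sub>·CCF<sub>c</sub> (equivalently the
mutation-level mean CCF): 1 = entirely clonal, → 0 = entirely subclonal.
Between-timepoint deltas are compared across immune groups with two-sided
rank-sum tests.

**Divergence.** Mutations are classified private/public between
timepoints by exact chrom/pos/ref/alt identity; matched overlap is tested
against an unmatched null built from *all ordered pairwise combinations*
of unrelated profiles (N profiles → N² overlap values).

**Neoantigen dynamics.** Binding-affinity tiers (≤100 nM strong,
≤500 nM weak), per-mutation delta-CCF between recurrence and baseline
(absent = CCF 0), and rank-sum comparisons of neoantigen vs control
dynamics — the genomic footprint immunoediting would leave.

**Immune evasion.** Loss-of-function calls (nonsense, frameshifts, other
indels, nonstop) in a packaged, editable catalogue of antigen-presentation
genes and CRISPR-screen CD8-killing-resistance hits; group comparisons by
Fisher's exact test and covariate associations by rank-sum tests.

**Promoter methylation.** Per-gene mean/median beta over TSS200, TSS1500
and 1stExon probes, with shift comparisons by neoantigen status.

## Worked example

```r
library(ClonalDivergence)

cfg <- runConfig(simulation = simulationConfig(n_patients = 15, seed = 1),
                 out_dir = "runs", seed = 1)
res <- runPipeline(cfg)
```

The run directory contains every stage's tables; the summary printed for
this seed is:

```
ClonalDivergence run (run-001)
seed: 1; stages: simulate, filter, ccf, divergence, neoantigen, evasion, methylation
filter: 3503 -> 2188 variants retained
divergence: median percent public 14.0%; matched vs null p = 1.25e-36
clonality: scores 0.48-0.91
neoantigen dynamics: pooled p = 0.495
evasion LoF: OR 1.56, p = 0.69
```

Reading the numbers: the dual FFPE filter (artefact-signature stage, then
the strict `VAF < 10%` exclusion) retains 62% of calls; most mutations
are private to one timepoint (median 14% public), yet matched pairs
overlap far more than unrelated profile pairs (median 24.6% vs 0%,
rank-sum p ≈ 1e-36) — the divergence is biological, not a filtering
artefact. Clonality scores span 0.48–0.91, and with the simulator's
selection coefficient at its default of 0 (no immunoediting), the
neoantigen delta-CCF test is, correctly, non-significant (p = 0.49).

The same stages run from the shell:

```sh
Rscript inst/scripts/run_pipeline.R all --seed 1 --out runs --patients 15
```

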