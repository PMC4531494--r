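# ClonoScope

Clonality and diversity analysis of immunoglobulin (IG) and T-cell
receptor (TR) repertoires from per-read V(D)J annotation tables.

## The problem

Adaptive immunity rests on an enormous diversity of B- and T-cell
antigen receptors generated by V(D)J recombination. AIRR sequencing of
a blood sample yields hundreds of thousands of reads, each annotated
(by an upstream alignment portal) with a functionality class, V/D/J
gene calls and CDR1/2/3 sequences. Researchers monitoring, say, a
transplantation course or a suspected clonal expansion then need to
answer: how many reads are productive? Which genes are used? How many
distinct clones — *clonotypes* — are present, how diverse is the
repertoire really once sequencing depth and read errors are accounted
for, and which clones persist across timepoints or cell fractions?

ClonoScope answers these questions for people analysing such
annotation tables: descriptive functionality and gene-usage
statistics, clonotype counting under a user-chosen clone definition,
model-based diversity estimation, V-(D)-J combination spectra,
multiplex-PCR primer efficiency, and multi-sample comparison and
tracking. A seeded synthetic-repertoire generator with complete ground
truth makes every stage testable without external data.

## The core model

The empirical diversity of a sample with `N` clonotype-bearing reads is
measured by rarefaction: for increasing subsample sizes `n`
(e.g. `n = 0, 1000, 2000, ...`), draw `n` of the `N` reads without
replacement and count the distinct clonotype keys,

    div_calc(n) = c_unique(rand(n, N)),

averaging five random subsamples per `n`. This curve rises steeply,
then bends towards a plateau — but never quite flattens, because read
errors keep manufacturing spuriously novel clonotypes. ClonoScope
therefore fits

    div_mod(n) = a · (1 − e^(−b·n)) + k·n

where **a** is the true number of unique clonotypes in the sample,
**b** the per-read saturation rate, and **k** the fraction of reads
whose apparent novelty is due to read errors. The three parameters are
optimised by an elitist (10+50) evolution strategy with self-adaptive
step sizes, minimising the sum of squared residuals against
`div_calc`; the fitted `a` is the diversity estimate reported.

## Worked example

```r
library(ClonoScope)

## a synthetic repertoire with known ground truth:
## 300 true clonotypes, 20,000 reads, 0.2% per-read CDR3 error
sim <- simulateRepertoire(SimulationConfig(nClonotypes = 300,
                                           nReads = 20000,
                                           errorRate = 0.002, seed = 42))
sim$records
#> RepertoireSet with 20000 reads
#>   functionality: productive=16424 unproductive=2224 unknown=202 no_result=1150

buildClonotypeTable(sim$records, ClonotypeDefinition("CDR3_AA"))
#> ClonotypeTable (CDR3_AA): 341 clonotypes from 18850 reads
#>                key count frequency
#>  KLHWVNLKWRQDYLCTV   136    0.721%
#>        TGWLPGAMPLP   135    0.716%
#>           ELTNGRKL   133    0.706%
#>   EPGNHNFVHPCDARYM   129    0.684%
#>        TLWLKIWHSIS   127    0.674%
#>   ...

res <- estimateRepertoireDiversity(sim$records, nStep = 500,
                                   config = ESConfig(seed = 1))
res$fit
#> DiversityModelFit: div_mod(n) = a*(1-exp(-b*n)) + k*n
#>   a = 298.888 (true unique clonotypes)
#>   b = 0.00291364 (saturation rate per read)
#>   k = 0.00226325 (read-error slope)
#>   objective (SSE) = 73.5872
```

Reading the output: the raw table shows **341** distinct CDR3 keys —
an overcount, since substitution errors split reads off their true
clones (the 1,150 `no_result` reads are excluded from all clonality
calculations). The model fit sees through this: `a = 298.9` against
the true 300, and `k = 0.0023` recovers the simulated 0.002 error
rate.

Other entry points follow the same pattern: `readSummary()` /
`writeSummary()` for annotation tables (a `SummaryDialect` remaps
column names of portal exports such as a `1_Summary` table onto the
canonical fields `sequence_id`, `functionality`, `v_call`, `d_call`,
`j_call`, `cdr1_aa`, `cdr2_aa`, `cdr3_aa`, `cdr3_nt`, `sequence_nt`),
`splitFasta()` / `mergeOutputs()` for portals with a 500,000-sequence
submission limit, `geneUsage()` and `combinationMatrix()` +
`mapToSpectrum()` for gene spectra, `matchPrimers()` for primer
efficiency, and `pairwiseCompare()` / `multiCompare()` /
`trackClonotypes()` for cross-sample work.

A command-line wrapper covering all of this lives at
`inst/scripts/clonoscope.R`:

```sh
Rscript inst/scripts/clonoscope.R simulate --n-reads 20000 --seed 42 --out-dir sim
Rscript inst/scripts/clonoscope.R diversity --in sim/summary.tsv --seed 1 --out-dir out
```

Every run writes a `run_manifest.tsv` (command, package version, seed,
input checksums) sufficient to reproduce its outputs exactly.

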