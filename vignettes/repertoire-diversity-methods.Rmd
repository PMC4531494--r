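---
title: "Methods: clonotype counting and model-based diversity estimation"
author: "ClonoScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype counting and model-based diversity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClonoScope)
```

This vignette is the package's account of its methods: the data model,
the clonotype and diversity machinery, the numerical choices behind
them, what the synthetic-data generator does and does not emulate, and
the known limitations. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Input model and the summary dialect

ClonoScope consumes one tab-separated table per sample, one row per
read, produced by an upstream V(D)J annotation service. Portals differ
in header naming and decorate their functionality tokens with
comments, so reading goes through a `SummaryDialect`: a mapping from
our ten logical fields to physical column names, a delimiter, and a
set of missing-value tokens. The canonical dialect is our own
definition — deliberately decoupled from any particular portal's
header set, which has historically drifted — and the mandatory fields
are the minimum for clonality work: `sequence_id`, `functionality`,
`v_call`, `j_call`, `cdr3_aa`. D-segment and nucleotide columns are
optional because IGK/IGL/TRA-like loci have no D genes at all.

Functionality normalisation is a case-insensitive prefix match,
checked in the order *unproductive*, *no result(s)* (or an empty
token), *productive*, *unknown* — the order matters because
"unproductive" contains "productive" as a substring. Unrecognised
tokens map to `unknown` with a warning rather than an error: one odd
token should not abort a 200,000-read analysis. Reads of class
`no_result` (no alignment found) are retained in functionality
summaries but excluded from every downstream calculation, and the
`ClonotypeDefinition` class enforces this by refusing `no_result` in
its include-set.

Whether `unknown` (and `unproductive`) reads should enter clonality
denominators is genuinely open — many repertoire studies restrict to
productive reads, others count everything alignable. We default to
including all three non-`no_result` classes and expose the choice as
the definition's `include` argument (`include = "productive"` gives
the restrictive convention), rather than hard-coding either.

## Clonotype definitions and counting

A clonotype key is derived per read under one of six modes: CDR1, CDR2
or CDR3 amino-acid sequence, CDR3 nucleotide sequence, the whole-read
nucleotide sequence, or the V-(D)-J gene combination at gene or allele
level (joined `V|D|J`, absent D rendered `-`). Key comparison is exact
string identity after upper-casing and whitespace stripping — no fuzzy
matching, no gap removal. The amino-acid alphabet admits `*` and `X`,
since annotation output legitimately contains stop codons in
unproductive CDR3s.

Counting is a plain tally; relative frequencies in clonotype tables
are percentages (0–100), matching the convention of published
clonality tables, while every other table in the package uses
fractions (0–1). All ranked tables share one deterministic tie-break —
descending count, then ascending key in C collation — so outputs are
byte-reproducible across platforms and locales.

Gene calls are parsed from IMGT-style nomenclature strings
(`"Homsap TRBV6-4*01 F"`): optional species word, gene name, optional
`*`-delimited allele, optional functionality flag. When a read carries
several comma-separated alternative calls we take the first, which is
the annotation portal's highest-scoring hit; this is a choice, not a
ground truth, and reads with ambiguous calls can instead be excluded
by filtering beforehand.

## Rarefaction

The empirical diversity curve subsamples *without* replacement: `n` of
the `N` clonotype-bearing reads, distinct keys counted, five
replicates per grid point averaged, the grid running `0, s, 2s, ..., N`
(step `s` defaulting to 1000 reads; `0` anchors the curve at the
origin and `N` itself is always the final point). Without-replacement
sampling is what "choose n out of N" means, and it fixes the analytic
oracle: the expected number of distinct clonotypes in such a subsample
is

$$E[c_{unique}(n)] = \sum_i \left(1 - \binom{N-N_i}{n}\big/\binom{N}{n}\right)$$

over clonotype abundances $N_i$. `expectedUnique()` evaluates this in
log-space (`lchoose`) so it is exact at any scale, and the test suite
holds the rarefaction means to it within 2% at 200 replicates. Had we
sampled with replacement the oracle would be multinomial and the curve
would saturate more slowly; the two are not interchangeable.

## The diversity model and its evolution-strategy fit

The model $div_{mod}(n) = a(1-e^{-bn}) + kn$ decomposes observed
richness into a saturating component (true clonotypes, level $a$,
rate $b$) and a linear component ($k$) for read-error-generated
novelty. Its assumptions are worth stating plainly:

* all true clonotypes are discoverable at the sample's depth (the
  exponential has a single rate — see the limitation below);
* errors generate novel keys at a constant per-read rate, i.e. an
  error almost never collides with an existing key (true for CDR3-long
  sequences over a 20-letter alphabet);
* subsampling noise around the means is homoscedastic enough that an
  unweighted least-squares objective is sensible. We fit the grid
  *means* (as the averaged-replicate formulation implies) and do not
  weight by replicate variance.

The fit is an elitist $(\mu+\lambda)$ evolution strategy,
$\mu = 10$ parents, $\lambda = 50$ offspring, 500 generations by
default. Each parameter carries its own mutation step size, adapted by
the standard log-normal rule with learning rate $\tau = 1/\sqrt{2d}$,
$d = 3$. Two scale decisions matter:

* $a$ lives on the linear scale (initial step 10% of the curve
  plateau), with negative proposals reflected at zero;
* $b$ and $k$ span orders of magnitude across data sets, so they are
  mutated multiplicatively (log scale, initial step 0.5 natural-log
  units) and floored at $10^{-12}$ — far below any meaningful rate —
  to keep multiplicative mutation defined.

Initialisation places the search inside the basin for typical
saturating curves: $a_0$ = the curve value at the largest grid point,
$b_0 = 3/n_{max}$ (so the exponential is ~95% saturated at the end of
the grid), $k_0$ = the slope of the last two grid points. Selection is
elitist over the union of parents and offspring, which gives the
testable guarantee that the best objective never increases across
generations; the per-generation best is exposed via `esTrace()`. There
is no recombination — with three parameters the population provides
ample diversity, and the omission keeps the algorithm exactly
reproducible from a single seed. A degenerate all-zero curve fits to
$a \approx k \approx 0$ without special-casing.

All randomness in the package — subsampling and ES alike — flows from
user-supplied seeds, and seeded code restores the caller's RNG state,
so package internals never perturb a user's own random stream.

## V-(D)-J spectra

Combination matrices count gene (or allele) tuples over `(V,J)`,
`(V,D)`, `(D,J)` or `(V,D,J)` among reads with complete calls for the
chosen axes. They are stored sparsely; `mapToSpectrum()` re-expresses
a matrix over the *complete* spectrum of a germline reference, with
explicit zero cells and axes in natural order (numeric family/member
sort: TRBV2 < TRBV6-4 < TRBV12-3, not ASCII order), so any two samples
mapped to the same reference are cell-for-cell comparable. Observed
names missing from the reference are appended under an "unknown"
section with a warning, never silently dropped — totals are conserved
by construction. The frequency threshold filter drops cells below a
fraction of the *original* total, which is deliberately not recomputed
so surviving frequencies keep their meaning.

The bundled reference (`inst/extdata/germline_reference_synthetic.tsv`,
version `synthetic-1.0`) is a constructed stand-in assembled from
publicly documented human TRB and IGH gene names; it includes
pseudogene/ORF entries with a functionality column users can filter
on, and any analysis can substitute its own reference file. It is
versioned so spectrum reports state what they were mapped against.

## Primer matching

Primer efficiency analysis is exact substring search, by design — the
question is "which primer *produced* this amplicon", and amplicons
contain their primer verbatim. Reverse primers are searched as reverse
complements because annotated reads are in V-to-J orientation
(`literal = TRUE` disables this). IUPAC degenerate codes in primers
match any compatible read base (multiplex panels are degenerate);
ambiguity codes on the read side are treated as literal characters. A
read contributes at most one hit per primer, so per-primer frequency
is "fraction of reads carrying the primer", and the denominator is
always *all* searched reads — reads with no forward (or reverse) hit
are reported separately rather than silently changing the denominator.

## Comparison and tracking

All comparers operate on exact key identity (no V-gene qualifier on
CDR3 keys, no tolerance): the top-`c` lists of each sample are
unioned, and every key's frequency is looked up in every sample, zero
where absent — a reported frequency is therefore always either 0 or
exactly the source table's value. The default `c = 20` follows the
common top-20 reporting protocol. Colour assignment for plots is a
deterministic hash of the key into a fixed palette, so a clonotype is
rendered identically in every report and across runs; a random
assignment would make longitudinal figures inconsistent.

## The synthetic-data generator

`simulateRepertoire()` emulates the data the analyses are designed
for: a multiplex-PCR repertoire with `nClonotypes` true clones
(distinct random CDR3 amino-acid keys, 8–20 residues, with V/D/J
assignments from the germline reference), reads drawn from an
abundance distribution, a functionality mix, and a per-read error
process that substitutes one CDR3 position with probability
`errorRate` — the minimal mechanism that produces the linear $k·n$
term the model describes. Defaults are fixed once:

* abundance: geometric with ratio 0.995, giving the
  saturating-then-linear empirical curves seen in deeply sequenced
  blood repertoires (uniform and lognormal alternatives exist);
* functionality mix 82/11/1/6% productive/unproductive/unknown/
  no-result, the proportions typical of heavy-chain annotation runs;
* `no_result` reads carry no calls and no CDR3, as in real output.

Ground truth covers every read (source clonotype, error flag), so
clonotype tables, rarefaction and the end-to-end diversity estimate
can all be checked against construction.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: junction-level V(D)J recombination
(insertions/deletions), somatic hypermutation, platform-specific
error profiles (errors here are single substitutions, uniformly
placed), PCR amplification bias coupling abundance to primer identity,
and multi-segment D calls. Tests built on it validate the *analysis
machinery*, not the biology of any particular locus.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at the scales the
methods are specified at: the functionality fixture at 237,269 reads,
FASTA split/merge at 1,200,003 records against the 500,000-record
portal limit, rarefaction accuracy at 2,000 reads × 200 replicates,
parameter recovery on a 51-point grid (noiseless plus 20 noisy
seeds), and the end-to-end estimate at 100,000 reads from 1,000
clonotypes. Unit tests use smaller instances (hundreds to thousands
of reads, 40–300 ES generations) chosen to exercise the same code
paths quickly.

## Known limitations

* **$k$ is not purely a read-error rate.** The model has a single
  saturation rate $b$, but a skewed abundance distribution makes the
  true (error-free) rarefaction curve a *mixture* of exponentials: its
  rare-clone tail is locally linear, and the least-squares optimum
  absorbs that tail into $k$. On error-free data simulated under the
  default geometric abundances, the fitted $k$ is therefore small but
  genuinely nonzero, and $a$ correspondingly underestimates richness
  by roughly the rare-clone mass (the acceptance script computes this
  as `endtoend_errorfree_fitted_k`). When the error-free curve truly
  plateaus — uniform abundances, depth well past saturation — $k$
  collapses to ~0 and $a$ is recovered within a few percent, which the
  test suite demonstrates. Interpret $a$ as "clonotypes discoverable
  at this depth" and $k$ as "novelty per additional read", error-driven
  or tail-driven.
* **Exact-identity clonotypes.** No clustering of near-identical CDR3s
  is attempted, so one true clone affected by errors splits into
  several keys (this is precisely what the diversity model corrects
  for at the *count* level, but per-clone tables retain the split).
* **First-call disambiguation.** Taking the first of several listed
  gene calls biases spectra toward the portal's scoring; usage tables
  and spectra inherit that bias.
* **Bundled reference completeness.** The synthetic reference covers
  TRB and IGH at the level needed for mapping and simulation; it is
  not an authoritative allele catalogue, and serious spectrum work
  should supply a current reference file.
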