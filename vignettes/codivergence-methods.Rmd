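---
title: "Methods: inferring the mode of endosymbiont acquisition"
author: "codiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring the mode of endosymbiont acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codiverge)
```

## The question

Maternally transmitted endosymbionts such as *Wolbachia* can reach a host
lineage three ways: **cladogenically** (the infection persists through a
host speciation event, so host and symbiont divergence times coincide),
by **introgression** (hybridization transfers the whole maternal
cytoplasm, so symbiont and mitochondrial divergences agree with each
other but are younger than the nuclear genome), or **horizontally**
(nonsexual transfer, leaving the symbiont younger than both host
genomes). If dated phylogenies of all three genomes were available the
modes would be trivially distinguishable; in practice only *relative*
divergences are estimable, and the symbiont and host evolve at very
different absolute rates. `codiverge` implements the comparative
workflow that works around this: codon-position-partitioned divergence
and relative-age chronograms, silent-site (k~s~) ratios judged against
published cladogenic calibrations, explicit-convention conversion to
calendar time, and read-depth copy-number scans for structural
differences between symbiont genomes.

## Ortholog filtering and concatenation

Genes enter the analysis only if they are **single copy** (exactly one
copy in every genome considered) and **full length** (identical observed
length across genomes); both rules are applied verbatim by
`filter_single_copy_full_length()`. Retained genes are concatenated in
input order with `concatenate_genes()`. Codon position is assigned *per
gene* — every gene starts in frame 1 — so concatenation can never shift
reading frames. Sites carrying a gap or `N` in a taxon are retained in
the matrix but excluded *pairwise* at comparison time, which gives every
pair its own usable-site denominator; how shared-gap columns entered the
published genome-wide denominators is generally not recoverable, so this
convention is an explicit, documented approximation. Coordinates are
stored and reported 1-based inclusive throughout (the native R
convention, and the convention of the CNV tables the scan mirrors).

## Divergence and its uncertainty

Pairwise divergence is the raw proportion of differing sites among
usable sites, per codon position and overall (`pairwise_divergence()`).
With genome-scale denominators and a handful of variants, a binomial
model is exact enough; 95% intervals use the **Jeffreys** prior
(`qbeta(0.025, x + 1/2, n - x + 1/2)`, lower bound pinned to 0 when no
variants are seen), which has near-nominal coverage down to single-digit
counts. Percentages are rendered at one significant figure below 0.01%
and two otherwise, matching how sub-0.1% whole-genome divergences are
conventionally reported. Multiple-hit correction at these scales
(10^-5^–10^-4^) changes estimates by less than one part in 10^4^ and is
deliberately omitted here; the chronogram model below handles it where
it matters.

## The strict-clock partitioned chronogram

The core estimator is `chronogram()`: a rooted topology is given, every
tip sits at age 0, and internal-node ages plus three per-codon-position
rate multipliers r~1~, r~2~, r~3~ are estimated by maximum likelihood.
The expected number of substitutions on a branch at position *p* is
r~p~ × (branch duration). Rates and times are jointly unidentifiable (a
chronogram fitted with all ages doubled and all rates halved has
identical likelihood — a property the test suite asserts), so the age of
a user-chosen **reference node is fixed at exactly 1** and all other
ages are reported relative to it.

The substitution model is **HKY** with empirical base frequencies and a
single transition/transversion ratio, not a richer GTR+Γ: at the
divergences this package targets (≤ 10^-1^ at third positions, far less
for the symbiont) relative node ages are insensitive to exchangeability
details, and the simpler likelihood is small enough to be fully
testable. Likelihoods are computed by Felsenstein pruning over
site patterns compressed per partition; gaps and `N` contribute a vector
of ones (uninformative). Optimization is Nelder-Mead on log-transformed
ages and rates, started from Jukes-Cantor distance heuristics (UPGMA-style
mean cross-pair distances, repaired to respect the topology). Degenerate
inputs — a partition with no variation, or zero differences overall —
fall back to topological-depth starting ages with floor rates of 10^-9^;
the optimizer's convergence code is surfaced as a warning, never
swallowed.

Uncertainty comes from a **parametric bootstrap** (`bootstrap = B`):
alignments are resimulated under the fitted model with the exact-HKY
sampler `simulate_clock_alignment()`, refitted warm-started with the
transition/transversion ratio held at its fitted value, and percentile
intervals taken with the (B+1)p order-statistic convention (quantile
type 6), which behaves better in the tails at moderate B than the
default interpolation. These are frequentist intervals standing in for
the Bayesian credible intervals a full MCMC treatment would give; at
these data sizes the two agree closely in width, but the package does
not claim numerical identity.

## Synonymous and nonsynonymous rates

`kaks_pair()` implements Nei–Gojobori (1986) counting: per codon, the
synonymous site fraction at each position is the fraction of non-stop
single-nucleotide changes that preserve the amino acid; differences
between codons are averaged over all minimal mutational pathways with
equal weight, pathways through stop codons excluded (a codon pair whose
every pathway crosses a stop is skipped and logged). Site totals average
the two sequences. Proportions below 3/4 get the Jukes–Cantor-style
correction −(3/4)·log(1 − 4p/3); at the k~s~ ≤ 0.12 scale this package
targets the correction is a few percent at most. The entire counting
surface is validated against an independent brute-force enumerator over
all 61 × 61 sense-codon pairs in the test suite.

## Classification against cladogenic calibrations

The inference core is a ratio comparison. The bundled calibration table
(`wolbachia_calibrations()`) collects published host and *Wolbachia*
k~s~/k~a~ values for one *Nasonia* wasp pair and six *Nomada* bee pairs
with evidence of codivergence (ratios 0.015–0.30), plus the focal
*Drosophila* pair itself (ratio 0.00025), flagged non-cladogenic.
`classify_transmission()` calls a system **cladogenic-plausible** when
the observed symbiont/host k~s~ ratio falls within a factor T~1~ = 2 of
the calibration *range* [min, max]. The factor two reflects how far
host-genome and cytoplasmic divergence times can plausibly disagree
under codivergence; the range (rather than, say, a single scaled median)
is used because the calibrations themselves span a 20-fold spread, and a
system matching any one of them cannot be said to reject codivergence.
Cladogenic transmission is **rejected** when the observed ratio is more
than T~2~ = 10 below the smallest calibration — deliberately
conservative; the focal system sits ≥ 60-fold below and rejects under
any T~2~ ≤ 60. After rejection, a mitochondrial divergence (rescaled to
the nuclear silent scale) splits introgression from horizontal transfer;
without one the call honestly degrades to `noncladogenic_transfer`
rather than guessing. Ratios in between give `indeterminate`. Every rule
is scale invariant.

## Calendar time

Published substitution-rate calibrations mix two conventions, and the
same divergence gives answers differing by a factor of ~2·g depending on
which is meant. `calibrate_time()` therefore takes the convention as an
explicit argument: `per_lineage` (t = d / (2·r·g), for rates quoted per
site per lineage per generation, g generations per year) and
`pairwise_divergence` (t = d / r, for rates quoted as pairwise
divergence per year). Both conventions are regression-tested against
their published anchor values (6,400 years for the symbiont pair under
the per-year *Nasonia*-derived rate; 1,600 years at the fast end of the
per-generation *Drosophila*-derived interval with g = 10). Interval
endpoints evaluate the rate interval's endpoints — the slow rate bounds
the age from above. Note the upper bound computed from the slow rate,
4 × 10^-5^ / (2 × 2.88 × 10^-10^ × 10) = 6,944, rounds to 6,900 at two
significant figures. A prominent caveat: temperate hosts may see half
the assumed 10 generations per year, inflating all ages by up to 2×.

## Read-depth CNV scan

`normalize_depth()` tiles the genome in non-overlapping 1-kb windows
(the profile convention; the step size of the original sliding windows
is not recoverable, and tiling is the conservative choice) and divides
each window mean by the genome-wide mean, making profiles invariant to
overall coverage. `call_cnv()` re-tiles at 500 bp, forms the
sample/control normalized ratio per window, and estimates the copy
number as `round(ploidy × ratio)` where ploidy is the window's copy
count *in the reference* (2 inside annotated segmental duplications such
as prophage repeats, 1 elsewhere) — so a duplication inside a collapsed
two-copy repeat is correctly called 2 → 3. Runs of at least K = 4
consecutive windows (2 kb) with the same non-reference copy estimate
merge into one call: the smallest biologically meaningful variant in the
motivating data is 2.5 kb, and K = 4 suppresses single-window Poisson
noise (the no-variant false-call rate at p < 10^-4^ is below 0.1 calls
per genome in null simulations). Each call's significance is a
two-sample Kolmogorov–Smirnov test of its windows' ratios against the
genome-wide background outside all calls; single-window calls are
reported with an undefined p-value rather than a fabricated one.
Segmentation by run-merging is not identical to HMM/LASSO segmentation
used by dedicated CNV tools, so published boundary coordinates are
pattern targets (sizes and copy changes), not bit-exact ones.

## What the generator simulates — and what it does not

`simulate_codon_alignment()` evolves codons site-independently along a
time-scaled tree as an event-based chain: proposals arrive at position
*p* at rate r~p~ per unit time and move to one of the other three bases
uniformly (κ = 1, uniform frequencies — chosen so the analytic
expectation 2·r~p~·t·L~p~ for pairwise differences holds exactly and the
ka/ks mechanics stay verifiable); proposals creating stops are rejected;
nonsynonymous proposals are accepted with probability ω. This
rejection-tuning reproduces a target k~a~/k~s~ without a full codon rate
matrix — sufficient at these divergences, and simple enough to verify
against the package's own NG86 estimator (recovery within 15% at 10^5^
codons is asserted in the tests). The chronogram's bootstrap instead
uses the exact-HKY nucleotide sampler so that resimulation matches the
fitted model.

`simulate_scenario()` wires three tracks to one host topology. Defaults
are the study conditions of the motivating system: host nuclear
pairwise divergences (1.10 × 10^-2^, 4.73 × 10^-3^, 9.20 × 10^-2^) per
codon position (k~s~ ≈ 0.12) over 18 nuclear genes of 500 codons; a
symbiont track of 703 genes totalling 704,883 bp with equal rates at all
three positions (ω = 1 — the empirical signature of very recently
diverged *Wolbachia*); symbiont clock set by a cladogenic calibration
ratio (default 0.13, the calibration median); transfers at 0.005 of the
host divergence time, reproducing the observed order-of-magnitude
discordance; and a single 15-kb non-recombining mitochondrial locus at
5× the nuclear silent rate (a typical insect mtDNA/nuclear ratio — the
truth table records the ratio so analyses can rescale). The fixtures
behind the chronogram studies are `wri_like_preset()` (3 symbiont taxa,
true root/reference ratio 3.51; when scaled below 704,883 bp the rates
scale up in proportion so the expected variant counts, ~28 within the
sister pair and ~100 to the outgroup, are preserved — at the natural
per-site rates a 48-kb alignment would carry ~2 variants and estimate
nothing) and `host_like_preset()` (5 taxa, true relative ages 1.96 and
0.72, root at 2.5 — a value interior to the plausible range, as only the
two benchmark ratios are constrained).

What the generator does **not** emulate: recombination (none detectable
in the motivating data), rate variation across sites within a partition,
context-dependent mutation, gene gain/loss, GC-biased composition, or
read-level artifacts (depth is Poisson per base; no GC or mappability
structure). Passing tests therefore demonstrate estimator correctness
under the stated model, not robustness to every feature of real data.

## Problem sizes and numerical choices

The simulation studies in the test suite use: 50 replicates × 50
bootstrap refits for each chronogram fixture (48 kb symbiont-like; 27 kb
host-like), 50 seeds for CNV recovery at 30× over a 1.45-Mb genome, and
200 replicates for Jeffreys coverage at d = 4 × 10^-5^, L = 7 × 10^5^ —
sizes chosen to hold Monte-Carlo error on a coverage proportion near
±4% while keeping the full suite runnable on a laptop core. Optimizer
tolerances: reltol 10^-9^ for initial fits (iteration cap 4000), 10^-8^
warm-started for bootstrap refits; rate floors 10^-10^, a kappa cap of
10^3^ and an age cap of 10^4^ guard against flat-likelihood drift on
degenerate data. Ties in CNV ratio values make the KS test's exact
p-value unavailable; the asymptotic value is used, which is accurate at
the window counts involved.

## Known limitations

* The chronogram assumes a strict clock per partition; lineage-specific
  rate variation biases relative ages with no internal diagnostic.
* Bootstrap percentile intervals can undercover slightly at small
  numbers of variants; the coverage study quantifies this under the
  fixture conditions only.
* NG86 ignores transition/transversion bias in site counting; with the
  simulator's κ = 1 this is exact, but on strongly ts-biased real data
  k~s~ is mildly overestimated.
* Classification inherits the calibration table's uncertainty; with only
  seven cladogenic calibrations spanning 20-fold, the
  `cladogenic_plausible` band is wide by construction.
* The CNV caller has no GC correction or mappability track and assumes a
  shared window grid between sample and control.

## A worked end-to-end run

```{r scenario, eval = FALSE}
scn <- simulate_scenario(scenario_config("introgression", seed = 1))
call <- analyze_scenario(scn)
call
#> <transmission_call> introgression
```

The acceptance script (`scripts/acceptance.R`) reruns the pipeline's
headline numbers from scratch; see the README for how to invoke it.
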