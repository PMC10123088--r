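---
title: "Probing DNA structure with non-denaturing bisulfite reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing DNA structure with non-denaturing bisulfite reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisreact)
```

## The measurement and its model

Bisulfite converts unmethylated cytosine to uracil, but in double-stranded
DNA the reaction requires the base to be accessible: locally unpaired,
flipped, or bent so that the anion can attack. Treating native (protein-free,
non-denatured) genomic DNA and sequencing deeply therefore turns the
C→T conversion fraction at each cytosine into a *structural* readout.
`bisreact` works from per-base pileup counts: at a reference C the
converted count is the T reads; at a reference G the complementary strand
carries the cytosine, so G→A reads are folded onto the C strand (contexts
reverse-complemented, 5′/3′ mirrored). Only the Watson–Crick complement
transition is treated as bisulfite-attributable; every other non-reference
read counts toward a per-site error rate that doubles as a sequencing/PCR
QC statistic.

Site-level filters follow the measurement design: read depth ≥ 500,
mean mapping quality ≥ 20, and exclusion of sites converted in more than
40% of reads, which at high depth is the signature of a heterozygous
C/T (or G/A) SNV rather than of conversion. The heterozygosity ceiling is
applied to all analyses by default (uniform treatment; it can be disabled
with `het_max_reactivity = Inf`).

## The polar gradient

The central quantity is the behaviour of maximal poly-dC:dG runs
("poly-C", defined on the strand carrying the Cs). Reactivity rises from
the 3′-terminal C toward the 5′-terminal C. The package summarises each
run-length class by its positional means and models the gradient
*geometrically*:

$$p(d) = p_0 \, g^{\,d},$$

where $d$ is the distance in bases from the run's 3′ end and $g$ the
per-step factor. The functional form of the real gradient is not known;
the geometric model is the simplest monotone choice with a single
recoverable parameter, and the estimator (weighted least squares on log
positional means, with run-length class as a covariate when pooling) is
exact when the model holds and a well-defined "average fold change per
step" when it does not. The 5′:3′ terminal ratio and the prevalence
(fraction of runs whose 5′-terminal reactivity strictly exceeds the
3′-terminal one; ties count as absent) are reported alongside.

CpG cytosines are mostly methylated in mammalian DNA and hence nearly
unreactive regardless of structure, so they are handled explicitly:
`gradient_profile()` defaults to restricting classes to D(C)nW runs
(3′ flank A or T, written `exclude-runs-with-3pG`), with
`exclude-CpG-sites` (drop only the 3′-terminal value of G-flanked runs)
and `include` as alternatives. `classify_cpg()` labels CpG sites below
0.4% reactivity as methylation-consistent ("CpG-low").

## Context effects and the quasibinomial model

Flanking-base effects are computed at isolated cytosines (DCD) for offsets
±1..±3. Because flanking bases are correlated with each other, the
significance test pairs sites by the *full remaining context*: for a given
offset and base, every stratum of the other context positions that
contains both target-flank and other-flank sites contributes one paired
difference of stratum means, and the differences go into a Wilcoxon
signed-rank test. This pairing is a design choice of this package (other
pairings are defensible); it is stated here and in the output metadata so
results are interpretable.

A-tracts — four or more consecutive A:T pairs with no TA step — rigidify
DNA and direct bending toward the minor groove at their junctions, the
opposite of the major-groove bending that favours bisulfite attack. Their
influence is modelled jointly with composition by a quasibinomial GLM of
converted counts out of depth (logit link, free dispersion) on: touching
5′ and 3′ A-tract indicators, local AT content (±20 bp window by default;
the window is a package choice, configurable), a 5′-T flank indicator and
a 5′-TA dinucleotide indicator. "Touching" means a zero-base gap between
tract and run terminus (`max_gap = 0`, configurable) — the adjacency
distance is another quantity the measurement itself does not pin down.
The IRLS fitter converges on relative deviance change < 1e-8 (cap 100
iterations), estimates dispersion as Pearson $\chi^2 /$ df, scales
standard errors by its square root and uses t-based p-values, matching
standard quasibinomial practice. Overdispersion (e.g. from site-to-site
heterogeneity) is thus absorbed into the inference rather than ignored.
Predictors that never vary in the data are dropped with a warning;
rank deficiency among varying predictors is an error naming the aliased
column.

## Nucleosome positioning and roll

Nucleosome-bound DNA alternates, with the ~10 bp helical period, between
bending toward the major groove (positive roll) and the minor groove
(negative roll). The package takes a dyad-relative roll profile of 146 or
147 values (for 146 the dyad sits between offsets −1 and +1; both
dialects load), derives positive-roll windows from the sign of the roll
after a 3-offset majority filter (the smoothing rule is a package choice —
the underlying crystal-structure profile has single-offset sign flips that
are not meaningful bands), and maps poly-C run ends to dyad offsets with
strand reflection so 5′ ends are comparable across strands. Enrichment of
ends in positive-roll windows is tested against the expectation
proportional to window width (chi-square), and per-offset end density is
regressed on roll. A run end inside several overlapping dyad footprints
contributes one incidence per dyad.

## Cyclizability and mutation rates

Loop-seq-style cyclizability tables carry three replicate scores per
50-mer; their arithmetic mean is the response. The package regresses it,
one predictor at a time (ordinary least squares, Pearson r), on windowed
model reactivity (a 4-mer lookup fitted from site data, unseen 4-mers
imputed by the global mean), G/C content, A-tract count and all sixteen
dinucleotide counts, and compares poly-C(≥4) content between the
most- and least-bendable halves (ties broken by sequence lexical order).
A replicate-noise report — the fraction of records whose replicate SD
exceeds the magnitude of their mean — quantifies how noisy such scores
are per sequence.

De novo mutation rates are per-site probabilities: hits (strand-folded
mutations; G→A counts as C→T) divided by genomic opportunities, stratified
by run-length bin (2–3, 4–6), 5′ flank (A/G/T), end (5′/3′) and class
(C→T, C→A, C→G). Every cytosine whose folded 3′ neighbour is G is removed
from numerator and denominator — CpG hypermutability is methylation-driven
and would otherwise swamp the structural signal at 3′ ends. The 5′:3′
ratio is reported per stratum, pooled per class, and pooled overall (both
the pooled-count ratio and the mean of per-stratum ratios, since the two
"average" readings differ). Roll-sign stratification assigns each
opportunity and hit per covering dyad, with Bonferroni-adjusted
homogeneity tests across strata.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted,
recoverable structure (`generate_genome`, `simulate_pileups`,
`simulate_dyads`, `simulate_mutations`, `simulate_cyclizability`). The
generative reactivity model is exactly the analysis model: $p = p_0 g^d$
times multiplicative flank modifiers (acting only at offsets outside the
run), times A-tract factors for touching tracts, with CpG sites drawn
methylated at a configurable fraction and set to a residual reactivity.
Converted counts are binomial in depth; off-target errors are binomial,
strand-symmetric and context-free, split uniformly over the available
bases. Dyads are anchored to planted run 5′ ends with the odds of
positive-roll offsets multiplied by a configurable factor. Mutations
arise per folded cytosine from centered IUPAC context patterns
(first match wins within a class).

Defaults describe the conditions the pipeline is designed for: isolated-C
reactivity ~2%, per-step gradient 1.5, 5′-G enhancement (×1.5) and 5′-T
suppression (×0.5), 3′-G suppression (×0.7), 42% suppression by touching
5′ A-tracts and 25% for 3′ tracts, 75% CpG methylation, 0.3% error, read
depth 6900 (deep-amplicon scale). Mutation rates are deliberately scaled
up from genome-scale values (~10⁻³–10⁻² per site) so that megabase-scale
synthetic genomes yield countable events; only rate *ratios* carry the
scientific content. The generator emulates site-level statistical
structure, not reads: there is no PCR amplification bias, no alignment
error, no R-loop/quadruplex structure, and flank effects are independent
and multiplicative by construction. Passing recovery tests therefore
demonstrates that the estimators are correct and calibrated, not that
real chromatin obeys the generative model.

All generators are pure functions of the configuration seed, with one RNG
stream per stage (seed + fixed offset), so any stage can be regenerated
independently and pipelines are byte-reproducible.

## Numerical and edge-case choices

- Coordinates are 1-based inclusive internally; BED converts at the I/O
  boundary. N bases are allowed in references; windows containing N are
  skipped, not errored.
- QC rules are strict-inequality readings of their thresholds: trimming
  keeps the first base with quality ≥ 32 from each end; reads of exactly
  500 bp or minimum quality exactly 22 pass.
- On the '-' strand, C reads (possible reverse-strand conversion
  bleed-through) are counted as errors, not conversions.
- Gradient prevalence counts ties as gradient-absent; enrichment ties in
  cyclizability ranking break lexically so results are deterministic.
- Welch's t-test is the default two-sample test; chi-square tests carry no
  continuity correction; the signed-rank test drops zero differences and
  switches to the normal approximation above n = 25 or under ties.
- Degenerate statistical inputs (constant samples, zero-variance
  predictors, empty strata) return flagged results or omit the stratum
  with a warning; they do not raise.

## Problem sizes used by the test suite

The suite validates parameter recovery at sizes chosen to give
comfortable statistical margins on a single CPU: 300 runs per length
class at depth 500 for gradient recovery (per-step ratio within ±10%);
10⁴ random 200-mers for detector/oracle equivalence; 10⁴ dyad placements
for enrichment-odds recovery within ±25%; ~3000 simulated mutations for
the 1.28× polarity ratio (recovered within the [1.14, 1.42] band); 2000
replicates for 5%-level calibration of each test; ~2000
A-tract-informative sites for GLM recovery of a 0.6 suppression factor
within ±30%.

## Known limitations

- The geometric gradient is a stand-in for an unknown functional form;
  the per-step ratio should be read as an average fold change.
- The Wilcoxon pairing for flank effects, the AT-content window, the
  A-tract adjacency distance and the roll-sign smoothing are package
  choices where the measurement leaves the design open; all are
  configurable and recorded in outputs.
- The per-50-mer reactivity model is a 4-mer lookup fitted from site
  data; with sparse site tables many 4-mers fall back to the global mean.
- The pipeline consumes pileup TSVs; producing them from BAM is left to
  standard counting tools.
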