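# bisreact

Non-denaturing bisulfite reactivity as a probe of DNA structure.

When double-stranded genomic DNA is treated with bisulfite *without*
denaturation, only cytosines that are structurally accessible — locally
melted, bent toward the major groove, or otherwise perturbed — convert to
uracil and read out as C→T after PCR and sequencing. The per-site
conversion fraction ("reactivity") is therefore a structural signal, not a
methylation signal. `bisreact` implements the full analysis around this
idea:

- **Strand-folded conversion scoring.** Pileup counts at reference C
  (C→T) and G (G→A, interpreted as C→T on the complementary strand) are
  folded onto one C-strand statistic, with depth ≥ 500, mapping quality
  ≥ 20 and a 40% heterozygosity ceiling as site filters.
- **The polar gradient.** Within a maximal poly-dC:dG run of length *n*,
  reactivity increases from the 3′-terminal C toward the 5′-terminal C.
  The package models the positional means as `p(d) = p0 · g^d`, where `d`
  is the distance from the 3′ end, and estimates the per-step factor `g`
  by weighted log-linear regression, along with the 5′:3′ terminal ratio
  and the per-class prevalence of the gradient.
- **Context effects.** Flanking-base means at isolated C (DCD) with
  paired Wilcoxon signed-rank tests; CpG classification (< 0.4%
  reactivity = methylation-consistent); A-tract detection (≥ 4 A:T pairs,
  no TA step) and a quasibinomial GLM of conversion counts on A-tract
  adjacency, local AT content, 5′-T and 5′-TA indicators.
- **Nucleosome positioning.** Poly-C run 5′/3′ ends are mapped to
  dyad-relative offsets (strand-reflected) and tested for enrichment in
  positive-roll (major-groove-bending) windows of a 146/147 bp roll
  profile, plus 7 bp sliding-window reactivity vs roll.
- **Cyclizability.** Per-50-mer regressions of loop-seq-style bendability
  (mean of three replicates) on windowed reactivity, G/C content, A-tract
  and dinucleotide counts; poly-C enrichment in the most-bendable half.
- **Mutation rates.** CpG-excluded de novo mutation rates at poly-C run
  ends, stratified by run length, 5′ flank, mutation class and nucleosome
  roll sign; rate = hits / genomic opportunities.
- **Synthetic data.** A generator that plants all of the above with
  recoverable parameters (gradient factor, flank modifiers, A-tract
  suppression, dyad enrichment odds, per-motif mutation rates), used by
  the test suite for end-to-end parameter-recovery checks.

## Worked example

Simulate a genome with planted structure and run every stage:

```r
library(bisreact)
cfg <- sim_config(genome_length = 30000L, depth = 500L,
                  polyc_spec = c(`2` = 150, `3` = 150, `4` = 150, `5` = 100),
                  atract_spec = c(`5` = 30), dyad_count = 2000L,
                  cyc_n = 2000L, seed = 42L)
res <- run_all(cfg, "demo")

res$gradient$ratios
#>   n ratio53 step_ratio n_runs
#>   1   1.000         NA   5334
#>   2   1.475      1.475   1193
#>   3   2.268      1.506    373
#>   4   3.552      1.528    184
#>   5   4.803      1.481    112
res$gradient$pooled_step_ratio
#> 1.498
```

The per-step ratio recovers the planted gradient factor (1.5): each step
toward the 5′ end of a run multiplies reactivity by ~1.5, and the 5′:3′
terminal ratio grows accordingly with run length. Other stages in the same
run recover the planted A-tract suppression from the quasibinomial GLM
(`res$atract_glm`), the off-target error level
(`res$error_summary$overall_mean` ≈ 0.003, i.e. 0.3% of reads), and the
dyad-relative asymmetry of run ends:

```r
res$end_enrichment$stats[, c("end", "frac_positive", "expected_frac", "chisq_p")]
#>   end frac_positive expected_frac   chisq_p
#>    5p         0.530         0.510   6.3e-10
#>    3p         0.507         0.510   2.7e-01
```

5′ ends sit in positive-roll windows more often than window width alone
predicts; 3′ ends do not — the planted signature of major-groove bending
at the 5′ ends of poly-C.

Every artifact (site table, gradient profile, flanking effects, GLM
coefficients, end-position table, cyclizability regressions, mutation-rate
table) is also written to the output directory as a commented TSV.

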