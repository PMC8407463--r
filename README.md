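# promarch — promoter architecture from bacterial TSS maps

`promarch` dissects sigma-70 promoter architecture from genome-scale
transcription start site (TSS) maps. Given a genome FASTA and a table of
experimentally mapped TSSs, it:

1. extracts strand-aware upstream windows on the no-zero TSS-relative
   axis (+1 = the TSS base, −1 = the base immediately upstream, no 0);
2. discovers the −10 promoter element with **two independent
   algorithms** — a ZOOPS (zero-or-one-occurrence-per-sequence)
   expectation-maximization mixture model, and a coordinate-ascent
   aligner that maximizes corrected information content
   `Rsequence = Σ_j [2 − H_j − e(n)]` with Schneider's small-sample
   correction `e(n) = 3/(2·ln 2·n)` bits;
3. registers each predicted −10 element on its conserved **TA
   dinucleotide** (nominally −12/−11) and reads the base at position −7
   (anchor + 5) to classify promoters −7T vs −7A/C/G;
4. searches −40..−28 for a −35 element (conditioned on a found −10) and
   computes spacer and discriminator lengths — the canonical promoter
   (−35 at −35..−30, −10 at −12..−7) has a 17 bp spacer and a 6 bp
   discriminator;
5. measures cross-method agreement (fraction of shared TSSs with equal
   TA anchors) and tests the −7 gene classes for essentiality
   (hypergeometric, BH-adjusted P ≤ 0.05) and functional-term
   enrichment (adjusted P ≤ 0.1), plus expression-trend comparison
   against size-matched randomized gene sets.

A synthetic-data generator (`simulate_promoter_dataset()`) plants known
−10/−35 elements, −7 compositions, spacer/discriminator distributions,
essentiality associations and expression trends, so the whole pipeline
is testable offline with ground truth. The methods vignette
(`vignettes/promoter-architecture.Rmd`) documents the models, defaults,
and design decisions.

## Worked example

```r
library(promarch)

ds  <- simulate_promoter_dataset(sim_config(n_tss = 500L, seed = 7L))
rep <- run_pipeline(ds$genome, ds$tss, run_config(),
                    terms = ds$terms, essential = ds$essential)
print(rep)
#> promarch pipeline report: 500 TSSs in
#>   [zoops] 447 calls; drops: no_occurrence=53; record conservation: TRUE
#>   [info] 500 calls; drops: none; record conservation: TRUE
#>   cross-method TA-anchor agreement: 0.890

print(rep$methods$zoops$model)
#> motif_model: width 10 | lambda 0.888 | sites 447 / 500 | objective 1661.43
#> consensus: TCGTATAAGG

print(rep$methods$zoops$summary)
#> architecture_summary over 447 promoter calls
#>   -7 base fractions: A=0.251 C=0.235 G=0.268 T=0.246
#>   spacer mode: 17 bp | discriminator mode: 6 bp

rep$enrichment$essentiality[, c("class_label", "term_id", "k", "K",
                                "p_adj", "significant")]
#>   class_label   term_id   k   K       p_adj significant
#> 1     -7A/C/G essential 110 132 0.003547407        TRUE
#> 2         -7T essential  22 132 0.998365867       FALSE
```

Reading this: the ZOOPS finder recovered the planted TATAAT-class motif
(`lambda` ≈ 0.89 matches the 0.9 planting probability; the 53 windows
without an occurrence are counted, so records are conserved), both
finders anchor the same TA position for 89% of shared TSSs, the modal
spacer (17 bp) and discriminator (6 bp) match the planted distributions,
the −7 base fractions recover the uniform planted composition, and the
planted odds-ratio-3 association between the −7A/C/G class and
essentiality is detected (adjusted P = 0.0035) while the −7T class shows
none — the structure reported for Alphaproteobacteria promoter sets.

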