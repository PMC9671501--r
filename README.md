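# nectarpe

Priority effects and alternative stable states in nectar microbial
communities: an analysis pipeline for ecologists and evolutionary
biologists studying how arrival order decides whether floral nectar ends up
bacteria-dominated or yeast-dominated, and how yeast populations adapt to
bacteria-conditioned environments.

The package implements four connected analysis stages, each with a seeded
synthetic-data generator that emulates its input at configurable scale
(with a truth log for recovery testing):

1. **Community dominance states** — flowers are classified from bacterial
   and yeast CFU counts with a CLAM-style multinomial rule: with
   supermajority threshold *K* = 2/3, a flower is bacteria-dominated when
   the one-sided exact binomial test rejects H₀: π_B ≤ *K* at α = 0.005
   (yeast symmetrically), co-dominated when both shares test significantly
   above 1 − *K*, and otherwise too rare to classify. Observed co-dominance
   is compared per site with the independence expectation
   P̂(bacteria-capable)·P̂(yeast-capable) by a paired t-test — a deficit
   indicates mutual exclusion, the fingerprint of priority effects.
2. **Nectar pH multimodality** — Hartigan's dip statistic (computed exactly
   via the greatest-convex-minorant / least-concave-majorant
   characterization, C++ kernel) with a Monte-Carlo uniform null, and
   best-of-restarts EM fits of k-component Gaussian mixtures compared by
   likelihood-ratio test (df = 3) and AIC = 2·params − 2·logL. Component
   means are reported as the pH modes (unmodified ≈ 7.8, yeast-conditioned
   ≈ 5.5, bacteria-conditioned ≈ 2.6).
3. **Priority-effect strength** — from factorial arrival-order microcosms
   (treatments BY, YB, −Y, Y−, B−, −B; first symbol arrives early):
   PE1 = log₁₀(B̄Y̅/−̄Y̅) − log₁₀(Y̅B̅/Y̅−̅) and PE2 = log₁₀(B̄Y̅/Y̅B̅), on
   round-averaged pseudocounted counts; more negative = stronger bacterial
   suppression of yeast.
4. **Evolve-and-resequence genomics** — downstream of variant calling:
   loss-of-heterozygosity calls (evolved homozygosity at ancestral-het
   sites) and sharing summaries, per-site permutation tests on
   continuity-corrected allele-count odds ratios between treatments,
   Weir–Cockerham F_ST (per-site components and genome-wide ratio of
   sums), candidate-site selection (p < 0.1, F_ST ∈ [0.3, 0.5]), singleton
   de novo mutation calling with a mappability-1 filter, 50-kb windowed
   counts, and nearest-gene annotation within 5 kb. I/O: VCF v4.2 (GT),
   sample-metadata CSV, bedGraph mappability, GFF3 genes.

## Worked example

```r
library(nectarpe)

# a 12-site x 96-flower survey with strong (but not total) mutual exclusion
sv <- gen_flower_survey(survey_sim_config(seed = 20150601))
cl <- classify_survey(sv$records)
table(cl$state)
#> bacteria_dominated    yeast_dominated       co_dominated           too_rare
#>                417                302                 25                408

ct <- codominance_test(summarize_sites(cl))
round(c(mean_diff_pp = ct$mean_diff_pp, ct$ci, p = ct$p), 4)
#> mean_diff_pp                            p
#>      -8.6011      -9.5988  -7.6033      0  (p = 1.0e-09)
```

Co-dominated flowers are 8.6 percentage points rarer than independent
colonization would predict — the planted mutual exclusion, recovered.

```r
# tri-modal nectar pH: dip test and mixture selection
ph <- gen_ph_samples(ph_sim_config(seed = 20220601))
dip_test(ph$ph, n_boot = 2000, seed = 20220602)[c("D", "p")]
#> $D [1] 0.0675196   $p [1] 0.0004997501

f2 <- fit_mixture(ph$ph, 2, seed = 1); f3 <- fit_mixture(ph$ph, 3, seed = 1)
compare_mixtures(f2, f3)[c("aic_small", "aic_big", "p_lrt")]
#> $aic_small [1] 2154.3   $aic_big [1] 1850.1   $p_lrt [1] 5.99e-67
mixture_modes(f3)
#> [1] 7.79 5.51 2.67
```

The distribution is non-unimodal (D = 0.068, Monte-Carlo p ≈ 5e-4), three
modes beat two by both LRT and AIC, and the fitted modes land on the
planted 7.8 / 5.5 / 2.6.

The numbered scripts under `analysis/` run all four stages end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_field_survey.R
Rscript analysis/02_nectar_ph.R
Rscript analysis/03_priority_effects.R
Rscript analysis/04_evo_genomics.R
```

For instance, `04_evo_genomics.R` simulates a full-scale (19.2 Mb) set of
evolved genomes, then reports the ancestor heterozygous at 26,496 sites
(0.138% of the genome), ~1,720 LOH events (mean ≈ 143 per lineage, 97.3%
of LOH sites shared by all 12 lineages), a handful of treatment-specific
divergent sites at F_ST 0.3–0.5 with permutation p < 0.1, and ~230 raw
singleton de novo mutations reduced to ~137 (≈ 11 per lineage) by the
mappability-1 filter — the structure the generator planted.

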