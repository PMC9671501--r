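---
title: "Methods: dominance states, pH mixtures, priority effects, and evolve-and-resequence genomics"
author: "nectarpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance states, pH mixtures, priority effects, and evolve-and-resequence genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nectarpe)
```

`nectarpe` implements the statistical core of an eco-evolutionary analysis
of nectar microbial communities: bacteria (e.g. *Acinetobacter*,
*Neokomagataea*) and yeasts (e.g. *Metschnikowia reukaufii*) colonize the
floral nectar of *Diplacus aurantiacus*, and early arrivers can suppress
late arrivers — a priority effect, mediated largely by bacterial
acidification of nectar. The package provides four analysis stages plus
seeded synthetic-data generators that emulate each stage's inputs, and the
`analysis/` scripts in the source repository run the stages end to end.

## 1. Dominance states of flower communities

Each flower yields two counts: bacterial and yeast CFU, cultured on
different media with different dilution series. `normalize_effort()`
rescales the counts by the per-group sampling effort (dilution x plated
volume) and rounds half-up, so the exact binomial machinery below operates
on integers.

Classification follows the CLAM (classification method) scheme with two
"habitats" collapsed to two microbial groups. With supermajority threshold
$K$ (default $2/3$) and significance level $\alpha$ (default 0.005):

* **bacteria-dominated** — the one-sided exact binomial test rejects
  $H_0\!: \pi_B \le K$, i.e. $P(X \ge b \mid n = b+y, K) \le \alpha$;
* **yeast-dominated** — symmetrically for the yeast share;
* **co-dominated** — CLAM's generalist class: *both* shares test
  significantly above the complementary threshold $1-K$, and the
  effort-scaled total reaches `coverage_limit` (default 10);
* **too rare** — everything else.

A design note on the co-dominated class: an alternative reading —
"co-dominated whenever neither dominance test rejects and the total is
large enough" — misfires on flowers carrying a modest count of one group
alone (e.g. $b = 12, y = 0$ cannot reject $\pi_B \le 2/3$ at
$\alpha = 0.005$ and would become "co-dominated"). Requiring both groups to
sit significantly above $1-K$ matches the published CLAM rule for
generalists and guarantees that surveys generated under complete mutual
exclusion contain no co-dominated calls. For $K > 0.5$ the two dominance
rejections are mutually exclusive, so the four states partition every
input.

The source study does not state the CLAM parameters it used; $K = 2/3$ is
CLAM's standard supermajority rule, $\alpha = 0.005$ its conventional
stringent level, and both are configurable via `clam_config()`.

**Co-dominance against an independence null.** Per site,
`expected_codominance()` computes
$\hat P(\text{bacteria-capable}) \cdot \hat P(\text{yeast-capable})$, where
each marginal counts the group-dominated plus co-dominated flowers — a
co-dominated flower evidences dominance-capable abundance of both groups.
`codominance_test()` then applies a paired (one-sample) t-test to the
per-site differences observed − expected, in percentage points. Zero
variance of the differences is flagged as degenerate, with the limiting
p-value (1 when the common difference is 0, else 0).

## 2. Nectar pH: multimodality and mixture models

Field nectar pH is expected to be a mixture of unmodified (~7.8),
yeast-conditioned (~5.5) and bacteria-conditioned (~2.6) nectar.

**Dip statistic.** `dip_statistic()` computes the maximum distance between
the empirical CDF and the closest unimodal CDF. The computation uses the
greatest-convex-minorant / least-concave-majorant characterization: $D$ is
the smallest band half-width $t$ such that a nondecreasing
convex-then-concave distribution function fits inside the $\pm t$ band
around the empirical CDF, minimized over mode placements (the fitted CDF
may jump upward at the mode). The minimal $t$ is found by bisection (48
halvings of $[0, 0.5]$, i.e. resolved far below any statistical
resolution) with an exact feasibility test per candidate: prefix
feasibility from the incremental convex hull of the band's upper envelope,
a slope-"momentum" bound that convexity propagates across knots, and the
mirror-image test for the concave side. $D$ always lies in
$[1/(2n), 1/4]$; a constant sample returns the lower bound by convention.
The kernel is C++ (via Rcpp), as dip implementations conventionally are.
The test suite checks it against an independent brute-force oracle that
minimizes over unimodal CDFs by linear programming at small $n$, and
against closed-form cases (two equal atoms give exactly $1/4$; $n$ equally
spaced points give exactly $1/(2n)$).

**Dip test.** `dip_test()` simulates the null from uniform(0, 1) samples of
the same $n$ (Hartigan's recommendation) rather than interpolation tables,
with the add-one Monte-Carlo estimator $p = (1 + \#\{D^\ast \ge D\})/(B+1)$;
the smallest reachable p-value is therefore $1/(B+1)$, not the analytic
near-zero value a table-based test can print.

**Mixture fits.** `fit_mixture()` is a best-of-restarts EM for a univariate
$k$-component Gaussian mixture. Initialization: means at evenly spaced
sample quantiles, equal weights, pooled (maximum-likelihood) variance;
restarts after the first jitter the means by $N(0, \mathrm{sd}(x)^2/4)$.
Variances are floored at `variance_floor` ($10^{-4}$ pH² by default) at
every M step, preventing the classical collapse of a component onto a
single observation; convergence is declared when the log-likelihood
increment falls below `tol` ($10^{-8}$). The log-likelihood trace of the
winning run is retained so monotonicity can be asserted.
`compare_mixtures()` reports the likelihood-ratio statistic with 3 degrees
of freedom (one extra weight, mean, and variance) against a plain
chi-square upper tail — the convention in this literature, knowingly
ignoring the boundary non-regularity of mixture LRTs (the true null
distribution is not exactly $\chi^2_3$; with effect sizes this large the
distinction is immaterial, but borderline LRT p-values should not be
over-read) — plus $\mathrm{AIC} = 2\,\text{params} - 2\log L$ with
$3k - 1$ parameters.

**Modes.** `mixture_modes()` reports component means, sorted descending, as
the distribution's modes. For well-separated components the mixture
density's local maxima coincide with component centers; an exact
density-mode search is deliberately out of scope. Equal means are reported
with a collision flag, and unconverged fits propagate a warning.

## 3. Priority-effect strength

Final CFU counts are log10-transformed with a pseudocount of 1 CFU
(`log_count()`), which keeps zeros finite and is negligible at microcosm
densities of $10^4$–$10^6$. With treatment codes `BY`, `YB`, `-Y`, `Y-`
(first symbol = early arriver; `-` = absent; the focal organism is yeast),
the two strength metrics are

$$\mathrm{PE1} = \log_{10}\frac{\overline{BY}}{\overline{-Y}}
              - \log_{10}\frac{\overline{YB}}{\overline{Y-}}, \qquad
  \mathrm{PE2} = \log_{10}\frac{\overline{BY}}{\overline{YB}},$$

and the growth difference is $\log_{10}\overline{BY} -
\log_{10}\overline{-Y}$. More negative values mean stronger bacterial
priority effects against yeast. PE1 is read as the growth of the late
arriver relative to its matching monoculture, contrasted across the two
arrival orders; the logarithm base — often left implicit in this
literature — is taken as 10 to match the log10 transform of the counts,
and is configurable.

`summarize_pe()` averages pseudocounted counts *within* round first and
then takes logs of the ratio of means ("densities were averaged by round");
`average = "logs"` switches to geometric means. Groups missing a required
treatment get `NA` for the affected metric with a diagnostic. Useful
identities, all tested: PE1 is antisymmetric under swapping the arrival
orders, PE1 and PE2 are invariant to common rescaling of the means, and
PE1 = PE2 whenever the two monoculture means coincide.

## 4. Evolve-and-resequence genomics

The genomics stage starts downstream of variant calling: a diploid
genotype matrix (sites x samples, coded hom-ref / het / hom-alt / missing)
for one ancestor and 12 evolved lineages (3 nectar treatments x 4
replicates), read from VCF v4.2 via `read_vcf()` (vcfR underneath; phased
separators accepted, multiallelic records skipped with a diagnostic,
position sorting enforced).

* `ancestral_het_sites()` / `call_loh()`: loss of heterozygosity is an
  evolved sample homozygous (either direction) at an ancestral-het site;
  missing genotypes are missing, never LOH.
* `loh_sharing_summary()`: per-lineage counts and the shared fraction. The
  study calls 97% of LOH sites "shared across lineages and treatments"
  without an operational definition; the default threshold here is LOH in
  *all* lineages, configurable via `sharing_threshold`.
* `site_or_permutation_test()`: per site, the odds ratio of alternate to
  reference allele counts between two treatment groups (diploids contribute
  two alleles), with 0.5 added to all four cells; the p-value compares
  $|\log \mathrm{OR}|$ (two-sided — the source states neither sidedness nor
  zero-cell handling) to its distribution under label shuffles across the
  two groups' pooled samples, with the add-one estimator.
  `permutation_scan()` memoizes identical genotype patterns, which makes
  genome-wide scans cheap when most LOH is shared.
* `wc_fst()`: Weir–Cockerham (1984) two-population variance components
  $a$, $b$, $c$ per site from allele frequencies, sample sizes and observed
  heterozygosity; per-site $F_{ST} = a/(a+b+c)$ (missing when the
  denominator is 0, e.g. monomorphic sites), genome-wide by ratio of sums —
  the combination Weir and Cockerham recommend and vcftools implements.
* `candidate_sites()`: permutation $p < 0.1$ and $F_{ST} \in [0.3, 0.5]$,
  bounds inclusive.
* `call_denovo_singletons()`: homozygous ancestor, exactly one evolved
  lineage differing, all others matching; any missing evolved genotype
  disqualifies the site (conservative, favoring precision). Because de novo
  calls require a homozygous ancestor, they are disjoint from LOH calls by
  construction.
* `filter_by_mappability()` keeps calls with mappability $\ge 1$ (uniquely
  mappable k-mer regions) from a bedGraph track; uncovered positions are
  dropped and counted.
* `window_mutation_counts()` uses 1-based windows `[1, w]`, `[w+1, 2w]`, …
  of 50 kb by default; `nearest_gene()` annotates sites with the closest
  gene within 5 kb (distance 0 inside a gene, else gap to the nearer end;
  ties broken by the smaller start coordinate).

Coordinates follow each format's convention: VCF and GFF3 are 1-based
closed, BED/bedGraph 0-based half-open; round-trips are tested. Only
biallelic SNPs are processed.

## The synthetic-data generators

Every input the pipeline consumes can be generated at configured scale with
a truth log for recovery testing. The defaults are the study conditions
where the study states them, and documented choices where it does not.

**Survey** (`gen_flower_survey()`): per flower, independent Bernoulli
colonization by each group (defaults 0.45 / 0.40 — the study reports no
colonization rates; these produce the mix of dominated, co-dominated and
too-rare flowers visible in its survey figure). When both groups colonize,
the `exclusion_strength` dial (default 0.85) decides between single-group
dominance (winner by fair coin; the loser is planted at
`suppressed_fraction` = 1% of the winner's abundance, pinning its share far
below $1-K$) and genuine co-dominance (both groups at a common lognormal
magnitude, default $10^{N(4,1)}$ CFU, with small independent jitter). At
`exclusion_strength = 0` co-dominance occurs exactly when both groups
colonize, making the two capabilities independent — the regime in which the
co-dominance test's p-values must be, and are, uniform. At 1 no flower
carries both groups at dominant abundance, so zero co-dominated calls is a
construction-level guarantee. Because the strength of the planted exclusion
and the colonization rates are not study-reported quantities, the
*magnitude* of the observed−expected deficit in synthetic surveys is not
comparable to the study's printed confidence interval — only its sign and
detectability are.

**pH** (`gen_ph_samples()`): the tri-modal Gaussian mixture with means
(7.8, 5.5, 2.6). The study reports no component weights or spreads; the
defaults (weights 0.40/0.35/0.25, sds 0.4/0.5/0.4 pH units) are placeholder
choices giving clearly separated modes. Values are clipped to the
indicator-strip range [2.0, 9.0] and rounded to 0.1 pH units (strip
resolution; configurable, `round_unit = NULL` disables). Boundary values
are retained as-is; no censoring model. Because weights and spreads are
placeholders, absolute log-likelihoods and AICs of fits to synthetic pH are
not comparable to the study's printed AICs; model *ordering* (k=3 over
k=2) and mode recovery are.

**Growth** (`gen_growth_experiment()`): the six-treatment factorial with
`n_replicates` x `n_rounds` records per treatment. The planted effect
suppresses only the late arriver facing an established competitor (default
2 log10 units on `BY`, matching the order of magnitude of bacterial
suppression of yeast in the study's growth figures), so noiseless data
recover PE1 = PE2 = −2 exactly up to the pseudocount (the test oracle
value is $\log_{10}\frac{10^3+1}{10^5+1}$). Default replicate noise is
0.25 log10 units.

**Genomes** (`gen_evolution_genomes()`): ancestral heterozygosity at
0.138% of a 19.2-Mb genome (~26,500 sites, the reported heterozygosity of
the sequenced ancestral strain). LOH is planted as 142 shared sites
(all lineages, one direction per site drawn fairly) plus 4
treatment-specific sites (all four lineages of one random treatment),
giving a 97.3% shared fraction, ~143 LOH events per lineage and ~1,720
events in total at default scale. De novo singletons are planted as
heterozygous calls at ancestor-hom-ref sites, Poisson(12) per lineage in
mappability-1 regions plus low-mappability singletons at 99/245 of the raw
total — so the mappability filter removes ~40% of raw singletons, matching
the reported reduction from 245 to 146. De novo sites are planted only at
ancestor-homozygous sites, keeping them disjoint from LOH and making
recovery against the truth log unambiguous (sensitivity 1, false-call rate
0, asserted in the acceptance tests; genotypes are noise-free by design).
The mappability track is piecewise constant in {1.0, 0.5} on 10-kb tiles
(10% low by default); genes are non-overlapping intervals, ~3,000 by
default. The invariant background (default 2,000 ancestor-homozygous sites
with no variation) mimics the bulk of a joint variant-call matrix at desk
scale rather than the study's 3 million sites. Chromosome count (7) is an
arbitrary even split; nothing downstream depends on it.

What the generators deliberately do **not** emulate: read-level error or
coverage (genotypes are exact), genotype-calling noise, linkage or
recombination structure (the yeast is clonal), selection dynamics,
pollinator behavior, and site-to-site environmental covariates. Passing
recovery tests therefore demonstrates the correctness of the downstream
computations, not robustness to upstream calling error.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen so the full suite completes in
well under a minute of CPU: surveys of 12 x 96 flowers (10,000 for
Monte-Carlo checks), pH samples of 576 and 5,000, genomes of 2 Mb for
recovery tests, 100 replicates for the AIC-preference check, 150–250
replicates for calibration checks, and dip bootstrap sizes of 99–1,999
depending on the check. The acceptance script runs the genome stage at
full 19.2-Mb scale and uses 499 dip bootstrap replicates and 1,000
permutations per site. EM restarts default to 20 for user-facing fits;
the repeated-fit tests use 3–10 restarts, which suffices on well-separated
synthetic mixtures.

Other numerical conventions: effort normalization and CFU emission round
half-up (never banker's rounding) so exact tests see integers; the dip
bisection uses an absolute feasibility slack of $10^{-12}$; EM guards
density underflow at $10^{-300}$ and empty components at effective weight
$10^{-12}$; the permutation and dip Monte-Carlo p-values use add-one
estimators and are therefore never 0; all generator and test randomness is
seeded, with `derive_seed()` deriving independent 32-bit sub-seeds per
stage.

## Known limitations

* The dip test's Monte-Carlo p cannot go below $1/(B+1)$; table-based
  implementations can print far smaller values for the same data.
* The mixture LRT's $\chi^2_3$ reference is the study's convention, not a
  correct boundary-case null.
* Permutation p-values on strongly discrete genotype patterns are
  conservative (ties in $|\log \mathrm{OR}|$); the calibration tests check
  validity (super-uniformity) and agreement with exhaustive enumeration
  rather than exact uniformity.
* `summarize_pe()` recovers planted effects exactly only up to the
  pseudocount; at realistic densities the discrepancy is $<10^{-4}$ log10
  units.
* The genomics stage trusts its input genotypes; there is no re-calling,
  phasing, or indel handling, and multiallelic records are skipped rather
  than decomposed by default.
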