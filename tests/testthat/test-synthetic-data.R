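test_that("generator configs validate their inputs", {
  expect_error(survey_sim_config(p_bact_colonized = 1.2), "probability")
  expect_error(survey_sim_config(exclusion_strength = -0.1), "probability")
  expect_error(survey_sim_config(flowers_per_site = 0), ">= 1")
  expect_error(ph_sim_config(weights = c(0.5, 0.6), means = c(1, 2),
                             sds = c(1, 1)), "sum to 1")
  expect_error(ph_sim_config(weights = c(0.5, 0.5), means = c(1, 2, 3),
                             sds = c(1, 1, 1)), "same length")
  expect_error(ph_sim_config(sds = c(-1, 1, 1)), "non-negative")
  expect_error(growth_sim_config(noise_sd_log10 = -1), "number")
  expect_error(genome_sim_config(ancestral_het_fraction = 0), "strictly")
})

test_that("all generators are deterministic given the seed", {
  s1 <- gen_flower_survey(survey_sim_config(n_sites = 3, seed = 42))
  s2 <- gen_flower_survey(survey_sim_config(n_sites = 3, seed = 42))
  expect_identical(s1, s2)
  p1 <- gen_ph_samples(ph_sim_config(n = 500, seed = 42))
  expect_identical(p1$ph, gen_ph_samples(ph_sim_config(n = 500, seed = 42))$ph)
  g1 <- gen_growth_experiment(growth_sim_config(seed = 42))
  expect_identical(g1, gen_growth_experiment(growth_sim_config(seed = 42)))
  cfg <- small_genome_config(seed = 42)
  e1 <- gen_evolution_genomes(cfg)
  e2 <- gen_evolution_genomes(cfg)
  expect_identical(e1$genotypes$geno, e2$genotypes$geno)
  # byte-identical emitted VCF
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(e1$genotypes, f1); write_vcf(e2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("survey exclusion dial shapes co-dominance as specified", {
  # full exclusion: no flower carries both groups at dominant abundance
  sim1 <- gen_flower_survey(survey_sim_config(n_sites = 2,
                                              flowers_per_site = 500,
                                              p_bact_colonized = 0.5,
                                              p_yeast_colonized = 0.5,
                                              exclusion_strength = 1,
                                              seed = 8))
  cl1 <- classify_survey(sim1$records)
  expect_equal(sum(cl1$state == "co_dominated"), 0)

  # independence: observed co-dominated fraction ~ product of the marginal
  # dominance-capable fractions (binomial error at n = 10,000)
  sim0 <- gen_flower_survey(survey_sim_config(n_sites = 1,
                                              flowers_per_site = 10000,
                                              exclusion_strength = 0,
                                              seed = 9))
  ss <- summarize_sites(classify_survey(sim0$records))
  obs <- ss$observed_codominance_prop
  expected <- ss$expected_codominance_prop
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 10000))

  # monotone non-increasing in exclusion strength (fixed seed ladder)
  fracs <- vapply(c(0, 0.3, 0.6, 1), function(ex) {
    sim <- gen_flower_survey(survey_sim_config(n_sites = 1,
                                               flowers_per_site = 10000,
                                               exclusion_strength = ex,
                                               seed = 10))
    mean(classify_survey(sim$records)$state == "co_dominated")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-9))
})

test_that("pH generator honours degenerate, empty, and mixture-mean cases", {
  d <- gen_ph_samples(ph_sim_config(n = 20, weights = 1, means = 7, sds = 0,
                                    seed = 1))
  expect_equal(d$ph, rep(7, 20))
  expect_length(gen_ph_samples(ph_sim_config(n = 0, seed = 1))$ph, 0)
  cfg <- ph_sim_config(n = 5000, weights = c(.4, .35, .25),
                       means = c(7.8, 5.5, 2.6), sds = c(.4, .5, .4),
                       seed = 2)
  s <- gen_ph_samples(cfg)
  mix_mean <- sum(cfg$weights * cfg$means)
  mix_var <- sum(cfg$weights * (cfg$sds^2 + cfg$means^2)) - mix_mean^2
  expect_equal(mix_mean, 5.695)  # closed-form sum(lambda * mu)
  expect_lt(abs(mean(s$ph) - mix_mean), 3 * sqrt(mix_var / 5000))
  expect_true(all(s$ph >= 2 & s$ph <= 9))
  # truth log covers every value
  expect_length(s$truth$component, 5000)
})

test_that("growth generator emits the full factorial design", {
  gr <- gen_growth_experiment(growth_sim_config(n_replicates = 3,
                                                n_rounds = 2, seed = 1))
  expect_equal(nrow(gr), 36)
  expect_equal(sort(unique(gr$treatment)), sort(GROWTH_TREATMENTS))
  expect_equal(as.vector(table(gr$treatment)), rep(6L, 6))
})

test_that("genome generator plants recoverable structure within bounds", {
  cfg <- small_genome_config(seed = 5)
  g <- gen_evolution_genomes(cfg)
  gm <- g$genotypes

  # genotype legality; ancestor never missing
  expect_true(all(gm$geno %in% c(0L, 1L, 2L, NA)))
  expect_false(anyNA(gm$geno[, "anc"]))

  # het-site count equals the configured genome fraction
  het <- ancestral_het_sites(gm, g$meta)
  expect_equal(length(het), round(cfg$ancestral_het_fraction * cfg$genome_length))

  # truth-log completeness: every planted event appears exactly once and
  # lies inside the genome
  tl <- g$truth
  expect_false(anyDuplicated(paste(tl$planted_loh$chrom, tl$planted_loh$pos)) > 0)
  expect_false(anyDuplicated(paste(tl$planted_denovo$chrom,
                                   tl$planted_denovo$pos)) > 0)
  chr_len <- ceiling(cfg$genome_length / cfg$n_chromosomes)
  expect_true(all(tl$planted_loh$pos >= 1 & tl$planted_loh$pos <= chr_len))
  expect_true(all(tl$planted_denovo$pos >= 1 & tl$planted_denovo$pos <= chr_len))

  # planted LOH fully recovered; per-lineage mean within 10% of expectation
  loh <- call_loh(gm, g$meta, het)
  found <- loh$site_index[rowSums(loh$loh, na.rm = TRUE) > 0]
  expect_setequal(found, tl$planted_loh$site)
  s <- loh_sharing_summary(loh)
  expect_lt(abs(s$mean_per_lineage - tl$loh_per_lineage_expected),
            0.1 * tl$loh_per_lineage_expected)

  # planted de novo singletons fully recovered before the mappability filter
  dn <- call_denovo_singletons(gm, g$meta)
  expect_setequal(paste(dn$chrom, dn$pos, dn$lineage),
                  paste(tl$planted_denovo$chrom, tl$planted_denovo$pos,
                        tl$planted_denovo$lineage))

  # nothing planted means nothing called
  g0 <- gen_evolution_genomes(small_genome_config(
    seed = 6, denovo_rate_per_lineage = 0, denovo_lowmap_fraction = 0))
  expect_equal(nrow(g0$truth$planted_denovo), 0)
  expect_equal(nrow(call_denovo_singletons(g0$genotypes, g0$meta)), 0)

  # sizing error when the genome cannot host the requested sites
  expect_error(gen_evolution_genomes(genome_sim_config(genome_length = 10000,
                                                       seed = 1)),
               "too small")
})
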