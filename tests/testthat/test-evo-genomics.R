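# Genotype codes: 0 hom-ref, 1 het, 2 hom-alt, NA missing.

test_that("ancestral het sites are exactly the ancestor's het calls", {
  fx <- toy_gm(list(c(1, rep(1, 8)),
                    c(0, rep(0, 8)),
                    c(1, rep(2, 8))))
  expect_equal(ancestral_het_sites(fx$gm, fx$meta), c(1L, 3L))
  fx0 <- toy_gm(list(c(0, rep(0, 8))))
  expect_length(ancestral_het_sites(fx0$gm, fx0$meta), 0)
  bad <- fx$meta; bad$is_ancestor[2] <- TRUE
  expect_error(ancestral_het_sites(fx$gm, bad), "exactly one ancestor")
})

test_that("LOH calls are evolved homozygosity at ancestral-het sites", {
  fx <- toy_gm(list(c(1, 2, 1, NA, rep(1, 5)),
                    c(1, 0, 0, 0, rep(1, 5))))
  loh <- call_loh(fx$gm, fx$meta)
  expect_true(loh$loh[1, 1])                       # het -> hom_alt
  expect_equal(unname(loh$direction[1, 1]), "to_alt")
  expect_false(loh$loh[1, 2])                      # stayed het
  expect_true(is.na(loh$loh[1, 3]))                # missing, not LOH
  expect_equal(unname(loh$direction[2, 1]), "to_ref")
  s <- loh_sharing_summary(loh)
  # missing genotypes are excluded from per-lineage counts
  expect_equal(unname(s$per_lineage[3]), 1)
  expect_equal(s$n_loh_sites, 2)
})

test_that("sharing summary handles full sharing and empty tables", {
  fx <- toy_gm(list(c(1, rep(2, 8))))
  s <- loh_sharing_summary(call_loh(fx$gm, fx$meta))
  expect_equal(s$shared_fraction, 1)
  expect_equal(s$mean_per_lineage, 1)
  fx2 <- toy_gm(list(c(1, rep(1, 8))))
  s2 <- loh_sharing_summary(call_loh(fx2$gm, fx2$meta))
  expect_true(s2$empty)
  expect_true(is.na(s2$shared_fraction))
  expect_equal(s2$total_events, 0)
})

test_that("permutation test matches exhaustive enumeration", {
  # all samples identical: every permutation ties, p = 1, OR = 1
  fx <- toy_gm(list(c(0, rep(1, 8))))
  r <- site_or_permutation_test(fx$gm, fx$meta, 1, "low_pH", n_perm = 200,
                                seed = 1)
  expect_equal(r$observed_or, 1)
  expect_equal(r$p, 1)
  # 4 hom-ref vs 4 hom-alt: exhaustive p = 2/70
  fx2 <- toy_gm(list(c(0, rep(0, 4), rep(2, 4))))
  p_exact <- oracle_perm_p(rep(0, 4), rep(2, 4))
  expect_equal(p_exact, 2 / 70)
  r2 <- site_or_permutation_test(fx2$gm, fx2$meta, 1, "low_pH",
                                 n_perm = 2000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(r2$p - p_exact), 3 * se + 1 / 2001)
  # a mixed pattern: Monte-Carlo agrees with enumeration too
  ga <- c(1, 1, 0, 0); gb <- c(2, 2, 2, 1)
  fx3 <- toy_gm(list(c(0, ga, gb)))
  p3 <- oracle_perm_p(ga, gb)
  r3 <- site_or_permutation_test(fx3$gm, fx3$meta, 1, "low_pH",
                                 n_perm = 2000, seed = 4)
  expect_lt(abs(r3$p - p3), 3 * sqrt(p3 * (1 - p3) / 2000) + 1 / 2001)
})

test_that("permutation scan memoizes identical patterns consistently", {
  fx <- toy_gm(list(c(0, rep(0, 4), rep(2, 4)),
                    c(1, rep(1, 8)),
                    c(0, rep(0, 4), rep(2, 4))))
  ps <- permutation_scan(fx$gm, fx$meta, sites = 1:3, group_b = "low_pH",
                         n_perm = 300, seed = 2)
  expect_equal(ps$p[1], ps$p[3])
  expect_equal(ps$p[2], 1)
})

test_that("Weir-Cockerham FST matches closed-form cases", {
  fx <- toy_gm(list(c(0, rep(0, 4), rep(2, 4)),   # fixed difference
                    c(1, rep(1, 8)),              # everyone het
                    c(0, rep(0, 8))))             # monomorphic
  fst <- wc_fst(fx$gm, fx$meta, group_b = "low_pH")
  expect_equal(fst$per_site$fst[1], 1)
  expect_equal(fst$per_site$fst[2], 0)
  expect_equal(fst$per_site$a[3], 0)
  expect_true(is.na(fst$per_site$fst[3]))
  # single polymorphic site: genome-wide equals that site's ratio
  # (the monomorphic site contributes nothing to either sum, and the
  # all-het site contributes only to the denominator)
  one <- wc_fst(fx$gm, fx$meta, group_b = "low_pH", sites = 1L)
  expect_equal(one$genome_wide, one$per_site$fst[1])
})

test_that("FST components match the ANOVA oracle on exhaustive small designs", {
  # all genotype compositions with 2..4 diploids per group
  comps <- list()
  for (n in 2:4) {
    for (a in 0:n) for (h in 0:(n - a)) {
      comps[[length(comps) + 1]] <- c(rep(0, n - a - h), rep(1, h), rep(2, a))
    }
  }
  worst <- 0
  for (g1 in comps) for (g2 in comps) {
    np <- max(length(g1), length(g2))
    fx <- toy_gm(list(rep(0L, 1 + 2 * np)), n_per = np)
    # pad unequal group sizes with missing genotypes
    geno <- matrix(NA_integer_, 1, 1 + 2 * np)
    geno[1, 1] <- 0L
    geno[1, 1 + seq_along(g1)] <- g1
    geno[1, 1 + np + seq_along(g2)] <- g2
    fx$gm$geno[] <- geno
    fst <- wc_fst(fx$gm, fx$meta, group_b = "low_pH")
    want <- oracle_fst_anova(g1, g2)
    got <- c(a = fst$per_site$a[1], b = fst$per_site$b[1],
             c = fst$per_site$c[1])
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-10)
})

test_that("candidate-site thresholds are inclusive on FST, strict on p", {
  perm <- data.frame(site = 1:5, p = c(0.05, 0.05, 0.15, 0.09, 0.1))
  fst <- data.frame(site = 1:5, fst = c(0.4, 0.6, 0.4, 0.3, 0.5))
  expect_equal(candidate_sites(perm, fst), c(1L, 4L))
  expect_equal(candidate_sites(perm, fst, p_max = 0.2), c(1L, 3L, 4L, 5L))
})

test_that("singleton de novo calls require a unique complete carrier", {
  fx <- toy_gm(list(c(0, 2, rep(0, 7)),        # single carrier -> call
                    c(0, 2, 2, rep(0, 6)),     # two carriers -> no call
                    c(0, 2, NA, rep(0, 6)),    # missing elsewhere -> no call
                    c(1, 2, rep(1, 7)),        # ancestor het -> no call
                    c(2, 1, rep(2, 7))))       # hom-alt ancestor, ref allele
  calls <- call_denovo_singletons(fx$gm, fx$meta)
  expect_equal(calls$site, c(1L, 5L))
  expect_equal(calls$sample_id, c("t1_1", "t1_1"))
  expect_equal(calls$allele, c("C", "A"))
  # de novo calls and ancestral-het sites are disjoint by construction
  expect_length(intersect(calls$site, ancestral_het_sites(fx$gm, fx$meta)), 0)
})

test_that("mappability filtering drops low scores and uncovered positions", {
  calls <- data.frame(site = 1:3, chrom = "chr1", pos = c(50, 150, 900),
                      lineage = "L1", sample_id = "t1_1", allele = "C",
                      mappability = NA_real_)
  track <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                      score = c(1.0, 0.5))
  out <- filter_by_mappability(calls, track)
  expect_equal(out$pos, 50)
  expect_equal(out$mappability, 1.0)
  expect_equal(attr(out, "n_uncovered"), 1L)
  expect_equal(attr(out, "n_low_mappability"), 1L)
  expect_error(filter_by_mappability(calls,
                                     data.frame(chrom = "chr1", start = 10,
                                                end = 5, score = 1)),
               "malformed")
})

test_that("window counts respect 1-based windows and conserve totals", {
  meta <- data.frame(sample_id = c("s1", "s2"), is_ancestor = FALSE,
                     treatment = c("normal", "low_pH"), lineage = c("s1", "s2"))
  calls <- data.frame(chrom = "chr1", pos = c(10, 49999, 50000, 50001),
                      sample_id = c("s1", "s1", "s1", "s2"))
  wc <- window_mutation_counts(calls, meta, window = 50000)
  first <- wc[wc$window_start == 1, ]
  expect_equal(sum(first$n_mutations), 3)      # 10, 49999, 50000
  expect_equal(wc$window_start[wc$n_mutations == 1 & wc$treatment == "low_pH"],
               50001)
  expect_equal(sum(wc$n_mutations), nrow(calls))
})

test_that("nearest gene annotation respects distance cutoff and tie-break", {
  genes <- data.frame(chrom = "chr1", start = c(10000, 20000),
                      end = c(12000, 22000), strand = "+",
                      gene_id = c("G1", "G2"))
  sites <- data.frame(chrom = "chr1", pos = c(11000, 7000, 30000, 16000))
  out <- nearest_gene(sites, genes)
  expect_equal(out$gene_id, c("G1", "G1", NA, "G1"))
  expect_equal(out$gene_distance, c(0, 3000, NA, 4000))
  # equidistant between gene ends: smaller start coordinate wins
  out2 <- nearest_gene(data.frame(chrom = "chr1", pos = 16000),
                       data.frame(chrom = "chr1", start = c(10000, 20000),
                                  end = c(12000, 22000), strand = "+",
                                  gene_id = c("A", "B")))
  expect_equal(out2$gene_id, "A")
})
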