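#!/usr/bin/env Rscript

# Evolve-and-resequence stage: simulate the post-variant-calling genotype
# matrix for one ancestor plus 12 evolved lineages (3 nectar treatments x 4
# replicates) at full genome scale, then run the downstream genomics
# pipeline: LOH calling and sharing, treatment-divergence permutation tests,
# Weir-Cockerham FST, candidate-site selection, singleton de novo calling
# with mappability filtering, 50-kb windowed counts and nearest-gene
# annotation. Emits the standard-format inputs (VCF/BED/GFF3) alongside.

library(nectarpe)

seed <- 20220915
dir.create("results", showWarnings = FALSE)

cfg <- genome_sim_config(seed = seed)
g <- gen_evolution_genomes(cfg)
gm <- g$genotypes
meta <- g$meta

chr_len <- table(factor(gm$sites$chrom))  # for the VCF header use true sizes
write_vcf(gm, "results/genomes.vcf",
          contig_lengths = setNames(rep(ceiling(cfg$genome_length /
                                                  cfg$n_chromosomes),
                                        cfg$n_chromosomes),
                                    unique(gm$sites$chrom)))
write_mappability_bed(g$mappability, "results/mappability.bed")
write_genes_gff3(g$genes, "results/genes.gff3")
write.csv(meta, "results/sample_meta.csv", row.names = FALSE)

het <- ancestral_het_sites(gm, meta)
cat(sprintf("Ancestor heterozygous at %d sites (%.3f%% of the %.1f-Mb genome)\n",
            length(het), 100 * length(het) / cfg$genome_length,
            cfg$genome_length / 1e6))

loh <- call_loh(gm, meta, het)
sh <- loh_sharing_summary(loh)
cat(sprintf("LOH: %d events across lineages (mean %.1f per lineage); %.1f%% of
LOH sites shared by all %d lineages\n",
            sh$total_events, sh$mean_per_lineage, 100 * sh$shared_fraction,
            ncol(loh$loh)))
write.csv(data.frame(loh$sites, loh$loh, check.names = FALSE),
          "results/loh_table.csv", row.names = FALSE)

for (grp in c("low_pH", "bact_conditioned")) {
  fst <- wc_fst(gm, meta, group_b = grp, sites = het)
  perm <- permutation_scan(gm, meta, sites = het, group_b = grp,
                           n_perm = 1000, seed = seed + nchar(grp))
  cand <- candidate_sites(perm, fst$per_site)
  cat(sprintf("normal vs %s: genome-wide FST = %.2g; %d candidate sites
(permutation p < 0.1, FST in [0.3, 0.5])\n",
              grp, fst$genome_wide, length(cand)))
  res <- merge(perm, fst$per_site[c("site", "fst")], by = "site")
  res$candidate <- res$site %in% cand
  write.csv(cbind(gm$sites[res$site, c("chrom", "pos")], res),
            sprintf("results/divergence_%s.csv", grp), row.names = FALSE)
}

dn <- call_denovo_singletons(gm, meta)
dnf <- filter_by_mappability(dn, g$mappability)
cat(sprintf("De novo singletons: %d called, %d after mappability-1 filter
(mean %.1f per lineage)\n", nrow(dn), nrow(dnf),
            nrow(dnf) / sum(!meta$is_ancestor)))

wc <- window_mutation_counts(dnf, meta, window = 50000)
write.csv(wc, "results/denovo_windows_50kb.csv", row.names = FALSE)

ann <- nearest_gene(dnf, g$genes, max_dist = 5000)
cat(sprintf("%d/%d filtered singletons lie within 5 kb of an annotated gene\n",
            sum(!is.na(ann$gene_id)), nrow(ann)))
write.csv(ann, "results/denovo_annotated.csv", row.names = FALSE)
write_run_manifest("results/04_manifest.json",
                   config = list(genome = cfg[setdiff(names(cfg), "seed")]),
                   seed = seed,
                   inputs = c("results/genomes.vcf", "results/mappability.bed",
                              "results/genes.gff3"))
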