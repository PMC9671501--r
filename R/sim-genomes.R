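#' Configuration for the synthetic evolve-and-resequence genomes
#'
#' Emulates the post-variant-calling genotype matrix of an experimental
#' evolution study on a diploid yeast: one heterozygous ancestor plus
#' evolved end-point clones (default 4 replicate lineages in each of 3
#' nectar treatments). Planted structure:
#'
#' * ancestral heterozygosity at a fixed fraction of the genome (default
#'   0.138%, i.e. ~26,490 sites on a 19.2-Mb genome);
#' * loss-of-heterozygosity (LOH): `shared_loh_sites` sites resolved to
#'   homozygosity in every lineage (laboratory adaptation) plus
#'   `treatment_loh_sites` sites resolved only in the four lineages of one
#'   treatment, the planted treatment-specific signal. With the defaults
#'   (142 shared + 4 specific) the shared fraction is 142/146 ~ 97% and the
#'   per-lineage LOH count ~142-146;
#' * singleton de novo mutations: per lineage, Poisson(`denovo_rate_per_lineage`)
#'   heterozygous singletons in uniquely mappable regions plus additional
#'   singletons in low-mappability regions so that a fraction
#'   `denovo_lowmap_fraction` of all planted singletons fails the
#'   mappability-1 filter;
#' * invariant background sites (ancestor homozygous, no variation among
#'   samples) mimicking the bulk of a variant-call matrix;
#' * a piecewise-constant mappability track with scores in {1.0, 0.5} and a
#'   sparse non-overlapping gene annotation.
#'
#' @param genome_length total genome size in bp.
#' @param n_chromosomes number of chromosomes (even split).
#' @param ancestral_het_fraction fraction of the genome heterozygous in the
#'   ancestor, in (0, 1).
#' @param n_lineages_per_treatment evolved replicate lineages per treatment.
#' @param treatments treatment labels.
#' @param shared_loh_sites LOH sites planted in all lineages.
#' @param treatment_loh_sites LOH sites planted in a single (random)
#'   treatment's lineages.
#' @param denovo_rate_per_lineage expected mappable singletons per lineage.
#' @param denovo_lowmap_fraction fraction of all planted singletons placed in
#'   low-mappability regions (to exercise the filter).
#' @param low_mappability_fraction fraction of the genome with mappability
#'   0.5 rather than 1.0.
#' @param mappability_tile_bp tile width of the mappability track.
#' @param n_background_sites invariant background sites in the matrix.
#' @param n_genes genes in the annotation.
#' @param seed integer seed.
#' @return a `genome_sim_config` list.
#' @export
genome_sim_config <- function(genome_length = 19200000,
                              n_chromosomes = 7L,
                              ancestral_het_fraction = 0.00138,
                              n_lineages_per_treatment = 4L,
                              treatments = EVO_TREATMENTS,
                              shared_loh_sites = 142L,
                              treatment_loh_sites = 4L,
                              denovo_rate_per_lineage = 12,
                              denovo_lowmap_fraction = 99 / 245,
                              low_mappability_fraction = 0.10,
                              mappability_tile_bp = 10000L,
                              n_background_sites = 2000L,
                              n_genes = 3000L,
                              seed = 1L) {
  assert_number(genome_length, "genome_length", min = 1000)
  assert_count(n_chromosomes, "n_chromosomes", min = 1L)
  assert_number(ancestral_het_fraction, "ancestral_het_fraction")
  if (ancestral_het_fraction <= 0 || ancestral_het_fraction >= 1) {
    stop_input("'ancestral_het_fraction' must lie strictly in (0, 1)")
  }
  assert_count(n_lineages_per_treatment, "n_lineages_per_treatment", min = 1L)
  assert_count(shared_loh_sites, "shared_loh_sites")
  assert_count(treatment_loh_sites, "treatment_loh_sites")
  assert_number(denovo_rate_per_lineage, "denovo_rate_per_lineage", min = 0)
  assert_prob(denovo_lowmap_fraction, "denovo_lowmap_fraction")
  if (denovo_lowmap_fraction >= 1) {
    stop_input("'denovo_lowmap_fraction' must be < 1")
  }
  assert_prob(low_mappability_fraction, "low_mappability_fraction")
  assert_count(mappability_tile_bp, "mappability_tile_bp", min = 100L)
  assert_count(n_background_sites, "n_background_sites")
  assert_count(n_genes, "n_genes")
  structure(as.list(environment()), class = "genome_sim_config")
}

#' Generate synthetic evolve-and-resequence genomes
#'
#' @param config a [genome_sim_config()].
#' @return list with
#'   `genotypes` (a [genotype_matrix()]), `meta` (sample metadata),
#'   `mappability` (0-based half-open track with scores), `genes`
#'   (1-based closed gene intervals), and `truth` (planted LOH sites,
#'   planted de novo singletons, and planted counts).
#' @export
gen_evolution_genomes <- function(config = genome_sim_config()) {
  stopifnot(inherits(config, "genome_sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  n_chr <- config$n_chromosomes
  chr_len <- rep(floor(L / n_chr), n_chr)
  chr_len[n_chr] <- L - sum(chr_len[-n_chr])
  chr_names <- sprintf("chr%d", seq_len(n_chr))
  chr_start0 <- cumsum(c(0, chr_len[-n_chr]))  # global 0-based starts

  # ---- samples ----------------------------------------------------------
  short <- c(normal = "norm", low_pH = "lowph", bact_conditioned = "bact")
  evolved_ids <- unlist(lapply(config$treatments, function(tr) {
    pre <- if (tr %in% names(short)) short[[tr]] else gsub("[^A-Za-z0-9]", "", tr)
    sprintf("%s_%d", pre, seq_len(config$n_lineages_per_treatment))
  }))
  meta <- data.frame(
    sample_id = c("anc", evolved_ids),
    is_ancestor = c(TRUE, rep(FALSE, length(evolved_ids))),
    treatment = c(NA, rep(config$treatments,
                          each = config$n_lineages_per_treatment)),
    lineage = c(NA, evolved_ids)
  )
  n_ev <- length(evolved_ids)

  # ---- mappability track ------------------------------------------------
  tiles <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
    starts <- seq(0, chr_len[ci] - 1, by = config$mappability_tile_bp)
    data.frame(chrom = chr_names[ci], start = starts,
               end = pmin(starts + config$mappability_tile_bp, chr_len[ci]))
  }))
  n_low <- round(config$low_mappability_fraction * nrow(tiles))
  tiles$score <- 1.0
  if (n_low > 0) tiles$score[sample.int(nrow(tiles), n_low)] <- 0.5

  # ---- site placement ---------------------------------------------------
  n_het <- round(config$ancestral_het_fraction * L)
  n_dn_map <- rpois(n_ev, config$denovo_rate_per_lineage)
  f <- config$denovo_lowmap_fraction
  n_dn_low <- rpois(n_ev, config$denovo_rate_per_lineage * f / (1 - f))
  n_sites <- n_het + config$n_background_sites + sum(n_dn_map) + sum(n_dn_low)
  if (n_sites * 4 > L) {
    stop_input("genome_length too small to place ", n_sites, " sites")
  }
  pool <- sample.int(L, min(L, max(4L * n_sites, n_sites + 1000L)))
  pool_chr <- findInterval(pool - 1L, chr_start0)
  pool_local <- pool - chr_start0[pool_chr]          # 1-based within chrom
  tile_score <- function(chr_idx, local_pos) {
    # all tiles have fixed width within a chromosome
    ti <- (local_pos - 1L) %/% config$mappability_tile_bp
    key <- paste(chr_names[chr_idx], ti * config$mappability_tile_bp)
    tiles$score[match(key, paste(tiles$chrom, tiles$start))]
  }
  pool_score <- tile_score(pool_chr, pool_local)
  hi_pool <- which(pool_score == 1.0)
  lo_pool <- which(pool_score == 0.5)
  if (length(hi_pool) < n_het + config$n_background_sites + sum(n_dn_map) ||
      length(lo_pool) < sum(n_dn_low)) {
    stop_input("genome_length too small for the requested site layout")
  }
  take_hi <- function(k) { out <- hi_pool[seq_len(k)]; hi_pool <<- hi_pool[-seq_len(k)]; out }
  take_lo <- function(k) { out <- lo_pool[seq_len(k)]; lo_pool <<- lo_pool[-seq_len(k)]; out }

  idx_het <- take_hi(n_het)
  idx_bg <- take_hi(config$n_background_sites)
  idx_dn_map <- lapply(n_dn_map, take_hi)
  idx_dn_low <- lapply(n_dn_low, take_lo)

  all_idx <- c(idx_het, idx_bg, unlist(idx_dn_map), unlist(idx_dn_low))
  kind <- c(rep("het", n_het), rep("bg", config$n_background_sites),
            rep("dn_map", sum(n_dn_map)), rep("dn_low", sum(n_dn_low)))
  dn_lineage <- c(rep(NA_character_, n_het + config$n_background_sites),
                  rep(evolved_ids, times = n_dn_map),
                  rep(evolved_ids, times = n_dn_low))

  ord <- order(pool_chr[all_idx], pool_local[all_idx])
  all_idx <- all_idx[ord]; kind <- kind[ord]; dn_lineage <- dn_lineage[ord]
  site_chr <- chr_names[pool_chr[all_idx]]
  site_pos <- pool_local[all_idx]
  n_total <- length(all_idx)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  # ---- genotypes --------------------------------------------------------
  geno <- matrix(NA_integer_, n_total, nrow(meta),
                 dimnames = list(NULL, meta$sample_id))
  is_het <- kind == "het"
  is_bg <- kind == "bg"
  is_dn <- kind %in% c("dn_map", "dn_low")
  anc_geno <- integer(n_total)
  anc_geno[is_het] <- GT_HET
  anc_geno[is_bg] <- ifelse(runif(sum(is_bg)) < 0.7, GT_HOM_REF, GT_HOM_ALT)
  anc_geno[is_dn] <- GT_HOM_REF
  geno[, "anc"] <- anc_geno
  for (s in evolved_ids) geno[, s] <- anc_geno

  # LOH planting at het sites
  het_rows <- which(is_het)
  n_loh <- config$shared_loh_sites + config$treatment_loh_sites
  if (n_loh > length(het_rows)) {
    stop_input("genome_length too small: only ", length(het_rows),
               " ancestral-het sites for ", n_loh, " planted LOH sites")
  }
  loh_rows <- sample(het_rows, n_loh)
  shared_rows <- loh_rows[seq_len(config$shared_loh_sites)]
  spec_rows <- setdiff(loh_rows, shared_rows)
  loh_dir <- sample(c(GT_HOM_REF, GT_HOM_ALT), n_loh, replace = TRUE)
  names(loh_dir) <- as.character(loh_rows)
  for (rw in shared_rows) geno[rw, evolved_ids] <- loh_dir[[as.character(rw)]]
  spec_treat <- if (length(spec_rows) > 0) {
    sample(config$treatments, length(spec_rows), replace = TRUE)
  } else character(0)
  for (i in seq_along(spec_rows)) {
    ids <- meta$sample_id[!meta$is_ancestor & meta$treatment == spec_treat[i]]
    geno[spec_rows[i], ids] <- loh_dir[[as.character(spec_rows[i])]]
  }

  # de novo singletons: carrier heterozygous, everyone else ancestral
  dn_rows <- which(is_dn)
  for (rw in dn_rows) geno[rw, dn_lineage[rw]] <- GT_HET

  sites <- data.frame(chrom = site_chr, pos = site_pos, ref = ref, alt = alt)
  gm <- genotype_matrix(sites, meta$sample_id, geno)

  # ---- genes ------------------------------------------------------------
  genes <- gen_gene_set(chr_names, chr_len, config$n_genes)

  truth <- list(
    planted_loh = data.frame(
      chrom = site_chr[loh_rows], pos = site_pos[loh_rows],
      site = match(loh_rows, seq_len(n_total)),
      direction = ifelse(loh_dir == GT_HOM_REF, "to_ref", "to_alt"),
      scope = c(rep("shared", length(shared_rows)),
                rep("treatment", length(spec_rows))),
      treatment = c(rep(NA_character_, length(shared_rows)), spec_treat)
    ),
    planted_denovo = data.frame(
      chrom = site_chr[dn_rows], pos = site_pos[dn_rows], site = dn_rows,
      lineage = dn_lineage[dn_rows],
      mappable = kind[dn_rows] == "dn_map"
    ),
    n_het_sites = n_het,
    loh_per_lineage_expected =
      config$shared_loh_sites +
      config$treatment_loh_sites / length(config$treatments),
    config = config
  )
  # truth table rows must refer to rows of the emitted matrix
  truth$planted_loh$site <- loh_rows

  list(genotypes = gm, meta = meta, mappability = tiles, genes = genes,
       truth = truth)
}

# Non-overlapping gene intervals: one candidate slot per gene, a random
# sub-interval of each slot.
gen_gene_set <- function(chr_names, chr_len, n_genes) {
  if (n_genes == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      gene_id = character(0)))
  }
  per_chr <- diff(round(seq(0, n_genes, length.out = length(chr_names) + 1)))
  out <- list()
  gi <- 0L
  for (ci in seq_along(chr_names)) {
    k <- per_chr[ci]
    if (k == 0) next
    slot <- chr_len[ci] / k
    glen <- pmax(200, round(runif(k, 0.2, 0.6) * slot))
    start <- round((seq_len(k) - 1) * slot + runif(k, 0.05, 0.3) * slot) + 1
    end <- pmin(start + glen - 1, chr_len[ci])
    out[[ci]] <- data.frame(
      chrom = chr_names[ci], start = start, end = end,
      strand = sample(c("+", "-"), k, replace = TRUE),
      gene_id = sprintf("GENE%05d", gi + seq_len(k))
    )
    gi <- gi + k
  }
  do.call(rbind, out)
}
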