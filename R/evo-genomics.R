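#' Construct a genotype matrix
#'
#' Container for diploid genotype calls at biallelic SNP sites. Genotypes are
#' coded `0` (hom-ref), `1` (het), `2` (hom-alt), `NA` (missing).
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param samples character vector of sample names.
#' @param geno integer matrix, `nrow(sites)` x `length(samples)`.
#' @return a `genotype_matrix` (list with `sites`, `samples`, `geno`).
#' @export
genotype_matrix <- function(sites, samples, geno) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites) || ncol(geno) != length(samples)) {
    stop_input("genotype matrix dimensions do not match sites/samples")
  }
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop_input("genotypes must be coded 0 (hom-ref), 1 (het), 2 (hom-alt) or NA")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_input("positions must be strictly increasing within chromosome ", ch)
    }
  }
  colnames(geno) <- samples
  structure(list(sites = sites, samples = samples, geno = geno),
            class = "genotype_matrix")
}

check_meta <- function(meta, samples = NULL) {
  meta <- as.data.frame(meta)
  stopifnot(all(c("sample_id", "is_ancestor") %in% names(meta)))
  if (sum(meta$is_ancestor) != 1L) {
    stop_input("sample metadata must flag exactly one ancestor")
  }
  if (!is.null(samples) && !setequal(meta$sample_id, samples)) {
    stop_input("sample metadata does not match genotype matrix samples")
  }
  meta
}

#' Sites heterozygous in the ancestral strain
#'
#' @param gm a [genotype_matrix()].
#' @param meta sample metadata with `sample_id` and `is_ancestor` (exactly
#'   one ancestor), plus `treatment` and `lineage` for evolved samples.
#' @return integer vector of site indices where the ancestor is heterozygous.
#' @export
ancestral_het_sites <- function(gm, meta) {
  meta <- check_meta(meta, gm$samples)
  anc <- meta$sample_id[meta$is_ancestor]
  which(gm$geno[, anc] == GT_HET)
}

#' Call loss-of-heterozygosity events
#'
#' An LOH event is an evolved sample being homozygous (either direction) at a
#' site where the ancestor is heterozygous. Missing evolved genotypes are
#' recorded as missing, never as LOH.
#'
#' @inheritParams ancestral_het_sites
#' @param het_sites site indices from [ancestral_het_sites()].
#' @return an `loh_table`: list with `sites` (data frame for the het sites),
#'   `loh` (logical matrix het-sites x evolved samples, NA = missing) and
#'   `direction` (character matrix, `"to_ref"`/`"to_alt"`/NA).
#' @export
call_loh <- function(gm, meta, het_sites = ancestral_het_sites(gm, meta)) {
  meta <- check_meta(meta, gm$samples)
  evolved <- meta$sample_id[!meta$is_ancestor]
  g <- gm$geno[het_sites, evolved, drop = FALSE]
  loh <- g == GT_HOM_REF | g == GT_HOM_ALT
  direction <- matrix(NA_character_, nrow(g), ncol(g),
                      dimnames = dimnames(g))
  direction[g == GT_HOM_REF] <- "to_ref"
  direction[g == GT_HOM_ALT] <- "to_alt"
  structure(list(sites = gm$sites[het_sites, , drop = FALSE],
                 site_index = het_sites, loh = loh, direction = direction),
            class = "loh_table")
}

#' Summarize LOH sharing across lineages
#'
#' @param loh_table output of [call_loh()].
#' @param sharing_threshold number of lineages with LOH at a site required to
#'   call the site "shared"; defaults to all evolved lineages.
#' @return list with `per_lineage` (named counts), `mean_per_lineage`,
#'   `total_events`, `per_site_sharing`, `n_loh_sites`, `shared_fraction`
#'   (NA with `empty = TRUE` when no LOH at all).
#' @export
loh_sharing_summary <- function(loh_table, sharing_threshold = NULL) {
  loh <- loh_table$loh
  if (is.null(sharing_threshold)) sharing_threshold <- ncol(loh)
  per_lineage <- colSums(loh, na.rm = TRUE)
  sharing <- rowSums(loh, na.rm = TRUE)
  is_loh_site <- sharing >= 1
  n_sites <- sum(is_loh_site)
  list(
    per_lineage = per_lineage,
    mean_per_lineage = mean(per_lineage),
    total_events = sum(per_lineage),
    per_site_sharing = sharing,
    n_loh_sites = n_sites,
    shared_fraction = if (n_sites > 0) {
      mean(sharing[is_loh_site] >= sharing_threshold)
    } else NA_real_,
    sharing_threshold = sharing_threshold,
    empty = n_sites == 0
  )
}

# Allele counts (alt, ref) from diploid genotype codes; missing dropped.
allele_counts <- function(g) {
  g <- g[!is.na(g)]
  c(alt = sum(g), ref = 2 * length(g) - sum(g))
}

log_or_cc <- function(ga, gb) {
  ca <- allele_counts(ga) + 0.5
  cb <- allele_counts(gb) + 0.5
  log((ca["alt"] / ca["ref"]) / (cb["alt"] / cb["ref"]))
}

#' Permutation test for treatment-specific allele-frequency divergence
#'
#' At one site, computes the continuity-corrected odds ratio of alternate to
#' reference allele counts between two treatment groups, then compares
#' `|log OR|` to its permutation distribution obtained by shuffling the
#' genotype data across the pooled samples of the two groups. Two-sided;
#' 0.5 is added to all four allele-count cells.
#'
#' @inheritParams ancestral_het_sites
#' @param site site index into `gm$sites`.
#' @param group_a,group_b treatment labels compared (defaults: control
#'   `"normal"` versus `group_b`).
#' @param n_perm number of label permutations.
#' @param seed optional seed.
#' @return a `permutation_result` list: `site`, `observed_or`, `p`,
#'   `n_perm`, `seed`; `skipped = TRUE` (with `p = NA`) when one group has
#'   no called genotypes at the site.
#' @export
site_or_permutation_test <- function(gm, meta, site, group_b,
                                     group_a = "normal", n_perm = 1000,
                                     seed = NULL) {
  meta <- check_meta(meta, gm$samples)
  sa <- meta$sample_id[!meta$is_ancestor & meta$treatment == group_a]
  sb <- meta$sample_id[!meta$is_ancestor & meta$treatment == group_b]
  ga <- gm$geno[site, sa]
  gb <- gm$geno[site, sb]
  if (all(is.na(ga)) || all(is.na(gb))) {
    message("site ", site, " skipped: a group is entirely missing")
    return(structure(list(site = site, observed_or = NA_real_, p = NA_real_,
                          n_perm = n_perm, seed = seed, skipped = TRUE),
                     class = "permutation_result"))
  }
  obs <- abs(log_or_cc(ga, gb))
  pooled <- c(ga, gb)
  na <- length(ga)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    perm <- abs(log_or_cc(pooled[idx], pooled[-idx]))
    if (perm >= obs - 1e-12) hits <- hits + 1L
  }
  structure(list(site = site,
                 observed_or = exp(unname(log_or_cc(ga, gb))),
                 p = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, skipped = FALSE),
            class = "permutation_result")
}

#' Permutation scan over many sites
#'
#' Runs [site_or_permutation_test()] for each site, memoizing by genotype
#' pattern: sites where the two groups show identical genotype data (common
#' under shared LOH) reuse one permutation run.
#'
#' @inheritParams site_or_permutation_test
#' @param sites site indices to scan.
#' @return data frame with `site`, `observed_or`, `p`.
#' @export
permutation_scan <- function(gm, meta, sites, group_b, group_a = "normal",
                             n_perm = 1000, seed = NULL) {
  meta <- check_meta(meta, gm$samples)
  sa <- meta$sample_id[!meta$is_ancestor & meta$treatment == group_a]
  sb <- meta$sample_id[!meta$is_ancestor & meta$treatment == group_b]
  pat <- apply(gm$geno[sites, c(sa, sb), drop = FALSE], 1, paste,
               collapse = ",")
  upat <- unique(pat)
  res <- vector("list", length(upat))
  names(res) <- upat
  for (i in seq_along(upat)) {
    site <- sites[match(upat[i], pat)]
    r <- site_or_permutation_test(gm, meta, site, group_b, group_a, n_perm,
                                  seed = if (is.null(seed)) NULL
                                         else derive_seed(seed, i))
    res[[i]] <- c(or = r$observed_or, p = r$p)
  }
  m <- do.call(rbind, res[pat])
  data.frame(site = sites, observed_or = unname(m[, "or"]),
             p = unname(m[, "p"]))
}

#' Weir-Cockerham FST between two treatment groups
#'
#' Per-site variance components of the Weir-Cockerham (1984) two-population
#' estimator computed from diploid genotypes: `a` (among populations), `b`
#' (among individuals within populations), `c` (within individuals, mean
#' heterozygosity / 2). Per-site FST is `a / (a + b + c)` (missing when the
#' denominator is zero, e.g. monomorphic sites); the genome-wide estimate is
#' the ratio of sums, the combination Weir and Cockerham recommend.
#'
#' Sites with fewer than 2 called diploids in either group are reported as
#' missing.
#'
#' @inheritParams site_or_permutation_test
#' @param sites site indices (default: all sites).
#' @return list with `per_site` (data frame `site`, `a`, `b`, `c`, `fst`)
#'   and `genome_wide`.
#' @export
wc_fst <- function(gm, meta, group_b, group_a = "normal", sites = NULL) {
  meta <- check_meta(meta, gm$samples)
  if (is.null(sites)) sites <- seq_len(nrow(gm$sites))
  sa <- meta$sample_id[!meta$is_ancestor & meta$treatment == group_a]
  sb <- meta$sample_id[!meta$is_ancestor & meta$treatment == group_b]
  g1 <- gm$geno[sites, sa, drop = FALSE]
  g2 <- gm$geno[sites, sb, drop = FALSE]

  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == GT_HET, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == GT_HET, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  ok <- n1 >= 2 & n2 >= 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  denom <- a + b + cc
  fst <- ifelse(!is.na(denom) & abs(denom) > 1e-12, a / denom, NA_real_)
  list(
    per_site = data.frame(site = sites, a = a, b = b, c = cc, fst = fst),
    genome_wide = sum(a[ok]) / sum(denom[ok])
  )
}

#' Select candidate divergent sites
#'
#' Sites whose permutation p-value is below `p_max` and whose per-site FST
#' falls in `[fst_lo, fst_hi]` (bounds inclusive).
#'
#' @param perm_results data frame with `site` and `p` ([permutation_scan()]).
#' @param fst_results per-site data frame with `site` and `fst`
#'   (`wc_fst()$per_site`).
#' @param p_max,fst_lo,fst_hi selection thresholds.
#' @return integer vector of selected site indices.
#' @export
candidate_sites <- function(perm_results, fst_results, p_max = 0.1,
                            fst_lo = 0.3, fst_hi = 0.5) {
  m <- merge(perm_results[c("site", "p")], fst_results[c("site", "fst")],
             by = "site")
  keep <- !is.na(m$p) & !is.na(m$fst) & m$p < p_max &
    m$fst >= fst_lo & m$fst <= fst_hi
  sort(m$site[keep])
}

#' Call singleton de novo mutations
#'
#' A singleton de novo call requires (i) a homozygous ancestor, (ii) exactly
#' one evolved lineage with a genotype differing from the ancestor, and
#' (iii) every other evolved lineage matching the ancestor. Any missing
#' evolved genotype disqualifies the site (conservative: favors precision).
#'
#' @inheritParams ancestral_het_sites
#' @return data frame of calls: `site`, `chrom`, `pos`, `lineage`,
#'   `sample_id`, `allele` (the non-ancestral allele), `mappability` (NA
#'   until [filter_by_mappability()] is applied).
#' @export
call_denovo_singletons <- function(gm, meta) {
  meta <- check_meta(meta, gm$samples)
  anc_id <- meta$sample_id[meta$is_ancestor]
  evolved <- meta$sample_id[!meta$is_ancestor]
  anc <- gm$geno[, anc_id]
  ev <- gm$geno[, evolved, drop = FALSE]

  hom_anc <- !is.na(anc) & anc != GT_HET
  complete <- rowSums(is.na(ev)) == 0
  diff <- ev != anc  # recycled by column
  n_diff <- rowSums(diff)
  idx <- which(hom_anc & complete & n_diff == 1L)
  if (length(idx) == 0) {
    return(data.frame(site = integer(0), chrom = character(0),
                      pos = integer(0), lineage = character(0),
                      sample_id = character(0), allele = character(0),
                      mappability = numeric(0)))
  }
  carrier_col <- apply(diff[idx, , drop = FALSE], 1, which)
  carrier <- evolved[carrier_col]
  lineage <- meta$lineage[match(carrier, meta$sample_id)]
  allele <- ifelse(anc[idx] == GT_HOM_REF, gm$sites$alt[idx],
                   gm$sites$ref[idx])
  data.frame(site = idx, chrom = gm$sites$chrom[idx], pos = gm$sites$pos[idx],
             lineage = lineage, sample_id = carrier, allele = allele,
             mappability = NA_real_, row.names = NULL)
}

#' Filter de novo calls by mappability
#'
#' Looks up each call's position in a piecewise-constant mappability track
#' (0-based half-open intervals) and keeps calls with score >= `min_score`.
#' Positions not covered by the track are treated as missing and dropped;
#' their count is attached as attribute `n_uncovered`.
#'
#' @param calls output of [call_denovo_singletons()].
#' @param track data frame with `chrom`, `start` (0-based), `end`, `score`.
#' @param min_score minimum mappability retained (default 1.0: uniquely
#'   mappable k-mer regions only).
#' @return the retained calls with `mappability` filled in.
#' @export
filter_by_mappability <- function(calls, track, min_score = 1.0) {
  track <- as.data.frame(track)
  if (any(track$end <= track$start) || any(track$start < 0)) {
    stop_input("malformed mappability track: need 0 <= start < end")
  }
  score <- rep(NA_real_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    sel <- which(calls$chrom == ch)
    if (nrow(tr) == 0) next
    tr <- tr[order(tr$start), , drop = FALSE]
    # 1-based position p is inside [start, end) iff start < p <= end
    iv <- findInterval(calls$pos[sel] - 1L, tr$start)
    inside <- iv >= 1 & calls$pos[sel] <= tr$end[pmax(iv, 1)]
    score[sel[inside]] <- tr$score[iv[inside]]
  }
  calls$mappability <- score
  n_uncovered <- sum(is.na(score))
  out <- calls[!is.na(score) & score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_uncovered") <- n_uncovered
  attr(out, "n_low_mappability") <- sum(!is.na(score) & score < min_score)
  out
}

#' Windowed de novo mutation counts per treatment
#'
#' Counts calls in fixed genomic windows (1-based windows of length `window`:
#' `[1, window]`, `[window + 1, 2 * window]`, ...), split by the carrier
#' lineage's evolution treatment.
#'
#' @param calls de novo calls (`chrom`, `pos`, `sample_id`).
#' @param meta sample metadata mapping samples to treatments.
#' @param window window size in bp (> 0).
#' @return data frame `chrom`, `window_start`, `window_end`, `treatment`,
#'   `n_mutations`.
#' @export
window_mutation_counts <- function(calls, meta, window = 50000) {
  assert_number(window, "window", min = 1)
  meta <- as.data.frame(meta)
  treatment <- meta$treatment[match(calls$sample_id, meta$sample_id)]
  w <- (calls$pos - 1) %/% window
  if (nrow(calls) == 0) {
    return(data.frame(chrom = character(0), window_start = numeric(0),
                      window_end = numeric(0), treatment = character(0),
                      n_mutations = integer(0)))
  }
  agg <- aggregate(list(n_mutations = rep(1L, nrow(calls))),
                   by = list(chrom = calls$chrom, w = w,
                             treatment = treatment),
                   FUN = sum)
  out <- data.frame(chrom = agg$chrom, window_start = agg$w * window + 1,
                    window_end = (agg$w + 1) * window,
                    treatment = agg$treatment, n_mutations = agg$n_mutations)
  out[order(out$chrom, out$window_start, out$treatment), , drop = FALSE]
}

#' Nearest annotated gene within a distance cutoff
#'
#' For each site, finds the gene (1-based closed intervals) minimizing the
#' distance: 0 when the site lies inside the gene, otherwise the gap to the
#' nearer gene end. Sites farther than `max_dist` from every gene are left
#' unannotated. Ties are broken by the smaller gene start coordinate.
#'
#' @param sites data frame with `chrom`, `pos`.
#' @param genes data frame with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @param max_dist maximum distance (bp) for annotation.
#' @return `sites` with `gene_id`, `gene_distance` appended (NA when no gene
#'   is within range).
#' @export
nearest_gene <- function(sites, genes, max_dist = 5000) {
  sites <- as.data.frame(sites)
  genes <- as.data.frame(genes)
  sites$gene_id <- NA_character_
  sites$gene_distance <- NA_real_
  for (i in seq_len(nrow(sites))) {
    g <- genes[genes$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    p <- sites$pos[i]
    d <- ifelse(p >= g$start & p <= g$end, 0,
                pmin(abs(p - g$start), abs(p - g$end)))
    ok <- d <= max_dist
    if (!any(ok)) next
    g <- g[ok, , drop = FALSE]
    d <- d[ok]
    best <- order(d, g$start)[1]
    sites$gene_id[i] <- g$gene_id[best]
    sites$gene_distance[i] <- d[best]
  }
  sites
}
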