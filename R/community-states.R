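#' CLAM-style classifier configuration
#'
#' Parameters of the multinomial (CLAM) dominance classifier. With two groups
#' (bacteria, yeast) the multinomial test reduces to one-sided exact binomial
#' tests of each group's share against the supermajority threshold `K`.
#'
#' @param K supermajority share threshold, in (0.5, 1). A flower is
#'   group-dominated when that group's share is significantly above `K`.
#' @param alpha significance level of each one-sided exact test.
#' @param coverage_limit minimum effort-scaled total count required to call a
#'   flower co-dominated rather than too rare.
#' @return a `clam_config` list.
#' @export
clam_config <- function(K = 2 / 3, alpha = 0.005, coverage_limit = 10) {
  assert_number(K, "K")
  if (K <= 0.5 || K >= 1) stop_input("'K' must lie strictly in (0.5, 1)")
  assert_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 0.5) stop_input("'alpha' must lie in (0, 0.5)")
  assert_number(coverage_limit, "coverage_limit", min = 1)
  structure(list(K = K, alpha = alpha, coverage_limit = coverage_limit),
            class = "clam_config")
}

#' Rescale plate counts to a common sampling effort
#'
#' Bacterial and yeast CFU are counted on different media with different
#' dilution series; dividing by the per-group effort (dilution x plated
#' volume) puts both on a common per-volume-of-nectar scale. Results are
#' rounded half-up to integers so that exact binomial tests remain
#' well-defined.
#'
#' @param records data frame with columns `bact_cfu`, `yeast_cfu` and
#'   (optionally) `bact_effort`, `yeast_effort` (default 1).
#' @return the input with columns `b_norm` and `y_norm` appended.
#' @export
normalize_effort <- function(records) {
  records <- as.data.frame(records)
  be <- if ("bact_effort" %in% names(records)) records$bact_effort else 1
  ye <- if ("yeast_effort" %in% names(records)) records$yeast_effort else 1
  if (any(!is.finite(be)) || any(!is.finite(ye)) || any(be <= 0) ||
      any(ye <= 0)) {
    stop_input("sampling efforts must be positive and finite")
  }
  if (any(records$bact_cfu < 0) || any(records$yeast_cfu < 0)) {
    stop_input("CFU counts must be non-negative")
  }
  records$b_norm <- round_half_up(records$bact_cfu / be)
  records$y_norm <- round_half_up(records$yeast_cfu / ye)
  records
}

#' Classify flowers into dominance states
#'
#' Applies the two-group CLAM scheme to effort-normalized counts `b` and
#' `y`. Dominance: a flower is bacteria-dominated when the one-sided exact
#' binomial test rejects H0 "bacterial share <= K" at level `alpha` (p-value
#' `P(X >= b | n = b + y, p = K)`); yeast-dominated symmetrically. For
#' `K > 0.5` the two rejections are mutually exclusive. Co-dominance is
#' CLAM's generalist class: both groups' shares must test significantly
#' above the complementary threshold `1 - K` (and the total must reach
#' `coverage_limit`); everything else is too rare to classify. This keeps a
#' flower with a modest count of one group alone out of the co-dominated
#' class, which the neither-test-rejects reading would not. The four states
#' partition every input.
#'
#' @param b,y non-negative integer vectors of effort-normalized bacterial and
#'   yeast counts.
#' @param cfg a [clam_config()].
#' @return data frame with columns `state` (factor with levels
#'   `bacteria_dominated`, `yeast_dominated`, `co_dominated`, `too_rare`),
#'   the one-sided dominance p-values `p_bact`, `p_yeast`, and the
#'   generalist-test p-values `p_bact_gen`, `p_yeast_gen`.
#' @export
classify_flower <- function(b, y, cfg = clam_config()) {
  stopifnot(inherits(cfg, "clam_config"))
  if (length(b) != length(y)) stop_input("'b' and 'y' must have equal length")
  if (any(b < 0) || any(y < 0)) stop_input("counts must be non-negative")
  b <- round_half_up(b)
  y <- round_half_up(y)
  n <- b + y
  # One-sided upper tails of the exact binomial tests: dominance (share > K)
  # and generalist presence (share > 1 - K).
  p_bact <- ifelse(n > 0, pbinom(b - 1, n, cfg$K, lower.tail = FALSE),
                   NA_real_)
  p_yeast <- ifelse(n > 0, pbinom(y - 1, n, cfg$K, lower.tail = FALSE),
                    NA_real_)
  p_bact_gen <- ifelse(n > 0, pbinom(b - 1, n, 1 - cfg$K, lower.tail = FALSE),
                       NA_real_)
  p_yeast_gen <- ifelse(n > 0, pbinom(y - 1, n, 1 - cfg$K, lower.tail = FALSE),
                        NA_real_)
  bact_dom <- !is.na(p_bact) & p_bact <= cfg$alpha
  yeast_dom <- !is.na(p_yeast) & p_yeast <= cfg$alpha
  if (any(bact_dom & yeast_dom)) {
    stop("internal error: both dominance tests rejected at K > 0.5")
  }
  codom <- !is.na(p_bact_gen) & p_bact_gen <= cfg$alpha &
    p_yeast_gen <= cfg$alpha & n >= cfg$coverage_limit
  state <- ifelse(bact_dom, "bacteria_dominated",
           ifelse(yeast_dom, "yeast_dominated",
           ifelse(codom, "co_dominated", "too_rare")))
  data.frame(
    state = factor(state, levels = flower_states()),
    p_bact = p_bact,
    p_yeast = p_yeast,
    p_bact_gen = p_bact_gen,
    p_yeast_gen = p_yeast_gen
  )
}

#' @rdname classify_flower
#' @export
flower_states <- function() {
  c("bacteria_dominated", "yeast_dominated", "co_dominated", "too_rare")
}

#' Classify a whole flower survey
#'
#' Normalizes each record's counts for sampling effort and classifies it;
#' record order is preserved.
#'
#' @param records flower survey data frame (`site_id`, `plant_id`,
#'   `flower_id`, `bact_cfu`, `yeast_cfu`, optional efforts).
#' @param cfg a [clam_config()].
#' @return the input records with `b_norm`, `y_norm`, `state`, `p_bact`,
#'   `p_yeast` appended.
#' @export
classify_survey <- function(records, cfg = clam_config()) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    out <- cbind(records,
                 data.frame(b_norm = integer(0), y_norm = integer(0),
                            state = factor(character(0),
                                           levels = flower_states()),
                            p_bact = numeric(0), p_yeast = numeric(0)))
    return(out)
  }
  key <- paste(records$site_id, records$flower_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_input("duplicated flower_id within a site: ",
               sub("\r", "/", key[duplicated(key)][1]))
  }
  records <- normalize_effort(records)
  cbind(records, classify_flower(records$b_norm, records$y_norm, cfg))
}

#' Expected co-dominance under independent distribution of the two groups
#'
#' The independence null for one site: the probability that a flower hosts
#' both groups at dominance-capable abundance if the two groups colonize
#' flowers independently. The marginal "capable" frequencies count the
#' group-dominated flowers plus the co-dominated flowers (a co-dominated
#' flower evidences dominance-capable abundance of both groups).
#'
#' @param n_bact,n_yeast,n_codom per-site counts of bacteria-dominated,
#'   yeast-dominated, and co-dominated flowers.
#' @param n total flowers at the site (> 0).
#' @return expected co-dominated proportion.
#' @export
expected_codominance <- function(n_bact, n_yeast, n_codom, n) {
  if (any(n <= 0)) stop_input("'n' must be positive")
  ((n_bact + n_codom) / n) * ((n_yeast + n_codom) / n)
}

#' Summarize classified flowers per site
#'
#' @param classified output of [classify_survey()].
#' @return data frame with one row per site: state counts, `n_flowers`,
#'   observed and expected co-dominance proportions.
#' @export
summarize_sites <- function(classified) {
  tab <- table(classified$site_id, classified$state)
  out <- data.frame(
    site_id = rownames(tab),
    n_flowers = as.integer(rowSums(tab)),
    n_bacteria_dominated = as.integer(tab[, "bacteria_dominated"]),
    n_yeast_dominated = as.integer(tab[, "yeast_dominated"]),
    n_co_dominated = as.integer(tab[, "co_dominated"]),
    n_too_rare = as.integer(tab[, "too_rare"]),
    row.names = NULL
  )
  out$observed_codominance_prop <- out$n_co_dominated / out$n_flowers
  out$expected_codominance_prop <- expected_codominance(
    out$n_bacteria_dominated, out$n_yeast_dominated, out$n_co_dominated,
    out$n_flowers
  )
  out
}

#' Paired test of observed vs expected co-dominance across sites
#'
#' One-sample t-test on the per-site differences (observed - expected)
#' expressed in percentage points. A negative mean difference indicates that
#' co-dominated flowers are rarer than the independence null predicts, i.e.
#' mutual exclusion of the two groups.
#'
#' @param site_summaries output of [summarize_sites()] (>= 2 sites).
#' @param conf_level confidence level of the reported interval.
#' @return list with `mean_diff_pp`, `ci` (length 2), `p`, `t`, `df`,
#'   `n_sites` and a `degenerate` flag set when the differences have zero
#'   variance (then `p` is the exact limit: 1 if the common difference is 0,
#'   otherwise 0).
#' @export
codominance_test <- function(site_summaries, conf_level = 0.95) {
  d <- 100 * (site_summaries$observed_codominance_prop -
                site_summaries$expected_codominance_prop)
  n <- length(d)
  if (n < 2) stop_input("need at least 2 sites for the paired test")
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0) {
    return(list(mean_diff_pp = mean(d), ci = c(mean(d), mean(d)),
                p = if (mean(d) == 0) 1 else 0,
                t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, n_sites = n, degenerate = TRUE))
  }
  tt <- t.test(d, conf.level = conf_level)
  list(mean_diff_pp = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), n_sites = n, degenerate = FALSE)
}
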