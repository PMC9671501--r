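#' Configuration for the synthetic flower survey
#'
#' Defines the colonization and mutual-exclusion structure of a simulated
#' field survey: each flower is independently colonized by bacteria and by
#' yeast; when both colonize, the exclusion dial decides whether one group
#' suppresses the other (a coin flip picks the winner) or the two co-occur
#' at comparable density. At `exclusion_strength = 0` co-dominance occurs
#' exactly when both groups colonize, so dominance-capability of the two
#' groups is independent across flowers; at 1 no flower ever carries both
#' groups at dominant abundance.
#'
#' @param n_sites number of sites.
#' @param flowers_per_site flowers sampled per site (default 96: 8 flowers
#'   from each of 12 plants).
#' @param p_bact_colonized,p_yeast_colonized per-flower colonization
#'   probabilities.
#' @param exclusion_strength probability in `[0, 1]` that a doubly-colonized
#'   flower resolves to single-group dominance.
#' @param cfu_log10_mean,cfu_log10_sd log10-scale abundance of a dominant
#'   (or co-dominant) group.
#' @param suppressed_fraction multiplicative abundance of the suppressed
#'   group relative to the dominant one (well below the classifier's
#'   supermajority threshold).
#' @param seed integer seed.
#' @return a `survey_sim_config` list.
#' @export
survey_sim_config <- function(n_sites = 12L, flowers_per_site = 96L,
                              p_bact_colonized = 0.45,
                              p_yeast_colonized = 0.40,
                              exclusion_strength = 0.85,
                              cfu_log10_mean = 4, cfu_log10_sd = 1,
                              suppressed_fraction = 0.01, seed = 1L) {
  assert_count(n_sites, "n_sites", min = 1L)
  assert_count(flowers_per_site, "flowers_per_site", min = 1L)
  assert_prob(p_bact_colonized, "p_bact_colonized")
  assert_prob(p_yeast_colonized, "p_yeast_colonized")
  assert_prob(exclusion_strength, "exclusion_strength")
  assert_number(cfu_log10_mean, "cfu_log10_mean")
  assert_number(cfu_log10_sd, "cfu_log10_sd", min = 0)
  assert_prob(suppressed_fraction, "suppressed_fraction")
  structure(as.list(environment()), class = "survey_sim_config")
}

#' Generate a synthetic flower survey
#'
#' @param config a [survey_sim_config()].
#' @return list with `records` (one row per flower: `site_id`, `plant_id`,
#'   `flower_id`, `bact_cfu`, `yeast_cfu`, `bact_effort`, `yeast_effort`)
#'   and `truth` (the planted per-flower state:
#'   `bacteria` / `yeast` / `codominant` / `none`).
#' @export
gen_flower_survey <- function(config = survey_sim_config()) {
  stopifnot(inherits(config, "survey_sim_config"))
  set.seed(config$seed)
  n <- config$n_sites * config$flowers_per_site

  bact_col <- runif(n) < config$p_bact_colonized
  yeast_col <- runif(n) < config$p_yeast_colonized
  excl <- runif(n) < config$exclusion_strength
  bact_wins <- runif(n) < 0.5

  state <- rep("none", n)
  state[bact_col & !yeast_col] <- "bacteria"
  state[!bact_col & yeast_col] <- "yeast"
  both <- bact_col & yeast_col
  state[both & !excl] <- "codominant"
  state[both & excl & bact_wins] <- "bacteria"
  state[both & excl & !bact_wins] <- "yeast"

  # Dominant abundance on the log10 scale; a suppressed co-colonizer is tied
  # to the winner's draw so its share never reaches the supermajority band.
  mag <- 10^rnorm(n, config$cfu_log10_mean, config$cfu_log10_sd)
  jit_b <- 10^rnorm(n, 0, 0.05)
  jit_y <- 10^rnorm(n, 0, 0.05)

  bact <- numeric(n)
  yeast <- numeric(n)
  is_b <- state == "bacteria"
  is_y <- state == "yeast"
  is_c <- state == "codominant"
  bact[is_b] <- mag[is_b]
  yeast[is_b] <- ifelse(yeast_col[is_b],
                        mag[is_b] * config$suppressed_fraction, 0)
  yeast[is_y] <- mag[is_y]
  bact[is_y] <- ifelse(bact_col[is_y],
                       mag[is_y] * config$suppressed_fraction, 0)
  bact[is_c] <- mag[is_c] * jit_b[is_c]
  yeast[is_c] <- mag[is_c] * jit_y[is_c]

  site <- rep(sprintf("S%02d", seq_len(config$n_sites)),
              each = config$flowers_per_site)
  plant_per_site <- pmax(1L, config$flowers_per_site %/% 8L)
  plant <- sprintf("%s_P%02d", site,
                   rep_len(rep(seq_len(plant_per_site), each = 8L),
                           config$flowers_per_site))
  flower <- sprintf("F%03d", rep(seq_len(config$flowers_per_site),
                                 times = config$n_sites))

  records <- data.frame(
    site_id = site, plant_id = plant, flower_id = flower,
    bact_cfu = round_half_up(bact), yeast_cfu = round_half_up(yeast),
    bact_effort = 1, yeast_effort = 1
  )
  list(records = records,
       truth = data.frame(site_id = site, flower_id = flower, state = state))
}
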