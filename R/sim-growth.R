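#' Configuration for the synthetic microcosm growth experiment
#'
#' Fully factorial arrival-order design with the six treatment codes of
#' [GROWTH_TREATMENTS]. The focal organism's final density is
#' `baseline_log10_alone` on the log10 scale, minus `pe_effect_log10` when
#' the competitor arrived first (i.e. late yeast under early bacteria, the
#' `BY` treatment); early arrivers and monocultures are unaffected. Gaussian
#' noise of sd `noise_sd_log10` is added on the log10 scale.
#'
#' @param baseline_log10_alone log10 final density without suppression.
#' @param pe_effect_log10 log10 suppression of the late arriver's growth
#'   when the competitor arrived first.
#' @param noise_sd_log10 replicate noise on the log10 scale (>= 0).
#' @param n_replicates replicates per treatment and round.
#' @param n_rounds experiment rounds (weeks).
#' @param strain,evolution_treatment labels copied onto every record.
#' @param seed integer seed.
#' @return a `growth_sim_config` list.
#' @export
growth_sim_config <- function(baseline_log10_alone = 5,
                              pe_effect_log10 = 2,
                              noise_sd_log10 = 0.25,
                              n_replicates = 8L, n_rounds = 2L,
                              strain = "MR1",
                              evolution_treatment = "ancestral",
                              seed = 1L) {
  assert_number(baseline_log10_alone, "baseline_log10_alone")
  assert_number(pe_effect_log10, "pe_effect_log10")
  assert_number(noise_sd_log10, "noise_sd_log10", min = 0)
  assert_count(n_replicates, "n_replicates", min = 1L)
  assert_count(n_rounds, "n_rounds", min = 1L)
  structure(as.list(environment()), class = "growth_sim_config")
}

#' Generate a synthetic growth experiment
#'
#' One record per treatment x replicate x round. The planted effect
#' suppresses only the late arriver facing an established competitor
#' (`BY` for the focal yeast; bacteria are not suppressed by late arrival
#' in the default parameterization), so on noiseless output
#' `PE1 = PE2 = -pe_effect_log10`.
#'
#' @param config a [growth_sim_config()].
#' @return data frame of growth records: `treatment`, `focal_cfu`, `strain`,
#'   `evolution_treatment`, `round`, `replicate`.
#' @export
gen_growth_experiment <- function(config = growth_sim_config()) {
  stopifnot(inherits(config, "growth_sim_config"))
  set.seed(config$seed)
  grid <- expand.grid(
    treatment = GROWTH_TREATMENTS,
    replicate = sprintf("R%02d", seq_len(config$n_replicates)),
    round = sprintf("round%d", seq_len(config$n_rounds)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  suppressed <- grid$treatment == "BY"
  log10_final <- config$baseline_log10_alone -
    ifelse(suppressed, config$pe_effect_log10, 0) +
    rnorm(nrow(grid), 0, config$noise_sd_log10)
  data.frame(
    treatment = grid$treatment,
    focal_cfu = round_half_up(10^log10_final),
    strain = config$strain,
    evolution_treatment = config$evolution_treatment,
    round = grid$round,
    replicate = grid$replicate
  )
}
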