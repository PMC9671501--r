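#' Configuration for synthetic nectar pH samples
#'
#' Gaussian-mixture model of field nectar pH. The default three components
#' represent unmodified nectar, yeast-conditioned nectar and
#' bacteria-conditioned nectar, centered at pH 7.8, 5.5 and 2.6. Component
#' weights and spreads are not reported for the field data and are set here
#' to plausible values (see the package vignette). Values are clipped to the
#' indicator-strip range `[2.0, 9.0]` and rounded to `round_unit` pH units
#' (0.1 by default; set `round_unit = NULL` to disable).
#'
#' @param n number of flowers measured.
#' @param weights mixture weights (must sum to 1 within 1e-9).
#' @param means,sds component means and standard deviations (pH units;
#'   `sds >= 0`, zero gives a degenerate point component).
#' @param clip_range instrument range; measurements outside are recorded at
#'   the boundary.
#' @param round_unit strip resolution in pH units, or NULL.
#' @param seed integer seed.
#' @return a `ph_sim_config` list.
#' @export
ph_sim_config <- function(n = 576L, weights = c(0.40, 0.35, 0.25),
                          means = c(7.8, 5.5, 2.6), sds = c(0.4, 0.5, 0.4),
                          clip_range = c(2.0, 9.0), round_unit = 0.1,
                          seed = 1L) {
  assert_count(n, "n", min = 0L)
  if (length(weights) != length(means) || length(means) != length(sds)) {
    stop_input("weights, means and sds must have the same length k")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_input("weights must be non-negative and sum to 1 (within 1e-9)")
  }
  if (any(sds < 0)) stop_input("sds must be non-negative")
  structure(as.list(environment()), class = "ph_sim_config")
}

#' Generate synthetic nectar pH measurements
#'
#' @param config a [ph_sim_config()].
#' @return list with `ph` (numeric vector of length `n`) and `truth`
#'   (list: `mixture_params` = the config, `component` = index of the
#'   generating component per value).
#' @export
gen_ph_samples <- function(config = ph_sim_config()) {
  stopifnot(inherits(config, "ph_sim_config"))
  set.seed(config$seed)
  n <- config$n
  if (n == 0L) {
    return(list(ph = numeric(0),
                truth = list(mixture_params = config, component = integer(0))))
  }
  comp <- sample.int(length(config$weights), n, replace = TRUE,
                     prob = config$weights)
  ph <- rnorm(n, config$means[comp], config$sds[comp])
  ph <- pmin(pmax(ph, config$clip_range[1]), config$clip_range[2])
  if (!is.null(config$round_unit)) {
    ph <- round_half_up(ph / config$round_unit) * config$round_unit
  }
  list(ph = ph, truth = list(mixture_params = config, component = comp))
}
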