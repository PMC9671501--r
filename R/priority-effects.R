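#' Log-transform a colony count
#'
#' `log10(cfu + pseudocount)`; the pseudocount (default 1 CFU) keeps zero
#' counts finite and is negligible at the densities observed in microcosms.
#'
#' @param cfu non-negative counts.
#' @param pseudocount added before taking the log.
#' @param base logarithm base.
#' @return transformed values.
#' @export
log_count <- function(cfu, pseudocount = 1, base = 10) {
  if (any(cfu < 0)) stop_input("counts must be non-negative")
  log(cfu + pseudocount, base = base)
}

#' Priority-effect strength, metric 1
#'
#' `PE1 = log(BY / -Y) - log(YB / Y-)`: the growth of the focal yeast when
#' bacteria arrived first, relative to its monoculture growth at the same
#' arrival time, contrasted against the reverse arrival order. More negative
#' values mean a stronger bacterial priority effect against yeast.
#'
#' @param mean_BY,mean_negY,mean_YB,mean_Yneg positive treatment means of
#'   (pseudocounted) final yeast densities: bacteria-first, late-alone,
#'   yeast-first, early-alone.
#' @param base logarithm base (10 matches the log-transform of counts).
#' @return PE1.
#' @export
pe1 <- function(mean_BY, mean_negY, mean_YB, mean_Yneg, base = 10) {
  if (any(c(mean_BY, mean_negY, mean_YB, mean_Yneg) <= 0)) {
    stop_input("treatment means must be positive")
  }
  log(mean_BY / mean_negY, base) - log(mean_YB / mean_Yneg, base)
}

#' Priority-effect strength, metric 2
#'
#' `PE2 = log(BY / YB)`: the focal yeast's growth contrast between the two
#' arrival orders.
#'
#' @inheritParams pe1
#' @return PE2.
#' @export
pe2 <- function(mean_BY, mean_YB, base = 10) {
  if (any(c(mean_BY, mean_YB) <= 0)) stop_input("treatment means must be positive")
  log(mean_BY / mean_YB, base)
}

#' Growth difference between invasion and monoculture
#'
#' `(BY) - (-Y)` on the log10-count scale: yeast growth under initial
#' bacterial dominance minus monoculture growth at the same initial density.
#'
#' @param log_BY,log_negY log-scale growth values.
#' @return the difference.
#' @export
growth_difference <- function(log_BY, log_negY) log_BY - log_negY

#' Summarize priority-effect statistics over a growth experiment
#'
#' Within each group (default: strain x evolution treatment x round),
#' treatment means are the arithmetic means of pseudocounted final counts;
#' PE1, PE2 and the growth difference are then computed from those means
#' ("average densities by round, then take logs"). The alternative
#' mean-of-logs averaging is available via `average = "logs"`, in which case
#' the "means" entering the formulas are geometric.
#'
#' Groups missing a treatment required by a metric get `NA` for that metric
#' (with a diagnostic message); PE2 only needs `BY` and `YB`, PE1 needs all
#' four yeast treatments.
#'
#' @param records growth records with columns `treatment`, `focal_cfu` and
#'   any of the grouping columns.
#' @param grouping character vector of grouping column names; entries absent
#'   from `records` are ignored.
#' @param pseudocount added to every count before averaging.
#' @param base logarithm base.
#' @param average `"counts"` (arithmetic mean of counts, then log) or
#'   `"logs"` (mean of log counts).
#' @return data frame with one row per group: grouping keys, component means
#'   `mean_BY`, `mean_negY`, `mean_YB`, `mean_Yneg`, and `pe1`, `pe2`,
#'   `growth_diff`.
#' @export
summarize_pe <- function(records,
                         grouping = c("strain", "evolution_treatment", "round"),
                         pseudocount = 1, base = 10,
                         average = c("counts", "logs")) {
  average <- match.arg(average)
  records <- as.data.frame(records)
  bad <- !(records$treatment %in% GROWTH_TREATMENTS)
  if (any(bad)) {
    stop_input("invalid treatment code in row ", which(bad)[1], ": '",
               records$treatment[bad][1], "'")
  }
  grouping <- intersect(grouping, names(records))
  if (length(grouping) == 0) {
    records$.group <- "all"
    grouping <- ".group"
  }
  key <- interaction(records[grouping], drop = TRUE, lex.order = TRUE)

  one_group <- function(idx) {
    gr <- records[idx, , drop = FALSE]
    tr_mean <- function(code) {
      v <- gr$focal_cfu[gr$treatment == code]
      if (length(v) == 0) return(NA_real_)
      if (average == "counts") mean(v + pseudocount)
      else base^mean(log(v + pseudocount, base))
    }
    m <- vapply(c("BY", "-Y", "YB", "Y-"), tr_mean, numeric(1))
    names(m) <- c("BY", "negY", "YB", "Yneg")
    p1 <- if (all(!is.na(m))) pe1(m["BY"], m["negY"], m["YB"], m["Yneg"], base)
          else NA_real_
    p2 <- if (!any(is.na(m[c("BY", "YB")]))) pe2(m["BY"], m["YB"], base)
          else NA_real_
    gd <- if (!any(is.na(m[c("BY", "negY")]))) {
      growth_difference(log(m["BY"], base), log(m["negY"], base))
    } else NA_real_
    out <- gr[1, grouping, drop = FALSE]
    out$mean_BY <- unname(m["BY"]); out$mean_negY <- unname(m["negY"])
    out$mean_YB <- unname(m["YB"]); out$mean_Yneg <- unname(m["Yneg"])
    out$pe1 <- unname(p1); out$pe2 <- unname(p2); out$growth_diff <- unname(gd)
    out
  }

  pieces <- lapply(split(seq_len(nrow(records)), key), one_group)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  n_skipped <- sum(is.na(out$pe1))
  if (n_skipped > 0) {
    message(n_skipped, " group(s) missing a treatment required for PE1; ",
            "metric set to NA there")
  }
  out
}
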