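#!/usr/bin/env Rscript

# Field-survey stage: simulate a regional flower survey (12 sites x 96
# flowers), classify every flower into a dominance state with the CLAM-style
# exact-binomial rule, and test whether co-dominated flowers are rarer than
# the independence null predicts.

library(nectarpe)

seed <- 20150601
dir.create("results", showWarnings = FALSE)

cfg <- survey_sim_config(seed = seed)
sim <- gen_flower_survey(cfg)
write_table_csv(sim$records, "results/survey_records.csv", "survey")

cl <- classify_survey(sim$records)
write.csv(cl, "results/survey_classified.csv", row.names = FALSE)

ss <- summarize_sites(cl)
write.csv(ss, "results/survey_site_summary.csv", row.names = FALSE)

ct <- codominance_test(ss)
write.csv(data.frame(mean_diff_pp = ct$mean_diff_pp, ci_low = ct$ci[1],
                     ci_high = ct$ci[2], t = ct$t, df = ct$df, p = ct$p,
                     n_sites = ct$n_sites),
          "results/codominance_test.csv", row.names = FALSE)
write_run_manifest("results/01_manifest.json",
                   config = list(survey = cfg[setdiff(names(cfg), "seed")]),
                   seed = seed)

cat(sprintf("Classified %d flowers: %s\n", nrow(cl),
            paste(sprintf("%s=%d", levels(cl$state), table(cl$state)),
                  collapse = ", ")))
cat(sprintf(
  "Observed co-dominance is %.1f pp %s than the independence expectation
(95%% CI [%.1f, %.1f], paired t-test p = %.2g, n = %d sites).\n",
  abs(ct$mean_diff_pp), if (ct$mean_diff_pp < 0) "lower" else "higher",
  ct$ci[1], ct$ci[2], ct$p, ct$n_sites))
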