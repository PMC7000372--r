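#!/usr/bin/env Rscript
# Dynamic 13C-bicarbonate labeling: model prediction and scenario fitting
# against the measured position-specific NMR enrichments.
#
# Finding: under the canonical WLP (both acetate carbons from the DIC
# pool, WLP fraction 0.2) the model predicts ~15% of the acetate produced
# during 8 h of labeled-titrant feeding to carry label. The measured NMR
# time course (methyl barely above natural abundance, carbonyl strongly
# labeled) is fitted far better by the formate-fed methyl branch variant.

suppressPackageStartupMessages(library(acetotrace))
dir.create("results/labeling", showWarnings = FALSE, recursive = TRUE)

cfg <- chemostat_config()
rates <- chemostat_rates()

series <- simulate_labeling(cfg, rates, scenario("CANONICAL_WLP", 0.2),
                            t_end = 8, t_step = 0.05)
pred <- produced_label_fraction(series, 8)
cat(sprintf("Canonical-WLP prediction: %.1f%% of acetate produced in 8 h labeled\n",
            pred))
cat(sprintf("DIC enrichment at 8 h: %.1f%%\n", 100 * tail(series$e_dic, 1)))

obs <- acetate_nmr()
cat("\nMeasured NMR observations (% 13C):\n"); print(as.data.frame(obs))

fits <- fit_scenario(obs, cfg, rates)
cat("\nScenario fits (ranked):\n"); print(as.data.frame(fits))
best <- fits$scenario[1]
cat(sprintf("\nBest-fitting scenario: %s (f_WLP = %.2f)\n",
            best, fits$f_wlp[1]))

write_tsv(as.data.frame(series), "results/labeling/canonical_series.tsv")
write_tsv(as.data.frame(fits), "results/labeling/scenario_fits.tsv")
jsonlite::write_json(
  list(produced_label_pct_8h = pred, best_scenario = best,
       best_f_wlp = fits$f_wlp[1]),
  "results/labeling/labeling_summary.json", auto_unbox = TRUE, digits = NA)
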