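#!/usr/bin/env Rscript
# Stage 3: AIC/BIC model selection across scenarios.
#
# Reads the per-scenario fit records from stage 2 and tabulates the
# exchange-model weights and the dual-threshold decision (both weights
# > 0.995 and a reduced chi-square drop). The null scenario should be
# spared; every exchange scenario should be flagged.

suppressPackageStartupMessages(library(bmcest))

truth <- read.csv(file.path("results", "ground_truth.csv"))

rows <- lapply(truth$scenario, function(nm) {
  rec <- jsonlite::read_json(file.path("results",
                                       paste0("fit_", nm, ".json")),
                             simplifyVector = TRUE)
  sel <- rec$selection
  data.frame(scenario = nm, w_aic_ex = sel$w_aic_ex,
             w_bic_ex = sel$w_bic_ex, r_chi2_ex = sel$r_chi2_ex,
             r_chi2_noex = sel$r_chi2_noex, decision = sel$decision)
})
sel <- do.call(rbind, rows)
write.csv(sel, file.path("results", "model_selection.csv"),
          row.names = FALSE)
print(sel, row.names = FALSE, digits = 4)

exch <- truth$p_es > 0
message(sprintf(
  "\n%d/%d exchange scenarios flagged significant; null flagged %s.",
  sum(sel$decision[exch] == "exchange-significant"), sum(exch),
  sel$decision[!exch]))
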