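#!/usr/bin/env Rscript
# Step 4: the replicate recovery study behind the identification argument.
# Simulates panels with a state-level confound that drives both the baseline
# mortality rate and mean gun ownership, then fits the Mundlak,
# fixed-effects, and (deliberately misspecified) pooled random-intercept
# models to each replicate.
# Writes: results/recovery_reps.csv, results/recovery_summary.csv,
#         results/manifest_recover.json

suppressPackageStartupMessages({
  library(optparse)
  library(gppanel)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1),
  make_option("--reps", type = "integer", default = 20),
  make_option("--out-dir", type = "character", default = "results")
)))
path <- function(f) file.path(opts$`out-dir`, f)
dir.create(opts$`out-dir`, showWarnings = FALSE, recursive = TRUE)

res <- recovery_study(
  generator_config(seed = opts$seed),
  n_reps = opts$reps,
  models = c("mundlak", "fixed_effects", "random_intercept"),
  sampler = sampler_config(2, 500, 500, seed = opts$seed + 1L)
)
utils::write.csv(as.data.frame(res), path("recovery_reps.csv"),
                 row.names = FALSE)
agg <- recovery_summary(res)
utils::write.csv(as.data.frame(agg), path("recovery_summary.csv"),
                 row.names = FALSE)
write_manifest(path("manifest_recover.json"), "recover", opts$seed,
               config = list(reps = opts$reps))

for (i in seq_len(nrow(agg))) {
  message(sprintf(
    "%-18s coverage %.0f%%  mean bias %+.4f (MC SE %.4f)",
    agg$model[i], 100 * agg$coverage[i], agg$mean_bias[i], agg$bias_mc_se[i]))
}
naive <- res[res$model == "random_intercept", ]
message(sprintf(
  "Pooled model biased by >2 posterior SDs in %d/%d replicates; the Mundlak
and fixed-effects fits absorb the state-level confound instead.",
  sum(abs(naive$estimate - naive$true) / naive$se > 2), opts$reps))
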