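#!/usr/bin/env Rscript

# Contrast the flux distributions of the two seasonal conditions:
# per-reaction flux fold changes (with the zero threshold and intensity
# categories), acetate cross-feeding ratios between methanogens and
# sulfide oxidizers, and the share of reducing power that the sulfate
# reducers route into respiration.

library(guildcom)

dir.create("results", showWarnings = FALSE)
model <- make_toy_community(toy_community_spec())
settings <- solver_settings(flux_resolution = "parsimonious")

sol_l <- maximize_growth(model, settings)
sol_h <- maximize_growth(apply_condition(model, condition_preset("H-OLR")),
                         settings)

cmp <- flux_comparison(sol_l, sol_h)
write_ffc_tsv(cmp, "results/ffc.tsv")
cat("Largest flux fold changes (high vs low loading):\n")
ok <- cmp[cmp$flag == "ok", ]
print(utils::head(ok[order(-abs(ok$ffc)),
                     c("guild", "reaction", "v_l", "v_h", "ffc",
                       "category")], 10), row.names = FALSE)

but <- flux_fold_change(sol_h$community_uptake[["but"]],
                        sol_l$community_uptake[["but"]])
cat(sprintf("\nButyrate uptake fold change: %.4f (%.2f-fold)\n",
            but$ffc, 2^but$ffc))

r_l <- exchange_ratio(sol_l, "ac", "MET", "SOB")$ratio
r_h <- exchange_ratio(sol_h, "ac", "MET", "SOB")$ratio
cat(sprintf("Acetate consumption, MET relative to SOB: %.2fx (low) -> %.2fx (high)\n",
            r_l, r_h))

p_l <- nadh_partition(sol_l, "SRB", "SR", "BUTOX")$percent
p_h <- nadh_partition(sol_h, "SRB", "SR", "BUTOX")$percent
cat(sprintf("NADH routed to sulfate respiration in SRB: %.1f%% (low) -> %.1f%% (high)\n",
            p_l, p_h))
cat("\nWrote results/ffc.tsv\n")
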