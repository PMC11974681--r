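#!/usr/bin/env Rscript
# 04: intrinsic neural timescales per region, their anaesthetic shortening,
# and whether the change is organised along the baseline map (tested against
# Moran-spectral-randomisation surrogates).

source(file.path("analysis", "_common.R"))

study <- build_study()
man <- study$manifest

rows <- list(); tests <- list()
for (sp in names(study$recordings)) {
  conds <- man[man$species == sp, ]
  avg_tau <- function(labels) {
    maps <- lapply(labels, function(cond)
      vapply(study$recordings[[sp]][[cond]],
             function(ts) timescale_map(ts)$tau,
             numeric(nrow(study$coords[[sp]]))))
    rowMeans(do.call(cbind, maps))
  }
  ta <- avg_tau(conds$awake); tn <- avg_tau(conds$anaes)
  cmp <- compare_timescale_conditions(ta, tn, paired = conds$paired[1])
  bc <- baseline_change_correlation(
    ta, tn - ta, build_moran_basis(study$coords[[sp]]),
    n_surrogates = 1000L, seed = child_seed(master_seed, "tau", sp))
  rows[[sp]] <- data.frame(species = sp, region = names(ta),
                           tau_awake = ta, tau_anaes = tn)
  tests[[sp]] <- list(p = cmp$p, mean_delta = cmp$mean_delta,
                      baseline_change_r = bc$r, baseline_change_p = bc$p)
  msg("%s: mean delta tau %.3f s (p = %.2g); baseline-change r = %.2f (p = %.3g)",
      sp, cmp$mean_delta, cmp$p, bc$r, bc$p)
}

utils::write.table(do.call(rbind, rows),
                   file.path(results_dir, "timescales.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(tests, file.path(results_dir, "timescale_tests.json"),
                     auto_unbox = TRUE, digits = NA)
msg("written: timescales.tsv, timescale_tests.json")
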