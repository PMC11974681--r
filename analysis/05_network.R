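#!/usr/bin/env Rscript
# 05: synchrony (FC), dynamical profile similarity (DPS), and their coupling,
# compared between awake and anaesthetised recordings per species.

source(file.path("analysis", "_common.R"))

study <- build_study()
man <- study$manifest

network <- list()
for (sp in names(study$recordings)) {
  row1 <- man[man$species == sp, ][1, ]
  per_cond <- lapply(c(row1$awake, row1$anaes), function(cond) {
    lapply(study$recordings[[sp]][[cond]], function(ts) {
      fm <- extract_feature_matrix(ts, reduced_catalog)
      list(fc = functional_connectivity(ts),
           dps = dynamical_profile_similarity(fm))
    })
  })
  fc_a <- lapply(per_cond[[1]], `[[`, "fc")
  fc_n <- lapply(per_cond[[2]], `[[`, "fc")
  dps_a <- lapply(per_cond[[1]], `[[`, "dps")
  dps_n <- lapply(per_cond[[2]], `[[`, "dps")
  cpl <- function(l) mean(vapply(l, function(e)
    synchrony_dynamics_coupling(e$fc, e$dps), numeric(1)))
  network[[sp]] <- list(
    fc = condition_summary(fc_a, fc_n, paired = row1$paired),
    dps = condition_summary(dps_a, dps_n, paired = row1$paired),
    coupling_awake = cpl(per_cond[[1]]), coupling_anaes = cpl(per_cond[[2]]))
  with(network[[sp]], msg(
    "%s: FC %.3f -> %.3f (p = %.3g); DPS %.3f -> %.3f (p = %.3g); coupling %.2f -> %.2f",
    sp, fc$mean_a, fc$mean_b, fc$p, dps$mean_a, dps$mean_b, dps$p,
    coupling_awake, coupling_anaes))
}

jsonlite::write_json(network, file.path(results_dir, "network.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
msg("written: network.json")
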