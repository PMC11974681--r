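#!/usr/bin/env Rscript
# 01: generate the synthetic multi-species anaesthesia study and write its
# on-disk form (recordings, coordinates, expression, connectome, manifest).

source(file.path("analysis", "_common.R"))

study <- build_study()
man <- study$manifest

msg("species blocks: %s", paste(names(study$recordings), collapse = ", "))
msg("contrasts: %d (multiplicities %s)", nrow(man),
    paste(table(man$species)[unique(man$species)], collapse = "/"))
msg("connectome: %d regions, density %.3f",
    nrow(study$connectome$C), study$connectome$density)

out <- file.path(results_dir, "study")
write_study(study, out)
msg("study written to %s", out)

truth <- planted_feature_signs()
utils::write.table(
  data.frame(feature_id = names(truth), planted_sign = unname(truth)),
  file.path(results_dir, "planted_signs.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
msg("planted anaesthesia directions: %d features", length(truth))
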