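#!/usr/bin/env Rscript
# 02: extract the time-series feature catalogue from every recording, form
# per-contrast Hedge's g effect matrices, and write the contrast-level and
# region-level summaries downstream scripts consume.

source(file.path("analysis", "_common.R"))

study <- build_study()
man <- study$manifest
catalog <- full_catalog
red_ids <- reduced_catalog$feature_id

msg("extracting %d features from all recordings ...", nrow(catalog))
feats <- lapply(names(study$recordings), function(sp)
  lapply(study$recordings[[sp]], function(cond_list)
    lapply(cond_list, extract_feature_matrix, catalog = catalog)))
names(feats) <- names(study$recordings)

effects <- lapply(seq_len(nrow(man)), function(i)
  contrast_effects(feats[[man$species[i]]][[man$awake[i]]],
                   feats[[man$species[i]]][[man$anaes[i]]],
                   contrast_id = man$contrast_id[i],
                   species_id = man$species[i]))

per_contrast_means <- t(vapply(effects, contrast_mean_effects,
                               numeric(nrow(catalog))))
rownames(per_contrast_means) <- man$contrast_id
write_matrix_tsv(per_contrast_means,
                 file.path(results_dir, "per_contrast_mean_effects.tsv"),
                 rowname_col = "contrast_id")
msg("per-contrast mean effects: %d x %d", nrow(per_contrast_means),
    ncol(per_contrast_means))

# species signatures and their cross-species correlations
signatures <- lapply(split(seq_len(nrow(man)), man$species), function(idx)
  species_signature(effects[idx])$mean_g)
sig <- correlate_signatures(signatures)
write_matrix_tsv(sig$r, file.path(results_dir, "signature_correlations.tsv"),
                 rowname_col = "species")
write_matrix_tsv(sig$p_adj,
                 file.path(results_dir, "signature_correlations_padj.tsv"),
                 rowname_col = "species")
ut <- upper.tri(sig$r)
msg("cross-species signature r: %.2f-%.2f (BH-adjusted p max %.2g)",
    min(sig$r[ut]), max(sig$r[ut]), max(sig$p_adj[ut]))

# per-region anaesthesia-change maps on the reduced set, averaged within
# species: input to the PLS stage
for (sp in names(study$recordings)) {
  idx <- which(man$species == sp)
  delta <- Reduce(`+`, lapply(effects[idx], function(e)
    e$g[, red_ids, drop = FALSE])) / length(idx)
  write_matrix_tsv(delta,
                   file.path(results_dir, sprintf("delta_g_%s.tsv", sp)))
}
msg("region-level delta-g maps written for %d species",
    length(study$recordings))

qc <- data.frame(contrast_id = man$contrast_id,
                 zero_filled = vapply(effects, function(e) e$zero_filled,
                                      numeric(1)))
utils::write.table(qc, file.path(results_dir, "effects_qc.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
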