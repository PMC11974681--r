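#!/usr/bin/env Rscript
# 06: PLS correlation of the regional anaesthesia-change maps (from 02)
# against gene-expression maps, with latent-variable significance from
# spatial-autocorrelation-preserving surrogates.

source(file.path("analysis", "_common.R"))

study <- build_study()

X_blocks <- list(); Y_blocks <- list(); bases <- list()
for (sp in names(study$recordings)) {
  Y_blocks[[sp]] <- read_matrix_tsv(
    file.path(results_dir, sprintf("delta_g_%s.tsv", sp)))
  X_blocks[[sp]] <- study$expression[[sp]]$expression
  bases[[sp]] <- build_moran_basis(study$coords[[sp]])
}

input <- suppressWarnings(zscore_concat(X_blocks, Y_blocks))
res <- pls_svd(input)
sig <- pls_significance(input, bases, n_surrogates = 1000L,
                        seed = child_seed(master_seed, "pls"))

k <- min(5, length(res$singular_values))
for (i in seq_len(k))
  msg("LV%d: %.1f%% of squared covariance, p = %.4g",
      i, 100 * res$cov_explained[i], sig$p[i])

write_matrix_tsv(res$gene_saliences,
                 file.path(results_dir, "pls_gene_saliences.tsv"),
                 rowname_col = "gene")
write_matrix_tsv(res$feature_saliences,
                 file.path(results_dir, "pls_feature_saliences.tsv"),
                 rowname_col = "feature")
jsonlite::write_json(
  list(singular_values = res$singular_values,
       cov_explained = res$cov_explained, p = sig$p,
       dropped_genes = input$dropped_genes,
       dropped_features = input$dropped_features),
  file.path(results_dir, "pls.json"), auto_unbox = TRUE, digits = NA)
msg("written: pls.json, pls_gene_saliences.tsv, pls_feature_saliences.tsv")
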