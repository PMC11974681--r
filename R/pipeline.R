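#' Pipeline configuration
#'
#' Every stochastic stage carries an explicit seed derived from the master
#' seed; stages can be toggled; the DMF stage is off by default because it is
#' the costly one.
#'
#' @param spec a [study_spec()] describing the synthetic study.
#' @param consistency_mode `"per_contrast"` (stricter, default) or
#'   `"per_species"`.
#' @param reduced_catalog use only the reduced representative feature set?
#' @param n_sign_surrogates surrogate matrices for the sign-consistency null.
#' @param n_pls_surrogates surrogate draws for PLS significance.
#' @param n_tau_surrogates surrogate draws for the baseline-change
#'   correlation.
#' @param run_pls,run_dmf stage toggles.
#' @param dmf DMF stage settings (list: `params`, `duration`, `n_sims`).
#' @param out_dir optional directory for stage artifacts.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = study_spec(),
                            consistency_mode = "per_contrast",
                            reduced_catalog = FALSE,
                            n_sign_surrogates = 10000L,
                            n_pls_surrogates = 1000L,
                            n_tau_surrogates = 1000L,
                            run_pls = TRUE, run_dmf = FALSE,
                            dmf = list(), out_dir = NULL, seed = 1L) {
  structure(list(spec = spec, consistency_mode = consistency_mode,
                 reduced_catalog = reduced_catalog,
                 n_sign_surrogates = as.integer(n_sign_surrogates),
                 n_pls_surrogates = as.integer(n_pls_surrogates),
                 n_tau_surrogates = as.integer(n_tau_surrogates),
                 run_pls = run_pls, run_dmf = run_dmf, dmf = dmf,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end synthetic-study pipeline
#'
#' Stages: synthetic data, feature extraction, effect-size contrasts,
#' sign-consistency with surrogate null and category enrichment, intrinsic
#' timescales (condition comparison and baseline-vs-change spatial-null
#' correlation), network synchrony / dynamical-profile similarity / coupling,
#' and PLS of dynamics-change maps against expression maps under Moran nulls.
#' Deterministic given the config seed. Returns a run report; with `out_dir`
#' set, also writes stage artifacts (TSV matrices, JSON report).
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  spec <- config$spec
  catalog <- feature_catalog(reduced = config$reduced_catalog)
  study <- make_multispecies_study(spec)
  man <- study$manifest

  # features per recording, then effect-size matrix per contrast
  feats <- lapply(names(study$recordings), function(sp) {
    lapply(study$recordings[[sp]], function(cond_list)
      lapply(cond_list, extract_feature_matrix, catalog = catalog))
  })
  names(feats) <- names(study$recordings)
  effects <- lapply(seq_len(nrow(man)), function(i) {
    contrast_effects(feats[[man$species[i]]][[man$awake[i]]],
                     feats[[man$species[i]]][[man$anaes[i]]],
                     contrast_id = man$contrast_id[i],
                     species_id = man$species[i])
  })
  per_contrast_means <- t(vapply(effects, contrast_mean_effects,
                                 numeric(nrow(catalog))))
  rownames(per_contrast_means) <- man$contrast_id

  cons <- consistent_features(per_contrast_means, mode = config$consistency_mode,
                              species_of_contrast = man$species)
  sign_p <- sign_null_pvalue(cons$observed_count, ncol(per_contrast_means),
                             cons$n_units,
                             n_surrogates = config$n_sign_surrogates,
                             seed = child_seed(config$seed, "signnull"))
  enrich <- category_enrichment(cons$feature_ids, catalog,
                                seed = child_seed(config$seed, "enrich"))
  signatures <- lapply(split(seq_len(nrow(man)), man$species), function(idx)
    species_signature(effects[idx])$mean_g)
  sig_cor <- if (length(signatures) >= 2) correlate_signatures(signatures) else NULL

  # timescales: per-region tau averaged over subjects and contrasts per species
  timescales <- list()
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
    basis <- build_moran_basis(study$coords[[sp]])
    bc <- baseline_change_correlation(ta, tn - ta, basis,
                                      n_surrogates = config$n_tau_surrogates,
                                      seed = child_seed(config$seed, "tau", sp))
    timescales[[sp]] <- list(tau_awake = ta, tau_anaes = tn,
                             p = cmp$p, mean_delta = cmp$mean_delta,
                             baseline_change_r = bc$r, baseline_change_p = bc$p)
  }

  # network stage: per-subject FC and DPS for the first contrast per species
  network <- list()
  for (sp in names(study$recordings)) {
    row1 <- man[man$species == sp, ][1, ]
    fc_a <- lapply(study$recordings[[sp]][[row1$awake]], functional_connectivity)
    fc_n <- lapply(study$recordings[[sp]][[row1$anaes]], functional_connectivity)
    dps_a <- lapply(feats[[sp]][[row1$awake]], dynamical_profile_similarity)
    dps_n <- lapply(feats[[sp]][[row1$anaes]], dynamical_profile_similarity)
    cpl_a <- mapply(synchrony_dynamics_coupling, fc_a, dps_a)
    cpl_n <- mapply(synchrony_dynamics_coupling, fc_n, dps_n)
    network[[sp]] <- list(
      fc = condition_summary(fc_a, fc_n, paired = row1$paired),
      dps = condition_summary(dps_a, dps_n, paired = row1$paired),
      coupling_awake = mean(cpl_a), coupling_anaes = mean(cpl_n))
  }

  # PLS of per-species dynamics-change maps vs expression maps
  pls <- NULL
  if (config$run_pls) {
    red_ids <- feature_catalog(reduced = TRUE)$feature_id
    Y_blocks <- list(); X_blocks <- list(); bases <- list()
    for (sp in names(study$recordings)) {
      idx <- which(man$species == sp)
      delta <- Reduce(`+`, lapply(effects[idx], function(e)
        e$g[, red_ids, drop = FALSE])) / length(idx)
      Y_blocks[[sp]] <- delta
      X_blocks[[sp]] <- study$expression[[sp]]$expression
      bases[[sp]] <- build_moran_basis(study$coords[[sp]])
    }
    input <- suppressWarnings(zscore_concat(X_blocks, Y_blocks))
    res <- pls_svd(input)
    sig <- pls_significance(input, bases,
                            n_surrogates = config$n_pls_surrogates,
                            seed = child_seed(config$seed, "pls"))
    pls <- list(singular_values = res$singular_values,
                cov_explained = res$cov_explained, p = sig$p)
  }

  dmf_res <- NULL
  if (config$run_dmf) {
    pars <- config$dmf$params %||% dmf_params()
    cal <- fic_calibrate(pars, study$connectome,
                         seed = child_seed(config$seed, "fic"))
    st <- dmf_simulate(pars, study$connectome,
                       duration = config$dmf$duration %||% 120,
                       seed = child_seed(config$seed, "dmfsim"),
                       J_FIC = cal$J_FIC, init = cal$state)
    dmf_res <- list(mean_rate = mean(st$rE_mean), converged = cal$converged)
  }

  report <- structure(list(
    n_contrasts = nrow(man),
    n_features = nrow(catalog),
    consistency = list(mode = cons$mode, observed_count = cons$observed_count,
                       feature_ids = cons$feature_ids, signs = cons$signs,
                       p = sign_p,
                       analytic_p = analytic_sign_probability(cons$n_units)),
    enrichment = enrich,
    signature_correlations = sig_cor,
    timescales = lapply(timescales, function(t)
      t[c("p", "mean_delta", "baseline_change_r", "baseline_change_p")]),
    network = network, pls = pls, dmf = dmf_res,
    per_contrast_means = per_contrast_means,
    seed = config$seed), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(per_contrast_means,
                     file.path(config$out_dir, "per_contrast_mean_effects.tsv"),
                     rowname_col = "contrast_id")
    tau_df <- do.call(rbind, lapply(names(timescales), function(sp)
      data.frame(species = sp, region = names(timescales[[sp]]$tau_awake),
                 tau_awake = timescales[[sp]]$tau_awake,
                 tau_anaes = timescales[[sp]]$tau_anaes)))
    utils::write.table(tau_df, file.path(config$out_dir, "timescales.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep_json <- report
    rep_json$per_contrast_means <- NULL
    jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
  }
  report
}
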