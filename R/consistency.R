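#' Features consistently perturbed across contrasts or species
#'
#' A feature survives the per-contrast filter iff its contrast-level mean
#' effect has the same strict sign in every contrast (all positive or all
#' negative; zeros break consistency — a zero-filled effect carries no
#' directional evidence). The per-species mode first averages contrasts within
#' species, then applies the same strict-sign test across species.
#'
#' @param per_contrast_means matrix (contrasts x features) of mean effect
#'   sizes; column names are feature ids.
#' @param mode `"per_contrast"` (default, the stricter criterion) or
#'   `"per_species"`.
#' @param species_of_contrast species label per row (required for
#'   `per_species`).
#' @return list of class `consistent_feature_set`: `feature_ids`, `signs`,
#'   `observed_count`, `n_units`, `mode`, `median_effect`, `all_zero_dropped`.
#' @export
consistent_features <- function(per_contrast_means,
                                mode = c("per_contrast", "per_species"),
                                species_of_contrast = NULL) {
  mode <- match.arg(mode)
  M <- as.matrix(per_contrast_means)
  stopifnot(nrow(M) >= 2 || mode == "per_species")
  if (mode == "per_species") {
    if (is.null(species_of_contrast) || length(species_of_contrast) != nrow(M))
      stop("per_species mode needs one species label per contrast row")
    M <- do.call(rbind, lapply(split.data.frame(M, species_of_contrast), colMeans))
  }
  if (nrow(M) < 2) stop("need at least 2 units (contrasts or species)")
  all_zero <- colSums(M != 0) == 0
  pos <- colSums(M > 0) == nrow(M)
  neg <- colSums(M < 0) == nrow(M)
  keep <- (pos | neg) & !all_zero
  ids <- colnames(M) %||% as.character(seq_len(ncol(M)))
  structure(list(feature_ids = ids[keep],
                 signs = ifelse(pos[keep], 1, -1),
                 observed_count = sum(keep),
                 n_units = nrow(M), mode = mode,
                 median_effect = apply(M[, keep, drop = FALSE], 2, stats::median),
                 all_zero_dropped = sum(all_zero)),
            class = "consistent_feature_set")
}

# consistent-feature count in each of n_surrogates random-sign matrices,
# generated chunk-wise as genuine i.i.d. +/-1 sign assignments
surrogate_consistency_counts <- function(n_features, n_contrasts, n_surrogates,
                                         seed = 1L, chunk = 200L) {
  counts <- integer(0)
  with_seed(seed, {
    done <- 0L
    while (done < n_surrogates) {
      k <- min(chunk, n_surrogates - done)
      s <- matrix(runif(n_features * n_contrasts * k) < 0.5,
                  nrow = n_features * k)
      npos <- rowSums(s)
      cons <- npos == 0L | npos == n_contrasts
      counts <- c(counts, colSums(matrix(cons, nrow = n_features)))
      done <- done + k
    }
  })
  counts
}

#' Surrogate-null p-value for the consistent-feature count
#'
#' Builds surrogate matrices in which every contrast-feature pair is
#' independently assigned a random sign (+1 or -1), counts the features with
#' full sign agreement in each, and returns the add-one-corrected proportion
#' of surrogates reaching the observed count.
#'
#' @param observed_count observed number of consistent features.
#' @param n_features,n_contrasts dimensions of the sign matrix.
#' @param n_surrogates number of surrogate matrices (>= 1000).
#' @param seed integer seed.
#' @param return_counts also return the per-surrogate counts.
#' @return p-value, or a list when `return_counts = TRUE`.
#' @export
sign_null_pvalue <- function(observed_count, n_features, n_contrasts,
                             n_surrogates = 10000L, seed = 1L,
                             return_counts = FALSE) {
  stopifnot(n_surrogates >= 1000)
  counts <- surrogate_consistency_counts(n_features, n_contrasts,
                                         n_surrogates, seed)
  p <- (1 + sum(counts >= observed_count)) / (n_surrogates + 1)
  if (return_counts) list(p = p, counts = counts) else p
}

#' Analytic probability of full sign agreement by chance
#'
#' Under a fair-coin sign null, an individual feature shows the same sign in
#' all contrasts with probability \eqn{2 \times 0.5^{n}} (two admissible
#' all-same-sign outcomes); 0.000122 for 14 contrasts.
#'
#' @param n_contrasts number of contrasts (>= 1).
#' @return probability.
#' @export
analytic_sign_probability <- function(n_contrasts) {
  stopifnot(n_contrasts >= 1)
  2 * 0.5^n_contrasts
}

#' Feature-category enrichment of a subset
#'
#' Draws `n_draws` random subsets of the same size from the catalogue (without
#' replacement within each draw), counts category memberships, and z-scores
#' the observed counts against this resampling null. Categories whose null
#' standard deviation is zero are flagged rather than scored.
#'
#' @param subset_ids feature ids of interest (subset of the catalogue).
#' @param catalog a [feature_catalog()].
#' @param n_draws number of null draws.
#' @param seed integer seed.
#' @return data.frame: `category`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `flagged`.
#' @export
category_enrichment <- function(subset_ids, catalog = feature_catalog(),
                                n_draws = 10000L, seed = 1L) {
  if (!all(subset_ids %in% catalog$feature_id))
    stop("subset contains ids not in the catalogue")
  cats <- feature_categories()
  fcat <- factor(catalog$category, levels = cats)
  idx <- match(subset_ids, catalog$feature_id)
  obs <- table(fcat[idx])
  n <- length(idx)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      table(fcat[sample.int(nrow(catalog), n)])
    }, numeric(length(cats)))
  })
  mu <- rowMeans(draws)
  sdv <- apply(draws, 1, stats::sd)
  flagged <- sdv == 0
  z <- ifelse(flagged, NA_real_, (as.numeric(obs) - mu) / sdv)
  data.frame(category = cats, observed = as.numeric(obs),
             null_mean = mu, null_sd = sdv, z = z, flagged = flagged,
             row.names = NULL)
}
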