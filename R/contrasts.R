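#' Hedge's g standardized mean difference
#'
#' \deqn{g = J \frac{\bar{x}_2 - \bar{x}_1}{s_{pooled}}, \quad
#'       J = 1 - \frac{3}{4(n_1+n_2) - 9}}
#' with the pooled sample standard deviation. The sign convention throughout
#' the package is anaesthesia minus awake: positive g means larger under
#' anaesthesia.
#'
#' @param awake,anaes numeric samples (>= 2 values each).
#' @return g, or `NaN` when the pooled variance is zero (downstream zero-fill
#'   handles it).
#' @export
hedges_g <- function(awake, anaes) {
  n1 <- length(awake); n2 <- length(anaes)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(awake) + (n2 - 1) * stats::var(anaes)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NaN)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * (mean(anaes) - mean(awake)) / sqrt(sp2)
}

#' Effect-size matrix for one awake-vs-anaesthesia contrast
#'
#' Entry (r, f) is Hedge's g across subjects of feature f in region r, on the
#' raw feature values (features are deliberately not normalised across regions
#' beforehand: effect sizes are already in standard-deviation units and hence
#' comparable across features). Non-finite effect sizes are set to zero and
#' counted.
#'
#' @param awake_features,anaes_features lists of `feature_matrix` (one per
#'   subject), sharing region labels and catalogue.
#' @param contrast_id,species_id identifiers carried in the result.
#' @return object of class `effect_size_matrix`: `g` (regions x features, all
#'   finite), `n_awake`, `n_anaes`, `zero_filled` (count), `excluded_features`
#'   (union of study-level exclusion flags).
#' @export
contrast_effects <- function(awake_features, anaes_features,
                             contrast_id = "contrast", species_id = "species") {
  stopifnot(length(awake_features) >= 2, length(anaes_features) >= 2)
  fm0 <- awake_features[[1]]
  for (fm in c(awake_features, anaes_features)) {
    if (!identical(fm$region_labels, fm0$region_labels))
      stop("region labels differ across subjects in contrast ", contrast_id)
    if (!identical(fm$feature_ids, fm0$feature_ids))
      stop("feature catalogues differ across subjects in contrast ", contrast_id)
  }
  stack <- function(fms) {
    # subjects x regions x features
    arr <- array(NA_real_, c(length(fms), nrow(fm0$values), ncol(fm0$values)))
    for (s in seq_along(fms)) arr[s, , ] <- fms[[s]]$values
    arr
  }
  aw <- stack(awake_features); an <- stack(anaes_features)
  g <- matrix(NA_real_, nrow(fm0$values), ncol(fm0$values),
              dimnames = dimnames(fm0$values))
  for (r in seq_len(nrow(g))) for (f in seq_len(ncol(g))) {
    g[r, f] <- tryCatch(hedges_g(aw[, r, f], an[, r, f]),
                        error = function(e) NaN)
  }
  nonfinite <- !is.finite(g)
  g[nonfinite] <- 0
  excluded <- Reduce(`|`, lapply(c(awake_features, anaes_features), `[[`, "excluded"))
  structure(list(g = g, contrast_id = contrast_id, species_id = species_id,
                 n_awake = length(awake_features), n_anaes = length(anaes_features),
                 zero_filled = sum(nonfinite),
                 excluded_features = excluded),
            class = "effect_size_matrix")
}

#' Per-contrast mean effect per feature
#' @param effects an `effect_size_matrix`.
#' @return named numeric vector (features), averaged over regions.
#' @export
contrast_mean_effects <- function(effects) colMeans(effects$g)

#' Species-level dynamical signature
#'
#' Mean feature-wise effect size across all contrasts of one species and
#' across all regions (unweighted grand mean: regions first, then contrasts).
#'
#' @param effects list of `effect_size_matrix` for one species.
#' @return list of class `species_signature`: `mean_g` (features), `species_id`,
#'   `contrasts_included`.
#' @export
species_signature <- function(effects) {
  if (length(effects) == 0) stop("empty effect-size list")
  ids <- colnames(effects[[1]]$g)
  for (e in effects) if (!identical(colnames(e$g), ids))
    stop("effect matrices share no common catalogue")
  m <- rowMeans(vapply(effects, contrast_mean_effects, numeric(length(ids))))
  structure(list(mean_g = m, species_id = effects[[1]]$species_id,
                 contrasts_included = vapply(effects, `[[`, "", "contrast_id")),
            class = "species_signature")
}

#' Correlate dynamical signatures across contrasts or species
#'
#' Pearson correlations between equal-length signature vectors, with
#' Benjamini-Hochberg adjustment over the upper triangle.
#'
#' @param signatures list of equal-length numeric vectors (>= 3 entries each).
#' @return list: `r` (symmetric, unit diagonal), `p`, `p_adj` (BH over the
#'   upper triangle; matrices with `NA` diagonal).
#' @export
correlate_signatures <- function(signatures) {
  k <- length(signatures)
  stopifnot(k >= 2)
  len <- unique(vapply(signatures, length, integer(1)))
  if (length(len) != 1 || len < 3) stop("signatures must share length >= 3")
  r <- diag(k); p <- matrix(NA_real_, k, k)
  nm <- names(signatures) %||% paste0("S", seq_len(k))
  dimnames(r) <- dimnames(p) <- list(nm, nm)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vi <- signatures[[i]]; vj <- signatures[[j]]
    if (stats::sd(vi) == 0 || stats::sd(vj) == 0) {
      r[i, j] <- r[j, i] <- NaN
    } else {
      ct <- stats::cor.test(vi, vj)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  ut <- upper.tri(p)
  p_adj <- p
  p_adj[ut] <- stats::p.adjust(p[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(r = r, p = p, p_adj = p_adj)
}
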