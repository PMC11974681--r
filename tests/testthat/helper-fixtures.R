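# shared fixtures, built in code

ar1_series <- function(n, phi, seed = 1, sd = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd))
}

# wrap a bare matrix as a recording
as_recording <- function(x, TR = 1, species = "test", condition = "cond",
                         subject = 1L) {
  rownames(x) <- sprintf("R%03d", seq_len(nrow(x)))
  structure(list(x = x, TR = TR, species = species, condition = condition,
                 subject = as.integer(subject), region_labels = rownames(x)),
            class = "regional_ts")
}

# wrap a bare regions x features matrix as a feature matrix
as_feature_matrix <- function(v) {
  rownames(v) <- rownames(v) %||% sprintf("R%03d", seq_len(nrow(v)))
  colnames(v) <- colnames(v) %||% sprintf("f%d", seq_len(ncol(v)))
  structure(list(values = v, feature_ids = colnames(v),
                 region_labels = rownames(v),
                 excluded = rep(FALSE, ncol(v)),
                 provenance = list(species = "test", condition = "c", subject = 1L)),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small five-species spec used by end-to-end tests
small_spec <- function(n_regions = c(12L, 10L, 9L, 9L, 14L),
                       n_timepoints = 300L, seed = 7L, ...) {
  study_spec(default_species_blocks(n_regions = n_regions),
             n_timepoints = n_timepoints, seed = seed, ...)
}
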