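#' The curated feature catalogue
#'
#' Registry of all implemented univariate time-series features, each tagged
#' with one of 18 broad dynamical categories (autocorrelation, correlation,
#' distribution, entropy, forecast, information theory, nonlinear, outliers,
#' preprocessing, scaling, spectrum, stationarity, statistics, surrogate,
#' symbolic, trend, wavelet, other), a reduced-set membership flag (the
#' canonical 22-feature representative subset), the input normalisation mode
#' (`z` = z-score the series first, `raw` = operate on raw values), a minimum
#' series length, and a conditional-exclusion flag for the two reduced-set
#' features known to fail filtering on some data (the acf-timescale feature
#' and the even-binned histogram AMI).
#'
#' @param reduced if `TRUE`, return only the reduced representative set.
#' @return data.frame with columns `feature_id`, `category`,
#'   `in_reduced_set`, `znorm`, `min_n`, `cond_exclude`.
#' @export
feature_catalog <- function(reduced = FALSE) {
  e <- function(id, cat, red, zn, mn, ce = FALSE)
    data.frame(feature_id = id, category = cat, in_reduced_set = red,
               znorm = zn, min_n = mn, cond_exclude = ce,
               stringsAsFactors = FALSE)
  cat <- rbind(
    e("AC_1", "autocorrelation", FALSE, "raw", 12),
    e("AC_2", "autocorrelation", FALSE, "raw", 14),
    e("AC_3", "autocorrelation", FALSE, "raw", 16),
    e("AC_4", "autocorrelation", FALSE, "raw", 18),
    e("AC_5", "autocorrelation", FALSE, "raw", 20),
    e("RM_AMI_1", "information theory", FALSE, "raw", 12),
    e("RM_AMI_2", "information theory", FALSE, "raw", 14),
    e("FC_LocalSimple_mean2_meanabserr", "forecast", FALSE, "raw", 14),
    e("FC_LocalSimple_mean3_meanabserr", "forecast", FALSE, "raw", 16),
    e("FC_LocalSimple_lfit4_meanabserr", "forecast", FALSE, "raw", 18),
    e("DN_HistogramMode_5", "distribution", TRUE, "z", 20),
    e("DN_HistogramMode_10", "distribution", TRUE, "z", 20),
    e("SB_BinaryStats_mean_longstretch1", "symbolic", TRUE, "z", 20),
    e("SB_BinaryStats_diff_longstretch0", "symbolic", TRUE, "z", 20),
    e("DN_OutlierInclude_p_001_mdrmd", "outliers", TRUE, "z", 20),
    e("DN_OutlierInclude_n_001_mdrmd", "outliers", TRUE, "z", 20),
    e("CO_f1ecac", "autocorrelation", TRUE, "z", 20, TRUE),
    e("CO_FirstMin_ac", "autocorrelation", TRUE, "z", 20),
    e("SP_Summaries_welch_rect_area_5_1", "spectrum", TRUE, "z", 20),
    e("SP_Summaries_welch_rect_centroid", "spectrum", TRUE, "z", 20),
    e("FC_LocalSimple_mean3_stderr", "forecast", TRUE, "z", 16),
    e("FC_LocalSimple_mean1_tauresrat", "forecast", TRUE, "z", 20),
    e("CO_trev_1_num", "nonlinear", TRUE, "z", 12),
    e("CO_HistogramAMI_even_2_5", "information theory", TRUE, "z", 20, TRUE),
    e("IN_AutoMutualInfoStats_40_gaussian_fmmi", "information theory", TRUE, "z", 30),
    e("MD_hrv_classic_pnn40", "other", TRUE, "z", 12),
    e("SB_MotifThree_quantile_hh", "symbolic", TRUE, "z", 20),
    e("CO_Embed2_Dist_tau_d_expfit_meandiff", "nonlinear", TRUE, "z", 30),
    e("SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1", "scaling", TRUE, "z", 30),
    e("SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1", "scaling", TRUE, "z", 30),
    e("SB_TransitionMatrix_3ac_sumdiagcov", "symbolic", TRUE, "z", 30),
    e("PD_PeriodicityWang_th0_01", "other", TRUE, "z", 30))
  stopifnot(!anyDuplicated(cat$feature_id),
            all(cat$category %in% feature_categories()))
  if (reduced) cat <- cat[cat$in_reduced_set, ]
  rownames(cat) <- NULL
  cat
}

#' The 18 broad feature categories
#' @return character vector.
#' @export
feature_categories <- function() {
  c("autocorrelation", "correlation", "distribution", "entropy", "forecast",
    "information theory", "nonlinear", "outliers", "preprocessing", "scaling",
    "spectrum", "stationarity", "statistics", "surrogate", "symbolic",
    "trend", "wavelet", "other")
}

.dynphen_cache <- new.env(parent = emptyenv())

cached_catalog <- function() {
  if (is.null(.dynphen_cache$catalog)) .dynphen_cache$catalog <- feature_catalog()
  .dynphen_cache$catalog
}

feature_fun <- function(feature_id) {
  switch(feature_id,
    AC_1 = function(x) lag_cor(x, 1),
    AC_2 = function(x) lag_cor(x, 2),
    AC_3 = function(x) lag_cor(x, 3),
    AC_4 = function(x) lag_cor(x, 4),
    AC_5 = function(x) lag_cor(x, 5),
    RM_AMI_1 = function(x) ami_gaussian(x, 1),
    RM_AMI_2 = function(x) ami_gaussian(x, 2),
    FC_LocalSimple_mean2_meanabserr = function(x) mean(abs(local_mean_forecast_res(x, 2))),
    FC_LocalSimple_mean3_meanabserr = function(x) mean(abs(local_mean_forecast_res(x, 3))),
    FC_LocalSimple_lfit4_meanabserr = function(x) mean(abs(local_lfit_forecast_res(x, 4))),
    DN_HistogramMode_5 = function(x) histogram_mode(x, 5),
    DN_HistogramMode_10 = function(x) histogram_mode(x, 10),
    SB_BinaryStats_mean_longstretch1 = sb_binarystats_mean_longstretch1,
    SB_BinaryStats_diff_longstretch0 = sb_binarystats_diff_longstretch0,
    DN_OutlierInclude_p_001_mdrmd = function(x) outlier_include_mdrmd(x, 1),
    DN_OutlierInclude_n_001_mdrmd = function(x) outlier_include_mdrmd(x, -1),
    CO_f1ecac = co_f1ecac,
    CO_FirstMin_ac = co_firstmin_ac,
    SP_Summaries_welch_rect_area_5_1 = sp_area_5_1,
    SP_Summaries_welch_rect_centroid = sp_centroid,
    FC_LocalSimple_mean3_stderr = function(x) stats::sd(local_mean_forecast_res(x, 3)),
    FC_LocalSimple_mean1_tauresrat = function(x) {
      res <- local_mean_forecast_res(x, 1)
      first_zero_ac(res) / first_zero_ac(x)
    },
    CO_trev_1_num = co_trev_1_num,
    CO_HistogramAMI_even_2_5 = co_histogram_ami_even_2_5,
    IN_AutoMutualInfoStats_40_gaussian_fmmi = in_ami_fmmi,
    MD_hrv_classic_pnn40 = md_pnn40,
    SB_MotifThree_quantile_hh = sb_motifthree_quantile_hh,
    CO_Embed2_Dist_tau_d_expfit_meandiff = co_embed2_dist_expfit_meandiff,
    SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1 = sc_fluct_dfa,
    SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1 = sc_fluct_rsrange,
    SB_TransitionMatrix_3ac_sumdiagcov = sb_transition_matrix_3ac_sumdiagcov,
    PD_PeriodicityWang_th0_01 = pd_periodicity_wang,
    stop("unknown feature_id: ", feature_id))
}

#' Compute one feature of one series
#'
#' Applies the catalogue's input-normalisation convention (z-score for the
#' representative-set features, raw values for autocorrelations and forecast
#' errors) and the minimum-length rule; degenerate inputs return `NaN` rather
#' than raising, so the study-level filtering rules can act on them.
#'
#' @param x numeric vector.
#' @param feature_id a catalogue feature id.
#' @return a single numeric value (possibly `NaN`).
#' @export
compute_feature <- function(x, feature_id) {
  cat <- cached_catalog()
  row <- cat[cat$feature_id == feature_id, ]
  if (nrow(row) == 0) stop("unknown feature_id: ", feature_id)
  x <- as.numeric(x)
  if (length(x) < row$min_n || !all(is.finite(x))) return(NaN)
  if (stats::sd(x) == 0) return(NaN)
  if (row$znorm == "z") x <- zscore(x)
  val <- tryCatch(feature_fun(feature_id)(x), error = function(e) NaN)
  if (length(val) != 1 || !is.numeric(val)) NaN else as.numeric(val)
}

#' Extract the regions-by-features matrix of one recording
#'
#' One row per region. Features that are non-finite for every region, or
#' constant across regions, are flagged as excluded at study level (the
#' pre-filtering rule); flagged values are retained in the matrix so callers
#' can audit them.
#'
#' @param ts a `regional_ts`.
#' @param catalog a [feature_catalog()] (or subset).
#' @return object of class `feature_matrix`: `values`, `feature_ids`,
#'   `region_labels`, `excluded` (logical per feature), `provenance`.
#' @export
extract_feature_matrix <- function(ts, catalog = feature_catalog()) {
  stopifnot(inherits(ts, "regional_ts"), nrow(ts$x) >= 2)
  if (nrow(catalog) == 0) stop("empty feature catalog")
  vals <- matrix(NA_real_, nrow(ts$x), nrow(catalog),
                 dimnames = list(ts$region_labels, catalog$feature_id))
  funs <- lapply(catalog$feature_id, feature_fun)
  for (i in seq_len(nrow(ts$x))) {
    x <- as.numeric(ts$x[i, ])
    degenerate <- !all(is.finite(x)) || stats::sd(x) == 0
    z <- if (degenerate) NULL else zscore(x)
    for (j in seq_len(nrow(catalog))) {
      if (degenerate || length(x) < catalog$min_n[j]) {
        vals[i, j] <- NaN
      } else {
        inp <- if (catalog$znorm[j] == "z") z else x
        v <- tryCatch(funs[[j]](inp), error = function(e) NaN)
        vals[i, j] <- if (length(v) == 1 && is.numeric(v)) as.numeric(v) else NaN
      }
    }
  }
  finite_cols <- colSums(is.finite(vals)) > 0
  const_cols <- apply(vals, 2, function(v) {
    f <- v[is.finite(v)]
    length(f) > 0 && stats::sd(f) == 0
  })
  structure(list(values = vals, feature_ids = catalog$feature_id,
                 region_labels = ts$region_labels,
                 excluded = !finite_cols | const_cols,
                 provenance = list(species = ts$species,
                                   condition = ts$condition,
                                   subject = ts$subject)),
            class = "feature_matrix")
}
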