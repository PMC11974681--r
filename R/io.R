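# TSV / JSON plumbing. All tabular output is TSV with header rows; matrices
# carry region labels so joins are label-checked, never positional.

#' Write a regional recording as TSV (one row per region, columns timepoints)
#' @param ts a `regional_ts`.
#' @param path output file.
#' @export
write_recording_tsv <- function(ts, path) {
  df <- data.frame(region = ts$region_labels, ts$x, check.names = FALSE)
  colnames(df) <- c("region", sprintf("t%d", seq_len(ncol(ts$x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regional recording written by [write_recording_tsv()]
#' @param path TSV file.
#' @param TR sampling interval (s).
#' @param species,condition,subject provenance labels.
#' @return a `regional_ts`.
#' @export
read_recording_tsv <- function(path, TR, species = "unknown",
                               condition = "unknown", subject = 1L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  structure(list(x = x, TR = TR, species = species, condition = condition,
                 subject = as.integer(subject), region_labels = df[[1]]),
            class = "regional_ts")
}

#' Write a labelled numeric matrix as TSV
#' @param m matrix with dimnames.
#' @param path output file.
#' @param rowname_col name for the first (label) column.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "region") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), m, check.names = FALSE)
  colnames(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_tsv()]
#' @param path TSV file.
#' @return numeric matrix with row labels from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a synthetic study to disk (recordings, coordinates, expression,
#' connectome, JSON manifest)
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (sp in names(study$recordings)) {
    for (cond in names(study$recordings[[sp]])) {
      for (s in seq_along(study$recordings[[sp]][[cond]])) {
        f <- file.path(dir, sprintf("ts_%s_%s_s%02d.tsv", sp, cond, s))
        write_recording_tsv(study$recordings[[sp]][[cond]][[s]], f)
        files[[length(files) + 1]] <-
          list(species = sp, condition = cond, subject = s, path = basename(f))
      }
    }
    cm <- study$coords[[sp]]
    rownames(cm) <- sprintf("R%03d", seq_len(nrow(cm)))
    colnames(cm) <- c("x", "y", "z")
    write_matrix_tsv(cm, file.path(dir, sprintf("coords_%s.tsv", sp)))
    write_matrix_tsv(study$expression[[sp]]$expression,
                     file.path(dir, sprintf("expression_%s.tsv", sp)))
  }
  write_matrix_tsv(study$connectome$C, file.path(dir, "connectome.tsv"))
  manifest <- list(TR = study$spec$TR, seed = study$spec$seed,
                   orientation = "rows=regions, columns=timepoints",
                   contrasts = study$manifest, recordings = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mp)
}
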