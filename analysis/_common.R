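# Shared setup for the numbered analysis drivers. Each script is a thin
# narrative wrapper over the package; all heavy lifting lives in R/.
#
# The study conditions (phi, kappa, contrast structure, subjects, factor
# count) are the package defaults and are never changed here. Region counts
# and recording length are scaled down from the full-size defaults
# (100/82/70/72/120 regions, 500 timepoints) so the whole chain runs in a few
# minutes on one CPU; the scaling is a runtime choice, not a scientific one.

suppressMessages(library(dynphen))

results_dir <- file.path("results")
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

master_seed <- 7L
analysis_spec <- study_spec(
  default_species_blocks(n_regions = c(40L, 33L, 28L, 29L, 48L)),
  n_timepoints = 300L, seed = master_seed)

reduced_catalog <- feature_catalog(reduced = TRUE)
full_catalog <- feature_catalog()

# deterministic: every script rebuilds the same study from the spec
build_study <- function() make_multispecies_study(analysis_spec)

msg <- function(...) cat(sprintf(...), "\n")
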