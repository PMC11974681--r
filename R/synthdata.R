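#' Default species blocks for a synthetic multi-species study
#'
#' Mirrors the layout of a five-species anaesthesia study: region counts
#' 100/82/70/72/120, contrast multiplicities 2/6/3/2/1 (14 awake-vs-anaesthesia
#' contrasts in total), paired designs everywhere except the mouse-like block.
#'
#' @param n_regions integer vector of regions (neurons for the nematode-like
#'   block) per species.
#' @param n_subjects integer vector (recycled) of subjects per condition.
#' @param n_contrasts integer vector of contrasts per species.
#' @param paired logical vector: does the block reuse subjects across
#'   conditions (within-subject design)?
#' @return list of block descriptors consumed by [study_spec()].
#' @export
default_species_blocks <- function(n_regions = c(100L, 82L, 70L, 72L, 120L),
                                   n_subjects = 10L,
                                   n_contrasts = c(2L, 6L, 3L, 2L, 1L),
                                   paired = c(TRUE, TRUE, TRUE, FALSE, TRUE)) {
  species <- c("human", "macaque", "marmoset", "mouse", "nematode")[seq_along(n_regions)]
  if (length(n_regions) > 5) species <- paste0("species", seq_along(n_regions))
  n_subjects <- rep_len(n_subjects, length(n_regions))
  n_contrasts <- rep_len(n_contrasts, length(n_regions))
  paired <- rep_len(paired, length(n_regions))
  mapply(function(sp, nr, ns, nc, pr) {
    list(species_id = sp, n_regions = as.integer(nr), n_subjects = as.integer(ns),
         paired = pr,
         contrasts = lapply(seq_len(nc), function(j) {
           c(awake = sprintf("awake%d", j), anaes = sprintf("anaes%d", j))
         }))
  }, species, n_regions, n_subjects, n_contrasts, paired, SIMPLIFY = FALSE)
}

#' Specify a synthetic multi-species anaesthesia study
#'
#' The generator family is a first-order autoregressive process per region,
#' driven by shared latent factors:
#' \deqn{x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\,(\kappa \sum_p L_{np} z_{p,t} + \epsilon_t)}
#' \eqn{\phi} sets the intrinsic timescale axis and \eqn{\kappa} the synchrony
#' axis; anaesthesia lowers both. The \eqn{\sqrt{1-\phi^2}} innovation
#' scaling keeps the stationary variance independent of \eqn{\phi}, so a
#' timescale change is not confounded with an amplitude change: lowering
#' \eqn{\phi} then raises short-horizon forecast errors (faster, less
#' predictable dynamics) instead of merely shrinking the signal. A smooth spatial gradient map per species
#' modulates \eqn{\phi} regionally (amplitude `gradient_amp`) so that regions
#' with longer awake timescales also show larger anaesthetic drops, and the
#' same map is used to plant the gene-expression association.
#'
#' @param species_blocks see [default_species_blocks()].
#' @param n_timepoints samples per recording.
#' @param TR sampling interval, seconds.
#' @param phi_awake,phi_anaes lag-1 autocorrelation targets in `[0, 1)`.
#' @param kappa_awake,kappa_anaes inter-regional coupling strengths (>= 0).
#' @param noise_sd innovation standard deviation.
#' @param n_factors number of shared latent factors.
#' @param gradient_amp amplitude of the regional phi gradient (0 disables).
#' @param n_genes genes per species expression matrix.
#' @param seed master seed; every sub-generator derives its own stream.
#' @return object of class `study_spec`.
#' @export
study_spec <- function(species_blocks = default_species_blocks(),
                       n_timepoints = 500L, TR = 1,
                       phi_awake = 0.8, phi_anaes = 0.4,
                       kappa_awake = 0.6, kappa_anaes = 0.1,
                       noise_sd = 1, n_factors = 3L,
                       gradient_amp = 0.15, n_genes = 81L, seed = 1L) {
  stopifnot(length(species_blocks) >= 1, n_timepoints >= 50,
            TR > 0, noise_sd > 0, n_factors >= 1,
            kappa_awake >= 0, kappa_anaes >= 0)
  for (phi in c(phi_awake, phi_anaes))
    if (phi < 0 || phi >= 1) stop("phi values must lie in [0, 1): nonstationary otherwise")
  if (gradient_amp < 0) stop("gradient_amp must be >= 0")
  spec <- list(species_blocks = species_blocks,
               n_timepoints = as.integer(n_timepoints), TR = TR,
               phi_awake = phi_awake, phi_anaes = phi_anaes,
               kappa_awake = kappa_awake, kappa_anaes = kappa_anaes,
               noise_sd = noise_sd, n_factors = as.integer(n_factors),
               gradient_amp = gradient_amp, n_genes = as.integer(n_genes),
               seed = as.integer(seed))
  class(spec) <- "study_spec"
  spec
}

n_contrasts_total <- function(spec) {
  sum(vapply(spec$species_blocks, function(b) length(b$contrasts), integer(1)))
}

spec_block <- function(spec, species) {
  for (b in spec$species_blocks) if (b$species_id == species) return(b)
  stop("unknown species: ", species)
}

#' Uniform random coordinates in the unit sphere
#' @param n_regions number of points.
#' @param seed integer seed.
#' @return `n_regions` x 3 matrix.
#' @export
make_region_coords <- function(n_regions, seed = 1L) {
  with_seed(seed, {
    pts <- matrix(rnorm(3 * n_regions), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2))
    pts * runif(n_regions)^(1 / 3)
  })
}

# smooth zero-mean Gaussian field(s) over coords, covariance exp(-d / scale)
gaussian_field <- function(coords, scale, n_fields = 1L, seed = 1L) {
  n <- nrow(coords)
  z <- with_seed(seed, matrix(rnorm(n * n_fields), n, n_fields))
  if (scale <= 0) return(z)
  d <- as.matrix(stats::dist(coords))
  K <- exp(-d / scale)
  L <- chol(K + diag(1e-8, n))
  t(L) %*% z
}

bfs_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Generate a distance-dependent weighted connectome
#'
#' Edges are drawn without replacement with probability decaying exponentially
#' in Euclidean distance, until the requested edge density is reached exactly
#' (up to rounding). Weights decay with distance with multiplicative
#' log-normal scatter, emulating streamline-count connectomes. The default
#' density of 0.27 follows typical consensus tractography densities, and
#' weights are normalised to a maximum of 0.2, the scaling convention of
#' whole-brain mean-field modelling (it places the usual global-coupling
#' range G of roughly 1-2.5 in the model's stable operating regime).
#'
#' @param n_regions number of regions.
#' @param coords optional `n_regions` x 3 coordinates; generated if `NULL`.
#' @param density target edge density in (0, 1].
#' @param seed integer seed.
#' @param decay_scale distance scale of the edge-probability decay; defaults
#'   to the mean pairwise distance.
#' @return list of class `connectome`: `C` (symmetric non-negative, zero
#'   diagonal), `coords`, `density` (realised), `labels`.
#' @export
make_connectome <- function(n_regions, coords = NULL, density = 0.27,
                            seed = 1L, decay_scale = NULL) {
  stopifnot(n_regions >= 2, density > 0, density <= 1)
  if (is.null(coords)) coords <- make_region_coords(n_regions, child_seed(seed, "coords"))
  if (nrow(coords) != n_regions) stop("coords must have n_regions rows")
  d <- as.matrix(stats::dist(coords))
  ut <- which(upper.tri(d))
  m <- max(1L, round(density * length(ut)))
  if (is.null(decay_scale)) decay_scale <- mean(d[ut])
  C <- matrix(0, n_regions, n_regions)
  with_seed(child_seed(seed, "edges"), {
    keep <- if (m >= length(ut)) ut else
      sample(ut, m, prob = exp(-d[ut] / decay_scale))
    w <- exp(-d[keep] / decay_scale) * exp(rnorm(length(keep), 0, 1))
    C[keep] <- 0.2 * w / max(w)
  })
  C <- C + t(C)
  if (!bfs_connected(C))
    stop("connectome generation failure: density ", density,
         " left the graph disconnected (largest component < n_regions)")
  labels <- sprintf("R%03d", seq_len(n_regions))
  dimnames(C) <- list(labels, labels)
  structure(list(C = C, coords = coords, labels = labels,
                 density = m / length(ut)),
            class = "connectome")
}

# species-level fixed structure: factor loadings and the phi gradient map
species_structure <- function(spec, species) {
  b <- spec_block(spec, species)
  n <- b$n_regions
  coords <- make_region_coords(n, child_seed(spec$seed, species, "coords"))
  L <- with_seed(child_seed(spec$seed, species, "loadings"),
                 matrix(runif(n * spec$n_factors, 0.5, 1.5), n) / sqrt(spec$n_factors))
  u <- drop(gaussian_field(coords, 0.5, 1L, child_seed(spec$seed, species, "gradient")))
  u <- u - mean(u)
  u <- u / (2 * max(abs(u)))           # in [-0.5, 0.5]
  list(block = b, coords = coords, loadings = L, gradient = u)
}

condition_phi_kappa <- function(spec, species, condition) {
  b <- spec_block(spec, species)
  aw <- vapply(b$contrasts, `[[`, "", "awake")
  an <- vapply(b$contrasts, `[[`, "", "anaes")
  if (condition %in% aw) list(phi = spec$phi_awake, kappa = spec$kappa_awake, awake = TRUE)
  else if (condition %in% an) list(phi = spec$phi_anaes, kappa = spec$kappa_anaes, awake = FALSE)
  else stop("condition '", condition, "' is not a label of species ", species)
}

#' Generate one regional recording
#'
#' @param spec a [study_spec()].
#' @param species species id from the spec.
#' @param condition an awake or anaesthesia label of that species.
#' @param subject subject index (seeds the recording stream).
#' @param seed optional explicit seed; defaults to a stream derived from the
#'   spec seed, species, condition and subject.
#' @return object of class `regional_ts`: `x` (regions x timepoints), `TR`,
#'   `species`, `condition`, `subject`, `region_labels`.
#' @export
make_regional_timeseries <- function(spec, species, condition, subject = 1L,
                                     seed = NULL) {
  st <- species_structure(spec, species)
  ck <- condition_phi_kappa(spec, species, condition)
  n <- st$block$n_regions
  Tn <- spec$n_timepoints
  amp <- spec$gradient_amp
  # regions with larger gradient: higher awake phi, larger anaesthetic drop
  phi <- if (ck$awake) ck$phi + amp * st$gradient else ck$phi - amp * st$gradient
  phi <- pmin(pmax(phi, 0), 0.97)
  seed <- seed %||% child_seed(spec$seed, species, condition, subject)
  burn <- 100L
  x <- with_seed(seed, {
    z <- matrix(rnorm(spec$n_factors * (Tn + burn)), spec$n_factors)
    eps <- matrix(rnorm(n * (Tn + burn), 0, spec$noise_sd), n)
    drive <- (ck$kappa * (st$loadings %*% z) + eps) * sqrt(1 - phi^2)
    out <- matrix(0, n, Tn + burn)
    out[, 1] <- drive[, 1]
    for (t in 2:(Tn + burn)) out[, t] <- phi * out[, t - 1] + drive[, t]
    out[, (burn + 1):(Tn + burn), drop = FALSE]
  })
  rownames(x) <- sprintf("R%03d", seq_len(n))
  structure(list(x = x, TR = spec$TR, species = species, condition = condition,
                 subject = as.integer(subject),
                 region_labels = rownames(x)),
            class = "regional_ts")
}

# scaled outlier-robust sigmoid, mapping a column into [0, 1]
robust_sigmoid <- function(x) {
  s <- stats::IQR(x) / 1.349
  if (!is.finite(s) || s == 0) s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0.5, length(x)))
  y <- 1 / (1 + exp(-(x - stats::median(x)) / s))
  (y - min(y)) / (max(y) - min(y))
}

#' Generate spatially autocorrelated gene-expression maps
#'
#' Each gene is an optional planted linear term in a supplied regional map
#' plus a smooth Gaussian random field, sigmoid-normalised into `[0, 1]`
#' column-wise (outlier-robust sigmoid). Positive `smoothness` gives each
#' column positive spatial autocorrelation (Moran's I) under inverse-distance
#' weights, which is what makes spatially-naive significance tests misleading
#' and the Moran-preserving null non-trivial.
#'
#' @param coords regions x 3 coordinates.
#' @param n_genes number of gene columns.
#' @param planted_map optional regional vector carrying the planted signal.
#' @param planted_gene_weights optional per-gene weights on `planted_map`.
#' @param smoothness spatial correlation length of the noise field (0 = iid).
#' @param noise_sd standard deviation of the noise field.
#' @param seed integer seed.
#' @return list: `expression` (regions x genes in `[0,1]`), `truth`
#'   (planted map and weights).
#' @export
make_expression_maps <- function(coords, n_genes, planted_map = NULL,
                                 planted_gene_weights = NULL,
                                 smoothness = 0.5, noise_sd = 1, seed = 1L) {
  n <- nrow(coords)
  if (!is.null(planted_map) && length(planted_map) != n)
    stop("planted_map length must equal nrow(coords)")
  if (is.null(planted_gene_weights) && !is.null(planted_map))
    planted_gene_weights <- rep(1, n_genes)
  noise <- gaussian_field(coords, smoothness, n_genes, child_seed(seed, "exprnoise")) * noise_sd
  E <- noise
  if (!is.null(planted_map)) {
    pm <- (planted_map - mean(planted_map)) / stats::sd(planted_map)
    E <- E + pm %o% planted_gene_weights
  }
  E <- apply(E, 2, robust_sigmoid)
  dimnames(E) <- list(sprintf("R%03d", seq_len(n)), sprintf("gene%03d", seq_len(n_genes)))
  list(expression = E,
       truth = list(planted_map = planted_map, gene_weights = planted_gene_weights))
}

#' Expected direction of anaesthetic change for generator-sensitive features
#'
#' When anaesthesia lowers the lag-1 autocorrelation phi, autocorrelation-type
#' features fall and short-horizon forecast errors rise (faster, less
#' predictable dynamics). Returns the planted signs, coded anaesthesia minus
#' awake.
#' @return named numeric vector of +1/-1.
#' @export
planted_feature_signs <- function() {
  c(AC_1 = -1, AC_2 = -1, AC_3 = -1, AC_4 = -1, AC_5 = -1,
    RM_AMI_1 = -1, RM_AMI_2 = -1, CO_f1ecac = -1,
    FC_LocalSimple_mean2_meanabserr = 1,
    FC_LocalSimple_mean3_meanabserr = 1,
    FC_LocalSimple_lfit4_meanabserr = 1,
    FC_LocalSimple_mean3_stderr = 1)
}

#' Assemble a complete synthetic multi-species study
#'
#' Generates every recording for every contrast of every species block, plus
#' coordinates, planted gene-expression maps, a connectome (first block's
#' coordinates, 27% density), and the ground-truth record.
#'
#' @param spec a [study_spec()].
#' @return object of class `synthetic_study` with elements `spec`,
#'   `recordings` (nested: species / condition / subject), `manifest`
#'   (data.frame of contrasts), `coords`, `expression`, `connectome`, `truth`.
#' @export
make_multispecies_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  recordings <- list(); coords <- list(); expression <- list()
  gradient_maps <- list()
  manifest <- NULL
  for (b in spec$species_blocks) {
    sp <- b$species_id
    st <- species_structure(spec, sp)
    coords[[sp]] <- st$coords
    gradient_maps[[sp]] <- st$gradient
    recordings[[sp]] <- list()
    for (j in seq_along(b$contrasts)) {
      pair <- b$contrasts[[j]]
      for (cond in pair) {
        recordings[[sp]][[cond]] <- lapply(seq_len(b$n_subjects), function(s)
          make_regional_timeseries(spec, sp, cond, subject = s))
      }
      manifest <- rbind(manifest, data.frame(
        species = sp, contrast_id = sprintf("%s_c%d", sp, j),
        awake = pair[["awake"]], anaes = pair[["anaes"]],
        paired = b$paired, n_subjects = b$n_subjects,
        stringsAsFactors = FALSE))
    }
    wts <- with_seed(child_seed(spec$seed, sp, "geneweights"),
                     runif(spec$n_genes, -1, 1))
    expression[[sp]] <- make_expression_maps(
      st$coords, spec$n_genes,
      planted_map = if (spec$gradient_amp > 0) st$gradient else NULL,
      planted_gene_weights = if (spec$gradient_amp > 0) wts else NULL,
      smoothness = 0.5, noise_sd = 1,
      seed = child_seed(spec$seed, sp, "expr"))
  }
  connectome <- make_connectome(spec$species_blocks[[1]]$n_regions,
                                coords = coords[[spec$species_blocks[[1]]$species_id]],
                                density = 0.27,
                                seed = child_seed(spec$seed, "connectome"))
  structure(list(spec = spec, recordings = recordings, manifest = manifest,
                 coords = coords, expression = expression,
                 connectome = connectome,
                 truth = list(feature_signs = planted_feature_signs(),
                              gradient_maps = gradient_maps)),
            class = "synthetic_study")
}
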