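#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every knob of the planted-truth simulator emulating a two-genotype
#' (heat-tolerant vs heat-sensitive) by three-temperature (25/30/35 degC)
#' design: six metabolome replicates and three transcriptome replicates per
#' cell, log-normal metabolite abundances with temperature-responsive marker
#' features, and negative-binomial gene counts organised into co-expressed
#' modules whose latent factors drive designated metabolite "traits".
#'
#' Temperature is encoded as an ordinal dose (25 -> 0, 30 -> 1, 35 -> 2) and
#' marker features respond linearly on the log2 scale: a shared marker gains
#' `marker_effect` log2 units per temperature step in both genotypes, a
#' genotype-specific marker only in its own genotype.
#'
#' @param n_features_metabolome number of metabolite features.
#' @param n_genes number of genes.
#' @param n_reps_metabolome metabolome replicates per genotype x temperature.
#' @param n_reps_transcriptome transcriptome replicates per genotype x
#'   temperature.
#' @param n_shared_markers markers responding in both genotypes.
#' @param n_specific_markers markers responding in exactly one genotype
#'   (this many per genotype).
#' @param marker_effect log2-fold-change per temperature step (>= 0). A
#'   scalar gives every marker the same effect; a vector is recycled over
#'   each marker set, planting graded effect sizes.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of length `n_modules`; gene counts per
#'   module, summing to at most `n_genes`.
#' @param module_trait_r target Pearson correlation between each module's
#'   latent factor and its designated metabolite trait (|r| < 1). Recycled to
#'   `n_modules`.
#' @param module_temp_weight fraction (on the correlation scale, in [0, 1))
#'   of each latent factor carried by the ordinal temperature dose; the rest
#'   is sample-level noise. A non-zero weight makes module genes genuinely
#'   temperature-responsive, so the differential-expression stage has planted
#'   signal too.
#' @param noise_sd log2-scale residual standard deviation (both omics).
#' @param nb_dispersion negative-binomial dispersion of gene counts
#'   (variance = mu + dispersion * mu^2).
#' @param baseline_log2_mean,baseline_log2_sd metabolite baseline location
#'   spread on the log2 scale.
#' @param gene_log2_mean,gene_log2_sd gene baseline location spread (log2).
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_features_metabolome = 500,
                       n_genes = 1000,
                       n_reps_metabolome = 6,
                       n_reps_transcriptome = 3,
                       n_shared_markers = 10,
                       n_specific_markers = 5,
                       marker_effect = 2.0,
                       n_modules = 4,
                       module_sizes = c(60, 80, 100, 120),
                       module_trait_r = 0.7,
                       module_temp_weight = 0.5,
                       noise_sd = 0.5,
                       nb_dispersion = 0.1,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       gene_log2_mean = 7,
                       gene_log2_sd = 1.5,
                       seed = 1L) {
  cfg <- list(n_features_metabolome = as.integer(n_features_metabolome),
              n_genes = as.integer(n_genes),
              n_reps_metabolome = as.integer(n_reps_metabolome),
              n_reps_transcriptome = as.integer(n_reps_transcriptome),
              n_shared_markers = as.integer(n_shared_markers),
              n_specific_markers = as.integer(n_specific_markers),
              marker_effect = marker_effect,
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              module_trait_r = rep_len(module_trait_r, n_modules),
              module_temp_weight = module_temp_weight,
              noise_sd = noise_sd,
              nb_dispersion = nb_dispersion,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              gene_log2_mean = gene_log2_mean,
              gene_log2_sd = gene_log2_sd,
              seed = as.integer(seed))
  counts <- c("n_features_metabolome", "n_genes", "n_reps_metabolome",
              "n_reps_transcriptome", "n_modules")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("`", nm, "` must be a positive count")
  if (cfg$n_shared_markers < 0L || cfg$n_specific_markers < 0L)
    stop("marker counts must be non-negative")
  if (any(cfg$marker_effect < 0))
    stop("`marker_effect` must be >= 0")
  n_marked <- cfg$n_shared_markers + 2L * cfg$n_specific_markers + cfg$n_modules
  if (n_marked > cfg$n_features_metabolome)
    stop("marker + trait feature counts exceed n_features_metabolome")
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("`module_sizes` must have length n_modules")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (any(abs(cfg$module_trait_r) >= 1))
    stop("|module_trait_r| must be < 1")
  if (cfg$module_temp_weight < 0 || cfg$module_temp_weight >= 1)
    stop("`module_temp_weight` must lie in [0, 1)")
  if (cfg$noise_sd <= 0 || cfg$nb_dispersion <= 0)
    stop("`noise_sd` and `nb_dispersion` must be positive")
  class(cfg) <- "sim_config"
  cfg
}

GENOTYPES <- c("sensitive", "tolerant")
TEMPERATURES <- c(25L, 30L, 35L)

# Full-factorial sample sheet for one omics layer.
design_table <- function(n_reps, prefix) {
  md <- expand.grid(replicate = seq_len(n_reps),
                    temperature_C = TEMPERATURES,
                    genotype = GENOTYPES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md <- md[, c("genotype", "temperature_C", "replicate")]
  md$sample_id <- sprintf("%s_%s_T%d_r%d", prefix, md$genotype,
                          md$temperature_C, md$replicate)
  md[, c("sample_id", "genotype", "temperature_C", "replicate")]
}

temperature_dose <- function(temperature_C) {
  match(temperature_C, TEMPERATURES) - 1L
}

#' Generate a metabolome matrix with planted markers and traits
#'
#' Draws log-normal abundances for `n_features_metabolome` features over the
#' full genotype x temperature x replicate design. Shared markers shift by
#' `marker_effect` log2 units per temperature step in both genotypes;
#' genotype-specific markers shift only in their genotype; `n_modules`
#' designated "trait" metabolites are constructed jointly with the module
#' latent factors (bivariate-normal construction) so that their abundance
#' correlates with the matching factor at the configured `module_trait_r`;
#' every other feature is exchangeable noise.
#'
#' The returned truth object also fixes the transcriptome-side module
#' memberships and per-sample latent factors, so that
#' [simulate_transcriptome()] can plant the matching co-expression structure.
#'
#' @param config a [sim_config()].
#' @return A list with elements `metabolome` (an [omics_matrix()]) and
#'   `truth` (class `synthetic_truth`: marker id sets, module membership,
#'   latent factors, trait assignments).
#' @export
simulate_metabolome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_features_metabolome
  feature_ids <- sprintf("met_%04d", seq_len(p))
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))

  md <- design_table(config$n_reps_metabolome, "M")
  n <- nrow(md)
  dose <- temperature_dose(md$temperature_C)

  ## disjoint special feature sets: shared, per-genotype, trait carriers
  n_special <- config$n_shared_markers + 2L * config$n_specific_markers +
    config$n_modules
  special <- sample(feature_ids, n_special)
  idx <- 0L
  take <- function(k) {
    out <- special[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  shared_ids <- take(config$n_shared_markers)
  sensitive_ids <- take(config$n_specific_markers)
  tolerant_ids <- take(config$n_specific_markers)
  trait_ids <- take(config$n_modules)

  baseline <- stats::rnorm(p, config$baseline_log2_mean, config$baseline_log2_sd)
  names(baseline) <- feature_ids
  log2v <- matrix(baseline, nrow = p, ncol = n,
                  dimnames = list(feature_ids, md$sample_id))
  log2v <- log2v + matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)

  eff_shared <- rep_len(config$marker_effect, length(shared_ids))
  log2v[shared_ids, ] <- log2v[shared_ids, , drop = FALSE] +
    outer(eff_shared, dose)
  for (g in GENOTYPES) {
    ids <- if (g == "sensitive") sensitive_ids else tolerant_ids
    in_g <- md$genotype == g
    log2v[ids, in_g] <- log2v[ids, in_g, drop = FALSE] +
      outer(rep_len(config$marker_effect, length(ids)), dose[in_g])
  }

  ## transcriptome-side design, latent factors, module membership
  md_t <- design_table(config$n_reps_transcriptome, "T")
  dose_t <- temperature_dose(md_t$temperature_C)
  w <- config$module_temp_weight
  dose_std <- as.numeric(scale(dose_t))
  factors <- matrix(0, config$n_modules, nrow(md_t),
                    dimnames = list(sprintf("module_%d", seq_len(config$n_modules)),
                                    md_t$sample_id))
  for (m in seq_len(config$n_modules)) {
    z <- as.numeric(scale(stats::rnorm(nrow(md_t))))
    factors[m, ] <- w * dose_std + sqrt(1 - w^2) * z
  }

  membership <- integer(config$n_genes)
  names(membership) <- gene_ids
  pool <- sample(gene_ids, sum(config$module_sizes))
  off <- 0L
  for (m in seq_len(config$n_modules)) {
    membership[pool[off + seq_len(config$module_sizes[m])]] <- m
    off <- off + config$module_sizes[m]
  }

  ## trait metabolites: aligned replicates follow the factor at target r,
  ## surplus replicates are exchangeable noise at the same marginal scale
  trait_assignments <- data.frame(feature_id = trait_ids,
                                  module = seq_len(config$n_modules),
                                  target_r = config$module_trait_r,
                                  stringsAsFactors = FALSE)
  aligned <- md$replicate <= config$n_reps_transcriptome
  key_m <- paste(md$genotype, md$temperature_C, md$replicate)
  key_t <- paste(md_t$genotype, md_t$temperature_C, md_t$replicate)
  map <- match(key_m[aligned], key_t)
  for (m in seq_len(config$n_modules)) {
    r <- config$module_trait_r[m]
    f_std <- as.numeric(scale(factors[m, map]))
    z <- as.numeric(scale(stats::rnorm(sum(aligned))))
    z <- as.numeric(scale(stats::lm.fit(cbind(1, f_std), z)$residuals))
    tr <- baseline[trait_ids[m]] +
      config$noise_sd * (r * f_std + sqrt(1 - r^2) * z)
    log2v[trait_ids[m], aligned] <- tr
    log2v[trait_ids[m], !aligned] <-
      baseline[trait_ids[m]] + stats::rnorm(sum(!aligned), 0, config$noise_sd)
  }

  truth <- structure(list(shared_marker_ids = sort(shared_ids),
                          sensitive_marker_ids = sort(sensitive_ids),
                          tolerant_marker_ids = sort(tolerant_ids),
                          module_membership = membership,
                          module_latent_factors = factors,
                          trait_assignments = trait_assignments),
                     class = "synthetic_truth")
  list(metabolome = omics_matrix(2^log2v, md, role = "metabolome"),
       truth = truth)
}

#' Generate a transcriptome count matrix around planted modules
#'
#' Module genes respond affinely (random loading in \[0.8, 1.2\]) to their
#' module's latent factor on the log2 scale, with log-normal residual noise;
#' counts are then drawn negative-binomially around the resulting mean.
#' Background genes are independent negative-binomial noise around a constant
#' per-gene baseline.
#'
#' @param config the same [sim_config()] used for the metabolome.
#' @param truth the `synthetic_truth` returned by [simulate_metabolome()].
#' @return An [omics_matrix()] with `role = "transcriptome"`.
#' @export
simulate_transcriptome <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  membership <- truth$module_membership
  if (length(membership) != config$n_genes)
    stop("truth module membership inconsistent with config n_genes")
  sizes <- tabulate(membership[membership > 0], nbins = config$n_modules)
  if (!identical(sizes, config$module_sizes))
    stop("truth module sizes inconsistent with config module_sizes")

  set.seed(config$seed + 1L)
  factors <- truth$module_latent_factors
  md <- design_table(config$n_reps_transcriptome, "T")
  if (!identical(colnames(factors), md$sample_id))
    stop("latent factor sample ids inconsistent with transcriptome design")
  n <- nrow(md)
  gene_ids <- names(membership)

  base <- stats::rnorm(config$n_genes, config$gene_log2_mean, config$gene_log2_sd)
  loading <- stats::runif(config$n_genes, 0.8, 1.2)
  log2mu <- matrix(base, config$n_genes, n,
                   dimnames = list(gene_ids, md$sample_id))
  in_mod <- membership > 0
  log2mu[in_mod, ] <- log2mu[in_mod, , drop = FALSE] +
    loading[in_mod] * factors[membership[in_mod], , drop = FALSE]
  log2mu <- log2mu + matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                            config$n_genes, n)
  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes, dimnames = dimnames(mu))
  omics_matrix(counts, md, role = "transcriptome")
}

#' Generate a full paired synthetic dataset
#'
#' Convenience wrapper running [simulate_metabolome()] then
#' [simulate_transcriptome()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `metabolome`, `transcriptome`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  met <- simulate_metabolome(config)
  txn <- simulate_transcriptome(config, met$truth)
  list(metabolome = met$metabolome, transcriptome = txn, truth = met$truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:\n")
  cat("  shared markers:     ", length(x$shared_marker_ids), "\n")
  cat("  sensitive-specific: ", length(x$sensitive_marker_ids), "\n")
  cat("  tolerant-specific:  ", length(x$tolerant_marker_ids), "\n")
  cat("  modules:            ",
      paste(tabulate(x$module_membership[x$module_membership > 0]),
            collapse = "/"), "genes\n")
  cat("  trait metabolites:  ",
      paste(x$trait_assignments$feature_id, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise / restore planted truth as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- list(shared_marker_ids = truth$shared_marker_ids,
              sensitive_marker_ids = truth$sensitive_marker_ids,
              tolerant_marker_ids = truth$tolerant_marker_ids,
              module_membership = as.list(truth$module_membership),
              module_latent_factors = list(
                modules = rownames(truth$module_latent_factors),
                samples = colnames(truth$module_latent_factors),
                values = truth$module_latent_factors),
              trait_assignments = truth$trait_assignments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  membership <- unlist(obj$module_membership)
  factors <- obj$module_latent_factors$values
  dimnames(factors) <- list(obj$module_latent_factors$modules,
                            obj$module_latent_factors$samples)
  structure(list(shared_marker_ids = obj$shared_marker_ids,
                 sensitive_marker_ids = obj$sensitive_marker_ids,
                 tolerant_marker_ids = obj$tolerant_marker_ids,
                 module_membership = membership,
                 module_latent_factors = factors,
                 trait_assignments = obj$trait_assignments),
            class = "synthetic_truth")
}
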