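# chance-corrected agreement between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small omics matrix with a full 2-genotype x 3-temperature design
toy_omics <- function(p = 20, reps = 3, role = "metabolome", seed = 1) {
  md <- expand.grid(replicate = seq_len(reps), temperature_C = c(25L, 30L, 35L),
                    genotype = c("sensitive", "tolerant"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md$sample_id <- sprintf("%s_T%d_r%d", md$genotype, md$temperature_C,
                          md$replicate)
  md <- md[, c("sample_id", "genotype", "temperature_C", "replicate")]
  set.seed(seed)
  v <- matrix(2^rnorm(p * nrow(md), 8, 1), p, nrow(md),
              dimnames = list(sprintf("f%02d", seq_len(p)), md$sample_id))
  if (role == "transcriptome") v <- round(v)
  omics_matrix(v, md, role = role)
}

# expression matrix with k planted modules driven by independent factors
planted_module_matrix <- function(sizes, n_noise, n_samples, noise_sd = 0.3,
                                  seed = 1) {
  set.seed(seed)
  k <- length(sizes)
  f <- matrix(rnorm(k * n_samples), k)
  rows <- list()
  truth <- integer(0)
  for (m in seq_len(k)) {
    rows[[m]] <- t(sapply(seq_len(sizes[m]), function(i)
      f[m, ] + rnorm(n_samples, 0, noise_sd)))
    truth <- c(truth, rep(m, sizes[m]))
  }
  rows[[k + 1]] <- matrix(rnorm(n_noise * n_samples), n_noise)
  truth <- c(truth, rep(0L, n_noise))
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("g%04d", seq_len(nrow(x))),
                      sprintf("s%02d", seq_len(n_samples)))
  names(truth) <- rownames(x)
  list(expr = x, truth = truth)
}

# importance profile from a named mda vector, as mda_importance() would build
make_profile <- function(mda, genotype = "A", oob = 1) {
  ord <- order(-mda, names(mda))
  rank <- integer(length(mda)); rank[ord] <- seq_along(mda)
  out <- data.frame(feature_id = names(mda), mda = as.numeric(mda),
                    rank = rank, stringsAsFactors = FALSE)
  attr(out, "genotype") <- genotype
  attr(out, "oob_accuracy") <- oob
  class(out) <- c("importance_profile", "data.frame")
  out
}
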