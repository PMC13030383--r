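# genes x samples view; log2-transform counts first for transcriptome input
expr_matrix <- function(expr) {
  if (inherits(expr, "omics_matrix")) {
    v <- expr$values
    if (expr$role == "transcriptome") v <- log2_safe(v)
    v
  } else as.matrix(expr)
}

#' Unsigned weighted adjacency
#'
#' a_ij = |pearson(x_i, x_j)|^beta, with the diagonal set to zero so that
#' connectivity sums and topological overlap denominators exclude
#' self-edges. Near-constant genes (undefined correlation) get zero
#' adjacency, with a warning.
#'
#' @param expr an [omics_matrix()] (counts are log2-transformed first) or a
#'   genes x samples matrix.
#' @param power soft-threshold exponent beta >= 1 (study setting: 9).
#' @return symmetric genes x genes matrix in \[0, 1\], zero diagonal.
#' @export
adjacency_matrix <- function(expr, power = 9) {
  if (power < 1) stop("`power` must be >= 1")
  v <- expr_matrix(expr)
  if (ncol(v) < 3) stop("need at least 3 samples")
  cc <- suppressWarnings(stats::cor(t(v)))
  if (anyNA(cc)) {
    warning("near-constant genes: undefined correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  a <- abs(cc)^power
  diag(a) <- 0
  a
}

# R^2 of the log-log degree-distribution fit, signed by the slope:
# positive only for the decreasing tail a scale-free network shows.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(c(r2 = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  kmid <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmid[ok]))
  c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency, computes per-gene
#' connectivity k_i = sum_j a_ij, and measures how well the degree
#' distribution follows a power law: the R^2 of log10(freq(k)) against
#' log10(k) over binned connectivities, counted only when the slope is
#' negative. Recommends the smallest power reaching `r2_cut`, falling back
#' to the best-fitting power.
#'
#' @param expr data as in [adjacency_matrix()].
#' @param candidate_powers powers to scan.
#' @param r2_cut signed R^2 considered an adequate scale-free fit.
#' @param n_bins connectivity histogram bins for the fit.
#' @return list of class `soft_threshold`: `power` (recommendation) and
#'   `table` (power, signed_r2, slope, mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_cut = 0.8, n_bins = 10) {
  v <- expr_matrix(expr)
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[is.na(cc)] <- 0
  acc <- abs(cc)
  diag(acc) <- 0
  rows <- lapply(candidate_powers, function(b) {
    k <- rowSums(acc^b)
    sf <- scale_free_fit(k, n_bins)
    signed <- if (is.na(sf["slope"])) NA_real_
              else sf[["r2"]] * -sign(sf[["slope"]])
    data.frame(power = b, signed_r2 = signed, slope = sf[["slope"]],
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$signed_r2) & tab$signed_r2 >= r2_cut)
  power <- if (length(ok)) tab$power[ok[1]]
           else tab$power[which.max(tab$signed_r2)]
  structure(list(power = power, table = tab, r2_cut = r2_cut),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("soft threshold: recommended power = %g (R2 cut %.2f)\n",
              x$power, x$r2_cut))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap similarity
#'
#' The standard unsigned TOM: for adjacency a with zero diagonal and
#' connectivity k_i = sum_u a_iu,
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},}
#' with TOM_ii = 1. Two genes overlap strongly when they are directly
#' connected and share neighbours.
#'
#' @param adj symmetric adjacency in \[0, 1\] with zero diagonal (from
#'   [adjacency_matrix()]).
#' @return symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("`adj` must be a square matrix")
  if (max(abs(adj - t(adj))) > 1e-12) stop("`adj` must be symmetric")
  if (any(adj < 0) || any(adj > 1)) stop("`adj` entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' @rdname tom_similarity
#' @export
tom_dissimilarity <- function(adj) 1 - tom_similarity(adj)

#' Module detection by static branch cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, cut at a
#' fixed height: branches that finish merging below `cut_height` become
#' candidate modules, and candidates smaller than `min_module_size` are sent
#' to the unassigned "grey" label. Modules are named `M1`, `M2`, ... in
#' decreasing size order. With pure-noise input, dissimilarities crowd
#' toward 1, nothing coheres into a branch of `min_module_size` genes below
#' the cut, and (almost) everything lands in grey.
#'
#' A single static cut trades off two failure modes: too high and weakly
#' bridged branches fuse, too low and loosely attached genes fragment away.
#' [coexpression_modules()] therefore runs this cut with a small
#' `min_module_size`, reunites same-source fragments by eigengene
#' correlation, and only then applies the real size filter.
#'
#' @param dissimilarity symmetric matrix from [tom_dissimilarity()].
#' @param min_module_size smallest gene count kept as a module (study
#'   setting: 50).
#' @param cut_height static dissimilarity cut (default 0.97).
#' @return named character vector: gene -> module label ("grey" =
#'   unassigned).
#' @export
detect_modules <- function(dissimilarity, min_module_size = 50,
                           cut_height = 0.97) {
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  names(labels) <- rownames(dissimilarity)
  for (i in seq_along(keep))
    labels[cl == as.integer(keep[i])] <- paste0("M", i)
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first left singular vector of its
#' standardized samples x genes submatrix: the dominant sample-space profile
#' (unit norm), sign-oriented to correlate positively with the module's mean
#' standardized expression.
#'
#' @param expr data as in [adjacency_matrix()].
#' @param labels gene -> module labels from [detect_modules()]; "grey" is
#'   skipped.
#' @return modules x samples matrix of unit-norm eigengenes.
#' @export
module_eigengenes <- function(expr, labels) {
  v <- expr_matrix(expr)
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods))
    return(matrix(numeric(), 0, ncol(v),
                  dimnames = list(NULL, colnames(v))))
  mods <- mods[order(-tabulate(factor(labels, levels = mods)))]
  eg <- t(vapply(mods, function(m) {
    X <- scale(t(v[names(labels)[labels == m], , drop = FALSE]))
    X[is.na(X)] <- 0  # constant genes carry no profile
    e <- svd(X, nu = 1, nv = 0)$u[, 1]
    if (stats::cor(e, rowMeans(X)) < 0) e <- -e
    e
  }, numeric(ncol(v))))
  dimnames(eg) <- list(mods, colnames(v))
  eg
}

#' Merge modules with similar eigengenes
#'
#' Clusters module eigengenes by correlation dissimilarity (1 - r, average
#' linkage) and fuses every group of modules merging below `cut_height`,
#' recomputing eigengenes and repeating until no further merges occur
#' (fixed point). `cut_height = 0` merges nothing.
#'
#' @param expr data as in [adjacency_matrix()].
#' @param labels gene -> module labels.
#' @param cut_height eigengene dissimilarity below which modules fuse
#'   (study setting: 0.25).
#' @return list: `labels` (relabelled `M1`... by decreasing size),
#'   `eigengenes`.
#' @export
merge_modules <- function(expr, labels, cut_height = 0.25) {
  repeat {
    eg <- module_eigengenes(expr, labels)
    if (nrow(eg) <= 1 || cut_height <= 0)
      return(list(labels = labels, eigengenes = eg))
    diss <- 1 - stats::cor(t(eg))
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    if (max(table(grp)) == 1)
      return(list(labels = labels, eigengenes = eg))
    for (g in unique(grp)) {
      members <- rownames(eg)[grp == g]
      if (length(members) > 1)
        labels[labels %in% members] <- members[1]
    }
    # normalize labels to M1.. by decreasing size
    mods <- setdiff(unique(labels), "grey")
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
    remap <- stats::setNames(paste0("M", seq_along(mods)),
                             mods[order(-sizes)])
    labels[labels != "grey"] <- remap[labels[labels != "grey"]]
  }
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each quantitative trait
#' (here: abundances of key metabolites), with two-sided Student-t p-values
#' on n - 2 degrees of freedom. Samples are aligned by shared column names.
#' Near-constant profiles correlate as 0, with a warning.
#'
#' @param eigengenes modules x samples matrix (or a `module_set`).
#' @param traits traits x samples matrix, or a named vector for one trait.
#' @return list with matrices `r` and `p` (modules x traits) and `n`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (inherits(eigengenes, "module_set")) eigengenes <- eigengenes$eigengenes
  if (is.null(dim(traits))) traits <- matrix(traits, 1,
                                             dimnames = list("trait",
                                                             names(traits)))
  shared <- intersect(colnames(eigengenes), colnames(traits))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  E <- t(eigengenes[, shared, drop = FALSE])
  Tr <- t(traits[, shared, drop = FALSE])
  sds_e <- apply(E, 2, stats::sd)
  sds_t <- apply(Tr, 2, stats::sd)
  if (any(sds_e == 0) || any(sds_t == 0))
    warning("near-constant profile(s): correlations reported as 0")
  r <- suppressWarnings(stats::cor(E, Tr))
  r[!is.finite(r)] <- 0
  n <- length(shared)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Align metabolite traits to transcriptome samples
#'
#' Builds a traits x samples matrix for [module_trait_correlation()] from
#' metabolome rows. When each transcriptome sample has a same-replicate
#' metabolome partner (matching genotype, temperature, replicate), those
#' values are used directly; otherwise metabolome replicates are averaged
#' within genotype x temperature and broadcast.
#'
#' @param metabolome the metabolome [omics_matrix()].
#' @param feature_ids metabolite ids to use as traits.
#' @param target_metadata metadata data.frame of the transcriptome samples.
#' @param method `"auto"`, `"replicate"` or `"group_mean"`.
#' @return traits x samples matrix with target sample ids as columns.
#' @export
align_traits <- function(metabolome, feature_ids, target_metadata,
                         method = c("auto", "replicate", "group_mean")) {
  method <- match.arg(method)
  stopifnot(inherits(metabolome, "omics_matrix"))
  missing_ids <- setdiff(feature_ids, rownames(metabolome$values))
  if (length(missing_ids))
    stop("trait features absent from metabolome: ",
         paste(missing_ids, collapse = ", "))
  md_m <- metabolome$metadata
  key_m <- paste(md_m$genotype, md_m$temperature_C, md_m$replicate)
  key_t <- paste(target_metadata$genotype, target_metadata$temperature_C,
                 target_metadata$replicate)
  v <- metabolome$values[feature_ids, , drop = FALSE]
  if (method == "auto")
    method <- if (all(key_t %in% key_m)) "replicate" else "group_mean"
  if (method == "replicate") {
    if (!all(key_t %in% key_m))
      stop("no replicate-level match for some transcriptome samples")
    out <- v[, match(key_t, key_m), drop = FALSE]
  } else {
    grp_m <- paste(md_m$genotype, md_m$temperature_C)
    grp_t <- paste(target_metadata$genotype, target_metadata$temperature_C)
    means <- vapply(unique(grp_m), function(g)
      rowMeans(v[, grp_m == g, drop = FALSE]), numeric(nrow(v)))
    if (nrow(v) == 1) means <- matrix(means, nrow = 1)
    colnames(means) <- unique(grp_m)
    out <- means[, match(grp_t, colnames(means)), drop = FALSE]
  }
  colnames(out) <- target_metadata$sample_id
  rownames(out) <- feature_ids
  out
}

#' Weighted co-expression module detection, end to end
#'
#' Adjacency -> topological overlap -> average-linkage tree cut into fine
#' proto-clusters (every branch of at least `proto_min` genes below
#' `cut_height`) -> eigengene-correlation merging, which both reunites
#' fragments of one underlying module and performs the conventional module
#' merge -> minimum-size filter. The two-stage cut-then-merge is what makes
#' detection robust at small sample sizes, where single static cuts either
#' fuse weakly bridged modules or shed their loosely attached genes.
#' Defaults follow the conventional unsigned-network parameterisation
#' (power 9, minimum module size 50, merge cut height 0.25).
#'
#' @param expr an [omics_matrix()] (transcriptome counts are
#'   log2-transformed) or genes x samples matrix.
#' @param power soft threshold; `NULL` runs [pick_soft_threshold()].
#' @param min_module_size,merge_cut_height,cut_height see
#'   [detect_modules()] and [merge_modules()].
#' @param proto_min smallest branch carried into the merge stage (a
#'   proto-cluster needs a few genes for a meaningful eigengene).
#' @return Object of class `module_set`: `labels`, `eigengenes`,
#'   `module_sizes`, `power`, `scale_free_r2`, parameters, and (after
#'   [module_trait_correlation()] results are attached by the caller)
#'   optionally `trait_cor`.
#' @export
coexpression_modules <- function(expr, power = 9, min_module_size = 50,
                                 merge_cut_height = 0.25, cut_height = 0.97,
                                 proto_min = 3) {
  if (is.null(power)) power <- pick_soft_threshold(expr)$power
  a <- adjacency_matrix(expr, power)
  sf <- scale_free_fit(rowSums(a))
  d <- 1 - tom_similarity(a)
  proto <- detect_modules(d, min_module_size = proto_min,
                          cut_height = cut_height)
  merged <- merge_modules(expr, proto, cut_height = merge_cut_height)
  labels <- merged$labels
  sizes <- table(labels)
  small <- setdiff(names(sizes)[sizes < min_module_size], "grey")
  labels[labels %in% small] <- "grey"
  mods <- setdiff(unique(labels), "grey")
  if (length(mods)) {
    remap <- stats::setNames(
      paste0("M", seq_along(mods)),
      mods[order(-vapply(mods, function(m) sum(labels == m), integer(1)))])
    labels[labels != "grey"] <- remap[labels[labels != "grey"]]
  }
  eigengenes <- module_eigengenes(expr, labels)
  structure(list(labels = labels, eigengenes = eigengenes,
                 module_sizes = table(labels), power = power,
                 scale_free_r2 = unname(sf["r2"] * -sign(sf["slope"])),
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height = cut_height, proto_min = proto_min,
                 adjacency = a),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  non_grey <- setdiff(names(x$module_sizes), "grey")
  cat(sprintf(
    "module_set: %d modules (+%d grey genes), power = %g, scale-free R2 = %.2f\n",
    length(non_grey), sum(x$labels == "grey"), x$power,
    ifelse(is.na(x$scale_free_r2), NA, x$scale_free_r2)))
  print(x$module_sizes)
  invisible(x)
}

#' @export
summary.module_set <- function(object, ...) {
  print(object)
  if (!is.null(object$trait_cor)) {
    cat("module-trait correlations:\n")
    print(round(object$trait_cor$r, 2))
  }
  invisible(object)
}

#' @export
plot.module_set <- function(x, ...) {
  if (!is.null(x$trait_cor)) {
    r <- x$trait_cor$r
    graphics::image(seq_len(ncol(r)), seq_len(nrow(r)), t(r),
                    zlim = c(-1, 1), axes = FALSE,
                    xlab = "trait", ylab = "module",
                    col = grDevices::hcl.colors(21, "Blue-Red"), ...)
    graphics::axis(1, seq_len(ncol(r)), colnames(r), las = 2)
    graphics::axis(2, seq_len(nrow(r)), rownames(r), las = 1)
  } else {
    graphics::barplot(sort(table(x$labels), decreasing = TRUE),
                      ylab = "genes", las = 2, ...)
  }
  invisible(x)
}
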