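# samples x features view of either a plain matrix (assumed samples x
# features) or an omics_matrix (stored features x samples).
as_sample_matrix <- function(x) {
  if (inherits(x, "omics_matrix")) t(x$values) else as.matrix(x)
}

#' Principal component variance summary
#'
#' Thin wrapper around the singular value decomposition of the centered (and
#' optionally unit-scaled) data, reporting the variance fraction explained by
#' each component and the per-sample scores — the usual first look at whether
#' samples separate by treatment.
#'
#' @param x an [omics_matrix()] (features x samples) or a samples x features
#'   numeric matrix.
#' @param n_components number of components to keep in the score matrix.
#' @param scale. logical; divide features by their standard deviation first.
#'   Recommended for metabolome intensities (mixed dynamic ranges); use
#'   `FALSE` for already log-transformed counts.
#' @return A list of class `pca_summary` with `variance_fraction` (all
#'   components, non-increasing), `scores` (samples x `n_components`) and
#'   `n_dropped` (zero-variance features excluded before scaling).
#' @export
pca_summary <- function(x, n_components = 2, scale. = TRUE) {
  m <- as_sample_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  v <- apply(m, 2, stats::var)
  n_dropped <- 0L
  if (all(v == 0)) {
    warning("constant matrix: all variance fractions are zero")
    vf <- rep(0, min(dim(m)))
    scores <- matrix(0, nrow(m), n_components,
                     dimnames = list(rownames(m),
                                     paste0("PC", seq_len(n_components))))
    out <- list(variance_fraction = vf, scores = scores, n_dropped = 0L)
    class(out) <- "pca_summary"
    return(out)
  }
  if (scale.) {
    keep <- v > 0
    n_dropped <- sum(!keep)
    if (n_dropped > 0)
      warning(n_dropped, " zero-variance features dropped before scaling")
    m <- m[, keep, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = scale.)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  out <- list(variance_fraction = vf,
              scores = fit$x[, seq_len(k), drop = FALSE],
              n_dropped = n_dropped)
  class(out) <- "pca_summary"
  out
}

#' @export
print.pca_summary <- function(x, ...) {
  vf <- x$variance_fraction
  k <- min(5, length(vf))
  cat("PCA:", paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * vf[seq_len(k)]),
                    collapse = ", "), "\n")
  invisible(x)
}

one_hot <- function(y) {
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Y
}

#' Partial least squares discriminant analysis with VIP scores
#'
#' Fits a PLS2 model by the NIPALS algorithm on column-standardized data
#' against the centered one-hot class response, and scores every feature by
#' its variable importance in projection,
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SS_a},}
#' where \eqn{SS_a} is the response variance captured by component \eqn{a}.
#' By construction the VIP scores satisfy mean(VIP^2) = 1, which the fit
#' verifies as a postcondition.
#'
#' @param x an [omics_matrix()] or a samples x features matrix.
#' @param y class labels, one per sample (factor or coercible); every class
#'   must have at least 2 samples.
#' @param n_components number of latent components.
#' @param scale. unit-variance scaling of features (standard for metabolomics).
#' @return Object of class `plsda`: scores `T`, weights `W`, loadings `P`,
#'   response loadings `Q`, `vip` (named vector), `r2y`, per-component `ss_y`,
#'   centering/scaling vectors, and the levels of `y`.
#' @export
plsda <- function(x, y, n_components = 2, scale. = TRUE) {
  X <- as_sample_matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  if (length(y) != nrow(X)) stop("length(y) must equal the number of samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance feature(s) excluded from PLS-DA")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mu <- colMeans(X)
  Xs <- sweep(X, 2, mu)
  if (scale.) Xs <- sweep(Xs, 2, sds, "/")
  Y0 <- scale(one_hot(y), center = TRUE, scale = FALSE)
  ymeans <- attr(Y0, "scaled:center")

  p <- ncol(Xs)
  A <- min(n_components, nrow(Xs) - 1L, p)
  W <- P <- matrix(0, p, A, dimnames = list(colnames(Xs), NULL))
  Q <- matrix(0, ncol(Y0), A, dimnames = list(colnames(Y0), NULL))
  Tm <- matrix(0, nrow(Xs), A, dimnames = list(rownames(Xs), NULL))
  ss_y <- numeric(A)
  Xr <- Xs; Yr <- Y0
  tss_y <- sum(Y0^2)
  for (a in seq_len(A)) {
    u <- Yr[, which.max(colSums(Yr^2))]
    t_old <- rep(Inf, nrow(Xr))
    for (it in seq_len(500)) {
      w <- drop(crossprod(Xr, u))
      w <- w / sqrt(sum(w^2))
      t_ <- drop(Xr %*% w)
      q <- drop(crossprod(Yr, t_)) / sum(t_^2)
      u <- drop(Yr %*% q) / sum(q^2)
      if (sqrt(sum((t_ - t_old)^2)) < 1e-12 * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    p_ <- drop(crossprod(Xr, t_)) / sum(t_^2)
    Xr <- Xr - tcrossprod(t_, p_)
    Yr <- Yr - tcrossprod(t_, q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
    ss_y[a] <- sum(q^2) * sum(t_^2)
  }
  r2y <- 1 - sum(Yr^2) / tss_y

  vip <- sqrt(p * drop(W^2 %*% ss_y) / sum(ss_y))
  names(vip) <- colnames(Xs)
  stopifnot(abs(mean(vip^2) - 1) < 1e-8)  # normalization identity

  structure(list(T = Tm, W = W, P = P, Q = Q, vip = vip, r2y = r2y,
                 ss_y = ss_y, n_components = A, center = mu,
                 scale = if (scale.) sds else NULL, y_means = ymeans,
                 levels = levels(y), y = y, dropped_features = dropped),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d components, %d features, %d samples, R2Y = %.3f\n",
              x$n_components, nrow(x$W), nrow(x$T), x$r2y))
  if (!is.null(x$q2)) cat(sprintf("  Q2 (CV) = %.3f\n", x$q2))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  cat("Top features by VIP:\n")
  print(utils::head(round(sort(object$vip, decreasing = TRUE), 3), 10))
  invisible(object)
}

#' @export
coef.plsda <- function(object, ...) {
  # regression coefficients on the standardized scale: B = W (P'W)^-1 Q'
  object$W %*% solve(crossprod(object$P, object$W), t(object$Q))
}

#' @param object a fitted `plsda` model.
#' @param newdata samples x features matrix or [omics_matrix()] covering the
#'   model's features.
#' @param type `"class"` for hard labels, `"response"` for the continuous
#'   class scores.
#' @param ... unused.
#' @rdname plsda
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  Xn <- as_sample_matrix(newdata)[, rownames(object$W), drop = FALSE]
  Xn <- sweep(Xn, 2, object$center)
  if (!is.null(object$scale)) Xn <- sweep(Xn, 2, object$scale, "/")
  R <- object$W %*% solve(crossprod(object$P, object$W))
  Yhat <- Xn %*% R %*% t(object$Q)
  Yhat <- sweep(Yhat, 2, object$y_means, "+")
  colnames(Yhat) <- object$levels
  if (type == "response") return(Yhat)
  factor(object$levels[max.col(Yhat, ties.method = "first")],
         levels = object$levels)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (lv in levels(factor(y))) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validation and response-permutation checks for a PLS-DA model
#'
#' Computes Q2 from stratified k-fold cross-validation (default 7-fold) and
#' permutation p-values for both R2Y and Q2 from label-shuffled refits
#' (default 200 permutations), using the add-one estimator
#' p = (1 + #\{perm >= observed\}) / (B + 1), whose smallest attainable value
#' is 1/(B+1).
#'
#' @param x data as in [plsda()].
#' @param y class labels.
#' @param n_components latent components per fit.
#' @param n_folds folds for Q2 (must not exceed the sample count).
#' @param n_permutations label permutations (>= 1).
#' @param seed integer seed controlling fold assignment and permutations.
#' @param scale. unit-variance scaling, as in [plsda()].
#' @return list of class `plsda_validation`: `q2`, `r2y`,
#'   `permutation_p_r2y`, `permutation_p_q2`, and the null distributions.
#' @export
validate_plsda <- function(x, y, n_components = 2, n_folds = 7,
                           n_permutations = 200, seed = 1, scale. = TRUE) {
  X <- as_sample_matrix(x)
  y <- factor(y)
  if (n_folds > nrow(X)) stop("n_folds exceeds the number of samples")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  set.seed(seed)

  q2_of <- function(yy) {
    Y <- scale(one_hot(yy), center = TRUE, scale = FALSE)
    fold <- stratified_folds(yy, n_folds)
    press <- 0
    for (k in sort(unique(fold))) {
      tr <- fold != k
      fit <- plsda(X[tr, , drop = FALSE], yy[tr],
                   n_components = n_components, scale. = scale.)
      Yhat <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
      Yobs <- one_hot(factor(yy, levels = levels(yy)))[!tr, , drop = FALSE]
      press <- press + sum((Yobs[, fit$levels, drop = FALSE] - Yhat)^2)
    }
    1 - press / sum(Y^2)
  }
  r2_of <- function(yy)
    plsda(X, yy, n_components = n_components, scale. = scale.)$r2y

  r2y <- r2_of(y)
  q2 <- suppressWarnings(q2_of(y))
  null_r2 <- null_q2 <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    null_r2[b] <- r2_of(yp)
    null_q2[b] <- suppressWarnings(q2_of(yp))
  }
  structure(list(q2 = q2, r2y = r2y,
                 permutation_p_r2y = (1 + sum(null_r2 >= r2y)) / (n_permutations + 1),
                 permutation_p_q2 = (1 + sum(null_q2 >= q2)) / (n_permutations + 1),
                 null_r2y = null_r2, null_q2 = null_q2,
                 n_folds = n_folds, n_permutations = n_permutations),
            class = "plsda_validation")
}

#' @export
print.plsda_validation <- function(x, ...) {
  cat(sprintf("PLS-DA validation: R2Y = %.3f, Q2 (%d-fold) = %.3f\n",
              x$r2y, x$n_folds, x$q2))
  cat(sprintf("  permutation p (B = %d): R2Y %.4g, Q2 %.4g\n",
              x$n_permutations, x$permutation_p_r2y, x$permutation_p_q2))
  invisible(x)
}

#' Per-feature two-sample Student t-tests with log2 fold changes
#'
#' Two-sided pooled-variance t-test per feature, plus the log2 ratio of raw
#' group means. A pseudo-count of half the smallest positive matrix value
#' keeps ratios finite when a group mean is zero. Features identical in both
#' groups get t = 0, p = 1.
#'
#' @param x an [omics_matrix()] or features x samples matrix.
#' @param group_a_ids,group_b_ids sample ids (or column indices) of the two
#'   groups; each needs >= 2 samples. Fold change is B over A.
#' @return data.frame: feature_id, t, p, log2_fold_change, mean_a, mean_b.
#' @export
univariate_tests <- function(x, group_a_ids, group_b_ids) {
  v <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  pick <- function(ids) if (is.character(ids)) match(ids, colnames(v)) else ids
  a <- v[, pick(group_a_ids), drop = FALSE]
  b <- v[, pick(group_b_ids), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")

  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (mb - ma) / se
  tt[se == 0 & mb == ma] <- 0
  df <- na + nb - 2
  p <- 2 * stats::pt(-abs(tt), df)
  p[se == 0 & mb == ma] <- 1

  pos <- v[v > 0]
  eps <- if (length(pos)) min(pos) / 2 else 0.5
  lfc <- log2((mb + eps * (mb == 0)) / (ma + eps * (ma == 0)))

  data.frame(feature_id = rownames(v), t = tt, p = p,
             log2_fold_change = lfc, mean_a = ma, mean_b = mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differentially accumulated metabolite (DAM) selection
#'
#' The intersection rule used throughout metabolomics screening: keep features
#' with VIP strictly greater than `vip_threshold` and univariate p strictly
#' below `p_threshold`; direction is the sign of the log2 fold change.
#'
#' @param vip a fitted [plsda()] model or a named numeric vector of VIP
#'   scores.
#' @param tests the data.frame from [univariate_tests()].
#' @param vip_threshold,p_threshold strict cutoffs (defaults 1.0 and 0.05).
#' @return A data.frame of class `differential_set` (all features, with a
#'   logical `selected` column) carrying the rule as attributes `rule`,
#'   `n_up`, `n_down`.
#' @export
select_dams <- function(vip, tests, vip_threshold = 1.0, p_threshold = 0.05) {
  if (inherits(vip, "plsda")) vip <- vip$vip
  idx <- match(tests$feature_id, names(vip))
  out <- data.frame(feature_id = tests$feature_id,
                    vip = as.numeric(vip[idx]),
                    p = tests$p,
                    log2_fold_change = tests$log2_fold_change,
                    stringsAsFactors = FALSE)
  out$selected <- !is.na(out$vip) & out$vip > vip_threshold & out$p < p_threshold
  out$direction <- ifelse(out$log2_fold_change > 0, "up", "down")
  attr(out, "rule") <- sprintf("VIP > %g & p < %g", vip_threshold, p_threshold)
  attr(out, "n_up") <- sum(out$selected & out$direction == "up")
  attr(out, "n_down") <- sum(out$selected & out$direction == "down")
  class(out) <- c("differential_set", "data.frame")
  out
}

#' Differentially expressed gene (DEG) calling between two groups
#'
#' Standard two-group count-based testing via edgeR: TMM size factors,
#' tagwise dispersion, exact test, Benjamini-Hochberg adjustment, then the
#' conventional rule |log2FC| >= `lfc_threshold` and FDR < `fdr_threshold`.
#'
#' @param counts an [omics_matrix()] with `role = "transcriptome"` or a raw
#'   count matrix (genes x samples).
#' @param group_a_ids,group_b_ids sample ids/indices of the two groups
#'   (fold change is B over A).
#' @param lfc_threshold,fdr_threshold selection rule (defaults 1 and 0.05).
#' @return A `differential_set` data.frame: feature_id, log2_fold_change,
#'   p, padj, direction, selected.
#' @export
select_degs <- function(counts, group_a_ids, group_b_ids,
                        lfc_threshold = 1, fdr_threshold = 0.05) {
  v <- if (inherits(counts, "omics_matrix")) counts$values else as.matrix(counts)
  if (nrow(v) == 0) {
    out <- data.frame(feature_id = character(), log2_fold_change = numeric(),
                      p = numeric(), padj = numeric(), direction = character(),
                      selected = logical(), stringsAsFactors = FALSE)
    class(out) <- c("differential_set", "data.frame")
    return(out)
  }
  pick <- function(ids) if (is.character(ids)) match(ids, colnames(v)) else ids
  ia <- pick(group_a_ids); ib <- pick(group_b_ids)
  group <- factor(rep(c("A", "B"), c(length(ia), length(ib))),
                  levels = c("A", "B"))
  dge <- edgeR::DGEList(counts = v[, c(ia, ib), drop = FALSE], group = group)
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateDisp(dge, stats::model.matrix(~group))
  et <- edgeR::exactTest(dge, pair = c("A", "B"))
  tab <- et$table
  padj <- stats::p.adjust(tab$PValue, method = "BH")
  out <- data.frame(feature_id = rownames(tab),
                    log2_fold_change = tab$logFC,
                    p = tab$PValue, padj = padj,
                    direction = ifelse(tab$logFC > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out$selected <- abs(out$log2_fold_change) >= lfc_threshold &
    out$padj < fdr_threshold
  attr(out, "rule") <- sprintf("|log2FC| >= %g & FDR < %g (edgeR exact test)",
                               lfc_threshold, fdr_threshold)
  class(out) <- c("differential_set", "data.frame")
  out
}

#' @export
print.differential_set <- function(x, ...) {
  cat(sprintf("differential_set: %d/%d selected (%s)\n",
              sum(x$selected), nrow(x),
              attr(x, "rule") %||% "no rule recorded"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Venn region counts for a list of id sets
#'
#' Counts, for every non-empty combination of the input sets, the elements
#' belonging to exactly that combination. Region counts therefore sum to the
#' size of the union.
#'
#' @param sets named list of character vectors (2 or more sets).
#' @return data.frame with columns `region` (set names joined by `&`) and
#'   `count`, covering all 2^n - 1 regions.
#' @export
venn_overlap <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("S", seq_along(sets))
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) memb <- matrix(memb, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  region <- apply(combos, 1, function(z) paste(names(sets)[unlist(z)],
                                               collapse = "&"))
  count <- apply(combos, 1, function(z)
    if (length(ids)) sum(apply(memb, 1, function(r) all(r == unlist(z)))) else 0L)
  data.frame(region = region, count = as.integer(count),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' K-means expression pattern discovery
#'
#' Rows are z-scored (so clusters group by profile shape, not magnitude) and
#' partitioned by k-means with `n_init` random restarts, keeping the solution
#' with the lowest within-cluster sum of squares.
#'
#' @param profiles an [omics_matrix()] or features x samples matrix.
#' @param k number of clusters (the study convention for DEG expression
#'   patterns is 12).
#' @param seed integer seed.
#' @param n_init random restarts.
#' @return list of class `cluster_assignment`: `cluster` (named integer in
#'   1..k), `k`, `tot_withinss`, `centers`.
#' @export
kmeans_patterns <- function(profiles, k = 12, seed = 1, n_init = 10) {
  v <- if (inherits(profiles, "omics_matrix")) profiles$values
       else as.matrix(profiles)
  sds <- apply(v, 1, stats::sd)
  z <- (v - rowMeans(v)) / ifelse(sds > 0, sds, 1)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant profile(s) z-scored to zero")
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  structure(list(cluster = stats::setNames(km$cluster, rownames(v)),
                 k = k, tot_withinss = km$tot.withinss,
                 centers = km$centers),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("k-means: %d profiles in %d clusters, total within-SS = %.2f\n",
              length(x$cluster), x$k, x$tot_withinss))
  print(table(x$cluster))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Classic qPCR arithmetic: the target gene's Ct is normalized to a reference
#' gene within each sample, the treated sample's dCt is referenced to the
#' calibrator's dCt, and the result is expressed as a fold change.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the calibrator.
#' @return 2^-((Ct_t,target - Ct_t,ref) - (Ct_c,target - Ct_c,ref)),
#'   vectorized over its arguments.
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_calibrator, ct_ref_calibrator) {
  2^-((ct_target_treated - ct_ref_treated) -
        (ct_target_calibrator - ct_ref_calibrator))
}
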