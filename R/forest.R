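#' Random-forest settings for the temperature classifiers
#'
#' @param n_trees trees per forest (study setting: 1000).
#' @param n_importance_repeats out-of-bag permutations per tree and feature
#'   when measuring mean decrease in accuracy.
#' @param seed integer seed for the forest fit.
#' @return list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000, n_importance_repeats = 10, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (n_importance_repeats < 1) stop("n_importance_repeats must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 n_importance_repeats = as.integer(n_importance_repeats),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Genotype-stratified random-forest classifier of temperature
#'
#' Fits a bagged decision-tree ensemble predicting the temperature treatment
#' (25/30/35 degC) from all features of ONE genotype, with
#' floor(sqrt(p)) candidate variables per split. The input must contain a
#' single genotype: the two cultivars' response strategies are modelled
#' independently, and mixing them is an error.
#'
#' Mean decrease in accuracy (MDA) is measured alongside the fit: for each
#' feature, its out-of-bag values are permuted (`n_importance_repeats` times
#' per tree) and the drop in out-of-bag accuracy is averaged over trees.
#'
#' @param x an [omics_matrix()] restricted to one genotype (use
#'   [subset_genotype()]), or a samples x features matrix with `labels`.
#' @param config a [forest_config()].
#' @param labels temperature labels, only needed when `x` is a bare matrix.
#' @return Object of class `temperature_forest`: the underlying
#'   `randomForest` fit, `oob_accuracy`, `genotype`, and `config`.
#' @export
temperature_forest <- function(x, config = forest_config(), labels = NULL) {
  if (inherits(x, "omics_matrix")) {
    g <- unique(x$metadata$genotype)
    if (length(g) != 1)
      stop("matrix contains ", length(g),
           " genotypes; fit one model per genotype")
    labels <- factor(x$metadata$temperature_C)
    X <- t(x$values)
    genotype <- g
  } else {
    if (is.null(labels)) stop("`labels` required for a bare matrix")
    X <- as.matrix(x)
    labels <- factor(labels)
    genotype <- "unspecified"
  }
  if (any(table(labels) < 2))
    stop("every temperature class needs at least 2 samples")
  p <- ncol(X)
  set.seed(config$seed)
  fit <- randomForest::randomForest(
    x = X, y = labels,
    ntree = config$n_trees,
    mtry = max(1L, floor(sqrt(p))),
    importance = TRUE,
    nPerm = config$n_importance_repeats)
  oob <- mean(fit$predicted == labels)
  structure(list(fit = fit, oob_accuracy = oob, genotype = genotype,
                 labels = labels, config = config,
                 feature_ids = colnames(X)),
            class = "temperature_forest")
}

#' @export
print.temperature_forest <- function(x, ...) {
  cat(sprintf(
    "temperature_forest (%s): %d trees, %d features, OOB accuracy %.3f\n",
    x$genotype, x$config$n_trees, length(x$feature_ids), x$oob_accuracy))
  invisible(x)
}

#' @export
predict.temperature_forest <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "omics_matrix")) t(newdata$values)
       else as.matrix(newdata)
  stats::predict(object$fit, X[, object$feature_ids, drop = FALSE], ...)
}

#' Out-of-bag permutation importance profile
#'
#' Extracts the mean decrease in accuracy per feature from a fitted
#' [temperature_forest()], together with importance ranks (1 = most
#' important; ties broken by feature id for a stable, strict ranking).
#'
#' By default the importance is scaled by its standard error across trees
#' (the conventional MDA display of random-forest software). Scaling matters
#' when several features carry redundant signal: trees then spread their
#' splits over the redundant set, the raw accuracy drop per feature becomes
#' a noisy fraction of the total signal, and dividing by the per-feature
#' standard error largely cancels that competition noise. Set
#' `scaled = FALSE` for the raw accuracy drop, whose scale is interpretable
#' (a perfect single predictor loses baseline accuracy down to chance when
#' permuted).
#'
#' @param model a `temperature_forest`.
#' @param scaled divide each importance by its standard error (default TRUE).
#' @return data.frame of class `importance_profile`: feature_id, mda, rank;
#'   attributes `genotype` and `oob_accuracy`.
#' @export
mda_importance <- function(model, scaled = TRUE) {
  stopifnot(inherits(model, "temperature_forest"))
  imp <- randomForest::importance(model$fit, type = 1, scale = scaled)
  mda <- stats::setNames(imp[, 1], rownames(imp))
  ord <- order(-mda, names(mda))
  rank <- integer(length(mda))
  rank[ord] <- seq_along(mda)
  out <- data.frame(feature_id = names(mda), mda = as.numeric(mda),
                    rank = rank, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "genotype") <- model$genotype
  attr(out, "oob_accuracy") <- model$oob_accuracy
  class(out) <- c("importance_profile", "data.frame")
  out
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("importance_profile (%s): %d features, OOB accuracy %.3f\n",
              attr(x, "genotype"), nrow(x), attr(x, "oob_accuracy")))
  top <- x[order(x$rank), ][1:min(5, nrow(x)), c("feature_id", "mda", "rank")]
  print(top, row.names = FALSE)
  invisible(x)
}

common_profiles <- function(prof_a, prof_b) {
  ids <- intersect(prof_a$feature_id, prof_b$feature_id)
  if (!length(ids)) stop("profiles share no features")
  list(ids = ids,
       a = stats::setNames(prof_a$mda, prof_a$feature_id)[ids],
       b = stats::setNames(prof_b$mda, prof_b$feature_id)[ids])
}

#' Spearman concordance of two importance rankings
#'
#' Tie-corrected Spearman rank correlation between the MDA profiles of the
#' two genotype models (average ranks for ties), with a two-sided p-value
#' from the t approximation on n - 2 degrees of freedom. A low rho says the
#' two cultivars rely on different features to discriminate temperature.
#'
#' @param prof_a,prof_b [mda_importance()] profiles (or data.frames with
#'   `feature_id` and `mda`).
#' @return list: `rho`, `p`, `n` (common features).
#' @export
rank_concordance <- function(prof_a, prof_b) {
  cp <- common_profiles(prof_a, prof_b)
  ra <- rank(-cp$a, ties.method = "average")
  rb <- rank(-cp$b, ties.method = "average")
  n <- length(ra)
  if (n < 3) stop("need at least 3 common features")
  rho <- stats::cor(ra, rb)
  p <- if (abs(rho) >= 1) 0
       else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p, n = n)
}

# clip negative MDA (permutation noise) to zero, then min-max normalize
normalize_importance <- function(mda) {
  x <- pmax(mda, 0)
  rng <- range(x)
  if (rng[2] == rng[1]) return(stats::setNames(rep(0, length(x)), names(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Cross-genotype consistency scores
#'
#' Importances are clipped at zero, min-max normalized within each model to
#' \[0, 1\], and compared: consistency_j = 1 - |n_A(j) - n_B(j)|. A feature
#' equally (un)important in both cultivars scores 1; a feature at the top of
#' one model and the bottom of the other scores 0.
#'
#' @param prof_a,prof_b [mda_importance()] profiles.
#' @return named numeric vector in \[0, 1\] over the common feature set.
#' @export
consistency_scores <- function(prof_a, prof_b) {
  cp <- common_profiles(prof_a, prof_b)
  na <- normalize_importance(cp$a)
  nb <- normalize_importance(cp$b)
  stats::setNames(1 - abs(na - nb), cp$ids)
}

#' Four-way consistency categorization of features
#'
#' A feature is "high importance" in a model when its normalized importance
#' reaches that model's `importance_quantile` (inclusive). Categories:
#' `shared` = high in both models AND consistency >= `consistency_threshold`;
#' `<genotypeA>_favored` / `<genotypeB>_favored` = high in exactly one model;
#' `uninformative` = everything else. The four categories partition the
#' common feature set.
#'
#' @param prof_a,prof_b [mda_importance()] profiles for the two genotypes.
#' @param importance_quantile quantile of normalized importance defining
#'   "high" (default 0.8).
#' @param consistency_threshold minimum consistency for `shared`
#'   (default 0.8).
#' @return Object of class `consistency_report`: per-feature table
#'   (feature_id, mda per genotype, normalized importances, consistency,
#'   category), Spearman `rho`/`p`, `category_counts`, genotype labels.
#' @export
categorize_features <- function(prof_a, prof_b,
                                importance_quantile = 0.8,
                                consistency_threshold = 0.8) {
  cp <- common_profiles(prof_a, prof_b)
  ga <- attr(prof_a, "genotype") %||% "A"
  gb <- attr(prof_b, "genotype") %||% "B"
  na <- normalize_importance(cp$a)
  nb <- normalize_importance(cp$b)
  cons <- 1 - abs(na - nb)
  high_a <- na >= stats::quantile(na, importance_quantile)
  high_b <- nb >= stats::quantile(nb, importance_quantile)

  category <- rep("uninformative", length(cp$ids))
  category[high_a & !high_b] <- paste0(ga, "_favored")
  category[high_b & !high_a] <- paste0(gb, "_favored")
  category[high_a & high_b & cons >= consistency_threshold] <- "shared"

  conc <- if (length(cp$ids) >= 3) rank_concordance(prof_a, prof_b)
          else list(rho = NA_real_, p = NA_real_)
  tab <- data.frame(feature_id = cp$ids,
                    mda_a = as.numeric(cp$a), mda_b = as.numeric(cp$b),
                    norm_a = as.numeric(na), norm_b = as.numeric(nb),
                    consistency = as.numeric(cons),
                    category = category,
                    row.names = NULL, stringsAsFactors = FALSE)
  lv <- c("shared", paste0(ga, "_favored"), paste0(gb, "_favored"),
          "uninformative")
  counts <- table(factor(category, levels = lv))
  structure(list(features = tab, spearman_rho = conc$rho,
                 spearman_p = conc$p, category_counts = counts,
                 genotype_a = ga, genotype_b = gb,
                 importance_quantile = importance_quantile,
                 consistency_threshold = consistency_threshold),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency_report (%s vs %s): %d features\n",
              x$genotype_a, x$genotype_b, nrow(x$features)))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$spearman_rho,
              x$spearman_p))
  print(x$category_counts)
  invisible(x)
}

#' @export
summary.consistency_report <- function(object, ...) {
  print(object)
  sh <- object$features[object$features$category == "shared", ]
  if (nrow(sh)) {
    cat(sprintf("  shared features: mean consistency %.3f\n",
                mean(sh$consistency)))
  }
  invisible(object)
}
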