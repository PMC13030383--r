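test_that("temperature classifier demands one genotype and sane classes", {
  x <- toy_omics(p = 10, reps = 3)
  expect_error(temperature_forest(x, forest_config(n_trees = 50)),
               "2 genotypes")
  one <- subset_genotype(x, "tolerant")
  drop2 <- subset_samples(one, one$metadata$temperature_C != 25 |
                            one$metadata$replicate == 1)
  expect_error(temperature_forest(drop2, forest_config(n_trees = 50)),
               "at least 2 samples")
  expect_error(forest_config(n_trees = 0), "n_trees")
})

test_that("a perfectly predictive feature drives accuracy and tops raw MDA", {
  set.seed(8)
  n_per <- 20
  labels <- factor(rep(c(25, 30, 35), each = n_per))
  n <- 3 * n_per
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", seq_len(n)), paste0("f", 1:4)))
  X[, 1] <- as.numeric(labels) + rnorm(n, 0, 0.01)
  fit <- temperature_forest(X, forest_config(n_trees = 500, seed = 3),
                            labels = labels)
  expect_gte(fit$oob_accuracy, 0.95)
  prof <- mda_importance(fit, scaled = FALSE)
  expect_identical(prof$feature_id[prof$rank == 1], "f1")
  # permuting the only informative feature sends the ensemble toward the
  # 1/3 chance floor (trees occasionally purify on noise, so allow slack)
  expect_lt(abs(prof$mda[prof$feature_id == "f1"] -
                  (fit$oob_accuracy - 1 / 3)), 0.2)
  # scaled profile ranks it first too
  expect_identical(mda_importance(fit)$feature_id[
    mda_importance(fit)$rank == 1], "f1")
})

test_that("shuffled labels give chance-level out-of-bag accuracy", {
  accs <- sapply(1:3, function(i) {
    ds <- simulate_metabolome(sim_config(n_features_metabolome = 100,
                                         seed = 60 + i))
    sub <- subset_genotype(ds$metabolome, "tolerant")
    set.seed(i)
    perm <- sample(sub$metadata$temperature_C)
    fit <- temperature_forest(t(sub$values),
                              forest_config(n_trees = 300, seed = i),
                              labels = perm)
    fit$oob_accuracy
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.2)
})

test_that("importance ranks are a strict permutation with stable ties", {
  prof <- make_profile(c(b = 0.5, a = 0.5, c = 0.1))
  expect_identical(sort(prof$rank), 1:3)
  expect_identical(prof$feature_id[prof$rank == 1], "a")  # id breaks the tie
})

test_that("rank concordance matches the tie-corrected Spearman oracle", {
  a <- make_profile(c(f1 = 5, f2 = 4, f3 = 3, f4 = 2, f5 = 1, f6 = 0.5))
  expect_equal(rank_concordance(a, a)$rho, 1)
  rev_b <- make_profile(c(f1 = 0.5, f2 = 1, f3 = 2, f4 = 3, f5 = 4, f6 = 5))
  expect_equal(rank_concordance(a, rev_b)$rho, -1)
  expect_identical(rank_concordance(a, rev_b)$p, 0)

  b <- make_profile(c(f1 = 2, f2 = 5, f3 = 2, f4 = 1, f5 = 4, f6 = 3))
  got <- rank_concordance(a, b)
  oracle <- suppressWarnings(
    cor.test(c(5, 4, 3, 2, 1, 0.5), c(2, 5, 2, 1, 4, 3),
             method = "spearman", exact = FALSE))
  expect_equal(got$rho, unname(oracle$estimate), tolerance = 1e-12)
  n <- 6
  p_oracle <- 2 * pt(-abs(got$rho * sqrt((n - 2) / (1 - got$rho^2))), n - 2)
  expect_equal(got$p, p_oracle, tolerance = 1e-12)
})

test_that("consistency scores follow the min-max agreement formula", {
  a <- make_profile(c(f1 = 10, f2 = 5, f3 = 0, f4 = -2, f5 = 7.5))
  b <- make_profile(c(f1 = 0, f2 = 2, f3 = 4, f4 = 1, f5 = 4))
  cons <- consistency_scores(a, b)
  # by hand: clip negatives, normalize a by /10, b by /4
  na <- c(1, 0.5, 0, 0, 0.75); nb <- c(0, 0.5, 1, 0.25, 1)
  expect_equal(unname(cons), 1 - abs(na - nb), tolerance = 1e-12)
  expect_identical(unname(cons["f2"]), 1)   # same normalized importance
  expect_identical(unname(cons["f1"]), 0)   # top of one, bottom of the other
  expect_true(all(cons >= 0 & cons <= 1))
})

test_that("categorization partitions features and honours the single-case rule", {
  set.seed(4)
  mda_a <- setNames(rexp(40), paste0("f", 1:40))
  mda_b <- setNames(rexp(40), paste0("f", 1:40))
  rep_ <- categorize_features(make_profile(mda_a, "sensitive"),
                              make_profile(mda_b, "tolerant"))
  expect_identical(sum(rep_$category_counts), 40L)
  expect_identical(sort(rep_$features$feature_id),
                   sort(paste0("f", 1:40)))
  expect_true(all(rep_$features$category %in%
                    c("shared", "sensitive_favored", "tolerant_favored",
                      "uninformative")))

  single <- categorize_features(make_profile(c(f1 = 3), "a"),
                                make_profile(c(f1 = 2), "b"))
  expect_identical(single$features$category, "shared")
})

test_that("categorization is equivariant under feature reordering", {
  set.seed(9)
  mda_a <- setNames(rexp(30), paste0("f", 1:30))
  mda_b <- setNames(rexp(30), paste0("f", 1:30))
  r1 <- categorize_features(make_profile(mda_a), make_profile(mda_b, "B"))
  perm <- sample(30)
  r2 <- categorize_features(make_profile(mda_a[perm]),
                            make_profile(mda_b[perm], "B"))
  m <- match(r1$features$feature_id, r2$features$feature_id)
  expect_identical(r1$features$category, r2$features$category[m])
  expect_equal(r1$spearman_rho, r2$spearman_rho, tolerance = 1e-12)
})

test_that("planted markers are recovered into the right categories", {
  ds <- simulate_dataset(sim_config(seed = 203))
  tr <- ds$truth
  fa <- temperature_forest(subset_genotype(ds$metabolome, "sensitive"),
                           forest_config(seed = 11))
  fb <- temperature_forest(subset_genotype(ds$metabolome, "tolerant"),
                           forest_config(seed = 12))
  pa <- mda_importance(fa); pb <- mda_importance(fb)
  top20a <- pa$feature_id[order(pa$rank)][1:20]
  top20b <- pb$feature_id[order(pb$rank)][1:20]
  expect_gte(sum(tr$shared_marker_ids %in% top20a), 8)
  expect_gte(sum(tr$shared_marker_ids %in% top20b), 8)

  rep_ <- categorize_features(pa, pb)
  ft <- rep_$features
  cat_of <- function(ids) ft$category[match(ids, ft$feature_id)]
  expect_gte(mean(cat_of(tr$shared_marker_ids) == "shared"), 0.7)
  expect_gte(mean(cat_of(tr$sensitive_marker_ids) == "sensitive_favored"), 0.6)
  expect_gte(mean(cat_of(tr$tolerant_marker_ids) == "tolerant_favored"), 0.6)
})
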