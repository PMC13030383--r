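test_that("PCA variance fractions match a direct eigendecomposition", {
  m <- matrix(c(1, 2, 3, 2, 4.1, 5.9, 10, 1, 7, 0, 3, 2), 4, 3)
  dimnames(m) <- list(paste0("s", 1:4), paste0("f", 1:3))
  ps <- pca_summary(m, n_components = 3, scale. = FALSE)
  ev <- eigen(cov(m))$values
  expect_equal(ps$variance_fraction, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(ps$variance_fraction) <= 1e-12))
  expect_lte(sum(ps$variance_fraction), 1 + 1e-12)
})

test_that("rank-1 data loads entirely on PC1 and constant data is flagged", {
  base <- c(1, 2, 3, 4)
  m <- outer(base, c(1, -2, 0.5, 3))
  dimnames(m) <- list(paste0("s", 1:4), paste0("f", 1:4))
  ps <- pca_summary(m, scale. = FALSE)
  expect_equal(ps$variance_fraction[1], 1, tolerance = 1e-12)

  const <- matrix(5, 4, 3, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  expect_warning(psc <- pca_summary(const), "constant")
  expect_true(all(psc$variance_fraction == 0))
})

test_that("VIP satisfies the normalization identity and ranks separators on top", {
  set.seed(1)
  X <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(paste0("s", 1:12), paste0("f", 1:10)))
  y <- rep(c("a", "b"), each = 6)
  fit <- plsda(X, y, n_components = 1)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-12)

  X2 <- X
  X2[, 3] <- ifelse(y == "a", 0, 10) + rnorm(12, 0, 0.01)
  fit2 <- plsda(X2, y, n_components = 1)
  expect_identical(names(which.max(fit2$vip)), "f3")
  expect_equal(mean(fit2$vip^2), 1, tolerance = 1e-12)
})

test_that("single-component VIP matches an independently coded NIPALS oracle", {
  X <- matrix(c(1.0, 2.1, 0.5, 3.3,
                2.0, 1.9, 1.1, 2.8,
                0.7, 2.5, 0.9, 3.0,
                1.4, 1.0, 2.2, 0.4,
                2.2, 0.8, 2.9, 0.2,
                1.8, 1.2, 2.4, 0.9), 6, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
  y <- factor(rep(c("lo", "hi"), each = 3))
  fit <- plsda(X, y, n_components = 1)

  # oracle: covariance weights of scaled X against centered one-hot response
  Xs <- scale(X)
  Y <- scale(cbind(y == "hi", y == "lo") * 1, center = TRUE, scale = FALSE)
  u <- Y[, 1]
  for (it in 1:200) {
    w <- drop(crossprod(Xs, u)); w <- w / sqrt(sum(w^2))
    tt <- drop(Xs %*% w)
    q <- drop(crossprod(Y, tt)) / sum(tt^2)
    u <- drop(Y %*% q) / sum(q^2)
  }
  vip_oracle <- sqrt(ncol(X) * w^2)  # single component: SS weights cancel
  expect_equal(unname(fit$vip), unname(vip_oracle), tolerance = 1e-8)
})

test_that("VIP agrees with the mixOmics implementation", {
  set.seed(7)
  X <- matrix(rnorm(15 * 20), 15, 20,
              dimnames = list(paste0("s", 1:15), paste0("f", 1:20)))
  y <- factor(rep(c("a", "b", "c"), each = 5))
  fit <- plsda(X, y, n_components = 2)
  mx <- mixOmics::plsda(X, y, ncomp = 2, scale = TRUE)
  expect_equal(unname(fit$vip), unname(mixOmics::vip(mx)[, 2]),
               tolerance = 1e-6)
})

test_that("plsda rejects degenerate classes and reports dropped features", {
  set.seed(2)
  X <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:5)))
  expect_error(plsda(X, c("a", rep("b", 9))), "at least 2 samples")
  X[, 2] <- 7
  expect_warning(fit <- plsda(X, rep(c("a", "b"), each = 5)), "zero-variance")
  expect_identical(fit$dropped_features, "f2")
  expect_false("f2" %in% names(fit$vip))
})

test_that("model validation honours permutation-p bounds and argument checks", {
  set.seed(3)
  y <- rep(c("a", "b"), each = 6)
  X <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("f", 1:8)))
  X[, 1] <- ifelse(y == "a", -5, 5) + rnorm(12, 0, 0.1)  # perfect separation
  val <- validate_plsda(X, y, n_components = 1, n_folds = 4,
                        n_permutations = 19, seed = 5)
  expect_equal(val$permutation_p_r2y, 1 / 20, tolerance = 1e-12)
  expect_gt(val$q2, 0.3)
  expect_lte(val$q2, val$r2y + 0.05)

  expect_error(validate_plsda(X, y, n_folds = 50), "n_folds")
  expect_error(validate_plsda(X, y, n_permutations = 0), "n_permutations")
})

test_that("univariate tests match the pooled-variance closed form", {
  m <- rbind(f1 = c(3, 4, 5, 6, 7, 8),
             f2 = c(1, 1, 1, 1, 1, 1),
             f3 = c(1, 2, 3, 2, 4, 6))
  colnames(m) <- paste0("s", 1:6)
  tt <- univariate_tests(m, paste0("s", 1:3), paste0("s", 4:6))

  oracle <- t.test(c(6, 7, 8), c(3, 4, 5), var.equal = TRUE)
  expect_equal(tt$t[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(tt$p[1], oracle$p.value, tolerance = 1e-12)

  expect_identical(tt$t[2], 0)          # identical groups
  expect_identical(tt$p[2], 1)
  expect_equal(tt$log2_fold_change[3], 1, tolerance = 1e-12)  # mean doubles

  expect_error(univariate_tests(m, "s1", paste0("s", 4:6)), "at least 2")
})

test_that("the DAM rule keeps exactly the strict VIP/p qualifiers", {
  vip <- c(a = 1.2, b = 0.9, c = 1.5, d = 1.01, e = 1.0, f = 2.0)
  tests <- data.frame(feature_id = names(vip),
                      p = c(0.01, 0.01, 0.2, 0.049, 0.01, 0.06),
                      log2_fold_change = c(2, -1, 1, -0.5, 1, 1),
                      stringsAsFactors = FALSE)
  dams <- select_dams(vip, tests)
  expect_identical(dams$feature_id[dams$selected], c("a", "d"))
  expect_identical(dams$direction[dams$selected], c("up", "down"))
  expect_identical(attr(dams, "n_up"), 1L)
  # rule holds for every member and fails for every non-member
  expect_true(all((dams$vip > 1 & dams$p < 0.05) == dams$selected))

  empty <- select_dams(numeric(), tests[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("DEG calling is calibrated on null counts and recovers planted folds", {
  set.seed(10)
  mu <- rep(2^runif(400, 5, 9), 6)
  null_counts <- matrix(rnbinom(400 * 6, mu = mu, size = 10), 400, 6,
                        dimnames = list(paste0("g", 1:400), paste0("s", 1:6)))
  degs <- select_degs(null_counts, paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(mean(degs$p < 0.05), 0.1)
  expect_lte(sum(degs$selected), 2)

  # planted two-fold shifts, balanced up/down, at low dispersion (0.01):
  # at n = 3 the standard error of log2FC is ~sqrt(2(1/mu + phi)/n)/ln2,
  # so a two-fold change is only reliably detectable once phi << 0.1
  base <- mu[1:400]
  planted <- matrix(rnbinom(400 * 6, mu = mu, size = 100), 400, 6,
                    dimnames = dimnames(null_counts))
  planted[1:20, 4:6] <- matrix(
    rnbinom(20 * 3, mu = 2 * base[1:20], size = 100), 20, 3)
  planted[21:40, 4:6] <- matrix(
    rnbinom(20 * 3, mu = 0.5 * base[21:40], size = 100), 20, 3)
  degs2 <- select_degs(planted, paste0("s", 1:3), paste0("s", 4:6),
                       lfc_threshold = 0.5)
  recall <- mean(degs2$selected[match(paste0("g", 1:40), degs2$feature_id)])
  expect_gte(recall, 0.9)

  empty <- select_degs(null_counts[0, ], paste0("s", 1:3), paste0("s", 4:6))
  expect_identical(nrow(empty), 0L)
})

test_that("Venn region counts match brute-force membership enumeration", {
  sets <- list(A = c("x", "y", "z", "w"), B = c("y", "z", "q"),
               C = c("z", "q", "r", "s"))
  vo <- venn_overlap(sets)
  ids <- unique(unlist(sets))
  brute <- table(sapply(ids, function(id)
    paste(names(sets)[sapply(sets, function(s) id %in% s)], collapse = "&")))
  for (i in seq_len(nrow(vo))) {
    expected <- if (vo$region[i] %in% names(brute)) brute[[vo$region[i]]] else 0L
    expect_identical(vo$count[i], as.integer(expected))
  }
  expect_identical(sum(vo$count), length(ids))

  disj <- venn_overlap(list(A = c("a", "b"), B = c("c")))
  expect_identical(disj$count[disj$region == "A&B"], 0L)
  same <- venn_overlap(list(A = c("a", "b"), B = c("a", "b")))
  expect_identical(same$count[same$region == "A&B"], 2L)
  expect_identical(sum(same$count), 2L)
})

test_that("k-means patterns recover planted profiles and degenerate cases", {
  set.seed(5)
  centers <- matrix(rnorm(4 * 10, sd = 3), 4, 10)
  x <- centers[rep(1:4, each = 30), ] + rnorm(120 * 10, sd = 0.3)
  dimnames(x) <- list(paste0("g", 1:120), paste0("s", 1:10))
  km <- kmeans_patterns(x, k = 4, seed = 2)
  expect_gte(ari(km$cluster, rep(1:4, each = 30)), 0.8)
  expect_identical(sort(unique(km$cluster)), 1:4)

  km1 <- kmeans_patterns(x, k = 1, seed = 2)
  z <- t(scale(t(x)))
  expect_equal(km1$tot_withinss, sum(scale(z, scale = FALSE)^2),
               tolerance = 1e-8)

  dup <- x[c(1, 1, 2, 2, 3, 3), ]
  rownames(dup) <- paste0("d", 1:6)
  km2 <- kmeans_patterns(dup, k = 3, seed = 1)
  expect_identical(unname(km2$cluster[1]), unname(km2$cluster[2]))
})

test_that("ddct reproduces hand-computed relative expression", {
  expect_identical(ddct(20, 15, 22, 17), 1)      # ddCt = 0
  expect_identical(ddct(21, 15, 22, 17), 0.5)    # ddCt = 1
  expect_identical(ddct(19, 15, 22, 17), 2)      # ddCt = -1
  expect_identical(ddct(22, 18, 25, 18), 8)      # worked case: 2^-(4-7)
})
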