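test_that("adjacency equals the elementwise |cor|^beta oracle", {
  set.seed(1)
  x <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  a <- adjacency_matrix(x, power = 9)
  cc <- abs(cor(t(x)))^9
  diag(cc) <- 0
  expect_equal(a, cc, tolerance = 1e-12)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))

  pair <- rbind(g1 = 1:10, g2 = 2 * (1:10) + 3)  # perfectly correlated
  colnames(pair) <- paste0("s", 1:10)
  expect_equal(adjacency_matrix(pair, 9)["g1", "g2"], 1, tolerance = 1e-12)
  expect_error(adjacency_matrix(x, power = 0.5), "power")
})

test_that("TOM matches a triple-loop brute-force oracle and its bounds", {
  tom_brute <- function(a) {
    n <- nrow(a)
    diag(a) <- 0
    k <- rowSums(a)
    out <- matrix(0, n, n, dimnames = dimnames(a))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    out
  }
  set.seed(2)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 20), 20)
    a <- (m + t(m)) / 2
    diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:20), paste0("g", 1:20))
    tom <- tom_similarity(a)
    expect_equal(tom, tom_brute(a), tolerance = 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
    off <- tom[upper.tri(tom)]
    bound <- (a / (max(rowSums(a)) + 1))[upper.tri(a)]
    expect_true(all(off >= bound - 1e-12))
  }
})

test_that("TOM handles complete-overlap and disconnected pairs", {
  # isolated connected pair
  a <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  a[1, 2] <- a[2, 1] <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
  expect_identical(tom[3, 4], 0)   # no edge, no shared neighbours

  bad <- a; bad[1, 3] <- 0.5
  expect_error(tom_similarity(bad), "symmetric")
  bad2 <- a; bad2[1, 2] <- bad2[2, 1] <- 1.5
  expect_error(tom_similarity(bad2), "\\[0, 1\\]")
})

test_that("module detection finds planted modules and applies the size rule", {
  pm <- planted_module_matrix(sizes = c(80, 80, 80), n_noise = 100,
                              n_samples = 40, noise_sd = 0.3, seed = 3)
  d <- tom_dissimilarity(adjacency_matrix(pm$expr, 6))
  labels <- detect_modules(d, min_module_size = 50)
  expect_identical(length(setdiff(unique(labels), "grey")), 3L)
  expect_gte(ari(labels, pm$truth), 0.8)

  small <- planted_module_matrix(sizes = 30, n_noise = 200, n_samples = 20,
                                 noise_sd = 0.3, seed = 4)
  d2 <- tom_dissimilarity(adjacency_matrix(small$expr, 6))
  lab2 <- detect_modules(d2, min_module_size = 50)
  expect_true(all(lab2[names(small$truth)[small$truth == 1]] == "grey"))

  set.seed(5)
  noise <- matrix(rnorm(300 * 18), 300, 18,
                  dimnames = list(paste0("g", 1:300), paste0("s", 1:18)))
  lab3 <- detect_modules(tom_dissimilarity(adjacency_matrix(noise, 9)), 50)
  expect_gte(mean(lab3 == "grey"), 0.9)
})

test_that("eigengenes are unit-norm, sign-oriented and match direct SVD", {
  set.seed(6)
  profile <- rnorm(12)
  x <- matrix(rep(profile, each = 10), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  labels <- setNames(rep("M1", 10), rownames(x))
  eg <- module_eigengenes(x + rnorm(120, 0, 1e-6), labels)
  expect_equal(sum(eg^2), 1, tolerance = 1e-8)
  expect_gt(cor(eg[1, ], profile), 0.999)   # equals the common profile

  y <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  eg1 <- module_eigengenes(y, labels)
  sv <- svd(scale(t(y)))$u[, 1]
  expect_equal(abs(cor(eg1[1, ], sv)), 1, tolerance = 1e-8)
  # flipping every gene leaves the oriented eigengene invariant
  eg2 <- module_eigengenes(max(y) - y, labels)
  expect_equal(abs(cor(eg1[1, ], eg2[1, ])), 1, tolerance = 1e-6)
})

test_that("module merging fuses same-factor modules and respects cut 0", {
  set.seed(7)
  f <- rnorm(20)
  x <- rbind(t(sapply(1:30, function(i) f + rnorm(20, 0, 0.2))),
             t(sapply(1:30, function(i) f + rnorm(20, 0, 0.2))),
             t(sapply(1:30, function(i) rnorm(20))))
  dimnames(x) <- list(paste0("g", 1:90), paste0("s", 1:20))
  labels <- setNames(c(rep("M1", 30), rep("M2", 30), rep("M3", 30)),
                     rownames(x))
  merged <- merge_modules(x, labels, cut_height = 0.25)
  expect_identical(length(setdiff(unique(merged$labels), "grey")), 2L)
  same <- merged$labels[c("g1", "g31")]
  expect_identical(unname(same[1]), unname(same[2]))  # M1+M2 fused
  # orthogonal module M3 untouched as a unit
  expect_identical(length(unique(merged$labels[paste0("g", 61:90)])), 1L)

  none <- merge_modules(x, labels, cut_height = 0)
  expect_identical(sort(unique(none$labels)), c("M1", "M2", "M3"))
})

test_that("module-trait correlation matches cor.test and handles alignment", {
  set.seed(8)
  eg <- matrix(rnorm(3 * 15), 3, 15,
               dimnames = list(paste0("M", 1:3), paste0("s", 1:15)))
  traits <- matrix(rnorm(2 * 15), 2, 15,
                   dimnames = list(c("t1", "t2"), paste0("s", 1:15)))
  mt <- module_trait_correlation(eg, traits)
  oracle <- cor.test(eg[2, ], traits[1, ])
  expect_equal(mt$r["M2", "t1"], unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(mt$p["M2", "t1"], oracle$p.value, tolerance = 1e-10)

  self <- module_trait_correlation(eg, eg[1, ])
  expect_equal(unname(self$r["M1", 1]), 1, tolerance = 1e-12)
  expect_lt(self$p["M1", 1], 1e-12)

  flat <- matrix(1, 1, 15, dimnames = list("flat", paste0("s", 1:15)))
  expect_warning(mtf <- module_trait_correlation(eg, flat), "near-constant")
  expect_true(all(mtf$r == 0))
})

test_that("trait alignment matches replicates or broadcasts group means", {
  ds <- simulate_dataset(sim_config(seed = 9))
  tid <- ds$truth$trait_assignments$feature_id[1]
  md_t <- ds$transcriptome$metadata

  rep_al <- align_traits(ds$metabolome, tid, md_t, method = "replicate")
  expect_identical(colnames(rep_al), md_t$sample_id)
  key_m <- with(ds$metabolome$metadata, paste(genotype, temperature_C, replicate))
  key_t <- with(md_t, paste(genotype, temperature_C, replicate))
  expect_equal(unname(rep_al[1, ]),
               unname(ds$metabolome$values[tid, match(key_t, key_m)]))

  gm <- align_traits(ds$metabolome, tid, md_t, method = "group_mean")
  grp_m <- with(ds$metabolome$metadata, paste(genotype, temperature_C))
  first <- paste(md_t$genotype[1], md_t$temperature_C[1])
  expect_equal(unname(gm[1, 1]),
               mean(ds$metabolome$values[tid, grp_m == first]))
  expect_error(align_traits(ds$metabolome, "nope", md_t), "absent")
})

test_that("soft threshold picks a power with a scale-free fit on hub data", {
  set.seed(42)
  n <- 150; p <- 400
  f <- rnorm(n)
  rho <- runif(p)^3 * 0.9
  X <- t(sapply(seq_len(p), function(j)
    sqrt(rho[j]) * f + sqrt(1 - rho[j]) * rnorm(n)))
  dimnames(X) <- list(paste0("g", 1:p), paste0("s", 1:n))
  st <- pick_soft_threshold(X)
  expect_gte(st$table$signed_r2[st$table$power == st$power], 0.8)
  expect_true(all(diff(st$table$mean_connectivity) <= 1e-9))

  set.seed(43)
  flatX <- matrix(rnorm(100 * 40), 100, 40,
                  dimnames = list(paste0("g", 1:100), paste0("s", 1:40)))
  st2 <- pick_soft_threshold(flatX, candidate_powers = 1:3)
  expect_lt(st2$table$signed_r2[1], 0.8)  # dense null is not scale-free
})

test_that("end-to-end module pipeline recovers planted structure", {
  ds <- simulate_dataset(sim_config(seed = 103))
  ms <- coexpression_modules(ds$transcriptome)
  truth <- ds$truth$module_membership[names(ms$labels)]
  expect_gte(ari(ms$labels, truth), 0.75)
  non_grey <- setdiff(unique(ms$labels), "grey")
  expect_identical(nrow(ms$eigengenes), length(non_grey))
  expect_true(all(table(ms$labels)[non_grey] >= 50))
  # gene-order equivariance
  set.seed(13)
  perm <- sample(nrow(ds$transcriptome$values))
  x2 <- omics_matrix(ds$transcriptome$values[perm, ],
                     ds$transcriptome$metadata, role = "transcriptome")
  ms2 <- coexpression_modules(x2)
  expect_gte(ari(ms$labels, ms2$labels[names(ms$labels)]), 0.95)
})
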