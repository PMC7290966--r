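test_that("pearson_correlation_matrix matches a direct-formula oracle", {
  s <- cbind(a = 1:5, b = 1:5, c = 5:1)
  fc <- pearson_correlation_matrix(s)
  expect_equal(fc$r[1, 2], 1)
  expect_equal(fc$r[1, 3], -1)
  expect_identical(unname(diag(fc$r)), rep(1, 3))

  withr::with_seed(5, {
    x <- matrix(rnorm(80), 20, 4)
    fc <- pearson_correlation_matrix(x)
    # independent textbook cov/(sd*sd) loop
    for (i in 1:4) for (j in 1:4) {
      num <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j])))
      den <- sqrt(sum((x[, i] - mean(x[, i]))^2) * sum((x[, j] - mean(x[, j]))^2))
      expect_equal(fc$r[i, j], num / den, tolerance = 1e-12)
    }
  })
  expect_error(pearson_correlation_matrix(matrix(1, 2, 3)), "3 time points")
})

test_that("zero-variance regions are flagged, zeroed, never NaN", {
  s <- cbind(rnorm(10), rep(2, 10), rnorm(10))
  fc <- pearson_correlation_matrix(s)
  expect_identical(fc$degenerate, 2L)
  expect_equal(fc$r[2, c(1, 3)], c(0, 0))
  expect_equal(fc$r[2, 2], 1)
  expect_false(any(is.na(fc$r)))
  # a frozen ferromagnetic trace gives an all-degenerate, flagged FC
  tr <- simulate_at_temperature(uniform_J(4, 1),
                                sim_params(temperature = 1e-6, seed = 3,
                                           n_equil_sweeps = 200,
                                           n_samples = 50,
                                           sample_interval_sweeps = 1))
  fcz <- pearson_correlation_matrix(tr$samples, kind = "simulated")
  expect_identical(fcz$degenerate, 1:4)
  expect_false(any(is.na(fcz$r)))
})

test_that("average_fc_over_runs is the entrywise mean with unit diagonal", {
  A <- pearson_correlation_matrix(matrix(rnorm(40), 10, 4))
  B <- pearson_correlation_matrix(matrix(rnorm(40), 10, 4))
  expect_equal(average_fc_over_runs(list(A, A))$r, A$r)
  M <- average_fc_over_runs(list(A, B))
  expect_equal(M$r[1, 2], (A$r[1, 2] + B$r[1, 2]) / 2)
  neg <- A; neg$r <- -A$r; diag(neg$r) <- 1
  zero <- average_fc_over_runs(list(A, neg))
  expect_true(all(abs(zero$r[upper.tri(zero$r)]) < 1e-12))
  expect_identical(diag(zero$r), rep(1, 4))
  # mean of 10 random matrices equals a per-entry loop mean
  fcs <- replicate(10, pearson_correlation_matrix(matrix(rnorm(40), 10, 4)),
                   simplify = FALSE)
  M10 <- average_fc_over_runs(fcs)
  manual <- Reduce(`+`, lapply(fcs, function(f) f$r)) / 10
  diag(manual) <- 1
  expect_equal(M10$r, manual, tolerance = 1e-12)
  expect_error(average_fc_over_runs(list()), "empty")
})

test_that("Mantel statistic is exact and the sampled p matches enumeration (N=4)", {
  withr::with_seed(31, {
    A <- random_J(4); A <- A + t(A); diag(A) <- 1
    B <- random_J(4); B <- B + t(B); diag(B) <- 1
  })
  # observed r equals brute-force Pearson over the 6 upper-triangle pairs
  a <- A[upper.tri(A)]; b <- B[upper.tri(B)]
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- mantel_test(A, B, n_permutations = 10000, seed = 77)
  expect_equal(res$r, r_manual, tolerance = 1e-14)

  # exact exceedance probability over all 24 node permutations
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  r_perm <- apply(perms, 1, function(p) {
    bp <- B[p, p][upper.tri(B)]
    stats::cor(a, bp)
  })
  p_exact <- mean(r_perm >= res$r - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / res$n_permutations)
  expect_lt(abs(res$p - p_exact), 4 * se + 2 / res$n_permutations)
})

test_that("Mantel handles identity, negation, degeneracy and symmetry", {
  withr::with_seed(9, {
    A <- random_J(6); A <- A + t(A); diag(A) <- 1
  })
  expect_equal(mantel_test(A, A, n_permutations = 10, seed = 1)$r, 1)
  B <- -A; diag(B) <- 1
  expect_equal(mantel_test(A, B, n_permutations = 10, seed = 1)$r, -1)
  # constant triangle -> degenerate r = 0, p = 1
  C <- matrix(0.5, 6, 6); diag(C) <- 1
  res <- mantel_test(A, C, n_permutations = 10, seed = 1)
  expect_true(res$degenerate)
  expect_identical(c(res$r, res$p), c(0, 1))
  # statistic symmetric in its arguments; invariant under joint relabelling
  D <- A + matrix(rnorm(36, sd = 0.1), 6, 6); D <- (D + t(D)) / 2; diag(D) <- 1
  expect_equal(mantel_r(A, D), mantel_r(D, A), tolerance = 1e-14)
  p <- sample(6)
  expect_equal(mantel_r(A[p, p], D[p, p]), mantel_r(A, D), tolerance = 1e-12)
})

test_that("Mantel test agrees with an established implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(13, {
    A <- random_J(10); A <- A + t(A); diag(A) <- 0
    B <- A + matrix(rnorm(100, sd = 0.3), 10, 10); B <- (B + t(B)) / 2
    diag(B) <- 0
  })
  ours <- mantel_test(A, B, n_permutations = 999, seed = 5)
  ref <- withr::with_seed(6, vegan::mantel(A, B, permutations = 999))
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("sampled Mantel p-values are super-uniform under the null", {
  withr::with_seed(41, {
    A <- random_J(8); A <- A + t(A); diag(A) <- 1
    ps <- replicate(200, {
      p <- sample(8)
      B <- A[p, p] + matrix(rnorm(64, sd = 0.5), 8, 8)
      B <- (B + t(B)) / 2; diag(B) <- 1
      mantel_test(A, B, n_permutations = 99)$p
    })
  })
  for (alpha in c(0.05, 0.1)) {
    expect_lt(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
  }
})

test_that("find_tstar is the argmax of the Mantel curve over the grid", {
  # mock sweep with three fixed simulated FCs
  base <- diag(4)
  mk <- function(v) {
    r <- base; r[upper.tri(r)] <- v; r <- r + t(r); diag(r) <- 1
    fc_obj <- pearson_correlation_matrix(matrix(rnorm(40), 10, 4))
    fc_obj$r <- r
    fc_obj
  }
  emp <- sims <- NULL
  withr::with_seed(55, {
    emp <- mk(c(0.9, 0.1, 0.3, 0.2, 0.8, 0.4))
    sims <- list(mk(rev(c(0.9, 0.1, 0.3, 0.2, 0.8, 0.4))),
                 mk(c(0.9, 0.1, 0.3, 0.2, 0.8, 0.4) + rnorm(6, sd = 0.01)),
                 mk(runif(6)))
  })
  sweep <- structure(list(temperatures = c(1, 2, 3), fc_mean = sims),
                     class = "susceptibility_curve")
  ts <- find_tstar(empirical = emp, sweep = sweep)
  expect_equal(ts$T_star, 2)
  expect_equal(ts$best_r, max(ts$mantel_curve))
  expect_true(ts$T_star %in% sweep$temperatures)
  expect_length(ts$mantel_curve, 3)
})

test_that("direct SC-FC correlation is affine-invariant with a hand oracle", {
  J <- normalize_coupling(random_J(5) + 0.05)
  fc <- 2 * J + 0.1; diag(fc) <- 1
  expect_equal(direct_sc_fc_correlation(J, fc), 1, tolerance = 1e-12)
  # hand-computed Pearson on a 4x4 instance (6 pairs)
  J4 <- matrix(0, 4, 4)
  J4[upper.tri(J4)] <- c(1, 2, 3, 4, 5, 6) / 6
  J4 <- J4 + t(J4)
  f4 <- matrix(0, 4, 4)
  f4[upper.tri(f4)] <- c(0.2, 0.1, 0.5, 0.3, 0.9, 0.4)
  f4 <- f4 + t(f4); diag(f4) <- 1
  expect_equal(direct_sc_fc_correlation(J4, f4),
               stats::cor(c(1, 2, 3, 4, 5, 6), c(0.2, 0.1, 0.5, 0.3, 0.9, 0.4)),
               tolerance = 1e-12)
  # independent random structure and function are near-uncorrelated
  withr::with_seed(3, {
    J84 <- normalize_coupling(random_J(84) + 1)
    r84 <- random_J(84); r84 <- r84 + t(r84); diag(r84) <- 1
  })
  expect_lt(abs(direct_sc_fc_correlation(J84, r84)), 0.1)
})

test_that("select_best_scan prefers the highest r with ties to t1", {
  mk <- function(r) structure(list(best_r = r), class = "tstar_result")
  expect_identical(select_best_scan(list(t1 = mk(0.30), t2 = mk(0.35))), "t2")
  expect_identical(select_best_scan(list(t1 = mk(0.30), t2 = mk(0.30))), "t1")
  expect_identical(select_best_scan(list(t2 = mk(0.2))), "t2")
  expect_error(select_best_scan(list()), "no scans")
})
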