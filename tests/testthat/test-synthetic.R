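test_that("lattice connectome has the right combinatorics", {
  Lp <- lattice_connectome(3, periodic = TRUE)
  expect_identical(dim(Lp), c(9L, 9L))
  expect_true(all(rowSums(Lp > 0) == 4))
  expect_identical(sum(Lp > 0), 36L)
  expect_identical(Lp, t(Lp))
  expect_true(all(diag(Lp) == 0))

  Lo <- lattice_connectome(3, periodic = FALSE)
  expect_identical(min(rowSums(Lo > 0)), 2)   # corners
  expect_identical(max(rowSums(Lo > 0)), 4)   # centre
  expect_error(lattice_connectome(1), "side")
})

test_that("geometric connectome follows its closed-form weight law", {
  # without Poisson rounding the weights are exactly (eps + dist)^-alpha,
  # rescaled to max_count
  raw <- geometric_connectome(n = 12, dim = 2, alpha = 1.5, seed = 3,
                              poisson = FALSE, max_count = 1e4)
  x <- attr(raw, "coordinates")
  d <- as.matrix(dist(x))
  w <- (1e-3 + d)^(-1.5); diag(w) <- 0
  expect_equal(unname(raw), unname(w / max(w) * 1e4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(raw, t(raw))
  expect_true(all(diag(raw) == 0) && all(raw >= 0))
  # Poisson-rounded counts are integers with max near max_count
  cnt <- geometric_connectome(n = 30, seed = 5, max_count = 1e4)
  expect_true(all(cnt == round(cnt)))
  expect_lt(abs(max(cnt) - 1e4) / 1e4, 0.1)
  expect_error(geometric_connectome(n = 10, alpha = 0), "alpha")
})

test_that("log-weight regression on log-distance recovers -alpha", {
  alpha <- 1.5
  raw <- geometric_connectome(n = 200, dim = 2, alpha = alpha, seed = 9,
                              poisson = FALSE)
  d <- as.matrix(dist(attr(raw, "coordinates")))
  ut <- upper.tri(d)
  fit <- stats::lm(log(raw[ut]) ~ log(d[ut]))
  expect_lt(abs(unname(coef(fit)[2]) + alpha), 0.05)
})

test_that("lesioning deletes the requested edge fraction and renormalizes", {
  raw <- geometric_connectome(n = 40, seed = 2)
  J <- normalize_coupling(raw)
  n_edges <- sum(J[upper.tri(J)] > 0)

  ident <- lesion_connectome(J, 0, attenuation = 1, seed = 1)
  expect_equal(unname(ident), unname(J), tolerance = 1e-12)

  les <- lesion_connectome(J, 0.5, attenuation = 0.7, seed = 1)
  kept <- sum(les[upper.tri(les)] > 0)
  expect_equal(kept, round(0.5 * n_edges))
  expect_identical(les, t(les))
  expect_true(all(diag(les) == 0))
  expect_equal(max(les), 1)
  expect_error(lesion_connectome(J, 1, seed = 1), "every edge")
})

test_that("synthetic BOLD reproduces the spin FC exactly at zero noise", {
  J <- normalize_coupling(geometric_connectome(n = 25, seed = 4))
  T0 <- mean_field_tc(J) * 0.7
  b <- synth_bold(J, T0, n_timepoints = 60, noise_sigma = 0, seed = 6)
  expect_identical(dim(b), c(60L, 25L))
  expect_true(all(b %in% c(-1, 1)))
  b2 <- synth_bold(J, T0, n_timepoints = 60, noise_sigma = 0.3, seed = 6)
  # the noiseless series is the underlying spin trace of the noisy one
  expect_true(all(abs(b2 - b) < 5 * 0.3 + 1e-9))
  expect_false(identical(b, b2))
})

test_that("synthetic cohorts honour the design counts and are reproducible", {
  spec <- cohort_spec(n_regions = 20, scan_length = 30,
                      sim = sim_params(n_equil_sweeps = 50, n_samples = 50,
                                       sample_interval_sweeps = 1),
                      master_seed = 7)
  coh <- synth_cohort(spec)
  expect_length(coh$subjects, 38)  # 25 + 6 + 3 + 4
  expect_identical(sum(lengths(lapply(coh$subjects, `[[`, "bold"))), 76L)
  groups <- vapply(coh$subjects, `[[`, character(1), "group")
  expect_identical(sum(groups == "HC"), 25L)
  expect_identical(sum(groups == "VS_UWS"), 6L)
  expect_identical(sum(groups == "MCS_MINUS"), 3L)
  expect_identical(sum(groups == "MCS_PLUS"), 4L)
  coh2 <- synth_cohort(spec)
  expect_identical(coh, coh2)
  # every generated connectome satisfies the coupling invariants
  for (s in coh$subjects[c(1, 26, 32, 36)]) {
    expect_identical(s$J, t(s$J))
    expect_true(all(diag(s$J) == 0) && all(s$J >= 0) && max(s$J) == 1)
    expect_identical(dim(s$bold$t1), c(30L, 20L))
  }
  # sidecar reproduces a subject's scan from its recorded seeds
  sid <- names(coh$subjects)[1]
  gt <- coh$ground_truth[[sid]]
  b <- synth_bold(coh$subjects[[sid]]$J, gt$T0, spec$scan_length,
                  spec$noise_sigma, seed = gt$seed_scans[["t1"]],
                  params = spec$sim)
  expect_identical(b, coh$subjects[[sid]]$bold$t1)
})

test_that("group edge density decreases with lesion severity", {
  dens <- matrix(NA_real_, 3, 4,
                 dimnames = list(NULL, c("HC", "MCS_PLUS", "MCS_MINUS", "VS_UWS")))
  for (s in 1:3) {
    spec <- cohort_spec(n_regions = 24,
                        n_per_group = c(HC = 2, VS_UWS = 2, MCS_MINUS = 2,
                                        MCS_PLUS = 2),
                        scan_length = 30,
                        sim = sim_params(n_equil_sweeps = 40, n_samples = 40,
                                         sample_interval_sweeps = 1),
                        master_seed = 100 + s)
    coh <- synth_cohort(spec)
    for (g in colnames(dens)) {
      Js <- lapply(Filter(function(x) x$group == g, coh$subjects), `[[`, "J")
      dens[s, g] <- mean(vapply(Js, function(J)
        mean(J[upper.tri(J)] > 0), numeric(1)))
    }
  }
  avg <- colMeans(dens)
  expect_true(avg["HC"] > avg["MCS_PLUS"])
  expect_true(avg["MCS_PLUS"] > avg["MCS_MINUS"])
  expect_true(avg["MCS_MINUS"] > avg["VS_UWS"])
})

test_that("written cohorts round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_regions = 15,
                      n_per_group = c(HC = 2, VS_UWS = 1, MCS_MINUS = 0,
                                      MCS_PLUS = 0),
                      lesion_fraction = c(HC = 0, MCS_PLUS = 0.1,
                                          MCS_MINUS = 0.2, VS_UWS = 0.3),
                      scan_length = 20,
                      sim = sim_params(n_equil_sweeps = 30, n_samples = 30,
                                       sample_interval_sweeps = 1),
                      master_seed = 11)
  coh <- synth_cohort(spec)
  man <- write_cohort(coh, dir)
  recs <- read_manifest(man)
  expect_length(recs, 3)
  rec <- load_subject(recs[[1]])
  sub <- coh$subjects[[rec$subject_id]]
  expect_equal(unname(rec$connectome), unname(sub$connectome),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(rec$bold$t1), unname(sub$bold$t1), tolerance = 1e-9)
})
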