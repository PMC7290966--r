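#' Square-lattice coupling matrix
#'
#' 2-D nearest-neighbour lattice of `side^2` nodes with unit couplings —
#' the classical ferromagnet whose exactly known critical point anchors
#' the engine's correctness checks.
#'
#' @param side Lattice side (>= 2).
#' @param periodic Wrap edges toroidally (default `TRUE`).
#' @return Coupling matrix of size `side^2`.
#' @export
lattice_connectome <- function(side, periodic = TRUE) {
  stopifnot(side >= 2)
  n <- side * side
  J <- matrix(0, n, n)
  id <- function(r, c) (r - 1L) * side + c
  for (r in seq_len(side)) for (c in seq_len(side)) {
    i <- id(r, c)
    for (step in list(c(1L, 0L), c(0L, 1L))) {
      rr <- r + step[1]; cc <- c + step[2]
      if (rr > side || cc > side) {
        if (!periodic) next
        rr <- ((rr - 1L) %% side) + 1L
        cc <- ((cc - 1L) %% side) + 1L
      }
      j <- id(rr, cc)
      if (i != j) J[i, j] <- J[j, i] <- 1
    }
  }
  validate_coupling(J)
  J
}

#' Geometric synthetic connectome
#'
#' Emulates a streamline-count structural connectome: `n` regions placed
#' uniformly in the unit `dim`-cube, raw weight
#' `w_ij = (eps + ||x_i - x_j||)^(-alpha)` with `eps = 1e-3`, rescaled so
#' the largest weight is about `max_count` and Poisson-rounded to integer
#' pseudo-streamline counts. Returns the raw count matrix (normalize with
#' [normalize_coupling()]); the generating coordinates are attached as
#' attribute `coordinates`.
#'
#' @param n Number of regions (>= dim + 2; default 84).
#' @param dim Embedding dimension (default 2).
#' @param alpha Positive distance-decay exponent (default 1.5).
#' @param seed Integer seed.
#' @param max_count Approximate largest streamline count (default 1e4).
#' @param poisson Apply Poisson rounding (default `TRUE`; `FALSE` keeps the
#'   continuous weights, useful for closed-form checks).
#' @return Symmetric non-negative count matrix with zero diagonal.
#' @export
geometric_connectome <- function(n = 84L, dim = 2L, alpha = 1.5, seed = 1L,
                                 max_count = 1e4, poisson = TRUE) {
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(n >= dim + 2)
  with_seed(seed, {
    x <- matrix(runif(n * dim), nrow = n, ncol = dim)
    d <- as.matrix(stats::dist(x))
    w <- (1e-3 + d)^(-alpha)
    diag(w) <- 0
    w <- w / max(w) * max_count
    counts <- matrix(0, n, n)
    iu <- which(upper.tri(w))
    counts[iu] <- if (poisson) rpois(length(iu), w[iu]) else w[iu]
    counts <- counts + t(counts)
    attr(counts, "coordinates") <- x
    counts
  })
}

#' Lesion a connectome
#'
#' Emulates diffuse structural damage: deletes a uniformly random fraction
#' of the existing edges (both symmetric entries zeroed) and multiplies the
#' survivors by a global attenuation factor, then renormalizes the result
#' to maximum 1.
#'
#' @param J Coupling (or raw count) matrix.
#' @param edge_delete_fraction Fraction of existing edges to delete, in
#'   `[0, 1]`.
#' @param attenuation Multiplier in `(0, 1]` applied to surviving edges.
#' @param seed Integer seed.
#' @return Lesioned, max-one-normalized coupling matrix.
#' @export
lesion_connectome <- function(J, edge_delete_fraction, attenuation = 1,
                              seed = 1L) {
  stopifnot(edge_delete_fraction >= 0, edge_delete_fraction <= 1,
            attenuation > 0, attenuation <= 1)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  iu <- which(upper.tri(J) & J > 0)
  if (!length(iu)) stop("connectome has no edges to lesion")
  n_del <- round(edge_delete_fraction * length(iu))
  if (n_del >= length(iu)) stop("lesion would delete every edge")
  out <- with_seed(derive_seed(seed, "lesion"), {
    kill <- if (n_del > 0) sample(iu, n_del) else integer(0)
    Jl <- J * attenuation
    Jl[kill] <- 0
    Jl[lower.tri(Jl)] <- 0
    Jl + t(Jl)
  })
  normalize_coupling(out)
}

#' BOLD-like surrogate scan
#'
#' Runs the spin model at temperature `T0`, takes the sampled spin vectors
#' as a time-by-regions series and adds independent Gaussian noise — a
#' minimal surrogate for a region-averaged resting-state BOLD acquisition
#' whose correlation structure is induced by the connectome.
#'
#' @param J Coupling matrix.
#' @param T0 Generating temperature (> 0).
#' @param n_timepoints Number of time points (default 480).
#' @param noise_sigma Gaussian noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @param params Template [sim_params()] for equilibration/interval
#'   settings.
#' @return Numeric `n_timepoints` x `N` matrix.
#' @export
synth_bold <- function(J, T0, n_timepoints = 480L, noise_sigma = 0.3,
                       seed = 1L, params = sim_params()) {
  stopifnot(T0 > 0, n_timepoints >= 3, noise_sigma >= 0)
  p <- params
  p$temperature <- T0
  p$n_samples <- as.integer(n_timepoints)
  p$seed <- derive_seed(seed, "bold-trace")
  tr <- simulate_at_temperature(J, p)
  series <- tr$samples * 1.0
  if (noise_sigma > 0) {
    series <- series + with_seed(derive_seed(seed, "bold-noise"), {
      matrix(rnorm(length(series), sd = noise_sigma), nrow = nrow(series))
    })
  }
  series
}

#' Synthetic cohort specification
#'
#' Defaults mirror the study design this package targets: 84 regions, 25
#' healthy controls and 6/3/4 patients in the VS/UWS, MCS- and MCS+ groups,
#' two 480-point scans per subject. Patient groups receive increasingly
#' severe random-edge-deletion lesions along MCS+ -> MCS- -> VS/UWS.
#'
#' @param n_regions Regions per connectome.
#' @param n_per_group Named counts for `HC`, `VS_UWS`, `MCS_MINUS`,
#'   `MCS_PLUS`.
#' @param embedding_dim Spatial dimension of the geometric generator.
#' @param decay_alpha Distance-decay exponent.
#' @param lesion_fraction Named per-group edge-deletion fractions
#'   (non-decreasing along MCS+ -> MCS- -> VS/UWS; HC must be 0).
#' @param attenuation Survivor attenuation for lesioned groups.
#' @param scan_length Time points per scan.
#' @param noise_sigma BOLD noise standard deviation.
#' @param master_seed Master seed for the whole cohort.
#' @param sim Template [sim_params()] used when generating scans.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 84L,
                        n_per_group = c(HC = 25L, VS_UWS = 6L,
                                        MCS_MINUS = 3L, MCS_PLUS = 4L),
                        embedding_dim = 2L, decay_alpha = 1.5,
                        lesion_fraction = c(HC = 0, MCS_PLUS = 0.15,
                                            MCS_MINUS = 0.3, VS_UWS = 0.45),
                        attenuation = 0.7, scan_length = 480L,
                        noise_sigma = 0.3, master_seed = 1L,
                        sim = sim_params(n_equil_sweeps = 500,
                                         n_samples = 500,
                                         sample_interval_sweeps = 1)) {
  stopifnot(all(.groups %in% names(n_per_group)),
            all(n_per_group >= 0),
            all(.groups %in% names(lesion_fraction)))
  lf <- lesion_fraction
  stopifnot(lf[["HC"]] == 0, all(lf >= 0), all(lf < 1),
            lf[["MCS_PLUS"]] <= lf[["MCS_MINUS"]],
            lf[["MCS_MINUS"]] <= lf[["VS_UWS"]])
  structure(list(n_regions = as.integer(n_regions),
                 n_per_group = n_per_group, embedding_dim = as.integer(embedding_dim),
                 decay_alpha = decay_alpha, lesion_fraction = lf,
                 attenuation = attenuation, scan_length = as.integer(scan_length),
                 noise_sigma = noise_sigma, master_seed = master_seed,
                 sim = sim),
            class = "cohort_spec")
}

# Coarse susceptibility-peak estimate used to pick the generating
# temperature of synthetic scans (the cohort emulates brains operating
# near criticality).
coarse_tc <- function(J, master_seed, subject_id, n_points = 12L,
                      n_runs = 2L, sim = sim_params(n_equil_sweeps = 300,
                                                    n_samples = 300,
                                                    sample_interval_sweeps = 1)) {
  sweep <- temperature_sweep(J, grid = default_temperature_grid(J, n_points),
                             params = sim, n_runs = n_runs,
                             master_seed = master_seed,
                             subject_id = paste0(subject_id, "-coarse"),
                             retain = "none")
  find_critical_temperature(sweep)$Tc
}

#' Generate a synthetic cohort
#'
#' Builds a full in-memory cohort with known ground truth: healthy
#' controls get intact geometric connectomes, patient groups get lesioned
#' variants with group-specific severity, and every subject gets two
#' BOLD-like scans generated near the subject's own critical temperature.
#' Identical `master_seed` gives a byte-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort` with `subjects` (each holding
#'   `subject_id`, `group`, `connectome` raw counts or lesioned couplings,
#'   `J` normalized coupling, `bold` list of scans `t1`/`t2`) and
#'   `ground_truth` sidecar (per-subject generating temperature, lesion
#'   parameters, seeds, and the spec).
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ms <- spec$master_seed
  subjects <- list()
  truth <- list()
  counter <- 0L
  for (grp in .groups) {
    n_g <- spec$n_per_group[[grp]]
    if (n_g == 0) next
    for (k in seq_len(n_g)) {
      counter <- counter + 1L
      sid <- sprintf("%s-%02d", sub("_", "", grp), k)
      seed_conn <- derive_seed(ms, sid, "connectome")
      raw <- geometric_connectome(spec$n_regions, spec$embedding_dim,
                                  spec$decay_alpha, seed = seed_conn)
      lf <- spec$lesion_fraction[[grp]]
      J <- if (lf > 0)
        lesion_connectome(raw, lf, spec$attenuation,
                          seed = derive_seed(ms, sid, "lesion"))
      else normalize_coupling(raw)
      T0 <- coarse_tc(J, ms, sid, sim = sim_params(
        n_equil_sweeps = min(300L, spec$sim$n_equil_sweeps),
        n_samples = min(300L, spec$sim$n_samples),
        sample_interval_sweeps = 1L))
      bold <- list()
      for (scan in c("t1", "t2")) {
        bold[[scan]] <- synth_bold(J, T0, spec$scan_length, spec$noise_sigma,
                                   seed = derive_seed(ms, sid, "scan", scan),
                                   params = spec$sim)
      }
      subjects[[sid]] <- list(subject_id = sid, group = grp,
                              connectome = raw, J = J, bold = bold)
      truth[[sid]] <- list(subject_id = sid, group = grp,
                           embedding_dim = spec$embedding_dim,
                           decay_alpha = spec$decay_alpha,
                           lesion_fraction = lf,
                           attenuation = if (lf > 0) spec$attenuation else 1,
                           T0 = T0,
                           seed_connectome = seed_conn,
                           seed_lesion = if (lf > 0) derive_seed(ms, sid, "lesion") else NA,
                           seed_scans = c(t1 = derive_seed(ms, sid, "scan", "t1"),
                                          t2 = derive_seed(ms, sid, "scan", "t2")))
    }
  }
  structure(list(subjects = subjects, ground_truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      paste(names(table(groups)), table(groups), sep = ":", collapse = ", "),
      "),", x$spec$n_regions, "regions,", x$spec$scan_length,
      "time points per scan\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes each connectome and scan as delimited text, a TSV manifest
#' readable by [read_manifest()], and a JSON ground-truth sidecar (when
#' jsonlite is available; otherwise an R `dput` sidecar).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    cpath <- file.path(dir, paste0(s$subject_id, "_connectome.csv"))
    write_matrix(s$connectome, cpath)
    bpaths <- vapply(names(s$bold), function(lab) {
      p <- file.path(dir, paste0(s$subject_id, "_bold_", lab, ".csv"))
      write_matrix(s$bold[[lab]], p)
      p
    }, character(1))
    list(subject_id = s$subject_id, group = s$group,
         connectome_path = basename(cpath),
         bold_t1_path = basename(bpaths[["t1"]]),
         bold_t2_path = if ("t2" %in% names(bpaths)) basename(bpaths[["t2"]]) else "")
  })
  manifest <- file.path(dir, "manifest.tsv")
  keys <- c("subject_id", "group", "connectome_path", "bold_t1_path", "bold_t2_path")
  lines <- vapply(rows, function(r)
    paste(vapply(keys, function(k) as.character(r[[k]]), character(1)),
          collapse = "\t"), character(1))
  writeLines(c(paste(keys, collapse = "\t"), lines), manifest)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dput(cohort$ground_truth, file.path(dir, "ground_truth.R"))
  }
  invisible(manifest)
}
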