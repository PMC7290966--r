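#' Run the full analysis over a cohort
#'
#' Fits every subject with [gim_fit()], assembles the per-subject results
#' table, and runs the group-comparison battery on each outcome (`Tc`,
#' `T_star`, `best_r`, `direct_r`, `D`): healthy controls versus all
#' patients (Welch t), a four-level one-way ANOVA, post-hoc
#' patient-group-versus-HC Welch t-tests with Benjamini-Hochberg
#' adjustment, and a paired t-test between the two scans' `T*` values. A
#' subject whose fit fails is recorded and skipped; the statistics run on
#' the survivors and are skipped (with a warning record) when fewer than
#' two groups have two subjects.
#'
#' @param cohort A `synthetic_cohort`, a manifest path, or a list of
#'   manifest records from [read_manifest()].
#' @param config A [gim_config()].
#' @param out_dir Optional directory; when given, per-subject and
#'   comparison TSV tables are written there.
#' @return Object of class `gim_cohort`: `fits`, `results` (data.frame),
#'   `comparisons` (data.frame or `NULL`), `failures`, `warnings`.
#' @export
run_cohort <- function(cohort, config = gim_config(), out_dir = NULL) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) {
    lapply(cohort$subjects, function(s)
      list(subject_id = s$subject_id, group = s$group,
           connectome = s$connectome, bold = s$bold))
  } else if (is.character(cohort)) {
    read_manifest(cohort)
  } else cohort

  fits <- list()
  failures <- list()
  for (rec in subjects) {
    res <- tryCatch(run_subject(rec, config = config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rec$subject_id]] <- list(subject_id = rec$subject_id,
                                         error = conditionMessage(res))
    } else {
      fits[[rec$subject_id]] <- res
    }
  }

  rows <- lapply(fits, function(f) {
    co <- coef(f)
    grab <- function(k) if (k %in% names(co)) unname(co[k]) else NA_real_
    tstar_scans <- vapply(c("t1", "t2"), function(lab)
      if (lab %in% names(f$scans)) f$scans[[lab]]$T_star else NA_real_,
      numeric(1))
    list(subject_id = f$subject_id, group = f$group,
         Tc = unname(co["Tc"]), T_star = grab("T_star"),
         T_star_t1 = tstar_scans[["t1"]], T_star_t2 = tstar_scans[["t2"]],
         best_r = grab("best_r"), r_at_Tc = grab("r_at_Tc"),
         direct_r = grab("direct_r"), gamma = grab("gamma"), D = grab("D"),
         best_scan = if (is.na(f$best_scan)) "" else f$best_scan)
  })
  results <- if (length(rows))
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  else NULL
  if (!is.null(results)) rownames(results) <- NULL

  warn <- character(0)
  comparisons <- NULL
  if (!is.null(results)) {
    cs <- cohort_statistics(results)
    comparisons <- cs$table
    warn <- cs$warnings
  }

  if (!is.null(out_dir) && !is.null(results)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(rows, file.path(out_dir, "subjects.tsv"))
    if (!is.null(comparisons))
      utils::write.table(comparisons, file.path(out_dir, "comparisons.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  structure(list(fits = fits, results = results, comparisons = comparisons,
                 failures = failures, warnings = warn, config = config),
            class = "gim_cohort")
}

#' Group-comparison battery on a cohort results table
#'
#' @param results Data.frame with columns `group` and the outcome columns
#'   (`Tc`, `T_star`, `best_r`, `direct_r`, `D`, `T_star_t1`,
#'   `T_star_t2`).
#' @param outcomes Outcome columns to compare.
#' @return List with `table` (one row per contrast per outcome; raw and
#'   BH-adjusted p for the post-hoc family) and `warnings`.
#' @export
cohort_statistics <- function(results,
                              outcomes = c("Tc", "T_star", "best_r",
                                           "direct_r", "D")) {
  warn <- character(0)
  groups_present <- unique(results$group)
  patient_groups <- setdiff(intersect(.groups, groups_present), "HC")
  big_enough <- vapply(groups_present, function(g)
    sum(results$group == g) >= 2, logical(1))
  if (sum(big_enough) < 2) {
    return(list(table = NULL,
                warnings = "fewer than 2 groups with >= 2 subjects; statistics skipped"))
  }

  rows <- list()
  add <- function(outcome, cmp) {
    rows[[length(rows) + 1]] <<- list(
      outcome = outcome, comparison = cmp$comparison_label, test = cmp$test,
      statistic = cmp$statistic,
      df = if (identical(cmp$test, "anova"))
        sprintf("%g,%g", cmp$df1, cmp$df2) else sprintf("%.4g", cmp$df),
      p = cmp$p_two_tailed, adjusted_p = NA_real_)
  }

  for (oc in intersect(outcomes, names(results))) {
    v <- results[[oc]]
    ok <- is.finite(v)
    hc <- v[ok & results$group == "HC"]
    pat <- v[ok & results$group != "HC"]
    if (length(hc) >= 2 && length(pat) >= 2 &&
        (stats::var(hc) > 0 || stats::var(pat) > 0)) {
      add(oc, welch_t_test(hc, pat, label = "HC vs patients"))
    }
    glist <- lapply(intersect(.groups, groups_present), function(g)
      v[ok & results$group == g])
    names(glist) <- intersect(.groups, groups_present)
    glist <- glist[lengths(glist) >= 2]
    if (length(glist) >= 2 && any(vapply(glist, stats::var, numeric(1)) > 0)) {
      add(oc, one_way_anova(glist, label = paste(names(glist), collapse = "/")))
    }
    # post-hoc family: each patient group vs HC, BH-adjusted within outcome
    ph_idx <- integer(0)
    for (g in patient_groups) {
      gv <- v[ok & results$group == g]
      if (length(gv) >= 2 && length(hc) >= 2 &&
          (stats::var(gv) > 0 || stats::var(hc) > 0)) {
        add(oc, welch_t_test(hc, gv, label = paste("HC vs", g)))
        ph_idx <- c(ph_idx, length(rows))
      }
    }
    if (length(ph_idx)) {
      adj <- fdr_adjust(vapply(rows[ph_idx], `[[`, numeric(1), "p"))
      for (i in seq_along(ph_idx)) rows[[ph_idx[i]]]$adjusted_p <- adj[i]
    }
  }

  # paired t between scans' T* (subjects with both scans)
  if (all(c("T_star_t1", "T_star_t2") %in% names(results))) {
    for (subset in list(HC = results$group == "HC",
                        patients = results$group != "HC")) {
      t1 <- results$T_star_t1[subset]
      t2 <- results$T_star_t2[subset]
      keep <- is.finite(t1) & is.finite(t2)
      if (sum(keep) >= 2 && stats::var(t1[keep] - t2[keep]) > 0) {
        lab <- if (all(results$group[subset] == "HC")) "HC" else "patients"
        add("T_star", paired_t_test(t1[keep], t2[keep],
                                    label = paste("t1 vs t2 (", lab, ")")))
      }
    }
  }

  tab <- if (length(rows))
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else NULL
  list(table = tab, warnings = warn)
}

#' @export
print.gim_cohort <- function(x, ...) {
  cat("Cohort analysis:", length(x$fits), "subjects fitted")
  if (length(x$failures)) cat(",", length(x$failures), "failed")
  cat("\n")
  if (!is.null(x$results)) {
    agg <- stats::aggregate(cbind(Tc, D) ~ group, data = x$results,
                            FUN = function(v) round(mean(v), 4))
    print(agg)
  }
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.gim_cohort <- function(object, ...) {
  cat("Per-subject parameters:\n")
  print(object$results)
  if (!is.null(object$comparisons)) {
    cat("\nGroup comparisons:\n")
    print(object$comparisons)
  }
  invisible(object)
}
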