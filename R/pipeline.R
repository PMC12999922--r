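#' Run the full per-patient analysis
#'
#' Splits the patient's SNVs into early and late sets, builds their SBS96
#' profiles, and refits each profile once per tumor site — the primary site
#' and every metastatic site — so 2 x (1 + number of metastatic sites) fits
#' are produced (minus timing classes that fall below \code{min_mutations},
#' which are skipped with a warning). Pairwise Signature Score comparisons
#' are computed across sites within each timing class, and between early
#' and late at every site.
#'
#' @param patient One patient entry of a \code{patient_cohort}.
#' @param catalog A \code{signature_catalog}.
#' @param prevalence A \code{prevalence_table}.
#' @param mapping Named site -> cancer-type vector.
#' @param min_mutant_reads Presence threshold for the early/late split.
#' @param min_mutations Minimum mutations for a timing class to be fit.
#' @param annotation Optional precomputed \code{\link{classify_early_late}}
#'   result.
#' @param ... Further arguments (\code{min_freq}, \code{prune_threshold},
#'   \code{rescue_cs_threshold}, \code{rescue_gain}) passed to
#'   \code{\link{refit_signatures}}.
#' @return List with \code{fits} (nested: timing class -> site ->
#'   \code{sigfit}), \code{scores} (one row per fit), \code{comparisons}
#'   (one row per pair), \code{skipped} (timing classes below the
#'   threshold).
#' @export
run_patient <- function(patient, catalog, prevalence, mapping,
                        min_mutant_reads = 1L, min_mutations = 100L,
                        annotation = NULL, ...) {
  if (is.null(annotation)) {
    annotation <- classify_early_late(patient, min_mutant_reads)
  }
  sites <- c(patient$primary_site, patient$metastatic_sites)
  if (anyDuplicated(sites)) {
    warning("duplicate site labels for patient ", patient$patient_id,
            " collapsed")
    sites <- unique(sites)
  }
  fits <- list()
  scores <- list()
  skipped <- character(0)
  for (tm in c("EARLY", "LATE")) {
    sub <- annotation[annotation$timing == tm, , drop = FALSE]
    if (nrow(sub) < min_mutations) {
      warning("patient ", patient$patient_id, ": ", tm, " class has ",
              nrow(sub), " mutations (< ", min_mutations, "), skipped")
      skipped <- c(skipped, tm)
      next
    }
    prof <- build_profile96(sub, paste0(patient$patient_id, ":", tm))
    fits[[tm]] <- list()
    for (site in sites) {
      fit <- refit_signatures(prof, catalog, prevalence, mapping, site,
                              timing = tm, ...)
      fits[[tm]][[site]] <- fit
      top2 <- top_k_signatures(fit, 2L)
      scores[[length(scores) + 1L]] <- data.frame(
        patient = patient$patient_id, timing = tm, prioritized_site = site,
        cancer_type = fit$cancer_type, cs = fit$cs, ss = fit$ss,
        se = fit$se, dominant_signature = fit$dominant$signature_id,
        dominant_fraction = fit$dominant$fraction,
        is_dominant = fit$dominant$is_dominant,
        rescue_used = fit$rescue_used,
        top_signatures = paste(sprintf("%s:%.3f", names(top2), top2),
                               collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  scores <- if (length(scores)) do.call(rbind, scores) else NULL

  comparisons <- list()
  add_cmp <- function(timing, site_a, site_b, a, b) {
    cmp <- compare_scores(a, b)
    comparisons[[length(comparisons) + 1L]] <<- data.frame(
      patient = patient$patient_id, timing = timing, site_a = site_a,
      site_b = site_b, delta_ss = cmp$delta,
      z = ifelse(cmp$degenerate, NA_real_, cmp$z),
      p_value = ifelse(cmp$degenerate, NA_real_, cmp$p_value),
      stringsAsFactors = FALSE)
  }
  for (tm in names(fits)) {
    st <- names(fits[[tm]])
    if (length(st) > 1L) {
      for (i in seq_len(length(st) - 1L)) {
        for (j in (i + 1L):length(st)) {
          add_cmp(tm, st[i], st[j], fits[[tm]][[st[i]]], fits[[tm]][[st[j]]])
        }
      }
    }
  }
  if (all(c("EARLY", "LATE") %in% names(fits))) {
    both <- intersect(names(fits$EARLY), names(fits$LATE))
    for (site in both) {
      add_cmp("EARLY_vs_LATE", site, site,
              fits$EARLY[[site]], fits$LATE[[site]])
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL
  list(fits = fits, scores = scores, comparisons = comparisons,
       skipped = skipped)
}

#' Run the analysis over a whole cohort
#'
#' Applies the patient-level QC filter, runs \code{\link{run_patient}} on
#' every retained patient, and (optionally) writes the score table,
#' comparison table, exclusion report, a markdown run report and a run
#' manifest into \code{out_dir}.
#'
#' @param cohort A \code{patient_cohort} (from
#'   \code{\link{read_variant_table}} or \code{\link{generate_cohort}}).
#' @param catalog,prevalence,mapping Reference inputs as in
#'   \code{\link{run_patient}}.
#' @param out_dir Optional output directory.
#' @param min_mutant_reads,min_mutations QC parameters.
#' @param apply_bh Add a Benjamini-Hochberg adjusted p-value column to the
#'   comparison table.
#' @param ... Passed on to \code{\link{refit_signatures}}.
#' @return List with \code{scores}, \code{comparisons}, \code{exclusions},
#'   \code{fits} (per patient), \code{files} (when written).
#' @export
run_cohort <- function(cohort, catalog, prevalence, mapping, out_dir = NULL,
                       min_mutant_reads = 1L, min_mutations = 100L,
                       apply_bh = FALSE, ...) {
  qc <- qc_filter_patients(cohort, min_mutations = min_mutations,
                           min_mutant_reads = min_mutant_reads)
  if (length(qc$cohort) == 0L) {
    stop("no patients pass QC (", nrow(qc$exclusions), " excluded)")
  }
  fits <- list()
  scores <- list()
  comparisons <- list()
  for (pid in names(qc$cohort)) {
    res <- run_patient(qc$cohort[[pid]], catalog, prevalence, mapping,
                       min_mutant_reads = min_mutant_reads,
                       min_mutations = min_mutations,
                       annotation = qc$annotations[[pid]], ...)
    fits[[pid]] <- res$fits
    if (!is.null(res$scores)) scores[[pid]] <- res$scores
    if (!is.null(res$comparisons)) comparisons[[pid]] <- res$comparisons
  }
  scores <- do.call(rbind, unname(scores))
  rownames(scores) <- NULL
  comparisons <- do.call(rbind, unname(comparisons))
  if (!is.null(comparisons)) {
    rownames(comparisons) <- NULL
    if (apply_bh) {
      comparisons$p_adj <- stats::p.adjust(comparisons$p_value, "BH")
    }
  }

  out <- list(scores = scores, comparisons = comparisons,
              exclusions = qc$exclusions, fits = fits, files = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- list(scores = file.path(out_dir, "scores.tsv"),
              comparisons = file.path(out_dir, "comparisons.tsv"),
              exclusions = file.path(out_dir, "exclusions.tsv"),
              report = file.path(out_dir, "report.md"),
              manifest = file.path(out_dir, "manifest.txt"))
    utils::write.table(scores, f$scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.table(comparisons, f$comparisons, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(qc$exclusions, f$exclusions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(cohort_report(out), f$report)
    writeLines(run_manifest(min_mutant_reads, min_mutations, apply_bh, ...),
               f$manifest)
    out$files <- f
  }
  out
}

# markdown run report: per patient and timing class, the dominant signature
# and the best-scoring prioritized site
cohort_report <- function(res) {
  lines <- c("# Temporal signature analysis report", "")
  lines <- c(lines, sprintf("Patients analyzed: %d; excluded: %d",
                            length(res$fits), nrow(res$exclusions)), "")
  if (nrow(res$exclusions)) {
    lines <- c(lines, "## Exclusions", "")
    lines <- c(lines, sprintf("- %s: %s (early=%d, late=%d)",
                              res$exclusions$patient_id,
                              res$exclusions$reason,
                              res$exclusions$early_n,
                              res$exclusions$late_n), "")
  }
  lines <- c(lines, "## Dominant signatures and best-scoring sites", "")
  sc <- res$scores
  for (pid in unique(sc$patient)) {
    for (tm in unique(sc$timing[sc$patient == pid])) {
      sub <- sc[sc$patient == pid & sc$timing == tm, , drop = FALSE]
      best <- sub[which.max(sub$ss), ]
      lines <- c(lines, sprintf(
        "- %s %s: best site %s (SS=%.3f, CS=%.3f); dominant %s (%.2f%s)",
        pid, tm, best$prioritized_site, best$ss, best$cs,
        best$dominant_signature, best$dominant_fraction,
        ifelse(best$is_dominant, ", >0.5", "")))
    }
  }
  lines
}

run_manifest <- function(min_mutant_reads, min_mutations, apply_bh, ...) {
  dots <- list(...)
  opts <- c(list(min_mutant_reads = min_mutant_reads,
                 min_mutations = min_mutations, apply_bh = apply_bh), dots)
  c(paste0("sigtempo_version\t",
           as.character(utils::packageVersion("sigtempo"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(opts), function(k) paste0(k, "\t", opts[[k]]), character(1)))
}
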