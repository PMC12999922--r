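#' Read a multi-sample somatic SNV table into a patient cohort
#'
#' The table is a TSV with header
#' `patient_id sample_id sample_site is_primary chrom pos ref alt context
#' mutant_reads ref_reads`. One row records the read evidence for one SNV in
#' one sample; rows for the same (patient, chrom, pos, ref, alt) across
#' samples are merged into one SNV record. A sample with no row at a
#' position is treated as assayed-and-absent (0 mutant reads). `context` may
#' be `.`, in which case a reference FASTA must be supplied for lookup.
#' Duplicate (patient, sample, position, alt) rows keep the maximum
#' mutant-read row, with a warning.
#'
#' @param path Path to the variant TSV.
#' @param fasta Optional reference FASTA used to fill missing contexts
#'   (requires the Biostrings package). Positions are 1-based and must map
#'   to the middle base of the 3-mer.
#' @return An object of class \code{patient_cohort}: a named list of
#'   patients, each a list with \code{patient_id}, \code{samples}
#'   (data.frame `sample_id`, `site`, `is_primary`), \code{primary_site}
#'   (NA if no primary sample), \code{metastatic_sites}, \code{snvs}
#'   (data.frame `chrom`, `pos`, `ref`, `alt`, `context`), and read-count
#'   matrices \code{mut_reads} / \code{ref_reads} (SNVs x samples).
#' @export
read_variant_table <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  # ref/alt columns of all "T" must not collapse to logical TRUE
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chrom = "character",
                                            ref = "character",
                                            alt = "character",
                                            context = "character"))
  need <- c("patient_id", "sample_id", "sample_site", "is_primary", "chrom",
            "pos", "ref", "alt", "context", "mutant_reads", "ref_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df$context <- toupper(as.character(df$context))
  df$context[df$context %in% c(".", "", "NA")] <- NA_character_

  # line numbers for error messages (header is line 1)
  line <- seq_len(nrow(df)) + 1L
  bases <- c("A", "C", "G", "T")
  bad <- !(df$ref %in% bases) | !(df$alt %in% bases) | df$ref == df$alt |
    !is.finite(df$pos) | df$pos < 1 |
    !is.finite(df$mutant_reads) | df$mutant_reads < 0 |
    !is.finite(df$ref_reads) | df$ref_reads < 0
  if (any(bad)) {
    stop("malformed variant row at line ", line[which(bad)[1]],
         " (ref/alt must be distinct A/C/G/T bases, pos >= 1, counts >= 0)")
  }

  needs_ctx <- is.na(df$context)
  if (any(needs_ctx)) {
    if (is.null(fasta)) {
      stop("rows without a context column require a reference FASTA")
    }
    df$context[needs_ctx] <- lookup_context(df$chrom[needs_ctx],
                                            df$pos[needs_ctx], fasta)
  }

  has_n <- !grepl("^[ACGT]{3}$", df$context)
  if (any(has_n)) {
    warning(sum(has_n), " row(s) with ambiguous (N) context bases dropped")
    df <- df[!has_n, , drop = FALSE]
    line <- line[!has_n]
  }
  mid_bad <- substr(df$context, 2L, 2L) != df$ref
  if (any(mid_bad)) {
    stop("context middle base does not match ref at line ",
         line[which(mid_bad)[1]])
  }

  # duplicate (patient, sample, pos, alt) rows: keep max mutant reads
  dup_key <- paste(df$patient_id, df$sample_id, df$chrom, df$pos, df$alt,
                   sep = "\r")
  if (anyDuplicated(dup_key)) {
    warning("duplicate (patient,sample,position,alt) rows collapsed ",
            "keeping the maximum mutant-read row")
    ord <- order(dup_key, -df$mutant_reads)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(dup_key[ord]), , drop = FALSE]
  }

  patients <- lapply(split(df, df$patient_id), build_patient)
  structure(patients[order(names(patients))], class = "patient_cohort")
}

# assemble one patient entry from its rows
build_patient <- function(pdf) {
  samp <- unique(pdf[, c("sample_id", "sample_site", "is_primary")])
  samp <- samp[order(samp$sample_id), , drop = FALSE]
  if (anyDuplicated(samp$sample_id)) {
    stop("inconsistent site/primary labels for sample(s) of patient ",
         pdf$patient_id[1])
  }
  names(samp) <- c("sample_id", "site", "is_primary")
  primary_site <- if (any(samp$is_primary == 1)) {
    samp$site[samp$is_primary == 1][1]
  } else NA_character_
  met_sites <- unique(samp$site[samp$is_primary != 1])

  key <- paste(pdf$chrom, pdf$pos, pdf$ref, pdf$alt, sep = "\r")
  snv_rows <- !duplicated(key)
  snvs <- pdf[snv_rows, c("chrom", "pos", "ref", "alt", "context"),
              drop = FALSE]
  ukey <- key[snv_rows]
  # contexts must agree across rows of the same SNV
  ctx_by_key <- tapply(pdf$context, key, function(x) length(unique(x)))
  if (any(ctx_by_key > 1)) {
    stop("conflicting contexts for the same SNV of patient ",
         pdf$patient_id[1])
  }
  rownames(snvs) <- NULL
  n_snv <- nrow(snvs)
  n_samp <- nrow(samp)
  mut <- matrix(0L, n_snv, n_samp,
                dimnames = list(NULL, samp$sample_id))
  refm <- mut
  i <- match(key, ukey)
  j <- match(pdf$sample_id, samp$sample_id)
  mut[cbind(i, j)] <- as.integer(pdf$mutant_reads)
  refm[cbind(i, j)] <- as.integer(pdf$ref_reads)

  list(patient_id = pdf$patient_id[1], samples = samp,
       primary_site = primary_site, metastatic_sites = met_sites,
       snvs = snvs, mut_reads = mut, ref_reads = refm)
}

# 3-mer context around 1-based pos from a reference FASTA (Biostrings)
lookup_context <- function(chrom, pos, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("context lookup from FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!all(chrom %in% names(seqs))) {
    stop("FASTA is missing sequence(s): ",
         paste(unique(setdiff(chrom, names(seqs))), collapse = ", "))
  }
  vapply(seq_along(chrom), function(k) {
    s <- seqs[[chrom[k]]]
    if (pos[k] < 2L || pos[k] > length(s) - 1L) {
      stop("position ", pos[k], " on ", chrom[k],
           " too close to the sequence edge for a 3-mer context")
    }
    toupper(as.character(Biostrings::subseq(s, pos[k] - 1L, pos[k] + 1L)))
  }, character(1))
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat("Patient cohort:", length(x), "patient(s)\n")
  for (p in x) {
    cat("  ", p$patient_id, ": ", nrow(p$samples), " samples, ",
        nrow(p$snvs), " SNVs, primary site ",
        ifelse(is.na(p$primary_site), "<missing>", p$primary_site),
        "\n", sep = "")
  }
  invisible(x)
}

#' Mutant-base presence rule
#'
#' A mutation counts as detected in a sample when its mutant-read count
#' reaches \code{min_mutant_reads} (default 1 read).
#'
#' @param mutant_reads Non-negative mutant read count(s).
#' @param reference_reads Non-negative reference read count(s) (unused by
#'   the rule; accepted so evidence pairs can be passed through).
#' @param min_mutant_reads Detection threshold, default 1.
#' @return Logical vector.
#' @export
is_present <- function(mutant_reads, reference_reads = NULL,
                       min_mutant_reads = 1L) {
  if (any(mutant_reads < 0)) stop("read counts must be non-negative")
  mutant_reads >= min_mutant_reads
}

#' Classify a patient's SNVs as early or late
#'
#' A mutation shared by (present in) all of the patient's samples is early;
#' a mutation absent from at least one sample is late.
#'
#' @param patient One patient entry of a \code{patient_cohort}.
#' @param min_mutant_reads Presence threshold passed to
#'   \code{\link{is_present}}.
#' @return A data.frame with one row per SNV: `chrom`, `pos`, `ref`, `alt`,
#'   `context`, `timing` ("EARLY"/"LATE"), plus the logical presence matrix
#'   as attribute \code{"presence"}.
#' @export
classify_early_late <- function(patient, min_mutant_reads = 1L) {
  if (nrow(patient$samples) < 2L) {
    stop("timing is undefined for a single-sample patient (",
         patient$patient_id, ")")
  }
  pres <- is_present(patient$mut_reads, min_mutant_reads = min_mutant_reads)
  pres <- matrix(pres, nrow(patient$snvs), nrow(patient$samples),
                 dimnames = dimnames(patient$mut_reads))
  timing <- ifelse(rowSums(pres) == ncol(pres), "EARLY", "LATE")
  out <- cbind(patient$snvs,
               data.frame(timing = timing, stringsAsFactors = FALSE))
  attr(out, "presence") <- pres
  out
}

#' Patient-level QC filter
#'
#' A patient is retained when both timing classes hold at least
#' \code{min_mutations} mutations (default 100) and a primary tumor sample
#' is present.
#'
#' @param cohort A \code{patient_cohort}.
#' @param annotations Named list of per-patient timing annotations from
#'   \code{\link{classify_early_late}} (names are patient ids). Computed on
#'   the fly when NULL.
#' @param min_mutations Minimum early and late counts, default 100.
#' @param min_mutant_reads Presence threshold used when annotations are
#'   computed here.
#' @return A list with \code{cohort} (retained \code{patient_cohort}),
#'   \code{annotations} (for the retained patients) and \code{exclusions}
#'   (data.frame `patient_id`, `reason`, `early_n`, `late_n`).
#' @export
qc_filter_patients <- function(cohort, annotations = NULL,
                               min_mutations = 100L, min_mutant_reads = 1L) {
  if (is.null(annotations)) {
    annotations <- lapply(cohort, classify_early_late,
                          min_mutant_reads = min_mutant_reads)
  }
  if (!all(names(cohort) %in% names(annotations))) {
    stop("annotations must cover every patient in the cohort")
  }
  keep <- character(0)
  excl <- data.frame(patient_id = character(0), reason = character(0),
                     early_n = integer(0), late_n = integer(0),
                     stringsAsFactors = FALSE)
  for (pid in names(cohort)) {
    ann <- annotations[[pid]]
    n_early <- sum(ann$timing == "EARLY")
    n_late <- sum(ann$timing == "LATE")
    reason <- NULL
    if (is.na(cohort[[pid]]$primary_site)) {
      reason <- "missing primary"
    } else if (n_early < min_mutations) {
      reason <- sprintf("early<%d", min_mutations)
    } else if (n_late < min_mutations) {
      reason <- sprintf("late<%d", min_mutations)
    }
    if (is.null(reason)) {
      keep <- c(keep, pid)
    } else {
      excl <- rbind(excl, data.frame(patient_id = pid, reason = reason,
                                     early_n = n_early, late_n = n_late,
                                     stringsAsFactors = FALSE))
    }
  }
  retained <- structure(cohort[keep], class = "patient_cohort")
  list(cohort = retained, annotations = annotations[keep],
       exclusions = excl)
}
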