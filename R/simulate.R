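#' Deterministic low-similarity toy signature catalog
#'
#' Builds synthetic signatures by concentrating probability mass on disjoint
#' blocks of the 96 channels: signature i places \code{within} of its mass
#' uniformly on its own block and spreads the remainder uniformly over the
#' other channels. Pairwise cosine similarity is low (about 0.11 at the
#' defaults), which makes mixture recovery well conditioned.
#'
#' @param n_sig Number of signatures (2..8).
#' @param within Probability mass on the signature's own channel block.
#' @param ids Signature names; default \code{"SBS-A"}, \code{"SBS-B"}, ...
#' @return A \code{signature_catalog}.
#' @export
toy_signature_catalog <- function(n_sig = 4, within = 0.9,
                                  ids = paste0("SBS-", LETTERS[seq_len(n_sig)])) {
  stopifnot(n_sig >= 2, n_sig <= 8, within > 0, within <= 1)
  block <- 96L %/% n_sig
  m <- matrix(0, 96L, n_sig, dimnames = list(sbs96_channels(), ids))
  for (i in seq_len(n_sig)) {
    own <- ((i - 1L) * block + 1L):(i * block)
    m[own, i] <- within / block
    m[-own, i] <- (1 - within) / (96L - block)
  }
  signature_catalog(m)
}

#' Build a profile directly from channel strings
#'
#' @param channels Character vector of SBS96 channel strings.
#' @param label Profile label.
#' @return A \code{profile96}.
#' @export
build_profile96_from_channels <- function(channels, label = "") {
  all_ch <- sbs96_channels()
  bad <- setdiff(unique(channels), all_ch)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  counts <- as.integer(table(factor(channels, levels = all_ch)))
  names(counts) <- all_ch
  structure(list(label = label, counts = counts, total = sum(counts)),
            class = "profile96")
}

# render a channel string to a concrete (ref, alt, context) SNV; the
# purine-strand representation is chosen with probability 0.5
channel_to_snv <- function(channel) {
  five <- substr(channel, 1L, 1L)
  ref <- substr(channel, 3L, 3L)
  alt <- substr(channel, 5L, 5L)
  three <- substr(channel, 7L, 7L)
  ctx <- paste0(five, ref, three)
  flip <- stats::runif(length(channel)) < 0.5
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- data.frame(ref = ref, alt = alt, context = ctx,
                    stringsAsFactors = FALSE)
  if (any(flip)) {
    out$ref[flip] <- unname(comp[ref[flip]])
    out$alt[flip] <- unname(comp[alt[flip]])
    out$context[flip] <- revcomp(ctx[flip])
  }
  out
}

#' Sample SNVs from a signature mixture
#'
#' Each SNV is drawn by first sampling a source signature from the mixture,
#' then a channel from that signature's 96-channel distribution; the channel
#' is rendered to a concrete (ref, alt, context) with the purine-strand
#' representation chosen uniformly at random. Uses the session RNG; seed
#' with \code{set.seed} for reproducibility.
#'
#' @param n Number of SNVs.
#' @param mixture Named non-negative vector summing to 1 over catalog
#'   signature ids.
#' @param catalog A \code{signature_catalog}.
#' @return Data.frame with columns `channel`, `source_signature`, `ref`,
#'   `alt`, `context` (n rows; empty when n = 0).
#' @export
sample_snvs_from_mixture <- function(n, mixture, catalog) {
  miss <- setdiff(names(mixture), colnames(catalog))
  if (length(miss)) {
    stop("mixture references signature(s) absent from catalog: ",
         paste(miss, collapse = ", "))
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-6) {
    stop("mixture must be non-negative and sum to 1")
  }
  if (n == 0L) {
    return(data.frame(channel = character(0), source_signature = character(0),
                      ref = character(0), alt = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  }
  src <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  channels <- vapply(src, function(s) {
    sample(rownames(catalog), 1L, prob = catalog[, s])
  }, character(1))
  snv <- channel_to_snv(channels)
  data.frame(channel = unname(channels), source_signature = unname(src),
             ref = snv$ref, alt = snv$alt, context = snv$context,
             stringsAsFactors = FALSE)
}

#' Assign per-sample presence and read-count evidence
#'
#' Early SNVs are present in every sample; late SNVs in a uniformly drawn
#' proper non-empty subset of samples. Sequencing depth is Poisson around
#' \code{read_depth} (floored at 1); where present, mutant reads are
#' binomial at allele fraction 0.5, floored at 1.
#'
#' @param n_snv Number of SNVs.
#' @param timing "EARLY" or "LATE" (applies to all n_snv SNVs).
#' @param sample_ids Character vector of >= 2 sample ids.
#' @param read_depth Mean sequencing depth.
#' @return List with logical \code{presence}, integer \code{mut_reads} and
#'   \code{ref_reads} matrices (n_snv x samples).
#' @export
assign_presence <- function(n_snv, timing, sample_ids, read_depth = 60) {
  k <- length(sample_ids)
  if (k < 2L) stop("need at least 2 samples")
  timing <- match.arg(timing, c("EARLY", "LATE"))
  pres <- matrix(TRUE, n_snv, k, dimnames = list(NULL, sample_ids))
  if (timing == "LATE" && n_snv > 0L) {
    # uniform over the 2^k - 2 proper non-empty subsets, via subset codes
    code <- sample.int(2L^k - 2L, n_snv, replace = TRUE)
    for (j in seq_len(k)) {
      pres[, j] <- bitwAnd(code, bitwShiftL(1L, j - 1L)) != 0L
    }
  }
  depth <- matrix(pmax(1L, stats::rpois(n_snv * k, read_depth)), n_snv, k)
  mut <- matrix(0L, n_snv, k, dimnames = list(NULL, sample_ids))
  if (n_snv > 0L) {
    drawn <- stats::rbinom(n_snv * k, as.vector(depth), 0.5)
    drawn <- pmin(pmax(drawn, 1L), as.vector(depth))
    mut[pres] <- matrix(drawn, n_snv, k)[pres]
  }
  refm <- depth - mut
  dimnames(refm) <- dimnames(mut)
  list(presence = pres, mut_reads = mut, ref_reads = refm)
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate a small metastatic WES cohort: 7 patients, each with
#' one primary-site sample and three metastatic samples; a few hundred
#' mutations per timing class; early mutations dominated by one
#' primary-site-associated signature (fraction 0.7) and late mutations a
#' three-signature mixture (0.40/0.35/0.25); the dominant early signature
#' is prevalent at the primary cancer type (f = 0.8, cohort N = 500) and
#' absent from the metastatic types; mean read depth 60.
#'
#' @param seed RNG seed.
#' @param n_patients Number of patients.
#' @param samples_per_patient Samples per patient (1 primary + the rest
#'   metastatic, assigned to \code{metastatic_sites} cyclically).
#' @param n_early,n_late Mutations per timing class per patient.
#' @param early_mixture,late_mixture Named generating fractions over the
#'   catalog's signatures (each sums to 1).
#' @param primary_site,metastatic_sites Site labels.
#' @param catalog A \code{signature_catalog}; default
#'   \code{toy_signature_catalog(4)}.
#' @param prevalence A \code{prevalence_table}; the default gives the
#'   dominant early signature f = 0.8 at the primary cancer type and 0 at
#'   the metastatic types.
#' @param mapping Named site -> cancer type vector.
#' @param read_depth Mean sequencing depth for evidence simulation.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 7L,
                              samples_per_patient = 4L,
                              n_early = 300L,
                              n_late = 200L,
                              early_mixture = c("SBS-A" = 0.7, "SBS-B" = 0.3),
                              late_mixture = c("SBS-B" = 0.40, "SBS-C" = 0.35,
                                               "SBS-D" = 0.25),
                              primary_site = "Lung",
                              metastatic_sites = c("Brain", "Liver", "Ovary"),
                              catalog = toy_signature_catalog(4),
                              prevalence = default_prevalence(),
                              mapping = c(Lung = "lung", Brain = "brain",
                                          Liver = "liver", Ovary = "ovary"),
                              read_depth = 60) {
  stopifnot(samples_per_patient >= 2L, n_early >= 1L, n_late >= 1L)
  for (mx in list(early_mixture, late_mixture)) {
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-6) {
      stop("mixtures must be non-negative and sum to 1")
    }
    miss <- setdiff(names(mx), colnames(catalog))
    if (length(miss)) {
      stop("mixture references signature(s) absent from catalog: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(seed = as.integer(seed), n_patients = n_patients,
                 samples_per_patient = samples_per_patient,
                 n_early = n_early, n_late = n_late,
                 early_mixture = early_mixture, late_mixture = late_mixture,
                 primary_site = primary_site,
                 metastatic_sites = metastatic_sites,
                 catalog = catalog, prevalence = prevalence,
                 mapping = mapping, read_depth = read_depth),
            class = "simulation_config")
}

# default prevalence: dominant early signature common at the primary type,
# absent (f = 0) from every metastatic type
default_prevalence <- function() {
  prevalence_table(data.frame(
    cancer_type = c(rep("lung", 3), rep("brain", 3), rep("liver", 3),
                    rep("ovary", 3)),
    signature_id = c("SBS-A", "SBS-B", "SBS-C",
                     "SBS-B", "SBS-C", "SBS-D",
                     "SBS-B", "SBS-C", "SBS-D",
                     "SBS-B", "SBS-C", "SBS-D"),
    frequency = c(0.8, 0.6, 0.5,
                  0.7, 0.4, 0.5,
                  0.3, 0.6, 0.7,
                  0.5, 0.3, 0.6),
    n_patients = 500L,
    stringsAsFactors = FALSE
  ))
}

#' Generate a synthetic multi-sample tumor cohort
#'
#' Draws, per patient, early mutations present in every sample and late
#' mutations present in proper sample subsets, from the configured
#' signature mixtures, and assembles them into the same cohort structure
#' \code{\link{read_variant_table}} produces. When \code{out_dir} is given,
#' writes `variants.tsv`, `catalog.tsv`, `prevalence.tsv`, `site_map.tsv`
#' and `truth.tsv`, consumable verbatim by the pipeline.
#'
#' @param config A \code{simulation_config}.
#' @param out_dir Optional output directory for the TSV files.
#' @return List with \code{cohort} (a \code{patient_cohort}), \code{truth}
#'   (data.frame `patient`, `snv_key`, `timing`, `source_signature`),
#'   \code{catalog}, \code{prevalence}, \code{mapping}, \code{config}, and
#'   \code{files} (paths, when written).
#' @export
generate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed)
  n_met_samples <- config$samples_per_patient - 1L
  sites <- c(config$primary_site,
             rep_len(config$metastatic_sites, n_met_samples))
  patients <- list()
  truth <- list()
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("SIM%03d", p)
    sample_ids <- sprintf("%s_S%d", pid, seq_len(config$samples_per_patient))
    samp <- data.frame(sample_id = sample_ids, site = sites,
                       is_primary = c(1L, rep(0L, n_met_samples)),
                       stringsAsFactors = FALSE)

    early <- sample_snvs_from_mixture(config$n_early, config$early_mixture,
                                      config$catalog)
    late <- sample_snvs_from_mixture(config$n_late, config$late_mixture,
                                     config$catalog)
    snvs <- rbind(early, late)
    timing <- c(rep("EARLY", config$n_early), rep("LATE", config$n_late))
    n <- nrow(snvs)
    snv_df <- data.frame(chrom = "chr1", pos = 1000L * seq_len(n),
                         ref = snvs$ref, alt = snvs$alt,
                         context = snvs$context, stringsAsFactors = FALSE)

    ev_e <- assign_presence(config$n_early, "EARLY", sample_ids,
                            config$read_depth)
    ev_l <- assign_presence(config$n_late, "LATE", sample_ids,
                            config$read_depth)
    mut <- rbind(ev_e$mut_reads, ev_l$mut_reads)
    refm <- rbind(ev_e$ref_reads, ev_l$ref_reads)

    patients[[pid]] <- list(patient_id = pid, samples = samp,
                            primary_site = config$primary_site,
                            metastatic_sites =
                              unique(sites[samp$is_primary == 0L]),
                            snvs = snv_df, mut_reads = mut, ref_reads = refm)
    truth[[pid]] <- data.frame(
      patient = pid,
      snv_key = paste(snv_df$chrom, snv_df$pos, snv_df$ref, snv_df$alt,
                      sep = ":"),
      timing = timing, source_signature = snvs$source_signature,
      stringsAsFactors = FALSE)

    # long-format variant rows: only samples where a read was observed for
    # the mutant base, plus reference-only rows so depth is recorded
    pres <- rbind(ev_e$presence, ev_l$presence)
    for (j in seq_along(sample_ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, sample_id = sample_ids[j], sample_site = sites[j],
        is_primary = samp$is_primary[j], chrom = snv_df$chrom,
        pos = snv_df$pos, ref = snv_df$ref, alt = snv_df$alt,
        context = snv_df$context, mutant_reads = mut[, j],
        ref_reads = refm[, j], stringsAsFactors = FALSE)
    }
  }
  cohort <- structure(patients, class = "patient_cohort")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(cohort = cohort, truth = truth, catalog = config$catalog,
              prevalence = config$prevalence, mapping = config$mapping,
              config = config, files = NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    variants <- do.call(rbind, rows)
    f <- list(
      variants = file.path(out_dir, "variants.tsv"),
      catalog = file.path(out_dir, "catalog.tsv"),
      prevalence = file.path(out_dir, "prevalence.tsv"),
      site_map = file.path(out_dir, "site_map.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    utils::write.table(variants, f$variants, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_catalog(config$catalog, f$catalog)
    utils::write.table(as.data.frame(config$prevalence), f$prevalence,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(site = names(config$mapping),
                 cancer_type = unname(config$mapping)),
      f$site_map, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, f$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- f
  }
  out
}
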