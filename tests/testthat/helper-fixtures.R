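# shared fixtures and independent oracles

# independent channel oracle: strand-normalize with chartr/rev, no calls
# into the package's channel machinery
oracle_channel <- function(ref, alt, ctx) {
  rc1 <- function(x) chartr("ACGT", "TGCA", x)
  rc3 <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  mapply(function(r, a, c3) {
    if (r %in% c("A", "G")) {
      r2 <- rc1(r); a2 <- rc1(a); c2 <- rc3(c3)
    } else {
      r2 <- r; a2 <- a; c2 <- c3
    }
    paste0(substr(c2, 1, 1), "[", r2, ">", a2, "]", substr(c2, 3, 3))
  }, ref, alt, ctx, USE.NAMES = FALSE)
}

# random concrete SNVs (any strand representation)
random_snvs <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ctx <- paste0(sample(bases, n, replace = TRUE), ref,
                sample(bases, n, replace = TRUE))
  data.frame(ref = ref, alt = unname(alt), context = ctx,
             stringsAsFactors = FALSE)
}

# minimal patient entry from a logical presence matrix (1 read where present)
patient_from_presence <- function(pres, pid = "P1") {
  n_samp <- ncol(pres)
  sample_ids <- paste0("S", seq_len(n_samp))
  colnames(pres) <- sample_ids
  n <- nrow(pres)
  snvs <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "C", alt = "T",
                     context = "ACA", stringsAsFactors = FALSE)
  mut <- matrix(as.integer(pres), n, n_samp, dimnames = list(NULL, sample_ids))
  refm <- matrix(30L, n, n_samp, dimnames = list(NULL, sample_ids))
  list(patient_id = pid,
       samples = data.frame(sample_id = sample_ids,
                            site = c("Lung", rep("Brain", n_samp - 1)),
                            is_primary = c(1L, rep(0L, n_samp - 1)),
                            stringsAsFactors = FALSE),
       primary_site = "Lung", metastatic_sites = "Brain",
       snvs = snvs, mut_reads = mut, ref_reads = refm)
}

# profile whose proportions are exactly a mixture of catalog signatures,
# scaled to (possibly fractional) counts — exact convex combination
exact_mixture_profile <- function(catalog, mixture, total = 1e5,
                                  label = "mix") {
  v <- as.numeric(unclass(catalog)[, names(mixture), drop = FALSE] %*%
                    mixture)
  counts <- v * total
  names(counts) <- rownames(catalog)
  structure(list(label = label, counts = counts, total = sum(counts)),
            class = "profile96")
}

# variant-table TSV writer for hand-built rows
write_variant_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("patient_id", "sample_id", "sample_site", "is_primary",
              "chrom", "pos", "ref", "alt", "context", "mutant_reads",
              "ref_reads")
  if (is.list(rows)) {  # list-matrix from rbind() of row lists
    rows <- matrix(vapply(rows, function(x) as.character(x), character(1)),
                   ncol = length(header))
  }
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small prevalence table over a toy catalog at one cancer type
toy_prevalence <- function(ids, f, n = 500L, cancer_type = "lung") {
  prevalence_table(data.frame(cancer_type = cancer_type, signature_id = ids,
                              frequency = f, n_patients = n,
                              stringsAsFactors = FALSE))
}
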