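row1 <- list("P1", "S1", "Lung", 1L, "chr1", 100L, "C", "T", "ACG", 12L, 40L)

test_that("variant table rows merge into per-SNV records", {
  path <- write_variant_tsv(do.call(rbind, list(row1)))
  coh <- read_variant_table(path)
  expect_s3_class(coh, "patient_cohort")
  p <- coh[["P1"]]
  expect_equal(nrow(p$snvs), 1L)
  expect_equal(unname(p$mut_reads[1, "S1"]), 12L)
  expect_equal(unname(p$ref_reads[1, "S1"]), 40L)

  # same SNV seen in two samples -> one record, two evidence entries
  row2 <- list("P1", "S2", "Brain", 0L, "chr1", 100L, "C", "T", "ACG", 7L, 33L)
  coh2 <- read_variant_table(write_variant_tsv(rbind(row1, row2)))
  p2 <- coh2[["P1"]]
  expect_equal(nrow(p2$snvs), 1L)
  expect_equal(unname(p2$mut_reads[1, c("S1", "S2")]), c(12L, 7L))
  expect_equal(p2$primary_site, "Lung")
  expect_equal(p2$metastatic_sites, "Brain")
})

test_that("malformed rows fail with the offending line number", {
  bad <- list("P1", "S1", "Lung", 1L, "chr1", 100L, "C", "C", "ACG", 5L, 10L)
  expect_error(read_variant_table(write_variant_tsv(rbind(row1, bad))),
               "line 3")
  mid <- list("P1", "S1", "Lung", 1L, "chr1", 101L, "C", "T", "ATG", 5L, 10L)
  expect_error(read_variant_table(write_variant_tsv(rbind(row1, mid))),
               "middle base")
})

test_that("duplicate sample rows keep the max mutant-read row, with warning", {
  dup <- list("P1", "S1", "Lung", 1L, "chr1", 100L, "C", "T", "ACG", 30L, 20L)
  expect_warning(
    coh <- read_variant_table(write_variant_tsv(rbind(row1, dup))),
    "duplicate")
  expect_equal(unname(coh[["P1"]]$mut_reads[1, "S1"]), 30L)
})

test_that("missing contexts are filled from a reference FASTA", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr9", "TTACGTT"), fa)
  norow <- list("P1", "S1", "Lung", 1L, "chr9", 4L, "C", "A", ".", 9L, 20L)
  expect_error(read_variant_table(write_variant_tsv(rbind(norow))),
               "FASTA")
  coh <- read_variant_table(write_variant_tsv(rbind(norow)), fasta = fa)
  expect_equal(coh[["P1"]]$snvs$context, "ACG")
})

test_that("presence rule compares mutant reads to the threshold", {
  expect_true(is_present(1, 50, min_mutant_reads = 1))
  expect_false(is_present(0, 80, min_mutant_reads = 1))
  expect_false(is_present(2, 10, min_mutant_reads = 3))
  expect_error(is_present(-1), "non-negative")
})

test_that("early/late classification matches a brute-force all-present oracle", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    pres <- matrix(runif(200 * k) < 0.8, 200, k)
    patient <- patient_from_presence(pres)
    ann <- classify_early_late(patient)
    oracle <- ifelse(apply(pres, 1, all), "EARLY", "LATE")
    expect_identical(ann$timing, oracle)
    # exhaustive and disjoint partition
    expect_equal(sum(ann$timing == "EARLY") + sum(ann$timing == "LATE"),
                 nrow(patient$snvs))
  }
})

test_that("classification is invariant to sample order and monotone in the threshold", {
  set.seed(22)
  pres <- matrix(runif(150 * 4) < 0.9, 150, 4)
  patient <- patient_from_presence(pres)
  patient$mut_reads[pres] <- sample(1:5, sum(pres), replace = TRUE)
  ann1 <- classify_early_late(patient)
  perm <- c(3, 1, 4, 2)
  patient2 <- patient
  patient2$samples <- patient$samples[perm, ]
  patient2$mut_reads <- patient$mut_reads[, perm]
  patient2$ref_reads <- patient$ref_reads[, perm]
  expect_identical(classify_early_late(patient2)$timing, ann1$timing)
  # raising the read threshold can only shrink the early set
  n_early <- vapply(1:6, function(thr) {
    sum(classify_early_late(patient, min_mutant_reads = thr)$timing ==
          "EARLY")
  }, numeric(1))
  expect_true(all(diff(n_early) <= 0))
})

test_that("single-sample patients are refused", {
  patient <- patient_from_presence(matrix(TRUE, 10, 1))
  expect_error(classify_early_late(patient), "single-sample")
})

test_that("QC retains only patients with both classes at threshold and a primary", {
  set.seed(23)
  mk <- function(n_early, n_late, primary = TRUE, pid = "P") {
    pres <- rbind(matrix(TRUE, n_early, 3),
                  cbind(matrix(TRUE, n_late, 2), rep(FALSE, n_late)))
    p <- patient_from_presence(pres, pid)
    if (!primary) {
      p$samples$is_primary <- 0L
      p$primary_site <- NA_character_
    }
    p
  }
  cohort <- structure(list(A = mk(150, 120, pid = "A"),
                           B = mk(99, 500, pid = "B"),
                           C = mk(200, 150, primary = FALSE, pid = "C")),
                      class = "patient_cohort")
  qc <- qc_filter_patients(cohort, min_mutations = 100L)
  expect_identical(names(qc$cohort), "A")
  excl <- qc$exclusions[order(qc$exclusions$patient_id), ]
  expect_identical(excl$patient_id, c("B", "C"))
  expect_identical(excl$reason, c("early<100", "missing primary"))
  expect_equal(excl$early_n[excl$patient_id == "B"], 99)
})
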