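#' Construct a signature catalog
#'
#' @param matrix A 96 x k numeric matrix; rows are the canonical SBS96
#'   channels (rownames must be the channel strings, any order), columns are
#'   signatures. Each column must sum to 1 within \code{tol} of 1 and is
#'   renormalized exactly.
#' @param tol Tolerance on column sums before renormalization.
#' @return An object of class \code{signature_catalog}: the 96 x k matrix in
#'   canonical row order, columns exactly normalized.
#' @export
signature_catalog <- function(matrix, tol = 1e-3) {
  channels <- sbs96_channels()
  if (is.null(rownames(matrix))) {
    if (nrow(matrix) != 96L) stop("catalog matrix must have 96 rows")
    rownames(matrix) <- channels
  }
  idx <- match(channels, rownames(matrix))
  if (anyNA(idx)) {
    stop("catalog channel set mismatch; first missing channel: ",
         channels[which(is.na(idx))[1]])
  }
  m <- as.matrix(matrix[idx, , drop = FALSE])
  if (is.null(colnames(m))) stop("catalog columns must be named signatures")
  if (any(m < 0)) stop("signature probabilities must be non-negative")
  cs <- colSums(m)
  bad <- abs(cs - 1) > tol
  if (any(bad)) {
    stop("signature column(s) do not sum to 1 within ", tol, ": ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  m <- sweep(m, 2L, cs, "/")
  structure(m, class = c("signature_catalog", "matrix", "array"))
}

#' Read a COSMIC-layout signature catalog
#'
#' Expects a TSV whose first column (`Type`) holds the 96 channel names and
#' whose remaining columns are signature probability vectors. Rows may be in
#' any order; they are re-sorted to canonical channel order.
#'
#' @param path Path to the TSV file.
#' @param tol Column-sum tolerance passed to \code{\link{signature_catalog}}.
#' @return A \code{signature_catalog}.
#' @export
read_catalog <- function(path, tol = 1e-3) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("catalog must have a Type column plus >=1 signature")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  signature_catalog(m, tol = tol)
}

#' Write a signature catalog in COSMIC layout
#'
#' @param catalog A \code{signature_catalog}.
#' @param path Output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(Type = rownames(catalog),
                   unclass(catalog)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cancer-type signature prevalence table
#'
#' TSV columns: `cancer_type  signature_id  frequency  n_patients`.
#' A (type, signature) pair absent from the table means frequency 0.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class \code{prevalence_table}.
#' @export
read_prevalence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cancer_type", "signature_id", "frequency", "n_patients")
  if (!all(need %in% names(df))) {
    stop("prevalence table must have columns: ", paste(need, collapse = ", "))
  }
  prevalence_table(df)
}

#' @rdname read_prevalence
#' @param df Data.frame with columns `cancer_type`, `signature_id`,
#'   `frequency`, `n_patients`.
#' @export
prevalence_table <- function(df) {
  if (any(df$frequency < 0 | df$frequency > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (any(df$n_patients < 1)) stop("n_patients must be >= 1")
  class(df) <- c("prevalence_table", "data.frame")
  df
}

# frequency f and cohort size N for each requested signature in a cancer
# type; absent pairs get f = 0 (N then irrelevant, set to 1)
prevalence_lookup <- function(prevalence, cancer_type, signature_ids) {
  sub <- prevalence[prevalence$cancer_type == cancer_type, , drop = FALSE]
  idx <- match(signature_ids, sub$signature_id)
  f <- ifelse(is.na(idx), 0, sub$frequency[idx])
  n <- ifelse(is.na(idx), 1, sub$n_patients[idx])
  data.frame(signature_id = signature_ids, f = f, n = n,
             stringsAsFactors = FALSE)
}

#' Read a tumor-site to cancer-type mapping
#'
#' Accepts a two-column TSV (`site  cancer_type`, with or without header) or
#' a `site=cancer_type` key-value file.
#'
#' @param path Path to the mapping file.
#' @return Named character vector: names are site labels, values the cancer
#'   types used as prevalence keys.
#' @export
read_site_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (all(grepl("=", lines, fixed = TRUE))) {
    parts <- strsplit(lines, "=", fixed = TRUE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
  }
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed site-map line: ", lines[which(bad)[1]])
  sites <- trimws(vapply(parts, `[`, character(1), 1L))
  types <- trimws(vapply(parts, `[`, character(1), 2L))
  keep <- !(sites == "site" & types == "cancer_type")  # optional header
  stats::setNames(types[keep], sites[keep])
}

#' Signatures expected at a tumor site
#'
#' Resolves the site through the site mapping and returns the signatures
#' whose prevalence in the mapped cancer type is at least \code{min_freq}
#' (default: any positive frequency), in catalog order.
#'
#' @param site Tumor-site label.
#' @param mapping Named vector from \code{\link{read_site_map}} (or built
#'   in code).
#' @param prevalence A \code{prevalence_table}.
#' @param catalog A \code{signature_catalog} (defines the returned order).
#' @param min_freq Minimum prevalence to be considered expected; signatures
#'   with frequency 0 are never returned.
#' @return Character vector of signature ids.
#' @export
allowed_signatures <- function(site, mapping, prevalence, catalog,
                               min_freq = 0) {
  if (!site %in% names(mapping)) {
    stop("tumor site '", site, "' has no cancer-type mapping")
  }
  ct <- mapping[[site]]
  ids <- colnames(catalog)
  pv <- prevalence_lookup(prevalence, ct, ids)
  thr <- max(min_freq, .Machine$double.xmin)
  ids[pv$f >= thr & pv$f > 0]
}
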