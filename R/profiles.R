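#' Build a 96-channel trinucleotide profile from SNVs
#'
#' Tallies SNVs into the canonical SBS96 channels (pyrimidine-centric;
#' purine-reference mutations are reverse-complemented by
#' \code{\link{channel_of}}).
#'
#' @param snvs A data.frame with columns \code{ref}, \code{alt},
#'   \code{context} (one row per SNV). Contexts must all be present.
#' @param label Profile label, conventionally \code{"<patient>:<timing>"}.
#' @return An object of class \code{profile96}: a list with \code{label},
#'   \code{counts} (named integer vector of length 96 in canonical order)
#'   and \code{total}.
#' @export
#' @examples
#' p <- build_profile96(data.frame(ref = "C", alt = "T", context = "ACG"), "ex")
#' p$counts[["A[C>T]G"]]
build_profile96 <- function(snvs, label = "") {
  channels <- sbs96_channels()
  counts <- integer(96)
  names(counts) <- channels
  if (nrow(snvs) > 0L) {
    if (any(is.na(snvs$context) | snvs$context == "" | snvs$context == ".")) {
      stop("all SNVs must have a trinucleotide context")
    }
    ch <- channel_of(snvs$ref, snvs$alt, snvs$context)
    tab <- table(factor(ch, levels = channels))
    counts <- as.integer(tab)
    names(counts) <- channels
  }
  structure(
    list(label = label, counts = counts, total = sum(counts)),
    class = "profile96"
  )
}

#' @export
print.profile96 <- function(x, ...) {
  cat("SBS96 profile '", x$label, "': ", x$total, " mutations\n", sep = "")
  nz <- x$counts[x$counts > 0]
  top <- sort(nz, decreasing = TRUE)
  top <- utils::head(top, 5L)
  if (length(top)) {
    cat("  top channels:",
        paste0(names(top), "=", top, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a single profile as TSV
#'
#' Columns `channel  count`, 96 rows in canonical order.
#'
#' @param profile A \code{profile96} object.
#' @param path Output file.
#' @export
write_profile96 <- function(profile, path) {
  df <- data.frame(channel = names(profile$counts),
                   count = unname(profile$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile96
#' @param label Label for the profile read back in.
#' @export
read_profile96 <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "count") %in% names(df))) {
    stop("profile file must have columns 'channel' and 'count'")
  }
  channels <- sbs96_channels()
  idx <- match(channels, df$channel)
  if (anyNA(idx)) {
    stop("profile file is missing channel(s): ",
         paste(utils::head(channels[is.na(idx)], 3L), collapse = ", "))
  }
  counts <- as.integer(df$count[idx])
  names(counts) <- channels
  structure(list(label = label, counts = counts, total = sum(counts)),
            class = "profile96")
}

#' Write several profiles as a channels-by-labels matrix
#'
#' @param profiles A list of \code{profile96} objects.
#' @param path Output TSV; first column `channel`, one column per label.
#' @export
write_profile_matrix <- function(profiles, path) {
  m <- vapply(profiles, function(p) unname(p$counts), numeric(96))
  colnames(m) <- vapply(profiles, function(p) p$label, character(1))
  df <- data.frame(channel = sbs96_channels(), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
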