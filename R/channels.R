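#' Canonical SBS96 channel order
#'
#' The 96 single-base-substitution channels in canonical order: substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G; within each class the 16 flanking
#' base pairs in lexicographic order of (5' base, 3' base) over A, C, G, T.
#' Channel strings have the COSMIC form \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  k <- 0L
  for (s in subs) {
    for (five in bases) {
      for (three in bases) {
        k <- k + 1L
        out[k] <- paste0(five, "[", s, "]", three)
      }
    }
  }
  out
}

# reverse complement of a vector of A/C/G/T strings (each any length)
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Map a single-base substitution to its SBS96 channel
#'
#' Purine-reference substitutions (ref A or G) are reverse-complemented,
#' together with their trinucleotide context, so every channel has a
#' pyrimidine (C or T) reference base.
#'
#' @param ref Single reference base, one of A/C/G/T.
#' @param alt Single alternate base, one of A/C/G/T, different from \code{ref}.
#' @param context 3-mer centered on the mutated base; the middle base must
#'   equal \code{ref}.
#' @return The channel string, e.g. \code{"A[C>T]G"}. Vectorized over all
#'   three arguments.
#' @export
#' @examples
#' channel_of("C", "T", "ACG")  # "A[C>T]G"
#' channel_of("G", "A", "AGC")  # "G[C>T]T"
channel_of <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt must be unambiguous bases (A/C/G/T)")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(context) != 3L)) stop("context must be a 3-mer")
  if (any(!grepl("^[ACGT]{3}$", context))) {
    stop("context contains ambiguous bases (only A/C/G/T allowed)")
  }
  if (any(substr(context, 2L, 2L) != ref)) {
    stop("context middle base must equal ref")
  }
  purine <- ref %in% c("A", "G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref2 <- ifelse(purine, comp[ref], ref)
  alt2 <- ifelse(purine, comp[alt], alt)
  ctx2 <- context
  if (any(purine)) ctx2[purine] <- revcomp(context[purine])
  paste0(
    substr(ctx2, 1L, 1L), "[", ref2, ">", alt2, "]", substr(ctx2, 3L, 3L)
  )
}

#' Integer index of a channel in the canonical order
#'
#' @param channel Channel string(s) such as \code{"A[C>T]G"}.
#' @return Integer index/indices in 1..96.
#' @export
channel_index <- function(channel) {
  idx <- match(channel, sbs96_channels())
  if (anyNA(idx)) {
    stop("unknown channel: ", paste(channel[is.na(idx)], collapse = ", "))
  }
  idx
}
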