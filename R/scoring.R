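#' Cosine similarity between two non-negative 96-vectors
#'
#' @param observed Numeric vector (e.g. a \code{profile96}'s counts) or a
#'   \code{profile96} object.
#' @param estimated Numeric vector of the same length.
#' @return Cosine similarity in [0, 1] for non-negative inputs.
#' @export
cosine_similarity <- function(observed, estimated) {
  if (inherits(observed, "profile96")) observed <- observed$counts
  if (inherits(estimated, "profile96")) estimated <- estimated$counts
  a <- as.numeric(observed)
  b <- as.numeric(estimated)
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Reconstruct a 96-channel profile from signature exposures
#'
#' Scales the exposure-weighted combination of signature probability vectors
#' to the observed total mutation count.
#'
#' @param fractions Named numeric vector of signature fractions (summing
#'   to 1), or a \code{sigfit} object.
#' @param catalog A \code{signature_catalog}.
#' @param total Observed total mutation count (>= 1).
#' @return Numeric 96-vector (named by channel) summing to \code{total}.
#' @export
reconstruct_profile <- function(fractions, catalog, total) {
  if (inherits(fractions, "sigfit")) fractions <- stats::coef(fractions)
  if (total < 1) stop("total mutation count must be >= 1")
  ids <- names(fractions)
  miss <- setdiff(ids, colnames(catalog))
  if (length(miss)) {
    stop("signature(s) missing from catalog: ", paste(miss, collapse = ", "))
  }
  v <- as.numeric(catalog[, ids, drop = FALSE] %*% fractions)
  names(v) <- rownames(catalog)
  total * v
}

#' Frequency-weighted Signature Score and its standard error
#'
#' The Signature Score of a fitted profile m is
#' \deqn{SS_m = CS_m \sum_i S_i f_i}
#' where \eqn{S_i} is the estimated fraction of signature i, \eqn{f_i} its
#' prevalence (fraction of patients carrying it) in the prioritized cancer
#' type, and \eqn{CS_m} the cosine similarity between observed and
#' reconstructed profiles. The score rewards fits that are both accurate and
#' composed of signatures plausible for the tissue. Its standard error
#' propagates the binomial sampling error of each estimated prevalence
#' (cohort of size \eqn{N_i}), treating the frequencies as independent:
#' \deqn{SE = CS_m \sqrt{\sum_i S_i^2 f_i (1 - f_i) / N_i}.}
#' Fractions and cosine similarity are point estimates, so the SE is an
#' underestimate of the full uncertainty.
#'
#' @param fractions Named numeric vector of signature fractions.
#' @param prevalence A \code{prevalence_table}.
#' @param cancer_type Cancer-type key into the prevalence table; signatures
#'   absent from the table contribute frequency 0.
#' @param cs Cosine similarity of the fit, in [0, 1].
#' @return List with \code{ss} and \code{se}.
#' @export
#' @examples
#' pv <- prevalence_table(data.frame(
#'   cancer_type = "lung", signature_id = c("A", "B"),
#'   frequency = c(0.8, 0.4), n_patients = 100))
#' signature_score(c(A = 0.5, B = 0.5), pv, "lung", cs = 0.9)
signature_score <- function(fractions, prevalence, cancer_type, cs) {
  if (cs < 0 || cs > 1) stop("cs must lie in [0, 1]")
  pv <- prevalence_lookup(prevalence, cancer_type, names(fractions))
  s <- as.numeric(fractions)
  ss <- cs * sum(s * pv$f)
  se <- cs * sqrt(sum(s^2 * pv$f * (1 - pv$f) / pv$n))
  list(ss = ss, se = se)
}

#' Dominant signature of an exposure set
#'
#' The signature with the largest fitted fraction; it is called dominant in
#' the strict sense when its fraction exceeds 0.5. Ties are broken by
#' catalog (input) order.
#'
#' @param fractions Named numeric fraction vector (catalog order) or a
#'   \code{sigfit} object.
#' @return List with \code{signature_id}, \code{fraction},
#'   \code{is_dominant}.
#' @export
dominant_signature <- function(fractions) {
  if (inherits(fractions, "sigfit")) fractions <- stats::coef(fractions)
  if (length(fractions) == 0L) stop("empty exposure set")
  i <- which.max(fractions)  # first maximum = catalog-order tie-break
  list(signature_id = names(fractions)[i],
       fraction = unname(fractions[i]),
       is_dominant = unname(fractions[i]) > 0.5)
}

#' Top-k signatures by fitted fraction
#'
#' @param fractions Named numeric fraction vector or \code{sigfit} object.
#' @param k Number of signatures to return (truncated to the number fitted).
#' @return Named numeric vector in descending fraction order, ties broken
#'   by catalog order.
#' @export
top_k_signatures <- function(fractions, k) {
  if (inherits(fractions, "sigfit")) fractions <- stats::coef(fractions)
  if (k < 1) stop("k must be >= 1")
  ord <- order(-as.numeric(fractions), seq_along(fractions))
  fractions[ord][seq_len(min(k, length(fractions)))]
}

#' Compare two Signature Scores
#'
#' Standardizes the score difference by the combined prevalence-propagated
#' standard errors and evaluates a two-sided normal tail probability. The
#' SEs are analytic (binomial error in the reference prevalences), so no
#' finite degrees of freedom apply and the normal reference is used. Because
#' fraction and cosine-similarity uncertainty is not propagated, the SEs —
#' and hence the p-values — are anti-conservative; the output carries a
#' fixed note to that effect.
#'
#' @param a,b Lists (or one-row data.frames) with elements \code{ss} and
#'   \code{se}, e.g. from \code{\link{signature_score}} or a \code{sigfit}.
#' @return List of class \code{score_comparison}: \code{delta} (ss_a -
#'   ss_b), \code{z}, \code{p_value} (NA when both SEs are zero, flagged
#'   \code{degenerate}), and \code{note}.
#' @export
compare_scores <- function(a, b) {
  if (inherits(a, "sigfit")) a <- list(ss = a$ss, se = a$se)
  if (inherits(b, "sigfit")) b <- list(ss = b$ss, se = b$se)
  if (!is.finite(a$se) || !is.finite(b$se)) stop("SEs must be finite")
  delta <- a$ss - b$ss
  pooled <- sqrt(a$se^2 + b$se^2)
  if (pooled == 0) {
    out <- list(delta = delta, z = NA_real_, p_value = NA_real_,
                degenerate = TRUE,
                note = "SEs reflect prevalence sampling error only and are likely underestimated")
    class(out) <- "score_comparison"
    return(out)
  }
  z <- delta / pooled
  # keep p strictly positive: extreme z underflows pnorm to exact 0
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  out <- list(delta = delta, z = z, p_value = p, degenerate = FALSE,
              note = "SEs reflect prevalence sampling error only and are likely underestimated")
  class(out) <- "score_comparison"
  out
}

#' @export
print.score_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("Score comparison: delta =", format(x$delta),
        "(degenerate: both SEs zero, p undefined)\n")
  } else {
    cat("Score comparison: delta =", format(x$delta),
        " z =", format(x$z), " p =", format.pval(x$p_value), "\n")
  }
  invisible(x)
}
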