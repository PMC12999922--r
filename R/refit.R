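#' Non-negative least-squares signature fit
#'
#' Fits a profile's channel proportions as a non-negative combination of a
#' subset of catalog signatures, minimizing Euclidean distance, and returns
#' the coefficients normalized to fractions summing to 1.
#'
#' @param profile A \code{profile96} object or a non-negative 96-vector of
#'   counts.
#' @param catalog A \code{signature_catalog}.
#' @param subset Character vector of signature ids to fit (default: all).
#' @return Named numeric vector of fractions over \code{subset}.
#' @export
nnls_fit <- function(profile, catalog, subset = colnames(catalog)) {
  counts <- if (inherits(profile, "profile96")) profile$counts else profile
  total <- sum(counts)
  if (total <= 0) stop("cannot fit an all-zero profile")
  if (length(subset) == 0L) stop("signature subset is empty")
  miss <- setdiff(subset, colnames(catalog))
  if (length(miss)) {
    stop("signature(s) not in catalog: ", paste(miss, collapse = ", "))
  }
  p <- as.numeric(counts) / total
  C <- unclass(catalog)[, subset, drop = FALSE]
  x <- pracma::lsqnonneg(C, p)$x
  if (sum(x) <= 0) stop("no signature attains a positive coefficient")
  stats::setNames(x / sum(x), subset)
}

# prune fractions below threshold and refit on survivors, iterating to a
# fixed point (each pass removes at least one signature or stops)
prune_and_refit <- function(counts, catalog, fractions, prune_threshold) {
  repeat {
    keep <- names(fractions)[fractions >= prune_threshold]
    if (length(keep) == 0L) {
      # degenerate: keep the single largest contributor
      keep <- names(fractions)[which.max(fractions)]
    }
    if (length(keep) == length(fractions)) return(fractions)
    fractions <- nnls_fit(counts, catalog, keep)
  }
}

#' Site-prioritized signature refitting
#'
#' The package's core estimator. Stage 1 fits the profile by restricted
#' NNLS using only the signatures expected at the prioritized tumor site
#' (positive prevalence in the mapped cancer type), then prunes fractions
#' below \code{prune_threshold} and refits on the survivors. If the
#' reconstruction's cosine similarity falls below
#' \code{rescue_cs_threshold}, Stage 2 greedily admits out-of-site catalog
#' signatures one at a time, each time taking the candidate with the
#' largest cosine-similarity gain (ties broken by catalog order), until the
#' best gain drops below \code{rescue_gain}. This mirrors the documented
#' behavior of reference-database refitters: expected signatures are
#' prioritized, but unexpected ones can emerge when the expected set fits
#' poorly.
#'
#' The returned object also carries the frequency-weighted Signature Score
#' \eqn{SS = CS \sum_i S_i f_i} and its prevalence-propagated standard
#' error (see \code{\link{signature_score}}), computed against the
#' prioritized site's cancer type.
#'
#' @param profile A \code{profile96} object.
#' @param catalog A \code{signature_catalog}.
#' @param prevalence A \code{prevalence_table}.
#' @param mapping Named site-to-cancer-type vector
#'   (\code{\link{read_site_map}}).
#' @param site Prioritized tumor-site label (must resolve through
#'   \code{mapping}).
#' @param min_freq Minimum prevalence for a signature to count as expected
#'   at the site (default: any positive prevalence).
#' @param prune_threshold Fractions below this are pruned and the fit
#'   re-solved (default 0.01).
#' @param rescue_cs_threshold Cosine similarity below which the rescue
#'   stage fires (default 0.85).
#' @param rescue_gain Minimum cosine-similarity gain for admitting another
#'   out-of-site signature (default 0.02).
#' @param rescue Set FALSE to disable the rescue stage.
#' @param timing Optional timing-class label ("EARLY"/"LATE") stored on the
#'   result.
#' @return An object of class \code{sigfit} with components
#'   \code{coefficients} (named fractions summing to 1), \code{cs},
#'   \code{ss}, \code{se}, \code{rescue_used}, \code{allowed},
#'   \code{dominant} (list from \code{\link{dominant_signature}}),
#'   \code{profile}, \code{fitted}, \code{site}, \code{cancer_type},
#'   \code{timing}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{residuals}, \code{predict}, \code{plot},
#'   \code{simulate}.
#' @export
#' @examples
#' cat96 <- toy_signature_catalog(3)
#' prof <- build_profile96_from_channels(
#'   rep(rownames(cat96)[which.max(cat96[, 1])], 50), "ex")
#' pv <- prevalence_table(data.frame(cancer_type = "lung",
#'   signature_id = colnames(cat96), frequency = c(0.8, 0.3, 0.2),
#'   n_patients = 100))
#' fit <- refit_signatures(prof, cat96, pv, c(Lung = "lung"), "Lung")
#' coef(fit)
refit_signatures <- function(profile, catalog, prevalence, mapping, site,
                             min_freq = 0, prune_threshold = 0.01,
                             rescue_cs_threshold = 0.85, rescue_gain = 0.02,
                             rescue = TRUE, timing = NA_character_) {
  stopifnot(inherits(profile, "profile96"))
  if (profile$total < 1) stop("profile has no mutations")
  allowed <- allowed_signatures(site, mapping, prevalence, catalog,
                                min_freq = min_freq)
  if (length(allowed) == 0L && !rescue) {
    stop("no signatures expected at site '", site,
         "' and rescue is disabled")
  }
  counts <- profile$counts

  fit_cs <- function(fractions) {
    est <- as.numeric(unclass(catalog)[, names(fractions), drop = FALSE] %*%
                        fractions)
    cosine_similarity(counts, est)
  }

  rescue_used <- FALSE
  if (length(allowed) > 0L) {
    fractions <- nnls_fit(counts, catalog, allowed)
    fractions <- prune_and_refit(counts, catalog, fractions, prune_threshold)
    cs <- fit_cs(fractions)
  } else {
    fractions <- stats::setNames(numeric(0), character(0))
    cs <- 0
  }

  if (rescue && cs < rescue_cs_threshold) {
    candidates <- setdiff(colnames(catalog), allowed)
    repeat {
      candidates <- setdiff(candidates, names(fractions))
      if (length(candidates) == 0L) break
      trial_cs <- vapply(candidates, function(id) {
        fit_cs(nnls_fit(counts, catalog, c(names(fractions), id)))
      }, numeric(1))
      best <- which.max(trial_cs)  # first max: catalog-order tie-break
      if (trial_cs[best] - cs < rescue_gain) break
      rescue_used <- TRUE
      fractions <- nnls_fit(counts, catalog,
                            c(names(fractions), candidates[best]))
      fractions <- prune_and_refit(counts, catalog, fractions,
                                   prune_threshold)
      cs <- fit_cs(fractions)
    }
    if (length(fractions) == 0L) {
      stop("rescue failed to admit any signature for site '", site, "'")
    }
  }

  # report in catalog order
  ord <- order(match(names(fractions), colnames(catalog)))
  fractions <- fractions[ord]

  cancer_type <- mapping[[site]]
  sc <- signature_score(fractions, prevalence, cancer_type, cs)
  est_counts <- reconstruct_profile(fractions, catalog, profile$total)

  structure(list(
    coefficients = fractions,
    cs = cs, ss = sc$ss, se = sc$se,
    rescue_used = rescue_used,
    allowed = allowed,
    dominant = dominant_signature(fractions),
    profile = profile, fitted = est_counts,
    site = site, cancer_type = cancer_type, timing = timing,
    catalog = catalog, prevalence = prevalence,
    control = list(min_freq = min_freq, prune_threshold = prune_threshold,
                   rescue_cs_threshold = rescue_cs_threshold,
                   rescue_gain = rescue_gain, rescue = rescue)
  ), class = "sigfit")
}

#' @export
coef.sigfit <- function(object, ...) object$coefficients

#' @export
fitted.sigfit <- function(object, ...) object$fitted

#' @export
residuals.sigfit <- function(object, ...) {
  object$profile$counts - object$fitted
}

#' Reconstructed profile at a chosen mutation total
#'
#' @param object A \code{sigfit}.
#' @param total Mutation count to scale the reconstruction to (default: the
#'   observed total).
#' @param ... Ignored.
#' @export
predict.sigfit <- function(object, total = object$profile$total, ...) {
  reconstruct_profile(object$coefficients, object$catalog, total)
}

#' @export
print.sigfit <- function(x, digits = 3, ...) {
  cat("Site-prioritized signature refit\n")
  cat("  profile: ", x$profile$label, " (", x$profile$total,
      " mutations)", sep = "")
  if (!is.na(x$timing)) cat("  timing:", x$timing)
  cat("\n  prioritized site:", x$site, "->", x$cancer_type, "\n")
  cat("  fractions:\n")
  print(round(x$coefficients, digits))
  cat("  CS =", format(x$cs, digits = digits),
      " SS =", format(x$ss, digits = digits),
      " (SE =", format(x$se, digits = digits), ")\n")
  if (x$rescue_used) cat("  rescue stage admitted out-of-site signature(s)\n")
  invisible(x)
}

#' @export
summary.sigfit <- function(object, ...) {
  pv <- prevalence_lookup_for(object)
  tab <- data.frame(
    signature = names(object$coefficients),
    fraction = unname(object$coefficients),
    prevalence = pv$f,
    expected_at_site = names(object$coefficients) %in% object$allowed,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$fraction), , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(table = tab, cs = object$cs, ss = object$ss, se = object$se,
              dominant = object$dominant, rescue_used = object$rescue_used,
              site = object$site, cancer_type = object$cancer_type,
              label = object$profile$label, timing = object$timing)
  class(out) <- "summary.sigfit"
  out
}

prevalence_lookup_for <- function(object) {
  prevalence_lookup(object$prevalence, object$cancer_type,
                    names(object$coefficients))
}

#' @export
print.summary.sigfit <- function(x, ...) {
  cat("Signature refit for", x$label, "at site", x$site,
      "(cancer type:", paste0(x$cancer_type, ")"), "\n")
  print(x$table)
  cat("dominant:", x$dominant$signature_id,
      sprintf("(%.2f, %s)", x$dominant$fraction,
              if (x$dominant$is_dominant) ">0.5" else "<=0.5"), "\n")
  cat("CS =", format(x$cs, digits = 4), " SS =", format(x$ss, digits = 4),
      " SE =", format(x$se, digits = 4),
      if (x$rescue_used) " [rescue used]" else "", "\n")
  invisible(x)
}

#' Plot observed vs reconstructed 96-channel profiles
#'
#' Base-graphics barplot of the observed counts with the reconstruction
#' overlaid as points, channels grouped by substitution class.
#'
#' @param x A \code{sigfit}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.sigfit <- function(x, ...) {
  cls <- rep(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), each = 16)
  cols <- c("C>A" = "#03BCEE", "C>G" = "black", "C>T" = "#E32926",
            "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")
  mids <- graphics::barplot(x$profile$counts, col = cols[cls], border = NA,
                            names.arg = rep("", 96),
                            ylab = "mutations",
                            main = paste0(x$profile$label, " (CS = ",
                                          round(x$cs, 3), ")"), ...)
  graphics::points(mids, x$fitted, pch = 16, cex = 0.5)
  graphics::legend("topright", legend = names(cols), fill = cols,
                   border = NA, bty = "n", cex = 0.7)
  invisible(x)
}

#' Simulate profiles from a fitted signature mixture
#'
#' Draws multinomial 96-channel count profiles from the fitted channel
#' distribution at the observed mutation total.
#'
#' @param object A \code{sigfit}.
#' @param nsim Number of simulated profiles.
#' @param seed Optional RNG seed.
#' @param ... Ignored.
#' @return A data.frame with 96 rows (channels) and \code{nsim} columns.
#' @export
simulate.sigfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted / sum(object$fitted)
  m <- stats::rmultinom(nsim, size = object$profile$total, prob = p)
  out <- as.data.frame(m)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(object$profile$counts)
  out
}
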