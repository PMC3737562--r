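# Cross-sample correlation of windowed contact profiles (Spearman rank
# correlation of running-median-smoothed profiles, window 21 by default)
# and transcriptional-activity quantification of contacted chromatin: the
# proportion of transcribed bases inside called interacting domains versus
# the non-interacting territory, in cis and trans.

#' Spearman correlation of two windowed profiles
#'
#' Both profiles are smoothed with a running median of window w, then the
#' Spearman rank correlation is computed over the shared analyzable ends
#' (zero-count ends included; ties get average ranks).
#'
#' @param x,y Numeric vectors over the same fragment-end universe.
#' @param w Odd smoothing window (default 21).
#' @return Spearman rho.
#' @export
windowed_correlation <- function(x, y, w = 21L) {
  if (length(x) != length(y)) stopf("profiles differ in length")
  if (length(x) < 10L) stopf("fewer than 10 shared analyzable ends")
  sx <- running_median(x, min(w, length(x) - (1 - length(x) %% 2)))
  sy <- running_median(y, min(w, length(y) - (1 - length(y) %% 2)))
  stats::cor(sx, sy, method = "spearman")
}

#' Align contact profiles on their shared fragment-end universe
#'
#' The two alleles' fragment-end databases can differ slightly (a SNP may
#' create or remove a second-cutter site), so profiles are intersected on
#' shared end identifiers before correlation.
#'
#' @param profiles Named list of \code{ContactProfile}s.
#' @param layer Value column to extract ("norm" or "smooth").
#' @return Named list of numeric vectors over the shared ends, in the
#'   first profile's order.
#' @export
align_profiles <- function(profiles, layer = "norm") {
  shared <- Reduce(intersect, lapply(profiles, function(p) p$end_id))
  shared <- profiles[[1]]$end_id[profiles[[1]]$end_id %in% shared]
  lapply(profiles, function(p) p[[layer]][match(shared, p$end_id)])
}

#' Pairwise correlation matrix of contact profiles
#'
#' @param profiles Named list of numeric vectors over a shared fragment-end
#'   universe (e.g. normalized profiles of several samples/alleles).
#' @param w Smoothing window.
#' @return List of class \code{CorrelationMatrix}: \code{rho} (symmetric
#'   matrix, unit diagonal, input label order preserved) and \code{w}.
#'   Cells whose pairwise computation fails are NA.
#' @export
correlation_matrix <- function(profiles, w = 21L) {
  if (length(profiles) < 2L) stopf("need at least 2 profiles")
  labels <- names(profiles)
  if (is.null(labels)) labels <- paste0("profile", seq_along(profiles))
  n <- length(profiles)
  rho <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(rho) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- tryCatch(windowed_correlation(profiles[[i]], profiles[[j]], w),
                    error = function(e) NA_real_)
      rho[i, j] <- r
      rho[j, i] <- r
    }
  }
  structure(list(rho = rho, w = as.integer(w)),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("Spearman correlation matrix (window %d):\n", x$w))
  print(round(x$rho, 2))
  invisible(x)
}

#' Proportion of transcribed bases in and outside interacting domains
#'
#' Exact interval intersection of a transcribed-interval track with the
#' called domains and their complement.
#'
#' @param domains An \code{InteractingDomains} object.
#' @param expression data.frame(chrom, start, end) of transcribed intervals
#'   (0-based half-open); overlapping intervals are merged first.
#' @return data.frame rows for regions "interacting" and "non_interacting":
#'   compartment, region, bases, transcribed, fraction (NA when the region
#'   has zero bases).
#' @export
transcribed_fraction <- function(domains, expression) {
  stopifnot(inherits(domains, "InteractingDomains"))
  expr <- do.call(rbind, lapply(split(expression, expression$chrom),
                                function(d) {
                                  data.frame(chrom = d$chrom[1],
                                             merge_intervals(d))
                                }))
  row_for <- function(intervals, region) {
    bases <- sum(intervals$end - intervals$start)
    transcribed <- sum(vapply(unique(intervals$chrom), function(chrom) {
      intersect_bases(intervals[intervals$chrom == chrom, , drop = FALSE],
                      expr[expr$chrom == chrom, , drop = FALSE])
    }, numeric(1)))
    data.frame(compartment = domains$compartment, region = region,
               bases = bases, transcribed = transcribed,
               fraction = if (bases > 0) transcribed / bases else NA_real_)
  }
  out <- rbind(row_for(domains$domains, "interacting"),
               row_for(domains$complement, "non_interacting"))
  rownames(out) <- NULL
  out
}

# per-domain (bases, transcribed) used as the bootstrap resampling unit
per_domain_transcribed <- function(domains_df, expression) {
  expr <- do.call(rbind, lapply(split(expression, expression$chrom),
                                function(d) {
                                  data.frame(chrom = d$chrom[1],
                                             merge_intervals(d))
                                }))
  t(vapply(seq_len(nrow(domains_df)), function(i) {
    d <- domains_df[i, , drop = FALSE]
    c(bases = d$end - d$start,
      transcribed = intersect_bases(d, expr[expr$chrom == d$chrom, ,
                                            drop = FALSE]))
  }, numeric(2)))
}

#' Contrast of transcriptional activity: interacting vs non-interacting
#'
#' Contrast = transcribed fraction inside interacting domains minus the
#' fraction in the non-interacting territory, with a 95 percent percentile
#' bootstrap CI obtained by resampling whole domains (bases within a domain
#' are not independent, so the domain is the resampling unit). With fewer
#' than 5 domains the contrast is reported without a CI.
#'
#' @param domains An \code{InteractingDomains} object (or a list of them;
#'   their domain sets are pooled and complements concatenated).
#' @param expression Transcribed-interval track.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return list(contrast, ci (length-2 or NULL), n_domains,
#'   fraction_interacting, fraction_non_interacting).
#' @export
compare_compartments <- function(domains, expression, n_boot = 1000L,
                                 seed = 1L) {
  if (inherits(domains, "InteractingDomains")) domains <- list(domains)
  dom_df <- do.call(rbind, lapply(domains, function(d) d$domains))
  comp_df <- do.call(rbind, lapply(domains, function(d) d$complement))
  if (is.null(dom_df) || nrow(dom_df) == 0L) {
    stopf("no interacting domains to contrast")
  }
  per_dom <- per_domain_transcribed(dom_df, expression)
  per_comp <- per_domain_transcribed(comp_df, expression)
  f_int <- sum(per_dom[, "transcribed"]) / sum(per_dom[, "bases"])
  f_non <- sum(per_comp[, "transcribed"]) / sum(per_comp[, "bases"])
  contrast <- f_int - f_non
  ci <- NULL
  n_dom <- nrow(per_dom)
  if (n_dom >= 5L && n_boot >= 2L) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample.int(n_dom, n_dom, replace = TRUE)
        sum(per_dom[pick, "transcribed"]) / sum(per_dom[pick, "bases"]) -
          f_non
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  } else if (n_boot == 1L) {
    ci <- c(contrast, contrast)  # degenerate resampling = point estimate
  }
  list(contrast = contrast, ci = ci, n_domains = n_dom,
       fraction_interacting = f_int, fraction_non_interacting = f_non)
}
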