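# Domainograms: multi-scale running-window significance of contacts. The
# per-end coverage is binarized (captured at least once or not), a
# background coverage rate pi is estimated separately for far-cis (beyond a
# viewpoint-proximal exclusion) and trans, and each window of w consecutive
# analyzable ends is scored with the upper-tail binomial probability of its
# covered count under Bernoulli(pi). The display scale runs from P = 1
# (no signal) to a floor of P = 1e-10; raw p-values are retained.

#' Binarize per-end coverage and estimate background rates
#'
#' An end is covered iff its raw capture count is >= 1. Ends within
#' \code{exclusion_radius} fragments of the viewpoint are masked out (the
#' near-cis polymer-decay signal saturates coverage and would swamp the
#' background estimate). The coverage fraction pi is computed separately
#' for far-cis and trans.
#'
#' @param profile A \code{ContactProfile} (carries raw counts over
#'   analyzable ends).
#' @param db The \code{FragmentEndDB}.
#' @param vp The \code{ViewpointSpec}.
#' @param exclusion_radius Masking radius around the viewpoint, in
#'   first-cutter fragments (>= 0). The default NULL uses the equivalent of
#'   1 Mb at the database's mean fragment length.
#' @return List of class \code{CoverageSet} with one element per
#'   compartment ("far_cis", "trans"), each holding ends (data.frame),
#'   covered (logical), and pi; plus the exclusion used.
#' @export
binarize_coverage <- function(profile, db, vp, exclusion_radius = NULL) {
  stopifnot(inherits(profile, "ContactProfile"))
  if (is.null(exclusion_radius)) {
    mean_frag <- mean(db$fragments$end - db$fragments$start)
    exclusion_radius <- max(1L, round(1e6 / mean_frag))
  }
  if (exclusion_radius < 0) stopf("exclusion_radius must be >= 0")
  fr <- db$fragments
  hit <- fr$chrom == vp$chrom & fr$start <= vp$pos & fr$end > vp$pos
  if (!any(hit)) stopf("viewpoint not inside any fragment")
  vp_idx <- fr$frag_idx[which(hit)[1]]

  cis <- profile$cis
  masked <- cis & abs(profile$frag_idx - vp_idx) <= exclusion_radius
  compartment <- ifelse(!cis, "trans", ifelse(masked, "masked", "far_cis"))

  mk <- function(comp) {
    sel <- compartment == comp
    ends <- profile[sel, c("end_id", "chrom", "start", "end", "frag_idx")]
    # contiguity blocks: significant runs must not be merged across the
    # masked viewpoint region or across chromosomes
    ends$block <- if (comp == "far_cis") {
      paste0(ends$chrom, ifelse(ends$frag_idx < vp_idx, ":L", ":R"))
    } else ends$chrom
    covered <- profile$raw[sel] >= 1L
    list(ends = ends, covered = covered,
         pi = if (sum(sel) > 0) mean(covered) else NA_real_)
  }
  structure(list(far_cis = mk("far_cis"), trans = mk("trans"),
                 exclusion_radius = exclusion_radius, vp_frag_idx = vp_idx),
            class = "CoverageSet")
}

#' Multi-scale running-window binomial significance (domainogram)
#'
#' For each window size w and each position i with a full centered window of
#' w consecutive analyzable ends, P[w, i] is the upper-tail binomial
#' probability of observing at least the covered count in w trials at rate
#' pi. Edge positions without a full window, and degenerate backgrounds
#' (pi = 0 or 1), score p = 1.
#'
#' @param covered Logical coverage vector over consecutive analyzable ends.
#' @param pi Background coverage rate in (0, 1).
#' @param W Integer vector of window sizes; max(W) <= length(covered).
#' @return List of class \code{Domainogram}: \code{P} (|W| x n matrix of
#'   raw p-values), \code{W}, \code{pi}, \code{floor} (1e-10, applied only
#'   at rendering).
#' @export
window_significance <- function(covered, pi, W) {
  n <- length(covered)
  W <- as.integer(W)
  if (any(W < 1L)) stopf("window sizes must be >= 1")
  if (max(W) > n) stopf("max window size exceeds vector length")
  P <- matrix(1, nrow = length(W), ncol = n,
              dimnames = list(paste0("w", W), NULL))
  degenerate <- is.na(pi) || pi <= 0 || pi >= 1
  if (degenerate) {
    warnf("degenerate background pi = %s; all p-values set to 1",
          format(pi))
  } else {
    x <- as.integer(covered)
    cs <- c(0L, cumsum(x))
    for (j in seq_along(W)) {
      w <- W[j]
      h <- (w - 1L) %/% 2L
      lo <- h + 1L
      hi <- n - (w - 1L - h)
      if (lo > hi) next
      # covered count in the w-window starting at position i - h
      k <- cs[(lo - h + w):(hi - h + w)] - cs[(lo - h):(hi - h)]
      tail_p <- stats::pbinom(0:w - 1L, w, pi, lower.tail = FALSE)
      P[j, lo:hi] <- tail_p[k + 1L]
    }
  }
  structure(list(P = P, W = W, pi = pi, n = n, floor = 1e-10),
            class = "Domainogram")
}

#' Render-scale p-values of a domainogram
#'
#' @param dg A \code{Domainogram}.
#' @return Matrix of -log10 p-values, capped at the display floor (10).
#' @export
domainogram_display <- function(dg) {
  pmin(-log10(pmax(dg$P, dg$floor)), -log10(dg$floor))
}

#' Empirical null calibration of the window significance model
#'
#' Simulates i.i.d. Bernoulli(pi) coverage and reports, per window size,
#' the fraction of windows reaching p < alpha, together with the exact
#' expected rate (the binomial tail mass at the critical count; the
#' discrete test is conservative, so empirical rates sit at or below
#' nominal alpha).
#'
#' @param pi Background rate.
#' @param W Window sizes.
#' @param n_ends Length of each simulated coverage vector.
#' @param n_sims Number of simulations (>= 100).
#' @param alpha Significance levels to tabulate.
#' @param seed Integer seed.
#' @return data.frame(w, alpha, empirical, exact, mc_se, n_windows).
#' @export
null_calibration <- function(pi, W, n_ends, n_sims, alpha = c(0.05, 0.01),
                             seed = 1L) {
  if (n_sims < 100L) stopf("n_sims must be >= 100")
  W <- as.integer(W)
  with_seed(seed, {
    # per-sim false-positive rates: windows overlap within one simulated
    # vector, so the MC standard error must come from across-simulation
    # variation, not pooled window counts
    rate <- array(NA_real_, dim = c(n_sims, length(W), length(alpha)))
    for (s in seq_len(n_sims)) {
      covered <- stats::runif(n_ends) < pi
      dg <- window_significance(covered, pi, W)
      for (j in seq_along(W)) {
        w <- W[j]
        h <- (w - 1L) %/% 2L
        idx <- (h + 1L):(n_ends - (w - 1L - h))
        p <- dg$P[j, idx]
        for (a in seq_along(alpha)) {
          rate[s, j, a] <- mean(p < alpha[a])
        }
      }
    }
    out <- expand.grid(w = W, alpha = alpha)
    out$empirical <- mapply(function(w, a) {
      mean(rate[, match(w, W), match(a, alpha)])
    }, out$w, out$alpha)
    out$exact <- mapply(function(w, a) {
      tail_p <- stats::pbinom(0:w - 1L, w, pi, lower.tail = FALSE)
      crit <- which(tail_p < a)
      if (length(crit) == 0L) 0 else tail_p[crit[1]]
    }, out$w, out$alpha)
    out$mc_se <- mapply(function(w, a) {
      stats::sd(rate[, match(w, W), match(a, alpha)]) / sqrt(n_sims)
    }, out$w, out$alpha)
    out$n_windows <- vapply(out$w, function(w) {
      (n_ends - w + 1L) * n_sims
    }, numeric(1))
    out
  })
}

#' Call interacting domains from a domainogram
#'
#' Benjamini-Hochberg correction of the p-values at one window size;
#' significant positions are merged into maximal runs of consecutive
#' analyzable ends and converted to genomic intervals. The complement over
#' the analyzable territory is returned as the non-interacting set.
#'
#' @param dg A \code{Domainogram}.
#' @param ends The ends data.frame of the corresponding \code{CoverageSet}
#'   compartment (same order as the coverage vector).
#' @param w_call Window size at which to call (must be in dg$W).
#' @param fdr FDR level in (0, 1).
#' @param compartment Label stored on the result ("cis" or "trans").
#' @return List of class \code{InteractingDomains}: \code{domains} and
#'   \code{complement} (data.frames chrom/start/end, disjoint, sorted),
#'   \code{compartment}, \code{fdr}, \code{w_call}.
#' @export
call_domains <- function(dg, ends, w_call, fdr = 0.05,
                         compartment = "cis") {
  stopifnot(inherits(dg, "Domainogram"))
  if (fdr <= 0 || fdr >= 1) stopf("fdr must be in (0, 1)")
  j <- match(as.integer(w_call), dg$W)
  if (is.na(j)) stopf("w_call = %d is not among the domainogram windows",
                      w_call)
  p <- dg$P[j, ]
  q <- stats::p.adjust(p, method = "BH")
  sig <- q <= fdr

  runs <- rle(sig)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  dom <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  block <- if ("block" %in% names(ends)) ends$block else ends$chrom
  for (r in which(runs$values)) {
    i0 <- idx_start[r]; i1 <- idx_end[r]
    # a run may not extend across a contiguity border (chromosome change
    # or the masked viewpoint region)
    seg <- ends[i0:i1, ]
    for (b in unique(block[i0:i1])) {
      s <- seg[block[i0:i1] == b, ]
      dom <- rbind(dom, data.frame(chrom = s$chrom[1], start = min(s$start),
                                   end = max(s$end)))
    }
  }
  dom <- dom[order(match(dom$chrom, unique(ends$chrom)), dom$start), ,
             drop = FALSE]
  rownames(dom) <- NULL

  comp <- do.call(rbind, lapply(unique(block), function(b) {
    sel <- block == b
    chrom <- ends$chrom[sel][1]
    terr <- data.frame(start = min(ends$start[sel]),
                       end = max(ends$end[sel]))
    d <- dom[dom$chrom == chrom & dom$start < terr$end &
               dom$end > terr$start, c("start", "end")]
    if (nrow(d) == 0L) return(data.frame(chrom = chrom, terr))
    left <- iranges_to_df(IRanges::setdiff(df_to_iranges(terr),
                                           df_to_iranges(d)))
    if (nrow(left) == 0L) return(NULL)
    data.frame(chrom = chrom, left)
  }))
  if (is.null(comp)) {
    comp <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0))
  }
  rownames(comp) <- NULL
  structure(list(domains = dom, complement = comp,
                 compartment = compartment, fdr = fdr,
                 w_call = as.integer(w_call)),
            class = "InteractingDomains")
}
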