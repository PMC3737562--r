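# Contact profiles: per-million normalization of capture counts over
# analyzable (unique, non-blind) fragment ends, running-median smoothing
# (default window 21 fragment ends, the smoothing used for locus-wide 4C
# profiles), and boundary detection as rapid drops in contact frequency.

#' Normalize capture counts to reads per million mapped
#'
#' @param counts Integer vector of raw per-end counts.
#' @param total_mapped Total mapped reads for the (viewpoint, allele,
#'   sample); must be > 0.
#' @return Numeric vector: counts * 1e6 / total_mapped.
#' @export
normalize_counts <- function(counts, total_mapped) {
  if (total_mapped <= 0) stopf("cannot normalize: no mapped reads")
  counts * 1e6 / total_mapped
}

#' Running median with symmetric shrinking edge windows
#'
#' Position i receives the median of the w values centered on it; near the
#' edges the largest centered odd window that fits is used, so the output
#' has the input's length without inventing data. w = 1 is the identity.
#'
#' @param values Numeric vector.
#' @param w Odd window size, 1 <= w <= length(values).
#' @return Smoothed numeric vector of the same length.
#' @export
running_median <- function(values, w) {
  n <- length(values)
  if (w %% 2 == 0) stopf("running-median window must be odd (got %d)", w)
  if (w < 1 || w > n) stopf("window must satisfy 1 <= w <= length(values)")
  if (w == 1L || n == 0L) return(values)
  out <- as.numeric(stats::runmed(values, w, endrule = "keep"))
  h <- (w - 1L) %/% 2L
  for (i in c(seq_len(h), n - seq_len(h) + 1L)) {
    k <- min(i - 1L, n - i)  # largest centered half-window that fits
    out[i] <- stats::median(values[(i - k):(i + k)])
  }
  out
}

#' Build a contact profile from a capture table
#'
#' Restricts to analyzable ends (unique and non-blind), orders the viewpoint
#' (cis) chromosome first, normalizes to reads per million mapped and
#' smooths with a running median per chromosome.
#'
#' @param ct A \code{CaptureTable}.
#' @param db The \code{FragmentEndDB} the table was mapped against.
#' @param vp The \code{ViewpointSpec} (fixes the cis chromosome).
#' @param w Running-median window in fragment ends (odd; default 21). Blocks
#'   shorter than w use the largest odd window that fits.
#' @return data.frame of class \code{ContactProfile}: end_id, chrom, start,
#'   end, frag_idx, raw, norm, smooth, cis; attributes viewpoint, allele,
#'   w, total_mapped.
#' @export
contact_profile <- function(ct, db, vp, w = 21L) {
  stopifnot(inherits(ct, "CaptureTable"), inherits(db, "FragmentEndDB"))
  ends <- db$ends
  keep <- ends$unique & !ends$blind
  prof <- ends[keep, c("end_id", "chrom", "start", "end", "frag_idx")]
  prof$raw <- unname(ct$counts[keep])
  prof$cis <- prof$chrom == vp$chrom
  ord <- order(!prof$cis, match(prof$chrom, unique(ends$chrom)), prof$start)
  prof <- prof[ord, ]
  rownames(prof) <- NULL
  prof$norm <- normalize_counts(prof$raw, ct$totals$mapped)
  prof$smooth <- NA_real_
  for (chrom in unique(prof$chrom)) {
    sel <- prof$chrom == chrom
    n <- sum(sel)
    wc <- min(w, if (n %% 2 == 1L) n else n - 1L)
    prof$smooth[sel] <- running_median(prof$norm[sel], wc)
  }
  structure(prof, class = c("ContactProfile", "data.frame"),
            viewpoint = vp$name, allele = ct$allele, w = w,
            total_mapped = ct$totals$mapped, cis_chrom = vp$chrom)
}

#' Build a contact profile directly from a raw count vector
#'
#' Count-level entry point (e.g. contacts sampled straight from a model on
#' a fragment grid, with no reads involved): same restriction, ordering,
#' normalization and smoothing as \code{\link{contact_profile}}.
#'
#' @param counts Integer vector aligned with \code{db$ends}.
#' @param db A \code{FragmentEndDB}.
#' @param cis_chrom The viewpoint chromosome.
#' @param w Running-median window.
#' @param viewpoint,allele Metadata labels.
#' @return A \code{ContactProfile}.
#' @export
counts_profile <- function(counts, db, cis_chrom, w = 21L,
                           viewpoint = "vp", allele = "A") {
  stopifnot(inherits(db, "FragmentEndDB"),
            length(counts) == nrow(db$ends))
  ct <- structure(list(counts = stats::setNames(as.integer(counts),
                                                db$ends$end_id),
                       totals = list(mapped = sum(counts)),
                       viewpoint = viewpoint, allele = allele),
                  class = "CaptureTable")
  contact_profile(ct, db, vp = list(chrom = cis_chrom, name = viewpoint),
                  w = w)
}

#' Detect contact-frequency boundaries in a smoothed profile
#'
#' Scores each position by the log2 ratio of mean smoothed signal over the
#' left flank to the right flank (a pseudocount keeps the ratio finite);
#' boundaries are local |score| maxima at or above the threshold. A positive
#' score is a left-to-right drop.
#'
#' @param profile A \code{ContactProfile} (cis part is used), or a numeric
#'   vector of smoothed values.
#' @param flank Flank width in fragment ends (>= 5).
#' @param threshold Minimum |score| to call a boundary (default 1, i.e. a
#'   2-fold drop).
#' @param eps Pseudocount in normalized units (default 0.5).
#' @return data.frame(index, score, direction) ranked by |score|; for a
#'   profile input also end_id, chrom, pos (the end's start coordinate) and
#'   frag_idx.
#' @export
detect_boundaries <- function(profile, flank = 10L, threshold = 1,
                              eps = 0.5) {
  if (flank < 5L) stopf("flank must be >= 5 fragment ends")
  is_prof <- inherits(profile, "ContactProfile")
  v <- if (is_prof) profile$smooth[profile$cis] else as.numeric(profile)
  n <- length(v)
  if (n < 2L * flank) stopf("profile shorter than 2 x flank")
  score <- rep(NA_real_, n)
  for (i in (flank + 1L):(n - flank + 1L)) {
    left <- mean(v[(i - flank):(i - 1L)])
    right <- mean(v[i:(i + flank - 1L)])
    score[i] <- log2((left + eps) / (right + eps))
  }
  # local maxima of |score| at or above threshold, greedy non-max
  # suppression within one flank width
  cand <- which(!is.na(score) & abs(score) >= threshold)
  cand <- cand[order(-abs(score[cand]))]
  picked <- integer(0)
  for (i in cand) {
    if (all(abs(i - picked) > flank)) picked <- c(picked, i)
  }
  out <- data.frame(index = picked, score = score[picked],
                    direction = ifelse(score[picked] > 0, "drop", "rise"))
  if (is_prof && nrow(out) > 0L) {
    cis <- profile[profile$cis, ]
    out$end_id <- cis$end_id[out$index]
    out$chrom <- cis$chrom[out$index]
    out$pos <- cis$start[out$index]
    out$frag_idx <- cis$frag_idx[out$index]
  }
  rownames(out) <- NULL
  out
}
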