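# Contact model: power-law decay in cis (p ~ distance^-alpha, the contact
# distribution expected from polymer physics), attenuated across topological
# domain boundaries, multiplied inside enriched regions, with a fixed share
# of probability mass on trans chromosomes. The viewpoint fragment and its
# two immediate neighbours are excluded (self-ligation / undigested
# products, standard 4C practice).

#' Construct a 4C contact model
#'
#' @param viewpoint list(chrom, pos): viewpoint location (0-based bp).
#' @param decay_exponent Positive cis decay exponent alpha.
#' @param domains Optional data.frame(chrom, start, end, attenuation):
#'   topological domains; crossing each domain boundary multiplies contact
#'   weight by its attenuation factor (in (0, 1)).
#' @param enriched Optional data.frame(chrom, start, end, fold): preferred
#'   contact regions, fold >= 1, applied in cis and trans.
#' @param trans_rate Probability mass assigned to trans chromosomes, in
#'   [0, 1).
#' @return List of class \code{ContactModel}.
#' @export
contact_model <- function(viewpoint, decay_exponent = 1,
                          domains = NULL, enriched = NULL, trans_rate = 0) {
  if (decay_exponent <= 0) stopf("decay_exponent must be > 0")
  if (trans_rate < 0 || trans_rate >= 1) stopf("trans_rate must be in [0,1)")
  if (!is.null(domains) && nrow(domains) > 0 &&
      any(domains$attenuation <= 0 | domains$attenuation >= 1)) {
    stopf("domain attenuation factors must lie in (0, 1)")
  }
  if (!is.null(enriched) && nrow(enriched) > 0 && any(enriched$fold < 1)) {
    stopf("enrichment folds must be >= 1")
  }
  structure(list(viewpoint = viewpoint, decay_exponent = decay_exponent,
                 domains = domains, enriched = enriched,
                 trans_rate = trans_rate),
            class = "ContactModel")
}

#' Per-fragment-end contact probabilities under a model
#'
#' Cis ends receive weight |x - x_vp|^-alpha (x = end midpoint), multiplied
#' by the attenuation factor once per domain boundary crossed and by the
#' fold factor inside enriched regions; the cis block is normalized to
#' 1 - trans_rate. Trans ends start uniform, are multiplied by enrichment,
#' and their block is normalized to trans_rate. The viewpoint fragment and
#' its two adjacent fragments receive probability 0. The vector sums to 1.
#'
#' @param model A \code{ContactModel}.
#' @param db A \code{FragmentEndDB}; the viewpoint must fall inside one of
#'   its fragments.
#' @return Numeric probability vector aligned with \code{db$ends}, with
#'   attributes \code{excluded} (row indices of the viewpoint-proximal
#'   exclusion) and \code{vp_frag_idx}.
#' @export
contact_probabilities <- function(model, db) {
  stopifnot(inherits(model, "ContactModel"), inherits(db, "FragmentEndDB"))
  ends <- db$ends
  if (nrow(ends) == 0L) stopf("empty fragment-end database")
  vp <- model$viewpoint
  fr <- db$fragments
  hit <- fr$chrom == vp$chrom & fr$start <= vp$pos & fr$end > vp$pos
  if (!any(hit)) stopf("viewpoint %s:%d not inside any fragment",
                       vp$chrom, vp$pos)
  vp_idx <- fr$frag_idx[which(hit)[1]]

  mid <- (ends$start + ends$end) / 2
  cis <- ends$chrom == vp$chrom
  w <- numeric(nrow(ends))

  d <- pmax(abs(mid[cis] - vp$pos), 1)
  w[cis] <- d^(-model$decay_exponent)

  if (!is.null(model$domains) && nrow(model$domains) > 0) {
    for (i in seq_len(nrow(model$domains))) {
      dom <- model$domains[i, ]
      if (dom$chrom != vp$chrom) next
      for (b in c(dom$start, dom$end)) {
        crossed <- cis & (pmin(mid, vp$pos) < b) & (b < pmax(mid, vp$pos))
        w[crossed] <- w[crossed] * dom$attenuation
      }
    }
  }
  w[!cis] <- 1  # uniform trans baseline before enrichment
  if (!is.null(model$enriched) && nrow(model$enriched) > 0) {
    for (i in seq_len(nrow(model$enriched))) {
      en <- model$enriched[i, ]
      inside <- ends$chrom == en$chrom & mid >= en$start & mid < en$end
      w[inside] <- w[inside] * en$fold
    }
  }

  excl <- which(cis & abs(ends$frag_idx - vp_idx) <= 1L)
  w[excl] <- 0

  p <- numeric(length(w))
  cis_sum <- sum(w[cis])
  trans_sum <- sum(w[!cis])
  cis_share <- if (trans_sum > 0) 1 - model$trans_rate else 1
  if (cis_sum > 0) p[cis] <- w[cis] / cis_sum * cis_share
  if (trans_sum > 0 && model$trans_rate > 0) {
    p[!cis] <- w[!cis] / trans_sum * model$trans_rate
  }
  if (sum(p) == 0) stopf("contact model puts no mass on any fragment end")
  p <- p / sum(p)
  attr(p, "excluded") <- excl
  attr(p, "vp_frag_idx") <- vp_idx
  p
}

#' Sample per-end contact counts from a probability vector
#'
#' @param p Probability vector over fragment ends.
#' @param n Number of contacts to draw.
#' @param seed Integer seed.
#' @return Integer count vector of the same length as \code{p}.
#' @export
sample_contacts <- function(p, n, seed) {
  with_seed(seed, {
    idx <- sample.int(length(p), n, replace = TRUE, prob = p)
    tabulate(idx, nbins = length(p))
  })
}
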