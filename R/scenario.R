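# Scenario builders: the synthetic study conditions. A two-chromosome F1
# genome (a 2 Mb viewpoint chromosome emulating the locus neighbourhood and
# a 5 Mb trans chromosome emulating the rest of the genome), a PE viewpoint
# over a planted SNP, a topological domain (+/- 300 kb, boundary
# attenuation 0.1) around the viewpoint, power-law cis decay (alpha = 1),
# 25 percent trans contact mass, and two conditions: a lymphoid ("bcell")
# contact model whose enriched regions both alleles share, and a "brain"
# model with disjoint enriched regions. The expression track is active
# (40 percent transcribed) on the lymphoid-contacted regions and quiet
# (10 percent) elsewhere.

# fractions of chromosome length occupied by preferred contact regions
BCELL_CIS_ENR <- rbind(c(0.040, 0.100), c(0.775, 0.835), c(0.875, 0.935))
BCELL_TRANS_ENR <- rbind(c(0.150, 0.180), c(0.450, 0.480), c(0.750, 0.780))
BRAIN_CIS_ENR <- rbind(c(0.150, 0.210), c(0.290, 0.350), c(0.700, 0.760))
BRAIN_TRANS_ENR <- rbind(c(0.020, 0.050), c(0.300, 0.330), c(0.600, 0.630))

frac_intervals <- function(chrom, len, fracs, extra) {
  data.frame(chrom = chrom, start = round(fracs[, 1] * len),
             end = round(fracs[, 2] * len), extra)
}

# pick a fragment near `target` suitable as a viewpoint: non-blind, decent
# size, and a SNP-free primer region at its 3' boundary
pick_vp_fragment <- function(seqs_a, snps, chrom, target, primer_len,
                             min_width = 600L, max_width = 8000L) {
  fr <- digest(seqs_a[[chrom]], FIRST_CUTTER, FIRST_OFFSET)
  fr$width <- fr$end - fr$start
  fr <- fr[fr$width >= min_width & fr$width <= max_width, ]
  fr <- fr[order(abs((fr$start + fr$end) / 2 - target)), ]
  for (i in seq_len(nrow(fr))) {
    s <- fr$start[i]; e <- fr$end[i]
    has_gatc <- grepl(SECOND_CUTTER, sub0(seqs_a[[chrom]], s, e),
                      fixed = TRUE)
    if (!has_gatc) next  # blind fragment, unusable viewpoint
    primer_clash <- any(snps$chrom == chrom & !is.na(snps$pos_A) &
                          snps$pos_A >= e - primer_len & snps$pos_A < e)
    if (primer_clash) next
    return(list(start = s, end = e))
  }
  stopf("no suitable viewpoint fragment near %s:%d", chrom, target)
}

#' Build the default paired-end synthetic scenario
#'
#' Generates the diploid genome, plants the viewpoint SNP, builds per-allele
#' fragment-end databases, and assembles the viewpoint spec, the per-
#' condition contact models, the expression compartments and track.
#'
#' @param seed Integer seed driving every stochastic choice.
#' @param cis_len,trans_len Chromosome lengths (bp).
#' @param n_snps Number of random background SNPs.
#' @param read_len Total read length (bp).
#' @param primer_len P1 primer length (bp).
#' @param decay_exponent Cis decay exponent alpha.
#' @param trans_rate Trans contact probability mass.
#' @param domain_halfwidth Topological-domain half-width around the
#'   viewpoint (bp).
#' @param attenuation Domain boundary attenuation factor.
#' @param fold Enrichment fold of preferred contact regions.
#' @param frac_active,frac_inactive Transcribed-base fractions of active /
#'   inactive compartments.
#' @param exclusion_bp Viewpoint-proximal mask radius for domainogram
#'   background estimation, in bp (converted to fragments).
#' @return List of class \code{Scenario} with hap, dbs, vp, models (bcell /
#'   brain, each list(A =, B =)), compartments, expression,
#'   exclusion_radius (fragments) and the parameters used.
#' @export
demo_scenario <- function(seed, cis_len = 2e6, trans_len = 5e6,
                          n_snps = 40L, read_len = 36L, primer_len = 16L,
                          decay_exponent = 1, trans_rate = 0.25,
                          domain_halfwidth = 3e5, attenuation = 0.1,
                          fold = 8, frac_active = 0.4, frac_inactive = 0.1,
                          exclusion_bp = 2e5) {
  lens <- c(chr12 = cis_len, chr6 = trans_len)
  hap <- generate_haplotypes(genome_spec(lens, n_snps = n_snps),
                             seed = seed)

  # viewpoint fragment near 0.55 * cis_len with a planted mid-fragment SNP
  vp_frag <- pick_vp_fragment(hap$seq$A, hap$snps, "chr12",
                              round(0.55 * cis_len), primer_len)
  snp_pos <- vp_frag$start + (vp_frag$end - vp_frag$start) %/% 2L
  ref <- char_at0(hap$seq$A[["chr12"]], snp_pos)
  planted <- FALSE
  for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
    hap2 <- tryCatch(plant_snp(hap, "chr12", snp_pos, alt),
                     error = function(e) NULL)
    if (!is.null(hap2)) { hap <- hap2; planted <- TRUE; break }
  }
  if (!planted) stopf("could not plant the viewpoint SNP")
  snp_row <- hap$snps[hap$snps$chrom == "chr12" &
                        hap$snps$pos_A == snp_pos, ]

  capture_len <- read_len - primer_len
  dbs <- list(A = build_fragment_end_db(hap$seq$A,
                                        map_prefix_len = capture_len),
              B = build_fragment_end_db(hap$seq$B,
                                        map_prefix_len = capture_len))

  snp_offset <- 10L
  p1_seq <- sub0(hap$seq$A[["chr12"]], vp_frag$end - primer_len,
                 vp_frag$end)
  vp_pos <- (vp_frag$start + vp_frag$end) %/% 2L
  vp <- viewpoint_spec(name = "vpPE", chrom = "chr12", pos = vp_pos,
                       strategy = "PE", p1_seq = p1_seq,
                       p2_start = snp_pos - snp_offset,
                       snp_offset = snp_offset,
                       base_A = snp_row$base_A, base_B = snp_row$base_B)

  domains <- data.frame(chrom = "chr12",
                        start = max(0, vp_pos - domain_halfwidth),
                        end = min(cis_len, vp_pos + domain_halfwidth),
                        attenuation = attenuation)
  enr <- function(cis_fr, trans_fr) {
    rbind(frac_intervals("chr12", cis_len, cis_fr,
                         data.frame(fold = fold)),
          frac_intervals("chr6", trans_len, trans_fr,
                         data.frame(fold = fold)))
  }
  mk_models <- function(enriched) {
    m <- contact_model(viewpoint = list(chrom = "chr12", pos = vp_pos),
                       decay_exponent = decay_exponent, domains = domains,
                       enriched = enriched, trans_rate = trans_rate)
    list(A = m, B = m)
  }
  models <- list(bcell = mk_models(enr(BCELL_CIS_ENR, BCELL_TRANS_ENR)),
                 brain = mk_models(enr(BRAIN_CIS_ENR, BRAIN_TRANS_ENR)))

  # expression compartments: active on the lymphoid-contacted regions
  active <- enr(BCELL_CIS_ENR, BCELL_TRANS_ENR)[, c("chrom", "start",
                                                    "end")]
  active$activity <- "active"
  inactive <- do.call(rbind, lapply(names(lens), function(chrom) {
    terr <- data.frame(start = 0L, end = lens[[chrom]])
    a <- active[active$chrom == chrom, c("start", "end")]
    gaps <- iranges_to_df(IRanges::setdiff(df_to_iranges(terr),
                                           df_to_iranges(a)))
    if (nrow(gaps) == 0L) return(NULL)
    data.frame(chrom = chrom, gaps, activity = "inactive")
  }))
  compartments <- rbind(active, inactive)
  compartments <- compartments[order(match(compartments$chrom, names(lens)),
                                     compartments$start), ]
  expression <- simulate_expression_track(compartments, frac_active,
                                          frac_inactive, seed = seed + 101L)

  mean_frag <- mean(dbs$A$fragments$end - dbs$A$fragments$start)
  structure(list(hap = hap, dbs = dbs, vp = vp, models = models,
                 domains = domains, compartments = compartments,
                 expression = expression,
                 exclusion_radius = max(1L, round(exclusion_bp / mean_frag)),
                 params = list(seed = seed, cis_len = cis_len,
                               trans_len = trans_len, read_len = read_len,
                               primer_len = primer_len,
                               decay_exponent = decay_exponent,
                               trans_rate = trans_rate,
                               domain_halfwidth = domain_halfwidth,
                               attenuation = attenuation, fold = fold,
                               frac_active = frac_active,
                               frac_inactive = frac_inactive,
                               exclusion_bp = exclusion_bp)),
            class = "Scenario")
}

#' Build a single-end RFLP scenario
#'
#' Like \code{\link{demo_scenario}} but the viewpoint fragment carries a
#' planted RFLP (DpnII site gained on allele B) between the P1 primer and
#' the fragment interior, so allele B yields self-religation products that
#' fail exact mapping and only allele A is analyzable.
#'
#' @inheritParams demo_scenario
#' @return A \code{Scenario} whose \code{vp} uses the SE strategy; the
#'   planted RFLP row is in \code{vp$rflp}.
#' @export
se_scenario <- function(seed, cis_len = 2e6, trans_len = 5e5,
                        n_snps = 20L, read_len = 36L, primer_len = 16L,
                        decay_exponent = 1, trans_rate = 0.2) {
  lens <- c(chr12 = cis_len, chr6 = trans_len)
  hap <- generate_haplotypes(genome_spec(lens, n_snps = n_snps),
                             seed = seed)
  vp_frag <- pick_vp_fragment(hap$seq$A, hap$snps, "chr12",
                              round(0.5 * cis_len), primer_len,
                              min_width = 1200L)
  # primer at the 5' boundary; RFLP planted just downstream of it
  hap <- plant_rflp(hap, "chr12", vp_frag$start + primer_len + 8L)
  capture_len <- read_len - primer_len
  dbs <- list(A = build_fragment_end_db(hap$seq$A,
                                        map_prefix_len = capture_len),
              B = build_fragment_end_db(hap$seq$B,
                                        map_prefix_len = capture_len))
  rflp <- detect_rflp(hap$snps[hap$snps$rflp &
                                 hap$snps$pos_A > vp_frag$start &
                                 hap$snps$pos_A < vp_frag$end, ],
                      hap$seq$A, hap$seq$B, db = dbs$B)
  if (nrow(rflp) == 0L || rflp$gained_on[1] != "B") {
    stopf("SE scenario failed to establish the viewpoint RFLP")
  }
  p1_seq <- sub0(hap$seq$A[["chr12"]], vp_frag$start,
                 vp_frag$start + primer_len)
  vp_pos <- (vp_frag$start + vp_frag$end) %/% 2L
  vp <- viewpoint_spec(name = "vpSE", chrom = "chr12", pos = vp_pos,
                       strategy = "SE", p1_seq = p1_seq, rflp = rflp[1, ])
  m <- contact_model(viewpoint = list(chrom = "chr12", pos = vp_pos),
                     decay_exponent = decay_exponent,
                     trans_rate = trans_rate)
  structure(list(hap = hap, dbs = dbs, vp = vp,
                 models = list(A = m, B = m),
                 params = list(seed = seed, cis_len = cis_len,
                               trans_len = trans_len, read_len = read_len,
                               primer_len = primer_len)),
            class = "Scenario")
}

#' Count-level fragment-grid scenario for the significance model
#'
#' A sequence-free regular fragment grid emulating genome-scale 4C: a 50 Mb
#' viewpoint chromosome and six 100 Mb trans chromosomes (the rest of the
#' genome), fragment size 4096 bp (the expected HindIII spacing on uniform
#' sequence). With 30 percent of contact mass spread uniformly over the
#' trans ends, sampling 1e5 contacts leaves the trans background coverage
#' in the sparse regime (about 10 percent of ends covered) that the
#' binomial window model assumes; the binomial null is exact there, so
#' domain-recovery performance is assessed in trans. Eight 200 kb enriched
#' regions (fold 8) are planted on the first trans chromosome. Far-cis
#' coverage instead rides the polymer-decay gradient, as in real
#' domainograms.
#'
#' @param cis_len Viewpoint-chromosome length (bp).
#' @param trans_len Length of each trans chromosome (bp).
#' @param n_trans Number of trans chromosomes.
#' @param frag_len Fragment size (bp).
#' @param fold Enrichment fold.
#' @return list(db, model, enriched, vp (list chrom/pos),
#'   exclusion_radius).
#' @export
grid_scenario <- function(cis_len = 5e7, trans_len = 1e8, n_trans = 6L,
                          frag_len = 4096L, fold = 8) {
  lens <- c(cis_len, rep(trans_len, n_trans))
  names(lens) <- c("chrA", paste0("chrB", seq_len(n_trans)))
  db <- fragment_end_grid(lens, frag_len)
  vp_pos <- round(cis_len / 2)
  enr_mb <- c(5, 17, 24, 38, 51, 63, 77, 90)
  enriched <- data.frame(chrom = "chrB1", start = enr_mb * 1e6,
                         end = enr_mb * 1e6 + 2e5, fold = fold)
  model <- contact_model(viewpoint = list(chrom = "chrA", pos = vp_pos),
                         decay_exponent = 1.6, enriched = enriched,
                         trans_rate = 0.3)
  list(db = db, model = model, enriched = enriched,
       vp = list(chrom = "chrA", pos = vp_pos),
       exclusion_radius = round(1e6 / frag_len))
}
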