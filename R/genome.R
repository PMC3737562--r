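# Synthetic diploid genomes: a haplotype pair emulating an F1 hybrid
# (C57BL/6-like allele "A" x FVB-like allele "B") whose sequences are
# identical except at planted SNPs. At least one SNP is a restriction
# fragment length polymorphism (RFLP) creating a second-cutter (DpnII)
# site on allele B only, which the single-end allele-specific strategy
# exploits. All coordinates are 0-based half-open.

FIRST_CUTTER  <- "AAGCTT"  # HindIII, cuts A^AGCTT
FIRST_OFFSET  <- 1L
SECOND_CUTTER <- "GATC"    # DpnII, cuts ^GATC
SECOND_OFFSET <- 0L

#' Describe a synthetic diploid genome
#'
#' @param lengths Named integer vector of chromosome lengths (bp); names are
#'   chromosome identifiers. Each length must be at least 10 kb.
#' @param n_snps Number of additional random SNPs to plant (beyond the one
#'   mandatory RFLP SNP).
#' @param plant_rflp Plant one SNP that creates a DpnII site on allele B only
#'   (default TRUE; the invariant of the haplotype pair requires at least one
#'   such site, so only disable it when planting one explicitly).
#' @param planted_snps Optional data.frame (chrom, pos, base_B) of SNPs to
#'   plant at fixed positions; base_A is the base already present.
#' @return A list of class \code{genome_spec}.
#' @export
genome_spec <- function(lengths, n_snps = 0L, plant_rflp = TRUE,
                        planted_snps = NULL) {
  if (is.null(names(lengths)) || any(names(lengths) == "")) {
    stopf("chromosome lengths must be named")
  }
  if (any(lengths < 10000)) stopf("chromosome lengths must be >= 10 kb")
  if (n_snps < 0) stopf("n_snps must be >= 0")
  structure(list(lengths = lengths, n_snps = as.integer(n_snps),
                 plant_rflp = plant_rflp, planted_snps = planted_snps),
            class = "genome_spec")
}

# TRUE iff substituting `alt` at 0-based `pos` neither sits inside an existing
# first-cutter site nor creates one on the alternate haplotype.
snp_site_ok <- function(seq, pos, alt, site = FIRST_CUTTER) {
  k <- nchar(site)
  len <- nchar(seq)
  w0 <- max(0L, pos - (k - 1L))
  w1 <- min(len, pos + k)
  win_a <- sub0(seq, w0, w1)
  if (grepl(site, win_a, fixed = TRUE)) return(FALSE)
  win_b <- replace_at0(win_a, pos - w0, alt)
  !grepl(site, win_b, fixed = TRUE)
}

# Find a position where overwriting 4 bases with GATA (allele A) / GATC
# (allele B) yields a clean RFLP: DpnII site on B only, no HindIII site
# created, no other DpnII site in the detection window. Returns the position
# or NA.
rflp_candidate_ok <- function(seq, p) {
  len <- nchar(seq)
  if (p < 8L || p + 12L > len) return(FALSE)
  w0 <- p - 8L; w1 <- min(len, p + 12L)
  win <- sub0(seq, w0, w1)
  off <- p - w0
  win_a <- replace_at0(win, off, "GATA")
  win_b <- replace_at0(win, off, "GATC")
  if (grepl(FIRST_CUTTER, win_a, fixed = TRUE)) return(FALSE)
  if (grepl(FIRST_CUTTER, win_b, fixed = TRUE)) return(FALSE)
  # detection window +/- (site length - 1) around the SNP at p+3
  det_a <- sub0(win_a, off - 3L + 3L, off + 3L + 4L)
  det_b <- sub0(win_b, off - 3L + 3L, off + 3L + 4L)
  n_b <- length(find_sites0(det_b, SECOND_CUTTER))
  !grepl(SECOND_CUTTER, det_a, fixed = TRUE) && n_b == 1L
}

#' Generate a synthetic haplotype pair
#'
#' Draws uniform-random ACGT chromosomes, plants the requested SNPs, and
#' returns the two haplotypes. The sequences are identical everywhere except
#' at SNP positions; no SNP sits inside (or creates) a HindIII recognition
#' site, so both alleles share one first-cutter fragment grid. One SNP (the
#' mandatory RFLP) creates a DpnII site on allele B only.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @param seed Integer seed; output is deterministic given (spec, seed).
#' @return A list of class \code{HaplotypePair} with elements
#'   \code{chrom_names}, \code{lengths} (list A/B), \code{seq} (list A/B of
#'   named character vectors) and \code{snps}, a data.frame with columns
#'   chrom, pos_A, pos_B (0-based), base_A, base_B, rflp (logical).
#' @export
generate_haplotypes <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    seqs <- lapply(spec$lengths, random_dna)
    names(seqs) <- names(spec$lengths)
    snps <- data.frame(chrom = character(0), pos = integer(0),
                       base_A = character(0), base_B = character(0),
                       rflp = logical(0))

    add_snp <- function(chrom, pos, base_A, base_B, rflp = FALSE) {
      snps[nrow(snps) + 1L, ] <<- list(chrom, as.integer(pos),
                                       base_A, base_B, rflp)
    }

    # user-planted SNPs (validated, errors on violation)
    if (!is.null(spec$planted_snps)) {
      for (i in seq_len(nrow(spec$planted_snps))) {
        row <- spec$planted_snps[i, ]
        s <- seqs[[row$chrom]]
        ref <- char_at0(s, row$pos)
        if (ref == row$base_B) stopf("planted SNP at %s:%d is not a change",
                                     row$chrom, row$pos)
        if (!snp_site_ok(s, row$pos, row$base_B)) {
          stopf(paste0("planted SNP at %s:%d lies inside or would create a ",
                       "first-cutter site; this would break the shared ",
                       "fragment grid"), row$chrom, row$pos)
        }
        add_snp(row$chrom, row$pos, ref, row$base_B)
      }
    }

    # mandatory RFLP SNP: overwrite GATA (A) / GATC (B), SNP at pos+3
    if (spec$plant_rflp) {
      chrom <- names(seqs)[1]
      len <- nchar(seqs[[chrom]])
      placed <- FALSE
      for (p in sample(seq(50L, len - 50L), min(500L, len - 100L))) {
        if (rflp_candidate_ok(seqs[[chrom]], p)) {
          seqs[[chrom]] <- replace_at0(seqs[[chrom]], p, "GATA")
          add_snp(chrom, p + 3L, "A", "C", rflp = TRUE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stopf("could not place the mandatory RFLP SNP")
    }

    # random SNPs, rejected near first-cutter sites and other SNPs
    if (spec$n_snps > 0L) {
      bases <- c("A", "C", "G", "T")
      placed <- 0L
      attempts <- 0L
      while (placed < spec$n_snps && attempts < 200L * spec$n_snps) {
        attempts <- attempts + 1L
        chrom <- sample(names(seqs), 1L,
                        prob = as.numeric(spec$lengths))
        pos <- sample.int(nchar(seqs[[chrom]]) - 20L, 1L) + 9L
        near <- snps$chrom == chrom & abs(snps$pos - pos) < 10L
        if (any(near)) next
        ref <- char_at0(seqs[[chrom]], pos)
        alt <- sample(setdiff(bases, ref), 1L)
        if (!snp_site_ok(seqs[[chrom]], pos, alt)) next
        add_snp(chrom, pos, ref, alt)
        placed <- placed + 1L
      }
      if (placed < spec$n_snps) stopf("could not place %d SNPs", spec$n_snps)
    }

    snps <- snps[order(match(snps$chrom, names(seqs)), snps$pos), ,
                 drop = FALSE]
    rownames(snps) <- NULL

    seq_b <- seqs
    for (i in seq_len(nrow(snps))) {
      seq_b[[snps$chrom[i]]] <-
        replace_at0(seq_b[[snps$chrom[i]]], snps$pos[i], snps$base_B[i])
    }

    snps_out <- data.frame(chrom = snps$chrom,
                           pos_A = snps$pos, pos_B = snps$pos,
                           base_A = snps$base_A, base_B = snps$base_B,
                           rflp = snps$rflp, stringsAsFactors = FALSE)
    structure(list(chrom_names = names(seqs),
                   lengths = list(A = vapply(seqs, nchar, 1L),
                                  B = vapply(seq_b, nchar, 1L)),
                   seq = list(A = unlist(seqs), B = unlist(seq_b)),
                   snps = snps_out),
              class = "HaplotypePair")
  })
}

#' Plant an extra SNP into an existing haplotype pair
#'
#' Used by scenario builders to position an allele-informative SNP inside a
#' chosen viewpoint fragment. The substitution is validated against the
#' first-cutter grid like all other SNPs.
#'
#' @param hap A \code{HaplotypePair}.
#' @param chrom,pos Location (0-based).
#' @param base_B Replacement base on allele B.
#' @return The modified \code{HaplotypePair}.
#' @export
plant_snp <- function(hap, chrom, pos, base_B) {
  stopifnot(inherits(hap, "HaplotypePair"))
  if (any(hap$snps$chrom == chrom & abs(hap$snps$pos_A - pos) < 10L)) {
    stopf("position %s:%d is too close to an existing SNP", chrom, pos)
  }
  ref <- char_at0(hap$seq$A[[chrom]], pos)
  if (ref == base_B) stopf("SNP at %s:%d is not a change", chrom, pos)
  if (!snp_site_ok(hap$seq$A[[chrom]], pos, base_B)) {
    stopf("SNP at %s:%d touches a first-cutter site", chrom, pos)
  }
  hap$seq$B[[chrom]] <- replace_at0(hap$seq$B[[chrom]], pos, base_B)
  hap$snps <- rbind(hap$snps,
                    data.frame(chrom = chrom, pos_A = pos, pos_B = pos,
                               base_A = ref, base_B = base_B, rflp = FALSE))
  hap$snps <- hap$snps[order(match(hap$snps$chrom, hap$chrom_names),
                             hap$snps$pos_A), , drop = FALSE]
  rownames(hap$snps) <- NULL
  hap
}

#' Plant a directed RFLP SNP near a given position
#'
#' Overwrites four bases with GATA on allele A and GATC on allele B at the
#' first admissible position scanning rightward from \code{pos}, creating a
#' DpnII site on allele B only. Used to position the RFLP inside a chosen
#' viewpoint fragment end for the single-end strategy.
#'
#' @inheritParams plant_snp
#' @param max_shift How far to scan for an admissible position.
#' @return The modified \code{HaplotypePair}.
#' @export
plant_rflp <- function(hap, chrom, pos, max_shift = 200L) {
  stopifnot(inherits(hap, "HaplotypePair"))
  s <- hap$seq$A[[chrom]]
  for (p in pos + 0:max_shift) {
    near <- hap$snps$chrom == chrom & abs(hap$snps$pos_A - (p + 3L)) < 10L
    if (any(near)) next
    if (!rflp_candidate_ok(s, p)) next
    hap$seq$A[[chrom]] <- replace_at0(s, p, "GATA")
    hap$seq$B[[chrom]] <- replace_at0(hap$seq$B[[chrom]], p, "GATC")
    hap$snps <- rbind(hap$snps,
                      data.frame(chrom = chrom, pos_A = p + 3L,
                                 pos_B = p + 3L, base_A = "A", base_B = "C",
                                 rflp = TRUE))
    hap$snps <- hap$snps[order(match(hap$snps$chrom, hap$chrom_names),
                               hap$snps$pos_A), , drop = FALSE]
    rownames(hap$snps) <- NULL
    return(hap)
  }
  stopf("no admissible RFLP position within %d bp of %s:%d",
        max_shift, chrom, pos)
}

#' Delete an interval from one allele
#'
#' Emulates programmed deletion (V(D)J-recombination-like) on one haplotype:
#' the chosen allele's chromosome is shortened, SNPs inside the interval are
#' dropped from that allele's coordinate map, downstream SNP coordinates are
#' shifted, and a liftover table mapping old to new coordinates is returned.
#'
#' @param hap A \code{HaplotypePair}.
#' @param allele "A" or "B".
#' @param chrom Chromosome name.
#' @param start,end Deleted interval, 0-based half-open.
#' @param protect Optional c(start, end) interval (e.g. the viewpoint primer
#'   region) that the deletion must not overlap; overlapping is an error.
#' @return list(hap = modified pair, liftover = data.frame(old_start,
#'   old_end, offset) describing the piecewise coordinate shift).
#' @export
apply_deletion <- function(hap, allele, chrom, start, end, protect = NULL) {
  stopifnot(inherits(hap, "HaplotypePair"), allele %in% c("A", "B"))
  len <- nchar(hap$seq[[allele]][[chrom]])
  if (start < 0 || end > len || start > end) {
    stopf("deletion [%d,%d) out of bounds for %s (length %d)",
          start, end, chrom, len)
  }
  if (!is.null(protect) && start < protect[2] && protect[1] < end) {
    stopf("deletion [%d,%d) overlaps the protected viewpoint region [%d,%d)",
          start, end, protect[1], protect[2])
  }
  shift <- end - start
  lift <- data.frame(old_start = c(0L, end), old_end = c(start, len),
                     offset = c(0L, -shift))
  if (shift == 0L) return(list(hap = hap, liftover = lift))

  s <- hap$seq[[allele]][[chrom]]
  hap$seq[[allele]][[chrom]] <- paste0(sub0(s, 0L, start), sub0(s, end, len))
  hap$lengths[[allele]][chrom] <- len - shift

  poscol <- paste0("pos_", allele)
  p <- hap$snps[[poscol]]
  on_chrom <- hap$snps$chrom == chrom & !is.na(p)
  inside <- on_chrom & p >= start & p < end
  after <- on_chrom & p >= end
  p[inside] <- NA_integer_
  p[after] <- p[after] - shift
  hap$snps[[poscol]] <- p
  list(hap = hap, liftover = lift)
}

#' Map positions through a deletion liftover table
#'
#' @param liftover The table returned by \code{\link{apply_deletion}}.
#' @param pos Integer vector of old 0-based positions.
#' @return New positions; NA for positions inside the deleted interval.
#' @export
lift_position <- function(liftover, pos) {
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(liftover))) {
    hit <- pos >= liftover$old_start[i] & pos < liftover$old_end[i]
    out[hit] <- pos[hit] + liftover$offset[i]
  }
  out
}

#' Simulate a transcribed-interval (expression) track
#'
#' Partitions each compartment interval into fixed tiles and marks a seeded
#' random subset transcribed so that the realized transcribed-base fraction
#' matches the requested proportion per compartment class.
#'
#' @param compartments data.frame(chrom, start, end, activity) with activity
#'   "active" or "inactive"; intervals 0-based half-open, non-overlapping.
#' @param frac_active,frac_inactive Target transcribed-base proportions in
#'   [0, 1] for the two compartment classes.
#' @param seed Integer seed.
#' @param tile Tile size in bp used to lay out transcribed intervals.
#' @return data.frame(chrom, start, end) of merged transcribed intervals,
#'   sorted and non-overlapping (BED-compatible).
#' @export
simulate_expression_track <- function(compartments, frac_active,
                                      frac_inactive, seed, tile = 1000L) {
  if (frac_active < 0 || frac_active > 1 || frac_inactive < 0 ||
      frac_inactive > 1) {
    stopf("transcribed fractions must lie in [0, 1]")
  }
  with_seed(seed, {
    pieces <- list()
    for (i in seq_len(nrow(compartments))) {
      row <- compartments[i, ]
      frac <- if (row$activity == "active") frac_active else frac_inactive
      if (frac == 0) next
      if (frac == 1) {
        pieces[[length(pieces) + 1L]] <-
          data.frame(chrom = row$chrom, start = row$start, end = row$end)
        next
      }
      width <- row$end - row$start
      n_tiles <- max(1L, floor(width / tile))
      tsize <- floor(width / n_tiles)
      k <- round(frac * n_tiles)
      if (k == 0L) next
      picked <- sort(sample.int(n_tiles, k))
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = row$chrom,
                   start = row$start + (picked - 1L) * tsize,
                   end = row$start + picked * tsize)
    }
    if (length(pieces) == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    bed <- do.call(rbind, pieces)
    out <- do.call(rbind, lapply(split(bed, bed$chrom), function(d) {
      m <- merge_intervals(d)
      data.frame(chrom = d$chrom[1], m)
    }))
    out <- out[order(match(out$chrom, unique(compartments$chrom)), out$start), ]
    rownames(out) <- NULL
    out
  })
}
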