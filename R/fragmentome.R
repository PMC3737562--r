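# In-silico double digestion. The mappable universe of 4C-seq is the set of
# first-cutter (HindIII) fragment ends trimmed to the nearest internal
# second-cutter (DpnII) site. Ends of fragments without an internal DpnII
# site are "blind" (retained, flagged, excluded from profile statistics);
# ends whose mapping prefix is not genome-unique are flagged non-unique.

#' In-silico digestion of a sequence
#'
#' Cuts at (site position + cut_offset) for every occurrence of the
#' recognition site, scanning every position so overlapping occurrences are
#' honoured. HindIII (AAGCTT) cuts A^AGCTT (offset 1); DpnII (GATC) cuts
#' ^GATC (offset 0).
#'
#' @param sequence Uppercase ACGT string.
#' @param recognition_site Uppercase ACGT recognition sequence.
#' @param cut_offset Cut position relative to the site start (bp).
#' @return data.frame(start, end): ordered fragments, 0-based half-open,
#'   tiling [0, nchar(sequence)) exactly.
#' @export
digest <- function(sequence, recognition_site, cut_offset) {
  if (nchar(recognition_site) == 0L) stopf("empty recognition site")
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L) {
    stopf("non-ACGT character '%s' at position %d (0-based)",
          substr(sequence, bad, bad), bad - 1L)
  }
  if (grepl("[^ACGT]", recognition_site)) {
    stopf("recognition site contains non-ACGT characters")
  }
  len <- nchar(sequence)
  cuts <- find_sites0(sequence, recognition_site) + cut_offset
  cuts <- cuts[cuts > 0L & cuts < len]
  b <- c(0L, sort(unique(cuts)), len)
  data.frame(start = b[-length(b)], end = b[-1])
}

# per-chromosome first-cutter fragment map for a set of sequences
fragment_map <- function(seqs, site = FIRST_CUTTER, offset = FIRST_OFFSET) {
  out <- lapply(names(seqs), function(chrom) {
    fr <- digest(seqs[[chrom]], site, offset)
    data.frame(chrom = chrom, frag_idx = seq_len(nrow(fr)), fr)
  })
  frs <- do.call(rbind, out)
  frs$frag_id <- seq_len(nrow(frs))
  rownames(frs) <- NULL
  frs
}

# Mark mapping prefixes that collide: exact duplicates, and keys that are a
# proper prefix of another key (a read matching the short key cannot be
# uniquely placed once truncation comes into play). Keys shorter than the
# minimum mappable length can never be mapped and are flagged non-unique
# outright. Returns a logical "unique" vector.
prefix_unique <- function(keys, min_len = 12L) {
  n <- length(keys)
  uniq <- !(keys %in% keys[duplicated(keys)])
  lens <- nchar(keys)
  uniq[lens < min_len] <- FALSE
  for (l in sort(unique(lens[lens >= min_len]))) {
    short <- which(lens == l)
    longer <- which(lens > l)
    if (length(longer) == 0L) next
    short_set <- keys[short]
    pre <- substr(keys[longer], 1L, l)
    hit <- pre %in% short_set
    if (any(hit)) {
      uniq[longer[hit]] <- FALSE
      uniq[short[short_set %in% pre[hit]]] <- FALSE
    }
  }
  uniq
}

#' Build the 4C fragment-end database
#'
#' For every first-cutter fragment, extracts the two end segments running
#' from the fragment boundary to the nearest internal second-cutter site
#' (the whole fragment for blind fragments). Chromosome-terminal fragments
#' contribute only the end at their internal (ligatable) boundary. Each end
#' stores its plus-strand sequence, its mapping sequence in read orientation
#' (reverse complement for 3' ends), and a mapping prefix of at most
#' \code{map_prefix_len} bp used for exact read lookup and uniqueness.
#'
#' @param seqs Named character vector of chromosome sequences (one
#'   haplotype).
#' @param first_cutter,second_cutter Recognition sites.
#' @param first_offset,second_offset Cut offsets.
#' @param map_prefix_len Mapping prefix length in bp (>= 12).
#' @param min_map_len Minimum mappable length (bp); ends whose mapping
#'   sequence is shorter can never be mapped and are flagged non-unique.
#' @return List of class \code{FragmentEndDB}: \code{$ends} (data.frame:
#'   end_id, frag_id, frag_idx, side, chrom, start, end, width, blind,
#'   unique, seq, mapseq, prefix), \code{$fragments} (the first-cutter
#'   fragment map) and the digestion parameters. \code{$stats} counts blind
#'   and non-unique ends.
#' @export
build_fragment_end_db <- function(seqs,
                                  first_cutter = FIRST_CUTTER,
                                  second_cutter = SECOND_CUTTER,
                                  first_offset = FIRST_OFFSET,
                                  second_offset = SECOND_OFFSET,
                                  map_prefix_len = 36L,
                                  min_map_len = 12L) {
  if (map_prefix_len < 12L) stopf("map_prefix_len must be >= 12")
  short <- nchar(seqs) < nchar(first_cutter)
  if (any(short)) {
    warnf("chromosome(s) %s shorter than the recognition site; skipped",
          paste(names(seqs)[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0L) {
    empty_ends <- data.frame(end_id = character(0), frag_id = integer(0),
                             frag_idx = integer(0), side = character(0),
                             chrom = character(0), start = integer(0),
                             end = integer(0), width = integer(0),
                             blind = logical(0), unique = logical(0),
                             seq = character(0), mapseq = character(0),
                             prefix = character(0))
    return(structure(list(ends = empty_ends,
                          fragments = data.frame(chrom = character(0),
                                                 frag_idx = integer(0),
                                                 start = integer(0),
                                                 end = integer(0),
                                                 frag_id = integer(0)),
                          first_cutter = first_cutter,
                          second_cutter = second_cutter,
                          map_prefix_len = as.integer(map_prefix_len),
                          stats = list(n_ends = 0L, n_blind = 0L,
                                       n_nonunique = 0L)),
                     class = "FragmentEndDB"))
  }
  fragments <- fragment_map(seqs, first_cutter, first_offset)

  per_chrom <- lapply(names(seqs), function(chrom) {
    s <- seqs[[chrom]]
    fr <- fragments[fragments$chrom == chrom, ]
    if (nrow(fr) < 2L) return(NULL)  # no internal first-cutter boundary
    g <- find_sites0(s, second_cutter) + second_offset
    slen <- nchar(second_cutter)
    # first/last internal second-cutter cut per fragment (full site inside)
    fc <- g[findInterval(fr$start + 0.5, g) + 1L]
    fc[!is.na(fc) & (fc + slen > fr$end)] <- NA
    lc_idx <- findInterval(fr$end - slen + 0.5, g)
    lc <- ifelse(lc_idx >= 1L, g[pmax(lc_idx, 1L)], NA)
    lc[!is.na(lc) & lc <= fr$start] <- NA
    blind <- is.na(fc)

    n <- nrow(fr)
    e5 <- ifelse(blind, fr$end, fc)    # 5' end: boundary -> first cut
    s3 <- ifelse(blind, fr$start, lc)  # 3' end: last cut -> boundary
    keep5 <- seq_len(n) > 1L           # terminal sides are not ligatable
    keep3 <- seq_len(n) < n
    ends <- rbind(
      data.frame(frag_id = fr$frag_id[keep5], frag_idx = fr$frag_idx[keep5],
                 side = "5p", chrom = chrom, start = fr$start[keep5],
                 end = as.integer(e5[keep5]), blind = blind[keep5]),
      data.frame(frag_id = fr$frag_id[keep3], frag_idx = fr$frag_idx[keep3],
                 side = "3p", chrom = chrom, start = as.integer(s3[keep3]),
                 end = fr$end[keep3], blind = blind[keep3]))
    if (nrow(ends) == 0L) return(NULL)
    ends <- ends[order(ends$frag_idx, ends$side == "3p"), ]
    ends$seq <- substring(s, ends$start + 1L, ends$end)
    ends
  })
  ends <- do.call(rbind, per_chrom[!vapply(per_chrom, is.null, TRUE)])
  if (is.null(ends) || nrow(ends) == 0L) {
    warnf("no fragment ends found")
    ends <- data.frame(frag_id = integer(0), frag_idx = integer(0),
                       side = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       blind = logical(0), seq = character(0))
  }
  ends$width <- ends$end - ends$start
  ends$mapseq <- ends$seq
  is3 <- ends$side == "3p"
  ends$mapseq[is3] <- revcomp(ends$seq[is3])
  ends$prefix <- substr(ends$mapseq, 1L, map_prefix_len)
  ends$unique <- prefix_unique(ends$prefix, min_len = min_map_len)
  ends$end_id <- sprintf("%s:%d:%s", ends$chrom, ends$frag_idx, ends$side)
  ends <- ends[, c("end_id", "frag_id", "frag_idx", "side", "chrom",
                   "start", "end", "width", "blind", "unique",
                   "seq", "mapseq", "prefix")]
  rownames(ends) <- NULL
  structure(list(ends = ends, fragments = fragments,
                 first_cutter = first_cutter, second_cutter = second_cutter,
                 map_prefix_len = as.integer(map_prefix_len),
                 stats = list(n_ends = nrow(ends),
                              n_blind = sum(ends$blind),
                              n_nonunique = sum(!ends$unique))),
            class = "FragmentEndDB")
}

#' @export
print.FragmentEndDB <- function(x, ...) {
  cat(sprintf(
    "FragmentEndDB: %d ends over %d fragments (%d chromosomes)\n",
    nrow(x$ends), nrow(x$fragments), length(unique(x$fragments$chrom))))
  cat(sprintf("  blind: %d  non-unique: %d  prefix length: %d\n",
              x$stats$n_blind, x$stats$n_nonunique, x$map_prefix_len))
  invisible(x)
}

#' Sequence-free regular fragment-end grid
#'
#' A FragmentEndDB-shaped object with fragments of fixed size and two abutting
#' ends per fragment, used for count-level studies of the significance model
#' where no sequence is needed (sampling contacts directly instead of reads).
#'
#' @param chrom_lens Named vector of chromosome lengths.
#' @param frag_len Fragment size in bp.
#' @return A \code{FragmentEndDB} with \code{seq}/\code{mapseq}/\code{prefix}
#'   set to NA and all ends unique and non-blind.
#' @export
fragment_end_grid <- function(chrom_lens, frag_len) {
  frag_list <- lapply(names(chrom_lens), function(chrom) {
    n <- max(1L, floor(chrom_lens[[chrom]] / frag_len))
    starts <- (seq_len(n) - 1L) * frag_len
    ends <- c(starts[-1], chrom_lens[[chrom]])
    data.frame(chrom = chrom, frag_idx = seq_len(n),
               start = starts, end = ends)
  })
  fragments <- do.call(rbind, frag_list)
  fragments$frag_id <- seq_len(nrow(fragments))
  half <- floor(frag_len / 2)
  mk <- function(side) {
    d <- fragments
    d$side <- side
    if (side == "5p") d$end <- d$start + half else d$start <- d$end - half
    d
  }
  ends <- rbind(mk("5p"), mk("3p"))
  ends <- ends[order(ends$frag_id, ends$side == "3p"), ]
  # terminal sides are not ligatable, as in the sequence-based DB
  drop <- (ends$frag_idx == 1L & ends$side == "5p") |
    (ends$frag_id %in% tapply(ends$frag_id, ends$chrom, max) &
       ends$side == "3p")
  ends <- ends[!drop, ]
  ends$width <- ends$end - ends$start
  ends$blind <- FALSE
  ends$unique <- TRUE
  ends$seq <- NA_character_
  ends$mapseq <- NA_character_
  ends$prefix <- NA_character_
  ends$end_id <- sprintf("%s:%d:%s", ends$chrom, ends$frag_idx, ends$side)
  ends <- ends[, c("end_id", "frag_id", "frag_idx", "side", "chrom",
                   "start", "end", "width", "blind", "unique",
                   "seq", "mapseq", "prefix")]
  rownames(ends) <- NULL
  structure(list(ends = ends, fragments = fragments,
                 first_cutter = NA, second_cutter = NA,
                 map_prefix_len = NA_integer_,
                 stats = list(n_ends = nrow(ends), n_blind = 0L,
                              n_nonunique = 0L)),
            class = "FragmentEndDB")
}

#' Detect restriction-site polymorphisms among SNPs
#'
#' Returns the SNPs for which a window of +/-(site length - 1) around the SNP
#' contains the second-cutter recognition site in exactly one haplotype,
#' annotated with the allele that gains the site and the site's position.
#'
#' @param snps data.frame with columns chrom, pos_A, pos_B, base_A, base_B
#'   (as in a \code{HaplotypePair}).
#' @param seqs_A,seqs_B Named character vectors of haplotype sequences.
#' @param second_cutter Recognition site (default DpnII GATC).
#' @param db Optional \code{FragmentEndDB} (of the gaining allele) used to
#'   annotate the affected fragment end id.
#' @return data.frame(chrom, pos_A, pos_B, base_A, base_B, gained_on,
#'   site_pos, end_id); zero rows if no RFLP.
#' @export
detect_rflp <- function(snps, seqs_A, seqs_B,
                        second_cutter = SECOND_CUTTER, db = NULL) {
  k <- nchar(second_cutter)
  out <- list()
  for (i in seq_len(nrow(snps))) {
    row <- snps[i, ]
    if (is.na(row$pos_A) || is.na(row$pos_B)) next
    win <- function(s, pos) {
      sub0(s, max(0L, pos - (k - 1L)), min(nchar(s), pos + k))
    }
    wa <- win(seqs_A[[row$chrom]], row$pos_A)
    wb <- win(seqs_B[[row$chrom]], row$pos_B)
    in_a <- grepl(second_cutter, wa, fixed = TRUE)
    in_b <- grepl(second_cutter, wb, fixed = TRUE)
    if (in_a == in_b) next
    gained_on <- if (in_b) "B" else "A"
    pos <- if (in_b) row$pos_B else row$pos_A
    w <- if (in_b) wb else wa
    site_pos <- find_sites0(w, second_cutter)[1] + max(0L, pos - (k - 1L))
    end_id <- NA_character_
    if (!is.null(db)) {
      hit <- db$ends$chrom == row$chrom & db$ends$start <= site_pos &
        db$ends$end > site_pos
      if (any(hit)) end_id <- db$ends$end_id[which(hit)[1]]
    }
    out[[length(out) + 1L]] <-
      data.frame(chrom = row$chrom, pos_A = row$pos_A, pos_B = row$pos_B,
                 base_A = row$base_A, base_B = row$base_B,
                 gained_on = gained_on, site_pos = site_pos, end_id = end_id)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), pos_A = integer(0),
                      pos_B = integer(0), base_A = character(0),
                      base_B = character(0), gained_on = character(0),
                      site_pos = integer(0), end_id = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
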