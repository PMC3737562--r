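# Allele assignment and exact fragment-end mapping. The PE strategy splits
# read pairs by the single base read-2 shows at the viewpoint SNP offset;
# the SE strategy relies on an RFLP (a DpnII site gained on one allele)
# that makes the assay itself single-allele, so mapped reads are tagged
# with the retained allele. Mapping is exact (no mismatches) against the
# fragment-end mapping prefixes.

#' Describe a 4C viewpoint
#'
#' @param name Viewpoint label.
#' @param chrom Chromosome.
#' @param pos Representative viewpoint position (0-based bp), used by the
#'   contact model and the viewpoint-proximal exclusion.
#' @param strategy "PE" (paired-end SNP split) or "SE" (single-end RFLP).
#' @param p1_seq P1 primer sequence; simulated read-1 starts with it and it
#'   is trimmed exactly before mapping.
#' @param p2_start For PE: 0-based start of read-2 on the viewpoint
#'   chromosome.
#' @param snp_offset For PE: 0-based offset of the allele-discriminating SNP
#'   base within read-2.
#' @param base_A,base_B For PE: expected read-2 base per allele.
#' @param rflp For SE: one row from \code{\link{detect_rflp}} (mandatory).
#' @return List of class \code{ViewpointSpec}.
#' @export
viewpoint_spec <- function(name, chrom, pos, strategy = c("PE", "SE"),
                           p1_seq, p2_start = NULL, snp_offset = NULL,
                           base_A = NULL, base_B = NULL, rflp = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "PE" &&
      (is.null(p2_start) || is.null(snp_offset) ||
       is.null(base_A) || is.null(base_B))) {
    stopf("PE viewpoint needs p2_start, snp_offset, base_A and base_B")
  }
  if (strategy == "SE" && is.null(rflp)) {
    stopf("SE viewpoint needs an RFLP site reference")
  }
  structure(list(name = name, chrom = chrom, pos = pos, strategy = strategy,
                 p1_seq = toupper(p1_seq), p2_start = p2_start,
                 snp_offset = snp_offset, base_A = base_A, base_B = base_B,
                 rflp = rflp),
            class = "ViewpointSpec")
}

#' Split read pairs by the viewpoint SNP base in read-2
#'
#' Assignment depends only on the single base at the SNP offset: an exact,
#' case-insensitive match to one allele's expected base routes the pair to
#' that allele's pool; anything else (including N, or a read-2 too short to
#' cover the offset) is ambiguous.
#'
#' @param r2 Character vector of read-2 sequences.
#' @param vp A PE \code{ViewpointSpec}.
#' @return list(pool = factor with levels A/B/ambiguous, reason = character
#'   vector, sizes = named table of pool sizes).
#' @export
split_by_snp <- function(r2, vp) {
  stopifnot(inherits(vp, "ViewpointSpec"))
  if (vp$strategy != "PE") stopf("split_by_snp requires a PE viewpoint")
  n <- length(r2)
  pool <- rep("ambiguous", n)
  reason <- rep("snp-base-unmatched", n)
  short <- nchar(r2) <= vp$snp_offset
  reason[short] <- "read2-too-short"
  base <- toupper(substr(r2, vp$snp_offset + 1L, vp$snp_offset + 1L))
  is_a <- !short & base == toupper(vp$base_A)
  is_b <- !short & base == toupper(vp$base_B)
  pool[is_a] <- "A"; reason[is_a] <- "snp-match"
  pool[is_b] <- "B"; reason[is_b] <- "snp-match"
  pool <- factor(pool, levels = c("A", "B", "ambiguous"))
  list(pool = pool, reason = reason, sizes = table(pool))
}

#' Tag single-end reads with the retained allele
#'
#' The SE assay's selectivity is a property of its design: the allele that
#' gains the second-cutter site yields no mappable product, so all mapped
#' reads belong to the allele lacking the extra site. No sequence filtering
#' is performed here.
#'
#' @param read_ids Character vector of read identifiers.
#' @param vp An SE \code{ViewpointSpec}.
#' @param rflp The RFLP site row (defaults to the one in \code{vp}).
#' @return data.frame(read_id, allele) with a provenance note attribute.
#' @export
enforce_se_allele <- function(read_ids, vp, rflp = vp$rflp) {
  if (is.null(rflp)) stopf("an RFLP site is required for the SE strategy")
  retained <- setdiff(c("A", "B"), rflp$gained_on)
  out <- data.frame(read_id = read_ids,
                    allele = rep(retained, length(read_ids)))
  attr(out, "note") <- sprintf(
    "allele %s gains a %s site at %s:%d; only allele %s is analyzable",
    rflp$gained_on, "second-cutter", rflp$chrom,
    if (rflp$gained_on == "B") rflp$pos_B else rflp$pos_A, retained)
  out
}

#' Trim the P1 primer from read-1
#'
#' Reads must begin with the exact primer sequence; mismatching reads are
#' rejected ("primer-mismatch") and remainders shorter than the minimum
#' mapping length are rejected ("too-short").
#'
#' @param r1 Character vector of read-1 sequences.
#' @param vp A \code{ViewpointSpec}.
#' @param min_len Minimum captured-sequence length after trimming (bp).
#' @return list(captured = character (NA unless accepted),
#'   status = character in accepted/primer-mismatch/too-short).
#' @export
trim_primer <- function(r1, vp, min_len = 12L) {
  plen <- nchar(vp$p1_seq)
  ok <- startsWith(toupper(r1), vp$p1_seq)
  captured <- rep(NA_character_, length(r1))
  captured[ok] <- substr(r1[ok], plen + 1L, nchar(r1[ok]))
  status <- ifelse(ok, "accepted", "primer-mismatch")
  short <- ok & nchar(captured) < min_len
  status[short] <- "too-short"
  captured[short] <- NA_character_
  list(captured = captured, status = status)
}

#' Map captured sequences exactly to fragment-end prefixes
#'
#' A read increments exactly one fragment end iff it exactly equals that
#' end's mapping prefix over the read's length (the prefix is already in
#' read orientation: plus strand for 5' ends, reverse complement for 3'
#' ends). Reads matching no end are unmapped; reads matching more than one,
#' or matching an end flagged non-unique, are discarded as non-unique;
#' blind ends are never incremented.
#'
#' @param captured Character vector (NAs allowed; counted as not-mapped
#'   input, status "not-assessed").
#' @param db A \code{FragmentEndDB}.
#' @param min_len Minimum read length considered mappable.
#' @return list(end_idx = integer row index into db$ends (NA unless status
#'   "mapped"), status = character in mapped/unmapped/multi/nonunique/
#'   blind/too-short/not-assessed).
#' @export
map_to_fragment_ends <- function(captured, db, min_len = 12L) {
  stopifnot(inherits(db, "FragmentEndDB"))
  if (nrow(db$ends) == 0L) stopf("empty fragment-end database")
  n <- length(captured)
  status <- rep("not-assessed", n)
  end_idx <- rep(NA_integer_, n)
  live <- which(!is.na(captured))
  if (length(live) == 0L) {
    return(list(end_idx = end_idx, status = status))
  }
  reads <- toupper(captured[live])
  rlen <- nchar(reads)
  status[live][rlen < min_len] <- "too-short"

  keys <- db$ends$prefix
  klen <- nchar(keys)
  nhits <- integer(length(live))
  cand <- rep(NA_integer_, length(live))
  for (l in sort(unique(klen))) {
    if (l < min_len) next  # such ends are not mappable at all
    rows <- which(klen == l)
    kl <- keys[rows]
    counts <- table(kl)
    uk <- names(counts)
    eligible <- which(rlen >= max(l, min_len))
    if (length(eligible) == 0L) next
    m <- match(substr(reads[eligible], 1L, l), uk)
    hit <- !is.na(m)
    if (!any(hit)) next
    hit_reads <- eligible[hit]
    add <- as.integer(counts[m[hit]])
    nhits[hit_reads] <- nhits[hit_reads] + add
    sing <- hit_reads[add == 1L]
    cand[sing] <- rows[match(substr(reads[sing], 1L, l), kl)]
  }

  assess <- rlen >= min_len
  st <- rep("unmapped", length(live))
  st[nhits >= 2L] <- "multi"
  one <- which(nhits == 1L)
  if (length(one) > 0L) {
    e <- cand[one]
    st[one] <- ifelse(db$ends$blind[e], "blind",
                      ifelse(!db$ends$unique[e], "nonunique", "mapped"))
  }
  status[live][assess] <- st[assess]
  mapped <- which(status[live] == "mapped")
  end_idx[live[mapped]] <- cand[mapped]
  list(end_idx = end_idx, status = status)
}

#' Assemble a per-allele capture table
#'
#' @param map_result Result of \code{\link{map_to_fragment_ends}}.
#' @param trim_status Status vector from \code{\link{trim_primer}}.
#' @param db The \code{FragmentEndDB} used for mapping.
#' @param viewpoint,allele,n_input Metadata; n_input is the number of reads
#'   entering this allele's pipeline (its pool size).
#' @param ambiguous_allele Reads lost at the allele-splitting step that are
#'   attributed to this table's accounting (0 for per-pool tables).
#' @return List of class \code{CaptureTable}: \code{counts} (named integer
#'   vector over db ends) and \code{totals}. The category totals sum to
#'   \code{n_input}.
#' @export
capture_table <- function(map_result, trim_status, db, viewpoint, allele,
                          n_input, ambiguous_allele = 0L) {
  counts <- integer(nrow(db$ends))
  names(counts) <- db$ends$end_id
  mapped_idx <- map_result$end_idx[!is.na(map_result$end_idx)]
  if (length(mapped_idx) > 0L) {
    tab <- tabulate(mapped_idx, nbins = nrow(db$ends))
    counts[] <- tab
  }
  totals <- list(
    input = n_input,
    mapped = sum(map_result$status == "mapped"),
    unmapped = sum(map_result$status == "unmapped"),
    multi = sum(map_result$status == "multi"),
    nonunique = sum(map_result$status == "nonunique"),
    blind_discarded = sum(map_result$status == "blind"),
    too_short = sum(trim_status == "too-short") +
      sum(map_result$status == "too-short"),
    primer_mismatch = sum(trim_status == "primer-mismatch"),
    ambiguous_allele = ambiguous_allele)
  structure(list(counts = counts, totals = totals, viewpoint = viewpoint,
                 allele = allele),
            class = "CaptureTable")
}

#' @export
print.CaptureTable <- function(x, ...) {
  t <- x$totals
  cat(sprintf("CaptureTable %s / allele %s: %d reads in, %d mapped\n",
              x$viewpoint, x$allele, t$input, t$mapped))
  cat(sprintf(
    "  unmapped %d, multi %d, nonunique %d, blind %d, too-short %d, primer %d\n",
    t$unmapped, t$multi, t$nonunique, t$blind_discarded, t$too_short,
    t$primer_mismatch))
  invisible(x)
}

#' Demultiplex and map a simulated (or external) read set
#'
#' PE: read pairs are split by the read-2 SNP base, then each pool's read-1
#' is trimmed and mapped against that allele's fragment-end database;
#' ambiguous pairs are discarded (allele purity over yield). SE: all reads
#' are tagged with the retained allele and mapped against its database.
#'
#' @param r1 data.frame(id, seq) of read-1.
#' @param r2 data.frame(id, seq) of read-2, or NULL for SE.
#' @param vp A \code{ViewpointSpec}.
#' @param dbs list(A =, B =) of \code{FragmentEndDB}s.
#' @param min_len Minimum mappable captured length.
#' @return list(tables = list per analyzed allele of \code{CaptureTable},
#'   pool = per-read allele assignment, reason = per-read assignment
#'   reason).
#' @export
demultiplex <- function(r1, r2, vp, dbs, min_len = 12L) {
  stopifnot(inherits(vp, "ViewpointSpec"))
  if (vp$strategy == "PE") {
    if (is.null(r2)) stopf("PE strategy requires read-2")
    sp <- split_by_snp(r2$seq, vp)
    tables <- list()
    for (al in c("A", "B")) {
      sel <- sp$pool == al
      tr <- trim_primer(r1$seq[sel], vp, min_len)
      mp <- map_to_fragment_ends(tr$captured, dbs[[al]], min_len)
      tables[[al]] <- capture_table(mp, tr$status, dbs[[al]], vp$name, al,
                                    n_input = sum(sel))
    }
    list(tables = tables, pool = sp$pool, reason = sp$reason,
         n_ambiguous = sum(sp$pool == "ambiguous"))
  } else {
    tag <- enforce_se_allele(r1$id, vp)
    al <- tag$allele[1]
    tr <- trim_primer(r1$seq, vp, min_len)
    mp <- map_to_fragment_ends(tr$captured, dbs[[al]], min_len)
    tables <- list()
    tables[[al]] <- capture_table(mp, tr$status, dbs[[al]], vp$name, al,
                                  n_input = nrow(r1))
    list(tables = tables,
         pool = factor(tag$allele, levels = c("A", "B", "ambiguous")),
         reason = rep("rflp-design", nrow(r1)), n_ambiguous = 0L)
  }
}
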