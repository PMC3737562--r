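# Seeded 4C read simulation with per-read ground truth. Paired-end reads:
# read-1 is the P1 primer followed by the captured fragment-end sequence
# (in read orientation), read-2 is the viewpoint-local sequence covering the
# allele-discriminating SNP. Single-end reads omit read-2; reads drawn from
# the allele that gains the extra DpnII site at an RFLP viewpoint carry a
# self-religation capture (viewpoint-local sequence downstream of the gained
# site) and therefore fail exact fragment-end mapping, as the assay design
# dictates.

# substitution errors: each base independently replaced by one of the three
# other bases with probability `rate`
mutate_reads <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  if (total == 0L) return(seqs)
  hits <- which(stats::runif(total) < rate)
  if (length(hits) == 0L) return(seqs)
  cum <- c(0L, cumsum(lens))
  read_i <- findInterval(hits - 0.5, cum)
  pos <- hits - cum[read_i]
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hits)) {
    r <- read_i[j]
    cur <- substr(seqs[r], pos[j], pos[j])
    substr(seqs[r], pos[j], pos[j]) <- sample(setdiff(bases, cur), 1L)
  }
  seqs
}

#' Simulate a 4C read set with ground truth
#'
#' Each read draws its allele 50/50 (F1 diploid), then a fragment end from
#' that allele's contact probability vector. Deterministic for a fixed seed.
#'
#' @param hap A \code{HaplotypePair}.
#' @param vp A \code{\link{viewpoint_spec}}.
#' @param dbs list(A =, B =) of \code{FragmentEndDB}s, one per allele.
#' @param models list(A =, B =) of \code{ContactModel}s.
#' @param n_reads Number of reads (pairs for the PE strategy).
#' @param read_len Total read length in bp (primer included for read-1);
#'   must exceed the P1 primer length by at least 4.
#' @param error_rate Per-base substitution probability applied to the
#'   captured portion of read-1 and to all of read-2. The primer bases are
#'   held error-free: a primer substitution can only fail the exact primer
#'   gate, lowering yield without adding information.
#' @param seed Integer seed.
#' @return List of class \code{ReadSim}: \code{r1}, \code{r2} (NULL for SE)
#'   as data.frames (id, seq), and \code{truth} (read_id, allele, chrom,
#'   end_id, truncated, origin). Origin is "contact" for informative
#'   captures, "self" for RFLP-excluded-allele self-religation products.
#' @export
simulate_reads <- function(hap, vp, dbs, models, n_reads, read_len,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(hap, "HaplotypePair"))
  if (n_reads < 0) stopf("n_reads must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0,1)")
  capture_len <- read_len - nchar(vp$p1_seq)
  if (capture_len < 4L) stopf("read_len must be >= primer length + 4")
  if (vp$strategy == "SE" && is.null(vp$rflp)) {
    stopf("SE strategy requires an RFLP site in the viewpoint spec")
  }

  p <- list(A = contact_probabilities(models$A, dbs$A),
            B = contact_probabilities(models$B, dbs$B))

  empty <- function() {
    truth <- data.frame(read_id = character(0), allele = character(0),
                        chrom = character(0), end_id = character(0),
                        truncated = logical(0), origin = character(0))
    r12 <- data.frame(id = character(0), seq = character(0))
    structure(list(r1 = r12,
                   r2 = if (vp$strategy == "PE") r12 else NULL,
                   truth = truth, viewpoint = vp$name),
              class = "ReadSim")
  }
  if (n_reads == 0L) return(empty())

  with_seed(seed, {
    allele <- sample(c("A", "B"), n_reads, replace = TRUE)
    ids <- sprintf("read%07d", seq_len(n_reads))
    captured <- character(n_reads)
    chrom <- character(n_reads)
    end_id <- rep(NA_character_, n_reads)
    truncated <- logical(n_reads)
    origin <- rep("contact", n_reads)

    excluded <- if (vp$strategy == "SE") vp$rflp$gained_on else NA_character_

    for (al in c("A", "B")) {
      sel <- which(allele == al)
      if (length(sel) == 0L) next
      if (!is.na(excluded) && al == excluded) {
        # self-religation product: sequence just after the gained site
        site_end <- vp$rflp$site_pos + nchar(SECOND_CUTTER)
        self_seq <- sub0(hap$seq[[al]][[vp$chrom]], site_end,
                         site_end + capture_len)
        captured[sel] <- self_seq
        origin[sel] <- "self"
        chrom[sel] <- vp$chrom
        next
      }
      ends <- dbs[[al]]$ends
      idx <- sample.int(length(p[[al]]), length(sel), replace = TRUE,
                        prob = p[[al]])
      captured[sel] <- substr(ends$mapseq[idx], 1L, capture_len)
      truncated[sel] <- nchar(ends$mapseq[idx]) < capture_len
      chrom[sel] <- ends$chrom[idx]
      end_id[sel] <- ends$end_id[idx]
    }

    captured <- mutate_reads(captured, error_rate)
    r1 <- data.frame(id = ids, seq = paste0(vp$p1_seq, captured))

    r2 <- NULL
    if (vp$strategy == "PE") {
      r2seq <- character(n_reads)
      for (al in c("A", "B")) {
        sel <- allele == al
        r2seq[sel] <- sub0(hap$seq[[al]][[vp$chrom]], vp$p2_start,
                           vp$p2_start + read_len)
      }
      r2 <- data.frame(id = ids, seq = mutate_reads(r2seq, error_rate))
    }

    truth <- data.frame(read_id = ids, allele = allele, chrom = chrom,
                        end_id = end_id, truncated = truncated,
                        origin = origin)
    structure(list(r1 = r1, r2 = r2, truth = truth, viewpoint = vp$name),
              class = "ReadSim")
  })
}
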