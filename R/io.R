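# Standard-format I/O. FASTA/FASTQ go through Biostrings; BED, bedGraph and
# TSV are plain tab tables written directly so the package's 0-based
# half-open convention is preserved bit-exactly on disk.

#' Write haplotype sequences as FASTA (one file per allele)
#' @param hap A \code{HaplotypePair}.
#' @param dir Output directory.
#' @return Named character vector of the two file paths.
#' @export
write_haplotypes_fasta <- function(hap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(A = file.path(dir, "haplotype_A.fa"),
             B = file.path(dir, "haplotype_B.fa"))
  for (al in c("A", "B")) {
    ss <- Biostrings::DNAStringSet(hap$seq[[al]])
    Biostrings::writeXStringSet(ss, paths[[al]])
  }
  paths
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write reads as FASTQ (Phred+33, constant quality)
#' @param reads data.frame(id, seq).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return data.frame(id, seq).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(data.frame(id = character(0),
                                             seq = character(0)))
  if (length(lines) %% 4 != 0) stopf("truncated FASTQ: %s", path)
  data.frame(id = sub("^@", "", lines[seq(1, length(lines), 4)]),
             seq = lines[seq(2, length(lines), 4)])
}

#' Write a data.frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open, sorted)
#' @param bed data.frame(chrom, start, end).
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  bed <- bed[order(bed$chrom, bed$start), c("chrom", "start", "end")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file
#' @param path BED path.
#' @return data.frame(chrom, start, end).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df
}

#' Write a profile layer as bedGraph
#' @param profile A \code{ContactProfile}.
#' @param layer Which value column to export ("norm" or "smooth").
#' @param path Output path.
#' @export
write_bedgraph <- function(profile, layer = c("norm", "smooth"), path) {
  layer <- match.arg(layer)
  df <- data.frame(chrom = profile$chrom, start = profile$start,
                   end = profile$end,
                   value = format(profile[[layer]], digits = 10,
                                  scientific = FALSE, trim = TRUE))
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path.
#' @return data.frame(chrom, start, end, value).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}

#' Export profile, domainogram and domain calls as browser tracks
#'
#' Writes the normalized and smoothed profile as bedGraph, the called
#' domains (and complement) as BED, and the p-value matrix in long TSV
#' format (window, end_id, chrom, start, end, p).
#'
#' @param profile A \code{ContactProfile}.
#' @param dg A \code{Domainogram} (or NULL to skip).
#' @param dg_ends Ends data.frame matching the domainogram columns.
#' @param domains An \code{InteractingDomains} (or NULL to skip).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of files written.
#' @export
export_tracks <- function(profile, dg = NULL, dg_ends = NULL,
                          domains = NULL, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, paste0(prefix, "_norm.bedGraph"))
  write_bedgraph(profile, "norm", f); files <- c(files, f)
  f <- file.path(dir, paste0(prefix, "_smooth.bedGraph"))
  write_bedgraph(profile, "smooth", f); files <- c(files, f)
  if (!is.null(dg)) {
    stopifnot(!is.null(dg_ends), ncol(dg$P) == nrow(dg_ends))
    long <- do.call(rbind, lapply(seq_along(dg$W), function(j) {
      data.frame(window = dg$W[j], end_id = dg_ends$end_id,
                 chrom = dg_ends$chrom, start = dg_ends$start,
                 end = dg_ends$end, p = dg$P[j, ])
    }))
    f <- file.path(dir, paste0(prefix, "_domainogram.tsv"))
    write_tsv(long, f); files <- c(files, f)
  }
  if (!is.null(domains)) {
    f <- file.path(dir, paste0(prefix, "_domains.bed"))
    write_bed(domains$domains, f); files <- c(files, f)
    f <- file.path(dir, paste0(prefix, "_noninteracting.bed"))
    write_bed(domains$complement, f); files <- c(files, f)
  }
  files
}

#' Serialize a fragment-end database as TSV plus end-sequence FASTA
#' @param db A \code{FragmentEndDB}.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written.
#' @export
write_fragment_end_db <- function(db, dir, prefix = "fragends") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  write_tsv(db$ends[, c("end_id", "frag_id", "side", "chrom", "start",
                        "end", "blind", "unique", "seq")], tsv)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  ss <- Biostrings::DNAStringSet(db$ends$seq)
  names(ss) <- db$ends$end_id
  Biostrings::writeXStringSet(ss, fa)
  c(tsv = tsv, fasta = fa)
}
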