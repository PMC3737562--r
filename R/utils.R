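# Internal helpers: seeded evaluation, 0-based coordinate string access,
# reverse complement, interval arithmetic shims around IRanges.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in this package take mandatory seeds and are
#' wrapped in `with_seed()` so nothing leaks into (or depends on) the global
#' random-number stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# substring of s over the 0-based half-open interval [start, end)
sub0 <- function(s, start, end) substr(s, start + 1L, end)

# single character at 0-based position
char_at0 <- function(s, pos) substr(s, pos + 1L, pos + 1L)

# overwrite characters of s at 0-based position `start` with `replacement`
replace_at0 <- function(s, start, replacement) {
  paste0(sub0(s, 0L, start), replacement,
         sub0(s, start + nchar(replacement), nchar(s)))
}

#' Reverse complement of DNA strings
#' @param x Character vector of ACGT(N) sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based start positions of every (possibly overlapping) occurrence of
# `pattern` in `subject`; plain exact matching.
find_sites0 <- function(subject, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

# data.frame(start, end) [0-based half-open] -> IRanges
df_to_iranges <- function(df) {
  if (nrow(df) == 0L) return(IRanges::IRanges())
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# IRanges -> data.frame(start, end) [0-based half-open]
iranges_to_df <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# merge possibly-overlapping 0-based intervals on one chromosome
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("start", "end")])
  out <- iranges_to_df(IRanges::reduce(df_to_iranges(df)))
  out[order(out$start), , drop = FALSE]
}

# total bases of intersection between two 0-based interval sets (one chrom)
intersect_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  sum(IRanges::width(IRanges::intersect(df_to_iranges(a), df_to_iranges(b))))
}

# random uniform ACGT sequence of length n as a single string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
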