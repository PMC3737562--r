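# Shared fixtures, built once per test run. Everything is generated in
# code under fixed seeds; the heavier scenario objects are memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small two-chromosome haplotype pair for genome/fragmentome unit tests
tiny_hap <- function() fixture("tiny_hap", {
  generate_haplotypes(genome_spec(c(c1 = 5e4, c2 = 5e4), n_snps = 20L),
                      seed = 42)
})

# the full default PE scenario (2 Mb cis + 5 Mb trans)
demo_sc <- function() fixture("demo_sc", demo_scenario(seed = 7))

# deep error-free read set and its demultiplexed tables
demo_sim <- function() fixture("demo_sim", {
  sc <- demo_sc()
  simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models$bcell,
                 n_reads = 1e5, read_len = 36, error_rate = 0, seed = 8)
})
demo_dm <- function() fixture("demo_dm", {
  sc <- demo_sc()
  sim <- demo_sim()
  demultiplex(sim$r1, sim$r2, sc$vp, sc$dbs)
})

se_sc <- function() fixture("se_sc", se_scenario(seed = 11))

grid_sc <- function() fixture("grid_sc", grid_scenario())

# independent running-median oracle: per-position sort-and-pick with
# symmetric shrinking windows at the edges
oracle_runmed <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    sort(x[(i - k):(i + k)])[k + 1L]
  }, numeric(1))
}

# independent digestion oracle: scan every position for the site
oracle_digest <- function(seq, site, offset) {
  n <- nchar(seq)
  k <- nchar(site)
  hits <- which(vapply(seq_len(n - k + 1L),
                       function(i) substr(seq, i, i + k - 1L) == site,
                       logical(1)))
  cuts <- hits - 1L + offset
  cuts <- cuts[cuts > 0 & cuts < n]
  b <- c(0L, sort(unique(cuts)), n)
  data.frame(start = b[-length(b)], end = b[-1])
}

# base-resolution interval overlap oracle (single chromosome)
oracle_overlap_bases <- function(a, b, len) {
  va <- logical(len); vb <- logical(len)
  for (i in seq_len(nrow(a))) va[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) vb[(b$start[i] + 1):b$end[i]] <- TRUE
  sum(va & vb)
}

random_intervals <- function(n, len, max_w = 500L) {
  s <- sort(sample.int(len - max_w, n))
  data.frame(start = s, end = s + sample.int(max_w, n))
}
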