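# In-silico digestion and fragment-end database construction.

test_that("digest handles trivial and single-site cases exactly", {
  expect_equal(digest("ACGTACGTAC", "AAGCTT", 1L),
               data.frame(start = 0L, end = 10L))
  # one HindIII site: CC AAGCTT GG cut at A^AGCTT
  expect_equal(digest("CCAAGCTTGG", "AAGCTT", 1L),
               data.frame(start = c(0L, 3L), end = c(3L, 10L)))
  # DpnII cuts ^GATC
  expect_equal(digest("AAGATCAA", "GATC", 0L),
               data.frame(start = c(0L, 2L), end = c(2L, 8L)))
  expect_error(digest("ACGTNACGT", "GATC", 0L), "position 4")
})

test_that("overlapping site occurrences are all cut", {
  # GAGA occurs at 0-based 0 and 2 in GAGAGA
  fr <- digest("GAGAGATTTT", "GAGA", 2L)
  expect_equal(fr$start, c(0L, 2L, 4L))
})

test_that("digestion equals the every-position scan oracle", {
  set.seed(101)
  for (i in 1:30) {
    s <- allele4C:::random_dna(2000L)
    expect_identical(digest(s, "AAGCTT", 1L),
                     oracle_digest(s, "AAGCTT", 1L))
    expect_identical(digest(s, "GATC", 0L), oracle_digest(s, "GATC", 0L))
  }
})

test_that("fragments tile every chromosome exactly", {
  hap <- tiny_hap()
  for (al in c("A", "B")) {
    for (chrom in hap$chrom_names) {
      fr <- digest(hap$seq[[al]][[chrom]], "AAGCTT", 1L)
      expect_equal(fr$start[1], 0L)
      expect_equal(fr$end[nrow(fr)], nchar(hap$seq[[al]][[chrom]]))
      expect_true(all(fr$start[-1] == fr$end[-nrow(fr)]))
    }
  }
})

test_that("both alleles share one first-cutter fragment grid", {
  hap <- tiny_hap()
  db_a <- build_fragment_end_db(hap$seq$A, map_prefix_len = 20)
  db_b <- build_fragment_end_db(hap$seq$B, map_prefix_len = 20)
  expect_identical(db_a$fragments, db_b$fragments)
})

test_that("expected fragment length on uniform sequence is near 4096 bp", {
  set.seed(77)
  s <- allele4C:::random_dna(4e6)
  fr <- digest(s, "AAGCTT", 1L)
  mean_len <- mean(fr$end - fr$start)
  expect_lt(abs(mean_len - 4096) / 4096, 0.2)
})

test_that("blind and internally-cut fragments get the stated end layout", {
  # chrom: [pad AAGCTT] [no GATC ...] [AAGCTT] [x GATC y] [AAGCTT pad]
  pad1 <- strrep("AC", 15)
  blind_body <- strrep("AG", 20)           # no GATC possible
  cut_body <- paste0(strrep("CA", 10), "GATC", strrep("TG", 10))
  s <- paste0(pad1, "AAGCTT", blind_body, "AAGCTT", cut_body, "AAGCTT",
              pad1)
  db <- build_fragment_end_db(c(c1 = s), map_prefix_len = 12)
  blind_frag <- db$ends[db$ends$blind & db$ends$frag_idx == 2L, ]
  expect_equal(nrow(blind_frag), 2L)  # both ends of the blind fragment
  # blind end sequences each span the whole fragment
  expect_equal(unique(blind_frag$start), min(blind_frag$start))
  expect_equal(unique(blind_frag$end), max(blind_frag$end))
  cut_frag <- db$ends[!db$ends$blind & db$ends$frag_idx == 3, ]
  e5 <- cut_frag[cut_frag$side == "5p", ]
  e3 <- cut_frag[cut_frag$side == "3p", ]
  # 5' end terminates at the GATC boundary; 3' end begins there
  expect_equal(e5$end, e3$start)
  expect_equal(substr(e3$seq, 1, 4), "GATC")
  # 5' end sequence begins with the HindIII remnant
  expect_equal(substr(e5$seq, 1, 5), "AGCTT")
})

test_that("every end sequence is re-found verbatim at its coordinates", {
  hap <- generate_haplotypes(genome_spec(c(c1 = 1e5), n_snps = 5L),
                             seed = 55)
  db <- build_fragment_end_db(hap$seq$A, map_prefix_len = 20)
  s <- hap$seq$A[["c1"]]
  extracted <- substring(s, db$ends$start + 1L, db$ends$end)
  expect_identical(db$ends$seq, extracted)
  # mapping sequence is the reverse complement for 3' ends
  is3 <- db$ends$side == "3p"
  expect_identical(db$ends$mapseq[is3],
                   allele4C:::revcomp(db$ends$seq[is3]))
  expect_identical(db$ends$mapseq[!is3], db$ends$seq[!is3])
})

test_that("non-unique and unmappably short prefixes are flagged", {
  keys <- c("AAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAA",  # duplicate
            "CCCCCCCCCCCC", "CCCCCCCCCCCCGG",        # prefix relation
            "GGGGTTTTGGGGTTTT",                      # clean
            "ACGT")                                  # too short to map
  u <- allele4C:::prefix_unique(keys, min_len = 12L)
  expect_equal(u, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("detect_rflp finds exactly the site-gaining SNPs", {
  # SNP turns GATG -> GATC on allele B
  a <- paste0(strrep("AC", 10), "GATG", strrep("CA", 10))
  b <- paste0(strrep("AC", 10), "GATC", strrep("CA", 10))
  snps <- data.frame(chrom = "c1", pos_A = 23L, pos_B = 23L,
                     base_A = "G", base_B = "C")
  r <- detect_rflp(snps, c(c1 = a), c(c1 = b))
  expect_equal(nrow(r), 1L)
  expect_equal(r$gained_on, "B")
  expect_equal(r$site_pos, 20L)
  # SNP with no site in either window is excluded
  a2 <- chartr("G", "T", a); b2 <- chartr("G", "T", b)
  expect_equal(nrow(detect_rflp(snps, c(c1 = a2), c(c1 = b2))), 0L)
})

test_that("detect_rflp equals a re-digestion diff oracle on random SNPs", {
  set.seed(202)
  n <- 300L
  s <- allele4C:::random_dna(2e4)
  pos <- sort(sample(seq(10L, 2e4 - 10L), n))
  pos <- pos[c(TRUE, diff(pos) >= 8L)]  # keep windows independent
  ref <- vapply(pos, function(p) substr(s, p + 1, p + 1), character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), character(1))
  b <- s
  for (i in seq_along(pos)) substr(b, pos[i] + 1, pos[i] + 1) <- alt[i]
  snps <- data.frame(chrom = "c1", pos_A = pos, pos_B = pos,
                     base_A = ref, base_B = alt)
  got <- detect_rflp(snps, c(c1 = s), c(c1 = b))
  # oracle: full-sequence site sets, differences near each SNP
  sa <- allele4C:::find_sites0(s, "GATC")
  sb <- allele4C:::find_sites0(b, "GATC")
  expected <- vapply(pos, function(p) {
    near_a <- sa[sa >= p - 3 & sa <= p]
    near_b <- sb[sb >= p - 3 & sb <= p]
    (length(near_a) > 0) != (length(near_b) > 0)
  }, logical(1))
  expect_setequal(got$pos_A, pos[expected])
})

test_that("a chromosome shorter than the site yields a warning and no ends", {
  expect_warning(db <- build_fragment_end_db(c(tiny = "ACG"),
                                             map_prefix_len = 12),
                 "shorter")
  expect_equal(nrow(db$ends), 0L)
})
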