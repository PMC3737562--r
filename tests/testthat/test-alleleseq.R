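# Allele splitting, primer trimming, exact fragment-end mapping and the
# capture-table accounting identity.

toy_vp <- function() {
  viewpoint_spec(name = "toy", chrom = "c1", pos = 100L, strategy = "PE",
                 p1_seq = "ACGTACGTACGTACGT", p2_start = 50L,
                 snp_offset = 4L, base_A = "A", base_B = "C")
}

test_that("split_by_snp partitions on the single SNP-offset base", {
  vp <- toy_vp()
  r2 <- c("GGGGATTTTT",  # A at offset 4
          "GGGGCTTTTT",  # C at offset 4
          "GGGGNTTTTT",  # N: ambiguous
          "GGGGGTTTTT",  # neither base
          "GGG")         # too short to cover the offset
  sp <- split_by_snp(r2, vp)
  expect_equal(as.character(sp$pool),
               c("A", "B", "ambiguous", "ambiguous", "ambiguous"))
  expect_equal(sp$reason[5], "read2-too-short")
  expect_equal(unname(as.integer(sp$sizes)), c(1L, 1L, 3L))
  # case-insensitive exact match
  expect_equal(as.character(split_by_snp("ggggattt", vp)$pool), "A")
})

test_that("trim_primer is exact and enforces the minimum length", {
  vp <- toy_vp()
  r1 <- c(paste0(vp$p1_seq, "ACGTACGTACGTAC"),   # accepted
          paste0("T", substr(vp$p1_seq, 2, 16), "ACGTACGTACGTAC"),
          paste0(vp$p1_seq, "ACGT"))             # remainder too short
  tr <- trim_primer(r1, vp)
  expect_equal(tr$status, c("accepted", "primer-mismatch", "too-short"))
  expect_equal(tr$captured[1], "ACGTACGTACGTAC")
  expect_true(all(is.na(tr$captured[2:3])))
})

test_that("exact mapping rejects any substitution and counts truth exactly", {
  hap <- generate_haplotypes(genome_spec(c(c1 = 5e4), n_snps = 0L),
                             seed = 12)
  db <- build_fragment_end_db(hap$seq$A, map_prefix_len = 20)
  ok <- which(db$ends$unique & !db$ends$blind & db$ends$width >= 20)
  reads <- substr(db$ends$mapseq[ok[1:20]], 1, 20)
  mp <- map_to_fragment_ends(reads, db)
  expect_equal(mp$end_idx, ok[1:20])
  expect_true(all(mp$status == "mapped"))
  # one substitution: unmapped (no-mismatch contract)
  mut <- reads[1]
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  expect_equal(map_to_fragment_ends(mut, db)$status, "unmapped")
  # blind ends are never incremented
  blind <- which(db$ends$blind & nchar(db$ends$prefix) >= 12)
  if (length(blind) > 0) {
    st <- map_to_fragment_ends(substr(db$ends$mapseq[blind[1]], 1, 20),
                               db)$status
    expect_true(st %in% c("blind", "multi"))
  }
  # zero reads: all-zero table with zero totals
  ct <- capture_table(map_to_fragment_ends(character(0), db),
                      character(0), db, "toy", "A", n_input = 0L)
  expect_true(all(ct$counts == 0L))
  expect_equal(ct$totals$mapped, 0L)
})

test_that("the accounting identity holds on the deep demultiplexed run", {
  dm <- demo_dm()
  for (al in c("A", "B")) {
    t <- dm$tables[[al]]$totals
    expect_equal(t$mapped + t$unmapped + t$multi + t$nonunique +
                   t$blind_discarded + t$too_short + t$primer_mismatch,
                 t$input)
  }
  n_total <- sum(vapply(dm$tables, function(x) x$totals$input, numeric(1)))
  expect_equal(n_total + dm$n_ambiguous, nrow(demo_sim()$r1))
})

test_that("error-free splitting reproduces the truth table exactly", {
  dm <- demo_dm()
  sim <- demo_sim()
  expect_equal(as.character(dm$pool), sim$truth$allele)
})

test_that("counts on unique non-blind ends equal the truth table", {
  sc <- demo_sc()
  sim <- demo_sim()
  dm <- demo_dm()
  for (al in c("A", "B")) {
    ends <- sc$dbs[[al]]$ends
    tr <- sim$truth[sim$truth$allele == al, ]
    truth_counts <- table(factor(tr$end_id, levels = ends$end_id))
    ok <- ends$unique & !ends$blind
    expect_equal(unname(dm$tables[[al]]$counts[ok]),
                 as.integer(truth_counts[ok]))
  }
})

test_that("swapping allele labels swaps the capture tables", {
  sc <- demo_sc()
  sim <- simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models$bcell,
                        5000, 36, 0, 33)
  vp_sw <- sc$vp
  vp_sw$base_A <- sc$vp$base_B
  vp_sw$base_B <- sc$vp$base_A
  dm <- demultiplex(sim$r1, sim$r2, sc$vp, sc$dbs)
  dm_sw <- demultiplex(sim$r1, sim$r2, vp_sw,
                       list(A = sc$dbs$B, B = sc$dbs$A))
  expect_equal(unname(dm$tables$A$counts), unname(dm_sw$tables$B$counts))
  expect_equal(unname(dm$tables$B$counts), unname(dm_sw$tables$A$counts))
  expect_equal(dm$tables$A$totals$mapped, dm_sw$tables$B$totals$mapped)
})

test_that("SE reads are tagged with the retained allele", {
  sc <- se_sc()
  expect_equal(sc$vp$rflp$gained_on, "B")
  tag <- enforce_se_allele(c("r1", "r2"), sc$vp)
  expect_equal(tag$allele, c("A", "A"))
  expect_match(attr(tag, "note"), "only allele A")
  expect_equal(nrow(enforce_se_allele(character(0), sc$vp)), 0L)
  expect_error(enforce_se_allele("r", sc$vp, rflp = NULL), "RFLP")
})

test_that("the RFLP design makes the site-gaining allele unmappable", {
  sc <- se_sc()
  sim <- simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models, 2000, 36, 0, 34)
  tr <- trim_primer(sim$r1$seq, sc$vp)
  mp <- map_to_fragment_ends(tr$captured, sc$dbs$A)
  mapped_by_allele <- table(factor(sim$truth$allele[mp$status == "mapped"],
                                   levels = c("A", "B")))
  expect_gt(mapped_by_allele[["A"]], 500)
  expect_lt(mapped_by_allele[["B"]], 0.01 * mapped_by_allele[["A"]])
})

test_that("trimmed simulated reads are substrings of their true end", {
  sc <- demo_sc()
  sim <- simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models$bcell,
                        1000, 36, 0, 35)
  tr <- trim_primer(sim$r1$seq, sc$vp)
  acc <- which(tr$status == "accepted")
  for (i in acc[1:200]) {
    end_row <- match(sim$truth$end_id[i], sc$dbs$A$ends$end_id)
    al <- sim$truth$allele[i]
    end_row <- match(sim$truth$end_id[i], sc$dbs[[al]]$ends$end_id)
    expect_true(startsWith(sc$dbs[[al]]$ends$mapseq[end_row],
                           tr$captured[i]))
  }
})
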