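# Synthetic diploid genomes: haplotype invariants, deletions, expression
# tracks, contact models and read simulation against independent oracles.

test_that("haplotype pairs differ exactly at their SNPs (brute-force diff)", {
  hap <- tiny_hap()
  for (chrom in hap$chrom_names) {
    a <- strsplit(hap$seq$A[[chrom]], "")[[1]]
    b <- strsplit(hap$seq$B[[chrom]], "")[[1]]
    expect_equal(length(a), length(b))
    diffs <- which(a != b) - 1L  # 0-based
    snp_pos <- sort(hap$snps$pos_A[hap$snps$chrom == chrom])
    expect_equal(sort(diffs), snp_pos)
  }
  # 20 random + 1 mandatory RFLP SNP in total
  expect_equal(nrow(hap$snps), 21L)
  # SNP list sorted by (chrom, position)
  expect_false(is.unsorted(hap$snps$pos_A[hap$snps$chrom == "c1"]))
})

test_that("generation is deterministic and the RFLP is allele-B-only", {
  spec <- genome_spec(c(c1 = 1e4), n_snps = 0L)
  h1 <- generate_haplotypes(spec, seed = 3)
  h2 <- generate_haplotypes(spec, seed = 3)
  expect_identical(h1$seq, h2$seq)
  expect_identical(h1$snps, h2$snps)
  # only the mandatory RFLP SNP is planted
  expect_equal(nrow(h1$snps), 1L)
  p <- h1$snps$pos_A[1]
  win <- function(s) substr(s, p - 2, p + 5)
  expect_false(grepl("GATC", win(h1$seq$A[["c1"]]), fixed = TRUE))
  expect_true(grepl("GATC", win(h1$seq$B[["c1"]]), fixed = TRUE))
})

test_that("SNPs touching first-cutter sites are rejected", {
  hap <- tiny_hap()
  site_pos <- allele4C:::find_sites0(hap$seq$A[["c1"]], "AAGCTT")[1]
  expect_error(
    generate_haplotypes(
      genome_spec(c(c1 = 5e4, c2 = 5e4), n_snps = 20L,
                  planted_snps = data.frame(chrom = "c1",
                                            pos = site_pos + 2L,
                                            base_B = "C")),
      seed = 42),
    "first-cutter")
})

test_that("no SNP creates or sits in a HindIII site on either allele", {
  hap <- tiny_hap()
  for (chrom in hap$chrom_names) {
    a_sites <- allele4C:::find_sites0(hap$seq$A[[chrom]], "AAGCTT")
    b_sites <- allele4C:::find_sites0(hap$seq$B[[chrom]], "AAGCTT")
    expect_identical(a_sites, b_sites)  # shared fragment grid
  }
})

test_that("apply_deletion shifts coordinates and lifts positions", {
  hap <- generate_haplotypes(genome_spec(c(c1 = 1e4), n_snps = 0L), seed = 3)
  # zero-length deletion is the identity
  res0 <- apply_deletion(hap, "B", "c1", 500L, 500L)
  expect_identical(res0$hap$seq, hap$seq)
  expect_equal(lift_position(res0$liftover, c(0L, 499L, 500L, 9999L)),
               c(0L, 499L, 500L, 9999L))
  # arithmetic case
  res <- apply_deletion(hap, "B", "c1", 100L, 200L)
  expect_equal(nchar(res$hap$seq$B[["c1"]]), 1e4 - 100L)
  expect_equal(nchar(res$hap$seq$A[["c1"]]), 1e4)
  expect_equal(lift_position(res$liftover, 250L), 150L)
  expect_true(is.na(lift_position(res$liftover, 150L)))
  # overlap with a protected region errors
  expect_error(apply_deletion(hap, "B", "c1", 100L, 200L,
                              protect = c(150L, 160L)), "protected")
})

test_that("liftover agrees with unique 20-mer re-location (k-mer oracle)", {
  hap <- generate_haplotypes(genome_spec(c(c1 = 5e4), n_snps = 0L), seed = 9)
  res <- apply_deletion(hap, "B", "c1", 20000L, 27000L)
  edited <- res$hap$seq$B[["c1"]]
  orig <- hap$seq$B[["c1"]]
  withr_seed <- 5
  set.seed(withr_seed)
  probes <- sample(c(sample(19900L, 25L), 27100L + sample(22000L, 25L)))
  for (p in probes) {
    kmer <- substr(orig, p + 1L, p + 20L)
    hit <- gregexpr(kmer, edited, fixed = TRUE)[[1]]
    if (length(hit) != 1L || hit[1] == -1L) next  # not unique in edited seq
    expect_equal(hit[1] - 1L, lift_position(res$liftover, p))
  }
  # SNP map: positions in the deleted interval are dropped for that allele
  hap2 <- tiny_hap()
  snp_in <- hap2$snps$pos_A[1]
  res2 <- apply_deletion(hap2, "A", hap2$snps$chrom[1],
                         snp_in - 5L, snp_in + 5L)
  expect_true(is.na(res2$hap$snps$pos_A[1]))
  expect_equal(res2$hap$snps$pos_B[1], snp_in)
})

test_that("expression track fractions match targets (base-count oracle)", {
  comp <- data.frame(chrom = c("c1", "c1"), start = c(0L, 30000L),
                     end = c(30000L, 50000L),
                     activity = c("active", "inactive"))
  bed <- simulate_expression_track(comp, 0.4, 0.1, seed = 4)
  expect_false(is.unsorted(bed$start))
  expect_true(all(bed$end > bed$start))
  # non-overlapping
  expect_true(all(diff(as.vector(rbind(bed$start, bed$end))) >= 0))
  for (i in 1:2) {
    region <- comp[i, c("start", "end")]
    got <- oracle_overlap_bases(bed[, c("start", "end")], region, 50000L) /
      (region$end - region$start)
    want <- if (comp$activity[i] == "active") 0.4 else 0.1
    expect_lt(abs(got - want), 0.05)
  }
  # degenerate proportions
  expect_equal(nrow(simulate_expression_track(comp, 0, 0, seed = 1)), 0L)
  full <- simulate_expression_track(comp[1, ], 1, 1, seed = 1)
  expect_equal(full$start, 0L)
  expect_equal(full$end, 30000L)
  expect_error(simulate_expression_track(comp, 1.2, 0, seed = 1), "0, 1")
})

test_that("contact probabilities sum to 1 and respect the trans share", {
  db <- fragment_end_grid(c(cA = 1e6, cB = 5e5), 4000L)
  set.seed(31)
  for (i in 1:100) {
    m <- contact_model(list(chrom = "cA", pos = sample.int(9e5, 1) + 5e4),
                       decay_exponent = runif(1, 0.5, 2.5),
                       trans_rate = runif(1, 0, 0.9))
    p <- contact_probabilities(m, db)
    expect_lt(abs(sum(p) - 1), 1e-9)
    trans_mass <- sum(p[db$ends$chrom == "cB"])
    expect_lt(abs(trans_mass - m$trans_rate), 1e-9)
  }
  # trans_rate 0: every trans end gets exactly 0
  m0 <- contact_model(list(chrom = "cA", pos = 5e5), trans_rate = 0)
  p0 <- contact_probabilities(m0, db)
  expect_true(all(p0[db$ends$chrom == "cB"] == 0))
})

test_that("viewpoint fragment and both neighbours carry zero probability", {
  db <- fragment_end_grid(c(cA = 1e5), 5000L)
  m <- contact_model(list(chrom = "cA", pos = 52500), trans_rate = 0)
  p <- contact_probabilities(m, db)
  vp_idx <- attr(p, "vp_frag_idx")
  near <- abs(db$ends$frag_idx - vp_idx) <= 1L
  expect_true(all(p[near] == 0))
  expect_true(all(p[!near] > 0))
})

test_that("closed-form decay ratios hold on an enumerable grid", {
  # 10 fragments of 1 kb; alpha = 1; no domains, no trans
  db <- fragment_end_grid(c(cA = 1e4), 1000L)
  m <- contact_model(list(chrom = "cA", pos = 1500), decay_exponent = 1,
                     trans_rate = 0)
  p <- contact_probabilities(m, db)
  mid <- (db$ends$start + db$ends$end) / 2
  d <- abs(mid - 1500)
  live <- which(p > 0)
  # hand-summed normalization over the surviving ends
  w <- 1 / d[live]
  expect_equal(p[live], w / sum(w), tolerance = 1e-12)
  # pairwise ratios equal inverse distance ratios
  i <- live[1]; j <- live[5]
  expect_equal(p[i] / p[j], d[j] / d[i], tolerance = 1e-12)
})

test_that("a large decay exponent concentrates mass on the nearest ends", {
  db <- fragment_end_grid(c(cA = 1e5), 5000L)
  m <- contact_model(list(chrom = "cA", pos = 52500),
                     decay_exponent = 30, trans_rate = 0)
  p <- contact_probabilities(m, db)
  nearest <- order(-p)[1:2]
  expect_gt(sum(p[nearest]), 0.99)
})

test_that("ends flanking a deletion gain contact probability", {
  hap <- generate_haplotypes(genome_spec(c(c1 = 2e5), n_snps = 0L),
                             seed = 17)
  res <- apply_deletion(hap, "B", "c1", 80000L, 120000L)
  db_a <- build_fragment_end_db(hap$seq$A, map_prefix_len = 20)
  db_b <- build_fragment_end_db(res$hap$seq$B, map_prefix_len = 20)
  m <- contact_model(list(chrom = "c1", pos = 50000), decay_exponent = 1,
                     trans_rate = 0)
  p_a <- contact_probabilities(m, db_a)
  p_b <- contact_probabilities(m, db_b)
  # total mass on the territory beyond the deletion is higher on the
  # deleted allele (it is linearly closer to the viewpoint)
  mass_a <- sum(p_a[db_a$ends$start >= 120000])
  mass_b <- sum(p_b[db_b$ends$start >= 80000])
  expect_gt(mass_b, mass_a)
})

test_that("simulated reads carry the allele's SNP base and match the model", {
  sc <- demo_sc()
  # n_reads = 0: valid empty output
  s0 <- simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models$bcell, 0, 36, 0, 1)
  expect_equal(nrow(s0$r1), 0L)
  expect_equal(nrow(s0$truth), 0L)
  # error-free PE: read-2 base at the SNP offset equals the truth allele's
  sim <- simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models$bcell,
                        2000, 36, 0, 21)
  base <- substr(sim$r2$seq, sc$vp$snp_offset + 1, sc$vp$snp_offset + 1)
  want <- ifelse(sim$truth$allele == "A", sc$vp$base_A, sc$vp$base_B)
  expect_equal(base, want)
  # determinism
  sim2 <- simulate_reads(sc$hap, sc$vp, sc$dbs, sc$models$bcell,
                         2000, 36, 0, 21)
  expect_identical(sim$r1$seq, sim2$r1$seq)
  expect_identical(sim$truth, sim2$truth)
})

test_that("empirical fragment-end frequencies fit the model (chi-square)", {
  sc <- demo_sc()
  sim <- demo_sim()
  p <- contact_probabilities(sc$models$bcell$A, sc$dbs$A)
  tr <- sim$truth[sim$truth$allele == "A", ]
  counts <- table(factor(tr$end_id, levels = sc$dbs$A$ends$end_id))
  live <- p > 0
  expected <- p[live] / sum(p[live]) * sum(counts)
  # pool ends with small expectation for a valid chi-square
  grp <- pmin(findInterval(cumsum(expected), seq(0, sum(counts), by = 8)),
              .Machine$integer.max)
  obs <- tapply(as.integer(counts[live]), grp, sum)
  exp <- tapply(expected, grp, sum)
  stat <- sum((obs - exp)^2 / exp)
  pval <- stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("sampling error shrinks with depth", {
  db <- fragment_end_grid(c(cA = 2e6), 4000L)
  m <- contact_model(list(chrom = "cA", pos = 1e6), decay_exponent = 1,
                     trans_rate = 0)
  p <- contact_probabilities(m, db)
  tv <- function(n) {
    f <- sample_contacts(p, n, seed = 100) / n
    sum(abs(f - p)) / 2
  }
  expect_lt(tv(1e5), tv(1e3))
})
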