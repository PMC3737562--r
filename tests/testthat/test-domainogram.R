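# Binarized coverage, binomial running-window significance, null
# calibration and domain calling.

test_that("binarize_coverage masks the viewpoint and recounts exactly", {
  sc <- demo_sc()
  dm <- demo_dm()
  prof <- contact_profile(dm$tables$A, sc$dbs$A, sc$vp, w = 21)
  cov <- binarize_coverage(prof, sc$dbs$A, sc$vp,
                           exclusion_radius = sc$exclusion_radius)
  # counting oracle: recompute pi from the profile rows
  for (comp in c("far_cis", "trans")) {
    sel <- match(cov[[comp]]$ends$end_id, prof$end_id)
    expect_equal(cov[[comp]]$pi, mean(prof$raw[sel] >= 1))
    expect_equal(cov[[comp]]$covered, prof$raw[sel] >= 1)
  }
  # masked ends are within the exclusion radius, and are cis only
  masked <- setdiff(prof$end_id[prof$cis], cov$far_cis$ends$end_id)
  midx <- match(masked, prof$end_id)
  expect_true(all(abs(prof$frag_idx[midx] - cov$vp_frag_idx) <=
                    sc$exclusion_radius))
  # degenerate cases
  z <- prof; z$raw <- 0L
  covz <- binarize_coverage(z, sc$dbs$A, sc$vp, 10)
  expect_equal(covz$far_cis$pi, 0)
  o <- prof; o$raw <- 1L
  covo <- binarize_coverage(o, sc$dbs$A, sc$vp, 10)
  expect_equal(covo$far_cis$pi, 1)
})

test_that("window significance matches closed forms", {
  # k = 0 in any window: upper tail at zero is 1
  dg <- window_significance(rep(FALSE, 30), 0.3, c(1, 5))
  expect_true(all(dg$P == 1))
  # w = 10, k = 10, pi = 0.5: p = 2^-10
  dg2 <- window_significance(rep(TRUE, 10), 0.5, 10)
  expect_equal(unname(dg2$P[1, 5]), 2^-10)
  # degenerate background warns and floors at 1
  expect_warning(dg3 <- window_significance(rep(TRUE, 10), 1, 3),
                 "degenerate")
  expect_true(all(dg3$P == 1))
  expect_error(window_significance(rep(TRUE, 5), 0.5, 10), "length")
})

test_that("the p-value matrix equals a direct binomial tail summation", {
  set.seed(70)
  covered <- runif(200) < 0.25
  pi <- 0.25
  W <- 1:20
  dg <- window_significance(covered, pi, W)
  tail_sum <- function(k, w) {
    if (k <= 0) return(1)
    sum(vapply(k:w, function(j) {
      choose(w, j) * pi^j * (1 - pi)^(w - j)
    }, numeric(1)))
  }
  for (w in W) {
    h <- (w - 1L) %/% 2L
    for (i in seq(h + 1L, 200L - (w - 1L - h), by = 13)) {
      k <- sum(covered[(i - h):(i - h + w - 1L)])
      expect_equal(unname(dg$P[w, i]), tail_sum(k, w), tolerance = 1e-12)
    }
    # positions without a full window score 1
    if (h >= 1) expect_true(all(dg$P[w, seq_len(h)] == 1))
  }
})

test_that("p is monotone in k and in the background rate", {
  for (w in c(5L, 20L)) {
    p_of_k <- vapply(0:w, function(k) {
      cov <- c(rep(TRUE, k), rep(FALSE, w - k))
      window_significance(cov, 0.3, w)$P[1, (w - 1L) %/% 2L + 1L]
    }, numeric(1))
    expect_true(all(diff(p_of_k) <= 0))
  }
  cov <- c(rep(TRUE, 8), rep(FALSE, 12))
  p_of_pi <- vapply(c(0.5, 0.3, 0.1, 0.05), function(pi) {
    window_significance(cov, pi, 20)$P[1, 10]
  }, numeric(1))
  expect_true(all(diff(p_of_pi) <= 0))
})

test_that("null calibration is conservative and near the exact tail mass", {
  cal <- null_calibration(pi = 0.2, W = c(5L, 20L), n_ends = 200L,
                          n_sims = 200L, seed = 71)
  for (i in seq_len(nrow(cal))) {
    expect_lte(cal$empirical[i], cal$alpha[i] + 1e-12)
    expect_lte(abs(cal$empirical[i] - cal$exact[i]), 2 * cal$mc_se[i])
  }
  # discreteness at w = 1, pi = 0.5: p floors at 0.5, never < 0.05
  cal1 <- null_calibration(pi = 0.5, W = 1L, n_ends = 100L,
                           n_sims = 100L, seed = 72)
  expect_true(all(cal1$empirical == 0))
})

test_that("domain calling merges runs and returns the exact complement", {
  ends <- data.frame(end_id = sprintf("e%02d", 1:40), chrom = "c1",
                     start = (0:39) * 100L, frag_idx = 1:40, block = "c1")
  ends$end <- ends$start + 100L
  # a single contiguous significant run
  covered <- rep(FALSE, 40); covered[15:24] <- TRUE
  dg <- window_significance(covered, 0.05, 5L)
  dom <- call_domains(dg, ends, 5L, fdr = 0.05, compartment = "cis")
  expect_equal(nrow(dom$domains), 1L)
  expect_lte(dom$domains$start, 1500)
  expect_gte(dom$domains$end, 2300)
  # complement plus domains tile the analyzable territory
  tot <- sum(dom$domains$end - dom$domains$start) +
    sum(dom$complement$end - dom$complement$start)
  expect_equal(tot, max(ends$end) - min(ends$start))
  # nothing significant: zero domains, complement is the whole territory
  dg0 <- window_significance(rep(FALSE, 40), 0.05, 5L)
  dom0 <- call_domains(dg0, ends, 5L, fdr = 0.05)
  expect_equal(nrow(dom0$domains), 0L)
  expect_equal(dom0$complement$start, min(ends$start))
  expect_equal(dom0$complement$end, max(ends$end))
  expect_error(call_domains(dg0, ends, 5L, fdr = 1.5), "fdr")
  expect_error(call_domains(dg0, ends, 7L, fdr = 0.05), "not among")
})

test_that("runs never merge across the masked viewpoint gap", {
  ends <- data.frame(end_id = sprintf("e%02d", 1:40), chrom = "c1",
                     start = c((0:19) * 100L, 10000L + (0:19) * 100L),
                     frag_idx = c(1:20, 121:140),
                     block = rep(c("c1:L", "c1:R"), each = 20))
  ends$end <- ends$start + 100L
  covered <- rep(FALSE, 40); covered[15:26] <- TRUE  # spans the gap
  dg <- window_significance(covered, 0.05, 5L)
  dom <- call_domains(dg, ends, 5L, fdr = 0.05)
  expect_gte(nrow(dom$domains), 2L)
  # no called interval crosses the gap between 2000 and 10000
  expect_true(all(dom$domains$end <= 2000 | dom$domains$start >= 10000))
})

test_that("designed enrichment is recovered on the genome-scale grid", {
  g <- grid_sc()
  p <- contact_probabilities(g$model, g$db)
  cnt <- sample_contacts(p, 1e5, seed = 73)
  prof <- counts_profile(cnt, g$db, "chrA")
  cov <- binarize_coverage(prof, g$db, g$vp,
                           exclusion_radius = g$exclusion_radius)
  expect_gt(cov$trans$pi, 0.05)
  expect_lt(cov$trans$pi, 0.2)
  dg <- window_significance(cov$trans$covered, cov$trans$pi, c(21L, 41L))
  dom <- call_domains(dg, cov$trans$ends, 41L, fdr = 0.05, "trans")
  truth <- g$enriched[, c("chrom", "start", "end")]
  tp <- sum(vapply(seq_len(nrow(dom$domains)), function(i) {
    d <- dom$domains[i, ]
    if (d$chrom != "chrB1") return(0)
    allele4C:::intersect_bases(d, truth)
  }, numeric(1)))
  called <- sum(dom$domains$end - dom$domains$start)
  expect_gte(tp / sum(truth$end - truth$start), 0.9)
  expect_lte((called - tp) / called, 0.1)
})
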