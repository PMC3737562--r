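#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study system.
#
# An F1-hybrid-like diploid genome (2 Mb viewpoint chromosome "chr12",
# 5 Mb trans chromosome "chr6"), 40 background SNPs plus one RFLP SNP that
# creates a DpnII site on allele B only, a paired-end viewpoint whose P2
# primer reads a planted SNP, two contact conditions (lymphoid "bcell"
# with shared enriched regions on both alleles; "brain" with disjoint
# regions), an expression track active over the lymphoid-contacted
# regions, and seeded 4C read sets: two deep runs (1e5 pairs, for
# profiles and correlation) and one sparse genome-wide run (7000 pairs,
# for domainograms and activity).

suppressMessages(library(allele4C))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("building scenario (seed ", seed, ") ...")
sc <- demo_scenario(seed = seed)
saveRDS(sc, file.path(out, "scenario.rds"))

write_haplotypes_fasta(sc$hap, out)
write_tsv(sc$hap$snps, file.path(out, "snps.tsv"))
write_bed(sc$expression, file.path(out, "expression.bed"))

rflp <- detect_rflp(sc$hap$snps, sc$hap$seq$A, sc$hap$seq$B, db = sc$dbs$B)
write_tsv(rflp, file.path(out, "rflp_sites.tsv"))

message(sprintf("genome: %s", paste(
  sprintf("%s %.1f Mb", names(sc$hap$lengths$A), sc$hap$lengths$A / 1e6),
  collapse = ", ")))
message(sprintf("SNPs: %d (of which %d create a DpnII RFLP)",
                nrow(sc$hap$snps), nrow(rflp)))
message(sprintf("viewpoint %s at %s:%d (PE; P2 SNP %s/%s at read offset %d)",
                sc$vp$name, sc$vp$chrom, sc$vp$pos, sc$vp$base_A,
                sc$vp$base_B, sc$vp$snp_offset))
message(sprintf("topological domain %.0f-%.0f kb, boundary attenuation %.2f",
                sc$domains$start / 1000, sc$domains$end / 1000,
                sc$domains$attenuation))

sims <- list(
  bcell = list(model = sc$models$bcell, n = 1e5, seed = seed + 1L),
  brain = list(model = sc$models$brain, n = 1e5, seed = seed + 2L),
  bcell_gw = list(model = sc$models$bcell, n = 7000, seed = seed + 11L))
for (nm in names(sims)) {
  s <- sims[[nm]]
  sim <- simulate_reads(sc$hap, sc$vp, sc$dbs, s$model, n_reads = s$n,
                        read_len = 36, error_rate = 0, seed = s$seed)
  write_fastq(sim$r1, file.path(out, paste0(nm, "_R1.fastq")))
  write_fastq(sim$r2, file.path(out, paste0(nm, "_R2.fastq")))
  write_tsv(sim$truth, file.path(out, paste0(nm, "_truth.tsv")))
  message(sprintf("simulated %-9s %6d read pairs", nm, s$n))
}
message("stage 1 done -> ", out)
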