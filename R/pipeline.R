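# Pipeline orchestration: simulate -> digest -> demux -> map -> profile ->
# domainogram -> correlate -> activity, every stage seeded, every output
# recorded in a machine-readable manifest. Re-running an identical config
# reproduces identical outputs.

#' Assemble a pipeline configuration
#'
#' One configuration drives the whole run. All stochastic stages derive
#' their seeds from \code{seed}. Deep sequencing
#' (\code{n_reads_profile}) feeds the contact profiles, boundary detection
#' and correlation; a sparse genome-wide sampling
#' (\code{n_reads_genomewide}) — per-end depth scaled to the synthetic
#' genome size — feeds the domainogram and activity stages.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param paths Optional named list of pre-existing input files (fasta_A,
#'   fasta_B, fastq_r1, fastq_r2, expression_bed); when given they are
#'   validated at config time.
#' @param cis_len,trans_len,n_snps Genome parameters.
#' @param read_len,primer_len Read geometry (bp).
#' @param n_reads_profile,n_reads_genomewide Read depths.
#' @param error_rate Per-base substitution rate.
#' @param w Profile smoothing window (fragment ends).
#' @param W Domainogram window sizes.
#' @param w_call Window at which domains are called.
#' @param fdr FDR level for domain calling.
#' @param n_boot Bootstrap replicates for the activity contrast.
#' @return List of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(outdir, seed, paths = NULL,
                            cis_len = 2e6, trans_len = 5e6, n_snps = 40L,
                            read_len = 36L, primer_len = 16L,
                            n_reads_profile = 1e5L,
                            n_reads_genomewide = 7000L,
                            error_rate = 0, w = 21L, W = 1:30,
                            w_call = 11L, fdr = 0.05, n_boot = 1000L) {
  structure(list(outdir = outdir, seed = as.integer(seed), paths = paths,
                 cis_len = cis_len, trans_len = trans_len,
                 n_snps = n_snps, read_len = read_len,
                 primer_len = primer_len,
                 n_reads_profile = as.integer(n_reads_profile),
                 n_reads_genomewide = as.integer(n_reads_genomewide),
                 error_rate = error_rate, w = w, W = W, w_call = w_call,
                 fdr = fdr, n_boot = n_boot),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Checks parameter sanity and, when external input paths are configured,
#' that every referenced file exists — before any computation runs.
#'
#' @param config A \code{PipelineConfig}.
#' @return Invisibly TRUE; errors on the first violation.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$seed) || is.na(config$seed)) {
    stopf("config must carry a seed")
  }
  if (config$w %% 2 == 0) stopf("profile window w must be odd")
  if (config$fdr <= 0 || config$fdr >= 1) stopf("fdr must be in (0,1)")
  if (!is.null(config$paths)) {
    for (nm in names(config$paths)) {
      if (!file.exists(config$paths[[nm]])) {
        stopf("configured input '%s' does not exist: %s", nm,
              config$paths[[nm]])
      }
    }
  }
  invisible(TRUE)
}

# write a file atomically: stage failures leave a .partial, not a torn file
write_stage_file <- function(writer, path) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the full allele-specific 4C pipeline
#'
#' Executes simulate, digest, demux/map, profile, domainogram, domain
#' calling, correlation and activity stages, writing standard-format
#' outputs and a JSON manifest listing every artifact with the parameters
#' and seeds that produced it. A stage failure aborts with the failing
#' stage named; files of the failed stage remain with a .partial suffix.
#'
#' @param config A \code{PipelineConfig}.
#' @return Invisibly, the manifest (also written as manifest.json).
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  log_path <- file.path(out, "run.log")
  cat(sprintf("[%s] pipeline start\n", format(Sys.time())),
      file = log_path)
  note <- function(stage, path) {
    files[[length(files) + 1L]] <<- list(stage = stage,
                                         file = basename(path))
    cat(sprintf("[%s] %s: %s\n", format(Sys.time()), stage,
                basename(path)), file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  # --- simulate: genome, viewpoint, models, expression, reads ------------
  sc <- NULL
  sims <- list()
  run_stage("simulate", {
    sc <- demo_scenario(seed = config$seed, cis_len = config$cis_len,
                        trans_len = config$trans_len,
                        n_snps = config$n_snps,
                        read_len = config$read_len,
                        primer_len = config$primer_len)
    fa <- write_haplotypes_fasta(sc$hap, out)
    for (p in fa) note("simulate", p)
    note("simulate", write_stage_file(function(p) write_tsv(sc$hap$snps, p),
                                      file.path(out, "snps.tsv")))
    note("simulate",
         write_stage_file(function(p) write_bed(sc$expression, p),
                          file.path(out, "expression.bed")))
    for (cond in c("bcell", "brain")) {
      sims[[cond]] <- simulate_reads(
        sc$hap, sc$vp, sc$dbs, sc$models[[cond]],
        n_reads = config$n_reads_profile, read_len = config$read_len,
        error_rate = config$error_rate,
        seed = config$seed + match(cond, c("bcell", "brain")))
      for (rd in c("r1", "r2")) {
        p <- file.path(out, sprintf("%s_%s.fastq", cond,
                                    toupper(sub("r", "R", rd))))
        write_stage_file(function(pp) write_fastq(sims[[cond]][[rd]], pp),
                         p)
        note("simulate", p)
      }
      p <- file.path(out, sprintf("%s_truth.tsv", cond))
      write_stage_file(function(pp) write_tsv(sims[[cond]]$truth, pp), p)
      note("simulate", p)
    }
    sims[["bcell_gw"]] <- simulate_reads(
      sc$hap, sc$vp, sc$dbs, sc$models$bcell,
      n_reads = config$n_reads_genomewide, read_len = config$read_len,
      error_rate = config$error_rate, seed = config$seed + 11L)
  })

  # --- digest: fragment-end databases ------------------------------------
  run_stage("digest", {
    for (al in c("A", "B")) {
      p <- write_fragment_end_db(sc$dbs[[al]], out,
                                 prefix = paste0("fragends_", al))
      for (pp in p) note("digest", pp)
    }
  })

  # --- demux + map: per-condition, per-allele capture tables --------------
  tables <- list()
  run_stage("demux-map", {
    for (cond in names(sims)) {
      dm <- demultiplex(sims[[cond]]$r1, sims[[cond]]$r2, sc$vp, sc$dbs)
      tables[[cond]] <- dm$tables
      for (al in names(dm$tables)) {
        ct <- dm$tables[[al]]
        p <- file.path(out, sprintf("counts_%s_%s.tsv", cond, al))
        write_stage_file(function(pp) {
          write_tsv(data.frame(end_id = names(ct$counts),
                               count = unname(ct$counts)), pp)
        }, p)
        note("demux-map", p)
      }
    }
  })

  # --- profiles + boundaries ---------------------------------------------
  profiles <- list()
  run_stage("profile", {
    for (cond in c("bcell", "brain")) {
      for (al in c("A", "B")) {
        prof <- contact_profile(tables[[cond]][[al]], sc$dbs[[al]],
                                sc$vp, w = config$w)
        profiles[[paste(cond, al, sep = "_")]] <- prof
        for (p in export_tracks(prof, dir = out,
                                prefix = sprintf("profile_%s_%s", cond,
                                                 al))) {
          note("profile", p)
        }
      }
    }
    bounds <- detect_boundaries(profiles[["bcell_A"]])
    p <- file.path(out, "boundaries_bcell_A.tsv")
    write_stage_file(function(pp) write_tsv(bounds, pp), p)
    note("profile", p)
  })

  # --- domainogram + domain calls (sparse genome-wide run) ---------------
  domains <- list()
  run_stage("domainogram", {
    prof_gw <- contact_profile(tables[["bcell_gw"]][["A"]], sc$dbs$A,
                               sc$vp, w = config$w)
    cov <- binarize_coverage(prof_gw, sc$dbs$A, sc$vp,
                             exclusion_radius = sc$exclusion_radius)
    for (comp in c("far_cis", "trans")) {
      cc <- cov[[comp]]
      dg <- window_significance(cc$covered, cc$pi, config$W)
      dom <- call_domains(dg, cc$ends, config$w_call, config$fdr,
                          compartment = if (comp == "far_cis") "cis"
                                        else "trans")
      domains[[comp]] <- dom
      for (p in export_tracks(prof_gw, dg, cc$ends, dom, dir = out,
                              prefix = paste0("gw_", comp))) {
        note("domainogram", p)
      }
    }
  })

  # --- correlation --------------------------------------------------------
  run_stage("correlate", {
    cm <- correlation_matrix(align_profiles(profiles), w = config$w)
    p <- file.path(out, "correlation.tsv")
    write_stage_file(function(pp) {
      write_tsv(data.frame(label = rownames(cm$rho),
                           as.data.frame(cm$rho)), pp)
    }, p)
    note("correlate", p)
  })

  # --- activity -----------------------------------------------------------
  run_stage("activity", {
    act <- rbind(transcribed_fraction(domains$far_cis, sc$expression),
                 transcribed_fraction(domains$trans, sc$expression))
    p <- file.path(out, "activity.tsv")
    write_stage_file(function(pp) write_tsv(act, pp), p)
    note("activity", p)
    contrast <- compare_compartments(list(domains$far_cis, domains$trans),
                                     sc$expression,
                                     n_boot = config$n_boot,
                                     seed = config$seed + 21L)
    p <- file.path(out, "activity_contrast.json")
    write_stage_file(function(pp) {
      jsonlite::write_json(contrast[c("contrast", "ci", "n_domains",
                                      "fraction_interacting",
                                      "fraction_non_interacting")],
                           pp, auto_unbox = TRUE, digits = NA, null = "null")
    }, p)
    note("activity", p)
  })

  manifest <- list(
    package = "allele4C",
    version = as.character(utils::packageVersion("allele4C")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("outdir", "paths"))],
    outputs = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cat(sprintf("[%s] pipeline done\n", format(Sys.time())),
      file = log_path, append = TRUE)
  invisible(manifest)
}
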