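# allele4C

Allele-specific 4C-seq analysis, end to end and fully testable on
synthetic data.

4C-seq (circular chromosome conformation capture with sequencing)
captures every genomic locus that contacts one chosen restriction
fragment — the *viewpoint* — and reports contact frequency along the
genome. In an F1 hybrid the two parental genomes differ at known SNPs,
so the assay can be made **allele-specific**: read pairs are assigned to
a parental allele by the SNP base read by the viewpoint primer (the
paired-end strategy), or the assay is restricted to one allele by a
restriction fragment length polymorphism that destroys the other
allele's template (the single-end strategy). This package implements
that analysis for people who want to study allele-resolved chromatin
architecture — or to develop and validate 4C methodology — without
touching real sequencing data: a seeded synthetic-data module generates
diploid genomes, contact models, FASTQ read sets with per-read ground
truth, and expression tracks, so every stage is verifiable against an
oracle.

## What it computes

* **Fragment-end database** — in-silico double digestion (HindIII
  `A^AGCTT`, then DpnII `^GATC`): the mappable universe of first-cutter
  fragment ends trimmed at the nearest internal second-cutter site, with
  blind and non-unique ends flagged. RFLP detection annotates SNPs that
  create a second-cutter site on one allele.
* **Allele demultiplexing and exact mapping** — PE pairs split on the
  read-2 SNP base; primer trimmed exactly; read-1 mapped with no
  mismatches to fragment-end prefixes; complete per-read accounting.
* **Contact profiles** — counts per end, normalized to reads per million
  mapped, smoothed with a running median of 21 fragment ends; boundary
  detection as local maxima of the log2 flank ratio
  `log2((mean_left + 0.5) / (mean_right + 0.5))`.
* **Domainograms** — coverage binarized per end, background rate `pi`
  estimated separately for far-cis and trans, and every running window of
  `w` analyzable ends scored with the upper-tail binomial probability
  `P(K >= k), K ~ Binom(w, pi)` over `w = 1..30`, displayed from `P = 1`
  to a floor of `1e-10`; interacting domains called at one window size
  after Benjamini–Hochberg correction.
* **Correlation and activity** — Spearman rank correlation of windowed
  profiles across alleles, tissues and viewpoints; proportion of
  transcribed bases inside interacting versus non-interacting territory,
  cis and trans, with a domain-resampling bootstrap CI.

## Worked example

The `analysis/` directory is a numbered workflow over the package
functions; run the scripts in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fragmentome.R
Rscript analysis/03_demux_map.R
Rscript analysis/04_profiles.R
Rscript analysis/05_domainograms.R
Rscript analysis/06_correlation_activity.R
```

Stage 1 builds the default synthetic system (seed 1): a 2 Mb viewpoint
chromosome and a 5 Mb trans chromosome, 42 SNPs (2 of them DpnII RFLPs),
a PE viewpoint at `chr12:1098749` inside a topological domain spanning
799–1399 kb with boundary attenuation 0.1, a lymphoid ("bcell") and a
"brain" contact condition, and three read sets. Stage 2 reports the
digestion landscape:

```
allele A: 1687 fragments (mean 4149 bp; 4096 expected), 3370 ends,
          189 blind (5.6%), 96 non-unique (2.8%)
shared HindIII grid: TRUE
```

Stage 3 demultiplexes and maps (error-free reads, so the pools match the
truth table exactly and ~94 % of reads map; the rest are blind-end or
short-end captures, all accounted for):

```
bcell: pools A/B/ambiguous = 49909/50091/0
  allele A: 49909 in, 46923 mapped (94.0%), blind 1630, too-short 1350
```

Stage 4 smooths the profiles and finds both designed domain boundaries
exactly (`nearest call 0 fragment(s) away`). Stage 5 binarizes the
sparse genome-wide run (far-cis `pi = 0.287`, trans `pi = 0.256`), calls
interacting domains, and confirms the null is conservative (empirical
false-positive rate 0.031 at nominal alpha 0.05 for `w = 20`, matching
the exact discrete tail mass 0.032). Stage 6 reproduces the two headline
patterns on synthetic data:

```
Spearman correlation (window 21):
        bcell_A bcell_B brain_A brain_B
bcell_A    1.00    0.77    0.21    0.20   # alleles share contacts,
brain_A    0.21    0.21    1.00    0.79   # tissues do not
transcribed-base fraction: interacting 0.324 vs non-interacting 0.118
contrast 0.206, 95% bootstrap CI [0.072, 0.292] over 9 domains
```

i.e. the two alleles of one tissue correlate strongly while tissues with
disjoint contact regions do not, and the chromatin contacted by the
viewpoint is markedly more transcribed than the non-contacted territory,
with the bootstrap CI excluding zero.

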