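---
title: "Allele-specific 4C-seq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific 4C-seq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allele4C)
```

# The measurement and its in-silico counterpart

4C-seq (circular chromosome conformation capture with sequencing)
measures which genomic loci contact one chosen restriction fragment, the
*viewpoint*. Chromatin is digested with a six-cutter (HindIII, `AAGCTT`,
cutting `A^AGCTT`), cross-linked partners are ligated, the circles are
trimmed with a four-cutter (DpnII, `GATC`, cutting `^GATC`) and
re-ligated, and inverse PCR across the viewpoint fragment end yields
reads that start in the viewpoint and continue into the captured
partner. The mappable unit is therefore the *fragment end*: the segment
of a HindIII fragment between its boundary and the nearest internal
DpnII site. Fragments with no internal DpnII site are *blind*; their
ends cannot be distinguished from undigested template and are flagged
and excluded from profile statistics. Ends whose mapping prefix is not
unique in the database are likewise flagged.

In an F1 hybrid, the two parental genomes differ at known SNPs, which
makes the assay allele-resolvable in two ways:

* **Paired-end (PE) strategy.** One primer (P2) reads across a SNP
  inside the viewpoint fragment; the mate (P1) reads into the captured
  sequence. Each pair is assigned to an allele by the single base read-2
  shows at the SNP offset; the capture in read-1 is then mapped against
  that allele's fragment-end database. Pairs whose SNP base matches
  neither or both expectations are discarded as ambiguous rather than
  split proportionally — allele purity is worth more than yield here.
* **Single-end (SE) strategy.** When a SNP creates an *extra* DpnII site
  on one allele (an RFLP), the 4C template of that allele falls apart
  between the two inverse primers and yields no product. The assay is
  single-allele by design: all mapped reads are tagged with the allele
  lacking the extra site. The package does not filter sequences to
  enforce this; instead the simulator emits the excluded allele's
  products as self-religation captures (viewpoint-local sequence
  downstream of the gained site), and the end-to-end test verifies that
  fewer than 1 % of them survive exact mapping.

Mapping itself is an exact, hash-style lookup of the primer-trimmed read
against fragment-end mapping prefixes — no external aligner. The
measurement contract is "no mismatches", so exact string equality is
both faithful and simpler to reason about: a read increments exactly one
end's count or is accounted for as unmapped, multi-hit, non-unique,
blind, too short, or primer-mismatched. The accounting identity (the
categories sum to the input) is asserted in the pipeline and the tests.

# The synthetic data generator

There is no real genome in this package; every analysis runs on
generated data with known ground truth. The generator is first-class,
tested code, and its defaults define the study conditions used
throughout the tests and the acceptance script.

**Genome.** Uniform 25 % base composition, so restriction-site density
is analytically predictable (expected HindIII spacing $4^6 = 4096$ bp —
the realized mean on 4 Mb of simulated sequence is checked within 20 %).
The default diploid system is a 2 Mb viewpoint chromosome (`chr12`,
after the murine chromosome carrying *IgH*) and a 5 Mb trans chromosome
standing in for the rest of the genome. Haplotypes are identical except
at planted SNPs; no SNP may sit in or create a HindIII site, so both
alleles share one first-cutter fragment grid (a precondition for
comparing alleles end-by-end). One mandatory SNP creates a DpnII site on
allele B only, exercising the RFLP machinery.

**Contact model.** Cis ends receive weight $p_i \propto |x_i -
x_{vp}|^{-\alpha}$ (the decay expected from polymer behaviour; default
$\alpha = 1$), multiplied by an attenuation factor (default 0.1) once
per topological-domain boundary crossed and by a fold factor (default 8)
inside preferred contact regions. Trans ends share a fixed probability
mass (default 0.25) uniformly before enrichment. The cis and trans
blocks are normalized separately to $1 - \text{trans\_rate}$ and
$\text{trans\_rate}$, which makes both the unit sum and the trans share
exact rather than approximate. The viewpoint fragment and its two
immediate neighbours get probability zero: self-ligation and undigested
products dominate there in real data, and excluding them is standard
practice. A deletion on one allele (V(D)J-recombination-like) shortens
that allele's coordinate system; because distances are computed on the
deleted coordinates, ends flanking the deletion gain contact probability
on that allele — the tested "two ends of the locus meet" behaviour.

**Reads.** Read-1 is the P1 primer plus the first bases of the sampled
end's mapping sequence (reverse complement for 3' ends, i.e. reads in
sequencing orientation); read-2 is the viewpoint-local sequence covering
the SNP. Alleles are drawn 50/50 (F1 diploid). Errors are substitutions
only — mapping is exact, so indels would only lower yield without adding
test power — applied to the captured part of read-1 and to all of
read-2; primer bases are held error-free so the primer gate stays a
deterministic yield filter. Reads from ends shorter than the capture
length are emitted truncated and flagged in the truth table. Defaults of
36 bp reads (16 bp primer + 20 bp capture) and $10^5$ pairs per deep run
are simulator parameters, not claims about any real dataset.

**Expression track.** Compartment intervals are tiled (1 kb tiles) and a
seeded subset is marked transcribed so that the realized transcribed-base
fraction matches the requested proportion (0.4 in "active", 0.1 in
"inactive" compartments by default, checked within ±0.05 by a
base-counting oracle).

Everything is seeded explicitly; seeds are arguments, never global
state, and identical (spec, seed) pairs reproduce byte-identical files.

# Profiles, boundaries

Capture counts over analyzable (unique, non-blind) ends are normalized
to reads per million mapped — the scale is arbitrary anyway, and total-
mapped is the simplest denominator that keeps samples comparable — and
smoothed with a running median over 21 fragment ends, the window used
for locus-wide 4C display. The edge policy is a symmetric shrinking
window (the largest centered odd window that fits), which keeps the
output the same length as the input without inventing data; the
implementation is oracle-tested against per-position sort-and-pick.

Boundaries are called on the smoothed cis profile as local maxima of
$\log_2\!\big((\bar{s}_{\text{left}} + \varepsilon)/(\bar{s}_{\text{right}}
+ \varepsilon)\big)$ over flanks of 10 ends, with $\varepsilon = 0.5$
normalized units and a default threshold of 1 (a two-fold drop). On the
default scenario the two designed domain boundaries (attenuation 0.1)
are localized exactly; steep decay flanks near the viewpoint and the
edges of enriched regions also produce candidates, which is the correct
behaviour — the test asserts that the designed boundaries are among the
calls within two fragments, not that they are the only calls.

# Domainograms: an explicit, testable null

The domainogram literature describes multi-scale running-window
significance maps without giving a closed-form null; this package fixes
one deliberately simple and fully testable model. Per-end coverage is
binarized (captured at least once or not), ends within an exclusion
radius of the viewpoint are masked (near-cis decay saturates coverage
and would swamp the background; default radius is the 1 Mb equivalent in
fragments, and the small default genome uses a 200 kb equivalent),
and a background coverage rate $\pi$ is estimated separately for far-cis
and trans — the two compartments genuinely differ. For a window of $w$
consecutive analyzable ends with $k$ covered,

$$P[w, i] = \Pr(K \ge k), \qquad K \sim \mathrm{Binom}(w, \pi),$$

computed for every window size (default 1–30) at every position with a
full centered window; edge positions score 1. Windows advance over
analyzable ends only, so mappability holes cannot masquerade as
depletion; significant runs are never merged across a chromosome border
or the masked viewpoint gap. The display maps $P$ from 1 (black) to a
floor of $10^{-10}$; raw p-values are retained. Calling applies
Benjamini–Hochberg correction at one window size only — the display
stays uncorrected, as domainogram colour scales conventionally are.

Because coverage is i.i.d. Bernoulli($\pi$) only under the generator's
uniform-trans regime, calibration and recovery are assessed where the
null is exact: `null_calibration` simulates i.i.d. coverage and confirms
the empirical false-positive rate sits at or below nominal $\alpha$
(the discrete test is conservative) and within twice the Monte-Carlo
standard error of the exact binomial tail mass — the MC error is
computed across simulations, since windows overlap within one vector.
Domain recovery is measured on a genome-scale fragment grid (50 Mb cis
plus six 100 Mb trans chromosomes, 4096 bp fragments) where $10^5$
sampled contacts leave the trans background at $\pi \approx 0.1$ and
eight 200 kb fold-8 regions are planted: at calling window 41 the calls
recover over 90 % of the planted bases with under 10 % false bases. The
calling window should be of the order of, but below, the expected
domain width in ends (here 97); small windows fragment domains into
pieces separated by coverage gaps, very large ones blur their edges.
In far-cis the same statistic rides the polymer-decay gradient, so
domainograms light up broadly around the viewpoint — as they do on real
data — and far-cis calls include the topological domain itself; that is
contact structure, not a false positive, but it is why recovery of
planted regions is quantified in trans.

# Correlation and activity

Profile similarity uses the Spearman rank correlation of running-median-
smoothed profiles (window 21 by default), zero-count ends included and
ties averaged — ranks make the comparison insensitive to the arbitrary
profile scale. The two alleles' databases can differ by a few ends
(where a SNP touches a DpnII site), so profiles are intersected on
shared end identifiers before correlating.

Transcriptional activity of contacted chromatin is the proportion of
transcribed *bases* (not genes) inside called interacting domains,
versus the non-interacting analyzable territory of the same compartment,
computed by exact interval intersection. The contrast carries a 95 %
percentile bootstrap CI obtained by resampling whole domains (1000
replicates): bases within a domain are nowhere near independent, so the
domain is the resampling unit; with fewer than 5 domains the contrast is
reported without a CI. What "non-interacting territory" means is a
genuine open choice — the whole genome, all analyzed chromosomes, or
the analyzable span — and this package uses the analyzable fragment-end
territory of the same compartment, which keeps the comparison within
the universe the assay can actually see.

# Two sequencing regimes, one genome

Real 4C runs put roughly one read per fragment end genome-wide; a 7 Mb
synthetic genome at $10^5$ reads is oversampled a thousand-fold. Rather
than shrink the deep runs (which the dense near-cis profiles need), the
default configuration uses two depths: $10^5$ pairs feed profiles,
boundary detection and correlation, and a sparse genome-wide run of
7000 pairs — chosen so the per-end background coverage lands in the
$\pi \approx 0.2\text{–}0.35$ regime the binomial window model assumes —
feeds the domainogram and activity stages. The methods report both
depths in their outputs; they are study-condition parameters of the
synthetic system, not tuning knobs.

# What the synthetic system does and does not show

The generator reproduces the statistical structure the analysis relies
on: power-law cis decay, sharp domain boundaries, preferred far-cis and
trans regions, allele-shared versus tissue-specific contacts, RFLP
selectivity, and compartment-structured transcription. It does not
emulate PCR duplicates, ligation biases, quality degradation, repeat
families (non-uniqueness here arises only from chance k-mer collisions
and short ends), chromatin-state-dependent digestion efficiency, or a
realistic SNP density. Passing tests therefore demonstrate that the
implementation is correct under its stated model, and that the
statistical machinery is calibrated where its assumptions hold — not
that the binomial null is adequate for any particular real library, nor
that real boundary calls would be two-fragment accurate. On real data
the far-cis background is itself structured, and the single-$\pi$
binomial null should be read as a display statistic more than a test.

# Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere internally and in BED and
bedGraph outputs. HindIII cuts at offset 1, DpnII at offset 0 — fixing
the cut chemistry fixes every coordinate bit-exactly. Uniqueness is
computed over mapping prefixes (36 bp by default; the default scenario
uses the 20 bp capture length so that uniqueness matches what mapping
can see), with prefix-of relations counting as collisions and ends
shorter than the 12 bp minimum mapping length flagged unmappable.
Degenerate backgrounds ($\pi \in \{0, 1\}$) warn and score $p = 1$
everywhere; a mapped total of zero is an error, not a silent NaN; an
empty read set yields valid empty FASTQ and truth tables; a zero-length
deletion is the identity with an identity liftover. All intervals pass
through `IRanges` for merging, intersection and complement.

# Limitations

* The binomial window null ignores coverage autocorrelation along the
  chromosome; p-values at adjacent positions share most of their
  windows. BH correction at the calling step treats them as exchangeable
  tests, which is conservative in rate but not a familywise guarantee.
* The SE strategy's selectivity is modelled, not enforced: real
  libraries show partial digestion and template switching that the
  simulator does not generate.
* The generator plants SNPs only outside first-cutter sites; real
  HindIII-site SNPs (which break the shared grid) are out of scope, as
  is mapping against a real reference.
* `run_pipeline` consumes its own simulated inputs; external FASTQ
  support is limited to validating configured paths and reusing the
  demultiplex/map stages directly.
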