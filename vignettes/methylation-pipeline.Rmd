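---
title: "Pooled two-group WGBS methylation analysis with methage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled two-group WGBS methylation analysis with methage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methage)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reads each cytosine as
methylated or unmethylated: bisulfite converts unmethylated C to U
(sequenced as T) while 5-methylcytosine is protected, so the per-site
counts of methylated (`mC`) and unmethylated (`umC`) reads measure the
methylation level. In studies of ageing muscle in birds, each group of
animals is often sequenced as a single pooled DNA library rather than
as replicates; `methage` implements the complete analysis chain for
that design: per-site methylation calling, corrected methylation
levels, context and functional-element profiles, sliding-window
differential methylation (DMR) detection, DMR-to-gene annotation, and
integration with expression and trait tables to nominate
promoter-methylation candidate genes. Every stage takes a data frame
and returns a tibble, so analyses chain with the pipe.

## The site model

Bisulfite conversion is imperfect: a small fraction `r` of truly
unmethylated cytosines escapes conversion and reads as methylated. An
unmethylated spike-in (lambda phage DNA) carried through library
preparation estimates it:

\[
\hat r = \frac{\sum mC_{\mathrm{spike}}}{\sum (mC + umC)_{\mathrm{spike}}}.
\]

A site with `m` methylated reads out of depth `n` is a true
methylation site when `m` is implausible under the non-conversion
null, measured by the exact binomial upper tail
\(P(X \ge m),\ X \sim \mathrm{Binomial}(n, \hat r)\). Sites need depth
\(\ge 5\) to be tested, and calls use a Benjamini–Hochberg q-value
threshold of 0.05. The adjustment runs separately within each sequence
context (CG, CHG, CHH — H is A, C or T) because CG methylation in
vertebrates is orders of magnitude more common than CHG/CHH: a joint
adjustment would let the CG sites dictate the CHH threshold.

The raw level \(ML = mC/(mC+umC)\) has expectation
\(ml + (1-ml)\,r\) under additive non-conversion noise, so the package
reports the inverted, corrected level

\[
ML_{\mathrm{corrected}} = \frac{ML - r}{1 - r},
\]

clipped to \([0, 1]\). This is the unique linear form whose
expectation removes the additive noise; with \(r = 0\) it is the
identity, and a site whose raw level equals the noise floor maps to 0.
Profile statistics (per-chromosome, per-element, metagene) average
`ml_corrected` over all covered (depth \(\ge 5\)) sites, not only
significant calls; composition statistics (the share of
methylcytosines per context, and the per-context methylated fraction
such as mCG/CG) use the calls. This mirrors the dual reporting
convention of WGBS studies, which quote both "percent of C sites
methylated" and "composition of the methylome".

## Coordinates and gene elements

Internally every interval is 0-based half-open; the per-cytosine
report dialect (the Bismark CX layout: chrom, 1-based position,
strand, mC, umC, context, trinucleotide) is converted exactly once at
I/O. Sites stay strand-specific — no destranding into CpG units — as
per-cytosine reports list them.

Genes (BED12) decompose into functional elements: the promoter is the
2 kb immediately upstream of the transcription start site,
strand-aware and clipped at chromosome boundaries; 5'/3'UTRs are the
exonic portions outside the CDS; introns are the gaps between exons.
When one label per site is needed (element-level profiles), overlaps
resolve by precedence promoter > 5'UTR > 3'UTR > exon > intron > CpG
island > repeat > intergenic; for DMR annotation the full multi-label
set is kept, because a single DMR can legitimately span promoter, UTR
and exon at once.

## The DMR scan

Differential methylation between the two pooled groups is scanned
with 1000 bp windows advanced in 100 bp steps (a chromosome shorter
than one window yields a single window covering it). Within a window,
each group's counts pool across its covered CG-context sites, and the
2×2 table of pooled methylated/unmethylated counts is tested with a
two-sided Fisher's exact test. With one pooled library per group there
is no replicate-level variance to model, which is why an exact
conditional test on pooled counts — rather than a beta-binomial or
smoothing model — is the natural choice; its null is exactly testable
against hypergeometric enumeration, which the test suite does.

Windows are significant when all of the following hold: p < 0.05, BH
FDR (across all tested windows) < 0.05, fold change of the
corrected-level means > 2 (computed as \((ml_2 + \varepsilon)/(ml_1 +
\varepsilon)\) or its reciprocal, whichever \(\ge 1\), with
\(\varepsilon = 10^{-6}\) guarding empty levels), and mean depth per
covered site > 5 in **both** groups. Keeping p < 0.05 alongside
FDR < 0.05 is redundant in practice but retained as an explicit
filter. Significant windows whose spans overlap or lie within one
step of each other merge into a DMR; at a 100 bp step any contiguous
signal appears as an overlapping run, so the merged span is the
union. A DMR is `hyper` when the group-2 level exceeds group 1,
`hypo` otherwise. The scan runs per context (CG by default; CHG/CHH
scans are a `context` argument away) so that sparse non-CG signal is
neither diluted nor dominated.

The scan is order-invariant in its inputs and every base is covered
by at most `window/step` windows. Bases within the last
`(size - window) mod step` bp of a chromosome fall outside all
windows; at 1000/100 geometry this is at most 99 bp per chromosome.

## Integration with expression and traits

Genes whose promoter/UTR/exon/intron overlaps a DMR are differentially
methylated genes (DMGs); the per-gene methylation direction is the
majority over supporting DMRs, with ties kept verbatim as
`"Hypo/hyper"`. Joining DMGs with the differentially expressed genes
(DEGs, supplied as an external label table) gives the joint table from
which candidates are filtered: promoter overlap required, methylation
`Hyper`, regulation `Down` — the classic promoter-silencing signature.
The filters are conjunctive, so adding one can never enlarge the set.

Expression classes split each sample's genes at the median positive
FPKM (zero-FPKM genes and ties go to `low`), a scale-free rule since
the published analyses state the two-class split but not its cutoff.
Gene–trait association uses plain Pearson correlation; under a pooled
design only group-level pairs exist (n = 2), so the per-cell n is
reported and a warning is raised below n = 3 — the correlations are
then descriptive, not inferential. Relative qPCR expression follows
\(2^{-\Delta\Delta Ct}\).

## What the simulator emulates — and what it does not

`sim_config()` fixes the study conditions: two pooled groups, CG
baseline 0.65 with CHG/CHH at 0.006, CpG islands hypomethylated at
0.1, Poisson depth with mean 30 per site and group, non-conversion
rate 0.005 (a simulation choice; such rates are rarely reported), and
a fully unmethylated spike-in of 2000 control cytosines. Depth can be
switched to negative-binomial via `overdispersion` for sensitivity
checks. Observed counts are
\(\mathrm{Binomial}(n,\ ml + (1-ml)\,r)\), folding conversion failure
into the success probability — the exact process the correction
formula inverts.

Planted DMRs carry known location, magnitude and direction. They sit
on an intermediate-methylation background: the lower group level
defaults to `base_ml = 0.25` and the higher to `base_ml + delta_ml`.
This mirrors where DMRs arise in real vertebrate genomes (partially
methylated domains, boundary shifts) and keeps the truth detectable
by the scan's own filters: a +0.3 shift on top of a 0.65 baseline
could never pass fold change > 2, so planting it there would create
ground truth the method is, by design, required to reject.
`plant_promoter_dmrs()` places hyper-DMRs over simulated promoters to
exercise the candidate filter end to end; expression then follows
\(\log FPKM = 3 - 4 \cdot ML_{\mathrm{promoter}} + \epsilon\) with
noise SD 0.2 per group, so a 0.3 promoter shift moves expression by
about 1.7 log2 units against a DE cutoff of |log2 FC| ≥ 1.

Known departures from real data, hence limits of what green tests
show: per-site true levels are unimodal per context rather than
bimodal (real CG sites are mostly near 0 or near 1, so simulated
composition statistics run higher than published ones); there are no
SNPs, mapping errors, M-bias or strand coverage asymmetry; depth is
independent across sites; and DE labels derive from the simulated
fold changes rather than from a replicate-aware RNA-seq model.

## Numerical and design choices

* Binomial tails come from `pbinom` and are verified against explicit
  term-by-term summation to 1e-12; BH against a sort/scale/cummin
  oracle; Fisher p-values against hypergeometric enumeration.
* Metagene bins are 20 (upstream 2 kb) / 60 (body, length-normalised)
  / 20 (downstream), a smoothness/desk-scale compromise exposed as
  arguments; genes shorter than the body bin count are excluded with
  a warning. Minus-strand genes are flipped so profiles read 5' to 3'.
* Degenerate inputs favour explicit signalling over silent zeros:
  depth-0 sites have `NA` corrected level, chromosomes or elements
  with no covered sites are absent rather than zero, a zero-depth
  spike-in or an all-zero-depth window is an error/skip, and equal
  group levels yield direction `"ambiguous"` (unreachable after the
  fold-change filter).
* Example and test problem sizes (60 kb to 2 Mb genomes, 10-120
  genes, depth 30) were chosen so that the full suite exercises every
  stage, including a complete 2 Mb end-to-end run, at desk scale.

## A short tour

```{r tour, eval = FALSE}
library(methage)

cfg <- sim_config(seed = 1, chrom_sizes = c(chr1 = 500000L),
                  n_genes = 40)
res <- run_pipeline(cfg, n_promoter_dmrs = 8)

res$conversion          # spike-in non-conversion estimate
glance(res$scan)        # windows tested / significant / DMRs
tidy(res$scan)          # the DMR table
res$candidates          # promoter-hyper, expression-down genes
autoplot(res$scan)      # per-group DMR level boxplots

# the bundled worked example: 18 joint DMG x DEG records
example_dmg_deg_table() |>
  select_candidates(methylation = NULL, regulation = NULL)
```
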