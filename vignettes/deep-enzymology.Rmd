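---
title: "Deep enzymology of DNA methyltransferase flanking preferences"
author: "flankPref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep enzymology of DNA methyltransferase flanking preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankPref)
```

# The measurement this package models

De novo DNA methyltransferases (DNMT3A, DNMT3B) methylate the cytosine of
CpG dinucleotides with an efficiency that depends strongly on the bases
flanking the target. Deep enzymology quantifies this dependence in a
single experiment:

* **Substrate pool.** Every molecule is `arm5 + N(10) + CG + N(10) + arm3`:
  a central CpG (optionally CpA/CpT/CpC) inside ten fully randomized
  bases per side, between fixed primer arms. Ten random bases per side
  make every context of half-width up to 10 present in a large pool;
  statistics are usually computed at half-width `k = 3`
  (`contextUniverseSize(3)` = `r contextUniverseSize(3L)` contexts) or
  `k = 2` (256).
* **Methylation.** The purified enzyme methylates each strand of each
  molecule with a context-dependent probability — the quantity to be
  estimated.
* **Hairpin ligation.** A C-free linker joins the top strand 3' end to
  the bottom strand 5' end, so one sequencing read carries both strands
  of one molecule.
* **Bisulfite conversion.** Unmethylated C reads as T;
  5-methylcytosine remains C. The read layout is therefore
  `bisulfite(top) + linker + bisulfite(reverse-complement(top))`, and
  aligning the two halves position by position recovers both the
  original duplex sequence and the methylation state of each strand.

# Read reconstruction

After quality trimming (3' bases below Q`r flankPrefConfig()$qmin` are
removed) and full-length selection (linker and primer-arm anchors
matched bisulfite-aware, i.e. a read T over a reference C is a match,
with a small mismatch allowance), each read is reconstructed from the
paired sense/antisense bases. Only six ordered base pairs are consistent
with bisulfite chemistry:

| sense | oriented antisense | original top base | information |
|-------|--------------------|-------------------|-------------|
| A | T | A | — |
| T | A | T | — |
| G | C | G | bottom C methylated |
| G | T | G | bottom C unmethylated |
| C | G | C | top C methylated |
| T | G | C | top C unmethylated |

The ten remaining pairs are chemistry-inconsistent mismatches; such
positions are masked `N` and molecules with more than
`maxPairMismatch` of them (default 1) fail QC. Unmethylated cytosines of
the fixed primer arms double as an internal conversion control
(`estimateConversion()`).

# Context statistics

For each molecule, the top-strand event contributes the context read
5'→3' around the top C; for CpG targets the bottom strand contributes the
reverse-complement context. Contexts are tabulated into a `ContextTable`
with raw level `m/n` and the shrinkage estimate `(m + 0.5)/(n + 1)`,
which keeps unobserved or shallow contexts finite and is used whenever
levels are ratioed. Derived summaries:

* `positionalEnrichment()` — per flank position, the population SD of
  observed/expected base frequencies among methylated events, normalized
  to the strongest position; `enrichmentPermutationNull()` provides a
  permutation null of the *maximum* over positions (a familywise
  statistic, so "observed below the null's 99th percentile" is a single
  well-calibrated comparison rather than one test per position).
* `topSiteMatrix()` — position frequency matrix of the most preferred
  contexts.
* `plus1Summary()` and `cpnSpecificity()` — +1-base and
  central-dinucleotide summaries.

# Comparing enzymes

`preferenceRatio()` divides each enzyme's smoothed profile by its own
mean over the shared, sufficiently covered contexts (each profile then
has mean 1, removing overall activity and exposure differences) and
ratios them; with DNMT3B as numerator this is the B/A preference.
`rankProfile()` gives deterministic ranks (1 = most preferred,
lexicographic ties). `similarityBins()` groups contexts by the number of
flank positions matching a reference site; the closed-form bin sizes at
`k = 3` are `choose(6, m) * 3^(6 - m)`:

```{r}
similarityBinSizes(3)
```

`countCpGSites()` / `repeatRankAnalysis()` enumerate CpG sites of repeat
consensus sequences with both strand contexts (tandem monomers can be
treated as circular) and keep, per enzyme, the better strand rank — in
cells, maintenance methylation propagates a mark regardless of which
strand was methylated first.

# Cellular methylomes

Downstream of a standard bisulfite aligner the package provides the
bespoke steps: the read-level non-conversion filter (a read end with 3 or
more methylated non-CpG cytosines is discarded), positional clipping
constants (4 bases at read-1 5' ends, 2 at read-2, 5 at 3' ends), exact
binomial methylation calling against the spike-in error rate with
Benjamini–Hochberg FDR control, spike-in (lambda) conversion QC with an
acceptance bound, symmetric-CpG strand collapsing, and
`genomicContextSummary()`, which aggregates sites with depth ≥ 10 into
the same context-table format as the in-vitro profiles (site-weighted:
each site contributes its level once, so deep sites do not dominate).

# The simulator

`generatePool()` / `simulateMethylation()` / `emitHairpinFastq()` invert
the analysis: a `PreferenceModel` with known per-context probabilities
(`lookupModel()` for explicit tables, `positionalModel()` /
`randomPreferenceModel()` for multiplicative per-position weights)
methylates a simulated pool, and reads are emitted with configurable
imperfections — conversion rate (default 0.998), inappropriate
conversion of methylated C (0.002), substitution error (0.001), and
low-quality 3' tails. With all imperfections off, reconstruction must be
(and is, in the test suite) exact; with defaults on, the pipeline's
conversion estimate and parameter recovery can be validated against
ground truth.

```{r}
cfg <- flankPrefConfig(flankLen = 2L, contextK = 2L,
                       conversionRate = 1, inappropriateConversion = 0,
                       seqError = 0, lowTailFrac = 0)
pool <- generatePool(500, cfg, seed = 1)
oc <- simulateMethylation(pool, constantModel(0.5), seed = 2)
fq <- tempfile(fileext = ".fastq")
emitHairpinFastq(pool, oc, fq, config = cfg, seed = 3)
res <- processHairpinReads(fq, cfg)
c(accepted = unname(res$counts[["accepted"]]),
  qcPass = unname(res$counts[["qcPass"]]))
```

# Parameter choices and limitations

* Defaults (`flankPrefConfig()`): 20-base primer arms, 10-base random
  flanks, 8-base C-free linker, Q20 trim threshold, one anchor mismatch,
  one pair mismatch, `k = 3`, coverage/depth thresholds of 10. These are
  typical values for this assay class, chosen so that noise-free
  round trips are exact and noisy defaults leave a few percent of reads
  rejected for length.
* The simulator draws flanks uniformly and errors independently per
  base; real libraries have synthesis bias, indels, and correlated
  errors, none of which are modeled. There is no indel handling in
  reconstruction — a read with an indel fails anchor matching instead.
* Methylation events on the two strands are drawn independently given
  the context; cooperative or processive behavior is not modeled.
* Enrichment/permutation analyses use modest problem sizes (hundreds of
  permutations, thousands of molecules) tuned for desk-scale runtimes;
  they scale linearly if more precision is needed.
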