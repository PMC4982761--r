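---
title: "Detecting transcription read-through from strand-specific RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcription read-through from strand-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthru)
```

## The problem

When transcription termination or 3'-end cleavage is impaired — for
example after knockdown of a transcription factor that recruits the
5'-3' exonuclease machinery to termination sites — RNA polymerase II
continues past the annotated transcription termination site (TTS) and
poly(A)+ libraries accumulate transcripts with long 3' untranslated
regions. In strand-specific RNA-seq this appears as signal on the gene's
own strand extending up to a few kilobases downstream of the TTS.
`readthru` quantifies that signal per gene, classifies genes whose
read-through expression changes between two conditions, summarizes the
signal as metagene profiles, and tests the condition differences.

## The procedure

**Coordinates and counting.** Everything is 0-based, half-open (the
BED/bedGraph convention); GTF input is converted on read. A sequenced
fragment contributes exactly one tag, at its strand-aware 5' end
(`start` for `+`, `end - 1` for `-`). This makes every tag fall into
exactly one window or bin, so counts are conserved and boundary cases
are unambiguous. Counting is strand-matched only: the protocol modelled
here preserves orientation, so antisense signal never counts toward a
gene.

**Quantification.** For each gene and library, the body count is the tag
count over the exons, reported as FPKM
(count / (length/1000) / (library_size/10^6), with the exonic length);
the read-through count is the tag count in the window of `window_bp`
(default 5000, commonly also 3000) bases downstream of the TTS, reported
as FPKM with the *actual* window length — windows clipped at a
chromosome edge keep their density interpretation rather than being
diluted by the nominal length.

**Tiers and filters.** Genes are tiered on control body FPKM: High above
500, Middle 100–500, Low 10–100, No below 10. The printed ranges share
endpoints, so the package fixes the convention Low = [10, 100],
Middle = (100, 500], High = (500, Inf): the strict ">" of the High
definition is preserved, 100 belongs to Low. Any consistent convention
would do; this one is documented and tested. A separate
differential-expression filter calls genes up/down when
|ln((treated + 0.1)/(control + 0.1))| exceeds 0.2; it is deliberately
*not* chained into read-through calling, because its role relative to
the tiering is a composition choice best left to the analyst — both are
exposed as composable gene-list operations.

**Read-through calls.** A gene is dropped as `excluded_overlap` when
another gene on the same strand intersects its downstream window with
condition-mean body FPKM ≥ 1 in either condition: whatever signal the
window holds cannot be attributed to read-through. (A flag extends
exclusion to both strands for unstranded reanalyses; a second flag also
drops genes lying inside another gene's window, the alternative reading
of the removal rule.) A gene is `excluded_low` when the *larger* of the
two condition means of read-through FPKM is at or below 0.5 — the floor
is applied to the larger mean so that a gene silent in control but
expressed after perturbation remains callable, which is precisely the
gain-of-read-through signature of interest. Remaining genes get
fold = mean over replicate pairs of (treated_i + 0.1)/(control_i + 0.1),
`up` above 1.4, `down` below 0.5, else `unchanged`. The 0.1-FPKM
pseudocount stabilizes ratios near zero and is configurable.

**Metagene profiles.** Fixed-anchor profiles lay 50-bp bins 5'→3' in
transcript orientation around the TSS or TTS; each bin is tags per
million, genes are weighted equally in the per-bin mean (the plainest
reading of averaging expression per bin), and bins beyond a chromosome
edge are missing rather than zero, with the mean dividing by the number
of contributing genes. The body-scaled metagene stretches each gene into
60 equal slices between fixed 3-kb flanks; tags are split fractionally
across slice boundaries and slice values are width-rescaled densities
(per 50-bp equivalent), so uniform coverage produces a flat profile
regardless of gene length — the package documents this rescaling
because the original body-scaling tool did not specify its own. The
8-kb anchor-centred per-gene matrix (160 columns) uses the same binning;
its column means equal the average profile exactly, an identity the
tests assert.

**Statistics.** The two-sample Kolmogorov–Smirnov test computes D
exactly over the pooled points and takes its p-value from the
asymptotic Kolmogorov series with effective size n1·n2/(n1+n2); exact
small-sample p-values are out of scope, and the suite verifies the
asymptotic size empirically (rejection rate at 0.05 within [0.03, 0.07]
under the null at n = 50). Fisher's exact test enumerates all tables
with the observed margins (r·c ≤ 9, total ≤ 500) and sums the
probabilities not exceeding the observed one — the standard
probability-ordering two-sided definition. The t-test defaults to
Welch's unequal-variance form, since nothing in the analysis licenses
equal variances; the pooled form is a flag. Co-occupancy uses Pearson
correlation of binned genome-wide tracks with average-linkage leaf
ordering on distance 1 − r. The pipeline's default KS comparison is
between the two conditions' per-bin average profile vectors over the
downstream region; a per-gene mode (read-through FPKM vectors) is also
provided, and the run report records which was used.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

* 300 single-exon genes tiled on one chromosome; gene lengths uniform
  on 1–4 kb; ordinary intergenic gaps uniform on 6–12 kb (beyond the
  5-kb window, so ordinary neighbours cannot contaminate), and 20% of
  junctions "closely spaced" — strand-matched with gaps of 0.2–4 kb —
  to exercise the exclusion rule. The truth table records the geometric
  flag per gene.
* Tier mix 5/15/50/30% across High/Middle/Low/No, with per-tier base
  FPKM 800/250/40/3 and lognormal jitter (sdlog 0.35). Body FPKM is
  equal across conditions; the perturbation acts only on read-through.
* Each transcript extends past its TTS with probability rho (baseline
  0.15); affected genes (50 of 300) multiply rho by `rho_fold`
  (default 3) in the treated condition. Extension lengths are uniform
  on (0, 5 kb], and the fragment start is uniform on the extended
  transcript, which makes aggregate downstream coverage slope off with
  distance without an extra shape parameter — the qualitative form seen
  in real read-through profiles.
* Fragment counts are Poisson with mean FPKM · (L/1000) · (depth/10^6).
  With two replicates per condition, as modelled here, overdispersion
  is not identifiable, and Poisson keeps every oracle closed-form.
* Two replicates per condition and a depth of 10^7 fragments per
  library. The depth mirrors 50-bp-read sequencing at roughly 50-fold
  body coverage for a mid-expression gene (FPKM 100 gives about one
  fragment start per exonic base); at that depth the fold thresholds
  separate a 3-fold rho change from Poisson noise comfortably.
* `library_size` defaults to the nominal depth rather than the stored
  tag count: the simulated genes are a slice of a transcriptome, and
  treating the slice as the whole library would inflate every FPKM by
  an order of magnitude and detach the absolute thresholds (tier
  bounds, the 0.5-FPKM floor) from their intended scale. A
  `library_size_mode = "stored"` switch restores the self-contained
  interpretation, under which stored tags equal the library size
  exactly (and the suite checks that conservation).

What the generator does *not* model: sequencing error, GC and
fragment-length bias, splicing noise, negative-binomial overdispersion
(available as nothing — by design), antisense leakage, and multi-isoform
structure (a multi-exon toggle exists solely to exercise exon-aware
counting). Passing tests therefore demonstrate the correctness of the
counting, classification, profiling and testing machinery under the
stated statistical model — not robustness to every artefact of real
libraries.

## Numerical and design choices

* Read-through fraction recovery: the density ratio r = rt_FPKM /
  body_FPKM inverts analytically to
  rho = r·W / (g·(L + r·W)) with g = 1 − (L/D)·log((L+D)/L), the
  expected fraction of a read-through transcript's fragments landing
  past the TTS under uniform placement. `estimate_rho()` implements
  this; on eligible genes (body FPKM ≥ 10, window and body free of
  neighbours) it recovers the simulated rho to within a few percent.
* Ties in tier bounds, bin edges and windows are all resolved by the
  half-open convention; there are no epsilon comparisons in counting.
* Degenerate inputs: empty replicate vectors, zero-length features,
  zero library sizes, unstranded records and negative kernel heights
  are errors; an unknown chromosome in counting yields 0 with a
  warning, because a library may legitimately lack a contig.
* Determinism: every stochastic step derives its stream from the
  configured seed (per-library streams are decoupled from call order),
  and the pipeline writes an md5 manifest so identical runs are
  byte-comparable.
* Problem sizes in the test-suite simulations (60–300 genes, depths of
  10^6–10^7, 10 seeds for recovery studies) were chosen so each
  statistical check has comfortable power while the whole suite stays
  quick to run routinely.

## Workflow layout

The numbered scripts under `analysis/` run the study end to end
(simulate → quantify → classify → metagene → stats), each a thin driver
over the package functions, printing what it found and writing tables
under `results/`; bulky regenerable raw data goes to `scratch/`. The
same stages are available as a single call, `run_pipeline()`, driven by
a validated configuration (`validate_config()`) that rejects unknown
keys and records every filled default.

## Known limitations

* Read-through FPKM counts every tag in the window, including tags of
  annotated downstream features; the analysis handles contamination by
  *removal* (the exclusion rule), not subtraction, mirroring the
  procedure it implements. Windows may be anchored at an alternative
  poly(A) site instead of the annotated TTS by editing the gene models
  before quantification.
* KS p-values are asymptotic; for very short profile vectors they are
  conservative.
* Fisher enumeration is exponential in table size; it refuses tables
  beyond r·c = 9 or totals above 500 rather than approximating.
* The exclusion rule and the strand-specific counting assume a clean
  strand-specific protocol; `both_strands = TRUE` emulates unstranded
  reanalysis but cannot recover strand-confounded signal.
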