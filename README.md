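# readthru

Detection of transcription read-through — the signature of 3'UTR
lengthening by alternative polyadenylation — from strand-specific
RNA-seq, as a tested R package plus a reproducible analysis workflow.

## What it does, for whom

When 3'-end processing is perturbed (e.g. knockdown of a factor that
promotes termination), poly(A)+ RNA-seq shows signal running past the
annotated transcription termination site (TTS) into downstream
sequence. This package is for analysts who want to quantify and compare
that signal between two conditions:

* **Quantify**: per gene and library, body FPKM over exons and
  read-through FPKM in the 5-kb (or 3-kb) window downstream of the TTS,
  counting strand-matched fragment 5' ends in 0-based half-open
  coordinates. FPKM = count / (L/1000) / (N/10^6) for feature length L
  and mapped-library size N.
* **Classify**: expression tiers on control body FPKM (High > 500,
  Middle 100–500, Low 10–100, No < 10); an ln-fold-change filter at
  |ln FC| > 0.2; read-through calls from the replicate-pair mean fold
  (trt + ε)/(ctrl + ε) with ε = 0.1 FPKM — *up* above 1.4, *down* below
  0.5 — applied only to genes whose read-through FPKM exceeds 0.5 and
  whose downstream window is free of an expressed same-strand
  neighbour (such genes are excluded as confounded).
* **Profile**: 50-bp binned, tags-per-million metagene profiles
  anchored at the TSS/TTS; body-scaled metagenes (3-kb flanks, 60 body
  slices); 8-kb anchor-centred per-gene matrices ordered by expression.
* **Test**: two-sample Kolmogorov–Smirnov (exact D over pooled points,
  asymptotic p with effective n = n1·n2/(n1+n2)); exact Fisher on small
  r×c tables (probability ordering, full enumeration); Pearson
  co-occupancy matrices with average-linkage leaf order; two-tailed
  Welch t-test.
* **Simulate**: a first-class generator of annotation, ground truth and
  stranded tag libraries with a controlled read-through perturbation,
  so the entire pipeline is validated offline. See the methods vignette
  (`vignettes/readthrough-analysis.Rmd`) for the model and defaults.

## Worked example

The numbered scripts under `analysis/` run the full study; each prints
what it found and writes tables under `results/` (bulky raw data under
`scratch/`). `Rscript analysis/01_simulate.R` through
`analysis/05_stats.R` print, on the default configuration (seed 42):

```
simulated 300 genes on a 4.81-Mb chromosome
50 affected genes, 53 close-packed genes
...
read-through calls: up=31, down=0, unchanged=141, excluded_overlap=53, excluded_low=75
tiers (control): High=8, Middle=50, Low=153, No=89
up-call sensitivity on eligible affected genes: 1.000 (n=28)
false-discovery proportion among up calls: 0.032 (n=31)
...
mean downstream-of-TTS signal: control 0.210, treated 0.282
...
Welch t on affected genes: t = -2.25, p = 0.0315
Fisher on affected x up-call: p = 1.04e-32
co-occupancy of replicate ChIP-like tracks: r = 0.990
```

That is: of 300 simulated genes, the 50 genes whose read-through
fraction tripled are recovered essentially perfectly (every eligible
affected gene is called *up*; 1 of 31 up-calls is a false discovery),
genes with a confounding neighbour are set aside rather than miscalled,
and the treated condition's averaged downstream-of-TTS signal rises by
the expected ~3/10ths.

The same stages run as one call:

```r
library(readthru)
report <- run_pipeline(
  list(simulation = list(n_genes = 300L), seed = 42L),
  out_dir = "scratch/run")
report$call_summary
```

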