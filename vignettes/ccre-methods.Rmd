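---
title: "Methods: building and classifying a cCRE registry"
author: "ccregistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and classifying a cCRE registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `ccregistry`, the parameters that
matter, the numerical conventions the implementation commits to where more
than one reasonable choice exists, and what the synthetic benchmark does and
does not demonstrate.

## The model

The registry treats accessible chromatin as the anchor signal. A DNase-seq
peak marks a candidate element; overlapping peaks from different experiments
are assumed to describe the same underlying element, so the pooled peak set
is reduced to **representative DHSs (rDHSs)** by a greedy argmax: the
highest-signal peak wins, absorbs everything it overlaps by at least one
base pair, and the loop repeats on the remainder. Two properties follow by
construction and are asserted as tests: the rDHS set is pairwise
non-overlapping, and every input peak overlaps at least one rDHS. Because
absorption only happens through overlap, the greedy loop restricted to a
connected overlap component is equivalent to the global loop; we verify this
output-equivalence against a brute-force implementation (which re-sorts the
full remaining set each iteration) on randomized instances rather than
assuming it.

Raw signals are not comparable across biosamples: DNase tracks are
depth-normalized read counts while ChIP tracks are fold change over input,
and even uniformly processed tracks differ in range. The pipeline therefore
standardizes within biosample: each assay's track is averaged over every
rDHS, log10-transformed, and converted to a Z-score against all other rDHSs
in the same biosample. The working assumption — approximately lognormal
background signal — makes the 95th-percentile threshold interpretable:
*Z* > 1.64 flags roughly the top 5% of rDHSs per biosample per assay. The
per-assay **max-Z** across biosamples then says "this element is high for
this mark *somewhere*", which is what a cell-type-agnostic registry needs.

Classification is a fixed decision table over the high/low state of
H3K4me3, H3K27ac and CTCF plus the distance *d* from the element's centre
to the nearest TSS:

| priority | condition | group |
|---|---|---|
| 1 | *d* ≤ 200 and high H3K4me3 | PLS |
| 2 | high H3K27ac and (*d* > 2000 or low H3K4me3) | pELS (*d* ≤ 2000) / dELS |
| 3 | high H3K4me3 | DNase-H3K4me3 |
| 4 | high CTCF | CTCF-only |

## Design choices at genuinely open points

**Priority of promoter identity.** The group definitions alone leave
multi-high states ambiguous (e.g. high H3K4me3 + H3K27ac + CTCF within
200 bp of a TSS), and read literally they leave the state (high H3K4me3,
high H3K27ac) at 200 < *d* ≤ 2000 with no group at all: the enhancer
definition demands low H3K4me3 near a TSS, and the DNase-H3K4me3 definition
demands low H3K27ac. The table above resolves both by ordered evaluation
with promoter identity dominating — the only ordering we found under which
the five groups are mutually exclusive *and* exhaustive over the seven
promotable states. The 21-row truth table in the test suite freezes this
choice.

**"Low relative H3K4me3"** for near-TSS enhancers is implemented as the
absolute threshold *Z* ≤ 1.64, not a ratio to H3K27ac, keeping a single
threshold vocabulary across the whole classifier.

**Band boundaries are inclusive above**: *d* = 200 is TSS-overlapping and
*d* = 2000 is proximal. The threshold itself is strict (*Z* must exceed
1.64), so a score of exactly 1.64 is low; a property test asserts the flag
flips at 1.64 + ε.

**Percentile floor.** The peak signal floor is the nearest-rank percentile
of the pooled signals of *all* experiments (rank ⌈*p*/100·*n*⌉), with
strict comparison; a floor of 0% imposes no constraint.

**Ties in the greedy loop** are broken by lowest (chrom, start, end,
experiment id). Any deterministic total order would do; this one makes the
output invariant to input permutation, which a property test checks.

**Standard deviation convention.** μ and σ are computed over the log10 of
the *nonzero* signals only, with the population (divide-by-N) σ. Zeros
cannot enter a log-scale mean, so their exclusion is forced; they are
reported with the sentinel *Z* = −10, far below any attainable real score.
At registry scale the population-vs-sample distinction is numerically
immaterial; population σ is used consistently in code, oracle and tests.

**Window clipping.** Histone windows (rDHS ± 500 bp) are clipped at
position 0; the denominator is the clipped window width. Positions beyond a
track's last record read as zero coverage and still count in the
denominator, matching how genome-wide signal files are averaged over BED
intervals. Right-clipping at a chromosome end would need chromosome sizes,
which bedGraph does not carry; for bedGraph-backed tracks the
beyond-last-record convention already yields the correct zeros.

**Tiers.** Tier assignment keys on the *pertinent* mark of the group call
(H3K4me3 for PLS and DNase-H3K4me3, H3K27ac for pELS/dELS, CTCF for
CTCF-only). Elements whose support never co-occurs appropriately fall into
a single "excluded" bucket and are dropped from the registry; the internal
sub-structure of excluded elements is not reproduced.

**TSS definition.** TSSs are the 5′ ends of transcripts carrying a
configurable GTF tag (default `"basic"`), de-duplicated by exact position.
Strand is retained for reporting, but distances are plain genomic
distances.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `z_threshold` | 1.64 | Z | high/low cutoff; round(qnorm(0.95), 2) |
| `signal_floor_pct` | 10 | percentile | global peak signal floor |
| `width_min`, `width_max` | 150, 350 | bp | retained peak widths |
| `fdr_max` | 1e-3 | rate | strict FDR cutoff |
| `tss_near` | 200 | bp | TSS-overlapping band |
| `tss_proximal` | 2000 | bp | proximal/distal split |
| `flank_histone` | 500 | bp | H3K4me3/H3K27ac averaging flank |
| `zero_sentinel` | −10 | Z | zero-raw-signal marker |

All are manifest-overridable; the run report records effective values.

## The synthetic benchmark

The generator (`sim_config()`, `simulate_registry_inputs()`) emulates the
*signal structure* the classifier assumes, not sequencing: flat-top signal
rectangles over planted elements (the classifier consumes window means, so
peak shape is irrelevant), lognormal background drawn independently per
locus, biosample and assay, multiplicative elevation of the class-specific
marks, per-biosample jittered peaks, and decoy peaks at background signal.
ChIP marks at unbound loci drop to zero coverage with probability
`mark_zero_prob`, exercising the sentinel path.

Default study conditions: 10 planted elements per class, effect size 8,
log10-background σ 0.3, 4 fully covered biosamples. The free layout
parameters were fixed once from a power analysis of the Z-score mixture:
with a decoy rate of 2.5×10⁻⁴/bp on a 2-Mb toy genome (~350 decoys
after spacing), the planted fraction of each per-assay Z vector stays near
0.05–0.12, so elevated loci sit 2–3 population SDs above the mean while
background loci rarely clear 1.64 in any of four biosamples. Elements sit
on a 12-kb grid with class-specific TSS offsets (0 bp for PLS, 1 kb for
pELS and DNase-H3K4me3, 4 kb for dELS and CTCF-only), which makes truth
labels well-defined by construction.

What passing recovery tests show: the pipeline's filters, normalization and
decision logic compose correctly, and the documented conditions give ≥ 90%
per-class recall and precision. What they do **not** show: performance on
real data, where background is heavy-tailed and spatially autocorrelated,
signal is correlated across biosamples, peak calling itself is noisy, and
assay coverage is sparse. The generator's independence assumptions make the
max-Z operator *harsher* than in real data in one respect — independent
noise across biosamples inflates the max — and milder in others (no
systematic batch structure).

The no-elevation calibration (effect size 1) checks that planted loci are
not promoted above the decoy false-positive rate. Because planted and decoy
loci are exchangeable under no elevation, the two observed rates are equal
in distribution, so the check is formalized as a one-sided exact test
(Fisher, α = 0.01) that the planted rate is not significantly greater — the
statistical content of "no more than" for two finite samples.

## Problem sizes and runtime

The test suite runs the full benchmark once per effect-size condition
(~1,500 peaks, ~375 rDHSs, 16 tracks), the oracle-equivalence suite on 200
random instances of ≤ 50 peaks, and the exhaustive decision-table
enumerations; the whole suite completes in about a minute on one CPU. These
sizes were chosen as the smallest at which every failure mode the tests
target (mixture inflation of σ, spurious max-Z highs, tie-breaking,
boundary bands) is actually exercised.

## Known limitations

- Peaks are inputs; the upstream peak caller (and its FDR machinery) is out
  of scope, as are consensus-DHS derivation, silencer categories,
  target-gene linkage and cross-species orthology.
- Signal tracks are text bedGraph; bigWig input would need a thin adapter.
- μ/σ exclude zero-signal rDHSs. A production registry built with a
  pseudo-count convention instead would shift all Z-scores slightly; this
  is the one numerical divergence risk against externally produced
  matrices.
- The per-biosample "mark-flag" labels for biosamples lacking DNase are
  reports, not positional group calls — without accessibility there is no
  element resolution.
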