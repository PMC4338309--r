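---
title: "Designing and evaluating species-specific eDNA assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating species-specific eDNA assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednassay)
```

## The problem

Environmental DNA (eDNA) surveillance detects an aquatic species from
the DNA it sheds into water. The assay at the core of such a program is
a PCR reaction that must satisfy three competing demands:

* **coverage** — it must amplify every haplotype of the target species,
  so primer sites must fall in regions with no within-species
  variation;
* **specificity** — it must amplify no co-occurring relative; in
  closely related cyprinids the mitogenomes differ at only a few
  percent of sites, and usable differences must be *clustered* so that
  several fall inside one primer's footprint;
* **sensitivity** — field samples hold degraded, low-copy DNA, so
  amplicons are kept short (< 400 bp) and reactions are replicated
  (four replicates per sample is the convention this package adopts as
  its default).

`ednassay` covers the computational workflow around these demands:
scanning an alignment for diagnostic regions, assembling candidate
assays, screening them in silico, quantifying template copies from
qPCR standard curves, and summarising replicate-level detection data.

## Diagnostic-window scanning

The input is an `aligned_panel`: a gapped multiple sequence alignment
with a group label per record (target species groups and a panel of
non-target relatives). For a window $w$ of primer length, the package
requires *zero within-target variation* — a column with more than one
distinct non-gap, non-N base among target members disqualifies the
window — and scores discrimination as

$$\mathrm{score}(w) \;=\; \min_{s \,\in\, \text{non-targets}}
\#\{\,j \in w : \text{base}_s(j) \text{ cannot pair with the target
consensus at } j\,\}$$

The **minimum** is the deliberate design choice here: cross-
amplification of even a single non-target species invalidates a
marker (initial marker panels in practice lose the majority of their
candidates to exactly this), so a window is only as good as its
discrimination against its *closest* non-target. The alternative —
averaging over non-targets — would let one divergent species mask a
dangerous identical one.

Decisions the alignment scan takes where the underlying procedure is
genuinely open:

* **Window length** defaults to 20 columns, a typical primer length;
  the published assays' oligos span 18–29 nt.
* **Gap/N handling**: a gap or N in any *target* member makes a column
  ineligible for primer placement (a primer must bind intact target
  sequence); a gap in a *non-target* counts as a difference (the
  non-target simply lacks pairable sequence there).
* **Consensus**: per column, the minimal IUPAC code covering all
  observed target bases. A non-target base "differs" when its base set
  does not intersect the consensus set, so the scan is conservative in
  the presence of ambiguity codes.
* **Tie-breaking** is deterministic: more worst-case differences in
  the 3′-terminal five bases, then stronger GC clamp, then leftmost
  coordinate.

`design_assays()` pairs windows (forward = consensus of the upstream
window; reverse = reverse complement of the downstream one) subject to
an amplicon cap of 400 bp — *inclusive of both primers*, the
convention used throughout the package — and a melting-temperature
envelope. Candidates are ranked by summed worst-case discrimination,
rewarding primers whose 3′-terminal window carries a non-target
mismatch, because a mismatch at the extension end is what actually
blocks amplification. Hydrolysis-probe (TaqMan) candidates require a
third discriminative window strictly between the primers: specific
binding at three sites rather than two is what makes probe-based qPCR
the more stringent assay format. Both primers (and the probe) are
required to carry at least one worst-case difference — a pair where
only one oligo discriminates would rest its specificity entirely on a
single site.

## Melting temperature

The package uses the basic GC-fraction formula

$$T_m = 64.9 + 41\,\frac{n_{GC} - 16.4}{N}$$

for oligos of ≥ 14 nt, with the Wallace rule $2(A{+}T) + 4(G{+}C)$ as
the short-oligo fallback. This is intentionally *not* a
nearest-neighbour thermodynamic model: its role is the coarse
screening question — is a primer's $T_m$ anywhere near the assay's
annealing temperature? It is sharp enough to expose, for example, a
legacy monitoring primer whose basic $T_m$ of ~37 °C sits 13 °C below
its assay's annealing step, a plausible cause of its field failures.
Degenerate positions count toward $n_{GC}$ only when *all* their
possibilities are G/C (S yes; R, Y, W, K, M, N no), giving a
conservative lower bound. Reported values are rounded half-up (one
decimal in tables, integer in summaries); half-up is used everywhere a
printed rate or temperature is reproduced, because that is how such
numbers are conventionally typeset.

## In-silico PCR

Binding-site search uses a substitution-only model: an oligo of length
$L$ binds a template stretch of exactly $L$ bases (no bulges), with
IUPAC codes matching by base-set intersection and gaps matching
nothing. Defaults for specificity screening are **max 2 mismatches per
oligo** and **a 3′-terminal mismatch disqualifies a site**. Wet-lab
screens do not report a crisp mismatch threshold separating
"amplifies" from "does not"; these two defaults are this package's
modelling decision, surfaced as arguments (`max_mm`,
`allow_3prime_mm`) so users can probe their sensitivity. Probes are
exempt from the 3′ rule (they are hydrolysed, not extended) and may
sit on either strand.

Templates are circular by default — mitochondrial genomes are circles,
and an amplicon may legitimately span the sequence origin
(`spans_origin`). Product length is counted inclusive of both primers,
and both template orientations are searched; predicting on the
reverse-complemented template yields the same products with strands
swapped, which the test suite asserts.

## Quantification

Plasmid-standard copies from mass use 650 Da per double-stranded base
pair and $N_A = 6.022\times10^{23}$, exactly the bench arithmetic, with
no end-group correction. Standard curves are ordinary least squares of
Cq on $\log_{10}$(copies); replicate wells enter as individual points
so the fit's $R^2$ (squared Pearson correlation) reflects replicate
variance rather than averaged means. Efficiency is
$10^{-1/\text{slope}} - 1$; a slope of $-\log_2 10 \approx -3.3219$
cycles per decade is exactly 100% (template doubles each cycle). A
fitted curve is an S3 object with `tidy()`, `glance()` and
`autoplot()` methods.

## Detection statistics

A sample is scored positive for a marker if **any** replicate is
positive; a qPCR replicate is positive when its Cq is numeric and
within the 40-cycle limit. Dilution-series sensitivity reports the
detection proportion per level, and the limit of detection uses a
**monotone-prefix** rule: the LOD is the most dilute level satisfying
the chosen rule (`all_replicates` = proportion 1, `majority` ≥ 0.5,
`any` > 0) with every more-concentrated level also satisfying it.
Real dilution series are not monotone at the bottom — single
replicates amplify at $10^{-6}$ after an all-negative $10^{-5}$, a
known signature of PCR stochasticity near one template copy per
reaction — and the prefix rule keeps such hits from extending the
reported LOD while their raw proportions remain visible.

Per-marker rates use per-marker denominators (NA cells — a marker
tested on fewer samples — shrink its own `n`, not the table's).
Multi-marker analysis reports the union count, per-marker exclusive
counts, and the any-marker total: in field data the union of two good
markers detects meaningfully more samples than either alone, because
degradation can destroy one marker locus in a sample while sparing
another.

## Synthetic data: what it does and does not show

`generate_panel()` is the package's test bed. Its defaults are the
study conditions the package is built around: **0.2%** of columns
variable within a target species, **5%** divergence between species,
substitutions only (so alignment length equals genome length, as in
the real carp alignment), and diagnostic differences planted as
clusters of 3 within 25-column windows shared by every non-target.
Sample sizes default to 6 + 4 target genomes and 5 non-target species,
a scaled-down version of the real panels chosen to keep the test suite
fast while preserving the worst-case-minimum structure; generation is
fully seeded and returns a ground-truth record (every planted variable
column and window), so recovery is checked against truth, not against
the scanner's own output.

What passing these tests shows: the scanner, designer and screener
recover planted signal exactly under the stated variation structure.
What they do not show: performance on real data with rate
heterogeneity, indels, alignment error, or eDNA degradation — none of
which the generator emulates. The published reference genomes are not
packaged, so checks against the deposited carp mitogenomes (the 14
printed amplicon lengths, the 34/40/823 variable-site counts) are
exercised structurally instead, on synthetic templates that embed each
published assay's own oligos at the printed spacing.

qPCR simulation (`generate_qpcr_run()`) draws
$C_q = \text{slope}\cdot\log_{10}(\text{copies}) + \text{intercept} +
\mathcal{N}(0, \sigma)$ with per-well dropout probability; with
$\sigma = 0$ and no dropout the standard-curve fitter recovers the
generating parameters exactly, and empirical dropout rates converge on
the specified probabilities.

## Numerical and interface conventions

* All user-facing tibbles report 1-based inclusive coordinates;
  `mismatch_profile()` positions are 0-based offsets from the oligo 5′
  end (offsets, not coordinates).
* `"no-amp"` in a Cq column on disk ↔ `NA` in memory.
* Deterministic outputs everywhere: fixed tie-breaks in ranking,
  mandatory seeds in generators.
* Problem sizes in the test suite (panels of ~0.5–2 kb, 150 + 60
  brute-force property cases) are chosen so the whole suite runs in
  about a minute while still exercising every code path against
  independent oracles.

## Known limitations

* No thermodynamic (nearest-neighbour, salt-corrected) $T_m$, no
  primer-dimer or hairpin checks — candidates from `design_assays()`
  should still go through a thermodynamic design tool before synthesis.
* The binding model has no indels and no amplification-efficiency
  prediction; a predicted product means binding is *possible*, not
  efficient.
* The LOD rules operate on observed proportions; no hierarchical
  occupancy modelling of detection probability.
* Alignment construction is out of scope: the package consumes
  pre-aligned FASTA.
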