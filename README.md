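# ednassay

Design and evaluation of species-specific environmental DNA (eDNA) PCR
assays in R.

Monitoring programs for aquatic invasive species — the motivating case
is bighead and silver carp (*Hypophthalmichthys nobilis* and
*H. molitrix*) in North American waterways — detect a species from the
traces of DNA it sheds into water. That requires PCR assays that (i)
amplify every haplotype of the target species, (ii) amplify nothing
else in the local fish community, and (iii) stay sensitive down to a
handful of template molecules per reaction. `ednassay` implements the
computational side of building and validating such assays from
whole-mitogenome alignments, for molecular ecologists and eDNA
monitoring programs.

## What it computes

**Diagnostic-window scanning.** Given an alignment of target and
non-target mitogenomes, every window of primer length is scored only if
it is invariant within the target group (a primer must bind all target
haplotypes); its score is the worst-case discrimination

```
score(w) = min over non-target sequences s of
           #{columns in w where s cannot base-pair with the target consensus}
```

the minimum because a single cross-amplifying species invalidates a
marker. `design_assays()` pairs high-scoring windows into candidate
primer pairs (amplicon < 400 bp, inclusive of both primers; melting
temperatures within a set envelope), with hydrolysis-probe (TaqMan)
candidates additionally requiring a probe window strictly between the
primers.

**IUPAC-aware in-silico PCR.** `find_sites()` and
`predict_amplicons()` search both strands of linear or circular
templates for primer binding sites under a substitution-only mismatch
model (degenerate bases match by base-set intersection). A mismatch at
a primer's 3′-terminal base blocks a site by default — the extension-
blocking mechanism that species-specific primers exploit.
`specificity_matrix()` screens an assay panel against a species panel:
an assay passes when it amplifies all target templates and no
non-target template.

**Quantification.** Plasmid-standard copy numbers from mass
(`copies = mass / (length × 650 Da/bp) × 6.022e23`), least-squares
standard curves of Cq on log10(copies) with
`efficiency = 10^(−1/slope) − 1`, Cq→copies inversion, and single- vs
multiplex-reaction Cq comparison. Curve fits are tidyverse-friendly:
`tidy()`, `glance()`, `autoplot()`.

**Detection statistics.** Replicate-level positive calls (positive if
any of the — typically four — replicates crosses the threshold within
40 cycles), dilution-series detection proportions and limits of
detection under a monotone-prefix rule, per-marker detection rates,
multi-marker union/complementarity analysis, and false-positive checks
on designated negative samples.

**Synthetic data.** Seeded generators for mitogenome panels with
controlled within-/between-species variation and planted diagnostic
windows (with a ground-truth record), and for qPCR runs with noise and
dropout — the test bed for everything above.

The tables of the published carp assay panel ship with the package:
`ednassay_example("table3_assays.tsv")` (14 assays),
`qapp_markers.tsv` (the legacy monitoring markers), and the field,
sensitivity and multiplex results tables.

## Worked example

```r
library(ednassay)

# the legacy bighead-carp monitoring primer melts far below its
# 50 degC annealing temperature -- one reason it underperforms in the field
qapp <- read_assay_table(ednassay_example("qapp_markers.tsv"))
round_half_up(basic_tm(qapp$forward[qapp$name == "QAPP-BH"]), 1)
#> [1] 37.4

# synthetic study: two target species + 5 non-targets, 0.2% within- and
# 5% between-species variation, two planted diagnostic windows
g <- generate_panel(ref_length = 1500, n_target_a = 6, n_target_b = 4,
                    n_nontarget = 5, n_diagnostic_windows = 2,
                    window_starts = c(600, 800), seed = 2001)
w <- scan_windows(g$panel, "A", win_len = 20)
head(w[, 1:4], 2)
#>   start   end within_target_variable min_nontarget_diffs
#> 1   605   624                      0                   3
#> 2   801   820                      0                   3

# the top-ranked windows sit in the planted regions (600-624, 800-824);
# pair them into an assay and screen it against the panel
cand <- design_assays(g$panel, "A")
cand[1, c("name", "forward", "reverse", "amplicon_length", "score")]
#> 1 A-cand-001 CGTTCCGGTAACTGTACTCC CCTTGTACCGGTGCATATGT      222     6

summarise_specificity(specificity_matrix(cand[1, ], g$panel, max_mm = 2))
#>   assay      n_target n_target_amplified n_nontarget n_nontarget_amplified passes
#> 1 A-cand-001        6                  6           9                     0 TRUE

# a perfect-efficiency standard curve: slope -3.3219 cycles/decade
d <- data.frame(copies = 10^(1:6), cq = -3.3219 * (1:6) + 40)
fit_standard_curve(d)
#> <standard_curve> Cq = -3.3219 * log10(copies) + 40
#> R2 = 1, efficiency = 100%, n = 6
```

The candidate amplicon (222 bp) spans both planted windows; the score
of 6 is the summed worst-case non-target differences of the two primer
sites, and the specificity screen confirms it amplifies all six target
copies and none of the nine non-target sequences.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
$(Rscript -e 'cat(system.file("exec/ednassay", package="ednassay"))') \
  oligostats --assays assays.tsv --out metrics.tsv
```

Subcommands: `scan`, `design`, `oligostats`, `insilico-pcr`,
`quantify`, `detect`, `sensitivity`, `combine`, `synth`.

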