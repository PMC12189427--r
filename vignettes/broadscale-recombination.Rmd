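---
title: "Broad-scale recombination maps from MLH1 foci and their association with genomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broad-scale recombination maps from MLH1 foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytorec)
```

## The problem

In pachytene oocytes, each crossover is visible as an MLH1 focus on the
synaptonemal complex (SC), the proteinaceous axis joining the paired
homologs. Scoring focus positions along the SC axes of many cells gives a
direct, sequencing-free picture of where crossovers happen on each
chromosome. Bird karyotypes make this especially informative: their few
large macrochromosomes show strikingly different crossover landscapes
between species — from chicken-like landscapes (rates elevated near the
ends but substantial recombination throughout) to strongly *polarized*
landscapes (most crossovers packed into the distal fifth, with
recombination deserts in the middle, as in the guinea fowl).

`cytorec` turns per-cell focus observations into broad-scale recombination
rate maps and asks whether interval-scale genomic features — GC content,
CpG-island density, gene density — track the recombination landscape.

## From axis coordinates to genomic intervals

At pachytene the DNA packing ratio along the axis is approximately
constant, so a focus at fraction $f$ of the axis length sits near genomic
position $f \cdot L$, where $L$ is the assembly length. The package keeps
all genomic coordinates 0-based half-open with the short-arm tip at 0;
chromosomes whose assembly runs the other way are flagged `inverted` and
fractions are reflected ($f \to 1-f$) before scaling.

Each chromosome is tiled into fixed intervals (default 2.5 Mb, roughly the
0.3 µm resolution limit of focus scoring on digitized SC images). The
interval count uses ceiling division and the trailing partial interval is
kept: a 194.4 Mb chromosome yields 78 intervals, the last one short. A
position exactly at $L$ closes into the final tile.

Focus positions recorded in micrometres are normalized by **that cell's
own SC length**, not the species mean: axis length varies substantially
between cells, and per-cell normalization is what makes fractions
comparable across cells. This was a genuinely open choice; the proportional
scaling argument holds per cell, so per-cell normalization is the
consistent reading.

## Foci to centimorgans

With $N$ cells scored and $f_i$ foci in interval $i$,

$$\mathrm{cM}_i = \frac{50\, f_i}{N}, \qquad
  \mathrm{rate}_i = \frac{\mathrm{cM}_i}{\ell_i / 10^6},$$

where $\ell_i$ is the interval's **true** length in bp. Dividing the
trailing partial interval by its true length (not the nominal grid size)
keeps rates comparable across intervals; this choice is not derivable from
the published descriptions, which say only "interval size in Mb". The
identity $\sum_i \mathrm{cM}_i = 50 \cdot (\text{total foci})/N$ holds for
any grid, and the suite asserts it to machine precision. Boundary ties
follow the half-open convention. Arm-restricted comparisons (needed where
one species' chromosome corresponds to an arm of the other's) are bp-range
masks applied to the interval grid before correlation.

## Feature tracks

**GC content** is $(C+G)/(A+C+G+T)$ per interval, case-insensitive, with
`N` excluded from both numerator and denominator; an all-`N` interval is
flagged missing rather than zero. GC windows equal the analysis intervals
directly — no separate window/shift mechanics.

**CpG islands** are called from sequence under Gardiner-Garden-style
criteria: length strictly greater than 200 bp, GC $\ge 0.5$, and
observed/expected CpG $\ge 0.6$ with
$\mathrm{obs/exp} = N_{CpG} \cdot L / (N_C N_G)$. The caller slides a
200 bp seed window at 1 bp steps, merges runs of qualifying windows
(windows containing `N` are disqualified), re-merges window-extended spans
that overlap, and within each span extracts maximal qualifying regions by a
leftmost-longest greedy search. Two consequences of this definition are
worth knowing:

* It is *not* equivalent to an unrestricted maximal-region search: a
  qualifying region whose leading stretch contains no qualifying 200 bp
  window will be missed. The test suite's brute-force oracle therefore
  implements the same two-phase definition by naive exhaustive search, and
  the caller must match it exactly on hundreds of random sequences.
* "Trimmed to the maximal qualifying extent" means islands absorb flanking
  low-GC sequence up to the point where GC would drop below 0.5 — a CpG
  repeat of 150 bp flanked by poly-A becomes a 300 bp island at GC exactly
  0.5. Only stretches whose maximal extension cannot exceed 200 bp are
  dropped.

The results are documented as Gardiner-Garden-style; they are not
bit-identical to any particular genome-browser dialect (whose
extension/trimming heuristics differ). Islands are assigned to intervals by
their start coordinate, mirroring gene-start counting and avoiding double
counting across boundaries.

**Gene density** counts gene start positions per interval, where a gene's
start is its lower genomic coordinate on either strand (a deliberate
simplification: for minus-strand genes this is the 3' end, but at 2.5 Mb
resolution the difference is immaterial and the uniform rule is
reproducible). Per chromosome, gene counts are also expressed as
percentages of the chromosome total, which sum to 100 by construction.

## Association

Associations are Spearman rank correlations of per-interval rate against
each feature, per chromosome and pooled across a named chromosome set
(typically the largest ones). Intervals with missing GC are excluded
pairwise. For strongly polarized landscapes, intervals with *zero*
recombination can dominate the ranks (zero inflation); `nonzero_only` mode
drops rate-zero pairs first. The mode is a flag, not hard-wired to a
species, so both landscapes can be analyzed both ways.

P-values are two-sided. For $n \le 8$ tie-free pairs the null distribution
is enumerated over all permutations; for $n = 9, 10$ the exact algorithm
of `stats::cor.test` is used; above that, the usual $t$ approximation.
Full enumeration at $n = 9, 10$ (0.4M-3.6M permutations) was judged not
worth the runtime given that `cor.test`'s exact path covers it. A constant
vector makes the coefficient undefined and is flagged (`NA` with an
explanatory method string) rather than silently returned as a number. No
multiple-testing correction is applied by default, matching the per-cell
significance-star convention of the figure this reproduces; a
Benjamini-Hochberg flag is available. Stars map as `*` < 0.05, `**` < 0.01,
`***` < 0.001, and `format_matrix()` blanks non-significant cells.

## What the simulator states, and what a green test establishes

The focus simulator draws per-cell crossover counts from
Poisson(`co_mean`), optionally resampling to $\ge 1$ (the obligate
chiasma). Positions come from a two-component mixture: with probability
`terminal_weight`, a Beta(1, 8) variate scaled to `[0, terminal_span]` and
reflected to either end with equal probability; otherwise uniform. The
Beta(1, 8) family is a choice, not an inference — the source observations
are qualitative (end-biased vs interstitial) — and both parameters are
exposed. Regime defaults encode the two landscapes under study:

| parameter | homogeneous_terminal | polarized |
|---|---|---|
| `terminal_weight` | 0.4 | 0.8 |
| `terminal_span` | 0.2 | 0.2 |

With these defaults the polarized regime places ~84% of crossovers within
the distal tenth of each end (a fifth of the chromosome in total), matching
the "nearly 80% within a fifth" description of guinea-fowl macrochromosomes
under the 10%-per-end reading; because "a fifth" is ambiguous (10% per end
vs 20% per end), recovery reports carry both definitions. Crossover counts
are Poisson, i.e. interference-free — interference is outside the analysis
scope and noted as an extension point. Default `n_cells = 135` and 6-7
chromosomes mimic the scale of the cytological datasets (133-138 cells).

The genome simulator plants a per-interval GC landscape
$gc_i = \text{baseline} + \text{amplitude}\,(2\Phi(z_i)-1)$ from standard
normal $z_i$ (defaults 0.42 ± 0.05, typical of avian macrochromosomes), and
a crossover placement intensity coupled to the $z_i$ through a Gaussian
copula with normal-scale correlation $r = 2\sin(\pi\rho_s/6)$, so the
planted Spearman correlation equals `coupling_rho` in expectation (exact at
$|\rho_s| = 1$). Bases are sampled i.i.d. at each interval's GC target.
Background CpGs are then dissolved by CpG→GpC swaps (iterated, because
swaps can create new CpGs at junctions). The default depletion (0.98,
residual obs/exp ≈ 0.02) is deliberately *stronger* than real vertebrate
genomes (obs/exp ≈ 0.2): at realistic depletion, random 200 bp fluctuations
qualify as islands about once per Mb, and the simulator's contract —
`cgi_rate = 0` means the caller finds nothing — is meant to hold by
construction. Planted islands (> 200 bp, GC-rich, CpG-enriched,
non-overlapping) arrive at `cgi_rate` per Mb and gene starts follow a
uniform Poisson process at `genes_per_Mb` (12/Mb default, the avian
macrochromosome ballpark).

What the simulator does **not** emulate: interference, centromere effects,
heterochromatin, isochore structure finer than the interval grid,
microchromosomes, sex differences, or realistic CpG-island length/content
distributions. A green end-to-end test therefore establishes that the
*pipeline arithmetic and statistics* recover planted truth — map length
$= 50 \cdot$ `co_mean`, coupling $\rho$, regime contrast — not that any
biological inference is correct.

## Numerical choices and degenerate inputs

* Fractions outside [0, 1] (or µm beyond the cell's SC length) are
  rejected record-by-record with the cell id in the message.
* `counts_to_cM` requires $N \ge 1$; zero-length intervals are rejected.
* Track summaries use the sample (n−1) standard deviation.
* All-zero rate vectors under `nonzero_only` raise "no recombining
  intervals" rather than returning an empty correlation.
* Fewer than 3 pairs in a scope: the test is skipped with a warning, never
  extrapolated.
* Seeded simulation restores the caller's RNG state afterwards, so
  `simulate_*` calls are deterministic without disturbing the session
  stream.

## Limitations

The pipeline treats the SC-to-genome proportionality as exact; real axes
show local packing variation, so positions are only interval-scale
accurate (which is why the grid is 2.5 Mb). Island calls follow the stated
criteria, not any browser-specific dialect. The micro-scale questions —
promoter-resolution recombination, methylation state of islands — are
explicitly out of scope: at 2.5 Mb resolution those signals are averaged
away.
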