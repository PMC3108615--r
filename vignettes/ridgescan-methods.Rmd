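---
title: "Detecting chromosomal expression domains: methods and design"
author: "ridgescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal expression domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Genes are laid out along chromosomes, and each gene carries one normalised
log-intensity per tissue (the intensity scale of the data this procedure was
designed for runs roughly from 9 to 14 log2 units). The object of interest
is not the single gene but the *local expression level* of a chromosomal
neighbourhood: a RIDGE is a stretch of the chromosome where embedded genes
are, as a group, expressed above the genomic norm; an anti-RIDGE is the
depressed counterpart. Single-gene noise is removed with a robust smoother
and domains are read off as long runs of elevated (or depressed) smoothed
values.

Formally, on each chromosome the mapped genes (genes with an expression
value) are ordered by start position, ties broken by end then by gene id.
For a tissue $t$ (or the per-gene average across tissues) the smoothed value
at gene position $i$ is the median of the window of $w$ positions centred at
$i$. At the chromosome ends the window shrinks symmetrically:

$$h_i = \min(i - 1,\; n - i,\; (w-1)/2), \qquad
  s_i = \mathrm{median}(x_{i-h_i}, \ldots, x_{i+h_i}).$$

This end rule is parameter-free, reduces to the interior definition, and
returns the raw value at the first and last position. Note that it is *not*
what `stats::runmed(endrule = "median")` computes — that variant re-smooths
the already smoothed series at the ends; `running_median()` therefore uses
`runmed` only for the interior and takes plain raw-value medians in the end
zones, and is tested against a brute-force window-sorting oracle.

With $m$ the median of all mapped genes' raw values genome-wide, position
$i$ qualifies as RIDGE-like when $s_i > m \cdot f_\uparrow$ and as
anti-RIDGE-like when $s_i < m / f_\downarrow$ (strict inequalities, so a
constant map yields nothing). Maximal runs of at least $k$ qualifying
positions become regions; the genomic extent of a region is the span from
the smallest start to the largest end of the genes in the run, and its
member genes are all annotation genes overlapping that span by at least one
base pair.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window` (w) | 39 | gene positions | smoothing window; 39 sits inside the empirically established 19–79 gene range of chromosomal domain sizes |
| `min_stretch` (k) | 10 | gene positions | minimum run length for a region |
| `fold_up` / `fold_down` | 1.25 / 1.45 | fold on the genomic median | qualification thresholds when not calibrating |
| `coverage_target` | 0.10 | genome fraction | calibration target per region kind |
| `fold_step`, `fold_max` | 0.01, 3 | fold | calibration grid `1+step, …, fold_max` |
| `control_quantile` | 0.999 | — | negative-control quantile for the expression threshold |
| `n_perm`, `n_samp` | 10,000 | replicates | permutation / resampling null sizes |

The asymmetry of the default folds (1.25 up vs 1.45 down) is not a modelling
statement: both values are what coverage calibration produced on the data
the defaults were taken from. Calibration evaluates the bp coverage of the
called regions on the fold grid and keeps the fold whose coverage is closest
to the target, resolving ties toward the larger (more stringent) fold; when
the coverage curve is flat at its maximum this tie rule means a saturating
target is answered by the *largest* fold that still attains maximal
coverage. The default grid step is 0.01: because the folds multiply a
log-scale median (~11), a step of 0.05 would move the threshold by about
half a log2 unit — far coarser than the coverage resolution the calibration
is supposed to deliver — whereas 0.01 resolves ~0.11 log2 units.

Two further choices are exposed rather than hard-coded. `fold_scale`
selects between applying the fold multiplicatively to the log-scale median
(`multiplicative`, the default and the convention of the original analysis)
and adding $\pm\log_2 f$ (`additive`, a true fold change on raw
intensities); since thresholds are normally re-calibrated to the coverage
target, the choice barely matters in practice. `coverage_unit` allows
coverage to be measured in qualifying gene positions instead of base pairs
as a sensitivity analysis.

## Statistical procedures

**Permutation null.** Gene positions are fixed; the per-gene values are
reassigned to positions uniformly at random, maps are rebuilt and regions
re-called with the *same* window, threshold and minimum stretch as the
observed analysis (the genomic median is permutation-invariant, so the
threshold is constant across permutations). The empirical p-value for
observing at least the actual region count is reported with the add-one
correction $(\#\{null \ge obs\} + 1)/(n_{perm} + 1)$ and as the plain
proportion. Because the threshold is calibrated on the observed data, the
procedure is mildly anti-conservative on very small genomes (observed counts
of 1–4); at study-like sizes the null p-values are close to uniform.

**Expression threshold and classes.** The threshold is the type-7
(linear-interpolation) quantile of the negative-control pool, the default
quantile method of the statistical environment the analysis was built in.
"Expressed" is strict (`value > tau`). HK and TS labels are explicitly
relative to the supplied tissue panel: a gene expressed in all five tissues
of a brain-dominated panel may well be tissue-restricted in a wider one.

**Set enrichment.** Resampling is *without replacement*, which matches a
hypergeometric null; the closed-form standard deviation
$100\sqrt{p(1-p)/n \cdot (N-n)/(N-1)}$ is used as an independent oracle in
the tests. Enrichment and depletion p-values are both computed; the
reported direction follows the sign of the deviation from the null mean.

**Region distribution.** The query-versus-rest 2×3 table (RIDGE /
anti-RIDGE / intermediate) is tested with Fisher's exact test; because the
published analyses of this kind do not always state their collapse, the 2×2
anti-RIDGE-versus-rest p-value is reported alongside. The background
universe defaults to all annotation genes with known location and is
configurable. The implementation is `stats::fisher.test`; tests compare it
against exhaustive enumeration of all tables with the observed margins.

**Genomic features.** Six per-gene features are extracted from the
annotation: genomic gene length; mean intron length (introns are gaps
between consecutive exons within a transcript; the default pools the introns
of all transcripts of a gene, a per-transcript-then-average variant is
available since the plain-language definition is ambiguous); GC fraction as
supplied; mean transcript length (summed exon lengths); mean exon count
(fractional when transcripts differ); mean pooled exon length. Group
comparisons use the two-sided Wilcoxon rank-sum test — exact when both
groups have ≤ 20 values and no ties, otherwise the normal approximation with
midranks, tie correction and continuity correction. No multiple-testing
correction is applied across the six features; raw p-values are reported.

## The simulator

`simulate_genome()` plants one RIDGE and one anti-RIDGE block per
chromosome (random order, separated by background segments), each budgeted
to cover 10% of the chromosome in bp, and draws gene structure from
class-conditional distributions: RIDGE genes have fewer exons, shorter
introns and higher GC than anti-RIDGE genes, with the background in
between. Expression classes are assigned with HK probability 0.35 inside
planted RIDGEs versus 0.18 elsewhere — reproducing HK over-representation on
RIDGEs — and, mirroring that asymmetry, HK probability 0.08 and silent
probability 0.20 inside planted anti-RIDGEs (domains of depressed
expression are by construction poor in ubiquitously expressed genes and
rich in silent ones).

`simulate_expression()` generates
$$x_{gt} = \mu_{bg} + \delta_g + c_{gt} + u_g + \varepsilon_{gt}$$
with background mean $\mu_{bg} = 11$ (the 9–14 intensity scale), domain
shift $\delta_g = \pm\delta$ (default 1.5 log2 units) inside planted
blocks, class terms ($+2.5$ for HK in all tissues; $+2.5$ in one tissue and
$-1.2$ elsewhere for TS; $-2.2$ for silent), a shared per-gene effect
$u_g \sim N(0, 0.8)$ inducing the high correlation observed between tissue
maps, and cell noise $\varepsilon \sim N(0, 0.5)$. Values are clipped to
$[8, 15]$. Negative controls are $N(9.3, 0.5)$, giving a 99.9% quantile
threshold around 10.8 on the same scale. All draws are governed by a single
seed; the same seed reproduces byte-identical artifacts.

Default genome size is 5 chromosomes × ~500 genes. The size matters for the
recovery guarantee: a planted block is resolvable by a $w$-gene median
filter only when it holds comfortably more than $w/2$ genes, and because
anti-RIDGE genes are long, a 10% bp block contains fewer of them (~40 at the
default profile). With the defaults, calibrated scans recover planted
domains with a mean bp-level Jaccard above 0.8 per kind across seeds.

**What the simulator does not emulate:** probe-level measurement error and
normalisation artifacts; chromosome-scale trends in gene density or GC
(isochores); overlapping genes and nested transcripts; dependence between a
gene's structure and its expression class beyond domain membership; any
sequence-level realism (GC is a number, not computed from sequence). Tests
passing on simulated data therefore validate the algorithmic behaviour of
the pipeline, not the biological fidelity of any particular dataset.

## Numerical and degenerate-input choices

* Internal coordinates are 1-based inclusive (GFF3 convention); BED export
  is 0-based half-open. Strand is carried but ignored.
* Gene order ties (identical starts) break by end, then gene id, making
  maps reproducible for any input.
* Median of an even-size set (only reachable in the test oracles) is the
  mean of the two central order statistics.
* A chromosome with fewer genes than the window still gets a map through
  the shrinking end windows; a single-gene chromosome maps to its raw value.
* Annotation records with `end < start` are dropped with a warning;
  duplicate gene ids are an error. Duplicate expression rows (multiple
  probes per gene) are averaged. Non-numeric expression cells are a hard
  error naming row and column.
* Genes overlapping regions of both kinds (possible only when a gene spans
  the gap between adjacent regions) are assigned the kind with the larger
  bp overlap.
* All text writers emit 12 significant digits, so write/read round trips
  are lossless at that precision.

## Problem sizes used in the test-suite

The suite exercises study-scale dimensions where the quantity being checked
depends on them (resampling nulls on a 13,234-gene universe with 10,000
replicates) and reduced simulated genomes elsewhere (2–5 chromosomes of
150–500 genes, permutation nulls of 99–200 replicates, 10-seed recovery
averages), sizes at which every checked property is stable across seeds.

## Known limitations

* The HK/TS dichotomy is panel-relative; with few, closely related tissues
  the HK set will absorb lineage-specific genes.
* Coverage calibration on the observed data makes the permutation test
  slightly anti-conservative for genomes with very few callable regions.
* Region extent is defined by gene spans, so regions can extend into the
  intergenic flank of their outermost member genes; alternative extent
  definitions (e.g. window midpoints) would shift boundaries by up to half
  a window.
* The member-gene rule is any-overlap; exact reproduction of published
  member counts may depend on whether the original analysis required full
  containment, which is not always stated.
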