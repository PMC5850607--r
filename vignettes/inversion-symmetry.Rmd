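---
title: "Quantifying symmetric inversion bias with X-type symmetry scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying symmetric inversion bias with X-type symmetry scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invsym)
```

## The problem

Large chromosomal inversions are a major source of structural variation in
bacteria and archaea. Strikingly, many of them are *symmetric*: their two
breakpoints lie at approximately equal distances from the replication origin
(*ori*), so the rearrangement pivots around the *ori*–*ter* axis of the
circular chromosome. In a dot plot of exact matches between two genomes, a
history of such inversions produces the familiar X shape — homologous
segments sit either on the main diagonal (collinear, forward orientation)
or on the anti-diagonal through the axis (inverted, reverse orientation).

Historical practice was to diagnose these X patterns by eye, which invites
reporting bias. `invsym` implements a geometric score that makes the
diagnosis quantitative, scalable, and applicable to pairs of genomes at
very different divergence levels.

## The model

### Input: maximal unique matches

A genome pair is summarized by its maximal unique matches (MUMs): exact
matches occurring exactly once in each genome and extendable in neither
direction, enumerated in both forward and reverse-complement orientation
(`find_mums()`, or `parse_mummer()` for MUMmer text output). Each MUM is
reduced to its midpoint in the alignment plane and carries the weight
`len / min_len`, so longer (more trustworthy) homology blocks speak with a
louder voice. The default minimal length is 20 bp — long enough that chance
matches are rare, short enough that diverged pairs retain a usable number
of matches; a stricter 100 bp mode is available as a robustness check.
Matches containing ambiguous bases are excluded, and matching is linear
(no wrap-spanning matches), mirroring how whole-genome aligners treat the
deposited linear records.

Pairs enter the symmetry analysis only if one orientation has at least 40
MUMs and the other at least 20 (`filter_alignment()`): an X pattern needs
both arms populated. The thresholds can be scaled down for the short
territories of the multi-origin workflow.

### The X-type symmetry score

For each candidate axis point $(i, j)$ of the alignment plane we ask how
well the matches fit an imaginary X centred there:

$$X_{i,j} = \sum f_m - \sum f + \sum r - \sum r_m$$

where $f$ and $r$ are residual deviations of forward- and
reverse-orientation match midpoints from the forward arm (the slope $+1$
line through $(i, j)$), and $f_m$, $r_m$ are the residuals of the same
points after mirroring about the vertical axis at $i$. The logic: an
inversion symmetric about $i$ moves sequence onto the reverse arm;
mirroring undoes it, so reverse matches created by such inversions have
small $r_m$ (and collinear forward matches have small $f$), while the
mirror scatters points that were *not* placed by a symmetric inversion.
Every residual is weighted, and $X_{i,j}$ is normalized by the total
weight so values are comparable between genome pairs.

Residuals are measured as circular vertical (axis-2) deviations from the
arm, in bp, rather than perpendicular distances: this is the simplest
reading under which mirroring exactly restores collinearity, and on
equal-length genomes it differs from the perpendicular convention only by
a constant factor, which cannot move the argmax. Positions are not
rescaled for unequal genome lengths (the dot-plot geometry is kept in bp);
an analysis in genome fractions can be emulated by rescaling coordinates
before calling the scorer.

`symmetry_matrix()` evaluates $X$ on a regular grid — 10 kb by default,
the resolution at which the score was designed to be scanned — and records
the maximum with a deterministic tie-break (smallest $i$, then $j$). For
genomes shorter than 1 Mb the grid refines to `max(1000, L/100)` bp so
that desk-scale simulated genomes keep a meaningful (~100-column) grid;
the refinement is flagged in the object and in the TSV output. Two exact
symmetries are worth knowing: duplicating every MUM leaves the matrix
unchanged (weight normalization), and $X_{i,j} = X_{i+L/2,\,j+L/2}$,
because an inversion axis is a full diameter of the circle — the point of
maximal symmetry is therefore only defined up to the antipode, which is
exactly why the D statistic below compares against *both* ori and ter.

### The D statistic

With the terminus defined antipodal to the origin,

$$D = \min\big(d(i^\*, ori),\; d(i^\*, ter)\big) / L$$

where $i^\*$ is the focal-genome coordinate of the symmetry maximum and
$d$ is circular distance. $D = 0$ means the dominant inversion axis
coincides with the *ori*–*ter* axis; the largest possible departure is a
quarter of the genome, $D = 0.25$ (`d_score_bound()` verifies the bound by
exhaustive enumeration). Per-genome summaries use the median D across all
pairwise comparisons the genome participates in (`median_d()`). D is
computed on axis 1 of the matrix; swap the inputs (or use the CLI's
`--focal 2`) for the partner genome's landmarks.

On small odd genome lengths the floored antipodal terminus lets the
integer-position maximum exceed $0.25$ by up to $1/(4L)$ — irrelevant at
genomic scale, but visible in toy examples.

## The inversion simulator

Because genuine inversion histories are unknown, the package's test bed is
a simulator (`evolve_pair()`) that generates an ancestral i.i.d. uniform
A/C/G/T genome (`ori = 0`, `ter = L/2`) and applies `n` sequential
inversions, each replacing a clockwise arc by its reverse complement,
followed by i.i.d. point substitutions:

* **random** — both breakpoints uniform on the circle (the null);
* **symmetric** — the inversion centre is ori or ter (equal probability)
  and the half-span is uniform on $(1, L/4)$, so breakpoints are exactly
  equidistant from the axis;
* **quasi** — symmetric, then one breakpoint shifted by up to `jitter` bp
  (default 2% of the genome).

Defaults are 50 inversions and a substitution rate of $10^{-3}$ per bp on
a 1 Mb genome. These values are the package's own choice of study
conditions: they yield on the order of a thousand MUMs per pair — sparse
enough to look like a diverged pair, dense enough that both orientations
clear the 40/20 filter. Substitutions are applied after all inversions;
at these rates the order only affects which exact matches fragment, not
the geometry being tested.

What the simulator does *not* emulate: indels, duplications,
translocations, horizontal transfer, gene-level organization, and
compositional heterogeneity (real genomes have skewed base composition and
repeat families that shape the MUM landscape). Passing recovery tests on
simulated pairs therefore demonstrates that the statistic correctly reads
an inversion-only signal, not that every real alignment is as clean.

Two properties anchor the test suite, both verified in
`tests/testthat/test-acceptance.R`:

* **Recovery** — pairs diverged by symmetric inversions about the
  *ori*–*ter* axis (1 Mb, 50 events, $\mu = 10^{-3}$) give
  $D \le 0.02$ — within two grid cells — in at least 95% of replicates.
* **Null calibration** — pairs diverged by unconstrained inversions give
  D consistent with Uniform(0, 0.25) (Kolmogorov–Smirnov, 200 kb genomes
  with the refined grid).

## Architecture features

Four *ori*–*ter*-linked features of adaptive genome architecture are
computed as covariates of symmetric inversion bias (`genome_features()`):

* `rrna_ori_distance()` — mean circular distance of rRNA genes to ori, as
  a percent of replichore size (L/2).
* `cog_j_z()` — enrichment of COG class J (translation) genes near ori: the
  mean J-gene ori-distance compared with all COG-annotated genes, as a
  Z-score; negative means J genes sit ori-proximal. The analytic form
  (deterministic) is the default; a seeded permutation form is available.
  They agree closely when J genes are a small fraction of the annotated
  set — at larger fractions the permutation null's without-replacement
  variance is visibly smaller, which is worth remembering when comparing
  the two.
* `leading_fraction()` — fraction of genes co-oriented with their
  replication fork, with the majority rule applied on top (the strand with
  more genes is called leading), so the value is in [0.5, 1].
* `octamer_bias()` — the most strand-biased octamer: every A/C/G/T 8-mer
  is counted on the forward strand of each replichore, and the motif with
  the largest raw count difference is returned. Selection uses the raw
  difference; the normalized bias $|c_1 - c_2|/(c_1 + c_2)$ is reported
  alongside for cross-genome comparability.

Gene positions are interval midpoints throughout — genes are short
relative to replichores, and one convention avoids a family of off-by-one
choices. Genomes lacking a feature (no rRNA annotation, no J genes, zero
variance) report `NA` with a warning, never a silent zero. A cumulative GC
skew trace (`gc_skew_profile()`) is included as a diagnostic of how
sharply nucleotide skew marks the replichore structure. Feature–D
relationships are assessed with Spearman rank correlations
(`feature_d_correlation()`), dropping missing genomes pairwise.

## Multi-origin territories

For archaea with several replication origins, symmetry around individual
origins and individual termini can be assessed separately. Termini between
adjacent origins are placed at arc midpoints — synchronously firing
origins with equal fork speeds meet halfway; the data to do better do not
usually exist. `split_territories()` builds ori-centred territories
(bounded by flanking termini, then trimmed so both arms are equal, ±1 bp)
or ter-centred territories (bounded by flanking origins, untrimmed — they
tile the genome exactly once). `match_territories()` pairs homologous
territories across taxa by MUM count, greedily, under a 10 kb
length-difference cap. `territory_d()` then measures D within the
linearized territory, against the centre or its counterpart half a
territory away — distances are linear here because a territory is an arc,
not a circle; normalizing by territory length reproduces the familiar
0–0.25 range.

## Phylogenetic controls

Comparing clades fairly requires comparable divergence levels.
`subsample_matched()` thins each clade's genome pairs to match a common
template of 16S distances: the template is binned into 20 equal-width bins
over its range, and each clade is sampled without replacement to the
largest integer multiple of the template histogram it can satisfy in every
occupied bin. The scheme is deliberately the simplest reproducible
histogram matcher: exact integer proportionality, seeded determinism, and
a hard refusal (empty sample with a warning) when a clade cannot cover an
occupied bin — matching must not extrapolate, so pairs outside the
template range are never drawn. Distance matrices arrive in PHYLIP square
format (`read_phylip_square()`); computing them is out of scope by design,
keeping this package free of a second method's fidelity questions.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, intervals half-open, all arithmetic modulo L;
  1-based external formats (MUMmer text, ori and annotation tables)
  convert at the parse boundary.
* Origin annotations within 3,500 bp merge to their circular midpoint
  (`merge_oris()`), the convention for multi-part origins; merging is
  idempotent.
* The argmax tie-break (smallest i, then j) and the seeded simulator make
  every pipeline output byte-reproducible.
* An all-ambiguous sequence, a genome with no rRNA, or a zero-variance
  distance set produce missing-feature markers, not zeros.
* Degenerate inversions (`a == b`) and empty MUM sets are errors, not
  silently empty results.

## Problem sizes used in the tests

The validation suite runs entirely on simulated data at desk scale: 50
replicates of 1 Mb pairs for symmetric recovery, 200 replicates of 200 kb
pairs for the null calibration, 100 random pairs up to 5 kb for
brute-force MUM equivalence, and 20 random configurations for the
symmetry-score oracle. `scripts/acceptance.R` recomputes the same
quantities end to end (30 symmetric and 100 random pairs) and writes them
as JSON. Clade-scale surveys of real genome collections are the package's
intended application but are not part of its tests.

## A worked example

```{r example}
cfg <- sim_config(L = 200000, n_inversions = 30, mode = "symmetric",
                  point_mutation_rate = 0.001, seed = 3)
pr <- evolve_pair(cfg)
pair <- filter_alignment(find_mums(pr$g1, pr$g2),
                         genome1 = pr$g1$id, genome2 = pr$g2$id)
pair
m <- symmetry_matrix(pair, pr$g1$L, pr$g2$L)
m
d_score(m, pr$g1, partner = pr$g2$id)
```

The argmax lands on the *ori*–*ter* axis and D is (near) zero, as it
should for a purely symmetric history; rerun with `mode = "random"` to see
D wander across (0, 0.25).

## Known limitations

* The symmetry score reads a *single dominant* axis; histories mixing
  several axes blur the maximum rather than reporting multiple axes.
* Linear match semantics lose matches spanning the arbitrary cut point of
  the deposited sequence; for typical genome pairs this affects at most
  one homology block.
* The eligibility filter is a hard gate, not a significance test; D
  carries no per-pair uncertainty. Aggregation (median D, clade
  distributions) is where inference belongs.
* `read_fasta()` keeps only the largest record when asked; secondary
  chromosomes and megaplasmids are out of scope.
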