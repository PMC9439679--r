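---
title: "Methods: differential chromatin architecture with loopdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential chromatin architecture with loopdelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`loopdelta` compares chromatin architecture between two conditions (a
control, "A", and a perturbed condition, "B" — e.g. wild-type versus
cohesin-subunit-deficient cells) from binned intra-chromosomal Hi-C
contact matrices. It covers four analysis layers — matrix balancing, A/B
compartments, insulation/TADs, and focal loops — plus the integration of
loop calls with gene promoters, differential-expression classes, and ChIP
peak occupancy. A synthetic-data generator with planted ground truth makes
every layer testable without external data.

# Models and procedures

## Balancing (iterative correction)

Per-bin multiplicative biases are removed with iterative correction (ICE):
weights $w_i$ are sought such that $b_{ij} = w_i w_j C_{ij}$ has uniform
row sums over non-masked bins. We use ICE rather than Knight–Ruiz: the
two share the balancing contract (doubly-stochastic-like rows), and ICE is
simpler to implement and to verify against a brute-force fixed-point
oracle. Weights are rescaled so the mean non-masked row sum equals 1,
which makes balanced values (and hence pile-ups) comparable between
samples of different depth.

Before iterating, bins with zero coverage — or coverage further than
`mad_max` (default 5) median absolute deviations from the median of the
non-zero bins — are masked. The MAD uses R's normal-consistent scaling
(constant 1.4826). The filter is meant to catch artifact bins far out in
the tails; with a tighter MAD convention it starts masking *structurally*
low-coverage bins (domain interiors near boundaries, chromosome ends),
which displaces insulation minima by several bins. Masked bins carry no
weight and are excluded from every downstream statistic.

## Compartments

At 100 kb resolution the balanced matrix is converted to
observed/expected (each entry divided by its diagonal's mean over
non-masked pairs), and the first eigenvector of the Pearson correlation
matrix of the O/E columns is taken as the compartment signal. The
correlation-matrix construction (rather than the O/E eigenvector
directly) is the common choice and is what makes a two-block checkerboard
separate exactly by sign. The sign is fixed against an activity
reference — ChIP peak coverage per bin by default, housekeeping-gene
density as an accepted alternative — so that positive values mean the
active A compartment.

Switches between conditions use a sign change plus a delta rule: a bin is
AB when $ev_A > 0$, $ev_B < 0$ and $|ev_A - ev_B| > 1.5$; BA
symmetrically. Because a threshold of 1.5 is only meaningful on a fixed
scale, each eigenvector is divided by its own standard deviation (no
centring, so signs survive) before the comparison; the scale on which a
1.5 delta is meant to be read is conventional rather than standardized,
so this scaling is a documented assumption of this package, prominently
surfaced via the `scale_ev` argument. Bins that do not switch
inherit the compartment of condition A (the control); this covers the
case of discordant signs with a small delta, which the four-category rule
otherwise leaves open.

## Insulation and TADs

Domain structure uses Crane-style diamond insulation at the native 10 kb
resolution: for bin $i$, the mean balanced value of the $w \times w$
diamond spanning rows $i-w..i-1$ and columns $i..i+w-1$ (window 100 kb,
so $w = 10$), log2-scaled to the chromosome-wide mean of diamond means.
The ratio makes the score invariant to global scaling. Diamonds
overlapping masked bins use the non-masked mean when at least half the
cells are defined, and are undefined otherwise.

Boundaries are local minima with *windowed prominence* at least 0.2 log2
units, where prominence is the drop from the highest score within one
window on each side. Measuring against the local shoulders — rather than
walking to the nearest lower minimum, as topographic prominence would —
prevents shallow mid-domain dips from inheriting the deep boundary dips
that flank them. Minima closer than one window are deduplicated keeping
the deeper one. TADs are the intervals between consecutive boundaries
(minimum 3 bins). Contact-ratio and corner-score TAD callers (HiCRatio,
arrowhead) are deliberately out of scope: one coherent insulation-based
method serves all domain analyses, including the cross-sample
PCA/similarity comparisons that are natively insulation-based.

Aggregate-TAD maps extract each TAD with one TAD-length flank from the
O/E matrix, block-average the $3L \times 3L$ window onto a fixed
$90 \times 90$ grid, and average over TADs.

## Loop calling

Loop significance follows the Fit-HiC construction, re-implemented in a
single pass: the mean contact probability per distance is smoothed with a
weighted spline *in log–log space* (contact decay is close to a power
law, so the spline is near-linear there and extrapolates sanely into
sparse distances), projected onto non-increasing monotonicity, and
combined with per-bin bias terms $b_i = 1/w_i$ (unit mean) to give
$p_{ij} = \mathrm{prior}(d_{ij})\, b_i b_j / Z$, renormalized to sum to 1
over all tested pairs. The p-value for a pixel with $k$ counts is the
binomial upper tail $P(X \ge k)$, $X \sim \mathrm{Binomial}(N, p_{ij})$
with $N$ the total tested count. Fit-HiC's optional second pass with
outlier removal is omitted: at desk scale on synthetic data it changes
little.

The candidate universe is all in-range bin pairs with non-masked anchors;
zero-count pairs have p-value 1 by construction, are counted in $N$, $Z$
and the Benjamini–Hochberg denominator, but are excluded from the table.
The tested range defaults to 30 kb–5 Mb. Loops are pairs with BH
q < 0.01; each carries the normalized, bias-corrected contact score
raw/expected.

Differential classification uses two cutoffs: a pair is A-specific iff
$q_A < 0.01$ and $q_B \ge 0.1$ (significant in one group and absent in
the other even under the loose cutoff), B-specific symmetrically, common
iff significant in both, and *indeterminate* when significant in one and
loosely present ($0.01 \le q < 0.1$) in the other — the two-cutoff rule
leaves that middle band deliberately unresolved.

## Integration

Genes are classed as down (FDR < 0.05, logFC ≤ −0.58, logCPM > 0), up
(symmetric), stable (|logFC| < 0.38, logCPM > 0) or other. A loop is
promoter-anchored for a gene when either anchor interval intersects the
half-open window [TSS − 2 kb, TSS + 2 kb); the full anchor interval is
used rather than the anchor midpoint (a documented convention — midpoint
assignment would miss promoters near anchor edges).
Promoter ChIP occupancy uses the same window and the same half-open
convention: a peak touching the window boundary exactly does not count.
Stratified loop-score comparisons use unpaired two-sided Wilcoxon
rank-sum tests (exact for small samples without ties, normal
approximation with tie correction otherwise — the `stats::wilcox.test`
policy, verified against full permutation enumeration in the tests).

Pile-ups average balanced local windows, each divided element-wise by the
mean of `n_shifts` random-shift controls: both anchors shifted by a
common diagonal offset drawn uniformly from ±[5·pad, 50·pad] bins, which
preserves anchor distance and thereby normalizes for distance decay.
Central enrichment is the centre pixel over the mean of the 3×3
upper-left and bottom-right corner blocks (3×3 is the coolpup-style
default; the block size is configurable). TSS pile-ups orient every window so transcription points
in the positive axis direction (minus-strand windows are reflected), omit
diagonal pixels, and report a stripe score: mean of the TSS-row pixels
downstream over upstream. The stripe *score* is this package's
quantification of a feature usually assessed visually on aggregate maps;
rows (promoter on the row anchor) define the stripe — a convention, since
only the plot is standard.

# The synthetic world

The generator is multiplicative on a power-law decay
$\mu_{ij} \propto \max(|i-j|,1)^{-\alpha}$: same-compartment pairs are
up-weighted by `compartment_strength`, cross-TAD pairs down-weighted by
$1-\texttt{tad\_insulation}$, planted dots and stripes multiply their
pixels, the matrix is scaled to the target depth and Poisson-sampled.
Defaults describe a desk-scale mammalian chromosome: 20 Mb at 10 kb bins,
$\alpha = 1$, 5e6 cis pairs per condition, ~2 Mb compartment blocks at
1.8-fold, ~800 kb TADs at insulation 0.7, 5+3+2 planted loops at 5-fold,
2-fold stripes over 200 kb, 10%/10% down/up genes at |logFC| ≥ 0.58.

Structural choices made for realism, fixed before any acceptance
measurement:

* **Compartment blocks are drawn in whole 100 kb units** so planted labels
  are exact at compartment resolution, with terminal blocks ≥ 1 Mb:
  chromosome ends have degenerate coverage in any Hi-C map, so no planted
  transition sits there.
* **TAD boundaries include every compartment edge** (domains nest inside
  compartments, as in real genomes) and planted TADs are never smaller
  than half the mean size: boundary spacing must stay above the
  insulation window's resolution limit to be recoverable by *any* caller,
  and sub-400 kb TADs are rare in mammalian maps.
* **Switch blocks are compartment-label islands only.** Their edges are
  not TAD boundaries, so the control condition's domain structure is
  unaffected by where switches are planted.
* **Loops live within TADs.** A planted dot spanning a boundary would be
  multiplied by the insulation down-weight — invisible to any
  distance-expectation caller — and cross-TAD loops are also biologically
  atypical.
* **Genes are placed 4:1 in the A compartment** (active genes live in A).
  This is also what gives the peak-coverage reference its correlation
  with the eigenvector; with uniformly placed genes, orientation would be
  a coin flip, which no real activity track exhibits.
* **Stripes extend only downstream of the TSS** in the strand direction,
  matching the observed one-sidedness of promoter stripes; stripe genes
  are drawn from down-regulated genes first. Planted DEG log-fold-changes
  are 0.58 plus a folded normal, so planted classes are recoverable by
  construction; "other" genes are low-expression (logCPM ≤ 0).
* **Promoter peaks** are planted wholly inside TSS ± 2 kb for flagged
  genes (80%/40%/60%/20% of down/up/stable/other genes), decoys only in
  gene deserts.

What the generator does **not** emulate: replicate-level biological
variability (Poisson only — no overdispersion knob is exercised),
per-bin mappability biases (weights are therefore near-uniform and the
bias-correction path is exercised only mildly), trans contacts,
restriction-fragment structure, and multi-chromosome genomes (one
chromosome; the configuration rejects more). A green test therefore
establishes algorithmic correctness against the stated generative model,
not performance on real library artifacts.

One benchmark consequence of the stated world: planted one-sided stripes
are genuine insulation discontinuities — exactly as real promoter stripes
are boundary-like — but the truth model does not label them as TAD
boundaries. Boundary recall/precision is therefore benchmarked on a
stripe-free world; with stripes present, the "false" boundary calls sit
at stripe anchors, i.e. they measure the generator's labelling semantics
rather than the caller. Stripes are benchmarked by their own score in the
pile-up criteria.

The loop-recovery FDR benchmark runs on decay-only null worlds (all
strengths 1): a distance-only prior cannot be correctly specified on a
matrix with compartment checkerboard, so a null with structure would
measure model misspecification, not the test's error control. On
structured matrices the caller is benchmarked by planted-loop recovery
instead.

# Numerical choices

* Balancing: `tol` 1e-5 on the relative row-sum deviation, `max_iter`
  200, failure to converge is an error reporting the residual.
* Distance prior: `smooth.spline` with per-distance pair-count weights,
  GCV-selected smoothness; monotone projection via `isoreg`; probability
  floor 1e-15.
* Eigenvector: dense `eigen` on the correlation matrix; the
  largest-|eigenvalue| vector, unit norm; degenerate (constant-row)
  correlation matrices are an error, as is orienting against a
  zero-variance reference.
* Boundary ties: minima closer than one window keep the deeper one;
  equal-depth ties resolve to the leftmost by the stable ordering.
* Equal-distance prior ties in loop outputs: rows are ordered by
  (bin1, bin2).
* Pile-ups: windows leaving the chromosome are skipped and counted;
  all-zero corner blocks raise an error rather than returning infinity;
  shift controls failing 50× their quota skip the locus.
* Seeds: every stochastic step derives its stream from the master seed by
  fixed offsets (`(seed * 7919 + offset) mod 2^31-25`), so one integer
  reproduces a whole run; library code saves and restores the caller's
  RNG state.

# Known limitations

* The two-cutoff differential rule has no power analysis: condition-
  specific calls at marginal depth drift into the indeterminate band.
* The distance prior is global; strong compartment structure inflates
  calls in same-label regions (visible as extra, truthful-but-unplanted
  enrichment calls on structured synthetic matrices).
* Insulation PCA/similarity assume identical bin grids across samples.
* The CLI's stages are cumulative (each runs its prerequisites) rather
  than resumable from on-disk intermediates.
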