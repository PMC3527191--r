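---
title: "Quantifying the carbon starvation response: hyphal morphometry, moderated-t differential expression and ontology summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the carbon starvation response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model of the biology

When a submerged culture of a filamentous fungus such as *Aspergillus
niger* exhausts its carbon source, the mycelium differentiates: older,
thick hyphae (mean diameter around 3 µm) formed during exponential
growth gradually empty and die, while carbon recycled from dying
compartments fuels a secondary population of thin, poorly branching
hyphae (around 1 µm). Empty "hyphal ghosts" — cell-wall exoskeletons
without cytoplasm — accumulate but remain intact. On the transcriptional
side, starvation induces autophagy and conidiation programs and
represses ribosome biogenesis, translation and secretion.

`mycostarve` implements the quantitative core of such a study as
reusable, tested components:

1. **morphometry** — hyphal diameter distributions from stained
   micrographs by a six-step skeleton algorithm;
2. **transcriptome** — empirical-Bayes moderated t-tests per starvation
   day versus exponential growth, with three-way Venn logic;
3. **ontology** — Fisher/Benjamini–Hochberg enrichment and a DAG-based
   reduction of day-wise enriched GO term sets to *common
   most-specific* terms;
4. **synthetic data** — ground-truthed generators for micrographs,
   ontologies, annotations and expression matrices, so every stage is
   verifiable without the original raw data.

# The six-step morphometry algorithm

Micrographs show Lactophenol-blue-stained mycelium: stained (cytoplasm
filled) hyphae are dark on a bright background, while unstained ghosts
appear only as faint wall outlines. The pipeline is:

1. *Binarize*: optional Gaussian smoothing (`smoothing_sigma`, default
   1 px), a global Otsu threshold with dark-foreground polarity, and
   removal of components below `min_object_px` (default 30 px). Otsu
   was chosen because it is parameter-free and testable; the exclusion
   of ghosts rests entirely on stain contrast, so holes are *not*
   filled and faint wall outlines fall on the background side of the
   threshold.
2. *Outline*: foreground pixels 8-adjacent to background (the image
   border counts as background).
3. *Skeletonize*: Zhang–Suen thinning to a one-pixel, 8-connected
   medial skeleton. No installed package provides 2-D thinning, so it
   is implemented here and tested for idempotence on thin lines,
   midline accuracy on ribbons and topology at crossings.
4. *Prune intersections*: every skeleton pixel with three or more
   skeleton neighbours is deleted, repeatedly, until only simple paths
   remain; isolated pixels are dropped. This is the minimal reading of
   "remove all intersections" and guarantees a well-defined local
   orientation everywhere.
5. *Combine with the outline* and
6. *Fragment and measure*: each simple path is cut into fragments of
   `fragment_len` pixels (default 7 — long enough for a stable
   orientation estimate, short enough to follow curvature; a terminal
   remainder of ≥ 3 px becomes its own fragment, shorter remainders
   merge into the previous one). From each fragment centre two rays are
   cast along ± the normal to the fragment orientation in 0.25-px steps
   until the first background crossing; the diameter is the sum of the
   two ray lengths times the pixel size. Two-sided measurement is
   robust to the skeleton sitting slightly off-centre; on straight
   noiseless tubes it agrees with twice the Euclidean distance
   transform within one pixel (a tested invariant). Samples are
   discarded when a ray exits the image or the diameter exceeds
   `max_diameter` (default 10 µm) — both symptoms of blob or crossing
   artifacts.

Pooled diameters are summarized as a Gaussian kernel density
(Silverman's rule by default) renormalized on a grid over
[0, `grid_max`], plus a thin/thick split at `split_threshold` (default
2.0 µm, the midpoint between the two population means; it is reported
alongside the fractions so the dependence is explicit).

Pixel-size calibration is a required input, not a constant: bit depth
and magnification-to-pixel mapping vary by instrument.

# What the micrograph generator emulates — and what it does not

`generate_mycelium_image()` renders tubes of constant width along
smooth random centre-lines (random start and heading, small per-step
angular jitter; headings reflect at the frame border so placement stays
spatially uniform). Diameters are drawn from a one- or two-component
normal mixture; defaults (3.0 ± 0.3 µm and 1.0 ± 0.15 µm, equal
weights) are the two populations observed under starvation. Stained
tubes are rendered at intensity 0.2 on a 0.9 background; a configurable
fraction of tubes are unstained ghosts drawn only as faint
(intensity 0.6) one-pixel wall outlines, so the default binarization
excludes them — by stain contrast, exactly as in the assay. Ghost flags
are drawn after tube geometry, so two fixtures at the same seed that
differ only in `empty_ghost_fraction` share identical tubes; this makes
matched-population comparisons (a Kolmogorov–Smirnov invariant in the
test suite) exact rather than approximate. Overlapping tubes simply
union their masks: crossings are deliberate, they exercise the
junction-pruning step.

The default frame is 800 × 800 px at 0.2 µm/px; with the 45 tubes per
image used in the recovery fixtures this gives roughly 10 % foreground
coverage, typical of a dispersed-mycelium field. Much denser frames
make tube crossings — where rays traverse a neighbouring tube and
overestimate the width — unrealistically frequent.

Not emulated: optics (point-spread function, shading, depth of field),
conidiophores, branching statistics, 3-D stacks. Passing the recovery
tests therefore shows that the measurement chain is unbiased on
ribbon-like objects with realistic crossing rates and noise, not that
it is robust to every imaging artifact of a real microscope.

# Moderated t-tests

Expression matrices enter already normalized (linear or log2 scale,
flagged). Row filtering (control probes, genetic elements) and
multi-probe averaging (arithmetic mean per sample of all probes of a
transcript) precede testing. For each starvation day versus the
exponential baseline, the per-gene pooled two-group variance
$s_g^2$ (with $d_g = n_1+n_0-2$ degrees of freedom) is shrunk towards a
prior $s_0^2$ with $d_0$ degrees of freedom:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \frac{\bar x_{g1}-\bar x_{g0}}
 {\tilde s_g\sqrt{1/n_1+1/n_0}} \sim t_{d_0+d_g}.$$

The hyperparameters come from closed-form moment matching on
$\log s_g^2$: the mean and variance of the log variances are equated to
the theoretical moments of a scaled log-F distribution, with
$\operatorname{trigamma}(d_0/2)$ recovered by Newton inversion. When
the variance of the log variances does not exceed
$\operatorname{trigamma}(d_g/2)$ the moment equation has no positive
solution and $d_0=\infty$ (all posterior variances equal $s_0^2$) — the
stated fallback. Setting $d_0=0$ recovers the ordinary pooled t-test;
both limits are asserted numerically, and the whole fit is
cross-checked against an independent reference implementation of the
same empirical-Bayes method in the test suite.

Calls use Benjamini–Hochberg q-values at a **strict** threshold
(`q < 0.005`; the boundary value is not significant — the source
procedure does not specify boundary semantics, so strictness is a
documented choice) and **no fold-change filter**. BH is applied per
contrast across genes, not pooled across contrasts, matching the
per-day q-value columns of the study's tables. Reported linear fold
changes are ratios of arithmetic group means of unrounded linear
values; the test statistic works on log2 means. These agree exactly
only when replicates are constant within groups, and the divergence is
documented rather than hidden.

The three day-wise call sets feed seven-region Venn counts per
direction, the conjoint (triple-intersection) counts, and the fraction
of the universe differentially expressed at one or more time points.

# Enrichment and the common most-specific reduction

Enrichment is a one-sided Fisher exact test per term: with $N$
population genes ($K$ carrying the term) and $n$ study genes ($k$
carrying it), $p = P(X \ge k)$ hypergeometrically. Terms with $K=0$ are
not tested and do not inflate the BH denominator. For Gene Ontology,
annotations are first closed under `is_a` ancestors (true-path rule;
on by default, switchable — the original tooling's behaviour is not
documented). With no DAG the same code path serves flat Pfam- or
KEGG-style annotations.

The *common most-specific* reduction summarizes several enriched-term
sets (e.g. up-lists of day 1, 3, 6): the union of the sets is reduced
to its most-specific terms; for each, candidate terms are scanned in
order of increasing shortest `is_a` distance, and at the first distance
where at least one candidate is present in *all* input sets, all
equally distant qualifying candidates become common (otherwise the term
is non-common); finally terms that are proper ancestors of other common
terms are removed. Two interpretation points were genuinely open and
are resolved as follows:

* **Distance 0 included** (`include_self = TRUE` by default): a
  most-specific term present in every input set is itself common. The
  literal "check all parental terms" wording would mark a term shared
  by all sets non-common, which contradicts the purpose of reporting
  shared overrepresentation; both behaviours are implemented.
* **Distance = shortest directed path**: the conventional reading of
  GO-term distance, and the one an independent breadth-first oracle can
  verify. Only `is_a` edges are used.

The implementation is property-tested against an independently written
brute-force trace of the same seven steps (distances via `igraph`) on
200 random DAG/set instances.

# Numerical and design choices

* Coordinates are (row, column), origin top-left, 0-offset at the first
  pixel; 8-connectivity throughout.
* Every generator takes a `seed` and is a pure function of its
  arguments; randomness never leaks into or out of a call
  (`withr::with_seed`).
* The replicate layout defaults to triplicate exponential and duplicate
  starvation cultures, the study design this package emulates;
  `generate_expression()` plants log2 effects with per-gene, per-group
  random sign and fold changes uniform in `fc_range`.
* Degenerate inputs fail loudly and early: constant images warn and
  return an empty mask; fewer than two diameter samples is an error
  (pool more micrographs); cycles or dangling `is_a` targets in an OBO
  file are errors naming the offender.
* Problem sizes in the tests and acceptance script (five 800²
  micrographs with 45 tubes each; 2 000-gene expression studies over
  20 null and 10 signal seeds; 200 random DAG instances; 1 000 Fisher
  tables) were chosen so each suite completes in minutes on one CPU
  while keeping Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* Headline counts of the original study (7 292 differentially expressed
  genes of 13 989; 1 722/2 182 conjoint genes) require the deposited
  microarray data plus chip annotation and are not reproduced here; the
  synthetic studies validate the *procedures*, not those numbers.
* Ray-cast widths at tube crossings can traverse a neighbouring tube;
  junction pruning and the `max_diameter` cap bound, but do not
  eliminate, this inflation. At realistic densities it shifts the thin
  fraction by a few hundredths at most.
* The KDE with Silverman bandwidth slightly broadens narrow diameter
  modes; modes are recovered within a few percent, not exactly.
* RMA-style preprocessing, multi-factor designs, GO namespace
  semantics and term–term similarity are out of scope.
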