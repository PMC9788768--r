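---
title: "Methods: scoring and interpreting CRISPR gene-body tiling scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and interpreting CRISPR gene-body tiling scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescan)
```

## The problem

A high-density CRISPR gene-body tiling scan asks not *whether* a gene is
essential but *where* within its protein the essentiality resides. A pooled
library of sgRNAs targeting every NGG protospacer-adjacent motif across a
gene's coding exons is delivered to Cas9-expressing cells; guides whose cut
sites disrupt functionally required protein regions drop out of the
population during culture, while guides landing in dispensable regions
persist. Sequencing the integrated guide cassettes at the start and end of
the screen, and mapping each guide's depletion to the protein residue its
cut site disrupts, converts a dropout screen into a one-dimensional map of
functional protein elements — and, run in two cell lines, a map of
*cell-line-selective* elements.

This package implements the full analysis path: saturating library
enumeration, backbone-anchored read counting, control-anchored scoring,
kernel smoothing onto residue coordinates, element calling, structure
projection, a permutation-based gene ranking for TSS-targeting
(CRISPRi) screens, and a generative simulator used for validation.

## Library design

For a coding sequence of length $L$ (a multiple of 3), every 20-nt
protospacer immediately 5′ of an NGG on either strand defines a candidate
guide. Cas9 cuts bluntly between protospacer positions 17 and 18, 3 bp from
the PAM; we record `cut_left`, the coding-strand coordinate of the base 5′
of the cut, and keep a guide when the cut lies strictly inside the CDS
($1 \le \mathrm{cut\_left} \le L-1$). This retention rule is symmetric
under reverse complementation — mirroring the template mirrors the guide
set — and guides whose protospacer or PAM overhangs into supplied flanking
sequence are retained, since what matters is where the lesion lands. The
cut is assigned to the codon containing `cut_left`:
$\mathrm{residue} = \lfloor (\mathrm{cut\_left}-1)/3 \rfloor + 1$.

Saturating designs of this kind reach densities around one guide per 6–7
coding bp (`guide_density()`); for a 607-residue target tiled by 284
guides that is 2.1 aa/sgRNA.

## Quantification

Screen amplicons carry the protospacer between two invariant vector
sequences: `CACCG` (the hU6 cassette end) and `GTTT` (the scaffold start).
`extract_protospacers()` takes the 20 nt after the *first* `CACCG`
occurrence if and only if they are followed by `GTTT`; anything else emits
nothing. Matching against the library is exact and case-insensitive: the
anchors already guarantee register, sequencing error is rare enough at
these read lengths that fuzzy matching buys little, and exact matching is
deterministic. Reads are searched in a single orientation (the amplicon is
directional); a warning fires when fewer than half the reads anchor, the
signature of reversed inputs. A guide's frequency is its count divided by
the sample's total *matched* count, so unmatched reads do not dilute the
denominator.

## Scoring model

For each replicate with paired day-0 and day-24 samples, the raw score of
guide $i$ is the log10 fold change in its library frequency,

$$L_i = \log_{10}\frac{(c^{24}_i + a)/(T^{24} + aN)}{(c^{0}_i + a)/(T^{0} + aN)},$$

with pseudocount $a = 0.5$ (configurable; 0 allowed, at the price of
$-\infty$ for extinct guides) applied to counts before frequency
conversion; $T$ is the matched total and $N$ the library size. Guides whose
day-0 frequency falls below 5% of the mean frequency (equivalently
$0.05/N$ for normalised frequencies) are excluded from that replicate: a
guide absent at baseline carries no dropout information. The filter is
applied at day 0 — the natural baseline — since depletion itself empties
day-24 counts for exactly the guides the screen is about.

Raw scores are then anchored per replicate to the two control sets: the
median of the negative controls (nonessential targets) is mapped to 0.0 and
the median of the positive controls (pan-essential targets such as *MYC*,
*BRD4*, *RPA3*, *PCNA*) to −1.0 by the unique linear map

$$\mathrm{NCS}_i = \frac{M_{\mathrm{neg}} - L_i}{M_{\mathrm{pos}} - M_{\mathrm{neg}}}.$$

Anchoring per replicate, from unfiltered controls only, makes the score
scale-free: adding any constant to all raw scores (e.g. a depth change)
leaves every NCS unchanged, and the post-normalisation control medians are
0.0 and −1.0 *exactly*, by construction. Medians use the midpoint
convention for even control counts. Replicates are averaged after
anchoring (arithmetic mean over the replicates in which the guide
survived the filter); guides filtered everywhere are dropped with a
logged list. Averaging precedes smoothing so that the smoother sees one
value per guide.

## Smoothing onto residue coordinates

Guides cutting within the same codon are first averaged into a single
value per occupied residue. The profile is then a Nadaraya–Watson kernel
regression evaluated at every integer residue $r$:

$$\hat v(r) = \frac{\sum_k w_k v_k}{\sum_k w_k}, \qquad
  w_k = \exp\!\left(-\frac{(r - r_k)^2}{2\sigma^2}\right),$$

over the occupied residues $r_k$. The default bandwidth is $\sigma = 5$
residues: at a saturating density of ~0.5 guides per residue this pools
roughly 10–15 guides per evaluation point, enough to suppress single-guide
efficacy noise while preserving elements in the 14–19-residue range typical
of called functional segments. Because the estimate is a convex combination
of its inputs it is always bounded by their range, normalises edge weights
by construction, and degrades gracefully: as $\sigma \to 0^+$ it returns
the codon-averaged values (weights are rescaled per evaluation point by the
nearest support weight, so tiny bandwidths cannot underflow to 0/0). A
profile from a single occupied residue is constant, with a warning.

## Element calling

A CRISPR-hypersensitive element is a maximal run of consecutive residues
with smoothed NCS at or below the calling threshold, default −1.0 — the
positive-control anchor, i.e. "as depleted as guides targeting
pan-essential genes". Runs shorter than `min_length = 5` residues are
discarded as smoothing-scale noise; no gap merging is performed, so calls
are a pure function of the threshold and continuity is governed entirely by
$\sigma$. Boundaries are threshold crossings of the smoothed curve.
Lowering the threshold can only shrink the called residue set
(anti-monotone coverage), and elements are disjoint, sorted and labelled
N→C.

For two-cell-line comparisons, elements are called on line A and classified
against line B over the same interval: **selective** when B's mean stays
above the rescue floor (−0.5, halfway to the positive-control anchor —
"not sensitive in B"), **shared** when B itself dips to the calling
threshold inside the interval, otherwise **none** (intermediate). When a
brief deep dip in B coexists with a high mean, selectivity wins — the mean
is the primary evidence that B tolerates loss of the region; both of B's
summary statistics are reported so borderline calls are auditable.

## Structure projection

Two carriers are provided for rendering profiles on 3D models: the
molecular-viewer attribute format (`attribute:` / `match mode: 1-to-1` /
`recipient: residues` headers followed by `TAB:residue TAB value` lines,
written at full precision and parseable by `read_residue_attributes()`),
and B-factor substitution into a PDB model, which rewrites only columns
61–66 of `ATOM` records in the chosen chain — every other byte of the
model, coordinates included, is preserved — clamping to the fixed-width
range [−99.99, 999.99]. Scores are written raw; colour mapping belongs to
the viewer.

## Gene ranking for TSS-targeting screens

For CRISPRi screens where each gene carries a handful of TSS-targeting
guides, `gene_level_scores()` ranks genes by depletion: the gene statistic
is the median replicate-averaged raw log fold change of its guides, and its
one-sided p-value comes from a permutation null — medians of random
size-matched sets drawn with replacement from the negative-control guides —
with the standard $+1$ correction, $(1 + \#\{\mathrm{null} \le \beta\})/(1
+ n_{\mathrm{perm}})$, and BH adjustment across genes. This is a
deliberately transparent ranking, not a reimplementation of the published
robust-rank aggregation tools for such screens; it is depletion-only
(enrichment is reported as $\beta > 0$ without a p-value) and exactly
reproducible under a seed. On fully null screens its p-values are uniform
(checked in the test suite against binomial bounds).

## The synthetic screen generator

The simulator produces screens with the statistical structure the analysis
assumes — and, deliberately, nothing more:

* **Fitness truth.** Each guide carries a fitness deficit $s \le 0$
  (doublings per generation lost). Guides inside a planted essential
  interval get the interval's depth $s^*$; outside guides get
  $s^*\,e^{-d^2/(2\cdot 3^2)}$ for residue distance $d$ (a half-Gaussian
  boundary roll-off of scale 3 residues, mimicking partial disruption near
  element edges) minus half-normal baseline noise (sd 0.05, truncated at
  0). Negative controls sit at $s = 0$, positive controls at $s = -1$.
* **Growth.** Abundance scales multiplicatively, $w_i \propto p^0_i\,
  2^{g s_i}$, with $g = 8$ generations approximating 24 days of
  fast-growing culture passaged every 4 days. A positive control at
  $s=-1$ therefore shows a raw log10 fold change of
  $\log_{10} 2^{-8} \approx -2.41$ against the neutral controls — after
  anchoring, exactly −1 by definition.
* **Counting noise.** Day-0 proportions are Dirichlet around uniform with
  concentration 10 per guide (day-0 coefficient of variation ≈ 32%, a
  typical plasmid-library skew); observed counts are multinomial at the
  configured depth, independently per replicate. The
  Dirichlet–multinomial pair keeps the simulation compositionally coherent
  with the frequency-based scoring, which a per-guide negative binomial
  would not.
* **Reads.** `emit_fastq()` wraps each protospacer in the vector anchors
  with random padding to a fixed read length and constant qualities;
  prefixes are redrawn if they contain the `CACCG` anchor, so
  extraction recovers the generating counts *exactly* at error rate 0.
  Sequencing error is not simulated (the default matching is exact).

The reference conditions used throughout the validation suite and the
acceptance script are: a 600-residue protein, 290 tiling guides, 50 + 50
controls, essential intervals at residues 114–129 and 502–519 with depth
$s^* = -1.2$, three replicates, $2\times10^6$ reads per sample, $\sigma =
5$. Under these conditions the pipeline recovers each planted interval
with Jaccard ≥ 0.5 and calls nothing on null screens, in at least 9 of 10
seeds — checked, not assumed, by the test suite. These sizes keep the
whole validation run in seconds on one core while leaving per-guide counts
(~5000 reads) deep enough that anchoring noise is negligible.

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real screens: position- and chromatin-dependent
cutting efficiency, off-target effects, in-frame repair producing
functional alleles (which attenuates true signals), PCR jackpotting beyond
Dirichlet skew, and sequencing error. Real profiles are noisier and real
element boundaries softer than simulated ones.

## Numerical choices and edge cases

* Pseudocount 0.5 keeps extinct guides finite; setting it to 0 reproduces
  the pure frequency ratio and is used in the hand-checked tests.
* Degenerate anchors ($M_{\mathrm{pos}} = M_{\mathrm{neg}}$), all-filtered
  control sets, zero-depth samples, and d0/d24 pairing gaps are hard
  errors — silently continuing would corrupt every downstream score.
* A CDS shorter than 23 nt without flanks yields an empty library with a
  warning, not an error; PAMs whose protospacer would run off the supplied
  sequence are skipped silently.
* B-factor clamping and absent chains warn rather than fail, since the
  annotation is a rendering aid.
* All stochastic components (control protospacer draws, simulation,
  permutation nulls) are reproducible under explicit seeds, and seeded
  code restores the caller's RNG state.

## A worked example

```{r example}
sim <- simulate_screen(seed = 1)
fit <- tiling_scan(sim$counts, sim$truth$manifest)
summary(fit)
```

```{r plot, fig.width = 7, fig.height = 4}
plot(fit)
```

The two called elements recover the planted intervals; the control medians
sit at their defining anchors.

## Known limitations

Single-CDS coordinates only (no introns or multi-exon genomic mapping); no
guide-efficacy covariates or off-target filtering; no variance bands on the
smoothed profile; element significance is by construction of the anchored
scale rather than by permutation FDR; the gene ranking is a transparent
stand-in, not a drop-in replacement for the published screen-analysis
tools.
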