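---
title: "Methods: calling RNA-protein interactions from protein microarray scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling RNA-protein interactions from protein microarray scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpscreen)
```

## The experiment and its signal model

A labeled RNA probe is incubated on a slide spotting ~9,400 recombinant
human proteins in duplicate, organized in sub-array blocks that each carry
bright positive-control features. The scanner reports, per spot, a
foreground median intensity at 635 nm (`F635`) and a local background
median (`B635`). The quantity analysed everywhere in this package is the
per-spot ratio

$$r = F_{635} / B_{635},$$

which is close to 1 for proteins the RNA does not bind — fluorescence
bleeds onto every spot roughly in proportion to its local background — and
elevated for bound proteins. Working on the ratio scale makes spots
comparable across a slide whose background varies smoothly by position.

Each protein's duplicate spots are summarised two ways:

* the **mean ratio** $\bar r_p$, used for the array-wide outlier statistic;
* the **minimum ratio** $\min_j r_{pj}$, used for the fold filter, so that a
  single bright speck of dust on one spot cannot create a hit.

The outlier statistic is a plain global Z-score,
$z_p = (\bar r_p - \mu)/s$, where $\mu$ and $s$ are the mean and sample
(n−1) standard deviation of $\bar r_p$ over all *non-control* proteins on
the same array. Controls are excluded because they are engineered bright
and would inflate $s$; at ~9,125 proteins the n vs n−1 choice is
numerically immaterial but is fixed for reproducibility. No log transform
is applied: the screening rule thresholds raw fold values, and we keep the
statistic on the scale on which its cutoffs are defined.

## The hit-calling rule

A protein is called a hit for one incubation when both of

* every duplicate ratio ≥ `fold_min` (default **2.5**), and
* $z_p$ ≥ `z_min` (default **3.0**)

hold. Both comparisons are **inclusive**; written descriptions of such
rules mix "greater than" and "at least", and we settled on ≥ so that a
protein sitting exactly on a published threshold is called. The rule is
monotone: raising either threshold can only remove hits (property-tested).

Probing the **antisense** transcript of the same locus provides a
per-locus specificity control: proteins that bind RNA without sequence
preference light up on both strands. `sense_specific()` removes any
protein significant on the antisense scan from the sense hit list (a set
difference at equal thresholds). The remaining interactions populate a
binary protein × RNA matrix; only proteins with at least one interaction
are kept as rows.

Proteins significant in a large fraction of *all* incubations — sense and
antisense alike, since stickiness on either strand is evidence of broad
binding — are reported separately by `common_binders()`. The denominator
is the full number of incubations (20 for a 10-locus screen), and the
default cutoff 0.75 corresponds to ≥ 15 of 20 scans.

## Clustering

The interaction matrix is clustered for display with agglomerative
hierarchical clustering, average linkage, on the **Jaccard distance**
between binary profiles. The classic desktop clustering tools leave the
metric to the user; Jaccard is the natural choice for sparse binary
profiles because shared absence carries no information here. Rows are
sorted lexicographically before clustering so output is deterministic, and
a small helper computes the distance with the convention d(∅, ∅) = 0
(needed for RNA columns with no hits, where the generic binary distance is
undefined). Ties in the merge sequence are therefore broken by label
order.

## Replicates, overlap, enrichment

* `replicate_concordance()` — Pearson r (and r²) of per-protein mean
  ratios between two scans, over all mutually usable non-control proteins,
  not only hits: concordance should hold across the whole dynamic range.
* `overlap_significance()` — one-sided Fisher exact test (the
  hypergeometric upper tail $P(X \ge k)$) for the overlap of two hit sets
  in a finite universe. One-sided over-representation is the only
  direction meaningful for replicate agreement.
* `term_enrichment()` — the same tail per annotation term, with the
  spotted-protein universe as background (not the genome: only spotted
  proteins can be hits). Benjamini–Hochberg correction is applied across
  all tested terms. The **EASE** variant (one hit removed from the term
  overlap before taking the tail, the conservative default of the DAVID
  web service) is available as `ease = TRUE`; the package defaults to the
  exact hypergeometric because a precisely defined statistic is easier to
  reproduce than a web service's.

All hypergeometric tails are validated in the test suite against
brute-force enumeration over every 2×2 table with universe ≤ 60, at 1e-12.

## Labeling QC

The dye-incorporation formulas use Beer–Lambert with a 1 cm-equivalent
normalized absorbance. Dye density is

$$\text{pmol dye} / \mu g\, \text{RNA} = \frac{A_{dye}}{\varepsilon_{dye}} \cdot V \cdot 10^{6} / m,$$

with $\varepsilon_{dye} = 250{,}000\ \mathrm{M^{-1}cm^{-1}}$ (Cy5), $V$ the
solution volume in µl (default 16, the protocol's resuspension volume) and
$m$ the RNA mass in µg. Absorbance is a concentration proxy, so a volume
is required to reach an amount; formulas quoted without it implicitly
assume a fixed volume, and making it explicit keeps the units honest —
users of cuvettes or drop spectrophotometers can supply their own
convention. The Base:Dye ratio is

$$\frac{(A_{260} - 0.05\, A_{dye})\, \varepsilon_{dye}}{A_{dye}\, \varepsilon_{base}},\qquad \varepsilon_{base} = 8250\ \mathrm{M^{-1}cm^{-1}},$$

the 0.05 being Cy5's bleed-through into the 260 nm reading. The acceptance
window of one dye per 700–1200 nt (inclusive at both ends) balances
scanner-visible signal against perturbation of native RNA structure; a
reference reading of (A260 = 0.843, A_dye = 0.03) gives exactly 850 nt per
dye with ~3 pmol dye per µg RNA.

## The simulator

`sim_config()` describes a screen; its defaults are the study conditions
the package is designed around and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 9125 | non-control proteins, spotted in duplicate |
| `n_blocks` | 48 | 22 × 22-spot sub-arrays (242 duplicated features each at most), duplicates adjacent |
| `controls_per_block` | 2 | bright positive-control features per block |
| `n_rnas` | 10 | loci, each probed sense + antisense (20 scans) |
| `background_log_mean`, `background_log_sd` | log 500, 0.4 | log-normal per-protein background level |
| `nonspecific_log_sd` | 0.1 | SD of the log ratio of non-binders (and around planted folds) |
| `duplicate_log_sd` | 0.05 | spot-to-spot log perturbation of the background level |
| `n_planted`, `planted_fold_range` | 137, 3–8 | sense-specific interactions; the fold range brackets validated examples near 3.2–3.6 |
| `n_shared`, `shared_fold_range` | 28, 3–6 | common binders, applied to both strands of 7–10 loci |

Noise is log-normal on both multiplicative scales (background and ratio),
the standard choice for fluorescence intensities. The generative model per
spot is `B635 = b · exp(δ)` with protein-level `b` and duplicate
perturbation `δ`, and `F635 = B635 · r` with `log r ~ N(log f, σ²)` where
`f` is the planted fold (1 for non-binders). Note that the measured ratio
is then exactly `r`: the duplicate perturbation moves the spot's
background level, not the ratio, which mirrors how ratio-based
quantification cancels spatial intensity variation. Intensities are
rounded to integers as a scanner reports medians. One master seed drives
everything; each scan derives a substream from (seed, rna, strand,
replicate), so any scan is reproducible in isolation and a replicate tag
gives fresh noise on identical truth.

What the simulator does **not** emulate: spatial artifacts (scratches,
gradients, edge effects), saturation, carry-over between duplicates
printed from one pin dip, or any correlation between protein abundance on
the spot and binding signal. Passing tests on simulated data therefore
demonstrate the correctness of the statistics and plumbing under a clean
noise model, not robustness to the failure modes of physical slides —
flagged-spot handling and the duplicate-minimum filter are the package's
defences there.

## Numerical and degenerate-input choices

* Spots with a negative scanner flag are kept at parse time and excluded
  at aggregation, so the exclusion is auditable (`attr(stats, "report")`);
  a spot with non-positive background is excluded the same way rather
  than producing an infinite ratio.
* A scan whose mean ratios are all identical has an undefined Z-score;
  `add_zscores()` errors by default, but the pipeline maps this degenerate
  case to all-zero Z-scores with a warning so that a perfectly flat null
  array yields an empty hit list rather than an abort.
* Control features are identified by configurable case-insensitive
  patterns (`default_control_patterns()`); array vendors vary their
  control nomenclature, so the list is a parameter, not a constant.
* Common-binder percentages are compared against the cutoff with a 1e-9
  slack so that 15/20 = 75 % passes a 0.75 threshold despite floating
  point.
* GPR parsing accepts both `ATF<TAB>1.0` and `ATF 1.0` magic lines,
  quoted or unquoted headers, and case-insensitive column names, because
  scanner exports vary; it refuses files with missing required columns,
  non-numeric intensities (reported with the row number), or duplicate
  spot coordinates.

## Problem sizes used in the shipped checks

The test suite exercises the full slide geometry (9,125 proteins, 20
scans) for the exact-recovery and error-rate checks — a noise-free screen
must reproduce its 137 planted interactions exactly, and with ratio noise
σ = 0.1 and planted folds ≥ 4, pooled sensitivity ≥ 0.95 and false-discovery
proportion ≤ 0.05 over 20 seeded screens. Unit and property tests run on
small configurations (hundreds of proteins, 3 loci) where the property at
stake does not depend on scale. `scripts/acceptance.R` recomputes the
headline quantities at full scale from a fresh seed on every run.

## Known limitations

* Between-array normalization is deliberately absent: each array is
  filtered against its own distribution, so scans of very different
  overall signal are comparable only at the hit-list level.
* Enrichment requires a pre-closed annotation map (ontology ancestors
  already propagated); no graph propagation is performed.
* The binary matrix ignores interaction strength; fold values remain
  available in the per-scan hit tables.
* Proteins flagged unusable on one array still count against the
  common-binder denominator for that array — every incubation is treated
  as a trial.
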