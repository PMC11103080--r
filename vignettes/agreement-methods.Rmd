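---
title: "Measuring multi-annotator agreement on ultrasound structure annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multi-annotator agreement on ultrasound structure annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoAgree)
```

## The problem and the data model

Assistive AI devices for ultrasound-guided regional anaesthesia (UGRA)
highlight anatomical structures on B-mode images. Evaluating such a device
against one or two experts conflates two things: how far the AI sits from
expert opinion, and how far experts sit from one another. `sonoAgree`
quantifies both on the same footing: every human annotation of a structure on
a scan is compared with every other human annotation (H-H), and the AI
annotation is compared with every human annotation (H-AI), with identical
metrics and pooling.

A study is described by a manifest: an annotator panel (humans plus at most
one AI), scans with explicit pixel dimensions (coordinates are validated
against them), and a structure catalogue. The default catalogue covers the
six "Plan A" block regions — interscalene (ISB), axillary (AxB), erector
spinae plane (ESPB), rectus sheath (RSB), adductor canal (ACB) and popliteal
sciatic (SNB) — with 20 quantitative structures in four classes. Arteries,
muscles and nerves are drawn as closed polygons ("region" kind);
fascial/serosal planes as open polylines ("line" kind). The pleura is carried
in the catalogue for qualitative assessment but flagged out of the
quantitative set, which is what reconciles the 20-structure count with the
region lists. Structures that the AI predicts as one unit are analysed as one
unit: the C5 and C6 nerve roots merge, as do the anterior and posterior
rectus sheath layers, giving 18 analysis groups. Region groups are compared
as the union mask of their members' polygons; line groups as the pooled point
set of their parts.

Annotations carry a four-way status. `present` holds geometry; `absent`
records a structure deemed not visible; `invalid_geometry` records a drawing
of the wrong kind (an enclosure for a line structure or vice versa) whose
geometry is discarded at detection, keeping only the flag; `image_skipped`
marks a scan an annotator never annotated. Coordinates use the raster
convention — origin at the top-left corner, x rightward, y downward, in
pixels — and are stored to 0.01 px, which preserves sub-pixel annotation
fidelity without float-noise churn in round-trips.

## Curation and the accounting audit

The inclusion rules operate per human annotator and scan, after grouping.
A scan on which an annotator annotated nothing is assumed to have been
omitted in error: all of its grouped entries are removed and counted as image
skips. A structure left unannotated while at least one other structure on the
scan was annotated is kept as an explicit empty "not visible" annotation.
Wrong-kind entries are removed and counted separately. The AI annotator is
exempt from the skip rule — an empty AI output is a genuine "not highlighted"
prediction and scores as absent. Two invariants hold on every input:
`analysed = grouped_potential − total_removed`, and removals partition into
skips plus wrong-kind. Curation marks its output, and a second pass is
defined as a no-op: once entries have been removed, a later pass cannot
distinguish them from never-annotated structures, so idempotence is achieved
by construction rather than re-derivation.

The deterministic `replicaStudy()` fixture exercises the full chain at the
standard panel size: 19 experts × 100 structure instances = 1900 potential
annotations, 1710 (19 × 90) after grouping, one annotator skipping one ISB
scan (3 grouped structures) and one ESPB scan (2), plus 26 wrong-kind
annotations placed (seeded, uniformly) on distinct ungrouped structures,
leaving 1679 analysed. The placement of the wrong-kind events does not affect
the audit totals, only which cells they land in.

## The metrics and their numerical choices

**Dice.** Computed on rasterized masks at native scan resolution, not on
polygon areas: the AI overlay is raster-native, and rasterization makes
"area" and "overlap" unambiguous for hand-drawn, possibly self-intersecting
outlines. A pixel is inside iff its centre lies inside the polygon under the
even-odd rule (deterministic and robust to small stylus crossings); grouped
components are OR-ed. On a 200×200 grid the rasterized Dice of two
radius-20 disks is within 0.01 of the closed-form circular-lens value, and
the rasterizer agrees *exactly* with an exhaustive pixel-centre
point-in-polygon test on 64×64 grids — both are standing tests.

**Hausdorff.** Drawn vertices are sparse, so chains are first resampled at
0.5 px arc-length spacing (keeping all original vertices); the point-set
distance then approximates the curve distance to sub-pixel accuracy
regardless of how annotators spaced their clicks. The default distance is the
symmetric max-of-min (the standard metric); a flag restores the literal
one-directional procedure, which matters for asymmetric cases such as a short
chain lying on a long one. The score normalizes by the longer image side
("maximum length/width of image"); since a distance can exceed that side, the
score is clamped at 1. A diagonal-denominator mode is provided, under which
clamping never triggers.

**Empty conventions.** One-sided disagreement — one annotator drew the
structure, the other deemed it not visible — scores 0 (Dice) / 1 (Hausdorff),
which is what produces the 0.00 minima typical of pooled panel tables.
Mutual absence carries no information about geometric agreement, so
both-empty pairs are excluded from pools and reported as a separate count;
a `bothEmpty = "perfect"` policy (1 / 0) exists for sensitivity analysis.

**Pooling.** All raw pairwise values across a structure's scans form one
pooled distribution per structure (not per-scan means averaged): a single
min–max range reaching 0.00 is only meaningful on pooled raw pairs. The
reported sd is the sample standard deviation (n − 1), flagged undefined for a
single pair; the median of an even pool is the midpoint of the central pair;
scopes with nothing poolable yield rows flagged with `n_pairs = 0` rather
than disappearing. Scores are rounded to 2 decimals only at presentation.

## The synthetic study generator

No public repository of raw expert panel annotations exists for this setting,
so the generator is a first-class module: it produces complete, loadable
studies with the statistical structure the analysis assumes.

Scenes are parametric: arteries are small near-circular blobs (radius
15–25 px at the default 512×384 scan size), nerves small flatter blobs
(9–16 px), muscles large elongated ellipses (45–70 px), all with low-order
harmonic boundary wobble; fascial planes are smooth open curves spanning most
of the image width. Annotators are profiles: Gaussian translation jitter of
the structure position (default σ 2 px), smooth correlated boundary noise
built from a low-order Fourier series along the outline parameter (default
σ 2.5 px, radial for outlines, perpendicular for lines — the low order keeps
perturbation periods ≥ 4 vertices and prevents self-intersection at default
amplitudes; radial excursions are clipped at 10% of the local radius),
log-normal area scale jitter (default σ 0.05), and the three error processes
seen in real panels: omitting a visible structure (p = 0.03), drawing the
wrong geometry kind (p = 0.015), skipping a whole scan (p = 0.003). The
defaults were chosen once as plausible for a consultant-level panel —
per-structure error rates of a few percent and whole-image skips of order
1 in 300 match the accounting a 19 × 90 panel produces (31 of 1710 removed).

Two design choices matter for interpretation:

* **Class difficulty is a multiplier, not a score.** Per-class multipliers
  (artery 0.7 < muscle 1.4 < nerve 3, fascia 1.5) scale every annotator's
  noise sigmas, mirroring how arteries (anechoic, pulsatile, sharp-walled)
  are easier targets than isoechoic, anatomically variable nerves. The
  resulting agreement ordering artery > muscle > nerve is an emergent
  property of the pipeline, asserted as an ordering in tests — never as
  target values.
* **Noise scales with structure size.** Effective sigmas are additionally
  multiplied by the structure's size relative to a radius-20 disk, so a
  70-px muscle attracts proportionally larger absolute uncertainty than a
  10-px nerve. Without this, class agreement would be dominated by how large
  each class's structures happen to be rather than by the difficulty
  parameters, and the ordering would be fragile.

The AI annotator is one more profile, by default with a larger positional
bias (translation σ 3 px) but smaller boundary noise (σ 1 px) and no
skip/wrong-kind errors — a deterministic system does not forget scans. This
reproduces the qualitative pattern that H-AI means sit slightly below H-H
while H-AI spreads are smaller, without hard-coding either.

Everything derives deterministically from a master seed via per-scan,
per-annotator sub-seeds, so a study serializes byte-identically across runs.

What the generator does **not** emulate: B-mode texture (only geometry is
simulated, so nothing can be said about image-driven failure modes), spatial
correlation of errors across structures in one scan, annotator-specific
systematic styles (all humans share one profile by default), or anatomical
co-location constraints between structures. Passing simulation tests
therefore validates the *analysis machinery* and its calibration — not any
claim about real expert behaviour.

## Calibration checks

Three simulation properties are verified routinely, with fixed seeds:

1. **Noise monotonicity** — mean pairwise Dice over 110 simulated pairs
   strictly decreases across boundary-noise levels 0.5, 2 and 5 px.
2. **Ordering recovery** — a 6-human, 12-scan study at 192×144 px (sizes
   chosen to keep the default suite fast; the ordering is scale-stable
   because noise tracks structure size) recovers artery > muscle > nerve in
   mean Dice, H-H and H-AI, across seeds.
3. **Jitter expectation** — with pure translation jitter σ = 5 px on a
   radius-20 disk, the centre offset is Rayleigh(σ)-distributed, so the
   expected Dice is the closed-form lens Dice integrated against that
   density (`expectedDiceTranslationJitter()`, via `stats::integrate`). The
   500-replicate Monte-Carlo mean at 200×200 px falls within 3 standard
   errors of this semi-analytic value.

## Qualitative module

Expert judgments of the AI overlay (TP/TN/FP/FN per structure,
risk-modification judgments per applicable adverse event, subjective 0–10
block scores) aggregate to proportions with their counts preserved.
Denominators always reflect the assessments actually recorded — missing
entries are represented as unrecorded, never imputed — which is why a
13-of-15 panel yields rates over 13. Event applicability is region-bound
(pneumothorax tallies make no sense for an adductor canal block) and
violations raise errors naming the region and event. The bundled
`qualitativeCounts()` table ships printed count cells from a published
15-assessment evaluation; `expandQualCounts()` reconstitutes per-expert
records from them (combined correct cells are labelled TP, since TP and TN
are not separable in a (TP+TN) cell — no rate depends on the split).

## Limitations

Dice and Hausdorff carry no clinical threshold: the framework reports
agreement, not adequacy. Rasterized Dice inherits O(perimeter/area) grid
error, negligible at native scan resolution but visible below ~64 px
structures; the minimum supported scan size is 64×64 px. The Hausdorff score
saturates at 1 under the max-side denominator. Vote maps are area-based only;
line-kind groups are rejected rather than approximated. The generator's
realism caveats above apply to any conclusion drawn from simulated studies.
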