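---
title: "Tracking labeled masks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking labeled masks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masktracker)
```

## The linking model

`masktracker` treats tracking as a sequence of independent two-frame
decisions. Objects are whatever the upstream segmentation delivered: one
positive integer label per connected region, background zero. No intensity
information is used — the tracker is deliberately blind to how the masks
were produced, which is what makes it segmentation-independent.

The linking cost between object $i$ at time $t$ and object $j$ at $t+1$ is

$$\mathrm{Cost}(i,j) \;=\; w_o\,(1 - O_{ij}) \;+\; w_c\,\delta_c(i,j)
\;+\; w_s\,\delta_s(i,j),$$

where each term is dimensionless and bounded in $[0,1]$ so that the three
weights are directly comparable:

* $O_{ij} = \dfrac{|i \cap j|}{\min(A_i, A_j)}$. Normalizing the shared
  pixel count by the *smaller* area means full engulfment of the smaller
  object scores 1. This keeps the overlap term informative through the two
  events where areas legitimately change a lot — division (daughter is half
  the mother) and under-segmentation (cluster is twice a source). The more
  common intersection-over-union normalization would penalize exactly those
  cases.
* $\delta_c = \min(d_{ij}, d_{\max}) / d_{\max}$, the centroid displacement
  capped at the largest plausible per-frame displacement $d_{\max}$.
* $\delta_s = |A_i - A_j| / \max(A_i, A_j)$, the relative area change.

A pair with *zero* overlap whose centroids are more than $d_{\max}$ apart is
infeasible: it can never be linked, which keeps the assignment sparse and
rules out teleporting identities. Pairs that do overlap are always feasible
regardless of distance (overlap is direct evidence of identity).

The assignment itself is the classical rectangular Hungarian problem,
solved exactly by a shortest-augmenting-path (Jonker–Volgenant style)
implementation in the package. Infeasible pairs are encoded as a finite
sentinel larger than any achievable total, so the solver returns the
minimum-cost matching among those of maximum feasible cardinality; sentinel
matches are dropped afterwards. Ties between equal-cost optima resolve
deterministically by the solver's fixed scan order (earlier rows and
columns preferred). We do not guarantee the lexicographically least optimal
matching — that is a strictly harder problem than assignment, and
determinism, not a particular tie, is what reproducibility needs.

Linking is strictly consecutive-frame; there is no multi-frame or
multi-hypothesis optimization. This is what bounds memory to two frames and
makes the runtime linear in sequence length.

## Event handling around the assignment

**Collisions.** When cells touch, segmentation frequently fuses them into
one label. A label $j$ at $t+1$ is declared a collision cluster when at
least two labels at $t$ each overlap $j$ by at least
`min_collision_overlap` of their own area (default 0.5: each source must be
majority-covered, which distinguishes a genuine merge from grazing
contact). The cluster is then split *before* mitosis detection and
assignment: each source's footprint intersection with the cluster seeds a
region, and every remaining cluster pixel joins the seed with the shortest
within-cluster 8-connected path (a geodesic distance, so the split respects
the cluster's geometry around concavities — a Euclidean nearest-seed rule
would cut across background). Equal distances go to the lower source label.
The split conserves the cluster's pixel count exactly and the sources
continue their tracks into the parts directly, bypassing the assignment.
Cluster pixels unreachable from any seed (possible only when a label's
region is disconnected) fall back to the nearest seed centroid.

**Fusion.** For colony tracking the same many-into-one evidence is not an
error but the phenomenon of interest. With `enable_fusion = TRUE` masks are
never modified; the parents' tracks end (`fused`), a child track is born,
and a fusion edge records the relation — the lineage tree runs in reverse.

**Mitosis.** Four indicators must all hold: (1) exactly two objects at
$t+1$ overlap the mother by at least `min_division_overlap` (default 0.2)
of their own area with the mother as their dominant source — if more than
two fragments qualify, the two largest-overlap fragments are tested as the
pair, the rest become new objects; (2) the mother's circularity
$4\pi A/P^2$ is at least `min_mother_circularity` (default 0.3) — cells
round up before dividing; (3) the daughters' combined overlap covers at
least `min_division_overlap` of the mother (low migration during division);
(4) daughter areas and aspect ratios agree within
`min_daughter_size_similarity` (0.5) and `min_daughter_aspect_similarity`
(0.7). Roundness is evaluated on the mother at frame $t$ only; a
multi-frame roundness trend would need a look-back buffer and a second
window parameter without changing the single decisive frame, so we kept the
single-frame test. The defaults are deliberately permissive — they are
meant to be tightened per cell line, and every one is in
`tracking_config()`.

**Dispositions.** Whatever the assignment leaves unmatched is explained:
unmatched at $t$ → mitotic mother, border exit, or interior death;
unmatched at $t+1$ → daughter, border entry, or interior birth. Every
object in every frame receives exactly one disposition, so object counts
always balance.

## Confidence index

Per track, the confidence is the mean of four binary indicators: lifespan
at least `min_track_lifespan` frames (default 5); never touching the image
border; never involved in a collision split or fusion; and no
frame-to-frame link costing more than half the maximum cost scale
$(w_o + w_c + w_s)/2$. The composition is this package's own: it covers
track completeness, boundary truncation, contact ambiguity and link
quality, and the four raw indicators are returned alongside the average so
users can re-weight them.

## Conventions and numerical choices

* Coordinates are 0-based `(row, col)`; centroids are unweighted means of
  pixel coordinates; frame numbers in all outputs are 0-based in mask file
  order.
* Connectivity is 8-connected everywhere (region adjacency, geodesic
  splits): phase-contrast cell masks are thin-bridged, and 4-connectivity
  would split them spuriously.
* Perimeter is the boundary-pixel count (object pixels with a 4-neighbour
  outside the object), the convention of the established image-analysis
  packages; circularity $4\pi A/P^2$ is clipped to 1 where discretization
  pushes it above. Note this convention reads moderately wavy blobs as
  fairly round; strongly elongated shapes still separate cleanly (a 10×40
  bar scores ≈ 0.55).
* Aspect ratio comes from the moment-equivalent ellipse with the $1/12$
  unit-pixel variance added to the second central moments, so a single
  pixel scores exactly 1 and a $1 \times L$ line scores $L$.
* Masks are written as 16-bit TIFF up to label 65535 and as scaled 32-bit
  samples above (exact round-trip for labels below $2^{23}$). Files whose
  pixel data are not non-negative integers are rejected.
* Degenerate inputs: an all-zero frame is a valid empty frame (all tracks
  passing through it die/are born around it); a one-frame sequence is a
  usage error; an all-infeasible cost matrix yields an empty matching.

## Accuracy metrics

Estimated tracks are mapped to reference tracks either by per-frame optimal
assignment on centroid distances gated at $\varepsilon$ (default 5 px, the
customary tolerance for simulated particle data — pairs at distance
$\ge \varepsilon$ are forbidden), or by mutual maximum overlap (each object
the other's unique argmax), the convention for extended objects whose
centroid definition is ambiguous. Optimal per-frame pairing rather than
greedy nearest-first keeps the metrics independent of object enumeration
order.

With $D$ the sum over reference positions of the paired distance (or
$\varepsilon$ when unpaired) and $D_{\mathrm{dummy}} = \varepsilon \cdot
n_{\mathrm{ref}}$:

$$\alpha = 1 - D / D_{\mathrm{dummy}}, \qquad
\beta = \frac{D_{\mathrm{dummy}} - D}
 {D_{\mathrm{dummy}} + \varepsilon\, n_{\mathrm{FP}}},$$

so $\alpha$ ignores spurious estimated positions while $\beta$ penalizes
them, and $0 \le \beta \le \alpha \le 1$ with equality iff no spurious
positions exist. Jaccard is $TP/(TP+FN+FP)$ over frame-to-frame decisions;
Jaccard Theta applies the same ratio to complete tracks (a reference track
counts as recovered only when one estimated track shadows its entire
lifetime). The degenerate empty-vs-empty case is defined as 1 and logged.
These closed forms follow the metrics' published descriptions
(distance-proportional, FP-ignoring vs FP-penalizing); the exact
normalizations in the original challenge scoring plugin are not public, so
ours are documented here as the package's definitions.

## What the simulator does and does not emulate

The simulator produces labeled masks plus exact ground truth. Particles are
rigid disks under Brownian, directed, or heading-switching motion with
reflective boundaries; Brownian tracks verify the 2D diffusion law
$\mathrm{MSD}(t) = 2\sigma^2 t$. Cells are deformable blobs — disks with a
low-order radial Fourier perturbation, chosen precisely so circularity and
aspect ratio are controllable and the four mitosis indicators can be
exercised independently. A division is announced two frames ahead (the
mother sheds its perturbation, rounding up) and then splits into two
equal-area daughters displaced symmetrically inside the mother's footprint.
Under-segmentation is emulated by collapsing touching cells into one label
in a *degraded* copy of the sequence while the truth keeps them separate;
per-frame labels are renumbered in raster order, as an independent
segmentation would. Colony fusion truly merges objects in both sequences
and freezes the partners' relative offsets.

The simulator renders masks only — no photometric noise, point-spread
functions, segmentation jitter along boundaries, apoptotic shrinkage, or
3D. Passing the end-to-end suites therefore shows that the *tracking logic*
is correct under controlled geometry and motion; it does not certify
performance on any particular microscope's segmentation errors, whose
boundary noise and systematic biases are outside the masks-only model.

## Validation problem sizes

The shipped test-and-acceptance battery uses: 200 random gated cost
matrices up to 6×6 against exhaustive enumeration; 15 well-separated cells
over 20 frames in a 320² field (exact recovery, all four metrics 1.0, and
stability under ±25% perturbation of each cost weight); 10 scheduled
divisions over 26 frames in 360² plus an equal-length division-free
control; a 20-cell, 30-frame, 200² contact scenario producing 50+ merge
events (exact pixel conservation, ≥95% identity agreement); a 3-colony
fusion sequence with two merges; and a 200-frame 512² streamed sequence
whose peak memory is compared against a 4-frame run. These sizes keep the
full battery in the low minutes on one core while still covering every
event type; all scenarios are regenerated from seeds at test time, never
stored.

## Known limitations

* Consecutive-frame linking only: an object that vanishes for one frame
  (segmentation dropout) ends its track and restarts as a new one.
* Collision splitting requires the sources to have been individually
  resolved in the previous frame; clusters present from frame 0 cannot be
  split, and a cluster that later separates will be read as a
  division-like event if it passes the mitosis criteria.
* Divisions into more than two fragments are resolved as one daughter pair
  plus new objects.
* The mother-roundness test is single-frame; slowly rounding mothers with a
  noisy final frame can be missed at strict thresholds.
* Metrics require the two mask sequences to share frame counts and
  dimensions; there is no partial-overlap alignment.
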