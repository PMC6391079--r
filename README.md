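# motionmesh

Superpixel optical-flow tracking and dynamic-mesh statistics for
collective cell migration in timelapse microscopy.

## What it is for

Assays in which dyed epithelial cell populations migrate, meet and form
(or fail to form) boundaries produce videos of thousands of densely packed
cells. Tracking single cells in such data is fragile; `motionmesh` instead
partitions frame 0 into regular, near-square **superpixels**, propagates
each one through time by averaging a dense Farnebäck optical-flow field
over its footprint, and analyses the resulting long-time tracks through
graphs built over them. It is aimed at quantitative biologists comparing
motion phenotypes across video cohorts — boundary formation, gap closure,
collectiveness, intermixing — without cell segmentation.

## The statistics at its core

With superpixel track positions $r_i(t)$ and the frozen frame-0 mesh
$N_i$ (neighbours within 1.2 average superpixel widths):

* **Mesh strain curve**
  $\varepsilon_i(t) = \frac{1}{|N_i|}\sum_{j \in N_i} \bigl| \,\lVert r_{ij}(t)\rVert - \lVert r_{ij}(0)\rVert \,\bigr|$,
  averaged over superpixels (and channels); **mesh stability index** =
  $1 -$ end gradient of the normalized curve on time rescaled to $[0,1]$.
  A plateaued (stable) video scores 1.
* **Mesh order**: the order parameter
  $\psi = \lVert \langle d_i/\lVert d_i\rVert \rangle \rVert$ computed on
  resultant mesh strain vectors $d_i(t)$ instead of velocities.
* **MSD** $\langle |r_i(t+\Delta t) - r_i(t)|^2 \rangle \sim \Delta t^\alpha$
  ($\alpha = 1$ diffusive, $\alpha = 2$ ballistic), **RMSD**, and spatial
  velocity correlation fitted with $a e^{-r/b}$.
* **Normalized velocity cross-correlation**: max-absolute
  cross-correlation of standardized 2-D velocity series over all lags,
  exactly 1 on self, bounded by 1.
* **Motion saliency map**: per-frame radius-neighbour-graph degree written
  at each superpixel's position, averaged over time and the frame-0
  partition; the **boundary formation index**
  $(\mu_{high} - \mu_{low})/\mu_{high}$ after an Otsu split scores 0 for
  uniform motion and 1 for motion concentrated on a line.
* Gap-closure detection (sweepline fronts, asymmetric-least-squares
  baseline), boundary lines with shape/infiltration/intermixing
  descriptors, kymographs, PCA motion maps of strain-curve signatures,
  and GMM/BIC clustering of superpixel tracks.

A bundled generator renders two-channel synthetic sheet-closure videos
with scripted outcomes (`coalesce`, `stable_boundary`, `push_through`) and
exact ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(motionmesh)

spec <- scenario_spec("stable_boundary", seed = 1)  # 96x192 px, 64 px gap
out  <- run_pipeline(list(spec = spec, n_superpixels = 200))
str(out$report)
```

```
$ n_superpixels           : int 200
$ n_frames                : int 42
$ kept_red                : int 91
$ kept_green              : int 90
$ closure_frame           : int 17
$ truth_closure_frame     : num 17
$ boundary_formation_index: num 0.754
$ mesh_stability_index    : num 1
$ mesh_order              : num 0.484
$ msd_alpha               : num 1.97
$ vcc_before              : num 0.453
$ vcc_after               : num 0.916
$ max_strain              : num 0.627
```

Reading the numbers: the two sheets advance at 2 px/frame across a 64 px
gap, so contact happens after 16 frame steps — the detector recovers frame
17 exactly (`closure_frame` vs `truth_closure_frame`). Motion piles up and
then arrests at the interface, giving a high boundary formation index
(0.75) and a perfectly plateaued strain curve (stability 1). Sheet motion
is directed, so the MSD exponent is near-ballistic (1.97), and red–green
velocity coupling roughly doubles once the sheets are in contact
(`vcc_before` 0.45 → `vcc_after` 0.92). Running the same pipeline on a
`push_through` scenario yields a lower boundary formation index and a
negative stability index — the orderings used to discriminate phenotypes.

A thin CLI wraps the same functions
(`inst/cli/motionmesh.R simulate | track | assign | measure | boundary |
map | cluster`).

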