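# nestweave

Digitization of interlocked-branch bird nests — and similar tangles of
tubular elements — from 3D tomographic image stacks, in R.

A nest woven from stiff dry twigs scanned by micro-CT yields a grayscale
stack in which twigs are visible but not separable: wherever two twigs
touch, their segmented volumes fuse and the curve skeleton of the fused
mass joins their centerlines with false bridges. nestweave implements the
full pipeline that turns such a stack into a per-branch digital model and
construction-order simulations:

1. **Two-track preprocessing** — a topology segmentation (z-averaging
   σ = 5 slices, 3D Gaussian σ = 1 voxel, cutoff 28, hole filling) and a
   metrology segmentation (3D Gaussian σ = 2 voxels, cutoff 24) from one
   8-bit stack with anisotropic spacing (e.g. 0.5 × 0.5 × 0.1 mm).
2. **Skeletonization and decomposition** — topology-preserving 3D thinning
   to a curve skeleton; iterative pruning of tail edges (T = 5 mm);
   elimination of every junction with a 2 mm trim off each incident edge,
   leaving only simple, fork-free edges.
3. **Fragment reconnection** — endpoint pairs ranked by the friendship
   score

   C = D · A · max(d₁,d₂) · max(a₁,a₂) · (t₂/t₁)^T

   with endpoint distance `D`, orientation mismatch `A`, line-to-point
   distances `dᵢ`, bearing mismatches `aᵢ` and a thickness-ratio term
   (floors 1.0 mm / 0.5 mm / 0.1 enforced before multiplication, exponent
   T = 3; lower C = better). Greedy best-first merging reassembles
   branches; residual short edges, which mark contact zones, are removed.
4. **Morphometry** — per-point diameters from an anisotropic Euclidean
   distance transform sampled at skeleton points; removal of branches with
   more than 10% zero-thickness points and interpolation of the rest;
   contact points wherever two branch surfaces come within tolerance;
   per-branch length, median thickness, connectivity, normalized
   connectivity and horizontal angle.
5. **Construction simulation** — over the branch contact network, the
   'Greedy' strategy (always place the branch most gravity-supported by
   the built structure) and the 'Gradual' strategy (erect a minimum viable
   skeleton, then infill least-supported first), with cumulative-mass
   curves.

Because no public nest CT scans exist, the package ships a first-class
synthetic phantom generator (`phantom_spec()`, `make_nest()`,
`voxelize()`) producing voxelized tangles of curved twigs with exact
ground truth — polylines, diameters, contacts, scaffold — so the whole
pipeline is testable end to end, plus `evaluate_recovery()` to score a
digitization against that truth.

Intended users: researchers in biological image analysis and animal
architecture who need per-element models from volumetric scans of fibrous
or woven structures (nests, root systems, fiber networks).

## Worked example

```r
library(nestweave)

# a 30-branch phantom at CT-like spacing, digitized end to end
res <- run_all(default_config(seed = 1))
print(res$summary)
```

```
<nest_summary> 35 branches, 45 contacts
  length    50.4 +/- 18.4 mm
  thickness 2.36 +/- 1.33 mm
  contacts  2.6 +/- 1.5 per branch
  63% of branches steeper than 45 degrees
```

The summary says: the pipeline reassembled 35 branches (the phantom
contains 30; a few remain split at dense contact zones), found 45 contact
regions, and reports the per-branch statistics that a real-nest analysis
would use — twig length and thickness distributions, contacts per branch,
and how many twigs stand steeper than 45°. Against the generator's ground
truth:

```r
ev <- evaluate_recovery(res$nest, res$branches, res$contacts)
ev$contact_recovery    # 1.0   — every true contact found
ev$spurious_merges     # 0     — no two twigs fused by the matcher
```

Construction orders and mass curves:

```r
net <- res$network
head(mass_curve(res$greedy))
head(mass_curve(res$gradual))    # same total, different trajectory
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/nestweave.R", package="nestweave"))')" \
  synth --seed 1 --out phantom.tif --truth truth.json
```

with subcommands `run`, `synth` and `preprocess`.

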