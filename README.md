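# headswivel

Euler-angle decomposition of ribosomal 30S head motion from macromolecular
coordinate models.

## What it is for

During mRNA-tRNA translocation -- and, notably, during spontaneous
frameshift-associated rearrangements that happen without EF-G -- the head
domain of the small ribosomal subunit (16S rRNA nucleotides 930-1380 plus
seven proteins) rotates as a rigid body relative to the 16S body. That
motion has two physically distinct parts: an in-plane rotation about a
well-defined axis (the **swivel**) and deviations out of that plane (the
**tilt**). `headswivel` is for structural biologists who want those two
numbers, plus the supporting atom-level measurements, from PDB or mmCIF
models, with every step testable against synthetic ground truth.

The core decomposition expresses the head's orientation change, measured in
a frame whose z axis is a calibrated pure-swivel axis, as intrinsic z-x-z
Euler angles

    R = Rz(psi) . Rx(theta) . Rz(phi)

where **phi + psi** is the net swivel, **theta** the tilt and **phi** the
tilt direction. The axis and the zero orientation are calibrated from a
pair of reference structures (a classical unrotated conformation and a
fully swiveled tilt-free one; for deposited ribosome entries the
conventional pair is 4V9D vs 4V4Q). All rigid fits are unweighted Kabsch
(SVD) superpositions of backbone P atoms, one per residue. Per-residue
displacement vectors are split exactly into a swivel component (rotation by
the measured net swivel about the calibrated axis line) and a tilt
remainder. Companion measurements cover heavy-atom contact calls (such as
the 16S G966-C1400 head-body gate), codon-anticodon hydrogen-bond
distances, nearest-phosphate searches (the G926 E-site boundary) and mRNA
backbone kink angles.

## Worked example

Everything below runs without any downloaded structure: the synthetic
generator builds a three-domain pseudo-ribosome (23S anchor, 16S body, 16S
head with the real residue numbering and marker placement) with known head
angles, here `(phi, theta, psi) = (10, 5, 8)` degrees plus 0.3 A of
coordinate noise.

```r
library(headswivel)

gen <- generate_pseudo_ribosome(
  synthetic_truth(phi = 10, theta = 5, psi = 8, sigma = 0.3, seed = 42))

cal <- calibrate_swivel(gen$classical, gen$swiveled,
                        gen$domains$head, gen$domains$body)
cal
#> <ribs_calibration> domain head: swivel axis (-0.0000, 0.0000, 1.0000), magnitude 21.000 deg

ori <- compute_orientation(gen$model, cal, gen$classical,
                           gen$domains$head, gen$domains$body)
ori
#> <ribs_orientation> SYNTH_MODEL (copy 1) head: net swivel 18.028 deg, tilt 4.952 deg [core rmsd 0.545 A, n = 178]
```

The calibration recovered the generator's swivel axis (global z) and the
21-degree reference swivel; the model's decomposition recovered the true
net swivel (10 + 8 = 18 degrees) and tilt (5 degrees) to within a few
hundredths of a degree under 0.3 A noise, fitting 178 head P atoms with a
core RMSD consistent with that noise. The displacement field splits
exactly into the two vector components:

```r
d <- decompose_displacements(gen$model, gen$classical, ori, cal,
                             gen$domains$head, gen$domains$body)
head(d[, c("resno", "total_norm", "swivel_norm", "tilt_norm")], 3)
#>   resno total_norm swivel_norm tilt_norm
#> 1   930      3.617       2.988     1.111
#> 2   933      4.822       4.789     1.631
#> 3   935      6.620       7.129     0.801
```

For file-based work, `run_angles()` and `run_measure()` drive the same
pipeline from a JSON/YAML configuration (reference paths, domain
definitions with chain maps and optional explicit core lists, per-copy
chain overrides for multi-copy asymmetric units, and a measurement list)
and write deterministic TSV reports. A thin command-line wrapper with
`angles`, `measure`, `vectors`, `calibrate`, `synth` and `recover`
subcommands is installed at `inst/scripts/headswivel.R`. To analyse
deposited entries, supply the local mmCIF/PDB files and a chain map per
entry; the vignette describes the calibration pair and conventions.

## Documentation

The methods vignette (`vignettes/head-swivel-analysis.Rmd`) documents the
model, the calibration, every tunable parameter with units and defaults,
the generator's scope and limits, and the numerical conventions (Euler
order, gimbal handling, tie-breaks, degenerate-input policy).
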