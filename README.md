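# pmir — photo-magnetic imaging: simulation, detection, reconstruction

Photo-magnetic imaging (PMI) warms tissue a fraction of a degree with a
near-infrared laser and measures the induced internal temperature rise with
magnetic-resonance thermometry. Because the temperature is measured *inside*
the object rather than only at its surface, inverting for the optical
absorption coefficient μa(**r**) yields far sharper images than diffuse
optical tomography. `pmir` implements a complete self-guided PMI pipeline on
2-D circular phantoms:

* **Forward model** — continuous-wave photon diffusion with Robin boundary
  conditions, −∇·(D∇Φ) + μaΦ = 0 with n·D∇Φ + AΦ = q₀ on the boundary
  (D = 1/(3(μa + μs′)), A = 0.2, laser spots as boundary-arc flux), coupled
  to the Pennes bioheat equation ρc ∂T/∂t − ∇·(k∇T) = Φμa with convective
  surface loss, both discretized with linear-triangle FEM on unstructured
  disk meshes and integrated by backward Euler.
* **Phantom factory** — seeded random 25-mm phantoms with 1–3 absorbing
  inclusions, rasterized 256 × 256 temperature-difference maps (measured
  minus homogeneous reference), plus the fixed representative test cases.
* **Two-stage hot-node detector** — a half-overlapping 7 × 7 tile grid
  (64-px tiles), a six-layer CNN tile classifier (compiled single-precision
  kernels, trained with Adam to >90% validation accuracy), then per-tile
  multi-linear regressors whose node votes are fused across overlapping
  tiles by vote ratio. The output is the set of mesh nodes predicted to lie
  inside inclusions ("hot nodes").
* **Reconstruction** — Levenberg–Marquardt minimization of the pixel-domain
  temperature misfit with a perturbation Jacobian, optionally regularized by
  the region-based soft-prior penalty matrix L built from the detected hot
  nodes (1 on the diagonal, −1/Nr within a region), with the standard
  Marquardt damping schedule.
* **Evaluation** — node-level confusion matrices, false-positive distances,
  per-region absorption statistics with a background artifact level, and
  line-profile FWHM resolvability.

See `vignettes/methods.Rmd` for the full model, parameter tables, numerical
choices and limitations.

## Worked example

Simulate a one-inclusion phantom and reconstruct it with the true hot nodes
as soft prior (a 300-node mesh keeps this under a minute):

```r
library(pmir)

# 300-node disk mesh, one absorbing inclusion
mesh <- generate_disk_mesh(radius = 12.5, target_node_count = 300, seed = 1)
phantom <- make_phantom(mesh, inclusions = list(
  list(shape = "circle", center = c(0, 5), radii = 2.5, mua = 0.023)))

# simulate the PMI measurement: 4-sided illumination, 8 s of heating
src <- source_spec()
th <- thermal_params()
ts <- simulate_pmi_measurement(phantom, src, th, duration = 8)
Tn <- ts$T[, ncol(ts$T)]          # final frame (deg C above baseline)
measured <- rasterize(Tn, mesh, resolution = 128)
print(measured)
#> temperature_map: 128x128 px, extent [-12.8,12.8]x[-12.8,12.8] mm, max 0.1371 C

# reconstruct the absorption map with the true hot nodes as soft prior
rec <- reconstruct(measured, mesh, src, th, duration = 8,
                   initial_mua = 0.01, prior = phantom$hot_nodes,
                   max_iter = 6)
print(rec)
#> pmi_recon: 6 iterations, objective 0.1741 -> 1.052e-22, soft prior

stats <- region_stats(rec$mua, phantom$mua,
                      regions = list(inclusion = phantom$hot_nodes),
                      background_nodes = setdiff(seq_len(mesh$n_nodes),
                                                 phantom$hot_nodes),
                      inclusion_nodes = phantom$hot_nodes,
                      reference_mua = 0.01)
print(stats)
#>      region  mean           sd truth percent_error
#> 1 inclusion 0.023 3.545016e-12 0.023  3.418084e-09
```

The full studies are one call each: `run_simulation_study(pmi_config())`
(corpus generation → detector training → evaluation on the representative
cases) and `run_experiment_twin(pmi_config())` (the printed two-inclusion
phantom: measurement simulation → homogeneous fit → detection → soft-prior
and no-prior reconstructions). A thin command-line wrapper with
`simulate` / `detect` / `reconstruct` / `study` / `twin` subcommands lives
at `inst/cli/pmi.R`.

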