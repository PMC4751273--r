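# periclear

Simulation of perivascular solute clearance from brain gray matter.

## The problem

Soluble amyloid-beta and other metabolites leave the brain in two stages:
they diffuse through the extracellular space (ECS) of gray matter, then
enter the basement membranes of capillary and artery walls and drain
convectively along them toward the brain surface. Tracer experiments show
3 kDa dextran up to 2.5 mm from an injection site within 5 minutes — far
beyond the reach of hindered diffusion. Failure of this perivascular
drainage pathway is implicated in Alzheimer's disease and cerebral amyloid
angiopathy, which is why the balance between diffusion and drainage is
worth quantifying.

`periclear` is for researchers who want to reproduce and probe that
balance in silico. It models the tracer with two co-located fields on a 2D
brain-slice-like domain:

```
ECS:       dc/dt  = div(D* grad c) - (u . grad) c - k_b c
membrane:  dcb/dt = -(u_b . grad) cb             + k_b c
```

with tortuosity-scaled effective diffusion `D*` (anisotropic in white
matter), optional bulk flow `u` along white-matter fibers, first-order
take-up at rate `k_b` into the membranes, and advection-only drainage at
the apparent velocity `u_b` (8.33e-6 m/s, i.e. 2.5 mm in 5 min). Transport
regimes are compared through the Péclet number `Pe = L U / D` and through
the detection distance: the farthest point whose concentration (in either
compartment) is at least 0.1% of the injected concentration.

The solver is an explicit CFL-stable finite-difference scheme (flux-form
central diffusion with a full tensor, first-order upwind advection) with
the stepping kernel in C++. Ten predefined cases scale `(D*, u, u_b, k_b)`
to ask whether diffusion alone (A-cases), diffusion plus bulk flow
(B-cases), or the full drainage model (C-cases) explains the observed
spread.

## Worked example

Reproduce the diffusion-only and full-drainage cases on the coronal-like
slice (8 × 5.5 mm brain, needle tip at (5.7, 2.8) mm, 25 µm grid):

```r
library(periclear)

p <- default_parameters()   # published parameter set, SI units
head(case_peclet(), 8)
#>   case_id  velocity        Pe
#> 1      A1 0.000e+00   0.00000
#> 4      B1 1.750e-07  11.06322
#> 7      C1 8.330e-06 526.60920
#> 8      C2 4.165e-06 263.30460

g <- make_slice(slice_spec("coronal_like"))
g
#> Geometry grid (coronal_like): 328 x 220 cells, dx = 25 um, 8.21 x 5.50 mm
#>   cells: exterior=7470, gray=60666, white=3808, needle=216
#>   needle tip at (5.70, 2.80) mm; 2 inflow cell(s)

simA1 <- run_simulation("A1", g, p)   # ~2 s
simC1 <- run_simulation("C1", g, p)
cat(format_case_table(summarize_cases(list(simA1, simC1))), sep = "\n")
#> Case       5 min (mm)     30 min (mm)   t->2.5mm (s)
#> A1               0.72            1.16    not reached
#> C1               2.45            2.46    not reached
```

Read: 5 minutes after the end of the injection, diffusion alone (A1,
Pe = 0) has carried detectable tracer 0.72 mm — close to the ~0.8 mm
radius seen experimentally for the diffuse cloud, and nowhere near the
brain surface. The full model (C1, Pe ≈ 527) has already driven the
membrane front to the brain boundary 2.46 mm away in the drainage
direction, where it stays pinned through 30 minutes; on this geometry the
boundary sits just short of the 2.5 mm reference distance, hence "not
reached" in the first-passage column. Per-compartment series
(`distance_timeseries(simC1, "membrane")`), the mass ledger
(`simC1$mass`) and full field snapshots (`simC1$snapshots`) are available
on every result.

`run_cases(run_config(out_dir = "out"))` runs the whole ten-case suite and
writes per-case CSV series, a summary table and a reproducibility
manifest; `convergence_study()` reruns a case across grid spacings and
reports probe-point convergence. See the vignette
(`vignettes/clearance-model.Rmd`) for the model, the geometry stand-ins
and all numerical choices.

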