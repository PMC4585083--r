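# ventriflow

Intraventricular blood-flow simulation and analysis for a left ventricle
whose wall motion is *prescribed* — the hemodynamics half of an image-based
heart-function model, written for computational cardiac physiologists who
want to study how wall kinematics shape intraventricular flow, blood
transport and washout without running an electromechanical solver.

## What it computes

The blood is an incompressible Newtonian fluid,

> ρ [∂**u**/∂t + (**u**·∇)**u**] = −∇p + μ∇²**u**,  ∇·**u** = 0,

solved on a fixed Cartesian grid with a sharp-interface immersed-boundary
method: the endocardial surface Γ(t) is a watertight triangulated mesh that
moves through the grid, and the no-slip condition **u** = **u**_wall on Γ(t)
is imposed through a multi-dimensional ghost-cell reconstruction.  Time
advancement is a second-order projection method (Adams–Bashforth advection,
Crank–Nicolson diffusion, geometric-multigrid pressure Poisson solve,
incremental pressure correction).  Defaults are canine blood at
ρ = 1.04 g/cm³, μ = 0.035 g/(cm·s) and a 0.5 s cycle.

Around the solver the package provides the full pipeline:

* **Synthetic moving ventricle** — a prolate-spheroid LV cavity with
  simplified atrial and aortic tube extensions, deformed so its cavity
  volume tracks a C¹ periodic volume waveform built from end-diastolic and
  end-systolic volumes (biphasic E/A filling, smooth ejection).  EF = SV/EDV
  arithmetic is exact by construction.
* **Diffeomorphic surface registration** — a greedy kernel flow on the
  currents matching metric maps one template onto every frame of a target
  sequence, producing the conformal (fixed-connectivity) surface sequences
  the solver consumes; hexahedral-face meshes can be subdivided into
  triangles (2n² per quad).
* **Lagrangian transport** — point-mass blood cells advected with RK4,
  injected at the mitral inlet in proportion to the instantaneous inflow,
  removed at the aortic outlet, and decomposed per cycle into direct inflow
  (I), retained inflow (II), delayed ejection (III) and residual volume
  (IV), giving DR = I/(I+II), WR = III/(III+IV), RR = 1−WR and the washout
  cycle count N₁% = −2/log₁₀(RR).
* **Flow diagnostics** — swirl strength (λ_ci) and Q fields, mitral-annulus
  velocity probes, volume-averaged cavity pressure, P–V loops and stroke
  work (shoelace area, 1 kPa·mL = 1 mJ).
* **Closed-loop Windkessel circulation** — two RC compartments per
  circulation, time-varying-elastance atria and right ventricle, diode
  valves, volume-driven LV; supplies the pre-/after-load pressures that
  anchor the absolute level of the incompressible solver's pressure.

## A worked example

```r
library(ventriflow)

# a normal canine-scale heart: EDV 41.2 mL, ESV 23.4 mL
wf <- make_volume_waveform(edv = 41.2, esv = 23.4, period = 0.5)
waveform_metrics(wf)
#>   edv_ml esv_ml sv_ml   ef_pct
#> 1   41.2   23.4  17.8 43.20388

tpl <- build_template(ventricle_template(), target_cavity_volume = 41.2)
kin <- ventricle_kinematics(tpl, wf, n_frames = 16)

# washout arithmetic: a washout ratio of 43.5% empties the ventricular
# blood pool to 1% in 8 cycles
transport_metrics(list(I = 27.8, II = 72.2, III = 43.5, IV = 56.5))
#>      dr    wr    rr        ef n1pct_real n1pct
#> 1 0.278 0.435 0.565 0.3565 ...   8.065775     8
```

A full desk-scale simulation (grid 32×32×64, Δt = 5·10⁻⁴ s, two cycles,
12,000 particles) runs in a few minutes:

```r
rep <- run_pipeline(run_config(list(
  case = "normal",
  geometry = list(synthetic = list(edv = 41.2, esv = 23.4)),
  grid = list(n = c(32, 32, 64)),
  time = list(dt = 5e-4, cycles = 2),
  particles = list(n = 12000, seed = 11))))
rep$metrics
#>    case  edv_ml  esv_ml   sv_ml  ef_pct dr_pct wr_pct n1pct stroke_work_mJ ...
#>  normal   41.28   23.40   17.88   43.32   38.8   48.1     7          164.3
```

(transport metrics vary a little with the particle seed and grid).
EDV/ESV/SV/EF restate the prescribed wall motion (a consistency check);
DR/WR/N₁% are measured from the tracked particles — for a healthy EF ≈ 43%
heart roughly a third of the atrial inflow is ejected within the same beat,
about half of the cycle-start ventricular blood is washed out per cycle,
and the residual pool falls below 1% in seven to eight beats.  The same run
for a failing heart (EDV 116.4, ESV 100.2, EF ≈ 14%) gives much smaller
mitral inflow velocity, a far smaller swirl-strength vortex volume, and
washout times of tens of cycles.

A thin command-line wrapper lives at `inst/cli/ventriflow.R`
(`generate | register | simulate | run`, each with `--config cfg.yaml`).

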