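# aortafem

Cohesive-zone finite elements for in-plane tear propagation in the
dissected aorta.

Aortic dissection advances by splitting the bonding between the
concentric elastic lamellae of the media: blood driven into the wall
peels the lamellar interface apart circumferentially and axially. This
package implements a quasi-static nonlinear finite-element framework
for that process:

* **Bulk wall**: the Holzapfel–Gasser–Ogden (HGO) fiber-reinforced,
  nearly incompressible hyperelastic model,

  W = C₁₀(Ī₁−3) + (1/D)((J²−1)/2 − ln J) + Σᵢ (k₁/2k₂)[exp(k₂εᵢ²) − 1],
  εᵢ = κ(Ī₁−3) + (1−3κ)(Ī₄,₆−1),

  with bundled medial and adventitial parameter sets for the human
  thoracic aorta (`hgo_media()`, `hgo_adventitia()`).
* **Lamellar interface**: zero-thickness cohesive elements with a
  bilinear mixed-mode traction–separation law — linear rise T = K·S to
  the initiation traction T_C, linear softening to zero at
  S_t = 2G_C/T_C (enclosed area = fracture energy G_C), quadratic
  nominal-stress initiation ⟨Tn⟩²/TnC² + Ts²/TsC² + Tt²/TtC² = 1
  (compression never damages), power-law energy failure
  (G_I/G_IC)^α + (G_II/G_IIC)^α + (G_III/G_IIIC)^α = 1, and mode mix
  ratio m = 1 − G_I/G_T. Calibrated constants for the human media are
  bundled (`cohesive_media()`: 131/97/120 kPa, 49/200/240 N/m).
* **Virtual calibration experiments**: T-peel of a medial strip, direct
  tension, and circumferential/axial interface shear, plus the inverse
  calibration loops that recover the fracture energies from measured
  curves (`run_peel_test()`, `calibrate_GIC()`, `run_direct_tension()`,
  `run_shear_test()`, `calibrate_shear_GC()`).
* **Idealized dissected aorta**: a bilayer tube (Ri = 7.5 mm,
  Ro = 9 mm, media:adventitia 5:3) with a parametric initial tear
  (central angle η, axial length s, depth ratio t), pressurized with
  follower loads in the true and false lumen until the first cohesive
  element is completely damaged — the critical propagation pressure P_c
  (`build_tube_mesh()`, `run_pressurization()`, `parameter_sweep()`),
  with opening-angle residual-stress prestrain
  (`apply_residual_prestrain()`) and a semi-analytic
  extension–inflation oracle (`semi_analytic_inflation()`).

The intended users are vascular biomechanics researchers who want a
transparent, scriptable implementation of calibrated cohesive-zone
dissection mechanics outside a commercial FE code.

## Worked example

Simulate the direct-tension and circumferential shear calibration
experiments with the bundled parameters:

```r
library(aortafem)

tension <- run_direct_tension()
attr(tension, "peak")        # 130.8 kPa  (mode-I initiation traction, 131)
attr(tension, "dissipated")  # ~49.0 mN/mm (mode-I fracture energy, 49)

shear <- run_shear_test(direction = "rtheta")
attr(shear, "peak")          # 96.9 kPa   (mode-II initiation traction, 97)
attr(shear, "dissipated")    # ~200 mN/mm (mode-II fracture energy, 200)
```

The peak tractions and traction–separation areas reproduce the
calibrated initiation tractions and fracture energies because the
interface law is exact by construction in its pure modes; the FEM
recovers them through an actual boundary-value problem.

The T-peel simulation of the medial strip (a few minutes):

```r
peel <- run_peel_test()
plateau_force(peel)          # ~23.7 mN/mm steady peel force per width
```

which sits a few percent below the rigid-arm energy-balance bound
G_IC/2 = 24.5 mN/mm and reproduces the experimental mean of 23 mN/mm
that fixed G_IC = 49 N/m in the first place.

A tube run is configured either programmatically or from a YAML file
(`parse_config()`; all keys carry unit suffixes):

```r
spec  <- tube_spec(n_circ = 8, n_axial = 4, half_model = TRUE,
                   half_axial = TRUE)
model <- build_tube_mesh(spec, tear_geometry(eta_deg = 150, s_mm = 10,
                                             t_ratio = 0.4))
res   <- run_pressurization(model, load_case(lambda_axial = 1.02))
res$event            # critical pressure, direction, mode mix
export_results(res, model, dir = "out")   # CSV summary + VTK fields
```

Coarse desk-scale meshes resolve the tear-front process zone with a
graded band and give direction-of-effect results in minutes;
quantitative critical pressures need production meshes (hours per case,
same API). A command-line interface (`exec/aortafem`) exposes
`run-tube`, `sweep`, `inflate`, `run-test`, `calibrate-peel` and
`calibrate-shear`.

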