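# xfpchromo

Force-field parameters and charge-fitting tools for fluorescent-protein
chromophores.

## The problem

The chromophores of GFP-family fluorescent proteins form by backbone
cyclization of three residues into an imidazolidinone ring with extended
π-conjugation. No standard protein force field describes them, so
molecular-dynamics studies of EGFP, EBFP, ECFP, EYFP, DsRed, or mCherry
need a dedicated, Cornell-compatible parameter set and residue charges
that stay balanced with the surrounding ff14SB/ff19SB protein.

`xfpchromo` is a toolkit for working with (and extending) such a
parameter set. It is aimed at simulators who want the parameters in
AMBER frcmod form, and at parameterizers who want the selection and
validation machinery — RESP charge fitting under residue-building
constraints, atom-type scoring against reference geometries, and
distribution-level trajectory validation — for new chromophores built
on the same imidazolidinone core.

## What it provides

* **Parameter database** (`builtin_parameter_set()`): the complete set
  of terms needed beyond ff14SB/ff19SB for seven chromophores (EGFP,
  EBFP in both HID and HIE histidine forms, ECFP, EYFP, DsRed,
  mCherry): 22 bonds, 56 angles, 25 torsions (40 rows with
  multi-component sidechain terms), 13 impropers, and 10 nonbonded
  entries, drawn from gaff 1.81 and ff14SB analogies. Emitted as an
  AMBER-parseable frcmod file with byte-stable serialization
  (`write_frcmod()` / `parse_frcmod()`) and wildcard-aware lookup
  (`frcmod_lookup()`).
* **Two-stage RESP charge fitting** (`resp_fit_two_stage()`): fits
  atom-centered charges `q` to an electrostatic-potential grid by
  minimizing

  ```
  sum_k ( V_k - sum_i q_i / r_ik )^2  +  sum_i a ( sqrt(q_i^2 + b^2) - b )
  ```

  subject to linear constraints, with the standard second stage that
  refits methyl/methylene groups under hydrogen rotational
  equivalence. Three constraint schemes mirror the charge models used
  to build removable residues: `free_fit` (equivalences only),
  `cap_fix` (ACE/NME capping groups sum to zero), and `amide_fix`
  (additionally pins terminal amide N/H and carbonyl C/O to the
  force-field consensus charges, with the proline-like variant for the
  H-less DsRed/mCherry amino terminus).
* **Atom-type model scoring** (`measure_named_bonds()`, `model_rmsd()`,
  `rank_models()`): bond-length RMSD of candidate atom-type systems
  (e.g. gaff `cc/cd` vs standard `CA/CA` vs gaff `ce/cf`) against a
  reference geometry, over configurable bond subsets.
* **Geometry kernels**: bond lengths/angles, dihedrals and impropers
  (AMBER central-third-atom convention), Kabsch superposition with
  chirality preservation, per-structure RMSD reports, and the charge
  mean-unsigned-error metric.
* **Trajectory validation** (`angle_series()`, `fit_gaussian()`,
  `compare_fits()`, `equilibration_ratio()`, `beta_slope()`):
  Gaussian center/σ summaries of internal-coordinate distributions,
  classical-vs-reference comparisons in units of the reference σ,
  and the SD-to-slope equilibration and beta-sheet stability metrics.
* **Synthetic fixtures** (`gen_esp_fixture()`, `gen_capped_topology()`,
  `gen_ou_angle_series()`, `gen_perturbed_structure()`): seeded,
  deterministic inputs with the statistical structure the methods
  assume.

## Worked example

Emit the parameter database and look an entry back up:

```r
library(xfpchromo)
doc <- builtin_parameter_set()
doc
#> <frcmod> 'xFP chromophore parameters (gaff 1.81 + ff14SB analogies)':
#>   10 mass, 22 bond, 56 angle, 40 torsion row(s) (25 term group(s)),
#>   13 improper, 10 nonbonded
frcmod_lookup(doc, "bond", c("cc", "cd"))
#>   a1 a2   k_r   r_eq     source
#> 1 cc cd 500.9 1.3729 gaff cc-cd
```

The `cc-cd` bond — the impure-aromatic carbon pair of the
imidazolidinone ring — has force constant 500.9 kcal mol⁻¹ Å⁻² and
equilibrium length 1.3729 Å.

Fit charges to a synthetic ESP grid generated from known charges on a
capped topology, then apply the `amide_fix` residue constraints:

```r
topo <- gen_capped_topology(n_sidechain_atoms = 1, with_amide_h = TRUE,
                            seed = 42)
set.seed(42)
q_true <- rnorm(n_atoms(topo), 0, 0.3)
q_true[1] <- q_true[1] - sum(q_true)          # make the net charge exactly 0
grid <- gen_esp_fixture(q_true, frame_coords(topo) * 1.889726, seed = 7)

q_fit <- resp_solve_stage(grid, total_charge = 0, restraint_a = 0)
max(abs(as.numeric(q_fit) - q_true))
#> 1.07e-13   # unrestrained noise-free fit recovers the generator

res2 <- resp_fit_two_stage(grid, topo, scheme_amide_fix(topo, total_charge = 0))
res2
#> <resp_result> scheme amide_fix: 22 charges, sum +0.000000,
#>   rel RMS fit 6.982e-01
res2$charges[topo$atoms$name == "N"]
#> -0.4157    # amide N pinned to the force-field consensus charge
```

The unrestrained fit reproduces the generating charges to machine precision;
the amide-fix fit trades ESP fidelity (its relative RMS error rises)
for charges that are exchangeable with the surrounding protein
residues — the same trade the shipped chromophore charges make.

A command-line front end covering `emit-frcmod`, `resp-fit`,
`score-types`, `compare-structures`, and `validate-angles` is installed
at `inst/cli/xfpchromo` (see `xfp_cli()`).

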