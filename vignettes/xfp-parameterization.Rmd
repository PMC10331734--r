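---
title: "Parameterizing fluorescent-protein chromophores: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing fluorescent-protein chromophores: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfpchromo)
```

# Scope and assumptions

GFP-family chromophores arise from backbone cyclization of a
three-residue tripeptide into a five-membered imidazolidinone ring with
extended π-conjugation — a chemistry no standard protein force field
covers. `xfpchromo` handles the classical-mechanics side of
parameterizing such chromophores for the Cornell family of AMBER force
fields (ff14SB/ff19SB): assembling and serializing the parameter
database, fitting residue charges, scoring candidate atom-type systems,
and validating chromophore behaviour at the level of
internal-coordinate distributions.

Everything quantum-mechanical is out of scope by design: the package
consumes electrostatic-potential (ESP) grids, reference geometries, and
per-frame secondary-structure counts produced elsewhere, and never runs
QM or MD itself. It also never guesses chemistry: bonds come from
CONECT records or an explicit bond list (distance-based bond perception
is deliberately absent, because chromophore connectivity is exactly the
kind of unusual chemistry such heuristics get silently wrong), and
atom roles come from annotation files, not inference.

# The parameter database

`builtin_parameter_set()` holds the bonded and nonbonded terms needed
beyond ff14SB/ff19SB for seven chromophores (EGFP, EBFP-HID, EBFP-HIE,
ECFP, EYFP, DsRed, mCherry): 22 bonds, 56 angles, 25 torsions (40 rows
once multi-component sidechain torsions are unrolled), 13 impropers,
and 10 nonbonded entries. gaff entries follow gaff version 1.81; no
alternative value sets are shipped. The database deliberately omits
mass/nonbonded entries for standard Cornell-family types (`CX`, `2C`,
`C*`, `N`, ...): a user is assumed to have loaded a complete base force
field, and the validator therefore checks the mass/nonbonded closure
only over the database's own new types.

Serialization choices:

* Sections are emitted in the fixed order MASS, BOND, ANGLE, DIHE,
  IMPROPER, NONBON, in as-shipped entry order, so output is
  deterministic and `write ∘ parse ∘ write` is byte-identical.
* Each numeric column uses a fixed decimal count matching the dominant
  precision of the source tables (bond force constants at 1 decimal,
  angle terms at 3, torsion barriers at 3, van der Waals parameters
  at 4). Values are stored and compared as numbers; the fixed format
  is what makes byte-stability testable.
* Multi-term torsions are stored as one logical torsion with ordered
  components and written with negative periodicity on all but the last
  term — the AMBER continuation convention. The emitter reproduces the
  shipped `paths_divisor` (IDIVF) values verbatim, including the
  explicit sidechain torsions that use 1 where wildcard terms use
  2/4/6; whether a consumer re-normalizes is left to the consumer.
* Duplicate detection canonicalizes bond/angle tuples to the
  lexicographically smaller of (tuple, reversed tuple).

Lookup follows AMBER matching semantics: bonds and angles match under
reversal; torsion lookup prefers fully explicit quadruples over
wildcard `X-..-X` entries (trying the reversed tuple too); improper
lookup keeps the third (central) atom fixed and treats the remaining
three as an unordered multiset with `X` matching anything.

# RESP charge fitting

Charges minimize the restrained least-squares objective

$$\chi^2(q) = \sum_k \Big(V_k - \sum_i \frac{q_i}{r_{ik}}\Big)^2
  + \sum_i a\,\big(\sqrt{q_i^2 + b^2} - b\big)$$

in atomic units, subject to linear constraints, solved by iterating the
restrained normal equations with Lagrange rows until
$\max_i |\Delta q_i|$ falls below the convergence tolerance.

Tunable parameters (all exposed through `resp_config()`):

| parameter | default | units | role |
|---|---|---|---|
| `restraint_a_stage1` | 0.0005 | au | weak stage-1 hyperbolic restraint |
| `restraint_a_stage2` | 0.001 | au | stronger stage-2 restraint |
| `restraint_b` | 0.1 | au | restraint width |
| `restrain_hydrogens` | `FALSE` | — | hydrogens are conventionally unrestrained |
| `convergence_tol` | 1e-6 | e | stop when max charge update is below this |
| `max_iterations` | 200 | — | hard cap; exceeding it is an error, not a warning |

The restraint magnitudes are the standard two-stage RESP values; they
are configuration, not fitted results. With `a = 0` the system is
linear and one solve suffices; the iteration then terminates on its
second pass with a zero update.

The two-stage structure follows standard practice: stage 1 fits all
atoms under the scheme's fix and group-sum constraints; stage 2 refits
only methyl/methylene carbons and their hydrogens (identified from the
bond graph: a carbon bonded to two or three hydrogens) with hydrogen
rotational-equivalence constraints, everything else frozen at stage-1
values. Topologies without such groups skip stage 2. Rotational
equivalence never spans groups; whether cap-methyl hydrogens are
equivalenced *within* each cap is genuinely ambiguous in the residue
charge-model tradition, so it is a flag
(`cap_hydrogen_equivalence`, default `TRUE`) rather than a constant.

Three constraint schemes encode progressively stronger residue-building
requirements:

1. `free_fit` — equivalences plus the total charge; the best
   atom-centered representation of the ESP, and the reference point
   for fit quality.
2. `cap_fix` — adds a zero group-sum over each capping group (ACE and
   NME), the minimal condition for cutting the caps away while leaving
   an integer-charge residue.
3. `amide_fix` — additionally fixes the terminal amide N/H and
   carbonyl C/O to the base force field's neutral consensus charges
   (`consensus_terminal_charges()`: N −0.4157, H 0.2719, C 0.5973,
   O −0.5679 e), so the residue's backbone charges are exchangeable
   with every other residue in the protein. When the topology has no
   amide hydrogen — the DsRed/mCherry chromophores, whose amino
   terminus is proline-like — there is no good consensus value for
   that nitrogen; it is left free and the carbonyl C and O of the
   adjacent ACE cap are fixed instead, giving the nitrogen a balanced
   charge environment. The comparable Cornell value for an H-less
   backbone nitrogen is the proline N at −0.2548 e.

Since the schemes' feasible sets are nested, the relative RMS fit error
`relative_rms_fit()` is nondecreasing from `free_fit` to `cap_fix` to
`amide_fix` on a fixed grid; the test suite asserts this on every
synthetic fixture. Fix constraints are implemented by freezing, so they
are satisfied exactly (not merely to solver tolerance); group sums and
equivalences are Lagrange rows, exact to linear-solver precision.

# Geometry conventions

* Angles are reported in degrees everywhere; radians are internal.
* Dihedrals use the right-hand convention about the j–k axis, reported
  in (−180°, 180°], with the sign matching the established structure
  and trajectory tools (bio3d, MDAnalysis, cpptraj): the value is
  invariant under full index reversal and negated by mirror
  reflection. (A torsion angle cannot be made antisymmetric under
  reversal in any fixed-handed convention — both the viewing axis and
  the end atoms flip together.)
* Impropers are the dihedral of the four atoms in listed order with
  the third atom central (the AMBER convention); planar trigonal
  centers give 180°, the minimum of every shipped improper term.
* Superposition is closed-form Kabsch via SVD with the determinant
  forced to +1, so a reflection can never masquerade as a rotation —
  molecular chirality is preserved even when a mirror image would fit
  better.
* Published structure comparisons align on ring heavy atoms but do not
  state the RMSD atom set, so `structure_rmsd()` reports all three
  candidate sets (all atoms, heavy atoms, alignment subset) rather
  than guessing.
* Atom and bond indices are 1-based throughout, the R convention.

Degenerate inputs error early and specifically: coincident atoms in an
angle, collinear spans in a dihedral, fewer than three or collinear
atoms in a superposition subset, grid points coincident with atom
positions (minimum separation 1e-6 Bohr).

# Atom-type scoring

`rank_models()` orders candidate bond-parameter models by
`model_rmsd()`, the root-mean-square deviation between model
equilibrium lengths and measured bond lengths over a named bond subset.
Exact ties are broken by a configurable priority order, default
`cc/cd` > standard-residue types > `ce/cf`, reflecting the selection
logic the shipped set itself followed: the impure-aromatic gaff types
win for the conjugated core, while for sidechains essentially unchanged
from their parent amino acid the standard types win — hence the
priority is an argument, not a constant. Ties are flagged in the
output so a priority-decided rank is never mistaken for a measured one.

The EGFP conjugated-unit bond list (`egfp_conjugated_bonds()`) names
the imidazolidinone, bridge, and deprotonated-tyrosine bonds a user
needs to reproduce the published model comparison against their own
QM-optimized or crystal geometries; the package's own tests use
synthetic geometries, since the reference structures are not
distributable data.

# Trajectory validation

`angle_series()` evaluates an angle definition per frame; dihedral
series are recentered onto the branch around their circular mean so a
unimodal distribution straddling ±180° is not split — recentering
changes values only by multiples of 360°. `fit_gaussian()` histograms
a series (bin edges anchored at integer multiples of the bin width, so
binning is deterministic) and fits
$A\,\exp(-(x-c)^2/2\sigma^2)$ to the bin counts by
Levenberg–Marquardt least squares, initialized at the sample mean and
SD; on optimizer failure it falls back to the sample moments with
`converged = FALSE`, and downstream comparisons refuse unconverged
inputs. Default bin widths follow the published comparisons: 2° for
bond angles, 5° for intra-ring dihedrals, 15° for the wide
ring-planarity dihedral.

`compare_fits()` reports the center shift, the shift in units of the
*reference* σ (the yardstick used to call distributions
distinguishable), and the width ratio classical σ / reference σ.

`equilibration_ratio()` scales the time axis so the window spans one
time unit; the OLS slope is then the total drift across the window and
the SD-to-|slope| ratio is invariant under affine rescaling of the
values. A ratio far above 1 (the published protocol demanded > 50 for
RMSD and > 1000 for energies) means fluctuation dominates drift.
`beta_slope()` converts an OLS fit of per-frame beta-sheet residue
counts to residues per microsecond; the counts come from an external
secondary-structure assignment — implementing DSSP is out of scope.

# Synthetic fixtures: what they do and do not show

The generators produce seeded, bit-reproducible inputs with exactly the
structure the methods assume:

* `gen_esp_fixture()` builds shell grids (default multipliers 1.4–2.0
  of a nominal per-atom radius, echoing standard ESP-grid practice)
  and evaluates exact Coulomb potentials, optionally noised. Because
  the generating charges are known, unconstrained noise-free fits must
  recover them — the strongest possible correctness oracle for the
  solver.
* `gen_capped_topology()` emulates the charge-fitting topologies:
  both caps with methyls, an amide nitrogen with or without hydrogen,
  a sidechain with methylene/methyl groups, full role/flag
  annotations.
* `gen_ou_angle_series()` produces stationary AR(1) series with
  requested marginal mean/SD — a stand-in for thermal angle
  fluctuations.
* `gen_perturbed_structure()` jitters coordinates isotropically for
  superposition and scoring tests.

What passing these tests shows: the solvers, constraints, serializers,
and statistics are implemented correctly. What it does not show: that
the shipped parameters reproduce quantum-mechanical chromophore
behaviour. Synthetic ESP grids are exact point-charge potentials with
no polarization structure; AR(1) series are unimodal and exactly
Gaussian; jittered topologies have no real chemistry. The quantities
that would test the parameters themselves — reference-geometry RMSD
tables, QM/MM distribution comparisons, beta-sheet slopes over
microsecond trajectories — require external QM and MD engines and are
exposed here as methods to run on such data, not as reproduced results.

# Problem sizes and numerical tolerances

The test suite and the acceptance script use sizes chosen to make the
oracles airtight while keeping a full run in tens of seconds: RESP
fixtures of 3–25 atoms with ≥ 4× more grid points than atoms on
multiple shells (generator recovery to 1e-6 e), 50 randomized frcmod
documents for byte-stability, 20 seeds × 10⁵ draws for Gaussian
recovery (mean center error within 0.1°, σ within 0.15°), 100 random
model-ranking fixtures against an independent sort, and a
coarse-to-fine rotation-grid search (10° grid, refinement, simplex
polish) as the superposition oracle at 1e-3 Å.

# Known limitations

* Annotation and charge-table content beyond what the package can
  verify is not shipped: per-atom type maps for all seven chromophores
  live in the parameter set's own distribution channels, and the
  package's annotation files cover the documented terminal atoms plus
  synthetic examples.
* The frcmod dialect is the one the emitter produces (plus tolerant
  whitespace); it is AMBER-parseable but not a universal frcmod
  reader.
* Trajectory input is multi-frame PDB or XYZ; binary trajectory
  formats would be an adapter on top, not core.
* CMAP backbone corrections are not part of the parameter set; with
  the `CX` alpha-carbon type the set is compatible with ff19SB without
  them.
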