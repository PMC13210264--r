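---
title: "Structure-based simulation of RNA folding: model, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based simulation of RNA folding: model, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofold)
```

## The model

`gofold` implements an all-heavy-atom structure-based (Gō-type) model for
RNA folding. A folded reference structure defines everything: atom pairs
within 4 Å in the native state are *native contacts* and attract; all
other pairs repel. The non-bonded potential is

$$
V = 4\epsilon_{\mathrm{nat}}\sum_{(i,j)\,\in\,\mathrm{native}}
  \left[\left(\frac{\sigma_{ij}}{r_{ij}}\right)^{12} -
        \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{10}\right]
 \;+\; 4\epsilon_{\mathrm{rep}}\sum_{(i,j)\,\notin\,\mathrm{native}}
  \left(\frac{\sigma_{\mathrm{rep}}}{r_{ij}}\right)^{12},
$$

where $\sigma_{ij}$ is the pair's distance in the native structure. This
12-10 form is implemented exactly as written: it is **zero** at
$r=\sigma$ and reaches its minimum $-0.26792\,\epsilon$ at
$r = \sigma\sqrt{6/5} \approx 1.0954\,\sigma$. The conventional
structure-based form $\epsilon[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$
(minimum exactly at $\sigma$) is available via
`go_parameters(form = "standard")` for users who prefer the SBM
convention; all defaults use the 12-10 form above.

Non-native pairs have no native distance, so a single global repulsive
radius `sigma_rep = 2.5` Å (a standard excluded-volume choice) stands in
for $\sigma_{ij}$ in the repulsive sum. The native term is truncated at
$3\sigma_{ij}$ and the repulsion at $3\sigma_{\mathrm{rep}}$, without
shifting; the neglected tails are below $10^{-5}$ kcal/mol.

Bonded geometry is maintained by native-geometry terms rather than a
transferable force field: harmonic bonds $k_b(r-r_0)^2$
($k_b = 100$ kcal/mol/Å$^2$), harmonic angles $k_a(\theta-\theta_0)^2$
($k_a = 20$ kcal/mol/rad$^2$) and periodic dihedrals
$k_d[1-\cos(\phi-\phi_0)]$ ($k_d = 1$ kcal/mol), with every equilibrium
value measured from the native structure. This removes any dependence on
external parameter files while keeping the native state an exact minimum
of the bonded terms. It is a deliberate substitution for a transferable
bonded force field, with one visible consequence: the bonded terms are
themselves native-biased, which matters for high-temperature unfolding
(below). Units throughout: kcal/mol, Å, amu, ps, K, with
$k_B = 0.0019872041$ kcal/(mol·K).

## Contact map and the meaning of Q

The folding reaction coordinate is the fraction of native contacts,
$Q$: a contact is *formed* when $r < \lambda\sigma$ with $\lambda = 1.2$
(configurable; any $\lambda \ge 1$ gives $Q = 1$ at the native state).
Folded and unfolded states are read as $Q > 0.8$ and $Q < 0.2$.

Two filters shape the contact map beyond the 4 Å rule:

* **intra-residue pairs are dropped** (structural, not folding,
  contacts), and
* **pairs fewer than six covalent bonds apart are dropped**
  (`min_bond_sep = 6`).

The second rule deserves explanation, because the map's raw definition
("any heavy-atom pair within 4 Å") admits pairs such as consecutive
backbone atoms whose mutual distance is pinned near its native value by
the bond, angle and dihedral terms *at any temperature*. Measured on the
bundled fixtures, such bonded-proximity pairs stay "formed" 85--95% of
the time even at 600--700 K, so a Q that counts them can never drop
below roughly 0.6 and no unfolded state exists by the $Q<0.2$
definition. Six bonds is the smallest separation at which base-stacking
pairs (which genuinely break and reform) are retained while the
covalently pinned pairs are removed. Users who want the literal
any-pair map can pass `min_bond_sep = 2`. The 1-2/1-3 *exclusion list*
used for the repulsive sum is a separate, conventional object and is
not affected; 1-4 pairs still interact non-bonded, except that
bonded-proximity pairs already sitting inside `sigma_rep` in the native
state are skipped from the repulsion (pushing on them would only strain
the native geometry the bonded terms define).

## Sampling

Dynamics are integrated with the BAOAB splitting of Langevin dynamics
(default timestep 2 fs, friction 1 ps$^{-1}$), which reduces exactly to
velocity Verlet when the friction is zero. Velocities are initialized
from the Maxwell--Boltzmann distribution; all stochastic streams are
seed-controlled and a trajectory is exactly reproducible from its
recorded `(seed, parameters)` metadata. The repulsive sum runs over a
Verlet neighbour list with a 2 Å skin, rebuilt whenever any atom has
moved more than half the skin since the last build -- a criterion that
makes the list provably identical to the all-pairs evaluation. Q is
evaluated every `stride` steps (default 100) for termination checks.
The timestep bound enforced at launch is
$\Delta t \le 0.2\cdot 2\pi/\omega_{\max}$ from the stiffest bond.

Folding runs start from configurations with zero formed native
contacts. Two generators are provided:

* `randomize_unfolded()` rebuilds the chain atom-by-atom with exact
  native bond lengths but randomized, outward-biased directions
  (near-straight persistent walk along the backbone, bases leaning
  against the chain direction), rejecting any placement that brings a
  non-bonded pair below 2 Å or forms a native contact, with local
  backtracking. Bond lengths are preserved exactly; angles and
  dihedrals are randomized, which is what breaks the local contacts.
* `generate_unfolded_ensemble()` follows the high-temperature protocol:
  each configuration is seeded geometrically as above and then
  equilibrated with Langevin dynamics at a temperature drawn uniformly
  from 550--700 K, returning the last zero-contact frame. Running the
  native-biased Gō potential itself hot cannot be relied on to *reach*
  strictly zero contacts from the folded state -- every local contact
  would have to break simultaneously -- which is why the geometric seed
  comes first. (Unfolded-ensemble generation in the literature typically
  uses a transferable force field for this stage; supporting one is out
  of scope here, and this two-step protocol is the package's own
  substitute.)

## Synthetic fixtures and their calibration

Because no experimental structure ships with the package, the
`synthetic_data` functions build idealized stem-loop RNAs from five
pseudo-heavy atoms per residue (P, O5', C4', O3' backbone plus one base
nitrogen): `make_hairpin()` (a single stem-loop) and `make_mini_trna()`
(four stem-loop arms labelled aas, asl, dsl, tsl around a hub, plus a
variable-loop linker routed past the modifiable guanosine so that
dsl--vl tertiary contacts and a G-site base pair exist, echoing the
elbow of a real tRNA). Geometry uses a 3.8 Å stacking rise and 2.9 Å
base-pairing distance, so the 4 Å rule yields both stacking and pairing
contacts. The backbone bond lengths were chosen so that every native
contact's pair distance is at most ~80% of its shortest bond-path
contour -- the geometric precondition for zero-contact unfolded states
to exist at all. The G site carries a compact four-atom base (N1, C2,
N2, N3) so `apply_m22g()` can attach the two N2 methyls in idealized
trigonal in-plane geometry (1.45 Å C--N2); in the modified base N2 is
no longer a hydrogen-bond donor, which is the entire local effect of
the modification in this model.

One number cannot be carried over from the full-atom parameterization:
the per-contact well depth. A full-atom tRNA has on the order of 40
native contacts per residue; the five-atom fixtures have ~1.3. With the
full-atom $\epsilon_{\mathrm{nat}} = 0.14$ kcal/mol the toy's entire
native contact energy is ~0.05 kcal/mol per residue and its folded
state is not even metastable at 200 K. `fixture_go_parameters()`
therefore renormalizes the depth so the *per-residue* native
stabilization matches the full-atom scale: $\epsilon = 10$ for the
hairpin gives clean two-state behaviour (folded at 300 K, near melting
at 353 K, unfolding excursions below $Q = 0.2$ at 600 K), and
$\epsilon = 18$ is used for toy-tRNA folding studies, whose four-arm
assembly pays a larger entropy. The 14:1 native:repulsive ratio of the
full-atom parameter set is preserved. These are frozen study
conditions, not tuning knobs: `go_parameters()` keeps the full-atom
defaults.

## Analyses

* **Q series**, global and per domain (intra-domain contacts only, so
  the domain Q's of the 2-D `q_tsl` × `q_dsl` density are independent
  axes; inter-domain contacts appear in the contact-frequency map
  instead).
* **Free-energy profile** $F(Q) = -k_B T \ln P(Q)$, from the pooled
  histogram of all frames of all trajectories with equal weight, 20
  bins of width 0.05, minimum shifted to zero, empty bins masked rather
  than smoothed.
* **Pathway classification**: a domain folds at the first frame where
  its Q exceeds 0.8 and stays above it for five consecutive analysis
  frames (the persistence rule suppresses transient spikes); the
  trajectory's label is the arrow-joined order of those events, ties
  broken by name and flagged.
* **Contact-frequency maps**: per residue pair, the fraction of frames
  with at least one formed native atom contact.
* **Base center-of-mass shifts**: $\Delta d = d_{\mathrm{mod}} -
  d_{\mathrm{unmod}}$ between mass-weighted base centers, averaged over
  frames gated on per-domain Q conditions (the "relevant structural
  domains folded" gate; the pipeline gates on dsl and asl at the
  folding threshold). Negative values mean the bases sit closer in the
  modified system.
* **Hydrogen bonds**: heavy-atom donor/acceptor pairs within 3.5 Å,
  from fixed per-base lists; no hydrogens or angles exist in the model,
  so this is deliberately a distance-only criterion.

## Numerical choices and degenerate inputs

Analytic forces match central differences to better than $10^{-5}$
relative error (asserted in the test suite); collinear angle triples
and degenerate dihedrals are guarded and contribute finite energy and
zero force; overlapping non-native atoms (r below $10^{-6}$ Å) abort
with the offending pair; the energy decomposition sums to the total to
accumulation precision. The native configuration is an exact stationary
point of the bonded terms, while the printed 12-10 native term crosses
zero there with an outward radial force of $8\epsilon/\sigma$ per
contact -- a property of this functional form that the test
suite asserts as such.

## Problem sizes used by the packaged studies

The bundled drivers and checks run at workstation scale, chosen once:
the 12-residue hairpin for temperature-response checks (10 seeds,
5×10^5 steps), the 61-residue toy tRNA for the two-system folding study
(8--12 trajectories per system, 1.5--2×10^5 steps at 353 K), 10^5-step
thermalization checks, and scripted-trajectory ensembles for the
classifier and density analyses. A full-scale study (60 trajectories
per system on a real ~76-nt tRNA, each run to completion) needs a
predicted or experimental structure as input and proportionally more
compute; the pipeline accepts such a structure unchanged via
`read_structure()`.

## What the toy studies do and do not show

Passing tests on the fixtures demonstrate that the potential, sampler
and analyses are implemented correctly and that the workflow
reproduces the *qualitative* phenomenology: hierarchical domain-wise
folding, sequential (corner-dominated) stem-loop formation, fewer
G-site hydrogen bonds once N2 is dimethylated. They do not constitute
evidence about real tRNA thermodynamics: the fixtures are
contact-sparse, their tertiary topology is only elbow-like, the
renormalized $\epsilon$ is a coarse-graining artifact, and complete
four-arm assembly at 353 K is kinetically frustrated on toy timescales
(trajectories that exhaust their step budget before global $Q > 0.8$
still classify by their domain events). Quantitative pathway
percentages for a real tRNA require its actual structure and
full-scale ensembles.
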