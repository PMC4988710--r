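---
title: "Modelling DNA-dependent dimerization of SOX Group E factors"
author: "soxdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA-dependent dimerization of SOX Group E factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxdimer)
```

# The problem

SOX8, SOX9 and SOX10 (the Group E subfamily of SOX transcription
factors) bind DNA through an HMG domain -- a three-helix, L-shaped fold
that engages the minor groove and bends the duplex sharply. Unlike other
SOX proteins, Group E members dimerize, but only when bound to DNA
carrying two inverted (A/T)(A/T)CAA(A/T)G-like sites separated by a
short spacer. Dimerization is mediated by a short region immediately
N-terminal to the HMG domain, believed to fold into a single amphipathic
helix (called alpha0 here, residues 72--84) that binds a hydrophobic
platform on the *partner* subunit's HMG domain. Mutations in this region
cause campomelic dysplasia.

`soxdimer` packages the quantitative workflows around this system:
sequence-level analysis of probes and of the dimerization helix, EMSA
titration fitting, and a coarse-grained, restraint-driven modelling
engine that assembles the full dimeric protein--DNA complex.

# Probe and helix sequence analysis

Binding probes are stored as `DuplexProbe` objects; only the top strand
is kept and the bottom strand is always its reverse complement.
`scanMotif()` matches IUPAC-degenerate patterns on both strands with a
per-position mismatch budget (no indels), reporting 0-based half-open
footprints in top-strand coordinates; hits overhanging the duplex ends
are never reported, even when the mismatch budget would allow a partial
match. `siteSpacing()` counts the base pairs strictly between two
inverted footprints, the geometry that defines a tandem dimer site.

```{r probes}
cc36 <- scanMotif(bundledProbes()$CC36, "CACAAAG")
siteHits(cc36)
siteSpacing(cc36)
```

The helical wheel (`wheelProjection()`, 100 degrees per residue for a
canonical alpha helix, configurable) places each residue of a region at
an angle that depends only on its position, so renumbering shifts labels
and not geometry. `hydrophobicFace()` reports the hydrophobic residues,
the smallest wheel arc covering them (the complement of the largest
angular gap, ties resolved toward the smallest start angle), and whether
that arc excludes every polar residue ("clean separation", the
amphipathic signature). The default hydrophobic alphabet is
{A, V, I, L, M, F, W, Y}; glycine, proline and cysteine are counted as
non-hydrophobic, and tyrosine is counted as hydrophobic because the
dimerization region's Y84 behaves as part of the hydrophobic face in the
mutagenesis data. `predictPhenotype()` is a deliberately transparent
lookup of that mutagenesis map (face residues 73, 76, 77, 80, 81, 84 and
platform residues 119, 142 abolish dimerization; assayed positions 78,
79, 118, 145 do not), not a trained predictor.

# EMSA quantitation

Titrations of a constant-DNA EMSA are modelled with the four-parameter
logistic curve

$$AB = d + \frac{a - d}{1 + (B/K_d)^b}$$

with $B$ the protein concentration (nM), $AB$ the normalized
shifted-band intensity, $a$ and $d$ the lower and upper asymptotes,
$K_d$ the midpoint and $b$ the steepness (Hill coefficient; values above
one indicate apparent cooperativity). Intensities are normalized to the
highest-concentration point of each titration, so $d$ is typically ~1.

`fit4PL()` estimates the four parameters by Levenberg--Marquardt least
squares with $K_d$ and $b$ parameterized on the log scale for
conditioning (estimates are reported on the linear scale). Starting
values are $a = \min(AB)$, $d = \max(AB)$, $K_d$ at the geometric middle
of the concentration grid and $b = 1$; convergence tolerance is 1e-10 on
the relative objective change with at most 500 iterations. Standard
errors come from the Gauss--Newton curvature at the optimum with the
delta method for the log-scale parameters; on noiseless data the
curvature is singular and the errors are reported as `NA` rather than
invented. The carried DNA concentration is not used by the model (the
assay keeps it roughly an order of magnitude below $K_d$); a warning is
emitted when it exceeds $K_d/5$, where ligand depletion would bias the
midpoint.

```{r fit}
sim <- simulateTitration(a = 0, d = 1, kd = 98, b = 4.4,
                         concGrid = logConcGrid(10, 450, 12))
fit4PL(sim)
```

Kinetics follow the elementary identities $k_{off} = \ln 2 / t_{1/2}$
and $k_{on} = k_{off} / K_d$, implemented literally in
`koffFromHalfLife()` and `konFromKdKoff()`. For the residence half-lives
reported for this system (about 10 min for the dimerizing construct,
about 1 min for the HMG domain alone) these formulas give
$k_{off} = 1.155\times10^{-3}$ and $1.155\times10^{-2}\,s^{-1}$; note
that applying $k_{off}/K_d$ with the fitted nanomolar affinities yields
on-rates around $10^4\,M^{-1}s^{-1}$, so any previously quoted rate that
disagrees with these identities cannot be reproduced from them -- the
package deliberately reports only what the stated formulas imply.

`classifyDimerization()` encodes the band-pattern logic of the
sub-stoichiometric assay: a dimerizing variant fills both half-sites
cooperatively (no singly occupied band), a non-dimerizing one populates
the intermediate. Band fractions are renormalized before thresholding
(default threshold 0.05 on the singly occupied fraction), so the call is
invariant to overall intensity scaling.

# Coarse-grained representation

All modelling uses one bead per protein residue (Calpha) and one frame
per base pair. A `DNAModel` stores per-base-pair origins and orthonormal
triads (x into the major groove, z along the local helix axis); strand
beads sit at +/-4.5 angstrom along the frame y axis, approximating the
phosphates, and are always derived from the frames. Proteins and DNA
share one coordinate system inside a `ComplexModel` (protein chains A/B,
DNA chains C/D).

`buildBDNA()` propagates frames with uniform or per-step twist / roll /
tilt / rise (defaults 36 degrees, 0, 0, 3.4 angstrom). Site-directed
bending (`applySiteBend()`) distributes a per-site bend across the
internal steps of each binding footprint as rotations about a fixed
bend axis, expressed in each local frame -- this phases the bend toward
the major groove at the site centre. With the default `"coplanar"`
phasing all sites share the bend axis of the first site's centre frame,
so two 54-degree site bends compose to exactly 108 degrees; with
`"per_site"` phasing each site bends about its own centre-frame axis and
the composition depends on the helical phase between sites. The default
of 54 degrees per site was chosen once so that the assembled dimer shows
the ~108-degree overall bend characteristic of this family's tandem
complexes, and is configurable.

`measureBend()` defines the overall bend as the angle between the mean
frame z axis over the first and last five base pairs. This
terminal-window definition is a documented choice: it is stable on short
duplexes, exact on single-rotation test cases, and insensitive to where
the bend sits, but it is not the only possible convention (axis-fitting
definitions can differ by a few degrees on kinked DNA).

# The restraint engine

All restraints are flat-bottom harmonics: each contributes
$k \cdot \max(0, |\Delta| - \mathrm{pad})^2$, zero inside its tolerance
band. Types:

* **distance** -- two-sided on a bead--bead distance (pads default 0.5
  angstrom, k = 1 in reduced units);
* **hbond** -- a distance specialization penalizing only the upper side
  (used for helix i,i+3 at 5.1 angstrom and i,i+4 at 6.2 angstrom);
* **torsion** -- two-sided on the four-bead pseudo-dihedral; the
  alpha-helical target is 50 degrees with a 10-degree half-width, and
  angular violations are converted to radians before squaring so the
  energy scale is commensurate with the distance terms;
* **air** -- an ambiguous interaction restraint: an upper bound on the
  $d_{eff} = (\sum_{ij} d_{ij}^{-6})^{-1/6}$ effective distance over all
  cross-pairs of two bead groups, satisfiable by any pair, always at
  most the minimum pairwise distance; coincident beads give 0 by
  convention;
* **planarity** -- an upper bound on the RMS deviation of a bead group
  from its least-squares plane.

The canonical atom-level AIR bound of 2.0 angstrom cannot be realized
between residue beads, which touch near 4--5 angstrom; the bead-level
AIR target is therefore 2.0 + 3.0 angstrom, a documented calibration
offset that preserves the "touch any member of the set" semantics at
coarse resolution.

Synthesis operations (`helixRestraints()`, `makeAIRs()`,
`deriveDNARestraints()`, `sampleContactRestraints()`) all emit
restraints that evaluate to zero on their source geometry -- for DNA
planarity this is achieved by setting each threshold to the source
geometry's own plane RMS plus the 0.5-angstrom half-width, since four
beads of two twisted base pairs are never exactly coplanar. Contact
sampling sorts the eligible cross-chain pair list lexicographically
before drawing without replacement, so seeds are portable across
platforms. Restraint sets serialize to a one-row-per-restraint TSV and
round-trip losslessly.

# Rigid-body docking

`dockTrials()` samples orientations of the dimerization helix on the
HMG platform. Each trial starts from a uniformly random rotation
(quaternion method) and a random point on a shell around the interface
(the centroid of AIR-restrained receptor residues; shell radius =
interface radius + mobile radius + 5 angstrom), then minimizes
AIR energy plus a soft-sphere clash penalty
$\sum \max(0, \sigma - d)^2$ with $\sigma = 4$ angstrom between
cross-chain beads. The local minimizer is a deterministic
coordinate-wise search over the six rigid degrees of freedom: each sweep
tries +/- the current step for three rotations and three translations,
keeps the first improvement, shrinks both steps by 0.7 after a sweep
with no improvement, and stops below a 1e-3 step or after 200 sweeps.
Because the minimizer is deterministic, randomness enters only through
the trial starts and the whole ensemble is reproducible from one seed.
The hot loop is implemented in C++ (`src/dock.cpp`); a vectorized R
implementation of the same energy is kept and cross-checked in the test
suite.

Candidates are ranked by energy (`rankSelect()`, ties by trial index)
and clustered by orientation (`clusterByOrientation()`): greedy leader
clustering on the interhelical angle between the posed helix axis and
the receptor alpha1 axis (principal components, oriented N to C), with
an N/N-versus-C/C terminus-proximity flag separating the two topologies
this interface can adopt. The bin count is emergent, not forced. The
representative is the lowest-energy member of the largest bin
(`pickRepresentative()`, deterministic tie-breaks by bin angle, then
trial index).

Upper-bound-only AIRs admit a degenerate zero-energy set -- a docked
helix can slide within its restraints without penalty -- so the
package's planted-problem validation (below) is designed to be
identifiable, and in the assembly the docked pose is subsequently pinned
by sampled two-sided contact restraints, exactly so that later stages do
not inherit this looseness.

# Synthetic fixtures and the planted docking problem

The generators exist so every stage is testable without downloads:

* `idealHelix()` -- Calpha beads on the canonical helix (1.5 angstrom
  rise, 100 degrees and 2.3 angstrom radius per residue).
* `toyHMG()` -- an idealized L-shaped three-helix fold with residues
  numbered 101--184 so the mutagenesis residue lists resolve (W115,
  A119, L142, ...). Helix phases are set so the platform residues A119
  and L142 point to the solvent-exposed outward face, away from alpha3.
  The sequence is synthetic (serine background with the
  mutagenesis-relevant identities placed); the fold is explicitly *not*
  a homology model -- its contract is topological, and users wanting
  realism can import a crystal-structure-derived PDB through
  `readPDB()`.
* `plantedDockingProblem()` -- the ground-truth docking task. The helix
  is laid side-on into the alpha1/alpha2 groove at a random position
  along it, a random tilt of up to 25 degrees, a random flip and a
  random spin, then slid out to a contact separation just above the
  clash diameter. Placements are screened for identifiability (most of
  the helix in contact, both receptor helices engaged) and the best
  admissible placement of a fixed number of seeded attempts is kept;
  AIRs are then generated from the true contact map in both directions
  and at two scales (all contacts within 8 angstrom, plus tight
  closest-shell contacts within 5 angstrom), each with its target set
  to the true-pose effective distance. The construction guarantees the
  AIRs are exactly satisfied at the planted pose and sharply peaked
  around it, which is what makes a 2-angstrom recovery criterion
  meaningful for an upper-bound restraint type.

What the synthetic data does *not* emulate: real HMG fold geometry,
sequence-dependent DNA structure, electrostatics, side chains, solvent,
or gel artifacts in titrations (noise is i.i.d. Gaussian). Tests passing
on these fixtures validate the machinery -- restraint bookkeeping,
search, clustering, assembly -- not biological accuracy of any
particular model.

# Assembly of the dimeric complex

`assembleDimer()` orchestrates the stages:

1. **Bent DNA** -- the tandem probe is scanned for its two inverted
   sites, straight B-DNA is built and bent 54 degrees per site
   (coplanar phasing), and self-consistent intra-strand, inter-strand
   and planarity restraints are derived.
2. **HMG placement** -- each domain is placed deterministically against
   the minor-groove side of its site's centre frame (binding face
   toward the DNA, the alpha1 arm toward the partner site), slid to a
   5-angstrom contact separation, and pinned by interface distance
   restraints taken from the placed geometry. Minus-strand sites use
   the dyad-flipped frame, so the two placements on a palindromic probe
   are related by the duplex 2-fold axis exactly.
3. **Dimerization helices** -- each chain's alpha0 is built at ideal
   helical geometry (its helix restraints evaluate to ~0 by
   construction, the converged endpoint of folding an extended segment
   under those restraints) and docked as a rigid body onto the partner
   HMG platform under the mutagenesis AIRs (400 trials, top 20, leader
   clustering). Candidates are additionally screened for chain
   connectivity: the helix C terminus must be reachable from the
   chain's own HMG N terminus through the 15-residue linker (at most
   ~56 angstrom); the lowest-energy bridgeable candidate, preferring
   the predominant orientation bin, is taken. Fifty contact restraints
   are then sampled from the chosen pose.
4. **Linker threading** -- residues 86--100 are placed on a circular
   arc between helix and domain, bowed away from the complex, with arc
   length matched to bonded spacing. The linker carries only bonded
   terms throughout -- it is deliberately left unrestrained, reflecting
   its replaceability in the real protein.
5. **Amalgamated refinement** -- all restraints are combined and the
   protein beads are refined by Metropolis Monte-Carlo under restraint
   + bonded + soft-core clash energy (sigma 3.5 angstrom between
   chains), with single-bead moves and occasional rigid moves of each
   alpha0 segment. The default schedule is geometric, 50 to 0.5 reduced
   temperature units over 8 stages of 2,000 steps; it is followed by a
   staged greedy quench (the T -> 0 limit of the Metropolis rule) at
   move amplitudes 0.5, 0.3, 0.15 and 0.08 angstrom, two stages' worth
   of steps each, which settles the model back into the flat bottoms of
   its restraints. DNA frames stay fixed during refinement; their
   restraints are satisfied by construction and monitored, not
   re-optimized.

`validateModel()` reports the overall DNA bend, restraint satisfaction,
the worst deviation, cross-chain clashes (pairs under 2.5 angstrom),
linker end-to-end spans, and the number of trans alpha0-to-partner-HMG
contacts per chain. The default assembly finishes in about half a
minute on one CPU with >99% of restraints satisfied, zero clashes, a
108-degree bend and both helices docked in trans; with the AIR lists
emptied the helices stay extended and the report flags the absence of
docking. A configuration toggle (`trans = FALSE`) lets the helix dock
its own HMG domain instead, for exploring the single-site hypothesis;
it is off by default.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: flat titrations and too-short
series are errors, not garbage fits; all-polar regions return an
undefined-arc report; coincident AIR beads give zero effective distance;
near-collinear toy folds warn. Deterministic tie-breaks are documented
at each selection point (energy ties by trial index; equal-size cluster
bins by leader angle). Every stochastic operation takes an explicit
seed, restores the caller's RNG state, and reproduces bit-identically.

The validation suite runs at desk scale by design: docking recovery
uses 10 planted problems of 400 trials each (a few minutes), the
Monte-Carlo fit checks use 100 simulated titrations per parameter set,
and the end-to-end assembly uses the default schedule above. These
sizes were chosen as the smallest at which the stochastic criteria are
stable.

# Limitations

The engine makes no claim of atomic accuracy or energetic realism: no
electrostatics, desolvation, side-chain packing or water refinement;
DNA is a rigid frame chain during refinement; the toy fold is a
topological stand-in. Comparisons against deposited crystal structures
(e.g. fold-similarity RMSDs) require external structures and are out of
scope; users can write models with `writePDB()` and superpose them in
standard tools.
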