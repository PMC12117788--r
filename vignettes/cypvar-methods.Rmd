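---
title: "Methods: structural and ensemble assessment of CYP missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural and ensemble assessment of CYP missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypvar)
```

`cypvar` assesses rare missense variants of CYP2C19 and CYP2D6 along two
complementary routes: an ensemble deleteriousness score translated to a
predicted relative-activity bin, and an explicit structural model of the
mutated enzyme scored by van der Waals contact/clash accounting and
access-channel proximity. A concordance module compares either route with
measured relative activities. This vignette documents the models, the
parameters that matter, the numerical conventions, and what the synthetic
test data do and do not establish.

## Structure model and preparation

A structure is a flat atom table (PDB author numbering, Ångström
coordinates) with het groups — waters, the heme, ligands — flagged per
atom. Preparation mirrors the usual cleanup before contact analysis: keep
the configured chains (crystal forms of these enzymes often carry several
copies; only one is analysed), remove waters, and drop every het group
except the heme, which is part of the functional unit of a P450 and must
stay in the model. Alternate locations resolve to the highest-occupancy
conformer, ties to altloc `A`.

Hydrogens are a convention, not a fact of the coordinate file: their
placement is tool-dependent and silently changes interaction counts. The
package therefore defaults to a heavy-atom-only model, with an optional
ideal-geometry mode that places backbone amide hydrogens (bisector
construction, 1.01 Å) and serine/threonine/tyrosine/cysteine hydroxyl/thiol
hydrogens. The hydrogen mode travels with every report.

Van der Waals radii come from a Bondi-type element table (C 1.70, N 1.55,
O 1.52, S 1.80, H 1.20, Fe 2.00 Å). Interactive modelling tools inherit
their radius sets implicitly; a reproducible pipeline has to pin one, so
the radius-set name is recorded in every report and the table is
swappable.

## Rotamer-based mutagenesis

`apply_mutation()` keeps the site's backbone fixed, removes the old side
chain, and rebuilds the target amino acid from ideal internal geometry:
Cβ is placed from the backbone with the C–N–Cα–Cβ improper at −122.6°
(the value measured on L-amino acids in crystal structures, which fixes
chirality), and the remaining atoms follow a per-amino-acid internal
coordinate table driven by the rotamer's χ angles. The bundled
backbone-independent library carries the common rotamers per amino acid
with prior probabilities summing to one; any library in the same tabular
format (`aa rot chi1..chi4 prob`) can be substituted.

Interactive tools leave the rotamer choice to the user; an algorithmic
pipeline needs a rule. Two are provided and recorded in provenance:

* `min-clash` (default): the candidate with the fewest overlaps ≥ 0.6 Å
  against the fixed environment; ties break by higher library probability,
  then lower index. This is the choice a structural biologist makes by eye.
* `probability`: the library's most common rotamer, ignoring the
  environment.

No backbone relaxation or energy minimisation follows the swap — the
mutant model is deliberately rigid, which is exactly why clash counts are
informative: a clash that relaxation would dissipate still marks local
strain. The flip side is documented under limitations.

## Contacts, clashes, hydrogen bonds

For atoms with radii $r_a$, $r_b$ at distance $d$ the overlap is
$o = r_a + r_b - d$. The conventions, all closed ("or greater")
comparisons:

* contact: $o \ge -0.4$ Å;
* clash: effective overlap $o - a \ge 0.6$ Å, where the allowance
  $a = 0.4$ Å applies only to hydrogen-bonded pairs (a favourable close
  approach is not strain);
* hydrogen bond: donor–acceptor distance within an element-pair base table
  (N·N 3.0, N·O 2.9, O·O 2.8, S-containing 3.3–3.5 Å) plus a 0.4 Å relax,
  and the antecedent–donor–acceptor angle at least 90° minus a 20° relax.
  With explicit hydrogens, the H···acceptor distance (base − 0.9 Å, plus
  relax) and a donor–H···acceptor angle ≥ 120° − relax are used instead.

Pairs within the site residue, and 1-2/1-3 neighbours across the peptide
bond, are excluded (configurable), matching standard clash-detection
practice. The neighbour search uses a cell list whose output is proved
equal, record for record, to an exhaustive $O(n^2)$ scan in the tests.

"Number of interactions" of a variant site is the count of contact records
(clashes and H-bonded pairs included) between the site residue's atoms and
all other atoms, counted as **atom pairs**. Published tables of this kind
rarely state the counting unit (atom pairs vs residues touched); atom-pair
counting is the stated convention here, and every report carries it, so
any deviation from an external count is attributable to unit, radius set,
hydrogen mode, rotamer choice, or ligand pose.

Clash-site distances follow a two-case rule: if the partner atom is in a
side chain or a het group (ligand, heme), the direct atom–atom distance is
reported; if it is a backbone atom, the distance from the site atom to the
partner residue's Cα is reported instead, as a reference length that does
not depend on the strained backbone atom itself.

Degenerate inputs: coincident atoms return the radius sum with a warning;
an empty environment yields an empty record set; an empty selection is an
error.

## Access channels

Channels are sphere chains: an ordered centerline with a local free
radius, resampled to ≤ 1.5 Å spacing (resampling is skipped when the
input is already finer, so loading is idempotent). Sphere lists exported
by Voronoi-based tunnel software can be imported directly; that is the
fidelity route. The built-in `find_channel_simple()` is a clearly labelled
simplified stand-in, not a reimplementation of the Voronoi algorithm: on a
regular occupancy grid (0.8 Å default spacing), each node's clearance is
its distance to the nearest atom surface minus a 1.4 Å water-probe radius,
and the channel is the path from the origin region (a 5 Å sphere around
the heme iron, the catalytic start point) to bulk solvent (nodes more than
10 Å from any atom — the surface cover radius) that maximises the minimum
clearance. The max-min value is found by binary search over clearance
levels with flood fill; the reported path is the breadth-first shortest
path at that level, with lexicographic tie-breaks, so the result is
deterministic. Tests verify the bottleneck against an independent max-min
Dijkstra oracle on small grids and against an analytic tube fixture (where
the iron's own excluded sphere caps the starting clearance — the analytic
truth accounts for it).

A residue is channel-proximal when the minimum over its atoms of
(distance to nearest centerline point − local radius, floored at 0) is at
most the proximity cutoff. No published number defines "close proximity";
the default is 4.5 Å — a van der Waals contact distance plus margin — and
the tests show the classification of the planted fixtures is stable for
cutoffs 3–6 Å.

## Ensemble score and activity bins

Five orthogonal predictors are used: LRT, MutationAssessor, PROVEAN,
VEST3, CADD. Each raw score becomes a binary deleterious call through a
documented per-predictor threshold and direction (LRT < 0.001 with lower
deleterious; MutationAssessor ≥ 1.935; PROVEAN ≤ −2.5; VEST3 ≥ 0.5; CADD
phred ≥ 20). The default aggregation is the **fraction of deleterious
calls among available calls**: every published score this pipeline is
checked against is a multiple of 0.2, i.e. $k/5$, which is what averaging
binary calls over five predictors produces. A mean-of-normalised-scores
mode (logistic squash centred on each threshold) is retained as an
alternative for frameworks that average continuous scores. Missing scores
shrink the denominator with a warning; a variant with no scores at all is
an error.

A score above 0.5 calls the variant deleterious. The score-to-activity
map anchors the published correspondences — 1.0 → 0 %, 0.8 → 0–10 %,
0.6 → 20–30 % — and extends to the rest of $[0, 1]$ by piecewise-linear
interpolation through those anchors (0 maps to 80–90 %). Only the three
anchors are externally grounded; the interpolated remainder is an
explicit extension and is swappable via the config.

## Relative activity and concordance

Measured relative activity expresses each replicate rate as
$100 \times \text{rate} / \overline{\text{reference rates}}$ and reports
the mean and sample SD ($n-1$) over replicates (assays here use three
independent expressions).

"Prediction matched experiment" needs a formal rule. The default,
`sd-overlap`, calls a pair concordant when the closed interval
[mean − SD, mean + SD] intersects the predicted bin, with a point
prediction of 0 % widened to [0, 10] — the lowest reportable class of the
scoring framework. On the packaged 11-variant reference table this rule
yields exactly 6 concordant variants (F114C, R186H, H251Q, A297V, R133C,
A305T), reproducing the published 6/11 headline; the count was first
confirmed by an independent manual recount before the rule was frozen.
Two alternatives ship for sensitivity analysis: `mean-in-bin` and a
`tolerance` rule; the rule id is recorded per row. Percentages render by
flooring (6/11 → 54 %), matching how such headline figures are printed.

## Synthetic data: what it shows and what it does not

Every pipeline input has a seeded generator whose ground truth is computed
by code independent of the module under test: ideal poly-alanine
helices/strands (with optional planted probe atoms at exact distances),
random-atom boxes with exhaustive double-loop contact enumeration,
five-predictor score tables with planted call patterns, lognormal
triplicate assays, and an analytic tube with a heme-like iron for the
channel finder. Generators are pure functions of (parameters, seed) and
restore the session RNG state.

Assay noise is lognormal and mean-preserving, because real assay SDs scale
with the mean. The reference batch is rescaled so that its sample mean is
exactly 100 units: in relative-activity assays the wild-type batch mean
*defines* the 100 % basis of each expression set, so recovery noise lives
on the relative measurements. Without that convention the ratio estimator
$100\,\bar X/\bar Y$ carries a relative bias of about $cv^2/n$ (≈ 3 % at
cv = 0.3, n = 3), which is a property of ratio estimation, not of the
implementation.

Passing these tests shows the geometry, counting, scoring and concordance
machinery is correct on inputs with known truth. It does **not** show that
clash counts on a real crystal structure match a particular published
table: those counts are convention-sensitive (radius set, hydrogen mode,
rotamer choice, docked ligand pose), which is precisely why every report
carries its conventions. Reproducing published interaction counts
requires the original crystal structures (4GQS, 3TBG) and docked substrate
poses, which are external downloads; the pipeline accepts them through the
same `prepare → mutate → variant_report` path used on synthetic data.

## Problem sizes and numerical choices

The test suite and acceptance script use: 50 random contact fixtures of
40–160 atoms (oracle equivalence is exact, not approximate), 1000 assay
draws, channel grids at 1.0 Å spacing over a ~30 Å tube, and 200–400
variant score tables. Comparisons of derived geometry use 1e-9 Å
(arithmetic identities), 1e-6 Å (distance rules), or one grid spacing
(discretised channel bottleneck). Boundary classifications are exact by
construction because both thresholds use closed comparisons.

## Known limitations

* Rigid-backbone mutagenesis: no relaxation or dynamics, so clash counts
  measure local strain in the unrelaxed model, not post-equilibration
  contacts.
* The grid channel finder is a stand-in: it finds one widest path, not a
  channel taxonomy, and its resolution is the grid spacing. Import the
  output of dedicated tunnel software when fidelity matters.
* The score-to-activity map is anchored at three published points;
  everything between is interpolation.
* Concordance is a descriptive fraction; with 11 variants no statistical
  performance claim is attempted.
* Predictor thresholds are conventions from the predictors' documentation;
  raw-score tables from annotation pipelines should be checked against the
  configured directions before scoring.
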