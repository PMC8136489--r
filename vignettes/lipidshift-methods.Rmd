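---
title: "Methods: from codon selection scans to lipid-swap feasibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from codon selection scans to lipid-swap feasibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

CD1 receptors are MHC-like cell-surface molecules that present lipid
antigens to T cells. Across primates, CD1 orthologs are unusually divergent
for immune receptors with little within-species polymorphism, which raises
the question of whether recurrent positive selection has reshaped their
lipid-binding grooves, and with what functional consequences. `lipidshift`
implements the inference chain that connects those questions: (i) site-wise
positive-selection detection on codon alignments over a fixed species tree,
(ii) mapping of sequence/structure conservation onto receptor models and
grid-based pocket volumetrics, and (iii) a thermodynamic "lipid swap"
analysis that converts docking free energies into dissociation constants
and asks whether an exogenous (pathogen-derived) lipid can displace the
tightest endogenous lipid, including single-site ancestral-substitution
scans.

The package deliberately stops where heavyweight external tools start:
alignments arrive aligned, trees arrive inferred, structures arrive
predicted or solved, and docking energies arrive computed. Everything
downstream of those inputs is implemented and tested here, and a
synthetic-data module can generate every input class with known ground
truth so that the whole chain is testable offline.

## Site-wise selection: models and tests

### Codon substitution model

Codon evolution follows the Goldman–Yang form on the 61 sense codons of
the standard code. The instantaneous rate from codon $i$ to $j$ is zero
unless the codons differ at exactly one nucleotide, and otherwise

$$q_{ij} \;=\; \pi_j \cdot \kappa^{\,\mathbb{1}[\text{transition}]} \cdot
\omega^{\,\mathbb{1}[\text{nonsynonymous}]},$$

with $\pi$ the F3×4 equilibrium frequencies (position-specific nucleotide
frequencies multiplied across codon positions, stop codons removed,
renormalised), $\kappa$ the transition/transversion ratio and $\omega$ the
dN/dS ratio. Generators are rescaled so branch lengths read as expected
substitutions per codon site. Because the chain is reversible, transition
matrices are obtained from a single symmetric eigendecomposition per
$\omega$ class; frequencies of codons never observed at some position are
floored at $10^{-10}$ (and renormalised) so the $\sqrt{\pi}$
symmetrisation stays well conditioned.

### Site-class mixtures and LRTs

Site-wise selection is tested with the standard nested pairs: M1 (classes
$\omega_0 < 1$ and $\omega = 1$) against M2 (adds $\omega_2 > 1$), and M7
(beta-distributed $\omega$ on $(0,1)$) against M8 (beta plus a selection
class $\omega_s \ge 1$ with weight $1 - p_0$). Beta mixtures are
discretised into `k_categories = 10` equal-probability classes evaluated
at the category medians. The likelihood of a site is the
proportion-weighted sum over classes of the Felsenstein pruning likelihood
(implemented over the 61-state space in C++; gaps are missing data with
flat partials). Each comparison is a likelihood ratio test with
$\chi^2_2$ reference, statistic clamped at zero. The boundary-mixture
refinement of the null distribution is documented here but not the
default, matching common practice; the $\chi^2_2$ reference is
conservative, which our calibration test accounts for by checking that the
empirical type-I error does not exceed the nominal band rather than
demanding it reach it.

Per-site evidence uses naive empirical Bayes: the posterior probability of
the $\omega > 1$ class given the fitted mixture. Full Bayes empirical
Bayes (prior averaging over a parameter grid) is out of scope, a choice
made explicit because reported "posterior probabilities" do not
distinguish the two.

### What is estimated, what is fixed

Branch lengths come from the input tree up to one global scale factor.
$\kappa$, $\omega$ and that scale are estimated under M0 (one-ratio);
site-model fits then hold $\kappa$ and the scale fixed and optimise only
the mixture parameters. Fixing $\kappa$ (not just the scale) is a
tractability choice: it removes one dimension from every mixture
optimisation and, in our recovery experiments, changes fitted mixtures
negligibly relative to their sampling noise. Optimisation is Nelder–Mead
on transformed parameters (logit for proportions and $\omega_0$, log for
beta shapes, $1 + e^x$ for $\omega_s$ and $\omega_2$, which enforces the
$\ge 1$ boundary smoothly). Five fixed starting points are screened by
likelihood and the best are polished; the alternative model of a nested
pair is additionally started from the null optimum, which guarantees
$\ln L_\text{alt} \ge \ln L_\text{null}$ up to optimizer tolerance.

### Counting scan (SLAC-style)

Independently of the ML path, a counting scan attributes changes to sites:
ancestral codons are reconstructed by Fitch parsimony (ties broken by
alphabetical codon order and recorded; unrooted trees are rooted at the
first alignment taxon; gapped tips act as wildcards), then each branch's
codon change is decomposed into single-nucleotide steps, averaging
synonymous/nonsynonymous step counts over all minimal orderings that avoid
stop codons (if every ordering passes through a stop, all orderings are
used and steps touching stops count as nonsynonymous). Expected site
counts are NG86-style: for each codon, 3 times the synonymous fraction of
its non-stop single-nucleotide neighbours, averaged over the column's
observed codons. Nonsynonymous excess is assessed with a two-tailed
binomial test of the (rounded) change counts against the expected
nonsynonymous proportion; path averaging can make counts fractional, and
rounding before an exact test is the documented compromise. Columns whose
composition has zero expected sites of either class (pure Met or Trp
columns) are excluded and flagged. Raw p-values drive the site calls, as
per-site thresholds do in the source analyses; a Benjamini–Hochberg column
is emitted alongside.

A site is called positively selected when the NEB posterior is at least
0.9 **and** the counting p-value is at most 0.1 (both configurable); the
intersection mirrors the stringent multi-test criterion the analysis chain
is built around.

## Structures: superposition, conservation, pockets

Kabsch superposition (SVD with the determinant correction) provides plain
RMSD; the refined variant iterates up to 5 cycles, each dropping pairs
whose deviation exceeds the mean plus 2 standard deviations of the current
deviation profile and refitting. The literal rule "deviation exceeding
$k\sigma$" would reject every pair of any tight-but-nonzero profile (mean
far above the standard deviation), so the mean-centred form is used, with
a $10^{-8}$ Å floor so numerically-zero profiles are never pruned. Both
plain and refined RMSD are reported because published pairwise RMSDs
rarely state their rejection convention.

Per-residue structural divergence across an ortholog ensemble is the mean
pairwise Cα distance after superposing all models onto the first (the
reference is configurable); conservation is that profile normalised so the
least divergent residue maps to 1 and the most divergent to 0. Scores are
painted into the B-factor column (sentinel 99.99 for unscored residues) so
any molecular viewer can colour by conservation. The alignment-column to
residue-number map is always emitted, making site references such as
"position 98" auditable against structures whose numbering differs.

Point mutations for ancestral-substitution scans are stub mutations: the
residue is renamed and side-chain atoms beyond Cβ removed. No rotamer is
built — a deliberate refusal to ship a side-chain packer — and the output
carries a REMARK saying the structure must be rebuilt before docking.

### Cavity volume and portals

Pocket volume is a probe-inflated occupancy grid: voxels within
(vdW + probe) of any atom are occupied, a flood fill from the bounding-box
exterior marks solvent, and the remaining free voxels are buried cavity;
volume is exactly voxel count × spacing³. Defaults are a 0.75 Å probe
(the probe used for the reference volume predictions) and 0.5 Å spacing
(the grid is ours; a convergence check on fixtures guards the choice).
This is a stated approximation to alpha-shape methods (CASTp): volumes are
comparable across inputs run with the same settings, not calibrated to
CASTp's absolute numbers.

Portals — passages a small probe can thread but a large one cannot — are
counted morphologically: take the space reachable from outside at the
small probe, subtract a chamfer (Euclidean-approximating) dilation of both
the large-probe exterior and the large-probe cavity, and count the
surviving connected components. The dilation radius is
$\sqrt{3}\,(r_\text{large} - r_\text{small})$ plus a two-voxel margin: the
$\sqrt{3}$ covers orthogonal concave corners, where the inter-probe
surface band is diagonally deeper than its face-on thickness (a plain
6-connected dilation demonstrably leaves corner artefacts on box-shaped
test cavities). Components smaller than 3 voxels are ignored.

## Affinities and the lipid-swap rule

Binding free energies convert to dissociation constants as
$K_d = \exp(\Delta G / RT)$ with $R = 0.0019872$ kcal mol⁻¹ K⁻¹ and
$T = 298.15$ K by default ($T$ is configurable and recorded in outputs;
the temperature behind published docking energies is rarely stated). Only
the lowest-energy pose per receptor–ligand pair enters any decision.

The swap call for a receptor compares the tightest endogenous ligand
against a named exogenous one: fold = $K_d^\text{best endo} /
K_d^\text{exo}$, verdict *swap* iff fold ≥ threshold. The default
threshold of 1 (exogenous at least as tight; ties swap) is a convention,
not a literature-calibrated cutoff — no published fold cutoff exists for
this decision — so all folds are always reported and any threshold can be
re-applied. The rule assumes the tightest endogenous lipid is abundantly
available, the same simplification the underlying analysis states.
Mutational scans difference two such tables ligand-by-ligand (fold change
of $K_d$, direction flags, verdict change) and summarise the endogenous
direction in one sentence.

## The synthetic-data module

The generators define the conditions every recovery test runs under:

* **Codon alignments** — 19 taxa and 300 codon sites by default (the
  study's taxon scale), random topologies with exponential branch lengths
  of mean 0.05 substitutions/codon site, $\kappa = 2$, uniform
  position-specific nucleotide frequencies, and a truth mixture: M7 with
  beta(0.5, 1.5) for null calibration (a purifying-skewed shape typical of
  conserved receptor-gene alignments), or M8 with $p_0 = 0.9$,
  $\omega_s = 4$ for power/recovery. Evolution uses the same
  mixture-scaled generators as the fitting code; truth $\omega$ classes
  are emitted per site.
* **Cavity fixtures** — pseudo-atom wall planes (element `D`, 1 Å radius)
  placed at vdW + probe outside the faces of a cubic void, so the
  probe-inflated surface coincides with the void analytically (a 4 Å void
  has exactly 64 ų). Wall planes extend past the corners by a
  non-half-integer margin so the void faces never land exactly on voxel
  centres of the default grids, which would make the discretised volume
  alignment-sensitive. Channel variants stack three wall planes (a wall
  thick enough that only the carved channels connect inside to outside)
  and carve cylinders that pass a 0.75 Å probe but block a 2.5 Å one.
* **Structure ensembles** — an ideal α-helical Cα trace replicated across
  models, with a contiguous loop displaced by Gaussian noise of known RMS
  amplitude and optional random rigid motions that superposition must
  undo.
* **Affinity tables** — endogenous ΔG drawn from a normal law; the
  exogenous ΔG is placed so the endogenous/exogenous $K_d$ fold equals a
  configured gap factor exactly; mutant backgrounds rescale endogenous
  and/or exogenous $K_d$ by configured factors; decoy higher-energy poses
  exercise the lowest-pose rule. Truth verdicts are computed from the
  truth $K_d$ values by the same fold rule.

Component RNG streams (tree, site classes, evolution, structure, affinity,
orientation) derive independently from the master seed, so adding one
stage never perturbs another and equal seeds give byte-identical outputs.

What the generators do **not** emulate: alignment error, recombination,
among-site rate variation beyond the $\omega$ mixture, real side-chain
chemistry, docking pose geometry, or structure-prediction error. Passing
recovery tests therefore demonstrates the inference machinery is correct
under its own model, not that real CD1 data satisfy that model.

## Numerical choices and degenerate inputs

* Pruning partials are rescaled per pattern when their maximum drops below
  $10^{-120}$; likelihood tolerances in oracle comparisons are $10^{-8}$
  log units.
* Pattern compression (unique site columns) feeds the likelihood; results
  are invariant to taxon order and site order.
* Monomorphic alignments fit but are flagged unidentifiable (mixture
  parameters are arbitrary at a flat likelihood).
* Fitch ties and the rooting of unrooted trees are deterministic and
  recorded; alphabetical codon order is the tie-break everywhere.
* All alignment and residue coordinates are 1-based closed intervals.
* The identity statistic defaults to amino-acid columns with gap-containing
  columns excluded from the denominator; both gap policies are exposed
  because published identity percentages rarely state theirs.
* Cleaning removes whole columns (never taxa), keeping the taxon set
  concordant with the tree.

## Experiment sizes used by the shipped checks

The calibration suite runs the study-scale data dimensions (19 taxa, 300
codons) at smoke replicate counts — 25 null and 10 power replicates —
sized so the whole suite stays interactive; the experiment function
(`lrt_experiment()`) takes the replicate count as a parameter for larger
runs. At 25 null replicates a [1%, 11%] band on the true rejection rate is
checked only from above (at most 4 rejections), since the lower bound is
not resolvable at that replicate count. Recovery checks for $\omega_s$ use
the median over power replicates within ±50% of truth.

## Known limitations

* **The counting arm is power-limited by construction.** Under the
  standard code a random single-nucleotide change is already ~75%
  nonsynonymous, so a two-tailed binomial on a site's handful of observed
  changes needs roughly nine or more all-nonsynonymous changes before its
  p-value can cross 0.1; at primate-scale divergence most sites never
  accumulate that many, and at deep divergence multi-step path averaging
  dilutes the nonsynonymous excess back toward the neutral expectation.
  The posterior-AND-counting intersection is therefore a high-precision,
  low-recall filter: in our recovery experiments the NEB arm alone finds
  most truly selected sites (every one it flags is true), while the
  intersection keeps only the strongest. Both tables are always emitted so
  users can weigh the arms themselves.
* NEB (not BEB) posteriors; $\chi^2$ (not boundary-mixture) LRT reference.
* SLAC here is counting-based with parsimony ancestors; it is not the
  likelihood-weighted SLAC of HyPhy, and branch-specific (episodic)
  selection tests are out of scope.
* The grid pocket method is not CASTp; absolute volumes differ by
  construction.
* Stub mutations are not dockable structures.
* The swap rule is an equilibrium argument on endpoint affinities; kinetics,
  lipid abundance and loading machinery are outside the model.
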