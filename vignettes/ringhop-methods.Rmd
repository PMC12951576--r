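---
title: "Methods: exit-vector aligned shape and ESP similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exit-vector aligned shape and ESP similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ringhop` ranks candidate aromatic heterocycles as replacements for a query
ring by how well they reproduce the query's substituent geometry, molecular
shape and electrostatic potential. This vignette records the model, the
numerical choices behind it, and what the test suite does and does not
demonstrate.

## Exit-vectors and why alignment is anchored on them

An exit-vector is an aromatic C–H or N–H bond: the position where a
substituent would be attached and the direction along which it would
project. A replacement ring that scores well on shape alone but throws its
substituents in the wrong direction is useless in a real molecule, so all
alignments here superpose exit-vectors first and only then measure
similarity.

## Library enumeration and filtering

Seed heterocycles (restricted to C/N/O/S/H) are functionalized at every
exit-vector: 7 substituents at carbon positions (methyl, fluoro, chloro,
cyano, methoxy, amino, trifluoromethyl) and 2 at pyrrole-like nitrogens
(methyl, acetyl). The carbon set was chosen to span electron donors and
acceptors with minimal conformational flexibility; the set sizes are fixed
by the enumeration arithmetic the package reproduces (6 C–H vectors × 7 =
42 products for indole, plus 2 N-products, 44 monofunctionalized molecules
in total), while the identities are configurable package defaults.
Bifunctionalization repeats the step on each mono product at its *remaining*
vectors — a substituted position has consumed its hydrogen. All products
deduplicate by OpenBabel canonical SMILES, which collapses
symmetry-equivalent attachments (benzene yields exactly 7 monosubstituted
products). Substitution itself is hydrogen-replacement graph surgery on the
explicit-hydrogen molecular graph, round-tripped through mol2 so that
aromaticity is re-perceived on the product.

Three filters follow:

* **Stability ("PEB") rules** — nine patterns for unstable or implausible
  motifs (carbon fraction < 20%, ≥ 4 ring nitrogens bonded together, ≥ 4
  heteroatoms bonded together, ≥ 3 exocyclic carbonyls, cyclic anhydride,
  cyclic thioester, N–N ring fusion, ≥ 2 sulfurs in a six-ring, bonded
  cyclic ester carbonyls). The SMARTS were written for this package.
  Tetrazole (either annular tautomer) is whitelisted as an exact structure:
  read literally, the nitrogen-chain rule would remove it, yet it is an
  established, stable pharmacophore. The chain rules use *ring* nitrogen
  membership rather than perceived aromaticity because aromaticity models
  disagree on extreme rings (OpenBabel rejects pentazole as aromatic;
  the rule must still catch it).
* **Exit-vector requirement** — a heterocycle with no remaining aromatic
  C–H/N–H cannot carry functionality and is dropped.
* **Planarity** — after 3D embedding, any molecule whose aromatic atoms
  deviate more than 0.3 Å from their least-squares plane is dropped. The
  0.3 Å default catches sp3-like puckering (an out-of-plane displacement of
  a genuinely pyramidalized ring atom is several tenths of an Ångström)
  while tolerating force-field noise, and is configurable.

Annular tautomers are distinct library entries throughout; inputs are taken
verbatim with no tautomer or protonation enumeration.

## Geometry and charges

A single conformer per molecule is built with OpenBabel's `gen3d`
(rule-based assembly followed by MMFF94 refinement). The chemistry in scope
is rigid mono-/bicyclic aromatics (the default substituents add at most one
rotatable bond), so one conformer represents each molecule well, and the
build is deterministic: the same SMILES always returns identical
coordinates. The recorded `seed` is provenance, not a source of randomness.

Partial charges use the Gasteiger–Marsili PEOE scheme, implemented in the
package with the original published parameter table: orbital
electronegativity χ(q) = a + bq + cq², charge transferred across each bond
proportional to the electronegativity difference over the donor's cation
electronegativity, damped by 0.5^k over 12 iterations. Heteroatoms
conjugated to an aromatic/sp2 system take sp2 parameters (aniline-type N,
aryl ethers). The implementation is validated in the tests against frozen
reference charges from an independent PEOE implementation (agreement to the
reference's printed 1e-4 precision). External charge sets (e.g. RESP,
AM1-BCC) can be attached via `assign_partial_charges(model = "external")`
or a two-column text file; totals must match the formal charge within 1e-3.

## Alignment

`kabsch_umeyama()` computes the optimal proper rotation by SVD with the
determinant correction; collinear correspondence sets are rejected because
they leave a free rotation. For a one-vector alignment the correspondence is
{ring atom, hydrogen terminal, ring atom + unit ring-plane normal}. A ring
*centroid* third point — the obvious first choice — is degenerate: the C→H
direction points radially away from the ring centre, so centroid, ring atom
and hydrogen are nearly collinear and the fit cannot pin the ring plane. The
unit-normal anchor fixes the plane exactly and leaves precisely the physical
two-fold ambiguity, which is resolved by scoring both flip states (the
`flip` state negates the normal — a 180° rotation about the vector axis).
Two-vector alignments use the four points {ring₁, H₁, ring₂, H₂}, scored in
both pair orders.

Two-vector candidate retrieval is hash-gated: the ring-atom distance *d*
falls into one of 18 uniform bins over 1.2–7.5 Å (clamped at the ends) and
the angle between the two C,N→H bond vectors into one of six 30° bins; the
8-bit key packs the distance bin into the high five bits and the angle bin
into the low three. The bin span covers the geometric range of exit-vector
pairs on mono- and bicyclic aromatics; uniform bins keep small geometric
perturbations within one bin in most of the range. Hashes are stored for
unordered pairs and both orders are tried at alignment time. Collapsing the
binning to a single cell makes the gated search provably identical to
exhaustive pair enumeration, which the tests exercise.

## Scoring

**Shape.** Each atom is a spherical Gaussian p·exp(−α r²) with p = 2.7 and α
chosen so the Gaussian integrates to the atom's van der Waals hard-sphere
volume (Bondi-type radii, H = 1.10 Å); hydrogens are included. The molecular
overlap O_AB is the first-order analytic sum of atom-pair product integrals,
without higher-order intersection corrections — standard practice for
Gaussian shape comparison, and validated against brute-force voxel
integration (0.2 Å grid) to within 2% in the tests. The shape similarity is
the Tanimoto index O_AB / (O_AA + O_BB − O_AB).

**ESP.** The Coulomb kernel 1/r is expanded in three Gaussians fitted over
0.5–10 Å (`scripts/fit_esp_kernel.R`; max relative error 4.7%, frozen into
the package). The field overlap of two charge distributions then reduces to
E_AB = Σᵢⱼ qᵢqⱼ L(dᵢⱼ) with L the kernel self-convolution, again analytic.
The raw ESP Tanimoto lies in [−1/3, 1] — negative when positive potential
overlaps negative — and is mapped linearly onto [0, 1], the convention of
Gaussian-field ESP comparison methods: identity scores 1, a sign-inverted
field 0. The raw value is reported alongside. A clamp-at-zero variant was
considered and rejected: it discards all resolution among anti-correlated
fields and is not what the cited ESP-comparison method does.

**Total.** total = w_shape·shape + w_esp·esp, default weights (1, 1), range
0–2. Searches report the single best (vector, flip/order) alignment per
library molecule; ties in the ranking break by ascending RegID, so output is
deterministic.

Self-matches score 2.0 to within ~10⁻⁵ rather than bitwise: the query embeds
in its input atom order while the library copy embeds from canonical SMILES,
and force-field convergence leaves ~10⁻⁴ Å differences between the two
builds. Tests and the acceptance script treat 1e-4 as exact for this reason.

## Series analysis

Given per-ligand (shape, esp, pIC50) records — producible with
`score_series()` against the most potent ligand's fragment — the convex
weighting w·shape + (1−w)·esp maximizing the Pearson correlation with pIC50
is found by bounded L-BFGS-B from five starts, with {0, 0.5, 1} always among
the candidates (so the optimized correlation never drops below the
equal-weight correlation) and an exhaustive 0.001-step grid as fallback.
The objective is smooth but not guaranteed unimodal in w, hence the
multi-start. `train_test_stability()` repeats the fit over random 80/20
splits (100 by default; the split ratio is a package choice) and reports
held-out correlations. Enrichment factors use
EF = (retrieved/cutoff) / (actives/library), with fraction cutoffs floored
to an integer rank — conservative and deterministic.

## What the fixtures do and do not show

The built-in catalogue behind `fixture_library()` holds 66 common mono- and
bicyclic aromatic heterocycles, including annular tautomer pairs. It makes
every workflow self-contained and is faithful to the chemistry class the
method targets, but it is small and hand-curated: passing tests demonstrate
correctness of enumeration, alignment, scoring and ranking machinery, not
screening performance on a production-scale library (hundreds of thousands
of molecules) or on externally curated seed sets. Scale-sensitive behaviour
is covered only as a trend (runtime roughly linear in library size over
8/16/32-molecule fixtures). Problem sizes used by the test suite and the
acceptance script — a ≤ 42-molecule seed library for the search checks, 50
synthetic records for weight recovery, ≤ 12-atom molecules for the voxel
oracles — were chosen so every oracle is exact or near-exact at desk scale.

## Known limitations

* Single-conformer rigid alignment: no torsional sampling; inappropriate
  beyond (near-)rigid ring systems.
* PEOE sigma charges are a deliberately cheap model; rankings are stable to
  charge-model choice only to the extent the underlying fields are, and an
  import hook is provided for higher-level charges.
* The PEB SMARTS are this package's readings of the nine published rules;
  borderline motifs may be judged differently by other implementations.
* OpenBabel aromaticity/canonicalization defines molecular identity;
  toolkits with different aromaticity models may dedupe differently at the
  margins.
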