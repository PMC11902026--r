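---
title: "Quadrupolar and structure-binding strength indices: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrupolar and structure-binding strength indices: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadbind)
```

## The scientific problem

Nucleoside-analogue drugs such as ribavirin bind their targets through the
same kinds of hydrogen bonds and stacking contacts that organize their
crystals. quadbind quantifies that parallel from two directions:

* **from the nucleus outward** — ¹⁴N nuclear quadrupole resonance (NQR)
  parameters report the electron density at each nitrogen, and their shifts
  between the isolated molecule, the crystalline solid and the
  protein–ligand complex localize binding effects per atom;
* **from the pocket inward** — docking energy decompositions, molecular
  similarity and contact-surface statistics compare how candidate ligands
  engage a pocket relative to a reference compound.

## NQR parameter algebra

A spin-1 nucleus in zero field has three transition frequencies determined
by the quadrupole coupling constant $C_q = e^2qQ/h$ (MHz) and the asymmetry
parameter $\eta \in [0, 1]$ of the electric field gradient (EFG) tensor:

$$\nu_\pm = \frac{C_q}{4}(3 \pm \eta), \qquad
  \nu_0 = \nu_+ - \nu_- = \frac{C_q}{2}\eta,$$

inverted by $C_q = \tfrac{2}{3}(\nu_+ + \nu_-)$ and
$\eta = 3(\nu_+ - \nu_-)/(\nu_+ + \nu_-)$. `params_from_frequencies()` and
`frequencies_from_params()` implement the pair; the roundtrip is exact to
1e-9 relative (property-tested). Physical inputs satisfy
$\nu_- < \nu_+ \le 2\nu_-$; frequency pairs implying $\eta > 1$ are rejected
with a validation error rather than silently clipped.

`efg_to_params()` diagonalizes a symmetric EFG tensor and orders principal
values by magnitude, $|q_{xx}| \le |q_{yy}| \le |q_{zz}|$. Magnitude
ordering (not algebraic) is what guarantees $\eta \in [0,1]$; $\eta$ is
computed as $|q_{xx} - q_{yy}|/|q_{zz}|$. Coupling constants are reported as
magnitudes, which is how they are measured; the signed $q_{zz}$ is retained
as an attribute. The a.u.-to-MHz conversion (about 2.3496 MHz per fm² per
a.u., from CODATA-2018 constants) is exposed as `efg_conversion_mhz()`, with
the ¹⁴N quadrupole moment defaulting to 2.044 fm².

### Spectral assignment

A spectrum of $3n$ lines from $n$ inequivalent nitrogens is ambiguous until
the lines are grouped into per-site triplets. `group_lines()` exploits the
internal constraint $\nu_0 = \nu_+ - \nu_-$: it enumerates (exact cover
search) all partitions into triplets whose closure residual
$|\nu_0 - (\nu_+ - \nu_-)|$ is below a tolerance. The default tolerance is
0.01 MHz, the order of resolution implied by three-decimal line positions;
for the bundled ribavirin spectrum a tolerance of 0.005 MHz leaves exactly
one consistent partition out of 15,400, which is the entire point of the
constraint. A leftover mode searches maximal disjoint triplet sets instead
of full partitions, so spurious lines from molecular motions do not derail
the grouping.

`assign_sites()` matches experimental parameter sets to calculated
candidates by exhaustively scoring all bijections (n ≤ 8) with the Pearson
correlation of the regenerated frequencies — frequencies, not parameters,
because that is the quantity a calculated-vs-experimental scatter plot
shows. Ties break on the smaller residual SD about the identity line, then
lexicographically, making the result deterministic.

## Quadrupolar indices

Six per-site indices difference the NQR parameters between contexts:
$\Delta^s, \delta^s$ (solid minus single molecule), $\Delta^c, \delta^c$
(complex minus single molecule) and $\Delta^{CS}, \delta^{CS}$ (complex
minus solid). $\Delta$ values carry MHz; $\delta$ values are dimensionless.
When all three contexts share one single-molecule reference the identities
$\Delta^{CS} = \Delta^c - \Delta^s$ and $\delta^{CS} = \delta^c - \delta^s$
hold exactly; in practice the single-molecule geometries underlying
solid-state and complexation calculations often differ, so the package
stores contexts per compound and never assumes the telescoping. Missing
contexts produce explicit errors (single indices) or `NA` (tabulation) —
never silent zeros. Sites are matched across contexts by exact label;
chemically different sites (e.g. a ring nitrogen that is sugar-substituted
only in the complex) can be compared only through an explicit alias map.

## Structure-binding strength indices

For each docking energy term $T \in \{BA, HB, SE, PL, VdW, RNA, ME\}$,

$$\mathrm{SBSI}_T = \frac{T_{\text{reference}} - T_{\text{ligand}}}{1 - s},$$

where $s \in [0,1]$ is a structural similarity between the ligand and the
reference. The numerator asks "does this ligand bind better than the
reference?", the denominator re-weights by structural novelty: a small
improvement from a near-copy counts as much as a large one from a very
different scaffold. At $s = 1$ the index diverges; the package returns
signed `Inf` (an explicit sentinel, `+Inf` for a zero numerator) rather
than a large float. `sbsi_classify()` splits ligands at zero: positive
SBAI = strongly binding (active), negative = weakly binding; an exact zero
classifies as strongly binding with a boundary warning. The binding
affinity enters as its own term rather than being derived from the
decomposition, since affinity estimates and term decompositions typically
come from different scoring models.

## Similarity kernels

Three kernels, all symmetric with range $[0,1]$ and self-similarity 1,
operating on implicit-hydrogen heavy-atom graphs parsed from SMILES
(OpenBabel via ChemmineR, with per-ring aromaticity perception):

* **Path fingerprint Tanimoto** — all simple labeled paths up to 7 bonds,
  canonicalized against reversal and hashed onto 2048 bits;
  $|A \cap B| / |A \cup B|$. Length and path depth are configurable. Hashed
  fingerprints are scheme-dependent, so two implementations rarely agree
  numerically; published similarity values are treated as inputs to the
  SBSI layer, not as oracles for this kernel.
* **Atom-pair Tanimoto** — multisets of (descriptor, descriptor,
  topological distance) with descriptors (element, heavy-neighbor count,
  aromatic flag); $\sum\min / \sum\max$ over the key union.
* **MCS similarity** — the *connected* maximal common edge subgraph (atoms
  matched on element + aromaticity, bonds on order), scored as
  $m/(e_a + e_b - m)$. The connected variant was chosen because the
  disconnected one inflates similarity through scattered fragment matches.
  The search is an exact branch-and-bound, complete in well under a second
  for drug-sized molecules (~20 heavy atoms); a configurable time budget
  (default 10 s) switches to a seeded randomized multi-start growth whose
  result is flagged `exact = FALSE`. Correctness is property-tested against
  exhaustive enumeration of connected common edge subgraphs on small
  graphs. Two edgeless graphs compare at 1 (no edge structure to
  distinguish); an edgeless vs a bonded graph at 0.

## Contact-surface statistics

From a symmetric matrix of Hirshfeld contact percentages $C_{XY}$, the
element surface fractions are $S_X = C_{XX} + \tfrac12\sum_{Y \ne X}
C_{XY}$ (renormalized to 100), random-mixing expectations are
$R_{XX} = s_x^2 \cdot 100$, $R_{XY} = 2 s_x s_y \cdot 100$, and the
enrichment ratio is $E_{XY} = C_{XY}/R_{XY}$ — above 1 a privileged
contact, below 1 a disfavored one. Pairs with $R_{XY} < 0.5\%$ are flagged
sparse instead of reported: tiny denominators make the ratio meaningless.
Percentage tables are accepted when they close to 100 within 1.5 (absolute),
accommodating per-cell rounding in published tables.

Contribution vectors (e.g. per-nitrogen contact channels) are compared by
RMSD and Euclidean distance under a zero-fill convention: the channel set is
the union of declared channels, a channel valued `NA` (an empty table cell)
still counts as a declared zero, and the RMSD denominator is the union
size. This convention is what reproduces published per-site RMSD values and
keeps $ED = RMSD\sqrt{n}$ an identity.

## Binding modes and B-factors

Binding modes — named vectors of per-residue interaction energies — are
compared over the union of residue identifiers with zero fill ("all
bindings included"): a residue contacted by only one ligand contributes its
full energy. `rmsd_bm()`, and Manhattan/Euclidean `mode_distance()`, are
true metrics on those zero-filled vectors, and Manhattan ≥ Euclidean on
every input by the norm inequality; published distance pairs violating the
inequality therefore cannot be outputs of these definitions and are
documented as excluded reference points.

B-factor profiles are compared after per-structure z-scoring
$B' = (B - \bar B)/\sigma_B$ using the *population* standard deviation (the
choice is immaterial to the shape, but population SD makes the two-residue
case exactly ±1 and is documented for reproducibility). $\Delta B'$ aligns
residues by identical identifiers by default — appropriate for
near-identical chains — with an explicit alignment table for anything else.

## The synthetic spectrum generator

`generate_spectrum()` emulates the assignment engine's real input: $n$
sites drawn uniformly from coupling-constant and asymmetry ranges
(defaults 2.4–4.6 MHz and 0.1–0.75, the ranges observed for amide and azine
nitrogens in nucleoside crystals), expanded to transition triplets,
perturbed by independent Gaussian line noise (default SD 0.002 MHz, the
scale of three-decimal line positions), with optional spurious lines drawn
uniformly over the spectral range, and deterministically shuffled under a
seed. It does **not** emulate line intensities, temperature drift,
overlapping lines, or correlated frequency errors from a shared field
calibration — so passing recovery tests show the combinatorial engine
works at realistic noise, not that every experimental spectrum is
automatically assignable. At the default noise with two spurious lines the
top-ranked grouping recovers at least 3 of 4 sites in at least 95 of 100
seeds (the threshold was fixed from a pilot run of the generator and then
frozen).

## Numerical choices and problem sizes

* Triplet closure tolerance 0.005–0.01 MHz depending on the data's printed
  precision; configurable everywhere.
* Exhaustive searches are sized to their combinatorics: partition search is
  exact cover over candidate triplets (12 lines is instantaneous),
  assignment is capped at n = 8 sites (40,320 bijections), MCS
  branch-and-bound carries a 10 s default budget.
* Property suites run at fixed seeds with 200–1000 random cases per
  invariant; the Monte-Carlo recovery check uses 100 generator seeds.
* Display rounding (1–3 decimals, matching how such tables are printed)
  happens only at report time; full precision is kept internally.

## Known limitations

* The toolkit consumes tabulated products of electronic-structure, docking
  and Hirshfeld-surface computations; it does not produce them.
* Hashed-fingerprint Tanimoto values are not comparable across fingerprint
  schemes.
* The exact MCS search is exponential in the worst case; beyond the time
  budget the randomized fallback gives a lower bound flagged as inexact.
* Aromaticity perception follows OpenBabel/ChemmineR ring analysis; exotic
  tautomers may be perceived differently than by other toolkits.
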