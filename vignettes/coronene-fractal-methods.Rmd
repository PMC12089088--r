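---
title: "Coronene fractals: construction, indices, entropy and spectra"
author: "coroneneFractals package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronene fractals: construction, indices, entropy and spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroneneFractals)
```

This vignette documents the models and numerical choices behind the
package: how the three fractal families are reconstructed as explicit
molecular graphs, how the degree-based indices and entropies are defined,
how the Hückel energetics are computed, and where the genuinely open
design decisions were resolved.

## 1. Reconstruction of the three families

The fractal families are specified in the literature by drawings plus
closed-form vertex/edge counts.  The package reconstructs them by a
*vertex substitution* rule: take a small benzenoid **template** on the
honeycomb lattice, replace each template vertex with one 24-atom coronene
unit, and fuse units across each template edge along one shared rim bond
(both bond endpoints identified pairwise).  Writing $V_T, E_T$ for the
template, the expansion obeys the exact identities

$$|V| = 24V_T - 2E_T, \qquad |E| = 30V_T - E_T,$$

and the degree-based edge partition

$$|E_{(2,2)}| = 6V_T - 2E_T,\quad |E_{(2,3)}| = 12V_T - 4E_T,\quad
  |E_{(3,3)}| = 12V_T + 5E_T.$$

Three template series reproduce every published count polynomial exactly
(verified symbolically and, in the test suite, by generating and counting
for all sizes up to 4):

* **ZHCF(n)** — hexagonal cells with cube coordinates
  $\max(|a|,|b|,|c|) \le n-1$: the zigzag series benzene, coronene,
  circumcoronene, … with $V_T = 6n^2$, $E_T = 9n^2 - 3n$.
* **AHCF(n)** — cells with $\max(|a-b|,|b-c|,|c-a|) \le 3(n-1)$: the
  armchair series benzene, hexabenzocoronene, … with
  $V_T = 18n^2-18n+6$, $E_T = 27n^2-33n+12$.
* **RCF(m,n)** — $n$ rows of $m$ linearly fused cells, consecutive rows
  disjoint and joined by $m$ vertical lattice bonds (perylene-type
  junctions): $V_T = 4mn+2n$, $E_T = 6mn-m+n$.

Consequences worth noting: the size parameter is a template size, not a
recursion depth (the published counts grow quadratically, which rules out
multi-generation self-similar recursion), and at size 1 all three
templates degenerate to benzene, so the three families coincide in a
single 132-atom graph — the package's tests confirm the three size-1
spectra are identical, which the published energetics table also shows.

**Geometry and merging.** Template vertices live on the honeycomb lattice
in integer half-unit coordinates, so vertex deduplication and the
induced-edge search are exact integer operations; no floating-point
coincidence detection is ever used.  Each template edge carries a
direction label $d \in \{0..5\}$ (its bearing quantized to 60° sectors —
ties cannot occur on the lattice), which selects the fusable rim bond
$F_d$ of the unit.  Unit centres sit at the template positions scaled by
$3\sqrt3$ bond lengths with the template frame rotated 30° relative to
the unit frame; with that choice the two atoms identified by a fusion
coincide geometrically, bonded atoms end up at distance $1$ (within
$10^{-9}$) and non-bonded atoms at distance $> 1.5$.

**Fusion orientation.** Each fusion could a priori identify the two rim
atom pairs in either order.  The two choices give isomorphic results for
a single fused pair (they differ by reflecting one unit), but around
closed rings of units the "swapped" convention produces a measurably
different (non-isomorphic) spectrum even though every count identity
still holds.  The package therefore pins the orientation geometrically —
the identification under which shared atoms coincide in the plane — and
treats that as part of the family definition.  `expandTemplate()` retains
the alternative as `swapIdentification = TRUE` for exactly this
diagnostic purpose.

`generateFractal()` refuses to return any graph whose atom count, bond
count or edge partition disagrees with the closed-form polynomials.

## 2. Modified reverse degrees and the index catalog

With maximum degree $\Delta(G)$ (always 3 here) and shift $k \ge 1$:

$$M_kRd(a) = \begin{cases}\Delta - d(a) + k, & k \le d(a)\\
 (\Delta - d(a) + k) \bmod \Delta, & k > d(a).\end{cases}$$

$\Delta$ is always taken from the input graph, never a global constant.
The mod branch can produce 0 (e.g. $d = 1, k = \Delta + 1$); because
harmonic-type contributions would then divide by zero and the source
material gives no convention, a zero reverse degree is an error rather
than a silent infinity.

Twelve symmetric edge functions make up the catalog (`indexNames()`).
One extraction ambiguity had to be resolved: the printed formula for the
geometric bi-Zagreb contribution is typeset without the radical, but only
$\sqrt{xy}/(x+y+xy)$ reproduces both the published polynomial
coefficients (e.g. $53.6823n^2 - 0.1059n$ for the zigzag family at
$k=1$) and all published entropy values for that index; the package uses
the radical form.

`indexValue()` computes any index on any graph, either by per-class
aggregation over the degree partition (exact, default) or bond-by-bond;
the two paths are cross-checked in the tests.
`indexValueClosedForm()` evaluates the published per-family polynomials
verbatim.  Comparing the two exposes a small set of typographical defects
in the published tables, catalogued by `closedFormErrata()` and excluded
from consistency checks:

* the armchair family's harmonic and hyper-Zagreb rows at $k=1$ are
  swapped;
* the armchair redefined-second-Zagreb $k=3$ linear coefficient lost a
  digit ($-65.55$ for $-655.5$);
* the $k=2$ geometric–arithmetic row is wrong for *all three* families
  (printed $\approx 1.7474\times$ the exact polynomial) — notably the
  published *entropy* tables for that same index and shift match the
  exact polynomial, which localizes the defect to the index tables.

## 3. Graph entropy, SIC and BIC

Each bond $ab$ receives probability $f(ab)/TI(G)$ and the entropy in bits
is computed through the simplified two-term form

$$I = \log_2 TI - \frac{1}{TI}\sum_{ab} f(ab)\log_2 f(ab),$$

aggregated over the three degree classes (counts × $f\log_2 f$), which is
both faster and free of per-edge rounding; the direct
$-\sum p\log_2 p$ path is retained and the two agree to $10^{-12}$ in the
tests.  Base-2 logarithms are used throughout, so entropies are in bits.

Jensen's inequality bounds the entropy by $\log_2|E|$ with equality
exactly when all contributions are equal (e.g. any single degree class);
this is asserted property-style.  The normalized measures are
$SIC = I/\log_2 TI$ and $BIC = I/\log_2|E|$.  Note that $SIC \le 1$ is
guaranteed only for indices whose contributions are $\ge 1$ (the
Zagreb-type indices, which are the ones used for the published complexity
comparisons); fractional-contribution indices (harmonic,
geometric–arithmetic, geometric bi-Zagreb) can push $TI$ below $|E|$ and
$SIC$ above 1.  A single-edge graph has entropy 0 and no defined BIC.

The entropy tables (`entropyTable()`) reproduce all 432 published cells
(three families × twelve indices × $k \in \{1,2,3\}$ × sizes 2–5,
rectangular with $m=n$) within $5\times10^{-5}$, i.e. to the printed four
decimals; the published finding that $k=2$ entropies exceed their $k=1$
and $k=3$ counterparts for the first Zagreb index is asserted on computed
values.

## 4. Spectral energetics

Eigenvalues come from a dense symmetric solver in double precision, after
a canonical coordinate-lexicographic atom ordering so spectra are
bit-reproducible across runs.  Frontier orbitals are selected *by rank*
(descending ranks $p/2$ and $p/2+1$), never by sign threshold — for large
fractals the gap closes and near-zero eigenvalues would make a sign test
fragile.  β is treated as a dimensionless unit.  The "per bond" columns
of the published energetics table are divisions by the *vertex* count
(verifiable from the printed numbers: $194.662/132 = 1.4747$); the
package names them per-atom quantities and implements the printed
arithmetic.

**Kekulé counts.** For these bipartite systems the Kekulé count is
$\sqrt{|\det A|}$ (the absolute constant term of the characteristic
polynomial), and $|\det A| = \det(B)^2$ for the biadjacency matrix $B$.
$\det B$ is computed by fraction-free (Bareiss) elimination, whose
intermediates are minors of $B$ and hence bounded by $3^{n/2}$ for these
degree-≤3 skeletons; carried in doubles this is exact up to about 132
atoms (bound $< 2^{53}$), with an explicit guard that refuses silently
inexact elimination.  The result is verified against $\det A$ computed
modulo two 25-bit primes, an independent congruence check of
$KC^2 = |\det A|$.  Beyond the exact range the package supplies
$\ln KC$ via LU log-determinant (relative error $\sim 10^{-12}$), which
is all the Herndon resonance energy $1.185\ln(KC)/p$ consumes; the exact
integer count is reported as `NA` there rather than as an approximation.
Whether $\sqrt{|\det A|}$ counts matchings correctly for arbitrary
coronoids with macrocyclic holes is not settled theory; the perfect-square
congruence check is the package's runtime diagnostic, and determinant
counts agree with brute-force perfect-matching enumeration on all
fixtures (benzene 2, naphthalene 3, anthracene 4, perylene, coronene 20).

## 5. Regression models

`fitLinear()` is ordinary least squares with $r^2$ the squared Pearson
correlation, $\mathrm{adj}\,r^2 = 1-(1-r^2)(n-1)/(n-2)$,
$SE = \sqrt{RSS/(n-2)}$ and $F = r^2(n-2)/(1-r^2)$.  The reference
dataset is the eleven structures of the published energetics table
(zigzag sizes 1–4, armchair 1–3, rectangular $m=n$ sizes 1–4 — the
rectangular sizes are interpreted with the $m=n$ convention the entropy
tables state).  Following the published models, the π-energy is regressed
on the raw $k=2$ first-Zagreb index while the other five properties use
that index's entropy.

Two reproduction details: the π-energy model is insensitive to whether
the printed or recomputed property values are used ($r^2 = 0.9999995$,
which the published table truncates to 0.999 — its own $F = 17582849$
implies exactly this $r^2$); the five per-atom/gap/diameter models match
the published statistics only when fitted on *unrounded recomputed*
property values (`mode = "computed"`), because the printed three-decimal
property values quantize too coarsely.  Predictions outside the fitted
descriptor range are flagged as extrapolations.

## 6. Problem sizes and runtime

Everything is desk scale.  The test suite generates all families up to
size 4 (up to 4704 atoms combinatorially), diagonalizes up to 900×900,
runs one exact 132-atom determinant, and completes in well under a
minute; the full energetics table for the eleven reference structures
(largest eigensolve 2424×2424) takes a few tens of seconds via the
`report` CLI subcommand.  The acceptance script runs in seconds.

## 7. Limitations

* Templates are fixed to the three families; arbitrary user templates
  would need their own direction-label validation.
* Hydrogens, bond orders, SMILES and 3D embedding are out of scope; the
  graphs are carbon σ-skeletons.
* Hückel here is the plain adjacency model — no heteroatom α/β
  corrections, no charged or radical systems (odd atom counts are handled
  but warned about).
* Exact Kekulé counts stop at the double-precision Bareiss bound
  (~132 atoms); larger systems get exact-enough logarithms, not integers.
* The entropy and index tables match published values at printed
  precision except for the documented errata, which are reported rather
  than reconciled.
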