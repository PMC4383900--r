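---
title: "Probabilistic knot typing and knotting fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic knot typing and knotting fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotscan)
```

## The model

Knot theory classifies *closed* curves; a protein backbone is open.
knotscan therefore treats the knot type of an open chain as a random
variable over closures: both termini are connected to two distinct
vertices of a truncated icosahedron placed on a large sphere enclosing
the chain, the two surface points joined by a great-circle arc on the
sphere. Because every added vertex lies on the sphere while the chain
is strictly inside, the closure arc itself can never pierce the chain;
only the two straight attachment segments can thread through the
structure, which is exactly the ambiguity the probabilistic view is
meant to quantify. The plurality knot type over `n_closures` draws is
the chain's dominant type, and the retained frequency map measures how
decided the call is.

Each closure is classified in three stages:

1. **KMT reduction.** For each triple of consecutive vertices, the
   middle one is removed when no other chain segment intersects the
   spanned triangle; passes iterate to a fixed point. The two segments
   adjacent to a triangle (sharing one corner) are not skipped but
   tested *away from the shared corner* (an in-plane wedge test): a
   strand hugging the triangle through its corner can obstruct the
   isotopy, and testing it costs only speed, never correctness.
   All boundary-degenerate contacts count as intersections
   (tolerance 1e-9, scale-relative), so a vertex is kept whenever
   removal could conceivably change topology. Exactly-collinear
   vertices (a point lying on the segment joining its neighbours) are
   dropped beforehand; the cleaned curve is pointwise identical.
2. **Projection.** Orthogonal projection along a seeded random
   direction. Directions are redrawn whenever the picture is not
   generic: an edge nearly parallel to the view axis, a crossing
   within 1e-9 of a vertex, a depth tie, two crossings nearly
   coincident on one segment, or overlapping collinear projections.
   Disjoint segments of one 3D line are *not* degenerate (they cannot
   cross) — this matters for chains with straight bridged runs.
3. **Invariants.** From the signed Gauss code the Wirtinger/Alexander
   matrix is assembled (one relation per crossing, one generator per
   arc); one row and column are deleted and the determinant is
   computed by fraction-free Bareiss elimination over Z[t] in 128-bit
   integer arithmetic, then normalized to the minimal-degree
   representative with value +1 at t = 1. This removes the usual
   ±t^k ambiguity, so the evaluations |Δ(−1)| and |Δ(−2)| are
   well-defined integers. The pair separates every knot in the
   built-in table — single evaluations would not (5₁ and 4₁ share
   |Δ(−1)| = 5; 5₂ and 7₁ share 7).

Chirality cannot be seen by the Alexander polynomial; where a label is
chiral-capable, the HOMFLY polynomial of the reduced diagram is
computed by skein recursion (convention `v⁻¹P(L₊) − vP(L₋) = zP(L₀)`,
unknot = 1) and compared against the stored reference curve of that
knot and its mirror. The package's `+` form of a chiral knot is the
variant whose reference diagram has positive writhe (for the
alternating table knots the reduced-diagram writhe sign is a reliable
handedness proxy). Diagrams above 16 crossings are not pushed through
the exponential skein recursion; the label then stays
`undetermined`, mirroring the practice of computing HOMFLY only for
selected subchains.

## The knot table and its provenance

`knot_signature_table()` is not a table of magic numbers: every entry
is regenerated from a constructive reference curve at first use. The
2-bridge knots (all knots through 7 crossings and most 8-crossing
ones) are built as 4-plats from the positive continued fraction of
their Schubert fraction p/q, which yields an independent arithmetic
cross-check — the knot determinant |Δ(−1)| must equal the continuant
p — exercised in the test suite. The remaining entries (8₅, 8₁₆, 8₁₇,
8₁₈, 8₁₉) are braid trace closures. Four 8-crossing knots (8₁₀, 8₁₅,
8₂₀, 8₂₁) are deliberately absent: their Alexander polynomials are
products of smaller knots' polynomials (e.g. Δ(8₂₀) = Δ(3₁)²), so
their signature cannot be told apart from a connected sum, and the
package prefers reporting `unknown` over mis-assigning composites.
For the same reason any unmatched signature — including genuine
composite chains — maps to `unknown` rather than to the nearest
table entry.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_closures` | 200 | random closures per (sub)chain; a few hundred matches the method's accepted practice. The plurality call stabilizes long before the frequency's second digit. |
| `inflation` | 10 | enclosing-sphere radius as a multiple of the chain's maximal centroid distance ("large" is the only requirement; 10x makes attachment segments nearly radial). |
| `arc_step_deg` | 10 | maximal angle between consecutive arc points; the arc stays on the sphere, so the step only controls polygon size. |
| `cutoff` | 4.5 Å | distance-gap threshold: about 1.15x the canonical 3.8 Å CA–CA virtual bond, so normal geometry is never flagged. |
| `stride` | 1 | fingerprint grid stride. Full O(N²) scans are exact; for long chains a coarse scan plus `refine_core_span()` recovers stride-1 core boundaries. |
| depth threshold | 10 | tails shorter than 10 residues are shallow, 10 or longer deep (the boundary case is assigned to "deep"). |
| `min_cells` | 3 | same-label regions smaller than this many cells are treated as closure noise, not territories. |

All stochastic draws — the icosahedron orientation, closure pairs,
projection directions — flow from one explicit master seed. Fingerprint
cells use seeds derived deterministically from (master, k, l, N) such
that cell (1, N) reproduces a standalone `dominant_knot()` call at the
master seed; one enclosing sphere and one rotated closure point set,
both built from the full chain, are shared by all cells. Identical
seed and parameters give bit-identical matrices.

## Fingerprint semantics

A chain is *knotted* when cell (1, N) is nontrivial and *slipknotted*
when (1, N) is trivial but some cell is not. Territories are
4-connected components of same-label cells in the (k, l) grid —
diagonal-only contact separates territories, a convention this package
fixes since no operational definition is standard. The knot core is
the region's shortest subchain (ties toward the N terminus). On a
knotted side the rest of the chain is a knot tail; on a slipknotted
side the longest terminal segment whose trimming leaves the
full-chain topology unchanged is the slipknot tail, and what remains
up to the core is the slipknot loop. When trimming from one side never
changes the topology before reaching the core (possible for two-sided
slipknots), the whole side is assigned to the tail and the loop is
empty on that side — the definitional edge cases are genuinely open
and this is the package's resolution. Notation strings list the
territories by decreasing subchain size (`K4_1_3_1`, `S3_1`, `U`);
chirality signs appear in element displays but not in notation tokens.

Because core boundaries are plurality calls on subchains whose closure
spectrum crosses 1/2 near the boundary, a core is minimal *relative to
the seeded sampling*: re-testing a boundary subchain with an unrelated
seed can flip a near-tie. The shrink-and-retest verification therefore
uses the same per-cell seed discipline as the scan.

Chains with missing structure (residue-numbering gaps, or adjacent
vertices much farther apart than the virtual bond) are bridged by
straight segments; every cell whose subchain spans a bridged segment
is listed in `masked_cells` and the whole result carries a `putative`
flag, since a reconstructed segment can pierce the real chain and
fabricate or destroy entanglement.

## The fixture generator

Parametric torus knots `(2,3)`, `(2,5)`, `(2,7)` and the figure-eight
curve provide knots of known type; `open_gap` removes a parameter-
space fraction to produce open chains. The slipknot fixture appends to
an open trefoil a terminal segment retraced back through the knotted
loop along a small lateral offset and led away radially: the full
chain closes to the unknot while the forward subchain is a trefoil,
giving notation `S3_1`. Its construction parameters (35% retraction,
0.35 offset) were chosen once for this geometry and frozen. The
6-stick minimal trefoil used by the reduction tests was located once
by seeded random search over hexagons, verified across 25 projections,
and frozen as coordinates.

What these fixtures emulate is topology, not protein realism: they
have no sequence, no excluded volume and no realistic bond geometry,
and their termini — unlike those of most real knotted proteins — lie
close to the tangle. Passing tests on them demonstrates the topological
machinery (closure, reduction, invariants, element extraction), not
performance on experimental structures; in particular, tightly wound
parametric curves with nearly coincident termini have intrinsically
lower dominant-knot frequencies (0.73–0.88 measured over 2000
closures) than a well-exposed chain, for which the dominant fraction
is 1.0 (the radial-termini test enumerates all closure pairs).

## Numerical choices and limitations

- Intersection tests are conservative: within tolerance of any
  boundary case they report "intersects", so KMT can only be slower,
  never wrong. Degenerate (zero-area) triangles are never removed.
- The Alexander determinant uses exact 128-bit integer polynomial
  arithmetic; coefficients of minors are bounded by 4^k for k
  crossings, safe beyond 60 crossings — far above anything a
  KMT-reduced diagram produces. Overflow aborts loudly rather than
  truncating.
- Problem sizes in the shipped tests (fixtures of 90–160 vertices,
  20–200 closures per call, stride 2–4 fingerprints, a 100-polygon
  noise sweep) were chosen as the smallest sizes at which every
  property is exercised away from its degenerate limit.
- Trajectory analysis reports per-frame dominant labels and a greedy
  core estimate; it does not attempt frame-to-frame correspondence of
  territories.
- Multi-chain entanglement (links), knotoids and virtual knots are out
  of scope; composite knots are reported `unknown` by design.
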