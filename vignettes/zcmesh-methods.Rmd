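---
title: "Methods: exact mesh moments, descriptors and the retrieval pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact mesh moments, descriptors and the retrieval pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zcmesh)
```

## The model

A closed triangular mesh with counter-clockwise facets determines a solid:
its indicator function $f$. The geometric moments of the solid are the
monomial volume integrals

$$ M_{ijk} = \int f(x)\, x^i y^j z^k \, dV, \qquad i + j + k \le N, $$

and the Zernike–Canterakis (ZC) moments are linear combinations of them:
the projections of $f$ onto the orthogonal basis
$Z_{nlm} = R_{nl}(r) Y_{lm}(\theta, \varphi)$ inside the unit ball. The
rotation-invariant descriptors are the per-$(n, l)$ norms over $m$. Two
shapes are compared through the Manhattan distance of their unit-sum
normalized descriptor vectors, optionally combined with three geometric
features (a residue-distance histogram, per-axis sizes, mesh volume) into
the penalised distance family ending at $\Delta_{zdsv}$, clipped at 2.

### Exact volume-like moments of a mesh

Each facet $(v_1, v_2, v_3)$ contributes the integral over the oriented
tetrahedron it spans with the origin. Mapping the unit simplex onto that
tetrahedron and expanding the monomials multinomially gives the closed
form per facet

$$ \det[v_1 v_2 v_3] \; S_{ijk} \; \frac{i!\,j!\,k!}{(i+j+k+3)!}, $$

where $S_{ijk}$ collects the multinomial vertex products with the simplex
integral weights. The package evaluates $S$ with three chained arrays
sharing one recurrence pattern: the first array is the trinomial-weighted
monomial expansion of one vertex, and each subsequent array descends along
the next vertex's coordinates while folding in the previous array — a
weighted Pascal-pyramid convolution. Only indices with $i+j+k \le N$ are
visited, so one facet costs $O(N^3)$ and the whole mesh $O(fN^3)$; the
factorial prefactor is evaluated once per index from the cached trinomial
table as $[(i|j|k)(n+1)(n+2)(n+3)]^{-1}$. The (0,0,0) entry is the signed
mesh volume, which makes a cheap internal consistency check.

The same integrals are also implemented by direct multinomial expansion
($O(fN^6)$, `geometric_moments_naive`). The two routes share no code
beyond the mesh container; their agreement on random closed meshes (max
absolute difference below 1e-10 at $N \le 8$, observed ~1e-17) is the
primary correctness anchor of the optimized kernel.

### From geometric to ZC moments

The basis functions are expanded into monomials once per order: solid
harmonics $r^l Y_{lm}$ from the Rodrigues form of the associated Legendre
polynomials, radial polynomials $R_{nl}$ from the standard hypergeometric
coefficient formula, normalised so $\int_0^1 R_{nl}^2 r^2\,dr = 1/3$ with
orthonormal $Y_{lm}$, i.e. $3\int_B Z\bar Z\,dV = 1$. The conversion is a
sparse complex dot product per $(n, l, m)$. Two properties pin the tables
down in tests without reference data: exact orthonormality of the basis
under closed-form ball monomial integration, and exact orthonormality of
the radial family under polynomial integration. Only $m \ge 0$ moments are
stored; $m < 0$ follows from the conjugation symmetry
$\Omega_{nl,-m} = (-1)^m \overline{\Omega_{nlm}}$, which is itself tested
against an independent projection onto the $m < 0$ polynomials.

### Numerical behaviour

The geometric-to-ZC conversion cancels heavily as the order grows; with
double precision the results degrade above order 35, so orders beyond 35
are rejected everywhere rather than silently computed. At $N = 20$ the
conversion amplifies moment-level perturbations by roughly $10^7$, which
is why facet accumulation uses compensated (Kahan) summation in extended
precision: the descriptor-level drift between different facet orderings is
then ~1e-14 (Manhattan), far inside the 1e-10 contract that parallel or
permuted accumulation must meet. Rotation invariance of the descriptors
holds to ~1e-12 on exact-moment fixtures. Icosphere fixtures retain
icosahedrally symmetric $l = 6, 10, \dots$ residuals of order
$\mathrm{edge}^2/8$ (the flat-facet sagitta), so the "sphere degeneracy"
of $l > 0$ descriptors is asserted at 1e-3 of the $(0,0)$ descriptor at
subdivision 4, decreasing with subdivision — not at machine precision,
which no practical triangulation reaches.

## The pipeline and its parameters

| parameter | default | meaning |
|---|---|---|
| `moment_order` | 20 | ZC truncation; the field's standard compromise between detail and stability (hard cap 35) |
| `outlier_p` | 0.9 | confidence level of the ellipsoid; radii are $s\sigma_d$ with $s = \sqrt{\chi^2_{3}(p)}$ (2.5003 at 0.9) |
| `outlier_rounds` | 3 | maximum align/trim iterations; 0 disables elimination |
| `surface_mode` | backbone | per-chain N/CA/C/O surfaces (merged by concatenation) capture chain conformation, not just the envelope |
| `decimation_factor` | 0.5 | facet reduction requested from the external decimation backend |
| `scale_method` | rpca | unit-ball divisor; `rpca` $= s(p{=}0.95)\,\sigma_x \approx 2.795483\,\sigma_x$, floored at the mesh rmax |
| `gamma_s`, `gamma_v` | −0.05, −0.1 | offsets of the size and volume penalty ratios; negative values reward matched geometry |
| histogram bins | 2 Å over 0–1000 Å | effective-atom distance distribution; the upper limit is configurable upward |

Distances are interpreted on a six-tier scale (0.2-wide tiers up to 1,
then a single "no similarity" tier up to the clip at 2); tier boundaries
double as the ROC operating points reported by the benchmark.

### Outlier elimination

Each round aligns the current guides (population covariance, SVD, proper
rotation), tests them against the closed confidence ellipsoid, and
permanently discards the strict exterior. The boundary counts as inside
because the rule targets points *outside* the ellipsoid. Population
(denominator $n$) standard deviations match the variance-maximisation
framing of the alignment; outliers are never re-admitted. After the loop
the final guide set is realigned once more, so the returned transform
exactly centers and diagonalises the guides that the histogram and size
features use. Iterated trimming is deliberately more aggressive than its
single-round χ² coverage: on a pure Gaussian cloud one round keeps ~90%
of the points at $p = 0.9$, but re-estimating σ on the trimmed sample
shrinks the ellipsoid, and three rounds keep roughly 78–80%. That is the
intended behaviour — the procedure trades a thin shell of boundary
residues for robustness to genuinely protruding fragments — and the tests
assert the single-round coverage and the iterated behaviour separately.
A geometric limit worth knowing: a collinear outlier cluster comprising a
fraction $f$ of the points saturates at Mahalanobis distance
$\sqrt{(1-f)/f}$ however far it sits, so at $p = 0.9$ ($s = 2.5$) clusters
with $f \gtrsim 0.14$ in a single direction cannot be fully eliminated.
The synthetic mini-protein generator therefore spreads its planted tail
across directions, mimicking a disordered terminus rather than a rigid
rod.

### Histogram smoothing

The raw 2 Å histogram of guide-atom distances is smoothed with the
Savitzky–Golay window-5, order-3 kernel $(-3, 12, 17, 12, -3)/35$ applied
over a mirrored (whole-sample reflective) boundary extension, then
negative values are clipped to zero and the vector is normalised to unit
sum — in that order. The mirror extension was chosen over the
terminal-window polynomial fit because it reproduces constant histograms
exactly *and* has zero response outside an interior impulse (the
polynomial-fit transient leaks ±1/70-scale values into the edge bins),
while still keeping the mass near bin 0 — where real proteins have
residues — inside the range. The two behaviours are regression-tested
(an interior unit count smooths to 12/41, 17/41, 12/41 after clipping and
renormalisation; a constant histogram is reproduced up to normalisation).

### Unit-ball scale factors

`rmax` (mesh vertices) always contains the mesh. The atom-based factors —
`rmax_over_0.7`, `two_rg`, `rpca` — are mesh-invariant but may fall short
of the mesh extent, so all of them are floored at the mesh rmax: the
volume-like integrals require the closed surface to sit inside the unit
ball. `1.8rg` is recognised and rejected with an explanation, because for
effective atoms it is always below that floor and silently degenerates to
`rmax`. The mesh is centered on the guide effective-atom centroid (not its
own vertex mean) so the mesh, the histogram and the size features share
one frame; the centering origin is exposed as a parameter of
`center_and_scale` for callers who prefer the vertex mean.

## What the synthetic data does and does not show

The fixture generators produce closed meshes with analytic volumes
(spheres, boxes, ellipsoids, two-lobe shapes), ideal-helix mini-proteins
with controllable decorations (waters, altlocs, MODRES selenomethionine,
REMARK 350 copies, planted distal tails), and Gaussian clouds with planted
outliers. These exercise every parsing, cleaning, selection, alignment and
moment path deterministically, and make the toy retrieval benchmark
(three jittered shape classes) separable by construction — its AUROC of
1.0 validates the plumbing from files to ROC, not retrieval power on real
proteins. Real molecular surfaces are rugged, multi-component and far from
any analytic solid; performance on them depends on the external surface
generator and the published validation archives, which are outside the
automated suite. Mesh decimation backends are likewise external: the
adapter enforces the contract (facet reduction, `tri_mesh` output,
identity at factor 0) against a mock backend only.

## Problem sizes in the automated suite

The tests run the optimized-vs-naive oracle on 4-facet tetrahedra and a
320-facet sphere at $N \le 8$, invariance and drift checks on 1280-facet
meshes at $N = 20$, and the degeneracy scan up to 20480 facets; the full
suite completes in well under a minute on one core. The kernel itself
processes ~80,000 facets at $N = 20$ in about a second, so database-scale
runs are surface-generation bound, not moment bound.

## Known limitations

* Orders above 35 are rejected; stable high-order moments need a
  different algorithm (direct facet quadrature), out of scope here.
* The mesh is trusted to be closed and consistently oriented; a broken
  mesh does not break the algorithm (signed contributions still sum) but
  its "volume" moments lose their meaning.
* PDB fixed-column input only; mmCIF is not parsed.
* Protein entities only: nucleic acids, ligands and ions are removed at
  the cleaning stage, and protein–non-protein interfaces are not modelled.
* Element-fallback van der Waals radii (for atoms missing from the
  NACCESS-style residue library) are conventional values, configurable
  via a replacement table.
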