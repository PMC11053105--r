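---
title: "Correlation networks of cephalometric measurements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation networks of cephalometric measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephnet)
```

## The model

A cephalometric measurement set is a subjects × variables numeric table
$X$ (here 65 variables drawn from nine classical analyses). The object of
study is its correlation structure:

- **Nodes** are variables; the **edge weight** between variables $i$ and
  $j$ is $|r_{ij}|$, the absolute Pearson correlation. Absolute values are
  used because each classical analysis fixes its own sign conventions
  (e.g. an anteroposterior discrepancy can be coded positive in one
  analysis and negative in another), so the sign of $r$ is not comparable
  across pairs; the signed matrix is retained for reporting.
- **Thresholded networks**: an edge is kept iff $|r_{ij}| \ge c$. The
  comparison is *inclusive*; the package applies the same rule at every
  cutoff. Cutoffs are chosen from the empirical weight distribution
  (histogram and cumulative probability distribution function over the
  $V(V-1)/2$ pairs), with 0.4 / 0.6 / 0.8 as the conventional nested
  triple: below 0.4 the bulk of pairs is noise-like, 0.8 isolates the
  tightly-bound groups, and 0.6 balances the two.
- **Clusters** are connected components of the thresholded network
  (size ≥ 2; singletons are "unclustered"). No community-detection
  algorithm is used — components and explicit clique checks only, because
  the scientific claim being examined is exactly "these variables are all
  pairwise strongly correlated" (a clique), not a modularity statement.
- **MST**: distances are $d_{ij} = 1 - |r_{ij}|$ and the minimum spanning
  tree is extracted with Kruskal's algorithm. The MST needs no cutoff at
  all, which is its point: it is the extreme summary at the other end of
  the information/legibility trade-off from the full weighted network.

Statistical significance never filters edges: at survey scale
(n ≈ 735) every $|r| \ge 0.4$ is overwhelmingly significant, so a p-value
filter would be vacuous; p-values are computed (t reference) for
reporting only.

## The measurement engine

Each variable is a *recipe* — data, not code — over four geometric
primitives on named 2D landmarks (coordinates in mm; x anterior-positive,
y superior-positive, origin at sella in the default template):
three-point interior angle, line–line angle (unsigned in [0°, 90°] or
signed in (−90°, 90°]), signed point-to-line distance, and scalar
projection along a line. Three deliberate choices:

- **Composite indices are linear combinations.** ODI = (A–B to
  mandibular plane) + (palatal plane angle); APDI = facial angle + A–B
  plane angle + palatal plane angle; the Björk Sum = saddle + articular +
  gonial angles; combination factor = ODI + APDI; the Holdaway difference
  = (L1 to NB) − (Pog to NB). Registering them this way makes the
  decomposition arguments about these indices *identities* that the test
  suite verifies to 1e−9°, rather than empirical regularities.
- **The Tweed triangle is a triangle.** FMA, IMPA and FMIA are the
  interior angles of the triangle formed by the Frankfort horizontal, the
  mandibular plane and the lower-incisor axis, so
  FMA + IMPA + FMIA = 180° holds exactly for every non-degenerate
  configuration — matching the clinical convention (IMPA ≈ 90°).
- **Sign conventions are anchored to the radiograph frame.** "Anterior
  positive" for point-to-line distances, "anterior end tilted up =
  positive" for signed line angles, and ANB as the signed angle at nasion
  from the N→B ray to the N→A ray (so ANB = SNA − SNB exactly).
  Consequently angles and signed quantities are invariant under
  translation and under rotations that keep the anterior direction
  anterior (the tested range is ±40°); a convention anchored to world
  axes cannot be invariant under arbitrary 180° flips, and is not meant
  to be.

One variable deserves a caveat: the classical *extraction index* mixes
several anatomical characteristics and its exact weighting is not
uniquely documented across sources. It is registered as a clearly-labelled
synthetic stand-in (combination factor + 0.2·interincisal angle + lower
lip to E-plane − 26) and excluded from the identity suite; users with the
authoritative definition can supply a custom registry
(`read_registry()` on a JSON file — the shipped registry is
`inst/extdata/registry.json`, version 1.0). Three mm-valued variables
whose classical names are ambiguous without their source tables (facial
depth, facial length on Y-axis, lower facial height as an angle) use
documented implementation choices (N–Go, S–Gn, palatal-to-mandibular
plane angle respectively); none of them participates in any identity.

Dependency order between recipes is topological, not numeric: ODI
(variable 60) legitimately references variable 61. `compute_table()`
validates acyclicity and evaluates in dependency order; any per-subject
geometric failure rejects that subject's whole row (complete-case
policy) and logs the reason.

## The synthetic world

The generator exists because the reference dataset this analysis pattern
targets (a 735-subject normal-occlusion survey) is access-restricted. It
samples from a multivariate normal — sufficient because Pearson
correlations fully parameterize a Gaussian, and correlations are all the
downstream stages consume — with a block-structured target:

- 10 blocks mirroring the recovered anatomical groups (the big
  incisor-position group split into its two subgroups), covering 52 of
  the 65 variables; 13 variables carry only background correlation.
- Within-block targets fixed per block in [0.86, 0.94]; between-block
  0.2; background 0.1. These are the *stated world*: chosen once from the
  qualitative group structure (tight clusters that separate cleanly at a
  0.8 cutoff, weak inter-group links), not tuned to any test outcome.
- n = 735 by default, matching the survey scale.
- Per-variable means come from evaluating the registry on the unperturbed
  landmark template (guaranteeing clinical plausibility and internal
  consistency); SDs are unit-typical (5° / 2.5 mm / 0.05 / 6). Both are
  cosmetic: every acceptance-relevant statistic is affine-invariant.

The target matrix is checked for positive semi-definiteness and, if
needed, repaired by eigenvalue clipping at 0 followed by diagonal
re-normalization (tolerance 1e−10); a spec whose repair moves any entry
by more than 0.05 is rejected as infeasible, naming the offending blocks.
Sampling uses the symmetric eigen square root (not Cholesky) so that
degenerate PSD targets — e.g. a perfectly correlated block — remain
sampleable, and is bit-reproducible under a fixed seed.

**What a green test does and does not establish.** The synthetic world
reproduces: the block/background correlation geometry, the 10-cluster
recovery at the 0.8 cutoff, nesting across cutoffs, and the MST
contraction structure. It does *not* reproduce real marginal
distributions, sex stratification, measurement error correlations between
geometrically adjacent variables, or the real data's mid-range
correlation mass — synthetic weight distributions have a gap between the
background (≈0.2) and the blocks (≈0.9), so the empirical fractions at
0.4/0.6/0.8 nearly coincide, unlike the graded 21–9–3% pattern real
craniofacial data shows. Headline empirical fractions are therefore
never acceptance surfaces; only combinatorial counts, structure
recovery, and oracle equivalences are.

## Numerical choices

- Angles via `atan2(|cross|, dot)` (stable near 0° and 180°); points
  closer than 1e−9 mm are coincident and raise a named error, as do
  degenerate lines and near-parallel line intersections.
- Kruskal ties broken by ascending lexicographic variable-name pair; with
  distinct weights the edge set equals Prim's (tested), with ties the
  output is still deterministic.
- Histogram bins: 20 on [0, 1] for |r| (40 on [−1, 1] signed),
  right-open except the last bin, so |r| = 1 lands in the top bin.
- Outlier handling in the pipeline: cells with |z| > 4 are counted and
  reported; removal happens only with an explicit flag, since no
  principled removal rule is part of the model.
- JSON serialization uses 17 significant digits so configs and landmark
  files round-trip bit-exactly.

## Known limitations

- 2D only; no image processing or automatic landmark detection.
- The landmark template is an idealized adult tracing; identities are
  asserted for arbitrary non-degenerate configurations, but template-
  specific values (e.g. a slightly proclined upper incisor) are only
  plausible, not normative.
- The MST layout in figures is force-directed and purely presentational.
- `is_clique` checks a given node set; maximal-clique enumeration is out
  of scope.
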