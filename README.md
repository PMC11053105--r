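# cephnet

Correlation-network analysis of cephalometric measurement sets.

## The problem

Orthodontic diagnosis rests on lateral-cephalometric measurements — angles,
distances and ratios between standardized anatomical landmarks (sella,
nasion, the A and B points, pogonion, gonion, ...). Dozens of classical
analyses (Downs, Tweed, Steiner, Coben, Jarabak, the Wits appraisal,
Ricketts, McNamara, Kim) each define their own 10–20 variables, and the
variables overlap heavily: SNA, SNB and ANB all describe anteroposterior
jaw position; ODI and APDI are literally linear combinations of other
variables. Choosing a measurement set without understanding this
correlation structure biases any downstream analysis, including
machine-learning models of malocclusion.

`cephnet` makes the structure explicit. For a subjects × variables
measurement table it:

1. computes the Pearson correlation matrix `R` and uses `|r_ij|` as the
   weight of the edge between variables *i* and *j* (absolute values,
   because sign conventions differ between analyses);
2. characterizes the edge-weight distribution (histogram, empirical CPDF,
   and the fraction of the `V(V−1)/2` pairs at or above each candidate
   cutoff) so that thresholds are data-driven rather than rule-of-thumb;
3. thresholds the network at nested cutoffs (default 0.4 / 0.6 / 0.8,
   inclusive), finds connected components and checks clusters for clique
   structure, and overlays the tight clusters found at the high cutoff on
   the looser network;
4. extracts the minimum spanning tree of the distance matrix
   `d_ij = 1 − |r_ij|` with Kruskal's algorithm (union–find, deterministic
   lexicographic tie-break) — a cutoff-free skeleton whose inter-cluster
   edges are the key links between variable groups.

Because the large normal-occlusion survey datasets this kind of analysis
is run on are access-restricted, the package also provides:

- a **measurement engine**: a declarative registry of 65 classical
  variables, each a small recipe over four geometric primitives
  (three-point angle, line–line angle, signed point-to-line distance,
  projection length) evaluated on named 2D landmarks, with composite
  indices (Sum, ODI, APDI, combination factor) registered as exact linear
  combinations so identities like `ANB = SNA − SNB`,
  `FMA + IMPA + FMIA = 180°` and
  `APDI = facial angle + A–B plane angle + palatal plane angle`
  are mechanically checkable;
- a **synthetic generator**: multivariate Gaussian tables with a
  prescribed block-correlation structure (10 anatomical variable groups by
  default), PSD-repaired by eigenvalue clipping, plus perturbed landmark
  sets from a template — so the whole pipeline is testable end to end.

## Worked example

```r
library(cephnet)
report <- run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
writeLines(readLines(file.path("demo_run", "report.txt")))
```

which prints (abridged):

```
cephnet 0.1.0 run report (seed 1, config 61ad7fe1e87ac0177c5f4b352e154bf7)
subjects: 735  variables: 65  pairs: 2080  (rejected rows: 0)
fraction of pairs at or above cutoff:
  >= 0.4 : 0.0683
  >= 0.6 : 0.0683
  >= 0.8 : 0.0683
clusters at the fine cutoff (size >= 2): 10
  C1 (10 members, clique): Incisor overjet, L1 to A-Pog, U1 to A-Pog, ...
  C5 (4 members, clique): Convexity of point A, Facial convexity, A-B plane angle, ANB
  ...
MST: 64 edges, total distance 21.8707, inter-cluster edges 22
```

Reading this: the default synthetic world has 735 subjects and 65
variables, hence 65·64/2 = 2,080 variable pairs. Thresholding |r| at 0.8
recovers exactly the 10 planted variable groups as connected components
(each one a clique), and the MST's 22 inter-cluster edges equal
(10 clusters + 13 unclustered variables) − 1 — the tree-contraction
identity for clusters that span connected subtrees. The three cutoff
fractions coincide here because the generator puts between-group
correlations near 0.2: synthetic data has no pairs in the 0.4–0.8 band,
one of the documented ways it is simpler than real craniofacial data.

Every artifact has a machine-readable twin: `corr.csv`, `weights.csv`,
`fraction_at_or_above.json`, `network_<cutoff>.graphml`/`.tsv`,
`clusters.json`, `mst.graphml`/`mst.tsv`/`mst.newick`, `report.json`.

The same stages are scriptable:

```sh
inst/cli/cephnet generate --out table.csv --seed 5 --n 735
inst/cli/cephnet corr     --in table.csv --out corr.csv
inst/cli/cephnet network  --corr corr.csv --cutoff 0.6 --overlay-cutoff 0.8 --graphml net.graphml
inst/cli/cephnet mst      --corr corr.csv --out tree.graphml
```

## Layout

- `R/geometry.R` — 2D primitives (x anterior+, y superior+, mm)
- `R/landmarks.R` — landmark sets, template, perturbation generator, I/O
- `R/registry.R` — the 65-variable declarative registry and evaluator
- `R/synthetic.R` — block-correlation Gaussian generator
- `R/corrnet.R` — correlation matrix, weight distribution, thresholding,
  components, cliques, overlays, comparisons, exports
- `R/mst.R` — 1 − |r| distances, Kruskal MST, cluster annotation
- `R/pipeline.R`, `R/cli.R` — end-to-end runs and the CLI
- `vignettes/correlation-networks.Rmd` — methods and design notes
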