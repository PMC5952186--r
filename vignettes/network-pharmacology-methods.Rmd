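---
title: "Methods: module enrichment and shortest-path target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module enrichment and shortest-path target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-herb prescriptions act through many ingredients on many protein
targets at once, so single-target pharmacology is a poor fit. netpharm
implements the standard network-pharmacology alternative: place everything
on a protein–protein interaction (PPI) network, find the densely
interconnected *topological modules* that carry disease mechanisms, ask
which modules are statistically enriched for the gene sets of interest
(herb targets, co-morbid diseases, co-morbid symptoms), and then ask which
individual drug targets sit *topologically close* to those modules and to
the aggregate phenotype gene groups. A protein that is simultaneously
proximal to a key disease module, to the pooled disease genes, and to the
pooled symptom genes is a candidate key target of the prescription.

## The procedure, stage by stage

### 1. Inputs

`read_network()` loads an undirected, unweighted PPI edge list (two-column
TSV or SIF). Gene symbols are normalized (trimmed, upper-cased — no alias
mapping, since curated symbol lists are assumed); self-loops and duplicate
edges are dropped and counted in a load report, and the load report
conserves line counts, so nothing is silently lost. Malformed lines are
fatal by default (`skip_bad_lines = FALSE`): for curated inputs, silent
data loss is worse than failure. The network is used as given; we do not
extract the largest connected component, because disconnection is handled
explicitly downstream through reachability accounting.

`read_seed_sets()` loads phenotype–gene associations (one gene per row,
categories `disease`/`symptom`/`herb`), drops genes absent from the
network (logged per set), excludes sets that become empty — curated
phenotypes with zero network genes simply cannot be tested — and appends
the three aggregate unions `Diseases`, `Symptoms`, `Herbs`.
`read_herb_table()` loads herb–ingredient–target records, collapsing rows
that duplicate the same (herb, ingredient, target) triple into one record;
`herb_seed_sets()` turns these into per-herb gene sets.

### 2. Topological modules

`detect_modules()` partitions the network by modularity-based community
detection. The default is greedy modularity maximization
(Clauset–Newman–Moore agglomeration), cut at the modularity maximum of the
merge path; asynchronous label propagation is available as a faster,
stochastic alternative. Both are delegated to igraph and made reproducible
by seeding; the quality score

$$Q = \sum_c \left(\frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2\right)$$

(intra-community edge fraction minus its degree-preserving expectation) is
implemented directly in the package and cross-checked against igraph in
the tests. Modules are labeled `M1..Mk` by decreasing size, ties broken by
the lexicographically smallest member gene, so labels are deterministic.
Communities below `min_size` (default 3) are pooled under the reserved
label `M0` and skipped by enrichment: a one- or two-gene module cannot
yield a meaningful overlap test. Module labels are a property of one run;
no attempt is made to reproduce any particular published numbering, which
depends on the interactome version.

### 3. Module enrichment

`fisher_enrichment()` scores a (module, seed group) pair with the
one-sided Fisher exact test on the 2×2 table
$[[k, g-k], [m-k, N-m-g+k]]$, i.e. the hypergeometric upper tail
$P(X \ge k)$. One-sided is deliberate: the question is enrichment; a
two-sided test would also flag depletion. The fold enrichment
("proportion") is

$$\mathrm{prop} = \frac{k/m}{g/N},$$

reported as 0 when $k = 0$ so the output table stays total. The background
universe defaults to all genes of the loaded network — both the modules
and the distance analysis live on the network, so that is the population
actually sampled. Positivity is the strict raw-p rule $p < \alpha$
(default 0.05) with no multiple-testing correction by default, matching
common practice in module enrichment screens; Benjamini–Hochberg is
available via `correction = "bh"`. `ora()` applies the same machinery to
GMT annotation collections as a platform-neutral over-representation
analysis; it uses the plain Fisher tail, not the EASE-style $k-1$
deflation some platforms apply.

### 4. Shortest-path proximity

`single_source_distances()` computes exact unweighted shortest paths
(Dijkstra with unit weights; verified equivalent to breadth-first search
and Floyd–Warshall in the tests). `summarize_to_group()` reduces a source
protein's profile against a gene group to min/max/average distance.
Conventions, each forced by how finite published summaries must have been
computed:

* unreachable group members are *excluded* from min/max/avg and surfaced
  through `n_reachable`/`n_total`, rather than entering as infinite
  penalties;
* if the source belongs to the group its self-distance 0 is included
  (hence `min_sp = 0` for in-group sources);
* a group with no reachable member yields `NA` statistics and can never be
  key.

`call_key_targets()` flags a (target, group) pair as key when
`avg_sp < threshold`, strictly, with threshold default 3 ("strongly
connecting"). Strictness matters: an average of 2.998833 is key, an
average of exactly 3.0 is not.

### 5. Prioritization

`select_key_modules()` ranks modules by positivity count (how many seed
groups are significantly enriched in them) and selects either the top-n
(default n = 2) or all modules above a minimum count. Top-by-positivity is
the package's reconstruction of "the modules with the clearly strongest
enrichment pattern"; it is configurable because no universal cutoff
exists. `intersect_key_targets()` applies the candidate conjunction: key
for **at least one** selected module AND for the aggregate-diseases group
AND for the aggregate-symptoms group. "At least one" rather than "all"
selected modules is intentional — distinct disease modules need not share
a drug target, and requiring all would usually empty the candidate list.
Candidates are ranked by mean supporting `avg_sp`, ascending: closer is
stronger. `pathway_key_overlap()` reports, per annotation set, the module
genes it contains and how many of those are key targets.

`run_pipeline()` chains all stages from a YAML/list configuration and
writes TSV reports plus a YAML manifest (inputs, parameters, seed, drop
logs, versions). All report numbers are written with fixed formats
(`avg_sp` to 6 decimal places, p-values to 6 significant digits), so a
re-run with the same configuration and seed is byte-identical — the
determinism contract is tested on checksums.

## The synthetic-data generator

Real curated inputs (interactome snapshots, OMIM/HPO-style phenotype
tables, herb databases) are not redistributable and not reproducible at
desk scale, so the package ships a generator that produces inputs with the
statistical structure the analysis assumes:

* `generate_network()` — a planted-partition (stochastic block model)
  graph. Defaults: 120 nodes, 4 equal communities, within-community edge
  probability $p_{in} = 0.3$, between $p_{out} = 0.01$. This contrast is
  strong enough that modularity detection should recover the planted
  labels essentially always, which is the point: the benchmark isolates
  the pipeline's behavior from detection ambiguity.
* `generate_seed_group()` — a seed set whose expected overlap with the
  planted module is $\mathrm{fold} \times (m/N) \times g$ (in-module count
  binomial with success probability $\mathrm{fold}\cdot m/N$, then
  sampling without replacement inside/outside). Fold 1 reproduces uniform
  sampling in expectation; the default fold 4 with a 15-gene group and a
  30/120 module places the whole group in-module — a maximally clean
  enrichment signal.
* `plant_proximal_target()` — one new node wired to
  `ceiling(attach_fraction × module_size)` module nodes (default half),
  emulating a drug target interacting densely with one disease module;
  `plant_control_target()` is its degree-matched null, wired to the same
  number of nodes chosen uniformly from the whole network.
* `generate_input_bundle()` — every file `run_pipeline()` consumes, from
  one spec. The herb table carries only the planted target: the
  degree-matched control is a topological null for the proximity
  comparison, not a plausible drug target, and in a 120-node benchmark a
  uniformly wired node often sits within average distance 3 of everything,
  so listing it as a drug target would tell us about the benchmark's small
  diameter, not about the pipeline.

What the generator does **not** emulate: scale-free degree tails, curation
noise (synonyms, species contamination), literature bias, or edge
confidence scores. Passing the recovery suites therefore shows the
pipeline is correct and well-calibrated under clean planted structure; it
does not certify performance on a real interactome, where hubs compress
distances and the universe choice matters more.

## Fixtures from the published worked example

`paper_fixture()` transcribes the two printed result tables of the study
this pipeline re-implements: the positive module-enrichment rows for six
modules and the shortest-path summaries of the two reported key targets
(CRH and NPPA). These are used purely as worked examples for the filter
rules — `fixture_positivity()` must reproduce the printed per-module
positive counts (12, 8, 4, 2, 2, 1) and the key-target conjunction on the
printed distance rows must return exactly CRH and NPPA. The underlying
interactome and databases are version-dependent and are not reproduced.

## Numerical and testing choices

* Fisher p-values come from the hypergeometric survival function; the test
  suite sweeps **all** 2×2 tables with universe ≤ 40 against an explicit
  `choose()`-sum oracle at 1e-12.
* Distance code is validated on 100 seeded Erdős–Rényi graphs (n = 200,
  edge probability 0.03, 20 sources each) against hand-coded BFS and
  Floyd–Warshall; recovery studies use 100 seeded replicates of the
  default 120-node benchmark. These sizes give stable rates while keeping
  the whole suite under a minute on one core.
* Ties in module labeling, record ordering and candidate ranking all have
  deterministic rules (documented above) so outputs are reproducible
  byte-for-byte.
* Degenerate inputs fail loudly: empty networks, empty gene sets, unknown
  categories, infeasible enrichment folds (the error reports the maximum
  feasible fold) and out-of-universe genes are all errors, not warnings.

## Known limitations

* The positivity rule uses raw p-values by default; with many modules and
  groups, expect false positives at the nominal rate (use
  `correction = "bh"` when screening widely).
* The "proportion" fold-enrichment definition and the network-as-universe
  choice are standard but not the only defensible readings; both are
  explicit parameters of the record schema rather than hidden constants.
* Average shortest-path proximity ignores degree bias: hubs are close to
  everything. The degree-matched control in the synthetic suite addresses
  this in benchmarking, but no z-score normalization is applied in the
  pipeline itself.
* Only disjoint (non-overlapping) modules are supported.
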