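---
title: "Comparative epistatic network analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative epistatic network analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episnet)
```

## The problem

Quantitative traits such as body mass index are shaped not only by the
additive effects of individual variants but by epistasis — statistical
interaction between loci, where the joint genotype effect deviates from the
sum of the marginal effects. Exhaustive pairwise interaction scans produce
very large tables of SNP pairs; network analysis turns them into something
interpretable. Each SNP becomes a node, each significant interaction an
edge weighted by its FDR-adjusted p-value, and the community structure of
the resulting graph groups loci that interact more among themselves than
with the rest of the genome — a natural candidate for shared biological
function.

episnet implements that pipeline for *two* interaction encodings and makes
their comparison the object of study, because the choice of encoding
changes which interactions are visible at all.

## Interaction encodings

Genotypes are minor-allele counts $g \in \{0, 1, 2\}$. For a pair of loci
the package provides:

* **Cartesian**: the multiplicative code $g_1 g_2$. This is the textbook
  product interaction; it is correlated with the marginal genotype codes,
  so loci involved in strong Cartesian epistasis typically also show
  single-locus signal.
* **XOR**: the exclusive-or of the heterozygosity indicators,
  $\mathbb{1}(g_1 = 1) \oplus \mathbb{1}(g_2 = 1)$, i.e. the penetrance
  table with rows $(0,1,0)$, $(1,0,1)$, $(0,1,0)$. At allele frequency
  $q = 0.5$ under Hardy–Weinberg equilibrium the conditional mean of the
  code is $1/2$ whatever the genotype at either locus, so the model has
  *zero* marginal effect and is invisible to any single-locus analysis —
  the classic "not linearly separable" penetrance model.

Three-locus codes are the direct generalizations (triple product; three-way
parity of the heterozygosity indicators). The two-locus XOR table is the
default but the encoding argument accepts any function of two genotype
vectors, so alternative penetrance tables can be plugged in without
touching the scan machinery.

## The pairwise scan

`pairwise_scan()` tests every unordered pair of post-filter loci with an
ordinary-least-squares model

$$y \sim \beta_0 + \beta_1 g_1 + \beta_2 g_2 + \beta_3\,\mathrm{code}(g_1, g_2),$$

reporting the two-sided t-test p-value for $\beta_3$. Main effects are
always included, so the interaction term is tested *beyond* anything
explainable additively. The three-way test (`threeway_test()`) includes all
three main effects and all three pairwise codes before the three-way code,
for the same reason. Benjamini–Hochberg correction is applied across the
full family of tests of one scan; pairwise and three-way families are
adjusted separately, since they are separate investigations.

Choices a user can change, with defaults:

| parameter | default | meaning |
|---|---|---|
| `min_maf` | 0.05 | minimum empirical minor-allele frequency (inclusive) |
| `alpha`   | 0.05 | FDR level for the `significant` flag |
| `encoding`| —    | `"xor"`, `"cartesian"`, or a custom code function |

Degenerate designs — constant genotype columns, aliased codes, fewer than
10 complete observations — are flagged and reported with $p = 1$ rather
than raised as errors, so a genome-scale scan never dies halfway.

## Network construction and threshold selection

An epistatic network $N = \{V, E, \tau\}$ admits an edge when its weight
(adjusted p-value) satisfies $\omega(e) \le \tau$; the inequality is
inclusive, and nodes are exactly the endpoints of admitted edges. Network
modularity is

$$Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} -
\gamma\frac{k_i k_j}{2m}\right]\delta(c_i, c_j)$$

with resolution $\gamma = 1$ by default, evaluated on the unweighted
adjacency of connected nodes. Communities come from greedy agglomerative
maximization: all-singleton start, repeatedly apply the merge with the
largest $\Delta Q$ (only edge-connected community pairs can improve $Q$ at
$\gamma \le 1$), stop when no merge increases $Q$.

`sweep_threshold()` raises $\tau$ from 0 in steps of $10^{-4}$ and records
metrics and greedy $Q$ at each grid point. Several details here were
genuinely open and are fixed as follows:

* **Sweep upper bound.** The grid ends at the first point at or above the
  largest observed weight, so the final grid network contains every input
  pair.
* **Tie-breaking for $\tau^\*$.** The smallest grid $\tau$ attaining the
  maximal $Q$ is selected, preferring the sparser network. Note that
  modularity of $k$ equally-sized disjoint communities is $1 - 1/k$
  regardless of their internal density, so the optimum often sits at a low
  threshold where a few strong, well-separated edges already form several
  components; this is a property of modularity itself, not an artifact.
* **Greedy tie-breaking.** Merges tied on $\Delta Q$ resolve to the
  lexicographically smallest community-id pair (ids follow locus order).
  This makes community detection — and everything downstream — fully
  deterministic.
* **Empty networks.** $Q$ is recorded as 0 when no edge is admitted, purely
  for sweep bookkeeping.
* **Floating-point thresholds.** Grid values like $0.0434$ are not exactly
  representable in binary; weight–threshold comparisons therefore allow a
  relative slack of one part in $10^9$ so that an edge whose weight
  "equals" a grid point is admitted at it, while $\tau = 0$ still admits
  only weight exactly 0.

## Comparing two networks

Positionally close SNPs carry largely redundant signal (linkage
disequilibrium), so network comparison treats loci within a base-pair
tolerance $\delta$ as interchangeable: $n_1 \approx n_2$ iff they share a
chromosome and $|p_1 - p_2| \le \delta$. The inequality is implemented
*inclusively*: a strict inequality would make the $\delta = 0$ comparison
vacuously empty, while exact-position overlap at $\delta = 0$ is precisely
the quantity one wants to report. Edges match when their endpoints match
pairwise in either orientation, existentially — one matching counterpart
suffices.

Community-level similarity is directional. For communities $C_a$, $C_b$
from the two networks,

$$\Lambda_{(C_a \to C_b)}(\delta) = \sum_{n^a_i \in C_a}
\max_{n^b_j \in C_b} f_\delta(n^a_i, n^b_j)$$

counts source-community nodes with at least one tolerant match. The curve
over the grid $\delta = \delta_{min}, \delta_{min}+s, \ldots, \delta_{max}$
(default 0–10 Mb, 1 Mb steps) is summarized by the discrete area

$$AUC = \sum_{k=0}^{M}
\frac{\Lambda(\delta_{min}+ks) + \Lambda(\delta_{min}+(k+1)s)}{2(M+1)},
\qquad M = \frac{\delta_{max}-\delta_{min}}{s} - 1,$$

normalized by $|C_a|$ to land in $[0, 1]$. The formula is implemented
literally — including the $(M+1)$ divisor, which differs from a
conventional trapezoid rule by its normalization — because the normalized
score's anchor points (0 for never-matching, 1 for always-saturated) depend
on that exact form. Because of the $|C_a|$ normalization the two
directional similarity matrices are not transposes of each other; a small
community contained in a large one scores 1 in one direction and a fraction
in the other.

## Triangle motifs and higher-order epistasis

A triangle — three SNPs all pairwise connected — is the natural candidate
generator for three-way epistasis: a genuine third-order effect tends to
leave pairwise traces on all three pairs. `enumerate_triangles()` lists
each triangle once; `classify_triangles()` marks a triangle *cis* when all
three loci share a chromosome within a 2 Mb span (default chosen at the
scale of a tight LD block in an outbred rodent population; configurable),
because such cliques are more parsimoniously explained by linkage
disequilibrium than by physiology. `test_triangles()` runs the full
three-way model per triangle and BH-adjusts within the triangle family
only. The significant triangles can be exported as a multigraph in which a
SNP pair shared by several significant triangles carries one parallel edge
per triangle.

## What the synthetic generator does and does not emulate

`simulate_genotypes()` draws each locus i.i.d. from Hardy–Weinberg
proportions $((1-q)^2,\, 2q(1-q),\, q^2)$; `simulate_phenotype()` adds
planted Cartesian/XOR pair and triple effects and Gaussian noise
($y = \sum\beta\,\mathrm{code} + \varepsilon$). This captures exactly the
features the pipeline's statistics rely on — penetrance-driven epistasis,
marginal invisibility of XOR at $q = 0.5$, quantitative noise — and makes
every downstream stage testable with known ground truth.

It deliberately does **not** emulate: linkage disequilibrium between loci
(columns are independent), relatedness or population structure of real
outbred populations, genotype missingness (readers accept it; the
simulator never emits it), main-effect or polygenic background, or
case/control ascertainment. Consequently, passing the simulation-based
tests demonstrates correctness of the statistical machinery and its
operating characteristics under the stated model — not robustness to LD
confounding or stratification in real data, which require the usual
GWAS-side corrections upstream of this package.

Default simulation conditions used throughout the test suite and the
acceptance script, chosen once at the scale of a small quantitative-trait
mapping study: 150–300 individuals, 8–16 loci at MAF 0.5 for planted-effect
studies, interaction effect sizes $\beta \approx 1$–1.5 against unit noise
($\sigma = 1$), and 50–200 replicate seeds for rate estimates. At these
sizes a planted XOR pair yields an interaction t-statistic around
$0.5\beta\sqrt{n}$, comfortably detectable, while remaining marginally
invisible.

## Known limitations

* Exhaustive scanning is $O(p^2)$ model fits; the pure-R implementation is
  appropriate up to a few thousand loci. The deposited-scale analyses the
  pipeline is designed around (10⁴ SNPs, ~5×10⁷ tests) should feed
  pre-computed pair tables in via `read_pairs()` rather than re-scanning.
* Greedy modularity maximization is a heuristic; it attains the exhaustive
  optimum on the small planted fixtures in the test suite but carries no
  global guarantee, and modularity's resolution limit (the $1 - 1/k$
  behaviour noted above) means $\tau^\*$ selects separation, not density.
* The tolerance-matching comparison treats chromosome labels as exact
  strings after normalization; cross-assembly coordinate comparison is out
  of scope.
* Functional enrichment itself (g:Profiler querying, GO analysis) is out
  of scope; the package prepares the range queries
  (`export_gprofiler_ranges()`) and stops there.
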