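---
title: "Methods: germline variation networks from pileups to risk calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline variation networks from pileups to risk calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Familial lung cancer shows strong aggregation in pedigrees, yet
single-locus analyses rarely find shared causal germline variants: the
individual variants differ between affected relatives. The hypothesis
this package operationalises is *network-level* susceptibility: each
patient carries many private nonsynonymous germline SNPs whose genes
interact densely in the protein–protein interaction (PPI) network and
concentrate in a PI3K/AKT-type pathway. The signature is then not any
particular variant but (i) the fraction of variant-containing genes in
the largest interconnected subgraph (the *main graph*), and (ii) the
counts of variant-containing genes in two pathway gene sets.

Because the patient exomes behind this design are not publicly
available, the package pairs every analysis stage with a seeded
synthetic generator, so each claim a test makes is a claim about a
fully stated world.

# Variant calling

The caller starts from per-position pileups (chromosome, 1-based
position, reference base, depth, A/C/G/T counts). Positions with depth
below `min_depth = 10` are discarded. At a retained position with depth
$d$, let $a$ be the count of the most frequent non-reference base. The
null hypothesis — every read matches the reference — is encoded as the
one-sided Fisher exact test of

$$\begin{pmatrix} a & d-a \\ 0 & d \end{pmatrix},$$

the observed sample against an ideal all-reference sample of equal
depth. Conditioning on the margins gives a closed-form upper tail: the
p-value is the single hypergeometric term

$$p(a, d) = \binom{2d-a}{d-a} \Big/ \binom{2d}{d}
          = \prod_{j=0}^{a-1} \frac{d-j}{2d-j},$$

and a variant is called when $p < \alpha = 0.01$. The published
description of this caller states the null and the threshold but not
the table; the construction above is the most literal encoding and is
used consistently. Its implied detection thresholds are a minimum alt
count of 6 at depth 10 and 7 at depth 30 — both verified against an
independent enumeration oracle in the tests.

Zygosity is annotated `hom` when $a/d \ge 0.85$, else `het`; the
original work never states a cutoff and the value only affects VCF
output, not any downstream statistic. Only the single most frequent
non-reference base is tested (SNP/SNV framing; no multi-allelic calls);
ties between alternative bases are resolved in fixed A < C < G < T
order.

*Germline* variants are calls in blood or para-cancer (adjacent normal)
tissue. *Somatic* variants are calls present in the cancer sample, not
called in the matched normal, **and** covered by at least `min_depth`
reads in the normal — absence must be evidenced, not merely uncovered.
Variant identity for all set operations is the full allele match
(chrom, pos, ref, alt); position-only matching is deliberately not
used.

# Coding consequences

Gene models are refFlat rows with UCSC 0-based half-open coordinates;
pileup/VCF coordinates are 1-based and converted on entry (stated once,
asserted in tests). A model whose concatenated CDS length is not a
multiple of 3 is flagged non-codable and skipped with a warning. For a
variant inside a codable CDS the affected codon is located in
translation order (reverse-complemented on the minus strand) and
translated with the standard genetic code. Per-transcript consequences
are collapsed by maximum severity, ordered
stop gain = stop loss > nonsynonymous > synonymous > noncoding —
any damaging transcript suffices for the gene-level network use. The
nonsynonymous set (including stop gain/loss) feeds all downstream
stages. Splice sites, UTR classes and indels are not modelled.

# Interaction network statistics

Edges come from a STRING-style table with per-channel scores on the
integer 0–1000 scale, divided by 1000 on read. The combined score over
the selected evidence channels (`experiments`, `databases`, `fusion` by
default) is the noisy-OR

$$s = 1 - \prod_c (1 - s_c),$$

**without** STRING's internal prior correction — the prior constant is
version-dependent and unspecified in the source material, so the
simpler aggregation is used and documented as a reconstruction. An edge
is kept when both endpoints are variant-containing genes and
$s \ge 0.700$ (inclusive, with a $10^{-9}$ tolerance against float
error). All variant genes are nodes, including isolates: an edgeless
gene still carries a SNP and belongs in the denominator of the
main-graph fraction.

The *main graph* is the largest connected component; size ties are
broken by the component containing the lexicographically smallest gene
name, making every statistic deterministic. On the main graph the
package computes: the characteristic path length (mean BFS distance
over unordered node pairs — all connected within the component;
disconnected pairs are excluded by construction rather than treated as
infinite, matching common network-viewer conventions), the
shortest-path histogram, the average neighbor count $2E/N$, and the
degree histogram. A single-node main graph has no pairs; its path
length is reported as 0 with a `degenerate` flag.

The power-law fit is an ordinary least-squares line on
$(\log_{10} k, \log_{10} n(k))$ over degrees $k > 0$ with $n(k) > 0$,
i.e. the straight line conventionally drawn through a log-log degree
distribution — not a maximum-likelihood tail estimate, which answers a
different question and would not match visual fits. At least three
distinct supported degrees are required; $r^2$ is computed directly
from residuals (so exact fits return 1 without numerical warnings).

Group comparisons delegate to the statistics core: two-tailed
Kolmogorov–Smirnov on per-node neighbor counts pooled within groups,
and two-tailed exact Mann–Whitney U on per-individual scalars (main
graph size, fraction).

# Statistics core

All tests used anywhere in the pipeline are implemented against
enumeration oracles:

* `fisher_exact`: hypergeometric conditioning on both margins;
  two-sided p sums all tables whose probability does not exceed the
  observed one (with a $1+10^{-7}$ relative tolerance for ties).
* `hypergeom_tail`: upper tail $P(X \ge k)$, the pathway enrichment
  p-value.
* `ks_two_sample`: $D = \sup |\hat F_x - \hat F_y|$ with the asymptotic
  Kolmogorov p-value at $\sqrt{n_{\mathrm{eff}}}\,D$,
  $n_{\mathrm{eff}} = n_x n_y / (n_x + n_y)$. No exact small-sample
  p-value is implemented; results carry `exact = FALSE`. The intended
  use is on pooled neighbor-count distributions large enough for the
  asymptotic form.
* `mann_whitney_exact`: $U = \min(U_x, U_y)$; for pooled
  $n \le 25$ the exact null distribution of the rank sum is built by a
  subset-sum recursion over the doubled mid-ranks — mathematically
  identical to enumerating all $\binom{n}{n_x}$ assignments (and
  verified against such an enumeration in tests) but feasible at the
  stated size bound, and correct under ties because the recursion runs
  on the mid-rank multiset itself. Larger samples fall back to the
  normal approximation with tie correction, flagged `exact = FALSE`.
* `woolf_or`: crude odds ratio $ad/bc$ with the Woolf interval
  $\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. The constant
  1.96 is fixed (not a quantile lookup) so printed intervals match the
  conventional two-decimal form exactly. Any zero cell triggers the
  Haldane–Anscombe correction (+0.5 to all cells) and a `corrected`
  flag. Rounding to two decimals happens only in the reporting layer.

No multiple-testing adjustment is applied anywhere: the reproduced
analyses report raw p-values.

# Pathway analysis

Gene sets are read from GMT (id, description, members; duplicates
within a line removed). Enrichment of a query gene set against pathway
$P$ uses the hypergeometric upper tail with population $N$ = the
background (default: union of all genes in the database, overridable),
$K = |P|$, $n$ = the query restricted to the background (genes outside
the background are dropped with a message), $k$ = overlap. The ranking
criterion of the online tools being replaced is unpublished; ranking is
by ascending p-value with ties broken by descending overlap then
pathway id, and ranking by raw overlap count is available behind a
flag. Top-$k$ lists (default $k = 10$) are intersected across
individuals to find shared pathways.

# Risk classification

Each individual is summarised by
(`n_pi3k_genes`, `n_cancer_pathway_genes`, `main_fraction`).

*Clustering.* Agglomerative hierarchical clustering on the two counts,
Euclidean distance, average linkage, cut at two clusters. Linkage and
metric are unstated in the source material; these are the most common
defaults. The cluster containing the largest feature sum is reported
first so group identity is input-order independent.

*Decision line (SVM).* The published classifier's details live in an
unavailable supplement; it is reconstructed as a hard-margin linear SVM
on the two pathway counts — the minimal model consistent with a
straight "optimal division line" in the count plane. In 2-D the
maximum-margin separator is computed exactly: the shortest segment
between the two classes' convex hulls (vertex–vertex and vertex–edge
candidates; separating-axis test for overlap) gives the support points,
and the boundary is its perpendicular bisector with geometric margin
half the gap. Non-separable inputs fall back to a deterministic
full-batch subgradient descent on the soft-margin objective with
penalty $C = 1$, flagged `separable = FALSE`.

*Explicit rule.* `high_risk` iff strictly more than 15 PI3K/AKT-type
genes **and** strictly more than 10 cancer-pathway genes; a main-graph
fraction strictly above 0.60 is reported as a separate supporting flag
rather than a third conjunct, because the source analyses present it as
a parallel criterion in a different figure.

# Epidemiology

A cohort table (one record per individual, `status` case/control plus
named categorical exposures) is tabulated into 2×2 tables per contrast;
`or_table` emits the conventional layout with reference rows at OR
1.00 and two-decimal rounding in the report columns only. Stratified
analyses compare each stratum against a named reference stratum. Only
*crude* odds ratios are computed: adjusted estimates would require the
study's individual-level covariates, which were never released — the
stratified output therefore reproduces structure and crude values
(e.g. 2.64 from the printed adenocarcinoma/squamous counts), explicitly
not the published covariate-adjusted 2.74.

# The synthetic world

The generator's defaults are the stated world; they were chosen once,
from the aggregate facts available (coverage "more than 91×" is the
only published distributional statement about the real exomes) and
toy-scale practicality, and are not tuned against test outcomes.

* **Genome/genes**: 60 kb single chromosome, 150 non-overlapping 1–2
  exon genes, CDS a multiple of 3 with a forced ATG start. A toy scale:
  real exome structure (96 Mb capture) is emulated in *kind*, not size.
* **Depth**: Poisson with mean 30 per position — variability ensures
  the ≥10× filter is actually exercised; 30× keeps heterozygote
  detection comfortably powered while staying cheap.
* **Errors**: per-read error rate 0.005 (mid-range Illumina
  substitution error); erroneous reads pick a uniformly random other
  base.
* **Germline sites**: alt-read probability 0.5 (het) or 1.0 (hom) in
  every tissue; het fraction 0.67, the roughly 2:1 het:hom ratio of
  typical germline call sets.
* **Somatic sites**: alt reads at `cancer_fraction = 0.3` (a tumor
  purity/clonality surrogate) in cancer tissue only.
* **Network**: preferential attachment (2 edges per node, 120 nodes)
  for a scale-free backbone, plus a planted 30-gene module with
  internal edge probability 0.5 — the dense neighborhood familial
  individuals sample from. Kept edges draw an `experiments` score from
  U(0.7, 0.95) (other channels 0), the simplest way to satisfy the
  0.700 combined threshold.
* **Pathways**: pathway 1 contains the whole planted module plus
  fillers; pathway 2 contains ~80% of pathway 1 plus random genes;
  the rest are random. This mirrors a module-bearing pathway and a
  correlated broader set.
* **Individuals**: familial patients draw N(20, 2) (clamped to ≥16)
  module genes plus 8 random fillers; controls draw 25 random genes.
  The clamp is part of the stated world: a "familial" individual is
  *defined* here as carrying a substantial module load, matching the
  count ranges the design targets (patients ≈ 20 ± 3 vs controls
  ≈ 8 ± 3 in pathway 1).
* **Cohort**: Bernoulli exposures at (0.30, 0.15), designed true OR
  $(0.3/0.7)/(0.15/0.85) = 2.4286$.

A single master seed expands into fixed per-stage child seeds, so any
stage can be regenerated independently and identical configurations are
byte-identical on disk. `plant_gene_variants` additionally lets the
full pipeline route (pileup → calling → annotation) hit exactly a
designed gene set, by planting one verified protein-altering variant
per gene.

**What the generator does not emulate** — and hence what a green test
does *not* establish about real data: linkage between sites, population
allele-frequency spectra, indels and structural variants, capture and
GC bias, mapping artifacts, FASTQ-level error profiles, and real PPI
topology beyond "scale-free plus a dense module". Tests on this world
validate the *machinery* (calling math, graph statistics, enrichment,
classifiers, odds ratios), not clinical claims.

# A detection limit worth stating

One acceptance claim is intentionally left failing. At somatic
alt-read fraction 0.3 and Poisson(30) depth, the caller's minimum alt
count is 7 at depth 30, so the per-site detection probability is

$$\mathbb{E}_{d \sim \mathrm{Pois}(30)}
  \big[ P(\mathrm{Binom}(d, 0.3) \ge t(d)) \big] \approx 0.80\text{–}0.84,$$

independent of seed. Somatic recall therefore cannot reach the 0.95
demanded of it under these stated parameters (germline recall ≈ 0.997
and all precisions ≈ 1 do pass). Raising `cancer_fraction` or the depth
would pass the bar, but both are stated values of the world, so the
assertion stays red and the limit is documented instead — it is, in
fact, the textbook reason tumor-only calling at modest purity needs
higher depth.

# Numerical choices and degenerate inputs

* Threshold comparisons that must be inclusive (combined score ≥ 0.700)
  use a $10^{-9}$ absolute tolerance.
* Component and ranking ties break lexicographically; alternative-base
  ties break in A < C < G < T order; everything downstream of a seed is
  deterministic.
* Empty inputs return empty, typed results (empty pileup → zero calls;
  empty gene set → empty graph; empty catalog → zero annotations).
  A single-node main graph reports path length 0 with a flag; an
  all-zero 2×2 table flows through the Haldane correction.
* Reported ORs/CIs are rounded to 2 decimals only in report columns;
  full-precision values ride alongside.

# Known limitations

* The Fisher table construction, the combined-score formula, the
  pathway-ranking criterion, and the SVM are documented
  reconstructions of under-specified methods; alternative readings
  would change absolute p-values but not the pipeline's contracts.
* KS p-values are asymptotic only.
* The exact MWU is limited to pooled $n \le 25$ before the normal
  fallback.
* Crude odds ratios only; no covariate adjustment.
* The CLI covers restartable stage execution but not distributed or
  streaming operation; pileups are held in memory per sample.
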