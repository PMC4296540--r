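---
title: "Methods: Pfam-level differential expression for communities without shared genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pfam-level differential expression for communities without shared genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfamdiff)
```

## The problem

Enrichment cultures run under different conditions (say, 35&nbsp;°C vs
55&nbsp;°C solid-state culture on the same feedstock) select microbial
communities with drastically different memberships.  Their metatranscriptomes
cannot be compared gene by gene: the two gene catalogs barely overlap, so a
per-gene fold change is undefined for almost every gene.  Communities doing
the same job, however, express overlapping *functions*.  pfamdiff therefore
pools mapped mRNA read counts by Pfam domain annotation and asks, per protein
family, whether one community expresses that function more than the other —
here aimed at carbohydrate-active enzyme families (glycoside hydrolases and
carbohydrate binding modules) relevant to lignocellulose deconstruction.

## Quantification model

For community $A$ and Pfam $i$,

$$P_{i,A} = \frac{p_{i,A}}{S_A}, \qquad
  p_{i,A} = \sum_{j=1}^{n_{i,A}} g_{j,i,A} / l_{j,i,A},$$

where $g$ is a gene's mapped-read count, $l$ its length in nucleotides
(mapped-read counts scale with nucleotide length, so the normalization is a
plain count/length ratio — deliberately not per-kilobase), and $S_A$ a
sequencing-depth size factor.  Genes carrying several Pfam annotations
contribute their full normalized count to each family; unannotated genes are
discarded before pooling.  $n_{i,A}$ counts the annotated genes with at least
one mapped read: the pooled sum is unchanged by zero-count genes, and this
definition keeps the observed group size identical to the group size the
permutation null samples (the wording "number of genes with annotation" could
also be read as including unexpressed genes, but that reading would make the
observed statistic and its null incommensurable).

Size factors use the median-of-ratios construction: each Pfam's $p_{i,A}$ is
divided by the geometric mean of that Pfam's values across communities, and
the per-community median of these ratios is $S_A$.  Pfams with a zero in any
community are dropped from the median (their geometric mean is zero); the
median over all Pfam-annotated categories is used, not just the target
families, because the size factor measures depth and must not be confounded
with the biology under test.  With two communities and an odd number of
usable Pfams, $S_A S_B = 1$ by construction.  For an even number we take the
arithmetic mean of the two central ratios, which breaks the identity by a
bounded amount; this is the conventional median and is the one place our
values can differ (harmlessly) from implementations that average on the log
scale.

## The pseudo-Pfam permutation test

The observed statistic for family $i$ is $D_i = P_{i,F} - P_{i,O}$, the focal
community minus the other.  Its null distribution is built by resampling:
draw $n_{i,F}$ genes uniformly *without replacement* from the focal
community's pool of annotated, expressed genes, sum their size- and
length-normalized counts, do the same with $n_{i,O}$ genes on the other side,
and record the difference.  Repeating this 10,000 times (default) gives the
null; the p-value is the smoothed exceedance probability

$$p = \frac{\#\{D_\text{pseudo} \ge D_i\} + 1}{N + 1},$$

one-sided in a *fixed* direction: the test screens for overexpression in the
focal community, so families overexpressed on the other side get p-values
near 1 (they are visible in the fold-change direction instead).  Because the
Monte-Carlo p-value wobbles between runs, the algorithm is run three times
(default) and the mean reported.  The pool values carry the size-factor
division so that pseudo-group sums and $D_i$ live on the same scale; with the
group sizes fixed per family, omitting that common division would only
rescale both sides of the comparison, so the choice is one of convenience,
not substance.

No multiple-testing adjustment is applied to these p-values, and significance
is called at an inclusive 0.10: in an enzyme-discovery screen a false
negative is lost forever while a false positive is weeded out by downstream
activity assays.  The stringency is instead provided by the second method and
the consensus rule.

Design notes:

* Sampling is without replacement — "select $n$ genes" means distinct genes.
* Add-one smoothing keeps p-values strictly positive; the exhaustive
  enumeration oracle used in the tests computes exact probabilities without
  smoothing, and the equivalence test budgets for the $1/(N{+}1)$ offset.
* For a fixed null the p-value is non-increasing in the signed $D_i$.
* The null assumes annotated expressed genes are exchangeable.  When per-Pfam
  baseline expression varies strongly, genes within a real family are
  correlated while pseudo-group members are not, and the test becomes
  anti-conservative.  The calibration suite therefore runs under the
  exchangeable regime (a common baseline rate); the consensus rule with the
  negative-binomial test is what controls false positives on heterogeneous
  data.  This limitation is inherent to the pseudo-group construction, not to
  this implementation.

## The pooled-duplicate negative-binomial test

The second method adapts the classical no-replicate count test.  Per-family
length-normalized sums are rounded to integers $k_{i,A}, k_{i,B}$ (the NB
machinery needs counts; rounding half to even), families at zero in both
communities are dropped, and the two size-normalized columns are temporarily
pooled and treated as duplicates to estimate a dispersion.  Per family,
duplicates give a method-of-moments mean $q_i$ and variance $w_i$; the
size-scaled shot noise $q_i \cdot \mathrm{mean}(1/S)$ is subtracted, and the
single dispersion $\alpha$ of the variance model
$\sigma^2 = \mu + \alpha\mu^2$ is estimated as the **median** of the moment
ratios $e_i/q_i^2$ over families with positive excess $e_i$ (zero if none).

Two choices deserve comment.  A one-parameter parametric trend replaces the
original local regression because ~30 family-level observations cannot
support a nonparametric variance fit.  And the median replaces an
origin-through least-squares fit of $e_i$ on $q_i^2$ because least squares is
$q^4$-weighted: the handful of genuinely discordant families — exactly the
ones the screen is designed to find, with folds of 30–130 — dominate such a
fit completely and push $\alpha$ high enough to erase all power (on default
synthetic data, $\hat\alpha \approx 1.9$ versus $\approx 0.25$ for the
median).  The median keeps a minority of true positives from setting the
dispersion for everyone while preserving the method's stated conservatism:
restricting to positive-excess families biases $\alpha$ upward, so when the
"most families are not differential" assumption fails the test loses power
rather than gaining false positives.

Given $\alpha$, each family is tested conditionally on its total
$k_S = k_A + k_B$: with $\hat q = k_S/(S_A + S_B)$ and NB marginals of means
$\hat q S_A$, $\hat q S_B$ (NB size $1/\alpha$; Poisson at $\alpha = 0$), the
two-sided p-value sums the probabilities of all splits no more likely than
the observed one (ties included), normalized by the total over all splits.
At $\alpha = 0$ and equal size factors this is exactly the two-sided
conditional binomial($k_S$, 1/2) test, which the test suite verifies to
$10^{-9}$ for all totals up to 50.  The computation is done in log space with
a relative tie tolerance of $10^{-7}$; adjacent split probabilities differ by
far more than that for the totals involved, so the tolerance only absorbs
floating-point noise in genuine ties.  These p-values are Benjamini–Hochberg
adjusted (`stats::p.adjust`), and significance is again called at an
inclusive 0.10.

**Consensus rule.**  A family is selected for follow-up only when *both*
methods call it at 0.10 — raw mean p for the permutation screen, BH-adjusted
p for the NB test.

## Descriptive layers

* *Sequencing metrics*: rRNA share of total reads, mapped share of mRNA
  reads, and the target-family ("lignocellulolytic") share of mapped reads,
  rounded to one decimal (two for the last, which is typically below 1%).
* *Composition*: each GH family's percentage of the summed GH-family
  expression.  CBM families are excluded from the denominator — binding
  modules are not hydrolases — and the shares are size-factor-free.
* *Taxon attribution*: per family, the share of normalized transcripts per
  genus (or rolled up per phylum), with the shortest descending-share prefix
  that strictly exceeds 50% flagged as the dominant genera; ties break
  alphabetically for determinism; unknown-taxon genes stay in the denominator
  but get no row.  A multi-Pfam gene's full normalized count goes to each of
  its families, consistent with the pooling rule, so a gene can appear under
  two families.
* *Top genes*: genes sorted by descending normalized count (ties by id), cut
  at cumulative coverage ≥ 90% by default — the short list that usually
  explains an overexpressed family.
* *Rarefaction*: expected distinct expressed genes at subsampled read depth,
  estimated by subsampling the integer mapped-read multiset without
  replacement (counts, not normalized values, are what a read subsample
  thins).  The tests pin the simulated means to the hypergeometric closed
  form $E[\text{detected}] = \sum_g \left(1 - \binom{T-c_g}{m}/\binom{T}{m}\right)$
  and cross-check that form against vegan's analytic rarefaction.

## The synthetic data generator

`synthetic_config()` / `simulate_communities()` produce the two-community
structure the analysis assumes, with known truth, so that every stage is
testable without any external download:

* Two communities with disjoint gene ids (a `shared_gene_frac` knob exists,
  default 0) but one shared Pfam universe.
* Per-gene counts are negative-binomial with mean
  `baseline(Pfam) × length × library factor × planted fold` and dispersion
  `alpha` (default 0.05).  Length enters multiplicatively so that the length
  normalization is genuinely exercised — an unnormalized analysis is visibly
  length-biased, and a property test asserts the normalization removes the
  trend.
* The per-Pfam baseline rate is log-normal across families (median 1 read per
  nucleotide, `sdlog = 1` by default: order-of-magnitude variation between
  families, and per-gene depths that put the two libraries in the millions of
  mapped reads, the regime the method is used in).  Setting `sdlog = 0` gives
  the exchangeable null used for calibration.
* The first community is sequenced `library_ratio = 4` times deeper, so the
  estimated size factors sit near 2 and 0.5 — approximately reciprocal and in
  a 4:1 ratio, the depth asymmetry the method must remove.
* Planted effects default to folds {130, 50, 30} on the first three target
  families, overexpressed in the shallow community — large folds, because
  that is the regime the consensus screen is designed for and reports.
* Genes per family: every family is guaranteed 3 genes per community and the
  remaining annotated genes are assigned uniformly (mean ≈ 8 genes/family at
  the defaults).  Differing gene complements between communities are a real
  feature of unrelated communities and the dominant source of null variance
  at the family level; the guaranteed minimum merely prevents degenerate
  empty families.
* 25% of genes are unannotated (they enter nothing but the library depth);
  10% of annotated genes carry a second Pfam; genus/phylum labels come from a
  per-family dominant-genus model (dominant genus with probability 0.6).

What the generator does *not* emulate: rRNA contamination and its filtering,
read-level errors and mapping ambiguity, assembly artifacts, shared genes
with divergent sequences, and taxon-correlated expression differences beyond
the planted folds.  Passing tests therefore demonstrate the statistical
machinery on data satisfying the method's own assumptions; they do not
certify behaviour on real mapped counts, where annotation quality and the
exchangeability caveat above matter.

## Problem sizes used by the validation suites

The test and acceptance runs use deliberately moderate sizes chosen to make
Monte-Carlo error negligible relative to the bands being checked: the
end-to-end recovery study uses 100 replicate datasets of 800 genes and 80
Pfams per community (30 targets, folds {130, 50, 30}) with 1,000 permutation
draws × 3 runs per family — at a 0.10 threshold the p-value resolution of
1/1001 is ample; the calibration study uses 500 null datasets of 400 genes /
40 Pfams; the oracle-equivalence checks run the full 10,000 draws on pools
small enough to enumerate.  A single default-size analysis
(1,200 genes × 2, 30 targets, 10,000 × 3 draws) runs in seconds.

## Degenerate inputs and numeric conventions

* Families absent from both communities: flagged not detected; no p-value,
  no fold change (the report prints them as missing).
* Zero in exactly one community: fold change undefined, direction still
  reported; both tests still run (the permutation null handles group size 0
  as an empty sum).
* No Pfam positive in every community: size factors are an error — there is
  no depth information to share.
* Fewer than 3 testable families: the dispersion estimate is an error rather
  than a guess.
* Rounding: count rounding is round-half-to-even; reported percentages follow
  the table conventions above; all medians are the conventional
  arithmetic-mean-of-central-pair for even lengths.
* Reproducibility: every stochastic entry point (`simulate_communities()`,
  `run_pseudo_pfam_test()`, `rarefaction_curve()`, `pfam_diff()`) takes a
  seed and is bit-reproducible given it.

## Known limitations

* The pseudo-Pfam null assumes exchangeable annotated expressed genes
  (see above); use the consensus call, not the permutation p alone.
* The pooled-duplicate dispersion cannot separate biological difference from
  depth-corrected noise with one library per community; $\alpha$ is an upper
  bound, and power suffers accordingly for modest folds.
* Rounding length-normalized sums to integers for the NB test discards
  information when families have few normalized counts; families whose sums
  round to zero on both sides are untestable by that method.
* The fixed screening direction means the permutation p-values only rank
  overexpression in the focal community; swap `focal` to screen the other
  way.
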