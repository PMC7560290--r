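---
title: "Evaluating reference-gene stability for relative qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reference-gene stability for relative qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative qPCR quantification expresses a target gene's abundance against one
or more reference genes (RGs) assumed to be stably expressed across the
samples being compared. A poor reference gene distorts every downstream fold
change, so candidate RGs must themselves be evaluated. In polyploid species
without a sequenced genome (hexaploid oat is the motivating case) an extra
complication appears: most genes exist as several near-identical homeologous
copies that may be expressed unequally between tissues, so a primer pair that
amplifies one copy does not necessarily report the gene's aggregate
expression. refstab covers both halves of the problem: the statistical
evaluation of candidate RGs from replicate-level Ct tables, and the sequence
work needed to place primers in regions identical across duplicated copies.

## Data model

The universal input is a long table of threshold cycles with one row per
technical observation: `sample`, `gene`, `replicate`, `ct`. Values must be
finite and inside `(0, 45]` — a 42-cycle programme plus margin; the bound is
configurable and violations are flagged, never silently dropped. Technical
replicates are averaged (`aggregate_replicates()`) into a genes x samples
matrix; biological replicates are kept as separate columns so that the
stability statistics see biological variance. A one-step "average everything
per condition" path is possible (aggregate a table whose `replicate` column
holds the biological replicates) but is not the default, because collapsing
biological replicates removes exactly the variance the algorithms are meant
to measure. Which of the two layouts a study should use cannot be decided
from the data; both are supported.

geNorm works on relative quantities rather than cycles:
$q_{is} = E_i^{\,\mathrm{Ct}^{\min}_i - \mathrm{Ct}_{is}}$, where $E_i$ is
the fold amplification per cycle (2.0 at 100% efficiency) and the per-gene
minimum is taken within the analysed sample set, so $\max_s q_{is} = 1$.
All stability algebra uses $E = 2$ by default — the Ct-based convention —
because per-gene efficiencies are rarely carried into stability scoring;
per-gene values can be supplied when they are known.

## The four stability algorithms

**Comparative delta-Ct.** For each ordered gene pair,
$\Delta \mathrm{Ct}_{ij}(s) = \mathrm{Ct}_i(s) - \mathrm{Ct}_j(s)$; the score
of gene $i$ is the mean over partners $j$ of the sample SD (n−1) of
$\Delta \mathrm{Ct}_{ij}$. Per-sample loading shifts cancel in the
difference, which is the method's point.

**geNorm.** With $A_{jk}(s) = \log_2 (q_j(s)/q_k(s))$, the pairwise
variation $V_{jk}$ is the sample SD of $A_{jk}$ and $M_j$ is the mean of
$V_{jk}$ over partners. At $E = 2$ this is algebraically identical to the
delta-Ct score — the suite asserts the identity to 1e−12. The canonical
stepwise mode repeatedly removes the highest-M gene and recomputes M within
the survivors; the reported rank is the reverse removal order. The final
surviving pair is unordered in the original procedure; refstab orders it by
full-set M, then alphabetically, and exposes both `full_set_M` and
`stepwise_M` since published tables rarely say which variant they print.
The pairwise-variation series compares normalisation factors
$\mathrm{NF}_n(s)$ (geometric mean of $q$ over the top $n$ genes):
$V_n = \mathrm{SD}_s[\log_2(\mathrm{NF}_n/\mathrm{NF}_{n+1})]$ for
$n = 2,\dots,k-1$. `optimal_rg_number()` applies the conventional rule: the
smallest $n$ with $V_n < 0.15$ is enough reference genes.

**NormFinder-style variance decomposition.** Working on $y = -\mathrm{Ct}$
(log2 expression up to constants), each sample is centred across genes to
remove loading. Ungrouped mode fits the additive model
$y_{ij} = \alpha_i + \beta_j + \varepsilon_{ij}$ with gene-specific error
variance $\sigma_i^2$. The two-way residuals $r_{ij}$ satisfy
$\mathbb{E}\!\left[\tfrac{1}{n-1}\sum_j r_{ij}^2\right]
 = \left(\tfrac{k-1}{k}\right)^2 \sigma_i^2
 + \tfrac{1}{k^2} \sum_{i' \ne i} \sigma_{i'}^2,$
a linear system whose closed-form solution is the estimator used:
$\hat\sigma^2_i = \tfrac{k}{k-2}\big(u_i - \tfrac{T}{k(k-1)}\big)$ with
$u_i = \sum_j r_{ij}^2/(n-1)$ and $T = \sum_i u_i$. It is exactly unbiased
for any $k \ge 3$; negative estimates are floored at zero before the square
root. The test suite checks it two ways: against the literal matrix solve of
the moment system, and against a numerically optimised REML fit of the
heteroscedastic two-way model. At five residual degrees of freedom the two
estimators disagree noticeably on any single draw (that is sampling noise,
not bias), so the REML comparison is made on per-gene estimates averaged
over 150 small instances, where both agree within a few percent. Grouped
mode combines the inter-group deviation $d_{ig}$ of gene $i$ in group $g$
(after sample centring, so $\sum_i d_{ig} = 0$ per group) with the
within-group error:
$\mathrm{stab}_i = \tfrac{1}{G} \sum_g \big( |d_{ig}| +
\sqrt{\hat\sigma^2_{ig} / n_g} \big)$. This is a deliberately transparent
moment formulation without the empirical-Bayes shrinkage of the original
software; correctness is defined by the recovery contracts in the test
suite, not bit-equality with legacy tools.

**BestKeeper.** Descriptive statistics on raw Ct: arithmetic and geometric
means, extremes, the classical BestKeeper "SD" (mean absolute deviation from
the arithmetic mean), the n−1 sample SD alongside, and
$\mathrm{CV\%} = \mathrm{SD}/\bar{\mathrm{Ct}} \times 100$. Published tables
often print "CV ± SD" without saying which number drives the ranking; both
keys are available (`rank_by = "sd"` is the default, and reproduces the
common pattern where a very highly expressed gene ranks first on SD despite
its low mean Ct inflating neither). BestKeeper deliberately works on the Ct
scale and is therefore sensitive to loading differences — the suite asserts
that sensitivity rather than hiding it.

Ranks are always ascending (1 = most stable) with average ranks on ties, and
`consensus_rank()` aggregates any set of rankings by the geometric mean of
each gene's ranks, consuming fractional ranks unchanged. A packaged fixture
with the published per-algorithm rank orders of ten oat candidate RGs in
four sample sets lets the consensus step be exercised offline; feeding those
sixteen rankings through `consensus_rank()` reproduces all eight published
most/least designations.

## Quantification

`fit_standard_curve()` fits Ct against log10 template amount by ordinary
least squares and converts the slope to an amplification efficiency,
$E(\%) = (10^{-1/\mathrm{slope}} - 1) \times 100$; a doubling reaction has
slope $-1/\log_{10} 2 \approx -3.32$. Curves are flagged reliable inside the
conventional 90–115% window (inclusive; a 1e−9 tolerance keeps boundary
values from flipping on float rounding). `relative_expression_ddct()`
implements $2^{-\Delta\Delta \mathrm{Ct}}$ with one or more reference genes
summarised by their arithmetic-mean Ct — equivalent, at $E = 2$, to
normalising by the geometric mean of their relative quantities. An
efficiency-corrected (Pfaffl-style) mode is out of scope. Error bars come
from applying the ddCt computation per biological replicate and taking the
SD of the fold changes (`ddct_replicate_summary()`).

## Duplicated-copy sequence handling

`pairwise_identity()` reports global-alignment identity (identical columns /
alignment length, end gaps included) under recorded scoring parameters
(default match +1, mismatch 0, linear gap penalty 1); published "similarity"
percentages rarely state their parameters, so identity here is
parameter-tagged rather than matched to any particular program.
`identical_windows()` finds every maximal substring shared exactly by all
copies — exact common-substring search, not an alignment, because "identical
region" means exact identity and alignment-based answers vary by aligner.
When a window occurs more than once in a copy, the first occurrence is the
reported coordinate. `in_silico_pcr()` places the forward primer on the
sense strand and the reverse complement of the reverse primer downstream of
it; coordinates are 1-based inclusive and the product length spans both
primers, the convention of published amplicon-length tables. Exact matching
is the default (two or more mismatches are already enough to discriminate
similar templates in practice); a mismatch-tolerant mode exists for
exploration. `check_primer_constraints()` evaluates the standard design
windows (length 20–24 nt, Tm 55–65 °C, GC 45–60%, product 80–200 bp) with a
nearest-neighbor Tm (SantaLucia 1998 unified parameters, 250 nM oligo,
50 mM Na+, entropy salt correction). Printed Tm columns produced by design
software use other parameter sets; the report records its method and makes
no attempt to match them. An oversized published product (e.g. 288 bp)
simply reports `product_size_ok = FALSE` — the flag reflects the window, not
the publication.

Real transcript sequences of the oat candidate panel are not redistributed
with the package. `synthetic_oat_transcripts()` instead builds clearly
labelled synthetic homeolog copies that embed the published primer pairs at
the published product spacings, diverging elsewhere; they exercise the
in-silico PCR and identical-window machinery, including the four-copy case
where every copy must yield the same product length.

## The synthetic Ct generator

`simulate_ct_table()` draws from the additive model
$\mathrm{Ct} = \mu_i + \lambda_{sb} + \delta_{i,g(s)} + \varepsilon_{isb} +
\tau$, with normal noise on the Ct (log) scale: a shared per-(sample,
biological replicate) loading shift $\lambda$, gene-specific biological
noise, tissue/group shifts $\delta$ for unstable genes, and technical
replicate noise — exactly the structure the stability algorithms assume
(loading cancels in ratio methods; group deltas create the inter-group
deviations NormFinder decomposes). Ground truth defines a gene's planted
stability as $\sqrt{\mathrm{Var}_g(\delta_{ig}) + \sigma_i^2}$ (group sizes
as weights). Each simulation keeps its drawn components, so
`rescale_loading()` can rebuild the same dataset with the loading SD scaled
— turning "loading cancels in delta-Ct and geNorm" into a deterministic
1e−9 assertion instead of a statistical one.

The packaged `benchmark_scenario()` emulates a small polyploid study:
10 genes, four sample groups (shoots and roots at two seedling stages),
3 biological x 3 technical replicates (12 biological units), loading SD
0.15 and technical SD 0.1 cycles. Two genes are planted stable (biological
SD 0.05 cycles); the rest span 0.40–0.80 cycles with tissue shifts of
0.3–0.7 cycles. Those numbers were chosen once: the spread matches the
dispersions typical of candidate RG panels, and the gap between the planted
pair and the third-best gene keeps the planted ordering identifiable at
12 units while $V_2$ stays below the 0.15 rule — i.e. the benchmark has a
recoverable ground truth, which is its purpose. Because 12 units is a small
sample, grouped NormFinder still misses the exact top-2 in a few percent of
seeds; the end-to-end property test therefore aggregates over 20 fixed
seeds rather than asserting one.

What the generator does *not* emulate: amplification-curve artefacts,
primer-dimer effects, PCR inhibition, non-normal outliers, or correlated
regulation between genes. Passing recovery tests on this generator shows
the estimators work under their own model assumptions; it does not certify
behaviour on pathological real-world plates.

A note on the pairwise-variation rule at high noise: $V_2$ compares the
2-gene and 3-gene normalisation factors, and with independent gene noise
$V_2 \approx \sigma_{(3)}/3$, where $\sigma_{(3)}$ is the across-sample SD
of the third-ranked gene. A panel whose third-best candidate has
$\sigma \ge 0.8$ cycles therefore cannot reach $V_2 < 0.15$ no matter how
stable the best pair is — two reference genes only "suffice" by the 0.15
rule when a reasonably stable third candidate exists. The high-noise
recovery scenario in the acceptance suite (all non-planted genes at
$\sigma \ge 0.8$) sits on the wrong side of that bound by construction, and
its $V_2$ values (~0.24) are reported as computed.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 100 seeded recovery scenarios
of 8 genes x 100 samples; 200 seeds of 10 genes x 500 samples for the
estimator-bias contract; 150 instances of 5 genes x 6 samples for the REML
comparison; 20 seeds of the packaged benchmark; 40–60 random 3x3 or 3x4
integer-grid matrices for oracle equality. These sizes give stable
statistics while keeping a full run in the low minutes on one core. All
logs are base 2; ties receive average ranks everywhere; negative variance
estimates are floored at zero; sample SDs use the n−1 denominator; the
geNorm final pair is tie-broken by full-set M then name; Ct bounds,
efficiency windows and the $V$ threshold are arguments, not constants.

## Limitations

Stability scores describe the sampled conditions only — a gene stable
across seedling tissues may be unstable in seeds, which is why sample sets
are first-class objects and results are always per-set. The NormFinder
implementation is a transparent moment estimator, not a reimplementation of
the original software's shrinkage, so its absolute stability values are not
comparable to that program's output (rankings generally are). BestKeeper's
correlation component is reported without p-values. The in-silico PCR is
exact-match by design and does not model thermodynamic binding of
mismatched primers.
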