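---
title: "Evaluating drug repurposing candidates from Mendelian disease comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating drug repurposing candidates from Mendelian disease comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidRx)
```

## The model

Mendelian diseases have well-characterized, druggable causal genes, while
the causal genes of complex diseases are usually uncertain. Health-record
studies show that many Mendelian diseases predispose their carriers to
specific complex diseases, and this comorbidity has been tied to pleiotropic
effects of the Mendelian causal genes. `comorbidRx` operationalizes that
observation as a drug-repurposing recommender and, more importantly, as an
evaluation framework for it.

The recommender is a relational join. Let $M$ be the set of Mendelian
diseases with causal gene sets $G(m)$, $C$ the complex diseases, $K \subseteq
M \times C$ the comorbidity relation, and $T(d)$ the gene-target set of drug
$d$. Drug $d$ is a *candidate* for complex disease $c$ iff

$$\exists\, m : (m, c) \in K \ \wedge\ G(m) \cap T(d) \neq \emptyset,$$

and every such $(m, g)$ pair is retained as provenance. The evaluation asks
whether candidates are enriched among drugs already investigated (registered
trials, grouped to Phase I–III or unknown phase) or indicated (approval
records plus Phase IV trials) for the same disease. Over the full cross
product of the drug universe (drugs targeting at least one Mendelian causal
gene) and the disease registry, we fit

$$\operatorname{logit} P(Y_{dc} = 1) = \beta_0 + \beta_1\,
\mathrm{cand}_{dc} + \gamma_{\mathrm{cat}(c)} + \beta_2\, |T(d)|,$$

reporting $e^{\beta_1}$ with a Wald 95% CI and two-sided p. The covariates
absorb two obvious confounders: disease categories differ hugely in trial
volume (oncology dominates), and promiscuous drugs are both more likely to
hit a Mendelian gene and more likely to be tried for new indications.

## Permutation nulls

The analytic p-value does not address the right null: candidate sets are
produced by a network join, so their size and structure depend on degree
sequences, shared genes, and hub drugs. Two degree-preserving rewirings
target the two halves of the join:

* **Comorbidity rewiring** — each Mendelian disease with $k$ comorbidities
  receives a uniform random $k$-subset of the complex diseases. Everything
  intrinsic to the disease (genes, drug links, comorbidity count) is kept;
  only *which* diseases it points to is randomized. A disease comorbid with
  the entire registry is a fixed point, which is why worlds dominated by
  high-degree Mendelian diseases keep a permuted OR above 1.
* **Drug-target rewiring** — each Mendelian causal gene targeted by $t$
  drugs receives a uniform random $t$-subset of the drug universe, used for
  the per-disease/per-gene prioritization null.

The empirical p is the plain exceedance fraction
$p = \#\{OR^{perm} \ge OR^{obs}\}/n$ (ties count; no $+1$ correction), so
$p = 0$ is reportable and printed as $< 1/n$. Replicates whose refit fails
(separation, single-class candidate flag) are excluded from the denominator
and counted. Under both schemes the pair-table rows, outcomes, and the
`n_targets` covariate stay at observed values — they are intrinsic to drugs
and the clinical record — and only the candidate flag is recomputed.

## Tunable parameters that matter

* `outcome_def` — `investigated_or_indicated` (default), `investigated_only`,
  `indicated_only`, or `phase_k` with the pair's *most advanced* phase, so a
  drug trialled at several phases counts once. Unknown-phase trials count as
  investigation by default (`include_unknown = TRUE`): a registered trial
  without phase metadata is still a trial; a switch excludes them.
* `adjust` — category enters one-hot with the largest category as the
  reference; `n_targets` enters as a raw integer count. Neither choice is
  forced by the science; `log_targets = TRUE` uses `log1p` instead. In a
  single-category table the category term is dropped automatically.
* `weights = "balanced"` — inverse class-frequency weights
  $w = N/(2 N_{class})$, the standard check that class imbalance is not
  driving $\hat\beta_1$; the default is unweighted.
* Perfect separation is reported (sentinel OR of `Inf`/`0`, flagged), never
  silently regularized.
* `n_perm` defaults to 1000 with one master seed; per-replicate seeds are
  drawn once from that seed, so replicates are order-independent and a run
  is exactly reproducible.

## Genetic similarity for cancers

For Mendelian-cancer pairs two metrics are combined; a pair is *similar* if
either is significant at 0.05.

* **Gene overlap** — exact one-sided hypergeometric tail for the overlap of
  the causal gene set with the cancer's driver genes (mutation and
  copy-number derived). The background universe is, by default, the genes of
  the expression matrix after filtering — the sources do not pin down a
  universe, so it is explicit and configurable.
* **Co-expression** — for each driver gene, the Spearman correlation of its
  tissue profile with every other gene is computed, and a one-sided rank-sum
  test asks whether the Mendelian set's correlations dominate the remaining
  genes'. P-values are BH-adjusted across the cancer's drivers and the
  minimum adjusted p is kept. Spearman was chosen because tissue expression
  summaries are strongly right-skewed; Pearson on `log1p` values is an
  option. Genes without complete tissue coverage are dropped at load;
  constant-expression genes are dropped from the comparison; if no Mendelian
  gene has expression data the call rests on overlap alone.

Two numerical notes. First, rank-sum p-values are computed by exhaustive
enumeration of the mid-rank statistic whenever the total sample is at most
12 (ties included) and by the tie-corrected normal approximation otherwise;
this keeps tiny fixtures exact (the minimum achievable p with a 2-gene set
against 10 background genes is $1/\binom{12}{2} = 1/66$). Second, the
combined similarity call is *conservative* under the null: the raw
co-expression p is uniform (the test suite checks this by
Kolmogorov–Smirnov), but taking the minimum of BH-adjusted p-values across
a cancer's drivers — which share the same Mendelian set and background, so
they are positively dependent — rejects well below 5% when nothing is
planted. The false-positive guarantee is therefore an upper bound at the
nominal level, not an equality.

## Prioritizing Mendelian diseases and genes

Each drug-targeted unit (Mendelian disease, or single causal gene) gets its
own enrichment fit: the candidate flag is restricted to the unit's drugs
crossed with its comorbid diseases (a gene inherits the comorbidities of
every disease listing it), on the full pair table with both covariates
retained. Significance is the drug-target permutation p (< 0.05). The
comparison "significant units are targeted by more drugs" uses the one-sided
rank-sum test, and is itself gated by a permutation that rewires all
Mendelian-gene drug links and recomputes the whole selection. Inside that
gate, unit significance uses the one-sided analytic Wald p on both the
observed and permuted sides — a nested inner permutation would be quadratic
in `n_perm`, and the gate only requires that the same selection rule be
applied on both sides. Replicates with no usable significant/non-significant
split contribute the least extreme statistic (rank-sum p of 1) rather than
being dropped.

## What the synthetic generator does and does not emulate

`generate_world()` draws a complete input bundle at the real data's scale by
default (90 Mendelian diseases, 65 complex diseases in six categories with
the observed category skew, ~600 genes, ~800 drugs, comorbidity density
2,908/5,850 ≈ 0.50) and, crucially, computes the candidate flag *through the
pipeline's own join* before drawing outcomes from the logistic model above.
That closes the loop: the planted `beta_candidate` is, by construction, the
estimand of `fit_enrichment()`, so parameter recovery is exact in
expectation. Choices a scientist would recognize:

* targets per drug are zero-truncated geometric (default p = 0.45), giving
  the heavy right tail of real target counts (hub targets reach dozens of
  drugs); causal genes per disease are zero-truncated Poisson (mean 6,
  ~594 genes over 90 diseases in the real registry).
* the baseline log-odds (−2.5) puts the marginal outcome rate near 10%,
  with category shifts (+0.6 neoplasms … −0.6 ophthalmological) mirroring
  the surplus of oncology trials; positive pairs draw a phase from a fixed
  categorical (I: .25, II: .25, III: .15, unknown: .15, indicated: .20)
  skewed toward early phases.
* `generate_expression()` plants one co-expressed module: module genes mix a
  shared latent tissue profile at correlation `module_correlation` with
  independent noise, the planted Mendelian set and one driver gene sit
  inside it, and all other drivers are background.

What it does **not** emulate: vocabulary noise and crosswalk loss (UMLS,
MeSH, RxNORM), drug combinations, correlated comorbidities between related
Mendelian diseases, batch structure in expression, or any dependence of
trial outcomes beyond the fitted covariates. A green test therefore
establishes internal statistical correctness — calibration, recovery,
degree conservation, exactness of the small-sample statistics — not that
the method's biological premise holds in real registries.

## Degenerate inputs and tie-breaks

Duplicate relations deduplicate with a warning; duplicate trial records
collapse to the most advanced phase (unknown ranks below Phase I); Phase IV
records fold into the indication set. Unresolvable identifiers are hard
errors naming the file and id. A complex disease with no comorbid Mendelian
disease yields an empty candidate set, not an error; an empty drug universe
is an error. Rank-sum ties use mid-ranks (exact enumeration small-sample,
tie-corrected variance otherwise); the permutation p counts ties as
exceedances, which is the conservative direction.

## Known limitations

The evaluation treats "in a trial" as a positive label, which conflates
investigation with success; phase stratification mitigates but does not
remove this. The per-unit analyses refit the same outcome vector many
times, so unit p-values are dependent across units; no cross-unit
multiplicity correction is applied (gating is by permutation instead).
The headline odds ratios of the original analyses are reproducible only
with licensed snapshots (DrugBank, AACT, OMIM, HPA, Firehose) and are out
of scope here; the package verifies the machinery on synthetic worlds with
known truth.
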