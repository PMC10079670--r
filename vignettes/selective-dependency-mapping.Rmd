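---
title: "Mapping selective dependencies from pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping selective dependencies from pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsel)
```

`depsel` analyzes genome-scale CRISPR knockout screens for a small
disease group of cell lines against a large reference panel. This
vignette is the package's account of the statistics it implements: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The differential-essentiality model

Screens summarize each (cell line, gene) pair by a *gene effect*
(negative = knockout impairs proliferation) and a *dependency
probability* in [0, 1]. For a panel of $n_1$ group lines and $n_2$
reference lines we model, per gene and per measure,

$$x_{cg} = \mu_g + \delta_g \cdot \mathbb{1}[c \in \text{group}] + \varepsilon_{cg},
\qquad \varepsilon_{cg} \sim N(0, \sigma_g^2),$$

and report $\hat\delta_g$ (the group-minus-reference mean difference)
under the conventional `logFC` label of two-group linear models. A true
log-ratio is undefined for gene-effect scores, which cross zero, so the
coefficient itself is the effect size throughout; a ratio variant is
deliberately not offered as a default anywhere.

With only a handful of group lines, per-gene variance estimates are
unstable, so sample variances $s_g^2$ (pooled within-group, $d$
residual degrees of freedom) are shrunk toward a common prior. The
hierarchical model takes $s_g^2 \mid \sigma_g^2$ as scaled
$\chi^2_d$ and $1/\sigma_g^2$ as scaled $\chi^2_{d_0}$; the
hyperparameters $(d_0, s_0^2)$ are fitted by moment matching on
$\log s_g^2$, using the digamma/trigamma identities for the mean and
variance of a log-$\chi^2$, with the trigamma function inverted by
Newton iteration (`trigamma_inverse()`). The posterior variance and
moderated statistic are

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
t_g = \frac{\hat\delta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}} \sim t_{d_0+d},$$

with two-sided p-values and Benjamini–Hochberg Q-values.

Numerical decisions:

* **No excess dispersion.** When the empirical variance of
  $\log s_g^2$ does not exceed $\psi'(d/2)$ (its expected value under a
  common variance), the prior is degenerate: $d_0 = \infty$,
  $\tilde s_g^2 = s_0^2 = \exp(\overline{\log s^2} - \psi(d/2) + \log(d/2))$,
  and the reference distribution is normal.
* **Zero sample variance.** Genes with $s_g^2 = 0$ receive the
  pure-shrinkage posterior $d_0 s_0^2/(d_0+d)$ rather than an infinite
  statistic.
* **Starved genes.** A gene with fewer than two usable observations in
  either arm (after per-gene missing-value removal) is flagged and
  excluded from moderation; fitting refuses to estimate
  hyperparameters from fewer than 10 usable genes.

The moderated t interpolates between the ordinary pooled two-sample t
($d_0 \to 0$) and a fixed-variance z-like statistic ($d_0 \to \infty$);
both limits are verified numerically in the tests, and the whole path
is checked against an independent from-scratch oracle and against
`limma` as a reference implementation.

## Nomination gates

Selective dependencies are nominated in two stages, each followed by
direction criteria (all thresholds live in `depsel_config()`):

| parameter | default | role |
|---|---|---|
| `stringent_p` | 0.01 | P gate, both measures, stringent stage |
| `stringent_lfc` | 0.5 | absolute mean-difference gate, both measures |
| `relaxed_p` | 0.02 | gene-effect P gate, relaxed stage |
| `relaxed_lfc_effect` | 0.4 | absolute gene-effect difference |
| `relaxed_lfc_prob` | 0.3 | absolute probability difference |
| `prob_cutoff` | 0.5 | mean group probability separating directions |

A group-selective call requires mean group dependency probability above
`prob_cutoff` and a positive probability difference; a
reference-selective call requires the converse. Whether the direction
criteria also apply at the stringent stage was an open design point;
they are applied at both stages by default (`direction_at_stringent`),
since a "selective dependency" that the group is not actually dependent
on is not meaningful at either stringency. Gate monotonicity — loosening
any threshold never removes a nominated gene — is a tested property.

## Networks

Co-essentiality uses Pearson correlation between dependency-probability
profiles across the full panel with pairwise-complete observations
(minimum overlap `min_pair_obs = 3`; the floor is our choice, the
analysis convention gives none). Edges require r ≥ `coess_threshold`
(0.18) — the comparison is **inclusive**, and likewise for the
interaction-confidence filter at ≥ 0.4. Connected components and
singletons are reported separately, and genes that lose all edges stay
in the graph as isolated nodes, so no nominated gene silently
disappears from the output.

## Biomarker scans

For each dependency gene the gene-effect profile is correlated with
every feature of one kind (expression log₂(TPM+1), gene-level copy
number, or 0/1 mutation indicators, optionally per variant class), plus
a univariate OLS fit per pair (slope test, $n-2$ df). Constant features
yield records with a missing `r` and a reason code rather than errors,
so genome-wide scans complete. Copy-number and expression correlates
are conventionally ranked by decreasing r, mutation correlates by
increasing r; the pipeline ranks a planted biomarker's list in the
direction of its planted association. No multiple-testing correction is
applied to the scan — it produces ranked correlate lists, not
significance calls. A perfect fit reports the smallest representable
positive p-value, never zero.

## Copy-number neighborhood scan

Copy-number correlates of a dependency often reflect a co-amplified or
co-deleted segment rather than one causal gene. The scan asks, for
window spans $w \in \{5{\times}10^5, \ldots, 5{\times}10^6\}$ bp (step
$5{\times}10^5$): is the correlate ranking enriched for genes whose
midpoints lie within the centered span $[m - w/2,\, m + w/2]$ around
the anchor midpoint $m$? Geometry decisions (the convention is not
fixed anywhere): $w$ is the **total** width so the printed grid keeps
its scale; membership is by gene midpoint (no double counting of
boundary-straddling genes); bounds are inclusive; and the anchor is a
member of its own window (it is typically the top correlate) — the last
two are config-reversible (`inclusive_bounds`, `include_anchor`).
Member sets are nested in $w$ by construction, a tested invariant.

Each window's member set is scored by pre-ranked permutation GSEA
against the correlate ranking; "maximum enrichment" means the smallest
permutation p (not the largest raw ES, which favors tiny sets), with
ties broken by larger |ES| and then by smaller span.

## Enrichment statistics

The pre-ranked enrichment score is the classic weighted running sum:
hits add $|m_i|^w / \sum_{\text{hits}} |m|^w$ (weight $w = 1$ by
default; equal increments if all hit metrics are zero), misses subtract
$1/(N - n_\text{hits})$, and ES is the signed maximal deviation. An
exact rational tie between the positive and negative extremum is
resolved toward the positive one, with a $10^{-12}$ tolerance so
floating-point noise cannot flip it. The implementation is verified
against exhaustive prefix enumeration over *all* subsets of small
rankings and against `fgsea` on random instances.

The permutation null draws random same-size gene sets from the ranking
(gene-label permutation — the appropriate null for a pre-ranked
analysis; no sample permutation is offered). The p-value is two-sided
on magnitude over all permutations,
$p = (1 + \#\{|ES^0| \ge |ES|\})/(1 + n_\text{perm})$, which is exactly
uniform under the null by exchangeability and honors the
$1/(n_\text{perm}+1)$ floor; the normalized score divides ES by the
mean |null ES| of matching sign (missing when fewer than 3 sign-matched
nulls exist). Identical seeds give bit-identical results; each gene set
gets its own named substream so results do not depend on evaluation
order.

Network list enrichment counts edges with one endpoint in the list and
the other in the gene set (each edge once) and compares against random
lists drawn stratified by degree (exact-degree strata when there are at
most 10 distinct degrees, merged degree-quantile bins otherwise, so
equal-degree nodes are never split across strata). This is a
deliberately simplified statistic whose contract is calibration —
near-uniform p under the null, a tested property — not numerical
identity with any published network-enrichment tool.

The list-size-normalized AUC summarizes adjusted enrichment p-values
over top-list sizes $g = 1..G$ ($G = 200$):
$\mathrm{AUC} = \frac{1}{G\,p_{\min}} \sum_g \min(-\log_{10} p_{\text{adj}}(g),\, p_{\min})$,
with $p_{\min} = 52$ the saturation constant at which an exact zero is
clipped. The integral is discretized as a unit-step sum over integer
$g$ (the natural reading for integer list sizes); missing grid values
are an error, never interpolated. Endpoints are forced by the formula:
AUC is 0, 1, and 0.5 for $p_{\text{adj}} \equiv 1$, $\equiv 0$, and
$\equiv 10^{-26}$.

## ZMAD signature scoring

Per gene, across all cell lines: center = median, scale = **mean**
absolute deviation about the median (the literal reading of the
procedure's description — "mean absolute deviation modified z-scores"),
computed on raw TPM with no pseudocount or log transform. Because the
ZMAD acronym is conventionally median-based, `median_abs_dev` is
available as a config option, unscaled (no 1.4826 consistency constant
— none is stated anywhere, so none is applied). Zero-scale genes carry
no information and are dropped with an exclusion log. The signature
score is the per-line mean ZMAD over present signature genes; the
packaged 38-gene ISG core signature reads the printed gene list with
the typographically garbled entry resolved to *SP110*. Lineage ranking
drops unannotated lines, single-line lineages and the "Engineered"
label, requires ≥ 2 lines per retained lineage, and breaks median ties
by lineage name for determinism.

## The synthetic panel

The generator (`simulate_panel()`) encodes the study-scale conditions
as its defaults: 500 reference + 4 group lines and 1000 genes, with 50
commonly essential, 20 group-selective and 10 reference-selective genes
planted at mean effect −1.0 over per-observation noise sd 0.2. The
signal-to-noise of a planted selective gene
($|\delta|/\sigma \cdot (1/n_1 + 1/n_2)^{-1/2} \approx 10$) mirrors the
strong, near-binary separation real selective dependencies show between
a dependent group and a non-dependent panel. Further planted structure:

* **Probability map:** $p = 1/(1 + e^{k(x - x_0)})$ with $k = 6$,
  $x_0 = -0.5$, independent $N(0, 0.02)$ noise, clipped to [0, 1] —
  only monotonicity and range are contractual, not any specific
  probability model.
* **Genome:** five 20-Mb chromosomes, gene midpoints every 100 kb.
  Background copy number is AR(1) along each chromosome (correlation
  length 10 genes, marginal sd 0.3 around 2), giving the spatial
  autocorrelation the window scan exploits.
* **Paralog-loss biomarker:** a 5-gene block centered on a "partner"
  gene shares a per-line segment deviation (sd 0.5); one dependency's
  effect tracks the partner's copy number with slope 0.75, so low
  partner copy number means stronger dependency. The block is compact
  enough that every window on the default grid covers it — the scan's
  job on this panel is to find the neighborhood, not to discriminate
  grid points.
* **Mutation biomarker:** one binary feature at 30% frequency abolishes
  a dependency (effect −1 → 0) in carrier lines, over 40 background
  features at 5% frequency.
* **ISG elevation:** group lines' TPM on the 38 signature genes is
  multiplied by $2^2 = 4$ — a chronic-interferon-scale induction —
  against log-normal baseline expression; reference lines carry 20
  round-robin lineage labels plus deliberate exclusion-rule bait (two
  "Engineered" lines, one single-line lineage).

All draws flow from one seed through named substreams
(`substream_seed()`), so two panels with the same seed serialize
byte-identically and adding a component never perturbs the others.

What the generator does **not** emulate: copy-number artifacts of
CRISPR cutting, screen quality variation, batch structure, correlated
gene modules beyond the planted ones, missing-value patterns of real
releases (missingness is off by default), or realistic mutation
spectra. Passing recovery tests therefore demonstrates that the
pipeline's statistics detect the structures they target at realistic
effect sizes and panel geometry — not that real-data preprocessing
issues are handled.

## Problem sizes and runtime

The test suite and the acceptance script run the default 504 × 1000
panel with 1000-permutation nulls, 500-replicate regression-null
calibration, 200 × 1000-permutation GSEA calibration, and exhaustive
ES enumeration over all subsets of 10-gene rankings — sizes chosen so
the full suite completes in about a minute while leaving the
permutation floors ($1/1001$) fine enough to resolve the planted
signals.

## Known limitations

* Single-factor two-group design only: no covariates, batch terms or
  weighted fits.
* The network-enrichment null is calibrated but simplified; it is not
  numerically comparable to published network-enrichment tools.
* The co-essentiality threshold (0.18) is taken as given, not derived
  from a null model of profile correlations.
* Full-scale reproduction of a real screening release requires the
  corresponding score matrices as local files; the package never
  downloads data.
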