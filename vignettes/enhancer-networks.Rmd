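---
title: "Tracing enhancer networks from DNA methylation and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing enhancer networks from DNA methylation and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenet)
```

## The model

Distal enhancers regulate gene expression from outside promoter regions,
and the enhancer state most tied to cell identity is the *active* state.
DNA methylation is a practical readout of that state in tissue samples:
an unmethylated enhancer corresponds to open chromatin that transcription
factors (TFs) can bind, a methylated enhancer to closed chromatin. This
package infers tumor-specific changes in enhancer activity from an array
beta-value matrix (methylation fraction per CpG probe, in [0, 1]) and
links those changes to gene expression, without requiring ChIP-seq or
chromatin accessibility assays on the tissue itself.

The workflow has five stages.

**1. Analysis universe (`build_universe()`).** Enhancer catalogs (BED) are
pooled and merged, restricted to *distal* elements — strictly more than
`min_dist = 1500` bases from any annotated TSS — and narrowed to their
open-chromatin subregions by base-pair intersection with peak sets
(DNase/FAIRE/NOMe-style). Array probes whose interrogated base falls in a
narrowed region form the *enhancer-probe universe*. All coordinates are
internally 0-based, half-open (BED semantics); probe manifests and TSS
tables, which are conventionally 1-based, are converted at read time. The
distal filter is strand-agnostic and measures to the TSS base itself; the
probe-level filter is applied in addition to the interval-level filter so
the guarantee holds per probe. The peak set is merged before
intersection, which makes narrowing idempotent.

**2. Classification (`classify_all()`).** Per probe, beta means are taken
over tumor, normal, and control (contamination-profile, e.g. leukocyte)
samples. With thresholds `unmeth_cut` (u) and `meth_cut` (m):

* `always_unmeth`: tumor < u and normal < u (active in both);
* `always_meth`: tumor > m and normal > m (inactive in both);
* `hyper`: normal < u and tumor > m — a *normal-specific* enhancer lost
  in tumors; vetoed if the control mean is also > m;
* `hypo`: normal > m and tumor < u — a *tumor-specific* enhancer gained
  in tumors; vetoed if the control mean is also < u;
* `unclassified` otherwise, including any probe with fewer than
  `min_nonmissing` observed samples in a group.

The control veto is the purity guard: bulk tumor tissue is a mixture of
tumor and normal/immune cells, so a probe that already looks tumor-like
in leukocytes may reflect contamination rather than tumor biology, and is
discarded. The veto is a pure disqualifier — with no control samples the
rule reduces to the unguarded classification. Defaults u = 0.3, m = 0.7
are the conventional beta cutpoints for clearly unmethylated/methylated
CpGs; the published cutoffs for this design are not in the main
literature text, so they are exposed as parameters.

**3–4. Link calling (`call_links()`).** For every differential (hypo or
hyper) probe and every gene, tumors are split on the probe's beta into
enhancer-*active* (beta < `active_cut`) and enhancer-*inactive*
(beta > `inactive_cut`) groups; intermediate samples are excluded, both
inequalities strict. Three statistics compare the gene's expression
between the groups:

* the Welch z statistic
  $z = (\bar x_a - \bar x_i)/\sqrt{s_a^2/n_a + s_i^2/n_i}$;
* an empirical p value from `n_perm` label permutations preserving group
  sizes, with the add-one rule
  $p = (1 + \#\{|z_\pi| \ge |z|\})/(1 + n_\mathrm{perm})$ (degenerate
  permutations count as $|z_\pi| = 0$);
* the two-sided Wilcoxon rank-sum p (exact enumeration when the two
  sides hold at most 12 tie-free values, else the normal approximation
  with tie and continuity correction).

Benjamini–Hochberg adjustment is applied globally across all tested
pairs. The default combination rule requires a link to pass BH at level
`alpha` on **both** the empirical and the Wilcoxon p value — the
permutation p is the primary statistic and the rank-sum acts as a
belt-and-braces guard against heavy-tailed expression; `method = "emp"`
or `"wilcoxon"` select a single statistic. Direction is the sign of z
(`+`: expression higher when the enhancer is active), and the category
pairs the probe class with the direction: hypo probes give
tumor-specific enhancer links `ET_Gplus`/`ET_Gminus`, hyper probes
normal-specific `EN_Gplus`/`EN_Gminus`. Links are annotated with the
distance from the probe to the gene's nearest TSS on the same
chromosome; `within_1mb` uses an inclusive 1 Mb cutoff.

Two choices here were genuinely open and are this package's decisions:
the z statistic is the Welch (unequal-variance) form, and the groups
compare *tumor versus tumor* (active vs inactive tumors) rather than
tumor versus normal. The tumor-vs-tumor contrast is what powers subgroup
analysis — a tumor-specific enhancer is typically active in only a
subset of tumors — and normals still enter through classification.

**5. Network summaries.** `count_links_per_gene()` ranks genes by the
number of *distinct* enhancer probes linked to them in a category; genes
linked to unusually many enhancers are candidate driver TFs (the
interpretation being that the TF's expression drives occupancy and
hypomethylation at its binding sites). `link_state_per_sample()` encodes,
per link and tumor, whether the enhancer is active in that sample (beta
< `active_cut`; missing beta counts as inactive — a deliberately
conservative convention, since an unobserved probe should not assert
enhancer activity). `binary_ward_cluster()` clusters the binary state
matrix with the asymmetric binary distance (discordant positions over
positions where at least one row is 1; an all-zero pair is assigned
distance 0, where `stats::dist` leaves `NaN`) and Ward linkage. We name
`ward.D2` as the variant because reproducibility requires committing to
one. `peak_overlap_enrichment()` tests whether TF ChIP peaks fall within
±100 bp (inclusive at both ends) of the probes of one set more often
than another, with the two-sided Fisher exact test and BH adjustment
across set pairs. `distance_summary()` bins same-chromosome link
distances into log-spaced bins (10 kb to 100 Mb, half-decade steps).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_dist` | 1500 bp | distal boundary, strict |
| `unmeth_cut` / `meth_cut` | 0.3 / 0.7 | beta thresholds for group means |
| `min_nonmissing` | 5 | per-group observation veto (clamped to group size) |
| `active_cut` / `inactive_cut` | 0.3 / 0.7 | per-sample enhancer state |
| `min_group` | 5 | minimum tumors per side of a link test |
| `n_perm` | 1000 | permutation resolution |
| `alpha` | 0.05 | BH FDR level |

One numerical point deserves emphasis: the smallest attainable empirical
p is $1/(n_\mathrm{perm}+1)$, and under BH a p value only survives if it
falls below $\alpha k/m$ where $m$ is the number of tested pairs and $k$
the number of discoveries. Genome-wide runs test tens of thousands of
pairs, so if only a few hundred links are real, `n_perm = 1000` cannot
resolve them — the floor sits above the BH threshold and *nothing* is
called. Choose `n_perm` so that $1/(n_\mathrm{perm}+1) \ll \alpha k/m$
for the discovery count you expect; the hub-recovery test in this
package runs at `n_perm = 4000` for exactly this reason.

## The synthetic cohort generator

`simulate_genome()` and `simulate_cohort()` produce data with the
statistical structure the pipeline assumes, plus ground truth for every
stage. The generator's world:

* Genes are laid out in 24 kb blocks, one enhancer (2 kb, with a 1.2 kb
  open-chromatin core) per block at more than 8 kb from every TSS; probes
  sit inside the cores. A decoy probe set (10% by default) is placed
  about 500 bp from TSSs inside promoter-proximal intervals, so the
  distal filter has real work to do.
* Non-decoy probes are partitioned into planted classes (defaults:
  25% hypo, 20% hyper, 25% always-unmethylated, 20% always-methylated,
  10% intermediate). Beta values are drawn from beta distributions with
  concentration `beta_noise = 30` (per-sample sd ≈ 0.05, matching the
  tight marginals of array betas) around class targets 0.1 / 0.85 / 0.5.
  Tumor betas are mixed with the probe's contamination-profile mean as
  $\beta_{obs} = (1-m)\,\beta + m\,\beta_{ctrl}$ with
  `purity_mix = 0.1`, the standard linear contamination approximation at
  a typical bulk-tissue contamination level.
* A driven tumor subgroup of fraction `driver_penetrance` (default 0.5)
  carries the tumor-specific signal: each of `n_tf_drivers = 5` driver
  TFs owns `targets_per_tf = 20` hypo probes and target genes. Within
  the subgroup a target probe is active per sample with probability
  `activity_rate` (default 1 — deterministically active, the plain
  reading of a subgroup-specific enhancer). Expression is Gaussian with
  unit sd on the log2 scale around gene-specific baselines drawn from
  U(4, 12); a target gene is shifted by `effect_size` sd (default 2)
  in samples where its own probe is active, negated for a
  `frac_negative = 0.2` repressed fraction, and each driver's expression
  tracks the standardized count of its active targets. The cohort
  defaults (100 tumors, 20 normals, 20 controls, 500 probes, 300 genes)
  are a deliberately desk-scale rendition of array cohorts that run to
  hundreds of tumors.
* The ground truth lists every (probe, gene) pair that is dependent *by
  construction*: `direct` pairs (probe with its own gene), `driver`
  pairs (probe with its driver TF), and — when `activity_rate = 1` and
  the subgroup is a strict subset — `shared_subgroup` pairs: in that
  regime every driven probe's state equals the subgroup indicator, so
  every driven probe is genuinely associated with every shifted gene,
  and an evaluation that ignored these pairs would mislabel true
  associations as false discoveries.

What the generator does **not** emulate: genomic sequence, copy number,
batch effects, probe cross-reactivity, expression count noise
(expression is Gaussian on the log scale, not negative binomial), or
correlated methylation between neighboring probes. A green test
establishes that the pipeline recovers the planted dependence structure
under its own assumptions — not that those assumptions hold on any
particular real cohort.

## A validation subtlety: classification of subgroup-specific probes

With `driver_penetrance = 0.5`, a planted hypo probe is unmethylated in
half the tumors (beta ≈ 0.17 after contamination) and methylated in the
rest (≈ 0.85), so its *mean* tumor beta sits near 0.51. The default
`unmeth_cut = 0.3` can never classify such a probe as hypo — that is
arithmetic, not a tuning observation. End-to-end validation on
subgroup cohorts therefore classifies with `unmeth_cut = 0.6,
meth_cut = 0.7`, placing the tumor-side cut above the mixture mean with
margin while keeping the normal side (0.85) above `meth_cut`. On real
cohorts the analogous decision — how deep into the tumor set a
subgroup-specific enhancer may reach and still be called — is exactly
what these two parameters express, which is why they are parameters.

## Numerical and degenerate-input choices

* Welch z with zero variance on both sides: 0 for equal means, a
  ±Inf sentinel (flagged `degenerate`) for unequal means; degenerate
  *permutations* count as $|z_\pi| = 0$, which is conservative.
* Permutation tie counting uses a relative tolerance of `1e-8` when
  comparing $|z_\pi|$ to $|z|$, so a permutation that reproduces the
  observed split cannot be lost to floating-point noise; the add-one
  rule keeps p strictly positive either way.
* Empty active or inactive sides are returned empty, not errors; pairs
  with fewer than `min_group` on a side are skipped and counted.
* Genes with all-zero expression are dropped before testing.
* `stats::dist(method = "binary")` returns `NaN` for a pair of all-zero
  rows; the clustering wrapper defines that distance as 0 (two samples
  with no active links are maximally similar, not incomparable).
* All randomness flows from explicit seeds; per-probe permutation seeds
  are derived deterministically from `link_params(seed)`, so runs are
  byte-identical given the same configuration.

## Known limitations

* Associations are correlational; the package deliberately makes no
  direct-target claims and does not integrate chromatin looping data.
* The three-statistic combination rule and the Welch tumor-vs-tumor
  contrast are this package's choices among defensible variants; both
  are configurable and recorded here rather than hidden.
* The classification operates on group means; strongly bimodal probes
  (small subgroups) need the threshold adjustment discussed above, or a
  quantile-based rule, which is not implemented.
* `wilcoxon_p()` switches from exact enumeration to the normal
  approximation above 12 observations; at the switch point the two
  differ by up to about 0.02 in p, which is immaterial at genome-wide
  FDR thresholds but visible if you compare single pairs.
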