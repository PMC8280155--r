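---
title: "Methods: network-centric screening for FOXM1-pathway inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-centric screening for FOXM1-pathway inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxnet)
```

## The screening model

The package implements a connectivity-map style screen: a compound is a
candidate inhibitor of a transcription-factor pathway when its
differential-expression signature resembles the signature of genetically
disrupting that pathway. Signatures are per-gene z-scores of one perturbation
versus controls in one cell line, in the style of the LINCS L1000 compendium.
Because no FOXM1 knockdown exists in that compendium, the screen scores
compounds against knockdown of *NPM1* — a partner protein FOXM1 depends on —
and, by guilt-by-association, against knockdowns of other members of the same
interaction neighborhood: chemical disruption anywhere in a subnetwork should
produce expression changes resembling the knockdown of its members.

For compound $c$ and cell line $\ell$ where both profiles exist,
`build_screen_features()` computes

* $d_{c\ell} = \rho(z_c, z_{\mathrm{proxy\,KD}})$, the direct Spearman
  correlation with the proxy knockdown, and
* the best and mean of $\rho(z_c, z_{p})$ over available partner knockdowns
  $p$.

Cell lines missing a knockdown profile are skipped, never zero-filled — a
sparsely profiled compound should be limited by the support rule below, not
additionally penalized inside its averages.

**Support rule.** A cell line supports a compound when
$d_{c\ell} \ge$ `support_threshold` (default 0.3). A compound qualifies only
with support in at least `min_support` = 4 cell lines. The four-line minimum
is the published screening rule; the 0.3 correlation cutoff is not published
and is exposed as a flag (0.3 Spearman is far outside the null spread at
~978 genes, where the null SD is about $1/\sqrt{977} \approx 0.032$).

**Ranking.** The default score is deterministic:
$\mathrm{mean}_{\ell\,\in\,\mathrm{supported}}
\left(d_{c\ell} + \lambda\,\max_p \rho(z_c, z_p)\right)$ with
$\lambda = 0.5$. The original screen used a random-forest classifier trained
on FDA-approved drugs; its features and labels live in cited prior work and
are not reconstructable, so the classifier is an opt-in contract instead:
`rank_candidates(training = ...)` fits a ridge-regularized logistic model on
the flattened per-cell-line feature vectors and ranks by predicted
probability (no decision-tree ensemble is available in the supported
dependency set, and any probabilistic binary classifier over the same feature
vector satisfies the contract). Unqualified compounds always rank below
qualified ones, with `-Inf` scores and lexicographic tie-breaks for a stable
order. The max (not mean) partner correlation feeds the score because a
single strong partner match *is* the association signal; the mean is also
reported for inspection.

## Consensus signatures

Replicates of one perturbation in one cell line are aggregated by a
MODZ-style weighted average, the LINCS convention: replicate $i$ receives
weight $w_i \propto \max(0.01, \sum_{j \ne i} \rho(z_i, z_j))$, normalized to
sum to one, with Spearman correlation by default. Discordant replicates are
thus down-weighted; two replicates always get weights ½/½; a single replicate
is returned unchanged. Plain `median` and `mean` are selectable — the
published consensus table does not state its aggregation rule, so the
packaged copy of that table is treated as fixture input (a single "replicate"
per column, for which every rule is the identity), never as a recomputation
target. The floor of 0.01 keeps weights positive when a replicate
anti-correlates with all others; correlations default to Spearman because
z-score signatures are heavy-tailed.

Panel tables (`panel_consensus_table()`) apply the same consensus across all
signatures of a perturbation and then restrict to the panel genes; MODZ
weights are computed on the full gene universe, where they are stable, not on
the eight-gene panel. Candidate comparison orders by *universality* (panel
genes with consensus $z \le -1$; the threshold is a package default, exposed
as a flag) and then *potency* (mean panel z, ascending).

## Codirectional DE signatures

`filter_de()` applies the published thresholds: fold change
$2^{\mathrm{log_2FC}} \ge 2$ (inclusive — "2-fold or higher") or
$\le 0.5$, with FDR strictly below 0.1 ("q-value < 0.1"). Both boundary
conventions follow the published phrasings and both thresholds are arguments.
When no FDR column is supplied it is computed by the package's own
Benjamini–Hochberg step-up
($q_i = \min_{j:\,p_{(j)} \ge p_{(i)}} p_{(j)} n/j$, capped at 1); when a
supplied column disagrees with the recomputation by more than $10^{-6}$ the
supplied column wins with a warning, because upstream pipelines (edgeR) may
have corrected over a different universe and refitting them is out of scope.
Biotype filtering (e.g. `protein_coding`) precedes thresholding, mirroring
the exclusion of non-coding genes; whether the published 16 275-gene universe
additionally reflects an expression floor is not stated, so no floor is
applied by default. Gene identity is exact string equality — no symbol
conversion.

`codirectional_intersection()` keeps genes significant in the *same*
direction in both cell models as the reliable responders (the combined
signature), and reports opposite-sign genes as discordant. The accounting
identity — both-significant = shared-up + shared-down + discordant — holds by
construction and is property-tested.

## Preranked enrichment

`gsea_preranked()` is the classical weighted Kolmogorov–Smirnov procedure:
walking down the ranked list, hits add $|r|^w / \sum_{hits}|r|^w$ (weight
exponent $w = 1$ by default; $w = 0$ reduces to the unweighted KS statistic,
which the tests verify against a brute-force oracle) and misses subtract
$1/(N - N_{hit})$; the enrichment score is the running sum's signed maximum
deviation. Exact magnitude ties between the positive and negative extremum
resolve positive, and ranking-value ties order by gene id, so results are
deterministic. The null distribution comes from gene-label permutation — the
only permutation scheme available for preranked input — with 1000 rounds by
default (the published setting). NES divides each ES by the mean magnitude of
its set's same-sign null scores; the nominal p is the same-sign null tail
fraction with a +1 continuity correction (never exactly zero); the FDR
q-value is the canonical pooled-null ratio over all sets, capped at 1.

The ranking metric fed to the published analysis is not stated (the inputs
carried log2 fold change, p and q); the package defaults to log2 fold change
with signed $-\log_{10} p$ selectable, claiming neither as the original
choice. Set-size bounds default to 15–500, the field's convention. Pathway
collections (e.g. PID) are user-supplied GMT files; none are bundled, for
licensing reasons.

## Colocalization

`manders_coefficients()` uses constant strictly-greater-than thresholds on
the 8-bit scale, set once per experiment (`coloc_batch()` enforces this by
construction). Two coefficient families are computed because "Manders'
overlap coefficient" is ambiguous between them in the common tooling:
thresholded M1/M2 (fraction of one channel's supra-threshold intensity lying
on the other channel's positive pixels) and the intensity-weighted overlap
coefficient $\sum GR / \sqrt{\sum G^2 \sum R^2}$ over the union support.
Pixels below both thresholds — including both-zero background — never enter
the support, avoiding background inflation. A coefficient whose denominator
mask holds fewer than 10 pixels is reported `NA` ("not applicable due to very
low signal"; the published table states no cutoff, 10 is a documented package
default). Group comparison uses the exact Mann–Whitney test below, matching
the 12-cells-per-condition design. The published per-condition coefficient
values depend on unstated thresholds and coefficient variant and are
therefore not recomputation targets.

## Exact Mann–Whitney and Pfaffl

The two-tailed Mann–Whitney p doubles the smaller one-sided tail (capped at
1) — the convention that reproduces the published exact p = 0.02857 for two
fully separated groups of four ($2/\binom{8}{4} = 2/70$). The alternative
"min-likelihood" two-tailed rule (sum of all outcomes no likelier than the
observed one) is selectable. The exact null distribution is built by
dynamic programming over the observed doubled midranks, which handles ties
(0.5 rank credit) without approximation, up to $n + m = 25$ — comfortably
covering the 12 + 12 imaging design; beyond that a tie-corrected,
continuity-corrected normal approximation is used and flagged inexact.

Pfaffl relative quantification is the closed form
$E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with efficiencies in fold per cycle
(1.95–2.05 corresponds to the 95–105 % the assays were validated to; percent
input is auto-detected by magnitude and logged). How the original analysis
combined its two reference transcripts is not stated; the package defaults to
the geometric mean of per-reference ratios — the standard multi-reference
normalization — with per-reference output selectable.

## What the synthetic generators state

The generators are a stated world, not a tuning dial; their defaults are the
conditions of the study they emulate.

* `simulate_screen()`: 978 landmark-like genes; the seven cell lines of the
  real screen; a proxy knockdown, five partner knockdowns, one planted
  compound and 49 noise decoys per line; three replicates per perturbation.
  The planted compound's latent signature is
  $\alpha z_{KD} + \sqrt{1-\alpha^2}\,\varepsilon$ (default $\alpha = 0.7$),
  so its marginal stays standard normal and its expected correlation with the
  knockdown is $\alpha$. Partner knockdowns use the same mixing with weight
  0.5 — a realistic within-subnetwork transcriptional similarity, chosen once
  (nothing in the source states it). Replicates carry fraction 0.8 of the
  latent variance. Noise is i.i.d. standard normal per gene: gene–gene
  correlation structure, batch effects and dose–response are *not* emulated,
  so a green recovery test establishes that the scoring recovers a planted
  correlation structure, not that it would survive L1000 covariance.
* `simulate_de_tables()`: a 16 275-gene protein-coding universe with planted
  shared-up/shared-down/discordant counts (defaults 577/687/77, the published
  accounting), 250 model-specific significant genes per model (a margin the
  publication does not print), planted log2 fold changes of ±2 with SD 0.05
  jitter (tight, so threshold crossings are unambiguous), planted p-values
  uniform on $(0, 10^{-4})$, null fold changes N(0, 0.2). The round trip
  through `filter_de()` + `codirectional_intersection()` recovers the planted
  counts exactly; this validates the thresholding and set algebra, not any
  count-model realism (no dispersion, no mean–variance relationship).
* `simulate_ranked_list()`: plants a 30-gene set uniformly within the top (or
  bottom) 10 % of a 2000-gene list; bottom placement yields the negative
  enrichment scores characteristic of pathway suppression.
* `simulate_coloc_images()`: disk-shaped red puncta, a green channel whose
  supra-threshold intensity is split between red-positive and red-free pixels
  in exactly the planted proportion (granularity 1/200 at the default 200
  green pixels), a nuclear ellipse, optional Gaussian intensity noise. Real
  point-spread blur, autofluorescence and segmentation error are not
  emulated.

All generators are bit-reproducible under a fixed seed; every downstream
recovery test consumes only generator outputs plus their truth records.

## Pipeline and numerical conventions

`run_pipeline()` executes config-selected stages (screen, panel, de, gsea) in
order, seeds every stochastic step from the single config seed, and emits a
report that is identical across reruns except for its timestamp. Configs are
YAML or JSON validated against an explicit schema; unknown keys and missing
input paths are reported by name. The published thresholds ("2-fold",
"FDR < 0.1", four-line support, 1000 permutations, enrichment FDR < 0.05)
are the defaults of the corresponding named keys.

Other conventions, in one place: similarity requires at least 3 shared genes
and drops (never imputes) unshared ones; `top_n` restriction applies to the
first signature's largest |z| genes and intentionally breaks symmetry;
Spearman uses average ranks for ties; RNG state is saved and restored around
every seeded computation, so package calls do not perturb the caller's
random stream; test-suite simulation scales are reduced from the stated
defaults where noted purely for runtime, with seeds fixed.

## Known limitations

* The real 264-compound LINCS hit list is not reproduced: it depends on the
  full external compendium, a proprietary partner list, and a classifier
  described only by citation.
* Signature realism is limited as described above; recovery results transfer
  to real L1000 data only to the extent the correlation structure does.
* TIFF input is not supported (no TIFF reader in the dependency set); PNG
  carries the same 8-bit channels losslessly, and all analysis operates on
  in-memory arrays.
* No gene-identifier conversion: inputs must share an id space.
* Cell segmentation is out of scope; one image (or user-delimited region) is
  one cell, matching the original per-cell analysis design.
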