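---
title: "Literature-scale enrichment of systemically variable methylation regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-scale enrichment of systemically variable methylation regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsivlit)
```

## The question

Epigenome-wide association studies (EWAS) overwhelmingly use the Illumina
HM450/EPIC arrays, whose probes mostly target CpG sites with negligible
interindividual variation. CoRSIVs — correlated regions of systemic
interindividual variation — are the opposite: methylation there differs
between people, is consistent across tissues within a person, and is stable
over time. If interindividual variation is what lets a probe associate with
disease, probes that happen to fall inside CoRSIVs should be reported in the
EWAS literature far more often than comparable probes elsewhere.

`corsivlit` implements that test as a reusable pipeline: mine probe IDs from
a corpus of papers grouped by MeSH disease category, tabulate how many
papers report each probe, compare CoRSIV probes against matched control
regions with a publication-weighted ratio, and calibrate it with a
permutation null. Sensitivity modules quantify *why* the enrichment arises
(test-retest stability, interindividual range, blood–brain concordance) and
what the reported probes map to (gene-set over-representation).

## The enrichment statistic

For a disease category, let the *incidence* of a probe be the number of
distinct papers in that category reporting it (a probe counts at most once
per paper). The occurrence spectrum tabulates, for each paper count
$i \ge 1$:

* $p_i$ — probes reported in exactly $i$ papers,
* $n_i$ — CoRSIV probes reported in exactly $i$ papers,
* $m_i$ — control probes reported in exactly $i$ papers, pooled over the
  $S$ control sets.

The truncation level $k$ is the highest $i$ at which at least 10 probes are
reported ($k = \max\{i : p_i \ge 10\}$), so the weighted sums never rest on
a handful of extreme probes. The enrichment ratio is

$$
\mathrm{ER} \;=\;
\frac{\sum_{i=1}^{k} i \, n_i / p_i}
     {\sum_{i=1}^{k} i \, (m_i / S) / p_i},
$$

the ratio of the weighted sum of CoRSIV-probe occurrences to the
set-averaged weighted sum of control-probe occurrences, with weights based
on the number of publications. Levels with $p_i = 0$ are skipped; a zero
denominator with a non-zero numerator is reported as $+\infty$ with a
warning. A sensitivity variant (`weights = "occurrence"`) drops the $1/p_i$
normalisation and computes $\sum i\,n_i / \sum i\,m_i/S$; and a
`contiguous = TRUE` variant of the $k$ rule requires every level up to $k$
to hold 10 probes rather than taking the literal maximum. The defaults are
the primary reading; both alternatives are kept because the verbal
definition admits either.

```{r ratio-example}
inc <- as_incidence(
  tibble::tibble(probe_id = sprintf("cg%08d", 1:3),
                 n_papers_reporting = c(1L, 1L, 2L)),
  term = "demo", n_papers = 4)
build_spectrum(inc, corsiv_probes = "cg00000003",
               control_sets = list("cg00000001"))
```

### Matched control regions

The full array is the wrong background: CoRSIVs are CpG-dense, so their
probes cluster in ways ordinary probes do not. Instead, each
Illumina-covered CoRSIV is matched — within each of `n_sets` control sets —
to a control region on the same chromosome with *exactly* the same number
of overlapping probes and approximately the same length. Exact probe-count
matching is the only reading consistent with the bookkeeping identity the
pipeline enforces on every successful run:

* control regions = `n_sets` × covered CoRSIVs,
* control probes = `n_sets` × CoRSIV probes.

Candidates are windows of `q` consecutive non-CoRSIV probes whose span
keeps at least `exclusion_buffer` bp (default 1,000) from every CoRSIV.
Assignment is greedy in a seeded random order of CoRSIVs, repeated per set,
without replacement across sets: the nearest-length candidate wins, with
ties broken by genomic distance to the CoRSIV and then lexicographic region
id, so the selection is a total order — deterministic for a given seed and
invariant to candidate input order. Selected regions never overlap one
another. `length_tolerance` (default 0.5) is a soft preference: candidates
within the tolerance are preferred, and only if none exists does the
nearest length win outright. A greedy rule was chosen over optimal
bipartite assignment for transparency and determinism; matching is on
chromosome, probe count and length, with CpG density deliberately not
matched by default (the probe-count criterion already constrains local
probe density).

One practical constraint follows from the identities: `n_sets` × (CoRSIV
probes) disjoint background windows must exist. On compact synthetic maps
(e.g. 5,000 probes with 200 CoRSIVs, ~450 CoRSIV probes, ~4,550 background
probes) ten disjoint sets cannot fit; the worked minimal-corpus examples
therefore use 5 sets, while 10 — the analysis design default — is used on
maps with a comfortable background budget (the calibration studies below
use 6,000–60,000 probes).

### Permutation null

Statistical significance comes from label permutation: each null draw
reassigns the "CoRSIV" label to $|$CoRSIV probes$|$ probes sampled without
replacement from the union of CoRSIV and pooled control probes, the
remainder forming pseudo-control sets of the original total size, and
recomputes the ratio. $k$ is held at its observed value — it is a function
of $p_i$, which label exchange does not touch — and the p-value uses the
add-one estimator $p = (1 + \#\{\mathrm{ER}_{null} \ge
\mathrm{ER}_{obs}\})/(1 + n_{iter})$, which can never return zero. P-values
below the permutation resolution therefore saturate at $1/(1+n_{iter})$;
no analytic tail approximation is applied by default because the null's
tail shape is not guaranteed.

Under a generative null in which CoRSIV and control probes are reported
with identical per-paper probability, labels are exchangeable, so the
permutation p-value is (discretely) uniform — the package's calibration
test checks exactly this over 200 replicate corpora, together with the
median ratio sitting inside a bootstrap Monte-Carlo band around 1.

### Decay curves and power projections

`decay_curve()` tabulates, per reporting threshold $t$, how many probes are
reported in at least $t$ papers and what percentage of them are CoRSIV
(resp. mean control) probes: the count decays roughly exponentially while
the CoRSIV share rises if enrichment concentrates among reliably reported
probes. `power_projection(ratio, coverage_fraction)` scales a ratio by the
reciprocal of the catalog's platform coverage — with 1,607 of 10,388
regions covered (15.5%), observed enrichments multiply by ~6.5 to project
the power of profiling every region rather than only the covered ones.

## Stability and variability metrics

The test-retest module quantifies why CoRSIV probes are reportable:

* **ICC** — one-way random-effects ICC(1,1),
  $(\mathrm{MSB} - \mathrm{MSW})/(\mathrm{MSB} + (v-1)\mathrm{MSW})$ with
  $v = 2$ visits; negative estimates are reported as computed. The source
  literature does not pin the variant, so a two-way consistency ICC(3,1)
  is available via `variant = "consistency"`; ICC(1,1) is the default
  because a visit in a test-retest design is not a crossed "rater".
* **IIR** — interindividual range, the 98th minus 2nd percentile of
  per-subject methylation (mean of the two visits; averaging is symmetric
  in the visits and variance-reducing). Percentiles use the
  linear-interpolation definition (`quantile` type 7) and this is fixed and
  documented because at ~92 subjects the 2nd/98th percentiles are
  interpolation-sensitive.
* **Trend tests** — per-probe metrics are binned by exact paper count
  (bins under 15 probes dropped) and the ordered trend is assessed with a
  Jonckheere–Terpstra test (tie-corrected normal approximation, two-sided).
  No pre-installed package provides the test, so it is implemented here
  and cross-checked against Kendall's tau, to which it is equivalent up to
  tie handling. The trend statistic itself is a package choice: the source
  analyses report trend p-values without naming their test.
* **Concordance** — blood–brain concordance scores are consumed as one
  summary correlation per probe; per-brain-region breakdowns are out of
  scope.

## Clustering and over-representation

Probes reported in ≥ 2 papers in at least one category form a binary
probe × category matrix. Rows are clustered with Jaccard distance and
average linkage — a standard choice for sparse binary data; the source
figure names neither metric nor linkage — after sorting rows by name so the
result is input-order invariant. Gene-set over-representation is the
one-sided hypergeometric tail $P(X \ge \mathrm{overlap})$ with
Benjamini–Hochberg adjustment across sets; the universe defaults to all
genes mappable from the probe map and is configurable, since the original
analysis does not state its universe.

## The synthetic-data generator

Every input has a seeded generator with recorded ground truth:

* **Probe map** (`gen_probe_map()`): probes at strictly increasing
  positions; CoRSIVs as disjoint intervals at least 3 kb from background
  probes, each holding `1 + Poisson(1.2)` probes (mean 2.2, matching the
  covered-catalog average); genic contexts drawn from a fixed vocabulary
  with CoRSIV probes biased toward TSS200.
* **Corpus** (`gen_corpus()`): each probe is reported in each paper
  independently — with probability $\pi$ (default 0.002) for background
  probes and $\min(1, r\pi)$ for CoRSIV probes, where $r$ is the planted
  per-category relative risk. Independence is the minimal model consistent
  with the permutation logic; no generative model is claimed by the source
  analysis. Documents are materialised as plain text with near-miss tokens
  (`cg1234567`, `CG12345678x`, ...) so the extractor's boundary rules are
  actually exercised. `sim_incidence()` draws the per-probe paper counts
  directly as Binomial($P$, prob) — distribution-identical to tallying the
  per-paper Bernoulli draws — for studies needing hundreds of replicate
  corpora.
* **Test-retest panel** (`gen_methylation_panel()`): betas are
  `clamp01(mu + subject effect + visit noise)` with per-group
  between-subject SD $\tau$ and within-subject SD $\sigma$; the true ICC
  $\tau^2/(\tau^2+\sigma^2)$ is recorded per probe. Defaults
  ($\tau, \sigma$) = (0.052, 0.024) for CoRSIV and (0.008, 0.018) for
  other probes reproduce the qualitative contrast real arrays show —
  median ICC ≈ 0.8 vs ≈ 0.16 and median IIR ≈ 0.2 vs ≈ 0.06 at 92
  subjects. Clamping to [0, 1] introduces negligible distortion at these
  variance scales because baselines are drawn in [0.2, 0.8].
* **Genes and concordance** (`gen_gene_sets()`, `gen_concordance()`): one
  gene per block of ~4 consecutive probes; one gene set planted to be
  CoRSIV-enriched; concordance scores centred at 0.40 (CoRSIV) vs 0.03.

Default corpus scale is 3 categories × 50 papers over 5,000 probes and 200
CoRSIVs with planted relative risks (11, 26, 24) — a desk-scale corpus
whose strong and weak categories bracket the effect sizes a real literature
corpus exhibits.

What the generator does **not** emulate: PDF/HTML layouts and
supplementary-table structure (documents are plain text); statistical
significance of probes inside papers (the automated pipeline counts
occurrences, not significant occurrences — a per-paper `probe_whitelist`
manifest column emulates manual curation); correlated reporting across
papers (citation copying, shared cohorts); spatial correlation of
methylation between neighbouring probes; cell-composition or batch
structure in the panel. Passing tests therefore demonstrate that the
statistics recover planted effects under the stated model, not that the
model captures every property of the real literature.

### Calibration studies and problem sizes

The package's own validation uses three fixed designs, chosen for adequate
counts in every cell before any results were inspected:

* **Null calibration**: 6,000 probes, 100 CoRSIVs, 10 control sets, one
  60-paper category at $\pi = 0.002$, $r = 1$; 200 replicate corpora, 400
  permutations each. Checks: permutation p-values uniform (KS test at
  $\alpha = 0.01$) and median ratio inside the bootstrap 95% band.
* **Planted-signal recovery**: 60,000 probes, 1,500 CoRSIVs, 10 sets, 150
  papers at $\pi = 2\times 10^{-5}$, $r \in \{1, 2, 5, 10, 20\}$ with 6
  corpora per $r$. At this small $\pi$ the spectrum stays in the $k = 1$
  regime, where the ratio estimates $r$ directly; the median over corpora
  must be strictly increasing and within ±25% of $r$. At larger $\pi$ the
  statistic legitimately exceeds $r$ once multi-paper occurrence levels are
  dominated by CoRSIV probes — that is the statistic's design, visible in
  the default end-to-end corpus, not an estimation failure.
* **ICC recovery**: a $\tau/\sigma$ grid spanning true ICC 0.03–0.97
  (including 0.5) at 500 subjects; median absolute error below 0.05.

## Numerical and interface conventions

* Coordinates are 0-based half-open throughout (BED-native); a probe is a
  single CpG point, and a probe at `pos = start` overlaps while
  `pos = end` does not. Strand is ignored: CpG methylation is
  strand-symmetric.
* A region inherits the majority context of its member probes; ties break
  toward the promoter (TSS200 > TSS1500 > 5UTR > Body > 3UTR > Intergenic).
* The context comparison is a 2 × 2 Pearson chi-square without Yates
  correction; zero margins raise an error pointing at exact tests.
* Papers annotated to several categories count in each; within one
  category a paper counts once however many of the category's MeSH
  descendants it carries.
* TSV outputs begin with `#` provenance lines (package version, seed,
  timestamp); BED files are kept comment-free for interoperability, with
  their provenance carried by the match-audit TSV and summary JSON.
* `compute_icc()` accepts two subjects (the formula is well defined and
  the degenerate equal-means case is instructive); panel-wide
  `stability_records()` requires at least three.

## Known limitations

* The permutation test holds $k$ fixed; re-deriving $k$ per draw
  (`refit_k`) is exposed but is a no-op under label exchange.
* P-values are floored at $1/(1+n_{iter})$; extremely small p-values
  require proportionally many iterations.
* The greedy matcher can exhaust a (chromosome, probe-count) candidate
  pool on dense maps even when a cleverer assignment would fit; the error
  names the offending CoRSIV, and `allow_cross_chromosome_fallback`
  relaxes the chromosome criterion explicitly.
* The enrichment ratio approximates the planted per-paper relative risk
  only in the small-$\pi$, $k = 1$ regime; elsewhere it is a
  publication-weighted enrichment, not a risk estimator.
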