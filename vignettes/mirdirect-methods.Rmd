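---
title: "Methods: the four-step direct-target screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-step direct-target screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mirdirect)
library(dplyr)
```

## The problem and the model

MicroRNAs repress genes post-transcriptionally. When repression proceeds by
transcript degradation, a microRNA and its target mRNA should move in
opposite directions: samples where the microRNA is abundant should show low
target mRNA, and vice versa. Seed-match databases predict far more targets
than are functional in any one tissue, so `mirdirect` implements a strict
screen that intersects four independent lines of evidence on patient-matched
tumor/normal expression data:

1. **Step 1 — microRNA dysregulation.** Each microRNA is scored with the
   signal-to-noise (SNR) statistic
   $s = (\bar{x}_T - \bar{x}_N) / (\sigma_T + \sigma_N)$ and assigned a
   two-sided permutation p-value under relabeling of the condition labels;
   features with $p < \alpha$ (default $\alpha = 0.001$) are kept, split by
   direction.
2. **Step 2 — mRNA dysregulation.** A gene is kept when it clears a two-fold
   change on the log2 scale *and* a permutation-based Benjamini–Hochberg FDR
   of 0.1. This deliberately simplifies a SAM-style analysis to the two
   published decision criteria (fold cutoff plus permutation FDR); no
   variance-moderating fudge factor is fit.
3. **Step 3 — conserved seed sites.** A candidate pair requires an exact
   seed-complement match (no G:U wobble, mismatches, or bulges) in the
   gene's 3'UTR in *every* required species (default human, mouse, rat,
   dog). Sites can be imported from a TargetScan-style flat file (the
   default path) or found de novo by scanning per-species UTR FASTA files.
4. **Step 4 — strict anti-correlation.** Up-regulated microRNAs paired with
   down-regulated targets are correlated across *tumor* samples; the
   reciprocal pairs across *normal* samples — in each case the class where
   the regulator is abundant and presumed active. A pair must have Pearson
   $r < P_0$ (default $-0.95$), a one-sided permutation p-value below 0.01,
   and a BH FDR below 0.2 across the candidate family.

The per-class screening mode follows the stepwise procedure as stated; a
`combined` mode (all samples pooled) is provided because pooled correlations
are what one inspects when validating pairs on noisier array data. Both are
selectable via `screen_config(mode = )`.

## Key parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `alpha_mirna` | 0.001 | p-value | Step-1 significance on the raw permutation p |
| `fold_cutoff` | 2 | linear fold | Step-2 effect-size gate |
| `fdr_mrna` | 0.1 | FDR | Step-2 BH threshold on permutation p |
| `B_mirna`, `B_mrna`, `B_pairs` | 1000 / 100 / 999 | count | Monte-Carlo permutation counts |
| `P0` | −0.95 | Pearson r | Step-4 anti-correlation cutoff |
| `p_threshold`, `fdr_pairs` | 0.01 / 0.2 | p / FDR | pair significance |
| `required_species` | human, mouse, rat, dog | — | conservation requirement |
| `site_type` | `7mer_m8` | — | seed definition for de novo scanning |

$P_0 = -0.95$ is appropriate for low-noise qPCR-derived microRNA data; on
array data the attainable anti-correlations are weaker (magnitudes of
0.5–0.6 are typical) and the cutoff should be relaxed with the permutation
p-value carrying the inferential weight.

### Permutation testing: exact where possible

`perm_mode = "auto"` enumerates **all** distinct condition relabelings
whenever there are at most `exhaustive_bound` (20 000) of them and reports
the exact proportion $p = \#\{|s^*| \ge |s_{obs}|\}/N$; otherwise it draws
`B` random relabelings and reports the add-one estimator
$p = (k+1)/(B+1) > 0$. The exact route matters at the matched-pair design
size: with 8 + 8 samples there are $\binom{16}{8} = 12\,870$ relabelings, so
the exact test resolves p-values down to $2/12870 \approx 1.6\times10^{-4}$,
comfortably below $\alpha = 0.001$, whereas a Monte-Carlo draw of 1000
permutations re-samples the observed labeling often enough to blunt the
extreme tail. A paired sign-flip scheme (`scheme = "paired_signflip"`,
within-patient label swaps) is available for the matched design; it is not
the default because its $2^{8} = 256$ relabelings cannot resolve
$p < 0.001$ at all.

The SNR denominator floors each group standard deviation at
$\max(0.2\,|\bar{x}|,\,10^{-8})$, the convention long associated with this
statistic in expression profiling; it protects against degenerate
variances at the cost of some power for features with large absolute
baselines. Set `sd_floor_frac = 0` to remove it.

For pair correlations the null permutes the sample order of the microRNA
vector relative to the mRNA vector within the screened class, one-sided
toward anti-correlation (the hypothesis is directional). For class sizes
$n \le 6$ all $n!$ orderings are enumerated exactly.

### Multiple testing

`bh_fdr()` is the Benjamini–Hochberg step-up adjustment. `storey_qvalues()`
estimates the null proportion $\hat\pi_0$ on a $\lambda$-grid with a cubic
smoothing spline; with fewer than 100 p-values the smoother is unreliable
and the function falls back to $\hat\pi_0 = 1$, i.e. BH. MicroRNA DE tables
report both.

### Comparative-Ct normalization

MicroRNA qPCR input is normalized per sample against a housekeeping
microRNA: relative expression $2^{-(Ct_f - Ct_{hk})}$, or
$-(Ct_f - Ct_{hk})$ on the log2 scale. No calibrator sample enters (none
exists in the tumor/normal design). "Most unchanged", the housekeeping
criterion, is not self-defining; the default operationalizes it as the
minimum $|s|$ between conditions on the Ct scale, with minimum overall
variance and minimum $|\Delta \bar{Ct}|$ as alternatives, and deterministic
tie-breaking (smaller variance, then lexicographic ID). The report records
which method chose the feature.

### Seed-site conventions

Seeds are read from mature microRNA positions 2–7 (`6mer`, `7mer_1A`) or
2–8 (`7mer_m8`, `8mer`), 5'→3'; the UTR match pattern is the reverse
complement, with an `A` appended opposite position 1 for `7mer_1A`/`8mer`.
All sequences are canonicalized to uppercase RNA so DNA and RNA input
behave identically. Coordinates are 0-based half-open on the sense strand.
`7mer_m8` is the default site type; the 6-nt family seeds in common use are
reachable with `site_type = "6mer"`. MicroRNAs with identical seeds can be
collapsed to families with `mirna_families()`. Conservation is
presence-based — at least one exact site anywhere in the orthologous UTR of
every required species, with the caller supplying comparable gene IDs —
rather than alignment-column identity, which would require whole-genome
alignments out of scope here. A gene absent from one species' UTR set
counts as having no site there.

Probe-to-gene collapsing is left to the caller: each expression row is one
feature, and multiple probes for a gene are screened independently.

## What the synthetic generator emulates

`generate_paired_expression()` reproduces the study design the screen
expects: 8 patients by default, each with one tumor and one normal sample,
Gaussian log2 expression (microRNA baselines near 0 as for log2 relative
expression, mRNA baselines in 4–12 as for log2 array intensities), a
condition shift of `effect_size` (default 2 = 4 noise SDs, `noise_sd` 0.5)
for DE features, and `n_edges` regulator–target pairs drawn bivariate
Gaussian with population correlation `rho` (default −0.99) inside the class
the per-class screen examines. Defaults of 40 microRNAs and 200 genes keep
a qPCR-panel-sized regulator set against a larger transcript pool; 3 edges
plus 3 extra DE microRNAs and 7 extra DE genes exercise both the
conservation filter (DE features without sites must not pair) and
multiplicity without making exact recovery a foregone conclusion: with
$P(r < -0.95 \mid \rho = -0.99, n = 8) \approx 0.98$ per edge and a
comparable DE pass rate at $\alpha = 0.001$, all-edge recovery sits near
0.9 per replicate.

`generate_utr_universe()` adds the sequence layer: unique-seed mature
22-mers for the whole panel, random background UTRs (default 300 nt)
scrubbed of accidental occurrences of the planted families' patterns,
planted sites in all required species for every edge, decoy sites in proper
species subsets (which the conservation filter must reject), and a matching
annotation table so the flat-file path can be tested against the de novo
path.

What the generator does **not** emulate: probe effects, saturation,
batch/array effects, heavy-tailed noise, correlated gene programs, or
partial seed matches. Passing tests on this test bed therefore demonstrate
the statistical machinery — calibration, exactness of the enumeration
paths, recovery under the stated signal model — not robustness to real
microarray artifacts.

## Numerical and degenerate-input choices

- Missing expression values are refused at load, never imputed; every
  downstream statistic assumes complete vectors.
- Constant vectors make a Pearson correlation undefined; such pairs are
  skipped with a message and reported in the `skipped` attribute rather
  than failing a run.
- Binarization maps values strictly greater than the training-midpoint
  threshold to 1; equality goes to 0. A voting tie (sum exactly 0) resolves
  to `normal` with a warning. Both rules are arbitrary but deterministic.
- Permutation-count comparisons use a $10^{-12}$ tolerance so the observed
  statistic always ties with itself in the enumerated null.
- Every stochastic operation requires an explicit seed; the resolved
  configuration (including the seed) is written next to every saved result,
  so a provenance log suffices to re-execute a run.

## Worked example

```{r example}
d <- generate_paired_expression(seed = 42)
u <- generate_utr_universe(d$truth, seed = 7)
res <- run_screen(d$mirna, d$mrna, d$metadata,
  annotation = u$annotation, config = screen_config(seed = 5),
  quiet = TRUE)
glance(res)
tidy(res) |> filter(passes)
d$truth$edges
```

All three planted edges pass all four steps; nothing else does. The
problem sizes above (40 microRNAs, 200 genes, 8 patients, 300-nt UTRs) are
the package defaults and are also the sizes its test suite simulates at.

```{r plot, fig.width = 5, fig.height = 3.5}
e <- d$truth$edges[1, ]
plot_pair(d$mirna, d$mrna, d$metadata, e$mirna_id, e$gene_id)
```

## Validation-style checks

The classifier used to confirm that a selected panel separates the classes
is the classical SNR-weighted voting rule: per-feature weight
$w = s$, boundary $b$ at the midpoint of the class means, vote
$w\,(x - b)$, tumor iff the vote sum is positive, optionally on binarized
values. `loo_accuracy()` refits everything — including binarization
thresholds — inside each leave-one-out fold, so the held-out sample cannot
leak into its own fold's model.

```{r loo}
panel <- d$mirna[d$mirna$feature_id %in% d$truth$de_mirna$feature_id, ]
as.numeric(loo_accuracy(panel, d$metadata, binarize_first = TRUE))
```

## Known limitations

- Translation-inhibition targets leave mRNA levels unchanged and are
  invisible to this screen by design; so are regulations through
  intermediate factors (no seed match) — finding those would need a
  seedless correlation scan and larger cohorts.
- The mRNA stage is a simplified SAM-analogue; it will not reproduce SAM's
  delta-table output exactly.
- Conservation-by-presence can differ from alignment-based conservation
  when orthologous UTRs contain non-orthologous sites.
- With 8 samples per class, the strict cutoff $P_0 = -0.95$ misses a real
  $\rho = -0.99$ edge about 2% of the time; sensitivity figures in the
  test suite and acceptance script quantify exactly this.
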