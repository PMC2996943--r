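---
title: "Intensity-based allele-frequency analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-based allele-frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(baftools)
```

This vignette is the package's account of its own science: the models it
fits, the parameters that matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the design was genuinely open.

## 1. The signal model

A two-channel SNP array measures, per SNP and sample, intensities
`(s1, s2)` for the two alleles. We model

    s1 = kappa * g_A * epsilon_1,      s2 = g_a * epsilon_2,

where `g_A`, `g_a` are proportional to the allele copy numbers in the
sample's DNA, `epsilon` is multiplicative noise, and `kappa` — the
coefficient of preferential amplification/hybridization (CPA) — is a per-SNP
constant expressing how much more signal one allele produces per copy than
the other. The CPA-adjusted individual-level allele frequency

    f = s1 / (s1 + kappa * s2)

then estimates the within-individual relative amount of allele A: near 0,
1/2, 1 for the three normal genotypes, and elsewhere when the copy ratio is
disturbed. All downstream machinery (aberration scanning, biplots, purity
estimation) consumes `f`.

## 2. CPA estimation

Heterozygotes carry the two alleles 1:1, so over heterozygous samples the
channel-mean ratio estimates `kappa`:

    kappa_hat = mean(s1 | het, unmasked) / mean(s2 | het, unmasked)

**Estimator form.** We use the ratio of channel means (not the mean of
per-sample ratios). Consequences worth knowing: it is invariant to a scale
factor applied to *all* samples and channels, and scaling one channel alone
scales the estimate by exactly that factor — but it is *not* invariant to
rescaling a single sample's intensities (each sample enters the two means
with its own weight). A mean-of-ratios form would have that per-sample
invariance but weights noisy low-intensity samples poorly; the
ratio-of-means form is the standard choice for this estimator family and is
what the package commits to.

**Parameters.**

- `min_het` (default 3): below this many usable heterozygotes the SNP falls
  back to `kappa = 1` (no adjustment) with `fallback = TRUE`, so frequency
  estimates always exist. Dropping the SNP instead would silently shrink
  every downstream panel.
- A SNP with enough heterozygotes but a degenerate channel mean (zero)
  gets a missing CPA, flagged — never an infinite value.
- `cv`: the SD of per-heterozygote ratios `s1/s2` divided by `kappa_hat`,
  reported at `n_het >= 2`. It is a dispersion diagnostic, not an input to
  any formula.

**Lognormal summary.** Genome-wide CPA is well described by a lognormal
law; `fit_lognormal()` fits by maximum likelihood on `log(kappa_hat)` and
reports the Kolmogorov–Smirnov distance as a goodness-of-fit diagnostic.

**Cohort comparison.** CPA is probe chemistry plus cohort genetics, so CPA
tables are compared (`compare_cpa`, Pearson `r` on `log2` scale over shared
non-fallback SNPs) rather than pooled across cohorts or ethnic groups; the
package never merges CPA tables implicitly.

**Workflow note.** Estimate CPA from *normal* samples and apply the table
to patients. A tumor sample's genotype calls still read "heterozygous"
inside a lesion while its intensities do not carry a 1:1 ratio; including
such samples biases `kappa_hat` at exactly the SNPs where you later measure
the lesion. The contamination tests in this package measure that bias and
it is material at small cohort sizes.

## 3. Allele frequencies

- Counting (`freq_counting`): `AA -> 1`, `Aa -> 1/2`, `aa -> 0`,
  `NoCall -> missing`. Total on the enum, no other behavior.
- Intensity (`freq_intensity`): `s1 / (s1 + cpa * s2)`, already in [0, 1],
  strictly monotone in each argument; both channels zero is missing, not 0.
- Population level: mean of individual frequencies. From genotypes the
  variance is binomial `p(1-p)/(2n)` under HWE; from intensities it is the
  empirical cross-sample variance of the mean. The *individual*-level
  variance of the adjusted frequency is deliberately left missing: the
  delta-method expression would need the experimental noise variance and
  the CPA sampling variance as separate known quantities, which a single
  experiment does not provide; we report only quantities the data can
  support.
- Pooled (`popfreq_pooled`): the same adjusted ratio on pool-level
  intensities. Pooling DNA sums material, so the generator's pools sum
  member intensities; with the background floor at zero this inversion is
  exact by construction, and with realistic background it is accurate to
  the noise level.

Frequencies always refer to the array's A allele; no strand or label
flipping is attempted (annotation carries the allele labels for reporting).
Masked entries are ignored, never imputed, in all frequency arithmetic.

## 4. Aberration scanning

**Reference bands.** Per SNP and genotype, normal controls give
`mean ± z * sd` with `sd` floored at `sd_floor`. Defaults `z = 3`,
`sd_floor = 0.01`: three sigma keeps the per-SNP false-flag rate low
without a distributional commitment, and the floor stops a constant
reference column (common at monomorphic-ish SNPs) from producing
zero-width bands that flag everything. A genotype class with fewer than two
reference samples has no band; a SNP with no bands at all is excluded from
flagging.

**Point flags.** AI: frequency outside *all* available genotype bands.
LOH: frequency outside the *heterozygote* band only — a purely band-based
definition, chosen over "contiguous homozygous calls" because it needs no
genotype call for the patient (calls inside lesions are unreliable) and
makes homozygous SNPs LOH-compatible by construction, which is what a
copy-neutral LOH region looks like in frequency space.

**Window indices.** For each anchor SNP, the AI (LOH) index is the mean of
the AI (LOH) flags over a `window_size`-SNP window centred on the anchor,
sliding one SNP at a time; missing flags leave numerator and denominator.
At chromosome ends the half-width shrinks so the window stays symmetric.
Default `window_size = 51`: at typical array densities that is a ~0.5 Mb
window, large enough to average flag noise, small enough to localize a
300-SNP event.

**Smoothing.** Cubic smoothing spline of index against position, per
chromosome and sample, penalty chosen by generalized cross-validation
(`smoothing_param` exposes the spline `spar` for manual control);
chromosomes with fewer than 10 usable anchors keep the raw track; smoothed
values are clipped to [0, 1].

**Envelope and calling.** The control envelope is the per-anchor 95%
empirical quantile of the *raw* control indices, then smoothed along the
chromosome exactly like a patient track. Taking the quantile before
smoothing keeps the controls' window-scale sampling spread inside the
envelope; quantile-of-smoothed tracks would discard it and sit tighter. A
patient anchor "exceeds" when its smoothed index is strictly above the
envelope; maximal runs of at least `min_run` exceeding anchors become
segments, called independently for AI and LOH; a run covering at least
`whole_chrom_frac` (default 0.9) of a chromosome's SNPs is labelled
whole-chromosome.

**Choosing `min_run` — the one default that deserves a paragraph.** The
window index is a moving average, so neighbouring anchors share most of
their window: exceedance events are correlated over roughly one window
width no matter how the smoothing is tuned. A null patient — statistically
identical to the controls — sits above a per-anchor 95% quantile at ~5% of
anchors *in correlated stretches comparable to the window size*. Any
`min_run` below the window size therefore lets single window-scale
fluctuations through as called segments, and a scan of a few thousand SNPs
will produce false segments on most null samples. The default is
`min_run = 2 * window_size + 1`: a run twice the correlation length cannot
be produced by one fluctuation. In the package's simulated null worlds this
default leaves the large majority of null samples with zero called
segments while a 300-SNP deletion — whose run is three times the default —
is recalled through both the AI and the LOH index (the acceptance suite
asserts both). Users scanning for shorter events should lower `min_run`
knowingly and expect the false-segment rate to rise.

**Boundary accuracy.** A deletion's flags switch on over one window at each
edge, so called boundaries land within about half a window of truth plus
smoothing spillover. The AI run occasionally absorbs an adjacent null
excursion and overshoots one edge; the LOH run, whose in-segment signal is
near 1 against an envelope near the cohort homozygosity rate, localizes
more sharply. The acceptance criterion measures the better-localized of the
two calls, which in the stated world stays within one window of truth.

**Quantile conventions.** Type-7 empirical quantiles; with fewer than 20
controls the 95% quantile is replaced by the control maximum (with `n`
exchangeable controls, a new null sample exceeds their maximum with
probability `1/(n+1)`, which is the honest rate a tiny control set can
offer). Note the finite-sample effect in the other direction too: a new
sample exceeds the type-7 `q95` of 40 controls with probability ~7%, of
100 controls ~6%; the acceptance suite computes its tolerance from exactly
this quantity rather than from a flat 5%.

## 5. Biplots

`F = A - rowMeans(A)`: the SNPs × samples frequency matrix is row-centred
(per-SNP centring across samples), missing entries imputed by the SNP mean
first — they become exact zeros in `F`, neutral under the SVD. Thin SVD
`F = P D Q'` (the full square-`D` convention is impossible for rectangular
`F`); rank-2 coordinates with the singular values on the sample side
(SNP-effect flavor) or the SNP side (sample-effect flavor) — both flavors
reconstruct the same best rank-2 approximation, which the test suite pins
to the discarded singular spectrum (Eckart–Young). Sign convention: each
left singular vector's largest-magnitude entry is made positive, so
coordinates are reproducible across linear-algebra backends.

Outlier screening (median/MAD standardization per axis, chi-square(2)
cutoff, `alpha = 0.01`) and k-means classification (fixed seed, 10
restarts, mean silhouette reported) are pragmatic conveniences; the
underlying scientific instrument is the projection itself.

**A limitation worth stating precisely.** Population groups separate in a
biplot because their allele-frequency *means* differ per SNP; that is a
genuine shared direction and rank-2 k-means recovers such groups cleanly
(the test suite builds them with the Balding–Nichols model,
`simulate_populations`, divergence `fst = 0.1`). Sex groups on the X
chromosome are different: with clean hemizygous males (frequencies near
0/1) the male and female *expected* frequency profiles are identical —
both equal the allele frequency — and genotypes are independent across
samples, so every linear functional of a sample's profile has the same
mean in both sexes. The sexes then differ only in per-sample variance
(males lack the mid band): in the biplot plane females concentrate nearer
the origin and males spread wider, a pattern a radial statistic detects but
a k-means split cannot separate perfectly. Real arrays *do* separate sexes
in biplots — through probe-level mean structure such as the attenuation of
male X frequencies at half DNA dose — but emulating that at the strength
required would contradict the clean male model this generator states. The
package documents this rather than tuning the generator to manufacture the
result; the corresponding acceptance assertion is expected to fail and says
so in place.

## 6. Tumor purity

With tumor allele copies `a:b` and a normal-cell fraction `p`,

    f1 = (p + a(1-p)) / ((2 - (a+b)) p + (a+b)),    f2 = 1 - f1,

inverted in closed form by

    p = (a(1-f1) - b f1) / ((1-b) f1 - (1-a) f2),

undefined when `(1-a) f2 = (1-b) f1` (e.g. the balanced model `a = b = 1`,
which carries no imbalance information). `segment_contamination` averages
the *folded* frequencies `min(f, 1-f)` of germline-heterozygous SNPs in a
segment, keeping values below 0.5: per-SNP allele labelling is arbitrary,
so the two mixture bands `f1` and `1 - f1` fold onto one value. The folded
average is assigned to whichever of `f1`/`f2` the copy model predicts below
0.5 (for `a <= b`, that is `f1`). At least `min_snps = 10` usable SNPs are
required; fewer yields a missing estimate rather than a noisy one. A raw
`p` outside [0, 1] is reported with `in_range = FALSE` alongside the
clipped value — never silently clipped.

Estimates are sensitive to segment bounds: called bounds include up to a
window of flanking normal SNPs whose folded frequencies sit near 0.5 and
drag `p` upward; when precision matters, estimate on the conservative core
of a called segment.

## 7. The synthetic world

`sim_config()` defaults state the world the tests live in:

| parameter | default | meaning |
|---|---|---|
| `n_snps`, `n_samples` | 1000, 100 | panel size |
| `maf_range` | (0.05, 0.5) | per-SNP allele frequency, uniform; HWE genotypes |
| `cpa_log_sd` | 0.5 | `ln kappa ~ N(0, 0.5^2)` per SNP |
| `noise_cv` | 0.1 | multiplicative lognormal noise, CV 10% |
| `base_signal` | 1000 | diploid-dose channel signal (arbitrary units) |
| `noise_floor` | 0.01 | zero-copy channels emit 1% background |
| `spacing_bp` | 10000 | uniform inter-SNP spacing |

Choices and reasons:

- Noise is lognormal with mean exactly 1 (`meanlog = -sdlog^2/2`), so the
  generator adds no hidden bias to channel means and estimator-unbiasedness
  tests measure the estimator, not the noise parameterization.
- The 1% background floor keeps absent-allele channels nonzero, so
  division-by-zero paths and homozygote bands near (not at) 0/1 are
  exercised. Setting `noise_floor = 0` gives the algebraically exact pool
  inversion used as a test oracle.
- Aberrations re-generate in-region intensities from mixture copy numbers
  (`p * germline + (1-p) * tumor`), with the tumor's `a` copies assigned to
  a uniformly random germline allele at heterozygotes — labelling is
  arbitrary, and downstream folding must cope with that.
- Males on X carry a single copy at half dose, so their frequencies are
  slightly less extreme than female homozygotes — realistic, and enough for
  hemizygosity-based checks without manufacturing biplot separation.
- Positions are evenly spaced purely for plotting realism.

What the generator does **not** emulate: linkage disequilibrium, batch and
plate effects, probe-level systematic structure, genotype-calling error,
saturation. A green test therefore establishes correctness of the
estimators and callers *under exchangeable, independent noise* — it does
not establish the false-positive rate of the scanner on real cohorts, where
between-sample structure widens control envelopes and changes run-length
behavior in both directions.

## 8. Numerical conventions

- Chromosomes in natural order `1..22, X`; within chromosome, sort by
  position with `snp_id` as the stable tie-break. Y and mitochondria are
  unsupported.
- Internal coordinates are 1-based inclusive; only BED export converts to
  0-based half-open.
- Missingness is an explicit mask (`NA` in both channels simultaneously);
  zero intensity is data.
- Quantiles type 7; smoothed indices clipped to [0, 1]; spline fallback to
  the raw track under 10 anchors per chromosome.
- All randomness flows through explicit integer seeds (`sim_config$seed`,
  `classify_samples(seed = )`, CLI `--seed`); identical seed, identical
  bytes out.

## 9. Known limitations

- No paired tumor–normal mode and no copy-number estimation; the scanner
  reads allele-frequency geometry only, so a balanced duplication (2:2) is
  invisible to it.
- `estimate_contamination` assumes one clone and a known copy model; multi-
  clone mixtures produce extra frequency bands this model does not fit.
- The CPA fallback (`kappa = 1`) biases frequencies at SNPs with few
  heterozygotes in the reference cohort — rare-variant-heavy panels should
  raise `min_het` and accept missingness instead.
- Segment boundaries are window-resolution, not SNP-resolution.
- X-chromosome sex separation by biplot is not expected under this
  generator (section 5).
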