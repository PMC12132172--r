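---
title: "Methods: from splicing-isoform composition to electrophile sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from splicing-isoform composition to electrophile sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicephys)
```

## The scientific problem

Insect TRPA1 ("wasabi receptor") channels are gated covalently by
electrophiles such as allyl isothiocyanate (AITC) and also by heat. In
drosophilid flies the *TrpA1* gene is alternatively spliced into
isoforms (CL, CS, DL, DS, EL) that differ at a short 5' exon and at an
internal exon pair roughly 2 kb downstream on the mRNA, and the
isoforms differ sharply in electrophile sensitivity: CL-type channels
respond at low AITC doses, DL-type channels only at high doses, and
CS/DS/EL are nearly inactive. Because gustatory neurons co-express
these isoforms, the *composition* of the isoform pool — not just total
expression — shapes how strongly a fly's bitter-sensing neurons respond
to mustard-oil electrophiles, and ultimately how strongly it avoids
them.

`splicephys` implements the full quantitative chain needed to study
this: (1) dose–response estimation from two-electrode voltage clamp
(TEVC) oocyte recordings with heat-current normalization; (2)
quantification of isoform composition from long amplicon reads; (3) an
additive mixture model linking composition to predicted cellular
response; and (4) scoring and normalization of proboscis extension
reflex (PER) feeding assays. Every stage has a seeded synthetic-data
generator with known ground truth, so the whole pipeline is testable
at desk scale.

## Heat-normalized dose–response estimation

Covalent activation does not reverse on wash-out, so one oocyte yields
exactly one AITC response and classical within-cell normalization
(consecutive doses on the same cell) is impossible. The protocol
modelled here stimulates each oocyte twice: a heat pulse (>40&nbsp;°C,
30 s), a 120 s wash, then a single 90 s AITC application at one of the
seven doses 0.001, 0.01, 0.03, 0.1, 0.3, 1, 3 mM. The heat-evoked
amplitude $I_{Heat}$ proxies the cell's channel expression, so the
normalized response $I_{AITC}/I_{Heat}$ is comparable across oocytes.
`raw_current_correlation()` checks the assumption behind this: the two
raw amplitudes should correlate positively across oocytes at a fixed
dose.

Extraction rules (`extract_heat_amplitude()`,
`extract_aitc_amplitude()`):

* $I_{Heat}$ is the peak deflection from the pre-stimulus baseline
  mean inside the heat window. The pre-stimulus baseline is used
  because the recordings begin from a stable holding current; this is
  one of the places where the underlying protocol is ambiguous and a
  convention had to be chosen.
* $I_{AITC}$ is measured against the mean current over the 5 s before
  AITC onset and reported **at the end of the 90 s window**, because
  the covalent response typically does not saturate within it. A
  response is instead called saturated — and its peak reported — when
  the peak occurs at least 2 s before the window end *and* the mean
  deflection over the final 2 s is at most 98% of that peak. This
  operationalizes a judgement that is usually made visually; the 2 s /
  98% constants are conventions, not fitted values.

Per-isoform curves are fit by `fit_dose_response()` as

$$f(c) = \frac{d}{1 + (e/c)^h},$$

the three-parameter log-logistic with lower asymptote fixed at zero,
written in Hill form to pin the sign of the slope: $d$ is the maximum
normalized current, $e$ the EC50 (by construction $f(e) = d/2$
exactly), and $h > 0$ the Hill slope. Fitting is Levenberg–Marquardt
nonlinear least squares (via minpack.lm) with multi-start over
$h_0 \in \{0.5, 1, 2\}$, $e_0$ initialized at the interpolated
half-max crossing of the per-dose means and $d_0$ at the largest
observed response; the best converged start by residual sum of squares
wins, and standard errors are the Gauss–Newton asymptotic ones.
Zero-dose recordings are excluded from fits: $f(0)=0$ holds
identically, so they carry no information about $e$ or $h$. For weakly
heat-responsive ("inactive") isoforms, whose small $I_{Heat}$ makes
normalization unstable, `use_raw = TRUE` fits raw $I_{AITC}$ instead.
The slope is estimated freely; no reported slope values exist to
constrain it against.

The test suite checks the fitter against an exhaustive profile grid
search: $(e, h)$ on 1%-spaced log grids with the linear parameter $d$
solved in closed form per node. The optimizer must land within one
grid step of the oracle's best node on every fixture.

## Synthetic TEVC data

The generators encode these modelling choices (all set in
`sim_config()`):

* **Sign convention.** Inward currents are negative; reported
  amplitudes are magnitudes of deflection.
* **Expression scale.** Log-normal across oocytes (median
  `expression_median` = 2 µA, `expression_sdlog` = 0.4): positive
  support and a realistic oocyte-to-oocyte spread that produces the
  observed positive correlation between raw heat and AITC currents.
* **Covalent kinetics.** The AITC response rises mono-exponentially to
  its plateau with a dose-dependent rate and never decays — the trace
  does not return to baseline within the record.
* **Noise.** Multiplicative log-normal noise with mean exactly 1 and
  CV `noise_cv` (default 0.2) on the AITC response, plus small
  additive recording noise (`trace_noise_sd`, traces only). In
  summary rows $I_{Heat}$ equals the expression scale exactly, so the
  normalized response is $f(c)$ times the single noise factor — the
  cleanest realization of "20% multiplicative noise on normalized
  responses", and `noise_cv = 0` makes replicates identical.
* **Sampling.** Traces default to 100 Hz. Rig digitization is in the
  kHz range, but the kinetics modelled here live on seconds, so the
  decimated rate changes nothing and keeps traces small; it is
  configurable.

What the generator does **not** model: temperature-threshold dynamics
of heat gating, desensitization, leak drift, endogenous oocyte
conductances, or series-resistance artifacts. Passing recovery tests
therefore demonstrates correctness of the estimation chain under the
stated noise model, not robustness to every pathology of real
recordings.

Parameter-recovery studies in the acceptance suite simulate 100
replicate datasets per isoform (8 oocytes per dose, the seven doses
above, CV 0.2) from the reported isoform parameters with $h = 1$ and
ask that the median recovered EC50 and maximum match the generating
values; problem sizes were chosen so each study runs in seconds while
leaving the Monte-Carlo error of the median well below the 5%
acceptance band.

## Amplicon classification and composition

Isoform-defining exons sit ~2 kb apart on the ~4 kb transcript, so
short reads cannot phase them; long amplicon reads can, at the price
of a high per-base error rate. The pipeline mirrors the established
analysis: classify each read to its best-hit reference, filter, count.

* `percent_identity()` computes a banded semi-global alignment (read
  end-to-end, reference end gaps free) under unit edit costs in C++,
  and reports $1 - d/\ell_{read}$ clamped at zero. The denominator is
  the read length rather than the alignment length: alignment length
  differs between co-optimal unit-cost alignments, whereas the edit
  distance is unique, so this convention (the one used by
  edit-distance libraries) makes identity deterministic and lets the
  test suite demand exact agreement with a full dynamic-programming
  oracle. The band half-width (default 150 bases, widened by the
  length difference) tolerates indel drift an order of magnitude
  beyond nanopore-scale error on these read lengths.
* `classify_read()` scores both strands — orientation is chosen by a
  fast k-mer vote, falling back to aligning both — and assigns the
  highest-identity reference. Exact ties (difference below $10^{-9}$)
  are left unassigned: precision over recall, since the established
  pipeline does not document a tie-break.
* `filter_reads()` keeps reads of length 3.8–4.5 kb with best-hit
  identity ≥ 85% and a unique best hit, recording the failure reason
  otherwise.
* `estimate_composition()` reports the multinomial MLE over passed
  reads with a seeded percentile bootstrap for uncertainty.
* `integer_ratio()` snaps a two-isoform proportion to the closest
  coprime integer ratio with parts ≤ 9 (ties: smaller sum, then
  smaller first part), the operation used to design cRNA co-injection
  mixtures. Nine gives headroom over the largest part that occurs in
  practice (seven) while keeping ratios readable.
* `compare_compositions()` models per-replicate proportions with a
  Gaussian group-means linear model, Tukey HSD contrasts and BH
  adjustment — Gaussian-on-proportions is statistically impure for
  compositional data but is kept deliberately for fidelity to the
  established analysis.
* `compute_tpm()` is the usual length-normalized rate scaled to
  $10^6$.

The read generator plants reads multinomially on a toy 5-isoform
reference set that reproduces the distinguishing geometry (a 150/90 bp
alternative 5' block and a 160 bp internal block separated by a 2 kb
shared spacer), applies a uniform error process (60% substitutions,
20% insertions, 20% deletions of `per_base_error`), jitters read ends,
emits random strands, and can replace a fraction of reads with junk —
half truncated fragments, half composition-shuffled sequences — so
both filter branches are exercised. It does **not** emulate real
nanopore error structure (homopolymer compression, quality
correlation), so classifier accuracy on synthetic reads bounds real
accuracy from above.

## Additive mixture model

A cell co-expressing isoforms with simplex weights $w$ is predicted to
respond as $\sum_i w_i f_i(c)$ — a convex combination, always between
the most and least responsive component. Additivity is modelled on
*normalized* responses: equal cRNA mass is injected regardless of
mixture, so weights are interpretable as molar fractions of the
functional pool (translation-efficiency differences between isoform
mRNAs would decouple this; they are treated as absorbed into the
effective weights). Inactive isoforms enter either as their own fitted
small-$d$ curves (default, since they show small but nonzero
responses) or as exact zeros when flagged.

`recover_weights()` inverts the model: simplex-constrained least
squares by projected gradient with multi-start (every vertex plus the
barycenter, stopping when the objective decrease falls below
$10^{-10}$), followed by an exact equality-constrained polish on the
active support via the KKT system. A condition-number check on the
component design matrix raises an identifiability warning when
component curves are near-collinear over the recorded doses — with two
identical components the data cannot apportion weight between them.

`compare_mixture_groups()` reproduces the two-group testing
convention: a variance-ratio F pretest at $\alpha = 0.05$ selects
Student's (pooled) or Welch's t-test. Normality is not pretested —
the synthetic responses are log-normal by construction, and the
original criterion for "fulfillment of parametric assumptions" is not
specified beyond that; this simplification is recorded in the result's
method label so downstream users can audit which branch ran.

## PER scoring and normalization

Each fly receives five presentations of a tastant; each is scored 1
(sustained proboscis extension and drinking), 0.5 (partial), or 0, so
totals range 0–5 in 0.5 steps. Scores are normalized to the group's
mean total at dose 0 (`normalize_per()`), making the group-level
zero-dose mean exactly 1; normalized scores above 1 are legitimate and
are not clipped. Within-group dose effects use pairwise Wilcoxon
rank-sum tests with BH adjustment (`dose_contrasts()`), on normalized
scores — within a group at a fixed dose the rank tests are invariant
to the normalization, so this choice only matters across groups. The
transgenic arm reports the ratio of test-genotype to control-genotype
mean normalized PER per dose (`genotype_ratio()`).

The behavioral generative model is a package convention, not an
established result: per trial, a fly responds with probability
$p_0 \cdot a(c)$ (baseline response rate times the group's relative
aversion curve, clamped to $[0,1]$), and a response is full with
probability 0.9, else partial. Two properties motivated it: the mean
normalized PER equals $a(c)$ exactly — independent of $p_0$ and of the
full/partial split — so the aversion curve *is* the ground truth for
the normalized readout; and it produces the discrete trial-level score
distribution the rank tests actually see. Satiety, learning across
trials, and olfactory modulation are not modelled.

## Statistical machinery

* **Wilcoxon rank-sum** is implemented from scratch: exact complete
  enumeration of group assignments (midranks for ties) when
  $n_1+n_2 \le 12$, otherwise a normal approximation with tie and
  continuity corrections — the regime split matches the group sizes
  that occur in practice (19–42 flies). The exact branch agrees with
  base R's exact test on tie-free data to $10^{-12}$ in the suite.
* **Kruskal–Wallis** omnibus comes from base R; the **Conover–Iman**
  post hoc (rank-transform t statistics with the omnibus-conditional
  variance estimate on $N-k$ degrees of freedom) is implemented here,
  as no installed package provides it.
* **ANOVA/Tukey** use base R's `aov()`/`TukeyHSD()`; since R provides
  exact studentized-range probabilities (`ptukey`), Tukey quantiles
  are exact rather than simulated.
* **BH adjustment** wraps `p.adjust` behind input validation; the
  suite verifies the step-up closed form
  $\min_{j \ge i} p_{(j)} m / j$ directly.
* All tests are two-sided (the original analyses do not state
  sidedness), and BH families are kept local — within one group's dose
  contrasts, within one set of pairwise contrasts — never pooled
  across analyses.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)

# 1. dose-response for one isoform from simulated recordings
rec <- gen_recording_set(list(DL = list(d = 4.29, e = 0.103, h = 1)), cfg)
fit <- fit_dose_response(rec)
coef(fit)

# 2. isoform composition from simulated nanopore-like reads
refs <- gen_isoform_references(cfg, c("CL", "DL"))
reads <- gen_amplicon_reads(refs, c(5, 2) / 7,
                            sim_config(seed = 2, read_count = 500))
asn <- filter_reads(classify_reads(reads$reads, refs))
est <- estimate_composition(asn, seed = 3)
integer_ratio(est$proportions)   # snaps back to 5:2

# 3. additive mixture prediction from the recovered composition
models <- list(CL = list(d = 3.05, e = 0.029, h = 1),
               DL = list(d = 4.29, e = 0.103, h = 1))
spec <- mixture_from_composition(est, models, use_integer_ratio = TRUE)
predict_mixture_response(spec, models, c(0.01, 0.1, 1))
```

## Known limitations

* The identity definition (edit distance over read length) differs
  subtly from a local-alignment identity as reported by heuristic
  search tools; on full-length amplicons the two agree closely, but
  thresholds tuned for one are not exactly portable to the other.
* Gaussian modelling of proportions ignores the simplex constraint;
  with few replicates near 0 or 1 its intervals can spill outside
  [0, 1].
* The additive mixture model excludes heteromeric subunit interaction
  by design; systematic curvature in mixture residuals would be
  evidence against it and is not detected automatically.
* Synthetic generators state idealized error models; conclusions about
  real recordings, real nanopore runs or real flies require the
  corresponding real-data checks.
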