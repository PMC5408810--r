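---
title: "Methods: single-sample Noob, virtual arrays and cell-type deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sample Noob, virtual arrays and cell-type deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylite)
```

`methylite` implements a preprocessing stack for Illumina Infinium
methylation BeadChips (450k/EPIC style) organized around three ideas:
background correction from out-of-band measurements with a *single-sample*
dye-bias step (ssNoob), probe-level harmonization of different array
generations into *virtual arrays*, and reference-based cell-type
deconvolution that works across platforms. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic test bed does and does not establish.

## The signal model

An Infinium probe reports a methylated intensity $M$ and an unmethylated
intensity $U$. Type I probes read two bead addresses in a single color
channel; Type II probes read one address in both channels. The methylation
level is summarized as a Beta value

$$\beta = \frac{M}{M + U + c},$$

with offset $c \ge 0$ (default 100 intensity units, the conventional
choice) stabilizing low-intensity probes, or as the M-value
$\log_2\{(M + c')/(U + c')\}$ (pseudocount $c' = 100$). With $c = 0$ and
$M = U = 0$ the ratio is 0/0; we return 0 with a warning, treating empty
signal as unmethylated-unknown.

### Normal-exponential background correction with out-of-band probes

Each observed intensity is modeled as $X = S + B$ with true signal
$S \sim \mathrm{Exp}(\text{mean } \alpha)$ and optical background
$B \sim N(\mu, \sigma^2)$. Type I probes read in their *non*-designated
channel (out-of-band, OOB) carry no target signal, so they are direct
draws from the background distribution. Per sample and channel we
estimate:

* $(\mu, \sigma)$: joint Huber location/scale (Proposal 2, tuning constant
  $k = 1.5$, iterated to relative tolerance $10^{-6}$) of the OOB
  intensities. The robust estimator shrugs off hot beads; a plain mean/sd
  mode (`method = "mean"`) is kept for oracle comparisons.
* $\alpha$: Huber location of the pooled in-band intensities of the
  channel, minus $\mu$, floored at `alpha_floor = 10` intensity units.

The corrected signal is the posterior mean $E[S \mid X = x]$. Because the
posterior of $S$ is a normal with mean $m = x - \mu - \sigma^2/\alpha$ and
sd $\sigma$ truncated to $(0, \infty)$,

$$E[S \mid X = x] = m + \sigma\,\frac{\phi(m/\sigma)}{\Phi(m/\sigma)}.$$

An `offset` (default 15 units) is added afterwards, the conventional guard
against near-zero denominators in downstream ratios.

Two properties of the estimators deserve a note. First, the Huber location
of the *foreground* — an exponential convolved with a normal, strongly
right-skewed — sits below the distribution mean, so $\alpha$ is estimated
with a negative bias of roughly 10–15% when signal dominates background.
This is intrinsic to using a robust location on a skewed distribution and
is accepted in exchange for outlier resistance; the correction itself is
insensitive to moderate mis-estimation of $\alpha$ (it only shifts $m$ by
$\sigma^2/\alpha$). Second, the pooled foreground of a real (or simulated)
array mixes exponentials with means $\alpha w$ across probes, so the
fitted $\alpha$ is an effective signal scale, not the per-probe truth.

### Dye-bias equalization: reference vs single-sample

The two color channels have systematically different gains. Normalization
control probes measure this: C/G-extension controls read in the green
channel, A/T-extension controls in the red channel, and their per-sample
averages $(\bar g_s, \bar r_s)$ estimate the channel gains. Equalization
rescales every Grn-channel signal by $L/\bar g_s$ and every Red-channel
signal by $L/\bar r_s$ for a reference level $L$:

* **reference mode** (classic Noob): $L = (\bar g_{\mathrm{ref}} +
  \bar r_{\mathrm{ref}})/2$ from one designated reference sample — the
  whole batch must be available;
* **single-sample mode** (ssNoob): $L_s = (\bar g_s + \bar r_s)/2$,
  computed within each sample. No other sample is consulted, so samples
  can be processed one at a time, in any batching, with bitwise-identical
  results — the property the test suite checks over explicit batch
  partitions.

The midpoint definition of $L_s$ is a design choice (the defining feature
of the single-sample mode is only that $L_s$ is within-sample). We chose
the midpoint because it makes the two modes share the Grn/Red factor
*ratio* exactly: in both modes the ratio of the two scale factors is
$\bar r_s / \bar g_s$. Consequently Beta values computed with offset 0 are
identical between Noob and ssNoob (scale cancels in $M/(M+U)$), and with
offset 100 they differ only through the interaction of the offset with the
per-sample overall scale $L/L_s$ — small when overall brightness is
comparable across samples. The acceptance suite asserts exact agreement at
offset 0 and a $10^{-3}$ bound at offset 100 on the standard fixture;
the offset-100 bound is our own quantification, not a claim inherited
from the reference-mode literature, and it degrades if per-sample overall
brightness varies strongly (see the generator notes below).

## Virtual arrays

Successive array generations share most CpG loci. Two matching rules are
implemented:

* **probe level** (`combine_arrays()`, `convert_array()`): a probe is
  shared only if probe id, design type *and* channel agree — same probe,
  same chemistry. This is the right notion before/at the signal level,
  where chemistry affects the measurement.
* **locus level** (`combine_at_locus_level()`): once methylated and
  unmethylated channels exist, loci are matched by probe id alone; a CpG
  assayed with different chemistry on the two platforms is retained, and
  both native design types are kept for stratified analyses.

Combination never alters a retained value — it is pure row/column
selection plus relabeling; the output manifest is tagged `VIRTUAL` with a
`behaves_as` platform and per-sample native-platform provenance. N-ary
combination is a left fold of the binary operation; an associativity test
guards this.

## Cell-type deconvolution

Given a reference panel of mean Beta profiles for $K$ sorted cell types,
a sample's proportions solve

$$\min_{b} \lVert y - X b \rVert^2 \quad \text{s.t.} \quad b \ge 0,\
\textstyle\sum_k b_k \le 1,$$

a convex quadratic program (solved with `quadprog`; an exhaustive
active-set enumeration serves as the independent oracle in tests). The
inequality sum constraint leaves an implicit "unexplained" component and
is robust to cell types missing from the reference; `sum_constraint =
"eq1"` switches to the simplex. Discriminative probes are chosen on the
reference at its native platform: probes passing a one-way F test across
types at significance $10^{-8}$ are ranked per type by a pooled-variance
two-sample t statistic, and the 50 most hyper- and 50 most hypomethylated
per type are retained (ties broken by probe id for determinism). For a
target on another platform, the target is first cast onto the reference
platform, so estimation uses only probes common to both arrays; the
overlap fraction is reported and a floor (default 50%) guards against
meaningless projections.

## Evaluation statistics

* `replicate_variance()`: unbiased per-CpG variance across technical
  replicates, stratified by design type — the standard measure of residual
  technical variation.
* `median_distance_score()`: per reference sample, the median Euclidean
  distance between its Beta profile and a set of query replicates.
  The field's reports do not pin down the metric; Euclidean is our
  default, Manhattan is available.
* `roc_from_scores()`: threshold sweep with smaller distance meaning
  "predicted same class"; the tie-averaged AUC equals the Mann–Whitney
  statistic (checked against exhaustive pair counting and pROC).
* `get_qc()`: median log2 methylated/unmethylated signal per sample;
  samples whose midpoint falls below 10.5 (default) are flagged.
* `get_sex()`: median log2 copy number (meth + unmeth) over chrX and chrY
  probes; the difference `yMed - xMed` above a cutoff (default −2)
  predicts Male. Cutoffs are reported, never silently applied.

## The synthetic test bed

`sim_config()` pins down a fully generative version of the signal model:
observed intensity $= f_{\text{channel}} \cdot (S + B)$ with
$S \sim \mathrm{Exp}(\alpha w)$ (where $w$ allocates a probe's signal
between meth/unmeth according to its true Beta), $B \sim N(\mu, \sigma^2)$
truncated at zero, OOB entries pure dye-scaled background, and controls
$f \cdot N(\text{control level}, \sigma^2)$.

Default condition values, chosen once as realistic array magnitudes:
background $\mu = 500$, $\sigma = 100$; signal scale $\alpha = 4000$
(median total intensities a few thousand units, as on real chips); bright
controls at 10000 units, 60 per channel; 1000 probes (150 Type I Grn,
150 Type I Red, 700 Type II). Two points deserve explanation:

* **Dye factors** default to channel *imbalance at constant overall
  brightness*: per sample, $f_{\mathrm{Grn}} = b$,
  $f_{\mathrm{Red}} = 2 - b$ with $b \sim U(0.75, 1.25)$ (Grn/Red ratio
  0.6–1.67). Scanner dye bias redistributes intensity between channels;
  overall per-sample brightness is a different artifact that control
  scaling corrects only incidentally. Holding brightness constant
  isolates the effect the dye-bias step targets. It also matters for the
  Noob/ssNoob comparison: the two modes differ by a per-sample overall
  scale $L/L_s$, and with a nonzero Beta offset a scale difference of
  $\delta$ perturbs Beta values by up to about $\delta/4$ at probes whose
  total signal is near the offset — so a fixture with freely varying
  brightness could not honestly meet a $10^{-3}$ Beta-agreement bound at
  offset 100. Explicit `dye_grn`/`dye_red` vectors override the default
  wherever a test wants brightness variation (the replicate-variance
  study draws both factors i.i.d. log-uniform on $[0.7, 1.4]$).
* **Technical replicates** (`shared_signal = TRUE`) share the exponential
  signal draw across samples and redraw only background, dye and
  rounding. Re-hybridizations of one specimen do not resample the
  biology; without sharing, the exponential draw (coefficient of
  variation 1) would swamp the dye effects the normalization removes and
  the replicate-variance comparison would measure nothing.

The generator rounds intensities to integers in [0, 65535] — the on-disk
IDAT representation — so IDAT and CSV round trips are exact. One master
seed drives deterministic substreams keyed by purpose and sample index,
so adding samples to a batch never perturbs earlier samples' draws
(without this, single-sample separability could not be tested honestly).
The background is truncated at zero even though the normexp fit assumes
an untruncated normal — a deliberate, realistic model mismatch; at the
default $\mu/\sigma = 5$ it is negligible, and recovery tolerances absorb
it.

What the synthetic bed does *not* emulate: real manifest content and the
published overlap between the 450k and EPIC designs (the overlap fraction
is a parameter, exercised at 0.933), bead-level replicate counts, spatial
chip artifacts, batch/plate effects, probe cross-hybridization, and real
sorted-cell reference panels (mixture profiles are constructed with
disjoint discriminative blocks, $\Delta\beta \sim U(0.3, 0.9)$, Dirichlet
mixing weights and clipped Gaussian Beta noise). Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
performance on any particular real dataset.

## Numerical choices

* The Mills ratio in the correction is evaluated in log space,
  `exp(dnorm(z, log) - pnorm(z, log))`, accurate far into the left tail;
  the quadrature comparison covers $m/\sigma \in [-20, 20]$ at relative
  $10^{-6}$. A clamp at the smallest positive double guards the
  astronomically deep tail where the exact expression rounds to zero.
* `quadprog` requires a positive-definite cross-product; collinear
  reference profiles trigger a warning and a tiny ridge
  ($10^{-8} \cdot \overline{\mathrm{diag}}$), i.e. the minimum-norm
  optimum is the documented tie-break.
* Probe-selection ties in the t ranking are broken lexicographically by
  probe id; selection is invariant to probe and sample order.
* IDAT parsing is directory-driven (format version 3): unknown field
  codes are never visited, so vendor additions are skipped rather than
  guessed at; other format versions raise an explicit unsupported-version
  error. Gzip is detected by magic bytes and decompressed in memory.

## Problem sizes

The test and acceptance workloads use 1000-probe arrays with 1–10
samples, 100 estimation replicates at 10,000 OOB draws, and 20-sample
mixture panels over 6 cell types — sizes at which every distributional
claim in the suite is stable across seeds while the whole suite runs in
seconds. Real arrays are ~500× larger per sample; all operations are
vectorized per sample and scale linearly in probes, and the streaming
contract of ssNoob means memory never needs to hold more than one sample.

## Known limitations

* The single-sample reference level $L_s$ is one defensible choice among
  several; alternatives (e.g. a fixed absolute level) would also be
  single-sample but would break the exact offset-0 Beta agreement with
  reference-mode Noob.
* $\alpha$ inherits the robust-location bias discussed above; downstream
  corrected signals are insensitive to it, but the logged $\alpha$ should
  not be read as an unbiased signal mean.
* `get_sex()` assumes the manifest annotates chrX/chrY probes and that
  copy number drives their total intensity; aneuploidies will confuse it.
* No Infinium I/II design-bias rescaling, SWAN/quantile/functional
  normalization, or differential-methylation analysis is included — the
  package covers acquisition, Noob/ssNoob, harmonization, deconvolution
  and QC.
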