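---
title: "Methods: from spike trains to combinatorial-coding summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike trains to combinatorial-coding summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and its statistic

In a hydrocarbon deorphanization screen, an ant odorant receptor (OR) is
expressed in the ab2A neuron of *Drosophila* (Orco-GAL4 driving a UAS-OR
transgene) and single-sensillum recordings are taken while a heated cartridge
delivers one cuticular hydrocarbon (HC) at a time. `orscreen` implements the
computation downstream of those recordings.

The response statistic for one trial is a windowed rate difference. Spikes
are counted in a 1 s pre-stimulus window $[-1, 0)$ and in a 200 ms response
window $[0.2, 0.4)$ — the odor needs roughly 200 ms to travel from the
cartridge to the antenna, so the response window is offset from the
stimulus-onset command at $t = 0$. Both counts are converted to frequencies
before subtraction:

$$\Delta = \frac{n_{[0.2,\,0.4)}}{0.2\ \mathrm{s}} - \frac{n_{[-1,\,0)}}{1\ \mathrm{s}}
\quad [\Delta\,\mathrm{spikes/s}].$$

Scaling the 200 ms count by 5 is required for the two terms to share units;
it also makes the statistic's granularity 5 spikes/s, which is why screen
values come out as multiples like 87.5 or 33.0. Each receptor's responses
are then corrected by subtracting the mean $\Delta$ of that receptor's
solvent (pentane) trials — subtraction rather than division, so the
statistic stays in $\Delta$ spikes/s. Replicates (six per stimulus by
default) are aggregated as mean $\pm$ SEM with the $n-1$ standard
deviation.

Two window conventions matter and are fixed package-wide: count windows are
half-open $[a, b)$ so adjacent windows partition time without double
counting, and "above threshold" is a strict inequality (a mean response of
exactly 30 is *below*; the heat-map highlighting convention is read the same
way).

# The synthetic experiment generator

Lab recordings cannot ship with a package, so every stage is validated
against a simulator with known ground truth. It is a first-class module, not
a test fixture.

**Spike trains.** A trial is a piecewise-homogeneous Poisson process:
spontaneous rate $b$ outside the stimulus epoch, evoked rate $e$ inside
$[0.2, 1.2]$ s (a 1 s puff delayed 200 ms), recorded over $[-1, 1.5]$ s. A
2 ms refractory period is enforced by deleting any spike closer than
$\tau$ to the previously kept one. Deletion dead time lowers a Poisson
rate $\lambda$ to $\lambda/(1 + \lambda\tau)$ — a 17% cut at 105 spikes/s,
which would bias every downstream estimate. The generator therefore
compensates: it simulates at intensity $\lambda = r/(1 - r\tau)$, which
makes the realized post-refractory rate equal the nominal rate exactly
(the dead-time renewal process has mean interval $\tau + 1/\lambda$). With
compensation the $\Delta$ estimator is unbiased at any rate; raw thinning
remains available via `compensate_refractory = FALSE`. Rates at or above
$1/\tau = 500$ spikes/s are rejected as unattainable.

**Archetypes.** Each receptor draws one of four generative archetypes,
defaulting to the mix of a 23-receptor screen repertoire (1 narrow, 6
broad, 4 inhibited, 12 non-responders; counts allocated by largest
remainder, shuffled by seed):

* *narrow* — one ligand, drawn among panel HCs of chain length $\ge$ C21
  (screens of this family find no excitatory hits below C21), with true
  $\Delta \sim U[60, 110]$; every other HC near 0.
* *broad* — Gaussian tuning over chain length: center $U[28, 35]$ carbons,
  width $U[2, 4]$, peak $U[30, 60]$ spikes/s. Parameters are redrawn (up to
  200 times) until at least 7 panel HCs sit above the 30 spikes/s
  threshold, so a "broad" receptor is broad by construction rather than in
  expectation only.
* *inhibited* — true $\Delta \sim U[-15, -5]$ on every HC. The spontaneous
  rate of this archetype is raised to 20 spikes/s: with the default
  5 spikes/s baseline a neuron silenced completely only reaches
  $-5\ \Delta$ spikes/s, so suppressions of $-10$ or deeper would be
  unobservable. Broadly inhibited units correspond to recordings with
  elevated spontaneous activity.
* *nonresponder* — evoked equals baseline everywhere.

The baseline default is 5 spikes/s, one sixth of the 30 $\Delta$ spikes/s
responder threshold (the threshold convention is "six times the native ab2A
spontaneous rate").

**Dose curves.** Every pair carries a saturating Hill curve
$\Delta(d) = \Delta_{\max}\, d^h / (ec_{50}^h + d^h)$ with
$ec_{50} \sim U[20, 60]$ nmol and $h \sim U[1.5, 3]$, anchored so the
screen dose (20 nmol) reproduces the drawn screen $\Delta$. With
$ec_{50} \ge 20$ nmol, no pair exceeds 10 $\Delta$ spikes/s at or below
2 nmol — the low-dose silence observed in such screens holds by
construction of the defaults, and `check_low_dose_silence()` verifies it on
dose-resolved estimates. The default dose series is
$\{0.2, 2, 20, 200\}$ nmol: decade steps bracketing the screen dose; the
source screens enumerate only 2 and 20 nmol, so the outer decades are a
package choice, set in configuration. Extrapolating a mid-curve screen
response to 200 nmol can imply implausible firing; evoked rates are clamped
at `max_rate = 300` spikes/s, mimicking spike-rate saturation.

**Seeding.** Randomness splits hierarchically (experiment → receptor →
trial) through a pure integer hash, so a fixed seed reproduces every spike
time byte-for-byte and appending a receptor leaves all other trains
untouched.

**What the generator does not emulate.** Adaptation across repeated
stimulation (screens report both sensitized and depressed responses at the
repeated dose), drifting baselines, recording artifacts, correlated noise
between the A and B units, and cartridge-to-cartridge dose variability.
Passing the recovery tests therefore shows the *computational pipeline* is
correct and well-calibrated for Poisson-like variability at the study's
replication depth; it does not certify performance on pathological
recordings.

# Tuning classification

From the response matrix each receptor gets a profile over its *non-missing*
cells: the count above threshold, the count of inhibitory pairs
($\Delta \le -10$ spikes/s), and the most efficacious ligand (argmax, ties
broken alphabetically). Classes follow the screen's vocabulary: `broad`
($\ge 7$ HCs above 30), `narrow` (exactly 1), `intermediate` (2–6),
and, with no excitatory hit, `inhibited` versus `nonresponder`. The screens
describe inhibited receptors only as having "several" inhibitory pairs; the
package requires $\ge 5$ (`inhibit_min`, configurable) as a documented
stand-in. All thresholds are arguments, never constants.

Dose-response curves are fitted by bounded Levenberg–Marquardt least
squares (`minpack.lm::nlsLM`) to the same Hill form, with
$h \in [0.3, 6]$, $ec_{50} \in [\min(d)/10, \max(d) \cdot 10]$, starting
values $\Delta_{\max} = \max(y)$, $ec_{50}$ at the geometric mid-dose,
$h = 1$. Fits refuse fewer than 3 distinct doses; non-convergence and
all-zero (undetermined) data are reported through a `converged` flag rather
than an error. Pair selection for dose assays uses solvent-normalized
deltas, matching how the screen statistic is defined everywhere else.

# Combinatorial-coding aggregates

The coding summaries treat missing pairs by *elimination*: every sum and
every denominator runs over tested cells only. This is forced by how
combined multi-study matrices are built — 22 of 70 receptors in the
combined repertoire were only ever tested on straight-chain alkanes, so a
global denominator would silently dilute branched-HC columns. The
per-HC "number of tested receptors" is therefore computed per column (the
global-count alternative is not offered; with full grids the two coincide).

* `subfamily_sum()` — cell-wise sums of member receptors per subfamily.
* `mean_response_per_hc()` — summed $\Delta$ over a column divided by its
  tested count; an untested column is missing, never zero.
* `receptivity()` — each response multiplied by the receptor's
  worker-antenna expression (FPKM), giving arbitrary units of
  $\Delta\,\mathrm{spikes/s} \times \mathrm{FPKM}$. Receptors without a
  worker FPKM value are dropped entirely (recorded in the object, reported,
  and excluded from downstream denominators), not zeroed; negative
  responses keep their sign, so inhibition carries negative receptivity.
* `rank_hcs()` — descending order with alphabetical tie-break (documented;
  real screen orderings contain no ties).

Receptivity is scale-equivariant in FPKM: multiplying all FPKM by a
constant rescales every receptivity value and leaves rankings unchanged, a
property the suite asserts, along with agreement of every aggregate with a
brute-force loop oracle on small matrices containing missing cells.

# Name harmonization

Combining receptor tables across annotation generations requires the
printed rename list (packaged as a TSV fixture, 20 renames plus one swapped
pair). The list is *chained* — one entry's new name is another entry's old
name — so `apply_rename_map()` applies all entries simultaneously over the
input vocabulary; sequential application would corrupt the chained and
swapped names. A rename that would collide two names in the output is a
hard error.

# Validation problem sizes

The suite validates at the study's own scale: single screens of 23
receptors × 39 HCs × 6 replicates (897 tested pairs, 5520 trials including
solvent); archetype recovery averaged over 20 independently seeded screens
(460 receptor classifications, observed ≈ 97% against a ≥ 90% requirement);
estimator consistency over 1000 trains at baseline 5 / evoked 105 spikes/s
(3-standard-error agreement with the analytic difference); and EC50
recovery over 100 noisy four-point dose series (median relative error
≈ 3%, required ≤ 25%). `scripts/acceptance.R` recomputes all of these from
scratch for any seed.

# Known limitations

* The packaged panel's cuticle flags, and the expression and subfamily
  tables, are transcriptions/synthetic stand-ins (marked in their headers);
  analyses of real screens should load the laboratory's own tables.
* Four-point dose series leave one residual degree of freedom for a
  three-parameter Hill fit; EC50 values from such designs are usable but
  their slope estimates are fragile, which is why bounds on $h$ are
  enforced rather than estimated freely.
* The two-unit amplitude sorter is deliberately minimal (2-means on peak
  amplitude). Equal-amplitude units are reported as unsortable rather than
  guessed; it is not a general spike sorter.
* Classification near the threshold is noise-limited at $n = 6$: a cell
  with true $\Delta \approx 30$ spikes/s has an SEM near 5.5, so broad
  receptors whose tuning curve barely clears the threshold are the dominant
  source of the ~3% misclassification observed in recovery runs.
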