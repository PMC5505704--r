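---
title: "Models and methods behind afmunfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind afmunfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

afmunfold analyzes constant-velocity AFM force spectroscopy of a serial
multi-domain construct — the smMLCK kinase domain with its flanking Fn3
and Ig-like domains on a Strep-tag tether — and ships a Monte-Carlo
pulling simulator with the same state structure. This vignette is the
package's own account of the models, the tunable parameters, the
numerical choices, and what validation on synthetic ensembles does and
does not demonstrate.

## Polymer elasticity and its inversion

Unfolded polypeptide elasticity is modeled by the Marko–Siggia
interpolation formula with persistence length $p = 0.4$ nm and thermal
energy $kT = 4.1$ pN·nm,

$$F(x) = \frac{kT}{p}\left[\frac{1}{4(1-x/L)^2} - \frac14 +
\frac{x}{L}\right],$$

strictly increasing in the extension $x$ and divergent as $x \to L$. An
optional enthalpic backbone correction is exposed through
`wlc_params(backbone_stiffness = K)`: a finite stretch modulus $K$ (pN)
rescales the entropic extension by $1 + F/K$, solved by fixed-point
iteration. The default is $K = \infty$ (correction off), which reduces to
the standard interpolation formula; the corrected variant exists because
high-force segments (Fn3, Ig, detachment, 100–250 pN) probe the regime
where backbone enthalpy becomes measurable, and because the correction's
published forms differ enough that a single constant should be a user
parameter, not a baked-in choice.

The analysis works in contour-length space: each sample $(x, F)$ is
mapped to the contour length $L$ of the WLC branch through it, by
bisection on $L \in (x + 10^{-3}\,\mathrm{nm},\, 10x]$ to a relative
tolerance of $10^{-9}$ (`wlc_inverse_contour()`). Below about 5 pN the
inversion is ill-conditioned — near zero force almost any long contour
length fits — so points under the 5 pN floor are flagged unusable rather
than transformed. The floor is deliberately below the 10–15 pN noise
band: it keeps the usable signal while discarding only the divergent
part.

## Rupture kinetics

Transitions follow Bell-Evans kinetics: escape rate
$k(F) = k_0 e^{F\Delta x / kT}$ over a single barrier at distance
$\Delta x$, which under a loading rate $r$ gives the rupture-force
density implemented in `bell_evans_pdf()` and the most probable rupture
force $F^* = (kT/\Delta x)\ln(r \Delta x / k_0 kT)$. Fits
(`bell_evans_fit()`) maximize the unbinned likelihood in
$(\log k_0, \log \Delta x)$ with $r$ held at its measured value; the
histogram (5 pN bins by default) is kept for display only, because
binned least squares wastes information at these sample sizes. The
likelihood is evaluated in log form so the far tail cannot overflow.

The loading rate entering both fits and simulator calibration is the
median over events of d$F$/d$t$, measured by a linear fit of raw force
against time over the trailing window in which a lightly smoothed force
stays within 10 pN of its pre-rupture peak. Using one estimator on both
sides of the comparison makes the calibration-to-analysis loop
self-consistent.

## Event detection

Curves are denoised with exact 1-D total-variation denoising — the
minimizer of $\tfrac12\sum(y_i-x_i)^2 + \lambda\sum|x_{i+1}-x_i|$,
computed by Condat's direct algorithm — which yields piecewise-constant
output ideal for thresholding force drops. The penalty defaults to
$\lambda = 2\hat\sigma$ with
$\hat\sigma = \mathrm{MAD}(\Delta F)/\sqrt2$, a robust noise estimate
insensitive to the sparse true jumps.

A rupture event is declared where the denoised force falls by at least
`min_drop` (default 15 pN, the upper edge of the instrument noise band)
from a candidate jump to the trough within the following 2 nm of
separation. Two guards remove artifacts: the event index snaps to the
largest single jump inside the fall window, collapsing noise "pre-echo"
candidates on the rising ramp ahead of a real drop, and the pre-drop
denoised level must be at least $0.8 \times$ `min_drop`, which rejects
pure-noise falls in the post-detachment baseline. Events closer than
1 nm merge (largest jump wins; earliest index on ties). The event force
is the *WLC-consistent pre-drop peak*: the local linear trend of the raw
(not denoised) force over the preceding 1 nm, evaluated at the drop.
Raw data avoids the amplitude shrinkage of the denoiser; a fitted trend
avoids the extreme-value bias of a windowed maximum, which at 5 pN noise
would inflate every peak by roughly $+9$ pN. On 500 simulated apo curves
the detector reaches precision and recall of 0.999 against the truth log
for drops of at least 20 pN, with event-force errors within
$\pm 0.5$ pN.

Bending correction subtracts the cantilever deflection
($\mathrm{sep} = z - F/k_c$), and zero force is the mean over the 20 nm
of travel after the last detected drop — normally the detachment
baseline — falling back to the final 20 nm with a warning when no such
window exists.

## Contour profiles, alignment, increments

Usable samples map through the inverse WLC onto a fixed grid (0–250 nm,
0.1 nm step) where a Gaussian kernel density estimate with 1 nm
bandwidth is evaluated by binned convolution (binning error is
negligible at 1/10 of the bandwidth) and renormalized to unit mass.
Curves with fewer than 50 usable points are excluded with a logged,
classed condition rather than an error, so ensemble drivers skip them.

Ensemble alignment is the two-pass scheme: every profile aligns to one
profile drawn uniformly at random (seeded, for reproducibility of the
otherwise arbitrary draw) by the integer grid shift within $\pm 20$ nm
minimizing the summed squared density difference; the mean of the
aligned set forms a template, and a second pass realigns every original
profile to that template, removing most of the bias of the initial
reference choice. Sub-grid refinement is pointless at a 0.1 nm grid
under a 1 nm kernel, so offsets are integer grid multiples.

Increments come from one Gaussian (amplitude, mean, sd) fitted per peak
window on the template by Levenberg–Marquardt least squares; an
increment is the difference of consecutive peak means and its error the
quadrature sum of the two peak standard deviations — quadrature being
the natural combination rule for two independently fitted widths.
Window centres default to the construct's expected branch contour
lengths: base + 3 nm (the S1 branch, after the small S0→S1 release),
then + L1→2, + L2→3, + 30 nm (post-Fn3), each $\pm 12$ nm. Centring on
the post-S0→S1 positions matters: the 3 nm S0→S1 release shifts every
later branch by the same amount. Fits that fail to converge, whose mean
escapes the window, or whose sd exceeds the window width are flagged
unreliable and excluded from increment formation. In apo ensembles the
S1 peak is often too broad to fit reliably — the S1→S2 transition near
30 pN transforms poorly and overlaps the S0 branch — which mirrors the
broad 25–40 nm ridge seen in measured apo data; the ATP-stabilized
condition, where S1→S2 ruptures near 60 pN, is the one that pins L1→2
sharply.

## Transition assignment and statistics

Each detected event's pre-drop branch contour length (inverse WLC of its
peak force and separation) is matched to the nearest expected branch
within 14 nm: S1→S2 on the base+3 branch, S2→S3 one small-lobe release
later, Fn3 after the full kinase, then a 30 nm Ig ladder (reported with
a collapsed `IG` label, since contour position cannot distinguish which
Ig-like domain unfolded first). The final event of a curve whose force
afterwards stays at baseline is labeled `DETACH` regardless of branch —
the tether can rupture from any state. An `override` hook stands where
an interactive review would be; the automated default applies none, and
assignment accuracy is instead measured against simulation truth
(≥ 95% on noisy 500-curve ensembles).

The fingerprint filter accepts curves with at least two labeled
kinase-region events and all branch lengths within the construct's
tether bound, logging a reason per rejection. Force statistics per
transition use the Bell-Evans ML fit; for S2→S3 the primary mode is the
1 pN-bandwidth KDE argmax, because that transition's force sample
deviates from the single-barrier shape (visible here as the superposition
of loading histories after the S1→S2 drop, and in measured data worse).
Fn3 statistics use only curves whose detachment follows the Fn3 event —
the subset on which cross-dataset force normalization is defined — and
`normalize_by_fn3()` rescales every force in a dataset by the ratio of
Fn3 modes, which is idempotent and recovers synthetic miscalibrations
(a constructed 1.2× force error is undone to ±0.02).

Heatmaps bin raw samples of accepted curves on a 750 × 750 grid after a
horizontal shift matching each curve's Fn3 (or, failing that, last)
rupture position to the ensemble median — a deliberately simple
landmark alignment for force-distance space, where no method is
canonical.

## The simulator: what it emulates, and what it does not

`simulate_curve()` integrates the pulling experiment per time step
($1/12500$ s; one sample per 0.064 nm at 800 nm/s): the piezo advances
by $v\,dt$, the cantilever deflection solves the force balance
$k_c d = F_{\mathrm{WLC}}(z - d; L_c)$ by bisection, the recorded force
is $k_c d$ plus Gaussian noise (5 pN sd), and each live transition fires
with probability $1 - e^{-k(F)dt}$, adding its released contour length.
Kinase transitions fire in strict S0→S1→S2→S3 order; Fn3, the Ig-like
domains and detachment compete by first passage throughout, so the
observed mechanical hierarchy is statistical, not enforced — including
the rare curve in which Fn3 unfolds at low force before the kinase,
which the fingerprint filter correctly rejects as non-characteristic.
Detachment ends the curve, followed by a 30 nm zero-force baseline tail.
A curve whose detachment has not fired within 400 nm is truncated with a
warning.

Condition presets encode the ligand signatures as target most-probable
forces: S1→S2 at 30 pN apo, 60 pN with ATP (45/50 pN for ADP/AMP-PNP,
whose stabilization is weaker); S2→S3 at 30 pN, 60 pN with RLC peptide;
Fn3 at 100 pN; Ig-like domains at 200/225/250 pN; a 3 nm, 15 pN S0→S1
barrier present in every condition except Ca²⁺/calmodulin (Ca²⁺ alone
changes nothing); detachment at 105 pN so that it overlaps the Fn3
regime and most curves end either before or after Fn3 unfolding.
Contour releases are 30.8 nm (small lobe), 61.8 nm (large lobe), 3 nm
(S0→S1), and 30 nm for Fn3 and each Ig-like domain, on a 30 nm folded
tether. Barrier distances are fixed per transition: 1.9 nm for the
kinase lobes (low-force conformational transitions have long soft
barriers; the resulting $kT/\Delta x \approx 2$ pN spread keeps their
force peaks sharp and sub-noise ruptures rare), 0.8 nm for S0→S1,
0.4/0.3 nm for the beta-sandwich Fn3/Ig unfolding, 0.5 nm for the
tether.

Rates $k_0$ are then *calibrated*, not stated: an analytic
initialization from the WLC series-compliance loading rate at the target
force, followed by a fixed-point loop (three iterations of a 200-curve
pilot ensemble under a fixed internal seed, isolated from the caller's
RNG stream) that adjusts each $k_0$ until the *reported statistic* — the
Bell-Evans fitted mode at the measured median loading rate, or the KDE
mode for S2→S3 and S0→S1 — matches the target on the pilot's own
censored samples. Iteration is necessary because transitions racing on a
shared branch censor each other: conditioning Fn3 statistics on
"detached after Fn3" removes the high-force tail that lost the race, so
each observed mode depends on every rate. Calibrated presets are cached
per condition and setup within a session.

`simulate_ensemble()` derives per-curve seeds from one master seed
(bit-identical reruns), and replaces a deterministic count
(`round(n * fraction)`) of curves at random positions with
non-characteristic contaminants — a short-range adhesion peak or an
immediate detachment — to exercise the fingerprint filter.

What the simulator does **not** emulate: refolding during retraction,
force-dependent rebinding, cantilever hydrodynamics and finite response
time, baseline drift and long-range adhesion tails, calibration error
between datasets (except when injected deliberately), or the manual
double-checking of assignments that a human analyst performs. Passing
the synthetic recovery tests therefore shows the pipeline is correct and
unbiased *under the generative model's assumptions*; on measured data
the transformation quality near the noise floor, not the pipeline
machinery, remains the limiting factor.

## Validation choices and problem sizes

End-to-end checks run on 500-curve ensembles per condition — enough to
pin each fitted mode to ~1 pN and each increment to well under 1 nm of
sampling error, while a full two-condition run completes in under a
minute — with 200-curve pilots inside preset calibration and smaller
seeded ensembles for unit-level properties. Independent oracles back
every numerical kernel: the inverse WLC against a plain-R
`uniroot` inversion, the denoiser against a box-constrained dual
quadratic program solved by L-BFGS-B, the Bell-Evans mode against
numeric maximization of the density, and the fitted $(k_0, \Delta x)$
against 5000-sample draws across a parameter grid (barrier-distance
recovery within 15%).

Two honest residuals are worth knowing. First, roughly 8–9% of noisy
apo-condition curves lose one kinase event below the detectable-drop
floor (true rupture under ~22 pN) and are rejected by the fingerprint
filter; this is the noise-floor limitation inherent to 30 pN transitions
at 5 pN noise with a 15 pN drop threshold, so filter-level exactness
(100% acceptance of clean ensembles; contaminated-fraction recovery) is
demonstrated on noiseless ensembles at the 10 pN sensitivity appropriate
to noiseless data. Second, the Fn3 force sample is intrinsically
censored by the detachment race; the preset calibration targets the
observed (censored) statistic, which is also what an experiment
measures, and the Ig-like domains unfold only rarely in standard
ensembles for the same reason — suppressing detachment reveals the full
mechanical hierarchy, and the package's tests do exactly that.
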