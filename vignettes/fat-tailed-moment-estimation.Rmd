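---
title: "Moment estimation when the moments may not exist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment estimation when the moments may not exist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildmoments)
```

## The model

A one-species chemical reaction network is a list of reactions, each with a
state change $\nu_j \in \{-1, +1\}$, a rate constant $c_j$ (1/s) and a
propensity $a_j(x)$: the instantaneous firing rate in state $x$, so that
$a_j(x)\,dt$ is the firing probability in $[t, t+dt)$. The master equation
for the state distribution $P(x,t)$ is linear but infinite-dimensional;
this package never integrates it directly. Instead it works with the two
standard moment summaries and asks when they can be trusted.

Four propensity forms are supported — constant, linear $c\,x$, idealized
quadratic $c\,x^2$, and mass-action second order $c\,x(x-1)$ — optionally
gated by a lower guard ($a_j = 0$ below a threshold state). Degree two is
all the study needs and keeps the closed moment equations exact in their
Taylor expansion.

Three named systems anchor the analysis:

* **P** (immigration-death): birth at constant rate 10, death at rate $x$.
  Stationary law Poisson(10); the mild control.
* **ideal / W**: the quadratic birth-death pair $2A \to A$, $2A \to 3A$ at
  unit rates. In its idealized form (pure $x^2$ propensities, death guarded
  by $[x \ge 2]$) the inverse-square law $\bar P(k) = 6/(\pi k)^2$
  satisfies the stationary balance
  $(x+1)^2 \bar P(x+1) + (x-1)^2 \bar P(x-1) - 2x^2 \bar P(x) = 0$
  *exactly*, term by term — a proper stationary distribution with no mean
  and no variance. System W is the physical variant: mass-action $x(x-1)$
  propensities (the count of ordered educt pairs) and a constant
  unit-rate immigration that removes the absorbing hole at $x \le 1$. Its
  rates are fixed by requiring the derived moment equations to come out as
  $d\tilde E/dt = 1$ and
  $d\tilde V/dt = 1 + 2(\tilde E(\tilde E - 1) + \tilde V)$; that match is
  asserted as a unit test.
* **pure growth**: the single reaction $2A \to 3A$ with propensity $x^2$.
  Under the variance-neglecting closure its expectation obeys
  $d\tilde E/dt = \tilde E^2$, which reaches infinity at $t = 1/\tilde
  E(0)$ — finite-time blow-up mirroring the finite escape time of every
  trajectory.

## Truncation closure

The moment equations truncate the hierarchy by setting all central moments
above the variance to zero. For propensities of degree $\le 2$ the
second-order Taylor expansion around $\tilde E$ is exact, so the only
approximation is the closure itself; no truncation-order choice arises.
Coefficients are derived symbolically over the monomial basis
$\{1, E, E^2, V, EV\}$ and kept exact (all study rates are integers), which
makes the printed-equation round-trip tests exact comparisons rather than
tolerance checks. Propensity guards are dropped in the closure — a Boolean
factor has no smooth expansion — matching how the closed equations of the
guarded idealized system are always written without it.

Integration uses `deSolve`'s `lsodar` (adaptive, relative tolerance
$10^{-9}$ by default) with a root function at the divergence threshold
(default $10^8$): lsodar's built-in root localization gives the crossing
time directly, which we adopted in place of a hand-rolled bisection on the
last accepted step — same contract, standard machinery. A non-finite
right-hand side is clamped so the root still fires: quadratic moment ODEs
genuinely blow up, and blow-up is a *result* here, never an error. With
$\tilde E' = \tilde E^2$, $\tilde E(0) = 1$, the threshold $10^8$ is
crossed at $t = 1 - 10^{-8}$; reporting it as the escape time is accurate
to $10^{-8}$, far inside the $10^{-2}$ tolerance used in the checks.

## The SSA engine

The direct method: in state $x$, wait $\tau \sim
\mathrm{Exp}(\lambda = \sum_j a_j(x))$, then fire reaction $j$ with
probability $a_j(x)/\lambda$. Two conventions matter downstream:

* **Draw counting.** `draw_count` counts every waiting-time draw including
  the final draw that crosses `t_end` without being committed. A
  trajectory of the fat-tailed system that ends at $x = 1$ (its start) has
  taken an even number of $\pm 1$ events, hence an odd draw count — the
  parity signature the diagnostics assert. If the total propensity is zero
  the trajectory rests with zero draws.
* **Reaction caps.** Fat-tailed and explosive systems produce trajectories
  whose step count is unbounded (escaped trajectories fire quadratically
  faster as they grow), so every simulation carries a cap (default 10 000
  committed reactions; the fat-tailed ensembles here use 5 000). Capped
  trajectories are retained and flagged, never dropped; estimators exclude
  them with an explicit count. The bias direction of that exclusion is
  known: capped trajectories are exactly the escaped ones, so tails — and
  with them means and variances — are *under*estimated. For escape-time
  analysis the cap works in our favour: the cap-hitting time is the escape
  proxy, censored at `t_end` when the horizon arrives first.

Recording uses $\{0\}$ plus 1000 logarithmically uniform points between
`t_min` and `t_end`, right-continuous piecewise-constant evaluation. The
paperless parameter here is `t_min`, set to $10^{-3}$ s: early times are
where a deterministic start decays fastest, and three decades below the
horizon covers every feature the analyses inspect. Trajectory $i$ of an
ensemble is seeded with `base_seed + i`, so ensembles are reproducible and
independent of execution order; the compiled inner loop draws from R's own
RNG stream.

## Estimators and diagnostics

The bias-free estimators $\hat E^n = \frac1n \sum_i x^{(i)}$ and $\hat V^n
= \frac{1}{n-1} \sum_i (x^{(i)} - \hat E^n)^2$ are computed as prefix
series over growing $n$ in one streaming (Welford) pass, checked against
the two-pass textbook formulas; $\hat V^1$ is reported as undefined, not 0.
Convergence of the prefix series is the operative diagnostic: mild samples
settle, wild samples keep jumping at any $n$.

Two threshold-free summaries quantify the jumping. The *gap* at sample $i$
is $|\log \hat V^i - \log \hat V^{i-1}|$ (on the mean series when a
variance prefix is nonpositive, flagged) — the log scale is the natural one
because wild estimators range over orders of magnitude, and no numeric
cutoff is imposed since any such cutoff would be arbitrary: ranking is
reported, the user judges. The *dominance ratio* is the largest
single-sample share of the final variance sum, in $[0,1]$.

Tail slopes come from ordinary least squares on $(\log k, \log \hat P(k))$
over nonzero bins (zeros dropped, no pseudocounts — pseudocounts would
manufacture tail mass). A polynomial tail $k^{\alpha}$ needs
$\alpha < -(m+1)$ for the $m$-th moment series to converge, so the
classification maps slope $\ge -2$ to "no mean", $[-3, -2)$ to
"no variance", below $-3$ to "all moments may exist" — applied to the 95%
band of the fitted slope, returning "inconclusive" when the band straddles
a boundary (the underlying criterion is a visual straight-line judgement;
the band makes it honest) or when fewer than 4 support points fall in the
fit range. Boundary slopes classify into their closed region with a
$10^{-9}$ guard so that exactly-tabulated power laws land deterministically.
The default fit range, 90th-percentile state up to the largest state seen
at least 5 times, keeps the fit in the tail but out of the noise floor.

Step counts per fixed horizon are the hardware-independent run-time proxy:
`step_stats` reports their mean (uncapped), the fraction exceeding a
threshold (capped trajectories count as exceeding whenever the cap does),
the odd fraction, and the fraction resting at a reference state at the
horizon (capped trajectories count as absent — a conservative convention
that can only lower the reported fractions).

## Reference distributions as synthetic data

The generator module produces the three illustrative samples: normal and
log-normal with common mean $e$ and variance $e^4 - e^2$ (the log-normal's
$\mu = 0$, $\sigma^2 = 2$ follow uniquely from those two equations), and
the inverse-square law. Inverse-square draws invert exact cumulative sums
up to $k = 10^6$ — covering all but $\sim 6\times 10^{-7}$ of the mass —
and the continuous Pareto tail $P(X > k) \approx 6/(\pi^2 k)$ beyond; the
switchover keeps the table bounded while staying exact where the mass
lives. The normal sample is deliberately not truncated at zero even though
molecule counts cannot be negative: it illustrates mild randomness, not a
chemical system.

What the synthetic ensembles emulate is the *distributional regime* —
mild versus wild — under exactly known ground truth. What they do not
emulate: multi-species coupling, propensities above degree two,
measurement noise, or any inference from real data. Tests passing here
show the estimators and detectors behave as theory predicts on systems
engineered to exercise them; they do not show that a given laboratory
system is (or is not) fat-tailed.

## Scale choices

Stochastic checks run at 2000–5000 trajectories with a 5000-reaction cap
for the fat-tailed system: an uncapped fat-tailed ensemble has unbounded
total step count (single escaped trajectories can dwarf the rest of the
ensemble combined), so capping is a methodological necessity, not merely a
convenience, and the capped fractions are reported alongside every
estimate. The early-time tail fit in the diagnostics uses 5000
trajectories because at $t \approx 0.05$ s most trajectories still rest at
the start and at least four occupied states are needed for a slope.
Analytic anchors (stationary balance over states 2..1000, normalization
partial sums to $K = 10^7$, closed-form moment solutions, the $1/E(0)$
blow-up law) carry the burden of exactness independent of ensemble size.

## Limitations

* One species only; the moment equations generalize but the bookkeeping
  (covariances) does not exist here.
* Truncation closure only; normal, log-normal or derivative-matching
  closures are out of scope, as are moments above order two.
* The tail-slope classifier assumes an eventually polynomial tail; it is
  not a general tail-index estimator (no Hill/MLE variant).
* Capped-trajectory exclusion biases late-time moment estimates downward;
  the exclusion counts let the user see how much of the ensemble is gone.
* For the physical fat-tailed system the inverse-square stationary law is
  an idealization argument, not a theorem: the balance is verified exactly
  for the idealized pure-$x^2$ system, and the physical system is checked
  numerically (tail slopes approaching $-2$, diverging prefix series).
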