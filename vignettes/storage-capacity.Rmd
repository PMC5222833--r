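---
title: "Storage capacity of Hopfield networks with autapses: model, theory, and simulation design"
author: "hopcapacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storage capacity of Hopfield networks with autapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopcapacity)
```

## The model

A network of $N$ binary neurons $s_i \in \{-1, +1\}$ evolves under the
deterministic, synchronous (parallel) sign dynamics

$$s_i(t+1) = \mathrm{sign}\Big[\sum_{j=1}^N J_{ij}\, s_j(t)\Big],$$

with no external input and no thermal noise. To act as an associative
memory, the coupling matrix is built from $P$ training patterns
$\xi^\mu \in \{-1,+1\}^N$ by the Hebbian rule
$J_{ij} = \frac{1}{P}\sum_\mu \xi_i^\mu \xi_j^\mu$. The package's central
object of study is the role of the *diagonal* of $J$: retaining it gives
every neuron a self-coupling (an autapse) of strength exactly 1, whereas the
classical Hopfield convention forces $J_{ii} = 0$. The two conventions have
dramatically different behavior at high storage load $\alpha = P/N$: with
autapses the local field of a stored pattern acquires a coherent term of
weight $N + P - 1$ that *grows* with $P$, so retrieval errors vanish again
for $P \gg N$; without them the coherent weight is only $N - 1$ and errors
saturate.

Everything here rests on **one-step stability**: a pattern counts as
retrieved iff a single synchronous update leaves it unchanged. Limit cycles
are never counted as successful retrieval, which is why one update
determines all the error statistics; the multi-step `evolve()` machinery is
provided separately for studying transients and cycles.

### sign(0)

The dynamics must decide what `sign(0)` means: with $N \cdot P$ even the
local field can be exactly zero. The package maps `sign(0)` to $+1$,
uniformly, everywhere (dynamics, exhaustive enumeration, Monte Carlo). This
makes every trajectory fully deterministic and makes the exhaustive oracle
and the simulator agree bit for bit. Any fixed tie-break is equally
defensible; results at the sizes studied are insensitive to the choice, but
bit-exact comparison across implementations requires fixing it.

## The analytic theory

Writing the one-step local field of a stored pattern as a coherent term plus
a noise term $T$ pooled over $(N-1)(P-1)$ crossed products, and
approximating $T$ as a zero-mean Gaussian with variance $(N-1)(P-1)$, the
single-bit error probability is

$$p_B = \tfrac12\left[1 - \mathrm{erf}\!\left(\frac{N+P-1}
{\sqrt{2(N-1)(P-1)}}\right)\right],$$

with numerator $N-1$ in the zero-diagonal convention. The vector- and
set-level quantities follow exactly: $p_V = 1-(1-p_B)^N$ and $N_V = P p_V$.
Three numerical points matter:

* **Tail stability.** $1-\mathrm{erf}(x)$ underflows catastrophically past
  $x \approx 6$ if computed literally; the high-load regime lives entirely
  in that tail. All tail probabilities go through
  `pnorm(..., lower.tail = FALSE)`, accurate to about $10^{-300}$, and
  $p_V$ uses `expm1`/`log1p` so that $p_V \approx N p_B$ survives when
  $p_B \sim 10^{-20}$.
* **Degenerate inputs.** $P = 1$ or $N = 1$ zero the noise variance. The
  Gaussian formula is then replaced by the exact statement: error
  probability 0 when the coherent term is positive. A log notice is
  emitted.
* **Validity boundary.** When $(N-1)(P-1) < N+P-1$ the coherent term
  exceeds the largest possible noise value and the *true* error probability
  is exactly zero while the Gaussian formula is small-positive. The CLI
  warns when a request falls in this regime, and Monte-Carlo tests compare
  against the exact statement there, not against the formula.

The asymptotic forms (obtained by the erf tail expansion and
$(1-p_B)^N \approx 1 - N p_B$) restore the $N \leftrightarrow P$ exchange
symmetry that the exact $N_V$ lacks. They are accurate near the
perfect-recovery contour $N_V \approx 1$ — at $N = 1000$ the relative error
is under 5% — but they are *not* uniformly valid: deep in the error tails at
small $N$ the dropped $-1$ terms enter the exponent and cost factors of
$e$. The test suite pins the approximation quality where it genuinely
holds (e.g. 18% at $N = 100$, $P = 2330$) rather than asserting a blanket
tolerance.

### Spurious states and discrimination

For a random probe outside the training set the coherent autapse
contribution is only $P$, giving the rejection probabilities
$\bar p_B, \bar p_V$ and the discrimination ratio
$\rho = \bar p_V / p_V = \frac{1+\alpha}{\alpha}e^{1+1/(2\alpha)}$,
which decreases monotonically to the limit $e \approx 2.718$. The finite
limit is the headline property: even when $J$ is dominated by its diagonal,
stored memories remain about 2.7 times more reliably retrieved than random
probes. The large-$N$ form of $\bar p_V$ is valid in the window
$N \ll P \ll N^2$; the tests evaluate it at $(N, P) = (500, 10^4)$ and
$(1000, 2\times10^4)$ where the relative error is below 10%.

## The perfect-recovery threshold

Setting $N_V = 1$ in the high-load regime and squaring gives
$\alpha e^{-\alpha} = 2\pi/N^4$, inverted by the Lambert function's $-1$
branch, $P(N) = -N W_{-1}(-2\pi/N^4)$, or approximately
$P(N) = N[\ln(N^4/2\pi) + \ln\ln(N^4/2\pi)]$. Three routes are computed and
reported side by side:

1. a bracketed `uniroot` search solving the exact $N_V(N, P) = 1$ over real
   $P$ (relative tolerance $10^{-9}$), on either the high-load branch
   ($P > N$) or the classical low-load branch ($P < N$);
2. the Lambert-W inversion, where $W_{-1}$ is computed by Halley iteration
   started from the log expansion (or from the branch-point series in
   $\sqrt{2(1+ex)}$ near $x = -1/e$, where the log guess is poor and plain
   iteration risks jumping to the principal branch), converged to a
   relative back-substitution residual below $10^{-12}$;
3. the logarithmic expansion. The $2\pi$ under the logarithm is
   forced by the derivation ($x = 2\pi/N^4$ in $-\ln x + \ln(-\ln x)$).

The threshold is continuous in $N$, so it is reported as a real number,
with the ceiling attached as the first guaranteed integer storage level.

A caution learned from the numbers: routes 2–3 agree with each other to
well under 2% for $N \ge 100$, but both sit systematically *above* the
exact root of route 1 — by 13% at $N = 100$, 8% at $N = 1000$, decaying
only logarithmically — because they inherit the asymptotic approximations.
Code that needs the exact contour should use the numeric root; the closed
forms are for scaling insight ($P(N) \gtrsim 4N\ln N$).

## The Monte-Carlo design

`estimate_retrieval()` re-creates the simulation protocol: per realization,
draw a fresh random training set, build $J$, present every stored pattern,
apply exactly one synchronous update, count flipped bits and imperfect
vectors. Defaults mirror the study conditions: networks of $N = 50..200$,
loads $P = 1..2000$, 1000 realizations per cell (the acceptance-scale grid
uses exactly that; unit tests use smaller replicate counts chosen only for
brevity, with correspondingly wider binomial tolerances).

Design choices where the protocol was open:

* **Pooling.** Bit and vector counts are pooled across realizations
  (identical expectation to averaging per-realization proportions, smaller
  variance); the per-realization proportions are recorded alongside.
* **Confidence intervals.** 95% Wilson score half-widths, which remain
  valid for proportions near 0 — most of the interesting regime.
* **Seeds.** One integer seed per experiment; realization $r$ re-seeds from
  a deterministic fold of $(\mathrm{seed}, r)$, and sweep cells fold
  $(\mathrm{seed}, N, P, \mathrm{convention})$ first, so any cell of any
  sweep can be reproduced in isolation and results do not depend on
  execution order.
* **Spurious probes.** The number of probes per realization is a free
  parameter; the default is $P$, mirroring the stored-pattern sample size.
  Probes colliding with a stored pattern are redrawn (probes must lie
  outside the training set); when no state outside the training set exists
  (possible only for tiny $N$) the operation reports a domain error.
* **Duplicates.** Random pattern sets may contain duplicates; they are kept
  and counted independently, matching the error-statistics convention.

What the generator emulates — and does not. Training sets are uniform,
independent fair spins, exactly the ensemble the closed forms assume.
Correlated or sparse memories, graded activity, dilution and asynchronous
or stochastic dynamics are all outside the model; agreement of simulation
with theory here validates the formulas *for this ensemble*, not for
structured real-world data.

## Exhaustive oracles and the fixed-point census

Two enumeration tools anchor the stochastic machinery:

* `exhaustive_bit_error()` averages the one-step bit-error fraction over
  *all* $2^{NP}$ pattern matrices ($NP \le 20$), giving the exact rational
  value the Monte-Carlo estimator must converge to — an oracle entirely
  independent of both the Gaussian theory and the RNG.
* `count_fixed_points()` tests every one of the $2^N$ states ($N \le 22$,
  processed in chunks of $2^{14}$ states so memory stays bounded) for
  one-step invariance.

`estimate_gamma()` uses the census on random fully connected symmetric
matrices — independent standard-normal off-diagonal weights, zero diagonal,
the spin-glass convention of the metastable-state literature (the ensemble
is a modelling choice: the weight distribution is not pinned down by the
scaling law itself) — and fits mean $\ln(\text{count})$ against $N$ by
least squares over $N = 10..16$ with 100 matrices per size. That range is
large enough for the exponential law to dominate its polynomial prefactor
yet cheap enough to enumerate exhaustively; the fitted slope lands at
$\gamma \approx 0.20$ nats per neuron with a standard error near 0.006,
consistent with the known exponential proliferation of metastable states in
random symmetric networks. A degenerate closed-form check (identity
couplings, count $2^N$, slope exactly $\ln 2$) exercises the same
census-plus-fit path.

## Known limitations

* The Gaussian noise model treats the $(N-1)(P-1)$ noise terms as
  independent; they are only pairwise independent (they share $\xi$
  factors). The closed forms are implemented as stated and validated against
  simulation within binomial tolerance, not asserted as exact.
* On the integer grid the exact maximum of $p_B$ at fixed $N$ sits at
  $P = N + 1$, not $P = N$ (the continuous argmax of the erf argument is at
  $P - 1 = N$); the peak load still tends to 1 for large networks, which is
  the meaningful statement.
* Basin-of-attraction sizes, multi-step convergence of non-training probes
  onto training fixed points, finite-temperature dynamics and the classical
  replica capacity $\alpha_c \approx 0.14$ are out of scope throughout.
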