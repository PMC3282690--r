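# smtrace

Kinetic analysis of single-molecule intensity time series — smFRET
donor/acceptor photon counts, single-channel fluorescence, or any other
trace that hops between discrete intensity levels.

## The problem

A single-molecule trace records one molecule until its fluorophore
photobleaches. The kinetics of interest (transition probabilities
between conformational states) are hidden behind shot noise, and the
amount of information per molecule varies enormously: trace length,
signal-to-noise ratio (SNR), and the number of observed transitions all
differ from molecule to molecule. Analyses that ignore this — notably
threshold crossing — systematically mistake noise for kinetics: at low
SNR, spurious crossings inflate rate estimates until they converge to
0.5 per time step, and a homogeneous population imaged at two SNRs can
masquerade as two kinetically distinct subpopulations.

`smtrace` implements the statistically grounded alternative:

* **Per-molecule hidden Markov model fits.** Each trace is fit by
  maximum likelihood (Baum-Welch) under a user-specified kinetic +
  emission model: arbitrary state counts and transition topologies,
  Poisson or Gaussian emissions per channel, emission ties (states that
  produce identical signals), and an optional detailed-balance
  (thermodynamic closure) constraint `pi_i A_ij = pi_j A_ji` for
  experiments at equilibrium. Channels are fitted directly — no FRET
  ratio is formed, so the noise model of each channel is honored. The
  likelihood is the forward contraction
  `p(x_{1:T}) = 1' (prod_t E_t A') pi_0`, with `A` the transition
  probability matrix and `E_t` the per-state emission densities.
* **Likelihood-ratio confidence intervals** for every fitted parameter:
  the parameter is varied around its MLE and the bounds are where the
  log-likelihood drops by `chi^2_1(level)/2` (1.3529 at 90%).
* **BIC model selection** across a model menu,
  `BIC = -2 log L + k log N`, with careful free-parameter bookkeeping
  (a detailed-balance constraint on a 3-cycle removes exactly one
  parameter; the initial distribution is tied to the stationary
  distribution and counts zero).
* **A thresholding baseline** (dwell-time extraction + geometric/
  exponential dwell MLE, censored dwells dropped, traces with fewer
  than two transitions excluded) for method comparison.
* **Uncertainty-weighted clustering** of molecules on up to three
  fitted parameters: an EM mixture in which each molecule carries its
  own covariance derived from its confidence intervals, so precisely
  measured molecules dominate cluster placement and apparent
  heterogeneity is judged against per-molecule uncertainty.
* **A simulator** with photobleaching-coupled trace lengths
  (`T x SNR = c`: more excitation power buys SNR but shortens the
  trace), Poisson or Gaussian emissions, and per-trace reproducible RNG
  streams. For a single Poisson channel with state means `mu_1, mu_2`,
  `SNR = |mu_2 - mu_1| / sqrt((mu_1 + mu_2)/2)`; independent channels
  combine in quadrature.

Everything is headless and scriptable; a thin CLI
(`inst/scripts/smtrace`) exposes
`simulate | fit | ci | select | threshold | cluster | experiment`.

## Worked example

Simulate one two-state molecule at SNR 5 (`k12 = k21 = 0.3`, Poisson
means 100 / 156.6, trace length `T = c/SNR = 2000` with `c = 10^4`),
fit it, and ask whether the data support two states at all:

```r
library(smtrace)
truth <- hmmParams(twoStateMatrix(0.3, 0.3),
                   mu = c(100, meansForSnr(5, 100)))
tr  <- simulateTrace(simConfig(truth, snr = 5, c = 1e4), seed = 42)
fit <- fitHmm(tr, modelSpec("2-state", 2))
fit
#> HmmFit of trace 'sim-42-1' to model '2-state'
#>   loglik = -8879.2979 after 4 iteration(s) (converged)
round(fittedParams(fit)@A, 4)
#>        [,1]   [,2]
#> [1,] 0.6986 0.3014
#> [2,] 0.3096 0.6904
confidenceInterval(tr, fit, "A[1,2]", level = 0.9)
#> k12 MLE 0.3014, 90% CI [0.2775, 0.3255]   (true value 0.3)
selectModel(list(fitHmm(tr, modelSpec("1-state", 1)), fit), tr)
#>     model     loglik k    N      bic deltaBic
#> 1 2-state  -8879.298 4 2000 17789.00    0.000
#> 2 1-state -13803.716 1 2000 27615.03 9826.033
```

The fitted transition probabilities bracket the truth, the 90% interval
quantifies the single-molecule uncertainty, and the BIC overwhelmingly
prefers the two-state model at this SNR.

Population-scale studies are one call each: `runSnrSweep()` (HMM vs
thresholding across SNR), `runModelSelectionStudy()` (six-model BIC
menu on three-state data), `runClusteringStudy()` (two kinetic
subpopulations), `runMixedSnrDemo()` (homogeneous population at mixed
SNR — the cautionary example above).

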