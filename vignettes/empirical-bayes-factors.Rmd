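---
title: "Empirical Bayes factors from summary statistics: models, biases and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical Bayes factors from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebfactor)
```

## The problem

Bayes factors for composite hypotheses need a prior on the parameter, and
from a position of genuine ignorance there is no satisfactory objective
choice: improper priors make the marginal likelihood ill-defined, and
"default" proper priors can be subjectively unreasonable.  The *posterior*
Bayes factor sidesteps this by re-using the posterior distribution from
the data at hand as the prior in the marginal likelihood for the same
data.  The cost is a bias: using the data twice systematically overstates
the evidence relative to a proper Bayes factor whose prior carries the
same amount of information.

This package implements the bias-corrected version, the *empirical Bayes
factor* (EBF).  The calibration target is a marginal likelihood whose
prior is the posterior from hypothetical *replicate data* — data
exchangeable with the observed data, in particular of the same size.  For
hypothesis $H$ with parameter region $\Theta_H$, posterior marginal
likelihood $M_H(x)$ and expected bias
$E_Y b_H(Y) = E_{X,Y}\big[\log M_H(X) - \log \int_{\Theta_H} f(X\mid\theta)\,
\pi(\theta\mid Y)\,d\theta \big/ \textstyle\int_{\Theta_H}\pi(\theta\mid Y)\,d\theta\big]$
(the expectation taken over the joint prior predictive of data and
replicate), the EBF in favour of $H_0$ over $H_1$ is

$$\mathrm{EBF}_{01}
 = \frac{M_{H_0}(x)\,e^{-E_Y b_{H_0}(Y)}}{M_{H_1}(x)\,e^{-E_Y b_{H_1}(Y)}}.$$

Everything else in the package is the computation of $M_H$ and
$E_Y b_H(Y)$ for the common test families, plus a multiple-testing
extension and an interpretation scale.

## Likelihood families

**Normal (z and chi-squared).** With likelihood
$\phi(x;\mu,\sigma^2)$ and a flat prior, $M_H$ on any region is a ratio of
normal cdf masses times $(4\pi\sigma^2)^{-1/2}$ — every integral is a cdf
difference, so the package evaluates these *exactly* with `pnorm` rather
than by quadrature.  The expected bias is $d/2$ for an unrestricted
$d$-dimensional mean, $1/4$ per one-sided component when both signs are a
priori possible, $1/2$ when the opposite sign is impossible by
definition, and $0$ for point and finite-interval hypotheses.  The
directional and interval values are *flat-prior limits*: the realised
bias at a fixed mean differs (this is why the Monte Carlo oracle below
restricts the normal family to the pivotal unrestricted case).  The
closed forms delivered by `ebf_z_twosided()`, `ebf_z_onesided()` and
`ebf_z_directional()` follow, e.g.
$\mathrm{EBF}_{01} = 2^{d/2} e^{-(z^2-d)/2}$ for the two-sided test.  On
the deviance scale the unrestricted corrected marginal likelihood equals
the maximised deviance penalised by $d(1+\log 2) \approx 1.69\,d$
(`deviance_criterion()`), an information-criterion-like quantity that
remains interpretable as a Bayes factor.

**Student t.** For an estimate with standard error $s$ and $\nu$ degrees
of freedom, the product of the two t densities in $M_H$ collapses
analytically to a scaled t with $2\nu+1$ df, so region masses are again
exact cdf differences.  The expected bias has no closed form; after
standardisation it reduces to a single integral over the lag
$D = X - Y$,
$$E_Y b_H(Y) = \int g_\nu(d)\,\{\log C(\nu) - \log g_\nu(d)\}\,dd,$$
where $g_\nu$ is the convolution density of two independent t variates
— i.e. $\log C(\nu)$ plus the differential entropy of $D$.  This
reduction (rather than literal 2-D quadrature) is the package's main
numerical design choice for the t and F families: it cuts the cost to
nested 1-D adaptive quadrature and is verifiable against a closed form at
$\nu = 1$, where $D$ is Cauchy with scale 2 and the bias is exactly
$\log 4 = 1.386$.  The heavy Cauchy tails are handled by splitting the
inner integral at its symmetry point with log compression of the
inter-peak trough, and truncating the outer integral at
$\max(10^6,\,2\,t_\nu^{-1}(1-10^{-8}))$; target absolute accuracy is
$5\times10^{-4}$, supporting 3-figure table reproduction.  Values are
cached per $\nu$; non-integer $\nu$ (fractional Wald df) is accepted.

**Binomial and negative binomial.** With a symmetric
$\mathrm{Beta}(\alpha,\alpha)$ prior the marginal likelihood is a ratio
of Beta functions times incomplete-Beta masses, all in log space so
counts in the thousands are safe.  The default is $\alpha = 1$: it is the
only choice whose prior predictive for the count is uniform,
$\Pr(x) = (n+1)^{-1}$, which matters because the expected bias is an
expectation *over that predictive*.  The bias is an exact
$(n+1)^2$-term double sum (`binom_bias()`), reproducing e.g. $\frac13\log 2$
at $n = 1$ by direct enumeration.  When the success count rather than the
trial count is fixed by design, the same Beta algebra yields the
negative-binomial EBF; its prior predictive over trial counts has
infinite mean, so `negbinom_bias()` evaluates the expectation by
vectorised Monte Carlo over the exact predictive
($p \sim \mathrm{Beta}(\alpha,\alpha)$, $n \sim x + \mathrm{NegBin}$)
with a fixed internal seed.  Fixing $x$ is our interpretation of
"replicate data of the same size" for this sampling model; it is the
quantity the design holds constant.  `ebf_binom_averaged()` averages the
bias-corrected marginal likelihoods across the two sampling models
(equal weights by default) for when the sampling scheme is uncertain.

**F / ANOVA.** For a scale ratio $r$ with improper prior
$\pi(r)\propto 1/r$, the squared F density collapses to an F with doubled
degrees of freedom, giving closed cumulative forms for any region of $r$;
the one-sided ANOVA comparison is $H_0: r = 1$ against $H_1: r < 1$.
Values $r > 1$ are implausible by construction there, so the one-sided
alternative carries the *unrestricted* expected bias — computed, like the
t bias, by scale-invariance reduction: the bias equals
$\log[B(\nu_1,\nu_2)/B(\nu_1/2,\nu_2/2)^2]$ plus the entropy of the
ratio of two independent F variates, with the inner density integrated
on the log scale against the heavy right tail.  At $(1,1)$ the ratio
density has the closed form $\log w/(\pi^2\sqrt w\,(w-1))$, used as a
cross-check.  All composite scale regions carry this bias; intermediate
df are always recomputed (and cached), never interpolated.

**P-values only.** When nothing but a P-value is available it is modelled
as $\mathrm{Beta}(1,\beta)$, $\beta > 1$, under the alternative and
uniform under the null.  The posterior marginal likelihood has the closed
form $M_H(p) = -(1 - 2L + 2L^2)/\{4L(1-L)\}$ with $L = \log(1-p)$
computed via `log1p`, which is exact to machine precision for arbitrarily
small $p$ — no separate small-$p$ expansion is needed once the three
positive terms are factored this way (the spec'd cancellation risk
applies to the raw $1/L^3$ form, not to this arrangement).  The bias
correction is the constant $\log(5/2) = 0.916$; `pvalue_bias()` evaluates
the fixed-$\beta$ double integral and finds values 0.86–0.92 for $\beta$
between 1.5 and 50, so the constant is an adequate default though the
"wide range" is flatter at large $\beta$ than near $\beta = 2$.  For
small $p$ the EBF reduces to the rule of thumb
$\mathrm{EBF}_{01} \approx 10p$, within 2% of exact for $p \le 0.01$;
`ebf_pvalue(method = "approx")` warns above $p = 0.1$.  $p \in \{0,1\}$
is rejected rather than clamped; the table interface offers an optional
floor (default $10^{-300}$) for pipeline robustness.

## Multiple testing

For $m$ tests with known standard errors sharing a region $\Theta$, each
test's posterior is replaced by a mixture of all single-test posteriors:
its own with weight 1, the others with a common weight $p_\Theta$ (the
prior probability that another test's parameter lies in $\Theta$).  Only
the own-data term of the mixture marginal likelihood is bias-corrected —
the cross terms involve independent data, and the bias of a log of a sum
has no tractable form, so no further correction is attempted.  All cross
integrals are closed normal convolutions.  With $m = 1$ or $p_\Theta = 0$
the single-test EBF is recovered exactly, which the tests assert to
machine precision.  The default $p_\Theta = 1$ follows from the observed
insensitivity: in the large-scale simulation the per-test log EBFs barely
move between $p_\Theta = 1$ and the generating value $0.1$, and remain
similar at $0.01$.  Pooling shrinks extreme EBFs and improves the
proportion of true positives above a threshold, while leaving ranks
almost unchanged; it is information sharing, not a multiplicity penalty.
The implementation is $O(m^2)$ dense matrix work, adequate to about
$10^4$ tests; only the normal ensemble is implemented, matching the
simulations being reproduced.

## The evidence-unit scale

Belief responds to evidence through the logistic function of log
posterior odds, and the effect of new evidence is its first derivative.
Defining "weaker" belief as that most easily moved, the sharpest boundary
between weaker and stronger belief sits where that effect changes
fastest — the zero of the third derivative, at log-odds
$x^* = \log(2+\sqrt3)$, i.e. $\sigma(x^*) = (3+\sqrt3)/6$.  A Bayes
factor of $2+\sqrt3 \approx 3.73$ therefore moves any weaker belief to a
stronger one: one *unit of evidence*.  The base is obtained by
root-finding on the third derivative at load time (with $2+\sqrt3$ as a
guard value should the root-finder fail) because the defining property,
not the numeric value, is primitive.  `calibration_table()` inverts each
closed form to find the P-values at 1–4 units: 0.038/0.008/0.002/0.0005
for the two-sided normal test — strikingly close to conventional
significance thresholds.

```{r calibration}
calibration_table(1:4)
```

## Monte Carlo validation and the simulation studies

`mc_expected_bias()` is a deliberately independent oracle: it simulates
observed/replicate pairs from each family's predictive (pivotal
standardisation for normal, t, F; $p$ drawn from the Beta prior for the
binomial families) and averages the defining log-ratio directly, with a
standard error.  The suite requires agreement with every quadrature and
exact-sum table entry within 3 Monte Carlo standard errors at $10^5$
replicates.  For t and F the per-draw inner convolution density is
evaluated through a 400-node spline interpolant of the same quadrature
integrand — the Monte Carlo randomness, which is what the check is about,
is independent of the deterministic outer integration being validated.

`run_limited_multiplicity()` reproduces the moderate-multiplicity study:
$m = 1,\dots,10$ tests, 10,000 datasets per cell, sample size 100 and
unit variance (standard error $1/\sqrt{100}$), one independent replicate
per observation, under three mean configurations — all zero, $N(0,1)$
per dataset, and a fixed grid on $[-5,5]$ (a single point at 0 when
$m = 1$, a choice the source leaves open).  Reported are the mixture
bias with and without the own-term correction, and mean square errors of
the adjusted single- and multiple-test log marginal likelihoods against
the replicate comparator; the comparator mixes the replicate posteriors
with the same weights, our reading of an under-specified detail.  Two
further interpretations worth stating: the study is run at
$p_\Theta = 1$ (the value used is not stated; the large-scale experiment
shows insensitivity), and the MSE errors use the *adjusted* marginal
likelihood — that is what reproduces the reported single-test MSE of
about $0.5$ (the unadjusted error would have second moment $3/4$).
`run_large_scale()` reproduces the screening experiment: 1000 tests, 900
null, 100 effects from $N(0,1)$, unit sampling variance.

What these generators emulate — independent normal summary statistics
with known standard errors and exchangeable effects — is exactly the
asymptotic regime the methods target.  What they do not emulate:
correlated tests, heavy-tailed or skewed estimator distributions,
misestimated standard errors, and effect distributions far from
normality.  Passing tests therefore certify the computations and the
internal consistency of the bias corrections, not robustness of the
method on real data violating those assumptions.

## Numerical choices and degenerate inputs

* Region masses everywhere use whichever cdf tail avoids cancellation; a
  region straddling the median is computed as $1 - F(a) - S(b)$ in
  linear space.  This keeps, e.g., the binomial marginal likelihood
  finite for regions holding mass $e^{-300}$.
* All internal logs are natural; base-10 and evidence units appear only
  in reporting.  Extreme inputs degrade gracefully: `ebf01` may under-
  or overflow to $0/\infty$ while `log_ebf01` stays exact.
* `favoured` is `"neutral"` only at exact equality `ebf01 == 1` — the
  knife edge $z^2 = 1+\log 2$ is treated as a point, not a band.
* Impossible hypotheses may carry $-\infty$ log marginal likelihood;
  both sides $-\infty$ is an error ("undefined evidence").
* Quadrature tolerances: `rel.tol = 1e-10` (inner) and `1e-8` (outer),
  against table targets of $5\times10^{-4}$; empty regions and
  zero-posterior-mass regions raise errors rather than returning
  $-\infty$ silently.
* Problem sizes in the default test run were chosen to exercise every
  code path at full published scale where deterministic (all bias-table
  grids) and at the published replicate counts for the simulations
  ($10^4$ datasets; $10^5$ draws for oracle checks).

## Known limitations

* Vector-valued hypotheses are supported only as products of independent
  one- and two-sided components (the bias is then additive); correlated
  interval regions in $d > 1$ are out of scope.
* The directional/interval normal and t biases are flat-prior limits, as
  discussed above; for a parameter pinned near a boundary the realised
  bias can differ.
* The P-value EBF inherits its Beta model; for non-parametric tests it
  is a rough measure, not an exact calibration.
* The multiple-testing heuristic corrects only the own-data term; the
  residual bias of the mixture's cross terms is unquantified.
* `p_theta` is a scalar shared across tests; per-test weights are a
  straightforward extension not implemented here.
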