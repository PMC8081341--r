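---
title: "Modelling karyotype evolution on the karyograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling karyotype evolution on the karyograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyograph)
```

## The walk on the karyograph

Karyotypes are summarized by two integers: the haploid arm number $x$
and the haploid chromosome number $y$. An acrocentric chromosome
contributes one arm, a metacentric two, so with $n_A = 2y - x$
acrocentrics and $n_M = x - y$ metacentrics every real karyotype sits in
the wedge $y \le x \le 2y$ of the lattice ("karyograph"). Four
rearrangement types move a karyotype to a lattice neighbour:

* centric fusion of two acrocentrics, rate $k_1$ per acrocentric pair:
  $(x, y) \to (x, y-1)$;
* centric fission of a metacentric, rate $k_2$ per metacentric:
  $(x, y) \to (x, y+1)$;
* A-M centromere movement (e.g. pericentric inversion), rate $k_3$ per
  acrocentric: $(x, y) \to (x+1, y)$;
* M-A movement, rate $k_4$ per metacentric: $(x, y) \to (x-1, y)$.

All rates are per million years. Chromosome and arm numbers never change
by more than one per event; non-centric fusions, telomere fusions and
dicentrics are outside the model. Optionally a whole-genome doubling
jump $(x, y) \to (2x, 2y)$ at constant rate $k_5$ extends the model for
taxa with appreciable polyploidization (plants, notably).

For computation the space is truncated at a user-chosen maximum
chromosome number `y_max` (35 for the fish analyses this model was
designed around, giving 665 states; smaller values for simulation
studies). Fission from $y = y_\max$ and doubling beyond it get rate
zero. We allow $y$ down to 1; fusion out of $y = 1$ is impossible anyway
because a single chromosome has no acrocentric pair. States are ordered
by ascending $(y, x)$ with dense 1-based indices, which keeps
serialized output and cached quantities stable across runs.

## Stationary distribution

The four-rate walk satisfies detailed balance. Writing
$K_f = k_2/k_1$ and $K_i = k_4/k_3$, balancing fission against fusion
along $y$ and A-M against M-A along $x$ gives

$$\pi(x, y) \propto \frac{(2K_f)^y\,K_i^{-x}}{(2y-x)!\,(x-y)!},$$

so the walk's equilibrium depends on the four rates only through the two
bias ratios. Summing over $x$ at fixed $y$ shows the chromosome number
is marginally zero-truncated Poisson with intensity
$\Lambda = 2K_f(K_i+1)/K_i^2$, and the metacentric count given $y$ is
$\mathrm{Binomial}(y, 1/(K_i+1))$; means, variances and modes in
`stationary_moments()` follow from these closed forms. We validated the
functional form (including the $(K_i + 1)$ numerator of $\Lambda$, which
is easy to mistype in flattened text) against the null space of the
generator: `stationary_numeric()` solves $\pi Q = 0$ directly and the
two agree elementwise to $10^{-15}$ on test grids. The distribution is
evaluated on the truncation and renormalized there; if the
truncated-Poisson tail beyond `y_max` exceeds $10^{-10}$ a warning
suggests enlarging the space. Polyploidization breaks the lattice
balance, so stationary computations refuse generators with $k_5 > 0$.
Mode ties are broken toward the smaller $(y, x)$ for determinism.

## Likelihoods

`mkn_loglik()` is standard Felsenstein pruning: per branch the partial
likelihood vector is propagated by $e^{Qt}$, with elementwise products
at nodes, per-node rescaling against underflow, and a flat (default) or
likelihood-weighted root prior. Instead of one matrix exponential per
branch we eigendecompose $Q$ once and apply
$V e^{\Lambda t} V^{-1} v$ per branch in $O(n^2)$; if the eigenbasis is
ill-conditioned (checked via $\max|V^{-1}|\max|V|$) we fall back to
`Matrix::expm` cached per unique branch length.

`musse_loglik()` implements the multi-state speciation–extinction
likelihood: along each branch

$$\frac{dE_i}{dt} = \mu_i - (\lambda_i+\mu_i)E_i + (QE)_i + \lambda_i E_i^2,
\qquad
\frac{dD_i}{dt} = -(\lambda_i+\mu_i)D_i + (QD)_i + 2\lambda_i E_i D_i,$$

with tip conditions $D_i = f_i\,[i = \text{observed}]$,
$E_i = 1 - f_i$ for sampling fraction $f_i$, and node joins
$D_i \leftarrow \lambda_i D_i^L D_i^R$. Branches are integrated with a
stiff-capable solver (`deSolve::lsoda`, default tolerances
rel $10^{-8}$ / abs $10^{-10}$, exposed as arguments).

When $\lambda$, $\mu$ and $f$ are state-constant and the tree is
ultrametric — models M0, M1 and M4 — the system separates exactly:
$u = 1 - E$ obeys the logistic equation $u' = (\lambda-\mu)u - \lambda u^2$
with a closed form, and the $D$ equation becomes $e^{Qt}$ transport
times the state-independent scalar
$\exp((\lambda-\mu)t)/g(t)^2$ with
$g(t) = 1 + \lambda u_0 (e^{rt}-1)/r$. This reduction makes the
constant-rate SSE likelihood as cheap as Mk-n; the ODE path remains for
the state-dependent models (M2/M3) and is cross-checked against the
closed form in the tests. With $\lambda \equiv 0$ the diversification
component degenerates; we define this limit as pure character transport,
which recovers the Mk likelihood exactly (verified in the tests).

Root handling defaults to a flat prior for Mk-n and likelihood
(FitzJohn-type) weighting for the SSE likelihood, both selectable, with
optional conditioning on survival (off by default); the choice is
recorded in the fit object because absolute log-likelihoods are
convention-dependent — model comparisons should always use differences
under identical settings.

## Model ladder and fitting

* **M0** — $k_1..k_4$ plus constant $\lambda, \mu$ (6 free parameters);
* **M0′** — M0 with the M2 group sampling fractions, for the nested
  test against M2;
* **M1** — M0 with $K_i = 1$, i.e. $k_4 \equiv k_3$ (5);
* **M2** — $k_1..k_4$ plus $(\lambda_m, \mu_m)$ on a focal karyotype set
  and $(\lambda_o, \mu_o)$ elsewhere (8);
* **M3** — M2 with $k_4 \equiv k_3$ (7);
* **M4** — M0 plus the doubling rate $k_5$ (7).

Sampling fractions per diversification group are the arithmetic mean of
the per-state fractions (species on the tree / species karyotyped); no
correction is applied for M0/M1/M4.

`fit_karyotype_model()` maximizes the likelihood over $\log_{10}$
parameters with `optim(method = "L-BFGS-B")` in a box (default
$[10^{-8}, 10]$). Because a single-start hill climb is not reproducible
across optimizers, we use multi-start by default: the conventional 0.1
prior for every rate, a Yule-informed heuristic
($\hat\lambda = (N-2)/\sum t$, $\hat\mu = \hat\lambda/2$, rates
$10^{-2}$), and seeded random draws from the log-uniform cube. The
returned object records convergence and the per-start trace.
`likelihood_ratio_test()`/`anova()` accept only registered nestings
(M1⊂M0, M1⊂M3, M3⊂M2, M0′⊂M2, M0⊂M4) with $\chi^2$ degrees of freedom
equal to the free-parameter difference.

## Ancestral reconstruction and branch statistics

`marginal_asr()` computes each internal node's marginal posterior by a
down pass (the pruning partials) and an up pass through the transpose of
each branch channel. For Mk and for constant-rate SSE fits the channel
is $e^{Qt}$ — state-independent scalars cancel in the per-node
normalization — while for M2/M3 the linear $D$-propagator of each branch
is rebuilt column-wise with the extinction profile fixed, which makes
the pinned-node posteriors exact (checked against an independent
integrator on small trees). Modal karyotypes break ties toward the
smaller $(y, x)$.

The "95% range" summary grows the smallest credible set by descending
probability until the target coverage and reports the min/max of $y$ and
$x$ over that set; because other constructions are defensible, an
equal-tail marginal-quantile variant is available via
`range_summary(..., method = "marginal")` and output is labelled with
the construction used.

Branch statistics use the fitted generator: the likelihood of a branch
length $t$ for a transition $i \to j$ is $[e^{Qt}]_{ij}$, evaluated
piecewise — a degree-170 Taylor polynomial accumulated on the row vector
for $t \in [0, 10)$ (the sparse-generator form avoids dense
exponentials), the matrix exponential for $t \in [10, 15000]$, and an
undefined result outside. `fit_branch_length()` maximizes this over $t$
from the conventional start of 10 with a log-spaced scan plus local
refinement (the profile can plateau or be multimodal); identical
endpoint modes define $t_f = 0$; results are cached per unique
transition. The unexpected region of a state distribution is the
largest ascending-probability prefix with cumulative mass strictly
below 1% (the "less than 1%" reading; ties by state index), and
branches classify as Expected (descendant inside the expected region at
the true duration $t_g$), Rapid/Conservative (inside only at the fitted
$t_f$, split by $t_f > t_g$ vs $t_g > t_f$), or Unusual (outside at
both).

Polyploidization events are called on branches whose descendant modal
karyotype exceeds the ancestral mode by more than 1.4-fold in **both**
chromosome and arm number (observed karyotypes at tips).

## What the synthetic generators emulate

`sim_bd_tree()` draws ultrametric birth–death trees conditioned on a
fixed extant tip count, standing in for empirical time-calibrated
phylogenies; `sim_karyotype_tips()` runs the exact Gillespie walk down
a fixed tree (no feedback of the character on diversification, matching
how the inference methods were originally evaluated); and
`random_rates()` draws $\log_{10} k \sim U(-4, -1)$, the design used in
the recovery studies. Problem sizes in the tests mirror the study
conditions at desk scale: recovery uses a 300-tip Yule tree with
`y_max = 8` and root $(6, 4)$ over 20 trials; method concordance uses
10 datasets on 150 tips; branch classification uses a 260-tip tree
(~500 branches); polyploidy recovery uses 50-tip fixtures with the
empirical-scale doubling rate $k_5 = 9.31\times10^{-3}$, `y_max = 12`,
root $(5, 4)$ and exchange rates of order $10^{-2.3}$–$10^{-2}$, chosen
once as realistic magnitudes. A caveat worth knowing when interpreting recovery results: a few
hundred tips do not identify every log-uniform draw. Rates near
$10^{-4}$ can generate no events on the whole tree, and a rate whose
source chromosome class (acrocentric or metacentric) is absent at the
equilibrium the chain reaches is invisible regardless of its value; for
such draws the maximum-likelihood estimate runs to the lower box bound,
and truth–estimate correlations plateau around 0.8 at 300 tips even
though the likelihood machinery is exact; with many more species such
degenerate draws become rare. Deeper trees do not help the
high-rate draws — they saturate to the stationary distribution, which
identifies only the bias ratios, not the absolute scale.

What passing these tests does *not* show:
real data add incomplete and biased sampling, rate heterogeneity across
clades and time, karyotyping error, and tree error — none of which the
generators emulate, and all of which the original analyses addressed
only partially (sampling fractions, taxon filtering).

## Numerical choices and limitations

* Eigendecomposition propagators are accepted only when well
  conditioned; otherwise cached `expm` calls are used. Negative
  round-off entries in propagated vectors are clamped at zero.
* ODE tolerances, the Taylor degree (170), the $t$ bounds (0–15000),
  the tail mass (1%), the 1.4 doubling threshold and the branch-fit
  start (10) are the conventional defaults and are all exposed as
  arguments.
* The fitted tree and states are stored in the fit object, so
  reconstruction and branch annotation are reproducible from it alone.
* Known limitations: rate coefficients are constant across the tree (no
  branch-specific or time-varying rates); no joint tree-and-character
  simulation under state-dependent diversification; marginal (not
  joint) reconstruction; karyotype space must be bounded, and taxa with
  frequent polyploidization need a generous `y_max` at real
  computational cost.
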