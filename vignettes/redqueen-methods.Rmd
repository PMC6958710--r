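---
title: "Models and methods: stochastic host-parasite Red Queen dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: stochastic host-parasite Red Queen dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redqueen)
```

## The scientific question

Negative frequency-dependent selection (NFDS) between hosts and their
specialised parasites produces the oscillating genotype frequencies known as
Red Queen dynamics: parasites chase the common host genotype, rare host
genotypes escape, grow, and are chased in turn. Deterministic models keep
these oscillations alive forever. Real populations are finite, so genetic
drift eventually removes a genotype from one of the two species, and once a
population is monoclonal the cycling is over. This package implements a
family of individual-based models spanning evolutionary game theory
(constant population size) and theoretical ecology (freely changing
population size), all sharing one biology — haploid, asexual, well-mixed
hosts and parasites interacting through a matching-allele infection matrix —
and measures the robustness of the oscillations by the **extinction time**:
the first time any genotype of the initial standing variation is lost from
either species.

The headline comparison: letting the population size change (ecological
feedback) and removing global intraspecific competition both *shorten*
extinction times; a fixed size and population-wide competition stabilise the
cycles.

## Matching alleles, payoffs and fitness

Parasite genotype $i$ infects host genotype $i$ and no other. The
interaction matrix has $\alpha$ on the diagonal (effect of a match, default
1) and $\beta$ elsewhere (mismatch, default 0). Payoffs are zero-sum: the
parasite's payoff against the host composition $h$ is
$\pi_{P,i} = \alpha h_i + \beta(1-h_i)$, and the host's payoff is the
complement $\pi_{H,i} = (\alpha + \beta) - (\alpha p_i + \beta(1-p_i))$, so
a host targeted by common matching parasites scores low. Only the parasite
payoff is fixed by a printed formula; for the host we chose the zero-sum
complement because (i) it keeps fitnesses in $[1-w,\,1+w\,(\alpha+\beta-1)]$,
non-negative for all selection intensities, (ii) in the two-type case with
$\alpha=1,\beta=0$ it reduces to the familiar $f_{H,1} = 1 - w_H + w_H p_2$,
and (iii) it mirrors, as a death rate, the Hybrid model's host mortality
$d_{H,1} = 1 - w_H + w_H(\alpha P_1 + \beta P_2)/N_P$. Selection intensity
$w \in [0,1]$ maps payoff to fitness as $f = 1 - w + w\pi$; $w = 0$ is
neutrality.

## The five continuous-time models and the two discrete-time processes

* **dtEvo⁺ / Evo⁺** (Moran): in each step one individual reproduces with
  probability proportional to $x_i f_i/\bar f$ and a uniformly chosen
  individual dies. The normalisation by the population mean fitness
  $\bar f$ is global intraspecific competition. Deterministic limit: the
  adjusted replicator dynamics.
* **dtEvo / Evo** (pairwise comparison): the Moran ratio $f_1/\bar f$ is
  replaced by $\tfrac12 + \tfrac12 (f_1 - f_2)/(\alpha - \beta)$ — a
  pairwise contest whose stake is the fitness difference scaled by the
  maximal payoff spread $\alpha-\beta$. Competition is local; the limit is
  the plain replicator dynamics. When $\alpha = \beta$ (or the fitnesses
  tie) the contest term is $\tfrac12$; the selection intensity $w$ enters
  through $f_1 - f_2 = w(\pi_1-\pi_2)$ and scales the contest away from
  $\tfrac12$ — dividing by $w(\alpha-\beta)$ instead would cancel $w$
  entirely, so we do not.
* **Hybrid**: explicit birth/death reactions whose per-capita rates come
  from the game (hosts die at $d_{H,i}$ above, parasites are born at
  $b_{P,i}$), while host births and parasite deaths are redistributed
  uniformly per capita so the total birth and death rates balance in each
  species at every state. Population size is controlled in expectation, not
  exactly. The exact redistribution scheme is not pinned down by any printed
  equation; uniform per-capita redistribution is the simplest scheme that
  balances the totals, and it makes the frequency drift exactly the
  replicator dynamics.
* **EcoEvo**: individual-based Lotka–Volterra. Host births at $b_H H_i$,
  parasite deaths at $d_P P_i$, and matching encounters that kill the host
  *or* reproduce the parasite — implemented as two independent channels,
  each at rate $\lambda H_i P_i$. With that reading the drift is
  $\dot H_i = H_i(b_H - \lambda P_i)$, $\dot P_i = P_i(\lambda H_i - d_P)$,
  whose equilibrium $H_i^* = d_P/\lambda$, $P_i^* = b_H/\lambda$ reproduces
  all the reference population sizes below; a single paired
  death-plus-birth event has the same drift and only changes the
  host–parasite noise correlation.
* **EcoEvo⁺**: EcoEvo plus genotype-blind host competition at rate
  $\mu H_i N_H$ (self-pairing included, so the host-only equilibrium is
  exactly the carrying capacity $K = b_H/\mu$). The host grows
  logistically; the interior equilibrium becomes
  $P_i^* = (b_H - \mu\, n\, H_i^*)/\lambda$.

The discrete-time processes update **both species simultaneously** in each
step, evaluating all payoffs at the pre-step state. Pre-step evaluation is
the only choice that keeps the two species' draws independent, which in turn
makes the two-species transition kernel a product of two per-species
triples — the property the exact extinction-time computation relies on.
Self-replacements (birth and death in the same genotype) consume a time
step. Extinction times of the dt processes are reported in steps and are not
rescaled to continuous time: the two clocks are not comparable, and the dt
pair is only ever compared within itself.

Genotype conversion ("mutation") is available for the ecological and Hybrid
models: each individual converts to either cyclic-neighbour genotype at rate
$\mu_H/2$ (hosts) or $\mu_P/2$ (parasites). Conversion changes genotype
counts, never totals. The constant-size Evo models exclude it (a conversion
would break the replacement-pair bookkeeping that conserves $N$).

## Exact mean extinction times (discrete time)

For two genotypes per species the dt state is $(H_1, P_1)$ on the grid
$\{0..N_H\} \times \{0..N_P\}$. States with $H_1 \in \{0, N_H\}$ or
$P_1 \in \{0, N_P\}$ are absorbing. The one-step kernel is the product of
the host and parasite triples (at most 9 non-zeros per row); the expected
first-loss time solves $(I - Q)\tau = 1$ over the transient interior, a
sparse LU solve (`Matrix`). Interior states are enumerated row-major,
`index = (H1-1) * (N_P-1) + P1`, which tests and external consumers can rely
on. The state-space guard is $2.5\times10^5$ states. Unit tests verify the
solver against a dense, independently-constructed full-kernel enumeration at
tiny sizes and against hand-solved neutral chains
($\tau(1,1) = 4/3$ for the Moran product kernel at $N_H = N_P = 2$,
$16/7$ for the pairwise kernel); Monte-Carlo ensembles at $N = 6$ agree
within three standard errors.

## The stochastic simulation engine

The continuous-time models are simulated with the direct-method Gillespie
algorithm: exponential waiting time at the total rate, category and genotype
chosen proportionally to rates. The five built-in models run in compiled
code (propensities recomputed per event in $O(n)$); arbitrary user-assembled
reaction systems run through the same semantics in an R loop. Trajectories
are recorded on a fixed time grid (the event-exact state held at each grid
time) to bound memory; extinction detection and revival logging always use
exact event states. A run halts at the first genotype loss (unless
disabled), at an all-rates-zero absorbing state, or at a time/event/total
population cap — censoring is always reported, never dropped.

Reproducibility: every experiment takes one master seed; replicate $r$ uses
the child seed produced by two rounds of a Lehmer (minimal-standard)
congruence on `(master, r)`, so ensembles are reproducible
replicate-by-replicate and independent of execution order, and all child
seeds stay below $2^{31}-1$.

Engine validation (also run by `scripts/acceptance.R`): a pure death chain
from 3 individuals is absorbed after $1 + 1/2 + 1/3 = 11/6$ time units on
average; a birth-only population matches the Yule mean $N_0 e^{bt}$;
constant-size models conserve $N_H, N_P$ exactly (integer equality along
whole trajectories); a parasite-free EcoEvo⁺ host population fluctuates
around $K$.

## Deterministic limits, equilibria and the stability dichotomy

`ode_rhs()` implements the replicator (Evo, Hybrid), adjusted replicator
(Evo⁺) and Lotka–Volterra (EcoEvo, with logistic host term for EcoEvo⁺)
right-hand sides; `integrate_ode()` wraps `deSolve::ode` (lsoda, default
`rtol = 1e-10`, `atol = 1e-12`). The right-hand sides carry the
selection-intensity-bearing fitness $f$, matching the stochastic rates; the
Evo drift is the replicator field divided by $\alpha-\beta$ (a constant time
rescaling from the pairwise normalisation), and the Hybrid count drift is
$N$ times the frequency drift — unit tests pin these correspondences
exactly against the reaction systems' mean-field drift.

Interior fixed points: the uniform point $1/n$ for the frequency models;
$H_i^* = d_P/\lambda$, $P_i^* = (b_H - \mu n H_i^*)/\lambda$ for the
ecological ones. The reference parameter sets recover the intended
population sizes: $b_H=6, d_P=1, K=100, \lambda=4/100$ gives
$(H^*, P^*) = (25, 25, 75, 75)$, totals $(50, 150)$; the five-genotype set
$K = 600, \lambda_0 = 10$ gives totals $(300, 900)$.

**Stability classification needs care.** In all the two-population frequency
games the host block of the Jacobian depends only on $p$ and the parasite
block only on $h$, so the linearisation at the interior point is exactly
center-like (purely imaginary eigenvalues) for Evo *and* Evo⁺ — the
adjusted replicator's attraction is a nonlinear effect. The integrated
amplitude decays as a power law, $d(t) \approx 0.71/\sqrt t$ for
$w_H = w_P = 1$ from $h_1 = 0.9$ (an amplitude equation of the form
$\dot a \propto -a^3$), not exponentially; reaching a $10^{-4}$ neighbourhood
of the uniform point by direct integration would take $t \sim 5\times10^7$
and is not attempted. `classify_fixed_point()` therefore works in two
stages: eigenvalues of the Jacobian in reduced coordinates (simplex
constraints eliminated; real part beyond `tol = 1e-8`, scaled by the
spectral radius, decides immediately — this settles EcoEvo⁺, whose
total-size mode is linearly damped by competition), and otherwise a
Poincaré-return probe: integrate from a perturbation of the
genotype-difference mode only (the linearly damped total-size mode would
contaminate the radii) and compare the radii at successive section
crossings. Radii shrinking by more than 0.1% per probe mark attraction,
growth marks repulsion, constancy neutrality. The probe's verdicts:
Evo⁺ and EcoEvo⁺ attracting ("stasis"), Evo, Hybrid and EcoEvo neutral
(closed NFDS cycles; the Evo orbit returns to within $4\times10^{-7}$ of its
start after one period, detected by first return to a Poincaré section, not
an assumed period formula). Orbit-closure sections use the first coordinate
whose initial derivative is non-zero, so starts at a turning point are
handled.

## The experiments and their problem sizes

* **Extinction ensembles**: equal-split initial states
  ($H_i(0) = N_H/n$, $P_i(0) = N_P/n$); means and medians over uncensored
  replicates with censored counts reported alongside; a fully censored
  ensemble is flagged unusable. The reference two-genotype comparison runs
  Evo⁺ against EcoEvo⁺ at $N_H = 50$, $N_P = 150$, $w_H = 0.5$, $w_P = 1$
  (the asymmetry mirrors the obligate parasite's full dependence on the
  interaction, while hosts also die of competition), 300 replicates per
  model in the shipped checks; Evo⁺ outlives EcoEvo⁺ by two orders of
  magnitude at these sizes.
* **Population-size sweep**: extinction time against the target equilibrium
  parasite size $N_P$ at $N_H = 250$, $K = 500$, $\lambda_0 = 4$. For the
  ecological models the sweep axis is the host birth rate; the target $N_P$
  is recomputed from the interior fixed point (never assumed), and the
  birth rate reaching a target is found by root solving. The shipped checks
  use $N_P \in \{30, 60, 100\}$ at 100 replicates per cell — small enough
  to run in seconds, large enough that every constant-size model exceeds
  every changing-size model cell by cell with wide margins. The dt pair is
  computed exactly (first-passage solve) at $N_P$ up to 200, where dtEvo⁺
  overtakes dtEvo (the attractive fixed point winning; the crossover sits
  between $N_P = 100$ and $200$ at these intensities). With the strongly
  diverging intensities $w_H = 0.5, w_P = 1$ the continuous-time Evo can
  outlive Evo⁺ at small sizes — a documented counter-intuitive regime — so
  the ordering checks assert constant-vs-changing and plus-vs-non-plus, not
  a total order.
* **Diversity decay**: 20 genotypes per species, EcoEvo⁺, parameters scaled
  from the two-genotype reference so each genotype keeps the per-genotype
  equilibrium (25 hosts, 75 parasites): $b_H = 6$, $d_P = 1$,
  $\lambda = 1/25$, $\mu$ chosen to hold those sizes ($K = 1000$). Without
  mutation each replicate's genotype count is non-increasing; the mean
  across 100 replicates decays log-linearly ($R^2 \approx 0.95$) over the
  window from $t = 0$ to the first time the mean drops below 2 (the decay
  phase; the monomorphic plateau is excluded). The headline statistic is the
  across-species mean diversity: parasite genotype losses lag host losses
  (a parasite genotype starves only after its matching host declines), so
  the parasite-only log-curve is slightly convex ($R^2 \approx 0.89$–$0.91$)
  while host-only is $\approx 0.98$; treating diversity as one statistic of
  the standing variation reflects the decay claim and is stable across
  seeds. Per-species fits remain available.
* **Mutation regime**: five genotypes, $N_H(0)=300$, $N_P(0)=900$,
  $b_H = 6$, $d_P = 1$, $K = 600$, $\lambda_0 = 10$, $\mu_H = 0.005$,
  $\mu_P = 0.01$, horizon $t = 300$ (a package choice: long enough to cover
  many oscillation periods and several sweep-revival cycles). Every revival —
  a genotype count leaving zero — is logged; revivals occur in essentially
  every run, and the dynamics mix NFDS cycling with arms-race sweeps.

## What the simulations do and do not emulate

The generator produces exactly the study conditions above: haploid asexual
clonal reproduction, a strict matching-allele matrix, well-mixed encounters,
no spatial structure, no life history, no within-host dynamics, and genetic
novelty only through cyclic neighbour conversion. Passing tests therefore
demonstrate the mathematical behaviour of these idealised processes — they
say nothing about gene-for-gene infection, sexual reproduction,
spatial refugia, or real host-parasite time series.

A caution established while validating the mutation regime: at the
five-genotype reference sizes the time-averaged totals do **not** sit near
the deterministic interior point $(300, 900)$. Demographic noise drives
selective sweeps; a monomorphic phase has the much smaller equilibrium
$(60, 324)$, surviving runs settle into a host-near-$K$, parasite-scarce
state, and a sizeable fraction of runs lose both populations within a few
hundred time units. This is a property of the process, not of the engine:
at tenfold size $(3000, 9000)$, where the deterministic pull dominates, the
time-averaged totals recover the interior point to a quarter percent (the
acceptance script recomputes both). The interior point describes these
population sizes only as a transient.

## Numerical choices and degenerate inputs

* Frequencies are always derived from integer counts; a frequency vector
  must sum to 1 within $10^{-12}$.
* $\alpha \ge \beta$ is required (the pairwise normalisation divides by
  $\alpha - \beta$); $\alpha = \beta$ and $w = 0$ are legal and give the
  neutral term $\tfrac12$ — degeneracy is handled, not an error.
* Boundary dt states return the degenerate triple $(0, 1, 0)$; once a
  genotype is absent nothing revives it (no mutation in the dt processes).
* Ties at a simultaneous host and parasite loss report the host, by
  convention.
* Genotype counts are stored as doubles but are exact integers throughout
  (all stoichiometries are $\pm1$; conservation tests assert integer
  equality).
* The categorical draw in the engine walks cumulative rates and falls back
  to the last positive channel against floating-point shortfall.
* `lam` may be given directly or as `lam0 / K`; both given and inconsistent
  is an error. `comp_rate = b_H / K` is derived the same way, but
  consistency is only enforced when `comp_rate > 0`: the unconstrained
  EcoEvo sweep legitimately sets `comp_rate = 0` while keeping `K` to scale
  `lam`.
* Configuration keys are validated closed-world (unknown keys are errors)
  and a run without an explicit seed refuses to start.

## Known limitations

Two genotypes only for the (dt)Evo processes (the constant-size analysis is
two-type); no tau-leaping or other accelerations (the exact algorithm is the
point); no analytic noise-averaged extinction-time approximation; no
gene-for-gene or asymmetric infection matrices; stability classification
beyond the built-in model families may return "inconclusive" when neither
the Jacobian nor the orbit probe is decisive.
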