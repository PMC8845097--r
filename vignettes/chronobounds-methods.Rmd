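---
title: "Bounding divergence times with a rate interval: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding divergence times with a rate interval: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronobounds)
```

## The problem and the model

Molecular sequences carry no direct information about time: the number of
substitutions separating two sequences is the product of a substitution
rate and a time duration, and the two are confounded. Any divergence-time
estimate is therefore an artefact of assumptions about rates and node
ages. Most modern methods buy precision with strong assumptions — a
parametric among-branch rate model, probability densities linking fossil
ages to clade ages, a birth–death prior on node ages. `chronobounds` takes
the opposite stance: it makes only the assumptions a user is willing to
state as hard intervals, and reports *everything* consistent with them.

The inputs are:

* a rooted phylogeny whose branch lengths $s_e$ are expected substitutions
  per site;
* an interval $[r_{\min}, r_{\max}]$ (substitutions/site/time) assumed to
  contain the true rate of every branch, with $0 < r_{\min} \le r_{\max}$;
* optional minimum and/or maximum age calibrations attached to nodes
  (addressed by tip sets, resolved to their MRCA), including the root.

Extant tips sit at age 0 (time before present). A branch with molecular
length $s_e$ evolved at some rate within the interval, so its time
duration $d_e$ must satisfy

$$ \frac{s_e}{r_{\max}} \;\le\; d_e \;\le\; \frac{s_e}{r_{\min}}. $$

These per-branch duration intervals, the tip pinning, and the calibrations
jointly constrain every node age $a_n$. The method computes, for each
node, the *youngest* and *oldest* feasible age,

$$ L(n) = \min a_n, \qquad U(n) = \max a_n, $$

over all age assignments satisfying every constraint, and returns the two
extreme chronograms: `tree_min` assigns every node $L(n)$, `tree_max`
assigns every node $U(n)$. No point estimate between them is ever
produced, deliberately: choosing one would require exactly the rate or age
model the method refuses to assume. The honest reading of the output is as
a *baseline of maximal uncertainty* against which more precise (more
strongly assuming) methods can be judged.

## The algorithm and why it is exact

The constraint system is a conjunction of difference constraints
($\ell_e \le a_{p(e)} - a_{c(e)} \le u_e$, plus bounds against a reference
fixed at 0), i.e. a simple temporal network whose constraint graph is tree
structured apart from the shared reference. Two sweeps solve it exactly:

1. **Upward (postorder).** Tips get $[0, 0]$. An internal node $n$ with
   children $c$ gets
   $L_{up}(n) = \max(\text{cal}_{\min}(n), \max_c (L_{up}(c) + \ell_c))$ and
   $U_{up}(n) = \min(\text{cal}_{\max}(n), \min_c (U_{up}(c) + u_c))$.
   After this pass each node's interval reflects everything at or below it.
2. **Downward (preorder).** The root keeps its upward interval; a child
   $c$ of parent $p$ gets
   $U(c) = \min(U_{up}(c), U(p) - \ell_c)$ and
   $L(c) = \max(L_{up}(c), L(p) - u_c)$.

If at any point $L > U$ (beyond floating-point tolerance) the constraints
are jointly infeasible, and the package raises a typed condition naming
the node by a pair of defining tips. Infeasibility is a first-class
outcome — it is the method's honest report that the stated assumptions
contradict each other — and the command-line wrapper maps it to its own
exit code rather than treating it as a crash.

Because every constraint couples a node only to its parent, children, or
the fixed reference, one upward and one downward sweep propagate all
information: the result equals the per-variable extrema of the difference
constraint system. The package carries an independent verification oracle,
`stp_oracle_bounds()`, which encodes the same system explicitly and
extracts per-node extrema by all-pairs shortest paths (Floyd–Warshall;
infeasibility = negative cycle). The test suite asserts elementwise
agreement (tolerance $10^{-9}$) and identical feasibility verdicts on
hundreds of random trees with random rates and calibrations. The oracle is
cubic in the node count and intended for trees up to a few hundred nodes;
the propagation engine is linear and is the production path.

Taking all lower bounds (or all upper bounds) simultaneously is itself a
feasible solution of a difference-constraint system — the
earliest/latest-solution property — which is why `tree_min` and `tree_max`
are valid chronograms branch by branch. On `tree_min` every defined branch
rate equals $r_{\max}$ and on `tree_max` every defined branch rate equals
$r_{\min}$: only the extreme rates can realise the extreme ages.

A useful consequence tested end to end: if some chronogram and per-branch
rates generated the molecular lengths exactly, with every branch rate
inside $[r_{\min}, r_{\max}]$ and all calibrations true, then every true
node age lies inside its reported $[L, U]$. Coverage is a theorem here,
not a statistical aspiration — provided the assumptions hold.

## Numerical choices

* **Feasibility tolerance.** Every comparison uses
  $\text{tol} = 10^{-9} \max(1, |L|, |U|)$. The method is exact arithmetic
  on sums; the tolerance only absorbs floating-point rounding.
* **Zero-length branches** are allowed and collapse parent and child to
  equal ages. A node whose subtending branches all have zero molecular
  length is pinned to its tips' age.
* **Polytomies** are supported: the recurrences take max/min over any
  number of children. A basal trifurcation (an unrooted tree written with
  three root children) is accepted as a rooted polytomy with a warning,
  since root placement affects the bounds.
* **$r_{\min} = 0$ is rejected** with an explanatory message: it makes all
  maximum ages infinite. The supported way to bound ages from above is a
  positive $r_{\min}$ together with a root maximum-age calibration.
* **Calibration propagation is full and exact**: a minimum age at a node
  raises ancestral minima whenever it exceeds what the molecular lengths
  already imply (by $L(p) \ge L(c) + \ell_c$), and a maximum age lowers
  descendant maxima. In the simulation design below the crown calibration
  in practice binds only at its own node, because ancestors' molecular
  minima already exceed the propagated value — but propagation is not
  artificially suppressed.
* **Newick output** prints up to 12 significant digits, so writing and
  re-reading a chronogram reproduces node ages to well within the
  feasibility tolerance.

## Choosing the rate interval: `set_auto_rates()`

Absolute rates are unidentifiable from a molecular tree alone, so the
heuristic needs an external age anchor, typically a believed root age.
Two terminal sister branches (a cherry) span exactly the same time, so
their molecular-length ratio is a pure rate ratio — the only model-free
estimate of rate variation available in the tree itself. The heuristic:

* central rate: $r_{mid}$ = mean molecular root-to-tip length divided by
  `root_age_anchor`;
* spread: $\rho$ = the **maximum** cherry ratio (an extremal statistic,
  matching the philosophy of bounding rather than averaging);
* $r_{\max} = r_{mid}\sqrt{\rho} \cdot \text{inflate}$,
  $r_{\min} = r_{mid} / (\sqrt{\rho} \cdot \text{inflate})$,

so $r_{\min} r_{\max} = r_{mid}^2$ (log-symmetric) and larger `inflate`
widens the interval monotonically, hence (by the engine's monotonicity)
never narrows any age interval. The default `inflate = 2` follows the
general advice to favour wider rate intervals unless there is an explicit
reason not to. Terminal branches may of course under-represent rate
variation deeper in the tree; the statistic is a heuristic, not an
estimator, and users with literature-based rate knowledge should supply
`rate_bounds()` directly. The exact statistic used by other
implementations of this idea is not documented, and no agreement with
them is claimed; a variance-based alternative could be plugged in behind
the same interface.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the simulation study design this package
ships: 24-taxon pure-birth (Yule) trees with extinction 0; optionally an
approximately 10-fold speciation-rate increase confined to one clade
(`shift_factor = 10`); independent per-branch rates from a lognormal with
real-space mean $m = 0.05$ and variance $v = 0.00025$
substitutions/site/time; molecular lengths over 50,000 sites. The
lognormal is parameterised by real-space moments (log-space parameters
$\sigma^2 = \ln(1 + v/m^2)$, $\mu = \ln m - \sigma^2/2$): a variance of
0.00025 against a mean of 0.05 is only sensible on the real scale, and
this matches common simulator conventions. $v = 0$ degenerates to a strict
clock.

Design choices where the process needed pinning down:

* **Clade shift mechanics.** When the extant lineage count first reaches
  `shift_trigger_lineages` (default 4), one extant lineage chosen
  uniformly at random is marked; it and all descendants thereafter
  speciate at `lambda0 * shift_factor`. The crown of the shifted clade
  (the first split of the marked lineage) is recorded for calibration.
* **Stopping rule.** Births accumulate until `n_taxa` lineages are
  extant; the tree is then extended by one further exponential waiting
  time — the time to the next, unobserved birth. Stopping exactly at the
  last birth would leave two zero-length terminal branches, degenerate
  for cherry statistics and implied rates; the memoryless tail is the
  natural way to observe $n$ extant taxa with positive terminal branches.
* **Molecular noise.** The full pipeline behind real data — simulate
  sequences, re-estimate branch lengths — is emulated by Poisson
  substitution-count sampling: per branch, count
  $\sim \text{Poisson}(\text{rate} \times \text{duration} \times
  \text{sites})$, length = count/sites. At these low divergences
  (expected lengths $\ll 1$) ignoring multiple hits is a good
  approximation, but it is an approximation: the noise model captures
  finite-data sampling error, not estimation bias, model misspecification
  or topology error. `noise = "none"` gives exact lengths
  (rate × duration; note the direction — molecular length is the product
  of rate and time, not a quotient).
* **Extinction** is rejected rather than half-implemented: the design
  this simulator reproduces uses a pure-birth process throughout.

`run_coverage_experiment()` wires these pieces into the coverage design:
per replicate, the root age is treated as known (root minimum = maximum =
true root age), rate bounds are either the exact envelope of the
replicate's true branch rates (`true_envelope`, the idealised best case
under which noiseless coverage is guaranteed) or derived by
`set_auto_rates()` anchored at the true root age; optionally a minimum
age constraint equal to 90% of the shifted clade's true crown age is
placed at that crown node. Infeasible replicates are counted and
reported, never silently dropped.

What passing these experiments does **not** show about real data: real
rate intervals are not envelopes of true rates (they are guesses), real
molecular branch lengths carry estimation error beyond Poisson sampling,
real topologies are uncertain, and real calibrations can be wrong.
Coverage there is conditional on the stated assumptions actually holding
— which is precisely the method's point.

## Problem sizes used by the shipped experiments

The test suite and the reproduction script run: 200 random instances
(5–40 tips, branch lengths in (0, 5], rate ratios up to 100, 0–3 random
calibrations) for engine/oracle agreement and extreme-chronogram
validity; 100 replicates of the 24-taxon shifted-Yule design for the
coverage and calibration experiments; 50 random ultrametric trees for the
strict-clock closed form; 10,000 lognormal and 1,000 Poisson draws for
the simulator's moment checks. These sizes give stable verdicts for
properties that are theorems (coverage, agreement, monotonicity) and
4-standard-error bands for the stochastic moment checks.

## Known limitations

* Only contemporaneous (extant) tips: calibration is via nodes;
  non-contemporaneous fossil tips are out of scope.
* No probabilistic calibration densities, no branching-process prior, no
  among-branch rate model — by design; their absence is the method.
* The bounds are exactly as good as the rate interval and calibrations
  supplied; a too-narrow interval silently excludes the truth, which no
  method can detect from the data alone.
* The shortest-path oracle is for verification, not production, above a
  few hundred nodes.
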