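---
title: "Training constrained fuzzy logic pathway models with cflopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training constrained fuzzy logic pathway models with cflopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cflopt)
```

## The modeling problem

A prior knowledge network (PKN) collects literature-derived signed, directed
interactions between signaling proteins. It is a scaffold, not a cell-type
specific model: many of its reactions are inactive, or even contradicted, in
any particular cell line. Given a perturbation dataset -- combinations of
stimuli and kinase inhibitors applied to cells, with phosphoprotein
activations read out at a single time point and scaled into $[0,1]$ --
`cflopt` trains the PKN to the data under a *constrained fuzzy logic* (cFL)
semantics, producing a quantitative, cell-type specific pathway model.

## Model semantics

Each species $j$ carries an activation $x_j^k \in [0,1]$ in experiment $k$.
Each reaction $i$ has reactant set $R_i$ (one or two species), at most one
inhibitor $I_i$, and one product, with $|R_i| + |I_i| \in \{1, 2\}$. The
reaction transmits

$$z_i^k = f\!\left(\;\prod_{j \in R_i} x_j^k \prod_{j \in I_i} (1 - x_j^k)\;\right),
\qquad
f(u) = a_i\,\frac{H(u)}{H(1)},\quad H(u) = \frac{u^n}{p_i^n + u^n},$$

a *normalized Hill* transfer function: $f(0) = 0$, $f(1) = a_i$, strictly
increasing, continuous and differentiable. The gain $a_i \in [0,1]$ scales
how much signal the reaction passes downstream (a reaction with $a_i = 0$ is
effectively removed); the midpoint $p_i$ sets where the sigmoid responds; the
Hill coefficient $n$ (shared, fixed at 4 by default) sets its steepness. The
bilinear product inside $f$ reproduces the Boolean AND (and AND-NOT) gate on
$\{0,1\}$ inputs. When several reactions $T_j$ produce the same species, their
activities combine by the probabilistic-sum OR,
$u \leftarrow u + z - u z$, which is commutative, associative, differentiable
and reduces to Boolean OR at the corners -- properties a max-based OR lacks.

Simulation operates at *pseudo steady state*: in each in-silico experiment
the treatment species (stimuli and inhibitor nodes) are clamped to their 0/1
treatment values, all free species start at 0, and the synchronous update
$x_j \leftarrow \mathrm{OR}_{i \in T_j}\, z_i$ is iterated until the largest
change falls below `tol` (default $10^{-9}$, `cfl_settings()`). For an
acyclic network this converges in depth-many sweeps and equals a single
topological pass; feedback loops iterate to a fixed point, and a
non-convergent (oscillating) loop is reported as an error naming the species
involved rather than silently averaged. Inhibitor treatments are modeled as
explicit inhibitor-node species with NOT edges into their target reactions,
exactly as drawn in logic-model PKNs, not as clamps on the target protein.
Whether inhibition should instead enter at the transfer-function level
($f(1-x)$ vs the $1-x$ inside the gate product used here) cannot be decided
from the gate's Boolean limits alone; the choice is isolated behind
`reaction_activity()` so it can be swapped.

## The estimation problem

With the Hill coefficient fixed, every reaction contributes two free
parameters $(a_i, p_i)$. `cfl_optimize()` minimizes the weighted
measurement-prediction mismatch over all measured cells,

$$\min_{a, p} \sum_k \sum_j \alpha_j^k\, \rho\!\left(x_j^k - \hat x_j^k\right),
\qquad \rho(r) = \sqrt{r^2 + \varepsilon},$$

a smoothed absolute deviation ($\varepsilon = 10^{-8}$) that agrees in shape
with the reported mean absolute error (MAE) while staying differentiable; a
squared loss is available behind `cfl_config(loss = "squared")`. The weights
$\alpha_j^k$ default to 1 (all nodes equally important). Goodness of fit is
always reported as the MAE over measured cells, conventionally quoted as a
percentage. The *null solution* -- all gains zero, no signal propagates --
provides the error ceiling (`null_mae()`).

The solver is a reduced-space, bounded quasi-Newton method:
`stats::optim(method = "L-BFGS-B")` over the $(a, p)$ box, with gradients by
central finite differences (step $10^{-6}$) through the simulation. Species
activations are computed by simulation rather than carried as constrained
variables, which keeps the problem at $2 \times$ (number of parameter
groups) unknowns with simple bounds.

### Numerical choices against local minima

The landscape of gated networks is multimodal in a characteristic way: a
vital reaction's gain can be driven to zero because reinstating it *alone*
-- without simultaneously adjusting gains downstream -- increases the
mismatch. Two strategies, both on by default in `cfl_config()`, address
this:

* **Continuation on the Hill coefficient** (`continuation = TRUE`): the
  problem is first solved with $n = 1$, a nearly linear and much smoother
  landscape, and the target-$n$ solve starts from that optimum.
* **Reinstatement check** (`polish = TRUE`): after the main solve, each
  eliminated reaction ($a_i < 0.05$) is reinstated at full gain and *held*
  there while the remaining parameters re-optimize, then released; the
  better optimum is kept. This automates the validation step of removing or
  restoring individual reactions and refitting to confirm they are truly
  dispensable.

On noiseless toy-model data these two measures take random-start fits from
roughly a 60% success rate to consistently reaching the global optimum.
Because the solver remains local and carries no global-optimality
certificate, `cfl_multistart()` still collects a *family* of solutions from
independent uniform-random starts inside the bounds: the family hedges
against residual local minima, and its per-reaction average activity (the
"average pathway") distinguishes reactions that are consistently required
from interchangeable alternatives. The standard deviation of the family's
MAEs as a function of family size (`family_statistics()`) indicates when
enough restarts have been collected.

### Search space

The gain is always bounded in $[0,1]$. The midpoint bounds matter more: the
default $p \in [0.1, 0.4375]$ is the preset selected by grid search over
lower/upper-bound pairs in $[0.1, 2.0]$ (`select_bounds()` reproduces this
analysis and reports MAE and wall time per pair; quality is governed mostly
by the lower bound). For small demonstration models the wider
`preset = "toy"` box $[0.3, 0.7]$ is used, bracketing over- and
under-responsive transfer functions around the nominal $p = 0.5$ initial
guess. The nominal initial guess is $a = 1$, $p = 0.5$ (clipped into the
bounds); `init = "random"` draws uniformly in the box.

## Network reduction

Perturbation datasets constrain far fewer parameters than a large PKN
carries. Two complementary reductions are provided.

**Equivalent-class compartmentalization** (`compartmentalize()`): species
that are neither measured nor treatments and whose simulated responses under
nominal parameters ($a = 1, p = 0.5, n = 4$) are identical across *every*
experiment cannot be distinguished by the data; they are grouped into
compartments, reactions are rewritten onto compartments, duplicates merged,
and intra-compartment wiring dropped ("not interrogated"). Under nominal
parameters with 0/1 clamps all activations sit at the Boolean corners, so
response equality is effectively exact and the tight grouping tolerance
($10^{-9}$) avoids accidental merges; measured-node predictions are
identical before and after reduction. The scheme handles feedback loops,
since grouping is driven by simulated responses rather than graph patterns.
It can be *over-aggressive* when few experimental conditions are available:
if two readouts downstream of one compartment respond to different stimuli,
the reduced model must misfit one of them.
`compartmentalization_report()` flags a post-fit MAE above threshold for
exactly this reason, and the warning should prompt a comparison against an
unreduced fit. `map_back()` projects a fitted reduced model onto the
original PKN, inheriting each compartment-level activity to the original
edges that cross compartment boundaries.

**Iterative pruning** (`prune_reactions()`): from a multistart baseline fit,
the reaction with the smallest maximum activity $\max_k z_i^k$ is removed
(ties to the smallest reaction id), the model refit, and the loop stops when
the refit MAE exceeds the baseline by more than `mae_tolerance` (default
0.01 absolute), restoring the last removal. Reactions removable without
penalty are conflicting or non-identifiable; the remainder is vital for the
fit. Maximum activity is the removal criterion because it is the quantity
used to rank reaction importance when rendering optimized pathways; mean
activity would underweight reactions active in few conditions. Each refit
uses a small multistart (default 5 restarts) so that a local minimum is not
mistaken for an MAE increase. The removal sequence is not unique -- the
returned trace records every step precisely so alternative orders can be
audited.

## Cross-validation

`cross_validate()` masks a random fraction $\varphi$ of the measured cells
(cell-wise by default; whole conditions behind `mode = "condition"`, since
either reading of "random portions of the dataset" is defensible), fits on
the remainder, and reports the MAE on all cells and on the excluded cells,
averaged over replicates (default 5 per fraction). On a redundant design,
held-out cells remain inferable at small $\varphi$ (excluded-data error near
zero); as $\varphi$ grows the model is progressively unconstrained and the
total error climbs toward the null-solution ceiling.

## Synthetic data and what passing tests show

`build_toy_model()` ships a fixed 10-reaction demonstration pathway (two
stimuli, two inhibitor nodes, one latent kinase, five measured signals; 4
AND gates, 4 NOT inputs, 4 OR gates, 20 free parameters), pinned in a SIF
fixture. `build_toy_design()` crosses three stimulus conditions with three
inhibitor conditions (9 experiments, 45 data cells).
`toy_ground_truth()` zeroes three gains -- the crosstalk reactions from the
PI3K branch into MEK12, JNK and P38 -- so that recovery tests have an exact
target. `generate_dataset()` simulates a ground truth and optionally adds
truncated-Gaussian noise (clipped to $[0,1]$ to preserve the activation
domain without changing the mismatch metric). `random_pathway()` builds
connected acyclic gated networks of arbitrary size (optionally with an
injected feedback cycle) for property tests.

The generator emulates the *structure* of perturbation screens -- treatment
designs, single-time-point activations in $[0,1]$, gate logic -- but not
measurement physics: no fluorescence saturation, plate effects, replicate
structure, or systematically conflicting measurements, and noise is
independent truncated-Gaussian. Tests passing on these fixtures therefore
demonstrate correctness of the algorithms (simulation semantics, estimation,
reduction logic), not that a particular biological dataset will fit well;
real data add conflicts that leave a residual error floor.

Problem sizes used in the shipped tests were chosen to exercise each
property at the smallest scale at which it is meaningful: the toy model for
estimation and pruning, 200 random networks of up to 12 species for the
Boolean-limit equivalence (exhaustive over all stimulus combinations),
random networks of 15--40 species for compartmentalization invariance, 20
random starts or seeds where medians over seeds are asserted, and 50
restarts for family-stability checks.

## Degenerate inputs and edge behavior

* A species with no producers and no clamp stays at 0 (empty OR).
* All-zero signals pass normalization untouched (no division by zero);
  negative raw values are refused rather than silently shifted.
* Duplicate treatment rows in a MIDAS file are averaged into one experiment
  and the averaging is reported.
* Pure-NOT reactions ($|R_i| = 0$, $|I_i| = 1$) are accepted and listed by
  `validate_pathway()`, including the unusual case of such a reaction
  targeting a stimulus.
* Pruning with `mae_tolerance = Inf` removes every reaction and ends at the
  null solution, flagged `exhausted`.
* Solver failures inside a run are caught and reported in the solution's
  `status` with the initial guess as fallback; the returned objective never
  exceeds the initial one.

## Limitations

The model is single-time-point: dynamics, transients and any activity
outside the measured regime are invisible. Connectivity is restricted to the
PKN -- gains can remove reactions but nothing adds new ones, so data
demanding absent connectivity leaves irreducible error. The optimizer is
local; the multistart family reduces but cannot eliminate the chance of
missing the global optimum. And parameters of reactions the data never
exercise remain at whatever value the solver leaves them -- the reduction
tools exist precisely to make that set explicit rather than to estimate it.
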