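---
title: "Measuring brain state transition cost with Schrödinger Bridges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain state transition cost with Schrödinger Bridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbridge)
```

## The model

`sbridge` treats whole-brain dynamics as a first-order Markov chain over a
small number of discrete states. Multivariate activity (e.g. parcellated
fMRI frames) is coarse-grained by cosine k-means into states $1,\dots,k$;
the resting condition supplies a baseline transition kernel
$Q_{j|i} = q(X_T = j \mid X_0 = i)$; and each experimental condition is
summarized by its empirical state distribution.

A transition from an initial distribution $\pi$ to a target distribution
$\pi'$ that the baseline dynamics would not reach on their own requires the
system to deviate from its baseline path law $q(X_0^T)$. We score that
deviation by the Kullback–Leibler divergence between the controlled path
law $p(X_0^T)$ (constrained to $p(X_0)=\pi$, $p(X_T)=\pi'$) and the
uncontrolled one, and define the transition cost as the minimum

$$\mathcal{C} \;=\; \min_{p:\,p(X_0)=\pi,\;p(X_T)=\pi'}
  D_{\mathrm{KL}}\!\left(p(X_0^T)\,\|\,q(X_0^T)\right).$$

The minimizer is the classical Schrödinger Bridge. Writing the path
divergence as an endpoint term plus a conditional term shows that the
conditional term is annihilated by matching the interior of the controlled
path to the baseline bridge $q(X_1^{T-1}\mid X_0, X_T)$, so the whole
problem collapses to a coupling problem on the endpoints:

$$\mathcal{C} = \min_{P}\; D_{\mathrm{KL}}(P \,\|\, Q), \qquad
  \sum_j P_{ij} = \pi_i,\quad \sum_i P_{ij} = \pi'_j,$$

with $Q_{ij} = \pi_i (K^T)_{ij}$ the endpoint joint of the baseline chain
($K$ the one-step kernel, composed $T$ times for horizons $T > 1$).
Expanding the objective as $\sum_{ij} C_{ij}P_{ij} - H(P)$ with
$C_{ij} = -\log Q_{ij}$ identifies it as entropy-regularized optimal
transport, which is strictly convex: the optimum is unique and has the
Gibbs form $P^*_{ij} = e^{\alpha_i + \beta_j} Q_{ij}$.

Key modeling assumptions, in order of importance:

* the coarse-grained dynamics are first-order Markov and time-homogeneous
  at rest;
* task conditions matter only through their *marginal* state
  distributions — the baseline alone supplies dynamics;
* costs are reported for the *optimally* controlled path, i.e. they are a
  lower bound on whatever the system actually does.

## Solving the endpoint problem

`solve_bridge()` alternates the two multiplier updates

$$\alpha_i = \log \pi_i - \log \textstyle\sum_j e^{\beta_j} Q_{ij}, \qquad
  \beta_j = \log \pi'_j - \log \textstyle\sum_i e^{\alpha_i} Q_{ij},$$

the Sinkhorn fixed-point iteration, entirely in the log domain
(`logsumexp`), which keeps the iteration stable when $Q$ carries very small
probabilities. Numerical choices worth knowing:

* **Gauge.** The multipliers are determined only up to an additive constant
  exchanged with the normalizer. On termination the global normalization is
  folded into $\alpha$, so the reported multipliers reproduce $P^*$ exactly
  and the grand sum is exactly 1.
* **Convergence.** Iteration stops when the maximum absolute marginal
  residual drops below `tol` (default `1e-10`) or `max_iter` (default
  `1e5`) is hit; the latter raises an error carrying the final residual
  rather than returning a half-converged object. When a comparison demands
  cost agreement at the `1e-10` scale, solve at `tol = 1e-13`: a marginal
  residual of $\varepsilon$ perturbs the cost by roughly
  $\|\alpha\|_\infty\varepsilon$, not $\varepsilon$.
* **Zeros.** $Q_{ij}=0$ is preserved exactly in $P^*$ ($-\infty$ in the log
  domain); no smoothing is ever applied silently. Target mass on states
  unreachable under $Q$ raises a named infeasibility error. The support
  precondition (positive row/column mass wherever the marginals are
  positive) is necessary but not sufficient for a sparse $Q$; genuinely
  empty transportation polytopes surface as the non-convergence error. An
  explicit `smoothing` argument mixes $Q$ with the uniform joint when the
  user accepts the (quantified) change in cost that entails.
* **KL convention.** $0\log 0 = 0$; mass of $P$ outside the support of $Q$
  is an error, never `Inf`, so failures are loud.
* **Units.** All costs are natural-log (nats); `transition_cost(...,
  units = "bits")` rescales on request.
* **Horizons.** For $T>1$ only the endpoint joint built from the $T$-step
  kernel enters the optimization; `reconstruct_full_path()` recovers the
  interior afterwards as a time-inhomogeneous chain via the backward
  recursion $h_t = K h_{t+1}$, $h_T = e^{\beta}$ (a Doob $h$-transform).
  States with $h_t(s) = 0$ carry zero probability under the controlled
  path; their kernel rows are set uniform purely to keep the object
  row-stochastic.

```{r worked}
K <- rbind(c(0.9, 0.1), c(0.2, 0.8))   # baseline kernel
pi <- c(0.5, 0.5)                      # initial state distribution
sol <- solve_bridge(pi, c(0.9, 0.1), uncontrolled_joint(pi, K, T = 1))
sol
```

## Estimation and trajectory bootstrap

State sequences from many subjects are pooled. The empirical distribution
of a condition counts state occupancies over all of its frames. The
baseline joint over consecutive states is estimated from the pooled list of
within-subject transition pairs; pairs that would span two subjects'
recordings are excluded, because that adjacency is an artifact of
concatenation.

Uncertainty is propagated by trajectory bootstrapping: each replicate
resamples, uniformly with replacement, (i) transition pairs into a joint
matrix (row-normalized into a kernel) and (ii) frames into condition
distributions, then recomputes the bridge cost. Defaults follow the
estimation conventions:

* draws per resample = the number of available items (pairs or frames);
* 100 replicates (`n_replicates`), each with its own deterministic child
  seed derived from one master seed, so the whole ensemble is reproducible
  bit for bit;
* within a replicate the kernel and the two marginals are resampled from
  independent streams, keeping replicates exchangeable;
* a replicate whose resampled kernel has an unobserved source state is
  recorded with an `infeasible` status and excluded from summaries — never
  silently dropped.

The pooled-variance two-sample $t$ test (`bootstrap_ttest`) compares two
replicate ensembles with $df = n_a + n_b - 2$; with the conventional
$100+100$ replicates, $df = 198$. Treating bootstrap replicates as
independent samples is anti-conservative, and no multiple-testing
correction is applied; both caveats are recorded in the returned objects so
users can correct externally.

## Coarse-graining

`fit_cosine_kmeans()` implements spherical k-means: frames and centroids
are unit-normalized and assignment maximizes the dot product (ties to the
lowest index). This is the natural reading of "cosine similarity as the
clustering distance" in high-dimensional activity data, where the direction
of the activity pattern, not its amplitude, defines the state. Since the
Euclidean-only `stats::kmeans` re-centers centroids off the sphere, the
Lloyd loop is implemented here directly, with k-means++-style seeding on
the sphere, 10 restarts by default, and empty clusters reseeded at the
worst-fit frame.

Explained variance is defined through the squared chordal distance
$\|x - c\|^2 = 2 - 2\cos(x, c)$ on the unit sphere, relative to the
dispersion around the single best direction, so it runs from 0 at $k=1$ to
1 when every frame has its own centroid. Two diagnostics guide the choice
of $k$: the explained-variance curve (`explained_variance_curve`), which
plateaus once $k$ exceeds the number of genuinely distinct patterns, and
the occupancy check (`occupancy_check`), which flags subject × condition
blocks in which some state never occurs — costs involving such blocks
would be estimated from zero counts. `balance_frames()` truncates every
condition to the smallest per-condition frame count (first frames kept) so
unequal recording lengths cannot bias the clustering.

No internal z-scoring or filtering is applied: frames are clustered exactly
as supplied, and any preprocessing is the caller's responsibility.

## What the synthetic generator does and does not emulate

`make_planted_hierarchy()` builds a fully known study: a sticky random
baseline kernel with a deliberately non-uniform stationary distribution
$\pi_0$, plus two task conditions whose target distributions tilt $\pi_0$
toward the rarely visited states, the "hard" condition (tilt 0.55) further
than the "easy" one (tilt 0.25). Because the bridge cost is convex in the
target and zero at the stationary target, costs along this common tilt ray
are strictly ordered by construction; the easy↔hard asymmetry is verified
against the true kernel at construction time, and the constructor errors
rather than returning a spec whose planted structure failed. The true
(infinite-data) pairwise costs ship with the spec as oracle values.

The default cohort is 96 subjects × 176 frames per condition — a
one-tenth-scale version of the large public fMRI cohorts this design
emulates (hundreds of subjects, 176-frame task runs), with the task-run
length kept at its realistic value. Activity matrices place the $k$ states
on mutually orthogonal unit directions in $M = 20$ dimensions with
isotropic Gaussian noise of sd $1/8$; baseline sequences are genuine Markov
chains started from $\pi_0$, task frames are i.i.d. draws from the tilted
distributions (their temporal order never enters any downstream
computation).

What the generator deliberately does *not* emulate: hemodynamic smoothing
and temporal autocorrelation within states, spatial correlation between
parcels, subject-level heterogeneity in kernels or distributions, and
non-orthogonal (merely separated) state patterns. Passing the recovery
tests therefore demonstrates correctness of the estimators and solver under
the stated model, not robustness to fMRI physiology.

## Reproducibility and problem sizes

Every stochastic function takes a seed and derives named child streams from
it (`subject:condition` for simulation, `repN:kernel` / `repN:cond` for
bootstrap replicates, `kmeans-restartN` for clustering), so a single master
seed reproduces every stage bitwise, and stages can be reproduced in
isolation. The test suite exercises: oracle agreement of the solver on 100
two-state and 20 three-state instances (against exhaustive 1-D minimization
and an interior-point solve, respectively), structural invariants on
couplings up to $k=16$, exhaustive path enumeration up to $k=4$, $T=4$,
kernel recovery from $10^3$–$10^5$ simulated steps of a $k=8$ chain,
planted-cluster recovery at $k=4$, and the full planted hierarchy at the
default study size with 100 bootstrap replicates. These sizes are the
package's reference configuration; all scale linearly (in frames and
replicates) if users want tighter error bars.

## Known limitations

* The cost is a lower bound attached to the *optimal* control; empirical
  paths will generally cost more, and nothing here estimates them.
* First-order Markovianity of the coarse-grained states is assumed, not
  tested; long-memory dynamics would bias both the kernel and the cost.
* The baseline kernel is pooled across subjects; subject-level costs are
  out of scope.
* Bootstrap $t$ tests overstate significance (replicates are not
  independent subjects); interpret $p$-values comparatively, not
  literally.
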