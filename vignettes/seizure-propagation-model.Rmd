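---
title: "Modelling seizure propagation and virtual resections with epispread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seizure propagation and virtual resections with epispread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epispread)
```

## The model

`epispread` treats the early phase of a focal seizure as an epidemic on a
weighted brain network. Nodes are atlas regions of interest (ROIs, e.g.
the 246 regions of the Brainnetome atlas); edge weights $w_{ij} \in [0,1]$
come from a functional connectivity matrix (typically uncorrected
amplitude envelope correlation from MEG, which retains the imprint of
structural connectivity) or from a synthetic surrogate. Dynamics follow
the susceptible-infected (SI) model: once a region joins the seizure it
stays in, and at every discrete step each infected node $i$ independently
recruits each susceptible neighbour $j$ with probability
$\beta\, w_{ij}$. The SI abstraction deliberately ignores inhibition and
seizure termination: it describes the recruitment order and speed during
the initial spread, which is what intracranial recordings of seizure
propagation capture, with a single free rate parameter $\beta$.

Networks are proportionally thresholded: at density $\theta$ the
strongest $\mathrm{round}(\theta N (N-1)/2)$ links survive with their
weights intact (thresholded, not binarized), and the mean connectivity is
reported as $\kappa = \theta N$ (the exact graph mean degree is
$\theta (N-1)$; both are stored). Ties at the threshold boundary are
broken by lexicographic edge order so retained sets are deterministic and
nested across $\theta$. For spreading experiments at different densities
the rate is controlled through the invariant $\beta\theta = 4\cdot10^{-4}$
(so $\beta = 0.01$ at 4% density), and extents are read off at the fixed
horizon $t_0 = 50$ steps with $N_R = 10^4$ Monte-Carlo realizations by
default.

Two seed definitions are supported: the resection area (RA) identified
from post-operative imaging (the retrospective default) and the seizure
onset zone (SOZ) hypothesized from stereo-EEG, which is the one available
prospectively.

## Fitting the density to a clinical pattern

Stereo-EEG (SEEG) samples a sparse, clinically chosen subset of ROIs
(30-60 in the cohort this model was developed on). A clinical seizure
pattern assigns each sampled ROI an activation step; contact points
mapping to the same ROI are merged at their earliest step (seizure-onset
semantics), and steps are converted to midpoint-tie ranks
$\mathrm{RANK}^{\mathrm{SEEG}}_i$.

The model-side pattern uses the slow-propagation limit $\beta \to 0$, in
which exactly one node is recruited per step, chosen with probability
proportional to its total link weight to the already-infected set. The
mean activation step per ROI over many invasion sequences, restricted to
the SEEG-sampled set and midpoint-ranked, gives
$\mathrm{RANK}^{\mathrm{SI}}_i$. The agreement between the two patterns
is the rank correlation

$$
C \;=\; \frac{\mathrm{cov}\!\left(\mathrm{RANK}^{\mathrm{SEEG}},
\mathrm{RANK}^{\mathrm{SI}}\right)}
{\sigma\!\left(\mathrm{RANK}^{\mathrm{SEEG}}\right)\,
\sigma\!\left(\mathrm{RANK}^{\mathrm{SI}}\right)},
$$

numerically the Pearson correlation of the rank vectors (equivalently the
tie-corrected Spearman coefficient; the ratio is invariant to population
vs sample moments). Significance comes from a two-sided permutation test
(default $10^4$ permutations of one rank vector). A rank-based U test is
sometimes quoted in this context, but it compares two samples rather than
testing an association; the permutation test is assumption-free and
respects the tied-rank structure, so it is what `pattern_correlation()`
reports.

`fit_threshold()` scans the density grid
$\theta \in \{0.01, 0.02, 0.04, 0.06, 0.08, 0.10, 0.15, \dots, 0.50\}$
(denser at low $\theta$, where the model is more sensitive) and computes
$C(\theta)$. Two numerical choices matter here:

* **Unreachable ROIs are censored, not dropped.** At low density a
  network fragments and some sampled ROIs cannot be reached from the
  seed. Dropping them would evaluate low-density networks only on the
  easy near-seed subset and inflate $C$ exactly where the network is
  worst; instead unreachable ROIs are ranked jointly last, consistent
  with an infection time censored at the integration horizon. Sampled
  ROIs absent from the clinical pattern (contacts that never activated)
  are excluded from both rankings.
* **First-maximum selection with a prominence band.** $C(\theta)$ is
  typically bimodal and the fit prefers the low-density maximum, which
  keeps only the fundamental pathways. A bare "lowest significant local
  maximum" rule is fragile: on flat stretches Monte-Carlo noise
  manufactures spurious local maxima (noise-free curves can even show
  exact ties on the rising shoulder), and tiny-but-significant bumps on
  fragmented networks would win despite sitting far below the true peak.
  `fit_threshold()` therefore accepts a local maximum only if it is
  significant *and* within `peak_tol` (default 1%, the Monte-Carlo noise
  scale of $\hat C$ at $10^3$ runs) of the best significant correlation,
  falling back to the global maximum (flagged) when nothing is
  significant.

`median_correlation_curve()` gives the cohort-level "average model"
(pointwise median of the per-patient curves), `average_network()` the
common-substrate variant, and `fully_connected_baseline()` the trivial
all-to-all control, for which the slow-propagation expectation is known
in closed form by exchangeability (seed at 0, everything else tied), so
its degenerate ranking is detected exactly rather than estimated.

## Virtual resections

A virtual resection zeroes all links of the selected nodes, leaving
network size unchanged. Its effect is the post-resection extent
$I_\mathcal{R}(t_0)$ — the expected fraction of *non-seed* nodes infected
at $t_0$, with $\beta$ re-derived from $\beta\theta$ at the patient's
fitted density — and the normalized $i_\mathcal{R} =
I_\mathcal{R}(t_0)/I(t_0)$. Counting non-seed nodes makes "complete
disconnection of the seed" give exactly zero, which is the natural
definition of a 100% effective resection (the still-formally-infected
seed would otherwise put a floor under every extent);
`propagation_extent(include_seed = TRUE)` provides the figure-style
curves that count every node.

Searching over node subsets is combinatorial, so the optimizer uses a
four-step scheme per resection size $S$:

1. **Candidate pool**: the seed and its first and second unweighted-hop
   neighbours — nodes further away have negligible influence on early
   spread.
2. **Surrogate search**: simulated annealing maximizes the mean
   *effective distance* from the seed. Each link gets the length
   $d_{ij} = 1 - \ln P_{ij}$ with row-stochastic
   $P_{ij} = w_{ij}/\sum_k w_{ik}$; likely spreading routes are short in
   this metric, and multi-source shortest paths from the seed predict
   arrival order. (The exact construction used alongside the original
   clinical study was published only in supplementary material; the form
   here is the standard effective-distance definition from the
   contagion-forecasting literature and should be read as a
   reconstruction.) The objective averages $\min(d, \mathrm{cap})$ over a
   *fixed* target set — all non-seed nodes — with unreachable and
   resected nodes contributing the cap (effective-distance diameter of
   the intact network plus one). The fixed denominator makes the
   objective provably non-decreasing when nodes are added to a
   resection; averaging only over surviving targets would not be.
3. **SI refinement**: the top distinct candidate sets by surrogate value
   (default 10), plus the previous size's best set extended by its best
   greedy addition (which keeps the optimal-extent curve non-increasing)
   and, at $S = S_\mathrm{RA}$, the trivial full-seed resection, are
   evaluated with full SI simulations.
4. **Selection**: the SI-minimal set wins; ties resolve by surrogate
   rank, then lexicographic node order.

The annealing schedule is geometric (cooling 0.95 per pool-sized block,
$200\,|\mathrm{pool}|$ proposals, 3 restarts) with the initial
temperature calibrated so a typical uphill-cost move on a short random
walk is accepted with probability 0.8. These defaults are justified by an
oracle suite: on small instances the annealer must match exhaustive
subset search exactly.

`resection_curve()` extracts the clinical summaries: $\mathcal{R}_{90}$
(smallest resection with $i_\mathcal{R} \le 0.1$), $\mathcal{R}_{100}$
(smallest with zero non-seed infections in *every* run — an exact-zero
criterion, verified by re-simulation at higher run counts in the tests),
$\mathcal{R}1$ (best single node), the relative sizes
$s_{90}, s_{100}$, and the seed statistics $\kappa_\mathrm{RA}$ and
$E_\mathrm{RA} = S_\mathrm{RA}\,\kappa_\mathrm{RA}$ used to relate
resection difficulty to seed embedding.

## The synthetic-patient generator

Clinical MEG/SEEG data of this kind cannot be shared, so the package
ships a generator whose draws exercise every stage of the pipeline:

* **Centroids** uniform in a 120 mm cube, the linear scale of a human
  brain; the default 90 ROIs keep a full pipeline run fast (246
  reproduces atlas size).
* **Weights** follow the exponential distance rule
  $w_{ij} = e^{-\lambda d_{ij}}\,\varepsilon_{ij}$ with symmetric
  lognormal noise. The decay defaults to $\lambda = 0.052$ per mm, the
  value obtained when the distance rule is refit at region-level atlas
  resolution (the literature value $0.188$ stems from far finer
  parcellations and would make weights span ~40 log-units across the
  box, leaving the spreading order insensitive to density); the noise
  scale 0.85 is calibrated so the surrogate correlates with its
  noise-free EDR backbone at $r \approx 0.7$, matching what AEC-MEG
  networks achieve against the atlas-resolution rule. `edr_matrix()`
  itself keeps the literature default $\lambda = 0.188$ for
  surrogate-validation use.
* **Seed**: the 4 ROIs nearest a random focus (range 3-12 clinically),
  required to be connected on the planted-density network — a resection
  area is contiguous tissue. Draws violating this are regenerated (the
  attempt count is recorded; about three quarters succeed first try).
* **SEEG sampling**: 30 ROIs (clinical range 30-60) drawn without
  replacement with probability $\propto e^{-d_\mathrm{seed}/30\,
  \mathrm{mm}}$, seed included — electrodes target the suspected onset
  zone but also sample remote cortex.
* **Clinical pattern**: the slow-propagation order on the
  $\theta^* = 0.10$ network, coarsened into 6 equal-count activation
  steps (typical seizures show about 6 propagation steps), emulating a
  clinician grouping contacts by when ictal activity first appears.

What the generator does *not* emulate: volume-conduction structure and
spatial correlations of real AEC matrices, hub architecture beyond what
distance dependence induces, electrode-geometry constraints (contacts
along straight trajectories), inter-seizure variability, or any
post-resection plasticity. Passing tests on synthetic patients therefore
show that the pipeline is correct and identifiable under its own
generative assumptions — not that the model is clinically valid.

## Problem sizes, tolerances and degenerate inputs

* The test and acceptance suites use 90-ROI synthetic cohorts, $10^3$
  slow-propagation runs per grid point for fits and a few hundred SI
  runs for resection toys; the atlas-size uniform-limit check runs the
  full $10^4$ realizations. A complete fit-plus-resection pass over a
  default patient takes on the order of a minute on one CPU.
* Monte-Carlo extents carry $\mathrm{SE} \lesssim 0.5/\sqrt{N_R}$;
  monotonicity of resection curves is asserted within 3 combined
  standard errors. The discrete-time SI mean differs from the continuous
  logistic solution by a few percent (the per-step infection probability
  $1-(1-\beta)^I$ is below $\beta I$, and early-phase stochasticity adds
  a downward Jensen bias), so mean-field comparisons use a 5-10%
  tolerance band rather than Monte-Carlo error bars.
* Degenerate cases are explicit: fully tied rankings make $C$ undefined
  and are reported as 0 with a flag (the fully connected baseline hits
  this by construction); a fully resected seed yields extent 0, not an
  error; isolated nodes are unreachable (infinite effective distance,
  `NA` activation step) rather than errors; loading rejects NaNs,
  out-of-range weights and asymmetries beyond $10^{-9}$ instead of
  repairing them.
* All randomness flows from a single master seed per entry point;
  per-stage streams are derived deterministically, so every fit, search
  and simulation is bit-reproducible at fixed configuration.

## Known limitations

* The SI model has no inhibition or termination; only the early
  recruitment order is meaningful, and extents are always read at a
  fixed short horizon.
* Effective distance is a reconstruction (see above); other published
  variants (e.g. without the multi-source minimum, or averaging over
  random walks rather than shortest paths) would change surrogate values
  but are screened out by the SI refinement step.
* The fitted density rests on one typical seizure pattern per patient;
  the method has no notion of pattern uncertainty.
* Simulated annealing offers no optimality guarantee for pools beyond
  the oracle-verified sizes; restarts and the greedy monotone hull
  mitigate but do not eliminate this.
* The candidate pool excludes nodes more than two hops from the seed by
  design; resections exploiting long-range topology are out of reach.

## A minimal worked example

```{r example, eval = FALSE}
library(epispread)

pat <- generate_patient(synthetic_patient_config(rng_seed = 11))
fit <- fit_threshold(pat$network, pat$clinical, pat$seed,
                     n_runs = 1000, n_perm = 2000, rng_seed = 21)
fit

net <- threshold_network(pat$network, fit$theta_max)
curve <- resection_curve(net, pat$seed,
                         cfg = si_config(n_runs = 500, rng_seed = 31),
                         rng_seed = 41)
curve$table
```
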