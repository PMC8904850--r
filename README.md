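# epispread

Individualized modelling of seizure propagation as an epidemic on brain
networks, and optimization of virtual resections.

## The problem

Epilepsy surgery removes or disconnects the brain tissue thought to
generate seizures, but seizure freedom is reached in only about two of
three patients, and the resection that would have sufficed is never known
in advance. `epispread` implements a deliberately simple, individually
fittable computational pipeline for this problem, aimed at researchers in
epilepsy network modelling:

1. **Model.** Seizure spread is a susceptible-infected (SI) epidemic on a
   weighted brain network `w_ij` (one node per atlas ROI; weights from
   MEG amplitude-envelope-correlation matrices or synthetic surrogates).
   At each step an infected node `i` recruits a susceptible neighbour `j`
   with probability `β·w_ij`; once recruited, a region stays in. The
   network is proportionally thresholded at density `θ` (strongest links
   kept, weights unchanged), with mean connectivity `κ = θN` and the rate
   controlled by the invariant `βθ = 4·10⁻⁴`.
2. **Fit.** For each patient, the density `θ` is fitted so that the
   model's slow-propagation (`β → 0`) recruitment order, restricted to
   the ROIs sampled by stereo-EEG, best reproduces the clinically
   observed activation ranking. Agreement is the rank correlation
   `C = cov(RANK_SEEG, RANK_SI) / (σ(RANK_SEEG)·σ(RANK_SI))` with
   permutation significance; the sparsest significant maximum of `C(θ)`
   is selected.
3. **Resect.** On the fitted network, virtual resections (zeroing all
   links of chosen nodes) are optimized per size `S` by simulated
   annealing on an effective-distance surrogate
   (`d_ij = 1 − ln(w_ij / Σ_k w_ik)`, multi-source shortest paths from
   the seed) followed by SI re-evaluation. Summaries: `R90`/`R100` (the
   smallest resections reducing spread at `t₀ = 50` steps by 90% / 100%),
   the best one-node resection `R1`, relative sizes `s90`, `s100`, and
   the seed statistic `E_RA = S_RA·κ_RA`.

Because clinical MEG/SEEG data of this kind are not shareable, the
package includes a first-class synthetic-patient generator
(exponential-distance-rule networks with calibrated noise, compact seeds,
SEEG-style biased sparse sampling, step-coarsened activation patterns) so
the whole pipeline is testable end to end.

## Worked example

```r
library(epispread)

pat <- generate_patient(synthetic_patient_config(rng_seed = 11))
pat
#> synthetic_patient: 90 ROIs, seed of 4, 30 sampled, theta* = 0.1

fit <- fit_threshold(pat$network, pat$clinical, pat$seed,
                     n_runs = 1000, n_perm = 2000, rng_seed = 21)
fit
#> fit_result (RA seed): theta_max = 0.1 (kappa = 9), C_max = 0.985 (p = 0.0005)

net <- threshold_network(pat$network, fit$theta_max)
curve <- resection_curve(net, pat$seed,
                         cfg = si_config(n_runs = 500, rng_seed = 31),
                         sa_cfg = sa_config(n_prop_per_node = 30, restarts = 2),
                         rng_seed = 41)
curve$table
#>   S         I_R       i_R    resected
#> 1 1 0.025465116 0.6141335          44
#> 2 2 0.014883721 0.3589456       31,44
#> 3 3 0.005953488 0.1435782    16,31,44
#> 4 4 0.000000000 0.0000000 16,31,44,58
```

Reading the output: the fit recovers the planted density (`theta* = 0.1`,
`theta_max = 0.1`) with rank correlation 0.985 between simulated and
"clinical" activation orders. The resection scan then shows the expected
fraction of non-seed regions recruited by step 50 (`I_R`) falling as the
resection grows; here the best single node (ROI 44) already cuts spread
to 61% of baseline (`i_R`), and disconnecting the full 4-node seed
(ROIs 16, 31, 44, 58) stops it exactly (`I_R = 0`), i.e. `s100 = 1` for
this patient.

Multi-patient orchestration: `fit_patients()`, `resect_patients()`,
`median_correlation_curve()` (average model), `average_network()`
(common substrate), `fully_connected_baseline()` (trivial control) and
`group_stats()` (paired/unpaired t-tests, correlation + least squares).
`patient_table()` ships the clinical cohort metadata used for realistic
parameter ranges. A thin command-line wrapper with `synth`, `simulate`,
`fit`, `resect` and `report` subcommands lives at
`system.file("cli", "epispread", package = "epispread")`.

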