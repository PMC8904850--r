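#' SI simulation configuration
#'
#' @param beta per-link infection probability per step, in \[0,1\]. If `NULL`
#'   it is derived from `beta_theta / theta` of the network at simulation
#'   time, which keeps the product `beta * theta` constant across network
#'   densities.
#' @param t0 evaluation horizon for propagation extents, in steps.
#' @param T maximum integration horizon for the probability map; defaults
#'   to `10 * N` at simulation time so censoring is negligible on
#'   connected networks.
#' @param n_runs number of Monte-Carlo realizations.
#' @param rng_seed master integer seed; every stochastic quantity derived
#'   from a simulation with the same seed is bit-reproducible.
#' @param beta_theta the constant `beta * theta` used to derive `beta`
#'   when it is not given explicitly (default `4e-4`, e.g. `beta = 0.01`
#'   at 4% density).
#' @return A list of class `si_config`.
#' @export
si_config <- function(beta = NULL, t0 = 50, T = NULL, n_runs = 1e4,
                      rng_seed = NULL, beta_theta = 4e-4) {
  if (!is.null(beta) && (beta < 0 || beta > 1)) stop("beta must be in [0, 1]")
  if (!is.null(T) && t0 > T) stop("t0 must not exceed T")
  if (n_runs < 1) stop("n_runs must be at least 1")
  structure(list(beta = beta, t0 = t0, T = T, n_runs = as.integer(n_runs),
                 rng_seed = rng_seed, beta_theta = beta_theta),
            class = "si_config")
}

resolve_beta <- function(cfg, net) {
  if (!is.null(cfg$beta)) return(cfg$beta)
  b <- cfg$beta_theta / net$theta
  if (b > 1) stop("derived beta = ", b, " exceeds 1; supply beta explicitly")
  b
}

resolve_T <- function(cfg, net) {
  if (!is.null(cfg$T)) return(as.integer(cfg$T))
  max(as.integer(10 * n_rois(net)), as.integer(cfg$t0))
}

#' Monte-Carlo SI epidemic simulation
#'
#' Synchronous discrete-time susceptible-infected dynamics: at each step,
#' every infected node independently infects each susceptible neighbour
#' `j` with probability `beta * w_ij`. Aggregates `n_runs` realizations
#' into the first-infection probability map `p_i(t)`, the infection curve
#' `I(t)` (fraction of all nodes infected by `t`, seed included), and the
#' mean infection time per ROI.
#'
#' @param net a [brain_network()].
#' @param seed nonempty set of seed ROI ids (infected at `t = 0`).
#' @param cfg an [si_config()].
#' @return An object of class `propagation_result` with elements `p`
#'   (`N x (T+1)` matrix, `p[i, t+1] = P(i first infected at step t)`),
#'   `infected_curve` (`I(t)`, `t = 0..T`), `mean_times` (expected
#'   first-infection step, censored at `T`), `censor_frac` (per-ROI
#'   fraction of runs never infected by `T`), `literal_time_sum`
#'   (`sum_t p_i(t)`, kept for audit; this is a total infection
#'   probability, not a time), `seed`, `beta`, `t0`, `T`, `n_runs`.
#' @export
simulate_si <- function(net, seed, cfg = si_config()) {
  stopifnot(inherits(net, "brain_network"))
  if (length(seed) == 0) stop("seed must be nonempty")
  idx <- roi_index(net, seed)
  beta <- resolve_beta(cfg, net)
  T <- resolve_T(cfg, net)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  counts <- si_simulate_cpp(net$weights, idx - 1L, beta, T, cfg$n_runs)
  n <- n_rois(net)
  p <- counts / cfg$n_runs
  tot <- rowSums(p)
  censor <- 1 - tot
  steps <- 0:T
  mean_times <- as.vector(p %*% steps) + censor * T
  infected_curve <- cumsum(colSums(p)) / n
  structure(
    list(p = p, infected_curve = setNames(infected_curve, steps),
         mean_times = setNames(mean_times, net$rois$roi_id),
         censor_frac = setNames(censor, net$rois$roi_id),
         literal_time_sum = setNames(tot, net$rois$roi_id),
         seed = sort(unique(as.integer(seed))),
         beta = beta, t0 = cfg$t0, T = T, n_runs = cfg$n_runs),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "propagation_result: %d ROIs, seed of %d, beta = %.3g, %d runs\n",
    nrow(x$p), length(x$seed), x$beta, x$n_runs))
  it0 <- x$infected_curve[as.character(min(x$t0, x$T))]
  cat(sprintf("  I(t0 = %d) = %.3f; mean censoring %.2g\n",
              x$t0, it0, mean(x$censor_frac)))
  invisible(x)
}

#' Mean infection times from a propagation result
#'
#' The expected first-infection step per ROI, computed from the
#' first-infection probability map (equivalently, the sum over `t` of the
#' survival probability). Seed nodes are always infected at time 0. Runs
#' in which a ROI is never infected within the horizon `T` are censored at
#' `T`; the per-ROI censoring fraction is attached as an attribute.
#'
#' @param res a `propagation_result` from [simulate_si()].
#' @return Named numeric vector of expected times with attribute
#'   `censor_frac`.
#' @export
mean_infection_times <- function(res) {
  stopifnot(inherits(res, "propagation_result"))
  out <- res$mean_times
  attr(out, "censor_frac") <- res$censor_frac
  out
}

#' Slow-propagation (beta -> 0) activation order
#'
#' In the slow-propagation limit exactly one new node is infected per step,
#' chosen with probability proportional to the total link weight between
#' the node and the already-infected set. Returns the mean activation step
#' per ROI over `n_runs` stochastic invasion sequences; seed nodes are at
#' step 0, nodes disconnected from the seed are unreachable and reported
#' as `NA`.
#'
#' @param net a [brain_network()].
#' @param seed nonempty set of seed ROI ids.
#' @param n_runs number of invasion sequences to sample.
#' @param rng_seed optional integer seed.
#' @return Named numeric vector of mean activation steps (`NA` =
#'   unreachable).
#' @export
slow_propagation_pattern <- function(net, seed, n_runs = 1e3,
                                     rng_seed = NULL) {
  stopifnot(inherits(net, "brain_network"))
  if (length(seed) == 0) stop("seed must be nonempty")
  idx <- roi_index(net, seed)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  res <- slow_propagation_cpp(net$weights, idx - 1L, as.integer(n_runs))
  mean_step <- ifelse(res$reached > 0, res$step_sum / res$reached, NA_real_)
  setNames(mean_step, net$rois$roi_id)
}

#' Propagation extent with and without a virtual resection
#'
#' Measures the spreading extent `I_R(t0)`: the expected fraction of
#' non-seed nodes infected at the horizon `t0` after resecting a node set,
#' and its value normalized by the pre-resection extent,
#' `i_R = I_R(t0) / I(t0)`. The infection rate is derived from the
#' constant `beta * theta` at the network's density unless `cfg$beta` is
#' set. Seed nodes that are resected are removed from the effective seed;
#' a fully resected seed gives extent exactly 0. Counting only non-seed
#' nodes makes complete disconnection of the seed yield `I_R(t0) = 0`
#' exactly.
#'
#' @param net a [brain_network()] (pre-resection).
#' @param seed nonempty set of seed ROI ids.
#' @param resected ROI ids to resect (may be empty).
#' @param cfg an [si_config()].
#' @param baseline_extent optional pre-computed pre-resection extent (for
#'   repeated calls against the same baseline).
#' @param include_seed if `TRUE`, extents count all infected nodes over
#'   `N` (figure-style curves) instead of non-seed nodes over
#'   `N - |seed|`.
#' @return List with `I_R` (post-resection extent at `t0`), `I0` (baseline
#'   extent), `i_R`, `resected`, and `all_runs_zero` (`TRUE` when no
#'   non-seed node was infected in any run).
#' @export
propagation_extent <- function(net, seed, resected = integer(0),
                               cfg = si_config(), baseline_extent = NULL,
                               include_seed = FALSE) {
  seed <- sort(unique(as.integer(seed)))
  resected <- sort(unique(as.integer(resected)))
  extent_of <- function(network, eff_seed) {
    if (length(eff_seed) == 0) return(list(extent = 0, zero = TRUE))
    res <- simulate_si(network, eff_seed, cfg)
    t0 <- min(cfg$t0, res$T)
    prob_by_t0 <- rowSums(res$p[, seq_len(t0 + 1), drop = FALSE])
    non_seed <- !(net$rois$roi_id %in% seed)
    if (include_seed) {
      ext <- sum(prob_by_t0) / n_rois(net)
    } else {
      ext <- sum(prob_by_t0[non_seed]) / sum(non_seed)
    }
    list(extent = ext, zero = sum(prob_by_t0[non_seed]) == 0)
  }
  if (is.null(baseline_extent)) {
    baseline_extent <- extent_of(net, seed)$extent
  }
  eff_seed <- setdiff(seed, resected)
  post <- extent_of(apply_resection(net, resected), eff_seed)
  list(I_R = post$extent, I0 = baseline_extent,
       i_R = if (baseline_extent > 0) post$extent / baseline_extent else NA_real_,
       resected = resected, all_runs_zero = post$zero)
}

#' Export a propagation result to TSV
#'
#' Writes `(roi_id, mean_time, censor_frac, total_infection_prob)` and the
#' infection curve `I(t)`, plus a JSON block echoing the simulation
#' parameters for provenance.
#'
#' @param res a `propagation_result`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
export_propagation <- function(res, dir, prefix = "propagation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roi_path <- file.path(dir, paste0(prefix, "_rois.tsv"))
  curve_path <- file.path(dir, paste0(prefix, "_curve.tsv"))
  cfg_path <- file.path(dir, paste0(prefix, "_config.json"))
  write.table(
    data.frame(roi_id = names(res$mean_times),
               mean_time = unname(res$mean_times),
               censor_frac = unname(res$censor_frac),
               total_infection_prob = unname(res$literal_time_sum)),
    roi_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(
    data.frame(t = as.integer(names(res$infected_curve)),
               I = unname(res$infected_curve)),
    curve_path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- list(seed = res$seed, beta = res$beta, t0 = res$t0, T = res$T,
              n_runs = res$n_runs)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), cfg_path)
  invisible(c(roi_path, curve_path, cfg_path))
}
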