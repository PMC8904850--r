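#' Effective distance to the seed
#'
#' Per-link effective length `d_ij = 1 - ln(P_ij)` with row-stochastic
#' transition probabilities `P_ij = w_ij / sum_k w_ik` (directed: out of
#' node `i`), and per-node distance the multi-source shortest-path length
#' over these lengths from the nearest seed node. Likely spreading routes
#' (high transition probability) are short in this metric, so effective
#' distance predicts epidemic arrival order and serves as a fast surrogate
#' for the SI dynamics. This construction follows the standard
#' effective-distance definition from the contagion-spreading literature;
#' the exact variant used in the original study is reconstructed here (its
#' derivation was only published in supplementary material).
#'
#' @param net a [brain_network()].
#' @param seed nonempty set of seed ROI ids.
#' @return Named numeric vector: 0 on the seed, `Inf` for unreachable
#'   (e.g. isolated/resected) nodes.
#' @export
effective_distance <- function(net, seed) {
  if (length(seed) == 0) stop("seed must be nonempty")
  idx <- roi_index(net, seed)
  g <- effdist_graph(net)
  d <- igraph::distances(g, v = idx, mode = "out",
                         weights = igraph::E(g)$effdist)
  out <- apply(d, 2, min)
  setNames(out, net$rois$roi_id)
}

# directed igraph whose edge attribute effdist holds 1 - log(P_ij)
effdist_graph <- function(net) {
  w <- net$weights
  s <- rowSums(w)
  P <- w / ifelse(s > 0, s, 1)
  P[s == 0, ] <- 0
  g <- igraph::graph_from_adjacency_matrix(P, mode = "directed",
                                           weighted = TRUE)
  igraph::E(g)$effdist <- 1 - log(igraph::E(g)$weight)
  g
}

#' Unreachable-node cap for the surrogate objective
#'
#' The effective-distance "diameter" of a network (largest finite pairwise
#' effective distance) plus one. Used so that nodes disconnected from the
#' seed contribute a large finite value to the surrogate objective,
#' keeping it finite while strictly rewarding disconnection.
#'
#' @param net a [brain_network()].
#' @return A single number.
#' @export
effdist_cap <- function(net) {
  g <- effdist_graph(net)
  d <- igraph::distances(g, mode = "out", weights = igraph::E(g)$effdist)
  max(d[is.finite(d)], 0) + 1
}

#' Surrogate containment objective of a resection
#'
#' The mean effective distance from the (remaining) seed to the non-seed
#' nodes after virtually resecting a node set. The mean runs over a fixed
#' target set — all non-seed nodes of the original network — with
#' unreachable and resected nodes contributing the finite cap (a resected
#' node is maximally contained). Larger values mean the epidemic is
#' pushed further away, so larger = better containment, and adding a node
#' to the resection can never decrease the objective. Used as a cheap
#' stand-in for the SI dynamics during the combinatorial search.
#'
#' @param net a [brain_network()] (pre-resection).
#' @param seed nonempty seed ROI ids.
#' @param resected ROI ids to resect (may include seed nodes).
#' @param cap unreachable-node contribution; defaults to
#'   [effdist_cap()] of the unresected network.
#' @return A single number (`cap` when everything is contained, 0 when
#'   there is no non-seed node).
#' @export
surrogate_objective <- function(net, seed, resected = integer(0),
                                cap = NULL) {
  if (is.null(cap)) cap <- effdist_cap(net)
  seed <- unique(as.integer(seed))
  resected <- unique(as.integer(resected))
  targets <- setdiff(net$rois$roi_id, seed)
  if (length(targets) == 0) return(0)
  eff_seed <- setdiff(seed, resected)
  if (length(eff_seed) == 0) return(cap)
  net_r <- apply_resection(net, resected)
  d <- effective_distance(net_r, eff_seed)[as.character(targets)]
  mean(pmin(d, cap))
}

#' Simulated-annealing configuration for resection search
#'
#' @param n_prop_per_node proposals per candidate-pool node per restart.
#' @param cool geometric cooling factor, applied once per pool-sized block
#'   of proposals.
#' @param restarts independent annealing restarts.
#' @param top_k number of distinct best sets to keep for SI refinement.
#' @param accept0 target acceptance probability of a typical uphill-cost
#'   move on the calibration walk that sets the initial temperature.
#' @return A list of class `sa_config`.
#' @export
sa_config <- function(n_prop_per_node = 200, cool = 0.95, restarts = 3,
                      top_k = 10, accept0 = 0.8) {
  stopifnot(n_prop_per_node >= 1, cool > 0, cool < 1, restarts >= 1,
            top_k >= 1, accept0 > 0, accept0 < 1)
  structure(list(n_prop_per_node = n_prop_per_node, cool = cool,
                 restarts = restarts, top_k = as.integer(top_k),
                 accept0 = accept0),
            class = "sa_config")
}

set_key <- function(s) paste(sort(s), collapse = ",")

# sample one element of a vector (safe for length-1 vectors)
pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Optimize a fixed-size resection by simulated annealing
#'
#' Searches size-`S` subsets of the candidate pool (by default the seed
#' and its first and second neighbours, [khop_neighborhood()] with
#' `k = 2`) maximizing the [surrogate_objective()]. The move is a single
#' swap of one member with one non-member; temperatures follow a geometric
#' schedule whose initial value is calibrated so a typical uphill-cost
#' move is accepted with probability `accept0`; several independent
#' restarts are run and the best distinct sets across all restarts kept.
#'
#' @param net a [brain_network()].
#' @param seed nonempty seed ROI ids.
#' @param S resection size (number of nodes), `1 <= S <= |pool|`.
#' @param sa_cfg an [sa_config()].
#' @param pool optional candidate ROI ids (default: 2-hop neighborhood).
#' @param cap unreachable cap, see [surrogate_objective()].
#' @param rng_seed optional integer seed.
#' @return List with `sets` (list of ROI-id vectors, best first) and
#'   `objectives` (their surrogate values).
#' @export
optimize_resection <- function(net, seed, S, sa_cfg = sa_config(),
                               pool = NULL, cap = NULL, rng_seed = NULL) {
  if (is.null(pool)) pool <- khop_neighborhood(net, seed, 2)
  pool <- sort(unique(as.integer(pool)))
  if (S > length(pool)) stop("S exceeds the candidate pool size")
  if (S < 1) stop("S must be at least 1")
  if (is.null(cap)) cap <- effdist_cap(net)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  obj <- function(s) surrogate_objective(net, seed, s, cap = cap)
  best <- new.env(parent = emptyenv())  # key -> objective
  remember <- function(s, v) {
    k <- set_key(s)
    if (is.null(best[[k]]) || best[[k]] < v) best[[k]] <- v
  }

  if (S == length(pool)) {
    remember(pool, obj(pool))
  } else {
    n_prop <- ceiling(sa_cfg$n_prop_per_node * length(pool))
    block <- length(pool)
    for (r in seq_len(sa_cfg$restarts)) {
      cur <- sample(pool, S)
      cur_v <- obj(cur)
      remember(cur, cur_v)
      # calibration walk: typical uphill-cost move magnitude sets T0
      deltas <- numeric(0)
      walk <- cur; walk_v <- cur_v
      for (i in seq_len(min(30, n_prop))) {
        out_node <- pick1(walk)
        in_node <- pick1(setdiff(pool, walk))
        cand <- c(setdiff(walk, out_node), in_node)
        cand_v <- obj(cand)
        remember(cand, cand_v)
        if (cand_v < walk_v) deltas <- c(deltas, walk_v - cand_v)
        walk <- cand; walk_v <- cand_v
      }
      T0 <- if (length(deltas) > 0) mean(deltas) / -log(sa_cfg$accept0)
            else 1e-3
      temp <- max(T0, 1e-12)
      for (i in seq_len(n_prop)) {
        out_node <- pick1(cur)
        in_node <- pick1(setdiff(pool, cur))
        cand <- c(setdiff(cur, out_node), in_node)
        cand_v <- obj(cand)
        remember(cand, cand_v)
        if (cand_v >= cur_v ||
            runif(1) < exp((cand_v - cur_v) / temp)) {
          cur <- cand; cur_v <- cand_v
        }
        if (i %% block == 0) temp <- temp * sa_cfg$cool
      }
    }
  }
  keys <- ls(best)
  vals <- vapply(keys, function(k) best[[k]], numeric(1))
  ord <- order(-vals, keys)
  top <- head(ord, sa_cfg$top_k)
  list(sets = lapply(keys[top],
                     function(k) as.integer(strsplit(k, ",")[[1]])),
       objectives = unname(vals[top]))
}

#' Evaluate candidate resections with SI dynamics and select the best
#'
#' Runs [propagation_extent()] for each candidate set and returns the one
#' with the smallest post-resection extent `I_R(t0)`. Ties are broken by
#' candidate order (candidates are passed in surrogate rank order), then
#' implicitly by lexicographic ROI order via the surrogate's own
#' tie-break.
#'
#' @param net a [brain_network()].
#' @param seed nonempty seed ROI ids.
#' @param candidates nonempty list of ROI-id vectors, best surrogate
#'   first.
#' @param cfg an [si_config()].
#' @param baseline_extent optional pre-computed pre-resection extent.
#' @param surrogates optional surrogate values aligned with `candidates`
#'   (recorded in the outcome).
#' @return A `resection_outcome` list: `resected`, `S`, `I_R`, `i_R`,
#'   `all_runs_zero`, `surrogate_objective`.
#' @export
evaluate_and_select <- function(net, seed, candidates, cfg = si_config(),
                                baseline_extent = NULL, surrogates = NULL) {
  if (length(candidates) == 0) stop("no candidate resections")
  if (is.null(baseline_extent)) {
    baseline_extent <- propagation_extent(net, seed, integer(0), cfg)$I_R
  }
  best <- NULL
  for (i in seq_along(candidates)) {
    ext <- propagation_extent(net, seed, candidates[[i]], cfg,
                              baseline_extent = baseline_extent)
    if (is.null(best) || ext$I_R < best$I_R) {
      best <- list(resected = sort(as.integer(candidates[[i]])),
                   S = length(candidates[[i]]),
                   I_R = ext$I_R, i_R = ext$i_R,
                   all_runs_zero = ext$all_runs_zero,
                   surrogate_objective =
                     if (is.null(surrogates)) NA_real_ else surrogates[i])
    }
  }
  structure(best, class = "resection_outcome")
}

#' Optimal virtual resection curve over resection size
#'
#' For each resection size `S = 1, 2, ...` finds the best resection by the
#' four-step method: (1) restrict candidates to the seed and its first and
#' second neighbours; (2) simulated annealing on the effective-distance
#' surrogate; (3) SI evaluation of the top surrogate candidates (plus, for
#' `S > 1`, the previous best set extended by the greedy best addition,
#' which keeps the optimal-extent curve non-increasing, and at
#' `S = |seed|` the trivial full-seed resection, which always stops
#' propagation); (4) selection of the SI-minimal set. The scan stops at
#' the first size with `I_R(t0) = 0` (at the latest `S = |seed|`).
#'
#' Summaries: `R90` is the smallest resection with `i_R <= 0.1`, `R100`
#' the smallest with zero non-seed infections in all runs, `R1` the best
#' single-node resection; `s90` and `s100` are their sizes relative to
#' the seed size, and `i_R1` the normalized extent of `R1`.
#'
#' @param net a [brain_network()] at the fitted density (its `theta`
#'   sets `beta` via the constant `beta * theta` unless `cfg$beta` is
#'   given).
#' @param seed nonempty seed ROI ids.
#' @param cfg an [si_config()].
#' @param sa_cfg an [sa_config()].
#' @param S_max largest size to scan (default `|seed|`, where the trivial
#'   resection guarantees full containment).
#' @param rng_seed master integer seed.
#' @return Object of class `resection_curve`: `outcomes` (list of
#'   `resection_outcome` per size), `table` (data.frame `S`, `I_R`,
#'   `i_R`, `resected`), `baseline_extent`, `R90`, `R100`, `R1`, `s90`,
#'   `s100`, `i_R1`, `seed_stats` and `outside_seed` (whether the
#'   selected `R90`/`R100` contain ROIs outside the seed).
#' @export
resection_curve <- function(net, seed, cfg = si_config(),
                            sa_cfg = sa_config(), S_max = NULL,
                            rng_seed = NULL) {
  seed <- sort(unique(as.integer(seed)))
  roi_index(net, seed)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max, 1000)
  pool <- khop_neighborhood(net, seed, 2)
  cap <- effdist_cap(net)
  if (is.null(S_max)) S_max <- length(seed)
  S_max <- min(S_max, length(pool))
  baseline <- propagation_extent(net, seed, integer(0), cfg)$I_R

  outcomes <- list()
  prev_best <- NULL
  for (S in seq_len(S_max)) {
    opt <- optimize_resection(net, seed, S, sa_cfg = sa_cfg, pool = pool,
                              cap = cap, rng_seed = sub_seeds[S])
    cands <- opt$sets
    surr <- opt$objectives
    if (!is.null(prev_best) && length(prev_best) == S - 1) {
      extra <- setdiff(pool, prev_best)
      if (length(extra) > 0) {
        grow <- vapply(extra, function(v) {
          surrogate_objective(net, seed, c(prev_best, v), cap = cap)
        }, numeric(1))
        gset <- sort(c(prev_best, extra[which.max(grow)]))
        if (!set_key(gset) %in% vapply(cands, set_key, character(1))) {
          cands <- c(cands, list(gset))
          surr <- c(surr, max(grow))
        }
      }
    }
    if (S == length(seed) &&
        !set_key(seed) %in% vapply(cands, set_key, character(1))) {
      cands <- c(cands, list(seed))
      surr <- c(surr, surrogate_objective(net, seed, seed, cap = cap))
    }
    out <- evaluate_and_select(net, seed, cands, cfg,
                               baseline_extent = baseline,
                               surrogates = surr)
    outcomes[[S]] <- out
    prev_best <- out$resected
    if (out$all_runs_zero) break
  }

  tab <- data.frame(
    S = vapply(outcomes, `[[`, numeric(1), "S"),
    I_R = vapply(outcomes, `[[`, numeric(1), "I_R"),
    i_R = vapply(outcomes, `[[`, numeric(1), "i_R"),
    resected = vapply(outcomes, function(o)
      paste(o$resected, collapse = ","), character(1)))

  pick_first <- function(ok) if (any(ok)) which(ok)[1] else NA_integer_
  i90 <- pick_first(tab$i_R <= 0.1)
  i100 <- pick_first(vapply(outcomes, `[[`, logical(1), "all_runs_zero"))
  ss <- seed_stats(net, seed)
  r90 <- if (is.na(i90)) NULL else outcomes[[i90]]
  r100 <- if (is.na(i100)) NULL else outcomes[[i100]]
  structure(
    list(outcomes = outcomes, table = tab, baseline_extent = baseline,
         R90 = r90, R100 = r100, R1 = outcomes[[1]],
         s90 = if (is.na(i90)) NA_real_ else tab$S[i90] / length(seed),
         s100 = if (is.na(i100)) NA_real_ else tab$S[i100] / length(seed),
         i_R1 = outcomes[[1]]$i_R,
         seed_stats = ss,
         outside_seed = list(
           R90 = if (is.null(r90)) NA else
             length(setdiff(r90$resected, seed)) > 0,
           R100 = if (is.null(r100)) NA else
             length(setdiff(r100$resected, seed)) > 0)),
    class = "resection_curve"
  )
}

#' @export
print.resection_curve <- function(x, ...) {
  cat(sprintf(
    "resection_curve: seed of %d, baseline extent %.3f\n",
    x$seed_stats$S_RA, x$baseline_extent))
  cat(sprintf("  s90 = %s, s100 = %s, i_R1 = %.3f\n",
              format(x$s90), format(x$s100), x$i_R1))
  invisible(x)
}

#' Seed (resection area) size and connectivity statistics
#'
#' `kappa_RA` is the mean number of nonzero-weight links incident to the
#' seed nodes and `E_RA = S_RA * kappa_RA` the total link count involving
#' the seed; larger values indicate a more strongly embedded seed that is
#' harder to contain with small resections.
#'
#' @param net a [brain_network()].
#' @param seed nonempty seed ROI ids.
#' @return List with `S_RA`, `kappa_RA`, `E_RA`.
#' @export
seed_stats <- function(net, seed) {
  if (length(seed) == 0) stop("seed must be nonempty")
  idx <- roi_index(net, unique(as.integer(seed)))
  deg <- rowSums(net$weights[idx, , drop = FALSE] > 0)
  list(S_RA = length(idx), kappa_RA = mean(deg),
       E_RA = length(idx) * mean(deg))
}

#' Export a resection curve to TSV and JSON
#'
#' @param curve a `resection_curve`.
#' @param path_tsv per-size table path.
#' @param path_json optional JSON summary path (R90/R100/R1, s90/s100,
#'   i_R1, E_RA).
#' @return Invisibly, the paths written.
#' @export
export_resection <- function(curve, path_tsv, path_json = NULL) {
  write.table(curve$table, path_tsv, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(path_json)) {
    s <- list(
      baseline_extent = curve$baseline_extent,
      R90 = if (is.null(curve$R90)) NULL else curve$R90$resected,
      R100 = if (is.null(curve$R100)) NULL else curve$R100$resected,
      R1 = curve$R1$resected,
      s90 = curve$s90, s100 = curve$s100, i_R1 = curve$i_R1,
      S_RA = curve$seed_stats$S_RA, kappa_RA = curve$seed_stats$kappa_RA,
      E_RA = curve$seed_stats$E_RA,
      outside_seed = curve$outside_seed)
    writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA,
                                null = "null"), path_json)
  }
  invisible(c(path_tsv, path_json))
}
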