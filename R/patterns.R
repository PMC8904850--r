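#' Midpoint-tie ranks
#'
#' Ranks a vector so that tied groups receive the midpoint of the
#' unadjusted ranks they span (e.g. steps `c(1, 1, 2)` become ranks
#' `c(1.5, 1.5, 3)`). The mean of the ranks is always `(n + 1) / 2`.
#'
#' @param x numeric vector.
#' @return Numeric rank vector of the same length.
#' @export
midpoint_ranks <- function(x) rank(x, ties.method = "average")

#' Construct a clinical SEEG propagation pattern
#'
#' The clinical pattern over the SEEG-sampled ROI subset: each sampled ROI
#' carries a positive activation step (step 1 = seizure onset zone per
#' SEEG) and the midpoint-tie rank of that step.
#'
#' @param sampled_rois ROI ids sampled by the SEEG electrodes.
#' @param activation_step positive integer step per sampled ROI.
#' @return Object of class `clinical_pattern` with `sampled_rois`,
#'   `activation_step` and `ranks` (all named by ROI id, sorted by id).
#' @export
clinical_pattern <- function(sampled_rois, activation_step) {
  sampled_rois <- as.integer(sampled_rois)
  if (anyDuplicated(sampled_rois)) stop("duplicated sampled ROI ids")
  if (length(activation_step) != length(sampled_rois)) {
    stop("activation_step and sampled_rois lengths differ")
  }
  if (any(activation_step < 1) || anyNA(activation_step)) {
    stop("activation steps must be positive")
  }
  ord <- order(sampled_rois)
  sampled_rois <- sampled_rois[ord]
  activation_step <- as.numeric(activation_step)[ord]
  structure(
    list(sampled_rois = sampled_rois,
         activation_step = setNames(activation_step, sampled_rois),
         ranks = setNames(midpoint_ranks(activation_step), sampled_rois)),
    class = "clinical_pattern"
  )
}

#' @export
print.clinical_pattern <- function(x, ...) {
  cat(sprintf("clinical_pattern: %d sampled ROIs, %d activation steps\n",
              length(x$sampled_rois), length(unique(x$activation_step))))
  invisible(x)
}

#' Assign contact points to the nearest ROI centroid
#'
#' Each electrode contact point (CP) is assigned the ROI whose mass-center
#' is nearest in Euclidean distance; ties go to the smaller ROI id.
#'
#' @param cp_coords matrix or data.frame of CP coordinates (columns x, y,
#'   z in mm).
#' @param rois ROI table with centroids.
#' @return Integer vector of ROI ids, one per CP.
#' @export
nearest_roi_assignment <- function(cp_coords, rois) {
  if (nrow(rois) == 0) stop("empty ROI table")
  cp <- as.matrix(cp_coords)
  if (!all(is.finite(cp))) stop("CP coordinates must be finite")
  cent <- as.matrix(rois[, c("x_mm", "y_mm", "z_mm")])
  # rois are sorted by roi_id, so which.min's first-hit rule = smaller id
  apply(cp, 1, function(pt) {
    d2 <- colSums((t(cent) - pt)^2)
    rois$roi_id[which.min(d2)]
  })
}

#' Load a clinical propagation pattern from TSV
#'
#' The file lists electrode contact points with columns `cp_id`,
#' `electrode_id`, `activation_step`, and either `roi_id` or coordinates
#' `x_mm`, `y_mm`, `z_mm` (assigned to the nearest ROI centroid). CPs
#' mapping to the same ROI are merged, the ROI taking the earliest
#' activation step among its CPs. CPs that never activate may simply be
#' absent from the file; the pattern then covers the activating subset.
#'
#' @param path path to the TSV file (header row required).
#' @param rois ROI table.
#' @return A [clinical_pattern()].
#' @export
load_clinical_pattern <- function(path, rois) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"activation_step" %in% names(df)) stop("missing activation_step column")
  if (any(df$activation_step < 1)) stop("activation steps must be positive")
  if (!"roi_id" %in% names(df)) {
    if (!all(c("x_mm", "y_mm", "z_mm") %in% names(df))) {
      stop("pattern file needs either roi_id or x_mm/y_mm/z_mm columns")
    }
    df$roi_id <- nearest_roi_assignment(df[, c("x_mm", "y_mm", "z_mm")], rois)
  }
  if (anyNA(df$roi_id)) stop("contact point without ROI assignment")
  if (!all(df$roi_id %in% rois$roi_id)) stop("pattern references unknown ROI ids")
  merged <- tapply(df$activation_step, df$roi_id, min)
  clinical_pattern(as.integer(names(merged)), as.numeric(merged))
}

#' Write a clinical pattern to TSV
#'
#' @param pattern a [clinical_pattern()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_pattern <- function(pattern, path) {
  df <- data.frame(cp_id = seq_along(pattern$sampled_rois),
                   electrode_id = 1L,
                   roi_id = pattern$sampled_rois,
                   activation_step = unname(pattern$activation_step))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model propagation pattern over the sampled ROI subset
#'
#' Restricts per-ROI mean infection (or activation) times to the
#' SEEG-sampled subset and ranks them with the midpoint-tie rule. This is
#' the simulated counterpart of the clinical SEEG ranking.
#'
#' @param times named per-ROI times (names = ROI ids), e.g. from
#'   [slow_propagation_pattern()] or [mean_infection_times()].
#' @param sampled ROI ids to keep.
#' @return Object of class `model_pattern` with `sampled_rois` and `ranks`.
#' @export
model_pattern <- function(times, sampled) {
  sampled <- sort(as.integer(sampled))
  key <- as.character(sampled)
  if (!all(key %in% names(times))) {
    stop("missing model time for sampled ROI(s): ",
         paste(setdiff(key, names(times)), collapse = ", "))
  }
  t_sub <- times[key]
  if (anyNA(t_sub)) {
    stop("model time is NA (unreachable) for sampled ROI(s): ",
         paste(key[is.na(t_sub)], collapse = ", "))
  }
  structure(list(sampled_rois = sampled,
                 ranks = setNames(midpoint_ranks(t_sub), sampled)),
            class = "model_pattern")
}

#' Rank-pattern correlation with permutation significance
#'
#' The correlation between two rank patterns over the same ROI set:
#' `C = cov(a, b) / (sd(a) * sd(b))`, the Pearson correlation of the two
#' midpoint-tie rank vectors (identical to the tie-corrected Spearman
#' rho, and invariant to using population vs sample moments). The
#' significance is a two-sided permutation test: one rank vector is
#' randomly permuted `n_perm` times and the p-value is the (add-one
#' smoothed) fraction of permutations with `|C*| >= |C|`.
#'
#' @param a,b rank vectors, or `clinical_pattern` / `model_pattern`
#'   objects defined on the same ROI set.
#' @param n_perm number of permutations for the p-value.
#' @param rng_seed optional integer seed for the permutations.
#' @return List with `C`, `p`, `n`.
#' @export
pattern_correlation <- function(a, b, n_perm = 1e4, rng_seed = NULL) {
  get_ranks <- function(x) if (is.list(x)) x$ranks else x
  ra <- get_ranks(a)
  rb <- get_ranks(b)
  if (is.list(a) && is.list(b) &&
      !identical(a$sampled_rois, b$sampled_rois)) {
    stop("patterns are defined on different ROI sets")
  }
  if (length(ra) != length(rb)) stop("rank vectors have different lengths")
  if (length(ra) < 3) stop("need at least 3 entries")
  if (sd(ra) == 0 || sd(rb) == 0) stop("constant ranking (zero variance)")
  C <- cor(ra, rb)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  perm <- replicate(n_perm, cor(ra, sample(rb)))
  p <- (1 + sum(abs(perm) >= abs(C))) / (n_perm + 1)
  list(C = unname(C), p = p, n = length(ra))
}

# Lowest-density significant local maximum of the correlation curve.
# A candidate must be >= both neighbours, significant, and within
# peak_tol (relative) of the best significant correlation: a genuine
# first maximum of a bimodal curve is comparable in height to the global
# one, whereas minor low-density fluctuations (Monte-Carlo noise on flat
# curve stretches, small significant bumps on fragmented networks) are
# not and must not be mistaken for it. Falls back to the global maximum,
# flagged non-significant, when no grid point is significant.
first_maximum <- function(C, p, alpha = 0.05, peak_tol = 0.01) {
  k <- length(C)
  is_locmax <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1 || C[i] >= C[i - 1]
    right_ok <- i == k || C[i] >= C[i + 1]
    left_ok && right_ok
  }, logical(1))
  sig <- p < alpha
  if (!any(sig)) return(list(index = which.max(C), significant = FALSE))
  floor_c <- (1 - peak_tol) * max(C[sig])
  cand <- which(is_locmax & sig & C >= floor_c)
  if (length(cand) == 0) cand <- which(sig & C >= floor_c)
  list(index = cand[1], significant = TRUE)
}

#' Fit the network density to a clinical pattern
#'
#' For each threshold on the grid, thresholds the network, simulates the
#' slow-propagation (beta -> 0) activation order from the seed, ranks it
#' over the SEEG-sampled ROIs and correlates it with the clinical ranking
#' ([pattern_correlation()]). The correlation curve over density is
#' typically bimodal; the fit selects the first (lowest-density) local
#' maximum that is significant (`p < 0.05`) and within `peak_tol` of the
#' best significant correlation — the sparsest network that captures the
#' fundamental pathways — falling back to the global maximum (flagged
#' non-significant) when no point on the grid is significant.
#'
#' Sampled ROIs unreachable from the seed at a given density are censored:
#' they are ranked jointly last, consistent with an infection time at the
#' integration horizon. This penalizes over-fragmented low-density
#' networks instead of silently evaluating them on the easy near-seed
#' subset. Seed ROIs inside the sampled set are ranked (at activation
#' step 0) unless `exclude_seed`.
#'
#' @param net unthresholded [brain_network()].
#' @param clinical a [clinical_pattern()].
#' @param seed nonempty set of seed ROI ids.
#' @param grid increasing vector of thresholds in (0, 1].
#' @param n_runs slow-propagation realizations per threshold.
#' @param n_perm permutations for each p-value.
#' @param rng_seed master integer seed (deterministic fit for a given seed).
#' @param seed_kind label for the seed definition, `"RA"` or `"SOZ"`.
#' @param exclude_seed drop seed ROIs from the rankings.
#' @param alpha significance threshold.
#' @param peak_tol relative tolerance for the first-maximum selection: a
#'   low-density local maximum is accepted only if its correlation is
#'   within this fraction of the best significant correlation on the
#'   grid (the Monte-Carlo noise scale of the correlation estimate).
#' @return Object of class `fit_result`: `curve` (data.frame `theta`,
#'   `kappa`, `C`, `p`, `n_ranked`, `n_unreachable`), `theta_max`,
#'   `kappa_max`, `c_max`, `p_max`, `significant`, `seed_kind`.
#' @export
fit_threshold <- function(net, clinical, seed, grid = default_theta_grid(),
                          n_runs = 1e3, n_perm = 1e4, rng_seed = NULL,
                          seed_kind = c("RA", "SOZ"), exclude_seed = FALSE,
                          alpha = 0.05, peak_tol = 0.01) {
  seed_kind <- match.arg(seed_kind)
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    stop("grid must be strictly increasing in (0, 1]")
  }
  roi_index(net, seed)  # validates seed
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2 * length(grid))
  sampled <- clinical$sampled_rois
  if (exclude_seed) sampled <- setdiff(sampled, as.integer(seed))
  if (length(sampled) < 3) stop("fewer than 3 sampled ROIs to rank")
  cl_ranks <- midpoint_ranks(clinical$activation_step[as.character(sampled)])
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    th <- grid[i]
    net_t <- threshold_network(net, th)
    times <- slow_propagation_pattern(net_t, seed, n_runs = n_runs,
                                      rng_seed = sub_seeds[2 * i - 1])
    tt <- times[as.character(sampled)]
    unreach <- is.na(tt)
    tt[unreach] <- Inf  # censored at the horizon: ranked jointly last
    m_ranks <- midpoint_ranks(tt)
    C <- 0; p <- 1
    if (sd(m_ranks) > 0 && sd(cl_ranks) > 0) {
      pc <- pattern_correlation(cl_ranks, m_ranks, n_perm = n_perm,
                                rng_seed = sub_seeds[2 * i])
      C <- pc$C; p <- pc$p
    }
    rows[[i]] <- data.frame(theta = th, kappa = th * n_rois(net),
                            C = C, p = p, n_ranked = length(sampled),
                            n_unreachable = sum(unreach))
  }
  curve <- do.call(rbind, rows)
  sel <- first_maximum(curve$C, curve$p, alpha, peak_tol)
  structure(
    list(curve = curve,
         theta_max = curve$theta[sel$index],
         kappa_max = curve$kappa[sel$index],
         c_max = curve$C[sel$index],
         p_max = curve$p[sel$index],
         significant = sel$significant,
         seed_kind = seed_kind),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result (%s seed): theta_max = %.3g (kappa = %.4g), C_max = %.3f (p = %.3g)%s\n",
    x$seed_kind, x$theta_max, x$kappa_max, x$c_max, x$p_max,
    if (x$significant) "" else " [non-significant fallback]"))
  invisible(x)
}

#' Export a fit result to TSV and JSON
#'
#' @param fit a `fit_result`.
#' @param path_tsv path for the per-threshold curve TSV.
#' @param path_json optional path for the JSON summary.
#' @return Invisibly, the paths written.
#' @export
export_fit_result <- function(fit, path_tsv, path_json = NULL) {
  write.table(fit$curve, path_tsv, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(path_json)) {
    s <- fit[c("theta_max", "kappa_max", "c_max", "p_max", "significant",
               "seed_kind")]
    writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA), path_json)
  }
  invisible(c(path_tsv, path_json))
}

#' Median correlation curve across patients ("average model")
#'
#' Pointwise median of per-patient correlation curves sharing the same
#' threshold grid; used to ask whether one common density could serve
#' patients without SEEG recordings.
#'
#' @param fits list of `fit_result` objects on a common grid.
#' @return List with `curve` (data.frame `theta`, `kappa`, `C_median`),
#'   `theta_max`, `kappa_max`, `c_max` of the median curve.
#' @export
median_correlation_curve <- function(fits) {
  if (length(fits) == 0) stop("empty fit list")
  thetas <- fits[[1]]$curve$theta
  for (f in fits) {
    if (!isTRUE(all.equal(f$curve$theta, thetas))) {
      stop("fits do not share the same threshold grid")
    }
  }
  Cs <- sapply(fits, function(f) f$curve$C)
  Cs <- matrix(Cs, nrow = length(thetas))
  med <- apply(Cs, 1, median)
  i <- which.max(med)
  list(curve = data.frame(theta = thetas, kappa = fits[[1]]$curve$kappa,
                          C_median = med),
       theta_max = thetas[i], kappa_max = fits[[1]]$curve$kappa[i],
       c_max = med[i])
}

#' Fully connected baseline fit
#'
#' Correlates the clinical pattern with the slow-propagation order on a
#' trivial fully connected network (`w_ij = 1` for all pairs), with no
#' density scan. On this network every non-seed node is exchangeable, so
#' the expected activation steps are known in closed form: 0 on the seed
#' and `(N - |seed| + 1) / 2` everywhere else. When no seed ROI lies in
#' the sampled set the model ranking is therefore fully tied and the
#' correlation undefined; it is then reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param clinical a [clinical_pattern()].
#' @param seed nonempty seed ROI ids.
#' @param n_rois total number of ROIs in the network.
#' @param n_perm,rng_seed permutation-test controls, as in
#'   [pattern_correlation()].
#' @return List with `C`, `p`, `degenerate`.
#' @export
fully_connected_baseline <- function(clinical, seed, n_rois,
                                     n_perm = 1e4, rng_seed = NULL) {
  if (length(seed) == 0) stop("seed must be nonempty")
  ids <- seq_len(n_rois)
  times <- setNames(ifelse(ids %in% as.integer(seed), 0,
                           (n_rois - length(unique(seed)) + 1) / 2), ids)
  mp <- model_pattern(times, clinical$sampled_rois)
  if (sd(mp$ranks) == 0 || sd(clinical$ranks) == 0) {
    return(list(C = 0, p = NA_real_, degenerate = TRUE))
  }
  pc <- pattern_correlation(clinical$ranks, mp$ranks, n_perm = n_perm,
                            rng_seed = rng_seed)
  list(C = pc$C, p = pc$p, degenerate = FALSE)
}
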