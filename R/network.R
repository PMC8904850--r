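#' Construct a ROI table
#'
#' Holds the identity of the atlas regions (ROIs) that label network nodes:
#' a 1-based atlas index, a text label, the hemisphere and the centroid
#' coordinates in mm.
#'
#' @param roi_id integer atlas indices (unique, contiguous from 1).
#' @param label character labels (defaults to `"ROI_<id>"`).
#' @param hemisphere one of `"left"`, `"right"`, `"subcortical"` per ROI.
#' @param x_mm,y_mm,z_mm centroid coordinates in mm.
#' @return A `data.frame` with columns `roi_id`, `label`, `hemisphere`,
#'   `x_mm`, `y_mm`, `z_mm`.
#' @export
roi_table <- function(roi_id, label = NULL, hemisphere = NULL,
                      x_mm = NULL, y_mm = NULL, z_mm = NULL) {
  roi_id <- as.integer(roi_id)
  n <- length(roi_id)
  if (anyDuplicated(roi_id) || !setequal(roi_id, seq_len(n))) {
    stop("roi_id must be unique and contiguous starting at 1")
  }
  if (is.null(label)) label <- paste0("ROI_", roi_id)
  if (is.null(hemisphere)) hemisphere <- rep("left", n)
  if (!all(hemisphere %in% c("left", "right", "subcortical"))) {
    stop("hemisphere must be 'left', 'right' or 'subcortical'")
  }
  coord <- function(v) if (is.null(v)) rep(0, n) else as.numeric(v)
  out <- data.frame(roi_id = roi_id, label = as.character(label),
                    hemisphere = hemisphere,
                    x_mm = coord(x_mm), y_mm = coord(y_mm), z_mm = coord(z_mm),
                    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(out[, c("x_mm", "y_mm", "z_mm")])))) {
    stop("ROI centroids must be finite")
  }
  out[order(out$roi_id), , drop = FALSE]
}

#' Read a ROI table from TSV
#'
#' Expects columns `roi_id`, `label`, `hemisphere`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A ROI table, see [roi_table()].
#' @export
load_roi_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("roi_id", "label", "hemisphere", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  }
  roi_table(df$roi_id, df$label, df$hemisphere, df$x_mm, df$y_mm, df$z_mm)
}

#' Construct a brain network
#'
#' A weighted, undirected brain network: a symmetric nonnegative weight
#' matrix with zero diagonal and entries in \[0,1\], ROI metadata, and the
#' density bookkeeping `theta` (fraction of retained links) and
#' `kappa = theta * N` (the network's mean connectivity as reported; the
#' exact graph mean degree `theta * (N - 1)` is stored alongside).
#'
#' @param weights symmetric numeric matrix, entries in \[0,1\], zero diagonal.
#' @param rois optional ROI table (defaults to ids `1..N` at the origin).
#' @param theta retained-link fraction in (0, 1].
#' @return An object of class `brain_network`.
#' @export
brain_network <- function(weights, rois = NULL, theta = 1) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weight matrix must be square")
  if (anyNA(weights)) stop("weight matrix contains NA/NaN entries")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (max(abs(weights - t(weights))) > 1e-9) {
    stop("weight matrix is not symmetric (tolerance 1e-9)")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(rois)) rois <- roi_table(seq_len(n))
  if (nrow(rois) != n) stop("ROI table size does not match the matrix")
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  dimnames(weights) <- list(rois$roi_id, rois$roi_id)
  structure(
    list(weights = weights, rois = rois, theta = theta,
         kappa = theta * n, mean_degree = theta * (n - 1),
         resected = integer(0)),
    class = "brain_network"
  )
}

#' @export
print.brain_network <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf(
    "brain_network: %d ROIs, %d links, theta = %.3g, kappa = %.4g\n",
    n, nz, x$theta, x$kappa))
  if (length(x$resected)) {
    cat("  resected ROIs:", paste(x$resected, collapse = ", "), "\n")
  }
  invisible(x)
}

n_rois <- function(net) nrow(net$weights)

# external ROI ids -> internal 1..N indices
roi_index <- function(net, ids) {
  idx <- match(as.integer(ids), net$rois$roi_id)
  if (anyNA(idx)) {
    stop("unknown ROI id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Load a connectivity matrix from a numeric TSV/CSV file
#'
#' Reads an `N x N` weight matrix (tab- or comma-separated; an optional
#' single header row of ROI ids is detected and dropped), validates it and
#' returns an unthresholded network (`theta = 1` bookkeeping). Matrices
#' that are asymmetric beyond a 1e-9 tolerance are rejected rather than
#' silently fixed; smaller asymmetries are averaged out.
#'
#' @param path path to the matrix file.
#' @param rois optional ROI table; its size must match the matrix.
#' @param sep field separator; guessed from the file extension by default.
#' @return A [brain_network()].
#' @export
load_network <- function(path, rois = NULL, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- read.table(path, header = FALSE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = "numeric",
                    comment.char = "")
  m <- as.matrix(raw)
  if (nrow(m) == ncol(m) + 1) {
    # single header row of ROI ids
    hdr <- m[1, ]
    if (all(is.finite(hdr)) && all(hdr == round(hdr))) m <- m[-1, , drop = FALSE]
  }
  if (nrow(m) != ncol(m)) stop("matrix file is not square: ",
                               nrow(m), " x ", ncol(m))
  if (anyNA(m)) stop("matrix file contains NaN/NA entries")
  if (!is.null(rois) && nrow(rois) != nrow(m)) {
    stop("ROI table has ", nrow(rois), " rows but matrix is ", nrow(m))
  }
  brain_network(m, rois = rois, theta = 1)
}

#' Write a connectivity matrix to TSV
#'
#' @param net a [brain_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  write.table(net$weights, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Proportionally threshold a network
#'
#' Keeps the `round(theta * N * (N - 1) / 2)` strongest links (surviving
#' weights unchanged, i.e. thresholded but not binarized) and zeroes the
#' rest. Ties at the boundary are broken by lexicographic edge order
#' (smaller row, then smaller column), so the retained set is deterministic
#' and nested across thresholds. Sets `kappa = theta * N`.
#'
#' @param net a [brain_network()].
#' @param theta retained-link fraction in (0, 1].
#' @return The thresholded [brain_network()].
#' @export
threshold_network <- function(net, theta) {
  stopifnot(inherits(net, "brain_network"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1) {
    stop("theta must be a single value in (0, 1]")
  }
  n <- n_rois(net)
  ut <- which(upper.tri(net$weights))
  k <- round(theta * n * (n - 1) / 2)
  w <- net$weights[ut]
  rc <- arrayInd(ut, c(n, n))
  ord <- order(-w, rc[, 1], rc[, 2])
  keep <- ord[seq_len(k)]
  new_w <- matrix(0, n, n)
  new_w[ut[keep]] <- w[keep]
  new_w <- new_w + t(new_w)
  out <- brain_network(new_w, rois = net$rois, theta = theta)
  out$resected <- net$resected
  out
}

#' Default threshold grid
#'
#' The non-uniform density grid used for fitting: step 0.02 up to 0.10
#' (with 0.01 prepended), then step 0.05 up to 0.50. Denser at low theta
#' because the model is more sensitive to connectivity changes there.
#'
#' @return Numeric vector of theta values, strictly increasing in (0, 1].
#' @export
default_theta_grid <- function() {
  c(0.01, 0.02, 0.04, 0.06, 0.08, 0.10, seq(0.15, 0.50, by = 0.05))
}

#' Exponential-distance-rule (EDR) surrogate network
#'
#' Builds a surrogate structural network in which connection weights decay
#' exponentially with the Euclidean distance between ROI centroids:
#' `w_ij = exp(-lambda * d_ij) * eps_ij`, with optional multiplicative
#' lognormal noise `eps` (median 1, symmetric, `eps = 1` when
#' `noise_sigma = 0`), clipped to \[0,1\]. The literature decay exponent for
#' this kind of surrogate is `lambda = 0.188` per mm.
#'
#' @param rois ROI table with centroid coordinates.
#' @param lambda positive decay rate per mm.
#' @param noise_sigma standard deviation of the log-noise (0 = no noise).
#' @param rng_seed optional integer seed for the noise.
#' @return A [brain_network()] with `theta = 1`.
#' @export
edr_matrix <- function(rois, lambda = 0.188, noise_sigma = 0,
                       rng_seed = NULL) {
  if (lambda <= 0) stop("lambda must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (nrow(rois) < 2) stop("need at least 2 ROIs")
  d <- as.matrix(dist(rois[, c("x_mm", "y_mm", "z_mm")]))
  w <- exp(-lambda * d)
  if (noise_sigma > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    n <- nrow(d)
    eps <- matrix(1, n, n)
    ut <- upper.tri(eps)
    eps[ut] <- rlnorm(sum(ut), meanlog = 0, sdlog = noise_sigma)
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    w <- w * eps
  }
  w <- pmin(pmax(w, 0), 1)
  diag(w) <- 0
  brain_network(w, rois = rois, theta = 1)
}

#' Pearson correlation between two networks
#'
#' Correlates the stacked off-diagonal connectivity of two equally sized
#' networks. The upper triangle is used; by symmetry the value is identical
#' to stacking all matrix columns.
#'
#' @param a,b [brain_network()] objects of equal dimension.
#' @return Pearson correlation coefficient.
#' @export
matrix_correlation <- function(a, b) {
  if (n_rois(a) != n_rois(b)) stop("networks have different dimensions")
  ut <- upper.tri(a$weights)
  x <- a$weights[ut]
  y <- b$weights[ut]
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance connectivity vector")
  cor(x, y)
}

#' Scan EDR decay exponents against a reference network
#'
#' Generic helper that evaluates [matrix_correlation()] between a network
#' and noise-free EDR surrogates over a grid of decay exponents and reports
#' the best-fitting exponent.
#'
#' @param net reference [brain_network()].
#' @param rois ROI table with centroids (defaults to `net$rois`).
#' @param lambdas grid of positive decay rates per mm.
#' @return `data.frame` with columns `lambda`, `correlation`; the attribute
#'   `best_lambda` holds the argmax.
#' @export
edr_scan <- function(net, rois = net$rois,
                     lambdas = exp(seq(log(0.01), log(1), length.out = 25))) {
  r <- vapply(lambdas, function(l) {
    matrix_correlation(net, edr_matrix(rois, lambda = l))
  }, numeric(1))
  out <- data.frame(lambda = lambdas, correlation = r)
  attr(out, "best_lambda") <- lambdas[which.max(r)]
  out
}

#' Virtually resect a set of ROIs
#'
#' Sets all connections of the given nodes to zero; the network size is
#' left unchanged, the resected nodes simply become isolated. The input
#' network is not modified. Resection is idempotent and commutes over set
#' union.
#'
#' @param net a [brain_network()].
#' @param resected ROI ids to disconnect (may be empty).
#' @return A new [brain_network()] with the nodes isolated; the cumulative
#'   resected set is recorded in `$resected`.
#' @export
apply_resection <- function(net, resected) {
  resected <- unique(as.integer(resected))
  if (length(resected) == 0) return(net)
  idx <- roi_index(net, resected)
  w <- net$weights
  w[idx, ] <- 0
  w[, idx] <- 0
  out <- net
  out$weights <- w
  out$resected <- sort(unique(c(net$resected, resected)))
  out
}

#' k-hop neighborhood of a seed
#'
#' Nodes whose unweighted shortest-path distance (hops over nonzero-weight
#' links) from any seed node is at most `k`; includes the seed itself.
#'
#' @param net a [brain_network()].
#' @param seed nonempty set of ROI ids.
#' @param k nonnegative hop count.
#' @return Sorted vector of ROI ids.
#' @export
khop_neighborhood <- function(net, seed, k) {
  if (length(seed) == 0) stop("seed must be nonempty")
  if (k < 0) stop("k must be nonnegative")
  idx <- roi_index(net, seed)
  if (k == 0) return(sort(unique(as.integer(seed))))
  g <- igraph::graph_from_adjacency_matrix(net$weights > 0, mode = "undirected")
  d <- igraph::distances(g, v = idx)
  reach <- apply(d, 2, min) <= k
  sort(net$rois$roi_id[reach])
}
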