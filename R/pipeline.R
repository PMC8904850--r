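#' Patient record
#'
#' File-backed description of one patient: paths to the connectivity
#' matrix, ROI table, clinical pattern and seed definitions, plus surgery
#' outcome metadata (carried along, never used by the model).
#'
#' @param id patient identifier.
#' @param network path to the connectivity matrix (TSV/CSV).
#' @param rois path to the ROI table (TSV).
#' @param pattern path to the clinical pattern (TSV).
#' @param ra_seed path to the resection-area seed list (newline-separated
#'   ROI ids).
#' @param soz_seed optional path to the SEEG-defined onset-zone seed list.
#' @param outcome `"SF"` (seizure free), `"NSF"` or `NA`.
#' @param engel Engel score text, metadata only.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(id, network, rois, pattern, ra_seed,
                           soz_seed = NULL, outcome = NA_character_,
                           engel = NA_character_) {
  if (!is.na(outcome) && !outcome %in% c("SF", "NSF")) {
    stop("outcome must be SF, NSF or NA")
  }
  structure(list(id = id, network = network, rois = rois,
                 pattern = pattern, ra_seed = ra_seed, soz_seed = soz_seed,
                 outcome = outcome, engel = engel),
            class = "patient_record")
}

#' Read a seed set from a file
#'
#' @param path newline-separated ROI ids (comma-separated also accepted).
#' @return Sorted integer vector of ROI ids.
#' @export
load_seed_set <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ids <- as.integer(unlist(strsplit(txt[nzchar(txt)], "[,[:space:]]+")))
  if (length(ids) == 0 || anyNA(ids)) stop("could not parse seed file: ", path)
  sort(unique(ids))
}

#' Load the files behind a patient record
#'
#' @param record a [patient_record()].
#' @return List with `id`, `network`, `rois`, `clinical`, `ra_seed`,
#'   `soz_seed` (`NULL` if absent), `outcome`, `engel`.
#' @export
load_patient <- function(record) {
  rois <- load_roi_table(record$rois)
  list(id = record$id,
       network = load_network(record$network, rois = rois),
       rois = rois,
       clinical = load_clinical_pattern(record$pattern, rois),
       ra_seed = load_seed_set(record$ra_seed),
       soz_seed = if (is.null(record$soz_seed)) NULL
                  else load_seed_set(record$soz_seed),
       outcome = record$outcome, engel = record$engel)
}

#' Mean connectivity matrix across patients
#'
#' Element-wise mean of the patients' unthresholded weight matrices, used
#' as a common substrate to ask whether individual connectivity is needed
#' to reproduce the clinical patterns.
#'
#' @param nets list of [brain_network()] objects of equal dimension.
#' @return A [brain_network()] with `theta = 1`.
#' @export
average_network <- function(nets) {
  if (length(nets) == 0) stop("empty network list")
  n <- n_rois(nets[[1]])
  for (net in nets) if (n_rois(net) != n) stop("networks differ in size")
  w <- Reduce(`+`, lapply(nets, `[[`, "weights")) / length(nets)
  brain_network(w, rois = nets[[1]]$rois, theta = 1)
}

#' Fit the density for a set of patients
#'
#' Runs [fit_threshold()] per patient and summarizes the results.
#' Per-patient failures are isolated: the error is logged as a warning
#' and the patient's row carries `NA`s while the run continues. Optionally
#' fits every patient on a common substrate (`common_net`, e.g. from
#' [average_network()]) instead of the individual network.
#'
#' @param patients list of loaded patients ([load_patient()]) or
#'   `synthetic_patient` objects.
#' @param grid threshold grid.
#' @param seed_kind `"RA"` (resection-area seed) or `"SOZ"`.
#' @param n_runs,n_perm,alpha passed to [fit_threshold()].
#' @param rng_seed master integer seed; per-patient seeds are derived
#'   from it deterministically.
#' @param common_net optional common substrate [brain_network()].
#' @return List with `table` (data.frame: `id`, `theta_max`, `kappa_max`,
#'   `c_max`, `p`, `significant`), `fits` (per-patient `fit_result`s) and
#'   `median_curve` (from [median_correlation_curve()], `NULL` when no
#'   fit succeeded).
#' @export
fit_patients <- function(patients, grid = default_theta_grid(),
                         seed_kind = c("RA", "SOZ"), n_runs = 1e3,
                         n_perm = 1e4, alpha = 0.05, rng_seed = NULL,
                         common_net = NULL) {
  seed_kind <- match.arg(seed_kind)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(patients))
  fits <- vector("list", length(patients))
  rows <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    id <- if (!is.null(p$id)) p$id else paste0("patient_", i)
    seed <- if (seed_kind == "SOZ" && !is.null(p$soz_seed)) p$soz_seed
            else if (!is.null(p$ra_seed)) p$ra_seed else p$seed
    net <- if (is.null(common_net)) p$network else common_net
    fit <- tryCatch(
      fit_threshold(net, p$clinical, seed, grid = grid, n_runs = n_runs,
                    n_perm = n_perm, rng_seed = sub_seeds[i],
                    seed_kind = seed_kind, alpha = alpha),
      error = function(e) {
        warning("fit failed for ", id, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      id = id,
      theta_max = if (is.null(fit)) NA_real_ else fit$theta_max,
      kappa_max = if (is.null(fit)) NA_real_ else fit$kappa_max,
      c_max = if (is.null(fit)) NA_real_ else fit$c_max,
      p = if (is.null(fit)) NA_real_ else fit$p_max,
      significant = if (is.null(fit)) NA else fit$significant)
  }
  ok <- !vapply(fits, is.null, logical(1))
  list(table = do.call(rbind, rows), fits = fits,
       median_curve = if (any(ok)) median_correlation_curve(fits[ok])
                      else NULL)
}

#' Virtual resection analysis for a set of patients
#'
#' Runs [resection_curve()] per patient on the network thresholded at the
#' fitted (or supplied) density, with `beta` derived from the constant
#' `beta * theta`. Failures are isolated as in [fit_patients()]. The
#' summary flags resections that include ROIs outside the seed.
#'
#' @param patients list of loaded or synthetic patients.
#' @param thetas per-patient densities (recycled), e.g. `theta_max` from
#'   [fit_patients()].
#' @param cfg an [si_config()].
#' @param sa_cfg an [sa_config()].
#' @param rng_seed master integer seed.
#' @return List with `table` (data.frame: `id`, `theta`, `S_RA`,
#'   `kappa_RA`, `E_RA`, `S_R90`, `S_R100`, `s90`, `s100`, `i_R1`,
#'   `outside_R90`, `outside_R100`) and `curves` (per-patient
#'   `resection_curve`s).
#' @export
resect_patients <- function(patients, thetas, cfg = si_config(),
                            sa_cfg = sa_config(), rng_seed = NULL) {
  thetas <- rep_len(thetas, length(patients))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(patients))
  curves <- vector("list", length(patients))
  rows <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    id <- if (!is.null(p$id)) p$id else paste0("patient_", i)
    seed <- if (!is.null(p$ra_seed)) p$ra_seed else p$seed
    cv <- tryCatch({
      net_t <- threshold_network(p$network, thetas[i])
      resection_curve(net_t, seed, cfg = cfg, sa_cfg = sa_cfg,
                      rng_seed = sub_seeds[i])
    }, error = function(e) {
      warning("resection failed for ", id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    curves[[i]] <- cv
    rows[[i]] <- if (is.null(cv)) {
      data.frame(id = id, theta = thetas[i], S_RA = NA_real_,
                 kappa_RA = NA_real_, E_RA = NA_real_, S_R90 = NA_real_,
                 S_R100 = NA_real_, s90 = NA_real_, s100 = NA_real_,
                 i_R1 = NA_real_, outside_R90 = NA, outside_R100 = NA)
    } else {
      data.frame(
        id = id, theta = thetas[i], S_RA = cv$seed_stats$S_RA,
        kappa_RA = cv$seed_stats$kappa_RA, E_RA = cv$seed_stats$E_RA,
        S_R90 = if (is.null(cv$R90)) NA_real_ else cv$R90$S,
        S_R100 = if (is.null(cv$R100)) NA_real_ else cv$R100$S,
        s90 = cv$s90, s100 = cv$s100, i_R1 = cv$i_R1,
        outside_R90 = cv$outside_seed$R90,
        outside_R100 = cv$outside_seed$R100)
    }
  }
  list(table = do.call(rbind, rows), curves = curves)
}

#' Paired, unpaired and regression statistics for group tables
#'
#' The simple group statistics used to compare model variants and relate
#' resection summaries to seed connectivity: paired two-sided Student
#' t-tests between matched per-patient values (e.g. two seed or network
#' definitions), unpaired t-tests between outcome groups (SF vs NSF), and
#' Pearson correlation with the least-squares line for summary-vs-`E_RA`
#' relations. Significance threshold `alpha = 0.05` throughout.
#'
#' @param paired named list of 2-column matrices / data.frames (or
#'   2-element lists) of matched values to compare pairwise.
#' @param groups named list of `list(x = values, g = group labels)` for
#'   unpaired comparisons (exactly 2 levels).
#' @param regressions named list of `list(x =, y =)` pairs for Pearson +
#'   least-squares fits.
#' @return List with one entry per input: for t-tests `t`, `df`, `p`,
#'   `mean_diff`; for regressions `r`, `p`, `slope`, `intercept`, `n`.
#' @export
group_stats <- function(paired = list(), groups = list(),
                        regressions = list()) {
  out <- list()
  for (nm in names(paired)) {
    ab <- paired[[nm]]
    x <- if (is.list(ab) && !is.data.frame(ab)) ab[[1]] else ab[, 1]
    y <- if (is.list(ab) && !is.data.frame(ab)) ab[[2]] else ab[, 2]
    ok <- complete.cases(x, y)
    if (sum(ok) < 2) stop("need >= 2 paired observations for ", nm)
    if (sd(x[ok] - y[ok]) == 0) {
      out[[nm]] <- list(t = 0, df = sum(ok) - 1, p = 1,
                        mean_diff = mean(x[ok] - y[ok]))
    } else {
      tt <- t.test(x[ok], y[ok], paired = TRUE)
      out[[nm]] <- list(t = unname(tt$statistic),
                        df = unname(tt$parameter),
                        p = tt$p.value, mean_diff = unname(tt$estimate))
    }
  }
  for (nm in names(groups)) {
    g <- groups[[nm]]
    lev <- unique(g$g[!is.na(g$g)])
    if (length(lev) != 2) stop("group comparison ", nm, " needs 2 levels")
    a <- g$x[g$g == lev[1] & !is.na(g$g)]
    b <- g$x[g$g == lev[2] & !is.na(g$g)]
    if (length(a) < 2 || length(b) < 2) {
      stop("need >= 2 observations per group for ", nm)
    }
    tt <- t.test(a, b, var.equal = TRUE)
    out[[nm]] <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value, mean_diff = mean(a) - mean(b),
                      levels = lev)
  }
  for (nm in names(regressions)) {
    xy <- regressions[[nm]]
    ok <- complete.cases(xy$x, xy$y)
    x <- xy$x[ok]; y <- xy$y[ok]
    if (length(x) < 3) stop("need >= 3 observations for regression ", nm)
    if (sd(x) == 0 || sd(y) == 0) stop("degenerate variance in ", nm)
    ct <- cor.test(x, y)
    fit <- lm(y ~ x)
    out[[nm]] <- list(r = unname(ct$estimate), p = ct$p.value,
                      slope = unname(coef(fit)[2]),
                      intercept = unname(coef(fit)[1]), n = length(x))
  }
  out
}

#' Clinical cohort summary table
#'
#' The per-patient clinical metadata of the 10-patient surgical cohort the
#' model was developed on: resection-area size in ROIs (`S_RA`), Engel
#' score and seizure-freedom outcome, the number of implanted SEEG
#' electrodes (`n_electrodes`), the total number of electrode contact
#' points (`n_contact_points`), and the number of atlas ROIs sampled by
#' the electrodes (`N_SR`). Useful as realistic input ranges for
#' [synthetic_patient_config()] and for the cohort-level worked examples.
#'
#' @return A `data.frame` with one row per patient.
#' @export
patient_table <- function() {
  path <- system.file("extdata", "patient_info.tsv", package = "epispread")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
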