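#' Ensemble parameterization: sampling, stability and control per fMCS
#'
#' For every feasible metabolome, `sets_per_fmcs` kinetic parameter sets are
#' drawn, calibrated to the input flux, classified for stability, and (for
#' stable sets) their flux/concentration control coefficients computed. Each
#' parameter set derives its RNG stream from
#' `(seed, fMCS index, set index)`, so any subset of the ensemble can be
#' recomputed independently and results do not depend on how work is
#' partitioned.
#'
#' @param model a `cbb_network` with `v0` set.
#' @param fmcs an `fmcs_set` from [generate_fmcs()].
#' @param sets_per_fmcs parameter sets per metabolome (full-scale default
#'   1000; reduce for quick runs).
#' @param seed master seed.
#' @param fcc compute flux control coefficients for stable sets.
#' @param saturation record substrate/product saturation ratios per set.
#' @param max_condition condition-number cutoff above which a stable set is
#'   excluded from control analysis (tallied in `counts$mca_dropped`).
#' @param verbose print per-fMCS progress.
#' @return a `cbb_ensemble`: list with
#'   \describe{
#'     \item{stability}{data frame (fmcs_index, set_index, max_real_part,
#'       stable, marginal).}
#'     \item{stable_fraction}{per-fMCS summary (fmcs_index, n_sets, n_stable,
#'       n_marginal, fraction).}
#'     \item{fcc}{matrix (stable sets x target*effector), with provenance in
#'       `fcc_index`; reshape per set with [fcc_matrix()].}
#'     \item{saturation}{matrix of log10([S]/K) per KM slot (optional).}
#'     \item{counts}{failure/drop tallies.}
#'   }
#' @export
sample_ensemble <- function(model, fmcs, sets_per_fmcs = 1000, seed = 1,
                            fcc = TRUE, saturation = TRUE,
                            max_condition = 1e12, verbose = FALSE) {
  stopifnot(inherits(model, "cbb_network"), inherits(fmcs, "fmcs_set"))
  if (is.null(model$v0)) stop("model has no input flux; use set_fluxes()", call. = FALSE)
  nr <- length(model$reaction_ids)
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  km_tab <- model$kin$constants[model$kin$constants$kind == "KM", , drop = FALSE]
  n_total <- fmcs$n * sets_per_fmcs

  stab <- data.frame(fmcs_index = rep(seq_len(fmcs$n), each = sets_per_fmcs),
                     set_index = rep(seq_len(sets_per_fmcs), fmcs$n),
                     max_real_part = NA_real_, stable = NA, marginal = NA)
  fcc_rows <- if (fcc) vector("list", n_total) else NULL
  fcc_prov <- if (fcc) matrix(NA_integer_, n_total, 2) else NULL
  sat_rows <- if (saturation) matrix(NA_real_, n_total, nrow(km_tab)) else NULL
  counts <- c(calibration_failures = 0, classification_failures = 0,
              mca_dropped = 0)
  v0 <- as.numeric(model$v0)
  row <- 0L; nst <- 0L
  for (i in seq_len(fmcs$n)) {
    conc <- fmcs_concentrations(model, fmcs, i)
    for (k in seq_len(sets_per_fmcs)) {
      row <- row + 1L
      ps <- sample_parameter_set(model, conc,
                                 seed = derive_seed(seed, "pset", row),
                                 fmcs_index = i)
      ps <- tryCatch(calibrate_vmax(model, ps, conc), error = function(e) NULL)
      if (is.null(ps)) { counts["calibration_failures"] <- counts["calibration_failures"] + 1; next }
      if (saturation)
        sat_rows[row, ] <- log10(conc[km_tab$metabolite] / ps$K[km_tab$index])
      E <- elasticity_matrix(model, ps, conc)
      st <- tryCatch(classify_stability(model, E), error = function(e) NULL)
      if (is.null(st)) { counts["classification_failures"] <- counts["classification_failures"] + 1; next }
      stab$max_real_part[row] <- st$max_real_part
      stab$stable[row] <- st$stable
      stab$marginal[row] <- st$marginal
      if (fcc && st$stable) {
        Cj <- tryCatch({
          Cx <- concentration_control(model, st, conc, max_condition = max_condition)
          flux_control(model, Cx, E, conc)
        }, error = function(e) NULL)
        if (is.null(Cj)) { counts["mca_dropped"] <- counts["mca_dropped"] + 1; next }
        nst <- nst + 1L
        fcc_rows[[nst]] <- as.numeric(Cj)
        fcc_prov[nst, ] <- c(i, k)
      }
    }
    .msg(verbose, "fMCS %d/%d: %.1f%% stable", i, fmcs$n,
         100 * mean(stab$stable[stab$fmcs_index == i], na.rm = TRUE))
  }
  sf <- do.call(rbind, lapply(split(stab, stab$fmcs_index), function(d)
    data.frame(fmcs_index = d$fmcs_index[1], n_sets = nrow(d),
               n_stable = sum(d$stable, na.rm = TRUE),
               n_marginal = sum(d$marginal, na.rm = TRUE),
               fraction = mean(d$stable, na.rm = TRUE))))
  rownames(sf) <- NULL
  fccm <- NULL; prov <- NULL
  if (fcc && nst > 0) {
    fccm <- do.call(rbind, fcc_rows[seq_len(nst)])
    colnames(fccm) <- as.vector(outer(model$reaction_ids, model$reaction_ids,
                                      function(t, e) paste(t, e, sep = "<-")))
    prov <- data.frame(fmcs_index = fcc_prov[seq_len(nst), 1],
                       set_index = fcc_prov[seq_len(nst), 2])
  }
  if (saturation) colnames(sat_rows) <- km_tab$const_id
  structure(list(stability = stab, stable_fraction = sf,
                 fcc = fccm, fcc_index = prov,
                 saturation = if (saturation) sat_rows else NULL,
                 reaction_ids = model$reaction_ids,
                 seed = seed, sets_per_fmcs = sets_per_fmcs,
                 counts = as.list(counts)),
            class = "cbb_ensemble")
}

#' @export
print.cbb_ensemble <- function(x, ...) {
  cat(sprintf("<cbb_ensemble> %d fMCS x %d sets; median stable fraction %.1f%%\n",
              nrow(x$stable_fraction), x$sets_per_fmcs,
              100 * stats::median(x$stable_fraction$fraction)))
  if (!is.null(x$fcc))
    cat(sprintf("  %d stable sets with control coefficients\n", nrow(x$fcc)))
  invisible(x)
}

#' Reshape one stored control-coefficient row into a matrix
#'
#' @param ensemble a `cbb_ensemble`.
#' @param i row index into `ensemble$fcc`.
#' @return matrix (targets x effectors).
#' @export
fcc_matrix <- function(ensemble, i) {
  nr <- length(ensemble$reaction_ids)
  matrix(ensemble$fcc[i, ], nr, nr,
         dimnames = list(target = ensemble$reaction_ids,
                         effector = ensemble$reaction_ids))
}
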