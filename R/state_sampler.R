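#' Sampling thermodynamically feasible metabolomes (fMCSs)
#'
#' Candidate metabolite concentration sets are drawn log-uniformly within
#' per-metabolite ranges and kept only if (i) every reaction with
#' thermodynamic data has a negative Gibbs free energy change in its defined
#' flux direction, (ii) the summed sampled concentration does not exceed the
#' cap (100 mM by default, reserving the remainder of the cellular budget for
#' metabolites outside the model), (iii) the cofactor pair ratios (ATP/ADP,
#' NADPH/NADP, NADH/NAD) lie within physiological bounds, and (iv) the
#' phosphate pool is a sampled multiple (1.1-5x) of the Pi concentration.
#' Sink reactions and the phosphate supply carry no thermodynamic data and
#' are exempt from the Gibbs filter.
#'
#' @name state_sampler
NULL

#' Log-uniform concentration sampling
#'
#' Each metabolite is drawn independently and uniformly in log10 space
#' between its bounds, giving even coverage of the concentration space.
#'
#' @param ranges a `conc_ranges` table ([default_ranges()], [read_ranges()]).
#' @param n number of candidate sets.
#' @param seed integer seed (draws are reproducible).
#' @return matrix (`n` x metabolites, mM), columns named.
#' @export
sample_log_uniform <- function(ranges, n, seed = NULL) {
  stopifnot(n >= 1, all(ranges$min_mM > 0))
  if (!is.null(seed)) set.seed(seed)
  lo <- log10(ranges$min_mM); hi <- log10(ranges$max_mM)
  u <- matrix(stats::runif(n * nrow(ranges)), n, nrow(ranges))
  m <- 10^(matrix(lo, n, nrow(ranges), byrow = TRUE) +
             u * matrix(hi - lo, n, nrow(ranges), byrow = TRUE))
  colnames(m) <- ranges$metabolite
  m
}

#' Gibbs free energy change of a reaction at given concentrations
#'
#' `dG = dG0' + RT ln Q` with `Q` the mass-action ratio in the reaction's
#' defined direction, concentrations converted to molar; water enters with
#' unit activity. A reaction without thermodynamic data (sinks, phosphate
#' supply) is not checkable and raises an error.
#'
#' @param model a `cbb_network`.
#' @param reaction reaction id or index.
#' @param conc named concentration vector (mM) covering the participants.
#' @param temperature temperature in K (default: the model's).
#' @return Gibbs energy change in kJ/mol.
#' @export
gibbs_energy <- function(model, reaction, conc, temperature = model$temperature) {
  j <- if (is.character(reaction)) match(reaction, model$reaction_ids) else reaction
  stopifnot(!is.na(j))
  r <- model$kin$rxn[[j]]
  dG0 <- model$kin$dG0[j]
  if (is.na(dG0))
    stop(sprintf("reaction '%s' has no standard Gibbs energy (not checkable)",
                 model$reaction_ids[j]), call. = FALSE)
  cm <- conc[model$metabolites$id[r$q_m]]
  if (anyNA(cm) || any(cm <= 0))
    stop("missing or non-positive participant concentrations", call. = FALSE)
  dG0 + .RGAS * temperature * sum(r$q_st * log(as.numeric(cm) / 1000))
}

# signed stoichiometry of thermodynamically checked reactions over all
# metabolites (water/sink pools excluded at compile time)
.thermo_matrix <- function(model) {
  chk <- which(!is.na(model$kin$dG0))
  Nq <- matrix(0, length(chk), nrow(model$metabolites))
  for (i in seq_along(chk)) {
    r <- model$kin$rxn[[chk[i]]]
    Nq[i, r$q_m] <- r$q_st
  }
  rownames(Nq) <- model$reaction_ids[chk]
  list(idx = chk, Nq = Nq)
}

#' Feasibility check of candidate metabolomes
#'
#' Re-evaluates, for each row of a candidate concentration matrix, the four
#' fMCS constraints (thermodynamics, total-concentration cap, cofactor
#' ratios, phosphate-pool multiplier range). Used both by the rejection
#' sampler and to re-verify retained samples.
#'
#' @param model a `cbb_network`.
#' @param ranges a `conc_ranges` object.
#' @param conc matrix (rows = candidate sets, columns = sampled metabolites).
#' @param ppool_multiple vector of PPool/Pi multipliers (recycled).
#' @return list: `feasible` (logical vector), `dG` (matrix over checked
#'   reactions), `ok_thermo`, `ok_cap`, `ok_ratio`, `ok_ppool` (logical
#'   vectors), `dG_violations` (per-reaction counts).
#' @export
check_feasibility <- function(model, ranges, conc, ppool_multiple) {
  stopifnot(is.matrix(conc))
  n <- nrow(conc)
  ppool_multiple <- rep_len(ppool_multiple, n)
  th <- .thermo_matrix(model)
  mt <- model$metabolites
  lnC <- matrix(0, n, nrow(mt))
  fx <- which(mt$fixed & !mt$activity_one)
  for (i in fx) lnC[, i] <- log(mt$conc_min[i] / 1000)
  smp <- match(colnames(conc), mt$id)
  lnC[, smp] <- log(conc / 1000)
  pp <- which(mt$role == "phosphate-pool")
  if (length(pp) && "Pi" %in% colnames(conc))
    lnC[, pp] <- log(ppool_multiple * conc[, "Pi"] / 1000)
  RT <- .RGAS * model$temperature
  dG <- matrix(model$kin$dG0[th$idx], n, length(th$idx), byrow = TRUE) +
    RT * lnC %*% t(th$Nq)
  colnames(dG) <- model$reaction_ids[th$idx]
  ok_thermo <- if (ncol(dG)) rowSums(dG >= 0) == 0 else rep(TRUE, n)
  ok_cap <- rowSums(conc) <= attr(ranges, "total_cap_mM")
  ok_ratio <- rep(TRUE, n)
  for (rr in attr(ranges, "ratios")) {
    if (!all(c(rr$num, rr$den) %in% colnames(conc))) next
    q <- conc[, rr$num] / conc[, rr$den]
    ok_ratio <- ok_ratio & q >= rr$min & q <= rr$max
  }
  pr <- attr(ranges, "ppool_multiple")
  ok_ppool <- ppool_multiple >= pr[1] & ppool_multiple <= pr[2]
  list(feasible = ok_thermo & ok_cap & ok_ratio & ok_ppool,
       dG = dG, ok_thermo = ok_thermo, ok_cap = ok_cap,
       ok_ratio = ok_ratio, ok_ppool = ok_ppool,
       dG_violations = colSums(dG >= 0))
}

#' Generate feasible metabolite concentration sets by rejection sampling
#'
#' Plain (non-adaptive) rejection sampling, vectorized over fixed-size round
#' blocks; each block derives its RNG stream from `(seed, block index)`, so
#' the result is identical however the rounds are chunked, and stops once
#' `target` feasible sets are found or `max_rounds` rounds are exhausted.
#'
#' @param model a `cbb_network`.
#' @param ranges a `conc_ranges` object covering all sampled metabolites.
#' @param max_rounds maximum number of sampling rounds.
#' @param target number of feasible sets wanted (default: unlimited, use all
#'   rounds).
#' @param seed integer master seed.
#' @param block_size rounds per vectorized block (fixed; part of the
#'   deterministic stream layout).
#' @return an `fmcs_set`: list with `concentrations` (matrix, feasible sets x
#'   sampled metabolites), `ppool_multiple`, `dG`, `n`, `rounds`,
#'   `acceptance_rate`, `rejections` (per-constraint tallies incl.
#'   per-reaction Gibbs violations), `seed`.
#' @export
generate_fmcs <- function(model, ranges, max_rounds = 1e6, target = Inf,
                          seed = 1, block_size = 1e5) {
  miss <- setdiff(model$metabolites$id[model$metabolites$sampled],
                  ranges$metabolite)
  if (length(miss))
    stop("ranges table is missing sampled metabolite(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pr <- attr(ranges, "ppool_multiple")
  keep_c <- list(); keep_p <- list(); keep_g <- list()
  rounds <- 0; found <- 0
  rej <- c(thermodynamics = 0, total_cap = 0, cofactor_ratio = 0)
  dG_viol <- NULL
  block <- 0L
  while (rounds < max_rounds && found < target) {
    block <- block + 1L
    nb <- min(block_size, max_rounds - rounds)
    set.seed(derive_seed(seed, "fmcs-block", block))
    cm <- sample_log_uniform(ranges, nb)
    pm <- runif_log10(nb, pr[1], pr[2])
    ck <- check_feasibility(model, ranges, cm, pm)
    rej["thermodynamics"] <- rej["thermodynamics"] + sum(!ck$ok_thermo)
    rej["total_cap"] <- rej["total_cap"] + sum(!ck$ok_cap)
    rej["cofactor_ratio"] <- rej["cofactor_ratio"] + sum(!ck$ok_ratio)
    dG_viol <- if (is.null(dG_viol)) ck$dG_violations else dG_viol + ck$dG_violations
    ok <- which(ck$feasible)
    if (length(ok)) {
      keep_c[[length(keep_c) + 1L]] <- cm[ok, , drop = FALSE]
      keep_p[[length(keep_p) + 1L]] <- pm[ok]
      keep_g[[length(keep_g) + 1L]] <- ck$dG[ok, , drop = FALSE]
      found <- found + length(ok)
    }
    rounds <- rounds + nb
  }
  if (found == 0)
    stop("infeasible configuration: no feasible metabolome in ", rounds,
         " rounds; rejections: ",
         paste(names(rej), rej, sep = "=", collapse = ", "),
         "; Gibbs violations by reaction: ",
         paste(names(dG_viol)[dG_viol > 0], dG_viol[dG_viol > 0],
               sep = "=", collapse = ", "), call. = FALSE)
  conc <- do.call(rbind, keep_c)
  pm <- unlist(keep_p)
  dG <- do.call(rbind, keep_g)
  if (found > target) {
    conc <- conc[seq_len(target), , drop = FALSE]
    pm <- pm[seq_len(target)]
    dG <- dG[seq_len(target), , drop = FALSE]
    found <- target
  }
  structure(list(concentrations = conc, ppool_multiple = pm, dG = dG,
                 n = found, rounds = rounds,
                 acceptance_rate = found / rounds,
                 rejections = as.list(rej), dG_violations = dG_viol,
                 seed = seed, block_size = block_size),
            class = "fmcs_set")
}

#' @export
print.fmcs_set <- function(x, ...) {
  cat(sprintf("<fmcs_set> %d feasible metabolome(s) from %g rounds (acceptance %.3g)\n",
              x$n, x$rounds, x$acceptance_rate))
  invisible(x)
}

#' Re-verify retained fMCSs against all feasibility constraints
#'
#' @param model a `cbb_network`.
#' @param ranges the `conc_ranges` used for sampling.
#' @param fmcs an `fmcs_set`.
#' @return logical vector, one entry per retained metabolome.
#' @export
verify_fmcs <- function(model, ranges, fmcs) {
  ck <- check_feasibility(model, ranges, fmcs$concentrations, fmcs$ppool_multiple)
  in_range <- apply(fmcs$concentrations, 1, function(x) {
    all(x >= ranges$min_mM[match(colnames(fmcs$concentrations), ranges$metabolite)] &
          x <= ranges$max_mM[match(colnames(fmcs$concentrations), ranges$metabolite)])
  })
  ck$feasible & in_range
}

#' Full concentration vector of one retained fMCS
#'
#' @param model a `cbb_network`.
#' @param fmcs an `fmcs_set`.
#' @param i index of the metabolome.
#' @return named vector over all metabolites ([full_concentrations()]).
#' @export
fmcs_concentrations <- function(model, fmcs, i) {
  full_concentrations(model, fmcs$concentrations[i, ], fmcs$ppool_multiple[i])
}

#' Write an fMCS set as TSV plus JSON sidecar
#'
#' @param fmcs an `fmcs_set`.
#' @param path output TSV path (matrix: rows = fMCS, columns = metabolites,
#'   plus `ppool_multiple`); sampling statistics go to `<path>.json`.
#' @export
write_fmcs <- function(fmcs, path) {
  tab <- data.frame(fmcs_index = seq_len(fmcs$n), fmcs$concentrations,
                    ppool_multiple = fmcs$ppool_multiple, check.names = FALSE)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = fmcs$seed, rounds = fmcs$rounds,
                            n = fmcs$n, acceptance_rate = fmcs$acceptance_rate,
                            rejections = fmcs$rejections,
                            block_size = fmcs$block_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
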