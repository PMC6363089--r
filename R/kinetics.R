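#' Rate laws, parameter sampling and Vmax calibration
#'
#' Reactions follow reversible Michaelis-Menten-like kinetics in
#' convenience-kinetics form. For a 1:1 conversion `A <-> B`:
#' \deqn{v = Vmax (A/K_A)(1 - B/(A Keq)) / (1 + A/K_A + B/K_B)}
#' generalized to multiple substrates/products by taking the product of the
#' substrate saturation terms in the numerator, the thermodynamic factor
#' `1 - Q/Keq` with `Q` the mass-action ratio (molar) in the reaction's
#' defined direction, and a denominator
#' `prod_s (sum_k (S/K_S)^k) + prod_p (sum_k (P/K_P)^k) - 1` plus one `I/K_I`
#' term per competitive inhibitor. Allosteric modifiers enter as
#' multiplicative prefactors `a/(K_a + a)` (activator) and `K_i/(K_i + i)`
#' (inhibitor). Irreversible reactions (the two bisphosphatases and the
#' sinks) omit the thermodynamic factor and the product pool; the phosphate
#' supply follows symmetric mass action `v = k (PPool - Pi)`.
#'
#' @name kinetics
NULL

#' Assemble the full concentration vector for a model
#'
#' Combines sampled concentrations with fixed boundary values, sink-pool
#' placeholders, and the phosphate pool (`PPool = ppool_multiple * Pi`).
#'
#' @param model a `cbb_network`.
#' @param sampled named vector of sampled concentrations (mM).
#' @param ppool_multiple PPool/Pi multiplier (used only if the model has a
#'   phosphate-pool species and a `Pi` metabolite).
#' @return named numeric vector over all metabolites, in declaration order.
#' @export
full_concentrations <- function(model, sampled, ppool_multiple = 2) {
  mt <- model$metabolites
  conc <- stats::setNames(rep(NA_real_, nrow(mt)), mt$id)
  conc[mt$fixed] <- mt$conc_min[mt$fixed]
  conc[mt$role == "sink-pool"] <- 1
  conc[names(sampled)] <- as.numeric(sampled)
  pp <- which(mt$role == "phosphate-pool")
  if (length(pp)) {
    conc[pp] <- if ("Pi" %in% names(conc) && is.finite(conc[["Pi"]]))
      ppool_multiple * conc[["Pi"]] else 1
  }
  if (anyNA(conc))
    stop("missing concentrations for: ",
         paste(mt$id[is.na(conc)], collapse = ", "), call. = FALSE)
  conc
}

# core rate-law evaluation at Vmax = 1 (and k = 1 for mass action);
# returns the vector f over reactions
.normalized_rates <- function(kin, K, conc) {
  n <- length(kin$rxn)
  f <- numeric(n)
  for (j in seq_len(n)) {
    r <- kin$rxn[[j]]
    if (r$rate_law == "mass-action-symmetric") {
      f[j] <- conc[r$sub_m] - conc[r$prod_m]
      next
    }
    s <- conc[r$sub_m] / K[r$km_sub]
    Fnum <- prod(s^r$sub_st)
    Dsub <- prod(vapply(seq_along(s), function(i) sum(s[i]^(0:r$sub_st[i])), 0))
    if (r$reversible) {
      p <- conc[r$prod_m] / K[r$km_prod]
      Dprod <- prod(vapply(seq_along(p), function(i) sum(p[i]^(0:r$prod_st[i])), 0))
      lq <- sum(r$q_st * log(conc[r$q_m] / 1000))
      num <- Fnum * (1 - exp(lq) / r$keq)
      den <- Dsub + Dprod - 1
    } else {
      num <- Fnum
      den <- Dsub
    }
    if (length(r$comp_m)) den <- den + sum(conc[r$comp_m] / K[r$comp_k])
    pref <- 1
    if (length(r$act_m)) {
      a <- conc[r$act_m]
      pref <- pref * prod(a / (K[r$act_k] + a))
    }
    if (length(r$inh_m)) {
      i <- conc[r$inh_m]
      pref <- pref * prod(K[r$inh_k] / (K[r$inh_k] + i))
    }
    f[j] <- pref * num / den
  }
  f
}

#' Evaluate reaction rates
#'
#' @param model a `cbb_network`.
#' @param params a `parameter_set` (see [sample_parameter_set()]), or a list
#'   with elements `K` (flat constant vector) and `vmax`.
#' @param conc full named concentration vector (mM), see
#'   [full_concentrations()].
#' @return named numeric vector of rates over reactions.
#' @examples
#' # A <-> B at equilibrium has zero rate
#' m <- build_network(two_metabolite_definition())
#' @export
reaction_rates <- function(model, params, conc) {
  f <- .normalized_rates(model$kin, params$K, conc)
  stats::setNames(params$vmax * f, model$reaction_ids)
}

#' Normalized rates (rate at Vmax = 1)
#'
#' The function `f` in `v = Vmax * f(X, K, Keq)`; for the mass-action
#' phosphate supply it is the concentration difference (rate at `k = 1`).
#'
#' @inheritParams reaction_rates
#' @param K flat vector of kinetic constants (see `model$kin$constants`).
#' @return named numeric vector over reactions.
#' @export
normalized_rates <- function(model, K, conc) {
  stats::setNames(.normalized_rates(model$kin, K, conc), model$reaction_ids)
}

#' Enzyme saturation fraction
#'
#' `S / (S + K)`, the fraction of enzyme occupied at substrate concentration
#' `S` and binding constant `K`. Sampling `K` in `[0.01, 100] x S` spans
#' saturations from 99.0% down to 0.99%.
#'
#' @param concentration metabolite concentration (> 0).
#' @param K binding constant in the same units (> 0).
#' @return saturation fraction in (0, 1).
#' @export
saturation_fraction <- function(concentration, K) {
  stopifnot(all(concentration > 0), all(K > 0))
  concentration / (concentration + K)
}

#' Saturation profile of a parameter set
#'
#' For every (metabolite, reaction) binding-constant slot, the substrate (or
#' product) saturation at the given state: the ratio `S/K` and the bounded
#' fraction `S/(S+K)`.
#'
#' @inheritParams reaction_rates
#' @return data frame: `reaction`, `metabolite`, `kind`, `ratio`, `fraction`.
#' @export
saturation_profile <- function(model, params, conc) {
  ct <- model$kin$constants
  km <- ct[ct$kind == "KM", , drop = FALSE]
  s <- conc[km$metabolite]
  data.frame(reaction = km$reaction, metabolite = km$metabolite,
             kind = km$kind, ratio = s / params$K[km$index],
             fraction = saturation_fraction(s, params$K[km$index]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample a kinetic parameter set around a metabolome
#'
#' Draws every free kinetic constant log-uniformly from
#' `[0.01, 100] x` the concentration of the constant's metabolite in the
#' given state (so saturations span 1-99%). Promiscuity-shared constants are
#' drawn once. `Vmax` is left unset; calibrate with [calibrate_vmax()].
#'
#' @param model a `cbb_network`.
#' @param conc full named concentration vector (see [full_concentrations()]).
#' @param seed integer seed (draws are reproducible).
#' @param fmcs_index provenance index stored on the result.
#' @return a `parameter_set`: list with `K`, `vmax` (NA until calibrated),
#'   `fmcs_index`, `seed`.
#' @export
sample_parameter_set <- function(model, conc, seed = NULL, fmcs_index = NA_integer_) {
  kin <- model$kin
  cmet <- conc[kin$constants$metabolite]
  if (anyNA(cmet))
    stop("regulator or reactant metabolite missing from the state: ",
         paste(unique(kin$constants$metabolite[is.na(cmet)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(kin$n_K)
  K <- 10^(log10(0.01 * cmet) + u * 4)   # log10 span [0.01x, 100x]
  structure(list(K = as.numeric(K), vmax = rep(NA_real_, length(kin$rxn)),
                 fmcs_index = fmcs_index, seed = seed),
            class = "parameter_set")
}

#' Calibrate Vmax to reproduce the input steady-state flux
#'
#' Solves `Vmax = v0 / f(X0, K, Keq)` per reaction so that the parameterized
#' model reproduces the input flux exactly at the generating state. For the
#' mass-action phosphate supply the rate constant is `k = v0 / (PPool - Pi)`.
#' A non-positive `f` signals a thermodynamic/direction conflict, which
#' cannot occur for states that passed the feasibility filter.
#'
#' @param model a `cbb_network` (with `v0` set, or pass `v0`).
#' @param params a `parameter_set`.
#' @param conc full named concentration vector.
#' @param v0 steady-state flux vector (defaults to `model$v0`).
#' @return the `parameter_set` with `vmax` filled in.
#' @export
calibrate_vmax <- function(model, params, conc, v0 = model$v0) {
  if (is.null(v0)) stop("no input flux vector; use set_fluxes()", call. = FALSE)
  f <- .normalized_rates(model$kin, params$K, conc)
  if (any(f <= 0))
    stop("internal consistency failure: normalized rate <= 0 for ",
         paste(model$reaction_ids[f <= 0], collapse = ", "),
         " (state violates the thermodynamic direction)", call. = FALSE)
  params$vmax <- as.numeric(v0) / f
  params
}

#' Tidy view of a parameter set
#'
#' @param x a `parameter_set`.
#' @param model the generating `cbb_network`.
#' @param ... unused.
#' @return data frame `reaction`, `constant_name`, `kind`, `metabolite`,
#'   `value` (Vmax rows included with kind `"Vmax"`).
#' @export
as.data.frame.parameter_set <- function(x, model, ...) {
  ct <- model$kin$constants
  kt <- data.frame(reaction = ct$reaction, constant_name = ct$const_id,
                   kind = ct$kind, metabolite = ct$metabolite,
                   value = x$K[ct$index], stringsAsFactors = FALSE)
  vt <- data.frame(reaction = model$reaction_ids,
                   constant_name = paste0(model$reaction_ids, ":Vmax"),
                   kind = "Vmax", metabolite = NA_character_,
                   value = x$vmax, stringsAsFactors = FALSE)
  rbind(kt, vt)
}
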