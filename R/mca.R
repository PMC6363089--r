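#' Metabolic control analysis at a stable steady state
#'
#' Scaled concentration control coefficients are computed from the reduced
#' Jacobian as
#' \deqn{C_X = -D_{X0}^{-1} L J'^{-1} S' D_{v0}}
#' and flux control coefficients as
#' \deqn{C_J = I + D_{v0}^{-1} (dv/dX) D_{X0} C_X}
#' with `D_X0`, `D_v0` diagonal matrices of the steady-state concentrations
#' and fluxes. The summation theorems (`sum_j C_X[i,j] = 0` per metabolite,
#' `sum_j C_J[i,j] = 1` per target flux) hold exactly up to numerical error
#' because `S' v0 = 0`, and are asserted downstream.
#'
#' @name mca
NULL

#' Concentration control coefficients
#'
#' @param model a `cbb_network`.
#' @param stability a `stability_result` for the state (must be stable; the
#'   reduced Jacobian is inverted).
#' @param conc full named steady-state concentration vector.
#' @param v0 steady-state flux vector (defaults to `model$v0`).
#' @param max_condition parameter sets whose reduced Jacobian has a
#'   condition number above this are rejected (returns an error of class
#'   `cbbkin_singular`), so near-singular states are tallied rather than
#'   silently producing garbage.
#' @return matrix `C_X` (balanced metabolites x reactions), scaled
#'   (dimensionless).
#' @export
concentration_control <- function(model, stability, conc, v0 = model$v0,
                                  max_condition = 1e12) {
  stopifnot(inherits(stability, "stability_result"))
  if (!stability$stable)
    stop("control coefficients are defined here only for stable states",
         call. = FALSE)
  J <- stability$jacobian_reduced
  bal0 <- model$metabolites$id[model$metabolites$role == "balanced"]
  if (nrow(J) == 0) {
    Cx <- matrix(0, length(bal0), length(model$reaction_ids),
                 dimnames = list(bal0, model$reaction_ids))
    return(Cx)
  }
  if (rcond(J) < 1 / max_condition)
    stop(structure(class = c("cbbkin_singular", "error", "condition"),
                   list(message = "reduced Jacobian is near-singular",
                        call = NULL)))
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  x0 <- conc[bal]
  Cx <- -diag(1 / x0, nrow = length(x0)) %*% model$L %*%
    solve(J, model$Sred %*% diag(as.numeric(v0), nrow = length(v0)))
  dimnames(Cx) <- list(bal, model$reaction_ids)
  Cx
}

#' Flux control coefficients
#'
#' @inheritParams concentration_control
#' @param C_X concentration control matrix from [concentration_control()].
#' @param elasticities elasticity matrix ([elasticity_matrix()]).
#' @return matrix `C_J` (target reactions x effector reactions), scaled.
#' @export
flux_control <- function(model, C_X, elasticities, conc, v0 = model$v0) {
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  Eb <- if (ncol(elasticities) == length(bal)) elasticities else
    elasticities[, bal, drop = FALSE]
  x0 <- conc[bal]
  Cj <- diag(length(v0)) +
    diag(1 / as.numeric(v0), nrow = length(v0)) %*% Eb %*%
    diag(x0, nrow = length(x0)) %*% C_X
  dimnames(Cj) <- list(target = model$reaction_ids, effector = model$reaction_ids)
  Cj
}

#' Control coefficients of one parameterized state
#'
#' Convenience wrapper computing elasticities, stability and both control
#' matrices; fails if the state is not stable.
#'
#' @inheritParams concentration_control
#' @param params calibrated `parameter_set`.
#' @return a `control_coefficients` list: `C_X`, `C_J`, `stability`,
#'   provenance fields.
#' @export
control_coefficients <- function(model, params, conc, v0 = model$v0) {
  E <- elasticity_matrix(model, params, conc)
  st <- classify_stability(model, E)
  Cx <- concentration_control(model, st, conc, v0)
  Cj <- flux_control(model, Cx, E, conc, v0)
  structure(list(C_X = Cx, C_J = Cj, stability = st,
                 fmcs_index = params$fmcs_index, seed = params$seed),
            class = "control_coefficients")
}

#' Finite-difference flux-control oracle
#'
#' Independent re-equilibration check of the Jacobian-based control
#' coefficients: the effector's Vmax is scaled by `(1 +/- delta)`, the new
#' steady state on the same conserved-moiety subspace is found by a damped
#' Newton solve, and the central log-log difference
#' `(ln v_j^+ - ln v_j^-) / (ln Vmax^+ - ln Vmax^-)` is returned for all
#' target fluxes.
#'
#' @inheritParams control_coefficients
#' @param effector_reaction reaction id or index whose activity is perturbed.
#' @param delta relative Vmax perturbation (default 1e-3).
#' @return named numeric vector (one flux control coefficient per target
#'   reaction), or `NULL` if either re-equilibration failed to converge.
#' @export
fcc_finite_difference_oracle <- function(model, params, conc,
                                         effector_reaction, delta = 1e-3) {
  e <- if (is.character(effector_reaction))
    match(effector_reaction, model$reaction_ids) else effector_reaction
  stopifnot(!is.na(e), e >= 1, e <= length(model$reaction_ids))
  one <- function(fac) {
    p <- params
    p$vmax[e] <- p$vmax[e] * fac
    ss <- .newton_steady_state(model, p, conc)
    if (!isTRUE(ss$converged)) return(NULL)
    ss$v
  }
  vp <- one(1 + delta); vm <- one(1 - delta)
  if (is.null(vp) || is.null(vm)) return(NULL)
  if (any(vp <= 0) || any(vm <= 0)) return(NULL)
  stats::setNames((log(vp) - log(vm)) / (log(1 + delta) - log(1 - delta)),
                  model$reaction_ids)
}
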