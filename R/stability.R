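#' Local stability analysis of parameterized steady states
#'
#' The Jacobian of the balanced subsystem at the steady state `X0` is
#' `S %*% E` with `E = dv/dX` the elasticity matrix. Conserved moieties make
#' this Jacobian structurally singular, so stability is classified on the
#' reduced Jacobian `J' = Sred %*% E %*% L` (with `S = L %*% Sred`), whose
#' dimension equals the rank of `S`: a steady state is locally stable iff
#' every eigenvalue of `J'` has negative real part. Eigenvalues within the
#' numerical tolerance of zero are conservatively classified unstable and
#' flagged "marginal".
#'
#' @name stability
NULL

#' Analytic elasticity matrix dv/dX
#'
#' Exact partial derivatives of every reaction rate with respect to every
#' metabolite concentration (mM), from closed-form differentiation of the
#' rate laws. Columns are returned for all metabolites in declaration order
#' (the derivative with respect to a fixed boundary species is the
#' mathematical one; downstream stability/control analysis subsets the
#' balanced columns, which is where fixed species drop out). Sink-pool
#' species never enter rate laws, so their columns are structurally zero.
#'
#' @param model a `cbb_network`.
#' @param params calibrated `parameter_set`.
#' @param conc full named concentration vector at the state (mM).
#' @return matrix (reactions x metabolites).
#' @export
elasticity_matrix <- function(model, params, conc) {
  kin <- model$kin
  K <- params$K
  nr <- length(kin$rxn); nm <- length(conc)
  E <- matrix(0, nr, nm, dimnames = list(model$reaction_ids, names(conc)))
  for (j in seq_len(nr)) {
    r <- kin$rxn[[j]]
    vmax <- params$vmax[j]
    if (r$rate_law == "mass-action-symmetric") {
      E[j, r$sub_m] <- E[j, r$sub_m] + vmax
      E[j, r$prod_m] <- E[j, r$prod_m] - vmax
      next
    }
    s <- conc[r$sub_m] / K[r$km_sub]
    Fnum <- prod(s^r$sub_st)
    Gs <- vapply(seq_along(s), function(i) sum(s[i]^(0:r$sub_st[i])), 0)
    dGs <- vapply(seq_along(s), function(i) {
      k <- seq_len(r$sub_st[i]); sum(k * s[i]^k) / conc[r$sub_m[i]]
    }, 0)
    Dsub <- prod(Gs)
    if (r$reversible) {
      p <- conc[r$prod_m] / K[r$km_prod]
      Gp <- vapply(seq_along(p), function(i) sum(p[i]^(0:r$prod_st[i])), 0)
      dGp <- vapply(seq_along(p), function(i) {
        k <- seq_len(r$prod_st[i]); sum(k * p[i]^k) / conc[r$prod_m[i]]
      }, 0)
      Dprod <- prod(Gp)
      qfac <- exp(sum(r$q_st * log(conc[r$q_m] / 1000))) / r$keq
      N <- Fnum * (1 - qfac)
      D <- Dsub + Dprod - 1
    } else {
      Gp <- numeric(0); dGp <- numeric(0)
      qfac <- 0
      N <- Fnum
      D <- Dsub
    }
    if (length(r$comp_m)) D <- D + sum(conc[r$comp_m] / K[r$comp_k])
    A <- 1
    if (length(r$act_m)) A <- A * prod(conc[r$act_m] / (K[r$act_k] + conc[r$act_m]))
    if (length(r$inh_m)) A <- A * prod(K[r$inh_k] / (K[r$inh_k] + conc[r$inh_m]))

    dN <- numeric(nm); dD <- numeric(nm); dA <- numeric(nm)
    for (i in seq_along(r$sub_m)) {
      m <- r$sub_m[i]; st <- r$sub_st[i]; cm <- conc[m]
      dN[m] <- dN[m] + Fnum * st / cm * (1 - qfac) + Fnum * st * qfac / cm
      dD[m] <- dD[m] + Dsub / Gs[i] * dGs[i]
    }
    for (i in seq_along(r$prod_m)) {
      m <- r$prod_m[i]; cm <- conc[m]
      if (r$reversible) {
        dN[m] <- dN[m] - Fnum * r$prod_st[i] * qfac / cm
        dD[m] <- dD[m] + Dprod / Gp[i] * dGp[i]
      }
    }
    for (i in seq_along(r$comp_m))
      dD[r$comp_m[i]] <- dD[r$comp_m[i]] + 1 / K[r$comp_k[i]]
    for (i in seq_along(r$act_m)) {
      m <- r$act_m[i]; a <- conc[m]; Ka <- K[r$act_k[i]]
      dA[m] <- dA[m] + A * Ka / (a * (Ka + a))
    }
    for (i in seq_along(r$inh_m)) {
      m <- r$inh_m[i]; Ki <- K[r$inh_k[i]]
      dA[m] <- dA[m] - A / (Ki + conc[m])
    }
    act <- which(dN != 0 | dD != 0 | dA != 0)
    E[j, act] <- vmax * (dA[act] * N / D + A * dN[act] / D -
                           A * N * dD[act] / D^2)
  }
  E
}

#' Classify local stability from the reduced Jacobian
#'
#' @param model a `cbb_network`.
#' @param elasticities matrix from [elasticity_matrix()] (all-metabolite or
#'   balanced-only columns are both accepted).
#' @return a `stability_result`: list with `jacobian_reduced`, `eigenvalues`,
#'   `max_real_part`, `stable`, `marginal`, `epsilon`.
#' @export
classify_stability <- function(model, elasticities) {
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  Eb <- if (ncol(elasticities) == length(bal)) elasticities else
    elasticities[, bal, drop = FALSE]
  J <- model$Sred %*% Eb %*% model$L
  if (any(!is.finite(J)))
    stop("non-finite entries in the reduced Jacobian (singular elasticities)",
         call. = FALSE)
  if (nrow(J) == 0)   # no independent dynamic species: trivially stable
    return(structure(list(jacobian_reduced = J, eigenvalues = complex(0),
                          max_real_part = -Inf, stable = TRUE,
                          marginal = FALSE, epsilon = 0),
                     class = "stability_result"))
  ev <- eigen(J, only.values = TRUE)$values
  mrp <- max(Re(ev))
  eps <- 1e-9 * (1 + max(Mod(ev)))
  structure(list(jacobian_reduced = J, eigenvalues = ev,
                 max_real_part = mrp,
                 stable = mrp < -eps,
                 marginal = abs(mrp) <= eps,
                 epsilon = eps),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %s (max Re eigenvalue = %.4g%s)\n",
              if (x$stable) "stable" else "unstable", x$max_real_part,
              if (x$marginal) ", marginal" else ""))
  invisible(x)
}

# time derivative of the balanced concentrations
.balanced_deriv <- function(model, params, conc_template, bal_idx) {
  force(model); force(params); force(conc_template); force(bal_idx)
  function(t, x, p) {
    conc_template[bal_idx] <- pmax(x, 1e-12)
    v <- params$vmax * .normalized_rates(model$kin, params$K, conc_template)
    list(as.numeric(model$S %*% v))
  }
}

#' ODE perturbation oracle for stability
#'
#' Independent dynamical check of the eigenvalue classification: perturb the
#' steady state by a small displacement inside the stoichiometric subspace
#' (so conserved moieties are respected), integrate `dX/dt = S v(X)` with a
#' stiff solver, and report whether the displacement shrinks below 10% of
#' its initial size within the horizon.
#'
#' @param model a `cbb_network` with `v0` set.
#' @param params calibrated `parameter_set`.
#' @param conc full named steady-state concentration vector.
#' @param relative_perturbation relative size of the initial displacement.
#' @param horizon integration horizon; the default is `1e6 x` the
#'   characteristic time `median(X0)/median(v0)`, long enough for modes with
#'   decay/growth rates down to ~1e-5 in flux units to manifest. The
#'   trajectory is integrated checkpoint by checkpoint (log-spaced) and
#'   stops as soon as the displacement falls below 10% of its initial size
#'   (returned) or grows 20-fold (diverged).
#' @param seed seed for the perturbation direction.
#' @return list with `returns_to_state` (`TRUE`/`FALSE`, or `NA` if the
#'   integration was inconclusive), `final_ratio`, `t_decided`.
#' @export
ode_perturbation_oracle <- function(model, params, conc,
                                    relative_perturbation = 1e-4,
                                    horizon = NULL, seed = 1) {
  bal <- which(model$metabolites$role == "balanced")
  x0 <- conc[bal]
  set.seed(derive_seed(seed, "ode-perturbation"))
  raw <- x0 * relative_perturbation * stats::rnorm(length(x0))
  # project onto the stoichiometric subspace (range of L)
  d <- as.numeric(model$L %*% qr.solve(model$L, raw))
  nd <- sqrt(sum((d / x0)^2))
  d <- d * (relative_perturbation / nd)
  if (is.null(horizon))
    horizon <- 1e6 * stats::median(x0) / stats::median(abs(model$v0))
  times <- 10^seq(log10(horizon) - 8, log10(horizon), length.out = 49)
  deriv <- .balanced_deriv(model, params, conc, bal)
  disp0 <- sqrt(sum((d / x0)^2))
  state <- x0 + d
  tprev <- 0
  ratio <- 1
  for (tk in times) {
    out <- try(suppressWarnings(
      deSolve::lsoda(y = state, times = c(tprev, tk), func = deriv,
                     parms = NULL, rtol = 1e-8, atol = 1e-10)),
      silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < 2 || any(!is.finite(out[2, -1]))) {
      # a blow-up after the displacement had already grown is divergence;
      # anything else is an integrator failure, i.e. inconclusive
      if (is.finite(ratio) && ratio > 2)
        return(list(returns_to_state = FALSE, final_ratio = ratio,
                    t_decided = tprev))
      return(list(returns_to_state = NA, final_ratio = ratio,
                  t_decided = NA_real_))
    }
    state <- out[2, -1]
    ratio <- sqrt(sum(((state - x0) / x0)^2)) / disp0
    if (!is.finite(ratio) || ratio > 20)
      return(list(returns_to_state = FALSE, final_ratio = ratio, t_decided = tk))
    if (ratio < 0.1)
      return(list(returns_to_state = TRUE, final_ratio = ratio, t_decided = tk))
    tprev <- tk
  }
  list(returns_to_state = ratio < 1, final_ratio = ratio, t_decided = horizon)
}

# Newton solve for the steady state nearest x0 within the conserved-moiety
# subspace; used by the finite-difference control-coefficient oracle.
.newton_steady_state <- function(model, params, conc, tol = NULL, max_iter = 80L) {
  bal <- which(model$metabolites$role == "balanced")
  x0 <- conc[bal]
  L <- model$L
  scale <- max(abs(params$vmax * .normalized_rates(model$kin, params$K, conc)))
  tol <- tol %||% (1e-12 * max(scale, 1))
  xi <- numeric(ncol(L))
  cc <- conc
  for (it in seq_len(max_iter)) {
    x <- x0 + as.numeric(L %*% xi)
    cc[bal] <- x
    v <- params$vmax * .normalized_rates(model$kin, params$K, cc)
    g <- as.numeric(model$Sred %*% v)
    if (length(g) == 0 || max(abs(g)) < tol)
      return(list(conc = cc, v = v, converged = TRUE, iter = it))
    E <- elasticity_matrix(model, params, cc)
    J <- model$Sred %*% E[, bal, drop = FALSE] %*% L
    step <- try(solve(J, -g), silent = TRUE)
    if (inherits(step, "try-error")) return(list(converged = FALSE))
    lam <- 1
    repeat {
      xn <- x0 + as.numeric(L %*% (xi + lam * step))
      if (all(xn > 0)) break
      lam <- lam / 2
      if (lam < 1e-8) return(list(converged = FALSE))
    }
    xi <- xi + lam * step
  }
  list(converged = FALSE)
}
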