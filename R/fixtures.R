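#' Synthetic inputs: steady-state fluxes, concentration ranges, toy models
#'
#' Everything the analysis needs that would otherwise come from external
#' files is generated here: a strictly positive steady-state flux vector on
#' the model's own stoichiometry (stand-in for a genome-scale FBA solution),
#' the per-metabolite concentration-range table, and toy networks with
#' closed-form steady states and control coefficients used as oracles.
#'
#' @name synthetic_fixtures
NULL

# stoichiometrically shaped target fluxes for the shipped CBB reactions
# (relative to Rubisco = 1; only used to pick one point of the flux polytope)
.CBB_FLUX_SHAPE <- c(
  Rubisco = 1, pgk = 1.9, gapd = 1.9, tpi = 0.9, fba = 0.45, ald = 0.4,
  FBPase = 0.45, tkt1 = 0.45, tkt2 = 0.4, SBPase = 0.4, rpe = 0.55,
  rpi = 0.35, prk = 1, pgm = 0.12, eno = 0.12, pyk = 0.1, pdh = 0.06,
  xfpk1 = 0.03, xfpk2 = 0.03, pta = 0.06, ATPSyn = 1.0, NADPase = 1.9,
  Supply_Pi = 0.3)

#' Generate a strictly positive steady-state flux vector
#'
#' Solves a small strictly convex program over the model's stoichiometry:
#' the flux vector closest to a stoichiometrically shaped target (with sink
#' targets scaled by the objective weights) subject to `Sred v = 0` and
#' direction bounds `1e-3 <= v <= 2`, so every reaction carries flux in its
#' defined direction (required by the thermodynamic filter and Vmax
#' calibration) and the optimum is unique and deterministic. The solution is
#' refined by projection onto the nullspace of `S` (machine-precision
#' steady-state residual) and rescaled so the largest flux is 1 (the
#' pipeline is unit-agnostic).
#'
#' @param model a `cbb_network`.
#' @param objective_weights optional named weights for the sink fluxes
#'   (default 1 for every reaction producing a sink-pool metabolite).
#' @param seed optional seed; when given, sink weights are jittered
#'   log-uniformly within a factor ~3 to produce varied admissible flux
#'   vectors.
#' @param flux_file optional path to a flux table (TSV `reaction`, `v0`);
#'   when supplied the file is validated with [validate_flux_vector()] and
#'   used instead of the optimizer.
#' @return a named numeric vector `v0` over reactions with attribute
#'   `provenance` (`"lp-generated"` or `"table-file"`).
#' @export
generate_flux_vector <- function(model, objective_weights = NULL, seed = NULL,
                                 flux_file = NULL) {
  stopifnot(inherits(model, "cbb_network"))
  rids <- model$reaction_ids
  if (!is.null(flux_file)) {
    tab <- utils::read.delim(flux_file, stringsAsFactors = FALSE)
    v <- stats::setNames(tab$v0, tab$reaction)[rids]
    if (anyNA(v)) stop("flux file is missing reactions: ",
                       paste(rids[is.na(v)], collapse = ", "), call. = FALSE)
    validate_flux_vector(model, v)
    attr(v, "provenance") <- "table-file"
    return(v)
  }
  S <- model$S
  n <- length(rids)
  if (n - nrow(model$Sred) < 1)
    stop("model has no degree of freedom in its nullspace", call. = FALSE)
  sink_idx <- which(vapply(model$reactions, function(r) {
    any(model$metabolites$role[match(names(r$stoichiometry), model$metabolites$id)]
        == "sink-pool" & unlist(r$stoichiometry) > 0)
  }, TRUE))
  w <- stats::setNames(rep(1, length(sink_idx)), rids[sink_idx])
  if (!is.null(objective_weights)) {
    w[names(objective_weights)] <- unlist(objective_weights)
  } else if (!is.null(seed)) {
    set.seed(derive_seed(seed, "flux-weights"))
    w <- w * runif_log10(length(w), 10^-0.5, 10^0.5)
  }
  target <- rep(0.2, n)
  names(target) <- rids
  shared <- intersect(rids, names(.CBB_FLUX_SHAPE))
  target[shared] <- .CBB_FLUX_SHAPE[shared]
  target[names(w)] <- 0.05 * w
  lb <- rep(1e-3, n); ub <- rep(2, n)
  # Dykstra's alternating projections: the point of
  # {Sred v = 0} inter [lb, ub] closest to the target (the strictly convex
  # program has a unique optimum, so the result is deterministic)
  N <- if (nrow(S)) pracma::nullspace(S) else diag(n)
  if (is.null(N)) {
    tal <- .flux_conflict_set(model)
    stop("model stoichiometry admits no steady-state flux; conflicting ",
         "metabolite(s): ", paste(tal, collapse = ", "), call. = FALSE)
  }
  x <- target; pd <- numeric(n); qd <- numeric(n)
  for (it in seq_len(20000L)) {
    y <- as.numeric(N %*% crossprod(N, x + pd)); pd <- x + pd - y
    x <- pmin(pmax(y + qd, lb), ub);             qd <- y + qd - x
    if (it %% 500L == 0L) {
      v <- as.numeric(N %*% crossprod(N, x))
      if (max(abs(v - x)) < 1e-12 && all(v >= lb - 1e-12)) break
    }
  }
  # final polish: exactly in the nullspace of S
  v <- as.numeric(N %*% crossprod(N, x))
  if (any(v <= 0)) {
    tal <- .flux_conflict_set(model)
    stop("flux program returned a non-positive component; conflicting ",
         "metabolite(s): ", paste(tal, collapse = ", "), call. = FALSE)
  }
  v <- v / max(v)
  names(v) <- rids
  validate_flux_vector(model, v)
  attr(v, "provenance") <- "lp-generated"
  v
}

# metabolites that cannot be balanced with all-positive fluxes
# (produced-only or consumed-only rows of S)
.flux_conflict_set <- function(model) {
  S <- model$S
  bad <- rownames(S)[apply(S, 1, function(r) all(r >= 0) || all(r <= 0)) &
                       apply(S, 1, function(r) any(r != 0))]
  if (!length(bad)) "none identified (bounds conflict)" else bad
}

#' Validate a steady-state flux vector
#'
#' Checks positivity in the defined direction and the steady-state residual
#' `max |S v|` against `tol` (relative to `max |v|`). On failure the error
#' names the unbalanced metabolites.
#'
#' @param model a `cbb_network`.
#' @param v named or ordered flux vector over reactions.
#' @param tol relative residual tolerance (default 1e-10).
#' @return `v`, invisibly.
#' @export
validate_flux_vector <- function(model, v, tol = 1e-10) {
  stopifnot(length(v) == length(model$reaction_ids))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("flux vector must be strictly positive in every reaction's defined direction",
         call. = FALSE)
  res <- as.numeric(model$S %*% as.numeric(v))
  bad <- abs(res) > tol * max(abs(v))
  if (any(bad))
    stop("flux vector is not at steady state; unbalanced metabolite(s): ",
         paste(sprintf("%s (%.3g)", rownames(model$S)[bad], res[bad]),
               collapse = ", "), call. = FALSE)
  invisible(v)
}

#' Read / write a flux table (TSV: reaction, v0)
#' @param path file path.
#' @rdname flux_table
#' @export
read_flux_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$v0, tab$reaction)
}

#' @param v named flux vector.
#' @rdname flux_table
#' @export
write_flux_table <- function(v, path) {
  utils::write.table(
    data.frame(reaction = names(v), v0 = sprintf("%.17g", v)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach an input flux vector to a model
#'
#' @param model a `cbb_network`.
#' @param v validated flux vector (see [validate_flux_vector()]).
#' @return the model with `v0` set.
#' @export
set_fluxes <- function(model, v) {
  validate_flux_vector(model, v)
  model$v0 <- stats::setNames(as.numeric(v), model$reaction_ids)
  model
}

#' Default concentration-range table for a model
#'
#' Extracts the per-metabolite sampling ranges and the physiological
#' constraints (total-concentration cap, cofactor-ratio bounds, phosphate-pool
#' multiplier range) from the model definition. For the shipped CBB model this
#' emulates the role of a published range table: log-scale ranges bracketing
#' literature concentrations by about two orders of magnitude.
#'
#' @param model a `cbb_network`.
#' @return a `conc_ranges` object: data frame (`metabolite`, `min_mM`,
#'   `max_mM`) over sampled metabolites with constraint attributes
#'   `total_cap_mM`, `ratios`, `ppool_multiple`.
#' @export
default_ranges <- function(model) {
  stopifnot(inherits(model, "cbb_network"))
  mt <- model$metabolites
  tab <- data.frame(metabolite = mt$id[mt$sampled],
                    min_mM = mt$conc_min[mt$sampled],
                    max_mM = mt$conc_max[mt$sampled],
                    stringsAsFactors = FALSE)
  cons <- model$definition$constraints %||% list()
  ratios <- lapply(cons$ratios %||% list(), function(r)
    list(num = r$num, den = r$den, min = as.numeric(r$min), max = as.numeric(r$max)))
  new_conc_ranges(tab,
                  total_cap_mM = as.numeric(cons$total_cap_mM %||% 100),
                  ratios = ratios,
                  ppool_multiple = as.numeric(unlist(cons$ppool_multiple %||% c(1.1, 5))))
}

#' Construct a concentration-range table
#'
#' @param tab data frame with columns `metabolite`, `min_mM`, `max_mM`.
#' @param total_cap_mM cap on the summed sampled concentrations (mM).
#' @param ratios list of cofactor-ratio constraints
#'   (`list(num=, den=, min=, max=)`).
#' @param ppool_multiple range of the PPool/Pi multiplier (min must be > 1).
#' @return a `conc_ranges` object.
#' @export
new_conc_ranges <- function(tab, total_cap_mM = 100, ratios = list(),
                            ppool_multiple = c(1.1, 5)) {
  stopifnot(all(c("metabolite", "min_mM", "max_mM") %in% names(tab)),
            all(tab$min_mM > 0), all(tab$min_mM <= tab$max_mM),
            total_cap_mM > 0, ppool_multiple[1] > 1,
            ppool_multiple[1] <= ppool_multiple[2])
  structure(tab, class = c("conc_ranges", "data.frame"),
            total_cap_mM = total_cap_mM, ratios = ratios,
            ppool_multiple = ppool_multiple)
}

#' Read / write a concentration-range table (TSV: metabolite, min_mM, max_mM)
#'
#' Constraint attributes (cap, ratios, PPool multiplier) are carried in a
#' JSON sidecar `<path>.json` when present.
#'
#' @param path file path.
#' @rdname ranges_io
#' @export
read_ranges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  extra <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = FALSE) else list()
  new_conc_ranges(tab,
                  total_cap_mM = as.numeric(extra$total_cap_mM %||% 100),
                  ratios = lapply(extra$ratios %||% list(), function(r)
                    list(num = r$num, den = r$den,
                         min = as.numeric(r$min), max = as.numeric(r$max))),
                  ppool_multiple = as.numeric(unlist(extra$ppool_multiple %||% c(1.1, 5))))
}

#' @param ranges a `conc_ranges` object.
#' @rdname ranges_io
#' @export
write_ranges <- function(ranges, path) {
  utils::write.table(as.data.frame(ranges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(total_cap_mM = attr(ranges, "total_cap_mM"),
                            ratios = attr(ranges, "ratios"),
                            ppool_multiple = attr(ranges, "ppool_multiple")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- toy models -------------------------------------------------------------

#' Minimal two-metabolite definition (A -> B)
#'
#' A single irreversible conversion with a fixed boundary substrate feeding A
#' and a sink draining B; used in examples and as the smallest structural
#' fixture.
#' @return a model definition list.
#' @export
two_metabolite_definition <- function() {
  list(name = "two_metabolite",
       metabolites = list(
         list(id = "A", name = "A", role = "balanced", conc_min = 0.1, conc_max = 10),
         list(id = "B", name = "B", role = "balanced", conc_min = 0.1, conc_max = 10),
         list(id = "PPool", name = "pool", role = "phosphate-pool")),
       reactions = list(
         list(id = "r1", stoichiometry = list(A = -1, B = 1),
              rate_law = "reversible-MM", dG0_prime = -10)))
}

#' Toy linear chain with closed-form control coefficients
#'
#' Builds an open `n_steps`-reaction chain `X0 -> X1 -> ... -> out` with a
#' fixed boundary substrate `X0` and an inert outflow pool, plus reference
#' quantities computed from the closed-form steady state by brute-force
#' perturbation (independently of the package's control-analysis pipeline).
#'
#' Regimes:
#' \describe{
#'   \item{`"first-order"`}{every internal step is reversible
#'     Michaelis-Menten with `Keq = 1` operated far below saturation
#'     (`K >> X`), i.e. effectively linear with rate constant
#'     `k_i = Vmax_i / K_i`; the terminal drain is irreversible first order.
#'     The chain flux is `J = X0 / sum(1/k_i)` and the flux control
#'     coefficient of step i is `(1/k_i) / sum(1/k_j)`.}
#'   \item{`"zero-order-supply"`}{the first step is fully saturated
#'     (zero order), so it holds complete control: its flux control
#'     coefficient over every flux is 1 and all others are 0.}
#' }
#'
#' @param n_steps number of reactions (>= 1).
#' @param saturation_regime `"first-order"` or `"zero-order-supply"`.
#' @param rate_constants optional positive vector (length `n_steps`) of
#'   first-order rate constants (default `seq(1, 2, ...)`).
#' @return a `toy_model` list: `model` (`cbb_network` with `v0` set),
#'   `K` (flat constant vector), `vmax`, `X0` (full named concentration
#'   vector at steady state), `reference` (list with `fcc` matrix and
#'   steady-state info).
#' @export
toy_linear_chain <- function(n_steps,
                             saturation_regime = c("first-order", "zero-order-supply"),
                             rate_constants = NULL) {
  stopifnot(n_steps >= 1)
  saturation_regime <- match.arg(saturation_regime)
  k <- rate_constants %||% seq(1, 2, length.out = n_steps)
  stopifnot(length(k) == n_steps, all(k > 0))
  ids <- if (n_steps > 1) paste0("X", seq_len(n_steps - 1)) else character(0)
  mets <- c(
    list(list(id = "X0", name = "boundary substrate", role = "boundary-unbalanced",
              conc_min = 1, conc_max = 1)),
    lapply(ids, function(i) list(id = i, name = i, role = "balanced",
                                 conc_min = 1e-6, conc_max = 1e6)),
    list(list(id = "Out", name = "outflow pool", role = "sink-pool"),
         list(id = "PPool", name = "pool", role = "phosphate-pool")))
  chain <- c("X0", ids, "Out")
  first_order <- saturation_regime == "first-order"
  rxns <- lapply(seq_len(n_steps), function(i) {
    st <- stats::setNames(list(-1, 1), c(chain[i], chain[i + 1]))
    last <- i == n_steps
    list(id = sprintf("R%d", i), stoichiometry = st,
         rate_law = if (!last && first_order) "reversible-MM" else "irreversible-MM",
         dG0_prime = if (!last && first_order) 0 else NULL)
  })
  model <- build_network(list(name = sprintf("chain%d", n_steps),
                              metabolites = mets, reactions = rxns))

  X0val <- 1
  if (first_order) {
    J <- X0val / sum(1 / k)
    x <- X0val - J * cumsum(1 / k)          # steady state, x[n] at the drain
    conc <- c(X0 = X0val, stats::setNames(x[seq_len(n_steps - 1)], ids))
    Kbig <- 1e6
    K <- numeric(model$kin$n_K); vmax <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      r <- model$kin$rxn[[i]]
      K[r$km_sub] <- Kbig
      if (length(r$km_prod)) K[r$km_prod] <- Kbig
      vmax[i] <- k[i] * Kbig
    }
    ref_flux <- function(kk) X0val / sum(1 / kk)
  } else {
    J <- 1                                   # saturated supply: v1 = Vmax1
    conc <- c(X0 = X0val, stats::setNames(rep(NA_real_, n_steps - 1), ids))
    K <- numeric(model$kin$n_K); vmax <- numeric(n_steps)
    r1 <- model$kin$rxn[[1]]
    K[r1$km_sub] <- 1e-8 * X0val             # ~zero order in X0
    vmax[1] <- J / (X0val / (X0val + K[r1$km_sub]))
    for (i in seq_len(n_steps)[-1]) {
      r <- model$kin$rxn[[i]]
      vmax[i] <- 2 * J                       # half-saturated at steady state
      Ki <- 1                                # X_i = K_i * J/(V_i - J) = K_i
      K[r$km_sub] <- Ki
      conc[chain[i]] <- Ki * J / (vmax[i] - J)
    }
    ref_flux <- function(kk) kk[1]           # supply sets the flux
    k <- c(1, rep(1, n_steps - 1))
  }
  # reference FCCs by brute-force perturbation of each step's activity,
  # using only the closed-form steady-state flux
  d <- 1e-6
  fcc <- vapply(seq_len(n_steps), function(i) {
    kp <- k; km <- k
    kp[i] <- k[i] * (1 + d); km[i] <- k[i] * (1 - d)
    (log(ref_flux(kp)) - log(ref_flux(km))) / (log(1 + d) - log(1 - d))
  }, 0)
  fcc_mat <- matrix(rep(fcc, each = n_steps), n_steps, n_steps,
                    dimnames = list(target = model$reaction_ids,
                                    effector = model$reaction_ids))
  v0 <- stats::setNames(rep(J, n_steps), model$reaction_ids)
  model <- set_fluxes(model, v0)
  full_conc <- full_concentrations(model, conc)
  # snap Vmax onto the exact steady state (removes the O(X/K) linearization
  # slack of the first-order regime)
  ps <- calibrate_vmax(model, list(K = K, vmax = vmax), full_conc)
  vmax <- ps$vmax
  structure(list(model = model, K = K, vmax = vmax, X0 = full_conc,
                 reference = list(fcc = fcc_mat, flux = J,
                                  regime = saturation_regime)),
            class = "toy_model")
}
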