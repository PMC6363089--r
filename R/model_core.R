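#' Network model construction for ensemble kinetic modeling
#'
#' A network model is defined by a structured definition (read from a JSON
#' model file or assembled in code) listing metabolites, reactions with signed
#' stoichiometries, rate-law kinds, standard transformed Gibbs energies,
#' regulators, and enzyme-promiscuity links. [build_network()] validates the
#' definition, assembles the stoichiometric matrix over balanced metabolites,
#' factorizes it into a full-rank reduced matrix and link matrix
#' (`S = L %*% Sred`), and compiles an indexed kinetic structure used by the
#' sampling, stability and control-analysis stages.
#'
#' @section Metabolite roles:
#' \describe{
#'   \item{balanced}{mass-balanced dynamic species; rows of `S`.}
#'   \item{boundary-unbalanced}{species held constant during dynamics. A
#'     degenerate concentration range (`min == max`) marks a fixed boundary
#'     species (CO2, O2, H2O); a non-degenerate range marks a species whose
#'     concentration is sampled per metabolome but not mass-balanced
#'     (NAD/NADH, whose only reaction in the network is pdh).}
#'   \item{sink-pool}{inert product pools of the lumped biomass sink
#'     reactions; they never enter rate laws or reaction quotients.}
#'   \item{phosphate-pool}{the abstract phosphate reservoir PPool, set per
#'     metabolome as a sampled multiple of the Pi concentration.}
#' }
#'
#' @name model_core
NULL

.RATE_LAWS <- c("reversible-MM", "irreversible-MM", "mass-action-symmetric",
                "lumped-supply")
.ROLES <- c("balanced", "boundary-unbalanced", "sink-pool", "phosphate-pool")

#' Read a model definition file
#'
#' Model files are JSON with top-level fields `name`, `temperature`,
#' `metabolites` and `reactions`; see the shipped
#' `system.file("extdata", "cbb_synechocystis.model", package = "cbbkin")`
#' for the schema.
#'
#' @param path path to a `.model` (JSON) file.
#' @return a model definition list suitable for [build_network()].
#' @export
read_model_definition <- function(path) {
  def <- jsonlite::read_json(path, simplifyVector = FALSE)
  def$metabolites <- lapply(def$metabolites, function(m) m)
  def
}

#' Write a model definition file
#'
#' @param def a model definition list, or a built network (its stored
#'   definition is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_definition <- function(def, path) {
  if (inherits(def, "cbb_network")) def <- def$definition
  jsonlite::write_json(def, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.def_err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.mets_table <- function(def) {
  ids <- vapply(def$metabolites, function(m) m$id, "")
  if (anyDuplicated(ids))
    .def_err("duplicated metabolite id(s): %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  role <- vapply(def$metabolites, function(m) m$role %||% "balanced", "")
  bad <- setdiff(unique(role), .ROLES)
  if (length(bad)) .def_err("unknown metabolite role(s): %s", paste(bad, collapse = ", "))
  getn <- function(m, f) { v <- m[[f]]; if (is.null(v)) NA_real_ else as.numeric(v) }
  cmin <- vapply(def$metabolites, getn, 0, f = "conc_min")
  cmax <- vapply(def$metabolites, getn, 0, f = "conc_max")
  act1 <- vapply(def$metabolites, function(m) isTRUE(m$activity_one), TRUE)
  nm <- vapply(def$metabolites, function(m) m$name %||% m$id, "")
  ok <- is.na(cmin) | is.na(cmax) | (cmin <= cmax & cmin > 0)
  if (!all(ok))
    .def_err("invalid concentration range for: %s", paste(ids[!ok], collapse = ", "))
  if (sum(role == "phosphate-pool") != 1L)
    .def_err("exactly one phosphate-pool metabolite is required (found %d)",
             sum(role == "phosphate-pool"))
  sampled <- (role == "balanced") |
    (role == "boundary-unbalanced" & !is.na(cmin) & !is.na(cmax) & cmin < cmax)
  if (any(role == "balanced" & (is.na(cmin) | is.na(cmax))))
    .def_err("balanced metabolites need a concentration range: %s",
             paste(ids[role == "balanced" & (is.na(cmin) | is.na(cmax))], collapse = ", "))
  fixed <- role %in% c("boundary-unbalanced") & !sampled
  data.frame(id = ids, name = nm, role = role, conc_min = cmin, conc_max = cmax,
             sampled = sampled, fixed = fixed, activity_one = act1,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build and validate a network model
#'
#' Validates the definition, assembles the stoichiometric matrix `S` over
#' balanced metabolites (declaration order for both rows and columns),
#' computes the conservation structure (`S = L %*% Sred`), compiles the
#' kinetic index structure, and reports structural counts. The number of
#' kinetic parameters is counted as: binding/inhibition/activation constants
#' (promiscuity-shared constants counted once) + one Vmax or rate constant
#' per reaction + one equilibrium constant per reaction with thermodynamic
#' data.
#'
#' @param def a model definition list ([read_model_definition()]) or a path
#'   to a model file.
#' @param temperature temperature in K used to derive equilibrium constants
#'   from standard transformed Gibbs energies; defaults to the definition's
#'   `temperature` field, else 298.15.
#' @return an object of class `cbb_network` with elements `metabolites`
#'   (data frame), `reactions` (list of reaction specs), `S`, `Sred`, `L`,
#'   `conservation` (left-nullspace basis, rows annihilate `S`), `kin`
#'   (compiled kinetic structure) and `counts`.
#' @examples
#' m <- build_network(two_metabolite_definition())
#' m$S            # 2 x 1 matrix (-1, +1)
#' @export
build_network <- function(def, temperature = NULL) {
  if (is.character(def)) def <- read_model_definition(def)
  stopifnot(is.list(def), !is.null(def$metabolites), !is.null(def$reactions))
  temperature <- temperature %||% (def$temperature %||% 298.15)
  mets <- .mets_table(def)

  rids <- vapply(def$reactions, function(r) r$id, "")
  if (anyDuplicated(rids))
    .def_err("duplicated reaction id(s): %s",
             paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (r in def$reactions) {
    if (is.null(r$rate_law)) .def_err("reaction '%s' has no rate law", r$id)
    if (!r$rate_law %in% .RATE_LAWS)
      .def_err("reaction '%s': unknown rate law '%s'", r$id, r$rate_law)
    st <- r$stoichiometry
    if (is.null(st) || !length(st)) .def_err("reaction '%s' has empty stoichiometry", r$id)
    unk <- setdiff(names(st), mets$id)
    if (length(unk))
      .def_err("reaction '%s': unknown metabolite(s) in stoichiometry: %s",
               r$id, paste(unk, collapse = ", "))
    if (!is.null(r$promiscuity_partner) && !r$promiscuity_partner %in% rids)
      .def_err("reaction '%s': promiscuity partner '%s' not found",
               r$id, r$promiscuity_partner)
    for (g in r$regulators %||% list()) {
      if (!g$metabolite %in% mets$id)
        .def_err("reaction '%s': regulator metabolite '%s' unknown", r$id, g$metabolite)
      if (!g$mode %in% c("competitive-inhibitor", "allosteric-inhibitor",
                         "allosteric-activator"))
        .def_err("reaction '%s': unknown regulator mode '%s'", r$id, g$mode)
    }
  }

  # stoichiometric matrix over balanced metabolites
  bal <- mets$id[mets$role == "balanced"]
  S <- matrix(0, length(bal), length(rids), dimnames = list(bal, rids))
  for (j in seq_along(def$reactions)) {
    st <- def$reactions[[j]]$stoichiometry
    for (mid in names(st)) if (mid %in% bal) S[mid, j] <- as.numeric(st[[mid]])
  }
  cons <- compute_conservation(S)

  kin <- .compile_kinetics(def, mets, temperature)

  model <- structure(list(
    name = def$name %||% "network",
    definition = def,
    temperature = temperature,
    metabolites = mets,
    reactions = def$reactions,
    reaction_ids = rids,
    S = S, Sred = cons$Sred, L = cons$L,
    conservation = cons$conservation,
    kin = kin,
    counts = list(
      n_reactions = length(rids),
      n_metabolites = nrow(mets),
      n_balanced = length(bal),
      n_K = kin$n_K,
      n_rate_constants = length(rids),
      n_keq = sum(!is.na(kin$dG0)),
      n_parameters = kin$n_K + length(rids) + sum(!is.na(kin$dG0)),
      n_conservation = nrow(cons$conservation),
      rank = nrow(cons$Sred))
  ), class = "cbb_network")
  model
}

#' @export
print.cbb_network <- function(x, ...) {
  co <- x$counts
  cat(sprintf("<cbb_network> %s\n", x$name))
  cat(sprintf("  %d reactions, %d metabolites (%d balanced, rank %d)\n",
              co$n_reactions, co$n_metabolites, co$n_balanced, co$rank))
  cat(sprintf("  %d kinetic parameters (%d K constants, %d Vmax/rate constants, %d Keq)\n",
              co$n_parameters, co$n_K, co$n_rate_constants, co$n_keq))
  cat(sprintf("  %d conservation relation(s)\n", co$n_conservation))
  invisible(x)
}

#' Conservation structure of a stoichiometric matrix
#'
#' Factorizes `S = L %*% Sred` where the rows of `Sred` are a maximal
#' linearly independent subset of the rows of `S` (the first such subset in
#' declaration order) and returns an integer basis of the left nullspace
#' (the conservation relations). Rank decisions and the nullspace basis are
#' computed by exact fraction-free integer elimination, so the factorization
#' is deterministic; `L` is then solved in double precision and verified
#' against `S` to 1e-12.
#'
#' @param S numeric matrix with integer entries (balanced metabolites x
#'   reactions).
#' @return list with `Sred`, `L`, `conservation` (matrix, possibly 0-row),
#'   and `kept` (indices of the independent rows of `S`).
#' @export
compute_conservation <- function(S) {
  stopifnot(is.matrix(S))
  if (any(abs(S - round(S)) > 1e-9))
    stop("compute_conservation() expects integer stoichiometric coefficients",
         call. = FALSE)
  S <- round(S)
  n <- nrow(S); m <- ncol(S)
  basis <- list()   # reduced echelon rows of [S | I]
  pivots <- integer(0)
  kept <- integer(0)
  gammas <- list()
  for (i in seq_len(n)) {
    r <- c(S[i, ], replace(numeric(n), i, 1))
    # eliminate at existing pivots (reduced echelon basis => order-free)
    for (k in seq_along(basis)) {
      p <- pivots[k]
      if (r[p] != 0) {
        b <- basis[[k]]
        r <- r * b[p] - b * r[p]
        g <- .gcd_vec(r)
        if (g > 1) r <- r / g
      }
    }
    if (any(r[seq_len(m)] != 0)) {
      p <- which(r[seq_len(m)] != 0)[1]
      # back-eliminate the new pivot from existing basis rows
      for (k in seq_along(basis)) {
        b <- basis[[k]]
        if (b[p] != 0) {
          b <- b * r[p] - r * b[p]
          g <- .gcd_vec(b)
          if (g > 1) b <- b / g
          basis[[k]] <- b
        }
      }
      basis[[length(basis) + 1L]] <- r
      pivots <- c(pivots, p)
      kept <- c(kept, i)
    } else {
      g <- r[m + seq_len(n)]
      d <- .gcd_vec(g)
      if (d > 1) g <- g / d
      if (g[i] < 0) g <- -g
      gammas[[length(gammas) + 1L]] <- g
    }
  }
  Sred <- S[kept, , drop = FALSE]
  if (length(kept)) {
    L <- t(qr.solve(t(Sred), t(S)))
    L[abs(L) < 1e-12] <- 0
  } else {
    L <- matrix(0, n, 0)
  }
  dimnames(L) <- list(rownames(S), rownames(S)[kept])
  gam <- if (length(gammas)) do.call(rbind, gammas) else matrix(0, 0, n)
  colnames(gam) <- rownames(S)
  if (length(kept) && max(abs(S - L %*% Sred)) > 1e-12)
    stop("internal error: S != L %*% Sred", call. = FALSE)
  list(Sred = Sred, L = L, conservation = gam, kept = kept)
}

# ---- kinetic structure compilation ------------------------------------------

# Builds, per reaction, index vectors into the metabolite table and into a
# flat vector of free kinetic constants. Promiscuity-shared constants (the
# `shared_with` field of a regulator) reference the owning reaction's KM slot
# and introduce no new constant.
.compile_kinetics <- function(def, mets, temperature) {
  rids <- vapply(def$reactions, function(r) r$id, "")
  midx <- stats::setNames(seq_len(nrow(mets)), mets$id)
  kinetic_part <- function(mid) {
    i <- midx[[mid]]
    !mets$activity_one[i] && mets$role[i] != "sink-pool"
  }

  reg <- new.env(parent = emptyenv())  # const_id -> flat index
  reg$tab <- list()                    # bookkeeping rows
  nK <- 0L
  get_const <- function(rid, kind, mid, new_ok = TRUE) {
    id <- paste(rid, kind, mid, sep = ":")
    if (!is.null(reg[[id]])) return(reg[[id]])
    if (!new_ok) return(NULL)
    nK <<- nK + 1L
    reg[[id]] <- nK
    reg$tab[[length(reg$tab) + 1L]] <- data.frame(
      const_id = id, reaction = rid, kind = kind, metabolite = mid,
      index = nK, stringsAsFactors = FALSE)
    nK
  }

  rxn <- vector("list", length(rids))
  dG0 <- rep(NA_real_, length(rids))
  # first pass: KM slots in declaration order (so shared references resolve
  # regardless of reaction order, a second pass wires regulators)
  for (j in seq_along(def$reactions)) {
    r <- def$reactions[[j]]
    st <- r$stoichiometry
    mids <- names(st)
    sgn <- vapply(mids, function(m) as.numeric(st[[m]]), 0)
    sub <- mids[sgn < 0]; prod <- mids[sgn > 0]
    ksub <- Filter(kinetic_part, sub)
    kprod <- Filter(kinetic_part, prod)
    reversible <- r$rate_law %in% c("reversible-MM", "lumped-supply")
    if (r$rate_law != "mass-action-symmetric") {
      for (m in ksub) get_const(r$id, "KM", m)
      if (reversible) for (m in kprod) get_const(r$id, "KM", m)
    }
    if (!is.null(r$dG0_prime)) dG0[j] <- as.numeric(r$dG0_prime)
  }
  # second pass: regulators and full per-reaction structure
  for (j in seq_along(def$reactions)) {
    r <- def$reactions[[j]]
    st <- r$stoichiometry
    mids <- names(st)
    sgn <- vapply(mids, function(m) as.numeric(st[[m]]), 0)
    sub <- mids[sgn < 0]; prod <- mids[sgn > 0]
    ksub <- Filter(kinetic_part, sub)
    kprod <- Filter(kinetic_part, prod)
    reversible <- r$rate_law %in% c("reversible-MM", "lumped-supply")
    q_keep <- vapply(mids, function(m) {
      i <- midx[[m]]
      !mets$activity_one[i] && mets$role[i] != "sink-pool"
    }, TRUE)

    comp_m <- integer(0); comp_k <- integer(0)
    act_m <- integer(0); act_k <- integer(0)
    inh_m <- integer(0); inh_k <- integer(0)
    for (g in r$regulators %||% list()) {
      if (!is.null(g$shared_with)) {
        ow <- g$shared_with
        k <- get_const(ow$reaction, "KM", ow$metabolite %||% g$metabolite,
                       new_ok = FALSE)
        if (is.null(k))
          .def_err("reaction '%s': shared constant %s:KM:%s not found",
                   r$id, ow$reaction, ow$metabolite %||% g$metabolite)
      } else {
        kind <- switch(g$mode, "competitive-inhibitor" = "KIc",
                       "allosteric-inhibitor" = "KIa",
                       "allosteric-activator" = "KA")
        k <- get_const(r$id, kind, g$metabolite)
      }
      mi <- midx[[g$metabolite]]
      if (g$mode == "competitive-inhibitor") {
        comp_m <- c(comp_m, mi); comp_k <- c(comp_k, k)
      } else if (g$mode == "allosteric-inhibitor") {
        inh_m <- c(inh_m, mi); inh_k <- c(inh_k, k)
      } else {
        act_m <- c(act_m, mi); act_k <- c(act_k, k)
      }
    }
    rxn[[j]] <- list(
      id = r$id, rate_law = r$rate_law,
      keq = if (!is.na(dG0[j])) exp(-dG0[j] / (.RGAS * temperature)) else NA_real_,
      sub_m = unname(midx[ksub]), sub_st = abs(sgn[match(ksub, mids)]),
      prod_m = unname(midx[kprod]), prod_st = abs(sgn[match(kprod, mids)]),
      km_sub = if (r$rate_law == "mass-action-symmetric") integer(0) else
        vapply(ksub, function(m) get_const(r$id, "KM", m, new_ok = FALSE), 0L),
      km_prod = if (reversible)
        vapply(kprod, function(m) get_const(r$id, "KM", m, new_ok = FALSE), 0L)
      else integer(0),
      q_m = unname(midx[mids[q_keep]]), q_st = unname(sgn[q_keep]),
      comp_m = comp_m, comp_k = comp_k,
      act_m = act_m, act_k = act_k,
      inh_m = inh_m, inh_k = inh_k,
      reversible = reversible)
  }
  const_tab <- if (length(reg$tab)) do.call(rbind, reg$tab) else
    data.frame(const_id = character(0), reaction = character(0),
               kind = character(0), metabolite = character(0),
               index = integer(0))
  list(rxn = rxn, n_K = nK, constants = const_tab, dG0 = dG0,
       reaction_ids = rids)
}
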