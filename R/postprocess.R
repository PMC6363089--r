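#' Ensemble-level statistics: stability deciles, saturation, FCC aggregation
#' and control-pattern clustering
#'
#' @name postprocess
NULL

#' Concentration densities in the most- and least-stable fMCS deciles
#'
#' Ranks the feasible metabolomes by their fraction of stable parameter
#' sets (ties broken deterministically by fMCS index), takes the top and
#' bottom 10%, and returns Gaussian kernel densities (Silverman bandwidth)
#' of the log10 concentrations per metabolite for the two groups. A
#' left-shifted top-decile density marks a metabolite whose low
#' concentrations favor stability.
#'
#' @param fmcs an `fmcs_set`.
#' @param stable_fraction per-fMCS summary (`ensemble$stable_fraction` or a
#'   data frame with `fmcs_index`, `fraction`).
#' @param metabolites subset of metabolite ids (default: all sampled).
#' @return list per metabolite: `top`, `bottom` (`stats::density` objects on
#'   log10 mM), `mean_diff` (mean log10 top minus bottom), plus attributes
#'   `top_idx`, `bottom_idx`.
#' @export
stability_decile_density <- function(fmcs, stable_fraction, metabolites = NULL) {
  sf <- as.data.frame(stable_fraction)
  n <- nrow(sf)
  if (n < 20)
    stop("deciles are undefined for fewer than 20 fMCSs (got ", n, ")",
         call. = FALSE)
  ndec <- floor(n / 10)
  ord_top <- order(-sf$fraction, sf$fmcs_index)
  ord_bot <- order(sf$fraction, sf$fmcs_index)
  top <- sf$fmcs_index[ord_top][seq_len(ndec)]
  bot <- sf$fmcs_index[ord_bot][seq_len(ndec)]
  mets <- metabolites %||% colnames(fmcs$concentrations)
  out <- lapply(mets, function(m) {
    lt <- log10(fmcs$concentrations[top, m])
    lb <- log10(fmcs$concentrations[bot, m])
    list(top = stats::density(lt, bw = "nrd0"),
         bottom = stats::density(lb, bw = "nrd0"),
         mean_diff = mean(lt) - mean(lb))
  })
  names(out) <- mets
  attr(out, "top_idx") <- top
  attr(out, "bottom_idx") <- bot
  out
}

#' Tidy table of decile densities
#'
#' @param dens result of [stability_decile_density()].
#' @return data frame `metabolite`, `group`, `log10_mM`, `density`.
#' @export
decile_density_table <- function(dens) {
  do.call(rbind, lapply(names(dens), function(m) {
    rbind(data.frame(metabolite = m, group = "top",
                     log10_mM = dens[[m]]$top$x, density = dens[[m]]$top$y),
          data.frame(metabolite = m, group = "bottom",
                     log10_mM = dens[[m]]$bottom$x, density = dens[[m]]$bottom$y))
  }))
}

#' Median and MAD of flux control coefficients over all stable sets
#'
#' Element-wise median and raw median absolute deviation (MAD, unscaled:
#' `median(|x - median(x)|)`) over every stable parameter set of every fMCS.
#'
#' @param fcc_records a `cbb_ensemble`, or a matrix with one flattened
#'   (targets x effectors) control matrix per row.
#' @return list with `median` and `mad` matrices (targets x effectors).
#' @export
aggregate_fcc <- function(fcc_records) {
  x <- if (inherits(fcc_records, "cbb_ensemble")) fcc_records$fcc else fcc_records
  if (is.null(x) || nrow(x) == 0) stop("no control-coefficient records", call. = FALSE)
  rid <- if (inherits(fcc_records, "cbb_ensemble")) fcc_records$reaction_ids else
    unique(sub("<-.*", "", colnames(x)))
  nr <- length(rid)
  med <- apply(x, 2, stats::median)
  md <- apply(x, 2, function(col) stats::median(abs(col - stats::median(col))))
  list(median = matrix(med, nr, nr, dimnames = list(target = rid, effector = rid)),
       mad = matrix(md, nr, nr, dimnames = list(target = rid, effector = rid)))
}

#' Saturation densities split by stability
#'
#' Densities of `log10([S]/K)` per binding-constant slot for stable versus
#' unstable parameter sets (the saturation analysis of enzyme-metabolite
#' pairs).
#'
#' @param ensemble a `cbb_ensemble` run with `saturation = TRUE`.
#' @param slots subset of constant ids (default: all KM slots).
#' @return list per slot: `stable`, `unstable` densities and `mean_diff`.
#' @export
saturation_stability_density <- function(ensemble, slots = NULL) {
  if (is.null(ensemble$saturation))
    stop("ensemble was run without saturation recording", call. = FALSE)
  ok <- !is.na(ensemble$stability$stable)
  st <- ensemble$stability$stable & ok
  un <- !ensemble$stability$stable & ok
  slots <- slots %||% colnames(ensemble$saturation)
  out <- lapply(slots, function(s) {
    xs <- ensemble$saturation[st, s]
    xu <- ensemble$saturation[un, s]
    list(stable = stats::density(xs, bw = "nrd0"),
         unstable = stats::density(xu, bw = "nrd0"),
         mean_diff = mean(xs) - mean(xu))
  })
  names(out) <- slots
  out
}

.tree_memberships <- function(hc) {
  res <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else res[[j]]
    res[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  res
}

# ordinary bootstrap support: the pre-PCA pattern dimensions are resampled
# with replacement, the scaling + PCA + clustering pipeline is re-run on each
# replicate, and each internal cluster of the reference tree is scored by the
# fraction of replicate trees containing it
.bootstrap_support <- function(M, ref_hc, make_tree, n_bootstrap, seed) {
  keys <- vapply(.tree_memberships(ref_hc), paste, "", collapse = "\r")
  hits <- numeric(length(keys))
  set.seed(seed)
  for (b in seq_len(n_bootstrap)) {
    cols <- sample.int(ncol(M), replace = TRUE)
    hb <- make_tree(M[, cols, drop = FALSE])
    if (is.null(hb)) next
    kb <- vapply(.tree_memberships(hb), paste, "", collapse = "\r")
    hits <- hits + (keys %in% kb)
  }
  hits / n_bootstrap
}

#' Cluster reactions by their control patterns
#'
#' Reproduces the control-pattern clustering pipeline: control coefficients
#' with absolute value below 1e-6 are rounded to zero, inverse-hyperbolic-sine
#' transformed, a random fraction of the pattern dimensions is subsampled,
#' columns are scaled to unit variance (constant columns dropped), the
#' patterns are rotated onto their principal components, and the resulting
#' reactions-by-components matrix is hierarchically clustered (correlation
#' distance, average linkage by default) with ordinary bootstrap support over
#' resampled pattern dimensions.
#'
#' "Effector" patterns describe how a reaction exerts control (its column of
#' the control matrix across targets and parameter sets); "target" patterns
#' describe how its flux is controlled.
#'
#' @param fcc_records a `cbb_ensemble` or a flattened FCC matrix (rows =
#'   stable sets).
#' @param what `"effector"` or `"target"`.
#' @param subsample_fraction fraction of pattern dimensions kept (default
#'   0.1).
#' @param n_bootstrap bootstrap replicates for cluster support.
#' @param seed RNG seed (subsample and bootstrap).
#' @param linkage linkage method for [stats::hclust()].
#' @return a `control_clustering`: list with `hclust`, `support` (per
#'   internal node, ordered as `hclust$merge`), `n_dimensions`,
#'   `dropped_constant`, `what`.
#' @export
cluster_control_patterns <- function(fcc_records,
                                     what = c("effector", "target"),
                                     subsample_fraction = 0.1,
                                     n_bootstrap = 100, seed = 1,
                                     linkage = "average") {
  what <- match.arg(what)
  x <- if (inherits(fcc_records, "cbb_ensemble")) fcc_records$fcc else fcc_records
  if (is.null(x) || nrow(x) == 0) stop("no control-coefficient records", call. = FALSE)
  rid <- if (inherits(fcc_records, "cbb_ensemble")) fcc_records$reaction_ids else
    unique(sub("<-.*", "", colnames(x)))
  nr <- length(rid); ns <- nrow(x)
  x <- ifelse(abs(x) < 1e-6, 0, x)
  x <- asinh(x)
  # rows of x are flattened (target, effector) matrices, target index fastest
  arr <- array(t(x), dim = c(nr, nr, ns))          # target x effector x set
  M <- if (what == "effector")
    matrix(aperm(arr, c(2, 1, 3)), nrow = nr)       # effector x (target, set)
  else
    matrix(arr, nrow = nr)                          # target x (effector, set)
  rownames(M) <- rid
  set.seed(derive_seed(seed, paste0("cluster-", what)))
  keep <- sort(sample.int(ncol(M), size = max(2, round(subsample_fraction * ncol(M)))))
  M <- M[, keep, drop = FALSE]
  dist_fun <- function(m) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    stats::as.dist(1 - cc)
  }
  dropped <- 0L
  make_rot <- function(m) {
    sdv <- apply(m, 2, stats::sd)
    ok <- sdv > 0 & is.finite(sdv)
    if (sum(ok) < 2) return(NULL)
    stats::prcomp(scale(m[, ok, drop = FALSE]), center = FALSE,
                  scale. = FALSE)$x               # reactions x components
  }
  make_tree <- function(m) {
    rot_b <- make_rot(m)
    if (is.null(rot_b)) return(NULL)
    stats::hclust(dist_fun(rot_b), method = linkage)
  }
  sdv0 <- apply(M, 2, stats::sd)
  dropped <- sum(sdv0 == 0 | !is.finite(sdv0))
  rot <- make_rot(M)
  if (is.null(rot)) stop("all pattern dimensions are constant", call. = FALSE)
  hc <- stats::hclust(dist_fun(rot), method = linkage)
  supp <- .bootstrap_support(M, hc, make_tree, n_bootstrap,
                             derive_seed(seed, paste0("boot-", what)))
  structure(list(hclust = hc, support = supp, n_dimensions = ncol(rot),
                 dropped_constant = dropped, what = what,
                 subsample_fraction = subsample_fraction,
                 n_bootstrap = n_bootstrap),
            class = "control_clustering")
}

#' @export
print.control_clustering <- function(x, ...) {
  cat(sprintf("<control_clustering> %s patterns, %d components, %d bootstraps\n",
              x$what, x$n_dimensions, x$n_bootstrap))
  invisible(x)
}

#' Export a control-pattern dendrogram as newick
#'
#' @param clustering a `control_clustering`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Base-graphics view of decile densities
#'
#' @param dens result of [stability_decile_density()].
#' @param metabolites subset to draw (default: first 9).
#' @export
plot_decile_densities <- function(dens, metabolites = NULL) {
  mets <- metabolites %||% utils::head(names(dens), 9)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(mets)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (m in mets) {
    d <- dens[[m]]
    xl <- range(d$top$x, d$bottom$x)
    yl <- range(d$top$y, d$bottom$y)
    plot(d$top, col = "purple", xlim = xl, ylim = yl, main = m,
         xlab = "log10 concentration (mM)")
    graphics::lines(d$bottom, col = "orange")
  }
  invisible(dens)
}
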