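#' Checkpointed analysis pipeline
#'
#' Orchestrates the full analysis — input fixtures, feasible-metabolome
#' sampling, ensemble parameterization with stability classification and
#' control analysis, and ensemble post-processing — with one on-disk
#' checkpoint per stage. Every stochastic stage derives its RNG stream from
#' `(master seed, stage name, block index)`, so rerunning a config is
#' bit-identical, any stage can be recomputed from the preceding checkpoint,
#' and results do not depend on work partitioning.
#'
#' Stage checkpoints (TSV + JSON sidecars) in `out_dir`:
#' `fluxes.tsv`, `fmcs.tsv` (+ `.json`), `stability.tsv`,
#' `stable_fraction.tsv`, `fcc_median.tsv`, `fcc_mad.tsv`,
#' `decile_densities.tsv`, `clustering_effector.nwk`,
#' `clustering_target.nwk`, `run.json`.
#'
#' @name pipeline_cli
NULL

.default_config <- function() {
  list(model = "cbb", ranges = "default", flux = "generate",
       max_rounds = 1e6, target_fmcs = 100, sets_per_fmcs = 1000,
       seed = 1, out_dir = "cbbkin_run", fcc = TRUE, saturation = TRUE,
       n_bootstrap = 100, subsample_fraction = 0.1, verbose = TRUE)
}

#' Read a pipeline run configuration
#'
#' @param path JSON file with any subset of the fields of
#'   [run_pipeline()]'s config (missing fields take defaults).
#' @return a config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(.default_config(), cfg)
}

.fmt_table <- function(d) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) sprintf("%.12g", x))
  d
}

.write_tsv <- function(d, path) {
  utils::write.table(.fmt_table(as.data.frame(d)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages run in order and checkpoint after each; an existing checkpoint is
#' reused (delete downstream files to recompute them — they are reproduced
#' identically). Any stage failure halts with a stage-tagged error and
#' leaves prior checkpoints in place.
#'
#' @param config a config list or a path to a JSON config. Fields: `model`
#'   (`"cbb"` or a model-file path), `ranges` (`"default"` or a TSV path),
#'   `flux` (`"generate"` or a TSV path), `max_rounds`, `target_fmcs`,
#'   `sets_per_fmcs`, `seed`, `out_dir`, `fcc`, `saturation`,
#'   `n_bootstrap`, `subsample_fraction`, `verbose`.
#' @return invisibly, a list with the model, fmcs, ensemble and summary
#'   objects.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  model <- stage("model", {
    if (identical(cfg$model, "cbb")) cbb_model() else build_network(cfg$model)
  })

  v0 <- stage("fluxes", {
    if (file.exists(pth("fluxes.tsv"))) {
      read_flux_table(pth("fluxes.tsv"))
    } else {
      v <- if (identical(cfg$flux, "generate"))
        generate_flux_vector(model) else
          generate_flux_vector(model, flux_file = cfg$flux)
      write_flux_table(v, pth("fluxes.tsv"))
      v
    }
  })
  model <- set_fluxes(model, v0)
  ranges <- stage("ranges", {
    if (identical(cfg$ranges, "default")) default_ranges(model) else
      read_ranges(cfg$ranges)
  })

  fmcs <- stage("sample-states", {
    if (file.exists(pth("fmcs.tsv"))) {
      .read_fmcs_checkpoint(model, pth("fmcs.tsv"))
    } else {
      fm <- generate_fmcs(model, ranges, max_rounds = cfg$max_rounds,
                          target = cfg$target_fmcs,
                          seed = derive_seed(cfg$seed, "sample-states"))
      write_fmcs(fm, pth("fmcs.tsv"))
      fm
    }
  })
  .msg(cfg$verbose, "states: %d fMCS (acceptance %.3g)", fmcs$n,
       fmcs$acceptance_rate)

  ens <- stage("ensemble", {
    if (file.exists(pth("stability.tsv")) && file.exists(pth("fcc.tsv"))) {
      .read_ensemble_checkpoint(model, cfg$out_dir)
    } else {
      e <- sample_ensemble(model, fmcs, sets_per_fmcs = cfg$sets_per_fmcs,
                           seed = derive_seed(cfg$seed, "ensemble"),
                           fcc = cfg$fcc, saturation = cfg$saturation,
                           verbose = cfg$verbose)
      .write_tsv(e$stability, pth("stability.tsv"))
      .write_tsv(e$stable_fraction, pth("stable_fraction.tsv"))
      if (!is.null(e$fcc))
        .write_tsv(data.frame(e$fcc_index, e$fcc, check.names = FALSE),
                   pth("fcc.tsv"))
      e
    }
  })
  .msg(cfg$verbose, "ensemble: median stable fraction %.1f%%",
       100 * stats::median(ens$stable_fraction$fraction))

  summary <- stage("postprocess", {
    agg <- if (!is.null(ens$fcc)) aggregate_fcc(ens) else NULL
    if (!is.null(agg)) {
      .write_tsv(data.frame(target = rownames(agg$median), agg$median,
                            check.names = FALSE), pth("fcc_median.tsv"))
      .write_tsv(data.frame(target = rownames(agg$mad), agg$mad,
                            check.names = FALSE), pth("fcc_mad.tsv"))
    }
    dens <- NULL
    if (fmcs$n >= 20) {
      dens <- stability_decile_density(fmcs, ens$stable_fraction)
      .write_tsv(decile_density_table(dens), pth("decile_densities.tsv"))
    }
    clus <- NULL
    if (!is.null(ens$fcc) && nrow(ens$fcc) >= 2) {
      clus <- list(
        effector = cluster_control_patterns(
          ens, "effector", subsample_fraction = cfg$subsample_fraction,
          n_bootstrap = cfg$n_bootstrap,
          seed = derive_seed(cfg$seed, "cluster")),
        target = cluster_control_patterns(
          ens, "target", subsample_fraction = cfg$subsample_fraction,
          n_bootstrap = cfg$n_bootstrap,
          seed = derive_seed(cfg$seed, "cluster")))
      export_dendrogram_newick(clus$effector, pth("clustering_effector.nwk"))
      export_dendrogram_newick(clus$target, pth("clustering_target.nwk"))
    }
    list(fcc = agg, deciles = dens, clustering = clus)
  })

  jsonlite::write_json(
    list(seed = cfg$seed, model = model$name,
         n_fmcs = fmcs$n, rounds = fmcs$rounds,
         acceptance_rate = fmcs$acceptance_rate,
         sets_per_fmcs = cfg$sets_per_fmcs,
         median_stable_fraction = stats::median(ens$stable_fraction$fraction),
         counts = ens$counts,
         package_version = as.character(utils::packageVersion("cbbkin"))),
    pth("run.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(model = model, fmcs = fmcs, ensemble = ens,
                 summary = summary, config = cfg))
}

.read_fmcs_checkpoint <- function(model, path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  conc <- as.matrix(tab[, !(names(tab) %in% c("fmcs_index", "ppool_multiple")),
                        drop = FALSE])
  th <- .thermo_matrix(model)
  ck <- check_feasibility(model, default_ranges(model), conc, tab$ppool_multiple)
  structure(list(concentrations = conc, ppool_multiple = tab$ppool_multiple,
                 dG = ck$dG, n = nrow(conc), rounds = side$rounds,
                 acceptance_rate = side$acceptance_rate,
                 rejections = side$rejections, seed = side$seed,
                 block_size = side$block_size),
            class = "fmcs_set")
}

.read_ensemble_checkpoint <- function(model, out_dir) {
  stab <- utils::read.delim(file.path(out_dir, "stability.tsv"))
  stab$stable <- as.logical(stab$stable)
  stab$marginal <- as.logical(stab$marginal)
  sf <- utils::read.delim(file.path(out_dir, "stable_fraction.tsv"))
  fcc <- NULL; prov <- NULL
  fp <- file.path(out_dir, "fcc.tsv")
  if (file.exists(fp)) {
    tab <- utils::read.delim(fp, check.names = FALSE)
    prov <- tab[, c("fmcs_index", "set_index")]
    fcc <- as.matrix(tab[, -(1:2), drop = FALSE])
  }
  structure(list(stability = stab, stable_fraction = sf, fcc = fcc,
                 fcc_index = prov, saturation = NULL,
                 reaction_ids = model$reaction_ids,
                 seed = NA_integer_,
                 sets_per_fmcs = max(stab$set_index),
                 counts = list()),
            class = "cbb_ensemble")
}
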