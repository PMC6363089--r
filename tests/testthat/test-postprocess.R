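# small synthetic helpers --------------------------------------------------

fake_fmcs <- function(n, mets = c("m1", "m2"), seed = 1) {
  set.seed(seed)
  conc <- matrix(runif_log10(n * length(mets), 0.01, 10), n,
                 dimnames = list(NULL, mets))
  structure(list(concentrations = conc, ppool_multiple = rep(2, n),
                 dG = NULL, n = n, rounds = n, acceptance_rate = 1,
                 seed = seed), class = "fmcs_set")
}

fake_ensemble <- function(fcc_rows, rids = NULL) {
  nr <- sqrt(ncol(fcc_rows))
  rids <- rids %||% sprintf("R%d", seq_len(nr))
  colnames(fcc_rows) <- as.vector(outer(rids, rids, function(t, e)
    paste(t, e, sep = "<-")))
  structure(list(fcc = fcc_rows, reaction_ids = rids,
                 stability = NULL, stable_fraction = NULL),
            class = "cbb_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("deciles are deterministic under ties and permutations", {
  fm <- fake_fmcs(40)
  sf <- data.frame(fmcs_index = 1:40, fraction = rep(0.5, 40))
  d1 <- stability_decile_density(fm, sf)
  expect_equal(attr(d1, "top_idx"), 1:4)      # tie-break by index
  expect_equal(attr(d1, "bottom_idx"), 1:4)   # both groups coincide
  expect_equal(d1$m1$mean_diff, 0)
  # permuting the summary rows changes nothing
  d2 <- stability_decile_density(fm, sf[sample(40), ])
  expect_equal(attr(d2, "top_idx"), attr(d1, "top_idx"))
  # fewer than 20 fMCS is an error
  expect_error(stability_decile_density(fake_fmcs(10),
                                        data.frame(fmcs_index = 1:10,
                                                   fraction = runif(10))),
               "fewer than 20")
})

test_that("a planted concentration-stability correlation shifts the decile densities", {
  fm <- fake_fmcs(100, seed = 5)
  # stability decreases with m1: the most stable decile has low m1
  frac <- 1 - rank(fm$concentrations[, "m1"]) / 101
  sf <- data.frame(fmcs_index = 1:100, fraction = frac)
  d <- stability_decile_density(fm, sf)
  expect_lt(d$m1$mean_diff, 0)
  expect_lt(abs(d$m2$mean_diff), 1)   # uncorrelated metabolite barely moves
})

test_that("FCC aggregation reproduces hand-computed medians and MADs", {
  x <- matrix(c(1, 2, 100), 3, 1)
  fe <- fake_ensemble(x)
  agg <- aggregate_fcc(fe)
  expect_equal(as.numeric(agg$median), 2)
  expect_equal(as.numeric(agg$mad), 1)
  # single record: median equals it, MAD 0
  agg1 <- aggregate_fcc(fake_ensemble(matrix(c(0.4), 1, 1)))
  expect_equal(as.numeric(agg1$median), 0.4)
  expect_equal(as.numeric(agg1$mad), 0)
  expect_error(aggregate_fcc(fake_ensemble(matrix(numeric(0), 0, 1))), "no control")
  # invariant to record ordering
  set.seed(2)
  y <- matrix(rnorm(25 * 9), 25, 9)
  a1 <- aggregate_fcc(fake_ensemble(y))
  a2 <- aggregate_fcc(fake_ensemble(y[sample(25), ]))
  expect_equal(a1, a2)
})

test_that("self-control medians dominate the diagonal in toy chains", {
  # ensemble of slightly noisy copies of the closed-form chain FCCs
  toy <- toy_linear_chain(4, "zero-order-supply")
  base <- as.numeric(toy$reference$fcc)
  set.seed(8)
  rows <- t(replicate(31, base + rnorm(16, sd = 1e-3)))
  agg <- aggregate_fcc(fake_ensemble(rows, rids = rownames(toy$reference$fcc)))
  expect_equal(agg$median["R1", "R1"], 1, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("the clustering pipeline transform is faithful: tiny values to zero, asinh elsewhere", {
  # two planted blocks of correlated effector patterns + check of rounding
  set.seed(31)
  nr <- 8; ns <- 60
  rids <- sprintf("R%d", 1:nr)
  rows <- matrix(0, ns, nr * nr)
  for (s in seq_len(ns)) {
    a <- rnorm(nr, sd = 2); b <- rnorm(nr, sd = 2)
    M <- cbind(sapply(1:4, function(i) a * runif(1, .8, 1.2)),
               sapply(1:4, function(i) b * runif(1, .8, 1.2)))
    rows[s, ] <- as.numeric(M)   # target x effector, effectors in two blocks
  }
  fe <- fake_ensemble(rows, rids = rids)
  cl <- cluster_control_patterns(fe, "effector", subsample_fraction = 0.5,
                                 n_bootstrap = 60, seed = 2)
  grp <- cutree(cl$hclust, k = 2)
  expect_true(all(grp[1:4] == grp[1]) && all(grp[5:8] == grp[5]) &&
                grp[1] != grp[5])
  # the two planted blocks are recovered with high bootstrap support
  memb <- local({
    hc <- cl$hclust
    res <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      pick <- function(j) if (j < 0) hc$labels[-j] else res[[j]]
      res[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
    }
    res
  })
  blockA <- which(vapply(memb, function(s) identical(s, sort(rids[1:4])), TRUE))
  expect_length(blockA, 1)
  expect_gte(cl$support[blockA], 0.95)
})

test_that("clustering is deterministic and merges duplicated patterns at height zero", {
  set.seed(12)
  rows <- matrix(rnorm(40 * 16), 40, 16)
  rows[, 13:16] <- rows[, 9:12]   # duplicate one effector pattern block
  fe <- fake_ensemble(rows, rids = c("a", "b", "c", "d"))
  c1 <- cluster_control_patterns(fe, "effector", subsample_fraction = 1,
                                 n_bootstrap = 40, seed = 9)
  c2 <- cluster_control_patterns(fe, "effector", subsample_fraction = 1,
                                 n_bootstrap = 40, seed = 9)
  expect_identical(c1$hclust$merge, c2$hclust$merge)
  expect_identical(c1$support, c2$support)
  # duplicated reactions c and d: first merge at height ~0 with full support
  pair <- which(vapply(seq_len(nrow(c1$hclust$merge)), function(i)
    setequal(c1$hclust$labels[-c1$hclust$merge[i, ]], c("c", "d")) &&
      all(c1$hclust$merge[i, ] < 0), TRUE))
  expect_length(pair, 1)
  expect_lt(c1$hclust$height[pair], 1e-10)
  expect_equal(c1$support[pair], 1)
})

test_that("dendrograms export as newick readable by ape", {
  set.seed(3)
  fe <- fake_ensemble(matrix(rnorm(30 * 25), 30, 25))
  cl <- cluster_control_patterns(fe, "target", subsample_fraction = 1,
                                 n_bootstrap = 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram_newick(cl, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, fe$reaction_ids)
})

test_that("asinh transform maps sub-threshold control values to exactly zero", {
  rows <- matrix(c(1e-7, -1e-8, 0.5, -2), 1, 4)
  fe <- fake_ensemble(rows, rids = c("u", "v"))
  # reproduce the documented pre-processing
  x <- ifelse(abs(fe$fcc) < 1e-6, 0, fe$fcc)
  expect_equal(asinh(x[1, 1:2]), c(0, 0), ignore_attr = TRUE)
  expect_equal(asinh(x[1, 3]), asinh(0.5), ignore_attr = TRUE)
})
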