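#' @keywords internal
"_PACKAGE"

# Gas constant, kJ mol^-1 K^-1
.RGAS <- 8.314e-3

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their RNG stream from a
#' `(master seed, stage name, block index)` triple so that results are
#' identical regardless of how work is chunked or which stages are re-run.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index integer block index (default 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage = "stage", index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(stage)) * (seq_along(utf8ToInt(as.character(stage))) %% 97 + 1))
  s <- (abs(master) %% 50021) * 40503 + (h %% 99991) * 1009 + (abs(index) %% 1e6) * 31
  as.integer(s %% 2147483561) + 1L
}

#' Log-uniform draws
#'
#' Draws whose `log10` is uniform on `[log10(lo), log10(hi)]` — the sampling
#' primitive used for concentrations, binding constants and the
#' phosphate-pool multiplier.
#'
#' @param n number of draws.
#' @param lo,hi positive bounds.
#' @return numeric vector of length `n`.
#' @export
runif_log10 <- function(n, lo, hi) {
  10^stats::runif(n, log10(lo), log10(hi))
}

# greatest common divisor of an integer vector (all values assumed integral)
.gcd_vec <- function(x) {
  g2 <- function(a, b) { a <- abs(a); b <- abs(b); while (b > 0) { t <- a %% b; a <- b; b <- t }; a }
  Reduce(g2, c(abs(x), 0))
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
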