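# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Radical-inverse (van der Corput) sequence in the given base.
van_der_corput <- function(n, base = 2L, start = 1L) {
  idx <- seq.int(start, length.out = n)
  out <- numeric(n)
  denom <- base
  while (any(idx > 0)) {
    out <- out + (idx %% base) / denom
    idx <- idx %/% base
    denom <- denom * base
  }
  out
}

#' Per-respondent quasi-random standard-normal draws
#'
#' Generates a matrix of standard-normal draws for simulated-likelihood
#' integration over the one-dimensional error component: a Halton (base 2)
#' sequence with the initial burn-in dropped, randomised by a seeded uniform
#' shift modulo 1 (a scrambling that preserves the low-discrepancy
#' structure), mapped through the normal quantile function and paired
#' antithetically (the second half of each respondent's draws mirrors the
#' first). Antithetic pairing reduces simulation variance and makes the
#' simulated likelihood exactly symmetric in the sign of the
#' error-component spread. Row `n` holds respondent `n`'s draws;
#' deterministic for a given seed.
#'
#' @param n_respondents Number of rows.
#' @param n_draws Number of draws per respondent; rounded up to an even
#'   number when antithetic pairing is on.
#' @param seed Integer seed for the scrambling shift.
#' @param burn Leading Halton points to discard (default 10).
#' @param antithetic Mirror the draws pairwise (default `TRUE`).
#' @return `n_respondents` x `n_draws` numeric matrix.
#' @export
halton_draws <- function(n_respondents, n_draws, seed = 1L, burn = 10L,
                         antithetic = TRUE) {
  n_respondents <- as.integer(n_respondents)
  n_draws <- as.integer(n_draws)
  n_gen <- if (antithetic) ceiling(n_draws / 2) else n_draws
  h <- van_der_corput(n_respondents * n_gen, base = 2L, start = burn + 1L)
  shift <- with_seed(seed, stats::runif(1))
  u <- (h + shift) %% 1
  # keep strictly inside (0,1) for qnorm
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  m <- matrix(stats::qnorm(u), nrow = n_respondents, ncol = n_gen, byrow = TRUE)
  if (antithetic) m <- cbind(m, -m)
  m
}

# Nearest positive-semidefinite repair by eigenvalue clipping; warns when a
# repair was needed.
nearest_psd <- function(m, tol = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1)) {
    return(m)
  }
  warning("covariance matrix is not positive semidefinite; clipping negative eigenvalues",
          call. = FALSE)
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

# Largest-remainder apportionment of n into parts proportional to weights.
apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    idx <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
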