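# Independent oracles and small fixtures shared across tests. Everything here
# is deliberately written without reusing the package's internals (plain
# loops, direct formulas) so the tests cross-check two code paths.

toy_catalog <- function() {
  structure(list(
    attribute_spec("eff", "Efficacy", "benefit", levels = c("lo", "hi"),
                   reference_index = 1L, numeric_values = c(0, 1), direction = 1L),
    attribute_spec("tox", "Toxicity", "risk", levels = c("none", "some"),
                   reference_index = 1L, numeric_values = c(0, 1), direction = -1L)
  ), class = "dce_catalog")
}

toy_catalog_23 <- function() {
  structure(list(
    attribute_spec("eff", "Efficacy", "benefit", levels = c("lo", "hi"),
                   reference_index = 1L, numeric_values = c(0, 1), direction = 1L),
    attribute_spec("tox", "Toxicity", "risk", levels = c("none", "mid", "bad"),
                   reference_index = 1L, numeric_values = c(0, 1, 2), direction = -1L)
  ), class = "dce_catalog")
}

# Reduced benefit-risk catalog used where fit speed matters.
small_catalog <- function() {
  structure(list(
    attribute_spec("orr", "Response rate", "benefit", levels = c("25", "55", "85"),
                   reference_index = 1L, numeric_values = c(25, 55, 85), direction = 1L),
    attribute_spec("os", "Survival", "benefit", levels = c("6mo", "15mo", "24mo"),
                   reference_index = 1L, numeric_values = c(6, 15, 24), direction = 1L),
    attribute_spec("crs", "CRS", "risk", levels = c("none", "high"),
                   reference_index = 1L, direction = -1L),
    attribute_spec("admin", "Administration", "administration",
                   levels = c("iv", "sc", "cart"), reference_index = 1L,
                   direction = 0L)
  ), class = "dce_catalog")
}

# Direct dummy coding of one alternative (1-based level indices), written
# independently of the package's code_levels().
oracle_code_row <- function(levels_row, catalog) {
  out <- numeric(0)
  for (j in seq_along(catalog)) {
    a <- catalog[[j]]
    ind <- numeric(length(a$levels))
    ind[levels_row[j]] <- 1
    out <- c(out, ind[-a$reference_index])
  }
  out
}

# Conditional-logit (sigma = 0) log-likelihood by direct probability
# computation over a long-format choice dataset.
oracle_clogit_loglik <- function(beta, data, catalog) {
  ll <- 0
  a_rows <- data[data$alternative == "A", , drop = FALSE]
  b_rows <- data[data$alternative == "B", , drop = FALSE]
  key_a <- paste(a_rows$respondent_id, a_rows$task_id)
  key_b <- paste(b_rows$respondent_id, b_rows$task_id)
  b_rows <- b_rows[match(key_a, key_b), , drop = FALSE]
  nms <- vapply(catalog, `[[`, "", "name")
  for (i in seq_len(nrow(a_rows))) {
    xa <- oracle_code_row(as.integer(a_rows[i, nms]), catalog)
    xb <- oracle_code_row(as.integer(b_rows[i, nms]), catalog)
    va <- sum(xa * beta)
    vb <- sum(xb * beta)
    pa <- exp(va) / (exp(va) + exp(vb))
    ll <- ll + log(if (a_rows$chosen[i] == 1L) pa else 1 - pa)
  }
  ll
}

# Choice probability of alternative A marginalised over the error component,
# by adaptive quadrature: integral of plogis(dv + sigma * e) dPhi(e).
oracle_mixed_prob <- function(dv, sigma) {
  stats::integrate(function(e) stats::plogis(dv + sigma * e) * stats::dnorm(e),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# Fisher information of a paired design at beta by direct summation of
# p (1 - p) d d' over tasks; independent of the package's info_matrix().
oracle_info <- function(A, B, beta, catalog) {
  K <- length(beta)
  M <- matrix(0, K, K)
  for (t in seq_len(nrow(A))) {
    d <- oracle_code_row(A[t, ], catalog) - oracle_code_row(B[t, ], catalog)
    v <- sum(d * beta)
    p <- 1 / (1 + exp(-v))
    M <- M + p * (1 - p) * (d %o% d)
  }
  M
}

oracle_d_error <- function(A, B, beta, catalog) {
  M <- oracle_info(A, B, beta, catalog)
  K <- ncol(M)
  dt <- det(M)
  if (!is.finite(dt) || dt <= 1e-300) return(Inf)
  dt^(-1 / K)
}

# All distinct unordered candidate tasks (pairs of distinct level profiles)
# of a catalog.
oracle_candidate_tasks <- function(catalog) {
  nlev <- vapply(catalog, function(a) length(a$levels), 1L)
  profiles <- as.matrix(expand.grid(lapply(nlev, seq_len)))
  colnames(profiles) <- NULL
  pairs <- utils::combn(nrow(profiles), 2)
  lapply(seq_len(ncol(pairs)), function(i) {
    list(a = profiles[pairs[1, i], ], b = profiles[pairs[2, i], ])
  })
}

# Exhaustive minimum D-error over all n_task-subsets of the candidate tasks.
oracle_min_d_error <- function(catalog, n_tasks, beta) {
  cands <- oracle_candidate_tasks(catalog)
  subsets <- utils::combn(length(cands), n_tasks)
  best <- Inf
  for (i in seq_len(ncol(subsets))) {
    sel <- cands[subsets[, i]]
    A <- do.call(rbind, lapply(sel, `[[`, "a"))
    B <- do.call(rbind, lapply(sel, `[[`, "b"))
    val <- oracle_d_error(A, B, beta, catalog)
    if (val < best) best <- val
  }
  best
}

# Build a dce_design directly from level matrices (bypasses the optimiser).
manual_design <- function(A, B, catalog, n_blocks = 1L, seed = 1L) {
  nms <- vapply(catalog, `[[`, "", "name")
  n <- nrow(A)
  per <- n %/% n_blocks
  tasks <- data.frame(task_id = seq_len(n),
                      block_id = rep(seq_len(n_blocks), each = per))
  for (j in seq_along(nms)) tasks[[paste0("A_", nms[j])]] <- A[, j]
  for (j in seq_along(nms)) tasks[[paste0("B_", nms[j])]] <- B[, j]
  tasks$is_stability_repeat <- FALSE
  tasks$source_task_id <- NA_integer_
  tasks$is_dominance_test <- FALSE
  dcebr:::new_design(tasks, n_blocks, seed, catalog)
}

# Shared quick-estimation settings for tests where speed matters.
quick_settings <- function(seed = 1L, n_draws = 60L) {
  ecl_settings(n_draws = n_draws, seed = seed)
}
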