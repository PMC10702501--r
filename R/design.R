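#' @useDynLib dcebr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- Design container ------------------------------------------------------

# A design is stored wide: one row per task with columns A_<attr> / B_<attr>
# holding 1-based level indices, plus validity flags. The catalog travels
# with the design so criteria and IO need no extra arguments.
new_design <- function(tasks, n_blocks, seed, catalog, d_error = NA_real_) {
  structure(
    list(tasks = tasks, n_blocks = as.integer(n_blocks), seed = as.integer(seed),
         catalog = as_catalog(catalog), d_error = d_error),
    class = "dce_design"
  )
}

#' @export
print.dce_design <- function(x, ...) {
  nexp <- sum(!x$tasks$is_stability_repeat & !x$tasks$is_dominance_test)
  nval <- nrow(x$tasks) - nexp
  cat(sprintf("<dce_design> %d experimental + %d validity tasks in %d blocks (D-error %.5g, seed %d)\n",
              nexp, nval, x$n_blocks, x$d_error, x$seed))
  invisible(x)
}

level_matrix <- function(design, alt = c("A", "B")) {
  alt <- match.arg(alt)
  nms <- catalog_names(design$catalog)
  as.matrix(design$tasks[, paste0(alt, "_", nms), drop = FALSE])
}

# Dummy-code a matrix of level indices (tasks x attributes, 1-based) into a
# tasks x K indicator matrix in coefficient_names() order.
code_levels <- function(lv, catalog) {
  K <- n_coefficients(catalog)
  X <- matrix(0, nrow(lv), K)
  col0 <- 0L
  for (j in seq_along(catalog)) {
    a <- catalog[[j]]
    nl <- length(a$levels)
    # column offset for level l (skipping the reference)
    pos <- integer(nl)
    pos[-a$reference_index] <- col0 + seq_len(nl - 1L)
    hit <- pos[lv[, j]]
    nz <- hit > 0L
    X[cbind(which(nz), hit[nz])] <- 1
    col0 <- col0 + nl - 1L
  }
  colnames(X) <- coefficient_names(catalog)
  X
}

experimental_tasks <- function(design) {
  design$tasks[!design$tasks$is_stability_repeat & !design$tasks$is_dominance_test, ,
               drop = FALSE]
}

# ---- D-error ---------------------------------------------------------------

# Fisher information of the paired conditional logit at `beta` for a matrix of
# alternative differences D (tasks x K): sum_t p_t (1-p_t) d_t d_t'.
info_matrix <- function(D, beta) {
  p <- stats::plogis(as.vector(D %*% beta))
  crossprod(D * sqrt(p * (1 - p)))
}

d_error_from_info <- function(M) {
  K <- ncol(M)
  if (qr(M)$rank < K) {
    return(Inf)
  }
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) {
    return(Inf)
  }
  exp(-as.numeric(ld$modulus) / K)
}

#' D-error of a choice design
#'
#' The determinant-based efficiency criterion of the paired conditional logit
#' model evaluated at prior coefficients: `det(I(beta)^-1)^(1/K)` where `I` is
#' the Fisher information accumulated over the experimental tasks and `K` the
#' number of part-worth coefficients. Lower is better. A design whose
#' information matrix is singular (no usable level variation) has D-error
#' `+Inf`, reported with a warning rather than an error.
#'
#' Validity tasks (stability repeats, dominance tests) are excluded: they are
#' engagement checks appended after optimisation, not part of the
#' information-bearing design.
#'
#' @param design A `dce_design`.
#' @param priors Named part-worth vector over [coefficient_names()] of the
#'   design's catalog, or `NULL` for the utility-neutral (all-zero) prior.
#' @return A single number; `+Inf` when the information matrix is singular.
#' @export
d_error <- function(design, priors = NULL) {
  stopifnot(inherits(design, "dce_design"))
  catalog <- design$catalog
  beta <- resolve_priors(priors, catalog)
  ex <- experimental_tasks(design)
  if (nrow(ex) < 1L) stop("design has no experimental tasks", call. = FALSE)
  sub <- design
  sub$tasks <- ex
  D <- code_levels(level_matrix(sub, "A"), catalog) -
    code_levels(level_matrix(sub, "B"), catalog)
  val <- d_error_from_info(info_matrix(D, beta))
  if (is.infinite(val)) {
    warning("singular information matrix: design carries no information on some coefficients",
            call. = FALSE)
  }
  val
}

resolve_priors <- function(priors, catalog) {
  nms <- coefficient_names(catalog)
  if (is.null(priors)) {
    return(stats::setNames(numeric(length(nms)), nms))
  }
  if (is.list(priors) && !is.null(priors$beta)) priors <- priors$beta
  missing <- setdiff(nms, names(priors))
  if (length(missing) > 0) {
    stop("priors lack coefficients: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  priors[nms]
}

# ---- Design generation (coordinate exchange) -------------------------------

task_signature <- function(arow, brow) {
  a <- paste(arow, collapse = ",")
  b <- paste(brow, collapse = ",")
  paste(min(a, b), max(a, b), sep = "|")
}

random_level_matrix <- function(n_tasks, nlev) {
  vapply(nlev, function(L) sample.int(L, n_tasks, replace = TRUE),
         integer(n_tasks))
}

#' Generate a D-efficient blocked choice design
#'
#' Builds a paired-alternative choice design by coordinate exchange: starting
#' from a random level assignment, single-cell level swaps are proposed for
#' every task, alternative and attribute in turn and accepted whenever they
#' strictly lower the D-error at the prior coefficients, for `n_sweeps` full
#' passes (stopping early when a pass makes no improvement). Tasks with
#' level-identical alternatives and duplicate tasks are never created. With
#' `n_restarts > 1` the search is repeated from independent random starts and
#' the best design kept. Tasks are then assigned to blocks greedily so as to
#' minimise the within-block imbalance of level counts. Deterministic for a
#' given seed.
#'
#' @param catalog A `dce_catalog` with at least 2 attributes.
#' @param n_tasks Number of experimental tasks (default 36), divisible by
#'   `n_blocks`.
#' @param n_blocks Number of blocks (default 3).
#' @param priors Prior part-worths for the D-error (default zero:
#'   utility-neutral design).
#' @param seed Integer seed.
#' @param n_sweeps Maximum coordinate-exchange passes (default 20).
#' @param n_restarts Independent random restarts (default 1).
#' @return A `dce_design` with its achieved D-error recorded.
#' @export
generate_design <- function(catalog, n_tasks = 36L, n_blocks = 3L, priors = NULL,
                            seed = 1L, n_sweeps = 20L, n_restarts = 1L) {
  catalog <- as_catalog(catalog)
  if (length(catalog) < 2L) {
    stop("catalog must have at least 2 attributes", call. = FALSE)
  }
  n_tasks <- as.integer(n_tasks)
  n_blocks <- as.integer(n_blocks)
  if (n_tasks %% n_blocks != 0L) {
    stop("n_tasks must be divisible by n_blocks", call. = FALSE)
  }
  beta <- resolve_priors(priors, catalog)
  nlev <- vapply(catalog, function(a) length(a$levels), 1L)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      res <- coordinate_exchange(catalog, n_tasks, beta, nlev, n_sweeps)
      if (is.null(best) || res$d_error < best$d_error) best <- res
    }
  })

  blocks <- assign_blocks(best$A, best$B, n_blocks, nlev)
  nms <- catalog_names(catalog)
  tasks <- data.frame(task_id = seq_len(n_tasks), block_id = blocks)
  for (j in seq_along(nms)) tasks[[paste0("A_", nms[j])]] <- best$A[, j]
  for (j in seq_along(nms)) tasks[[paste0("B_", nms[j])]] <- best$B[, j]
  tasks$is_stability_repeat <- FALSE
  tasks$source_task_id <- NA_integer_
  tasks$is_dominance_test <- FALSE
  new_design(tasks, n_blocks, seed, catalog, d_error = best$d_error)
}

# One coordinate-exchange run from a fresh random start; uses the current RNG
# stream. Returns level matrices and achieved D-error.
coordinate_exchange <- function(catalog, n_tasks, beta, nlev, n_sweeps) {
  J <- length(catalog)
  repeat {
    A <- random_level_matrix(n_tasks, nlev)
    B <- random_level_matrix(n_tasks, nlev)
    same <- rowSums(A != B) == 0L
    if (any(same)) {
      # re-draw one attribute of B where identical
      for (t in which(same)) {
        j <- sample.int(J, 1L)
        B[t, j] <- sample(setdiff(seq_len(nlev[j]), A[t, j]), 1L)
      }
    }
    sigs <- vapply(seq_len(n_tasks), function(t) task_signature(A[t, ], B[t, ]), "")
    if (!anyDuplicated(sigs)) break
  }

  XA <- code_levels(A, catalog)
  XB <- code_levels(B, catalog)
  D <- XA - XB
  p <- stats::plogis(as.vector(D %*% beta))
  w <- p * (1 - p)
  M <- crossprod(D * sqrt(w))
  cur <- d_error_from_info(M)

  col_offset <- c(0L, cumsum(nlev - 1L))
  row_for <- function(arow, brow) {
    # difference row of indicators for one task
    d <- numeric(ncol(D))
    for (j in seq_len(J)) {
      ref <- catalog[[j]]$reference_index
      if (arow[j] != ref) {
        d[col_offset[j] + arow[j] - (arow[j] > ref)] <- d[col_offset[j] + arow[j] - (arow[j] > ref)] + 1
      }
      if (brow[j] != ref) {
        d[col_offset[j] + brow[j] - (brow[j] > ref)] <- d[col_offset[j] + brow[j] - (brow[j] > ref)] - 1
      }
    }
    d
  }

  sigs <- vapply(seq_len(n_tasks), function(t) task_signature(A[t, ], B[t, ]), "")

  for (sweep in seq_len(n_sweeps)) {
    improved <- FALSE
    for (t in seq_len(n_tasks)) {
      for (alt in 1:2) {
        for (j in seq_len(J)) {
          lev_now <- if (alt == 1) A[t, j] else B[t, j]
          for (l in seq_len(nlev[j])) {
            if (l == lev_now) next
            arow <- A[t, ]
            brow <- B[t, ]
            if (alt == 1) arow[j] <- l else brow[j] <- l
            if (all(arow == brow)) next
            sig <- task_signature(arow, brow)
            if (sig %in% sigs[-t]) next
            dnew <- row_for(arow, brow)
            vnew <- as.numeric(crossprod(dnew, beta))
            pnew <- stats::plogis(vnew)
            wnew <- pnew * (1 - pnew)
            Mnew <- M - w[t] * tcrossprod(D[t, ]) + wnew * tcrossprod(dnew)
            val <- d_error_from_info(Mnew)
            if (val < cur - 1e-12) {
              if (alt == 1) A[t, j] <- l else B[t, j] <- l
              D[t, ] <- dnew
              w[t] <- wnew
              M <- Mnew
              cur <- val
              sigs[t] <- sig
              improved <- TRUE
            }
          }
        }
      }
    }
    if (!improved) break
  }
  list(A = A, B = B, d_error = cur)
}

# Greedy block assignment minimising the sum over attributes and levels of the
# squared deviation of within-block level counts (both alternatives counted)
# from the uniform expectation.
assign_blocks <- function(A, B, n_blocks, nlev) {
  n_tasks <- nrow(A)
  per_block <- n_tasks %/% n_blocks
  J <- ncol(A)
  counts <- lapply(seq_len(n_blocks), function(b) lapply(nlev, function(L) numeric(L)))
  sizes <- integer(n_blocks)
  blocks <- integer(n_tasks)
  for (t in seq_len(n_tasks)) {
    open <- which(sizes < per_block)
    cost <- vapply(open, function(b) {
      tot <- 0
      for (j in seq_len(J)) {
        cj <- counts[[b]][[j]]
        cj[A[t, j]] <- cj[A[t, j]] + 1
        cj[B[t, j]] <- cj[B[t, j]] + 1
        expct <- 2 * (sizes[b] + 1) / nlev[j]
        tot <- tot + sum((cj - expct)^2)
      }
      tot
    }, 1.0)
    b <- open[which.min(cost)]
    blocks[t] <- b
    sizes[b] <- sizes[b] + 1L
    for (j in seq_len(J)) {
      counts[[b]][[j]][A[t, j]] <- counts[[b]][[j]][A[t, j]] + 1
      counts[[b]][[j]][B[t, j]] <- counts[[b]][[j]][B[t, j]] + 1
    }
  }
  blocks
}

# ---- Validity tasks --------------------------------------------------------

best_level <- function(a) {
  if (a$direction == 1L) length(a$levels) else if (a$direction == -1L) 1L else NA_integer_
}
worst_level <- function(a) {
  if (a$direction == 1L) 1L else if (a$direction == -1L) length(a$levels) else NA_integer_
}

#' Append stability and dominance validity tasks to each block
#'
#' For every block, two engagement-check tasks are appended: (a) a stability
#' task that repeats, level for level, the experimental task at position
#' `repeat_position` within the block, and (b) a dominance task in which
#' alternative A is weakly better than alternative B on every ordered
#' attribute (higher benefit, lower risk) and strictly better on at least
#' one, with the administration mode held equal across the pair so that no
#' preference over administration is assumed. The dominance task's
#' non-dominant alternative is taken from a seed-determined experimental task
#' of the block.
#'
#' @param design A `dce_design` without validity tasks.
#' @param repeat_position 1-based position of the task to repeat within each
#'   block (default 3, i.e. the third task the respondent sees).
#' @return A `dce_design` with `2 * n_blocks` additional flagged tasks.
#' @export
add_validity_tasks <- function(design, repeat_position = 3L) {
  stopifnot(inherits(design, "dce_design"))
  catalog <- design$catalog
  nms <- catalog_names(catalog)
  tasks <- design$tasks
  if (any(tasks$is_stability_repeat | tasks$is_dominance_test)) {
    stop("design already has validity tasks", call. = FALSE)
  }
  per_block <- nrow(tasks) / design$n_blocks
  repeat_position <- as.integer(repeat_position)
  if (repeat_position < 1L || repeat_position > per_block) {
    stop("repeat_position out of range: blocks have ", per_block, " tasks",
         call. = FALSE)
  }
  admin_like <- which(vapply(catalog, function(a) a$direction == 0L, TRUE))
  ordered <- which(vapply(catalog, function(a) a$direction != 0L, TRUE))
  next_id <- max(tasks$task_id)
  extra <- list()
  for (b in seq_len(design$n_blocks)) {
    btasks <- tasks[tasks$block_id == b, , drop = FALSE]
    btasks <- btasks[order(btasks$task_id), , drop = FALSE]
    src <- btasks[repeat_position, , drop = FALSE]
    stab <- src
    next_id <- next_id + 1L
    stab$task_id <- next_id
    stab$is_stability_repeat <- TRUE
    stab$source_task_id <- src$task_id
    # dominance task: base the non-dominant alternative on a seed-chosen task
    base <- with_seed(design$seed * 1000L + b, {
      btasks[sample.int(nrow(btasks), 1L), , drop = FALSE]
    })
    dom <- base
    next_id <- next_id + 1L
    dom$task_id <- next_id
    dom$is_dominance_test <- TRUE
    dom$source_task_id <- NA_integer_
    for (j in ordered) {
      dom[[paste0("A_", nms[j])]] <- best_level(catalog[[j]])
    }
    for (j in admin_like) {
      dom[[paste0("B_", nms[j])]] <- dom[[paste0("A_", nms[j])]]
    }
    # guarantee at least one strict difference on an ordered attribute
    strict <- any(vapply(ordered, function(j) {
      dom[[paste0("B_", nms[j])]] != dom[[paste0("A_", nms[j])]]
    }, TRUE))
    if (!strict) {
      j <- ordered[1]
      dom[[paste0("B_", nms[j])]] <- worst_level(catalog[[j]])
    }
    extra[[length(extra) + 1L]] <- stab
    extra[[length(extra) + 1L]] <- dom
  }
  design$tasks <- rbind(tasks, do.call(rbind, extra))
  rownames(design$tasks) <- NULL
  design
}

# Which alternative (if any) weakly dominates the other on ordered attributes.
# Returns "A", "B" or NA.
dominant_alternative <- function(task_row, catalog) {
  nms <- catalog_names(catalog)
  better_a <- 0L
  better_b <- 0L
  for (j in seq_along(catalog)) {
    a <- catalog[[j]]
    if (a$direction == 0L) next
    la <- task_row[[paste0("A_", nms[j])]]
    lb <- task_row[[paste0("B_", nms[j])]]
    # utility-ordered position: higher is better
    pa <- if (a$direction == 1L) la else -la
    pb <- if (a$direction == 1L) lb else -lb
    if (pa > pb) better_a <- better_a + 1L
    if (pb > pa) better_b <- better_b + 1L
  }
  if (better_a > 0L && better_b == 0L) return("A")
  if (better_b > 0L && better_a == 0L) return("B")
  NA_character_
}

# ---- IO --------------------------------------------------------------------

#' Write or read a design as a long-format CSV
#'
#' One row per alternative with columns `task_id`, `block_id`, `alternative`
#' (A/B), one column per attribute holding the 0-based level index,
#' `is_stability_repeat` and `is_dominance_test`. Writing then reading then
#' writing again is byte-identical.
#'
#' @param design A `dce_design`.
#' @param path File path.
#' @param catalog Catalog used to interpret the attribute columns on read.
#' @return `read_design()` returns a `dce_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "dce_design"))
  nms <- catalog_names(design$catalog)
  long <- do.call(rbind, lapply(c("A", "B"), function(alt) {
    out <- data.frame(task_id = design$tasks$task_id,
                      block_id = design$tasks$block_id,
                      alternative = alt)
    for (nm in nms) out[[nm]] <- design$tasks[[paste0(alt, "_", nm)]] - 1L
    out$is_stability_repeat <- as.integer(design$tasks$is_stability_repeat)
    out$is_dominance_test <- as.integer(design$tasks$is_dominance_test)
    out
  }))
  long <- long[order(long$task_id, long$alternative), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, catalog) {
  catalog <- as_catalog(catalog)
  nms <- catalog_names(catalog)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task_id", "block_id", "alternative", nms,
            "is_stability_repeat", "is_dominance_test")
  missing <- setdiff(need, names(long))
  if (length(missing) > 0) {
    stop("design file lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- long[long$alternative == "A", ]
  b <- long[long$alternative == "B", ]
  a <- a[order(a$task_id), ]
  b <- b[order(b$task_id), ]
  tasks <- data.frame(task_id = a$task_id, block_id = a$block_id)
  for (nm in nms) tasks[[paste0("A_", nm)]] <- a[[nm]] + 1L
  for (nm in nms) tasks[[paste0("B_", nm)]] <- b[[nm]] + 1L
  tasks$is_stability_repeat <- a$is_stability_repeat == 1
  tasks$source_task_id <- NA_integer_
  tasks$is_dominance_test <- a$is_dominance_test == 1
  # reconstruct stability sources by matching levels within block
  lev_cols <- c(paste0("A_", nms), paste0("B_", nms))
  for (i in which(tasks$is_stability_repeat)) {
    cand <- which(tasks$block_id == tasks$block_id[i] &
                    !tasks$is_stability_repeat & !tasks$is_dominance_test)
    hit <- cand[vapply(cand, function(s) {
      all(tasks[s, lev_cols] == tasks[i, lev_cols])
    }, TRUE)]
    if (length(hit) >= 1L) tasks$source_task_id[i] <- tasks$task_id[hit[1]]
  }
  design <- new_design(tasks, n_blocks = length(unique(tasks$block_id)),
                       seed = NA_integer_, catalog = catalog)
  exp_only <- design
  exp_only$tasks <- experimental_tasks(design)
  D <- code_levels(level_matrix(exp_only, "A"), catalog) -
    code_levels(level_matrix(exp_only, "B"), catalog)
  design$d_error <- d_error_from_info(info_matrix(D, resolve_priors(NULL, catalog)))
  design
}
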