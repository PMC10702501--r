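test_that("d_error matches a brute-force information matrix on a toy design", {
  toy <- toy_catalog()
  A <- rbind(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  B <- rbind(c(2L, 2L), c(1L, 2L), c(2L, 1L), c(1L, 1L))
  des <- manual_design(A, B, toy)
  zero <- stats::setNames(numeric(2), coefficient_names(toy))
  expect_equal(d_error(des, zero), oracle_d_error(A, B, zero, toy),
               tolerance = 1e-12)
  pri <- stats::setNames(c(0.7, -0.4), coefficient_names(toy))
  expect_equal(d_error(des, pri), oracle_d_error(A, B, pri, toy),
               tolerance = 1e-12)
})

test_that("a design without level variation has infinite D-error", {
  toy <- toy_catalog()
  A <- matrix(1L, 36, 2)
  B <- matrix(2L, 36, 2)
  des <- manual_design(A, B, toy)
  expect_warning(val <- d_error(des), "singular")
  expect_identical(val, Inf)
})

test_that("d_error is invariant to swapping the two alternatives of a task", {
  toy <- toy_catalog_23()
  set.seed(11)
  A <- cbind(sample(1:2, 6, TRUE), sample(1:3, 6, TRUE))
  B <- cbind(sample(1:2, 6, TRUE), sample(1:3, 6, TRUE))
  keep <- rowSums(A != B) > 0
  A <- A[keep, , drop = FALSE]
  B <- B[keep, , drop = FALSE]
  pri <- stats::setNames(c(0.3, -0.2, -0.5), coefficient_names(toy))
  swapped <- manual_design(B, A, toy)
  expect_equal(d_error(manual_design(A, B, toy), pri), d_error(swapped, pri),
               tolerance = 1e-12)
})

test_that("generate_design returns a valid blocked 36-task design", {
  cat8 <- default_catalog()
  des <- generate_design(cat8, 36, 3, seed = 1, n_sweeps = 3)
  expect_s3_class(des, "dce_design")
  expect_equal(nrow(des$tasks), 36L)
  expect_equal(as.integer(table(des$tasks$block_id)), rep(12L, 3))
  expect_false(anyDuplicated(des$tasks$task_id) > 0)

  nms <- vapply(cat8, function(a) a$name, "")
  A <- as.matrix(des$tasks[, paste0("A_", nms)])
  B <- as.matrix(des$tasks[, paste0("B_", nms)])
  nlev <- vapply(cat8, function(a) length(a$levels), 1L)
  for (j in seq_along(nms)) {
    expect_true(all(A[, j] %in% seq_len(nlev[j])))
    expect_true(all(B[, j] %in% seq_len(nlev[j])))
  }
  # no task has level-identical alternatives, no duplicated tasks
  expect_true(all(rowSums(A != B) > 0))
  sigs <- vapply(seq_len(36), function(t) {
    dcebr:::task_signature(A[t, ], B[t, ])
  }, "")
  expect_false(anyDuplicated(sigs) > 0)
  # recorded D-error agrees with recomputation
  expect_equal(d_error(des), des$d_error, tolerance = 1e-10)
  # deterministic per seed
  des2 <- generate_design(cat8, 36, 3, seed = 1, n_sweeps = 3)
  expect_equal(des$tasks, des2$tasks)
})

test_that("coordinate exchange beats a random design at the same seed", {
  cat8 <- default_catalog()
  opt <- generate_design(cat8, 36, 3, seed = 1, n_sweeps = 5)
  rnd <- generate_design(cat8, 36, 3, seed = 1, n_sweeps = 0)
  expect_lt(opt$d_error, rnd$d_error)
})

test_that("coordinate exchange attains the exhaustive minimum on toy catalogs", {
  for (cat_fn in list(toy_catalog, toy_catalog_23)) {
    toy <- cat_fn()
    K <- n_coefficients(toy)
    zero <- stats::setNames(numeric(K), coefficient_names(toy))
    opt_min <- oracle_min_d_error(toy, 4, zero)
    des <- generate_design(toy, 4, 1, seed = 2, n_sweeps = 10, n_restarts = 5)
    expect_equal(des$d_error, opt_min, tolerance = 1e-8)
  }
})

test_that("optimised designs keep level frequencies near uniform", {
  cat8 <- default_catalog()
  des <- generate_design(cat8, 36, 3, seed = 1, n_sweeps = 20)
  nms <- vapply(cat8, function(a) a$name, "")
  for (j in seq_along(cat8)) {
    lv <- c(des$tasks[[paste0("A_", nms[j])]], des$tasks[[paste0("B_", nms[j])]])
    tab <- tabulate(lv, length(cat8[[j]]$levels))
    unif <- length(lv) / length(cat8[[j]]$levels)
    expect_true(all(abs(tab - unif) <= 0.25 * unif),
                info = paste("attribute", nms[j]))
  }
})

test_that("generate_design validates its inputs", {
  one_attr <- structure(list(default_catalog()[[1]]), class = "dce_catalog")
  expect_error(generate_design(one_attr, 4, 1), "at least 2 attributes")
  expect_error(generate_design(default_catalog(), 10, 3), "divisible")
})

test_that("validity tasks append a stability repeat and a dominance task per block", {
  cat8 <- default_catalog()
  des <- generate_design(cat8, 36, 3, seed = 4, n_sweeps = 2)
  full <- add_validity_tasks(des, repeat_position = 3)
  expect_equal(nrow(full$tasks), 36L + 2L * 3L)

  nms <- vapply(cat8, function(a) a$name, "")
  lev_cols <- c(paste0("A_", nms), paste0("B_", nms))
  stab <- full$tasks[full$tasks$is_stability_repeat, ]
  expect_equal(nrow(stab), 3L)
  for (i in seq_len(3)) {
    src <- full$tasks[full$tasks$task_id == stab$source_task_id[i], ]
    expect_equal(src$block_id, stab$block_id[i])
    # the repeated task is the third task of its block as seen by respondents
    btasks <- des$tasks[des$tasks$block_id == stab$block_id[i], ]
    expect_equal(src$task_id, sort(btasks$task_id)[3])
    expect_equal(unname(unlist(stab[i, lev_cols])), unname(unlist(src[lev_cols])))
  }

  dom <- full$tasks[full$tasks$is_dominance_test, ]
  expect_equal(nrow(dom), 3L)
  for (i in seq_len(3)) {
    expect_equal(dcebr:::dominant_alternative(dom[i, ], cat8), "A")
    # benefits weakly higher, risks weakly lower for the dominant alternative
    for (a in cat8) {
      la <- dom[[paste0("A_", a$name)]][i]
      lb <- dom[[paste0("B_", a$name)]][i]
      if (a$direction == 1L) expect_gte(la, lb)
      if (a$direction == -1L) expect_lte(la, lb)
      if (a$direction == 0L) expect_equal(la, lb)  # administration held equal
    }
  }

  expect_error(add_validity_tasks(des, repeat_position = 13), "out of range")
})

test_that("design CSV round trip is byte-identical and rebuilds sources", {
  cat8 <- default_catalog()
  des <- add_validity_tasks(generate_design(cat8, 12, 2, seed = 5, n_sweeps = 2))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_design(des, p1)
  back <- read_design(p1, cat8)
  write_design(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # stability sources are reconstructed from level identity
  expect_equal(back$tasks$source_task_id[back$tasks$is_stability_repeat],
               des$tasks$source_task_id[des$tasks$is_stability_repeat])
})
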