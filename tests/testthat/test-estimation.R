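# Shared small dataset for estimation tests (moderate size keeps fits fast).
est_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cat8 <- default_catalog()
      des <- add_validity_tasks(generate_design(cat8, 36, 3, seed = 21,
                                                n_sweeps = 2))
      prof <- simulate_profiles(150, seed = 22)
      beta <- utilities_from_importance(cat8, rrmm_rai_scores()) * 0.04
      truth <- true_model(beta, sigma = 0.8, optout_rate = 0.05)
      data <- simulate_choices(des, prof, truth, seed = 23)
      cache <<- list(catalog = cat8, design = des, profiles = prof,
                     beta = beta, truth = truth, data = data)
    }
    cache
  }
})

test_that("the design matrix dummy-codes against each reference level", {
  fx <- est_fixture()
  dm <- build_design_matrix(fx$data, fx$catalog)
  expect_equal(ncol(dm$X), 23L)
  expect_equal(dm$labels, coefficient_names(fx$catalog))

  # a row at the reference level of every attribute codes to zero
  ref_row <- fx$data[1, ]
  for (a in fx$catalog) ref_row[[a$name]] <- a$reference_index
  dm_ref <- build_design_matrix(ref_row, fx$catalog)
  expect_equal(unname(dm_ref$X[1, ]), numeric(23))

  # row order permutes with the data
  set.seed(24)
  perm <- sample(nrow(fx$data))
  dm_perm <- build_design_matrix(fx$data[perm, ], fx$catalog)
  expect_equal(dm_perm$X, dm$X[perm, ], ignore_attr = TRUE)

  bad <- fx$data
  bad$orr[5] <- 99L
  expect_error(build_design_matrix(bad, fx$catalog), "row 5")
})

test_that("simulated likelihood collapses to the conditional logit at sigma 0", {
  fx <- est_fixture()
  sub <- fx$data[fx$data$respondent_id <= 12, ]
  dm <- build_design_matrix(sub, fx$catalog)
  draws <- halton_draws(12, 25, seed = 3)
  beta <- fx$beta
  val <- simulated_loglik(c(beta, 0), dm, draws)
  expect_equal(val, oracle_clogit_loglik(beta, sub, fx$catalog),
               tolerance = 1e-10)

  # neutral parameters: every binary choice has probability 1/2
  n_choices <- sum(sub$alternative == "A")
  expect_equal(simulated_loglik(c(numeric(23), 0), dm, draws),
               n_choices * log(0.5), tolerance = 1e-12)

  expect_error(simulated_loglik(c(numeric(23), NA), dm, draws), "non-finite")
  expect_error(simulated_loglik(numeric(5), dm, draws), "parameters")
})

test_that("the simulated likelihood is stable in the number of draws", {
  fx <- est_fixture()
  sub <- fx$data[fx$data$respondent_id <= 60, ]
  dm <- build_design_matrix(sub, fx$catalog)
  par <- c(fx$beta, 0.8)
  v1 <- simulated_loglik(par, dm, halton_draws(60, 300, seed = 1))
  v2 <- simulated_loglik(par, dm, halton_draws(60, 600, seed = 1))
  expect_lt(abs(v1 - v2) / 60, 1e-3)
})

test_that("the optimum improves on the null and is invariant to relabelling", {
  fx <- est_fixture()
  fit <- estimate_ecl(fx$data, fx$catalog, quick_settings(seed = 5))
  expect_true(fit$converged)
  expect_gt(fit$log_likelihood, fit$null_log_likelihood)
  expect_gte(fit$estimates[["sigma"]], 0)

  # relabel A <-> B everywhere: part-worths unchanged, |sigma| unchanged
  flipped <- fx$data
  flipped$alternative <- ifelse(flipped$alternative == "A", "B", "A")
  fit2 <- estimate_ecl(flipped, fx$catalog, quick_settings(seed = 5))
  expect_equal(fit2$estimates[1:23], fit$estimates[1:23], tolerance = 1e-6)
  expect_equal(fit2$estimates[["sigma"]], fit$estimates[["sigma"]],
               tolerance = 1e-6)
})

test_that("estimates are stable under respondent permutation", {
  fx <- est_fixture()
  fit <- estimate_ecl(fx$data, fx$catalog, quick_settings(seed = 6))
  permuted <- fx$data
  ids <- sort(unique(fx$data$respondent_id))
  set.seed(25)
  new_ids <- stats::setNames(sample(ids), ids)  # random relabelling
  permuted$respondent_id <- unname(new_ids[as.character(permuted$respondent_id)])
  fit2 <- estimate_ecl(permuted, fx$catalog, quick_settings(seed = 6))
  # draws reattach to different respondents, so equality is to MSL noise
  expect_equal(fit2$estimates, fit$estimates, tolerance = 0.08)
})

test_that("validity tasks are excluded from the likelihood by default", {
  fx <- est_fixture()
  fit <- estimate_ecl(fx$data, fx$catalog, quick_settings(seed = 7))
  expect_equal(fit$n_choices, 150L * 12L)
  fit_all <- estimate_ecl(fx$data, fx$catalog,
                          ecl_settings(n_draws = 60L, seed = 7,
                                       include_validity = TRUE))
  expect_equal(fit_all$n_choices, 150L * 14L)
})

test_that("a spread of zero is recovered as negligible", {
  # Wald z for sigma is unreliable at the boundary (the likelihood is even
  # in sigma), so the check is on the magnitude of the estimate itself:
  # negligible against the Gumbel scale of 1 and far below the 0.8 of the
  # study-condition generator.
  cat8 <- default_catalog()
  des <- generate_design(cat8, 36, 3, seed = 31, n_sweeps = 2)
  prof <- simulate_profiles(250, seed = 32)
  beta <- utilities_from_importance(cat8, rrmm_rai_scores()) * 0.04
  for (rep in 1:5) {
    data <- simulate_choices(des, prof, true_model(beta, sigma = 0),
                             seed = 40 + rep)
    fit <- estimate_ecl(data, cat8, ecl_settings(n_draws = 80, seed = rep))
    expect_lt(abs(fit$estimates[["sigma"]]), 0.4)
  }
})

test_that("estimation guards its preconditions", {
  fx <- est_fixture()
  one_task <- fx$data[fx$data$task_id == fx$data$task_id[1], ]
  expect_error(estimate_ecl(one_task, fx$catalog), "at least two tasks")
})

test_that("fits serialise to JSON and CSV", {
  fx <- est_fixture()
  fit <- estimate_ecl(fx$data[fx$data$respondent_id <= 60, ], fx$catalog,
                      quick_settings(seed = 8, n_draws = 40))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_fit(fit, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$log_likelihood, fit$log_likelihood, tolerance = 1e-12)
  expect_equal(length(back$estimates), 24L)
  tab <- utils::read.csv(cp)
  expect_equal(tab$estimate, unname(fit$estimates), tolerance = 1e-10)
})
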