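# Fixture: one dataset without true interactions, one with a caregiver
# effect on ORR, both on the small catalog for speed.
het_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- small_catalog()
      des <- generate_design(sc, 12, 2, seed = 51, n_sweeps = 3)
      prof <- simulate_profiles(300, seed = 52)
      imp <- c(orr = 40, os = 30, crs = 20, admin = 10)
      beta <- utilities_from_importance(sc, imp) * 0.03
      shift <- c("orr:55" = 0.5, "orr:85" = 1.0)
      data0 <- simulate_choices(des, prof, true_model(beta, sigma = 0.5),
                                seed = 53)
      data1 <- simulate_choices(
        des, prof,
        true_model(beta, sigma = 0.5,
                   interactions = list(has_caregiver = shift)),
        seed = 53
      )
      sg <- subgroup_spec("has_caregiver", rule = 1,
                          labels = c("no_caregiver", "caregiver"))
      cache <<- list(catalog = sc, design = des, profiles = prof, beta = beta,
                     shift = shift, data0 = data0, data1 = data1, sg = sg)
    }
    cache
  }
})

test_that("subgroup rules must split respondents into two non-empty groups", {
  fx <- het_fixture()
  all_in <- subgroup_spec("has_caregiver", rule = c(0, 1))
  expect_error(fit_with_interactions(fx$data0, fx$catalog, all_in,
                                     quick_settings()),
               "two non-empty groups")
  expect_error(
    fit_with_interactions(fx$data0, fx$catalog,
                          subgroup_spec("nonexistent", rule = 1),
                          quick_settings()),
    "not found"
  )
})

test_that("interacted fits nest the pooled fit and recover null interactions", {
  fx <- het_fixture()
  pooled <- estimate_ecl(fx$data0, fx$catalog, quick_settings(seed = 54))
  inter <- fit_with_interactions(fx$data0, fx$catalog, fx$sg,
                                 quick_settings(seed = 54))
  # nesting: the larger model cannot fit worse (same data, same draw seed)
  expect_gte(inter$log_likelihood, pooled$log_likelihood - 1e-4)
  # no true interactions: every interaction coefficient is within 3 SEs of 0
  z <- inter$estimates[inter$int_cols] / inter$std_errors[inter$int_cols]
  expect_true(all(abs(z) < 3))
  # base part-worths agree with the pooled fit within their own uncertainty
  # (the base columns are informed mainly by the smaller group 0)
  dev <- abs(inter$estimates[inter$base_cols] -
               pooled$estimates[seq_along(inter$base_cols)])
  expect_true(all(dev <= 3 * inter$std_errors[inter$base_cols]))
})

test_that("group utilities are base plus interaction by construction", {
  fx <- het_fixture()
  inter <- fit_with_interactions(fx$data1, fx$catalog, fx$sg,
                                 quick_settings(seed = 55))
  u0 <- subgroup_utilities(inter, "no_caregiver")
  u1 <- subgroup_utilities(inter, "caregiver")
  expect_equal(unname(u1 - u0), unname(inter$estimates[inter$int_cols]),
               tolerance = 1e-12)
  expect_error(subgroup_utilities(inter, "martians"), "unknown group")

  plain <- estimate_ecl(fx$data0, fx$catalog, quick_settings(seed = 55))
  expect_error(subgroup_utilities(plain, "caregiver"), "no subgroup")
})

test_that("a true caregiver ORR shift is detected and shifts subgroup RAI", {
  fx <- het_fixture()
  inter <- fit_with_interactions(fx$data1, fx$catalog, fx$sg,
                                 ecl_settings(n_draws = 100, seed = 56))
  est <- inter$estimates[inter$int_cols]
  se <- inter$std_errors[inter$int_cols]
  for (nm in names(fx$shift)) {
    k <- paste0(nm, ":has_caregiver")
    expect_lt(abs(est[[k]] - fx$shift[[nm]]), 3 * se[[k]])
  }
  r0 <- subgroup_rai(inter, fx$catalog, "no_caregiver", n_draws = 300, seed = 57)
  r1 <- subgroup_rai(inter, fx$catalog, "caregiver", n_draws = 300, seed = 57)
  expect_equal(sum(r0$importance_percent), 100, tolerance = 1e-9)
  expect_equal(sum(r1$importance_percent), 100, tolerance = 1e-9)
  expect_gt(r1$importance_percent[r1$attribute == "orr"],
            r0$importance_percent[r0$attribute == "orr"])
})

test_that("zero interactions give the two groups identical RAI", {
  fx <- het_fixture()
  inter <- fit_with_interactions(fx$data0, fx$catalog, fx$sg,
                                 quick_settings(seed = 58))
  zeroed <- inter
  zeroed$estimates[zeroed$int_cols] <- 0
  r0 <- compute_rai(subgroup_utilities(zeroed, "no_caregiver"), fx$catalog)
  r1 <- compute_rai(subgroup_utilities(zeroed, "caregiver"), fx$catalog)
  expect_equal(r1$importance_percent, r0$importance_percent)
})

test_that("complementing the rule swaps the subgroup outputs", {
  fx <- het_fixture()
  inter <- fit_with_interactions(fx$data1, fx$catalog, fx$sg,
                                 quick_settings(seed = 59))
  sg_flip <- subgroup_spec("has_caregiver", rule = 0,
                           labels = c("caregiver", "no_caregiver"))
  inter_flip <- fit_with_interactions(fx$data1, fx$catalog, sg_flip,
                                      quick_settings(seed = 59))
  r_cg <- subgroup_rai(inter, fx$catalog, "caregiver", n_draws = 200, seed = 60)
  r_cg_flip <- subgroup_rai(inter_flip, fx$catalog, "caregiver",
                            n_draws = 200, seed = 60)
  # same group of people, opposite parametrisation: equal up to optimiser noise
  expect_equal(r_cg$importance_percent, r_cg_flip$importance_percent,
               tolerance = 0.5)

  cmp <- subgroup_comparison(inter, fx$catalog, n_draws = 200, seed = 61)
  expect_equal(nrow(cmp$rai), 4L)
  expect_equal(nrow(cmp$interactions), 7L)
  expect_true(all(c("rai_no_caregiver", "rai_caregiver") %in% names(cmp$rai)))
})
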