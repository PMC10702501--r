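# ---- Subgroup specification ------------------------------------------------

#' Define a binary subgroup of respondents
#'
#' A subgroup is a binarisation of one respondent covariate: a predicate
#' function (e.g. `function(age) age >= 60`) or a set of values
#' (`rule = "US"` puts respondents with `country == "US"` in group 1). The
#' two label strings name group 0 (rule FALSE) and group 1 (rule TRUE).
#'
#' @param covariate Covariate column name in the choice data / profiles.
#' @param rule A function of the covariate returning logical, or a vector of
#'   values defining membership of group 1.
#' @param labels Character pair `c(group0, group1)`.
#' @return An object of class `dce_subgroup`.
#' @export
subgroup_spec <- function(covariate, rule, labels = c("group0", "group1")) {
  stopifnot(length(labels) == 2L)
  structure(list(covariate = covariate, rule = rule,
                 labels = as.character(labels)),
            class = "dce_subgroup")
}

# 0/1 indicator per row of a choice dataset (or profile table); errors when
# the rule does not split respondents into two non-empty groups.
subgroup_indicator <- function(subgroup, data) {
  stopifnot(inherits(subgroup, "dce_subgroup"))
  if (!subgroup$covariate %in% names(data)) {
    stop("covariate '", subgroup$covariate, "' not found", call. = FALSE)
  }
  v <- data[[subgroup$covariate]]
  z <- if (is.function(subgroup$rule)) subgroup$rule(v) else v %in% subgroup$rule
  z <- as.logical(z)
  if (anyNA(z)) stop("subgroup rule produced NA", call. = FALSE)
  by_resp <- tapply(z, data$respondent_id, function(x) x[1])
  if (all(by_resp) || !any(by_resp)) {
    stop("subgroup rule must split respondents into two non-empty groups",
         call. = FALSE)
  }
  as.numeric(z)
}

# ---- Interacted fit --------------------------------------------------------

#' Fit the error-component logit with attribute-by-subgroup interactions
#'
#' Augments the design matrix with one interaction column per part-worth
#' (the level indicator multiplied by the 0/1 group indicator) and estimates
#' all coefficients jointly; group-0 utilities are the base part-worths and
#' group-1 utilities are base plus interaction.
#'
#' @param data A `dce_choices` data.frame containing the covariate.
#' @param catalog A `dce_catalog`.
#' @param subgroup A [subgroup_spec()].
#' @param settings See [ecl_settings()].
#' @return An `ecl_fit` carrying the interaction column indices and group
#'   labels.
#' @export
fit_with_interactions <- function(data, catalog, subgroup,
                                  settings = ecl_settings()) {
  estimate_ecl(data, catalog, settings = settings, subgroup = subgroup)
}

#' Group-specific part-worth utilities from an interacted fit
#'
#' @param fit An `ecl_fit` from [fit_with_interactions()].
#' @param group One of the fit's two group labels.
#' @return Named part-worth vector for the requested group.
#' @export
subgroup_utilities <- function(fit, group) {
  stopifnot(inherits(fit, "ecl_fit"))
  if (is.null(fit$group)) {
    stop("fit has no subgroup interactions", call. = FALSE)
  }
  gi <- match(group, fit$group$labels)
  if (is.na(gi)) {
    stop("unknown group '", group, "'; fit has groups: ",
         paste(fit$group$labels, collapse = ", "), call. = FALSE)
  }
  base <- fit$estimates[fit$base_cols]
  if (gi == 2L) base <- base + unname(fit$estimates[fit$int_cols])
  names(base) <- fit$labels[fit$base_cols]
  base
}

#' RAI scores for one subgroup of an interacted fit
#'
#' Computes relative attribute importance on the group-specific utilities
#' (base part-worths for group 0, base plus interaction for group 1), with
#' Krinsky-Robb confidence intervals propagating the joint covariance of
#' base and interaction coefficients.
#'
#' @param fit An `ecl_fit` from [fit_with_interactions()].
#' @param catalog A `dce_catalog`.
#' @param group One of the fit's two group labels.
#' @param n_draws,seed Krinsky-Robb settings.
#' @return A `dce_rai` data.frame.
#' @export
subgroup_rai <- function(fit, catalog, group, n_draws = 2000L, seed = 1L) {
  catalog <- as_catalog(catalog)
  util <- subgroup_utilities(fit, group)
  gi <- match(group, fit$group$labels)
  point <- compute_rai(util, catalog)
  if (!is.null(fit$covariance)) {
    idx <- c(fit$base_cols, fit$int_cols)
    sims <- kr_draws(fit$estimates[idx], fit$covariance[idx, idx, drop = FALSE],
                     n_draws, seed)
    nb <- length(fit$base_cols)
    rai_sims <- apply(sims, 1, function(par) {
      b <- par[seq_len(nb)]
      if (gi == 2L) b <- b + par[nb + seq_len(nb)]
      names(b) <- fit$labels[fit$base_cols]
      rng <- attribute_ranges(b, catalog)
      100 * rng / sum(rng)
    })
    qs <- apply(rai_sims, 1, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    point$ci_low <- qs[1, ]
    point$ci_high <- qs[2, ]
  }
  attr(point, "group") <- group
  attr(point, "n_kr_draws") <- as.integer(n_draws)
  attr(point, "seed") <- as.integer(seed)
  point
}

#' Two-group subgroup comparison report
#'
#' Side-by-side RAI scores (with CIs) for both groups of an interacted fit,
#' plus the interaction coefficients with z statistics and nominal
#' (uncorrected, exploratory) p-values.
#'
#' @param fit An `ecl_fit` from [fit_with_interactions()].
#' @param catalog A `dce_catalog`.
#' @param n_draws,seed Krinsky-Robb settings.
#' @return A list with `rai` (two-group table) and `interactions`
#'   (coefficient table).
#' @export
subgroup_comparison <- function(fit, catalog, n_draws = 2000L, seed = 1L) {
  catalog <- as_catalog(catalog)
  labs <- fit$group$labels
  r0 <- subgroup_rai(fit, catalog, labs[1], n_draws = n_draws, seed = seed)
  r1 <- subgroup_rai(fit, catalog, labs[2], n_draws = n_draws, seed = seed + 1L)
  rai <- data.frame(
    attribute = r0$attribute,
    rai_group0 = r0$importance_percent, ci_low_group0 = r0$ci_low,
    ci_high_group0 = r0$ci_high,
    rai_group1 = r1$importance_percent, ci_low_group1 = r1$ci_low,
    ci_high_group1 = r1$ci_high,
    stringsAsFactors = FALSE
  )
  names(rai) <- sub("group0", labs[1], names(rai), fixed = TRUE)
  names(rai) <- sub("group1", labs[2], names(rai), fixed = TRUE)
  est <- fit$estimates[fit$int_cols]
  se <- fit$std_errors[fit$int_cols]
  z <- est / se
  interactions <- data.frame(
    term = fit$labels[fit$int_cols], estimate = unname(est),
    std_error = unname(se), z = unname(z),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  list(rai = rai, interactions = interactions,
       covariate = fit$group$covariate, labels = labs)
}
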