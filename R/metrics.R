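# ---- Relative attribute importance -----------------------------------------

# Accept a named part-worth vector, a list with a beta element, or an
# ecl_fit (base part-worths only).
as_beta <- function(params) {
  if (inherits(params, "ecl_fit")) {
    return(params$estimates[params$base_cols])
  }
  if (is.list(params) && !is.null(params$beta)) {
    return(params$beta)
  }
  params
}

attribute_ranges <- function(beta, catalog) {
  vapply(catalog, function(a) {
    u <- attribute_utilities(beta, a)
    max(u) - min(u)
  }, 1.0)
}

#' Relative attribute importance (RAI) scores
#'
#' For each attribute, the utility range is the difference between its best
#' and worst level utility (the reference level, at utility zero, included);
#' the RAI score is the attribute's range as a percentage of the sum of all
#' ranges. Scores are conditional on the level ranges studied and sum to
#' 100.
#'
#' @param params Named part-worth vector covering all non-reference levels
#'   (or an `ecl_fit`, whose base part-worths are used).
#' @param catalog A `dce_catalog`.
#' @return A data.frame of class `dce_rai` with columns `attribute`, `label`,
#'   `utility_range`, `importance_percent`, `ci_low`, `ci_high` (the CIs are
#'   `NA` here; see [rai_confidence_intervals()]).
#' @export
compute_rai <- function(params, catalog) {
  catalog <- as_catalog(catalog)
  beta <- as_beta(params)
  rng <- attribute_ranges(beta, catalog)
  if (all(rng == 0)) {
    stop("all attribute utility ranges are zero: no preference information",
         call. = FALSE)
  }
  out <- data.frame(
    attribute = catalog_names(catalog),
    label = vapply(catalog, `[[`, "", "label"),
    utility_range = unname(rng),
    importance_percent = unname(100 * rng / sum(rng)),
    ci_low = NA_real_, ci_high = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("dce_rai", "data.frame")
  out
}

#' Krinsky-Robb confidence intervals for RAI scores
#'
#' Draws coefficient vectors from the multivariate normal at the fit's
#' estimates and covariance, computes the RAI scores for every draw and
#' reports the 2.5 and 97.5 percentiles around the point scores.
#' Deterministic per seed. A covariance that is not positive semidefinite is
#' repaired by eigenvalue clipping with a warning.
#'
#' @param fit An `ecl_fit` with a valid covariance matrix.
#' @param catalog A `dce_catalog`.
#' @param n_draws Number of Krinsky-Robb draws (default 2000).
#' @param seed Integer seed.
#' @return A `dce_rai` data.frame with `ci_low` / `ci_high` filled in;
#'   attributes `n_kr_draws` and `seed` record the settings.
#' @export
rai_confidence_intervals <- function(fit, catalog, n_draws = 2000L, seed = 1L) {
  stopifnot(inherits(fit, "ecl_fit"))
  if (is.null(fit$covariance)) {
    stop("fit has no covariance matrix", call. = FALSE)
  }
  catalog <- as_catalog(catalog)
  idx <- fit$base_cols
  beta <- fit$estimates[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  point <- compute_rai(beta, catalog)
  sims <- kr_draws(beta, V, n_draws, seed)
  rai_sims <- apply(sims, 1, function(b) {
    names(b) <- names(beta)
    rng <- attribute_ranges(b, catalog)
    100 * rng / sum(rng)
  })
  qs <- apply(rai_sims, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  point$ci_low <- qs[1, ]
  point$ci_high <- qs[2, ]
  attr(point, "n_kr_draws") <- as.integer(n_draws)
  attr(point, "seed") <- as.integer(seed)
  point
}

# Multivariate-normal parameter draws with PSD repair; returns n x K matrix.
kr_draws <- function(mu, V, n_draws, seed) {
  V <- nearest_psd(V)
  with_seed(seed, MASS::mvrnorm(n_draws, mu = mu, Sigma = V))
}

# ---- Minimal acceptable benefit / marginal rates of substitution -----------

#' Minimal acceptable benefit for a risk or administration change
#'
#' Computes how much of a benefit attribute (on its natural scale:
#' percentage points of overall response rate, or months of overall
#' survival) exactly offsets the utility loss of moving a risk or
#' administration attribute from one level to another. The default
#' `"linear"` method linearises the benefit attribute over its full level
#' range: one unit of benefit is worth `range / scale_width` utility, so the
#' required benefit is `delta_u * scale_width / range`. The `"piecewise"`
#' method instead inverts the piecewise-linear utility function of the
#' benefit attribute from its reference level and returns `NA` (with a
#' warning) when the utility loss exceeds what the benefit scale can offset.
#'
#' When a covariance matrix is supplied, Krinsky-Robb percentile confidence
#' intervals are attached.
#'
#' @param params Named part-worth vector (or `ecl_fit`).
#' @param catalog A `dce_catalog`.
#' @param risk_attribute Name of the attribute whose change is queried.
#' @param to_level Level label the attribute moves to (from `from_level`).
#' @param benefit_attribute Name of the compensating benefit attribute; must
#'   carry numeric level values.
#' @param from_level Level label the change starts from; defaults to the
#'   risk attribute's reference level.
#' @param covariance Optional covariance of the part-worths (ordered as
#'   `params`); an `ecl_fit` supplied as `params` provides its own.
#' @param n_draws,seed Krinsky-Robb settings.
#' @param method `"linear"` (default) or `"piecewise"`.
#' @return A data.frame of class `dce_mab` with one row: the queried change,
#'   the benefit scale, `required_benefit` and (when a covariance is
#'   available) `ci_low` / `ci_high`.
#' @export
compute_mab <- function(params, catalog, risk_attribute, to_level,
                        benefit_attribute, from_level = NULL,
                        covariance = NULL, n_draws = 2000L, seed = 1L,
                        method = c("linear", "piecewise")) {
  catalog <- as_catalog(catalog)
  method <- match.arg(method)
  if (inherits(params, "ecl_fit") && is.null(covariance) &&
      !is.null(params$covariance)) {
    covariance <- params$covariance[params$base_cols, params$base_cols,
                                    drop = FALSE]
  }
  beta <- as_beta(params)
  risk <- catalog_attribute(catalog, risk_attribute)
  benefit <- catalog_attribute(catalog, benefit_attribute)
  if (is.null(benefit$numeric_values)) {
    stop("benefit attribute '", benefit_attribute, "' has no numeric scale",
         call. = FALSE)
  }
  from_level <- from_level %||% risk$levels[risk$reference_index]
  if (!to_level %in% risk$levels) {
    stop("unknown level '", to_level, "' for attribute '", risk_attribute, "'",
         call. = FALSE)
  }
  if (!from_level %in% risk$levels) {
    stop("unknown level '", from_level, "' for attribute '", risk_attribute, "'",
         call. = FALSE)
  }

  required <- function(b) {
    u_risk <- attribute_utilities(b, risk)
    du <- u_risk[from_level] - u_risk[to_level]
    u_ben <- attribute_utilities(b, benefit)
    if (method == "linear") {
      slope <- (max(u_ben) - min(u_ben)) / benefit$scale_width
      if (slope == 0) return(NA_real_)
      unname(du / slope)
    } else {
      piecewise_benefit(du, u_ben, benefit)
    }
  }
  point <- required(beta)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(covariance)) {
    sims <- kr_draws(beta, covariance, n_draws, seed)
    vals <- apply(sims, 1, function(b) {
      names(b) <- names(beta)
      required(b)
    })
    ci <- stats::quantile(vals, probs = c(0.025, 0.975), names = FALSE,
                          na.rm = TRUE)
  }
  out <- data.frame(
    attribute = risk_attribute, from_level = from_level, to_level = to_level,
    benefit_attribute = benefit_attribute,
    benefit_scale = paste0("per ", benefit$scale_width, "-unit range"),
    required_benefit = point, ci_low = ci[1], ci_high = ci[2],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("dce_mab", "data.frame")
  out
}

# Invert the piecewise-linear benefit utility from the reference value:
# smallest benefit increment m (in scale units) with
# u(x_ref + m) - u(x_ref) = du.
piecewise_benefit <- function(du, u_ben, benefit) {
  x <- benefit$numeric_values
  ref <- benefit$reference_index
  # utility gain relative to reference as a function of the numeric value
  gain <- u_ben - u_ben[ref]
  if (du < min(gain) - 1e-12 || du > max(gain) + 1e-12) {
    warning("utility change exceeds the benefit attribute's range; MAB undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (any(diff(gain) <= 0) && du != 0) {
    # non-monotone utilities: fall back to the first crossing
    for (i in seq_len(length(x) - 1)) {
      g0 <- gain[i]; g1 <- gain[i + 1]
      if ((g0 - du) * (g1 - du) <= 0 && g1 != g0) {
        xx <- x[i] + (du - g0) / (g1 - g0) * (x[i + 1] - x[i])
        return(unname(xx - x[ref]))
      }
    }
    return(NA_real_)
  }
  xx <- stats::approx(gain, x, xout = du, ties = "ordered")$y
  unname(xx - x[ref])
}

#' All benefit-risk trade-offs of the default study design
#'
#' Convenience wrapper around [compute_mab()] computing the ten trade-offs
#' reported by the study: the four risk attributes at their worst level and
#' the CAR-T administration bundle versus IV/SC every 3 weeks, each against
#' both the overall-response-rate scale (percentage points) and the
#' overall-survival scale (months).
#'
#' @param params Named part-worth vector or `ecl_fit`.
#' @param catalog A `dce_catalog` (default [default_catalog()]).
#' @param ... Passed to [compute_mab()] (e.g. `covariance`, `n_draws`,
#'   `seed`).
#' @return A `dce_mab` data.frame with ten rows.
#' @export
mab_table <- function(params, catalog = default_catalog(), ...) {
  queries <- list(
    list(attr = "crs", to = "high"),
    list(attr = "ocular", to = "60"),
    list(attr = "neuropathy", to = "50"),
    list(attr = "diarrhea", to = "20"),
    list(attr = "admin", to = "cart_once")
  )
  out <- do.call(rbind, lapply(c("orr", "os"), function(ben) {
    do.call(rbind, lapply(queries, function(q) {
      compute_mab(params, catalog, q$attr, q$to, ben, ...)
    }))
  }))
  rownames(out) <- NULL
  out
}

# ---- Utility construction from importance weights --------------------------

#' Part-worth utilities with ranges proportional to importance weights
#'
#' Builds a part-worth vector whose per-attribute utility ranges are
#' proportional to the supplied importance weights: benefit utilities rise
#' linearly in the numeric level values from 0 at the reference to the
#' weight at the best level; risk utilities fall linearly to minus the
#' weight at the worst level; for unordered attributes the reference level
#' sits at 0, the final level at minus the weight, and intermediate levels
#' at interior values. [compute_rai()] on the result reproduces the weights
#' (normalised to percentages) exactly.
#'
#' @param catalog A `dce_catalog`.
#' @param importance Named positive vector, one entry per attribute.
#' @return Named part-worth vector over [coefficient_names()].
#' @export
utilities_from_importance <- function(catalog, importance) {
  catalog <- as_catalog(catalog)
  nms <- catalog_names(catalog)
  missing <- setdiff(nms, names(importance))
  if (length(missing) > 0) {
    stop("importance lacks attributes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(importance <= 0)) stop("importance weights must be positive", call. = FALSE)
  beta <- numeric(0)
  for (a in catalog) {
    imp <- importance[[a$name]]
    L <- length(a$levels)
    if (a$direction != 0L && !is.null(a$numeric_values)) {
      v <- a$numeric_values
      frac <- (v - min(v)) / (max(v) - min(v))
      u <- if (a$direction == 1L) imp * frac else -imp * frac
    } else if (a$direction != 0L) {
      # ordered without a numeric scale: equally spaced positions
      pos <- (seq_len(L) - a$reference_index) / max(abs(seq_len(L) - a$reference_index))
      u <- if (a$direction == 1L) imp * pos else -imp * pos
    } else {
      # unordered: reference at 0, last level at -imp, interiors in between
      u <- -imp * 0.5 * seq_len(L) / L
      u[a$reference_index] <- 0
      u[L] <- -imp
    }
    u <- u - u[a$reference_index]
    bu <- u[-a$reference_index]
    names(bu) <- paste0(a$name, ":", a$levels[-a$reference_index])
    beta <- c(beta, bu)
  }
  beta
}

#' Reported relative-importance scores of the RRMM preference study
#'
#' The published RAI scores of the eight attributes (overall response rate
#' 29.8, overall survival 20.4, administration 12.4, cytokine release
#' syndrome 11.9, peripheral neuropathy 9.2, ocular adverse events 7.1,
#' severe diarrhea 3.0; duration of response takes the remainder to 100).
#' Useful as importance weights for [utilities_from_importance()] when
#' reproducing the study's trade-off calculations.
#'
#' @return Named numeric vector over the [default_catalog()] attribute
#'   names, summing to 100.
#' @export
rrmm_rai_scores <- function() {
  c(orr = 29.8, dor = 6.2, os = 20.4, neuropathy = 9.2, ocular = 7.1,
    crs = 11.9, diarrhea = 3.0, admin = 12.4)
}

#' Write RAI or MAB tables as tidy CSV
#'
#' @param x A `dce_rai` or `dce_mab` data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
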