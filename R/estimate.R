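# ---- Design matrix ---------------------------------------------------------

#' Build the dummy-coded design matrix for a choice dataset
#'
#' Each row of the matrix corresponds to one row (one alternative) of the
#' long-format choice data; columns are indicators for the non-reference
#' levels of every attribute, in the stable order of [coefficient_names()]
#' (catalog order, then level order). An alternative sitting at the reference
#' level of every attribute codes to an all-zero row. When a
#' [subgroup_spec()] is supplied, one interaction column per base column is
#' appended: the base indicator multiplied by the respondent's 0/1 group
#' indicator, labelled `attribute:level:covariate`.
#'
#' @param data A `dce_choices` data.frame.
#' @param catalog A `dce_catalog`.
#' @param subgroup Optional [subgroup_spec()] requesting interaction columns.
#' @return An object of class `dce_design_matrix`: list with the numeric
#'   matrix `X`, the row metadata `rows` (respondent, task, alternative,
#'   chosen), column labels and, for interacted matrices, the indices of base
#'   and interaction columns.
#' @export
build_design_matrix <- function(data, catalog, subgroup = NULL) {
  catalog <- as_catalog(catalog)
  nms <- catalog_names(catalog)
  missing <- setdiff(nms, names(data))
  if (length(missing) > 0) {
    stop("choice data lacks attribute columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lv <- as.matrix(data[, nms, drop = FALSE])
  for (j in seq_along(catalog)) {
    bad <- which(!(lv[, j] %in% seq_along(catalog[[j]]$levels)))
    if (length(bad) > 0) {
      stop("invalid level index ", lv[bad[1], j], " for attribute '", nms[j],
           "' in row ", bad[1], call. = FALSE)
    }
  }
  X <- code_levels(lv, catalog)
  labels <- coefficient_names(catalog)
  base_cols <- seq_len(ncol(X))
  int_cols <- integer(0)
  group <- NULL
  if (!is.null(subgroup)) {
    z <- subgroup_indicator(subgroup, data)
    Xi <- X * z
    colnames(Xi) <- paste0(labels, ":", subgroup$covariate)
    int_cols <- ncol(X) + seq_len(ncol(Xi))
    X <- cbind(X, Xi)
    labels <- colnames(X)
    group <- list(covariate = subgroup$covariate, labels = subgroup$labels)
  }
  structure(
    list(
      X = X,
      rows = data.frame(
        respondent_id = data$respondent_id,
        task_id = data$task_id,
        alternative = data$alternative,
        chosen = data$chosen
      ),
      labels = labels, base_cols = base_cols, int_cols = int_cols,
      group = group
    ),
    class = "dce_design_matrix"
  )
}

# Pair the two alternatives of every task into difference rows: D = x_A - x_B,
# s = +1 if A chosen else -1, and a 0-based respondent index aligned to the
# sorted unique respondent ids.
prepare_panel <- function(dm) {
  rows <- dm$rows
  ai <- which(rows$alternative == "A")
  bi <- which(rows$alternative == "B")
  key_a <- paste(rows$respondent_id[ai], rows$task_id[ai])
  key_b <- paste(rows$respondent_id[bi], rows$task_id[bi])
  m <- match(key_a, key_b)
  if (anyNA(m) || length(ai) != length(bi)) {
    stop("choice data is not a complete set of two-alternative tasks", call. = FALSE)
  }
  bi <- bi[m]
  chosen_sum <- rows$chosen[ai] + rows$chosen[bi]
  if (any(chosen_sum != 1L)) {
    stop("each task must have exactly one chosen alternative", call. = FALSE)
  }
  ids <- sort(unique(rows$respondent_id))
  list(
    D = dm$X[ai, , drop = FALSE] - dm$X[bi, , drop = FALSE],
    s = ifelse(rows$chosen[ai] == 1L, 1, -1),
    resp = match(rows$respondent_id[ai], ids) - 1L,
    respondent_ids = ids
  )
}

# ---- Simulated log-likelihood ----------------------------------------------

#' Panel simulated log-likelihood of the error-component logit
#'
#' For each respondent, the product over their tasks of the binary logit
#' probability of the chosen alternative at utility `V + sigma * eta * 1[A]`
#' is averaged over the respondent's error-component draws; the function
#' returns the sum over respondents of the logs of these averages. With
#' `sigma = 0` every draw coincides and the value equals the closed-form
#' conditional-logit log-likelihood.
#'
#' @param params Numeric vector `c(beta, sigma)` with `beta` in the column
#'   order of `dm`, or a list with elements `beta` and `sigma`.
#' @param dm A [build_design_matrix()] result (carries both the matrix and
#'   the row alignment of the data).
#' @param draws Matrix of standard-normal draws, one row per respondent in
#'   ascending `respondent_id` order (see [halton_draws()]).
#' @return The simulated log-likelihood (a single number).
#' @export
simulated_loglik <- function(params, dm, draws) {
  stopifnot(inherits(dm, "dce_design_matrix"))
  par <- flatten_params(params, ncol(dm$X))
  panel <- prepare_panel(dm)
  if (nrow(draws) != length(panel$respondent_ids)) {
    stop("draws must have one row per respondent (", length(panel$respondent_ids),
         ")", call. = FALSE)
  }
  ecl_msl_core(par, panel$D, panel$s, panel$resp, as.matrix(draws), FALSE)$loglik
}

flatten_params <- function(params, K) {
  if (is.list(params)) params <- c(params$beta, params$sigma)
  params <- as.numeric(params)
  if (length(params) != K + 1L) {
    stop("expected ", K + 1L, " parameters (beta plus sigma), got ",
         length(params), call. = FALSE)
  }
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  params
}

# ---- Estimation ------------------------------------------------------------

#' Estimation settings for the error-component logit
#'
#' @param n_draws Error-component draws per respondent (default 500,
#'   scrambled Halton).
#' @param seed Seed for the draw scrambling.
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param robust Also compute the respondent-clustered sandwich covariance.
#' @param include_validity Include stability/dominance tasks in the
#'   likelihood (default `FALSE`: they are engagement checks, and a stability
#'   repeat would double-count its source task).
#' @param start Optional start values `c(beta, sigma)`; default is zero
#'   part-worths with a small positive spread (0.1) so the search starts off
#'   the stationary point that `sigma = 0` is for the symmetric likelihood.
#' @return A list of settings for [estimate_ecl()].
#' @export
ecl_settings <- function(n_draws = 500L, seed = 1L, maxit = 500L,
                         reltol = 1e-9, robust = FALSE,
                         include_validity = FALSE, start = NULL) {
  list(n_draws = as.integer(n_draws), seed = as.integer(seed),
       maxit = as.integer(maxit), reltol = reltol, robust = robust,
       include_validity = include_validity, start = start)
}

#' Estimate the error-component logit by maximum simulated likelihood
#'
#' Maximises [simulated_loglik()] over the part-worths and the
#' error-component spread by BFGS with the analytic gradient, using seeded
#' scrambled-Halton draws. Standard errors come from the inverse numerical
#' Hessian; a respondent-clustered sandwich covariance is added when
#' `settings$robust` is `TRUE`. Validity tasks are excluded from the
#' likelihood by default and opt-out flags are ignored (the forced choice is
#' analysed). The spread is unidentified in sign and reported as its
#' absolute value.
#'
#' @param data A `dce_choices` data.frame.
#' @param catalog A `dce_catalog`.
#' @param settings See [ecl_settings()].
#' @param subgroup Optional [subgroup_spec()]; when given, attribute-by-group
#'   interaction columns are estimated jointly (see
#'   [fit_with_interactions()]).
#' @return An object of class `ecl_fit`: estimates, standard errors,
#'   covariance, log-likelihood and estimation metadata. Non-convergence is
#'   reported via the `converged` flag, not an error; a singular Hessian
#'   yields missing standard errors with a warning.
#' @export
estimate_ecl <- function(data, catalog, settings = ecl_settings(), subgroup = NULL) {
  catalog <- as_catalog(catalog)
  if (!isTRUE(settings$include_validity) &&
      all(c("is_stability_repeat", "is_dominance_test") %in% names(data))) {
    data <- data[data$is_stability_repeat == 0L & data$is_dominance_test == 0L, ,
                 drop = FALSE]
  }
  tasks_per_resp <- table(data$respondent_id[data$alternative == "A"])
  if (length(tasks_per_resp) < 1L || max(tasks_per_resp) < 2L) {
    stop("need at least one respondent with at least two tasks", call. = FALSE)
  }
  dm <- build_design_matrix(data, catalog, subgroup = subgroup)
  panel <- prepare_panel(dm)
  K <- ncol(dm$X)
  draws <- halton_draws(length(panel$respondent_ids), settings$n_draws,
                        seed = settings$seed)

  # line searches call fn alone many times: keep it gradient-free
  nll <- function(par) {
    -ecl_msl_core(par, panel$D, panel$s, panel$resp, draws, FALSE)$loglik
  }
  ngr <- function(par) {
    -ecl_msl_core(par, panel$D, panel$s, panel$resp, draws, TRUE)$gradient
  }
  start <- settings$start %||% c(numeric(K), 0.1)
  opt <- stats::optim(start, nll, ngr, method = "BFGS",
                      control = list(maxit = settings$maxit,
                                     reltol = settings$reltol))
  par <- opt$par
  full <- ecl_msl_core(par, panel$D, panel$s, panel$resp, draws, TRUE,
                       isTRUE(settings$robust))
  grad_norm <- sqrt(sum(full$gradient^2))

  H <- tryCatch(stats::optimHess(par, nll, ngr), error = function(e) NULL)
  covariance <- NULL
  std_errors <- rep(NA_real_, K + 1L)
  if (!is.null(H)) {
    covariance <- tryCatch(solve(H), error = function(e) NULL)
  }
  if (is.null(covariance)) {
    warning("singular Hessian: standard errors unavailable", call. = FALSE)
  } else {
    covariance <- (covariance + t(covariance)) / 2
    std_errors <- sqrt(pmax(diag(covariance), 0))
  }
  robust_covariance <- NULL
  if (isTRUE(settings$robust) && !is.null(covariance)) {
    meat <- crossprod(full$scores)
    robust_covariance <- covariance %*% meat %*% covariance
  }

  # sign of sigma is unidentified: report |sigma| and flip its covariance rows
  if (par[K + 1L] < 0) {
    par[K + 1L] <- -par[K + 1L]
    flip <- function(V) {
      if (is.null(V)) return(NULL)
      V[K + 1L, ] <- -V[K + 1L, ]
      V[, K + 1L] <- -V[, K + 1L]
      V
    }
    covariance <- flip(covariance)
    robust_covariance <- flip(robust_covariance)
  }

  nm <- c(dm$labels, "sigma")
  names(par) <- nm
  names(std_errors) <- nm
  if (!is.null(covariance)) dimnames(covariance) <- list(nm, nm)
  structure(
    list(
      estimates = par, std_errors = std_errors, covariance = covariance,
      robust_covariance = robust_covariance,
      log_likelihood = full$loglik, null_log_likelihood = -nll(c(numeric(K), 0)),
      gradient_norm = grad_norm,
      n_draws = settings$n_draws, draw_type = "scrambled_halton",
      seed = settings$seed, converged = opt$convergence == 0L,
      optim_message = opt$message %||% "",
      n_respondents = length(panel$respondent_ids), n_choices = nrow(panel$D),
      labels = dm$labels, base_cols = dm$base_cols, int_cols = dm$int_cols,
      group = dm$group, settings = settings
    ),
    class = "ecl_fit"
  )
}

#' @export
print.ecl_fit <- function(x, ...) {
  cat(sprintf("<ecl_fit> %d respondents, %d choices, logLik %.3f (null %.3f)%s\n",
              x$n_respondents, x$n_choices, x$log_likelihood,
              x$null_log_likelihood,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- coef_table(x)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coefficient table of an error-component logit fit
#'
#' @param fit An `ecl_fit`.
#' @return A data.frame with term, estimate, std_error, z and p columns.
#' @export
coef_table <- function(fit) {
  z <- fit$estimates / fit$std_errors
  data.frame(
    term = names(fit$estimates),
    estimate = unname(fit$estimates),
    std_error = unname(fit$std_errors),
    z = unname(z),
    p_value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Serialise a fit to JSON and CSV
#'
#' Writes estimates, standard errors, the covariance matrix and estimation
#' metadata as JSON, and the flat coefficient table as CSV next to it.
#'
#' @param fit An `ecl_fit`.
#' @param json_path Path of the JSON file.
#' @param csv_path Optional path of the coefficient CSV.
#' @return `json_path`, invisibly.
#' @export
write_fit <- function(fit, json_path, csv_path = NULL) {
  payload <- list(
    estimates = as.list(fit$estimates),
    std_errors = as.list(fit$std_errors),
    covariance = fit$covariance,
    log_likelihood = fit$log_likelihood,
    null_log_likelihood = fit$null_log_likelihood,
    n_draws = fit$n_draws, draw_type = fit$draw_type, seed = fit$seed,
    converged = fit$converged, n_respondents = fit$n_respondents,
    n_choices = fit$n_choices
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(coef_table(fit), csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
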