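# ---- Respondent profiles ---------------------------------------------------

#' Default respondent strata specification
#'
#' Country counts and covariate distributions emulating the RRMM
#' patient-preference study sample: 296 respondents across six countries
#' (US 100, UK 49, Italy 45, Germany 43, France 39, Spain 20), mean age 63.8
#' (SD 8.0) years, 52% male, 84% with a caregiver, 2-8 prior lines of
#' therapy (median 3), anti-tumour response status 46%/31%/23%
#' (partial/complete/none) and fatigue severity 6%/50%/44%
#' (none/mild-moderate/severe).
#'
#' @return A list with elements `country_counts`, `age_mean`, `age_sd`,
#'   `p_male`, `p_caregiver`, `prior_lines` (list `size`, `prob` for a
#'   shifted binomial on 2..2+size), `response_probs`, `fatigue_probs`.
#' @export
default_strata_spec <- function() {
  list(
    country_counts = c(US = 100L, UK = 49L, IT = 45L, DE = 43L, FR = 39L, ES = 20L),
    age_mean = 63.8, age_sd = 8.0,
    p_male = 0.52, p_caregiver = 0.84,
    prior_lines = list(size = 6L, prob = 0.2),
    response_probs = c(partial = 0.46, complete = 0.31, none = 0.23),
    fatigue_probs = c(none = 0.06, mild_moderate = 0.50, severe = 0.44)
  )
}

#' Simulate respondent covariate profiles
#'
#' Draws `n` respondent profiles with exact country counts (apportioned
#' proportionally when `n` differs from the specified totals) and independent
#' covariates at the specified probabilities. Age is normal, truncated below
#' at 18; the number of prior therapy lines is `2 + Binomial(size, prob)`,
#' respecting the eligibility floor of two prior lines. Deterministic per
#' seed.
#'
#' @param n Number of respondents.
#' @param strata_spec See [default_strata_spec()].
#' @param seed Integer seed.
#' @return A data.frame of class `dce_profiles` with one row per respondent.
#' @export
simulate_profiles <- function(n, strata_spec = default_strata_spec(), seed = 1L) {
  n <- as.integer(n)
  probs <- c(strata_spec$p_male, strata_spec$p_caregiver,
             strata_spec$response_probs, strata_spec$fatigue_probs,
             strata_spec$prior_lines$prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities in strata_spec must lie in [0, 1]", call. = FALSE)
  }
  if (n == 0L) {
    out <- data.frame(respondent_id = integer(), country = character(),
                      age_years = numeric(), male = integer(),
                      has_caregiver = integer(), n_prior_lines = integer(),
                      response_status = character(), fatigue_severity = character())
    class(out) <- c("dce_profiles", "data.frame")
    return(out)
  }
  cc <- strata_spec$country_counts
  counts <- if (sum(cc) == n) as.integer(cc) else apportion(n, cc)
  with_seed(seed, {
    country <- rep(names(cc), counts)
    age <- round(strata_spec$age_mean + strata_spec$age_sd * stats::rnorm(n), 1)
    age <- pmax(age, 18)
    male <- stats::rbinom(n, 1L, strata_spec$p_male)
    caregiver <- stats::rbinom(n, 1L, strata_spec$p_caregiver)
    lines <- 2L + stats::rbinom(n, strata_spec$prior_lines$size,
                                strata_spec$prior_lines$prob)
    resp <- sample(names(strata_spec$response_probs), n, replace = TRUE,
                   prob = strata_spec$response_probs)
    fatigue <- sample(names(strata_spec$fatigue_probs), n, replace = TRUE,
                      prob = strata_spec$fatigue_probs)
    out <- data.frame(
      respondent_id = seq_len(n), country = country, age_years = age,
      male = male, has_caregiver = caregiver, n_prior_lines = lines,
      response_status = resp, fatigue_severity = fatigue,
      stringsAsFactors = FALSE
    )
    class(out) <- c("dce_profiles", "data.frame")
    out
  })
}

# ---- True (data-generating) model ------------------------------------------

#' Specify the data-generating error-component utility model
#'
#' @param beta Named part-worth vector over the catalog's
#'   [coefficient_names()] (reference levels carry no coefficient).
#' @param sigma Error-component spread (>= 0); a per-respondent N(0, sigma^2)
#'   term added to alternative A's utility in every task.
#' @param interactions Optional named list: covariate name -> named vector of
#'   part-worth shifts applied per unit of the covariate.
#' @param optout_rate Probability in `[0, 1]` that a task is flagged opt-out
#'   (independently of, and never overwriting, the forced choice).
#' @return An object of class `dce_true_model`.
#' @export
true_model <- function(beta, sigma = 0, interactions = NULL, optout_rate = 0) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (optout_rate < 0 || optout_rate > 1) {
    stop("optout_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(beta = beta, sigma = sigma,
                 interactions = interactions, optout_rate = optout_rate),
            class = "dce_true_model")
}

# ---- Choice simulation -----------------------------------------------------

#' Simulate panel choices from an error-component random-utility process
#'
#' Respondents are assigned to design blocks round-robin and answer their
#' block's experimental tasks plus its validity tasks. For each task, the
#' utility of alternative j is
#' `V = x_j' (beta + sum_c z_c gamma_c) + sigma * eta * 1[j = A] + epsilon_j`
#' with `eta` standard normal drawn once per respondent and `epsilon`
#' independent standard Gumbel; the alternative with the larger utility is
#' chosen. Opt-out is flagged per task with probability `optout_rate`,
#' independent of the forced choice. Deterministic per seed.
#'
#' @param design A `dce_design` (with or without validity tasks).
#' @param profiles A `dce_profiles` data.frame; any covariate named in
#'   `truth$interactions` must be one of its columns.
#' @param truth A [true_model()].
#' @param seed Integer seed.
#' @return A long-format data.frame of class `dce_choices`: two rows per
#'   (respondent, task), with level-index columns per attribute, `chosen`,
#'   `optout`, validity flags and the respondent covariates.
#' @export
simulate_choices <- function(design, profiles, truth, seed = 1L) {
  stopifnot(inherits(design, "dce_design"), inherits(truth, "dce_true_model"))
  if (is.na(design$n_blocks) || design$n_blocks < 1L ||
      !"block_id" %in% names(design$tasks)) {
    stop("design without blocks", call. = FALSE)
  }
  catalog <- design$catalog
  nms <- catalog_names(catalog)
  cn <- coefficient_names(catalog)
  beta <- resolve_priors(truth$beta, catalog)
  gammas <- truth$interactions %||% list()
  for (cov in names(gammas)) {
    if (!cov %in% names(profiles)) {
      stop("interaction covariate '", cov, "' not found in profiles", call. = FALSE)
    }
  }
  n <- nrow(profiles)
  block_of <- ((seq_len(n) - 1L) %% design$n_blocks) + 1L

  with_seed(seed, {
    eta <- stats::rnorm(n)
    out <- vector("list", design$n_blocks)
    for (b in seq_len(design$n_blocks)) {
      ridx <- which(block_of == b)
      if (length(ridx) == 0L) next
      bt <- design$tasks[design$tasks$block_id == b, , drop = FALSE]
      bt <- bt[order(bt$task_id), , drop = FALSE]
      sub <- design
      sub$tasks <- bt
      XA <- code_levels(level_matrix(sub, "A"), catalog)
      XB <- code_levels(level_matrix(sub, "B"), catalog)
      Tt <- nrow(bt)
      nR <- length(ridx)
      vA <- matrix(as.vector(XA %*% beta), Tt, nR)
      vB <- matrix(as.vector(XB %*% beta), Tt, nR)
      for (cov in names(gammas)) {
        g <- numeric(length(cn))
        names(g) <- cn
        gv <- gammas[[cov]]
        unknown <- setdiff(names(gv), cn)
        if (length(unknown) > 0) {
          stop("interaction coefficients name unknown levels: ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        g[names(gv)] <- gv
        z <- as.numeric(profiles[[cov]][ridx])
        vA <- vA + as.vector(XA %*% g) %o% z
        vB <- vB + as.vector(XB %*% g) %o% z
      }
      uA <- vA + rep(truth$sigma * eta[ridx], each = Tt) -
        log(-log(matrix(stats::runif(Tt * nR), Tt, nR)))
      uB <- vB - log(-log(matrix(stats::runif(Tt * nR), Tt, nR)))
      choseA <- uA > uB
      optout <- matrix(stats::rbinom(Tt * nR, 1L, truth$optout_rate), Tt, nR)

      base <- data.frame(
        respondent_id = rep(profiles$respondent_id[ridx], each = Tt),
        task_id = rep(bt$task_id, nR),
        block_id = b
      )
      rowsA <- base
      rowsA$alternative <- "A"
      rowsB <- base
      rowsB$alternative <- "B"
      for (j in seq_along(nms)) {
        rowsA[[nms[j]]] <- rep(bt[[paste0("A_", nms[j])]], nR)
        rowsB[[nms[j]]] <- rep(bt[[paste0("B_", nms[j])]], nR)
      }
      rowsA$chosen <- as.integer(as.vector(choseA))
      rowsB$chosen <- 1L - rowsA$chosen
      rowsA$optout <- as.vector(optout)
      rowsB$optout <- rowsA$optout
      flagS <- rep(as.integer(bt$is_stability_repeat), nR)
      flagD <- rep(as.integer(bt$is_dominance_test), nR)
      rowsA$is_stability_repeat <- flagS
      rowsB$is_stability_repeat <- flagS
      rowsA$is_dominance_test <- flagD
      rowsB$is_dominance_test <- flagD
      out[[b]] <- rbind(rowsA, rowsB)
    }
    data <- do.call(rbind, out)
    data <- data[order(data$respondent_id, data$task_id, data$alternative), ]
    cov_cols <- setdiff(names(profiles), "respondent_id")
    idx <- match(data$respondent_id, profiles$respondent_id)
    for (cc in cov_cols) data[[cc]] <- profiles[[cc]][idx]
    rownames(data) <- NULL
    attr(data, "covariates") <- cov_cols
    attr(data, "attribute_cols") <- nms
    attr(data, "seed") <- as.integer(seed)
    class(data) <- c("dce_choices", "data.frame")
    data
  })
}

# ---- Choice data IO --------------------------------------------------------

#' Write or read a long-format choice dataset CSV
#'
#' Columns: `respondent_id`, `task_id`, `block_id`, `alternative`, one
#' 0-based level-index column per attribute, `chosen`, `optout`,
#' `is_stability_repeat`, `is_dominance_test`, then covariate columns.
#' Writing then reading then writing is byte-identical.
#'
#' @param data A `dce_choices` data.frame.
#' @param path File path.
#' @param catalog Catalog identifying the attribute columns; on write it may
#'   be omitted when `data` carries its attribute names (as datasets produced
#'   by [simulate_choices()] and [read_choice_data()] do).
#' @return `read_choice_data()` returns a `dce_choices` data.frame;
#'   `write_choice_data()` returns `path` invisibly.
#' @export
write_choice_data <- function(data, path, catalog = NULL) {
  nms <- if (is.null(catalog)) attr(data, "attribute_cols") else catalog_names(as_catalog(catalog))
  if (is.null(nms)) stop("supply a catalog to identify attribute columns", call. = FALSE)
  out <- as.data.frame(data)
  for (nm in nms) out[[nm]] <- out[[nm]] - 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path, catalog) {
  catalog <- as_catalog(catalog)
  nms <- catalog_names(catalog)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "task_id", "alternative", nms, "chosen")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("choice data file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in nms) data[[nm]] <- data[[nm]] + 1L
  fixed <- c("respondent_id", "task_id", "block_id", "alternative", nms,
             "chosen", "optout", "is_stability_repeat", "is_dominance_test")
  attr(data, "covariates") <- setdiff(names(data), fixed)
  attr(data, "attribute_cols") <- nms
  class(data) <- c("dce_choices", "data.frame")
  data
}
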