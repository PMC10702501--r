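# ---- Internal validity -----------------------------------------------------

#' Stability, dominance and opt-out summary of a choice dataset
#'
#' Computes the three engagement statistics of the survey design: the
#' fraction of respondents choosing the same alternative in the stability
#' repeat as in its source task, the fraction choosing the dominant
#' alternative of the dominance test, and the fraction of task instances
#' flagged opt-out. Rates are computed only over respondents who saw the
#' relevant task; when a dataset contains no validity tasks the rates are
#' `NA` (absent), not zero.
#'
#' @param data A `dce_choices` data.frame.
#' @param design The `dce_design` that produced the tasks (identifies
#'   validity tasks and their sources).
#' @return An object of class `dce_validity`: the three rates plus a
#'   per-respondent flag table.
#' @export
validity_summary <- function(data, design) {
  stopifnot(inherits(design, "dce_design"))
  a_rows <- data[data$alternative == "A", , drop = FALSE]
  chose_a <- stats::setNames(a_rows$chosen == 1L,
                             paste(a_rows$respondent_id, a_rows$task_id))
  tasks <- design$tasks
  resp_ids <- sort(unique(a_rows$respondent_id))

  flags <- data.frame(respondent_id = resp_ids,
                      stability_consistent = NA,
                      dominance_passed = NA,
                      n_optout = NA_integer_)

  stab <- tasks[tasks$is_stability_repeat, , drop = FALSE]
  for (i in seq_len(nrow(stab))) {
    rep_id <- stab$task_id[i]
    src_id <- stab$source_task_id[i]
    if (is.na(src_id)) next
    for (r in resp_ids) {
      k_rep <- paste(r, rep_id)
      k_src <- paste(r, src_id)
      if (!is.na(chose_a[k_rep]) && !is.na(chose_a[k_src])) {
        flags$stability_consistent[flags$respondent_id == r] <-
          chose_a[[k_rep]] == chose_a[[k_src]]
      }
    }
  }

  dom <- tasks[tasks$is_dominance_test, , drop = FALSE]
  for (i in seq_len(nrow(dom))) {
    winner <- dominant_alternative(dom[i, , drop = FALSE], design$catalog)
    if (is.na(winner)) next
    for (r in resp_ids) {
      k <- paste(r, dom$task_id[i])
      if (!is.na(chose_a[k])) {
        flags$dominance_passed[flags$respondent_id == r] <-
          (chose_a[[k]] && winner == "A") || (!chose_a[[k]] && winner == "B")
      }
    }
  }

  if ("optout" %in% names(a_rows)) {
    n_opt <- tapply(a_rows$optout, a_rows$respondent_id, sum)
    flags$n_optout <- as.integer(n_opt[as.character(resp_ids)])
  }

  rate <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  structure(
    list(
      stability_consistency_rate = rate(flags$stability_consistent),
      dominance_pass_rate = rate(flags$dominance_passed),
      optout_rate = if ("optout" %in% names(a_rows)) mean(a_rows$optout) else NA_real_,
      flags = flags
    ),
    class = "dce_validity"
  )
}

#' @export
print.dce_validity <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f%%", 100 * v)
  cat("<dce_validity>\n",
      "  stability consistency: ", fmt(x$stability_consistency_rate), "\n",
      "  dominance pass rate:   ", fmt(x$dominance_pass_rate), "\n",
      "  opt-out rate:          ", fmt(x$optout_rate), "\n", sep = "")
  invisible(x)
}

# ---- Pipeline --------------------------------------------------------------

#' Default pipeline configuration
#'
#' The packaged study conditions: the eight-attribute catalog, a 36-task /
#' 3-block D-efficient design with validity tasks, 296 respondents in six
#' country strata, true part-worths with ranges proportional to the study's
#' reported importance scores (scaled to realistic utility magnitudes), a
#' moderate error component and a small opt-out rate.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("dcebr_run_")) {
  list(
    mode = "simulate",
    seed = as.integer(seed),
    out_dir = out_dir,
    design = list(n_tasks = 36L, n_blocks = 3L, n_sweeps = 20L,
                  repeat_position = 3L),
    simulation = list(n_respondents = 296L, utility_scale = 0.04,
                      sigma = 0.8, optout_rate = 0.05, interactions = NULL),
    estimation = list(n_draws = 500L, robust = FALSE),
    metrics = list(kr_draws = 2000L),
    subgroup = list(covariate = "has_caregiver", group1_values = c(1),
                    labels = c("no_caregiver", "caregiver"))
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- default_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_lists(a[[nm]], b[[nm]])
      } else {
        b[[nm]]
      }
    }
    a
  }
  merge_lists(base, config)
}

#' Run the full benefit-risk DCE pipeline
#'
#' Executes design generation, choice simulation (or loading of an existing
#' choice dataset in `estimate-only` mode), error-component logit
#' estimation, RAI and MAB computation, subgroup heterogeneity and validity
#' checks, writing all tables, a fit JSON, a run log and a plain-text
#' summary report to the output directory. Fully deterministic given the
#' configuration seeds.
#'
#' @param config A configuration list or the path of a YAML configuration
#'   file; unspecified entries fall back to [default_config()]. In
#'   `estimate-only` mode the config must name `choices_file` and
#'   `design_file`.
#' @param quiet Suppress progress messages.
#' @return A list with the design, data, fit, RAI, MAB, subgroup and
#'   validity results (invisibly reproduced on disk under `out_dir`).
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  cfg <- read_config(config)
  if (!cfg$mode %in% c("simulate", "estimate-only")) {
    stop("mode must be 'simulate' or 'estimate-only'", call. = FALSE)
  }
  if (cfg$mode == "estimate-only") {
    for (f in c("choices_file", "design_file")) {
      if (is.null(cfg[[f]])) {
        stop("estimate-only mode requires '", f, "' in the config", call. = FALSE)
      }
      if (!file.exists(cfg[[f]])) {
        stop(f, " does not exist: ", cfg[[f]], call. = FALSE)
      }
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- as.integer(cfg$seed)
  catalog <- if (is.null(cfg$catalog) || identical(cfg$catalog, "default")) {
    default_catalog()
  } else {
    read_catalog(cfg$catalog)
  }

  if (cfg$mode == "simulate") {
    say("generating D-efficient design ...")
    design <- generate_design(catalog, n_tasks = cfg$design$n_tasks,
                              n_blocks = cfg$design$n_blocks, seed = seed,
                              n_sweeps = cfg$design$n_sweeps)
    design <- add_validity_tasks(design, cfg$design$repeat_position)
    write_design(design, file.path(cfg$out_dir, "design.csv"))

    say("simulating ", cfg$simulation$n_respondents, " respondents ...")
    profiles <- simulate_profiles(cfg$simulation$n_respondents, seed = seed + 1L)
    beta <- utilities_from_importance(catalog, rrmm_rai_scores()) *
      cfg$simulation$utility_scale
    interactions <- cfg$simulation$interactions
    if (!is.null(interactions)) {
      interactions <- lapply(interactions, function(x) unlist(x))
    }
    truth <- true_model(beta, sigma = cfg$simulation$sigma,
                        interactions = interactions,
                        optout_rate = cfg$simulation$optout_rate)
    data <- simulate_choices(design, profiles, truth, seed = seed + 2L)
    write_choice_data(data, file.path(cfg$out_dir, "choices.csv"))
  } else {
    say("loading design and choices ...")
    design <- read_design(cfg$design_file, catalog)
    data <- read_choice_data(cfg$choices_file, catalog)
    truth <- NULL
  }

  say("estimating error-component logit ...")
  settings <- ecl_settings(n_draws = cfg$estimation$n_draws, seed = seed + 3L,
                           robust = isTRUE(cfg$estimation$robust))
  fit <- estimate_ecl(data, catalog, settings)
  write_fit(fit, file.path(cfg$out_dir, "fit.json"),
            file.path(cfg$out_dir, "coefficients.csv"))

  say("computing RAI and MAB ...")
  rai <- rai_confidence_intervals(fit, catalog, n_draws = cfg$metrics$kr_draws,
                                  seed = seed + 4L)
  mab <- mab_table(fit, catalog, n_draws = cfg$metrics$kr_draws,
                   seed = seed + 5L)
  write_table_with_meta(rai, file.path(cfg$out_dir, "rai.csv"), seed, cfg$mode)
  write_table_with_meta(mab, file.path(cfg$out_dir, "mab.csv"), seed, cfg$mode)

  subgroup_out <- NULL
  if (!is.null(cfg$subgroup) && !is.null(cfg$subgroup$covariate) &&
      cfg$subgroup$covariate %in% names(data)) {
    say("fitting subgroup interactions (", cfg$subgroup$covariate, ") ...")
    sg <- subgroup_spec(cfg$subgroup$covariate,
                        rule = cfg$subgroup$group1_values,
                        labels = cfg$subgroup$labels)
    sg_fit <- tryCatch(
      fit_with_interactions(data, catalog, sg, settings),
      error = function(e) {
        say("subgroup fit skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(sg_fit)) {
      subgroup_out <- subgroup_comparison(sg_fit, catalog,
                                          n_draws = cfg$metrics$kr_draws,
                                          seed = seed + 6L)
      write_table_with_meta(subgroup_out$rai,
                            file.path(cfg$out_dir, "subgroup_rai.csv"),
                            seed, cfg$mode)
      write_table_with_meta(subgroup_out$interactions,
                            file.path(cfg$out_dir, "subgroup_interactions.csv"),
                            seed, cfg$mode)
    }
  }

  validity <- validity_summary(data, design)

  log_path <- file.path(cfg$out_dir, "run_log.json")
  cfg_log <- cfg
  # paths are environment-specific, not part of the reproducible result
  cfg_log$out_dir <- NULL
  cfg_log$choices_file <- NULL
  cfg_log$design_file <- NULL
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("dcebr")),
         r_version = R.version.string, mode = cfg$mode, seed = seed,
         config = cfg_log, timestamp_omitted_for_determinism = TRUE),
    log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  write_report(file.path(cfg$out_dir, "report.txt"), cfg, fit, rai, mab,
               subgroup_out, validity)
  say("done: ", cfg$out_dir)
  invisible(list(config = cfg, design = design, data = data, truth = truth,
                 fit = fit, rai = rai, mab = mab, subgroup = subgroup_out,
                 validity = validity))
}

# Tables other than the round-trip formats carry their provenance as a
# comment header line (readable back with read.csv(comment.char = "#")).
write_table_with_meta <- function(x, path, seed, mode) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dcebr seed=%d mode=%s", seed, mode), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_report <- function(path, cfg, fit, rai, mab, subgroup_out, validity) {
  fmt_rate <- function(v) if (is.na(v)) "absent" else sprintf("%.1f%%", 100 * v)
  lines <- c(
    "Benefit-risk DCE pipeline report",
    "================================",
    sprintf("mode: %s   seed: %d   respondents: %d   choices: %d",
            cfg$mode, cfg$seed, fit$n_respondents, fit$n_choices),
    sprintf("log-likelihood: %.3f (null %.3f), %d Halton draws, converged: %s",
            fit$log_likelihood, fit$null_log_likelihood, fit$n_draws,
            fit$converged),
    sprintf("error-component spread |sigma|: %.3f (SE %.3f)",
            fit$estimates[["sigma"]], fit$std_errors[["sigma"]]),
    "",
    "Relative attribute importance (%, 95% CI):",
    sprintf("  %-12s %5.1f  [%.1f, %.1f]", rai$attribute,
            rai$importance_percent, rai$ci_low, rai$ci_high),
    "",
    "Minimal acceptable benefit (ORR percentage points / OS months):",
    sprintf("  %-12s %s -> %s vs %-4s : %5.1f  [%.1f, %.1f]", mab$attribute,
            mab$from_level, mab$to_level, mab$benefit_attribute,
            mab$required_benefit, mab$ci_low, mab$ci_high),
    "",
    "Internal validity:",
    sprintf("  stability consistency: %s", fmt_rate(validity$stability_consistency_rate)),
    sprintf("  dominance pass rate:   %s", fmt_rate(validity$dominance_pass_rate)),
    sprintf("  opt-out rate:          %s", fmt_rate(validity$optout_rate))
  )
  if (!is.null(subgroup_out)) {
    lines <- c(lines, "",
               sprintf("Subgroup heterogeneity (%s: %s vs %s), interaction p-values are nominal/exploratory:",
                       subgroup_out$covariate, subgroup_out$labels[1],
                       subgroup_out$labels[2]),
               sprintf("  %-12s %5.1f%% vs %5.1f%%", subgroup_out$rai$attribute,
                       subgroup_out$rai[[2]], subgroup_out$rai[[5]]))
  }
  writeLines(lines, path)
  invisible(path)
}
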