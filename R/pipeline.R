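#' Pipeline run configuration
#'
#' Collects every tunable decision value of the end-to-end analysis in one
#' object, so a run is fully described by its config (and reruns with the
#' same config and seed are reproducible). Either `input` (a long CSV) or
#' `dataset` (an in-memory [esm_dataset()]) must be provided when the
#' pipeline runs.
#'
#' @param input Path to a long-format prompt CSV.
#' @param dataset An [esm_dataset()] (takes precedence over `input`).
#' @param output_dir Directory for the run artifacts; `NULL` keeps
#'   everything in memory.
#' @param stress_types Stress measures to analyse.
#' @param max_delay,min_prompts Compliance-filter settings.
#' @param event_threshold,activity_threshold Stress dichotomisation
#'   cut-offs.
#' @param max_lag Named modelled window length K per stress type.
#' @param centering Outcome standardisation method (see
#'   [center_and_standardize()]).
#' @param covariates Adjust models for centred age and gender; turning
#'   this off yields the unadjusted model variant.
#' @param sensitivity Also fit the subsequent-stressor control models.
#' @param alpha Significance level.
#' @param seed Seed recorded in the summary (the analysis itself is
#'   deterministic; the seed matters only when the input is simulated).
#' @param verbose Print stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, dataset = NULL, output_dir = NULL,
                       stress_types = c("event", "activity", "composite"),
                       max_delay = 15, min_prompts = 20,
                       event_threshold = 4, activity_threshold = 4,
                       max_lag = c(event = 1, activity = 2, composite = 2),
                       centering = "grand",
                       covariates = TRUE, sensitivity = TRUE,
                       alpha = 0.05, seed = NULL, verbose = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stress_types <- match.arg(stress_types, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$max_lag)) raw$max_lag <- unlist(raw$max_lag)
  do.call(run_config, raw)
}

.write_artifact <- function(obj, config, file) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(obj, file.path(config$output_dir, file), row.names = FALSE,
            na = "")
}

#' Run the end-to-end trajectory analysis
#'
#' Executes the full sequence: compliance filtering, scoring and
#' standardisation, per-stress-type trajectory coding, per-group
#' within-group models (reactivity and recovery against baseline),
#' sensitivity models controlling for subsequent stressors, joint models
#' with group main effects and time x group interactions (baseline,
#' reactivity, and recovery-period contrasts between groups), step-up
#' multiple-testing correction across the three stress measures, and
#' adjusted predictive margins for the trajectory figure. Every exclusion
#' is logged and the stage counts reconcile (input = retained + removed).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `esm_run`: `tables` (descriptives,
#'   within-group, sensitivity, between-group), `fits`, `windows`,
#'   `margins`, `exclusions`, `filter_log`, and `summary`. When
#'   `config$output_dir` is set the artifacts are also written as CSV /
#'   YAML as soon as each stage completes, so partial artifacts survive
#'   a failing stage (the error names the stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  stage_name <- NULL
  stage <- function(name, expr) {
    stage_name <<- name
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ds <- stage("load", {
    if (!is.null(config$dataset)) config$dataset
    else if (!is.null(config$input)) read_esm_long(config$input)
    else stop("run_config needs either `dataset` or `input`")
  })
  n_input_prompts <- nrow(ds$prompts)
  n_input_persons <- nrow(ds$persons)

  filt <- stage("compliance_filter", {
    apply_compliance_filter(ds, max_delay = config$max_delay,
                            min_prompts = config$min_prompts)
  })
  .write_artifact(filt$log, config, "filter_log.csv")

  derived <- stage("preprocess", {
    derive_prompts(filt$dataset,
                   event_threshold = config$event_threshold,
                   activity_threshold = config$activity_threshold,
                   centering = config$centering)
  })

  descr <- stage("descriptives", {
    if (length(unique(filt$dataset$persons$group)) >= 2) {
      descriptive_table(filt$dataset, derived, alpha = config$alpha)
    } else NULL
  })
  if (!is.null(descr)) {
    .write_artifact(descr$per_group, config, "table1_descriptives.csv")
    .write_artifact(descr$tests, config, "table1_tests.csv")
  }

  persons <- filt$dataset$persons
  fits <- list(); windows <- list()
  within_rows <- list(); sens_rows <- list(); between_rows <- list()
  main_rows <- list(); excl_rows <- list(); margins <- NULL

  for (st in config$stress_types) {
    frame <- stage(paste0("trajectory_", st), {
      fr <- code_time_since(derived, stress_type = st,
                            max_lag = config$max_lag[[st]])
      flag_subsequent_stress(fr, derived)
    })
    excl_rows[[st]] <- exclusion_summary(frame)
    af <- analysis_frame(frame, derived, persons)
    groups <- levels(af$group)

    # H1: separate model per group, all time points against baseline
    per_group_contrasts <- list()
    for (g in groups) {
      fit <- stage(paste0("fit_", st, "_", g), {
        fit_lmm(af[af$group == g, ],
                model_spec(stress_type = st,
                           covariates = config$covariates))
      })
      fits[[paste(st, g, sep = ".")]] <- fit
      wc <- within_group_contrasts(fit, alpha = config$alpha)
      per_group_contrasts[[g]] <- wc
      ct <- coef_table(fit)
      cov_rows <- ct[ct$term %in% c("age_c", "female"), , drop = FALSE]
      within_rows[[paste(st, g)]] <- data.frame(
        stress_type = st, group = g,
        term = c(wc$label, cov_rows$term),
        b = c(wc$b, cov_rows$b),
        ci_low = c(wc$ci_low, cov_rows$ci_low),
        ci_high = c(wc$ci_high, cov_rows$ci_high),
        p = c(wc$p, cov_rows$p), stringsAsFactors = FALSE)

      if (isTRUE(config$sensitivity)) {
        sfit <- stage(paste0("fit_sens_", st, "_", g), {
          fit_lmm(af[af$group == g, ],
                  model_spec(stress_type = st,
                             covariates = config$covariates,
                             subsequent_stress_control = TRUE))
        })
        fits[[paste(st, g, "sens", sep = ".")]] <- sfit
        swc <- within_group_contrasts(sfit, alpha = config$alpha)
        sct <- coef_table(sfit)
        extra <- sct[sct$term %in% c("age_c", "female",
                                     "subsequent_stress"), , drop = FALSE]
        sens_rows[[paste(st, g)]] <- data.frame(
          stress_type = st, group = g,
          term = c(swc$label, extra$term),
          b = c(swc$b, extra$b),
          ci_low = c(swc$ci_low, extra$ci_low),
          ci_high = c(swc$ci_high, extra$ci_high),
          p = c(swc$p, extra$p), stringsAsFactors = FALSE)
      }
    }

    # H2: group added as a predictor (no interaction) for the main effect
    gfit <- stage(paste0("fit_group_", st), {
      fit_lmm(af, model_spec(stress_type = st,
                             include_group_terms = TRUE,
                             covariates = config$covariates))
    })
    fits[[paste(st, "group", sep = ".")]] <- gfit
    # H3/H4: time_since x group interaction for the between-group
    # baseline, reactivity and recovery contrasts and the margins
    jfit <- stage(paste0("fit_joint_", st), {
      fit_lmm(af, model_spec(stress_type = st,
                             include_group_terms = TRUE,
                             include_interaction = TRUE,
                             covariates = config$covariates))
    })
    fits[[paste(st, "joint", sep = ".")]] <- jfit
    me <- group_main_effect(gfit)
    main_rows[[st]] <- data.frame(stress_type = st,
                                  chi_square = me$statistic, df = me$df,
                                  p = me$p_value, stringsAsFactors = FALSE)

    bg <- rbind(between_group_contrasts(jfit, "t-1", alpha = config$alpha),
                between_group_contrasts(jfit, "t0", alpha = config$alpha))

    win <- recovery_window(per_group_contrasts, alpha = config$alpha)
    windows[[st]] <- win
    # a recovery-period contrast only exists when some group is still
    # depressed after t0 (otherwise there is no continuous recovery period)
    if (any(win$per_group > 1) && jfit$converged) {
      for (pr in .group_pairs(jfit$groups)) {
        rc <- recovery_contrast(jfit, win$window, pair = pr,
                                alpha = config$alpha)
        bg <- rbind(bg, data.frame(
          pair = rc$pair, timepoint = rc$window, b = rc$b,
          ci_low = rc$ci_low, ci_high = rc$ci_high, se = rc$se, p = rc$p,
          note = NA_character_, stringsAsFactors = FALSE))
      }
    }
    bg <- cbind(stress_type = st, bg)
    between_rows[[st]] <- bg

    if (st == config$stress_types[length(config$stress_types)] ||
        st == "composite") {
      margins <- stage(paste0("margins_", st),
                       cbind(stress_type = st, adjusted_margins(jfit)))
    }
  }

  table2 <- do.call(rbind, within_rows); rownames(table2) <- NULL
  table3 <- if (length(sens_rows)) {
    x <- do.call(rbind, sens_rows); rownames(x) <- NULL; x
  } else NULL
  table4 <- do.call(rbind, between_rows); rownames(table4) <- NULL
  main_effects <- do.call(rbind, main_rows); rownames(main_effects) <- NULL
  exclusions <- do.call(rbind, excl_rows); rownames(exclusions) <- NULL

  # step-up correction across stress measures, per hypothesis family
  simes_mark <- function(tab, by_cols) {
    tab$simes_significant <- NA
    fam <- interaction(tab[by_cols], drop = TRUE)
    for (f in levels(fam)) {
      i <- which(fam == f & !is.na(tab$p))
      if (length(i) < 2) {
        tab$simes_significant[i] <- tab$p[i] < config$alpha
        next
      }
      tab$simes_significant[i] <- .hochberg(tab$p[i],
                                            config$alpha)$significant
    }
    tab
  }
  table2 <- stage("simes", simes_mark(table2, c("group", "term")))
  if (!is.null(table3)) table3 <- simes_mark(table3, c("group", "term"))
  table4 <- simes_mark(table4, c("pair", "timepoint"))

  .write_artifact(table2, config, "table2_within_group.csv")
  if (!is.null(table3)) {
    .write_artifact(table3, config, "table3_sensitivity.csv")
  }
  .write_artifact(table4, config, "table4_between_group.csv")
  .write_artifact(main_effects, config, "group_main_effects.csv")
  .write_artifact(exclusions, config, "trajectory_exclusions.csv")
  if (!is.null(margins)) .write_artifact(margins, config, "margins.csv")

  n_retained <- nrow(filt$dataset$prompts)
  summary_list <- stage("summary", list(
    package_version = as.character(utils::packageVersion("esmrecovery")),
    seed = config$seed,
    counts = list(
      input = list(persons = n_input_persons, prompts = n_input_prompts),
      removed_prompts = sum(filt$log$n_prompts_removed),
      removed_persons = sum(filt$log$n_persons_removed),
      analytic = list(persons = nrow(filt$dataset$persons),
                      prompts = n_retained),
      reconciles = (n_retained + sum(filt$log$n_prompts_removed)) ==
        n_input_prompts
    ),
    filter_log = filt$log,
    decisions = list(
      max_delay_min = config$max_delay,
      min_prompts = config$min_prompts,
      event_threshold = config$event_threshold,
      activity_threshold = config$activity_threshold,
      max_lag = as.list(config$max_lag),
      centering = config$centering,
      covariates = config$covariates,
      sensitivity = config$sensitivity,
      alpha = config$alpha,
      estimation = "ML",
      simes = "step-up across stress measures per hypothesis family"
    ),
    recovery_windows = lapply(windows, function(w) {
      list(per_group = as.list(w$per_group),
           overall_end = w$overall_end,
           all_recovered = w$all_recovered)
    })
  ))
  if (!is.null(config$output_dir)) {
    yaml::write_yaml(summary_list,
                     file.path(config$output_dir, "summary.yaml"))
  }

  structure(list(tables = list(descriptives = descr, within = table2,
                               sensitivity = table3, between = table4,
                               main_effects = main_effects),
                 fits = fits, windows = windows, margins = margins,
                 exclusions = exclusions, filter_log = filt$log,
                 derived = derived, summary = summary_list,
                 config = config),
            class = "esm_run")
}

#' @export
print.esm_run <- function(x, ...) {
  cat("ESM trajectory analysis run\n")
  cat("analytic sample: ", x$summary$counts$analytic$persons, " persons, ",
      x$summary$counts$analytic$prompts, " prompts\n", sep = "")
  cat("\nGroup main effects:\n")
  print(x$tables$main_effects, row.names = FALSE, digits = 4)
  cat("\nRecovery windows (first recovered lag per group):\n")
  for (st in names(x$windows)) {
    w <- x$windows[[st]]
    cat("  ", st, ": ",
        paste(names(w$per_group), "t", w$per_group, sep = "",
              collapse = ", "),
        "; window t1..t", w$overall_end, "\n", sep = "")
  }
  invisible(x)
}
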