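#' Model specification for the trajectory mixed models
#'
#' @param stress_type Stress measure the model is fitted for.
#' @param groups Optional subset of groups to keep (default: all present).
#' @param include_group_terms Add group main effects.
#' @param include_interaction Add the time_since x group interaction
#'   (requires `include_group_terms`).
#' @param covariates Adjust for grand-mean-centred age and gender
#'   (female indicator).
#' @param subsequent_stress_control Add the subsequent-stressor control
#'   variable (sensitivity models).
#' @param estimation `"ML"` (default, matching the reference multilevel
#'   implementation) or `"REML"`.
#' @param random_slope_t0 Add a person-level random slope for the `t0`
#'   indicator (sensitivity option, default off).
#' @return A `model_spec` list.
#' @export
model_spec <- function(stress_type = c("composite", "event", "activity"),
                       groups = NULL,
                       include_group_terms = FALSE,
                       include_interaction = FALSE,
                       covariates = TRUE,
                       subsequent_stress_control = FALSE,
                       estimation = c("ML", "REML"),
                       random_slope_t0 = FALSE) {
  stress_type <- match.arg(stress_type)
  estimation <- match.arg(estimation)
  if (include_interaction && !include_group_terms) {
    stop("include_interaction requires include_group_terms")
  }
  structure(list(stress_type = stress_type, groups = groups,
                 include_group_terms = include_group_terms,
                 include_interaction = include_interaction,
                 covariates = covariates,
                 subsequent_stress_control = subsequent_stress_control,
                 estimation = estimation,
                 random_slope_t0 = random_slope_t0),
            class = "model_spec")
}

#' Assemble the analysis frame for model fitting
#'
#' Joins the included rows of a trajectory frame to the standardised
#' outcome and the person-level covariates, producing the modelling data:
#' `pa_z`, `time_since` (factor with baseline `"t-1"` as reference),
#' `group` (factor, controls as reference), grand-mean-centred age,
#' a female indicator, and the subsequent-stress control (0 at `t-1`/`t0`).
#'
#' @param frame A `trajectory_frame`, ideally after
#'   [flag_subsequent_stress()].
#' @param derived Derived prompt table.
#' @param persons Person table of the filtered dataset.
#' @return Data frame of included rows ready for [fit_lmm()].
#' @export
analysis_frame <- function(frame, derived, persons) {
  f <- frame[frame$included, , drop = FALSE]
  i <- match(.key(f), .key(derived))
  f$pa_z <- derived$pa_z[i]
  j <- match(f$person_id, persons$person_id)
  f$group <- factor(persons$group[j],
                    levels = intersect(.esm_groups, unique(persons$group)))
  f$age <- persons$age[j]
  f$female <- as.integer(persons$gender[j] == "female")
  f$subsequent_stress[is.na(f$subsequent_stress)] <- 0L
  f <- f[!is.na(f$pa_z), , drop = FALSE]
  lags <- sort(unique(f$time_since))
  lev <- c("t-1", paste0("t", 0:(attr(frame, "max_lag"))))
  f$time_since <- factor(f$time_since, levels = intersect(lev, lags))
  f$day_id <- paste(f$person_id, f$day_index, sep = ":")
  # age centred at the grand mean of this model's analytic sample
  f$age_c <- f$age - mean(persons$age[persons$person_id %in% f$person_id],
                          na.rm = TRUE)
  attr(f, "stress_type") <- attr(frame, "stress_type")
  attr(f, "max_lag") <- attr(frame, "max_lag")
  f
}

#' Fit the three-level linear mixed model
#'
#' Fits `pa_z ~ time_since (+ group + time_since:group) (+ age_c + female)
#' (+ subsequent_stress)` with random intercepts for persons and for days
#' within persons (assessments at level 1, days at level 2, persons at
#' level 3), by maximum likelihood unless the spec requests REML.
#' Inference downstream is large-sample Wald (normal / chi-square).
#'
#' @param data Analysis frame from [analysis_frame()] (or any data frame
#'   with the same columns).
#' @param spec A [model_spec()].
#' @return Object of class `esm_fit`: fixed effects `beta`, their
#'   covariance `vcov`, variance components `var_person`, `var_day`,
#'   `var_resid`, `loglik`, `converged`, sample sizes, the underlying
#'   `lme4` fit (`model`), and the data used.
#' @export
fit_lmm <- function(data, spec = model_spec()) {
  if (!is.null(spec$groups)) {
    data <- data[data$group %in% spec$groups, , drop = FALSE]
    data$group <- droplevels(data$group)
  }
  data <- droplevels(data[!is.na(data$pa_z), , drop = FALSE])
  if (length(unique(data$person_id)) < 2) {
    stop("fit_lmm needs at least 2 persons")
  }
  has_ts <- is.factor(data$time_since) && nlevels(data$time_since) >= 2
  rhs <- if (has_ts) "time_since" else "1"
  if (spec$include_group_terms) rhs <- c(rhs, "group")
  if (spec$include_interaction && has_ts) rhs <- c(rhs, "time_since:group")
  if (spec$covariates) rhs <- c(rhs, "age_c", "female")
  if (spec$subsequent_stress_control) rhs <- c(rhs, "subsequent_stress")
  re_person <- if (spec$random_slope_t0) {
    data$is_t0 <- as.integer(data$time_since == "t0")
    "(1 + is_t0 | person_id)"
  } else "(1 | person_id)"
  form <- as.formula(paste("pa_z ~", paste(rhs, collapse = " + "), "+",
                           re_person, "+ (1 | day_id)"))
  ctrl <- lmerControl(calc.derivs = FALSE,
                      check.conv.singular = "ignore")
  warnings_seen <- character()
  fit <- withCallingHandlers(
    lmer(form, data = data, REML = identical(spec$estimation, "REML"),
         control = ctrl),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  conv_opt <- fit@optinfo$conv$opt
  converged <- (is.null(conv_opt) || conv_opt == 0) &&
    !any(grepl("failed to converge|unable to evaluate|Downdated",
               warnings_seen, ignore.case = TRUE))
  vc <- as.data.frame(VarCorr(fit))
  get_vc <- function(g) {
    i <- which(vc$grp == g & (is.na(vc$var1) | vc$var1 == "(Intercept)") &
                 is.na(vc$var2))
    if (length(i)) vc$vcov[i[1]] else 0
  }
  beta <- fixef(fit)
  V <- as.matrix(vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(
    beta = beta, vcov = V,
    var_person = get_vc("person_id"), var_day = get_vc("day_id"),
    var_resid = vc$vcov[vc$grp == "Residual"][1],
    loglik = as.numeric(logLik(fit)),
    converged = converged, warnings = warnings_seen,
    n_obs = nrow(data),
    n_days = length(unique(data$day_id)),
    n_persons = length(unique(data$person_id)),
    spec = spec, model = fit, data = data,
    timepoints = levels(data$time_since),
    groups = levels(data$group)
  ), class = "esm_fit")
}

#' @export
print.esm_fit <- function(x, ...) {
  cat("Three-level LMM (", x$spec$estimation, "), stress type: ",
      x$spec$stress_type, "\n", sep = "")
  cat(x$n_obs, " prompts, ", x$n_days, " days, ", x$n_persons,
      " persons; logLik = ", format(x$loglik, digits = 6), "\n", sep = "")
  cat("variance components: person ", format(x$var_person, digits = 4),
      ", day ", format(x$var_day, digits = 4),
      ", residual ", format(x$var_resid, digits = 4), "\n", sep = "")
  if (!x$converged) cat("** model did not converge **\n")
  print(coef_table(x, check_convergence = FALSE), row.names = FALSE,
        digits = 3)
  invisible(x)
}

# Wald inference for the linear combination L'beta. L is a named numeric
# vector over coefficient names; unnamed coefficients count as 0.
.lincom <- function(fit, L, label, alpha = 0.05) {
  bad <- setdiff(names(L), names(fit$beta))
  if (length(bad)) {
    stop("coefficient(s) not in model: ", paste(bad, collapse = ", "))
  }
  v <- setNames(numeric(length(fit$beta)), names(fit$beta))
  v[names(L)] <- L
  b <- sum(v * fit$beta)
  se <- sqrt(drop(t(v) %*% fit$vcov %*% v))
  z <- qnorm(1 - alpha / 2)
  data.frame(label = label, b = b,
             ci_low = b - z * se, ci_high = b + z * se,
             se = se, p = 2 * pnorm(-abs(b / se)),
             stringsAsFactors = FALSE)
}

.ts_coef <- function(fit, tp) paste0("time_since", tp)

# interaction coefficient name, robust to term ordering
.int_coef <- function(fit, tp, grp) {
  cand <- c(paste0("time_since", tp, ":group", grp),
            paste0("group", grp, ":time_since", tp))
  hit <- cand[cand %in% names(fit$beta)]
  if (length(hit) == 0L) NA_character_ else hit[1]
}

#' Full fixed-effect table
#'
#' All fixed effects of a fit with Wald 95% CIs and two-sided p-values.
#'
#' @param fit An `esm_fit`.
#' @param alpha CI level is `1 - alpha`.
#' @param check_convergence Error on non-converged fits (default `TRUE`).
#' @return Data frame with `term`, `b`, `ci_low`, `ci_high`, `se`, `p`.
#' @export
coef_table <- function(fit, alpha = 0.05, check_convergence = TRUE) {
  if (check_convergence && !fit$converged) {
    stop("model did not converge; no contrasts computed")
  }
  out <- do.call(rbind, lapply(names(fit$beta), function(nm) {
    .lincom(fit, setNames(1, nm), nm, alpha)
  }))
  names(out)[1] <- "term"
  out
}

#' Within-group contrasts against baseline
#'
#' Compares positive affect at each post-baseline time point (`t0` ...
#' `tK`) with the baseline `t-1` (the reference category), i.e. the
#' coefficient of each `time_since` dummy, with Wald 95% CI and p-value.
#' On an interaction fit, pass `group` to obtain that group's contrasts
#' (reference-group dummy plus interaction term).
#'
#' @param fit An `esm_fit` with `t-1` as reference.
#' @param timepoints Character vector of time points (default: all
#'   modelled `t0` ... `tK`). A requested time point absent from the model
#'   yields a labelled `NA` row, never a silent skip.
#' @param group Optional group label for interaction fits.
#' @param alpha CI level is `1 - alpha`.
#' @return Data frame of contrasts (`label`, `b`, `ci_low`, `ci_high`,
#'   `se`, `p`, `note`).
#' @export
within_group_contrasts <- function(fit, timepoints = NULL, group = NULL,
                                   alpha = 0.05) {
  if (!fit$converged) stop("model did not converge; no contrasts computed")
  if (is.null(timepoints)) {
    timepoints <- setdiff(fit$timepoints, "t-1")
  }
  ref_group <- fit$groups[1]
  rows <- lapply(timepoints, function(tp) {
    nm <- .ts_coef(fit, tp)
    if (!nm %in% names(fit$beta)) {
      return(data.frame(label = tp, b = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, se = NA_real_, p = NA_real_,
                        note = "time point not in model",
                        stringsAsFactors = FALSE))
    }
    L <- setNames(1, nm)
    if (!is.null(group) && !identical(group, ref_group)) {
      inm <- .int_coef(fit, tp, group)
      if (is.na(inm)) {
        return(data.frame(label = tp, b = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, se = NA_real_, p = NA_real_,
                          note = "interaction term not in model",
                          stringsAsFactors = FALSE))
      }
      L <- c(L, setNames(1, inm))
    }
    cbind(.lincom(fit, L, tp, alpha), note = NA_character_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(group)) out$group <- group
  out
}

#' Joint Wald test of the group main effect
#'
#' Tests that all group main-effect coefficients are zero (interaction
#' terms, if present, are not part of this test) with a Wald chi-square
#' on as many degrees of freedom as there are group dummies.
#'
#' @param fit An `esm_fit` including group terms.
#' @return List of class `esm_wald`: `statistic`, `df`, `p_value`.
#' @export
group_main_effect <- function(fit) {
  idx <- grepl("^group", names(fit$beta)) & !grepl(":", names(fit$beta))
  if (!any(idx)) stop("fit has no group main-effect terms")
  b <- fit$beta[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  if (rcond(V) < .Machine$double.eps * 100) {
    stop("singular covariance among group terms: ",
         paste(names(b), collapse = ", "))
  }
  W <- drop(t(b) %*% solve(V, b))
  structure(list(statistic = W, df = length(b),
                 p_value = pchisq(W, df = length(b), lower.tail = FALSE)),
            class = "esm_wald")
}

#' @export
print.esm_wald <- function(x, ...) {
  cat(sprintf("Wald chi-square(%d) = %.2f, p = %.3g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

.group_pairs <- function(groups) {
  pairs <- list(c("at_risk", "control"), c("patient", "control"),
                c("patient", "at_risk"))
  Filter(function(p) all(p %in% groups), pairs)
}

# L for the difference "a - b" in group main-effect dummies (reference
# group has no dummy -> contributes nothing)
.group_dummy_L <- function(fit, a, b) {
  L <- numeric(0)
  na <- paste0("group", a); nb <- paste0("group", b)
  if (na %in% names(fit$beta)) L <- c(L, setNames(1, na))
  if (nb %in% names(fit$beta)) L <- c(L, setNames(-1, nb))
  L
}

#' Between-group contrasts at baseline and at the stressor prompt
#'
#' Pairwise group contrasts (at-risk vs controls, patients vs controls,
#' patients vs at-risk) from an interaction fit. At `"t-1"` the contrast
#' is the difference in expected baseline positive affect (the group
#' dummies). At `"t0"` it is the difference in stress reactivity, i.e.
#' the difference in the change from baseline to the stressor prompt
#' (the time_since x group interaction terms) - the quantity the
#' reactivity hypothesis is about.
#'
#' @param fit An `esm_fit` with group and interaction terms.
#' @param timepoint `"t-1"` or `"t0"`.
#' @param alpha CI level is `1 - alpha`.
#' @return Data frame with one row per pair (`pair`, `timepoint`, `b`,
#'   `ci_low`, `ci_high`, `se`, `p`, `note`). A non-converged fit yields
#'   `NA` rows with an explanatory note rather than an error, so the
#'   non-convergence is propagated into the reported tables.
#' @export
between_group_contrasts <- function(fit, timepoint = c("t-1", "t0"),
                                    alpha = 0.05) {
  timepoint <- match.arg(timepoint)
  pairs <- .group_pairs(fit$groups)
  if (!length(pairs)) stop("fit has fewer than 2 groups")
  empty <- function(pair, note) {
    data.frame(pair = paste(pair[1], "vs", pair[2]), timepoint = timepoint,
               b = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               se = NA_real_, p = NA_real_, note = note,
               stringsAsFactors = FALSE)
  }
  if (!fit$converged) {
    return(do.call(rbind, lapply(pairs, empty,
                                 note = "model did not converge")))
  }
  rows <- lapply(pairs, function(pr) {
    if (timepoint == "t-1") {
      L <- .group_dummy_L(fit, pr[1], pr[2])
    } else {
      ia <- .int_coef(fit, "t0", pr[1])
      ib <- .int_coef(fit, "t0", pr[2])
      L <- numeric(0)
      if (!is.na(ia)) L <- c(L, setNames(1, ia))
      if (!is.na(ib)) L <- c(L, setNames(-1, ib))
      if (!length(L)) return(empty(pr, "interaction terms not in model"))
    }
    out <- .lincom(fit, L, paste(pr[1], "vs", pr[2]), alpha)
    data.frame(pair = out$label, timepoint = timepoint, b = out$b,
               ci_low = out$ci_low, ci_high = out$ci_high, se = out$se,
               p = out$p, note = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Determine the recovery window from within-group contrasts
#'
#' A group has recovered at the first follow-up prompt whose deviation
#' from baseline is no longer significant at `alpha`. The overall
#' recovery period runs from `t1` to the latest recovery point across
#' groups (at minimum the single point `t1`), e.g. `t1`-`t2` when at
#' least one group is still below baseline at `t1` and all groups have
#' recovered by `t2`.
#'
#' @param within_list Named list (one element per group) of within-group
#'   contrast tables from [within_group_contrasts()] covering `t1` ...
#'   `tK`.
#' @param alpha Significance level (default 0.05).
#' @return List: `per_group` (first recovered lag per group; `K + 1`
#'   when a group never recovers within the window), `overall_end`,
#'   `window` (integer lags `1:overall_end`), `all_recovered`.
#' @export
recovery_window <- function(within_list, alpha = 0.05) {
  if (!length(within_list) || is.null(names(within_list))) {
    stop("within_list must be a named list of contrast tables")
  }
  per_group <- vapply(within_list, function(tab) {
    lab <- tab$label
    ks <- suppressWarnings(as.integer(sub("^t", "", lab)))
    keep <- !is.na(ks) & ks >= 1
    if (!any(keep)) stop("contrast table has no follow-up time points")
    ks <- ks[keep]
    p <- tab$p[keep]
    o <- order(ks)
    ks <- ks[o]; p <- p[o]
    if (anyNA(p)) stop("missing p-value in contrast sequence")
    rec <- ks[p >= alpha]
    if (length(rec)) rec[1] else max(ks) + 1L
  }, integer(1))
  K <- max(vapply(within_list, function(tab) {
    ks <- suppressWarnings(as.integer(sub("^t", "", tab$label)))
    max(ks, na.rm = TRUE)
  }, integer(1)))
  all_recovered <- all(per_group <= K)
  overall_end <- min(max(per_group), K)
  overall_end <- max(overall_end, 1L)
  list(per_group = per_group, overall_end = overall_end,
       window = seq_len(overall_end), all_recovered = all_recovered)
}

#' Average deviation from baseline over the recovery period
#'
#' Quantifies affective recovery as the mean deviation of positive affect
#' from baseline over the follow-up window (e.g. `t1`-`t2`). On a
#' per-group fit (no `pair`) this is the mean of the window's
#' `time_since` coefficients (baseline is the reference, so its
#' coefficient is zero). With `pair` on an interaction fit it is the
#' between-group difference of these means, obtained from the
#' corresponding interaction-coefficient average, with delta-method Wald
#' CI and p-value.
#'
#' @param fit An `esm_fit`.
#' @param window Integer vector of follow-up lags, e.g. `1:2`.
#' @param pair Optional `c(group_a, group_b)` for the between-group
#'   contrast `a - b`.
#' @param alpha CI level is `1 - alpha`.
#' @return One-row contrast data frame labelled e.g. `"t1-t2"`.
#' @export
recovery_contrast <- function(fit, window, pair = NULL, alpha = 0.05) {
  if (!fit$converged) stop("model did not converge; no contrasts computed")
  if (!length(window) || any(window < 1)) {
    stop("window must contain follow-up lags >= 1")
  }
  tps <- paste0("t", window)
  missing_tp <- tps[!vapply(tps, function(tp)
    .ts_coef(fit, tp) %in% names(fit$beta), logical(1))]
  if (length(missing_tp)) {
    stop("window extends beyond the modelled lags: ",
         paste(missing_tp, collapse = ", "))
  }
  w <- 1 / length(tps)
  label <- if (length(tps) > 1) {
    paste0(tps[1], "-", tps[length(tps)])
  } else tps
  if (is.null(pair)) {
    L <- setNames(rep(w, length(tps)), vapply(tps, .ts_coef, "", fit = fit))
    return(.lincom(fit, L, label, alpha))
  }
  ref_group <- fit$groups[1]
  term_for <- function(grp, tp) {
    if (identical(grp, ref_group)) return(NULL)  # reference: deviation is
    nm <- .int_coef(fit, tp, grp)                # carried by the dummies
    if (is.na(nm)) stop("interaction term missing for group ", grp,
                        " at ", tp)
    nm
  }
  L <- setNames(numeric(0), character(0))
  for (tp in tps) {
    a <- term_for(pair[1], tp)
    b <- term_for(pair[2], tp)
    if (!is.null(a)) L[a] <- (if (a %in% names(L)) L[a] else 0) + w
    if (!is.null(b)) L[b] <- (if (b %in% names(L)) L[b] else 0) - w
  }
  if (!length(L)) stop("pair does not involve any interaction terms")
  out <- .lincom(fit, L, paste(pair[1], "vs", pair[2], label), alpha)
  out$pair <- paste(pair[1], "vs", pair[2])
  out$window <- label
  out
}

# Step-up (Simes/Hochberg) closure over a vector of p-values: reject all
# hypotheses up to the largest rank k with p_(k) <= alpha / (m - k + 1).
.hochberg <- function(p, family_alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  thresholds <- family_alpha / (m - seq_len(m) + 1)
  ok <- which(sorted <= thresholds)
  kmax <- if (length(ok)) max(ok) else 0L
  sig_sorted <- seq_len(m) <= kmax
  sig <- logical(m)
  sig[o] <- sig_sorted
  list(significant = sig, thresholds = thresholds, order = o, kmax = kmax)
}

#' Simes (step-up) correction across the three stress measures
#'
#' Each hypothesis is tested once per stress measure (event, activity,
#' composite), so each family holds three p-values. Sorted ascending,
#' the most significant p-value is compared with `alpha/3` (0.0167,
#' which reports as .02 at two decimals), the second with `alpha/2`
#' (.03 at two decimals) and the third with `alpha`; the step-up closure
#' then rejects every hypothesis up to the largest rank passing its
#' threshold, which makes the decision monotone in the p-values.
#'
#' @param p_values Numeric vector of exactly three p-values in (0, 1].
#' @param family_alpha Family-wise level (default 0.05).
#' @return Object of class `simes_outcome`: `p_values`, `significant`
#'   (flags in input order), `thresholds_exact`, `thresholds_rounded`
#'   (two decimals), and the sort order.
#' @export
#' @examples
#' simes_correct(c(0.001, 0.026, 0.2))$significant  # TRUE FALSE FALSE
simes_correct <- function(p_values, family_alpha = 0.05) {
  if (length(p_values) != 3) {
    stop("simes_correct expects exactly 3 p-values (one per stress measure)")
  }
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  h <- .hochberg(p_values, family_alpha)
  structure(list(p_values = p_values, significant = h$significant,
                 thresholds_exact = h$thresholds,
                 thresholds_rounded = round(h$thresholds, 2),
                 order = h$order, family_alpha = family_alpha),
            class = "simes_outcome")
}

#' @export
print.simes_outcome <- function(x, ...) {
  cat("Simes step-up correction at family alpha =", x$family_alpha, "\n")
  df <- data.frame(p = x$p_values[x$order],
                   threshold = x$thresholds_exact,
                   significant = x$significant[x$order])
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Adjusted predictive margins by group and time point
#'
#' Model-based expected positive affect per group x time point with the
#' adjustment covariates held at their analytic-sample means (centred age
#' at 0, the female indicator at its observed share, the
#' subsequent-stress control - if present - at its observed mean). These
#' are the quantities plotted as group trajectories with 95% CI error
#' bars.
#'
#' @param fit An `esm_fit` (typically the interaction model).
#' @param alpha CI level is `1 - alpha`.
#' @return Data frame: `group`, `time_since`, `margin`, `ci_low`,
#'   `ci_high`, `se`.
#' @export
adjusted_margins <- function(fit, alpha = 0.05) {
  if (!fit$converged) stop("model did not converge; no margins computed")
  groups <- fit$groups
  if (is.null(groups) || !length(groups)) groups <- NA_character_
  covar_means <- c(age_c = 0,
                   female = mean(fit$data$female),
                   subsequent_stress = mean(fit$data$subsequent_stress))
  rows <- list()
  for (g in groups) for (tp in fit$timepoints) {
    L <- setNames(1, "(Intercept)")
    if (tp != "t-1") L[.ts_coef(fit, tp)] <- 1
    if (!is.na(g) && g != groups[1]) {
      gnm <- paste0("group", g)
      if (gnm %in% names(fit$beta)) L[gnm] <- 1
      if (tp != "t-1") {
        inm <- .int_coef(fit, tp, g)
        if (!is.na(inm)) L[inm] <- 1
      }
    }
    for (cv in names(covar_means)) {
      if (cv %in% names(fit$beta)) L[cv] <- covar_means[[cv]]
    }
    est <- .lincom(fit, L, paste(g, tp), alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, time_since = tp, margin = est$b,
      ci_low = est$ci_low, ci_high = est$ci_high, se = est$se,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
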