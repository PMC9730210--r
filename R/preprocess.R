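#' Score momentary positive affect
#'
#' Mean of the three positive-affect items (cheerful, relaxed, satisfied)
#' on the 1-7 scale. At least `min_items` non-missing items are required,
#' otherwise the score is missing.
#'
#' @param cheerful,relaxed,satisfied Numeric vectors of item responses
#'   (1-7 or `NA`).
#' @param min_items Minimum number of observed items (default 2).
#' @return Numeric vector of scores.
#' @export
#' @examples
#' score_positive_affect(7, 1, NA)  # 4
score_positive_affect <- function(cheerful, relaxed, satisfied,
                                  min_items = 2) {
  m <- cbind(cheerful, relaxed, satisfied)
  if (any(m < 1 | m > 7, na.rm = TRUE)) {
    stop("positive-affect items must lie in 1..7 (mask invalid values as NA)")
  }
  n_ok <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[n_ok < min_items] <- NA_real_
  out
}

#' Recode bipolar event pleasantness to 1-7 unpleasantness
#'
#' Maps the bipolar event-pleasantness rating (-3 = very unpleasant ...
#' +3 = very pleasant) onto a 1-7 unpleasantness scale matching the other
#' items: `4 - x`, so +3 becomes 1 (very pleasant) and -3 becomes 7
#' (very unpleasant).
#'
#' @param x Numeric vector in -3..3 (or `NA`).
#' @return Numeric vector in 1..7.
#' @export
recode_event_unpleasantness <- function(x) {
  if (any(x < -3 | x > 3, na.rm = TRUE)) {
    stop("event pleasantness must lie in -3..3")
  }
  4 - x
}

#' Score activity-related stress
#'
#' Mean of the four current-activity items ("costs energy", "skilled at
#' this" reverse coded, "a challenge", "prefer doing something else") on
#' the 1-7 scale; higher = more stressful activity. The skilled item is
#' reverse coded as `8 - x` before averaging. At least `min_items`
#' non-missing items are required.
#'
#' @param energy,skilled,challenge,prefer_else Numeric item vectors
#'   (1-7 or `NA`); `skilled` is the raw (not yet reversed) response.
#' @param min_items Minimum number of observed items (default 2).
#' @return Numeric vector of activity-stress scores.
#' @export
#' @examples
#' score_activity(6, 2, 5, 7)  # mean(6, 6, 5, 7) = 6
score_activity <- function(energy, skilled, challenge, prefer_else,
                           min_items = 2) {
  m <- cbind(energy, 8 - skilled, challenge, prefer_else)
  if (any(m < 1 | m > 7, na.rm = TRUE)) {
    stop("activity items must lie in 1..7 (mask invalid values as NA)")
  }
  n_ok <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[n_ok < min_items] <- NA_real_
  out
}

#' Dichotomise momentary stress
#'
#' Marks a prompt as event-stressed when the recoded event unpleasantness
#' exceeds `event_threshold` (default 4, i.e. the original bipolar rating
#' was negative) and as activity-stressed when the activity score exceeds
#' `activity_threshold` (default 4, above the scale midpoint). The
#' composite measure is the logical OR: presence of one or both types of
#' stress. A missing score yields a `FALSE` flag together with a
#' missingness marker column, so "no stress" and "not assessed" stay
#' distinguishable.
#'
#' @param derived Data frame with `event_unpleasantness` and
#'   `activity_score` columns.
#' @param event_threshold,activity_threshold Strict lower cut-offs on the
#'   1-7 scales.
#' @return `derived` with logical columns `event_stress`,
#'   `activity_stress`, `composite_stress` and marker columns
#'   `event_stress_missing`, `activity_stress_missing`.
#' @export
flag_stress <- function(derived, event_threshold = 4,
                        activity_threshold = 4) {
  eu <- derived$event_unpleasantness
  as_ <- derived$activity_score
  derived$event_stress <- !is.na(eu) & eu > event_threshold
  derived$activity_stress <- !is.na(as_) & as_ > activity_threshold
  derived$composite_stress <- derived$event_stress | derived$activity_stress
  derived$event_stress_missing <- is.na(eu)
  derived$activity_stress_missing <- is.na(as_)
  derived
}

#' Centre and standardise positive affect
#'
#' Produces the standardised outcome `pa_z`. Two methods are supported:
#'
#' * `"person_day"`: sequential demeaning - subtract each person's mean,
#'   then the person-day mean of the person-centred values - followed by
#'   division by the overall (population) standard deviation of the
#'   doubly-centred values. The result has overall mean 0 and SD 1 and
#'   within-person means of 0; all between-person and between-day level
#'   differences are removed.
#' * `"grand"`: plain z-standardisation around the grand mean. Person and
#'   day level differences are retained (the multilevel model's random
#'   intercepts absorb them); this is the scale on which between-group
#'   level contrasts are estimable.
#'
#' @param derived Data frame with `person_id`, `day_index`, `pa_raw`.
#' @param method `"person_day"` or `"grand"`.
#' @return `derived` with a `pa_z` column added.
#' @export
center_and_standardize <- function(derived,
                                   method = c("person_day", "grand")) {
  method <- match.arg(method)
  x <- derived$pa_raw
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  }
  if (method == "grand") {
    s <- pop_sd(x)
    if (is.na(s) || s == 0) {
      warning("positive affect has zero variance; pa_z set to 0")
      derived$pa_z <- ifelse(is.na(x), NA_real_, 0)
      return(derived)
    }
    derived$pa_z <- (x - mean(x, na.rm = TRUE)) / s
    return(derived)
  }
  n_per_person <- ave(!is.na(x), derived$person_id, FUN = sum)
  single <- n_per_person < 2 & !is.na(x)
  if (any(single)) {
    warning(sum(single),
            " prompt(s) from persons with a single observed prompt ",
            "excluded from centering (pa_z set to NA)")
    x[single] <- NA
  }
  pc <- x - ave(x, derived$person_id,
                FUN = function(v) mean(v, na.rm = TRUE))
  pdc <- pc - ave(pc, paste(derived$person_id, derived$day_index, sep = "\r"),
                  FUN = function(v) mean(v, na.rm = TRUE))
  s <- pop_sd(pdc)
  if (is.na(s) || s == 0) {
    warning("doubly-centred positive affect has zero variance; pa_z set to 0")
    derived$pa_z <- ifelse(is.na(pdc), NA_real_, 0)
  } else {
    derived$pa_z <- pdc / s
  }
  derived
}

#' Derive scored prompts from an ESM dataset
#'
#' Runs the full scoring chain on a (typically compliance-filtered)
#' dataset: masks validation-flagged cells, scores positive affect and
#' activity stress, recodes event unpleasantness, dichotomises the stress
#' measures, and standardises the outcome.
#'
#' @param ds An [esm_dataset()].
#' @param event_threshold,activity_threshold Passed to [flag_stress()].
#' @param centering Passed to [center_and_standardize()]; the pipeline
#'   default is `"grand"` so that between-group level contrasts remain
#'   estimable (see the package vignette).
#' @param min_items Passed to the scoring functions.
#' @return Data frame of derived prompts: keys, raw activity/event items
#'   (reverse-coded where applicable), `pa_raw`, `pa_z`,
#'   `event_unpleasantness`, `activity_score`, and the stress flags.
#' @export
derive_prompts <- function(ds, event_threshold = 4, activity_threshold = 4,
                           centering = c("grand", "person_day"),
                           min_items = 2) {
  centering <- match.arg(centering)
  p <- ds$prompts
  v <- attr(ds, "validation")
  if (!is.null(v)) {
    for (i in seq_len(nrow(v))) {
      if (v$column[i] %in% names(.esm_ranges)) {
        p[v$row[i], v$column[i]] <- NA
      }
    }
  }
  d <- p[, c("person_id", "day_index", "beep_index")]
  d$pa_raw <- score_positive_affect(p$pa_cheerful, p$pa_relaxed,
                                    p$pa_satisfied, min_items = min_items)
  d$event_unpleasantness <- recode_event_unpleasantness(p$event_pleasantness)
  d$activity_score <- score_activity(p$act_energy, p$act_skilled,
                                     p$act_challenge, p$act_prefer_else,
                                     min_items = min_items)
  # indicator items kept for the composite-measure PCA check
  d$ind_event_unpleasantness <- d$event_unpleasantness
  d$ind_act_energy <- p$act_energy
  d$ind_act_skilled_rev <- 8 - p$act_skilled
  d$ind_act_challenge <- p$act_challenge
  d$ind_act_prefer_else <- p$act_prefer_else
  d <- flag_stress(d, event_threshold = event_threshold,
                   activity_threshold = activity_threshold)
  d <- center_and_standardize(d, method = centering)
  d <- d[order(d$person_id, d$day_index, d$beep_index), ]
  rownames(d) <- NULL
  attr(d, "centering") <- centering
  attr(d, "thresholds") <- c(event = event_threshold,
                             activity = activity_threshold)
  d
}

#' Principal-component check of the composite stress measure
#'
#' Principal components of the five stress indicators (recoded event
#' unpleasantness and the four activity items, skilled reverse coded) on
#' the correlation scale, used to justify collapsing them into a single
#' composite presence measure. Components are retained by the
#' eigenvalue > `retain_above` rule.
#'
#' @param derived Derived prompt table from [derive_prompts()].
#' @param retain_above Eigenvalue retention threshold (default 1).
#' @return Object of class `esm_pca`: `loadings` (5 x k matrix of
#'   eigenvector loadings for retained components), `variance_explained`
#'   (proportions for all five components, non-increasing),
#'   `n_components_retained`, `eigenvalues`, `n_used`.
#' @export
pca_justification <- function(derived, retain_above = 1) {
  cols <- c("ind_event_unpleasantness", "ind_act_energy",
            "ind_act_skilled_rev", "ind_act_challenge",
            "ind_act_prefer_else")
  missing_cols <- setdiff(cols, names(derived))
  if (length(missing_cols)) {
    stop("derived table lacks indicator column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  m <- derived[, cols]
  names(m) <- c("event_unpleasantness", "act_energy", "act_skilled_rev",
                "act_challenge", "act_prefer_else")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 50) {
    stop("pca_justification needs at least 50 complete prompts, got ",
         nrow(m))
  }
  sds <- vapply(m, sd, numeric(1))
  if (any(sds == 0)) {
    warning("singular correlation matrix (constant indicator); ",
            "no retention decision")
    return(structure(list(loadings = NULL, variance_explained = NULL,
                          eigenvalues = NULL,
                          n_components_retained = NA_integer_,
                          n_used = nrow(m)),
                     class = "esm_pca"))
  }
  cm <- cor(m)
  eig <- eigen(cm, symmetric = TRUE)
  ve <- eig$values / sum(eig$values)
  n_ret <- sum(eig$values > retain_above)
  loadings <- eig$vectors[, seq_len(max(n_ret, 1L)), drop = FALSE]
  rownames(loadings) <- names(m)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  structure(list(loadings = loadings, variance_explained = ve,
                 eigenvalues = eig$values,
                 n_components_retained = n_ret, n_used = nrow(m)),
            class = "esm_pca")
}

#' @export
print.esm_pca <- function(x, ...) {
  cat("PCA of the 5 stress indicators (", x$n_used, " prompts)\n", sep = "")
  if (is.null(x$variance_explained)) {
    cat("singular correlation matrix; no retention decision\n")
    return(invisible(x))
  }
  cat("variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n", sep = "")
  cat("components retained (eigenvalue > 1): ", x$n_components_retained,
      "\n", sep = "")
  invisible(x)
}
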