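#' Default column mapping for long-format ESM files
#'
#' Maps the canonical column names used throughout the package to the
#' column names found in a CSV file. The default is the identity mapping.
#'
#' @param ... Named character entries overriding individual mappings,
#'   e.g. `person_id = "subject"` when the file calls the identifier
#'   column `subject`.
#' @return Named character vector: names are canonical columns, values are
#'   file columns.
#' @export
#' @examples
#' esm_schema(person_id = "subject")
esm_schema <- function(...) {
  schema <- setNames(.esm_columns, .esm_columns)
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), .esm_columns)
    if (length(bad)) {
      stop("unknown schema entries: ", paste(bad, collapse = ", "))
    }
    schema[names(override)] <- override
  }
  schema
}

# Range/type validation of a prompt table. Returns a data.frame with one
# row per flagged cell (row, column, value, issue). Values are flagged,
# not coerced; scoring functions mask flagged cells downstream.
.validate_prompts <- function(prompts, design = NULL) {
  flags <- list()
  add <- function(rows, column, issue) {
    if (!length(rows)) return()
    flags[[length(flags) + 1L]] <<- data.frame(
      row = rows, column = column,
      value = as.character(prompts[[column]][rows]),
      issue = issue, stringsAsFactors = FALSE
    )
  }
  for (col in names(.esm_ranges)) {
    if (!col %in% names(prompts)) next
    x <- prompts[[col]]
    rng <- .esm_ranges[[col]]
    add(which(!is.na(x) & (x < rng[1] | x > rng[2])), col, "out_of_range")
  }
  if ("response_delay_min" %in% names(prompts)) {
    x <- prompts$response_delay_min
    add(which(!is.na(x) & x < 0), "response_delay_min", "negative_delay")
  }
  if ("scheduled_time" %in% names(prompts) && !is.null(design) &&
      !is.null(design$day_start) && !is.null(design$day_end)) {
    mins <- .clock_to_min(prompts$scheduled_time)
    lo <- .clock_to_min(design$day_start)
    hi <- .clock_to_min(design$day_end)
    add(which(!is.na(mins) & (mins < lo | mins > hi)),
        "scheduled_time", "outside_sampling_window")
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(row = integer(), column = character(), value = character(),
               issue = character(), stringsAsFactors = FALSE)
}

.clock_to_min <- function(x) {
  parts <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", as.character(x)))
  vapply(parts, function(p) {
    if (length(p) < 3) return(NA_real_)
    as.numeric(p[2]) * 60 + as.numeric(p[3])
  }, numeric(1))
}

.min_to_clock <- function(m) {
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Construct a prompt-level ESM dataset
#'
#' Bundles a long-format prompt table with a person table and the sampling
#' design. One row of `prompts` is one scheduled signal; unanswered signals
#' are rows with a missing `response_delay_min` and missing item responses.
#'
#' @param prompts Data frame with the canonical columns (see [esm_schema()]).
#' @param persons Optional person-level data frame (`person_id`, `group`,
#'   `age`, `gender`); derived from `prompts` when `NULL`.
#' @param design List describing the sampling design: `days`,
#'   `beeps_per_day`, `day_start`, `day_end`, `block_minutes`.
#' @param provenance Free-text note on where the data came from.
#' @return An object of class `esm_dataset`: a list with elements
#'   `prompts`, `persons`, `design`, `provenance`, and a `validation`
#'   attribute listing flagged cells.
#' @export
esm_dataset <- function(prompts, persons = NULL,
                        design = list(days = max(prompts$day_index),
                                      beeps_per_day = max(prompts$beep_index),
                                      day_start = "07:30", day_end = "22:30",
                                      block_minutes = 90),
                        provenance = "") {
  needed <- setdiff(.esm_columns, c("group", "age", "gender"))
  missing_cols <- setdiff(needed, names(prompts))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- duplicated(.key(prompts))
  if (any(dup)) {
    stop("duplicate (person_id, day_index, beep_index) prompt key(s), e.g. ",
         gsub("\r", "/", .key(prompts)[which(dup)[1]]))
  }
  if (is.null(persons)) {
    for (col in c("group", "age", "gender")) {
      if (!col %in% names(prompts)) {
        stop("missing required column(s): ", col)
      }
    }
    persons <- unique(prompts[, c("person_id", "group", "age", "gender")])
    if (anyDuplicated(persons$person_id)) {
      bad <- persons$person_id[duplicated(persons$person_id)]
      stop("group/age/gender not constant within person(s): ",
           paste(unique(bad), collapse = ", "))
    }
  }
  if (!all(prompts$person_id %in% persons$person_id)) {
    stop("prompts reference person_id values absent from the person table")
  }
  if (any(!is.na(persons$age) & persons$age <= 0)) {
    stop("age must be positive")
  }
  ds <- structure(
    list(prompts = prompts, persons = persons, design = design,
         provenance = provenance),
    class = "esm_dataset"
  )
  attr(ds, "validation") <- .validate_prompts(prompts, design)
  ds
}

#' @export
print.esm_dataset <- function(x, ...) {
  n_ans <- sum(!is.na(x$prompts$response_delay_min))
  cat("ESM dataset: ", nrow(x$persons), " persons, ",
      nrow(x$prompts), " scheduled prompts (", n_ans, " answered)\n", sep = "")
  cat("design: ", x$design$days, " days x ", x$design$beeps_per_day,
      " beeps\n", sep = "")
  v <- attr(x, "validation")
  if (!is.null(v) && nrow(v)) {
    cat("validation: ", nrow(v), " flagged cell(s)\n", sep = "")
  }
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a long-format prompt-level ESM CSV
#'
#' One row per scheduled prompt; empty cells are missing values.
#' Out-of-range item responses are flagged in the dataset's `validation`
#' attribute and retained, never silently coerced.
#'
#' @param path Path to the CSV file.
#' @param schema Column mapping from [esm_schema()].
#' @return An [esm_dataset()].
#' @export
read_esm_long <- function(path, schema = esm_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  prompts <- raw[, unname(schema)]
  names(prompts) <- names(schema)
  num_cols <- c("age", "day_index", "beep_index", "response_delay_min",
                names(.esm_ranges))
  for (col in num_cols) {
    x <- prompts[[col]]
    if (!is.numeric(x)) {
      x[!is.na(x) & !nzchar(trimws(x))] <- NA
      prompts[[col]] <- suppressWarnings(as.numeric(x))
    }
  }
  esm_dataset(prompts, provenance = paste0("read from ", basename(path)))
}

#' Write a prompt-level ESM dataset back to CSV
#'
#' Inverse of [read_esm_long()]: writes one row per scheduled prompt with
#' the canonical columns; missing values become empty cells.
#'
#' @param ds An [esm_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_esm_long <- function(ds, path) {
  out <- merge(ds$prompts[, setdiff(names(ds$prompts),
                                    c("group", "age", "gender"))],
               ds$persons, by = "person_id", sort = FALSE)
  out <- out[order(out$person_id, out$day_index, out$beep_index),
             .esm_columns]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Compliance filtering of prompts and persons
#'
#' Applies the two-stage inclusion rule used in signal-contingent ESM
#' protocols: first remove prompts that were not answered within
#' `max_delay` minutes of the signal (unanswered prompts count as such) or
#' on which every positive-affect and stress item is missing; then remove
#' persons left with fewer than `min_prompts` prompts.
#'
#' @param ds An [esm_dataset()].
#' @param max_delay Maximum allowed response delay in minutes (default 15).
#' @param min_prompts Minimum number of retained prompts a person must have
#'   to stay in the sample (default 20).
#' @return A list with `dataset` (the filtered [esm_dataset()]) and `log`,
#'   a data frame with one row per removal reason
#'   (`stage`, `reason`, `n_prompts_removed`, `n_persons_removed`).
#'   The prompt-level stage distinguishes unanswered prompts, prompts over
#'   the delay limit, and answered prompts with all items missing, so the
#'   contributions stay separable.
#' @export
apply_compliance_filter <- function(ds, max_delay = 15, min_prompts = 20) {
  p <- ds$prompts
  n_input <- nrow(p)

  unanswered <- is.na(p$response_delay_min)
  late <- !unanswered & p$response_delay_min > max_delay
  items <- c(.pa_items, "event_pleasantness", .act_items)
  all_missing <- !unanswered & !late &
    rowSums(!is.na(p[, items, drop = FALSE])) == 0L

  drop1 <- unanswered | late | all_missing
  kept <- p[!drop1, , drop = FALSE]

  n_per_person <- table(factor(kept$person_id,
                               levels = ds$persons$person_id))
  low <- names(n_per_person)[n_per_person < min_prompts]
  drop2 <- kept$person_id %in% low
  kept2 <- kept[!drop2, , drop = FALSE]

  log <- data.frame(
    stage = c("prompt_level", "prompt_level", "prompt_level", "person_level"),
    reason = c("unanswered",
               sprintf("delay_gt_%g_min", max_delay),
               "all_items_missing",
               sprintf("fewer_than_%d_prompts", min_prompts)),
    n_prompts_removed = c(sum(unanswered), sum(late), sum(all_missing),
                          sum(drop2)),
    n_persons_removed = c(0L, 0L, 0L, length(low)),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(log$n_prompts_removed) + nrow(kept2) == n_input)

  if (nrow(kept2) == 0L) {
    stop("no analyzable data: every prompt was removed by the compliance filter")
  }
  persons <- ds$persons[ds$persons$person_id %in% kept2$person_id, ,
                        drop = FALSE]
  out <- esm_dataset(kept2, persons = persons, design = ds$design,
                     provenance = paste0(ds$provenance,
                                         " | compliance-filtered"))
  list(dataset = out, log = log)
}

#' Compliance percentage
#'
#' Integer-rounded percentage of scheduled prompts that were answered,
#' rounded half-up (so 47/60 = 78.33 reports as 78 and 49/60 = 81.67 as 82).
#'
#' @param n_answered Number of answered prompts (vectorised).
#' @param n_scheduled Number of scheduled prompts.
#' @return Integer percentage(s).
#' @export
#' @examples
#' compliance_percentage(45, 60)  # 75
compliance_percentage <- function(n_answered, n_scheduled) {
  if (any(n_scheduled <= 0)) stop("n_scheduled must be positive")
  if (any(n_answered < 0 | n_answered > n_scheduled)) {
    stop("n_answered must lie in [0, n_scheduled]")
  }
  as.integer(floor(100 * n_answered / n_scheduled + 0.5))
}

#' Person-level descriptive table with between-group tests
#'
#' Summarises the analytic sample per group the way staging studies report
#' it: gender counts, mean (SD) age, observations per person, stressful
#' days per person, and mean raw positive affect, with one-way ANOVA F
#' tests for person-level means, a Pearson chi-square for gender, and
#' unadjusted pairwise contrasts flagged at `alpha`. The unpleasantness of
#' the first daily stressor is reported on both candidate scales (recoded
#' 1-7 unpleasantness and the magnitude of the original bipolar rating),
#' since printed tables in this literature are ambiguous about which is
#' used.
#'
#' @param ds A compliance-filtered [esm_dataset()].
#' @param derived Derived prompt table from [derive_prompts()].
#' @param alpha Significance level for flagging pairwise contrasts.
#' @return List of class `esm_descriptives` with elements `per_group`,
#'   `gender_counts`, `tests`, and `contrasts`.
#' @export
descriptive_table <- function(ds, derived, alpha = 0.05) {
  persons <- ds$persons
  if (length(unique(persons$group)) < 2) {
    stop("descriptive_table needs at least 2 groups")
  }
  persons$group <- factor(persons$group,
                          levels = intersect(.esm_groups,
                                             unique(persons$group)))

  d <- derived
  per <- data.frame(person_id = persons$person_id,
                    group = persons$group,
                    age = persons$age,
                    female = as.integer(persons$gender == "female"))
  idx <- split(seq_len(nrow(d)), factor(d$person_id,
                                        levels = persons$person_id))
  per$n_obs <- vapply(idx, length, integer(1))
  per$stressful_days <- vapply(idx, function(i) {
    length(unique(d$day_index[i][d$composite_stress[i] %in% TRUE]))
  }, integer(1))
  per$pa_mean <- vapply(idx, function(i) mean(d$pa_raw[i], na.rm = TRUE),
                        numeric(1))

  # first composite stressor of each day, skipping days where it fell on
  # the first prompt (no baseline there, mirroring the analysis exclusions)
  first_u <- vapply(idx, function(i) {
    di <- d[i, ]
    u <- unlist(lapply(split(seq_len(nrow(di)), di$day_index), function(j) {
      f <- which(di$composite_stress[j] %in% TRUE)
      if (length(f) == 0L || f[1] == 1L) return(NA_real_)
      di$event_unpleasantness[j[f[1]]]
    }))
    mean(u, na.rm = TRUE)
  }, numeric(1))
  per$first_stressor_unpleasantness_1to7 <- first_u
  per$first_stressor_unpleasantness_bipolar_mag <- abs(first_u - 4)

  stats_of <- function(x, g) {
    data.frame(mean = tapply(x, g, mean, na.rm = TRUE),
               sd = tapply(x, g, function(v) {
                 v <- v[!is.na(v)]
                 if (length(v) < 2) NA_real_ else sd(v)
               }))
  }
  vars <- c(age = "age", n_obs = "n_obs", stressful_days = "stressful_days",
            pa_mean = "pa_mean",
            first_stressor_unpleasantness_1to7 =
              "first_stressor_unpleasantness_1to7",
            first_stressor_unpleasantness_bipolar_mag =
              "first_stressor_unpleasantness_bipolar_mag")
  per_group <- data.frame(group = levels(per$group),
                          n = as.integer(table(per$group)))
  for (v in names(vars)) {
    s <- stats_of(per[[vars[v]]], per$group)
    per_group[[paste0(v, "_mean")]] <- s$mean
    per_group[[paste0(v, "_sd")]] <- s$sd
  }

  gender_counts <- table(gender = ifelse(per$female == 1, "female", "male"),
                         group = per$group)

  small <- any(table(per$group) < 2)
  tests <- data.frame(characteristic = character(), statistic = numeric(),
                      df1 = numeric(), df2 = numeric(), p = numeric())
  contrasts <- data.frame(characteristic = character(), pair = character(),
                          p = numeric(), significant = logical())
  if (small) {
    warning("a group has fewer than 2 persons; SDs undefined, tests skipped")
  } else {
    for (v in names(vars)) {
      x <- per[[vars[v]]]
      ok <- is.finite(x)
      g <- droplevels(per$group[ok])
      # a characteristic can be unobserved (e.g. no stressors at all);
      # between-group tests then have nothing to compare
      if (sum(ok) < 3 || nlevels(g) < 2 || var(x[ok]) < 1e-12) next
      fit <- aov(x[ok] ~ g)
      an <- summary(fit)[[1]]
      tests <- rbind(tests, data.frame(
        characteristic = v, statistic = an[["F value"]][1],
        df1 = an[["Df"]][1], df2 = an[["Df"]][2],
        p = an[["Pr(>F)"]][1]))
      pt <- pairwise.t.test(x[ok], g, p.adjust.method = "none")
      pm <- pt$p.value
      for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
        if (is.na(pm[i, j])) next
        contrasts <- rbind(contrasts, data.frame(
          characteristic = v,
          pair = paste(rownames(pm)[i], "vs", colnames(pm)[j]),
          p = pm[i, j], significant = pm[i, j] < alpha))
      }
    }
    cs <- suppressWarnings(chisq.test(gender_counts, correct = FALSE))
    tests <- rbind(tests, data.frame(
      characteristic = "gender", statistic = unname(cs$statistic),
      df1 = unname(cs$parameter), df2 = NA_real_, p = cs$p.value))
  }
  structure(list(per_group = per_group, gender_counts = gender_counts,
                 tests = tests, contrasts = contrasts, alpha = alpha),
            class = "esm_descriptives")
}

#' @export
print.esm_descriptives <- function(x, ...) {
  cat("Sample characteristics by group\n")
  print(x$per_group[, 1:2], row.names = FALSE)
  cat("\nBetween-group tests (ANOVA F / chi-square):\n")
  print(x$tests, row.names = FALSE, digits = 4)
  sig <- x$contrasts[x$contrasts$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("\nPairwise contrasts significant at alpha =", x$alpha, ":\n")
    print(sig[, c("characteristic", "pair", "p")], row.names = FALSE,
          digits = 3)
  }
  invisible(x)
}
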