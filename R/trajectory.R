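#' First stressor of a day
#'
#' Returns the beep index of the first prompt of a day on which the given
#' stress type was reported, or `NA` if the day is stress-free. Prompts
#' must be the day's compliant (answered) prompts in beep order.
#'
#' @param day_prompts Derived prompt rows of one person-day, sorted by
#'   `beep_index`.
#' @param stress_type One of `"event"`, `"activity"`, `"composite"`.
#' @return Beep index (integer) or `NA`.
#' @export
find_first_stressor <- function(day_prompts,
                                stress_type = c("composite", "event",
                                                "activity")) {
  stress_type <- match.arg(stress_type)
  flag <- day_prompts[[paste0(stress_type, "_stress")]] %in% TRUE
  pos <- which(flag)
  if (length(pos) == 0L) NA_integer_ else day_prompts$beep_index[pos[1]]
}

# default post-stressor window length per stress type (number of modelled
# follow-up prompts t1..tK)
.default_max_lag <- c(event = 1L, activity = 2L, composite = 2L)

#' Code time relative to the first daily stressor
#'
#' Builds the trajectory frame for one stress type: for every included
#' person-day the prompt at the day's first stressor becomes `t0`, the
#' answered prompt immediately before it becomes the baseline `t-1`, and
#' the following answered prompts become `t1` ... `tK`. All labels are
#' defined over answered (compliant) prompts, so a missed beep shifts the
#' labels to the next answered prompt.
#'
#' Exclusions mirror the standard first-stressor design: persons who never
#' report the stress type, days without it, days where it falls on the
#' day's first answered prompt (no baseline available), prompts before the
#' baseline, and prompts beyond the modelled window.
#'
#' @param derived Derived prompt table ([derive_prompts()]) from a
#'   compliance-filtered dataset; rows are answered prompts.
#' @param stress_type One of `"composite"`, `"event"`, `"activity"`.
#' @param max_lag Number of modelled follow-up prompts K (default: 1 for
#'   event stress, 2 for activity and composite).
#' @return A `trajectory_frame` data frame: keys, `stress_type`,
#'   `time_since` (`"t-1"`, `"t0"`, `"t1"`, ... or `NA`), `included`,
#'   `exclusion_reason`, `subsequent_stress` (filled by
#'   [flag_subsequent_stress()]).
#' @export
code_time_since <- function(derived,
                            stress_type = c("composite", "event",
                                            "activity"),
                            max_lag = NULL) {
  stress_type <- match.arg(stress_type)
  if (is.null(max_lag)) max_lag <- .default_max_lag[[stress_type]]
  if (!is.numeric(max_lag) || max_lag < 1) {
    stop("max_lag must be a positive integer")
  }
  max_lag <- as.integer(max_lag)

  ord <- order(derived$person_id, derived$day_index, derived$beep_index)
  d <- derived[ord, ]
  flag <- d[[paste0(stress_type, "_stress")]] %in% TRUE

  day_f <- factor(paste(d$person_id, d$day_index, sep = "\r"))
  day_i <- as.integer(day_f)
  # within-day position over answered prompts (rows are sorted by day)
  sizes <- tabulate(day_i, nbins = nlevels(day_f))
  pos <- sequence(sizes[sort(unique(day_i))])
  stopifnot(length(pos) == nrow(d))

  firstpos <- rep(NA_integer_, nlevels(day_f))
  sel <- which(flag)
  if (length(sel)) {
    keep <- !duplicated(day_i[sel])
    firstpos[day_i[sel][keep]] <- pos[sel][keep]
  }

  person_f <- factor(d$person_id)
  ever <- tapply(flag, person_f, any)
  person_ever <- as.logical(ever[as.integer(person_f)])

  fp <- firstpos[day_i]
  rel <- pos - fp

  time_since <- rep(NA_character_, nrow(d))
  reason <- rep(NA_character_, nrow(d))

  never <- !person_ever
  no_stress <- !never & is.na(fp)
  first_prompt <- !never & !is.na(fp) & fp == 1L
  in_day <- !never & !no_stress & !first_prompt

  reason[never] <- "never_stressed"
  reason[no_stress] <- "no_stress_day"
  reason[first_prompt] <- "first_prompt_stressor"
  reason[in_day & rel < -1L] <- "pre_baseline"
  reason[in_day & rel > max_lag] <- "beyond_window"

  lab <- in_day & rel >= -1L & rel <= max_lag
  time_since[lab] <- ifelse(rel[lab] == -1L, "t-1",
                            paste0("t", rel[lab]))

  out <- data.frame(person_id = d$person_id, day_index = d$day_index,
                    beep_index = d$beep_index, stress_type = stress_type,
                    time_since = time_since,
                    included = !is.na(time_since),
                    exclusion_reason = reason,
                    subsequent_stress = NA_integer_,
                    stringsAsFactors = FALSE)
  attr(out, "max_lag") <- max_lag
  attr(out, "stress_type") <- stress_type
  class(out) <- c("trajectory_frame", "data.frame")
  out
}

#' Flag subsequent stressors in the recovery window
#'
#' For rows labelled `t1` ... `tK`, records whether the same stress type
#' was (1) or was not (0) reported at that prompt itself, providing the
#' control variable for the subsequent-stress sensitivity models. Baseline
#' and `t0` rows keep `NA` (the covariate is defined only after the first
#' stressor and enters the model as 0 there).
#'
#' @param frame A `trajectory_frame` from [code_time_since()].
#' @param derived The derived prompt table the frame was coded from.
#' @return The frame with `subsequent_stress` filled in.
#' @export
flag_subsequent_stress <- function(frame, derived) {
  stress_type <- attr(frame, "stress_type")
  i <- match(.key(frame), .key(derived))
  if (anyNA(i)) stop("frame rows missing from the derived table")
  flag <- derived[[paste0(stress_type, "_stress")]][i]
  post <- frame$included & !frame$time_since %in% c("t-1", "t0")
  frame$subsequent_stress <- ifelse(post, as.integer(flag %in% TRUE),
                                    NA_integer_)
  frame
}

#' Exclusion accounting for a trajectory frame
#'
#' Tallies the exclusions applied by [code_time_since()], reproducible by
#' brute-force enumeration of the raw stress flags.
#'
#' @param frame A `trajectory_frame`.
#' @return One-row data frame: `stress_type`, `n_persons_never_stressed`,
#'   `n_days_without_stress`, `n_days_first_prompt_stressor`,
#'   `n_prompts_pre_baseline`, `n_prompts_beyond_window`,
#'   `n_prompts_included`.
#' @export
exclusion_summary <- function(frame) {
  dkey <- paste(frame$person_id, frame$day_index, sep = "\r")
  data.frame(
    stress_type = attr(frame, "stress_type"),
    n_persons_never_stressed =
      length(unique(frame$person_id[frame$exclusion_reason %in%
                                      "never_stressed"])),
    n_days_without_stress =
      length(unique(dkey[frame$exclusion_reason %in% "no_stress_day"])),
    n_days_first_prompt_stressor =
      length(unique(dkey[frame$exclusion_reason %in%
                           "first_prompt_stressor"])),
    n_prompts_pre_baseline = sum(frame$exclusion_reason %in% "pre_baseline"),
    n_prompts_beyond_window =
      sum(frame$exclusion_reason %in% "beyond_window"),
    n_prompts_included = sum(frame$included),
    stringsAsFactors = FALSE
  )
}
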