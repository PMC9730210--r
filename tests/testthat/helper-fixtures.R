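# In-code fixtures and independent oracles shared across the test files.

# Small fully-crossed prompt grid with benign defaults: every prompt
# answered quickly, neutral affect, no stress. Tests tweak cells.
make_toy_prompts <- function(person_ids = c("A", "B", "C"),
                             groups = c("control", "at_risk", "patient"),
                             days = 2, beeps = 3,
                             ages = rep(35, length(person_ids)),
                             genders = rep("female", length(person_ids))) {
  grid <- expand.grid(beep_index = seq_len(beeps),
                      day_index = seq_len(days),
                      person_id = person_ids,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$person_id, grid$day_index, grid$beep_index), ]
  i <- match(grid$person_id, person_ids)
  data.frame(
    person_id = grid$person_id,
    group = groups[i],
    age = ages[i],
    gender = genders[i],
    day_index = grid$day_index,
    beep_index = grid$beep_index,
    scheduled_time = sprintf("%02d:%02d",
                             7 + grid$beep_index, 30),
    response_delay_min = 5,
    pa_cheerful = 4, pa_relaxed = 4, pa_satisfied = 4,
    event_pleasantness = 1,
    act_energy = 2, act_skilled = 6, act_challenge = 2,
    act_prefer_else = 2,
    stringsAsFactors = FALSE
  )
}

make_toy_dataset <- function(prompts = make_toy_prompts(), ...) {
  esm_dataset(prompts, ...)
}

# Brute-force re-derivation of time_since labels and exclusion reasons
# from raw stress flags, written with explicit loops so it shares no code
# with code_time_since().
oracle_time_since <- function(derived, stress_type, K) {
  flag_col <- paste0(stress_type, "_stress")
  out <- data.frame(person_id = derived$person_id,
                    day_index = derived$day_index,
                    beep_index = derived$beep_index,
                    time_since = NA_character_,
                    exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$day_index, out$beep_index), ]
  d <- derived[order(derived$person_id, derived$day_index,
                     derived$beep_index), ]
  for (p in unique(d$person_id)) {
    rows_p <- which(d$person_id == p)
    if (!any(d[[flag_col]][rows_p] %in% TRUE)) {
      out$exclusion_reason[rows_p] <- "never_stressed"
      next
    }
    for (dy in unique(d$day_index[rows_p])) {
      rows <- rows_p[d$day_index[rows_p] == dy]
      flags <- d[[flag_col]][rows] %in% TRUE
      hit <- which(flags)
      if (length(hit) == 0) {
        out$exclusion_reason[rows] <- "no_stress_day"
        next
      }
      f1 <- hit[1]
      if (f1 == 1) {
        out$exclusion_reason[rows] <- "first_prompt_stressor"
        next
      }
      for (i in seq_along(rows)) {
        if (i < f1 - 1) {
          out$exclusion_reason[rows[i]] <- "pre_baseline"
        } else if (i == f1 - 1) {
          out$time_since[rows[i]] <- "t-1"
        } else if (i <= f1 + K) {
          out$time_since[rows[i]] <- paste0("t", i - f1)
        } else {
          out$exclusion_reason[rows[i]] <- "beyond_window"
        }
      }
    }
  }
  out
}

# Dense multivariate-normal log-likelihood of a two-random-intercept
# model, evaluated directly from the marginal covariance matrix. `fixed`
# is the fixed-effects formula used to build the design matrix.
oracle_mvn_loglik <- function(data, fixed, beta, var_person, var_day,
                              var_resid) {
  X <- stats::model.matrix(fixed, data)
  stopifnot(ncol(X) == length(beta))
  Zp <- stats::model.matrix(~ 0 + factor(person_id), data)
  Zd <- stats::model.matrix(~ 0 + factor(day_id), data)
  n <- nrow(data)
  Sigma <- var_person * tcrossprod(Zp) + var_day * tcrossprod(Zd) +
    var_resid * diag(n)
  r <- data$pa_z - drop(X %*% beta)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  q <- sum(backsolve(ch, r, transpose = TRUE)^2)
  -0.5 * (n * log(2 * pi) + logdet + q)
}

# Minimal stand-in for an esm_fit, for contrast arithmetic on known
# coefficient vectors.
fake_fit <- function(beta, se = NULL, vcov = NULL,
                     timepoints = c("t-1", "t0", "t1", "t2"),
                     groups = "control") {
  if (is.null(vcov)) {
    stopifnot(!is.null(se), length(se) == length(beta))
    vcov <- diag(se^2, nrow = length(beta))
  }
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov = vcov, converged = TRUE,
                 timepoints = timepoints, groups = groups,
                 data = data.frame(female = 0.5, subsequent_stress = 0)),
            class = "esm_fit")
}

# Shared small simulated scenario for model tests (kept small on purpose).
small_sim <- function(seed, n = 30, preset = "paper-like", ...) {
  cfg <- scenario_library(preset,
                          n_per_group = c(control = n, at_risk = n,
                                          patient = n),
                          seed = seed, ...)
  generate_esm(cfg)
}

prep_frame <- function(sim, stress_type = "composite") {
  filt <- apply_compliance_filter(sim$dataset)
  d <- derive_prompts(filt$dataset)
  fr <- code_time_since(d, stress_type)
  fr <- flag_subsequent_stress(fr, d)
  list(af = analysis_frame(fr, d, filt$dataset$persons),
       derived = d, frame = fr, persons = filt$dataset$persons,
       dataset = filt$dataset)
}
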