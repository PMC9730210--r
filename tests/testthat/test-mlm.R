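test_that("with zero variance components fixed effects equal OLS", {
  sim <- small_sim(601, n = 20, preset = "no-random-effects")
  pf <- prep_frame(sim)
  af <- pf$af[pf$af$group == "control", ]
  fit <- fit_lmm(af, model_spec("composite", covariates = TRUE))
  ols <- lm(pa_z ~ time_since + age_c + female, data = af)
  expect_true(fit$converged)
  expect_lt(fit$var_person, 1e-6)
  expect_lt(fit$var_day, 1e-6)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("ML solution matches a dense MVN likelihood maximised directly", {
  # small two-level layout; oracle: numerical ML over the dense marginal
  # covariance, sharing no code with lme4
  set.seed(77)
  n_p <- 6; n_d <- 3; n_b <- 4
  d <- expand.grid(beep = seq_len(n_b), day_index = seq_len(n_d),
                   person_id = sprintf("P%d", seq_len(n_p)))
  u <- rnorm(n_p, 0, sqrt(0.4))
  v <- rnorm(n_p * n_d, 0, sqrt(0.2))
  d$day_id <- paste(d$person_id, d$day_index)
  d$x <- rep(c(0, 1), length.out = nrow(d))
  d$pa_z <- 0.5 + 0.3 * d$x + u[as.integer(factor(d$person_id))] +
    v[as.integer(factor(d$day_id))] + rnorm(nrow(d), 0, sqrt(0.5))
  d$time_since <- factor(ifelse(d$x == 1, "t0", "t-1"),
                         levels = c("t-1", "t0"))

  fit <- fit_lmm(d, model_spec("composite", covariates = FALSE))
  expect_true(fit$converged)
  expect_lte(nrow(d), 200)

  # oracle 1: dense evaluation at the fitted estimates equals the
  # reported log-likelihood
  ll_dense <- oracle_mvn_loglik(d, ~ time_since, fit$beta,
                                fit$var_person, fit$var_day, fit$var_resid)
  expect_equal(ll_dense, fit$loglik, tolerance = 1e-6)

  # oracle 2: direct numerical maximisation does not beat the fit
  X <- model.matrix(~ time_since, d)
  obj <- function(par) {
    vp <- exp(par[1]); vd <- exp(par[2]); ve <- exp(par[3])
    Zp <- model.matrix(~ 0 + factor(person_id), d)
    Zd <- model.matrix(~ 0 + factor(day_id), d)
    Sigma <- vp * tcrossprod(Zp) + vd * tcrossprod(Zd) +
      ve * diag(nrow(d))
    ch <- chol(Sigma)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, d$pa_z, transpose = TRUE)
    beta <- qr.solve(Xi, yi)
    r <- yi - Xi %*% beta
    0.5 * (nrow(d) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  }
  opt <- optim(log(c(0.4, 0.2, 0.5)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-4)
  expect_equal(sort(exp(opt$par)),
               sort(c(fit$var_person, fit$var_day, fit$var_resid)),
               tolerance = 1e-2)
})

test_that("balanced two-person toy matches closed-form ML estimates", {
  # balanced one-way random-effects layout: a = 2 persons, n = 2 obs.
  # Closed-form ML: sigma_e^2 = SSW / (a (n - 1)),
  # tau = S_b / a - sigma_e^2 / n with S_b = sum (ybar_i - ybar)^2.
  y <- c(0, 0.2, 1, 1.2)
  d <- data.frame(person_id = rep(c("A", "B"), each = 2),
                  day_index = 1, beep_index = rep(1:2, 2),
                  day_id = rep(c("A1", "B1"), each = 2),
                  pa_z = y,
                  time_since = factor("t-1", levels = c("t-1", "t0")))
  fit <- suppressMessages(fit_lmm(d, model_spec("composite",
                                                covariates = FALSE)))
  ybar <- mean(y)
  means <- c(mean(y[1:2]), mean(y[3:4]))
  ssw <- sum((y - rep(means, each = 2))^2)
  sigma_e <- ssw / (2 * (2 - 1))
  tau <- sum((means - ybar)^2) / 2 - sigma_e / 2
  expect_equal(unname(fit$beta[["(Intercept)"]]), ybar, tolerance = 1e-6)
  # person and person-day intercepts share one grouping here, so only
  # their sum is identified
  expect_equal(fit$var_person + fit$var_day, tau, tolerance = 1e-4)
  expect_equal(fit$var_resid, sigma_e, tolerance = 1e-4)
})

test_that("adding group terms can only increase the ML log-likelihood", {
  sim <- small_sim(602, n = 15)
  pf <- prep_frame(sim)
  f0 <- fit_lmm(pf$af, model_spec("composite"))
  f1 <- fit_lmm(pf$af, model_spec("composite", include_group_terms = TRUE))
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("within-group contrasts reproduce the Wald CI arithmetic", {
  fit <- fake_fit(beta = c("(Intercept)" = 0.1, "time_sincet0" = -0.38,
                           "time_sincet1" = -0.12, "time_sincet2" = -0.02),
                  se = c(0.05, 0.0357, 0.04, 0.04))
  wc <- within_group_contrasts(fit)
  t0 <- wc[wc$label == "t0", ]
  expect_equal(t0$b, -0.38)
  expect_equal(round(t0$ci_low, 2), -0.45)
  expect_equal(round(t0$ci_high, 2), -0.31)
  expect_lt(t0$p, 0.001)
  # requested time point missing from the model -> labelled gap, no skip
  gap <- within_group_contrasts(fit, timepoints = c("t0", "t3"))
  expect_equal(nrow(gap), 2)
  expect_true(is.na(gap$b[gap$label == "t3"]))
  expect_match(gap$note[gap$label == "t3"], "not in model")
})

test_that("contrasts equal differences of adjusted predictive margins", {
  sim <- small_sim(603, n = 15)
  pf <- prep_frame(sim)
  fit <- fit_lmm(pf$af, model_spec("composite", include_group_terms = TRUE,
                                   include_interaction = TRUE))
  m <- adjusted_margins(fit)
  wc <- within_group_contrasts(fit)
  for (tp in c("t0", "t1", "t2")) {
    ref <- fit$groups[1]
    diff_m <- m$margin[m$group == ref & m$time_since == tp] -
      m$margin[m$group == ref & m$time_since == "t-1"]
    expect_equal(wc$b[wc$label == tp], diff_m, tolerance = 1e-10)
  }
  # margins invariant: reference group at baseline equals the intercept
  # plus the covariate contribution
  ref_m <- m$margin[m$group == fit$groups[1] & m$time_since == "t-1"]
  expect_equal(ref_m,
               unname(fit$beta[["(Intercept)"]] +
                        fit$beta[["female"]] * mean(fit$data$female)),
               tolerance = 1e-10)
})

test_that("group main effect is the 1-df Wald square for two groups", {
  fit <- fake_fit(beta = c("(Intercept)" = 0, "grouppatient" = -0.4),
                  se = c(0.1, 0.08), groups = c("control", "patient"))
  me <- group_main_effect(fit)
  expect_equal(me$statistic, (-0.4 / 0.08)^2, tolerance = 1e-10)
  expect_equal(me$df, 1)
  expect_error(group_main_effect(fake_fit(c("(Intercept)" = 1),
                                          se = 1)), "no group")
})

test_that("three groups give a 2-df group test on real fits", {
  sim <- small_sim(604, n = 15)
  pf <- prep_frame(sim)
  fit <- fit_lmm(pf$af, model_spec("composite", include_group_terms = TRUE))
  me <- group_main_effect(fit)
  expect_equal(me$df, 2)
  expect_true(me$p_value > 0 && me$p_value <= 1)
})

test_that("pairwise contrasts satisfy the linear-algebra identity", {
  sim <- small_sim(605, n = 15)
  pf <- prep_frame(sim)
  fit <- fit_lmm(pf$af, model_spec("composite", include_group_terms = TRUE,
                                   include_interaction = TRUE))
  for (tp in c("t-1", "t0")) {
    bg <- between_group_contrasts(fit, tp)
    b <- setNames(bg$b, bg$pair)
    expect_equal(b[["patient vs at_risk"]],
                 b[["patient vs control"]] - b[["at_risk vs control"]],
                 tolerance = 1e-10)
  }
})

test_that("non-convergence is propagated, not silently repaired", {
  fit <- fake_fit(beta = c("(Intercept)" = 0, "grouppatient" = -0.4),
                  se = c(0.1, 0.08), groups = c("control", "patient"))
  fit$converged <- FALSE
  bg <- between_group_contrasts(fit, "t-1")
  expect_true(all(is.na(bg$b)))
  expect_match(bg$note[1], "did not converge")
  expect_error(within_group_contrasts(fit), "converge")
  expect_error(recovery_contrast(fit, 1), "converge")
})

test_that("recovery window follows the first non-significant follow-up", {
  tabs <- list(
    patient = data.frame(label = c("t0", "t1", "t2"),
                         p = c(0.001, 0.02, 0.71)),
    at_risk = data.frame(label = c("t0", "t1", "t2"),
                         p = c(0.001, 0.03, 0.23)),
    control = data.frame(label = c("t0", "t1", "t2"),
                         p = c(0.001, 0.32, 0.9)))
  w <- recovery_window(tabs)
  expect_equal(unname(w$per_group),
               c(patient = 2L, at_risk = 2L, control = 1L),
               ignore_attr = TRUE)
  expect_equal(w$overall_end, 2L)
  expect_equal(w$window, 1:2)
  expect_true(w$all_recovered)

  all_quick <- lapply(tabs, function(t) {
    t$p <- c(0.001, 0.4, 0.9); t
  })
  w2 <- recovery_window(all_quick)
  expect_equal(w2$overall_end, 1L)  # minimal window: the single point t1

  never <- tabs
  never$patient$p <- c(0.001, 0.01, 0.01)
  w3 <- recovery_window(never)
  expect_false(w3$all_recovered)
  expect_equal(unname(w3$per_group[["patient"]]), 3L)
})

test_that("recovery contrast is the mean deviation over the window", {
  fit <- fake_fit(beta = c("(Intercept)" = 0, "time_sincet0" = -0.4,
                           "time_sincet1" = -0.12, "time_sincet2" = -0.02),
                  se = rep(0.05, 4))
  rc <- recovery_contrast(fit, 1:2)
  expect_equal(rc$b, -0.07, tolerance = 1e-12)
  expect_error(recovery_contrast(fit, 1:3), "beyond the modelled")
  expect_error(recovery_contrast(fit, integer(0)), "follow-up")
})

test_that("between-group recovery equals the mean of per-lag contrasts", {
  sim <- small_sim(606, n = 15)
  pf <- prep_frame(sim)
  fit <- fit_lmm(pf$af, model_spec("composite", include_group_terms = TRUE,
                                   include_interaction = TRUE))
  pair <- c("patient", "control")
  rc12 <- recovery_contrast(fit, 1:2, pair = pair)
  rc1 <- recovery_contrast(fit, 1, pair = pair)
  rc2 <- recovery_contrast(fit, 2, pair = pair)
  expect_equal(rc12$b, (rc1$b + rc2$b) / 2, tolerance = 1e-10)
})

test_that("step-up correction matches the worked thresholds", {
  out <- simes_correct(c(0.001, 0.026, 0.2))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$thresholds_exact, c(0.05 / 3, 0.025, 0.05))
  expect_equal(out$thresholds_rounded, c(0.02, 0.03, 0.05))
  expect_equal(simes_correct(c(0.9, 0.9, 0.9))$significant, rep(FALSE, 3))
  # flags returned in input order
  out2 <- simes_correct(c(0.2, 0.001, 0.026))
  expect_equal(out2$significant, c(FALSE, TRUE, FALSE))
  expect_error(simes_correct(c(0.1, 0.2)), "exactly 3")
  expect_error(simes_correct(c(0, 0.2, 0.3)), "0, 1")
})

test_that("step-up decisions are monotone in the p-values", {
  set.seed(5)
  for (i in 1:200) {
    p <- round(runif(3, 0.001, 0.999), 3)
    base <- simes_correct(p)$significant
    j <- sample(3, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    better <- simes_correct(pmax(p2, 1e-6))$significant
    expect_true(all(better >= base),
                info = paste("p:", paste(p, collapse = ","),
                             "->", paste(p2, collapse = ",")))
  }
})
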