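test_that("CSV round-trip preserves values, missingness and shape", {
  prompts <- make_toy_prompts()
  prompts$pa_cheerful[4] <- NA
  prompts$response_delay_min[7] <- NA  # unanswered prompt
  prompts$event_pleasantness[2] <- -3
  ds <- esm_dataset(prompts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_esm_long(ds, path)
  ds2 <- read_esm_long(path)
  expect_equal(nrow(ds2$prompts), 3 * 2 * 3)
  expect_equal(nrow(ds2$persons), 3)
  expect_equal(ds2$prompts, ds$prompts, ignore_attr = TRUE)
  expect_true(is.na(ds2$prompts$pa_cheerful[4]))
  expect_true(is.na(ds2$prompts$response_delay_min[7]))
})

test_that("out-of-range values are flagged and retained, never coerced", {
  prompts <- make_toy_prompts()
  prompts$pa_cheerful[5] <- 9
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(prompts, path, row.names = FALSE, na = "")
  ds <- read_esm_long(path)
  v <- attr(ds, "validation")
  expect_equal(nrow(v), 1)
  expect_equal(v$column, "pa_cheerful")
  expect_equal(v$issue, "out_of_range")
  # row retained with the original value
  expect_equal(nrow(ds$prompts), nrow(prompts))
  expect_equal(ds$prompts$pa_cheerful[v$row], 9)
  # scoring masks the flagged cell instead of using it (fixture affect is
  # constant, so standardisation warns about zero variance)
  d <- suppressWarnings(derive_prompts(ds))
  expect_equal(d$pa_raw[v$row], 4)  # mean of the two remaining items
})

test_that("schema and integrity errors name the problem", {
  prompts <- make_toy_prompts()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(prompts[, setdiff(names(prompts), "event_pleasantness")],
            path, row.names = FALSE)
  expect_error(read_esm_long(path), "event_pleasantness")
  dup <- rbind(prompts, prompts[1, ])
  expect_error(esm_dataset(dup), "duplicate")
  bad_group <- prompts
  bad_group$group[1] <- "patient"  # person A otherwise control
  expect_error(esm_dataset(bad_group), "constant")
  expect_error(read_esm_long(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("compliance filter removes nothing on a fully compliant person", {
  ds <- make_toy_dataset(make_toy_prompts(days = 6, beeps = 10))
  out <- apply_compliance_filter(ds, min_prompts = 20)
  expect_equal(nrow(out$dataset$prompts), nrow(ds$prompts))
  expect_true(all(out$log$n_prompts_removed == 0))
  expect_true(all(out$log$n_persons_removed == 0))
})

test_that("compliance filter stages match a brute-force row scan", {
  prompts <- make_toy_prompts(days = 6, beeps = 10)
  set.seed(31)
  n <- nrow(prompts)
  prompts$response_delay_min <- sample(c(NA, 2, 10, 16, 40), n,
                                       replace = TRUE,
                                       prob = c(.15, .3, .3, .15, .1))
  # a handful of answered prompts with every item missing
  blank <- sample(which(!is.na(prompts$response_delay_min) &
                          prompts$response_delay_min <= 15), 4)
  items <- c("pa_cheerful", "pa_relaxed", "pa_satisfied",
             "event_pleasantness", "act_energy", "act_skilled",
             "act_challenge", "act_prefer_else")
  prompts[blank, items] <- NA
  ds <- esm_dataset(prompts)
  out <- apply_compliance_filter(ds, max_delay = 15, min_prompts = 20)

  # independent enumeration over rows
  unanswered <- sum(is.na(prompts$response_delay_min))
  late <- sum(!is.na(prompts$response_delay_min) &
                prompts$response_delay_min > 15)
  allmiss <- length(blank)
  keep1 <- !is.na(prompts$response_delay_min) &
    prompts$response_delay_min <= 15 &
    !(seq_len(n) %in% blank)
  tab <- table(prompts$person_id[keep1])
  low_persons <- names(tab)[tab < 20]
  stage2 <- sum(keep1 & prompts$person_id %in% low_persons)

  log <- out$log
  expect_equal(log$n_prompts_removed[log$reason == "unanswered"], unanswered)
  expect_equal(log$n_prompts_removed[grepl("delay", log$reason)], late)
  expect_equal(log$n_prompts_removed[log$reason == "all_items_missing"],
               allmiss)
  expect_equal(log$n_prompts_removed[grepl("fewer_than", log$reason)],
               stage2)
  expect_equal(log$n_persons_removed[grepl("fewer_than", log$reason)],
               length(low_persons))
  # row conservation: retained + removed equals the input count
  expect_equal(nrow(out$dataset$prompts) + sum(log$n_prompts_removed),
               n)
})

test_that("a person with 19 valid prompts is removed at the person stage", {
  prompts <- make_toy_prompts(person_ids = c("A", "B"),
                              groups = c("control", "patient"),
                              days = 6, beeps = 10)
  # person A answers only 19 prompts in time
  a_rows <- which(prompts$person_id == "A")
  prompts$response_delay_min[a_rows[20:60]] <- NA
  ds <- esm_dataset(prompts)
  out <- apply_compliance_filter(ds, min_prompts = 20)
  expect_false("A" %in% out$dataset$persons$person_id)
  expect_equal(out$log$n_persons_removed[grepl("fewer", out$log$reason)], 1)
  # one more answered prompt keeps the person
  prompts$response_delay_min[a_rows[20]] <- 3
  out2 <- apply_compliance_filter(esm_dataset(prompts), min_prompts = 20)
  expect_true("A" %in% out2$dataset$persons$person_id)
})

test_that("compliance filtering is idempotent", {
  sim <- small_sim(404, n = 10, preset = "high-missingness")
  once <- apply_compliance_filter(sim$dataset)
  twice <- apply_compliance_filter(once$dataset)
  expect_equal(twice$dataset$prompts, once$dataset$prompts)
  expect_true(all(twice$log$n_prompts_removed == 0))
  expect_true(all(twice$log$n_persons_removed == 0))
  expect_error(
    apply_compliance_filter(sim$dataset, max_delay = -1, min_prompts = 1e6),
    "no analyzable data")
})

test_that("compliance_percentage rounds half-up and guards its domain", {
  expect_identical(compliance_percentage(45, 60), 75L)
  expect_identical(compliance_percentage(49, 60), 82L)
  expect_identical(compliance_percentage(47, 60), 78L)  # 78.33 -> 78
  expect_identical(compliance_percentage(60, 60), 100L)
  expect_identical(compliance_percentage(0, 60), 0L)
  # monotone nondecreasing in n_answered for fixed n_scheduled
  pcts <- compliance_percentage(0:60, 60)
  expect_true(all(diff(pcts) >= 0))
  expect_error(compliance_percentage(1, 0), "positive")
  expect_error(compliance_percentage(61, 60), "n_answered")
})

test_that("descriptive table reproduces closed-form ANOVA and chi-square", {
  # two groups of three persons, ages chosen for an easy hand calculation
  ages <- c(30, 40, 50, 60, 70, 80)
  prompts <- make_toy_prompts(person_ids = paste0("P", 1:6),
                              groups = rep(c("control", "patient"),
                                           each = 3),
                              ages = ages,
                              genders = rep("male", 6))
  ds <- esm_dataset(prompts)
  d <- suppressWarnings(derive_prompts(ds))  # constant toy affect
  tab <- descriptive_table(ds, d)
  # hand computation: group means 40 and 70, grand 55
  ssb <- 3 * (40 - 55)^2 + 3 * (70 - 55)^2   # 1350
  ssw <- sum((ages[1:3] - 40)^2) + sum((ages[4:6] - 70)^2)  # 400
  f_hand <- (ssb / 1) / (ssw / 4)
  got <- tab$tests[tab$tests$characteristic == "age", ]
  expect_equal(got$statistic, f_hand, tolerance = 1e-10)
  expect_equal(c(got$df1, got$df2), c(1, 4))

  # 2x2 gender table (10,10 / 20,0): Pearson chi-square by closed form
  prompts2 <- make_toy_prompts(
    person_ids = sprintf("Q%02d", 1:40),
    groups = rep(c("control", "patient"), each = 20),
    genders = c(rep(c("male", "female"), each = 10),
                rep("male", 20)),
    days = 1, beeps = 2)
  ds2 <- esm_dataset(prompts2)
  tab2 <- descriptive_table(ds2, suppressWarnings(derive_prompts(ds2)))
  chi_hand <- 40 * (10 * 0 - 10 * 20)^2 / (20 * 20 * 30 * 10)
  got2 <- tab2$tests[tab2$tests$characteristic == "gender", ]
  expect_equal(got2$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(got2$df1, 1)
})

test_that("identical groups produce F = 0 and no flagged contrasts", {
  prompts <- make_toy_prompts(person_ids = paste0("P", 1:9),
                              groups = rep(c("control", "at_risk",
                                             "patient"), each = 3),
                              ages = rep(c(30, 40, 50), times = 3))
  ds <- esm_dataset(prompts)
  tab <- descriptive_table(ds, suppressWarnings(derive_prompts(ds)))
  got <- tab$tests[tab$tests$characteristic == "age", ]
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_false(any(tab$contrasts$significant[
    tab$contrasts$characteristic == "age"]))
})

test_that("groups with fewer than 2 persons report NA SD and skip tests", {
  prompts <- make_toy_prompts(person_ids = c("A", "B", "C"),
                              groups = c("control", "control", "patient"))
  ds <- esm_dataset(prompts)
  d <- suppressWarnings(derive_prompts(ds))
  expect_warning(tab <- descriptive_table(ds, d), "fewer than 2")
  expect_true(is.na(tab$per_group$age_sd[tab$per_group$group == "patient"]))
  expect_equal(nrow(tab$tests), 0)
})
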