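test_that("residuals follow the measured-minus-estimated sign convention", {
  rs <- residual_set(mgfr = c(100, 90), egfr = c(80, 90))
  expect_equal(rs$residual, c(20, 0))
  expect_equal(rs$ape, c(0.2, 0))
  expect_error(residual_set(numeric(0), numeric(0)), class = "gfreval_empty")
  expect_error(residual_set(c(100, 90), 80), class = "gfreval_invalid")

  tbl <- random_patients(4, seed = 11)
  rs2 <- compute_residuals(tbl, "cockcroft_gault")
  by_hand <- tbl$mgfr - evaluate_model(tbl, "cockcroft_gault")$egfr_absolute
  expect_equal(rs2$residual, by_hand)
})

test_that("the toy 4-patient example reproduces hand-computed metrics exactly", {
  m <- compute_metrics(toy_residuals())
  expect_equal(m$bias, 0.0)
  expect_equal(m$precision, 26.25)   # type-7 quartiles of (-25,-10,10,20)
  expect_equal(m$accuracy, 17.5)
  expect_equal(m$one_minus_p20, 0.25)  # APE exactly 0.20 is not counted

  perfect <- residual_set(c(50, 80, 110), c(50, 80, 110))
  mp <- compute_metrics(perfect)
  expect_equal(unlist(mp[c("bias", "precision", "accuracy", "one_minus_p20")]),
               c(bias = 0, precision = 0, accuracy = 0, one_minus_p20 = 0))

  single <- residual_set(100, 88)
  ms <- compute_metrics(single)
  expect_equal(ms$bias, 12)
  expect_equal(ms$precision, 0)
  expect_equal(ms$accuracy, 12)
})

test_that("metrics agree with the brute-force oracle on random cohorts", {
  for (k in 1:100) {
    withr::with_seed(1000 + k, {
      n <- sample(2:50, 1)
      mgfr <- runif(n, 20, 180)
      egfr <- mgfr * exp(rnorm(n, 0, 0.25))
    })
    got <- compute_metrics(residual_set(mgfr, egfr))
    want <- oracle_metrics(mgfr, egfr)
    expect_equal(got$bias, want$bias, tolerance = 1e-10)
    expect_equal(got$precision, want$precision, tolerance = 1e-10)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-10)
    expect_equal(got$one_minus_p20, want$one_minus_p20, tolerance = 1e-10)
  }
})

test_that("RMSE ignores row order and 1-P20 is scale invariant", {
  withr::with_seed(21, {
    mgfr <- runif(40, 30, 150)
    egfr <- mgfr + rnorm(40, 0, 20)
  })
  a <- compute_metrics(residual_set(mgfr, egfr))
  perm <- sample(40)
  b <- compute_metrics(residual_set(mgfr[perm], egfr[perm]))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$one_minus_p20, b$one_minus_p20)
  scaled <- compute_metrics(residual_set(3.7 * mgfr, 3.7 * egfr))
  expect_equal(scaled$one_minus_p20, a$one_minus_p20)
})

test_that("bootstrap CIs are deterministic given a seed and collapse on constants", {
  rs <- residual_set(mgfr = rep(100, 30), egfr = rep(80, 30))
  ci <- bootstrap_ci(rs, "accuracy", reps = 2000, seed = 9)
  expect_equal(ci$conf.low, ci$conf.high)
  expect_equal(ci$estimate, 20)

  withr::with_seed(3, {
    mgfr <- runif(50, 40, 140)
    egfr <- mgfr + rnorm(50, 0, 15)
  })
  rs2 <- residual_set(mgfr, egfr)
  a <- bootstrap_ci(rs2, "bias", reps = 300, seed = 42)
  b <- bootstrap_ci(rs2, "bias", reps = 300, seed = 42)
  c <- bootstrap_ci(rs2, "bias", reps = 300, seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$conf.low, c$conf.low)))
  expect_true(a$conf.low <= a$estimate && a$estimate <= a$conf.high)
  expect_error(bootstrap_ci(residual_set(100, 90), "bias"), class = "gfreval_invalid")
})

test_that("bootstrap CI width shrinks as the sample grows", {
  widths <- vapply(c(100, 1000, 10000), function(n) {
    withr::with_seed(n, {
      mgfr <- runif(n, 40, 140)
      egfr <- mgfr + rnorm(n, 0, 15)
    })
    ci <- bootstrap_ci(residual_set(mgfr, egfr), "accuracy", reps = 400, seed = 5)
    ci$conf.high - ci$conf.low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("a model compared with itself gives delta 0 and p 1", {
  tbl <- random_patients(30, seed = 31)
  cmp <- compare_models(tbl, "ckd_epi", "ckd_epi", metric = "accuracy",
                        reps = 200, seed = 1)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("clearly different models are detected on generated data", {
  sc <- generate_cohort(cohort_config(n = 1000, seed = 77))
  cmp <- compare_models(sc$cohort, "ckd_epi", "cockcroft_gault",
                        metric = "accuracy", reps = 400, seed = 2)
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$delta, 0)  # truth model is more accurate
  swap <- compare_models(sc$cohort, "cockcroft_gault", "ckd_epi",
                         metric = "accuracy", reps = 400, seed = 2)
  expect_equal(swap$delta, -cmp$delta)
})

test_that("subgroups partition the cohort and reduce to global metrics", {
  tbl <- random_patients(60, seed = 41)
  glob <- compute_metrics(compute_residuals(tbl, "wright"))
  one_bin <- subgroup_metrics(tbl, models = "wright", by = "age",
                              breaks = c(0, 200))
  expect_equal(one_bin$accuracy, glob$accuracy)
  expect_equal(one_bin$n, 60L)

  by_sex <- subgroup_metrics(tbl, models = c("wright", "mayo"), by = "sex")
  expect_equal(sum(by_sex$n[by_sex$model_id == "wright"]), 60L)
  for (s in c("male", "female")) {
    sub <- tbl[tbl$sex == s, ]
    want <- oracle_metrics(sub$mgfr,
                           evaluate_model(sub, "wright")$egfr_absolute)
    got <- by_sex[by_sex$subgroup == s & by_sex$model_id == "wright", ]
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$bias, want$bias)
  }

  quart <- subgroup_metrics(tbl, models = "wright", by = "creatinine")
  expect_equal(sum(quart$n), 60L)
})

test_that("matched draws match exactly on sex and within the age tolerance", {
  tbl <- random_patients(200, seed = 51)
  tbl$race_black <- c(rep(TRUE, 15), rep(FALSE, 185))
  draws <- matched_draw_comparison(tbl, n_draws = 3, age_tolerance = 2, seed = 8)
  expect_equal(nrow(draws), 3 * 3)
  expect_true(all(draws$n_pairs + draws$n_unmatched == 15))

  # the matching contract itself
  minority <- tbl[tbl$race_black, ]
  majority <- tbl[!tbl$race_black, ]
  m <- withr::with_seed(1, gfreval:::match_one_draw(minority, majority, 2))
  expect_equal(minority$sex[m$minority_idx], majority$sex[m$majority_idx])
  expect_true(all(abs(minority$age[m$minority_idx] -
                        majority$age[m$majority_idx]) <= 2))
  expect_equal(anyDuplicated(m$majority_idx), 0)
})

test_that("identical groups never reach significance; a shifted group does", {
  withr::with_seed(61, {
    base <- random_patients(40, seed = 611)
    twin <- base
    twin$patient_id <- paste0("T", twin$patient_id)
  })
  both <- dplyr::bind_rows(dplyr::mutate(base, race_black = TRUE),
                           dplyr::mutate(twin, race_black = FALSE))
  calm <- matched_draw_comparison(both, n_draws = 5, age_tolerance = 2, seed = 3)
  expect_true(all(calm$p_value > 0.05))

  shifted <- both
  shifted$creatinine[shifted$race_black] <- shifted$creatinine[shifted$race_black] + 0.5
  hot <- matched_draw_comparison(shifted, n_draws = 5, age_tolerance = 2, seed = 3)
  creat <- hot[hot$variable == "creatinine", ]
  expect_gt(mean(creat$p_value < 0.05), 0.5)
})

test_that("evaluation objects tidy, glance and plot", {
  tbl <- random_patients(50, seed = 71)
  ev <- evaluate_models(tbl, models = c("ckd_epi", "wright"), reps = 100, seed = 4)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 4)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(ev)
  expect_equal(gl$n, 50)
  expect_equal(gl$n_models, 2L)
  expect_s3_class(autoplot(ev), "ggplot")
})
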