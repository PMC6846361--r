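test_that("default strata reproduce the published per-center margins", {
  strata <- default_strata()
  expect_equal(sum(strata$n), 3786)
  expect_equal(sum(strata$n_female), 1709)
  expect_equal(sum(strata$n_black), 22)
  by_center <- dplyr::summarise(dplyr::group_by(strata, center),
                                n = sum(n), .groups = "drop")
  expect_equal(by_center$n[by_center$center == "Manchester"], 1777L)
  expect_equal(by_center$n[by_center$center == "Cambridge"], 404L)
  by_dx <- dplyr::summarise(dplyr::group_by(strata, diagnosis_group),
                            n = sum(n), .groups = "drop")
  expect_equal(by_dx$n[by_dx$diagnosis_group == "solid_cancer"], 3484L)
  expect_equal(by_dx$n[by_dx$diagnosis_group == "hematological_cancer"], 136L)
  expect_equal(by_dx$n[by_dx$diagnosis_group == "noncancer"], 166L)

  small <- default_strata(500)
  expect_equal(sum(small$n), 500)
  expect_true(all(small$n_female <= small$n))
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_config(n = 150, seed = 99))
  b <- generate_cohort(cohort_config(n = 150, seed = 99))
  expect_identical(tibble::as_tibble(a$cohort), tibble::as_tibble(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n = 150, seed = 100))
  expect_false(identical(a$cohort$creatinine, c$cohort$creatinine))
})

test_that("generated cohorts pass every inclusion filter with zero exclusions", {
  sc <- generate_cohort(cohort_config(n = 400, seed = 5))
  f <- apply_inclusion_filters(sc$cohort)
  expect_equal(nrow(f), 400)
  expect_true(all(cohort_filter_log(f)$n_excluded == 0))
  expect_true(all(abs(as.numeric(sc$cohort$creatinine_date -
                                   sc$cohort$mgfr_date)) <= 30))
  expect_equal(nrow(select_first_mgfr(f)), 400)
})

test_that("zero noise closes the loop: truth-model eGFR equals mGFR", {
  sc <- generate_cohort(cohort_config(n = 300, creatinine_noise = 0,
                                      mgfr_noise = 0, seed = 13))
  expect_equal(sc$cohort$mgfr, sc$truth$true_gfr)
  rs <- compute_residuals(sc$cohort, sc$config$truth_model)
  expect_lt(sqrt(mean(rs$residual^2)), 1e-6)
})

test_that("a numerically inverted truth model also closes the loop", {
  sc <- generate_cohort(cohort_config(n = 120, truth_model = "camgfr",
                                      creatinine_noise = 0, mgfr_noise = 0,
                                      seed = 17))
  rs <- compute_residuals(sc$cohort, "camgfr")
  expect_lt(sqrt(mean(rs$residual^2)), 1e-6)
})

test_that("more mGFR noise means more RMSE for every model", {
  rmse_at <- function(noise) {
    sc <- generate_cohort(cohort_config(n = 600, mgfr_noise = noise, seed = 23))
    vapply(gfr_model_ids(), function(id) {
      compute_metrics(compute_residuals(sc$cohort, id))$accuracy
    }, numeric(1))
  }
  lo <- rmse_at(2)
  hi <- rmse_at(20)
  expect_true(all(hi > lo))
})

test_that("center calibration bias scales creatinine and degrades accuracy", {
  sc <- generate_cohort(cohort_config(n = 400, seed = 29))
  co <- sc$cohort

  unchanged <- inject_center_bias(co, c(Manchester = 1.0))
  expect_equal(unchanged$creatinine, co$creatinine)

  biased <- inject_center_bias(co, c(Manchester = 1.10))
  man <- co$center == "Manchester"
  expect_equal(biased$creatinine[man], co$creatinine[man] * 1.10)
  expect_equal(biased$creatinine[!man], co$creatinine[!man])

  # multiplicativity: two sqrt-factor passes equal one full-factor pass
  twice <- inject_center_bias(inject_center_bias(co, c(Manchester = sqrt(1.10))),
                              c(Manchester = sqrt(1.10)))
  expect_equal(twice$creatinine, biased$creatinine)

  # higher creatinine lowers every model's eGFR there; Mayo is exempted
  # around its clamp, where the published quadratic is locally flat or
  # even increasing (stationary point at 0.8055 mg/dL)
  for (id in gfr_model_ids()) {
    e0 <- evaluate_model(tibble::as_tibble(co)[man, ], id)$egfr_absolute
    e1 <- evaluate_model(tibble::as_tibble(biased)[man, ], id)$egfr_absolute
    strict <- if (id == "mayo") co$creatinine[man] >= 0.81 else TRUE
    expect_true(all((e1 < e0)[strict]), label = paste(id, "eGFR drops under assay bias"))
  }
  rmse0 <- compute_metrics(compute_residuals(tibble::as_tibble(co)[man, ],
                                             sc$config$truth_model))$accuracy
  rmse1 <- compute_metrics(compute_residuals(tibble::as_tibble(biased)[man, ],
                                             sc$config$truth_model))$accuracy
  expect_gt(rmse1, rmse0)

  expect_error(inject_center_bias(co, c(Nowhere = 1.1)), class = "gfreval_invalid")
  expect_error(inject_center_bias(co, c(Manchester = -1)), class = "gfreval_invalid")
})

test_that("marginal calibration holds across seeds", {
  meds_age <- numeric(10); means_gfr <- numeric(10)
  for (i in 1:10) {
    sc <- generate_cohort(cohort_config(seed = 200 + i))
    meds_age[i] <- median(sc$cohort$age)
    means_gfr[i] <- mean(sc$truth$true_gfr)
  }
  expect_lt(abs(mean(meds_age) - 57), 1)
  expect_lt(abs(mean(means_gfr) - 86), 1)
})

test_that("generator configs survive a YAML round trip", {
  cfg <- cohort_config(n = 250, seed = 7, creatinine_noise = 0.1,
                       center_calibration = c(Manchester = 1.05))
  path <- file.path(tempdir(), "config.yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$n, 250)
  expect_equal(back$creatinine_noise, 0.1)
  expect_equal(back$center_calibration, c(Manchester = 1.05))
  a <- generate_cohort(cfg)
  b <- generate_cohort(back)
  expect_identical(tibble::as_tibble(a$cohort), tibble::as_tibble(b$cohort))

  expect_error(cohort_config(creatinine_noise = -1), class = "gfreval_invalid")
  expect_error(cohort_config(truth_model = "nope"), class = "gfreval_invalid")
})
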