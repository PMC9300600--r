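test_that("identical config and seed give bit-identical cohorts", {
  cfg <- synthetic_config(n = 2000, seed = 99)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_population(synthetic_config(n = 2000, seed = 100))
  expect_false(identical(p1$weight, p3$weight))
})

test_that("generated cohorts satisfy the participant-table invariants", {
  pop <- generate_population(synthetic_config(n = 5000, seed = 41))
  expect_true(all(pop$age >= 20 & pop$age <= 110))
  for (col in c("weight", "height", "waist_circ", "hip_circ",
                "total_fat_mass", "trunk_fat_mass", "lean_mass")) {
    expect_true(all(pop[[col]] > 0, na.rm = TRUE), label = col)
  }
  for (cn in condition_columns()) {
    expect_true(all(pop[[cn]] %in% c(0, 1) | is.na(pop[[cn]])), label = cn)
  }
  expect_true(all(pop$trunk_fat_mass <= pop$total_fat_mass, na.rm = TRUE))
  # documented synthetic correlation structure
  m <- pop[pop$sex == "male", ]
  expect_gt(cor(log(m$waist_circ), log(m$weight), use = "complete.obs"),
            0.85)
  expect_gt(cor(log(m$waist_circ), log(m$hip_circ), use = "complete.obs"),
            0.75)
})

test_that("a flat prevalence model hits its intercept", {
  prev <- list(flat = list(intercept = 30, coef = c(waist_circ = 0)))
  pop <- generate_population(synthetic_config(n = 1000, seed = 42,
                                              prevalence = prev,
                                              missing_rates = 0))
  expect_lt(abs(mean(pop$flat) - 0.30), 0.03)
})

test_that("zero missingness leaves no gaps; default rates create some", {
  pop0 <- generate_population(synthetic_config(n = 1000, seed = 43,
                                               missing_rates = 0))
  expect_false(anyNA(pop0))
  popd <- generate_population(synthetic_config(n = 5000, seed = 43))
  expect_true(anyNA(popd$waist_circ))
  expect_false(anyNA(popd$sex))
  expect_false(anyNA(popd$age))
})

test_that("an invalid covariance is rejected", {
  anthro <- norse:::default_anthro_model()
  anthro$male$cov[1, 2] <- 1   # asymmetric-breaking / non-PSD
  anthro$male$cov[2, 1] <- 1
  expect_error(synthetic_config(n = 10, anthro = anthro),
               class = "norse_config_error")
})

test_that("linear ground truth is the configured coefficient", {
  prev <- list(c1 = list(intercept = 30, coef = c(waist_circ = 5)))
  cfg <- synthetic_config(n = 100, seed = 44, prevalence = prev)
  expect_equal(ground_truth_norse(cfg, "waist_circ", "c1"), 5)
  expect_equal(ground_truth_norse(cfg, "height", "c1"), 0)
  expect_error(ground_truth_norse(cfg, "waist_circ", "absent"),
               class = "norse_config_error")
})

test_that("age-modulated ground truth averages the multiplier over brackets", {
  m <- function(age) 1 - abs(age - 60) / 80
  prev <- list(c1 = list(intercept = 30, coef = c(waist_circ = 10),
                         age_mult = m))
  cfg <- synthetic_config(n = 100, seed = 45, prevalence = prev)
  aw <- cfg$age_weights
  in_br <- aw$age >= 40 & aw$age <= 49
  expected <- 10 * sum(aw$weight[in_br] * m(aw$age[in_br])) /
    sum(aw$weight[in_br])
  expect_equal(ground_truth_norse(cfg, "waist_circ", "c1",
                                  age_range = c(40, 49)), expected)
})

test_that("logistic ground truth matches a finite-difference Monte Carlo", {
  prev <- list(c1 = list(intercept = -1.2, coef = c(waist_circ = 0.8),
                         link = "logistic"))
  cfg <- synthetic_config(n = 100, seed = 46, prevalence = prev,
                          missing_rates = 0)
  gt <- ground_truth_norse(cfg, "waist_circ", "c1", nsim = 40000,
                           seed = 901)
  # oracle: central finite difference of P(%) in z on the same cohort
  sim <- synthetic_config(n = 40000, seed = 901, prevalence = prev,
                          missing_rates = 0)
  pop <- generate_population(sim)
  d <- pop[pop$sex == "male", ]
  z <- derive_biomarker(d, "waist_circ")$zscores
  h <- 1e-4
  fd <- mean((plogis(-1.2 + 0.8 * (z + h)) -
                plogis(-1.2 + 0.8 * (z - h))) / (2 * h)) * 100
  expect_lt(abs(gt - fd) / abs(fd), 0.01)
})

test_that("the estimator recovers a configured true NORSE of 10", {
  prev <- list(c1 = list(intercept = 25, coef = c(waist_circ = 10)))
  cfg <- synthetic_config(n = 200000, seed = 47, prevalence = prev,
                          missing_rates = 0)
  pop <- generate_population(cfg)
  fit <- norse(c1 ~ waist_circ, pop, sex = "male")
  expect_lt(abs(unname(fit$norse) -
                  ground_truth_norse(cfg, "waist_circ", "c1")), 1)
})

test_that("synthetic cohorts round-trip through the CSV ingest path", {
  pop <- generate_population(synthetic_config(n = 300, seed = 48))
  path <- tempfile(fileext = ".csv")
  write_participants(pop, path)
  back <- read_participants(path)
  expect_equal(back$waist_circ, pop$waist_circ, tolerance = 1e-12)
  expect_identical(back$sex, pop$sex)
  expect_equal(back$hypertension, pop$hypertension)
})
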