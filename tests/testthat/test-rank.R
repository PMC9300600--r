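test_that("ranking aggregation averages unrounded and sorts descending", {
  scores <- expand.grid(biomarker = c("a", "b"), sex = c("male", "female"),
                        condition = condition_columns(),
                        stringsAsFactors = FALSE)
  scores$norse <- ifelse(scores$biomarker == "a", 5, 7)  # constant rows
  rk <- norse_ranking_table(scores)
  expect_equal(rk$ranking$biomarker, c("b", "a"))
  expect_equal(rk$ranking$key, c(7, 5))
  expect_equal(rk$ranking$rank, 1:2)
  expect_equal(unique(rk$column_avg$avg_norse), 6)
})

test_that("cross-sex keys come from unrounded per-sex averages", {
  # per-sex means 9.1666... and 7.65: the key must round to 8.4, not 8.5
  scores <- data.frame(
    biomarker = "whr", sex = rep(c("male", "female"), each = 6),
    condition = rep(condition_columns(), 2),
    norse = c(14.3, 10.8, 11.5, 12.4, 3.3, 2.7,
              13.4, 9.6, 7.9, 10.6, 1.2, 3.2))
  rk <- norse_ranking_table(scores)
  expect_equal(round_half_away(rk$ranking$avg_male, 1), 9.2)
  expect_equal(round_half_away(rk$ranking$avg_female, 1), 7.7)
  expect_equal(round_half_away(rk$ranking$key, 1), 8.4)
})

test_that("separation tables compute y - x per condition and average", {
  scores <- data.frame(
    x = "hip_circ", y = "waist_circ",
    sex = rep(c("male", "female"), each = 6),
    condition = rep(condition_columns(), 2),
    x_norse = c(-15.1, -12.1, -19.5, -25.1, -5.2, -6.4,
                -15.1, -9.8, -10.6, -16.1, -1.3, -1.1),
    y_norse = c(26.4, 20.5, 23.6, 29.7, 8.0, 7.6,
                25.3, 20.5, 14.0, 19.5, 3.5, 4.0))
  st <- norse_separation_table(scores)
  expect_equal(st$scores$separation[1], 41.5)
  m <- st$per_sex[st$per_sex$sex == "male", ]
  expect_equal(round_half_away(m$x_avg, 1), -13.9)
  expect_equal(round_half_away(m$y_avg, 1), 19.3)
  expect_equal(round_half_away(m$sep_avg, 1), 33.2)
  f <- st$per_sex[st$per_sex$sex == "female", ]
  expect_equal(round_half_away(f$sep_avg, 1), 23.5)
  # the cross-sex key is the mean of the per-sex separation averages
  expect_equal(st$ranking$key,
               mean(c(m$sep_avg, f$sep_avg)), tolerance = 1e-12)
})

test_that("half-away rounding matches report-table arithmetic", {
  expect_equal(round_half_away(7.65, 1), 7.7)
  expect_equal(round_half_away(-7.65, 1), -7.7)
  expect_equal(round_half_away(28.35, 1), 28.4)
  expect_equal(round_half_away(mean(c(45.9 / 6, 55 / 6)), 1), 8.4)
  expect_equal(round_half_away(2.04, 1), 2.0)
})

test_that("rank_norse_1d orders biomarkers by their true effect", {
  prev <- list(
    c_strong = list(intercept = 30, coef = c(whr = 12)),
    c_weak = list(intercept = 30, coef = c(whr = 4)))
  cfg <- synthetic_config(n = 20000, seed = 31, prevalence = prev,
                          missing_rates = 0)
  pop <- generate_population(cfg)
  rk <- rank_norse_1d(pop, biomarkers = c("whr", "height"),
                      conditions = c("c_strong", "c_weak"))
  expect_equal(rk$ranking$biomarker[1], "whr")
  whr_scores <- rk$scores[rk$scores$biomarker == "whr", ]
  strong <- whr_scores$norse[whr_scores$condition == "c_strong"]
  weak <- whr_scores$norse[whr_scores$condition == "c_weak"]
  expect_true(all(strong > weak))
})

test_that("ranking order is invariant to per-biomarker unit changes", {
  cfg <- synthetic_config(n = 15000, seed = 32, missing_rates = 0)
  pop <- generate_population(cfg)
  bms <- c("whr", "waist_circ", "bmi", "height")
  rk1 <- rank_norse_1d(pop, biomarkers = bms)
  pop2 <- pop
  pop2$waist_circ <- pop2$waist_circ / 100
  reg2 <- biomarker_registry()
  # waist-based formulas keep their own units; only the raw waist column
  # biomarker changes scale
  reg2$whr$formula <- function(d) (d$waist_circ * 100) / d$hip_circ
  reg2$rfm$formula <- function(d) 64 - 20 * d$height / (d$waist_circ * 100) +
    12 * (d$sex == "female")
  rk2 <- rank_norse_1d(pop2, biomarkers = bms, registry = reg2)
  expect_equal(rk2$ranking$biomarker, rk1$ranking$biomarker)
  expect_equal(rk2$ranking$key, rk1$ranking$key, tolerance = 1e-9)
})

test_that("underivable biomarkers are dropped with a warning", {
  cfg <- synthetic_config(n = 3000, seed = 33, missing_rates = 0)
  pop <- generate_population(cfg)
  pop$total_fat_mass <- NULL
  expect_warning(
    rk <- rank_norse_1d(pop, biomarkers = c("whr", "pbf"),
                        conditions = "hypertension"),
    "underivable")
  expect_false("pbf" %in% rk$ranking$biomarker)
})

test_that("rank_norse_2d ranks pairs and finds the configured best pair", {
  prev <- list(cond = list(intercept = 30,
                           coef = c(waist_circ = 16, weight = -10)))
  cfg <- synthetic_config(n = 30000, seed = 34, prevalence = prev,
                          missing_rates = 0)
  pop <- generate_population(cfg)
  pairs <- data.frame(x = c("weight", "height"),
                      y = c("waist_circ", "upper_arm_len"))
  rk <- rank_norse_2d(pop, pairs = pairs, conditions = "cond")
  expect_equal(nrow(rk$ranking), 2)
  expect_equal(rk$ranking$x[1], "weight")
  expect_equal(rk$ranking$y[1], "waist_circ")
  top <- rk$scores[rk$scores$x == "weight", ]
  expect_true(all(top$x_norse < 0))
  expect_true(all(top$y_norse > 0))
  path <- tempfile(fileext = ".csv")
  write_ranking(rk, path)
  expect_equal(nrow(read.csv(path)), 2)
})
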